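#' Read a 2D image from PNG, TIFF or single-slice NIfTI
#'
#' Grayscale images are returned as matrices in `[0, 1]`; RGB(A) PNG/TIFF
#' are returned as `rows x cols x channels` arrays. TIFF and NIfTI support
#' require the optional `tiff` / `RNifti` packages.
#'
#' @param path File path; format from the extension
#'   (`.png`, `.tif(f)`, `.nii(.gz)`).
#' @return Numeric matrix or array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    img <- tiff::readTIFF(path)
  } else if (ext == "nii") {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI requires the 'RNifti' package")
    }
    img <- as.array(RNifti::readNifti(path))
    if (length(dim(img)) > 2) img <- img[, , 1]
  } else {
    stop("unsupported image format: .", ext)
  }
  if (length(dim(img)) == 3 && dim(img)[3] == 1) img <- img[, , 1]
  img
}

#' Read a binary mask (nonzero = in)
#'
#' @param path PNG/TIFF/NIfTI file.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0
}

#' Write a matrix as a grayscale PNG
#'
#' @param values Numeric matrix; rescaled to `[0, 1]` if needed unless
#'   `rescale = FALSE`.
#' @param path Output path.
#' @param rescale Min-max rescale before writing?
#' @export
write_image_png <- function(values, path, rescale = FALSE) {
  v <- as.matrix(values)
  v[!is.finite(v)] <- 0
  if (rescale && diff(range(v)) > 0) v <- (v - min(v)) / diff(range(v))
  v <- pmin(pmax(v, 0), 1)
  png::writePNG(v, path)
  invisible(path)
}

#' Write a label field as an indexed PNG with a JSON sidecar
#'
#' Label indices are stored in the PNG (scaled by 1/255); the sidecar
#' (same path with `.json` appended) records the index-to-name mapping
#' and, optionally, a fitted model and seed for provenance.
#'
#' @param field A [label_field()].
#' @param path Output PNG path.
#' @param model Optional [gmrf_model()] stored in the sidecar.
#' @param seed Optional seed stored in the sidecar.
#' @export
write_labels_png <- function(field, path, model = NULL, seed = NULL) {
  png::writePNG(field$labels / 255, path)
  side <- list(label_set = field$label_set)
  if (!is.null(model)) {
    side$model <- list(
      mu = as.list(model$mu),
      beta00 = as.list(model$beta00),
      beta = unname(apply(model$beta, 1, as.numeric, simplify = FALSE)),
      gamma = as.list(model$gamma),
      n_neighbors = model$neighborhood$n
    )
  }
  if (!is.null(seed)) side$seed <- seed
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a label field written by [write_labels_png()]
#'
#' @param path PNG path (the `.json` sidecar must sit beside it).
#' @return List with `labels` ([label_field()]) and the sidecar list.
#' @export
read_labels_png <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  idx <- round(png::readPNG(path) * 255)
  list(labels = label_field(idx, side$label_set), sidecar = side)
}
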