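#' Canonical MRI label set
#'
#' Ordered tissue label set used throughout the package: cell body (CB,
#' pooled substantia gelatinosa and lesion), grey matter (GM), partial
#' volume (PV), white matter (WM) and background (BG). The ordering also
#' fixes deterministic tie-breaking (argmax ties resolve to the earlier
#' label).
#'
#' @return Character vector of length 5.
#' @export
mri_labels <- function() c("CB", "GM", "PV", "WM", "BG")

#' Default prior tissue proportions
#'
#' Prior label proportions for the annealed GMRF segmentation, estimated
#' from near-recovered (day 28) cords. Order follows [mri_labels()].
#'
#' @return Named numeric simplex vector over CB, GM, PV, WM, BG.
#' @export
default_gamma <- function() {
  c(CB = 0.010, GM = 0.045, PV = 0.030, WM = 0.061, BG = 0.854)
}

#' Default histology landmark positions
#'
#' Per-tissue mean (myelin, cellularity) staining densities used as
#' histology-side landmarks when no subject-specific histology
#' segmentation is available. Myelin is the normalized blue (eriochrome
#' cyanine) channel, cellularity the normalized red (neutral red) channel.
#'
#' @return 3x2 numeric matrix with rows WM, GM, CB and columns
#'   `myelin`, `cellularity`.
#' @export
default_hist_landmarks <- function() {
  m <- rbind(
    WM = c(0.735, 0.230),
    GM = c(0.333, 0.666),
    CB = c(0.341, 0.785)
  )
  colnames(m) <- c("myelin", "cellularity")
  m
}

#' Construct an image grid
#'
#' A 2D intensity lattice with a binary tissue mask. Masked-in values must
#' be finite; intensities are expected in `[0, 1]` after normalization
#' (enforced when `check_range = TRUE`).
#'
#' @param values Numeric matrix of pixel intensities.
#' @param mask Logical matrix of the same shape (`TRUE` = tissue). Default
#'   is all `TRUE`.
#' @param check_range If `TRUE`, error when masked-in values fall outside
#'   `[0, 1]`.
#' @return An object of class `image_grid` with fields `values`, `mask`.
#' @export
image_grid <- function(values, mask = NULL, check_range = FALSE) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!identical(dim(mask), dim(values))) {
    stop("mask must have the same shape as values")
  }
  if (any(!is.finite(values[mask]))) {
    stop("masked-in values must be finite")
  }
  if (check_range && (any(values[mask] < 0) || any(values[mask] > 1))) {
    stop("masked-in values must lie in [0, 1]")
  }
  structure(list(values = values, mask = mask), class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf(
    "<image_grid %dx%d, %d/%d masked-in, range [%.3g, %.3g]>\n",
    nrow(x$values), ncol(x$values), sum(x$mask), length(x$mask),
    suppressWarnings(min(x$values[x$mask])),
    suppressWarnings(max(x$values[x$mask]))
  ))
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$values)

#' Construct a hidden label field
#'
#' Per-pixel hard tissue assignment over an ordered label set. Labels may
#' be given as a character matrix or as integer indices into `label_set`.
#'
#' @param labels Character or integer matrix.
#' @param label_set Ordered character vector of admissible labels.
#' @return An object of class `label_field` with an integer `labels`
#'   matrix and the `label_set`.
#' @export
label_field <- function(labels, label_set = mri_labels()) {
  labels <- as.matrix(labels)
  if (is.character(labels)) {
    idx <- match(labels, label_set)
    if (any(is.na(idx))) {
      stop("labels contain values outside the label set: ",
           paste(unique(labels[is.na(idx)]), collapse = ", "))
    }
    labels <- matrix(idx, nrow(labels), ncol(labels))
  }
  storage.mode(labels) <- "integer"
  if (any(labels < 1L | labels > length(label_set))) {
    stop("label indices out of range")
  }
  structure(list(labels = labels, label_set = label_set),
            class = "label_field")
}

#' @export
print.label_field <- function(x, ...) {
  tab <- table(factor(x$label_set[x$labels], levels = x$label_set))
  cat(sprintf("<label_field %dx%d: %s>\n", nrow(x$labels), ncol(x$labels),
              paste(names(tab), tab, sep = "=", collapse = " ")))
  invisible(x)
}

#' @export
dim.label_field <- function(x) dim(x$labels)

#' Per-pixel label names
#'
#' @param field A [label_field()].
#' @return Character matrix of label names.
#' @export
label_names <- function(field) {
  matrix(field$label_set[field$labels],
         nrow(field$labels), ncol(field$labels))
}

#' Build a symmetric lattice neighbourhood system
#'
#' Returns the `n_neighbors` nearest lattice displacements around a pixel,
#' sorted by radial distance then by angle from the +x axis
#' (counter-clockwise, with the y coordinate increasing downward), with
#' each offset and its negation sharing one symmetric parameter slot. The
#' 20-neighbour system spans squared radii 1, 2, 4 and 5 and yields 10
#' unique parameter slots; slot 1 is the horizontal nearest pair, slot 2
#' the vertical nearest pair.
#'
#' @param n_neighbors One of 4, 8, 12, 20 (complete symmetric shells).
#' @return An object of class `neighborhood` with fields `offsets`
#'   (n x 2 integer matrix of `(dy, dx)`), `slot` (length-n integer map to
#'   parameter slots) and `n_slots`.
#' @export
build_neighborhood <- function(n_neighbors = 20) {
  shells <- c(`4` = 1, `8` = 2, `12` = 4, `20` = 5)
  key <- as.character(n_neighbors)
  if (length(n_neighbors) != 1 || !key %in% names(shells)) {
    stop("n_neighbors must be one of 4, 8, 12, 20")
  }
  r2max <- shells[[key]]
  grid <- expand.grid(dy = -2:2, dx = -2:2)
  r2 <- grid$dy^2 + grid$dx^2
  keep <- r2 >= 1 & r2 <= r2max
  grid <- grid[keep, , drop = FALSE]
  r2 <- r2[keep]
  # angle from +x axis, counter-clockwise; y increases downward so the
  # screen-space "up" direction is -dy
  ang <- atan2(-grid$dy, grid$dx) %% (2 * pi)
  ord <- order(r2, ang)
  offsets <- as.matrix(grid[ord, c("dy", "dx")])
  rownames(offsets) <- NULL
  slot <- integer(nrow(offsets))
  next_slot <- 1L
  for (k in seq_len(nrow(offsets))) {
    if (slot[k] > 0L) next
    slot[k] <- next_slot
    neg <- which(offsets[, 1] == -offsets[k, 1] &
                 offsets[, 2] == -offsets[k, 2])
    slot[neg] <- next_slot
    next_slot <- next_slot + 1L
  }
  structure(list(offsets = offsets, slot = slot,
                 n_slots = max(slot), n = nrow(offsets)),
            class = "neighborhood")
}

#' @export
print.neighborhood <- function(x, ...) {
  cat(sprintf("<neighborhood: %d offsets, %d symmetric parameter slots>\n",
              x$n, x$n_slots))
  invisible(x)
}

# Shift a matrix by a lattice offset: out[i, j] = M[i + dy, j + dx],
# zero-filled outside the lattice.
shift_matrix <- function(M, dy, dx) {
  nr <- nrow(M)
  nc <- ncol(M)
  out <- matrix(0, nr, nc)
  ys <- seq_len(nr) + dy
  xs <- seq_len(nc) + dx
  vy <- ys >= 1L & ys <= nr
  vx <- xs >= 1L & xs <= nc
  if (any(vy) && any(vx)) {
    out[vy, vx] <- M[ys[vy], xs[vx]]
  }
  out
}
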