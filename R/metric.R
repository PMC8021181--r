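#' Precision-scaled Mahalanobis distance maps
#'
#' For each requested tissue, computes at every masked-in pixel the
#' squared residual of the pixel's intensity from that tissue's
#' conditional prediction, scaled by the tissue's conditional variance:
#' `d_il = ((x_i - mu_l) - sum_j beta_{l,j} (x_j - mu_j))^2 / beta_{l,00}`
#' where the neighbour means come from each neighbour's current label and
#' background neighbours are excluded. With `squared = FALSE` the square
#' root is returned instead (a sensitivity switch; the squared form is the
#' default).
#'
#' @param image An [image_grid()].
#' @param labels Current [label_field()].
#' @param model A fitted [gmrf_model()].
#' @param tissues Tissue labels to measure distance from (not BG).
#' @param squared Return the squared form (default) or its square root.
#' @return 3D array `rows x cols x length(tissues)` (NA off-mask), with
#'   dimnames on the tissue axis.
#' @export
mahalanobis_maps <- function(image, labels, model,
                             tissues = c("WM", "GM", "CB"),
                             squared = TRUE) {
  li <- match(tissues, model$label_set)
  if (any(is.na(li))) stop("unknown tissue label(s)")
  if (any(model$label_set[li] == "BG")) stop("BG is not a valid target tissue")
  if (any(model$beta00[li] <= 0)) stop("beta00 must be positive")
  x <- image$values
  lab_idx <- labels$labels
  lab_idx[!image$mask] <- model$bg
  nb <- model$neighborhood
  mu_field <- matrix(model$mu[lab_idx], nrow(x), ncol(x))
  r <- x - mu_field
  r[lab_idx == model$bg] <- 0
  # per-slot sums of centred neighbour values (BG/off-lattice excluded)
  S1 <- vector("list", nb$n_slots)
  for (s in seq_len(nb$n_slots)) S1[[s]] <- matrix(0, nrow(x), ncol(x))
  for (k in seq_len(nb$n)) {
    s <- nb$slot[k]
    S1[[s]] <- S1[[s]] + shift_matrix(r, nb$offsets[k, 1], nb$offsets[k, 2])
  }
  out <- array(NA_real_, c(nrow(x), ncol(x), length(tissues)),
               dimnames = list(NULL, NULL, tissues))
  for (q in seq_along(li)) {
    l <- li[q]
    pred <- x - model$mu[l]
    for (s in seq_len(nb$n_slots)) {
      pred <- pred - model$beta[l, s] * S1[[s]]
    }
    d <- pred^2 / model$beta00[l]
    if (!squared) d <- sqrt(d)
    d[!image$mask] <- NA_real_
    out[, , q] <- d
  }
  out
}

#' Mahalanobis distance of one pixel from one tissue mean
#'
#' Scalar form of [mahalanobis_maps()].
#'
#' @param i Pixel position `c(row, col)`.
#' @param l Tissue label (not BG).
#' @param image An [image_grid()].
#' @param labels Current [label_field()].
#' @param model A fitted [gmrf_model()].
#' @param squared Squared form (default) or its square root.
#' @return Non-negative scalar.
#' @export
mahalanobis_distance <- function(i, l, image, labels, model,
                                 squared = TRUE) {
  d <- mahalanobis_maps(image, labels, model, tissues = l,
                        squared = squared)
  unname(d[i[1], i[2], 1])
}

#' Fit per-channel scales aligning the MRI and histology metric spaces
#'
#' Each Mahalanobis distance channel (one per anchor tissue) is multiplied
#' by a constant; Nelder-Mead minimizes the root-mean-squared mismatch
#' between the scaled MRI tissue-mean distance triples and the
#' inter-landmark Euclidean distances implied by the histology (myelin,
#' cellularity) positions, over all ordered tissue pairs (self-distances
#' implied as 0). Deterministic: fixed start at unit scales with one
#' restart from the optimum.
#'
#' @param mri_landmarks `k x k` matrix: row = tissue, column = distance
#'   channel; entry `(m, l)` is tissue `m`'s mean distance in channel `l`.
#' @param hist_landmarks `k x 2` matrix of (myelin, cellularity) tissue
#'   positions, rows aligned with `mri_landmarks`.
#' @return Numeric vector of `k` positive scales.
#' @export
fit_scales <- function(mri_landmarks, hist_landmarks) {
  mri_landmarks <- as.matrix(mri_landmarks)
  hist_landmarks <- as.matrix(hist_landmarks)
  k <- nrow(mri_landmarks)
  if (k < 3 || nrow(hist_landmarks) < 3) {
    stop("at least 3 landmarks are required on both sides")
  }
  D_hist <- as.matrix(stats::dist(hist_landmarks))
  obj <- function(log_s) {
    s <- exp(log_s)
    mism <- sweep(mri_landmarks, 2, s, `*`) - D_hist
    sqrt(mean(mism^2))
  }
  fit <- stats::optim(rep(0, k), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 2000))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 2000))
  # code 10 flags simplex degeneracy, which also occurs at a tight
  # optimum; only the iteration-limit code signals true non-convergence
  if (fit$convergence == 1) {
    stop("scale optimization did not converge: code ", fit$convergence,
         ", value ", fit$value)
  }
  s <- exp(fit$par)
  names(s) <- colnames(mri_landmarks)
  s
}

#' Multilaterate a planar position from anchor distances
#'
#' Finds the planar point minimizing the sum of squared mismatches between
#' its Euclidean distances to the anchors and the supplied distances,
#' using Nelder-Mead started from the anchor centroid (with one restart
#' from the first optimum). Deterministic.
#'
#' @param distances Non-negative distances, one per anchor.
#' @param anchors `k x 2` matrix of anchor positions (non-collinear).
#' @return Length-2 numeric position (myelin, cellularity).
#' @export
multilaterate <- function(distances, anchors) {
  anchors <- as.matrix(anchors)
  k <- nrow(anchors)
  if (k < 3) stop("at least 3 anchors are required")
  if (length(distances) != k) stop("one distance per anchor required")
  # collinearity check via the triangle area of the first three anchors
  a <- anchors[2, ] - anchors[1, ]
  b <- anchors[3, ] - anchors[1, ]
  area2 <- abs(a[1] * b[2] - a[2] * b[1])
  scale2 <- max(sum(a^2), sum(b^2), .Machine$double.eps)
  if (area2 < 1e-8 * scale2) stop("anchors are (near-)collinear")
  obj <- function(p) {
    dd <- sqrt(rowSums(sweep(anchors, 2, p, `-`)^2))
    sum((dd - distances)^2)
  }
  p0 <- colMeans(anchors)
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 2000))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 2000))
  unname(fit$par)
}

#' Unsupervised (myelin, cellularity) feature maps
#'
#' End-to-end metric learning: computes the per-pixel Mahalanobis distance
#' triple to the WM, GM and CB tissue means, forms the MRI-side tissue
#' landmarks (the per-tissue mean of the triples over pixels carrying that
#' label), fits the per-channel scales against the histology landmark
#' geometry, and multilaterates every masked-in non-background pixel into
#' the histology (myelin, cellularity) plane. Partial-volume pixels are
#' mapped; background pixels are excluded (NA).
#'
#' @param image An [image_grid()].
#' @param labels A [label_field()] containing WM, GM and CB.
#' @param model A fitted [gmrf_model()].
#' @param hist_landmarks `3 x 2` histology landmark matrix with rows
#'   named WM, GM, CB (default [default_hist_landmarks()]).
#' @param squared Use the squared distance form (default) or its root.
#' @return Object of class `feature_map`: matrices `myelin` and
#'   `cellularity` (NA off-mask/BG), plus `scales`, `mri_landmarks`,
#'   `hist_landmarks`.
#' @export
feature_maps <- function(image, labels, model,
                         hist_landmarks = default_hist_landmarks(),
                         squared = TRUE) {
  tissues <- rownames(hist_landmarks)
  if (is.null(tissues)) {
    tissues <- c("WM", "GM", "CB")
    rownames(hist_landmarks) <- tissues
  }
  if (!all(tissues %in% labels$label_set)) {
    stop("labels must contain all anchor tissues: ",
         paste(tissues, collapse = ", "))
  }
  d <- mahalanobis_maps(image, labels, model, tissues, squared = squared)
  lab_idx <- labels$labels
  lab_idx[!image$mask] <- match("BG", labels$label_set)
  mri_lm <- matrix(NA_real_, length(tissues), length(tissues),
                   dimnames = list(tissues, tissues))
  for (m in seq_along(tissues)) {
    inl <- lab_idx == match(tissues[m], labels$label_set)
    if (!any(inl)) stop("no pixels carry tissue ", tissues[m])
    for (l in seq_along(tissues)) {
      mri_lm[m, l] <- mean(d[, , l][inl])
    }
  }
  scales <- fit_scales(mri_lm, hist_landmarks)
  use <- image$mask & lab_idx != match("BG", labels$label_set)
  idx <- which(use)
  myel <- matrix(NA_real_, nrow(lab_idx), ncol(lab_idx))
  cell <- matrix(NA_real_, nrow(lab_idx), ncol(lab_idx))
  dmat <- vapply(seq_along(tissues), function(l) d[, , l][idx],
                 numeric(length(idx)))
  if (length(idx) == 1) dmat <- matrix(dmat, 1)
  dmat <- sweep(dmat, 2, scales, `*`)
  for (q in seq_along(idx)) {
    p <- multilaterate(dmat[q, ], hist_landmarks)
    myel[idx[q]] <- p[1]
    cell[idx[q]] <- p[2]
  }
  structure(list(myelin = myel, cellularity = cell, scales = scales,
                 mri_landmarks = mri_lm, hist_landmarks = hist_landmarks),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf(
    "<feature_map %dx%d: myelin [%.3f, %.3f], cellularity [%.3f, %.3f]>\n",
    nrow(x$myelin), ncol(x$myelin),
    min(x$myelin, na.rm = TRUE), max(x$myelin, na.rm = TRUE),
    min(x$cellularity, na.rm = TRUE), max(x$cellularity, na.rm = TRUE)
  ))
  invisible(x)
}
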