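#' Fit a Gaussian mixture model with BIC model selection
#'
#' Fits Gaussian mixtures by EM for every candidate component count and
#' keeps the model minimizing `BIC = -2 loglik + p log(N)` (`p` = free
#' parameter count). Fitting is delegated to the `mclust` EM machinery
#' with unconstrained (free) component covariances; a small diagonal
#' regularization guards the returned covariances.
#'
#' @param samples Numeric vector (1D) or matrix with one feature vector
#'   per row (2D+).
#' @param k_candidates Integer vector of component counts to try.
#' @param seed Integer seed (EM initialization is deterministic given it).
#' @return Object of class `gmm_model`: `n_components`, `weights`,
#'   `means` (d x k matrix), `covariances` (d x d x k array), `bic`
#'   (named vector over candidates, our sign convention), `loglik`, `d`.
#' @export
fit_gmm <- function(samples, k_candidates = 1:5, seed = 1L) {
  X <- if (is.null(dim(samples))) matrix(samples, ncol = 1) else as.matrix(samples)
  n <- nrow(X)
  d <- ncol(X)
  if (n < 10 * max(k_candidates)) {
    stop("need at least 10 x max(k_candidates) samples")
  }
  if (all(apply(X, 2, stats::var) < 1e-12)) {
    stop("degenerate input: all samples (near) identical")
  }
  model_name <- if (d == 1) "V" else "VVV"
  Xd <- if (d == 1) X[, 1] else X
  set.seed(as.integer(seed))
  fits <- list()
  bics <- rep(NA_real_, length(k_candidates))
  names(bics) <- as.character(k_candidates)
  # free parameters: weights (k-1) + means (k d) + covariances (k d(d+1)/2)
  n_par <- function(k) (k - 1) + k * d + k * d * (d + 1) / 2
  for (i in seq_along(k_candidates)) {
    k <- k_candidates[i]
    # EM from mclust's default (model-based hierarchical) initialization,
    # plus a k-means start; the higher-likelihood solution wins (the EM
    # surface for very unequal cluster sizes has local optima)
    cand <- list()
    fit_hc <- tryCatch(
      suppressWarnings(Mclust(X, G = k, modelNames = model_name,
                              verbose = FALSE)),
      error = function(e) NULL
    )
    if (!is.null(fit_hc) && !is.na(fit_hc$loglik)) cand <- c(cand, list(fit_hc))
    if (k > 1) {
      fit_km <- tryCatch({
        km <- suppressWarnings(stats::kmeans(X, k, nstart = 10))
        suppressWarnings(me(modelName = model_name, data = Xd,
                            z = unmap(km$cluster)))
      }, error = function(e) NULL)
      if (!is.null(fit_km) && !is.na(fit_km$loglik)) cand <- c(cand, list(fit_km))
    }
    if (length(cand) == 0) next
    ll <- vapply(cand, function(f) f$loglik, numeric(1))
    fit <- cand[[which.max(ll)]]
    bics[i] <- -2 * fit$loglik + n_par(k) * log(n)
    fits[[i]] <- fit
  }
  if (all(is.na(bics))) {
    stop("EM failed for every candidate k (",
         paste(k_candidates, collapse = ", "), ")")
  }
  best <- which.min(bics)
  fit <- fits[[best]]
  k <- k_candidates[best]
  means <- matrix(fit$parameters$mean, nrow = d, ncol = k)
  covs <- array(0, c(d, d, k))
  if (d == 1) {
    sig <- fit$parameters$variance$sigmasq
    if (length(sig) == 1) sig <- rep(sig, k)
    for (g in seq_len(k)) covs[, , g] <- sig[g]
  } else {
    covs[, , ] <- fit$parameters$variance$sigma
  }
  for (g in seq_len(k)) {
    covs[, , g] <- covs[, , g] + diag(1e-6, d)
  }
  w <- as.numeric(fit$parameters$pro)
  structure(list(
    n_components = k,
    weights = w / sum(w),
    means = means,
    covariances = covs,
    bic = bics,
    loglik = fit$loglik,
    d = d
  ), class = "gmm_model")
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("<gmm_model: %d components, %dD, BIC %.1f>\n",
              x$n_components, x$d, min(x$bic, na.rm = TRUE)))
  invisible(x)
}

# Per-component log densities for rows of X (d = 1 or 2 supported).
gmm_log_dens <- function(model, X) {
  k <- model$n_components
  out <- matrix(NA_real_, nrow(X), k)
  for (g in seq_len(k)) {
    mu <- model$means[, g]
    S <- model$covariances[, , g, drop = TRUE]
    if (model$d == 1) {
      out[, g] <- stats::dnorm(X[, 1], mu, sqrt(S), log = TRUE)
    } else {
      S <- matrix(S, model$d, model$d)
      ch <- chol(S)
      z <- forwardsolve(t(ch), t(X) - mu)
      out[, g] <- -0.5 * colSums(z^2) - sum(log(diag(ch))) -
        0.5 * model$d * log(2 * pi)
    }
  }
  out
}

# Posterior responsibilities (rows sum to 1).
gmm_posterior <- function(model, X) {
  lp <- sweep(gmm_log_dens(model, X), 2, log(model$weights), `+`)
  m <- apply(lp, 1, max)
  p <- exp(lp - m)
  p / rowSums(p)
}

#' Map mixture components to tissue labels
#'
#' For 1D (T2 intensity) models, components are sorted by ascending mean:
#' the darkest is BG (when present), then WM, PV, GM and CB, reflecting
#' the T2 brightness ordering (WM dark, GM brighter, cell-rich tissue
#' brightest). For 2D (blue, red) histology models, WM is the component
#' with the highest blue mean, CB the highest red mean among the rest, BG
#' (when present) the component closest to the background colour, and GM
#' the remainder.
#'
#' @param model A `gmm_model`.
#' @param modality `"mri"` or `"histology"`.
#' @param with_bg Whether a background component is among the mixture.
#' @param bg_color Background (blue, red) position for histology.
#' @return Character vector: label name per component.
#' @export
map_components <- function(model, modality = c("mri", "histology"),
                           with_bg = FALSE, bg_color = c(0, 0)) {
  modality <- match.arg(modality)
  k <- model$n_components
  lab <- character(k)
  if (modality == "mri") {
    ord <- order(model$means[1, ])
    names_full <- if (with_bg) c("BG", "WM", "PV", "GM", "CB") else
      c("WM", "PV", "GM", "CB")
    if (k != length(names_full)) {
      stop("expected ", length(names_full), " components, got ", k)
    }
    lab[ord] <- names_full
  } else {
    remaining <- seq_len(k)
    if (with_bg) {
      dist_bg <- colSums((model$means - bg_color)^2)
      bg <- which.min(dist_bg)
      lab[bg] <- "BG"
      remaining <- setdiff(remaining, bg)
    }
    if (length(remaining) != 3) {
      stop("expected ", if (with_bg) 4 else 3, " components, got ", k)
    }
    wm <- remaining[which.max(model$means[1, remaining])]
    lab[wm] <- "WM"
    remaining <- setdiff(remaining, wm)
    cb <- remaining[which.max(model$means[2, remaining])]
    lab[cb] <- "CB"
    lab[setdiff(remaining, cb)] <- "GM"
  }
  lab
}

#' Segment images with a fitted Gaussian mixture
#'
#' Assigns each masked-in pixel to the label of its posterior-argmax
#' component (ties to the lower component index); masked-out pixels get
#' BG.
#'
#' @param model A `gmm_model`.
#' @param grids One [image_grid()] (1D model) or a list of two (2D model,
#'   e.g. blue and red histology channels) sharing a mask.
#' @param component_labels Character vector naming the label of each
#'   component (e.g. from [map_components()]). Must draw from `label_set`.
#' @param label_set Ordered output label set.
#' @return A [label_field()].
#' @export
segment_gmm <- function(model, grids, component_labels,
                        label_set = mri_labels()) {
  if (inherits(grids, "image_grid")) grids <- list(grids)
  if (length(grids) != model$d) {
    stop("model dimensionality (", model$d, ") does not match the number ",
         "of input grids (", length(grids), ")")
  }
  if (length(component_labels) != model$n_components) {
    stop("component/label count mismatch: ", model$n_components,
         " components vs ", length(component_labels), " labels")
  }
  if (!all(component_labels %in% label_set)) {
    stop("component labels outside label set")
  }
  mask <- grids[[1]]$mask
  X <- do.call(cbind, lapply(grids, function(g) g$values[mask]))
  post <- gmm_posterior(model, X)
  comp <- apply(post, 1, which.max)
  lab_idx <- matrix(match("BG", label_set), nrow(mask), ncol(mask))
  lab_idx[mask] <- match(component_labels, label_set)[comp]
  label_field(lab_idx, label_set)
}
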