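#' Simulate a GMRF texture by Gibbs sampling
#'
#' Given a fixed label field and a complete model, initializes every
#' masked-in pixel at its label mean and repeatedly resamples each pixel
#' from its single-site Gaussian conditional, visiting the lattice in
#' coding-set order (no two simultaneously updated pixels are
#' neighbours). The chain runs unclipped; the returned field is clipped to
#' `[0, 1]` only at output. Deterministic given the seed.
#'
#' @param labels A [label_field()] (held fixed).
#' @param model A [gmrf_model()].
#' @param n_sweeps Number of full-lattice sweeps (default 200, past
#'   burn-in for the parameter ranges used here).
#' @param seed Integer seed.
#' @param mask Optional logical matrix; defaults to non-BG pixels.
#' @param clip Clip the output to `[0, 1]`?
#' @return An [image_grid()] with the simulated texture (BG pixels 0).
#' @export
simulate_field <- function(labels, model, n_sweeps = 200, seed = 1L,
                           mask = NULL, clip = TRUE) {
  if (n_sweeps < 1) stop("n_sweeps must be >= 1")
  lab_idx <- labels$labels
  if (is.null(mask)) mask <- lab_idx != model$bg
  lab_idx[!mask] <- model$bg
  nr <- nrow(lab_idx)
  nc <- ncol(lab_idx)
  x <- matrix(model$mu[lab_idx], nr, nc)
  x[!mask] <- 0
  row_mod <- (matrix(seq_len(nr), nr, nc) - 1L) %% 3L
  col_mod <- (matrix(seq_len(nc), nr, nc, byrow = TRUE) - 1L) %% 3L
  sd_field <- matrix(sqrt(model$beta00[lab_idx]), nr, nc)
  mu_field <- matrix(model$mu[lab_idx], nr, nc)
  # labels are fixed, so the symmetrized per-offset neighbour weights
  # w_k(i) = 0.5 * (beta_{l_i,s} + beta00_{l_i} beta_{l_j,s}/beta00_{l_j})
  # can be precomputed once (zero for BG pixels or BG neighbours)
  nb <- model$neighborhood
  ratio <- model$beta / model$beta00
  ratio[model$bg, ] <- 0
  nonbg <- lab_idx != model$bg
  W <- vector("list", nb$n)
  for (k in seq_len(nb$n)) {
    s <- nb$slot[k]
    lj <- shift_matrix(lab_idx, nb$offsets[k, 1], nb$offsets[k, 2])
    ok <- lj > 0 & nonbg
    lj[lj == 0] <- model$bg
    wk <- 0.5 * (model$beta[cbind(as.vector(lab_idx), s)] +
                   model$beta00[lab_idx] * ratio[cbind(as.vector(lj), s)])
    wk[!ok | lj == model$bg] <- 0
    W[[k]] <- matrix(wk, nr, nc)
  }
  sel_sets <- list()
  for (cy in 0:2) for (cx in 0:2) {
    sel_sets[[length(sel_sets) + 1L]] <- mask & row_mod == cy & col_mod == cx
  }
  for (sweep in seq_len(n_sweeps)) {
    set.seed(sweep_seed(seed, sweep))
    for (sel in sel_sets) {
      if (!any(sel)) next
      r <- x - mu_field
      r[!nonbg] <- 0
      m <- mu_field
      for (k in seq_len(nb$n)) {
        m <- m + W[[k]] *
          shift_matrix(r, nb$offsets[k, 1], nb$offsets[k, 2])
      }
      x[sel] <- stats::rnorm(sum(sel), m[sel], sd_field[sel])
    }
  }
  if (clip) x <- pmin(pmax(x, 0), 1)
  x[!mask] <- 0
  image_grid(x, mask)
}
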