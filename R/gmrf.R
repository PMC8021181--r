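#' Construct a GMRF tissue model
#'
#' Per-label texture parameters of the Gaussian Markov random field: label
#' mean `mu_l`, conditional variance `beta00_l`, and the symmetric
#' neighbour weights `beta_{l,j}` (one per parameter slot of the
#' neighbourhood system), plus prior label proportions `gamma`. The
#' background label is fixed at `mu = 0`, `beta00 = 1e-30`, `beta = 0`,
#' which pins zero-intensity pixels to BG during sampling.
#'
#' @param mu Named numeric vector of label means (one per label).
#' @param beta00 Named numeric vector of conditional variances (> 0).
#' @param beta Numeric matrix, labels x parameter slots.
#' @param gamma Prior label proportions (simplex over `label_set`).
#' @param label_set Ordered label names; must contain `"BG"`.
#' @param neighborhood A [build_neighborhood()] system.
#' @return Object of class `gmrf_model`.
#' @export
gmrf_model <- function(mu, beta00, beta = NULL, gamma = NULL,
                       label_set = mri_labels(),
                       neighborhood = build_neighborhood(20)) {
  L <- length(label_set)
  bg <- match("BG", label_set)
  if (is.na(bg)) stop("label_set must contain BG")
  if (is.null(beta)) beta <- matrix(0, L, neighborhood$n_slots)
  if (is.null(gamma)) {
    gamma <- if (identical(label_set, mri_labels())) default_gamma() else
      stats::setNames(rep(1 / L, L), label_set)
  }
  mu <- expand_named(mu, label_set, 0)
  beta00 <- expand_named(beta00, label_set, 1e-30)
  gamma <- expand_named(gamma, label_set, NA)
  beta <- as.matrix(beta)
  if (nrow(beta) != L || ncol(beta) != neighborhood$n_slots) {
    stop("beta must be ", L, " x ", neighborhood$n_slots)
  }
  rownames(beta) <- label_set
  # background fix
  mu[bg] <- 0
  beta00[bg] <- 1e-30
  beta[bg, ] <- 0
  if (any(beta00 <= 0)) stop("beta00 must be positive")
  if (any(!is.finite(beta))) stop("beta must be finite")
  if (abs(sum(gamma) - 1) > 1e-8) stop("gamma must sum to 1")
  structure(list(mu = mu, beta00 = beta00, beta = beta, gamma = gamma,
                 label_set = label_set, bg = bg,
                 neighborhood = neighborhood),
            class = "gmrf_model")
}

expand_named <- function(x, label_set, bg_default) {
  out <- stats::setNames(rep(NA_real_, length(label_set)), label_set)
  if (is.null(names(x))) {
    if (length(x) != length(label_set)) stop("parameter length mismatch")
    out[] <- x
  } else {
    out[names(x)] <- x
  }
  if (!is.na(bg_default) && is.na(out["BG"])) out["BG"] <- bg_default
  if (any(is.na(out))) {
    stop("missing parameter for label(s): ",
         paste(label_set[is.na(out)], collapse = ", "))
  }
  out
}

#' @export
print.gmrf_model <- function(x, ...) {
  cat(sprintf("<gmrf_model: %d labels (%s), %d neighbour slots>\n",
              length(x$label_set), paste(x$label_set, collapse = ","),
              x$neighborhood$n_slots))
  invisible(x)
}

#' Simulated-annealing temperature schedule
#'
#' The heuristic logarithmic cooling schedule
#' `t(n) = log(4) / log(3 + n)` for `n <= 253`, followed by five
#' zero-temperature (iterated-conditional-modes) iterations for
#' `253 < n < 259`. The nonzero part ends at `t(253) = 0.25`.
#'
#' @param n Iteration index (vectorized), `1 <= n <= 258`.
#' @return Temperature(s).
#' @export
temperature <- function(n) {
  if (any(n < 1 | n > 258)) stop("iteration index must lie in 1..258")
  ifelse(n <= 253, log(4) / log(3 + n), 0)
}

# Sufficient statistics of the current state for the site conditionals.
# Returns, per parameter slot s, S1[[s]] = sum over the slot's offsets of
# the shifted centred field (x_j - mu_{l(j)}), and S2 = sum over all
# offsets of shifted (beta_{l(j),s}/beta00_{l(j)}) * (x_j - mu_{l(j)}).
# Background and off-lattice neighbours contribute zero (Q == 0 rule).
site_stats <- function(x, lab_idx, model) {
  nb <- model$neighborhood
  mu_field <- matrix(model$mu[lab_idx], nrow(x), ncol(x))
  r <- x - mu_field
  r[lab_idx == model$bg] <- 0
  S1 <- vector("list", nb$n_slots)
  for (s in seq_len(nb$n_slots)) S1[[s]] <- matrix(0, nrow(x), ncol(x))
  S2 <- matrix(0, nrow(x), ncol(x))
  ratio <- model$beta / model$beta00  # labels x slots
  ratio[model$bg, ] <- 0
  for (k in seq_len(nb$n)) {
    s <- nb$slot[k]
    dy <- nb$offsets[k, 1]
    dx <- nb$offsets[k, 2]
    S1[[s]] <- S1[[s]] + shift_matrix(r, dy, dx)
    qs <- matrix(ratio[cbind(as.vector(lab_idx), s)], nrow(x), ncol(x))
    S2 <- S2 + shift_matrix(qs * r, dy, dx)
  }
  list(S1 = S1, S2 = S2)
}

# Conditional mean field for hypothesized label l at every pixel:
# mu_l + 0.5 * sum_s beta[l,s] S1_s + 0.5 * beta00_l * S2
# (the conditional of the joint Gaussian whose precision matrix uses
# symmetrized off-diagonal entries; in a homogeneous region this reduces
# to mu_l + sum_j beta_{l,s(j)} (x_j - mu_j) with variance beta00_l).
cond_mean_field <- function(model, stats, l_idx) {
  m <- model$mu[l_idx]
  for (s in seq_along(stats$S1)) {
    m <- m + 0.5 * model$beta[l_idx, s] * stats$S1[[s]]
  }
  m + 0.5 * model$beta00[l_idx] * stats$S2
}

# Log conditional densities for every label: list of matrices.
cond_logdens_fields <- function(x, lab_idx, model, stats = NULL) {
  if (is.null(stats)) stats <- site_stats(x, lab_idx, model)
  lapply(seq_along(model$label_set), function(l) {
    m <- cond_mean_field(model, stats, l)
    v <- model$beta00[l]
    -0.5 * log(2 * pi * v) - (x - m)^2 / (2 * v)
  })
}

#' Single-site conditional density of the GMRF
#'
#' Gaussian conditional density of a pixel's intensity given its
#' neighbours, under hypothesized label `l`: the mean is
#' `mu_l + sum_k w_k (x_k - mu_k)` and the variance `beta00_l`, where the
#' weight of a neighbour in parameter slot `s` is the symmetrized
#' precision entry `0.5 * (beta_{l,s} + beta00_l * beta_{l_k,s} /
#' beta00_{l_k})` (reducing to `beta_{l,s}` when the neighbour carries the
#' same label). Background or missing neighbours are excluded.
#'
#' @param x_i Pixel intensity.
#' @param neighbor_values Intensities aligned with the model's
#'   neighbourhood offsets (`NA` = off-lattice/missing).
#' @param neighbor_mus Label means of the neighbours.
#' @param l Target label name (not BG).
#' @param model A [gmrf_model()].
#' @param neighbor_labels Optional neighbour label names; default assumes
#'   the homogeneous case (all neighbours share `l`).
#' @param log Return the log density?
#' @return Density (or log density) value.
#' @export
conditional_density <- function(x_i, neighbor_values, neighbor_mus, l,
                                model, neighbor_labels = NULL,
                                log = FALSE) {
  mom <- conditional_moments(neighbor_values, neighbor_mus, l, model,
                             neighbor_labels)
  ld <- stats::dnorm(x_i, mom$mean, sqrt(mom$var), log = TRUE)
  if (log) ld else exp(ld)
}

#' Conditional mean and variance at a single site
#'
#' @inheritParams conditional_density
#' @return List with `mean` and `var`.
#' @export
conditional_moments <- function(neighbor_values, neighbor_mus, l, model,
                                neighbor_labels = NULL) {
  li <- match(l, model$label_set)
  if (is.na(li)) stop("unknown label: ", l)
  if (li == model$bg) stop("conditional density is undefined for BG target")
  if (model$beta00[li] <= 0) stop("beta00 must be positive")
  nb <- model$neighborhood
  if (length(neighbor_values) != nb$n) {
    stop("neighbor_values must align with the ", nb$n, "-offset system")
  }
  if (is.null(neighbor_labels)) neighbor_labels <- rep(l, nb$n)
  lk <- match(neighbor_labels, model$label_set)
  use <- !is.na(neighbor_values) & !is.na(lk) & lk != model$bg
  m <- model$mu[li]
  if (any(use)) {
    s <- nb$slot[use]
    w <- 0.5 * (model$beta[cbind(li, s)] +
                  model$beta00[li] * model$beta[cbind(lk[use], s)] /
                  model$beta00[lk[use]])
    m <- m + sum(w * (neighbor_values[use] - neighbor_mus[use]))
  }
  list(mean = unname(m), var = unname(model$beta00[li]))
}

#' Annealed label-proposal probabilities at one pixel
#'
#' The tempered proposal distribution over labels: proportional to
#' `(conditional density x prior gamma)^(1/t)`, normalized over labels;
#' at `t = 0` it degenerates to a one-hot vector at the argmax (iterated
#' conditional modes), ties broken toward the earlier label.
#'
#' @param i Pixel position `c(row, col)`.
#' @param labels Current [label_field()].
#' @param image An [image_grid()].
#' @param model A [gmrf_model()].
#' @param t Temperature (>= 0).
#' @return Named probability vector over the label set.
#' @export
proposal_probabilities <- function(i, labels, image, model, t) {
  if (t < 0 || !is.finite(t)) stop("temperature must be finite and >= 0")
  x <- image$values
  lab_idx <- labels$labels
  stats <- site_stats(x, lab_idx, model)
  L <- length(model$label_set)
  lp <- vapply(seq_len(L), function(l) {
    m <- model$mu[l]
    for (s in seq_along(stats$S1)) {
      m <- m + 0.5 * model$beta[l, s] * stats$S1[[s]][i[1], i[2]]
    }
    m <- m + 0.5 * model$beta00[l] * stats$S2[i[1], i[2]]
    v <- model$beta00[l]
    -0.5 * log(2 * pi * v) - (x[i[1], i[2]] - m)^2 / (2 * v)
  }, numeric(1))
  w <- lp + log(model$gamma)
  if (!all(is.finite(w) | w == -Inf)) stop("non-finite proposal inputs")
  p <- anneal_softmax(matrix(w, 1), t)
  stats::setNames(as.numeric(p), model$label_set)
}

# Rows of W are per-pixel (log density + log prior) over labels; returns
# tempered probabilities (one-hot argmax at t = 0). All arithmetic in the
# log domain until the final exponentiation.
anneal_softmax <- function(W, t) {
  rm <- apply(W, 1, max)
  if (t == 0) {
    P <- matrix(0, nrow(W), ncol(W))
    P[cbind(seq_len(nrow(W)), max.col(W, ties.method = "first"))] <- 1
    return(P)
  }
  Z <- exp((W - rm) / t)
  Z / rowSums(Z)
}

#' One annealed Gibbs sweep over the label field
#'
#' Partitions the lattice into 9 coding sets (residue classes of the pixel
#' coordinates mod 3, within which no two pixels are neighbours of the
#' 20-offset system) and updates each set simultaneously by sampling from
#' the tempered proposal distribution. Masked-out pixels are frozen at BG.
#'
#' @param labels Current [label_field()].
#' @param image An [image_grid()].
#' @param model A [gmrf_model()].
#' @param t Temperature (`0` gives deterministic ICM updates).
#' @param seed Optional integer seed (the sweep is deterministic given it).
#' @return Updated [label_field()].
#' @export
gibbs_sweep <- function(labels, image, model, t, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- image$values
  mask <- image$mask
  lab_idx <- labels$labels
  lab_idx[!mask] <- model$bg
  nr <- nrow(x)
  nc <- ncol(x)
  row_mod <- (matrix(seq_len(nr), nr, nc) - 1L) %% 3L
  col_mod <- (matrix(seq_len(nc), nr, nc, byrow = TRUE) - 1L) %% 3L
  lg <- log(model$gamma)
  for (cy in 0:2) for (cx in 0:2) {
    sel <- mask & row_mod == cy & col_mod == cx
    if (!any(sel)) next
    ld <- cond_logdens_fields(x, lab_idx, model)
    W <- vapply(seq_along(ld), function(l) ld[[l]][sel] + lg[l],
                numeric(sum(sel)))
    if (sum(sel) == 1) W <- matrix(W, 1)
    P <- anneal_softmax(W, t)
    if (t == 0) {
      pick <- max.col(P, ties.method = "first")
    } else {
      u <- stats::runif(nrow(P))
      cum <- t(apply(P, 1, cumsum))
      pick <- 1L + rowSums(cum < u)
    }
    lab_idx[sel] <- as.integer(pick)
  }
  label_field(lab_idx, labels$label_set)
}

#' Pseudo-likelihood least-squares estimation of GMRF parameters
#'
#' For each non-background label: the label mean is the average in-label
#' intensity; the neighbour weights are the least-squares coefficients of
#' the centred pixel value on the 10 symmetric-pair sums of centred
#' neighbour values (background and off-lattice neighbours dropped); the
#' conditional variance is the residual variance of that regression. This
#' is the maximum pseudo-likelihood estimator of the conditional
#' autoregression. Labels with fewer than `min_pixels` pixels fall back to
#' independent-pixel estimates (`beta = 0`, `beta00` = in-label variance)
#' with a warning. The background label stays fixed.
#'
#' @param labels A [label_field()].
#' @param image An [image_grid()].
#' @param neighborhood A [build_neighborhood()] system.
#' @param gamma Prior proportions carried into the returned model.
#' @param min_pixels Pixel floor per label (default 50).
#' @return A [gmrf_model()] with fitted `mu`, `beta00`, `beta`.
#' @export
estimate_params <- function(labels, image, neighborhood = build_neighborhood(20),
                            gamma = NULL, min_pixels = 50) {
  label_set <- labels$label_set
  bg <- match("BG", label_set)
  x <- image$values
  mask <- image$mask
  lab_idx <- labels$labels
  lab_idx[!mask] <- bg
  L <- length(label_set)
  mu <- stats::setNames(numeric(L), label_set)
  beta00 <- stats::setNames(rep(1e-30, L), label_set)
  beta <- matrix(0, L, neighborhood$n_slots,
                 dimnames = list(label_set, NULL))
  for (l in seq_len(L)) {
    if (l == bg) next
    inl <- lab_idx == l & mask
    if (any(inl)) mu[l] <- mean(x[inl])
  }
  # centred fields use the freshly estimated means
  tmp <- gmrf_model(mu = mu, beta00 = stats::setNames(rep(1, L), label_set),
                    beta = beta, gamma = rep(1 / L, L),
                    label_set = label_set, neighborhood = neighborhood)
  st <- site_stats(x, lab_idx, tmp)
  for (l in seq_len(L)) {
    if (l == bg) next
    inl <- lab_idx == l & mask
    n <- sum(inl)
    if (n == 0) next
    if (n < min_pixels) {
      warning("label ", label_set[l], " has only ", n,
              " pixels; falling back to independent-pixel estimates")
      beta00[l] <- max(stats::var(x[inl]), 1e-10)
      if (!is.finite(beta00[l])) beta00[l] <- 1e-10
      next
    }
    X <- vapply(st$S1, function(s) s[inl], numeric(n))
    y <- x[inl] - mu[l]
    fit <- stats::lm.fit(X, y)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    # project onto the diagonal-dominance stability region: the implied
    # joint precision is positive definite only if the absolute neighbour
    # weights sum below 1 over the full offset set (each slot counts
    # twice); invalid estimates would make the conditionals degenerate
    total <- 2 * sum(abs(cf))
    if (total > 0.95) cf <- cf * 0.95 / total
    beta[l, ] <- cf
    res <- y - X %*% cf
    dof <- max(n - fit$rank, 1)
    beta00[l] <- max(sum(res^2) / dof, 1e-10)
  }
  gmrf_model(mu = mu, beta00 = beta00, beta = beta, gamma = gamma,
             label_set = label_set, neighborhood = neighborhood)
}

#' Annealed GMRF segmentation
#'
#' Alternates one tempered Gibbs sweep with pseudo-likelihood parameter
#' re-estimation for the full annealing schedule (258 iterations; the
#' final 5 run at zero temperature, i.e. iterated conditional modes), then
#' returns the hard label field and the fitted model. The single seed
#' expands into per-sweep substreams for reproducibility.
#'
#' @param image An [image_grid()].
#' @param init Initial [label_field()] (e.g. a GMM segmentation).
#' @param model0 Optional initial [gmrf_model()]; when `NULL`, parameters
#'   are estimated from `init` before the first sweep.
#' @param seed Integer seed.
#' @param n_iterations Number of annealing iterations (<= 258).
#' @param gamma Prior label proportions (defaults to the model's, or
#'   [default_gamma()]).
#' @return List with `labels` ([label_field()]) and `model`
#'   ([gmrf_model()]).
#' @export
segment_gmrf <- function(image, init, model0 = NULL, seed = 1L,
                         n_iterations = 258L, gamma = NULL) {
  if (n_iterations < 1 || n_iterations > 258) {
    stop("n_iterations must lie in 1..258")
  }
  if (is.null(gamma)) {
    gamma <- if (!is.null(model0)) model0$gamma else
      if (identical(init$label_set, mri_labels())) default_gamma() else NULL
  }
  nb <- if (!is.null(model0)) model0$neighborhood else build_neighborhood(20)
  labels <- init
  model <- if (is.null(model0)) {
    estimate_params(labels, image, nb, gamma = gamma)
  } else {
    model0
  }
  for (n in seq_len(n_iterations)) {
    labels <- gibbs_sweep(labels, image, model, temperature(n),
                          seed = sweep_seed(seed, n))
    model <- estimate_params(labels, image, nb, gamma = gamma)
  }
  list(labels = labels, model = model)
}

# Derive a per-sweep substream seed from the master seed (kept < 2^31).
sweep_seed <- function(seed, n) {
  as.integer((as.double(seed) %% 65536 * 104729 + n * 7919) %% 2147483647)
}

#' Drop an obsolete label and renormalize the prior
#'
#' Removes a label (typically PV when comparing against a histology
#' segmentation that lacks it), renormalizes `gamma` over the remaining
#' labels, and reassigns pixels that carried the dropped label to the
#' zero-temperature argmax of the tempered proposal over the remaining
#' labels. The reassignment argmax is evaluated under the full model, so
#' neighbouring pixels still carrying the obsolete label contribute with
#' their fitted parameters.
#'
#' @param labels A [label_field()].
#' @param model The fitted [gmrf_model()].
#' @param image The [image_grid()] the labels refer to (needed to evaluate
#'   the conditional densities during reassignment; may be omitted when no
#'   pixel carries the obsolete label).
#' @param obsolete Label name to drop.
#' @return List with updated `labels` and `model` over the reduced set.
#' @export
drop_label_renormalize <- function(labels, model, image = NULL,
                                   obsolete = "PV") {
  old_set <- model$label_set
  oi <- match(obsolete, old_set)
  if (is.na(oi)) stop("label not present: ", obsolete)
  new_set <- old_set[old_set != obsolete]
  if (sum(new_set != "BG") < 3) {
    stop("dropping ", obsolete, " would leave fewer than 3 tissue groups; ",
         "multilateration needs at least 3")
  }
  keep <- which(old_set != obsolete)
  gamma <- model$gamma[keep] / sum(model$gamma[keep])
  lab_idx <- labels$labels
  todo <- which(lab_idx == oi)
  if (length(todo) > 0) {
    if (is.null(image)) {
      stop("image is required to reassign pixels carrying ", obsolete)
    }
    ld <- cond_logdens_fields(image$values, lab_idx, model)
    W <- vapply(keep, function(l) ld[[l]][todo] + log(gamma[old_set[l]]),
                numeric(length(todo)))
    if (length(todo) == 1) W <- matrix(W, 1)
    lab_idx[todo] <- keep[max.col(W, ties.method = "first")]
  }
  new_model <- gmrf_model(
    mu = model$mu[keep], beta00 = model$beta00[keep],
    beta = model$beta[keep, , drop = FALSE], gamma = gamma,
    label_set = new_set, neighborhood = model$neighborhood
  )
  list(labels = label_field(remap_labels(lab_idx, old_set, new_set),
                            new_set),
       model = new_model)
}

remap_labels <- function(lab_idx, old_set, new_set) {
  map <- match(old_set, new_set)
  matrix(map[lab_idx], nrow(lab_idx), ncol(lab_idx))
}
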