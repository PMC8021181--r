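#' Phantom configuration
#'
#' Parameters of the synthetic spinal-cord phantom: cord ellipse geometry,
#' per-tissue MRI texture (mean, conditional variance, neighbour weights),
#' and per-tissue histology channel means/sds. Contrast presets scale the
#' within-tissue noise: `"high"` (sd 0.03; adjacent tissue means are >= 5
#' sd apart), `"medium"` (sd 0.05) and `"low"` (sd 0.08).
#'
#' @param contrast `"high"`, `"medium"` or `"low"`.
#' @param pv_ring Insert a partial-volume ring at the WM/GM interface?
#' @param lesion Insert a lesion disc (labelled CB) in ventral WM?
#' @param dark_core With `lesion`, make the lesion core darker than WM on
#'   MRI (reproduces the known dark-core failure mode).
#' @param beta Tissue x slot matrix of neighbour weights (rows CB, GM,
#'   PV, WM). The defaults make texture tissue-dependent — coherent
#'   white-matter tracts carry the strongest nearest-pair coupling,
#'   grey matter a moderate isotropic one, and cell-rich tissue is
#'   nearly independent-pixel — mirroring the tissue-wise parameter
#'   separation seen in real cords.
#' @param n_sweeps Gibbs sweeps for the MRI texture simulation.
#' @return Named list of settings.
#' @export
phantom_config <- function(contrast = c("high", "medium", "low"),
                           pv_ring = TRUE, lesion = FALSE,
                           dark_core = FALSE,
                           beta = rbind(
                             CB = c(0.02, 0.02, rep(0, 8)),
                             GM = c(0.10, 0.10, 0.05, 0.05, rep(0, 6)),
                             PV = c(0.15, 0.02, 0, 0, 0.05, rep(0, 5)),
                             WM = c(0.25, 0.05, 0.02, 0.02, 0.10, rep(0, 5))
                           ),
                           n_sweeps = 200) {
  contrast <- match.arg(contrast)
  sd <- switch(contrast, high = 0.03, medium = 0.05, low = 0.08)
  list(
    contrast = contrast,
    sd = sd,
    # T2 brightness ordering: WM dark, PV, GM, CB bright
    mri_mu = c(CB = 0.85, GM = 0.60, PV = 0.45, WM = 0.30, BG = 0),
    beta = beta,
    pv_ring = pv_ring,
    lesion = lesion,
    dark_core = dark_core,
    n_sweeps = n_sweeps,
    hist_means = rbind(WM = c(0.735, 0.230),
                       GM = c(0.333, 0.666),
                       CB = c(0.341, 0.785),
                       PV = c((0.735 + 0.333) / 2, (0.230 + 0.666) / 2)),
    hist_sd = 0.10
  )
}

#' Generate a synthetic spinal-cord phantom
#'
#' Draws a cord ellipse on a background canvas, an H-shaped grey-matter
#' region with small dorsal cell-body blobs (emulating the substantia
#' gelatinosa), an optional partial-volume ring at the WM/GM interface and
#' an optional ventral lesion disc; fills the MRI channel with a
#' Gibbs-sampled GMRF texture per tissue and the paired histology channels
#' with per-tissue Gaussian noise around the configured (myelin,
#' cellularity) means. Fully deterministic given the seed.
#'
#' @param size `(rows, cols)`, at least 32 x 32 (default 64 x 64).
#' @param config A [phantom_config()] list.
#' @param seed Integer seed.
#' @return Object of class `phantom`: `labels` ([label_field()]), `mri`
#'   ([image_grid()]), `hist_blue`, `hist_red` ([image_grid()]s),
#'   `lesion_mask`, `gen_model` (the generating [gmrf_model()]),
#'   `config`, `seed`, `proportions`.
#' @export
make_phantom <- function(size = c(64, 64), config = phantom_config(),
                         seed = 1L) {
  if (any(size < 32)) stop("phantom size must be at least 32 x 32")
  nr <- size[1]
  nc <- size[2]
  cy <- (nr + 1) / 2
  cx <- (nc + 1) / 2
  Y <- matrix(seq_len(nr), nr, nc)
  X <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # cord ellipse: semi-axes scale with the canvas (12/32 vertical,
  # 16/32 horizontal at the default 64x64)
  ay <- nr * 12 / 64
  ax <- nc * 16 / 64
  cord <- ((Y - cy) / ay)^2 + ((X - cx) / ax)^2 <= 1
  lab <- matrix("BG", nr, nc)
  lab[cord] <- "WM"
  sc <- min(nr, nc) / 64
  # H-shaped grey matter: two vertical bars plus a crossbar; dimensions
  # chosen so the label composition tracks the prior proportions gamma
  bar_hw <- max(1, round(2 * sc))          # half-width of each bar
  bar_off <- round(7 * sc)                 # bar centre offset from midline
  bar_hh <- round(9 * sc)                  # half-height
  gm <- (abs(abs(X - cx) - bar_off) <= bar_hw & abs(Y - cy) <= bar_hh) |
    (abs(Y - cy) <= max(1, round(3 * sc)) &
       abs(X - cx) <= bar_off + bar_hw)
  gm <- gm & cord
  lab[gm] <- "GM"
  # dorsal cell-body blobs at the top of each bar (substantia gelatinosa)
  cb_r <- max(1.5, 2.8 * sc)
  for (sgn in c(-1, 1)) {
    blob <- (Y - (cy - bar_hh))^2 + (X - (cx + sgn * bar_off))^2 <= cb_r^2
    lab[blob & cord] <- "CB"
  }
  lesion_mask <- matrix(FALSE, nr, nc)
  if (isTRUE(config$lesion)) {
    les <- (Y - (cy + round(8 * sc)))^2 + (X - cx)^2 <= (3 * sc)^2
    lesion_mask <- les & cord & lab == "WM"
    lab[lesion_mask] <- "CB"
  }
  if (isTRUE(config$pv_ring)) {
    # one-pixel WM ring bordering GM/CB (8-connected)
    tissue <- lab %in% c("GM", "CB")
    dim(tissue) <- dim(lab)
    border <- matrix(0, nr, nc)
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      border <- border + shift_matrix(tissue * 1, dy, dx)
    }
    lab[border > 0 & lab == "WM"] <- "PV"
  }
  labels <- label_field(lab, mri_labels())
  mask <- cord

  mu <- config$mri_mu
  if (isTRUE(config$lesion) && isTRUE(config$dark_core)) {
    # dark-core failure mode: lesion pixels (CB label) darker than WM;
    # approximated by pulling the CB mean below WM
    mu["CB"] <- max(0.05, mu["WM"] - 0.10)
  }
  L <- length(mri_labels())
  cb <- config$beta
  if (is.null(dim(cb))) cb <- matrix(rep(cb, 4), 4, byrow = TRUE,
                                     dimnames = list(c("CB", "GM", "PV", "WM")))
  beta <- matrix(0, L, ncol(cb), dimnames = list(mri_labels(), NULL))
  beta[rownames(cb), ] <- cb
  gen_model <- gmrf_model(
    mu = mu,
    beta00 = stats::setNames(c(rep(config$sd^2, L - 1), 1e-30), mri_labels()),
    beta = beta, gamma = default_gamma(),
    label_set = mri_labels()
  )
  mri <- simulate_field(labels, gen_model, n_sweeps = config$n_sweeps,
                        seed = seed, mask = mask)

  set.seed(sweep_seed(seed, 100003L))
  hb <- matrix(0, nr, nc)
  hr <- matrix(0, nr, nc)
  for (t in rownames(config$hist_means)) {
    inl <- lab == t & mask
    n <- sum(inl)
    if (n == 0) next
    hb[inl] <- stats::rnorm(n, config$hist_means[t, 1], config$hist_sd)
    hr[inl] <- stats::rnorm(n, config$hist_means[t, 2], config$hist_sd)
  }
  hb <- pmin(pmax(hb, 0), 1)
  hr <- pmin(pmax(hr, 0), 1)
  tab <- table(factor(lab, levels = mri_labels()))
  proportions <- as.numeric(tab) / length(lab)
  names(proportions) <- mri_labels()

  structure(list(
    labels = labels,
    mri = mri,
    hist_blue = image_grid(hb, mask),
    hist_red = image_grid(hr, mask),
    lesion_mask = lesion_mask,
    gen_model = gen_model,
    config = config,
    seed = seed,
    proportions = proportions
  ), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %dx%d, contrast %s, seed %d>\n",
              nrow(x$mri$values), ncol(x$mri$values),
              x$config$contrast, x$seed))
  print(round(x$proportions, 3))
  invisible(x)
}
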