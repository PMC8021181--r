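#' GMM-initialized annealed GMRF segmentation of an MR image
#'
#' The full unsupervised segmentation stage: fits a 4-component Gaussian
#' mixture to the masked-in T2 intensities (background is known from the
#' mask), maps components to WM, PV, GM and CB by ascending mean, then
#' refines the 5-label field with the annealed GMRF (full schedule).
#'
#' @param image A normalized [image_grid()].
#' @param seed Integer seed.
#' @param gamma Prior label proportions (default [default_gamma()]).
#' @param n_iterations Annealing iterations (<= 258).
#' @return List with `labels`, `model`, and `init` (the GMM
#'   initialization).
#' @export
segment_mri <- function(image, seed = 1L, gamma = default_gamma(),
                        n_iterations = 258L) {
  v <- image$values[image$mask]
  gm <- fit_gmm(v, k_candidates = 4, seed = seed)
  comp_labels <- map_components(gm, "mri", with_bg = FALSE)
  init <- segment_gmm(gm, image, comp_labels)
  fit <- segment_gmrf(image, init, seed = seed, gamma = gamma,
                      n_iterations = n_iterations)
  list(labels = fit$labels, model = fit$model, init = init)
}

#' End-to-end unsupervised myelin and cellularity estimation
#'
#' Runs [segment_mri()], drops the partial-volume label before metric
#' learning, and produces the (myelin, cellularity) feature maps by
#' Mahalanobis multilateration against the histology landmarks.
#'
#' @param image A normalized [image_grid()].
#' @param hist_landmarks Histology landmark matrix
#'   (default [default_hist_landmarks()]).
#' @param seed Integer seed.
#' @param drop_pv Drop the PV label before multilateration? (PV pixels are
#'   still mapped; only the label/prior are removed.)
#' @return List with `features` ([feature_maps()] result), `labels`,
#'   `model`, `segmentation` (the full [segment_mri()] output).
#' @export
estimate_features <- function(image,
                              hist_landmarks = default_hist_landmarks(),
                              seed = 1L, drop_pv = FALSE) {
  seg <- segment_mri(image, seed = seed)
  labels <- seg$labels
  model <- seg$model
  if (drop_pv) {
    dropped <- drop_label_renormalize(labels, model, image, "PV")
    labels <- dropped$labels
    model <- dropped$model
  }
  fm <- feature_maps(image, labels, model, hist_landmarks)
  list(features = fm, labels = labels, model = model, segmentation = seg)
}
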