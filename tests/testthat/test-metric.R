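metric_model <- function(beta_wm = c(0.3, rep(0, 9))) {
  gmrf_model(mu = c(CB = 0.8, GM = 0.6, PV = 0.45, WM = 0.4, BG = 0),
             beta00 = c(CB = 0.01, GM = 0.01, PV = 0.01, WM = 0.04,
                        BG = 1e-30),
             beta = rbind(CB = 0, GM = 0, PV = 0, WM = beta_wm, BG = 0))
}

test_that("the precision-scaled distance follows its closed forms", {
  m <- metric_model(beta_wm = rep(0, 10))
  # residual zero at the tissue mean
  img <- image_grid(matrix(0.4, 5, 5))
  lf <- label_field(matrix("WM", 5, 5))
  expect_equal(mahalanobis_distance(c(3, 3), "WM", img, lf, m), 0)
  # one conditional-sd deviation scores exactly 1
  img2 <- image_grid(matrix(0.4, 5, 5) + diag(5) * 0)
  img2$values[3, 3] <- 0.4 + sqrt(0.04)
  expect_equal(mahalanobis_distance(c(3, 3), "WM", img2, lf, m), 1,
               tolerance = 1e-12)
  # hand evaluation with one neighbour pair active:
  # (0.2 - 0.3*0.1 - 0.3*0.1)^2 / 0.04 = 0.49
  m2 <- metric_model(beta_wm = c(0.3, rep(0, 9)))
  v <- matrix(0.4, 5, 5)
  v[3, 3] <- 0.6          # x_i - mu = 0.2
  v[3, 2] <- v[3, 4] <- 0.5  # horizontal pair deviations +0.1
  img3 <- image_grid(v)
  expect_equal(mahalanobis_distance(c(3, 3), "WM", img3, lf, m2), 0.49,
               tolerance = 1e-12)
  # square-root variant
  expect_equal(mahalanobis_distance(c(3, 3), "WM", img3, lf, m2,
                                    squared = FALSE), 0.7,
               tolerance = 1e-12)
  expect_error(mahalanobis_maps(img3, lf, m2, tissues = "BG"), "BG")
})

test_that("a tissue's distance channel ignores relabelling of other tissues", {
  ph <- fixture_phantom()
  m <- ph$gen_model
  d1 <- mahalanobis_maps(ph$mri, ph$labels, m, "WM")
  swapped <- label_names(ph$labels)
  swapped[swapped == "GM"] <- "TMP"
  swapped[swapped == "CB"] <- "GM"
  swapped[swapped == "TMP"] <- "CB"
  # swap GM and CB labels but also swap their parameters, so each pixel
  # keeps its own (mu, beta) and only the naming changes
  m2 <- gmrf_model(
    mu = replace(m$mu, c("GM", "CB"), m$mu[c("CB", "GM")]),
    beta00 = replace(m$beta00, c("GM", "CB"), m$beta00[c("CB", "GM")]),
    beta = {
      b <- m$beta
      b[c("GM", "CB"), ] <- b[c("CB", "GM"), ]
      b
    },
    gamma = m$gamma, label_set = m$label_set
  )
  d2 <- mahalanobis_maps(ph$mri, label_field(swapped, m$label_set), m2, "WM")
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("scale fitting recovers identity and closed-form optima", {
  hl <- default_hist_landmarks()
  D <- as.matrix(stats::dist(hl))
  expect_equal(unname(fit_scales(D, hl)), c(1, 1, 1), tolerance = 1e-4)
  expect_equal(unname(fit_scales(2 * D, hl)), c(0.5, 0.5, 0.5),
               tolerance = 1e-4)
  # optimizer contract: returned scales never lose to unit scales
  set.seed(2)
  M <- D + matrix(runif(9, 0, 0.3), 3, 3)
  s <- fit_scales(M, hl)
  obj <- function(s) sqrt(mean((sweep(M, 2, s, `*`) - D)^2))
  expect_lte(obj(s), obj(c(1, 1, 1)))
  expect_error(fit_scales(D[1:2, ], hl[1:2, ]), "3 landmarks")
})

test_that("multilateration matches exact geometry and a grid-search oracle", {
  anch <- rbind(c(0, 0), c(1, 0), c(0, 1))
  p_true <- c(0.25, 0.5)
  d <- sqrt(rowSums(sweep(anch, 2, p_true)^2))
  expect_equal(multilaterate(d, anch), p_true, tolerance = 1e-3)
  # anchor order must not matter
  perm <- c(3, 1, 2)
  expect_equal(multilaterate(d[perm], anch[perm, ]), p_true,
               tolerance = 1e-3)
  # grid-search oracle for degenerate (all-zero) and noisy distances
  grid_opt <- function(dd) {
    gs <- seq(-0.5, 1.5, length.out = 200)
    grid <- as.matrix(expand.grid(gs, gs))
    o <- apply(grid, 1, function(p) {
      sum((sqrt(rowSums(sweep(anch, 2, p, `-`)^2)) - dd)^2)
    })
    grid[which.min(o), ]
  }
  h <- 2 / 199
  expect_lt(max(abs(multilaterate(c(0, 0, 0), anch) - grid_opt(c(0, 0, 0)))),
            1.5 * h)
  set.seed(6)
  dn <- d * (1 + runif(3, -0.05, 0.05))
  expect_lt(max(abs(multilaterate(dn, anch) - grid_opt(dn))), 1.5 * h)
  expect_error(multilaterate(c(1, 1, 1), rbind(c(0, 0), c(1, 1), c(2, 2))),
               "collinear")
})

test_that("feature maps land tissue pixels near their histology landmarks", {
  ph <- fixture_phantom()
  seg <- fixture_segmentation()
  fm <- memo("features64", feature_maps(ph$mri, seg$labels, seg$model))
  hl <- default_hist_landmarks()
  # the pixel closest to the WM landmark in MRI metric space should map
  # near the WM histology position
  d <- mahalanobis_maps(ph$mri, seg$labels, seg$model)
  wm_px <- which(label_names(seg$labels) == "WM" & ph$mri$mask)
  best <- wm_px[which.min(d[, , "WM"][wm_px])]
  expect_lt(abs(fm$myelin[best] - hl["WM", 1]), 0.15)
  expect_lt(abs(fm$cellularity[best] - hl["WM", 2]), 0.15)
  # BG pixels are excluded
  expect_true(all(is.na(fm$myelin[!ph$mri$mask])))
  # determinism of the full metric-learning stage
  fm2 <- feature_maps(ph$mri, seg$labels, seg$model)
  expect_identical(fm$myelin, fm2$myelin)
  expect_identical(fm$scales, fm2$scales)
})
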