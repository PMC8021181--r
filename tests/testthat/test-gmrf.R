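test_that("the annealing schedule follows the logarithmic cooling law", {
  expect_identical(temperature(1), 1)
  expect_equal(temperature(253), 0.25, tolerance = 1e-15)
  expect_identical(temperature(255), 0)
  expect_identical(temperature(258), 0)
  tt <- temperature(1:258)
  expect_true(all(diff(tt) <= 0))
  expect_error(temperature(0), "1..258")
  expect_error(temperature(259), "1..258")
})

two_label_model <- function(beta = rbind(WM = c(0.2, 0.1, 0.05, 0, 0, 0, 0.02, 0, 0, 0),
                                         BG = 0),
                            beta00 = c(WM = 0.04, BG = 1e-30)) {
  gmrf_model(mu = c(WM = 0.5, BG = 0), beta00 = beta00, beta = beta,
             gamma = c(WM = 0.5, BG = 0.5), label_set = c("WM", "BG"))
}

test_that("site conditionals match the analytically conditioned joint Gaussian", {
  m <- two_label_model()
  nb <- m$neighborhood
  for (sz in list(c(4, 4), c(5, 5), c(3, 5))) {
    nr <- sz[1]; nc <- sz[2]
    Q <- assemble_Q(nr, nc, m, "WM")
    expect_lt(max(abs(Q - t(Q))), 1e-12)
    expect_gt(min(eigen(Q, symmetric = TRUE, only.values = TRUE)$values), 0)
    Sig <- solve(Q)
    set.seed(nr * 100 + nc)
    x <- matrix(runif(nr * nc, 0.3, 0.7), nr, nc)
    for (p in unique(c(1, nr * nc, sample(nr * nc, 4)))) {
      r0 <- (p - 1) %% nr + 1; c0 <- (p - 1) %/% nr + 1
      rest <- setdiff(seq_len(nr * nc), p)
      S12 <- Sig[p, rest, drop = FALSE]
      sol <- solve(Sig[rest, rest], cbind(as.vector(x)[rest] - 0.5, t(S12)))
      cmean <- 0.5 + S12 %*% sol[, 1]
      cvar <- Sig[p, p] - S12 %*% sol[, 2]
      nv <- rep(NA_real_, nb$n); nm <- rep(NA_real_, nb$n)
      for (k in seq_len(nb$n)) {
        r1 <- r0 + nb$offsets[k, 1]; c1 <- c0 + nb$offsets[k, 2]
        if (r1 >= 1 && r1 <= nr && c1 >= 1 && c1 <= nc) {
          nv[k] <- x[r1, c1]; nm[k] <- 0.5
        }
      }
      mom <- conditional_moments(nv, nm, "WM", m)
      expect_lt(abs(mom$mean - cmean), 1e-8)
      expect_lt(abs(mom$var - cvar), 1e-8)
    }
  }
})

test_that("the conditional density is a proper Gaussian with the stated mode", {
  m <- two_label_model(beta = rbind(WM = rep(0, 10), BG = 0))
  nb <- m$neighborhood
  none <- rep(NA_real_, nb$n)
  expect_equal(conditional_density(0.5, none, none, "WM", m),
               1 / sqrt(2 * pi * 0.04), tolerance = 1e-12)
  # density integrates to one (trapezoid over +-10 sd)
  m2 <- two_label_model()
  set.seed(9)
  nv <- runif(nb$n, 0.3, 0.7); nm <- rep(0.5, nb$n)
  xs <- seq(0.5 - 10 * 0.2, 0.5 + 10 * 0.2, length.out = 20001)
  dens <- vapply(xs, function(x) conditional_density(x, nv, nm, "WM", m2),
                 numeric(1))
  integral <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(xs))
  expect_equal(integral, 1, tolerance = 1e-6)
  expect_error(conditional_density(0.5, none, none, "BG", m), "BG")
  expect_error(conditional_moments(none, none, "XX", m), "unknown")
})

test_that("proposal probabilities temper toward the argmax indicator", {
  # two labels with identical conditionals: the prior decides
  m <- gmrf_model(mu = c(WM = 0.5, GM = 0.5, CB = 0.5, BG = 0),
                  beta00 = c(WM = 0.01, GM = 0.01, CB = 0.01, BG = 1e-30),
                  beta = matrix(0, 4, 10),
                  gamma = c(WM = 0.25, GM = 0.50, CB = 0.25, BG = 0),
                  label_set = c("WM", "GM", "CB", "BG"))
  img <- image_grid(matrix(0.5, 5, 5))
  lf <- label_field(matrix("WM", 5, 5), c("WM", "GM", "CB", "BG"))
  p <- proposal_probabilities(c(3, 3), lf, img, m, t = 1)
  expect_equal(unname(p[c("WM", "GM", "CB")]), c(0.25, 0.5, 0.25),
               tolerance = 1e-10)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # t -> 0+ converges to the one-hot argmax branch
  set.seed(77)
  mism <- 0
  for (rep in 1:100) {
    x <- matrix(runif(25, 0.2, 0.8), 5, 5)
    img <- image_grid(x)
    lf <- label_field(matrix(sample(c("WM", "GM", "CB"), 25, TRUE), 5, 5),
                      c("WM", "GM", "CB", "BG"))
    m2 <- gmrf_model(mu = c(WM = 0.3, GM = 0.6, CB = 0.8, BG = 0),
                     beta00 = c(WM = 0.01, GM = 0.02, CB = 0.01, BG = 1e-30),
                     beta = matrix(runif(40, -0.02, 0.05), 4, 10),
                     gamma = c(WM = 0.3, GM = 0.3, CB = 0.4, BG = 0),
                     label_set = c("WM", "GM", "CB", "BG"))
    p_small <- proposal_probabilities(c(3, 3), lf, img, m2, t = 1e-3)
    p_zero <- proposal_probabilities(c(3, 3), lf, img, m2, t = 0)
    mism <- mism + unname(which.max(p_small) != which.max(p_zero))
    expect_equal(sum(p_small), 1, tolerance = 1e-9)
  }
  expect_equal(mism, 0)
})

test_that("gibbs sweeps are deterministic, respect the mask, and ICM settles", {
  ph <- fixture_phantom()
  m <- ph$gen_model
  # empty mask: nothing changes
  empty <- image_grid(matrix(0, 8, 8), matrix(FALSE, 8, 8))
  lf0 <- label_field(matrix("BG", 8, 8))
  expect_identical(gibbs_sweep(lf0, empty, m, 1, seed = 1)$labels, lf0$labels)
  # same seed, same state -> identical sweep
  s1 <- gibbs_sweep(ph$labels, ph$mri, m, 0.5, seed = 99)
  s2 <- gibbs_sweep(ph$labels, ph$mri, m, 0.5, seed = 99)
  expect_identical(s1$labels, s2$labels)
  # zero-temperature sweeps: label changes shrink to a fixed point
  set.seed(4)
  scram <- ph$labels$labels
  flip <- which(ph$mri$mask)[sample(sum(ph$mri$mask), 60)]
  scram[flip] <- sample(1:4, 60, replace = TRUE)
  lab <- label_field(scram, ph$labels$label_set)
  changes <- integer(5)
  for (i in 1:5) {
    nxt <- gibbs_sweep(lab, ph$mri, m, 0, seed = i)
    changes[i] <- sum(nxt$labels != lab$labels)
    lab <- nxt
  }
  expect_true(all(diff(changes) <= 0))
  expect_equal(changes[5], 0)
})

test_that("pseudo-likelihood estimation recovers iid fields and warns on floors", {
  set.seed(12)
  ls <- c("WM", "BG")
  x <- matrix(rnorm(64 * 64, 0.5, 0.05), 64, 64)
  img <- image_grid(x)
  lf <- label_field(matrix("WM", 64, 64), ls)
  est <- estimate_params(lf, img, gamma = c(WM = 0.5, BG = 0.5))
  expect_lt(abs(est$mu["WM"] - 0.5) / 0.5, 0.05)
  expect_lt(abs(est$beta00["WM"] - 0.0025) / 0.0025, 0.05)
  expect_true(all(abs(est$beta["WM", ]) < 0.05))
  # single-pixel label triggers the fallback path with a warning
  lab2 <- matrix("WM", 64, 64)
  lab2[1, 1] <- "GM"
  lf2 <- label_field(lab2, c("WM", "GM", "BG"))
  expect_warning(
    est2 <- estimate_params(lf2, img,
                            gamma = c(WM = 0.4, GM = 0.3, BG = 0.3)),
    "falling back"
  )
  expect_true(all(est2$beta["GM", ] == 0))
})

test_that("dropping an obsolete label renormalizes the prior and reassigns by argmax", {
  ph <- fixture_phantom()
  seg <- fixture_segmentation()
  dropped <- drop_label_renormalize(seg$labels, seg$model, ph$mri, "PV")
  expect_equal(sum(dropped$model$gamma), 1, tolerance = 1e-12)
  expect_false("PV" %in% dropped$labels$label_set)
  expect_false(any(label_names(dropped$labels) == "PV"))
  # brute-force oracle: every reassigned pixel carries the argmax of
  # (log conditional + log renormalized prior) over the remaining labels
  old <- seg$labels
  pv_idx <- which(label_names(old) == "PV")
  keep_labels <- setdiff(seg$model$label_set, "PV")
  gam <- seg$model$gamma[keep_labels] / sum(seg$model$gamma[keep_labels])
  for (p in pv_idx[seq_len(min(12, length(pv_idx)))]) {
    rc <- c((p - 1) %% nrow(old$labels) + 1, (p - 1) %/% nrow(old$labels) + 1)
    lp <- vapply(keep_labels, function(l) {
      nb <- seg$model$neighborhood
      nv <- rep(NA_real_, nb$n); nm <- rep(NA_real_, nb$n)
      nl <- rep(NA_character_, nb$n)
      for (k in seq_len(nb$n)) {
        r1 <- rc[1] + nb$offsets[k, 1]; c1 <- rc[2] + nb$offsets[k, 2]
        if (r1 >= 1 && r1 <= nrow(old$labels) &&
            c1 >= 1 && c1 <= ncol(old$labels)) {
          nl[k] <- old$label_set[old$labels[r1, c1]]
          nv[k] <- ph$mri$values[r1, c1]
          nm[k] <- seg$model$mu[nl[k]]
        }
      }
      if (l == "BG") return(-Inf)
      conditional_density(ph$mri$values[rc[1], rc[2]], nv, nm, l,
                          seg$model, neighbor_labels = nl, log = TRUE) +
        log(gam[l])
    }, numeric(1))
    expect_identical(label_names(dropped$labels)[p],
                     keep_labels[which.max(lp)])
  }
  # a field with no pixels of the obsolete label keeps its labels; only
  # the prior is renormalized
  no_pv <- label_names(old)
  no_pv[no_pv == "PV"] <- "WM"
  clean <- drop_label_renormalize(label_field(no_pv, seg$model$label_set),
                                  seg$model, obsolete = "PV")
  expect_equal(label_names(clean$labels), no_pv)
  expect_equal(sum(clean$model$gamma), 1, tolerance = 1e-12)
  # a 4-label field cannot lose another tissue group
  expect_error(drop_label_renormalize(dropped$labels, dropped$model,
                                      ph$mri, "CB"),
               "3 tissue")
})

test_that("an all-background field stays background under segmentation", {
  img <- image_grid(matrix(0, 12, 12), matrix(FALSE, 12, 12))
  init <- label_field(matrix("BG", 12, 12))
  m0 <- gmrf_model(mu = c(CB = 0.8, GM = 0.6, PV = 0.45, WM = 0.3, BG = 0),
                   beta00 = c(CB = 0.01, GM = 0.01, PV = 0.01, WM = 0.01,
                              BG = 1e-30),
                   beta = matrix(0, 5, 10))
  out <- segment_gmrf(img, init, model0 = m0, seed = 1, n_iterations = 3)
  expect_true(all(label_names(out$labels) == "BG"))
})
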