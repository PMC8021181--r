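test_that("median regression minimizes absolute loss and resists outliers", {
  set.seed(5)
  n <- 4000
  x <- runif(n)
  y <- 0.5 + 2 * x + stats::rexp(n) - stats::rexp(n)  # Laplace noise
  cf <- myelinmetric:::lad_fit(cbind(1, x), y)
  expect_lt(abs(cf[2] - 2), 0.1)
  # 25% symmetric heavy-tail contamination barely moves the fit
  yc <- y
  bad <- sample(n, n / 4)
  yc[bad] <- y[bad] + sample(c(-1, 1), n / 4, TRUE) * stats::rcauchy(n / 4)
  cfc <- myelinmetric:::lad_fit(cbind(1, x), yc)
  expect_lt(abs(cfc[2] - cf[2]), 0.15)
  # constant predictor: the fit is the median
  z <- c(rep(1, 50), 2, 3, 100)
  cf0 <- myelinmetric:::lad_fit(matrix(1, length(z)), z)
  expect_equal(unname(cf0[1]), stats::median(z), tolerance = 1e-6)
})

segreg_toy <- function(seed, lesion = FALSE) {
  set.seed(seed)
  lab <- matrix(rep(c("WM", "GM"), each = 16 * 8), 16, 16)
  x <- matrix(runif(256, 0.2, 0.8), 16, 16)
  resp <- matrix(0, 16, 16)
  resp[lab == "WM"] <- 0.7 - 0.5 * x[lab == "WM"]
  resp[lab == "GM"] <- 0.2 + 0.4 * x[lab == "GM"]
  lm <- NULL
  if (lesion) {
    lm <- matrix(FALSE, 16, 16)
    lm[1:6, 1:6] <- TRUE
    resp[lm] <- 0.9
  }
  list(image = image_grid(x), labels = label_field(lab), response = resp,
       lesion_mask = lm)
}

test_that("segmentation regression fits per-label and honours lesion overrides", {
  subs <- lapply(1:3, segreg_toy)
  m <- fit_segreg(subs, loss = "MAE")
  pr <- predict_segreg(m, subs[[1]]$image, subs[[1]]$labels)
  use <- !is.na(pr)
  # saturated per-label linear truth: training residual median ~ 0
  resid <- pr[use] - subs[[1]]$response[use]
  expect_lt(abs(stats::median(resid)), 1e-6)
  expect_gt(stats::cor(pr[use], subs[[1]]$response[use]), 0.999)
  # lesion pixels use the LESION coefficients only
  subsl <- lapply(4:6, segreg_toy, lesion = TRUE)
  ml <- fit_segreg(subsl, loss = "MAE")
  prl <- predict_segreg(ml, subsl[[1]]$image, subsl[[1]]$labels,
                        subsl[[1]]$lesion_mask)
  expect_equal(unname(prl[subsl[[1]]$lesion_mask]),
               rep(0.9, sum(subsl[[1]]$lesion_mask)), tolerance = 1e-6)
  # unseen label at prediction time errors by name
  expect_error(predict_segreg(m, subsl[[1]]$image, subsl[[1]]$labels,
                              subsl[[1]]$lesion_mask), "LESION")
  # RMSE loss with per-subject intercepts also reproduces the structure
  mr <- fit_segreg(subs, loss = "RMSE")
  prr <- predict_segreg(mr, subs[[1]]$image, subs[[1]]$labels)
  expect_gt(stats::cor(prr[use], subs[[1]]$response[use]), 0.999)
})

test_that("identity-basis additive models nest as expected", {
  ph <- fixture_phantom()
  resp <- ph$hist_blue$values
  exact <- fit_additive(ph$mri, ph$mri$values, "markov-", "RMSE")
  expect_equal(unname(exact$coefficients), c(0, 1), tolerance = 1e-8)
  r2 <- function(model, lesion_mask = NULL) {
    p <- predict(model, ph$mri, lesion_mask)
    u <- !is.na(p)
    1 - sum((resp[u] - p[u])^2) / sum((resp[u] - mean(resp[u]))^2)
  }
  m0 <- fit_additive(ph$mri, resp, "markov-", "RMSE")
  m1 <- fit_additive(ph$mri, resp, "markov", "RMSE")
  expect_gte(r2(m1), r2(m0))
  # lesion dummy variant needs its mask and adds structure
  lm <- matrix(FALSE, 64, 64)
  lm[30:36, 30:36] <- ph$mri$mask[30:36, 30:36]
  m2 <- fit_additive(ph$mri, resp, "markov+", "RMSE", lesion_mask = lm)
  expect_gte(r2(m2, lm), r2(m1) - 1e-8)
  expect_error(fit_additive(ph$mri, resp, "markov+", "RMSE"), "lesion mask")
})

test_that("leave-one-out folds match a hand-rolled split loop", {
  subs <- lapply(1:3, segreg_toy)
  fit_fn <- function(tr) fit_segreg(tr, loss = "MAE")
  pred_fn <- function(m, s) predict_segreg(m, s$image, s$labels)
  cv <- loocv(subs, fit_fn, pred_fn)
  expect_equal(nrow(cv), 3)
  # independent re-implementation of the fold loop
  for (i in 1:3) {
    m <- fit_fn(subs[-i])
    p <- pred_fn(m, subs[[i]])
    keep <- is.finite(p) & is.finite(subs[[i]]$response)
    y <- subs[[i]]$response[keep]
    r2 <- 1 - sum((y - p[keep])^2) / sum((y - mean(y))^2)
    expect_equal(cv$r2[i], r2, tolerance = 1e-12)
    expect_equal(cv$pearson[i], stats::cor(p[keep], y), tolerance = 1e-12)
  }
  # noiseless identical subjects give perfect folds
  expect_true(all(cv$r2 > 0.999))
  expect_error(loocv(subs[1:2], fit_fn, pred_fn), "3 subjects")
})
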