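# Least-absolute-deviation (median, tau = 0.5) regression via iteratively
# reweighted least squares. Written here because the environment favours a
# small self-contained solver; converges to the L1 optimum up to `eps`
# smoothing of the weights.
lad_fit <- function(X, y, maxit = 200, eps = 1e-8, tol = 1e-10) {
  X <- as.matrix(X)
  cf <- stats::lm.fit(X, y)$coefficients
  cf[is.na(cf)] <- 0
  for (it in seq_len(maxit)) {
    r <- y - X %*% cf
    w <- 1 / pmax(abs(r), eps)
    fit <- stats::lm.wfit(X, y, as.numeric(w))
    new_cf <- fit$coefficients
    new_cf[is.na(new_cf)] <- 0
    if (max(abs(new_cf - cf)) < tol) {
      cf <- new_cf
      break
    }
    cf <- new_cf
  }
  cf
}

#' Symmetric-pair texture predictors
#'
#' For every pixel, the sum of the raw intensities of each symmetric
#' neighbour pair (one column per parameter slot of the neighbourhood
#' system); off-lattice and masked-out neighbours are dropped from the
#' sums. These are the Markov texture covariates used by the supervised
#' comparators.
#'
#' @param image An [image_grid()].
#' @param neighborhood A [build_neighborhood()] system.
#' @return 3D array `rows x cols x n_slots`.
#' @export
markov_texture <- function(image, neighborhood = build_neighborhood(20)) {
  x <- image$values
  xm <- x
  xm[!image$mask] <- 0
  out <- array(0, c(nrow(x), ncol(x), neighborhood$n_slots))
  for (k in seq_len(neighborhood$n)) {
    s <- neighborhood$slot[k]
    out[, , s] <- out[, , s] +
      shift_matrix(xm, neighborhood$offsets[k, 1], neighborhood$offsets[k, 2])
  }
  out
}

# Assemble the per-pixel training frame for one subject.
segreg_frame <- function(image, labels, response, lesion_mask = NULL,
                         subject = "s1",
                         neighborhood = build_neighborhood(20)) {
  tex <- markov_texture(image, neighborhood)
  bg <- match("BG", labels$label_set)
  use <- image$mask & labels$labels != bg
  lab <- labels$label_set[labels$labels[use]]
  if (!is.null(lesion_mask)) {
    lab[lesion_mask[use]] <- "LESION"
  }
  df <- data.frame(
    label = lab,
    x = image$values[use],
    subject = subject,
    y = response[use],
    stringsAsFactors = FALSE
  )
  for (s in seq_len(dim(tex)[3])) {
    df[[paste0("T", s)]] <- tex[, , s][use]
  }
  df
}

#' Fit a segmentation-regression model
#'
#' Regresses a histology response (myelin or cellularity density) on MRI
#' signal intensity and the symmetric-pair Markov texture covariates,
#' independently for each segmented label. Under the MAE loss each
#' per-label fit is a median (tau = 0.5) regression; under the RMSE loss
#' it is least squares with per-subject intercepts (fixed-effect dummies
#' capturing the subject effect), predictions using the average
#' intercept. Pixels inside a lesion mask form an extra `LESION` label
#' overriding the segmentation. Labels below the pixel floor fall back to
#' the pooled fit with a warning.
#'
#' @param subjects List of per-subject lists with elements `image`
#'   ([image_grid()]), `labels` ([label_field()]), `response` (numeric
#'   matrix) and optional `lesion_mask` (logical matrix).
#' @param loss `"MAE"` (median regression) or `"RMSE"` (least squares).
#' @param min_pixels Per-label training floor (default 30).
#' @param neighborhood A [build_neighborhood()] system.
#' @return Object of class `segreg_model` with per-label coefficient
#'   vectors.
#' @export
fit_segreg <- function(subjects, loss = c("MAE", "RMSE"), min_pixels = 30,
                       neighborhood = build_neighborhood(20)) {
  loss <- match.arg(loss)
  frames <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    segreg_frame(s$image, s$labels, s$response, s$lesion_mask,
                 subject = paste0("s", i), neighborhood = neighborhood)
  })
  df <- do.call(rbind, frames)
  pred_cols <- c("x", grep("^T", names(df), value = TRUE))
  fit_one <- function(sub) {
    X <- cbind(`(Intercept)` = 1, as.matrix(sub[, pred_cols]))
    if (loss == "RMSE" && length(unique(sub$subject)) > 1) {
      sf <- factor(sub$subject)
      D <- stats::model.matrix(~ sf)[, -1, drop = FALSE]
      Xs <- cbind(X, D)
      fit <- stats::lm.fit(Xs, sub$y)
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      subj_eff <- cf[-seq_len(ncol(X))]
      cf <- cf[seq_len(ncol(X))]
      # population-level intercept: average over subjects (baseline = 0)
      cf[1] <- cf[1] + mean(c(0, subj_eff))
      cf
    } else if (loss == "RMSE") {
      cf <- stats::lm.fit(X, sub$y)$coefficients
      cf[is.na(cf)] <- 0
      cf
    } else {
      as.numeric(lad_fit(X, sub$y))
    }
  }
  pooled <- fit_one(df)
  labs <- sort(unique(df$label))
  coefs <- list()
  for (l in labs) {
    sub <- df[df$label == l, , drop = FALSE]
    if (nrow(sub) < min_pixels) {
      warning("label ", l, " has only ", nrow(sub),
              " training pixels; using the pooled fit")
      coefs[[l]] <- pooled
    } else {
      coefs[[l]] <- fit_one(sub)
    }
  }
  structure(list(coefs = coefs, loss = loss, pred_cols = pred_cols,
                 labels = labs, neighborhood = neighborhood),
            class = "segreg_model")
}

#' Predict a response map from a segmentation-regression model
#'
#' Applies each pixel's label-specific coefficients. Lesion-mask pixels
#' use the `LESION` coefficients. Background pixels are excluded (NA).
#'
#' @param model A `segreg_model`.
#' @param image An [image_grid()].
#' @param labels A [label_field()].
#' @param lesion_mask Optional logical matrix.
#' @return Numeric matrix of predictions (NA at BG/off-mask).
#' @export
predict_segreg <- function(model, image, labels, lesion_mask = NULL) {
  tex <- markov_texture(image, model$neighborhood)
  bg <- match("BG", labels$label_set)
  use <- image$mask & labels$labels != bg
  lab <- labels$label_set[labels$labels[use]]
  if (!is.null(lesion_mask)) lab[lesion_mask[use]] <- "LESION"
  unseen <- setdiff(unique(lab), model$labels)
  if (length(unseen) > 0) {
    stop("label(s) absent from training: ", paste(unseen, collapse = ", "))
  }
  X <- cbind(1, image$values[use])
  for (s in seq_len(dim(tex)[3])) X <- cbind(X, tex[, , s][use])
  out <- matrix(NA_real_, nrow(image$values), ncol(image$values))
  pred <- numeric(nrow(X))
  for (l in unique(lab)) {
    rows <- lab == l
    pred[rows] <- X[rows, , drop = FALSE] %*% model$coefs[[l]]
  }
  out[use] <- pred
  out
}

#' Fit an identity-basis additive model
#'
#' The linear member of the additive-model family: least squares (RMSE)
#' or median regression (MAE) of the response on T2 intensity alone
#' (`"markov-"`), intensity plus the symmetric-pair texture covariates
#' (`"markov"`), or additionally a binary lesion dummy with
#' lesion-by-intensity structure (`"markov+"`, where non-lesion terms are
#' gated by `1 - lesion`). Spline bases are out of scope; only the
#' identity basis is implemented.
#'
#' @param image An [image_grid()].
#' @param response Numeric matrix aligned with the image.
#' @param variant `"markov-"`, `"markov"` or `"markov+"`.
#' @param loss `"RMSE"` or `"MAE"`.
#' @param lesion_mask Logical matrix (required for `"markov+"`).
#' @param neighborhood A [build_neighborhood()] system.
#' @return Object of class `additive_model`.
#' @export
fit_additive <- function(image, response,
                         variant = c("markov", "markov-", "markov+"),
                         loss = c("RMSE", "MAE"), lesion_mask = NULL,
                         neighborhood = build_neighborhood(20)) {
  variant <- match.arg(variant)
  loss <- match.arg(loss)
  d <- additive_design(image, variant, lesion_mask, neighborhood)
  y <- response[image$mask]
  qrX <- qr(d$X)
  if (qrX$rank < ncol(d$X)) {
    bad <- colnames(d$X)[qrX$pivot[(qrX$rank + 1):ncol(d$X)]]
    stop("rank-deficient design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  cf <- if (loss == "RMSE") {
    stats::lm.fit(d$X, y)$coefficients
  } else {
    as.numeric(stats::setNames(lad_fit(d$X, y), colnames(d$X)))
  }
  cf[is.na(cf)] <- 0
  names(cf) <- colnames(d$X)
  structure(list(coefficients = cf, variant = variant, loss = loss,
                 neighborhood = neighborhood),
            class = "additive_model")
}

additive_design <- function(image, variant, lesion_mask, neighborhood) {
  use <- image$mask
  x <- image$values[use]
  if (variant == "markov+") {
    if (is.null(lesion_mask)) stop("markov+ requires a lesion mask")
    li <- as.numeric(lesion_mask[use])
    X <- cbind(`(Intercept)` = rep(1, length(x)),
               x_nonlesion = x * (1 - li), x_lesion = x * li)
  } else {
    X <- cbind(`(Intercept)` = rep(1, length(x)), x = x)
  }
  if (variant %in% c("markov", "markov+")) {
    tex <- markov_texture(image, neighborhood)
    for (s in seq_len(dim(tex)[3])) {
      ts <- tex[, , s][use]
      if (variant == "markov+") ts <- ts * (1 - as.numeric(lesion_mask[use]))
      X <- cbind(X, ts)
      colnames(X)[ncol(X)] <- paste0("T", s)
    }
  }
  list(X = X, use = use)
}

#' Predict from an additive model
#'
#' @param object An `additive_model`.
#' @param image An [image_grid()].
#' @param lesion_mask Logical matrix (for `"markov+"` models).
#' @param ... Unused.
#' @return Numeric matrix of predictions (NA off-mask).
#' @export
predict.additive_model <- function(object, image, lesion_mask = NULL, ...) {
  d <- additive_design(image, object$variant, lesion_mask,
                       object$neighborhood)
  out <- matrix(NA_real_, nrow(image$values), ncol(image$values))
  out[d$use] <- d$X %*% object$coefficients
  out
}

#' Leave-one-out cross-validation over subjects
#'
#' For each subject, fits on the remaining subjects and evaluates on the
#' held-out one. Error across folds is summarized by the standard
#' deviation.
#'
#' @param subjects List of per-subject data (passed to `fit_fn` /
#'   `predict_fn`).
#' @param fit_fn `function(train_subjects)` returning a model.
#' @param predict_fn `function(model, subject)` returning a prediction
#'   vector/matrix aligned with `subject$response`.
#' @return Data frame with one row per fold (`r2`, `pearson`,
#'   `residual_cor`) plus attributes `mean` and `sd`.
#' @export
loocv <- function(subjects, fit_fn, predict_fn) {
  n <- length(subjects)
  if (n < 3) stop("leave-one-out needs at least 3 subjects")
  rows <- lapply(seq_len(n), function(i) {
    model <- fit_fn(subjects[-i])
    s <- subjects[[i]]
    pred <- predict_fn(model, s)
    truth <- s$response
    keep <- is.finite(pred) & is.finite(truth)
    p <- pred[keep]
    y <- truth[keep]
    ss_res <- sum((y - p)^2)
    ss_tot <- sum((y - mean(y))^2)
    resid <- y - p
    data.frame(
      fold = i,
      r2 = 1 - ss_res / ss_tot,
      pearson = stats::cor(p, y),
      residual_cor = if (stats::sd(resid) > 0) stats::cor(resid, y) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "mean") <- colMeans(out[, -1], na.rm = TRUE)
  attr(out, "sd") <- apply(out[, -1], 2, stats::sd, na.rm = TRUE)
  out
}
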