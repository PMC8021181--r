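#' Confusion matrix between two label fields
#'
#' Cross-tabulates truth against prediction over included pixels, reports
#' raw counts, per-mille entries (rounded half-up, so the table sums to
#' 1000 up to rounding), overall accuracy and its exact
#' (Clopper-Pearson) 95% binomial confidence interval.
#'
#' @param truth,pred [label_field()]s of the same shape.
#' @param exclude Labels to exclude (default `"BG"`).
#' @return List with `counts`, `permille`, `n`, `accuracy`, `ci`
#'   (class `confusion`).
#' @export
confusion <- function(truth, pred, exclude = "BG") {
  if (!identical(dim(truth$labels), dim(pred$labels))) {
    stop("shape mismatch between truth and prediction")
  }
  tn <- label_names(truth)
  pn <- label_names(pred)
  keep <- !(tn %in% exclude) & !(pn %in% exclude)
  lev <- union(setdiff(truth$label_set, exclude),
               setdiff(pred$label_set, exclude))
  counts <- table(factor(tn[keep], levels = lev),
                  factor(pn[keep], levels = lev))
  counts <- unclass(counts)
  n <- sum(counts)
  if (n == 0) stop("no pixels left after exclusion")
  permille <- round_half_up(1000 * counts / n)
  correct <- sum(diag(counts))
  ci <- stats::binom.test(correct, n)$conf.int
  structure(list(counts = counts, permille = permille, n = n,
                 accuracy = correct / n, ci = as.numeric(ci)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("Confusion matrix (N = %d), accuracy %.1f%% (CI %.1f-%.1f%%)\n",
              x$n, 100 * x$accuracy, 100 * x$ci[1], 100 * x$ci[2]))
  print(x$permille)
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

#' Summary arithmetic on a per-mille confusion matrix
#'
#' Recovers the overall accuracy (diagonal sum / 10, in percent), the
#' per-class composition of the truth (row sums / 10, percent), and the
#' implied counts for a given total, from a confusion matrix expressed in
#' per-mille units (truth in rows, prediction in columns).
#'
#' @param permille Square numeric matrix in per-mille units.
#' @param n Optional total pixel count for implied counts.
#' @return List with `accuracy_pct`, `composition_pct`, and (given `n`)
#'   `counts`.
#' @export
permille_summary <- function(permille, n = NULL) {
  permille <- as.matrix(permille)
  out <- list(
    accuracy_pct = sum(diag(permille)) / 10,
    composition_pct = rowSums(permille) / 10
  )
  if (!is.null(n)) out$counts <- permille * n / 1000
  out
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y Paired numeric values.
#' @param exclude_mask Optional logical; `TRUE` entries are dropped.
#' @param conf.level Confidence level (default 0.95).
#' @return List with `r` and `ci`.
#' @export
pearson_ci <- function(x, y, exclude_mask = NULL, conf.level = 0.95) {
  if (!is.null(exclude_mask)) {
    x <- x[!exclude_mask]
    y <- y[!exclude_mask]
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 4) stop("need at least 4 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the inputs")
  }
  ct <- stats::cor.test(x, y, conf.level = conf.level)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int))
}

#' ROC area under the curve with a DeLong confidence interval
#'
#' AUC via the rank (Mann-Whitney) formulation with midrank ties, and its
#' 95% confidence interval from the DeLong covariance estimator (both
#' through pROC).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param binary_truth Logical or 0/1 vector.
#' @return List with `auc`, `ci` and the underlying `roc` object.
#' @export
roc_auc <- function(scores, binary_truth) {
  truth <- as.integer(as.logical(binary_truth))
  if (length(unique(truth)) < 2) stop("both classes must be present")
  r <- pROC::roc(truth, scores, quiet = TRUE, direction = "<",
                 levels = c(0, 1))
  ci <- pROC::ci.auc(r, method = "delong")
  list(auc = as.numeric(pROC::auc(r)), ci = as.numeric(ci)[c(1, 3)],
       roc = r)
}

#' Compare two paired AUCs with the DeLong test
#'
#' @param scores_a,scores_b Two score vectors on the same cases.
#' @param binary_truth Shared truth vector.
#' @return Two-sided p-value.
#' @export
compare_auc <- function(scores_a, scores_b, binary_truth) {
  truth <- as.integer(as.logical(binary_truth))
  ra <- pROC::roc(truth, scores_a, quiet = TRUE, direction = "<",
                  levels = c(0, 1))
  rb <- pROC::roc(truth, scores_b, quiet = TRUE, direction = "<",
                  levels = c(0, 1))
  as.numeric(pROC::roc.test(ra, rb, method = "delong", paired = TRUE)$p.value)
}

#' Two-sided Mann-Whitney test
#'
#' Exact for small untied samples, normal approximation with tie
#' correction otherwise.
#'
#' @param a,b Numeric samples.
#' @return Two-sided p-value.
#' @export
mannwhitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("samples must be nonempty")
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- !has_ties && length(a) < 50 && length(b) < 50
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  )
}

#' Per-pixel median map across aligned images
#'
#' @param images List of [image_grid()]s with identical shapes.
#' @return An [image_grid()]: per-pixel median, mask = intersection of
#'   masks.
#' @export
cohort_median_map <- function(images) {
  if (length(images) == 0) stop("at least one image is required")
  dims <- lapply(images, function(g) dim(g$values))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("shape mismatch across images")
  }
  vals <- vapply(images, function(g) g$values,
                 matrix(0, nrow(images[[1]]$values), ncol(images[[1]]$values)))
  med <- apply(vals, c(1, 2), stats::median)
  mask <- Reduce(`&`, lapply(images, function(g) g$mask))
  med[!mask] <- 0
  image_grid(med, mask)
}
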