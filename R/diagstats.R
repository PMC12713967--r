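#' Multi-class confusion matrix over index bins
#'
#' Cross-tabulates a reference severity measure (e.g. polysomnographic
#' AHI) against a predicted index (e.g. the respiratory-related
#' heart-rate-acceleration index) over half-open bins `[lo, hi)` defined
#' by `bin_edges`; the first bin is `(-Inf, e1)` and the last is
#' unbounded above. Every pair lands in exactly one cell.
#'
#' @param true_vals reference values, events/h.
#' @param pred_vals predicted values, events/h; same length.
#' @param bin_edges strictly increasing cut points (default
#'   `c(5, 10, 15, 30)`, the conventional AHI severity cuts).
#' @return An object of class `confusion_matrix`: a counts matrix (rows =
#'   true bins, cols = predicted bins) with `bin_edges` attached.
#' @export
bin_confusion <- function(true_vals, pred_vals,
                          bin_edges = c(5, 10, 15, 30)) {
  if (length(true_vals) != length(pred_vals))
    stop("true_vals and pred_vals must have equal length")
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  k <- length(bin_edges) + 1L
  labs <- c(paste0("<", bin_edges[1]),
            if (k > 2) paste0("[", bin_edges[-length(bin_edges)], ",",
                              bin_edges[-1], ")"),
            paste0(">=", bin_edges[length(bin_edges)]))
  bt <- findInterval(true_vals, bin_edges) + 1L
  bp <- findInterval(pred_vals, bin_edges) + 1L
  counts <- matrix(0L, k, k, dimnames = list(true = labs, pred = labs))
  for (i in seq_along(bt)) counts[bt[i], bp[i]] <- counts[bt[i], bp[i]] + 1L
  structure(counts, bin_edges = bin_edges, class = "confusion_matrix")
}

#' Build a confusion matrix from pre-tabulated counts
#'
#' @param counts square integer matrix (rows = true bins, cols = predicted
#'   bins, both ordered by increasing severity).
#' @param bin_edges the cut points separating the bins.
#' @return A `confusion_matrix`.
#' @export
confusion_from_counts <- function(counts, bin_edges) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) ||
      nrow(counts) != length(bin_edges) + 1L)
    stop("counts must be square with length(bin_edges) + 1 bins")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(counts, bin_edges = bin_edges, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> n = %d\n", sum(x)))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Collapse a multi-class confusion matrix to a 2x2 table
#'
#' Dichotomizes at (possibly different) cut points for the reference and
#' the predictor: positive means at or above the cut. Cuts must coincide
#' with bin edges of the matrix so the collapse is a pure cell summation.
#'
#' @param cm a `confusion_matrix`.
#' @param true_cut,pred_cut cut points in events/h.
#' @return A 2x2 integer matrix with rows `true >= cut` / `true < cut` and
#'   columns `pred >= cut` / `pred < cut` (so `[1,1]` = TP, `[1,2]` = FN,
#'   `[2,1]` = FP, `[2,2]` = TN).
#' @export
collapse_confusion <- function(cm, true_cut, pred_cut = true_cut) {
  stopifnot(inherits(cm, "confusion_matrix"))
  edges <- attr(cm, "bin_edges")
  it <- match(true_cut, edges)
  ip <- match(pred_cut, edges)
  if (is.na(it) || is.na(ip))
    stop("cut points must coincide with bin edges (",
         paste(edges, collapse = ", "), ")")
  m <- unclass(cm)
  pos_t <- (it + 1L):nrow(m)   # bins at or above the cut
  neg_t <- 1:it
  pos_p <- (ip + 1L):ncol(m)
  neg_p <- 1:ip
  matrix(c(sum(m[pos_t, pos_p, drop = FALSE]),
           sum(m[neg_t, pos_p, drop = FALSE]),
           sum(m[pos_t, neg_p, drop = FALSE]),
           sum(m[neg_t, neg_p, drop = FALSE])),
         2, 2,
         dimnames = list(true = c(paste0(">=", true_cut),
                                  paste0("<", true_cut)),
                         pred = c(paste0(">=", pred_cut),
                                  paste0("<", pred_cut))))
}

#' Diagnostic statistics of a 2x2 table
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' percent agreement (all as percentages), plus Cohen's kappa computed
#' from the marginals. Ratios with a zero denominator are reported as
#' `NA`, never as 0.
#'
#' @param tab 2x2 matrix as returned by [collapse_confusion()] (`[1,1]` =
#'   TP, `[1,2]` = FN, `[2,1]` = FP, `[2,2]` = TN).
#' @param cutoff_true,cutoff_pred optional cut points recorded in the
#'   report.
#' @return An object of class `diagnostic_report`.
#' @export
diagnostic_stats <- function(tab, cutoff_true = NA_real_,
                             cutoff_pred = NA_real_) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  tp <- tab[1, 1]; fn <- tab[1, 2]; fp <- tab[2, 1]; tn <- tab[2, 2]
  n <- tp + fn + fp + tn
  if (n == 0) stop("empty table")
  ratio <- function(a, b) if (b > 0) 100 * a / b else NA_real_
  p_o <- (tp + tn) / n
  p_e <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else NA_real_
  structure(list(sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 ppv = ratio(tp, tp + fp),
                 npv = ratio(tn, tn + fn),
                 agreement = 100 * p_o,
                 kappa = kappa, n = n,
                 cutoff_true = cutoff_true, cutoff_pred = cutoff_pred,
                 table = tab),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  pct <- function(v) ifelse(is.na(v), "NA", sprintf("%.0f%%", v))
  cat(sprintf("<diagnostic_report> n = %d", x$n))
  if (!is.na(x$cutoff_true))
    cat(sprintf("  (true >= %g, pred >= %g)", x$cutoff_true, x$cutoff_pred))
  cat("\n")
  cat(sprintf("  sensitivity %s  specificity %s  PPV %s  NPV %s\n",
              pct(x$sensitivity), pct(x$specificity), pct(x$ppv),
              pct(x$npv)))
  cat(sprintf("  agreement %s  kappa %.2f\n", pct(x$agreement), x$kappa))
  invisible(x)
}

icc_label <- function(v) {
  if (is.na(v)) NA_character_
  else if (v < 0.5) "poor"
  else if (v < 0.75) "moderate"
  else if (v <= 0.9) "good"
  else "excellent"
}

#' Intraclass correlation (two-way random, absolute agreement, single)
#'
#' ICC(A,1): the agreement form of the intraclass correlation for single
#' measurements under a two-way random-effects model, estimated from the
#' two-way ANOVA mean squares, with the F-distribution 95% confidence
#' interval. Interpretation bands: below 0.50 poor, 0.50-0.75 moderate,
#' 0.75-0.90 good, above 0.90 excellent.
#'
#' @param a,b paired measurements (e.g. an estimated index and the
#'   reference AHI); at least 3 complete pairs.
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `icc`: estimate, `ci` (length 2),
#'   `interpretation`, `n`, and the mean squares.
#' @export
icc_agreement <- function(a, b, conf_level = 0.95) {
  ok <- is.finite(a) & is.finite(b)
  y <- cbind(a[ok], b[ok])
  n <- nrow(y); k <- ncol(y)
  if (n < 3) stop("ICC needs at least 3 complete pairs")
  gm <- mean(y)
  rm_ <- rowMeans(y); cm_ <- colMeans(y)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm_ - gm)^2) / (k - 1)
  mse <- sum((y - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm_) + gm)^2) / ((n - 1) * (k - 1))
  est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  aa <- (k * est) / (n * (1 - est))
  bb <- 1 + (k * est * (n - 1)) / (n * (1 - est))
  v <- (aa * msc + bb * mse)^2 /
    ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
  f1 <- stats::qf(1 - alpha / 2, n - 1, v)
  f2 <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f1 * mse) /
    (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f2 * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  structure(list(estimate = est, ci = c(lo, hi),
                 interpretation = icc_label(est), n = n,
                 ms = c(msr = msr, msc = msc, mse = mse),
                 model = "two-way random, absolute agreement, single (A,1)"),
            class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.2f (95%% CI %.2f-%.2f), n = %d: %s agreement\n",
              x$estimate, x$ci[1], x$ci[2], x$n, x$interpretation))
  invisible(x)
}

#' Bland-Altman analysis
#'
#' Differences are taken as `estimate - reference`, so a negative mean
#' difference means the estimate underestimates the reference. Limits of
#' agreement are `mean +/- 1.96 * SD` of the differences.
#'
#' @param estimate,reference paired measurements, at least 2 pairs.
#' @return An object of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa` (lower, upper), and plot-ready `means` / `diffs`.
#' @export
bland_altman <- function(estimate, reference) {
  ok <- is.finite(estimate) & is.finite(reference)
  e <- estimate[ok]; r <- reference[ok]
  if (length(e) < 2) stop("Bland-Altman needs at least 2 pairs")
  d <- e - r
  m <- mean(d); s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa = c(lower = m - 1.96 * s, upper = m + 1.96 * s),
                 means = (e + r) / 2, diffs = d, n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.2f (SD %.2f), LoA %.2f to %.2f, n = %d\n",
              x$mean_diff, x$sd_diff, x$loa[1], x$loa[2], x$n))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, xlab = "mean of pair",
                 ylab = "difference (estimate - reference)", ...)
  graphics::abline(h = c(x$mean_diff, x$loa), lty = c(1, 2, 2),
                   col = c("blue", "red", "red"))
  invisible(x)
}

#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' The AUC is computed from midranks, which handles ties and equals the
#' trapezoidal area under the empirical ROC curve over all thresholds.
#' Curve points (FPR, TPR) are returned for plotting.
#'
#' @param scores numeric predictor values (higher = more likely positive).
#' @param labels binary labels (0/1 or logical); both classes required.
#' @return An object of class `roc_curve`: `auc`, `fpr`, `tpr`,
#'   `thresholds`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0,
                numeric(1))
  structure(list(auc = auc, fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                 thresholds = c(Inf, thr, -Inf), n_pos = n1, n_neg = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "1 - specificity",
                 ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

cor_label <- function(v) {
  av <- abs(v)
  if (is.na(av)) NA_character_
  else if (av < 0.10) "negligible"
  else if (av < 0.40) "weak"
  else if (av < 0.70) "moderate"
  else if (av < 0.90) "strong"
  else "very strong"
}

#' Correlation between an index and the reference, optionally adjusted
#'
#' Pearson or Spearman correlation with an asymptotic two-sided p-value.
#' When covariates are supplied the partial correlation is computed by
#' residualising both variables on the covariates with a linear model
#' (for Spearman, ranks are taken first, then residualised), and the
#' p-value uses the partial-correlation t statistic with
#' `n - 2 - n_covariates` degrees of freedom. Interpretation bands:
#' below 0.10 negligible, 0.10-0.39 weak, 0.40-0.69 moderate, 0.70-0.89
#' strong, 0.90-1.0 very strong.
#'
#' @param x,y numeric vectors of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @param adjust_for optional data.frame of covariates (e.g. age, BMI,
#'   sex); must be complete where supplied.
#' @return A list with `estimate`, `p_value`, `method`, `adjusted`,
#'   `interpretation`, `n`.
#' @export
cor_assoc <- function(x, y, method = c("pearson", "spearman"),
                      adjust_for = NULL) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  if (is.null(adjust_for)) {
    ct <- stats::cor.test(x, y, method = method, exact = FALSE)
    est <- unname(ct$estimate)
    return(list(estimate = est, p_value = ct$p.value, method = method,
                adjusted = FALSE, interpretation = cor_label(est),
                n = length(x)))
  }
  covs <- as.data.frame(adjust_for)
  if (nrow(covs) != length(x)) stop("covariates must match x in length")
  if (anyNA(covs)) stop("covariates must be complete")
  mm <- stats::model.matrix(~ ., data = covs)
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
    num <- vapply(covs, is.numeric, logical(1))
    covs[num] <- lapply(covs[num], rank)
    mm <- stats::model.matrix(~ ., data = covs)
  }
  rx <- stats::lm.fit(mm, x)$residuals
  ry <- stats::lm.fit(mm, y)$residuals
  est <- stats::cor(rx, ry)
  k <- ncol(mm) - 1L
  df <- length(x) - 2L - k
  tval <- est * sqrt(df / (1 - est^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(estimate = est, p_value = p, method = method, adjusted = TRUE,
       interpretation = cor_label(est), n = length(x))
}
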