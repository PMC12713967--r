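test_that("binning is half-open and conserves every pair", {
  cm <- bin_confusion(c(3, 7), c(2, 6), bin_edges = c(5, 10, 15, 30))
  expect_equal(unname(diag(unclass(cm))), c(1, 1, 0, 0, 0))
  expect_equal(sum(bin_confusion(numeric(0), numeric(0))), 0)
  # boundary values fall in the upper bin
  cm2 <- bin_confusion(c(5, 10, 30), c(4.999, 15, 100))
  m <- unclass(cm2)
  expect_equal(m[2, 1], 1)  # true 5 -> [5,10), pred 4.999 -> <5
  expect_equal(m[3, 4], 1)
  expect_equal(m[5, 5], 1)
  set.seed(30)
  tv <- rexp(653, 1 / 20)
  pv <- pmax(0, tv + rnorm(653, 0, 8))
  expect_equal(sum(bin_confusion(tv, pv)), 653)
  expect_error(bin_confusion(1:3, 1:2), "equal length")
  expect_error(bin_confusion(1:3, 1:3, bin_edges = c(10, 5)),
               "strictly increasing")
})

test_that("collapsing sums cells exactly and conserves margins", {
  cm <- validation_confusion()
  t2 <- collapse_confusion(cm, 10, 5)
  expect_equal(unname(as.vector(t2)), c(410, 28, 60, 155))
  expect_equal(sum(t2), 653)
  # collapse at extreme edges conserves row/column sums
  lo <- collapse_confusion(cm, 5, 5)
  hi <- collapse_confusion(cm, 30, 30)
  expect_equal(sum(lo), sum(hi))
  expect_equal(sum(lo[1, ]), sum(unclass(cm)[2:5, ]))
  expect_equal(sum(hi[1, ]), sum(unclass(cm)[5, ]))
  expect_error(collapse_confusion(cm, 12, 5), "bin edges")
  # identity on a 2-bin matrix
  cm2 <- confusion_from_counts(matrix(c(7, 2, 1, 9), 2), bin_edges = 5)
  expect_equal(unname(as.vector(collapse_confusion(cm2, 5, 5))),
               c(9, 1, 2, 7))  # reordered to TP, FP, FN, TN
})

test_that("diagnostic metrics match the defining formulas", {
  perfect <- matrix(c(50, 0, 0, 50), 2)
  r <- diagnostic_stats(perfect)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_equal(r$agreement, 100)
  expect_equal(r$kappa, 1)
  # random tables vs hand formulas
  set.seed(31)
  for (i in 1:50) {
    cells <- rmultinom(1, 200, runif(4, 0.05, 1))
    tp <- cells[1]; fn <- cells[2]; fp <- cells[3]; tn <- cells[4]
    r2 <- diagnostic_stats(matrix(c(tp, fp, fn, tn), 2))
    expect_equal(r2$sensitivity,
                 if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_)
    expect_equal(r2$ppv,
                 if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_)
    expect_equal(r2$agreement, 100 * (tp + tn) / 200)
    po <- (tp + tn) / 200
    pe <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / 200^2
    expect_equal(r2$kappa, (po - pe) / (1 - pe))
  }
  # zero denominators give NA, not 0
  r3 <- diagnostic_stats(matrix(c(0, 0, 5, 15), 2))  # no predicted positives
  expect_true(is.na(r3$ppv))
  expect_equal(r3$sensitivity, 0)
  # kappa = 0 for independent marginals
  r4 <- diagnostic_stats(matrix(c(40, 40, 10, 10), 2))
  expect_equal(r4$kappa, 0)
  expect_error(diagnostic_stats(matrix(0, 2, 2)), "empty")
})

test_that("ICC(A,1) matches an external reference and degenerate cases", {
  a <- c(10.2, 4.1, 7.7, 15.0, 2.3, 9.9, 12.5, 6.8)
  b <- c(11.0, 3.5, 8.2, 14.1, 3.0, 9.1, 13.9, 6.0)
  r <- icc_agreement(a, b)
  # frozen reference values (pingouin ICC(A,1) on the same pairs)
  expect_equal(r$estimate, 0.979922, tolerance = 1e-5)
  expect_equal(unname(r$ci), c(0.9033, 0.9960), tolerance = 1e-3)
  expect_equal(r$interpretation, "excellent")
  # identical pairs with between-subject variance -> ICC 1
  x <- c(1, 5, 9, 13)
  expect_equal(icc_agreement(x, x)$estimate, 1)
  # independent pairs -> near 0
  set.seed(32)
  expect_lt(abs(icc_agreement(rnorm(500), rnorm(500))$estimate), 0.1)
  expect_error(icc_agreement(1:2, 1:2), "at least 3")
  expect_equal(icc_agreement(c(1, 2, 3), c(1.4, 2.4, 3.4))$interpretation,
               icc_label(icc_agreement(c(1, 2, 3),
                                       c(1.4, 2.4, 3.4))$estimate))
})

test_that("ICC recovers the simulated agreement across its range", {
  set.seed(33)
  for (rho in c(0.2, 0.5, 0.8)) {
    subj <- rnorm(1000, 0, sqrt(rho))
    a <- subj + rnorm(1000, 0, sqrt(1 - rho))
    b <- subj + rnorm(1000, 0, sqrt(1 - rho))
    expect_lt(abs(icc_agreement(a, b)$estimate - rho), 0.05)
  }
})

test_that("Bland-Altman mean, SD and limits follow the definition", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(unname(ba0$loa), c(0, 0))
  ba1 <- bland_altman(c(4, 5, 6), c(1, 2, 3))
  expect_equal(ba1$mean_diff, 3)
  expect_equal(ba1$sd_diff, 0)
  set.seed(34)
  e <- rnorm(200, 10, 2); r <- rnorm(200, 10, 2)
  ba2 <- bland_altman(e, r)
  expect_equal(ba2$mean_diff, mean(e - r))
  expect_equal(unname(ba2$loa),
               mean(e - r) + c(-1.96, 1.96) * sd(e - r))
  expect_equal(ba2$diffs, e - r)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("rank AUC handles separation, ties and cross-checks with pROC", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(1, 1, 2, 2), c(0, 1, 0, 1))$auc, 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  # invariance under strictly monotone score transforms
  set.seed(35)
  sc <- rnorm(300); lab <- rbinom(300, 1, plogis(sc))
  expect_equal(roc_auc(sc, lab)$auc, roc_auc(exp(sc), lab)$auc)
  expect_equal(roc_auc(sc, lab)$auc, roc_auc(rank(sc), lab)$auc)
  skip_if_not_installed("pROC")
  p <- pROC::roc(lab, sc, quiet = TRUE, direction = "<")
  expect_equal(roc_auc(sc, lab)$auc, as.numeric(pROC::auc(p)))
})

test_that("correlations follow rank logic and adjustment removes confounding", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(cor_assoc(x, x, "pearson")$estimate, 1)
  expect_equal(cor_assoc(x, x, "spearman")$estimate, 1)
  # monotone nonlinear: Spearman 1, Pearson < 1
  y <- x^3
  expect_equal(cor_assoc(x, y, "spearman")$estimate, 1)
  expect_lt(cor_assoc(x, y, "pearson")$estimate, 1)
  expect_error(cor_assoc(rep(1, 5), x), "zero variance")
  # pure confounding: unadjusted correlation vanishes after adjustment
  set.seed(36)
  z <- rnorm(400)
  a <- 2 * z + rnorm(400, 0, 0.5)
  b <- -1.5 * z + rnorm(400, 0, 0.5)
  un <- cor_assoc(a, b, "pearson")
  ad <- cor_assoc(a, b, "pearson", adjust_for = data.frame(z = z))
  expect_gt(abs(un$estimate), 0.5)
  expect_lt(abs(ad$estimate), 0.15)
  ads <- cor_assoc(a, b, "spearman", adjust_for = data.frame(z = z))
  expect_lt(abs(ads$estimate), 0.15)
  # factor covariates are accepted (sex-style adjustment)
  sex <- sample(c("male", "female"), 400, replace = TRUE)
  adf <- cor_assoc(a, b, "pearson",
                   adjust_for = data.frame(z = z, sex = sex))
  expect_true(is.finite(adf$p_value))
  expect_equal(cor_assoc(x, c(1.2, 1.9, 3.3, 3.9, 5.1),
                         "pearson")$interpretation, "very strong")
})
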