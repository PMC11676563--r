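test_that("micro AUROC matches hand-computed pooled examples", {
  # pos {0.9, 0.4}, neg {0.6, 0.2}: 3 of 4 pairs correctly ordered
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE)),
               0.75)
  expect_equal(auroc(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(rep(0.3, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)),
               0.5)
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "degenerate")
  # micro pooling flattens the visit x label matrix
  s <- matrix(c(0.9, 0.1, 0.4, 0.8), 2, 2)
  y <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  expect_equal(micro_auroc(s, y), auroc(as.numeric(s), as.logical(y)))
})

test_that("rank-based AUROC equals the brute-force pairwise oracle", {
  set.seed(19)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(auroc(scores, labels), o_auroc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("cv_bootstrap yields the expected matrix for plug-in scorers", {
  set.seed(5)
  y <- cbind(ahf = runif(120) < 0.3, ecopd = runif(120) < 0.25,
             pneumonia = runif(120) < 0.25, other = FALSE)
  y[, "other"] <- rowSums(y[, 1:3]) == 0
  perfect <- function(tr, te) (y[te, , drop = FALSE]) * 1
  constant <- function(tr, te) matrix(0.5, length(te), 4)
  m1 <- cv_bootstrap(y, perfect, seed = 3)
  expect_equal(dim(m1), c(10L, 10L))
  expect_true(all(m1 == 1))
  m2 <- cv_bootstrap(y, constant, seed = 3)
  expect_true(all(m2 == 0.5))
})

test_that("with boots = 1 and frac = 1 cv_bootstrap is plain k-fold CV", {
  set.seed(6)
  y <- cbind(a = runif(80) < 0.4, b = runif(80) < 0.3,
             c = runif(80) < 0.3, d = runif(80) < 0.5)
  scores <- matrix(runif(320), 80, 4)
  fit <- function(tr, te) scores[te, , drop = FALSE]
  m <- cv_bootstrap(y, fit, folds = 5, boots = 1, frac = 1, seed = 9)
  folds <- attr(m, "fold_idx")
  direct <- vapply(folds, function(idx)
    micro_auroc(scores[idx, , drop = FALSE], y[idx, , drop = FALSE]),
    numeric(1))
  expect_equal(as.numeric(m), direct)
  # the folds partition the cohort and are label-pattern stratified
  expect_equal(sort(unlist(folds)), 1:80)
})

test_that("resampling draws exactly 90% without replacement by default", {
  y <- cbind(a = rep(c(TRUE, FALSE), 50), b = TRUE & FALSE,
             c = rep(c(TRUE, FALSE), each = 50), d = TRUE)
  y[, "b"] <- rep(c(TRUE, FALSE), length.out = 100)
  seen <- new.env()
  fit <- function(tr, te) {
    assign("te_len", length(te), envir = seen)
    matrix(runif(length(te) * 4), ncol = 4)
  }
  m <- cv_bootstrap(y, fit, folds = 5, boots = 3, frac = 0.9, seed = 2)
  expect_equal(dim(m), c(5L, 3L))
  expect_true(all(is.finite(m)))
})

test_that("summaries are the median and interpolated 2.5/97.5 percentiles", {
  m <- matrix(c(rep(0.8, 50), rep(0.9, 50)), 10, 10)
  s <- summarize_auroc(m)
  expect_equal(s, c(median = 0.85, p2.5 = 0.8, p97.5 = 0.9))
  expect_equal(summarize_auroc(matrix(0.7)), c(median = 0.7, p2.5 = 0.7,
                                               p97.5 = 0.7))
  set.seed(13)
  x <- matrix(runif(100), 10, 10)
  s2 <- summarize_auroc(x)
  expect_equal(s2[["p2.5"]], o_percentile(as.numeric(x), 0.025))
  expect_equal(s2[["p97.5"]], o_percentile(as.numeric(x), 0.975))
  expect_equal(summarize_auroc(matrix(c(0.6, NaN), 1, 2)),
               c(median = 0.6, p2.5 = 0.6, p97.5 = 0.6))
  expect_error(summarize_auroc(matrix(NaN, 2, 2)), "NaN")
})

test_that("sens_at_spec returns the best point above the floor", {
  # separable scores: perfect operating point
  s <- sens_at_spec(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(s), c(1, 1, 0.5))
  # all scores equal: only sensitivity 0 at specificity 1 clears 0.75
  expect_equal(sens_at_spec(rep(0.4, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE,
                                           FALSE))[["sensitivity"]], 0)
  expect_equal(sens_at_spec(rep(0.4, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE,
                                           FALSE))[["specificity"]], 1)
  # impossible floor triggers the degenerate branch with a warning
  expect_warning(
    out <- sens_at_spec(c(0.5, 0.6), c(FALSE, TRUE), floor = 1),
    "specificity")
  expect_equal(unname(out), c(0, 1, Inf))
})

test_that("sens_at_spec agrees with exhaustive confusion-table enumeration", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(6:14, 1)
    scores <- round(runif(n), 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    got <- suppressWarnings(sens_at_spec(scores, labels, floor = 0.75))
    want <- o_sens_at_spec(scores, labels, floor = 0.75)
    expect_equal(got[["sensitivity"]], want[["sensitivity"]])
    if (is.finite(want[["threshold"]])) {
      expect_gt(got[["specificity"]], 0.75)
    }
  }
})

test_that("the per-label operating-point table covers all four labels", {
  set.seed(29)
  y <- cbind(ahf = runif(60) < 0.3, ecopd = runif(60) < 0.3,
             pneumonia = runif(60) < 0.3, other = runif(60) < 0.5)
  s <- matrix(runif(240), 60, 4, dimnames = list(NULL, colnames(y)))
  tab <- suppressWarnings(sens_spec_table(s, y))
  expect_equal(tab$label, label_levels())
  expect_true(all(tab$specificity > 0.75 | tab$sensitivity == 0))
})

test_that("subgroup performance reflects planted heterogeneity", {
  set.seed(31)
  n <- 400
  young <- rep(c(TRUE, FALSE), each = n / 2)
  y <- matrix(runif(4 * n) < 0.3, n, 4)
  scores <- matrix(runif(4 * n), n, 4)
  # signal only in the young subgroup
  scores[young, ] <- scores[young, ] + y[young, ] * 2
  rep_ <- subgroup_report(scores, y, ifelse(young, "<=75", ">75"), boots = 50)
  a_young <- rep_$auroc[rep_$group == "<=75"]
  a_old <- rep_$auroc[rep_$group == ">75"]
  expect_gt(a_young, 0.95)
  expect_lt(abs(a_old - 0.5), 0.07)
  expect_gt(a_young, a_old)
  # degenerate group (single pooled class) gives a NaN row
  y2 <- matrix(TRUE, 10, 4)
  rep2 <- subgroup_report(matrix(runif(40), 10, 4), y2,
                          rep("g", 10), boots = 5)
  expect_true(is.nan(rep2$auroc))
})
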