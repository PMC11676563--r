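# Evaluation protocol: micro-averaged AUROC over pooled (visit, label)
# pairs, 10-fold cross-validation with 10 bootstrap evaluations per fold,
# median (2.5-97.5 percentile) summaries, sensitivity at a specificity
# floor, and subgroup breakdowns.

#' Binary AUROC (Mann-Whitney form)
#'
#' `P(score_pos > score_neg) + 0.5 * P(tie)` computed from midranks.
#'
#' @param scores Numeric vector.
#' @param labels Logical/0-1 vector.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("degenerate labels: need at least one positive and one negative",
         call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties with the 1/2 convention
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Micro-averaged AUROC over the pooled (visit, label) pairs
#'
#' All visit-label score/truth pairs across the four labels are pooled into
#' one binary problem, weighting every visit equally.
#'
#' @param scores Numeric matrix, visits x labels.
#' @param labels Logical matrix of the same shape.
#' @return Micro AUROC.
#' @export
micro_auroc <- function(scores, labels) {
  stopifnot(identical(dim(scores), dim(labels)))
  auroc(as.numeric(scores), as.logical(labels))
}

#' Cross-validation with bootstrapped evaluations
#'
#' Splits the visits into `folds` folds stratified by label pattern; for each
#' fold the model is fitted on the remaining folds via `fit_score`, then
#' `boots` evaluations are performed, each on a random `frac` share of the
#' held-out fold, yielding a folds x boots matrix of micro AUROC values.
#' `resample = "subsample"` (default) draws the 90% evaluation subset without
#' replacement, i.e. exactly 90% of the evaluation set is used;
#' `"bootstrap"` draws with replacement to the same size.  A resample whose
#' pooled pairs lack one class is recorded as NaN with a warning.
#'
#' @param labels Logical matrix, visits x 4.
#' @param fit_score `function(train_idx, test_idx)` returning a
#'   `length(test_idx) x 4` score matrix for the held-out visits.
#' @param folds,boots Number of folds and bootstrap evaluations (default 10).
#' @param frac Share of the evaluation fold per bootstrap (default 0.9).
#' @param seed RNG seed controlling fold assignment and resampling.
#' @param resample Subsampling scheme, see above.
#' @return `folds x boots` numeric matrix of micro AUROC values, with the
#'   per-fold test indices attached as attribute `"fold_idx"`.
#' @export
cv_bootstrap <- function(labels, fit_score, folds = 10, boots = 10,
                         frac = 0.9, seed = 1,
                         resample = c("subsample", "bootstrap")) {
  resample <- match.arg(resample)
  n <- nrow(labels)
  stopifnot(n >= folds)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)

  # stratified fold assignment: deal each label pattern round-robin
  pattern <- apply(labels, 1, paste, collapse = "")
  fold_of <- integer(n)
  offset <- 0L
  for (pt in sort(unique(pattern))) {
    idx <- sample(which(pattern == pt))
    fold_of[idx] <- ((seq_along(idx) + offset - 1L) %% folds) + 1L
    offset <- offset + length(idx)
  }

  mat <- matrix(NA_real_, folds, boots)
  fold_idx <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_idx <- which(fold_of == f)
    fold_idx[[f]] <- test_idx
    scores <- fit_score(which(fold_of != f), test_idx)
    stopifnot(nrow(scores) == length(test_idx), ncol(scores) == ncol(labels))
    m <- length(test_idx)
    for (b in seq_len(boots)) {
      take <- sample.int(m, size = max(1L, floor(frac * m)),
                         replace = resample == "bootstrap")
      val <- tryCatch(
        micro_auroc(scores[take, , drop = FALSE],
                    labels[test_idx[take], , drop = FALSE]),
        error = function(e) {
          warning(sprintf("fold %d bootstrap %d: %s", f, b, conditionMessage(e)),
                  call. = FALSE)
          NaN
        })
      mat[f, b] <- val
    }
  }
  attr(mat, "fold_idx") <- fold_idx
  mat
}

#' Median and 2.5/97.5 percentiles of an AUROC matrix
#'
#' @param mat Numeric matrix (NaN entries from degenerate bootstraps are
#'   ignored).
#' @return Named numeric vector `c(median=, p2.5=, p97.5=)`, using linear
#'   interpolation for the percentiles.
#' @export
summarize_auroc <- function(mat) {
  vals <- mat[is.finite(mat)]
  if (length(vals) == 0) stop("all entries are NaN", call. = FALSE)
  q <- quantile(vals, c(0.025, 0.975), type = 7, names = FALSE)
  c(median = median(vals), p2.5 = q[1], p97.5 = q[2])
}

#' Maximum sensitivity at a specificity floor
#'
#' Scans every achievable operating point (thresholds at midpoints between
#' adjacent distinct scores, plus below-minimum and above-maximum); among
#' points with specificity strictly above `floor`, returns the one with the
#' highest sensitivity, breaking ties towards the lowest threshold.  If no
#' point clears the floor, returns sensitivity 0 at specificity 1 with an
#' infinite threshold and a warning.
#'
#' @param scores Numeric vector; a visit is called positive when its score
#'   exceeds the threshold.
#' @param labels Logical/0-1 vector with both classes present.
#' @param floor Specificity floor (default 0.75).
#' @return Named numeric vector `c(sensitivity=, specificity=, threshold=)`.
#' @export
sens_at_spec <- function(scores, labels, floor = 0.75) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  stopifnot(n_pos > 0, n_neg > 0)
  u <- sort(unique(scores))
  thr <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
           u[length(u)] + 1)
  sens <- vapply(thr, function(t) sum(scores > t & labels) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(scores <= t & !labels) / n_neg,
                 numeric(1))
  ok <- spec > floor
  if (!any(ok)) {
    warning(sprintf("no operating point with specificity > %g", floor),
            call. = FALSE)
    return(c(sensitivity = 0, specificity = 1, threshold = Inf))
  }
  best <- which(ok)[which.max(sens[ok])]  # which.max ties -> first = lowest thr
  c(sensitivity = sens[best], specificity = spec[best], threshold = thr[best])
}

#' Per-label sensitivity/specificity table
#'
#' Applies [sens_at_spec()] to each label column, mirroring the per-diagnosis
#' operating-point report.
#'
#' @param scores,labels Visit x label matrices.
#' @param floor Specificity floor.
#' @return data.frame with one row per label.
#' @export
sens_spec_table <- function(scores, labels, floor = 0.75) {
  out <- t(vapply(seq_len(ncol(scores)), function(j)
    sens_at_spec(scores[, j], labels[, j], floor), numeric(3)))
  data.frame(label = colnames(labels), out, row.names = NULL)
}

#' Subgroup micro AUROC report
#'
#' Computes micro AUROC within each subgroup of visits, with a bootstrap
#' percentile interval over visits.
#'
#' @param scores,labels Visit x label matrices.
#' @param groups Factor (or coercible) of length `nrow(scores)`.
#' @param boots Bootstrap resamples for the interval (default 200).
#' @param seed RNG seed.
#' @return data.frame with group, n, auroc, p2.5, p97.5 (NaN rows for groups
#'   where the AUROC is undefined).
#' @export
subgroup_report <- function(scores, labels, groups, boots = 200, seed = 1) {
  groups <- as.factor(groups)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  rows <- lapply(levels(groups), function(g) {
    idx <- which(groups == g)
    a <- tryCatch(micro_auroc(scores[idx, , drop = FALSE],
                              labels[idx, , drop = FALSE]),
                  error = function(e) NaN)
    if (is.nan(a)) {
      return(data.frame(group = g, n = length(idx), auroc = NaN,
                        p2.5 = NaN, p97.5 = NaN))
    }
    bs <- vapply(seq_len(boots), function(b) {
      take <- sample(idx, length(idx), replace = TRUE)
      tryCatch(micro_auroc(scores[take, , drop = FALSE],
                           labels[take, , drop = FALSE]),
               error = function(e) NaN)
    }, numeric(1))
    q <- quantile(bs[is.finite(bs)], c(0.025, 0.975), names = FALSE)
    data.frame(group = g, n = length(idx), auroc = a, p2.5 = q[1], p97.5 = q[2])
  })
  do.call(rbind, rows)
}
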