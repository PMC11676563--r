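# Expert-feature baseline: nine clinically chosen variables, iterative
# random-forest imputation of missing numerics, and one-vs-rest gradient
# boosted trees scored through the same evaluation pipeline as the network.

.icd_from_dx <- function(codes) sub("^DX:", "", codes)

#' Extract the nine expert baseline features
#'
#' Age, sex, a diagnosis of heart failure / COPD / pneumonia registered
#' anywhere in the health system within five years before the index visit, a
#' diagnosis of AHF / eCOPD / pneumonia registered at an ED within one year
#' before the index visit, and the triage temperature at the index visit
#' (missing allowed).  History flags use the same ICD-10 prefix rules as the
#' label mapping, applied to `DX:`-prefixed event codes.
#'
#' @param events Event table.
#' @param visits Index-visit table (needs `onsite_age`, `onsite_sex`,
#'   `onsite_temp`).
#' @return data.frame with `visit_id` plus the nine features.
#' @export
extract_features <- function(events, visits) {
  n <- nrow(visits)
  ev <- data.table::as.data.table(events)
  ev <- ev[startsWith(ev$code, "DX:") & ev$visit_id %in% visits$visit_id]
  vidx <- match(ev$visit_id, visits$visit_id)
  age_s <- as.numeric(visits$index_time)[vidx] - as.numeric(ev$event_time)
  icd <- toupper(gsub(".", "", .icd_from_dx(ev$code), fixed = TRUE))

  in_set <- function(prefixes) {
    Reduce(`|`, lapply(prefixes, function(p) startsWith(icd, p)))
  }
  flag <- function(sel) {
    out <- logical(n)
    out[unique(vidx[sel])] <- TRUE
    out
  }
  y5 <- 5 * 365.25 * 86400
  y1 <- 365.25 * 86400
  is_hf <- in_set(.icd10_ahf_prefixes)
  is_copd <- in_set(.icd10_ecopd_prefixes)
  is_pneu <- in_set(.icd10_pneu_prefixes)
  if (nrow(ev) == 0) is_hf <- is_copd <- is_pneu <- logical(0)
  at_ed <- ev$context == "ED"

  data.frame(
    visit_id = visits$visit_id,
    age = visits$onsite_age,
    sex = visits$onsite_sex,
    hist_hf_5y = flag(is_hf & age_s < y5),
    hist_copd_5y = flag(is_copd & age_s < y5),
    hist_pneu_5y = flag(is_pneu & age_s < y5),
    ed_ahf_1y = flag(is_hf & at_ed & age_s < y1),
    ed_ecopd_1y = flag(is_copd & at_ed & age_s < y1),
    ed_pneu_1y = flag(is_pneu & at_ed & age_s < y1),
    temperature = visits$onsite_temp)
}

#' Iterative random-forest imputation
#'
#' MissForest-style scheme: columns are initialized by mean (continuous) or
#' mode (categorical/logical) fill, then repeatedly each missing-bearing
#' column is regressed on all others with a random forest (fitted on its
#' originally observed rows) and its missing entries replaced by the
#' predictions, until the normalized change in the imputed values increases
#' or `max_iter` is reached; the result from the last improving iteration is
#' returned.  Deterministic under a fixed seed.
#'
#' @param table data.frame with numeric and/or logical columns; no column may
#'   be entirely missing.
#' @param max_iter Maximum sweeps (default 10).
#' @param num_trees Trees per forest (default 100).
#' @param seed RNG seed.
#' @return The completed data.frame.
#' @export
impute_missforest <- function(table, max_iter = 10, num_trees = 100,
                              seed = 1) {
  stopifnot(is.data.frame(table))
  miss <- vapply(table, function(x) sum(is.na(x)), numeric(1))
  if (any(miss == nrow(table))) {
    stop("column entirely missing: ",
         names(table)[miss == nrow(table)][1], call. = FALSE)
  }
  if (all(miss == 0)) return(table)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)

  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  obs_mask <- lapply(table, function(x) !is.na(x))
  filled <- table
  for (cl in names(table)) {
    x <- filled[[cl]]
    if (!anyNA(x)) next
    fill <- if (is.numeric(x)) mean(x, na.rm = TRUE) else {
      ux <- x[!is.na(x)]
      names(sort(table(ux), decreasing = TRUE))[1]
    }
    x[is.na(x)] <- fill
    filled[[cl]] <- x
  }

  targets <- names(miss)[miss > 0][order(miss[miss > 0])]
  prev_diff <- Inf
  best <- filled
  for (it in seq_len(max_iter)) {
    old <- filled
    for (cl in targets) {
      obs <- obs_mask[[cl]]
      dat <- filled
      dat[[cl]] <- table[[cl]]  # original values where observed
      fml <- stats::as.formula(paste0("`", cl, "` ~ ."))
      fit <- ranger::ranger(fml, data = dat[obs, , drop = FALSE],
                            num.trees = num_trees, seed = seed + it,
                            num.threads = 1)
      pred <- predict(fit, data = filled[!obs, , drop = FALSE],
                      num.threads = 1)$predictions
      x <- filled[[cl]]
      x[!obs] <- pred
      filled[[cl]] <- x
    }
    # normalized change in imputed values (continuous columns)
    num_t <- intersect(targets, num_cols)
    if (length(num_t)) {
      dnum <- sum(vapply(num_t, function(cl)
        sum((filled[[cl]] - old[[cl]])^2), numeric(1))) /
        max(sum(vapply(num_t, function(cl) sum(filled[[cl]]^2), numeric(1))),
            .Machine$double.eps)
    } else {
      dnum <- mean(vapply(targets, function(cl)
        mean(filled[[cl]] != old[[cl]]), numeric(1)))
    }
    if (dnum >= prev_diff) return(best)  # stop when the change increases
    prev_diff <- dnum
    best <- filled
  }
  best
}

#' Train the boosted-tree baseline
#'
#' One-vs-rest gradient boosted trees (logistic objective) per label over the
#' nine expert features.
#'
#' @param features data.frame from [extract_features()] (after imputation;
#'   the `visit_id` column is ignored).
#' @param labels Logical matrix, visits x 4.
#' @param nrounds,max_depth,eta Booster settings (defaults 200, 6, 0.1).
#' @param seed RNG seed.
#' @return A `carenet_baseline` object (list of per-label boosters).
#' @export
train_baseline <- function(features, labels, nrounds = 200, max_depth = 6,
                           eta = 0.1, seed = 1) {
  X <- .baseline_matrix(features)
  stopifnot(nrow(X) == nrow(labels))
  models <- lapply(seq_len(ncol(labels)), function(j) {
    yj <- as.numeric(labels[, j])
    if (length(unique(yj)) < 2) {
      stop("single-class label: ", colnames(labels)[j], call. = FALSE)
    }
    dtrain <- xgboost::xgb.DMatrix(X, label = yj, nthread = 1)
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1, seed = seed + j),
      data = dtrain, nrounds = nrounds, verbose = 0)
  })
  structure(list(models = models, feature_names = colnames(X)),
            class = "carenet_baseline")
}

#' Score visits with the baseline
#' @param model A `carenet_baseline`.
#' @param features Feature data.frame.
#' @return Probability matrix, visits x 4.
#' @export
predict_baseline <- function(model, features) {
  X <- .baseline_matrix(features)
  dX <- xgboost::xgb.DMatrix(X, nthread = 1)
  out <- vapply(model$models, function(m) predict(m, dX),
                numeric(nrow(X)))
  colnames(out) <- label_levels()
  out
}

.baseline_matrix <- function(features) {
  f <- features[, setdiff(names(features), "visit_id"), drop = FALSE]
  X <- as.matrix(data.frame(lapply(f, as.numeric)))
  storage.mode(X) <- "double"
  X
}
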