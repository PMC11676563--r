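# Synthetic EHR cohort generator.
#
# Emulates the statistical structure the network assumes: per-visit event
# streams spread over the pre-index window across six care contexts, with
# label-dependent "signal" codes emitted at an elevated rate, label-shifted
# vital signs, onsite triage variables with missingness, and multilabel
# ICD-10 outcomes at realistic prevalences.  Ground truth (planted codes and
# exact posterior logits under the generative model) is returned so recovery
# and ceiling tests are possible.

#' Simulation configuration
#'
#' Defaults reflect the cohort the model targets: label prevalences
#' 15.5/14.0/13.3% for AHF/eCOPD/pneumonia, a log-normal events-per-visit
#' distribution with median 352 and IQR 134--838 over a one-year window
#' (counts are capped at 2,000, keeping visits in the 10^0--10^3 events
#' range), 2% missingness for onsite vitals, and no label noise.  Each of the
#' four labels (including "other") owns `k_signal` disjoint signal codes
#' whose emission rate is multiplied by `exp(gamma)` when the label is
#' active; each signal code also has a "home" care context it prefers, so
#' that context-level attention is testable.
#'
#' @param n_visits Number of index visits to simulate.
#' @param vocab_size Number of background event codes V (default 200).
#' @param k_signal Signal codes per label (default 5; `4 * k_signal <= V`).
#' @param gamma Signal log-rate effect (default 1.5).
#' @param prevalence Base prevalences of the three disease labels.
#' @param events_meanlog,events_sdlog,events_cap Log-normal event-count
#'   distribution (median 352, IQR 134--838) and per-visit cap.
#' @param context_probs Background context mixture over [context_levels()].
#' @param home_context_prob Probability a signal-code occurrence is emitted
#'   in its home context instead of a background draw.
#' @param missing_rate Missingness rate for onsite vitals (default 0.02,
#'   matching the ~2% missing triage temperature).
#' @param label_noise Symmetric label-flip probability eta (default 0;
#'   0--0.07 emulates the 1.9--6.6% pre-adjudication label inaccuracy).
#' @param signal_mode `"codes"` plants signal in event-code rates (default);
#'   `"history"` makes labels depend only on prior-diagnosis history flags
#'   (and vitals stay label-shifted), the regime where the expert-feature
#'   baseline has all the signal.
#' @param history_prevalence,history_tpr History-mode parameters: prevalence
#'   of each disease history flag, and the share of label probability carried
#'   by the flag (P(history | label), the sensitivity of the flag as a
#'   predictor); P(label | history) is derived per label so the configured
#'   prevalences are preserved.
#' @param vitals_per_visit Mean number of historical measurements per vital.
#' @param vital_effect Multiplier on the label-dependent vital-sign mean
#'   shifts (1 = default effect sizes, 0 = vitals carry no label signal).
#' @param window_weeks,n_periods Timeline settings (see [timeline_config()]).
#' @param seed RNG seed; a fixed seed reproduces the cohort exactly.
#' @return A `carenet_simconfig` list.
#' @export
sim_config <- function(n_visits = 2000,
                       vocab_size = 200,
                       k_signal = 5,
                       gamma = 1.5,
                       prevalence = c(ahf = 0.155, ecopd = 0.140,
                                      pneumonia = 0.133),
                       events_meanlog = log(352),
                       events_sdlog = log(838 / 134) / (2 * stats::qnorm(0.75)),
                       events_cap = 2000,
                       context_probs = c(PRIMARY_CARE = 0.30,
                                         OUTPATIENT_SPECIALIST = 0.15,
                                         ED = 0.10, INPATIENT = 0.10,
                                         AMBULATORY = 0.05, OTHERS = 0.30),
                       home_context_prob = 0.7,
                       missing_rate = 0.02,
                       label_noise = 0,
                       signal_mode = c("codes", "history"),
                       history_prevalence = 0.15,
                       history_tpr = 0.9,
                       vitals_per_visit = 3,
                       vital_effect = 1,
                       window_weeks = 52,
                       n_periods = 10,
                       seed = 1) {
  signal_mode <- match.arg(signal_mode)
  stopifnot(all(prevalence > 0), all(prevalence < 1),
            length(prevalence) == 3, n_visits >= 0)
  if (4 * k_signal > vocab_size) {
    stop("infeasible config: 4 * k_signal exceeds vocab_size", call. = FALSE)
  }
  stopifnot(label_noise >= 0, label_noise < 0.5)
  if (signal_mode == "history" &&
      (history_tpr >= 1 ||
       any(history_tpr * prevalence / history_prevalence >= 1))) {
    stop("infeasible history-mode config", call. = FALSE)
  }
  structure(
    c(as.list(environment())),
    class = "carenet_simconfig"
  )
}

# Vital-sign model: population mean/sd and additive shifts under the three
# disease labels (AHF raises pulse and lowers systolic BP; eCOPD raises
# breathing frequency and lowers saturation; pneumonia raises temperature).
.vital_model <- function() {
  list(
    codes = default_numeric_vars(),  # SBP, PULSE, TEMP, SPO2, RESP
    mean = c(135, 85, 36.9, 95, 18),
    sd = c(18, 14, 0.6, 3.2, 4),
    shift = rbind(  # rows: ahf, ecopd, pneumonia
      c(-8, 12, 0.0, 0.0, 0),
      c(0, 0, 0.0, -3.0, 4),
      c(0, 0, 0.9, 0.0, 0))
  )
}

.dx_codes <- function() c(ahf = "DX:I50.9", ecopd = "DX:J44.9",
                          pneumonia = "DX:J18.9")

.main_dx_pool <- function() {
  list(ahf = c("I50.9", "I50.0", "I11.0"),
       ecopd = c("J44.0", "J44.1"),
       pneumonia = c("J18.9", "J15.9", "J12.8"),
       other = c("R06.0", "J45.9", "I48.9", "I26.9", "R07.4"))
}

#' Generate a synthetic cohort
#'
#' Draws labels from their prevalences, event counts from the capped
#' log-normal, then emits each visit's event stream: background codes
#' uniformly, signal codes of active labels at `exp(gamma)` times the
#' background rate (preferring their home context), prior-diagnosis history
#' events, and vital-sign measurements whose means shift with the labels.
#' Onsite triage variables are drawn last, with missingness.  Main-diagnosis
#' ICD-10 codes are emitted to match the (optionally noise-flipped) labels so
#' the full label-mapping pipeline applies.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional directory; if given, writes `events.tsv`,
#'   `visits.tsv` and `ground_truth.json` there.
#' @return List with `events`, `visits` (data.tables in the interchange
#'   layout) and `truth` (planted signal codes, observed labels, exact
#'   posterior logits under the generative model).
#' @export
generate_cohort <- function(cfg = sim_config(), out_dir = NULL) {
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)

  n <- cfg$n_visits
  V <- cfg$vocab_size
  k <- cfg$k_signal
  ctxs <- context_levels()
  vm <- .vital_model()
  labs4 <- label_levels()

  bg_codes <- sprintf("EV:%04d", seq_len(V))
  sig_idx <- matrix(sample.int(V, 4 * k), nrow = k)  # columns: ahf ecopd pneu other
  colnames(sig_idx) <- labs4
  home_pairs <- list(ahf = c("PRIMARY_CARE", "OTHERS"),
                     ecopd = c("OTHERS", "PRIMARY_CARE"),
                     pneumonia = c("ED", "INPATIENT"),
                     other = c("OUTPATIENT_SPECIALIST", "PRIMARY_CARE"))
  # per background code: signal label (0 = background) and home context
  code_label <- integer(V)
  code_home <- integer(V)
  for (j in seq_len(4)) {
    code_label[sig_idx[, j]] <- j
    code_home[sig_idx[, j]] <- match(home_pairs[[j]][(seq_len(k) %% 2) + 1L], ctxs)
  }

  index_time <- as.POSIXct("2019-06-01 12:00:00", tz = "UTC") +
    (seq_len(max(n, 1)) - 1) * 3600
  window_s <- cfg$window_weeks * 7 * 86400

  # --- labels ---------------------------------------------------------------
  if (cfg$signal_mode == "history") {
    hist_flags <- matrix(rbinom(n * 3, 1, cfg$history_prevalence), n, 3)
    p1 <- cfg$history_tpr * cfg$prevalence / cfg$history_prevalence
    p0 <- (1 - cfg$history_tpr) * cfg$prevalence /
      (1 - cfg$history_prevalence)
    pl <- sweep(hist_flags, 2, p1, `*`) + sweep(1 - hist_flags, 2, p0, `*`)
    y3 <- matrix(rbinom(n * 3, 1, pl), n, 3)
  } else {
    hist_flags <- matrix(rbinom(n * 3, 1, 0.10), n, 3)
    y3 <- matrix(rbinom(n * 3, 1, rep(cfg$prevalence, each = n)), n, 3)
  }
  colnames(y3) <- labs4[1:3]
  y_true <- cbind(y3, other = as.integer(rowSums(y3) == 0))

  flip <- matrix(rbinom(n * 3, 1, cfg$label_noise), n, 3)
  y3_obs <- (y3 + flip) %% 2
  y_obs <- cbind(y3_obs, other = as.integer(rowSums(y3_obs) == 0))
  colnames(y_obs) <- labs4

  # --- event counts and background/signal codes -----------------------------
  N <- pmin(pmax(round(rlnorm(n, cfg$events_meanlog, cfg$events_sdlog)), 1),
            cfg$events_cap)
  if (n == 0) N <- integer()
  gam_eff <- if (cfg$signal_mode == "codes") cfg$gamma else 0
  combo <- y_true[, 1] * 4 + y_true[, 2] * 2 + y_true[, 3] + 1  # 1..8 (other implied)

  ev_code_i <- integer(sum(N))
  ev_visit <- rep(seq_len(max(n, 1))[seq_len(n)], N)
  pos <- split(seq_len(sum(N)), factor(ev_visit[seq_len(sum(N))],
                                       levels = seq_len(n)))
  for (cb in sort(unique(combo))) {
    vis <- which(combo == cb)
    act <- c(as.integer(intToBits(cb - 1))[3:1], 0)
    act[4] <- as.integer(sum(act[1:3]) == 0)  # other active iff no disease
    w <- rep(1, V)
    for (j in which(act == 1)) w[sig_idx[, j]] <- exp(gam_eff)
    idx <- unlist(pos[vis], use.names = FALSE)
    if (length(idx)) {
      ev_code_i[idx] <- sample.int(V, length(idx), replace = TRUE,
                                   prob = w / sum(w))
    }
  }

  ev_ctx <- sample(ctxs, sum(N), replace = TRUE, prob = cfg$context_probs)
  is_sig <- code_label[ev_code_i] > 0
  take_home <- is_sig & runif(sum(N)) < cfg$home_context_prob
  ev_ctx[take_home] <- ctxs[code_home[ev_code_i[take_home]]]
  ev_age <- runif(sum(N), 1, window_s - 1)

  events <- data.table::data.table(
    patient_id = sprintf("P%05d", ev_visit),
    visit_id = sprintf("V%05d", ev_visit),
    event_time = index_time[ev_visit] - ev_age,
    context = ev_ctx,
    code = bg_codes[ev_code_i],
    value_class = NA_character_,
    numeric_value = NA_real_)

  # --- history-diagnosis events ---------------------------------------------
  dx <- .dx_codes()
  hrows <- list()
  for (j in 1:3) {
    vis <- which(hist_flags[, j] == 1)
    cnt <- 1L + rpois(length(vis), 0.5)
    vv <- rep(vis, cnt)
    if (length(vv)) {
      hrows[[j]] <- data.table::data.table(
        patient_id = sprintf("P%05d", vv),
        visit_id = sprintf("V%05d", vv),
        event_time = index_time[vv] - runif(length(vv), 1, window_s - 1),
        context = sample(c("PRIMARY_CARE", "ED", "INPATIENT"), length(vv),
                         replace = TRUE, prob = c(0.5, 0.3, 0.2)),
        code = dx[j],
        value_class = NA_character_,
        numeric_value = NA_real_)
    }
  }

  # --- vital-sign measurement events ----------------------------------------
  shift_mat <- cfg$vital_effect * (y3 %*% vm$shift)  # n x 5 mean shifts
  vrows <- list()
  for (v in seq_along(vm$codes)) {
    cnt <- rpois(n, cfg$vitals_per_visit)
    vv <- rep(seq_len(n), cnt)
    if (length(vv)) {
      vrows[[v]] <- data.table::data.table(
        patient_id = sprintf("P%05d", vv),
        visit_id = sprintf("V%05d", vv),
        event_time = index_time[vv] - runif(length(vv), 1, window_s - 1),
        context = sample(c("PRIMARY_CARE", "ED", "INPATIENT", "AMBULATORY"),
                         length(vv), replace = TRUE),
        code = vm$codes[v],
        value_class = NA_character_,
        numeric_value = round(rnorm(length(vv), vm$mean[v] + shift_mat[vv, v],
                                    vm$sd[v]), 1))
    }
  }

  events <- data.table::rbindlist(c(list(events), hrows, vrows))
  events[, event_time := as.POSIXct(round(as.numeric(event_time)),
                                    origin = "1970-01-01", tz = "UTC")]

  # --- onsite variables and main diagnoses ----------------------------------
  onsite_vitals <- matrix(rnorm(n * 5, rep(vm$mean, each = n) +
                                  shift_mat, rep(vm$sd, each = n)), n, 5)
  onsite_vitals <- round(onsite_vitals, 1)
  miss <- matrix(runif(n * 5) < cfg$missing_rate, n, 5)
  onsite_vitals[miss] <- NA

  pool <- .main_dx_pool()
  main_dx <- vapply(seq_len(n), function(i) {
    act <- labs4[1:3][y3_obs[i, ] == 1]
    if (length(act) == 0) {
      sample(pool$other, 1)
    } else {
      paste(vapply(act, function(l) sample(pool[[l]], 1), character(1)),
            collapse = ";")
    }
  }, character(1))

  visits <- data.table::data.table(
    visit_id = sprintf("V%05d", seq_len(n)),
    patient_id = sprintf("P%05d", seq_len(n)),
    index_time = index_time[seq_len(n)],
    main_dx_codes = main_dx,
    onsite_hospital = sample(1:2, n, TRUE),
    onsite_ambulance = rbinom(n, 1, 0.5),
    onsite_arrival_hour = sample(0:23, n, TRUE),
    onsite_arrival_day = sample(1:7, n, TRUE),
    onsite_arrival_week = sample(1:52, n, TRUE),
    onsite_ed_occupancy = rpois(n, 25),
    onsite_triage_priority = sample(1:5, n, TRUE,
                                    prob = c(0.06, 0.49, 0.38, 0.06, 0.01)),
    onsite_age = pmin(pmax(round(rnorm(n, 72, 13)), 18), 100),
    onsite_sex = rbinom(n, 1, 0.5),
    onsite_sbp = onsite_vitals[, 1],
    onsite_pulse = onsite_vitals[, 2],
    onsite_temp = onsite_vitals[, 3],
    onsite_spo2 = onsite_vitals[, 4],
    onsite_resp = onsite_vitals[, 5])

  truth <- list(
    signal_codes = setNames(lapply(seq_len(4), function(j) bg_codes[sig_idx[, j]]),
                            labs4),
    home_contexts = home_pairs,
    gamma = gam_eff,
    labels = y_obs == 1,
    labels_latent = y_true == 1,
    config = cfg)
  truth$logits <- .posterior_logits(events, visits, truth, onsite_vitals,
                                    hist_flags)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_events(events, file.path(out_dir, "events.tsv"))
    write_visits(visits, file.path(out_dir, "visits.tsv"))
    jsonlite::write_json(
      list(signal_codes = truth$signal_codes, gamma = truth$gamma,
           labels = truth$labels, logits = truth$logits),
      file.path(out_dir, "ground_truth.json"), digits = NA)
  }
  list(events = events, visits = visits, truth = truth)
}

# Exact per-visit posterior logits of the four labels under the generative
# model: combines the label prior (or history-conditional prior), the
# multinomial code-rate likelihood over the 8 disease-label combinations, and
# the Gaussian vital-sign likelihoods.  These logits are the information
# ceiling: no classifier can beat them in expectation.
.posterior_logits <- function(events, visits, truth, onsite_vitals,
                              hist_flags) {
  cfg <- truth$config
  n <- nrow(visits)
  if (n == 0) {
    return(matrix(numeric(), 0, 4, dimnames = list(NULL, label_levels())))
  }
  vm <- .vital_model()
  k <- cfg$k_signal
  V <- cfg$vocab_size
  eg <- exp(truth$gamma)

  combos <- as.matrix(expand.grid(ahf = 0:1, ecopd = 0:1, pneumonia = 0:1))
  other_c <- as.integer(rowSums(combos) == 0)

  vidx <- match(events$visit_id, visits$visit_id)
  is_bg <- startsWith(events$code, "EV:")
  # signal-code counts per visit per label, and total background-stream count
  n_sig <- matrix(0, n, 4)
  for (j in seq_len(4)) {
    m <- is_bg & events$code %in% truth$signal_codes[[j]]
    n_sig[, j] <- tabulate(vidx[m], nbins = n)
  }
  n_tot <- tabulate(vidx[is_bg], nbins = n)

  # Gaussian vital log-likelihood per visit per combo, expressed as a ratio
  # against the shift-free case so combos with identical shifts are exactly
  # tied (no spurious float noise enters the posterior)
  vit_ll <- matrix(0, n, 8)
  is_vit <- events$code %in% vm$codes
  vit_var <- match(events$code[is_vit], vm$codes)
  vit_vis <- vidx[is_vit]
  vit_val <- events$numeric_value[is_vit]
  for (cc in seq_len(8)) {
    shift <- cfg$vital_effect * as.numeric(combos[cc, ] %*% vm$shift)
    if (all(shift == 0)) next
    ll <- dnorm(vit_val, vm$mean[vit_var] + shift[vit_var],
                vm$sd[vit_var], log = TRUE) -
      dnorm(vit_val, vm$mean[vit_var], vm$sd[vit_var], log = TRUE)
    acc <- rep(0, n)
    if (length(ll)) {
      s <- rowsum(ll, group = vit_vis)
      acc[as.integer(rownames(s))] <- s[, 1]
    }
    for (v in which(shift != 0)) {
      obs <- which(!is.na(onsite_vitals[, v]))
      acc[obs] <- acc[obs] +
        dnorm(onsite_vitals[obs, v], vm$mean[v] + shift[v], vm$sd[v],
              log = TRUE) -
        dnorm(onsite_vitals[obs, v], vm$mean[v], vm$sd[v], log = TRUE)
    }
    vit_ll[, cc] <- acc
  }

  # prior per visit per combo
  prior_ll <- matrix(0, n, 8)
  for (cc in seq_len(8)) {
    if (cfg$signal_mode == "history") {
      p1 <- cfg$history_tpr * cfg$prevalence / cfg$history_prevalence
      p0 <- (1 - cfg$history_tpr) * cfg$prevalence /
        (1 - cfg$history_prevalence)
      pv <- sweep(hist_flags, 2, p1, `*`) + sweep(1 - hist_flags, 2, p0, `*`)
      prior_ll[, cc] <- rowSums(log(pv) %*% diag(combos[cc, ]) +
                                  log(1 - pv) %*% diag(1 - combos[cc, ]))
    } else {
      prior_ll[, cc] <- sum(combos[cc, ] * log(cfg$prevalence) +
                              (1 - combos[cc, ]) * log(1 - cfg$prevalence))
    }
  }

  # code-rate likelihood per combo, centered on the first combo so that
  # visit-level constants cancel exactly rather than in floating point
  code_ll <- matrix(0, n, 8)
  logZ <- vapply(seq_len(8), function(cc) {
    act <- c(combos[cc, ], other_c[cc])
    log(V + (eg - 1) * k * sum(act))
  }, numeric(1))
  for (cc in seq_len(8)) {
    act <- c(combos[cc, ], other_c[cc])
    code_ll[, cc] <- truth$gamma * (n_sig %*% act) -
      n_tot * (logZ[cc] - logZ[1])
  }

  lp <- prior_ll + code_ll + vit_ll
  lp <- lp - apply(lp, 1, max)
  post <- exp(lp) / rowSums(exp(lp))

  p4 <- cbind(post %*% combos, other = post[, other_c == 1])
  eta <- cfg$label_noise
  if (eta > 0) {
    p3 <- p4[, 1:3] * (1 - eta) + (1 - p4[, 1:3]) * eta
    # other = no flipped disease label; average over combos
    p_oth <- as.numeric(post %*% apply(combos, 1, function(y)
      prod(y * eta + (1 - y) * (1 - eta))))
    p4 <- cbind(p3, other = p_oth)
  }
  p4 <- pmin(pmax(p4, 1e-12), 1 - 1e-12)
  logits <- qlogis(p4)
  colnames(logits) <- label_levels()
  logits
}

#' AUROC ceiling from the generative ground truth
#'
#' Scores the exact posterior logits recorded at generation time against the
#' realized labels.  No classifier trained on the same inputs can exceed this
#' in expectation, so it bounds what any model can achieve on the cohort.
#'
#' @param truth `truth` element from [generate_cohort()].
#' @param labels Optional logical label matrix (defaults to the cohort's
#'   observed labels).
#' @param idx Optional visit subset (e.g. a held-out test set).
#' @return List with `per_label` (named numeric, 4) and `micro` AUROC.
#' @export
bayes_oracle_auc <- function(truth, labels = truth$labels, idx = NULL) {
  logits <- truth$logits
  if (!is.null(idx)) {
    logits <- logits[idx, , drop = FALSE]
    labels <- labels[idx, , drop = FALSE]
  }
  per <- vapply(seq_len(4), function(j) auroc(logits[, j], labels[, j]),
                numeric(1))
  names(per) <- label_levels()
  list(per_label = per, micro = micro_auroc(logits, labels))
}
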