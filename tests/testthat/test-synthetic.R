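test_that("the same seed reproduces the cohort exactly; a new seed does not", {
  a <- tiny_cohort(n = 15, seed = 21)
  b <- tiny_cohort(n = 15, seed = 21)
  expect_identical(a$events, b$events)
  expect_identical(a$visits, b$visits)
  expect_identical(a$truth$logits, b$truth$logits)
  c <- tiny_cohort(n = 15, seed = 22)
  expect_false(identical(a$events, c$events))
})

test_that("written cohort files are byte-identical across same-seed runs", {
  d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
  generate_cohort(sim_config(n_visits = 6, seed = 9,
                             events_meanlog = log(20), events_sdlog = 0.4),
                  out_dir = d1)
  generate_cohort(sim_config(n_visits = 6, seed = 9,
                             events_meanlog = log(20), events_sdlog = 0.4),
                  out_dir = d2)
  for (f in c("events.tsv", "visits.tsv", "ground_truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("n_visits = 0 yields schema-valid empty files", {
  d <- file.path(tempdir(), "sim0")
  co <- generate_cohort(sim_config(n_visits = 0), out_dir = d)
  expect_equal(nrow(co$events), 0)
  expect_equal(nrow(co$visits), 0)
  ev <- read_events(file.path(d, "events.tsv"))
  vi <- read_visits(file.path(d, "visits.tsv"))
  expect_equal(nrow(ev), 0)
  expect_equal(nrow(vi), 0)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(vocab_size = 10, k_signal = 5), "infeasible")
  expect_error(sim_config(prevalence = c(0.5, 0.5, 1.5)))
})

test_that("label prevalence matches the configured rates", {
  # event-stream settings do not affect label draws, so a light stream
  # keeps this cheap at n = 10,000
  co <- generate_cohort(sim_config(n_visits = 10000, seed = 31,
                                   events_meanlog = log(3),
                                   events_sdlog = 0.2, vitals_per_visit = 0))
  prev <- colMeans(co$truth$labels)
  expect_lt(abs(prev[["ahf"]] - 0.155), 0.015)
  expect_lt(abs(prev[["ecopd"]] - 0.140), 0.015)
  expect_lt(abs(prev[["pneumonia"]] - 0.133), 0.015)
  # "other" completes the label set: true iff no disease label
  expect_equal(co$truth$labels[, "other"],
               rowSums(co$truth$labels[, 1:3]) == 0,
               ignore_attr = TRUE)
  # every visit's main_dx codes reproduce its labels through the mapper
  m <- label_matrix(co$visits$main_dx_codes)
  expect_equal(unname(m), unname(co$truth$labels))
})

test_that("event counts have the configured median and stay in 1..cap", {
  co <- generate_cohort(sim_config(n_visits = 800, seed = 13,
                                   vitals_per_visit = 0))
  ev <- co$events[startsWith(co$events$code, "EV:")]
  n_ev <- as.numeric(table(factor(ev$visit_id,
                                  levels = co$visits$visit_id)))
  expect_gte(min(n_ev), 0)
  expect_lte(max(n_ev), 2000)
  expect_gt(median(n_ev), 300)
  expect_lt(median(n_ev), 420)
})

test_that("every planted signal code is enriched among its label positives", {
  co <- generate_cohort(sim_config(n_visits = 5000, seed = 17,
                                   vitals_per_visit = 1))
  ev <- co$events[startsWith(co$events$code, "EV:")]
  vidx <- match(ev$visit_id, co$visits$visit_id)
  n_stream <- tabulate(vidx, nbins = 5000)
  wins <- 0L
  for (lab in label_levels()) {
    pos <- co$truth$labels[, lab]
    for (code in co$truth$signal_codes[[lab]]) {
      cnt <- tabulate(vidx[ev$code == code], nbins = 5000)
      rate_pos <- sum(cnt[pos]) / sum(n_stream[pos])
      rate_neg <- sum(cnt[!pos]) / sum(n_stream[!pos])
      wins <- wins + (rate_pos > rate_neg)
    }
  }
  expect_equal(wins, 20L)  # sign test: P(20/20 | p=0.5) = 2^-20 << 0.01
})

test_that("signal codes prefer their home contexts", {
  co <- generate_cohort(sim_config(n_visits = 400, seed = 23,
                                   vitals_per_visit = 0))
  sig_code <- co$truth$signal_codes$pneumonia[1]
  homes <- co$truth$home_contexts$pneumonia
  ctx <- co$events$context[co$events$code == sig_code]
  expect_gt(length(ctx), 50)
  expect_gt(mean(ctx %in% homes), 0.5)
})

test_that("the oracle ceiling reacts to signal strength as expected", {
  # no code signal, no vital signal: the posterior collapses to the label
  # priors, so per-label discrimination is exactly chance
  co0 <- generate_cohort(sim_config(n_visits = 5000, gamma = 0,
                                    vital_effect = 0, seed = 29,
                                    events_meanlog = log(30),
                                    events_sdlog = 0.5,
                                    vitals_per_visit = 1))
  per <- bayes_oracle_auc(co0$truth)$per_label
  expect_true(all(abs(per - 0.5) < 0.02))
  # overwhelming signal: near-perfect separation per label
  co1 <- generate_cohort(sim_config(n_visits = 400, gamma = 8, seed = 29,
                                    events_meanlog = log(30),
                                    events_sdlog = 0.5))
  expect_true(all(bayes_oracle_auc(co1$truth)$per_label > 0.98))
})

test_that("label noise flips labels at the configured rate", {
  co <- generate_cohort(sim_config(n_visits = 4000, label_noise = 0.05,
                                   seed = 37, events_meanlog = log(5),
                                   events_sdlog = 0.2, vitals_per_visit = 0))
  flips <- mean(co$truth$labels[, 1:3] != co$truth$labels_latent[, 1:3])
  expect_gt(flips, 0.03)
  expect_lt(flips, 0.07)
})
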