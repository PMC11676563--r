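# Shared fixture builders: tiny cohorts, tiny models, hand-made bundles.

tiny_cohort <- function(n = 40, seed = 11, ...) {
  generate_cohort(sim_config(
    n_visits = n, seed = seed,
    events_meanlog = log(40), events_sdlog = 0.6, ...))
}

cohort_vocab <- function(cohort, min_count = 5) {
  build_vocabulary(
    cohort$events$code[!cohort$events$code %in% default_numeric_vars()],
    min_count = min_count)
}

tiny_model <- function(vocab, bundle, d = 4, H = 3, seed = 5, ...) {
  carenet_init(vocab, n_period_numeric = ncol(bundle$period_numeric),
               n_onsite = length(bundle$onsite),
               carenet_config(embed_dim = d, hidden = H, att_dim = 2 * H,
                              ff_dim = 6, ...),
               seed = seed)
}

# hand-made bundle: tokens is a list of M lists of 6 integer vectors
manual_bundle <- function(tokens, P = 2, Q = 3,
                          labels = c(ahf = TRUE, ecopd = FALSE,
                                     pneumonia = FALSE, other = FALSE),
                          period_numeric = NULL, onsite = NULL) {
  M <- length(tokens)
  structure(list(
    visit_id = "T1",
    tokens = tokens,
    period_numeric = period_numeric %||%
      matrix(0, M, P),
    period_mask = matrix(0, M, P),
    onsite = onsite %||% rep(0, Q),
    onsite_mask = rep(1, Q),
    labels = labels,
    n_periods = M, n_contexts = 6L), class = "carenet_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_tokens <- function(M) {
  lapply(seq_len(M), function(p) lapply(1:6, function(cc) integer()))
}
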