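# Skip-gram pretraining of event-code embeddings over per-patient
# chronological event sequences.

#' Build the pretraining corpus
#'
#' One token-id sequence per patient, covering the patient's whole
#' observation window in chronological order (ties broken by code string, the
#' same canonical order used in the visit tensors), so the result is
#' invariant to input row order.  Continuous-variable measurement events are
#' excluded, matching their exclusion from the token cells.
#'
#' @param events Event table ([read_events()] layout).
#' @param vocab Vocabulary from [build_vocabulary()].
#' @param numeric_vars Codes handled as continuous variables, not tokens.
#' @return Named list of integer vectors (0-based token ids), one per patient.
#' @export
build_corpus <- function(events, vocab,
                         numeric_vars = default_numeric_vars()) {
  ev <- data.table::as.data.table(events)
  ev <- ev[!ev$code %in% numeric_vars]
  data.table::setorder(ev, patient_id, event_time, code)
  split(vocab_id(vocab, ev$code), ev$patient_id)
}

#' Pretrain skip-gram embeddings
#'
#' Standard skip-gram with negative sampling (unigram^0.75 noise
#' distribution, per-position reduced window) run single-threaded, so results
#' are identical under a fixed seed.  Input rows are initialized
#' random-normal (sd 0.1); codes absent from the corpus keep that
#' initialization, and the EMPTY row (id 0) never occurs in a corpus and
#' stays zero.
#'
#' @param corpus From [build_corpus()].
#' @param vocab The matching vocabulary (defines the table height).
#' @param d Embedding dimension (default 16).
#' @param window Maximum context window (default 5).
#' @param negatives Negative samples per positive pair (default 5).
#' @param epochs Passes over the corpus (default 3).
#' @param lr SGD learning rate (default 0.025).
#' @param seed RNG seed.
#' @return Numeric matrix `vocab$size x d`, rows ordered by token id.
#' @export
train_skipgram <- function(corpus, vocab, d = 16, window = 5, negatives = 5,
                           epochs = 3, lr = 0.025, seed = 1) {
  stopifnot(d > 0, length(corpus) > 0)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  V <- vocab$size
  Win <- matrix(rnorm(V * d, sd = 0.1), V, d)
  Win[1, ] <- 0  # EMPTY
  Wout <- matrix(0, V, d)
  .sg_train_cpp(lapply(corpus, as.integer), Win, Wout,
                as.integer(window), as.integer(negatives),
                as.integer(epochs), lr, as.integer(seed))
}

#' Cosine similarity between embedding rows
#' @param emb Embedding matrix.
#' @param i,j Row indices (1-based).
#' @return Cosine similarity.
#' @export
embedding_cosine <- function(emb, i, j) {
  a <- emb[i, ]; b <- emb[j, ]
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
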