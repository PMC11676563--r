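# Model-level R surface over the compiled core: configuration, parameter
# initialization, forward pass with captured attention state, the evidential
# loss, training and prediction, and checkpointing.

#' Network configuration
#'
#' Desk-scale defaults chosen for CPU training: 16-dimensional embeddings and
#' GRU hidden states, attention dimension 2H, a 32-unit feed-forward head,
#' Adam with batch size 32 for 20 epochs, and the KL annealing weight ramping
#' linearly to 1 over the first 10 epochs.  All are configurable for larger
#' runs.
#'
#' @param embed_dim Token embedding dimension d.
#' @param hidden GRU hidden size H (bidirectional output is 2H).
#' @param att_dim Attention projection dimension (default `2 * hidden`).
#' @param ff_dim Feed-forward head width.
#' @param lr,batch,epochs Adam learning rate, mini-batch size, epochs.
#' @param anneal_epochs Epochs over which the evidential KL weight ramps to 1.
#' @param sg_window,sg_negatives,sg_epochs,sg_lr Skip-gram pretraining
#'   settings.
#' @return A `carenet_config` list.
#' @export
carenet_config <- function(embed_dim = 16, hidden = 16, att_dim = 2 * hidden,
                           ff_dim = 32, lr = 3e-3, batch = 32, epochs = 20,
                           anneal_epochs = 10, sg_window = 5,
                           sg_negatives = 5, sg_epochs = 3, sg_lr = 0.025) {
  structure(as.list(environment()), class = "carenet_config")
}

.init_mat <- function(nr, nc, fan_in = nc) {
  matrix(rnorm(nr * nc, sd = 1 / sqrt(max(fan_in, 1))), nr, nc)
}

.init_gru <- function(H, in_dim) {
  list(W = .init_mat(3 * H, in_dim), U = .init_mat(3 * H, H, H),
       b = rep(0, 3 * H))
}

.init_att <- function(A, in_dim) {
  list(W = .init_mat(A, in_dim), b = rep(0, A),
       q = rnorm(A, sd = 1 / sqrt(A)))
}

#' Initialize a network
#'
#' @param vocab Vocabulary the event-token ids refer to.
#' @param n_period_numeric Number of continuous per-period variables P.
#' @param n_onsite Number of onsite variables Q.
#' @param cfg A [carenet_config()].
#' @param embeddings Optional pretrained embedding matrix (vocab size x d,
#'   e.g. from [train_skipgram()]); falls back to random-normal init
#'   (sd 0.1) with the EMPTY row pinned at zero.
#' @param seed RNG seed for the initialization.
#' @return A `carenet_model` object.
#' @export
carenet_init <- function(vocab, n_period_numeric, n_onsite,
                         cfg = carenet_config(), embeddings = NULL,
                         seed = 1) {
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  V <- vocab$size
  d <- cfg$embed_dim; H <- cfg$hidden; A <- cfg$att_dim; Fd <- cfg$ff_dim
  P <- n_period_numeric; Q <- n_onsite
  if (is.null(embeddings)) {
    embeddings <- matrix(rnorm(V * d, sd = 0.1), V, d)
    embeddings[1, ] <- 0  # EMPTY
  }
  stopifnot(nrow(embeddings) == V, ncol(embeddings) == d)
  g1 <- function() .init_gru(H, d)
  g2 <- function() .init_gru(H, 2 * H)
  g3 <- function() .init_gru(H, 2 * H + 2 * P)
  params <- c(
    list(E = embeddings, empty_ctx = matrix(rnorm(2 * H * 6, sd = 0.1),
                                            2 * H, 6)),
    setNames(unlist(lapply(list(g1(), g1(), g2(), g2(), g3(), g3()),
                           identity), recursive = FALSE),
             as.vector(t(outer(c("g1f", "g1b", "g2f", "g2b", "g3f", "g3b"),
                               c("W", "U", "b"), paste, sep = "_")))),
    setNames(unlist(lapply(1:3, function(i)
      .init_att(A, 2 * H)), recursive = FALSE),
      as.vector(t(outer(c("a1", "a2", "a3"), c("W", "b", "q"),
                        paste, sep = "_")))),
    list(ffW1 = .init_mat(Fd, 2 * H + 2 * Q), ffb1 = rep(0, Fd),
         ffW2 = .init_mat(8, Fd), ffb2 = rep(0, 8))
  )
  structure(
    list(params = params, cfg = cfg, vocab = vocab,
         dims = list(V = V, d = d, H = H, A = A, P = P, Q = Q, F = Fd),
         log = NULL),
    class = "carenet_model")
}

#' @export
print.carenet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    "<carenet_model> d=%d H=%d | P=%d per-period + Q=%d onsite numerics | %s parameters%s\n",
    x$dims$d, x$dims$H, x$dims$P, x$dims$Q, format(np, big.mark = ","),
    if (is.null(x$log)) " (untrained)" else
      sprintf(" | trained %d epochs, final loss %.4f",
              nrow(x$log), x$log$loss[nrow(x$log)])))
  invisible(x)
}

#' Forward pass for one visit
#'
#' Runs the three-layer hierarchy on a visit bundle: per (period, context)
#' cell the event tokens are embedded, encoded by a bidirectional GRU and
#' attention-pooled into a context embedding (empty cells contribute a
#' learned per-context empty embedding); per period the six context
#' embeddings are encoded/pooled and concatenated with the period's
#' continuous variables; the period representations are encoded/pooled,
#' concatenated with the onsite variables and passed through the feed-forward
#' head whose softplus outputs are the per-label evidence pairs.
#'
#' @param model A `carenet_model`.
#' @param bundle A `carenet_bundle`.
#' @param detail If `TRUE`, also return hidden-state matrices and pooled
#'   vectors (for diagnostics and invariant checks).
#' @return List with `evidence` (named 8-vector: `e_pos` then `e_neg` per
#'   label), `prob` (expected label probabilities alpha/S), `uncertainty`
#'   (2/S per label) and `state` (attention weights at all three levels).
#' @export
carenet_forward <- function(model, bundle, detail = FALSE) {
  res <- .cn_forward_cpp(model$params, bundle, detail)
  ev <- as.numeric(res$evidence)
  alpha <- ev[1:4] + 1
  beta <- ev[5:8] + 1
  S <- alpha + beta
  state <- res[setdiff(names(res), "evidence")]
  state$att_period <- as.numeric(state$att_period)
  state$att_event <- lapply(state$att_event, function(row)
    lapply(row, as.numeric))
  if (detail) {
    state$pooled_period <- lapply(state$pooled_period, as.numeric)
    state$pooled_patient <- as.numeric(state$pooled_patient)
    state$patrep <- as.numeric(state$patrep)
  }
  list(evidence = setNames(ev, c(paste0("e_pos.", label_levels()),
                                 paste0("e_neg.", label_levels()))),
       prob = setNames(alpha / S, label_levels()),
       uncertainty = setNames(2 / S, label_levels()),
       state = state)
}

#' Evidential loss
#'
#' Per label, with evidence pair `(e_pos, e_neg)`, `alpha = e_pos + 1`,
#' `beta = e_neg + 1`, `S = alpha + beta` and `p = alpha / S`, the loss is the
#' Beta Bayes risk of the squared error,
#' `(y - p)^2 + p (1 - p) / (S + 1)`, plus `lambda` times the KL divergence
#' from the misleading-evidence projection `Beta(1 + (1-y) e_pos,
#' 1 + y e_neg)` to the uniform `Beta(1, 1)`; the total is the sum over
#' labels.  With zero evidence the prediction is maximally uncertain
#' (`p = 0.5`, uncertainty 1) at zero KL penalty.
#'
#' @param e_pos,e_neg Non-negative evidence vectors (one entry per label).
#' @param y Binary label vector of the same length.
#' @param lambda Annealing weight in `[0, 1]` for the KL term.
#' @return Scalar loss (sum over labels), with the per-label terms in
#'   attribute `"per_label"`.
#' @export
evidential_loss <- function(e_pos, e_neg, y, lambda = 0) {
  stopifnot(length(e_pos) == length(e_neg), length(y) == length(e_pos),
            lambda >= 0, lambda <= 1)
  if (any(e_pos < 0) || any(e_neg < 0)) {
    stop("negative evidence", call. = FALSE)
  }
  y <- as.numeric(y)
  alpha <- e_pos + 1
  beta <- e_neg + 1
  S <- alpha + beta
  p <- alpha / S
  risk <- (y - p)^2 + p * (1 - p) / (S + 1)
  at <- 1 + (1 - y) * e_pos
  bt <- 1 + y * e_neg
  kl <- lgamma(at + bt) - lgamma(at) - lgamma(bt) +
    (at - 1) * digamma(at) + (bt - 1) * digamma(bt) -
    (at + bt - 2) * digamma(at + bt)
  per <- risk + lambda * kl
  structure(sum(per), per_label = per)
}

#' Train the network
#'
#' End-to-end mini-batch training with Adam on the evidential loss; the KL
#' annealing weight is `min(1, epoch / anneal_epochs)`.  Deterministic for a
#' fixed seed (single-threaded).
#'
#' @param model A `carenet_model` (embeddings are fine-tuned).
#' @param bundles List of visit bundles with labels.
#' @param epochs,lr,batch Override the model config when non-NULL.
#' @param seed Seed for batch shuffling.
#' @return The model with updated parameters and a training log
#'   (`model$log`: epoch, loss, lambda).
#' @export
carenet_train <- function(model, bundles, epochs = NULL, lr = NULL,
                          batch = NULL, seed = 1) {
  stopifnot(length(bundles) >= 2)
  y <- bundle_labels(bundles)
  if (sum(colSums(y) > 0) < 2) {
    stop("need at least two labels present in the training data",
         call. = FALSE)
  }
  cfg <- model$cfg
  epochs <- epochs %||% cfg$epochs
  lr <- lr %||% cfg$lr
  batch <- batch %||% cfg$batch
  fit <- .cn_train_cpp(model$params, bundles, lr, batch, epochs,
                       as.integer(seed), cfg$anneal_epochs)
  model$params <- fit$params
  model$log <- data.frame(
    epoch = seq_len(epochs) - 1L,
    loss = as.numeric(fit$loss),
    lambda = pmin(1, (seq_len(epochs) - 1L) / cfg$anneal_epochs))
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict label probabilities for a list of visits
#'
#' @param model Trained `carenet_model`.
#' @param bundles List of bundles.
#' @param type `"prob"` for expected label probabilities (the score used for
#'   all ranking metrics), `"evidence"` for the raw 8-column evidence matrix,
#'   `"uncertainty"` for per-label 2/S.
#' @return Numeric matrix, one row per visit.
#' @export
carenet_predict <- function(model, bundles, type = c("prob", "evidence",
                                                     "uncertainty")) {
  type <- match.arg(type)
  ev <- .cn_predict_cpp(model$params, bundles)
  if (type == "evidence") {
    colnames(ev) <- c(paste0("e_pos.", label_levels()),
                      paste0("e_neg.", label_levels()))
    return(ev)
  }
  alpha <- ev[, 1:4, drop = FALSE] + 1
  beta <- ev[, 5:8, drop = FALSE] + 1
  out <- if (type == "prob") alpha / (alpha + beta) else 2 / (alpha + beta)
  colnames(out) <- label_levels()
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a JSON archive of all parameter arrays plus the
#' configuration and vocabulary, portable across platforms.
#'
#' @param model A `carenet_model`.
#' @param path File path (`.json`).
#' @return `path` invisibly; `carenet_load()` returns the model.
#' @export
carenet_save <- function(model, path) {
  obj <- list(params = model$params, cfg = unclass(model$cfg),
              dims = model$dims,
              vocab = list(codes = model$vocab$codes,
                           min_count = model$vocab$min_count),
              log = model$log)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname carenet_save
#' @export
carenet_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- obj$params
  vecs <- c("g1f_b", "g1b_b", "g2f_b", "g2b_b", "g3f_b", "g3b_b",
            "a1_b", "a1_q", "a2_b", "a2_q", "a3_b", "a3_q", "ffb1", "ffb2")
  for (nm in names(params)) {
    params[[nm]] <- if (nm %in% vecs) as.numeric(params[[nm]]) else
      as.matrix(params[[nm]])
  }
  vocab <- structure(
    list(codes = obj$vocab$codes,
         id = setNames(seq_along(obj$vocab$codes) + 1L, obj$vocab$codes),
         n_reserved = 2L, size = length(obj$vocab$codes) + 2L,
         min_count = obj$vocab$min_count),
    class = "carenet_vocab")
  structure(
    list(params = params, cfg = structure(obj$cfg, class = "carenet_config"),
         vocab = vocab, dims = obj$dims, log = obj$log),
    class = "carenet_model")
}

#' Bidirectional GRU sequence encoder
#'
#' Runs the standard GRU recurrences (update/reset gates, tanh candidate)
#' forward and backward over the input sequence and concatenates the two
#' hidden-state streams, preserving the sequence length.
#'
#' @param X Numeric matrix, `T x d` (rows are time steps).
#' @param params List with forward (`Wf`, `Uf`, `bf`) and backward
#'   (`Wb`, `Ub`, `bb`) GRU parameters; `W` is `3H x d`, `U` is `3H x H`
#'   (gate order: update, reset, candidate), `b` length `3H`.
#' @return `T x 2H` matrix of hidden states (forward then backward halves).
#' @export
encode_sequence <- function(X, params) {
  stopifnot(is.matrix(X), nrow(X) >= 1, all(is.finite(X)))
  f <- .cn_gru_cpp(params$Wf, params$Uf, params$bf, t(X))
  rev_idx <- rev(seq_len(nrow(X)))
  b <- .cn_gru_cpp(params$Wb, params$Ub, params$bb,
                   t(X[rev_idx, , drop = FALSE]))
  cbind(t(f), t(b)[rev_idx, , drop = FALSE])
}

#' Attention pooling
#'
#' Projects each hidden state through a tanh layer (`u_t = tanh(W h_t + b)`),
#' scores it against a learned query (`a = softmax(u_t . q)`) and returns the
#' attention-weighted sum `s = sum_t a_t h_t`.
#'
#' @param H Numeric matrix, `T x I` of hidden states (rows are positions).
#' @param params List with `W` (`A x I`), `b` (length A), `q` (length A).
#' @return List with `weights` (length T, non-negative, summing to 1) and
#'   `pooled` (length I).
#' @export
attention_pool <- function(H, params) {
  stopifnot(is.matrix(H), nrow(H) >= 1)
  res <- .cn_att_cpp(params$W, params$b, params$q, t(H))
  list(weights = as.numeric(res$weights), pooled = as.numeric(res$pooled))
}

#' Mean evidential loss of a model over a set of visits
#'
#' @param model A `carenet_model`.
#' @param bundles List of bundles with labels.
#' @param lambda KL annealing weight (0 gives the pure Bayes-risk term).
#' @return Mean loss per visit.
#' @export
carenet_loss <- function(model, bundles, lambda = 0) {
  .cn_loss_cpp(model$params, bundles, lambda)
}
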