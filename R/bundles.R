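# Turning raw event streams into the per-visit tensors the network consumes:
# a ragged [period][context] grid of token-id sequences, a per-period matrix
# of continuous variables (last observation per period + observed mask), the
# onsite vector with its mask, and the label set.

.datatable.aware <- TRUE

#' Default continuous per-period variables
#'
#' Event codes treated as continuous vital-sign measurements rather than
#' categorical tokens: systolic blood pressure, pulse, temperature, oxygen
#' saturation and breathing frequency.
#' @return Character vector of codes.
#' @export
default_numeric_vars <- function() {
  c("VITAL:SBP", "VITAL:PULSE", "VITAL:TEMP", "VITAL:SPO2", "VITAL:RESP")
}

#' Encode visits as period x context tensor bundles
#'
#' Events are windowed to the observation window, assigned to timeline
#' periods ([segment_timeline()]) and care contexts, and tokenized against
#' the vocabulary (unknown/rare codes become the NA token).  Within each
#' (period, context) cell tokens are ordered chronologically with ties broken
#' by code string, so the encoding is invariant to input row order.  Events
#' listed in `numeric_vars` are diverted to the continuous per-period matrix,
#' which keeps the most recent observation of each variable per period plus
#' an observed/missing indicator.
#'
#' @param events Event table ([read_events()] layout) holding the pre-index
#'   history of the visits.
#' @param visits Index-visit table ([read_visits()] layout).
#' @param vocab Vocabulary from [build_vocabulary()].
#' @param cfg Timeline configuration.
#' @param numeric_vars Codes handled as continuous variables.
#' @return List of `carenet_bundle` objects, one per row of `visits`.
#' @export
cohort_bundles <- function(events, visits, vocab, cfg = timeline_config(),
                           numeric_vars = default_numeric_vars()) {
  visits <- data.table::as.data.table(visits)
  n <- nrow(visits)
  M <- cfg$n_periods
  ctxs <- context_levels()
  P <- length(numeric_vars)
  labels <- label_matrix(visits$main_dx_codes)

  onsite_cols <- grep("^onsite_", names(visits), value = TRUE)
  onsite <- as.matrix(visits[, onsite_cols, with = FALSE])
  if (length(onsite_cols) == 0) onsite <- matrix(0, n, 0)
  storage.mode(onsite) <- "double"
  onsite_mask <- 1 - is.na(onsite)
  onsite[is.na(onsite)] <- 0

  ev <- data.table::as.data.table(events)
  ev <- ev[ev$visit_id %in% visits$visit_id]
  vidx <- match(ev$visit_id, visits$visit_id)
  if (nrow(ev)) {
    p <- segment_timeline(ev$event_time, visits$index_time[vidx], cfg)
    keep <- !is.na(p)
    ev <- ev[keep]; vidx <- vidx[keep]; p <- p[keep]
  } else {
    p <- integer()
  }

  pnum <- array(0, dim = c(M, P, n))
  pmask <- array(0, dim = c(M, P, n))
  grp <- rep(list(integer()), n * M * 6L)

  if (nrow(ev)) {
    is_num <- ev$code %in% numeric_vars & !is.na(ev$numeric_value)
    if (any(is_num)) {
      nv <- data.table::data.table(
        vidx = vidx[is_num], p = p[is_num],
        var = match(ev$code[is_num], numeric_vars),
        t = ev$event_time[is_num], value = ev$numeric_value[is_num])
      data.table::setorder(nv, vidx, p, var, t)
      last <- nv[, list(value = value[.N]), by = c("vidx", "p", "var")]
      pnum[cbind(last$p + 1L, last$var, last$vidx)] <- last$value
      pmask[cbind(last$p + 1L, last$var, last$vidx)] <- 1
    }
    tk <- data.table::data.table(
      vidx = vidx[!is_num], p = p[!is_num],
      ctx = match(ev$context[!is_num], ctxs) - 1L,
      t = ev$event_time[!is_num], code = ev$code[!is_num])
    if (nrow(tk)) {
      data.table::setorder(tk, vidx, p, ctx, t, code)
      tk[, id := vocab_id(vocab, code)]
      key <- ((tk$vidx - 1L) * M + tk$p) * 6L + tk$ctx + 1L
      filled <- split(tk$id, factor(key, levels = sort(unique(key))))
      grp[as.integer(names(filled))] <- filled
    }
  }

  lapply(seq_len(n), function(i) {
    base <- (i - 1L) * M * 6L
    tokens <- lapply(seq_len(M) - 1L, function(pp) {
      lapply(seq_len(6L) - 1L, function(cc) grp[[base + pp * 6L + cc + 1L]])
    })
    structure(
      list(visit_id = visits$visit_id[i],
           tokens = tokens,
           period_numeric = pnum[, , i, drop = FALSE][, , 1],
           period_mask = pmask[, , i, drop = FALSE][, , 1],
           onsite = onsite[i, ], onsite_mask = onsite_mask[i, ],
           labels = setNames(labels[i, ], label_levels()),
           n_periods = M, n_contexts = 6L),
      class = "carenet_bundle")
  })
}

#' Encode a single visit
#'
#' Convenience wrapper around [cohort_bundles()] for one index visit.
#'
#' @param events Event table rows belonging to the visit's patient.
#' @param visit One-row visit table.
#' @inheritParams cohort_bundles
#' @return A `carenet_bundle`.
#' @export
build_bundle <- function(events, visit, vocab, cfg = timeline_config(),
                         numeric_vars = default_numeric_vars()) {
  stopifnot(nrow(visit) == 1)
  cohort_bundles(events, visit, vocab, cfg, numeric_vars)[[1]]
}

#' @export
print.carenet_bundle <- function(x, ...) {
  nt <- sum(lengths(unlist(x$tokens, recursive = FALSE)))
  cat(sprintf(
    "<carenet_bundle> visit %s: %d tokens over %d periods x 6 contexts; labels: %s\n",
    x$visit_id, nt, x$n_periods,
    paste(names(x$labels)[x$labels], collapse = "+")))
  invisible(x)
}

#' Stack bundle labels into a matrix
#' @param bundles List of bundles.
#' @return Logical matrix n x 4.
#' @export
bundle_labels <- function(bundles) {
  matrix(unlist(lapply(bundles, `[[`, "labels")), ncol = 4, byrow = TRUE,
         dimnames = list(NULL, label_levels()))
}
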