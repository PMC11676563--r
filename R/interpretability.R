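# Attention-product interpretability: per-visit event importances (event
# weight x context weight x period weight), cohort-level variable ranking,
# and the data behind per-visit attention plots.

#' Per-visit event importance from the attention hierarchy
#'
#' For each event occurrence in cell (period p, context c) the importance is
#' the product of its event-level attention weight, the context weight of
#' (p, c) and the period weight of p.  Occurrences of the same code within
#' the visit are summed.  Because each attention group sums to one and empty
#' cells carry no events, the total importance mass per visit is at most 1.
#'
#' @param state `state` element of a [carenet_forward()] result.
#' @param bundle The bundle that forward pass consumed.
#' @param vocab Vocabulary used to name the codes.
#' @return Named numeric vector: summed importance per code.
#' @export
visit_event_importance <- function(state, bundle, vocab) {
  M <- bundle$n_periods
  codes <- character(0)
  w <- numeric(0)
  for (p in seq_len(M)) {
    ap <- state$att_period[p]
    for (cc in seq_len(6)) {
      tok <- bundle$tokens[[p]][[cc]]
      if (length(tok) == 0) next
      ae <- state$att_event[[p]][[cc]]
      if (length(ae) != length(tok)) {
        stop("state/bundle mismatch in cell (", p - 1, ",", cc - 1, ")",
             call. = FALSE)
      }
      codes <- c(codes, vocab_code(vocab, tok))
      w <- c(w, ae * state$att_context[p, cc] * ap)
    }
  }
  if (length(w) == 0) return(setNames(numeric(0), character(0)))
  tapply_sum <- rowsum(w, group = codes)
  setNames(as.numeric(tapply_sum), rownames(tapply_sum))
}

#' Cohort-level variable ranking
#'
#' Sums per-code importances over visits (weights of the same type of event
#' from different visits are added) and ranks codes by the total, descending;
#' ties break by code string.
#'
#' @param importances List of named vectors from [visit_event_importance()].
#' @return data.frame with columns rank, code, importance (sorted).
#' @export
cohort_ranking <- function(importances) {
  stopifnot(length(importances) >= 1)
  all_codes <- unlist(lapply(importances, names), use.names = FALSE)
  all_w <- unlist(importances, use.names = FALSE)
  if (length(all_w) == 0) {
    return(data.frame(rank = integer(), code = character(),
                      importance = numeric()))
  }
  s <- rowsum(all_w, group = all_codes)
  code <- rownames(s)
  imp <- as.numeric(s)
  ord <- order(-imp, code, method = "radix")
  data.frame(rank = seq_along(ord), code = code[ord],
             importance = imp[ord], row.names = NULL)
}

#' Write a variable ranking as TSV
#' @param ranking From [cohort_ranking()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  data.table::fwrite(ranking, path, sep = "\t", quote = FALSE, eol = "\n")
  invisible(path)
}

#' Data behind a per-visit attention plot
#'
#' Emulates the three-panel visit plot: period weights, the context weights
#' of the highest-attention period, and the top events (by event attention)
#' of the highest-attention context within it.  Argmax ties break to the
#' lowest period/context index.
#'
#' @param state,bundle,vocab As in [visit_event_importance()].
#' @param top_n Events to keep in the event panel (default 10).
#' @return List with `period` (M weights, period 0 = most recent), `context`
#'   (6 named weights of the argmax period), `events` (named event weights),
#'   and `empty` flag when the visit has no events at all.
#' @export
attention_plot_data <- function(state, bundle, vocab, top_n = 10) {
  M <- bundle$n_periods
  period <- setNames(state$att_period,
                     sprintf("period_%d", seq_len(M) - 1L))
  nonempty <- vapply(seq_len(M), function(p)
    any(lengths(bundle$tokens[[p]]) > 0), logical(1))
  if (!any(nonempty)) {
    return(list(period = period, context = NULL, events = NULL, empty = TRUE))
  }
  p_star <- which.max(state$att_period)
  ctx_w <- setNames(state$att_context[p_star, ], context_levels())
  cells <- lengths(bundle$tokens[[p_star]])
  c_star <- which.max(state$att_context[p_star, ])
  events <- NULL
  if (cells[c_star] > 0) {
    ae <- state$att_event[[p_star]][[c_star]]
    nm <- vocab_code(vocab, bundle$tokens[[p_star]][[c_star]])
    ord <- order(-ae, nm, method = "radix")
    keep <- head(ord, top_n)
    events <- setNames(ae[keep], nm[keep])
  }
  list(period = period,
       argmax_period = p_star - 1L,
       context = ctx_w,
       argmax_context = context_levels()[c_star],
       events = events,
       empty = FALSE)
}
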