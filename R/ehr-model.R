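#' Care contexts
#'
#' The six sources an event can originate from in the regional health system:
#' primary care, outpatient specialist care, the emergency department,
#' inpatient care, ambulatory (ambulance) care, and a residual "others"
#' context (prescriptions, labs, radiology, smoking status, ...).
#'
#' @return Character vector of the six context names, in canonical order.
#' @export
context_levels <- function() {
  c("PRIMARY_CARE", "OUTPATIENT_SPECIALIST", "ED", "INPATIENT",
    "AMBULATORY", "OTHERS")
}

#' Value classes for binned laboratory results
#' @return Character vector of the four value-class names.
#' @export
value_class_levels <- function() c("LOW", "NORMAL", "HIGH", "NA")

# ICD-10 prefix sets defining the three disease labels.  Matching is by
# prefix on the dot-stripped code, so I50.9 -> AHF, J44.1 -> eCOPD.
.icd10_ahf_prefixes  <- c("I110", "I130", "I132", "I50")
.icd10_ecopd_prefixes <- c("J44")
.icd10_pneu_prefixes <- c("J100", "J110", "J12", "J13", "J14", "J15",
                          "J16", "J17", "J18")

.normalize_icd10 <- function(codes) {
  norm <- toupper(gsub(".", "", codes, fixed = TRUE))
  ok <- grepl("^[A-Z][0-9]{2}[0-9A-Z]*$", norm)
  if (any(!ok)) {
    stop("malformed ICD-10 code: ", paste(codes[!ok], collapse = ", "),
         call. = FALSE)
  }
  norm
}

.has_prefix <- function(codes, prefixes) {
  any(outer(codes, prefixes, FUN = startsWith))
}

#' Map ICD-10 main-diagnosis codes to the four-way label set
#'
#' Acute heart failure is defined by ICD-10 codes I11.0, I13.0, I13.2 or I50;
#' eCOPD by J44; pneumonia by J10.0, J11.0 or J12--J18; any code outside
#' those sets contributes the "other diagnoses" label.  Prefix matching on
#' the dot-stripped code covers subcodes, and because a visit may carry more
#' than one main diagnosis the four flags are not mutually exclusive.
#'
#' @param codes Character vector of ICD-10 codes (at least one).
#' @return Named logical vector `c(ahf=, ecopd=, pneumonia=, other=)` with at
#'   least one flag `TRUE`.
#' @examples
#' map_icd10_to_labelset("I50.9")
#' map_icd10_to_labelset(c("J44.1", "I50.0"))
#' @export
map_icd10_to_labelset <- function(codes) {
  if (length(codes) == 0 || all(is.na(codes)) || all(!nzchar(codes))) {
    stop("no main diagnosis", call. = FALSE)
  }
  codes <- .normalize_icd10(codes[nzchar(codes) & !is.na(codes)])
  is_ahf  <- vapply(codes, .has_prefix, logical(1), .icd10_ahf_prefixes)
  is_ecopd <- vapply(codes, .has_prefix, logical(1), .icd10_ecopd_prefixes)
  is_pneu <- vapply(codes, .has_prefix, logical(1), .icd10_pneu_prefixes)
  c(ahf = any(is_ahf), ecopd = any(is_ecopd), pneumonia = any(is_pneu),
    other = any(!is_ahf & !is_ecopd & !is_pneu))
}

#' Label names in canonical order
#' @return `c("ahf", "ecopd", "pneumonia", "other")`
#' @export
label_levels <- function() c("ahf", "ecopd", "pneumonia", "other")

#' Build the n x 4 label matrix for a visit table
#'
#' @param main_dx_codes Character vector; per visit, the semicolon-separated
#'   main ICD-10 diagnosis codes (as stored in `visits.tsv`).
#' @return Logical matrix with one row per visit and columns
#'   [label_levels()].
#' @export
label_matrix <- function(main_dx_codes) {
  out <- t(vapply(strsplit(main_dx_codes, ";", fixed = TRUE),
                  map_icd10_to_labelset, logical(4)))
  colnames(out) <- label_levels()
  out
}

#' Bin a laboratory value against its reference interval
#'
#' Blood tests enter the event stream as categorical tokens: a value below
#' the reference interval is `LOW`, above it `HIGH`, and otherwise `NORMAL`;
#' both interval boundaries count as `NORMAL`.  Missing values map to the
#' `"NA"` class, mirroring the NA markers kept in the raw feed.
#'
#' @param value Numeric vector of measured values (NA allowed).
#' @param ref_low,ref_high Reference interval bounds, `ref_low < ref_high`.
#' @return Character vector over [value_class_levels()].
#' @export
bin_lab_value <- function(value, ref_low, ref_high) {
  if (!is.finite(ref_low) || !is.finite(ref_high) || ref_low >= ref_high) {
    stop("invalid reference interval: ref_low must be < ref_high",
         call. = FALSE)
  }
  out <- rep("NA", length(value))
  obs <- !is.na(value)
  out[obs & value < ref_low] <- "LOW"
  out[obs & value > ref_high] <- "HIGH"
  out[obs & value >= ref_low & value <= ref_high] <- "NORMAL"
  out
}

#' Timeline configuration
#'
#' The pre-index observation window is split into `n_periods` equal spans;
#' period 0 is the span ending at the index time (most recent), period
#' `n_periods - 1` the oldest.
#'
#' @param window_weeks Positive number of weeks of history used (default 52,
#'   i.e. one year).
#' @param n_periods Number of equal periods M (default 10).
#' @return A `carenet_timeline` list with the window in seconds and the
#'   period span.
#' @export
timeline_config <- function(window_weeks = 52, n_periods = 10) {
  stopifnot(window_weeks > 0, n_periods >= 1, n_periods == as.integer(n_periods))
  window_s <- window_weeks * 7 * 86400
  structure(
    list(window_weeks = window_weeks, n_periods = as.integer(n_periods),
         window_s = window_s, span_s = window_s / n_periods),
    class = "carenet_timeline"
  )
}

#' Assign events to timeline periods
#'
#' Computes `floor(age / span)` where `age = index_time - event_time` and
#' `span = window / M`.  Events at least one full window old fall outside the
#' observation window and are dropped (returned as `NA`).
#'
#' @param event_time POSIXct vector of event timestamps (UTC).
#' @param index_time POSIXct scalar, the index-visit time.
#' @param cfg A [timeline_config()].
#' @return Integer vector of 0-based period indices; `NA` for dropped events.
#' @export
segment_timeline <- function(event_time, index_time, cfg = timeline_config()) {
  age <- as.numeric(index_time) - as.numeric(event_time)
  if (any(age <= 0)) stop("event after index", call. = FALSE)
  p <- as.integer(floor(age / cfg$span_s))
  p[age >= cfg$window_s] <- NA_integer_
  p
}

# ---------------------------------------------------------------------------
# Vocabulary

#' Reserved token ids
#'
#' Id 0 is the EMPTY token (placeholder for empty period/context cells, its
#' embedding is pinned at zero) and id 1 the NA token absorbing unknown or
#' rare codes.
#' @return Named integer vector `c(EMPTY = 0L, NA = 1L)`.
#' @export
reserved_tokens <- function() c(EMPTY = 0L, "NA" = 1L)

#' Build the event-code vocabulary
#'
#' Codes with corpus frequency below `min_count` are not given their own id;
#' they map to the reserved NA token instead of being dropped.  Retained
#' codes are sorted lexicographically and numbered from 2 upwards, after the
#' reserved EMPTY (0) and NA (1) ids, so the mapping is deterministic.
#'
#' @param codes Character vector of all event codes in the training corpus.
#' @param min_count Minimum corpus frequency (default 5).
#' @return A `carenet_vocab` object.
#' @export
build_vocabulary <- function(codes, min_count = 5) {
  tab <- table(codes)
  keep <- sort(names(tab)[tab >= min_count], method = "radix")
  structure(
    list(codes = keep,
         id = setNames(seq_along(keep) + 1L, keep),  # 0-based ids from 2
         n_reserved = 2L,
         size = length(keep) + 2L,
         min_count = min_count),
    class = "carenet_vocab"
  )
}

#' @export
print.carenet_vocab <- function(x, ...) {
  cat(sprintf("<carenet_vocab> %d codes + 2 reserved tokens (EMPTY, NA)\n",
              length(x$codes)))
  invisible(x)
}

#' Look up token ids for event codes
#'
#' @param vocab A [build_vocabulary()] object.
#' @param codes Character vector.
#' @return Integer vector of 0-based token ids; unknown codes map to the NA
#'   token (id 1).
#' @export
vocab_id <- function(vocab, codes) {
  i <- vocab$id[codes]
  i[is.na(i)] <- 1L
  unname(i)
}

#' Recover code strings from token ids
#' @param vocab A vocabulary.
#' @param ids Integer vector of 0-based token ids.
#' @return Character vector ("<EMPTY>", "<NA>" for reserved ids).
#' @export
vocab_code <- function(vocab, ids) {
  out <- character(length(ids))
  out[ids == 0L] <- "<EMPTY>"
  out[ids == 1L] <- "<NA>"
  real <- ids >= 2L
  out[real] <- vocab$codes[ids[real] - 1L]
  out
}
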