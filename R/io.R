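# File I/O for the two tab-separated interchange formats.
#
# events.tsv: patient_id, visit_id, event_time, context, code, value_class,
#             numeric_value   (ISO-8601 UTC timestamps, "" = missing)
# visits.tsv: visit_id, patient_id, index_time, main_dx_codes (";"-separated),
#             then any number of onsite_* numeric columns.

.event_cols <- c("patient_id", "visit_id", "event_time", "context", "code",
                 "value_class", "numeric_value")

.parse_time <- function(x, what, path) {
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  bad <- which(is.na(t) | !nzchar(x))
  if (length(bad)) {
    stop(sprintf("%s: invalid %s at line %d: '%s'", path, what,
                 bad[1] + 1L, x[bad[1]]), call. = FALSE)
  }
  t
}

.format_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Read an event-stream table
#'
#' @param path Path to an `events.tsv` file (UTF-8, tab-separated, header
#'   `patient_id visit_id event_time context code value_class numeric_value`).
#' @return A `data.table` with `event_time` parsed as POSIXct (UTC),
#'   `value_class` and `numeric_value` NA where the field is empty.
#' @export
read_events <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = "character",
                          na.strings = NULL, header = TRUE)
  if (!identical(names(dt), .event_cols)) {
    stop(sprintf("%s: expected header %s at line 1", path,
                 paste(.event_cols, collapse = " ")), call. = FALSE)
  }
  if (nrow(dt) == 0) {
    dt[, `:=`(event_time = as.POSIXct(character(), tz = "UTC"),
              numeric_value = numeric())]
    return(dt[])
  }
  dt[, event_time := .parse_time(event_time, "event_time", path)]
  bad_ctx <- which(!dt$context %in% context_levels())
  if (length(bad_ctx)) {
    stop(sprintf("%s: unknown context '%s' at line %d", path,
                 dt$context[bad_ctx[1]], bad_ctx[1] + 1L), call. = FALSE)
  }
  bad_code <- which(!nzchar(dt$code))
  if (length(bad_code)) {
    stop(sprintf("%s: empty code at line %d", path, bad_code[1] + 1L),
         call. = FALSE)
  }
  dt[, value_class := ifelse(nzchar(value_class), value_class, NA_character_)]
  bad_vc <- which(!is.na(dt$value_class) &
                    !dt$value_class %in% value_class_levels())
  if (length(bad_vc)) {
    stop(sprintf("%s: unknown value_class '%s' at line %d", path,
                 dt$value_class[bad_vc[1]], bad_vc[1] + 1L), call. = FALSE)
  }
  suppressWarnings(dt[, numeric_value :=
                        ifelse(nzchar(numeric_value),
                               as.numeric(numeric_value), NA_real_)])
  dt[]
}

#' Write an event-stream table in canonical form
#'
#' Canonical form means ISO-8601 UTC timestamps, empty strings for missing
#' optional fields and up to 15 significant digits for numeric values, so
#' that `write_events(read_events(f))` is byte-identical for files produced
#' by this writer.
#'
#' @param events A data.frame/data.table with the [read_events()] columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- data.table::data.table(
    patient_id = as.character(events$patient_id),
    visit_id = as.character(events$visit_id),
    event_time = .format_time(events$event_time),
    context = as.character(events$context),
    code = as.character(events$code),
    value_class = ifelse(is.na(events$value_class), "",
                         as.character(events$value_class)),
    numeric_value = ifelse(is.na(events$numeric_value), "",
                           format(events$numeric_value, digits = 15,
                                  trim = TRUE, scientific = FALSE))
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read an index-visit table
#'
#' @param path Path to a `visits.tsv` file; required columns `visit_id`,
#'   `patient_id`, `index_time`, `main_dx_codes`, plus zero or more numeric
#'   `onsite_*` columns ("" = missing, kept as NA).
#' @return A `data.table` with `index_time` parsed as POSIXct (UTC).
#' @export
read_visits <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = "character",
                          na.strings = NULL, header = TRUE)
  need <- c("visit_id", "patient_id", "index_time", "main_dx_codes")
  if (length(names(dt)) < 4 || !identical(names(dt)[1:4], need)) {
    stop(sprintf("%s: expected columns %s first at line 1", path,
                 paste(need, collapse = " ")), call. = FALSE)
  }
  extra <- setdiff(names(dt), need)
  if (length(extra) && !all(startsWith(extra, "onsite_"))) {
    stop(sprintf("%s: unexpected column '%s'", path,
                 extra[!startsWith(extra, "onsite_")][1]), call. = FALSE)
  }
  if (nrow(dt) == 0) {
    dt[, index_time := as.POSIXct(character(), tz = "UTC")]
    for (cl in extra) data.table::set(dt, j = cl, value = numeric())
    return(dt[])
  }
  dt[, index_time := .parse_time(index_time, "index_time", path)]
  bad <- which(!nzchar(dt$main_dx_codes))
  if (length(bad)) {
    stop(sprintf("%s: no main diagnosis at line %d", path, bad[1] + 1L),
         call. = FALSE)
  }
  for (cl in extra) {
    suppressWarnings(data.table::set(
      dt, j = cl,
      value = ifelse(nzchar(dt[[cl]]), as.numeric(dt[[cl]]), NA_real_)))
  }
  dt[]
}

#' Write an index-visit table in canonical form
#' @param visits A data.frame/data.table with the [read_visits()] columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_visits <- function(visits, path) {
  out <- data.table::data.table(
    visit_id = as.character(visits$visit_id),
    patient_id = as.character(visits$patient_id),
    index_time = .format_time(visits$index_time),
    main_dx_codes = as.character(visits$main_dx_codes)
  )
  for (cl in grep("^onsite_", names(visits), value = TRUE)) {
    data.table::set(out, j = cl,
                    value = ifelse(is.na(visits[[cl]]), "",
                                   format(visits[[cl]], digits = 15,
                                          trim = TRUE, scientific = FALSE)))
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, eol = "\n")
  invisible(path)
}

#' Persist an embedding table as TSV
#'
#' One row per token: the token string followed by its d coordinates.
#'
#' @param emb Numeric matrix, vocabulary size x d, rows ordered by token id.
#' @param vocab The matching vocabulary.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, vocab, path) {
  stopifnot(nrow(emb) == vocab$size)
  out <- data.table::data.table(token = vocab_code(vocab, seq_len(nrow(emb)) - 1L))
  for (j in seq_len(ncol(emb))) {
    data.table::set(out, j = paste0("v", j),
                    value = format(emb[, j], digits = 9, trim = TRUE))
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read an embedding table written by [write_embeddings()]
#' @param path Path to the TSV.
#' @return Numeric matrix with token strings as rownames.
#' @export
read_embeddings <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt$token
  storage.mode(m) <- "double"
  m
}
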