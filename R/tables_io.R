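#' Canonical column map for selection tables
#'
#' Maps model fields to the column headers expected in a Raven-style
#' selection table. Annotation columns in Raven are free-form, so every name
#' can be overridden; fields other than `begin_time`/`end_time` are optional
#' in the input.
#'
#' @return Named character vector: model field -> file column header.
#' @export
raven_column_map <- function() {
  c(event_id = "Selection",
    begin_time = "Begin Time (s)",
    end_time = "End Time (s)",
    element_type = "Element Type",
    long_call_id = "Long Call ID",
    individual_id = "Individual ID",
    parent_pulse_id = "Parent Pulse ID")
}

rn_event_columns <- c("event_id", "individual_id", "long_call_id",
                      "element_type", "parent_pulse_id",
                      "begin_time", "end_time")

# Normalize free-form element-type annotations ("Bubble sub-pulse",
# "grumble_sub_pulse", "Sub-pulse transitory element", ...) onto the
# canonical vocabulary; unrecognized strings pass through untouched so that
# validate_event_table() can report them.
normalize_element_type <- function(x) {
  key <- gsub("[^a-z]+", "_", tolower(trimws(as.character(x))))
  key <- gsub("^_|_$", "", key)
  syn <- c(
    full_pulse = "full_pulse", pulse = "full_pulse",
    grumble_sub_pulse = "grumble_sub_pulse", grumble = "grumble_sub_pulse",
    sub_pulse_transitory = "sub_pulse_transitory",
    sub_pulse_transitory_element = "sub_pulse_transitory",
    transitory = "sub_pulse_transitory",
    pulse_body = "pulse_body",
    bubble_sub_pulse = "bubble_sub_pulse", bubble = "bubble_sub_pulse"
  )
  hit <- syn[key]
  unname(ifelse(is.na(hit), as.character(x), hit))
}

#' Build an event table from a data frame
#'
#' Coerces a plain data frame of annotated vocal events into the internal
#' event-table form: canonical column names and types, events sorted by
#' `begin_time` within `long_call_id`, element types normalized onto the
#' closed vocabulary, and (optionally) sub-pulse containment inferred by
#' time interval when no parent link is given. A sub-pulse is assigned to
#' the full pulse whose `[begin, next-pulse-begin)` interval (half-open on
#' the right) contains its onset.
#'
#' @param df Data frame with at least `begin_time` and `end_time` columns
#'   (seconds).
#' @param infer_parents Infer missing `parent_pulse_id` links from onset
#'   containment (default `TRUE`).
#' @param provenance Optional source description stored as an attribute.
#' @return A tibble of class `rn_events`.
#' @export
as_event_table <- function(df, infer_parents = TRUE, provenance = NULL) {
  df <- tibble::as_tibble(df)
  if (!all(c("begin_time", "end_time") %in% names(df)))
    rn_abort("event table needs 'begin_time' and 'end_time' columns",
             "rn_schema_error")
  for (col in rn_event_columns) {
    if (!col %in% names(df))
      df[[col]] <- if (col %in% c("begin_time", "end_time")) NA_real_ else NA_character_
  }
  df$begin_time <- as.numeric(df$begin_time)
  df$end_time <- as.numeric(df$end_time)
  for (col in setdiff(rn_event_columns, c("begin_time", "end_time"))) {
    x <- as.character(df[[col]])
    x[!is.na(x) & x == ""] <- NA_character_
    df[[col]] <- x
  }
  if (all(is.na(df$event_id))) df$event_id <- sprintf("evt%05d", seq_len(nrow(df)))
  if (all(is.na(df$long_call_id))) df$long_call_id <- "LC1"
  if (all(is.na(df$individual_id))) df$individual_id <- "IND1"
  df$element_type <- normalize_element_type(df$element_type)
  if (anyDuplicated(df$event_id))
    rn_abort(sprintf("duplicate event_id: %s",
                     paste(unique(df$event_id[duplicated(df$event_id)]),
                           collapse = ", ")),
             "rn_validation_error")
  df <- dplyr::arrange(df, .data$long_call_id, .data$begin_time)
  df <- df[, c(rn_event_columns, setdiff(names(df), rn_event_columns))]
  if (infer_parents) df <- infer_parent_pulses(df)
  structure(df, class = c("rn_events", class(tibble::tibble())),
            provenance = provenance)
}

# Fill missing parent_pulse_id for sub-pulse rows by onset containment in
# the enclosing full pulse's [begin, next-pulse-begin) interval.
infer_parent_pulses <- function(df) {
  sub_rows <- which(df$element_type %in% sub_pulse_types() &
                      is.na(df$parent_pulse_id))
  if (!length(sub_rows)) return(df)
  for (lc in unique(df$long_call_id[sub_rows])) {
    in_lc <- df$long_call_id == lc
    pulses <- df[in_lc & df$element_type == "full_pulse", ]
    rows <- sub_rows[df$long_call_id[sub_rows] == lc]
    if (!nrow(pulses)) next
    brk <- c(pulses$begin_time, Inf)
    idx <- findInterval(df$begin_time[rows], brk)  # 0 = before first pulse
    ok <- idx >= 1
    df$parent_pulse_id[rows[ok]] <- pulses$event_id[idx[ok]]
  }
  df
}

#' Read a Raven-style selection table
#'
#' Reads a tab-delimited selection table (or a CSV/TSV equivalent) into a
#' validated event table. Column headers are matched through `column_map`;
#' unmapped columns are preserved untouched as annotation columns. Times
#' must be decimal seconds with a `.` decimal point (parsing is
#' locale-independent).
#'
#' @param path File path.
#' @param column_map Named character vector, model field -> file column; see
#'   [raven_column_map()].
#' @param sep Field separator; default `"\t"`, or `","` when `path` ends in
#'   `.csv`.
#' @param infer_parents Passed to [as_event_table()].
#' @return An `rn_events` tibble.
#' @export
read_selection_table <- function(path, column_map = raven_column_map(),
                                 sep = NULL, infer_parents = TRUE) {
  if (!file.exists(path))
    rn_abort(sprintf("file not found: %s", path), "rn_io_error")
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.delim(path, sep = sep, check.names = FALSE,
                           colClasses = "character", na.strings = c("NA", ""),
                           stringsAsFactors = FALSE)
  for (fld in c("begin_time", "end_time")) {
    col <- column_map[[fld]]
    if (is.null(col) || !col %in% names(raw))
      rn_abort(sprintf("required column '%s' (mapped to field '%s') missing from %s",
                       if (is.null(col)) fld else col, fld, path),
               "rn_schema_error")
  }
  df <- tibble::as_tibble(raw)
  present <- column_map[column_map %in% names(df)]
  names(df)[match(present, names(df))] <- names(present)
  for (fld in c("begin_time", "end_time")) {
    vals <- suppressWarnings(as.numeric(df[[fld]]))
    bad <- which(is.na(vals) & !is.na(df[[fld]]))
    if (length(bad))
      rn_abort(sprintf("unparseable %s value '%s' at data row %d of %s",
                       fld, df[[fld]][bad[1]], bad[1], path),
               "rn_parse_error")
    df[[fld]] <- vals
  }
  as_event_table(df, infer_parents = infer_parents,
                 provenance = list(path = path, sep = sep))
}

#' Write an event table as a Raven-style selection table
#'
#' Writes tab-delimited output with canonical Raven headers, times formatted
#' as decimal seconds with six digits, one row per event. `write -> read ->
#' write` is byte-stable.
#'
#' @param table An `rn_events` tibble.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_selection_table <- function(table, path) {
  cmap <- raven_column_map()
  out <- as.data.frame(table, check.names = FALSE)
  out$begin_time <- sprintf("%.6f", out$begin_time)
  out$end_time <- sprintf("%.6f", out$end_time)
  names(out)[match(names(cmap), names(out))] <- unname(cmap)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    rn_abort(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
             "rn_io_error")
  invisible(path)
}

#' Validate an event table
#'
#' Report-based validation: never raises on malformed content. Checks the
#' structural invariants of the event model: positive durations,
#' non-negative times, element types from the closed vocabulary, and
#' sub-pulse parent links resolving to a full pulse in the same long call.
#'
#' @param table An `rn_events` tibble (or coercible data frame).
#' @return Tibble with columns `kind`, `event_id`, `message`; zero rows iff
#'   the table is valid.
#' @export
validate_event_table <- function(table) {
  v <- list()
  add <- function(kind, ids, msg) {
    if (length(ids))
      v[[length(v) + 1]] <<- tibble::tibble(kind = kind,
                                            event_id = as.character(ids),
                                            message = msg)
  }
  bad_dur <- table$event_id[!is.na(table$end_time) & !is.na(table$begin_time) &
                              table$end_time <= table$begin_time]
  add("negative duration", bad_dur, "end_time <= begin_time")
  add("negative time", table$event_id[!is.na(table$begin_time) & table$begin_time < 0],
      "begin_time < 0")
  add("unknown element_type",
      table$event_id[!is.na(table$element_type) &
                       !table$element_type %in% element_types()],
      "element_type outside the closed vocabulary")
  is_sub <- table$element_type %in% sub_pulse_types()
  add("orphan sub-pulse", table$event_id[is_sub & is.na(table$parent_pulse_id)],
      "sub-pulse without parent_pulse_id")
  linked <- which(is_sub & !is.na(table$parent_pulse_id))
  if (length(linked)) {
    key <- paste(table$long_call_id, table$event_id)
    pulse_key <- key[table$element_type == "full_pulse"]
    bad <- linked[!paste(table$long_call_id[linked],
                         table$parent_pulse_id[linked]) %in% pulse_key]
    add("orphan sub-pulse", table$event_id[bad],
        "parent_pulse_id does not resolve to a full_pulse in the same long call")
  }
  add("duplicate event_id", unique(table$event_id[duplicated(table$event_id)]),
      "event_id not unique")
  if (!length(v))
    return(tibble::tibble(kind = character(), event_id = character(),
                          message = character()))
  dplyr::bind_rows(v)
}
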