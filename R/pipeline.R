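#' Run the full rhythm analysis on an event table
#'
#' Orchestrates the per-type pipeline: IOIs -> duration filter -> rhythm
#' ratios -> band counts -> density peaks -> tempo summaries, then the
#' nested (cross-stratum) analysis and, optionally, the band-preference
#' count model. Element types with too few ratios for a density (fewer
#' than 10) are skipped and listed, mirroring how single-element pulse
#' types behave in real tables.
#'
#' @param events An `rn_events` tibble.
#' @param bands An [isochrony_bands()] object.
#' @param min_t,max_t IOI filter bounds, s (defaults 0.025 and 5).
#' @param fit_model Fit [fit_band_count_model()] (default `TRUE`; needs >=
#'   2 individuals).
#' @param model_method Passed to [fit_band_count_model()].
#' @param quartile_unit Unit for [quartile_extent_test()] (default
#'   `"long_call_id"`); the test is skipped if the data cannot support it.
#' @return Object of class `rn_report`: per-type tibbles and objects, see
#'   `print()`.
#' @export
analyze_long_calls <- function(events, bands = isochrony_bands(),
                               min_t = 0.025, max_t = 5,
                               fit_model = TRUE,
                               model_method = "auto",
                               quartile_unit = "long_call_id") {
  present <- intersect(element_types(), unique(events$element_type))
  ioi_raw <- lapply(present, function(tt) compute_iois(events, tt))
  names(ioi_raw) <- present
  ioi <- lapply(ioi_raw, filter_iois, min_t = min_t, max_t = max_t)
  filter_log <- tibble::tibble(
    element_type = present,
    n_raw = vapply(ioi_raw, nrow, integer(1)),
    n_filtered = vapply(ioi, nrow, integer(1)))

  ratios_list <- lapply(ioi, compute_ratios, bands = bands)
  ratios <- dplyr::bind_rows(ratios_list)
  skipped <- present[vapply(ratios_list, nrow, integer(1)) < 10]
  with_peaks <- setdiff(present, skipped)
  peaks <- lapply(ratios_list[with_peaks], ratio_density)

  tempos <- dplyr::bind_rows(lapply(ioi[vapply(ioi, nrow, integer(1)) > 0],
                                    tempo_summary))
  counts <- band_counts(ratios, bands = bands)

  sub_present <- intersect(sub_pulse_types(), present)
  nested <- NULL; nested_peaks <- list(); nested_pooled_peak <- NULL
  quartile <- NULL
  if ("full_pulse" %in% present && length(sub_present)) {
    sub_ioi <- dplyr::bind_rows(ioi[sub_present])
    if (nrow(sub_ioi)) {
      nested <- pair_nested_iois(sub_ioi, ioi[["full_pulse"]])
      if (nrow(nested) >= 10)
        nested_pooled_peak <- nested_density_peak(nested)
      for (tt in unique(nested$sub_type)) {
        nt <- nested[nested$sub_type == tt, ]
        if (nrow(nt) >= 10) nested_peaks[[tt]] <- nested_density_peak(nt)
      }
      quartile <- tryCatch(
        quartile_extent_test(nested, unit = quartile_unit),
        rn_insufficient_data = function(e) NULL)
    }
  }

  model <- NULL
  if (fit_model && length(unique(ratios$individual_id)) >= 2 &&
      nrow(counts) > 0) {
    model <- tryCatch(fit_band_count_model(counts, method = model_method),
                      rhythmnest_error = function(e) NULL)
  }

  structure(list(
    filter_log = filter_log, iois = ioi, ratios = ratios,
    band_count_table = counts, tempo_summaries = tempos,
    ratio_peaks = peaks, skipped_types = skipped,
    nested = nested, nested_peaks = nested_peaks,
    nested_pooled_peak = nested_pooled_peak,
    quartile_test = quartile, band_model = model,
    binomial_check = if (nrow(counts)) binomial_band_check(counts, bands),
    bands = bands, filter_bounds = c(min_t, max_t)
  ), class = "rn_report")
}

#' @export
print.rn_report <- function(x, ...) {
  cat("Long-call rhythm report\n")
  cat("  intervals per type (raw -> filtered):\n")
  for (i in seq_len(nrow(x$filter_log)))
    cat(sprintf("    %-22s %5d -> %5d\n", x$filter_log$element_type[i],
                x$filter_log$n_raw[i], x$filter_log$n_filtered[i]))
  if (length(x$ratio_peaks)) {
    cat("  restricted ratio-density peaks:\n")
    for (tt in names(x$ratio_peaks))
      cat(sprintf("    %-22s %.3f\n", tt,
                  x$ratio_peaks[[tt]]$restricted_peak_location))
  }
  if (length(x$skipped_types))
    cat("  skipped (too few ratios):", paste(x$skipped_types, collapse = ", "), "\n")
  if (!is.null(x$nested_pooled_peak))
    cat(sprintf("  nested sub/full tempo-ratio peak (pooled): %.3f (~1:%.0f)\n",
                x$nested_pooled_peak$peak_location,
                1 / x$nested_pooled_peak$peak_location))
  if (!is.null(x$band_model))
    cat(sprintf("  band model LRT: Chisq = %.2f, df = %d, p = %.3g\n",
                x$band_model$lrt_chisq, x$band_model$lrt_df,
                x$band_model$lrt_p))
  invisible(x)
}

# Condense an rn_report into plain lists for JSON serialization.
report_summary <- function(x) {
  peak_list <- lapply(x$ratio_peaks, function(p) list(
    global = p$peak_location, restricted = p$restricted_peak_location,
    n = p$n, bw = p$bw))
  out <- list(
    filter_bounds = x$filter_bounds,
    intervals = as.list(stats::setNames(x$filter_log$n_filtered,
                                        x$filter_log$element_type)),
    intervals_raw = as.list(stats::setNames(x$filter_log$n_raw,
                                            x$filter_log$element_type)),
    ratio_peaks = peak_list,
    skipped_types = x$skipped_types,
    tempo = lapply(split(x$tempo_summaries, x$tempo_summaries$element_type),
                   function(r) list(n = r$n, mean_t = r$mean_t, sd_t = r$sd_t,
                                    mean_rate = r$mean_rate,
                                    sd_rate = r$sd_rate)),
    on_off_counts = lapply(
      split(x$band_count_table,
            x$band_count_table$element_type),
      function(d) as.list(stats::setNames(
        tapply(d$count, as.character(d$band), sum), unique(as.character(d$band))))
    )
  )
  if (!is.null(x$nested_pooled_peak))
    out$nested_peak <- x$nested_pooled_peak$peak_location
  if (length(x$nested_peaks))
    out$nested_peaks_by_type <- lapply(x$nested_peaks,
                                       function(p) p$peak_location)
  if (!is.null(x$quartile_test))
    out$quartile_test <- list(units = x$quartile_test$units,
                              W = x$quartile_test$W,
                              p_value = x$quartile_test$p_value)
  if (!is.null(x$band_model))
    out$band_model <- list(lrt_chisq = x$band_model$lrt_chisq,
                           lrt_df = x$band_model$lrt_df,
                           lrt_p = x$band_model$lrt_p,
                           method = x$band_model$method_used)
  out
}

write_manifest <- function(dir, config, seed) {
  jsonlite::write_json(
    list(package = "rhythmnest",
         version = as.character(utils::packageVersion("rhythmnest")),
         r_version = as.character(getRversion()),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed, config = config),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA, null = "null")
}

#' One-shot runs: simulate, analyze, discriminate
#'
#' File-level entry points behind the command-line wrapper: each reads
#' and/or writes an output directory with a machine-readable manifest
#' (config + versions + seed) sufficient to reproduce the run.
#'
#' `simulate_run()` writes a synthetic selection table
#' (`events.selections.txt`), acoustic table (`acoustics.csv`) and
#' generating spec. `analyze_run()` reads a selection table, runs
#' [analyze_long_calls()], and writes `summary.json` plus tidy TSVs
#' (IOIs, ratios, band counts, density curves, nested ratios).
#' `pdfa_run()` reads an acoustic CSV/TSV, runs [pdfa_crossed()], and
#' writes `pdfa.json` plus the permutation null distribution as TSV.
#'
#' @param output_dir Output directory (created if missing).
#' @param spec A [synthetic_spec()].
#' @param seed RNG seed.
#' @return The output directory, invisibly (`analyze_run` returns the
#'   `rn_report`, `pdfa_run` the `rn_pdfa`, both invisibly).
#' @export
simulate_run <- function(output_dir, spec = synthetic_spec(), seed = 1) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- generate_dataset(spec, seed = seed)
  write_selection_table(ds$events, file.path(output_dir, "events.selections.txt"))
  utils::write.table(ds$acoustics, file.path(output_dir, "acoustics.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  cfg <- unclass(spec)
  cfg$acoustic_means <- as.data.frame(cfg$acoustic_means)
  write_manifest(output_dir, cfg, seed)
  invisible(output_dir)
}

#' @param input Path to a selection table (`analyze_run`) or acoustic
#'   table (`pdfa_run`).
#' @param column_map Passed to [read_selection_table()].
#' @param ... Passed to [analyze_long_calls()] or [pdfa_crossed()].
#' @rdname simulate_run
#' @export
analyze_run <- function(input, output_dir, column_map = raven_column_map(),
                        seed = 1, ...) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  events <- read_selection_table(input, column_map = column_map)
  res_rep <- withr::with_seed(as.integer(seed), analyze_long_calls(events, ...))
  jsonlite::write_json(report_summary(res_rep),
                       file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  tsv <- function(d, f) utils::write.table(
    d, file.path(output_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  tsv(dplyr::bind_rows(res_rep$iois), "iois.tsv")
  tsv(res_rep$ratios, "ratios.tsv")
  tsv(res_rep$band_count_table, "band_counts.tsv")
  for (tt in names(res_rep$ratio_peaks))
    tsv(data.frame(grid = res_rep$ratio_peaks[[tt]]$grid,
                   density = res_rep$ratio_peaks[[tt]]$density),
        sprintf("density_%s.tsv", tt))
  if (!is.null(res_rep$nested)) tsv(res_rep$nested, "nested_ratios.tsv")
  write_manifest(output_dir, list(input = input, extra = names(list(...))),
                 seed)
  invisible(res_rep)
}

#' @param variables Feature columns for [pdfa_crossed()].
#' @param n_sel,n_perm Passed to [pdfa_crossed()].
#' @rdname simulate_run
#' @export
pdfa_run <- function(input, output_dir, variables = acoustic_variables(),
                     n_sel = 100, n_perm = 1000, seed = 1, ...) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  data <- read_acoustic_table(input)
  res <- pdfa_crossed(data, variables = variables, n_sel = n_sel,
                      n_perm = n_perm, seed = seed, ...)
  jsonlite::write_json(
    list(observed_pct_selected = res$observed_pct_selected,
         observed_pct_cross = res$observed_pct_cross,
         expected_pct = res$expected_pct, p_value = res$p_value,
         n_sel = res$n_sel, n_perm = res$n_perm, n_cases = res$n_cases),
    file.path(output_dir, "pdfa.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  utils::write.table(data.frame(null_pct_selected = res$null_distribution),
                     file.path(output_dir, "pdfa_null.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_manifest(output_dir, list(input = input, variables = variables,
                                  n_sel = n_sel, n_perm = n_perm), seed)
  invisible(res)
}

#' Read an acoustic-measure table
#'
#' CSV or TSV with the seven feature columns plus test/control factor
#' columns. Raven-style synonyms (`Delta.Time`, `Peak.Freq`, `Peak.Time`,
#' `PFC.Avg.Slope`, `PFC.Max.Slope`, `Avg.Entropy`, `SNR.NIST.Quick`,
#' `Sub-pulse-type`, `Individual.ID`) are renamed onto the canonical
#' names.
#'
#' @param path File path (`.csv` comma-separated, otherwise tab).
#' @return Tibble.
#' @export
read_acoustic_table <- function(path) {
  if (!file.exists(path))
    rn_abort(sprintf("file not found: %s", path), "rn_io_error")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.delim(path, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  syn <- c("Delta.Time" = "duration", "Peak.Freq" = "peak_frequency",
           "Peak.Time" = "peak_time", "PFC.Avg.Slope" = "pfc_avg_slope",
           "PFC.Max.Slope" = "pfc_max_slope", "Avg.Entropy" = "avg_entropy",
           "SNR.NIST.Quick" = "snr_nist_quick",
           "Sub-pulse-type" = "sub_pulse_type",
           "Individual.ID" = "individual_id")
  hit <- names(raw) %in% names(syn)
  names(raw)[hit] <- unname(syn[names(raw)[hit]])
  tibble::as_tibble(raw)
}
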