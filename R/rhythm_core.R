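#' Compute inter-onset intervals for one element type
#'
#' An inter-onset interval (IOI, t_k) is the time from one element's begin
#' time to the next element of the same type in the same long call; only
#' begin times enter the computation. For sub-pulse types the default also
#' requires both elements of a pair to share the same enclosing full pulse
#' (`within_parent = TRUE`), so no IOI spans a pulse boundary. A new
#' `sequence_id` starts whenever the pairing constraint breaks (change of
#' long call or of parent pulse).
#'
#' @param table An `rn_events` tibble.
#' @param element_type One canonical element type, see [element_types()].
#' @param within_parent Require pairs to share `parent_pulse_id`. Default:
#'   `TRUE` for sub-pulse types, `FALSE` (ignored) for `full_pulse`.
#' @return Tibble of class `rn_ioi` with columns `t_k`, `element_type`,
#'   `long_call_id`, `individual_id`, `sequence_id`, `source_event_id`,
#'   `parent_pulse_id`, `pos` (position of the interval within its
#'   sequence). An empty tibble if the type is absent.
#' @export
compute_iois <- function(table, element_type, within_parent = NULL) {
  if (!element_type %in% element_types())
    rn_abort(sprintf("unknown element_type '%s'", element_type),
             "rn_type_error")
  if (is.null(within_parent))
    within_parent <- element_type != "full_pulse"
  el <- table[!is.na(table$element_type) & table$element_type == element_type, ]
  empty <- tibble::tibble(
    t_k = numeric(), element_type = character(), long_call_id = character(),
    individual_id = character(), sequence_id = integer(),
    source_event_id = character(), parent_pulse_id = character(),
    pos = integer())
  if (nrow(el) < 2) return(new_ioi_series(empty))
  el <- dplyr::arrange(el, .data$long_call_id, .data$begin_time)
  grp <- el$long_call_id
  if (within_parent) {
    par <- ifelse(is.na(el$parent_pulse_id), "<orphan>", el$parent_pulse_id)
    grp <- paste(grp, par, sep = "\r")
  }
  run <- cumsum(c(TRUE, grp[-1] != grp[-length(grp)]))
  keep <- which(c(run[-1] == run[-length(run)], FALSE))  # first of each pair
  if (!length(keep)) return(new_ioi_series(empty))
  out <- tibble::tibble(
    t_k = el$begin_time[keep + 1L] - el$begin_time[keep],
    element_type = element_type,
    long_call_id = el$long_call_id[keep],
    individual_id = el$individual_id[keep],
    sequence_id = run[keep],
    source_event_id = el$event_id[keep],
    parent_pulse_id = el$parent_pulse_id[keep]
  )
  out$sequence_id <- match(out$sequence_id, unique(out$sequence_id))
  out$pos <- stats::ave(seq_len(nrow(out)), out$sequence_id,
                        FUN = seq_along)
  new_ioi_series(out)
}

new_ioi_series <- function(df) {
  structure(df, class = c("rn_ioi", class(tibble::tibble())))
}

#' Filter inter-onset intervals by duration
#'
#' Retains intervals with `min_t < t_k < max_t` (strict bounds). Removal of
#' an interior interval splits its sequence: the pieces on either side get
#' distinct `sequence_id`s, so ratios are never computed across a gap.
#'
#' @param series An `rn_ioi` tibble.
#' @param min_t,max_t Open duration bounds in seconds (defaults 0.025 and 5).
#' @return Filtered `rn_ioi` tibble with recomputed `sequence_id`/`pos`.
#' @export
filter_iois <- function(series, min_t = 0.025, max_t = 5) {
  stopifnot(min_t < max_t)
  keep <- series$t_k > min_t & series$t_k < max_t
  out <- series[keep, ]
  if (!nrow(out)) return(new_ioi_series(out))
  brk <- c(TRUE, out$sequence_id[-1] != out$sequence_id[-nrow(out)] |
             diff(out$pos) != 1L)
  out$sequence_id <- cumsum(brk)
  out$pos <- stats::ave(seq_len(nrow(out)), out$sequence_id, FUN = seq_along)
  new_ioi_series(out)
}

#' Compute rhythm ratios from an IOI series
#'
#' The rhythm ratio of two temporally adjacent intervals is
#' `r_k = t_k / (t_k + t_{k+1})`; it equals 0.5 under perfect isochrony and
#' is unchanged by any global rescaling of time. Ratios are formed only
#' within a `sequence_id` run, and each is labelled with its isochrony band.
#'
#' @param series An `rn_ioi` tibble.
#' @param bands An [isochrony_bands()] object.
#' @return Tibble of class `rn_ratio` with columns `r_k`, `band`,
#'   `element_type`, `individual_id`, `long_call_id`, `sequence_id`.
#' @export
compute_ratios <- function(series, bands = isochrony_bands()) {
  n <- nrow(series)
  first <- if (n) c(series$sequence_id[-1] == series$sequence_id[-n], FALSE)
           else logical(0)
  idx <- which(first)
  out <- tibble::tibble(
    r_k = series$t_k[idx] / (series$t_k[idx] + series$t_k[idx + 1L]),
    element_type = series$element_type[idx],
    individual_id = series$individual_id[idx],
    long_call_id = series$long_call_id[idx],
    sequence_id = series$sequence_id[idx]
  )
  out$band <- classify_band(out$r_k, bands)
  out <- out[, c("r_k", "band", "element_type", "individual_id",
                 "long_call_id", "sequence_id")]
  structure(out, class = c("rn_ratio", class(tibble::tibble())))
}

#' Count ratios per isochrony band
#'
#' Tallies on-/off-isochrony (and outside) ratio counts per group, carrying
#' each band's total width for use as an exposure offset in the count
#' model. Groups with no ratio in a band get an explicit zero. Counts
#' conserve: on + off + outside = total per group.
#'
#' @param ratios An `rn_ratio` tibble.
#' @param group_by Character vector of grouping columns (default
#'   `c("element_type", "individual_id")`).
#' @param bands An [isochrony_bands()] object.
#' @param drop_outside Drop the `outside` rows (default `FALSE`).
#' @return Tibble with the grouping columns plus `band`, `count`,
#'   `band_width`.
#' @export
band_counts <- function(ratios, group_by = c("element_type", "individual_id"),
                        bands = isochrony_bands(), drop_outside = FALSE) {
  stopifnot(all(group_by %in% names(ratios)))
  if (!nrow(ratios)) {
    out <- tibble::tibble(band = factor(character(),
                                        levels = c("on", "off", "outside")),
                          count = integer(), band_width = numeric())
    for (g in rev(group_by)) out <- tibble::add_column(
      out, !!g := character(), .before = 1)
    return(out)
  }
  out <- dplyr::count(ratios, dplyr::across(dplyr::all_of(group_by)),
                      .data$band, name = "count", .drop = FALSE)
  # .drop = FALSE completes bands but can also create type x individual
  # combinations absent from the data when group columns are factors; keep
  # only groups that occur, with all three bands each.
  seen <- dplyr::distinct(ratios, dplyr::across(dplyr::all_of(group_by)))
  out <- dplyr::semi_join(out, seen, by = group_by)
  out$band_width <- unname(bands$widths[as.character(out$band)])
  if (drop_outside) out <- out[out$band != "outside", ]
  out
}

#' Ratio density and peak extraction
#'
#' Gaussian-kernel density of the ratio distribution on a uniform grid over
#' \[0, 1\] (Silverman's rule bandwidth by default, no boundary
#' correction), with the global peak and the peak restricted to the
#' isochrony-reporting window (0.400, 0.600). The restricted peak is the
#' headline quantity when asking whether a stratum is isochronous.
#'
#' @param ratios An `rn_ratio` tibble or a numeric vector of ratios.
#' @param bw Bandwidth specification passed to [stats::density()]
#'   (default `"nrd0"`, Silverman's rule).
#' @param n_grid Grid size (default 512).
#' @param restrict Length-2 window for the restricted peak, default
#'   `c(0.400, 0.600)` (open).
#' @param from,to Grid limits (defaults 0 and 1).
#' @return Object of class `rn_density`: `grid`, `density`, `bw`, `n`,
#'   `peak_location`, `peak_density`, `restricted_peak_location`,
#'   `restricted_peak_density`.
#' @export
ratio_density <- function(ratios, bw = "nrd0", n_grid = 512,
                          restrict = c(0.400, 0.600), from = 0, to = 1) {
  x <- if (is.data.frame(ratios)) ratios$r_k else as.numeric(ratios)
  x <- x[is.finite(x)]
  if (length(x) < 10)
    rn_abort(sprintf("density needs >= 10 ratio values, got %d", length(x)),
             "rn_insufficient_data")
  d <- stats::density(x, bw = bw, kernel = "gaussian", n = n_grid,
                      from = from, to = to)
  i_max <- which.max(d$y)
  res <- list(grid = d$x, density = d$y, bw = d$bw, n = length(x),
              peak_location = d$x[i_max], peak_density = d$y[i_max],
              restricted_peak_location = NA_real_,
              restricted_peak_density = NA_real_,
              restrict = restrict)
  inside <- which(d$x > restrict[1] & d$x < restrict[2])
  if (length(inside)) {
    j <- inside[which.max(d$y[inside])]
    res$restricted_peak_location <- d$x[j]
    res$restricted_peak_density <- d$y[j]
  }
  structure(res, class = "rn_density")
}

#' @export
print.rn_density <- function(x, ...) {
  cat(sprintf("Ratio density: n = %d, bw = %.4g\n", x$n, x$bw))
  cat(sprintf("  global peak      %.4f (density %.3f)\n",
              x$peak_location, x$peak_density))
  if (!is.na(x$restricted_peak_location))
    cat(sprintf("  restricted peak  %.4f on (%.3f, %.3f)\n",
                x$restricted_peak_location, x$restrict[1], x$restrict[2]))
  invisible(x)
}

#' Local maxima of a density curve
#'
#' Grid points that are strict local maxima of the estimated density;
#' useful for checking uni- vs bimodality of a ratio distribution.
#'
#' @param d An `rn_density` object.
#' @param min_density Ignore maxima with density below this value
#'   (default: 5% of the global peak).
#' @return Numeric vector of ratio locations.
#' @export
density_local_maxima <- function(d, min_density = 0.05 * d$peak_density) {
  y <- d$density
  n <- length(y)
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  i <- i[y[i] >= min_density]
  d$grid[i]
}

#' Tempo summary of an IOI series
#'
#' Mean and sd of the intervals, and of the per-interval rates `1/t_k`
#' (Hz). The mean rate is the mean of `1/t_k`, not `1/mean(t_k)`: the two
#' differ markedly for skewed interval distributions, and the per-interval
#' mean is what the pooled sub-pulse tempo in the source protocol reflects;
#' `1/mean(t_k)` is recoverable from `mean_t`.
#'
#' @param series An `rn_ioi` tibble.
#' @param by Optional grouping column (e.g. `"element_type"`); `NULL`
#'   summarizes the whole series as one row.
#' @return Tibble with `element_type`, `n`, `mean_t`, `sd_t`, `mean_rate`,
#'   `sd_rate`.
#' @export
tempo_summary <- function(series, by = NULL) {
  if (!nrow(series))
    rn_abort("tempo_summary on an empty IOI series", "rn_insufficient_data")
  one <- function(df) tibble::tibble(
    element_type = paste(unique(df$element_type), collapse = "+"),
    n = nrow(df),
    mean_t = mean(df$t_k), sd_t = stats::sd(df$t_k),
    mean_rate = mean(1 / df$t_k), sd_rate = stats::sd(1 / df$t_k))
  if (is.null(by)) return(one(series))
  dplyr::bind_rows(lapply(split(series, series[[by]]), one))
}
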