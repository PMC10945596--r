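#' Pair sub-pulse IOIs with their enclosing full-pulse IOI
#'
#' The cross-stratum tempo relation: each sub-pulse interval is divided by
#' the interval of its enclosing full pulse, where the enclosing pulse's
#' interval runs from that pulse's onset to the next pulse's onset
#' (consistent with intervals defined from begin times only, not pulse
#' durations). Sub-pulses inside the final pulse of a call have no
#' enclosing interval and contribute nothing; sub-pulse intervals whose
#' parent cannot be resolved are skipped with a message.
#'
#' @param sub_series `rn_ioi` tibble of one or more sub-pulse types.
#' @param full_series `rn_ioi` tibble of `full_pulse` intervals from the
#'   same event table (typically after [filter_iois()]).
#' @return Tibble of class `rn_nested` with columns `nested_ratio`,
#'   `sub_type`, `individual_id`, `long_call_id`, `parent_pulse_id`,
#'   `sub_t_k`, `full_t_k`.
#' @export
pair_nested_iois <- function(sub_series, full_series) {
  full_t <- stats::setNames(full_series$t_k, full_series$source_event_id)
  parent <- sub_series$parent_pulse_id
  unresolved <- sum(is.na(parent))
  hit <- !is.na(parent) & parent %in% names(full_t)
  dropped_last <- sum(!hit) - unresolved
  if (unresolved > 0)
    message(sprintf("pair_nested_iois: skipped %d sub-pulse interval(s) with unresolvable parent",
                    unresolved))
  s <- sub_series[hit, ]
  out <- tibble::tibble(
    nested_ratio = s$t_k / unname(full_t[s$parent_pulse_id]),
    sub_type = s$element_type,
    individual_id = s$individual_id,
    long_call_id = s$long_call_id,
    parent_pulse_id = s$parent_pulse_id,
    sub_t_k = s$t_k,
    full_t_k = unname(full_t[s$parent_pulse_id])
  )
  structure(out, class = c("rn_nested", class(tibble::tibble())),
            n_unresolved = unresolved, n_no_next_pulse = dropped_last)
}

#' Density peak of the nested tempo-ratio distribution
#'
#' Gaussian KDE of sub-pulse/full-pulse interval ratios on
#' \[0, max(ratio)\], same conventions as [ratio_density()]; the global
#' peak is the cross-stratum tempo relation (e.g. 0.046 is a 1:22 nesting).
#'
#' @param series An `rn_nested` tibble or numeric vector of nested ratios.
#' @inheritParams ratio_density
#' @return An `rn_density` object (its restricted peak window is the full
#'   support, so global and restricted peaks coincide).
#' @export
nested_density_peak <- function(series, bw = "nrd0", n_grid = 512) {
  x <- if (is.data.frame(series)) series$nested_ratio else as.numeric(series)
  x <- x[is.finite(x)]
  if (length(x) < 10)
    rn_abort(sprintf("nested density needs >= 10 values, got %d", length(x)),
             "rn_insufficient_data")
  ratio_density(x, bw = bw, n_grid = n_grid,
                restrict = c(0, max(x)), from = 0, to = max(x))
}

# Equal-count quartile blocks of a sorted sample: block j holds the items
# with ceiling(4 * i / n) == j, i the sorted index. Near-equal sizes when n
# is not divisible by 4.
quartile_blocks <- function(x) {
  x <- sort(x)
  split(x, ceiling(4 * seq_along(x) / length(x)))
}

# Extent of a pair of quartile blocks = sum of the two per-block ranges.
# (Pooling adjacent central blocks into one range would make the
# peripheral extent the whole-sample range, trivially >= the central one;
# summing per-block ranges makes central and peripheral extents equal in
# expectation for a uniform sample, which is the calibration this test
# needs.)
block_extent <- function(blocks, which) {
  sum(vapply(blocks[which], function(b) diff(range(b)), numeric(1)))
}

#' Central- vs peripheral-quartile extent test
#'
#' Peakedness test of the nested-ratio distribution: per unit (default:
#' long call), the sorted ratios are split into four equal-count blocks;
#' the central extent is the summed range of the two middle blocks and the
#' peripheral extent the summed range of the outer two. A paired one-sided
#' Wilcoxon signed-rank test across units asks whether central extents are
#' systematically smaller (a peaked, i.e. rhythmically concentrated,
#' distribution). Exact null distribution for <= 25 units (no ties),
#' normal approximation with continuity correction otherwise.
#'
#' @param series An `rn_nested` tibble.
#' @param unit Grouping column defining the paired unit (default
#'   `"long_call_id"`).
#' @param min_units Minimum number of usable units (default 6).
#' @param min_obs Minimum observations per unit (default 8); smaller units
#'   are dropped.
#' @return Object of class `rn_quartile_test`: `units`, `central_extents`,
#'   `peripheral_extents`, `W` (signed-rank statistic: the sum of positive
#'   ranks of central - peripheral, so strongly peaked data drive W toward
#'   0), `p_value`, `method`.
#' @export
quartile_extent_test <- function(series, unit = "long_call_id",
                                 min_units = 6, min_obs = 8) {
  stopifnot(unit %in% names(series))
  parts <- split(series$nested_ratio, series[[unit]])
  parts <- parts[vapply(parts, length, integer(1)) >= min_obs]
  if (length(parts) < min_units)
    rn_abort(sprintf("need >= %d units with >= %d observations; got %d",
                     min_units, min_obs, length(parts)),
             "rn_insufficient_data")
  central <- peripheral <- numeric(length(parts))
  for (i in seq_along(parts)) {
    b <- quartile_blocks(parts[[i]])
    central[i] <- block_extent(b, c("2", "3"))
    peripheral[i] <- block_extent(b, c("1", "4"))
  }
  d <- central - peripheral
  if (all(d == 0)) {
    W <- 0; p <- 1; method <- "degenerate (all differences zero)"
  } else {
    exact <- length(parts) <= 25
    ht <- suppressWarnings(
      stats::wilcox.test(central, peripheral, paired = TRUE,
                         alternative = "less", exact = exact,
                         correct = TRUE))
    W <- unname(ht$statistic)
    p <- ht$p.value
    method <- ht$method
  }
  structure(list(units = length(parts), unit = unit,
                 central_extents = central, peripheral_extents = peripheral,
                 W = W, p_value = p, method = method),
            class = "rn_quartile_test")
}

#' @export
print.rn_quartile_test <- function(x, ...) {
  cat(sprintf("Central- vs peripheral-quartile extent test (%d %s units)\n",
              x$units, x$unit))
  cat(sprintf("  median central %.4g, peripheral %.4g\n",
              stats::median(x$central_extents),
              stats::median(x$peripheral_extents)))
  cat(sprintf("  W = %.4g, one-sided p = %.4g (%s)\n", x$W, x$p_value,
              x$method))
  invisible(x)
}
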