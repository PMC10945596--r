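#' Long-call element-type vocabulary
#'
#' The closed vocabulary of element types recognized throughout the package.
#' `full_pulse` is the higher temporal stratum; the other four are sub-pulse
#' types nested inside full pulses. `acoustic_sub_pulse_types()` returns the
#' three sub-pulse types that carry acoustic feature vectors and enter the
#' discriminant analysis.
#'
#' @return Character vector of canonical element-type names.
#' @export
element_types <- function() {
  c("full_pulse", "grumble_sub_pulse", "sub_pulse_transitory",
    "pulse_body", "bubble_sub_pulse")
}

#' @rdname element_types
#' @export
sub_pulse_types <- function() {
  setdiff(element_types(), "full_pulse")
}

#' @rdname element_types
#' @export
acoustic_sub_pulse_types <- function() {
  c("grumble_sub_pulse", "sub_pulse_transitory", "bubble_sub_pulse")
}

#' Isochrony band definitions
#'
#' Rhythm ratios r_k = t_k / (t_k + t_{k+1}) equal 0.5 under perfect
#' isochrony (1:1 rhythm). Band membership uses strict inequalities; a value
#' exactly on a boundary belongs to no band (it is counted as `outside`).
#' The on-isochrony band brackets 0.5; the two off-isochrony flanks sit
#' symmetrically outside it. Widths (on: 0.115, off: 0.085 summed over both
#' flanks) serve as exposure offsets in the band-preference count model.
#'
#' @param on Numeric length-2, open interval around isochrony.
#' @param off_low,off_high Numeric length-2 open intervals flanking `on`.
#' @return An object of class `rn_bands` with elements `on`, `off_low`,
#'   `off_high` and a named `widths` vector (`on`, `off`, `outside`).
#' @export
isochrony_bands <- function(on = c(0.440, 0.555),
                            off_low = c(0.400, 0.440),
                            off_high = c(0.555, 0.600)) {
  stopifnot(length(on) == 2, length(off_low) == 2, length(off_high) == 2,
            on[1] < on[2], off_low[1] < off_low[2], off_high[1] < off_high[2],
            off_low[2] <= on[1], on[2] <= off_high[1])
  widths <- c(
    on = on[2] - on[1],
    off = (off_low[2] - off_low[1]) + (off_high[2] - off_high[1])
  )
  widths <- c(widths, outside = 1 - sum(widths))
  structure(
    list(on = on, off_low = off_low, off_high = off_high, widths = widths),
    class = "rn_bands"
  )
}

#' Classify rhythm ratios into isochrony bands
#'
#' @param r Numeric vector of ratio values in (0, 1).
#' @param bands An [isochrony_bands()] object.
#' @return Factor with levels `on`, `off`, `outside`. Boundary values fall
#'   in no band and are labelled `outside`.
#' @export
classify_band <- function(r, bands = isochrony_bands()) {
  out <- rep("outside", length(r))
  out[r > bands$on[1] & r < bands$on[2]] <- "on"
  out[(r > bands$off_low[1] & r < bands$off_low[2]) |
        (r > bands$off_high[1] & r < bands$off_high[2])] <- "off"
  factor(out, levels = c("on", "off", "outside"))
}

#' @export
print.rn_bands <- function(x, ...) {
  cat("Isochrony bands (open intervals):\n")
  cat(sprintf("  on : (%.3f, %.3f)  width %.3f\n", x$on[1], x$on[2],
              x$widths[["on"]]))
  cat(sprintf("  off: (%.3f, %.3f) u (%.3f, %.3f)  width %.3f\n",
              x$off_low[1], x$off_low[2], x$off_high[1], x$off_high[2],
              x$widths[["off"]]))
  invisible(x)
}
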