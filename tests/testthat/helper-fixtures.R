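# In-code fixtures and independent oracles shared across test files.

# Event table from explicit full-pulse onsets (one long call, one
# individual); optional named list sub_onsets: parent pulse index ->
# data.frame(onset, type).
make_pulse_events <- function(onsets, sub_onsets = NULL, dur = 0.2,
                              long_call_id = "LC1", individual_id = "I1") {
  ev <- tibble::tibble(
    event_id = sprintf("p%02d", seq_along(onsets)),
    individual_id = individual_id, long_call_id = long_call_id,
    element_type = "full_pulse", parent_pulse_id = NA_character_,
    begin_time = onsets, end_time = onsets + dur)
  if (!is.null(sub_onsets)) {
    for (pi in names(sub_onsets)) {
      so <- sub_onsets[[pi]]
      ev <- dplyr::bind_rows(ev, tibble::tibble(
        event_id = sprintf("p%02d_s%02d", as.integer(pi), seq_len(nrow(so))),
        individual_id = individual_id, long_call_id = long_call_id,
        element_type = so$type,
        parent_pulse_id = sprintf("p%02d", as.integer(pi)),
        begin_time = so$onset, end_time = so$onset + dur / 4))
    }
  }
  as_event_table(ev, infer_parents = FALSE)
}

# Bare IOI series from a vector of intervals (single sequence).
make_ioi <- function(t_k, element_type = "full_pulse", sequence_id = 1L,
                     long_call_id = "LC1", individual_id = "I1") {
  rhythmnest:::new_ioi_series(tibble::tibble(
    t_k = t_k, element_type = element_type, long_call_id = long_call_id,
    individual_id = individual_id, sequence_id = sequence_id,
    source_event_id = sprintf("%s_e%03d", long_call_id, seq_along(t_k)),
    parent_pulse_id = NA_character_,
    pos = stats::ave(seq_along(t_k), sequence_id, FUN = seq_along)))
}

# Acoustic null-world table: every case drawn from one shared Gaussian
# regardless of label.
make_null_acoustics <- function(n_ind = 5, n_per_cell = 12, p = 7) {
  types <- c("A", "B", "C")
  n <- n_ind * length(types) * n_per_cell
  d <- tibble::tibble(
    individual_id = rep(sprintf("i%02d", seq_len(n_ind)),
                        each = length(types) * n_per_cell),
    sub_pulse_type = rep(rep(types, each = n_per_cell), times = n_ind))
  feats <- matrix(stats::rnorm(n * p), n, p)
  colnames(feats) <- paste0("v", seq_len(p))
  dplyr::bind_cols(d, tibble::as_tibble(feats))
}

# Independent oracle: exact one-sided ("less") paired Wilcoxon signed-rank
# p-value by exhaustive enumeration of all 2^n sign assignments.
enum_signrank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- as.vector(signs %*% rk)
  list(V = v_obs, p_less = mean(v_null <= v_obs))
}

# Independent oracle: brute-force open-interval membership scan.
brute_band_counts <- function(r, bands = isochrony_bands()) {
  on <- 0L; off <- 0L; outside <- 0L
  for (v in r) {
    if (v > bands$on[1] && v < bands$on[2]) on <- on + 1L
    else if ((v > bands$off_low[1] && v < bands$off_low[2]) ||
             (v > bands$off_high[1] && v < bands$off_high[2])) off <- off + 1L
    else outside <- outside + 1L
  }
  c(on = on, off = off, outside = outside)
}
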