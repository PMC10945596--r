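test_that("nested ratios divide sub-pulse IOIs by the enclosing pulse IOI", {
  tab <- make_pulse_events(
    c(0, 2, 4), sub_onsets = list(
      `1` = data.frame(onset = c(0.1, 0.2), type = "grumble_sub_pulse"),
      `3` = data.frame(onset = c(4.1, 4.2), type = "grumble_sub_pulse")))
  full <- compute_iois(tab, "full_pulse")
  sub <- compute_iois(tab, "grumble_sub_pulse")
  nst <- pair_nested_iois(sub, full)
  # pulse 1 IOI = 2.0, sub IOI = 0.1 -> 0.05; pulse 3 is last (no IOI): dropped
  expect_equal(nrow(nst), 1)
  expect_equal(nst$nested_ratio, 0.05)

  # unresolvable parent is skipped with a message, not fatal
  sub_orphan <- sub
  sub_orphan$parent_pulse_id <- NA_character_
  expect_message(res <- pair_nested_iois(sub_orphan, full), "unresolvable")
  expect_equal(nrow(res), 0)
})

test_that("nested ratios are invariant to global time rescaling", {
  base <- make_pulse_events(
    c(0, 2, 4, 6), sub_onsets = list(
      `1` = data.frame(onset = c(0.1, 0.25, 0.4), type = "bubble_sub_pulse"),
      `2` = data.frame(onset = c(2.1, 2.3), type = "bubble_sub_pulse")))
  scaled_df <- tibble::as_tibble(base)
  scaled_df$begin_time <- scaled_df$begin_time * 7.3
  scaled_df$end_time <- scaled_df$end_time * 7.3
  scaled <- as_event_table(scaled_df, infer_parents = FALSE)
  n1 <- pair_nested_iois(compute_iois(base, "bubble_sub_pulse"),
                         compute_iois(base, "full_pulse"))
  n2 <- pair_nested_iois(compute_iois(scaled, "bubble_sub_pulse"),
                         compute_iois(scaled, "full_pulse"))
  expect_equal(n1$nested_ratio, n2$nested_ratio, tolerance = 1e-12)
})

test_that("nested density peak finds the cross-stratum tempo relation", {
  withr::with_seed(13, {
    d <- nested_density_peak(rnorm(1000, 0.05, 0.005))
    expect_lt(abs(d$peak_location - 0.05), 0.005)
  })
  tiny <- nested_density_peak(0.05 * exp(rnorm(50, 0, 0.001)))
  expect_lt(abs(tiny$peak_location - 0.05), 0.003)
  expect_error(nested_density_peak(rep(0.05, 5)),
               class = "rn_insufficient_data")
})

test_that("the generator's tempo nesting is recovered at several depths", {
  # sub tempo = rho x pulse tempo; peak must recover rho within 10%
  for (rho in c(0.02, 0.046, 0.1)) {
    spec <- synthetic_spec(
      n_calls = 12, sub_tempo_means = c(grumble_sub_pulse = rho * 1.696,
                                        sub_pulse_transitory = 0.239,
                                        bubble_sub_pulse = 0.186),
      full_tempo_cv = 0.1, sub_tempo_cv = 0.1)
    ds <- generate_dataset(spec, seed = 100 + round(1000 * rho))
    full <- filter_iois(compute_iois(ds$events, "full_pulse"))
    sub <- compute_iois(ds$events, "grumble_sub_pulse")
    pk <- nested_density_peak(pair_nested_iois(sub, full))$peak_location
    expect_lt(abs(pk / rho - 1), 0.1)
  }
})

test_that("quartile extents separate peaked from flat units", {
  # sharply peaked: central extent smaller, one-sided p significant
  withr::with_seed(17, {
    peaked <- tibble::tibble(
      nested_ratio = rnorm(20 * 16, 0.05, 0.005),
      long_call_id = rep(sprintf("lc%02d", 1:20), each = 16))
    qt <- quartile_extent_test(peaked)
    expect_lt(qt$p_value, 0.05)
    expect_gte(mean(qt$central_extents < qt$peripheral_extents), 0.95)
  })

  # uniform units: no peakedness, p roughly uniform
  pu <- withr::with_seed(19, vapply(1:100, function(i) {
    u <- tibble::tibble(nested_ratio = runif(15 * 12),
                        long_call_id = rep(sprintf("u%02d", 1:15), each = 12))
    quartile_extent_test(u)$p_value
  }, numeric(1)))
  expect_gt(mean(pu), 0.35)
  expect_lt(mean(pu <= 0.05), 0.15)

  # identical extents in every unit -> all differences zero -> p = 1
  evenly <- tibble::tibble(
    # exact binary spacing so block ranges are bit-identical across units
    nested_ratio = rep(0:11, 8) * 0.25 + rep(0:7, each = 12) * 16,
    long_call_id = rep(sprintf("e%02d", 1:8), each = 12))
  qt0 <- quartile_extent_test(evenly)
  expect_equal(qt0$p_value, 1)
  expect_equal(qt0$W, 0)

  expect_error(quartile_extent_test(
    tibble::tibble(nested_ratio = runif(20),
                   long_call_id = rep(c("a", "b"), each = 10))),
    class = "rn_insufficient_data")
})

test_that("signed-rank p-values equal exhaustive sign-flip enumeration", {
  withr::with_seed(23, {
    for (n in c(5, 8, 12)) {
      x <- rnorm(n); y <- rnorm(n)
      ht <- wilcox.test(x, y, paired = TRUE, alternative = "less",
                        exact = TRUE)
      oracle <- enum_signrank(x, y)
      expect_equal(unname(ht$statistic), oracle$V)
      expect_equal(ht$p.value, oracle$p_less, tolerance = 1e-12)
    }
  })
  # and through the quartile test itself on a small unit set
  withr::with_seed(29, {
    dat <- tibble::tibble(
      nested_ratio = rnorm(10 * 12, 0.05, 0.004),
      long_call_id = rep(sprintf("w%02d", 1:10), each = 12))
    qt <- quartile_extent_test(dat)
    oracle <- enum_signrank(qt$central_extents, qt$peripheral_extents)
    expect_equal(qt$W, oracle$V)
    expect_equal(qt$p_value, oracle$p_less, tolerance = 1e-12)
  })
})
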