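test_that("IOIs come from consecutive same-type elements of one call", {
  tab <- make_pulse_events(c(0, 1.7, 3.4))
  s <- compute_iois(tab, "full_pulse")
  expect_equal(s$t_k, c(1.7, 1.7))
  expect_equal(s$sequence_id, c(1L, 1L))

  expect_error(compute_iois(tab, "squeak"), class = "rn_type_error")
  expect_equal(nrow(compute_iois(tab, "bubble_sub_pulse")), 0)
})

test_that("within_parent keeps sub-pulse IOIs inside one pulse", {
  tab <- make_pulse_events(
    c(0, 2), sub_onsets = list(
      `1` = data.frame(onset = c(0.2, 0.4), type = "bubble_sub_pulse"),
      `2` = data.frame(onset = c(2.2, 2.4), type = "bubble_sub_pulse")))
  s <- compute_iois(tab, "bubble_sub_pulse")  # within_parent default TRUE
  expect_equal(nrow(s), 2)                    # one IOI per pulse
  expect_equal(s$t_k, c(0.2, 0.2))
  expect_equal(s$sequence_id, c(1L, 2L))      # never a cross-pulse IOI

  s2 <- compute_iois(tab, "bubble_sub_pulse", within_parent = FALSE)
  expect_equal(nrow(s2), 3)                   # includes the 1.8 s bridge
})

test_that("duration filter uses strict bounds and splits sequences", {
  s <- make_ioi(c(0.02, 1.0, 6.0))
  expect_equal(filter_iois(s)$t_k, 1.0)
  expect_equal(nrow(filter_iois(make_ioi(0.025))), 0)  # boundary excluded

  # removing an interior interval must not let ratios bridge the gap
  s3 <- filter_iois(make_ioi(c(1.0, 0.01, 1.0)))
  expect_equal(nrow(s3), 2)
  expect_equal(length(unique(s3$sequence_id)), 2)
  expect_equal(nrow(compute_ratios(s3)), 0)
})

test_that("rhythm ratios match the defining formula and band labels", {
  r1 <- compute_ratios(make_ioi(c(1.0, 1.0)))
  expect_equal(r1$r_k, 0.5)
  expect_equal(as.character(r1$band), "on")

  r2 <- compute_ratios(make_ioi(c(1.0, 3.0)))
  expect_equal(r2$r_k, 0.25)
  expect_equal(as.character(r2$band), "outside")

  r3 <- compute_ratios(make_ioi(c(1.0, 1.2)))
  expect_equal(r3$r_k, 1.0 / 2.2, tolerance = 1e-12)
  expect_equal(as.character(r3$band), "on")

  # band boundaries are open: a ratio exactly on a boundary is in no band
  expect_equal(as.character(classify_band(c(0.440, 0.555, 0.400, 0.600))),
               rep("outside", 4))
})

test_that("band counting conserves totals and matches a brute-force scan", {
  rr <- structure(tibble::tibble(
    r_k = c(0.5, 0.5, 0.42, 0.3), band = classify_band(c(0.5, 0.5, 0.42, 0.3)),
    element_type = "full_pulse", individual_id = "I1", long_call_id = "LC1",
    sequence_id = 1L), class = c("rn_ratio", class(tibble::tibble())))
  bc <- band_counts(rr)
  expect_equal(setNames(bc$count, as.character(bc$band)),
               c(on = 2L, off = 1L, outside = 1L))
  expect_equal(bc$band_width[as.character(bc$band) == "on"], 0.115)
  expect_equal(bc$band_width[as.character(bc$band) == "off"], 0.085)

  expect_equal(nrow(band_counts(rr[0, ])), 0)

  withr::with_seed(99, {
    for (i in 1:20) {
      r <- runif(200)
      lab <- classify_band(r)
      counts <- table(lab)
      oracle <- brute_band_counts(r)
      expect_equal(as.integer(counts[c("on", "off", "outside")]),
                   as.integer(oracle))
      expect_equal(sum(counts), length(r))  # conservation
    }
  })
})

test_that("uniform ratios split between bands proportionally to width", {
  withr::with_seed(4, {
    r <- runif(1000, 0.4, 0.6)
    counts <- brute_band_counts(r)
    # expectation 575:425; binomial sd ~15.6
    expect_lt(abs(counts[["on"]] - 575), 60)
  })
})

test_that("density peaks locate unimodal and bimodal ratio distributions", {
  withr::with_seed(8, {
    x <- rnorm(500, 0.5, 0.01)
    d <- ratio_density(x, n_grid = 2048)
    expect_lt(abs(d$peak_location - 0.5), 0.01)
    expect_equal(d$peak_location, d$restricted_peak_location)
    # density integrates to ~1 (trapezoid over a grid finer than the bw)
    dx <- diff(d$grid[1:2])
    integral <- (sum(d$density) - (d$density[1] + d$density[2048]) / 2) * dx
    expect_lt(abs(integral - 1), 1e-3)
  })

  # alternating 1 s / 2 s intervals: ratios exactly 1/3 and 2/3
  r_alt <- compute_ratios(make_ioi(rep(c(1, 2), 30)))
  expect_true(all(abs(sort(unique(r_alt$r_k)) - c(1 / 3, 2 / 3)) < 1e-12))
  d_alt <- ratio_density(r_alt)
  peaks <- density_local_maxima(d_alt)
  expect_true(any(abs(peaks - 1 / 3) < 0.02))
  expect_true(any(abs(peaks - 2 / 3) < 0.02))
  expect_false(any(peaks > 0.44 & peaks < 0.555))

  expect_error(ratio_density(rep(0.5, 9)), class = "rn_insufficient_data")
})

test_that("tempo summaries report interval and rate moments", {
  ts <- tempo_summary(make_ioi(c(2, 2, 2)))
  expect_equal(ts$mean_t, 2)
  expect_equal(ts$sd_t, 0)
  expect_equal(ts$mean_rate, 0.5)
  expect_equal(ts$n, 3)
  expect_error(tempo_summary(make_ioi(numeric())),
               class = "rn_insufficient_data")

  # mean rate is mean(1/t), distinct from 1/mean(t) for skewed intervals
  sk <- tempo_summary(make_ioi(c(0.1, 0.1, 0.8)))
  expect_gt(sk$mean_rate, 1 / sk$mean_t)
})

test_that("ratios are scale-invariant and reverse to their mirror image", {
  withr::with_seed(21, {
    for (i in 1:10) {
      t <- rlnorm(30, 0, 0.4)
      r <- compute_ratios(make_ioi(t))$r_k
      r_scaled <- compute_ratios(make_ioi(t * runif(1, 0.1, 100)))$r_k
      expect_equal(r, r_scaled, tolerance = 1e-12)
      r_rev <- compute_ratios(make_ioi(rev(t)))$r_k
      expect_equal(sort(r_rev), sort(1 - r), tolerance = 1e-12)
    }
  })
})

test_that("perfect isochrony gives exactly 0.5 and 100% on-isochrony", {
  r <- compute_ratios(make_ioi(rep(0.73, 50)))
  expect_true(all(r$r_k == 0.5))
  expect_true(all(r$band == "on"))
})

test_that("widening the filter window never loses intervals", {
  withr::with_seed(31, {
    t <- rlnorm(200, 0, 1)
    s <- make_ioi(t)
    n_narrow <- nrow(filter_iois(s, 0.1, 2))
    n_wide <- nrow(filter_iois(s, 0.05, 4))
    expect_gte(n_wide, n_narrow)
    kept_narrow <- filter_iois(s, 0.1, 2)$source_event_id
    kept_wide <- filter_iois(s, 0.05, 4)$source_event_id
    expect_true(all(kept_narrow %in% kept_wide))
  })
})

test_that("isochronous trains with <=10% jitter put the peak near 0.5", {
  hits <- withr::with_seed(55, vapply(1:10, function(i) {
    t <- 1.5 * exp(rnorm(300, 0, sqrt(log(1 + 0.1^2))))
    d <- ratio_density(compute_ratios(make_ioi(t)))
    d$restricted_peak_location
  }, numeric(1)))
  expect_gte(mean(hits > 0.48 & hits < 0.52), 0.9)
})
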