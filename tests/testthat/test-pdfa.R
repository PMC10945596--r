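test_that("LDA separates well-separated clusters and matches MASS::lda", {
  withr::with_seed(3, {
    n <- 60
    x <- rbind(matrix(rnorm(n * 2), n, 2),
               matrix(rnorm(n * 2, mean = 6), n, 2))  # Mahalanobis ~ 6 sd
    y <- rep(c("a", "b"), each = n)
    fit <- fit_lda(x, y)
    acc <- mean(as.character(predict(fit, x)$class) == y)
    expect_gte(acc, 0.99)

    # shuffled labels: accuracy collapses to about the max prior (0.5)
    ys <- sample(y)
    fit_s <- fit_lda(x, ys)
    acc_s <- mean(as.character(predict(fit_s, x)$class) == ys)
    expect_lt(abs(acc_s - 0.5), 0.15)

    # independent oracle: same classifications as MASS::lda
    x3 <- matrix(rnorm(90 * 4), 90, 4) +
      matrix(rep(c(0, 1, 2), each = 30), 90, 4)
    y3 <- rep(c("a", "b", "c"), each = 30)
    mine <- predict(fit_lda(x3, y3), x3)$class
    mass <- predict(MASS::lda(x3, grouping = y3), x3)$class
    expect_equal(as.character(mine), as.character(mass))
  })

  expect_error(fit_lda(matrix(rnorm(10), 5, 2), rep("a", 5)),
               class = "rn_design_error")
})

test_that("singular covariance errors unless a ridge is supplied", {
  withr::with_seed(5, {
    x <- matrix(rnorm(40), 20, 2)
    x <- cbind(x, x[, 1])  # exactly collinear
    y <- rep(c("a", "b"), each = 10)
    expect_error(fit_lda(x, y), "ridge", class = "rn_singular_error")
    fit <- fit_lda(x, y, ridge = 1e-6)
    expect_s3_class(fit, "rn_lda")
  })
})

test_that("the permutation scheme never crosses control blocks", {
  withr::with_seed(11, {
    for (i in 1:20) {
      blocks <- sample(letters[1:4], 60, replace = TRUE)
      labels <- sample(c("x", "y", "z"), 60, replace = TRUE)
      perm <- rhythmnest:::permute_within_blocks(labels, blocks)
      for (b in unique(blocks)) {
        expect_equal(sort(perm[blocks == b]), sort(labels[blocks == b]))
      }
    }
  })
})

test_that("pDFA is reproducible, affine-invariant, and detects separation", {
  withr::with_seed(41, {
    sep <- make_null_acoustics(n_ind = 4, n_per_cell = 10)
    shift <- c(A = 0, B = 4, C = 8)  # 4 pooled SDs between neighbours
    sep$v1 <- sep$v1 + shift[sep$sub_pulse_type]
  })
  vars <- paste0("v", 1:7)
  r1 <- pdfa_crossed(sep, vars, test_factor = "sub_pulse_type",
                     n_sel = 10, n_perm = 199, seed = 9)
  r2 <- pdfa_crossed(sep, vars, test_factor = "sub_pulse_type",
                     n_sel = 10, n_perm = 199, seed = 9)
  expect_identical(r1$null_distribution, r2$null_distribution)
  expect_identical(r1$p_value, r2$p_value)

  expect_gte(r1$observed_pct_selected, 95)
  expect_equal(r1$p_value, 1 / 200)  # attainable minimum, add-one rule

  # affine rescaling of a feature changes nothing (same seed)
  resc <- sep
  resc$v3 <- resc$v3 * 1000 - 77
  r3 <- pdfa_crossed(resc, vars, test_factor = "sub_pulse_type",
                     n_sel = 10, n_perm = 199, seed = 9)
  expect_equal(r3$p_value, r1$p_value)
  expect_equal(r3$observed_pct_selected, r1$observed_pct_selected,
               tolerance = 1e-8)
})

test_that("null-world features give chance-level classification", {
  null_d <- withr::with_seed(43, make_null_acoustics(n_ind = 5,
                                                     n_per_cell = 12))
  res <- pdfa_crossed(null_d, paste0("v", 1:7),
                      test_factor = "sub_pulse_type",
                      n_sel = 10, n_perm = 200, seed = 3)
  expect_gte(res$p_value, 0.05)
  # balanced 3-class labels: chance near 1/3, inflated above it by
  # resubstitution on finite selections (the same reason the field's
  # expected values exceed 1/k)
  expect_gt(res$expected_pct, 33)
  expect_lt(res$expected_pct, 50)
  expect_lt(abs(res$observed_pct_selected - res$expected_pct), 8)
})

test_that("design problems are reported specifically", {
  d <- withr::with_seed(47, make_null_acoustics(n_ind = 3, n_per_cell = 6))
  expect_error(pdfa_crossed(d, c("v1", "nope"),
                            test_factor = "sub_pulse_type"),
               "nope", class = "rn_schema_error")

  # a 1-case cell is dropped with a warning naming it
  d1 <- d[-(which(d$individual_id == "i01" & d$sub_pulse_type == "A")[-1]), ]
  expect_warning(
    pdfa_crossed(d1, paste0("v", 1:7), test_factor = "sub_pulse_type",
                 n_sel = 2, n_perm = 100, seed = 1),
    "i01:A")

  # all labels constant within every control level -> unusable design
  d2 <- d; d2$sub_pulse_type <- "A"
  expect_error(suppressWarnings(
    pdfa_crossed(d2, paste0("v", 1:7), test_factor = "sub_pulse_type",
                 n_perm = 100)),
    class = "rn_design_error")
})
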