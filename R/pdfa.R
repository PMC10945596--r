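#' Fisher linear discriminant
#'
#' Linear discriminant analysis with pooled within-class covariance and
#' priors proportional to class frequencies. A ridge term can be added to
#' the pooled covariance (as a fraction of its mean diagonal) when it is
#' singular or near-singular. This is the classifier inside the permuted
#' discriminant analysis; it matches the classification rule of
#' [MASS::lda()] at `ridge = 0`.
#'
#' @param x Numeric matrix (cases x features).
#' @param y Class labels (>= 2 classes with >= 2 cases each).
#' @param ridge Ridge fraction added to the pooled covariance diagonal
#'   (default 0).
#' @return Object of class `rn_lda` with `means`, `cov`, `cov_inv`,
#'   `priors`, `classes`.
#' @export
fit_lda <- function(x, y, ridge = 0) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2)
    rn_abort("LDA needs >= 2 classes", "rn_design_error")
  tab <- table(y)
  if (any(tab < 2))
    rn_abort(sprintf("every class needs >= 2 cases (violated: %s)",
                     paste(names(tab)[tab < 2], collapse = ", ")),
             "rn_design_error")
  if (!all(is.finite(x)))
    rn_abort("features must be finite", "rn_validation_error")
  k <- nlevels(y); n <- nrow(x); p <- ncol(x)
  means <- do.call(rbind, lapply(levels(y), function(cl)
    colMeans(x[y == cl, , drop = FALSE])))
  rownames(means) <- levels(y)
  centred <- x - means[as.integer(y), , drop = FALSE]
  S <- crossprod(centred) / (n - k)
  if (ridge > 0) S <- S + diag(ridge * mean(diag(S)), p)
  cov_inv <- tryCatch(solve(S), error = function(e) e)
  if (inherits(cov_inv, "error"))
    rn_abort(paste("pooled within-class covariance is singular;",
                   "drop collinear variables or set a ridge > 0"),
             "rn_singular_error")
  structure(list(means = means, cov = S, cov_inv = cov_inv,
                 priors = as.numeric(tab) / n, classes = levels(y)),
            class = "rn_lda")
}

#' @param object An `rn_lda` model.
#' @param newdata Numeric matrix of cases to classify.
#' @param ... Unused.
#' @return `predict.rn_lda`: list with `class` (factor) and `posterior`
#'   (matrix).
#' @rdname fit_lda
#' @export
predict.rn_lda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  # Linear discriminant scores: x' S^-1 mu_c - mu_c' S^-1 mu_c / 2 + log pi_c
  A <- object$cov_inv %*% t(object$means)              # p x k
  const <- -0.5 * colSums(t(object$means) * A) + log(object$priors)
  scores <- sweep(newdata %*% A, 2, const, "+")
  post <- exp(scores - apply(scores, 1, max))
  post <- post / rowSums(post)
  colnames(post) <- object$classes
  cls <- factor(object$classes[max.col(scores, ties.method = "first")],
                levels = object$classes)
  list(class = cls, posterior = post)
}

# Permute labels independently within each block (control-factor level);
# a label never moves across blocks.
permute_within_blocks <- function(labels, blocks) {
  out <- labels
  for (b in unique(blocks)) {
    i <- which(blocks == b)
    out[i] <- labels[i][sample.int(length(i))]
  }
  out
}

#' Crossed permuted discriminant function analysis
#'
#' Tests whether a test factor (e.g. sub-pulse type) is acoustically
#' distinct while controlling for a crossed control factor (e.g.
#' individual identity). Observed classification: `n_sel` times, a
#' balanced subset is drawn (within each control level, the same number of
#' cases per test level, equal to that level's smallest cell), an LDA is
#' fit on the subset, and the percentage correct is recorded on the
#' selected cases (resubstitution) and on the held-out remainder
#' (cross-classification); percentages are averaged over selections. Null
#' distribution: `n_perm` times, test-factor labels are permuted within
#' control-factor blocks only (that is what controls for individual
#' identity) and one selection/DFA cycle is run. The p-value uses the
#' add-one convention, `p = (1 + #(null >= observed)) / (n_perm + 1)`, so
#' its minimum is `1/(n_perm + 1)`; the expected (chance) percentage is
#' the mean of the null distribution.
#'
#' Cells with fewer than 2 cases are dropped with a warning, as are
#' control levels left with fewer than 2 test levels.
#'
#' @param data Data frame of cases.
#' @param variables Character vector of numeric feature columns.
#' @param test_factor,control_factor Column names of the test and control
#'   factors.
#' @param n_sel Number of random balanced selections (default 100).
#' @param n_perm Number of permutations (default 1000; minimum 100).
#' @param n_to_sel Optional cap on the per-cell selection size.
#' @param ridge Ridge fraction passed to [fit_lda()].
#' @param standardize Z-score the features first (LDA is affine-invariant,
#'   so this only affects numerical conditioning; default `FALSE`).
#' @param seed Optional RNG seed; with a fixed seed the full result is
#'   reproducible.
#' @return Object of class `rn_pdfa`: `observed_pct_selected`,
#'   `observed_pct_cross`, `expected_pct`, `p_value`,
#'   `null_distribution`, `n_sel`, `n_perm`, `n_cases`, `dropped_cells`.
#' @export
pdfa_crossed <- function(data, variables,
                         test_factor = "sub_pulse_type",
                         control_factor = "individual_id",
                         n_sel = 100, n_perm = 1000, n_to_sel = NULL,
                         ridge = 0, standardize = FALSE, seed = NULL) {
  if (n_perm < 100)
    rn_abort("n_perm must be >= 100", "rn_design_error")
  if (n_sel < 1)
    rn_abort("n_sel must be >= 1", "rn_design_error")
  missing_cols <- setdiff(c(variables, test_factor, control_factor),
                          names(data))
  if (length(missing_cols))
    rn_abort(sprintf("missing column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             "rn_schema_error")
  x <- as.matrix(data[, variables, drop = FALSE])
  storage.mode(x) <- "double"
  if (standardize) x <- scale(x)
  y <- factor(as.character(data[[test_factor]]))
  g <- factor(as.character(data[[control_factor]]))

  # Drop unusable cells, then control levels with < 2 remaining test levels.
  cell <- table(g, y)
  keep <- rep(TRUE, nrow(x))
  dropped <- character()
  for (gi in rownames(cell)) for (yi in colnames(cell)) {
    if (cell[gi, yi] > 0 && cell[gi, yi] < 2) {
      keep[g == gi & y == yi] <- FALSE
      dropped <- c(dropped, sprintf("%s:%s (n=%d)", gi, yi, cell[gi, yi]))
    }
  }
  lv_ok <- names(which(apply(table(g[keep], droplevels(y[keep])) >= 2, 1, sum) >= 2))
  bad_levels <- setdiff(unique(as.character(g[keep])), lv_ok)
  if (length(bad_levels)) {
    dropped <- c(dropped, sprintf("%s:<2 test levels>", bad_levels))
    keep[g %in% bad_levels] <- FALSE
  }
  if (length(dropped))
    warning(sprintf("pdfa_crossed: dropped cells/levels: %s",
                    paste(dropped, collapse = "; ")), call. = FALSE)
  x <- x[keep, , drop = FALSE]
  y <- droplevels(y[keep]); g <- droplevels(g[keep])
  if (nlevels(y) < 2 || nlevels(g) < 1 || nrow(x) < 4)
    rn_abort(sprintf(
      "unusable design after cell dropping (%d cases, %d test levels, %d control levels)",
      nrow(x), nlevels(y), nlevels(g)), "rn_design_error")

  # Per-control-level selection size: smallest nonzero cell in that level.
  m_per_level <- apply(table(g, y), 1, function(r) min(r[r > 0]))
  if (!is.null(n_to_sel)) m_per_level <- pmin(m_per_level, n_to_sel)

  one_cycle <- function(labels) {
    sel <- logical(length(labels))
    for (gi in levels(g)) {
      m <- m_per_level[[gi]]
      for (yi in unique(labels[g == gi])) {
        i <- which(g == gi & labels == yi)
        sel[i[sample.int(length(i), min(m, length(i)))]] <- TRUE
      }
    }
    fit <- fit_lda(x[sel, , drop = FALSE], labels[sel], ridge = ridge)
    pred_sel <- predict(fit, x[sel, , drop = FALSE])$class
    pct_sel <- 100 * mean(as.character(pred_sel) ==
                            as.character(labels[sel]))
    pct_cross <- NA_real_
    if (any(!sel)) {
      pred_x <- predict(fit, x[!sel, , drop = FALSE])$class
      pct_cross <- 100 * mean(as.character(pred_x) ==
                                as.character(labels[!sel]))
    }
    c(pct_sel, pct_cross)
  }

  run <- function() {
    obs <- vapply(seq_len(n_sel), function(i) one_cycle(y), numeric(2))
    null <- vapply(seq_len(n_perm), function(i) {
      one_cycle(permute_within_blocks(y, g))[1]
    }, numeric(1))
    list(obs = rowMeans(obs, na.rm = TRUE), null = null)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  observed <- res$obs[1]
  p <- (1 + sum(res$null >= observed)) / (n_perm + 1)
  structure(list(
    observed_pct_selected = observed,
    observed_pct_cross = res$obs[2],
    expected_pct = mean(res$null),
    p_value = p,
    null_distribution = res$null,
    n_sel = n_sel, n_perm = n_perm, n_cases = nrow(x),
    test_factor = test_factor, control_factor = control_factor,
    variables = variables, dropped_cells = dropped, seed = seed
  ), class = "rn_pdfa")
}

#' @export
print.rn_pdfa <- function(x, ...) {
  cat("Crossed permuted discriminant function analysis\n")
  cat(sprintf("  test factor %s within control factor %s (%d cases, %d variables)\n",
              x$test_factor, x$control_factor, x$n_cases,
              length(x$variables)))
  cat(sprintf("  correctly classified, selected cases: %.1f%% (expected %.1f%%)\n",
              x$observed_pct_selected, x$expected_pct))
  cat(sprintf("  correctly cross-classified:           %.1f%%\n",
              x$observed_pct_cross))
  cat(sprintf("  p = %.4g (%d permutations within %s blocks)\n",
              x$p_value, x$n_perm, x$control_factor))
  invisible(x)
}
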