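# build rows so that the condition-mean matrix equals `cm` exactly
rows_from_condition_means <- function(cm, n_subjects = 2) {
  x <- cm[rep(seq_len(nrow(cm)), each = n_subjects), , drop = FALSE]
  list(x = x, conditions = rep(rownames(cm) %||% seq_len(nrow(cm)),
                               each = n_subjects),
       subjects = rep(seq_len(n_subjects), nrow(cm)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("identical condition means yield no latent variables", {
  inp <- rows_from_condition_means(matrix(5, 3, 4))
  fit <- task_pls(inp$x, inp$conditions, inp$subjects, n_perm = 0, n_boot = 0)
  expect_identical(length(fit$d), 0L)
})

test_that("two conditions give exactly one LV with a symmetric contrast", {
  set.seed(31)
  cm <- matrix(rnorm(10), 2, 5)
  inp <- rows_from_condition_means(cm)
  fit <- task_pls(inp$x, inp$conditions, inp$subjects, n_perm = 0, n_boot = 0)
  expect_identical(length(fit$d), 1L)
  expect_equal(abs(fit$design_saliences[, 1]), rep(1 / sqrt(2), 2),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$covariance_explained, 1)
})

test_that("singular structure matches an independent eigendecomposition oracle", {
  set.seed(32)
  cm <- matrix(rnorm(18), 3, 6)
  inp <- rows_from_condition_means(cm)
  fit <- task_pls(inp$x, inp$conditions, inp$subjects, n_perm = 0, n_boot = 0)
  centered <- sweep(cm, 2, colMeans(cm))
  # oracle: singular values from the eigenvalues of the centered Gram matrix
  ev <- eigen(tcrossprod(centered), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(fit$d, sqrt(ev[ev > 1e-12]), tolerance = 1e-10)
  expect_equal(sum(fit$d^2), sum(centered^2), tolerance = 1e-8)
  # salience orthonormality on both sides
  k <- length(fit$d)
  expect_equal(crossprod(fit$design_saliences), diag(k), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(crossprod(fit$feature_saliences), diag(k), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("feature scaling is equivariant: singular values scale, saliences and BSRs do not", {
  set.seed(33)
  x <- matrix(rnorm(60), 15, 4) + rep(c(0, 1, 0), each = 5)
  conds <- rep(c("a", "b", "c"), each = 5)
  subj <- rep(1:5, 3)
  f1 <- task_pls(x, conds, subj, n_perm = 0, n_boot = 100, seed = 99)
  f2 <- task_pls(10 * x, conds, subj, n_perm = 0, n_boot = 100, seed = 99)
  expect_equal(f2$d, 10 * f1$d, tolerance = 1e-10)
  expect_equal(f2$design_saliences, f1$design_saliences, tolerance = 1e-10)
  expect_equal(f2$bootstrap_ratios, f1$bootstrap_ratios, tolerance = 1e-8)
})

test_that("fixed seed makes permutation p and bootstrap ratios reproducible", {
  set.seed(34)
  x <- matrix(rnorm(120), 15, 8) + rep(c(0, 0.8, 0), each = 5)
  conds <- rep(c("a", "b", "c"), each = 5)
  subj <- rep(1:5, 3)
  f1 <- task_pls(x, conds, subj, n_perm = 60, n_boot = 60, seed = 7)
  f2 <- task_pls(x, conds, subj, n_perm = 60, n_boot = 60, seed = 7)
  expect_identical(f1$perm_p, f2$perm_p)
  expect_identical(f1$bootstrap_ratios, f2$bootstrap_ratios)
})

test_that("an overwhelming effect drives the permutation p to its 0/n floor", {
  # with 12 subjects the chance of a permutation aligning every subject's
  # planted condition (the only way to reach the observed singular value)
  # is negligible
  set.seed(35)
  ns <- 12
  x <- matrix(rnorm(3 * ns * 2, sd = 0.01), 3 * ns, 2)
  x[seq_len(ns), 1] <- x[seq_len(ns), 1] + 50
  fit <- task_pls(x, rep(c("a", "b", "c"), each = ns), rep(seq_len(ns), 3),
                  n_perm = 100, n_boot = 0, seed = 1)
  expect_identical(fit$perm_p[1], 0)
})

test_that("permutation rejection rate is calibrated under the exchangeable null", {
  set.seed(36)
  rejections <- vapply(seq_len(200), function(i) {
    inp <- null_pls_input(n_subjects = 12, n_features = 15)
    fit <- task_pls(inp$x, inp$conditions, inp$subjects, n_perm = 100,
                    n_boot = 0)
    fit$perm_p[1] < 0.05
  }, logical(1))
  rate <- mean(rejections)
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / 200)
  expect_gte(rate, 0.05 - ci_half - 1e-9)
  expect_lte(rate, 0.05 + ci_half + 1e-9)
})

test_that("duplicating every subject shrinks bootstrap SEs and grows the ratios", {
  set.seed(37)
  x <- matrix(rnorm(90), 15, 6) + rep(c(0, 1.2, 0), each = 5)
  conds <- rep(c("a", "b", "c"), each = 5)
  f1 <- task_pls(x, conds, rep(1:5, 3), n_perm = 0, n_boot = 200, seed = 5)
  x2 <- rbind(x, x)
  f2 <- task_pls(x2, c(conds, conds), c(rep(1:5, 3), rep(6:10, 3)),
                 n_perm = 0, n_boot = 200, seed = 5)
  expect_gt(median(abs(f2$bootstrap_ratios[, 1]) - abs(f1$bootstrap_ratios[, 1])), 0)
})

test_that("zero-SD bootstrap guard distinguishes no-evidence from degeneracy", {
  # all subjects identical: bootstrap resampling cannot vary the saliences
  cm <- cbind(c(0, 1, 0), 0, 0)
  rownames(cm) <- c("a", "b", "c")
  inp <- rows_from_condition_means(cm, n_subjects = 4)
  fit <- task_pls(inp$x, inp$conditions, inp$subjects, n_perm = 0,
                  n_boot = 50, seed = 2)
  expect_identical(fit$bootstrap_ratios[2, 1], 0)   # zero salience, zero SD
  expect_true(is.na(fit$bootstrap_ratios[1, 1]))    # nonzero salience, zero SD
})

test_that("input validation rejects unbalanced designs and degenerate sizes", {
  x <- matrix(rnorm(20), 5, 4)
  expect_error(task_pls(x, c("a", "a", "b", "b", "b"), c(1, 2, 1, 2, 2)),
               "exactly one row per condition")
  expect_error(task_pls(x[1:4, ], rep("a", 4), 1:4), "at least 2 conditions")
  inp <- rows_from_condition_means(matrix(rnorm(6), 2, 3), n_subjects = 2)
  expect_error(task_pls(inp$x, inp$conditions, inp$subjects, n_perm = 0,
                        n_boot = 10), "at least 3 subjects")
})

test_that("missing feature columns are dropped and recorded before the fit", {
  set.seed(38)
  inp <- null_pls_input(n_subjects = 4, n_features = 6)
  inp$x[2, 3] <- NA
  expect_message(fit <- task_pls(inp$x, inp$conditions, inp$subjects,
                                 n_perm = 0, n_boot = 0), "dropping 1")
  expect_identical(fit$dropped_columns, 3L)
  expect_identical(nrow(fit$feature_saliences), 5L)
})

test_that("stable windows report maximal threshold-crossing runs with signs", {
  fi <- data.frame(channel = rep(c("A", "B"), each = 10),
                   time_ms = rep(seq(0, 90, 10), 2))
  fit <- structure(list(
    bootstrap_ratios = cbind(c(rep(0, 3), 2.5, 2.6, 2.2, rep(0, 4),
                               rep(-3, 2), rep(0, 8))),
    feature_saliences = cbind(c(rep(0, 3), rep(0.5, 3), rep(0, 4),
                                rep(-0.4, 2), rep(0, 8))),
    feature_index = fi), class = "task_pls")
  w <- stable_windows(fit, 1, threshold = 2, min_run = 3)
  expect_identical(nrow(w), 1L)
  expect_identical(w$channel, "A")
  expect_equal(c(w$start, w$end), c(30, 50))
  expect_identical(w$sign, 1)
  # shorter minimum run also surfaces the 2-point negative run on B
  w2 <- stable_windows(fit, 1, threshold = 2, min_run = 2)
  expect_identical(nrow(w2), 2L)
  expect_identical(w2$sign[w2$channel == "B"], -1)
  # all ratios below threshold: empty report
  w3 <- stable_windows(fit, 1, threshold = 5, min_run = 1)
  expect_identical(nrow(w3), 0L)
})
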