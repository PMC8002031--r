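make_trials <- function(rt, participant = 1, session = 1, lexicality = "word",
                        correct = 1) {
  data.frame(participant = participant, session = session,
             lexicality = lexicality, rt_ms = rt,
             correct = rep_len(correct, length(rt)))
}

test_that("RT outlier rule removes exactly the trials beyond 2.5 SD of single-pass statistics", {
  # all-equal RTs: SD 0, nothing removed
  eq <- make_trials(rep(500, 100))
  expect_identical(nrow(exclude_rt_outliers(eq)$retained), 100L)

  # 99 x 500 ms plus one 5000 ms: only the extreme trial exceeds the
  # criterion computed from the full group
  g <- make_trials(c(rep(500, 99), 5000))
  m <- mean(g$rt_ms); s <- sd(g$rt_ms)
  expect_true(abs(5000 - m) > 2.5 * s && abs(500 - m) < 2.5 * s)
  res <- exclude_rt_outliers(g)
  expect_identical(nrow(res$retained), 99L)
  expect_true(all(res$retained$rt_ms == 500))
  expect_identical(res$report$n_excluded, 1L)

  # large-n Gaussian: exclusion fraction near the analytic two-tailed
  # normal mass beyond 2.5 SD
  set.seed(4)
  big <- make_trials(rnorm(2e5, 800, 100))
  frac <- 1 - nrow(exclude_rt_outliers(big)$retained) / 2e5
  expect_lt(abs(frac - 2 * pnorm(-2.5)), 0.002)

  # groups of < 2 trials: SD undefined, retained whole, with a warning
  lone <- make_trials(c(500, 900), participant = c(1, 2))
  expect_warning(res <- exclude_rt_outliers(lone), "< 2 trials")
  expect_identical(nrow(res$retained), 2L)

  expect_error(exclude_rt_outliers(make_trials(c(500, -1))), "positive")
})

test_that("statistics are computed once: the rule is not iterated", {
  set.seed(8)
  g <- make_trials(c(rnorm(60, 500, 20), 700, 2000))
  first <- exclude_rt_outliers(g)$retained
  second <- exclude_rt_outliers(first)$retained
  # re-running on the cleaned set uses new, tighter statistics and can
  # remove more: single-pass semantics are observable
  expect_lt(nrow(second), nrow(first))
})

test_that("incorrect-trial removal keeps exactly the correct rows", {
  allc <- make_trials(1:10 * 100)
  expect_identical(exclude_incorrect(allc), allc)
  mixed <- make_trials(1:8 * 100, correct = c(1, 0, 1, 1, 0, 0, 1, 1))
  expect_identical(nrow(exclude_incorrect(mixed)), 5L)
  none <- exclude_incorrect(make_trials(1:4 * 100, correct = 0))
  expect_identical(nrow(none), 0L)
  # downstream averaging refuses the empty set clearly
  cfg <- tiny_config(trials = 4, seed = 1)
  ep <- generate_epochs(cfg, 1, 1)
  expect_error(average_erp(subset_trials(ep, integer(0))), "empty")
})

test_that("segment partition follows the sequential-remainder rule", {
  p950 <- partition_segments(950)
  expect_identical(attr(p950, "sizes"), rep(95L, 10))
  expect_identical(which(p950 == 1), 1:95)

  p1003 <- partition_segments(1003)
  expect_identical(attr(p1003, "sizes"),
                   c(101L, 101L, 101L, rep(100L, 7)))
  expect_identical(which(p1003 == 2), 102:202)

  expect_identical(attr(partition_segments(10), "sizes"), rep(1L, 10))
  expect_error(partition_segments(9), "cannot partition")

  # property: sizes within 1 of each other, summing to n, chronological
  for (n in c(17, 40, 101, 957, 1999)) {
    p <- partition_segments(n)
    sz <- attr(p, "sizes")
    expect_identical(sum(sz), as.integer(n))
    expect_lte(max(sz) - min(sz), 1L)
    expect_true(!is.unsorted(p))
  }
})

test_that("ERP averaging baseline-corrects per trial and is linear in trial sets", {
  cfg <- tiny_config(n_participants = 1, trials = 12, seed = 6,
                     channels = eeg_montage()[1:3])
  ep <- generate_epochs(cfg, 1, 1)
  erp <- average_erp(ep)
  bl <- ep$times >= -200 & ep$times < 0
  expect_lt(max(abs(rowMeans(erp$mean[, bl]))), 1e-9)

  # single trial: identity up to its own baseline mean
  e1 <- average_erp(subset_trials(ep, 1))
  raw <- ep$data[1, , ]
  expect_equal(e1$mean, raw - rowMeans(raw[, bl]), ignore_attr = TRUE)

  # +v / -v pair cancels
  sym <- ep
  sym$data[2, , ] <- -sym$data[1, , ]
  e2 <- average_erp(subset_trials(sym, 1:2))
  expect_lt(max(abs(e2$mean)), 1e-12)

  # linearity: concatenation equals the trial-count-weighted mean
  ea <- average_erp(subset_trials(ep, 1:4))
  eb <- average_erp(subset_trials(ep, 5:12))
  eall <- average_erp(ep)
  expect_equal(eall$mean, (4 * ea$mean + 8 * eb$mean) / 12, tolerance = 1e-12)
})

test_that("a planted component is recovered by averaging at its latency", {
  amp <- -3
  comp <- erp_component("N170", c("Fp1", "Fp2"), 185, 90, rep(amp, 3))
  cfg <- tiny_config(n_participants = 1, trials = 500, seed = 10,
                     channels = eeg_montage()[1:3], components = list(comp),
                     noise_sd = 5)
  ep <- generate_epochs(cfg, 1, 1)
  erp <- average_erp(ep)
  peak_sample <- which.min(abs(ep$times - 185))
  got <- erp$mean["Fp1", peak_sample]
  expect_lt(abs(got - amp), 3 * 5 / sqrt(500) + 0.2)
  # channel without the component stays near zero there
  expect_lt(abs(erp$mean["F7", peak_sample]), 3 * 5 / sqrt(500))
})

test_that("the epochs container round-trips through the text format", {
  cfg <- tiny_config(n_participants = 1, trials = 3, seed = 12,
                     channels = eeg_montage()[1:2])
  ep <- generate_epochs(cfg, 1, 1)
  path <- file.path(tempdir(), "epochs_rt")
  write_epochs(ep, path)
  back <- read_epochs(path)
  expect_equal(back$data, ep$data, tolerance = 1e-6)
  expect_identical(back$channels, ep$channels)
  expect_equal(back$times, ep$times)
  expect_equal(back$trial_meta$rt_ms, ep$trial_meta$rt_ms, tolerance = 1e-6)
  unlink(path, recursive = TRUE)
})
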