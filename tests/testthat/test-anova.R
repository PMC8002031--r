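make_cells <- function(y, n, a = 2, b = 3) {
  data.frame(participant = rep(seq_len(n), each = a * b),
             lexicality = rep(rep(c("word", "nonword"), each = b), n),
             session = rep(rep(seq_len(b), a), n),
             dv = y)
}

test_that("constant data give zero F everywhere", {
  tab <- make_cells(rep(7, 24), 4)
  fit <- rm_anova(tab, "dv", c("lexicality", "session"))
  expect_equal(fit$F, rep(0, 3))
  expect_equal(fit$eta_g, rep(0, 3))
})

test_that("two-level effects trivially satisfy sphericity with epsilon 1", {
  set.seed(41)
  tab <- make_cells(rnorm(24), 4)
  fit <- rm_anova(tab, "dv", c("lexicality", "session"))
  lex <- fit[fit$effect == "lexicality", ]
  expect_identical(lex$gg_eps, 1)
  expect_true(is.na(lex$mauchly_W))
  expect_false(lex$gg_applied)
})

test_that("F statistics match the aov() error-strata oracle on a constructed dataset", {
  set.seed(42)
  y <- round(rnorm(24, 700, 60) +
               rep(c(0, -20, -40, 60, 30, 10), 4), 1)
  tab <- make_cells(y, 4)
  fit <- rm_anova(tab, "dv", c("lexicality", "session"))

  tab$participant <- factor(tab$participant)
  tab$lexicality <- factor(tab$lexicality)
  tab$session <- factor(tab$session)
  or <- summary(aov(dv ~ lexicality * session +
                      Error(participant / (lexicality * session)), tab))
  getF <- function(stratum, row) or[[stratum]][[1]][row, "F value"]
  expect_equal(fit$F[fit$effect == "lexicality"],
               getF("Error: participant:lexicality", 1), tolerance = 1e-8)
  expect_equal(fit$F[fit$effect == "session"],
               getF("Error: participant:session", 1), tolerance = 1e-8)
  expect_equal(fit$F[fit$effect == "lexicality:session"],
               getF("Error: participant:lexicality:session", 1),
               tolerance = 1e-8)

  # sums-of-squares conservation across the full partition
  strata <- attr(fit, "strata")
  expect_equal(strata[["total"]],
               sum(fit$SS) + sum(fit$error_SS) + strata[["subjects"]],
               tolerance = 1e-8)

  # generalized eta-squared from its defining ratio, recomputed directly
  denom <- strata[["subjects"]] + sum(fit$error_SS)
  expect_equal(fit$eta_g, fit$SS / (fit$SS + denom), tolerance = 1e-12)
})

test_that("Mauchly and Greenhouse-Geisser agree with the car mlm oracle", {
  skip_if_not_installed("car")
  set.seed(43)
  n <- 10
  base <- matrix(rnorm(n * 3, 700, 50), n, 3)
  base[, 3] <- base[, 3] + 2 * base[, 1] # break sphericity
  tab <- make_cells(rep(NA_real_, n * 6), n)
  for (p in seq_len(n)) {
    tab$dv[tab$participant == p & tab$lexicality == "word"] <- base[p, ]
    tab$dv[tab$participant == p & tab$lexicality == "nonword"] <-
      base[p, ] + c(10, 40, 90) + rnorm(3, 0, 5)
  }
  fit <- rm_anova(tab, "dv", c("lexicality", "session"))

  wide <- matrix(NA_real_, n, 6)
  for (p in seq_len(n)) {
    wide[p, 1:3] <- tab$dv[tab$participant == p & tab$lexicality == "word"]
    wide[p, 4:6] <- tab$dv[tab$participant == p & tab$lexicality == "nonword"]
  }
  idata <- data.frame(lexicality = factor(rep(c("w", "n"), each = 3)),
                      session = factor(rep(1:3, 2)))
  mlm <- lm(wide ~ 1)
  av <- car::Anova(mlm, idata = idata, idesign = ~ lexicality * session,
                   type = "III")
  s <- suppressWarnings(summary(av, multivariate = FALSE)) # HF eps > 1 note
  sph <- s$sphericity.tests
  gg <- s$pval.adjustments
  ses <- fit[fit$effect == "session", ]
  expect_equal(ses$mauchly_W, sph["session", "Test statistic"],
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(ses$mauchly_p, sph["session", "p-value"], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(ses$gg_eps, gg["session", "GG eps"], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(ses$p_gg, gg["session", "Pr(>F[GG])"], tolerance = 1e-6,
               ignore_attr = TRUE)
  uni <- s$univariate.tests
  expect_equal(ses$F, uni["session", "F value"], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("epsilon stays within its theoretical bounds on random covariance structures", {
  set.seed(44)
  for (i in 1:200) {
    k <- sample(3:5, 1)
    n <- k + sample(2:6, 1)
    y <- matrix(rnorm(n * k), n, k) %*% matrix(rnorm(k * k), k, k)
    tab <- data.frame(participant = rep(seq_len(n), each = k),
                      cond = rep(seq_len(k), n), dv = as.vector(t(y)))
    fit <- rm_anova(tab, "dv", "cond")
    expect_gte(fit$gg_eps, 1 / (k - 1) - 1e-9)
    expect_lte(fit$gg_eps, 1 + 1e-9)
  }
})

test_that("paired follow-ups match the closed-form t and d_z", {
  set.seed(45)
  tab <- data.frame(participant = rep(1:20, 2),
                    session = rep(c(1, 2), each = 20),
                    mean_rt = c(rnorm(20, 800, 90), rnorm(20, 750, 90)))
  fu <- paired_followups(tab, "mean_rt", "session", list(c(1, 2)),
                         alpha = 0.017)
  d1 <- tab$mean_rt[1:20] - tab$mean_rt[21:40]
  expect_equal(fu$t, mean(d1) / (sd(d1) / sqrt(20)), tolerance = 1e-12)
  expect_equal(fu$d, mean(d1) / sd(d1), tolerance = 1e-12)
  expect_equal(fu$p, t.test(tab$mean_rt[1:20], tab$mean_rt[21:40],
                            paired = TRUE)$p.value, tolerance = 1e-12)

  # identical samples: t = 0, d = 0... but SD of differences is 0, so the
  # result is flagged undefined rather than reported as a number
  same <- tab
  same$mean_rt[21:40] <- same$mean_rt[1:20]
  fu0 <- paired_followups(same, "mean_rt", "session", list(c(1, 2)))
  expect_false(fu0$defined)
  expect_true(is.na(fu0$t))
  # constant nonzero differences likewise undefined
  shift <- tab
  shift$mean_rt[21:40] <- shift$mean_rt[1:20] - 1
  fu1 <- paired_followups(shift, "mean_rt", "session", list(c(1, 2)))
  expect_false(fu1$defined)
})

test_that("incomplete designs are rejected", {
  set.seed(46)
  tab <- make_cells(rnorm(24), 4)
  expect_error(rm_anova(tab[-1, ], "dv", c("lexicality", "session")),
               "complete")
  tab$dv[3] <- NA
  expect_error(rm_anova(tab, "dv", c("lexicality", "session")), "missing")
})
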