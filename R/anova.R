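#' Summarise trial rows into a participant-level behavioural table
#'
#' Applies the exclusion chain (RT outliers per participant x session x
#' lexicality, then incorrect responses for the RT summary) and aggregates
#' to one row per participant x session x lexicality: mean RT over correct
#' outlier-free trials and proportion correct over outlier-free trials.
#'
#' @param trials Data frame of trial rows (participant, session, lexicality,
#'   rt_ms, correct).
#' @param sd_crit RT-outlier criterion in SD units.
#' @return Data frame with columns participant, session, lexicality,
#'   mean_rt, accuracy, n_trials; attribute `exclusion_report`.
#' @export
behavioural_table <- function(trials, sd_crit = 2.5) {
  ex <- exclude_rt_outliers(trials, sd_crit = sd_crit)
  kept <- ex$retained
  correct <- exclude_incorrect(kept)
  key <- function(d) interaction(d$participant, d$session, d$lexicality,
                                 drop = FALSE, lex.order = TRUE)
  acc <- tapply(kept$correct, key(kept), mean)
  rt <- tapply(correct$rt_ms, key(correct), mean)
  n <- tapply(correct$rt_ms, key(correct), length)
  cells <- expand.grid(participant = sort(unique(trials$participant)),
                       session = sort(unique(trials$session)),
                       lexicality = sort(unique(trials$lexicality)),
                       stringsAsFactors = FALSE)
  k <- interaction(cells$participant, cells$session, cells$lexicality,
                   lex.order = TRUE)
  cells$mean_rt <- as.numeric(rt[as.character(k)])
  cells$accuracy <- as.numeric(acc[as.character(k)])
  cells$n_trials <- as.integer(n[as.character(k)])
  structure(cells, exclusion_report = ex$report)
}

# Orthonormal contrast matrix for a k-level within factor.
orth_contrasts <- function(k) {
  ct <- stats::contr.helmert(k)
  sweep(ct, 2, sqrt(colSums(ct^2)), "/")
}

# Mauchly sphericity test and Greenhouse-Geisser epsilon from per-subject
# effect-contrast scores (n x df matrix of orthonormal contrast scores).
sphericity_stats <- function(scores) {
  n <- nrow(scores)
  p <- ncol(scores)
  s <- stats::cov(scores)
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(ev)^2 / (p * sum(ev^2))
  if (!is.finite(eps)) eps <- 1 # degenerate zero-variance contrasts
  if (p < 2 || any(ev <= 0)) {
    return(list(W = NA_real_, p_mauchly = NA_real_, eps = max(eps, 1 / p)))
  }
  W <- prod(ev) / (mean(ev)^p)
  d <- 1 - (2 * p^2 + p + 2) / (6 * p * (n - 1))
  chi2 <- -(n - 1) * d * log(W)
  df <- p * (p + 1) / 2 - 1
  list(W = W, p_mauchly = stats::pchisq(chi2, df, lower.tail = FALSE),
       eps = eps)
}

#' Repeated-measures ANOVA with sphericity handling
#'
#' A fully within-subject one- or two-factor ANOVA (e.g. lexicality x
#' session, or session alone for simple main effects) from an explicit
#' sums-of-squares decomposition: each effect is tested against
#' its own effect-by-subject interaction. For effects with more than one
#' numerator degree of freedom, Mauchly's sphericity test is run on the
#' orthonormal effect contrasts and, when it rejects at `sphericity_alpha`,
#' the Greenhouse-Geisser corrected p-value (epsilon-scaled degrees of
#' freedom) is adopted. Effect size is generalized eta-squared with all
#' subject-related variance in the denominator
#' (`SS_effect / (SS_effect + SS_subjects + all error SS)`).
#'
#' @param table Data frame with one row per subject x cell.
#' @param dv Name of the dependent-variable column.
#' @param within Names of the one or two within-subject factor columns.
#' @param id Name of the subject-id column.
#' @param sphericity_alpha Mauchly alpha below which the GG correction is
#'   applied.
#' @return Object of class `anova_rm`: a data frame of effects with columns
#'   SS, df1, df2, F, p, eta_g, mauchly_W, mauchly_p, gg_eps, df1_gg,
#'   df2_gg, p_gg, p_reported, gg_applied; attribute `strata` holds the
#'   full SS partition.
#' @export
rm_anova <- function(table, dv, within, id = "participant",
                     sphericity_alpha = 0.05) {
  stopifnot(is.data.frame(table), dv %in% names(table),
            all(within %in% names(table)), id %in% names(table),
            length(within) %in% 1:2)
  if (length(within) == 1)
    return(rm_anova_oneway(table, dv, within, id, sphericity_alpha))
  fa <- factor(table[[within[1]]])
  fb <- factor(table[[within[2]]])
  fs <- factor(table[[id]])
  a <- nlevels(fa); b <- nlevels(fb); n <- nlevels(fs)
  if (n < 3) stop("repeated-measures ANOVA needs at least 3 subjects")
  y <- table[[dv]]
  if (anyNA(y)) stop("missing cell(s) in the within-subject design")
  if (any(table(fs, fa, fb) != 1))
    stop("design must be complete: one observation per subject per cell")

  gm <- mean(y)
  m_s <- tapply(y, fs, mean); m_a <- tapply(y, fa, mean); m_b <- tapply(y, fb, mean)
  m_ab <- tapply(y, list(fa, fb), mean)
  m_as <- tapply(y, list(fa, fs), mean)
  m_bs <- tapply(y, list(fb, fs), mean)

  ss_s <- a * b * sum((m_s - gm)^2)
  ss_a <- n * b * sum((m_a - gm)^2)
  ss_b <- n * a * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, m_b, "+") + gm)^2)
  ss_as <- b * sum((m_as - outer(m_a, m_s, "+") + gm)^2)
  ss_bs <- a * sum((m_bs - outer(m_b, m_s, "+") + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_abs <- ss_tot - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs

  df <- list(a = a - 1, b = b - 1, ab = (a - 1) * (b - 1),
             as = (a - 1) * (n - 1), bs = (b - 1) * (n - 1),
             abs = (a - 1) * (b - 1) * (n - 1))
  denom_g <- ss_s + ss_as + ss_bs + ss_abs

  # per-subject cell matrix (subject x ab cells, cells ordered b-within-a)
  cellmat <- matrix(NA_real_, n, a * b)
  cell_idx <- (as.integer(fa) - 1) * b + as.integer(fb)
  cellmat[cbind(as.integer(fs), cell_idx)] <- y
  ca <- orth_contrasts(a); cb <- orth_contrasts(b)
  one_a <- matrix(1 / sqrt(a), a, 1); one_b <- matrix(1 / sqrt(b), b, 1)
  contr <- list(a = kronecker(ca, one_b), b = kronecker(one_a, cb),
                ab = kronecker(ca, cb))

  effects <- data.frame(effect = c(within[1], within[2],
                                   paste(within, collapse = ":")),
                        SS = c(ss_a, ss_b, ss_ab),
                        error_SS = c(ss_as, ss_bs, ss_abs),
                        df1 = c(df$a, df$b, df$ab),
                        df2 = c(df$as, df$bs, df$abs),
                        stringsAsFactors = FALSE)
  effects$F <- (effects$SS / effects$df1) / (effects$error_SS / effects$df2)
  effects$F[effects$SS == 0] <- 0 # constant effect: no evidence, not 0/0
  effects$p <- stats::pf(effects$F, effects$df1, effects$df2, lower.tail = FALSE)
  effects$eta_g <- ifelse(effects$SS == 0, 0, effects$SS / (effects$SS + denom_g))

  sph <- lapply(contr, function(cm) sphericity_stats(cellmat %*% cm))
  effects$mauchly_W <- vapply(sph, `[[`, 0, "W")
  effects$mauchly_p <- vapply(sph, `[[`, 0, "p_mauchly")
  effects$gg_eps <- vapply(sph, `[[`, 0, "eps")
  one_df <- effects$df1 < 2
  effects$mauchly_W[one_df] <- NA_real_
  effects$mauchly_p[one_df] <- NA_real_
  effects$gg_eps[one_df] <- 1
  effects$df1_gg <- effects$gg_eps * effects$df1
  effects$df2_gg <- effects$gg_eps * effects$df2
  effects$p_gg <- stats::pf(effects$F, effects$df1_gg, effects$df2_gg,
                            lower.tail = FALSE)
  effects$gg_applied <- !one_df & !is.na(effects$mauchly_p) &
    effects$mauchly_p < sphericity_alpha
  effects$p_reported <- ifelse(effects$gg_applied, effects$p_gg, effects$p)

  structure(effects, class = c("anova_rm", "data.frame"),
            strata = c(subjects = ss_s, total = ss_tot,
                       error_a = ss_as, error_b = ss_bs, error_ab = ss_abs),
            n = n, dv = dv)
}

# One-factor fully-within ANOVA: the effect is tested against its
# subject-by-effect interaction; eta_g keeps subject variance in the
# denominator.
rm_anova_oneway <- function(table, dv, within, id, sphericity_alpha) {
  fb <- factor(table[[within]])
  fs <- factor(table[[id]])
  b <- nlevels(fb); n <- nlevels(fs)
  if (n < 3) stop("repeated-measures ANOVA needs at least 3 subjects")
  y <- table[[dv]]
  if (anyNA(y)) stop("missing cell(s) in the within-subject design")
  if (any(table(fs, fb) != 1))
    stop("design must be complete: one observation per subject per cell")
  gm <- mean(y)
  m_s <- tapply(y, fs, mean); m_b <- tapply(y, fb, mean)
  ss_s <- b * sum((m_s - gm)^2)
  ss_b <- n * sum((m_b - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_bs <- ss_tot - ss_s - ss_b
  cellmat <- matrix(NA_real_, n, b)
  cellmat[cbind(as.integer(fs), as.integer(fb))] <- y
  sph <- sphericity_stats(cellmat %*% orth_contrasts(b))
  eff <- data.frame(effect = within, SS = ss_b, error_SS = ss_bs,
                    df1 = b - 1, df2 = (b - 1) * (n - 1),
                    stringsAsFactors = FALSE)
  eff$F <- (eff$SS / eff$df1) / (eff$error_SS / eff$df2)
  eff$F[eff$SS == 0] <- 0
  eff$p <- stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  eff$eta_g <- ifelse(eff$SS == 0, 0, eff$SS / (eff$SS + ss_s + ss_bs))
  eff$mauchly_W <- sph$W
  eff$mauchly_p <- sph$p_mauchly
  eff$gg_eps <- sph$eps
  if (eff$df1 < 2) {
    eff$mauchly_W <- NA_real_; eff$mauchly_p <- NA_real_; eff$gg_eps <- 1
  }
  eff$df1_gg <- eff$gg_eps * eff$df1
  eff$df2_gg <- eff$gg_eps * eff$df2
  eff$p_gg <- stats::pf(eff$F, eff$df1_gg, eff$df2_gg, lower.tail = FALSE)
  eff$gg_applied <- eff$df1 >= 2 & !is.na(eff$mauchly_p) &
    eff$mauchly_p < sphericity_alpha
  eff$p_reported <- ifelse(eff$gg_applied, eff$p_gg, eff$p)
  structure(eff, class = c("anova_rm", "data.frame"),
            strata = c(subjects = ss_s, total = ss_tot, error_b = ss_bs),
            n = n, dv = dv)
}

#' @export
print.anova_rm <- function(x, digits = 4, ...) {
  cat("Repeated-measures ANOVA on", attr(x, "dv"),
      "(n =", attr(x, "n"), "subjects)\n")
  show <- data.frame(effect = x$effect,
                     F = signif(x$F, digits),
                     df1 = ifelse(x$gg_applied, round(x$df1_gg, 2), x$df1),
                     df2 = ifelse(x$gg_applied, round(x$df2_gg, 2), x$df2),
                     p = signif(x$p_reported, digits),
                     eta_g = signif(x$eta_g, digits),
                     GG = ifelse(x$gg_applied, "yes", ""))
  print(show, row.names = FALSE)
  invisible(x)
}

#' Paired-sample follow-up t-tests with Cohen's d
#'
#' Paired t-tests between levels of one factor, holding the rest of the
#' design fixed, with Cohen's d computed as the mean difference divided by
#' the SD of the differences (d_z) and a significance flag at a supplied
#' (typically Bonferroni-adjusted) alpha. Zero-variance difference vectors
#' are reported as undefined rather than producing an infinite statistic.
#'
#' @param table Participant-level data frame (one row per subject x level).
#' @param dv Dependent-variable column name.
#' @param factor_name Column holding the compared factor.
#' @param pairs List of length-2 vectors of level labels to compare.
#' @param id Subject-id column name.
#' @param alpha Per-comparison alpha (e.g. 0.017 for three Bonferroni-corrected
#'   comparisons).
#' @return Data frame with columns level1, level2, t, df, se, p, d,
#'   significant, defined.
#' @export
paired_followups <- function(table, dv, factor_name, pairs, id = "participant",
                             alpha = 0.017) {
  out <- lapply(pairs, function(pr) {
    d1 <- table[table[[factor_name]] == pr[1], c(id, dv)]
    d2 <- table[table[[factor_name]] == pr[2], c(id, dv)]
    if (anyDuplicated(d1[[id]]) || anyDuplicated(d2[[id]]))
      stop("one observation per subject per level required; ",
           "aggregate or subset the remaining factors first")
    m <- merge(d1, d2, by = id)
    diffs <- m[[paste0(dv, ".x")]] - m[[paste0(dv, ".y")]]
    n <- length(diffs)
    sdd <- stats::sd(diffs)
    if (!is.finite(sdd) || sdd == 0) {
      return(data.frame(level1 = pr[1], level2 = pr[2], t = NA_real_,
                        df = n - 1, se = 0, p = NA_real_, d = NA_real_,
                        significant = NA, defined = FALSE,
                        stringsAsFactors = FALSE))
    }
    se <- sdd / sqrt(n)
    tt <- mean(diffs) / se
    p <- 2 * stats::pt(-abs(tt), n - 1)
    data.frame(level1 = pr[1], level2 = pr[2], t = tt, df = n - 1, se = se,
               p = p, d = mean(diffs) / sdd, significant = p < alpha,
               defined = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
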