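#' Configuration for a full simulated-study run
#'
#' Bundles the simulation, entropy and inference settings for
#' [run_study()]. The two alpha families follow the analysis design:
#' across-session latent variables are tested at 0.05, within-session
#' analyses (one per session) are Bonferroni corrected at 0.008.
#'
#' @param sim A [sim_config()].
#' @param mse An [mse_params()].
#' @param n_perm Permutations per PLS analysis (0 = descriptive only).
#' @param n_boot Bootstrap samples per PLS analysis (0 = none).
#' @param bsr_threshold Bootstrap-ratio stability threshold.
#' @param alpha_across Alpha for the across-session analyses.
#' @param alpha_within Alpha for each within-session analysis.
#' @param n_segments Number of chronological within-session segments.
#' @param min_run_ms Minimum stable-window duration for ERP features, ms.
#' @param mse_window Entropy window: `"full"` epoch or `"post"`-stimulus.
#' @param seed Master seed for the resampling streams (the simulation uses
#'   `sim$seed`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), mse = mse_params(),
                       n_perm = 500, n_boot = 500, bsr_threshold = 2,
                       alpha_across = 0.05, alpha_within = 0.008,
                       n_segments = 10, min_run_ms = 10,
                       mse_window = c("full", "post"), seed = sim$seed) {
  stopifnot(inherits(sim, "sim_config"), inherits(mse, "mse_params"),
            n_perm >= 0, n_boot >= 0, n_segments >= 2)
  structure(list(sim = sim, mse = mse, n_perm = n_perm, n_boot = n_boot,
                 bsr_threshold = bsr_threshold, alpha_across = alpha_across,
                 alpha_within = alpha_within, n_segments = n_segments,
                 min_run_ms = min_run_ms,
                 mse_window = match.arg(mse_window),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full simulated study
#'
#' Executes the complete analysis chain on synthetic data: per participant
#' and session, epochs are generated, RT outliers (+/- `sd_crit` SD per
#' participant x session x lexicality) and incorrect trials are excluded,
#' and the retained trials are averaged into session-level ERPs and
#' multiscale-entropy matrices as well as `n_segments` chronological
#' within-session segment means. Eight task-PLS analyses are then fitted
#' (ERP and MSE features, each across sessions and within each of the three
#' sessions), with permutation tests, bootstrap ratios and stable-window
#' extraction, followed by the behavioural chain (repeated-measures ANOVAs
#' on RT and accuracy plus session follow-ups per lexicality). The whole
#' run is deterministic in the configured seeds.
#'
#' @param config A [run_config()].
#' @return Object of class `study_report`: `analyses` (named list of 8
#'   entries, each with `fit`, `windows`, `alpha`, `significant_lvs`,
#'   `status`), `behavioural` (table, anova_rt, anova_accuracy, followups),
#'   and `log` (exclusion and undefined-entropy counts).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sim <- config$sim
  n_sub <- sim$n_participants
  n_ses <- sim$n_sessions
  subj_ids <- as.character(seq_len(n_sub))
  ses_ids <- paste0("session", seq_len(n_ses))
  seg_ids <- paste0("segment", seq_len(config$n_segments))

  erp_across <- mse_across <- stats::setNames(
    replicate(n_sub, list(), simplify = FALSE), subj_ids)
  erp_within <- mse_within <- stats::setNames(
    replicate(n_ses, stats::setNames(replicate(n_sub, list(), simplify = FALSE),
                                     subj_ids), simplify = FALSE), ses_ids)
  trial_rows <- list()
  excl_log <- list()
  undefined_entropy <- 0L
  total_entropy_cells <- 0L

  for (p in seq_len(n_sub)) {
    for (s in seq_len(n_ses)) {
      ep <- generate_epochs(sim, p, s)
      trial_rows[[length(trial_rows) + 1L]] <- ep$trial_meta
      ex <- exclude_rt_outliers(ep$trial_meta,
                                group_vars = c("participant", "session",
                                               "lexicality"))
      kept <- exclude_incorrect(ex$retained)
      if (nrow(kept) < config$n_segments)
        stop("participant ", p, " session ", s, ": only ", nrow(kept),
             " retained trials; cannot form ", config$n_segments, " segments")
      excl_log[[length(excl_log) + 1L]] <-
        data.frame(participant = p, session = s,
                   n_total = nrow(ep$trial_meta),
                   n_rt_excluded = nrow(ep$trial_meta) - nrow(ex$retained),
                   n_incorrect = nrow(ex$retained) - nrow(kept))
      ep <- subset_trials(ep, match(rownames(kept), rownames(ep$trial_meta)))

      erp_across[[p]][[ses_ids[s]]] <-
        average_erp(ep, condition = ses_ids[s])$mean
      tri_ent <- mse_trials(ep, config$mse, config$mse_window)
      undefined_entropy <- undefined_entropy + sum(is.na(tri_ent))
      total_entropy_cells <- total_entropy_cells + length(tri_ent)
      mse_across[[p]][[ses_ids[s]]] <-
        mse_average(tri_ent, ep$channels, ep$sampling_rate,
                    condition = ses_ids[s])$entropy

      seg <- partition_segments(dim(ep$data)[1], config$n_segments)
      for (g in seq_len(config$n_segments)) {
        idx <- which(seg == g)
        erp_within[[s]][[p]][[seg_ids[g]]] <-
          average_erp(subset_trials(ep, idx), condition = seg_ids[g])$mean
        mse_within[[s]][[p]][[seg_ids[g]]] <-
          mse_average(tri_ent, ep$channels, ep$sampling_rate,
                      condition = seg_ids[g], trials = idx)$entropy
      }
    }
  }

  times <- sim$times
  scales <- seq_len(config$mse$n_scales)
  min_run_erp <- max(1L, round(config$min_run_ms * sim$sampling_rate / 1000))
  analyses <- list()
  fit_family <- function(maps, positions, posname, alpha, min_run, label, slot) {
    if (config$n_perm == 0 && config$n_boot == 0) status <- "descriptive"
    else status <- "run"
    st <- stack_features(maps, sim$channels, positions, posname)
    fit <- task_pls(st$x, st$conditions, st$subjects,
                    n_perm = config$n_perm, n_boot = config$n_boot,
                    seed = stream_seed(config$seed, 9000L + slot, 0L, 3L),
                    feature_index = st$feature_index)
    sig <- if (!is.null(fit$perm_p)) which(fit$perm_p < alpha) else integer(0)
    windows <- NULL
    if (!is.null(fit$bootstrap_ratios) && length(sig))
      windows <- do.call(rbind, lapply(sig, function(lv)
        stable_windows(fit, lv, config$bsr_threshold, min_run)))
    list(label = label, status = status, alpha = alpha, fit = fit,
         significant_lvs = sig, windows = windows)
  }

  analyses$erp_across <- fit_family(erp_across, times, "time_ms",
                                    config$alpha_across, min_run_erp,
                                    "ERP across sessions", 1L)
  analyses$mse_across <- fit_family(mse_across, scales, "scale",
                                    config$alpha_across, 1L,
                                    "MSE across sessions", 2L)
  for (s in seq_len(n_ses)) {
    analyses[[paste0("erp_within_", s)]] <-
      fit_family(erp_within[[s]], times, "time_ms", config$alpha_within,
                 min_run_erp, paste("ERP within session", s), 2L + as.integer(s))
    analyses[[paste0("mse_within_", s)]] <-
      fit_family(mse_within[[s]], scales, "scale", config$alpha_within,
                 1L, paste("MSE within session", s), 10L + as.integer(s))
  }

  trials <- do.call(rbind, trial_rows)
  btab <- behavioural_table(trials)
  anova_rt <- rm_anova(btab, "mean_rt", c("lexicality", "session"))
  anova_acc <- rm_anova(btab, "accuracy", c("lexicality", "session"))
  fu <- list()
  pairs <- utils::combn(sort(unique(btab$session)), 2, simplify = FALSE)
  for (lx in sort(unique(btab$lexicality))) {
    fu[[lx]] <- paired_followups(btab[btab$lexicality == lx, ], "mean_rt",
                                 "session", pairs, alpha = 0.017)
  }

  structure(list(analyses = analyses,
                 behavioural = list(table = btab, anova_rt = anova_rt,
                                    anova_accuracy = anova_acc,
                                    followups_rt = fu),
                 log = list(exclusions = do.call(rbind, excl_log),
                            undefined_entropy = undefined_entropy,
                            total_entropy_cells = total_entropy_cells),
                 config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Simulated-study report:", length(x$analyses), "PLS analysis families\n")
  for (nm in names(x$analyses)) {
    a <- x$analyses[[nm]]
    sig <- if (a$status == "descriptive") "descriptive"
    else if (length(a$significant_lvs))
      paste("significant LV(s):", paste(a$significant_lvs, collapse = ", "))
    else "no significant LV"
    cat(sprintf("  %-24s %s (alpha = %g)\n", a$label, sig, a$alpha))
  }
  ex <- x$log$exclusions
  cat(sprintf("Exclusions: %.1f%% RT outliers, then %.1f%% incorrect\n",
              100 * sum(ex$n_rt_excluded) / sum(ex$n_total),
              100 * sum(ex$n_incorrect) / (sum(ex$n_total) - sum(ex$n_rt_excluded))))
  cat("Behavioural ANOVA (RT):\n")
  print(x$behavioural$anova_rt)
  invisible(x)
}

#' Write a study report to disk
#'
#' Persists the JSON summary (singular values, covariance explained,
#' permutation p-values, significant LVs per family, behavioural ANOVA
#' rows, exclusion log) plus per-family CSVs of design saliences and stable
#' windows.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- lapply(report$analyses, function(a) {
    list(label = a$label, status = a$status, alpha = a$alpha,
         singular_values = a$fit$d,
         covariance_explained = a$fit$covariance_explained,
         perm_p = a$fit$perm_p, significant_lvs = a$significant_lvs)
  })
  jsonlite::write_json(
    list(analyses = summ,
         behavioural_anova_rt = as.data.frame(report$behavioural$anova_rt),
         exclusions = report$log$exclusions,
         undefined_entropy = report$log$undefined_entropy),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  for (nm in names(report$analyses)) {
    a <- report$analyses[[nm]]
    utils::write.csv(a$fit$design_saliences,
                     file.path(dir, paste0(nm, "_design_saliences.csv")))
    if (!is.null(a$windows))
      utils::write.csv(a$windows,
                       file.path(dir, paste0(nm, "_stable_windows.csv")),
                       row.names = FALSE)
  }
  utils::write.csv(report$behavioural$table,
                   file.path(dir, "behavioural_table.csv"), row.names = FALSE)
  invisible(dir)
}
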