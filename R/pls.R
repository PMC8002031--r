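#' Task partial least squares for condition x feature neural data
#'
#' Fits the task-PLS model: subject rows are averaged within condition, the
#' resulting condition x feature matrix is grand-mean centered column-wise
#' across conditions, and its singular value decomposition yields latent
#' variables (LVs) pairing a condition contrast (design saliences) with a
#' feature weighting (electrode/timepoint or electrode/scale saliences);
#' the singular value measures the covariance strength, and
#' `covariance_explained` for LV k is `s_k^2 / sum(s^2)`. Inference follows
#' the standard resampling scheme: permutation tests shuffle each subject's
#' condition labels independently (subject order fixed) and count how often
#' a permuted singular value reaches the observed one; bootstrap resampling
#' draws subjects with replacement (each subject's full condition set kept
#' intact), refits, aligns the resampled LVs to the original via an
#' orthogonal Procrustes rotation of the design-salience space, and reports
#' the bootstrap ratio (original feature salience / SD of its bootstrap
#' distribution) whose magnitude >= 2 is conventionally read as stable.
#'
#' @param x Numeric matrix, rows = subject-condition observations, columns =
#'   features. Columns containing missing values are dropped (and recorded
#'   in the fit) before entry.
#' @param conditions Condition label per row (>= 2 distinct values; every
#'   subject must contribute every condition exactly once).
#' @param subjects Subject id per row.
#' @param n_perm Number of permutations (0 skips the permutation test).
#' @param n_boot Number of bootstrap samples (0 skips; otherwise >= 2, and
#'   at least 3 subjects are required).
#' @param seed Optional integer seed making resampling reproducible.
#' @param feature_index Optional data frame describing the columns of `x`
#'   (e.g. channel and time_ms, or channel and scale); carried through to
#'   [stable_windows()].
#' @return Object of class `task_pls` with elements `d` (singular values),
#'   `design_saliences` (conditions x LV), `feature_saliences`
#'   (features x LV), `covariance_explained`, `perm_p`, `bootstrap_ratios`,
#'   `boot_sd`, `conditions`, `n_subjects`, `feature_index`,
#'   `dropped_columns`.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 15, 4)
#' x[1:5, 1] <- x[1:5, 1] + 3  # condition A differs on feature 1
#' fit <- task_pls(x, rep(c("A", "B", "C"), each = 5),
#'                 subjects = rep(1:5, 3), n_perm = 50, n_boot = 50, seed = 1)
#' print(fit)
task_pls <- function(x, conditions, subjects, n_perm = 500, n_boot = 500,
                     seed = NULL, feature_index = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(conditions), nrow(x) == length(subjects),
            n_perm >= 0, n_boot >= 0)
  conditions <- as.character(conditions)
  subjects <- as.character(subjects)
  cond_levels <- unique(conditions)
  subj_levels <- unique(subjects)
  nc <- length(cond_levels)
  ns <- length(subj_levels)
  if (nc < 2) stop("task PLS needs at least 2 conditions")
  if (ns < 2) stop("task PLS needs at least 2 subjects")
  tab <- table(factor(subjects, subj_levels), factor(conditions, cond_levels))
  if (any(tab != 1))
    stop("every subject must contribute exactly one row per condition")
  if (!is.null(feature_index) && nrow(feature_index) != ncol(x))
    stop("feature_index must describe every column of x")

  dropped <- which(colSums(!is.finite(x)) > 0)
  if (length(dropped)) {
    message("dropping ", length(dropped),
            " feature column(s) with missing values before PLS")
    x <- x[, -dropped, drop = FALSE]
    if (!is.null(feature_index))
      feature_index <- feature_index[-dropped, , drop = FALSE]
  }
  if (ncol(x) == 0) stop("no complete feature columns left")

  ci <- match(conditions, cond_levels)
  si <- match(subjects, subj_levels)
  core <- pls_core(x, ci, si, nc, ns)
  k <- core$k
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }

  perm_p <- NULL
  if (n_perm > 0 && k > 0) {
    exceed <- numeric(k)
    for (b in seq_len(n_perm)) {
      pci <- ci
      for (s in seq_len(ns)) {
        rows <- which(si == s)
        pci[rows] <- ci[rows][sample.int(length(rows))]
      }
      dperm <- pls_core(x, pci, si, nc, ns, values_only = TRUE)
      dperm <- c(dperm, rep(0, max(0, k - length(dperm))))
      exceed <- exceed + (dperm[seq_len(k)] >= core$d - 1e-12)
    }
    perm_p <- exceed / n_perm
  }

  bsr <- boot_sd <- NULL
  if (n_boot > 0 && k > 0) {
    if (ns < 3) stop("bootstrap resampling needs at least 3 subjects")
    if (n_boot < 2) stop("n_boot must be 0 or at least 2")
    vs <- matrix(0, ncol(x), k)
    vs2 <- matrix(0, ncol(x), k)
    used <- 0L
    for (b in seq_len(n_boot)) {
      bs <- sample.int(ns, ns, replace = TRUE)
      rows <- unlist(lapply(bs, function(s) which(si == s)), use.names = FALSE)
      bx <- x[rows, , drop = FALSE]
      bci <- ci[rows]
      bsi <- rep(seq_len(ns), each = nc)
      bc <- pls_core(bx, bci, bsi, nc, ns)
      kk <- min(k, bc$k)
      if (kk < 1) next
      # orthogonal Procrustes: rotate the bootstrap design-salience basis
      # onto the original so that axis flips/rotations across resamples do
      # not inflate the feature-salience SEs
      m <- crossprod(bc$u[, seq_len(kk), drop = FALSE],
                     core$u[, seq_len(kk), drop = FALSE])
      sv <- svd(m)
      q <- sv$u %*% t(sv$v)
      vrot <- bc$v[, seq_len(kk), drop = FALSE] %*% q
      if (kk < k) vrot <- cbind(vrot, matrix(0, ncol(x), k - kk))
      vs <- vs + vrot
      vs2 <- vs2 + vrot^2
      used <- used + 1L
    }
    if (used >= 2) {
      var_b <- (vs2 - vs^2 / used) / (used - 1)
      boot_sd <- sqrt(pmax(var_b, 0))
      bsr <- core$v / boot_sd
      bsr[boot_sd == 0 & core$v == 0] <- 0      # no signal, no instability
      bsr[boot_sd == 0 & core$v != 0] <- NA_real_ # degenerate: undefined
    }
  }

  rownames(core$u) <- cond_levels
  structure(list(d = core$d,
                 design_saliences = core$u,
                 feature_saliences = core$v,
                 covariance_explained = if (k > 0) core$d^2 / sum(core$d^2) else numeric(0),
                 perm_p = perm_p,
                 bootstrap_ratios = bsr,
                 boot_sd = boot_sd,
                 conditions = cond_levels,
                 n_subjects = ns,
                 n_perm = if (k > 0) n_perm else 0,
                 n_boot = if (k > 0) n_boot else 0,
                 feature_index = feature_index,
                 dropped_columns = dropped,
                 centered_frobenius_sq = core$frob2,
                 call = match.call()),
            class = "task_pls")
}

# Condition-mean + grand-mean-centering + SVD core. Returns singular values
# above a rank tolerance, with a deterministic sign convention (the
# largest-magnitude feature salience of each LV is positive).
pls_core <- function(x, ci, si, nc, ns, values_only = FALSE) {
  cm <- rowsum(x, ci, reorder = TRUE) / as.vector(table(ci))
  cm <- sweep(cm, 2, colMeans(cm))
  sv <- svd(cm)
  tol <- max(dim(cm)) * max(sv$d, 0) * .Machine$double.eps * 100
  keep <- which(sv$d > tol)
  if (values_only) return(sv$d[keep])
  k <- length(keep)
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(v[, j]))
    if (v[i_max, j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  list(d = sv$d[keep], u = u, v = v, k = k, frob2 = sum(cm^2))
}

#' @export
print.task_pls <- function(x, digits = 4, ...) {
  k <- length(x$d)
  cat("Task PLS:", length(x$conditions), "conditions,", x$n_subjects,
      "subjects,", nrow(x$feature_saliences), "features\n")
  if (k == 0) {
    cat("No latent variables (identical condition means).\n")
    return(invisible(x))
  }
  tab <- data.frame(LV = seq_len(k),
                    singular_value = signif(x$d, digits),
                    pct_covariance = round(100 * x$covariance_explained, 2))
  if (!is.null(x$perm_p)) tab$perm_p <- x$perm_p
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.task_pls <- function(object, bsr_threshold = 2, ...) {
  k <- length(object$d)
  n_stable <- if (!is.null(object$bootstrap_ratios))
    colSums(abs(object$bootstrap_ratios) >= bsr_threshold, na.rm = TRUE)
  else rep(NA_integer_, k)
  structure(list(fit = object, bsr_threshold = bsr_threshold,
                 n_stable = n_stable), class = "summary.task_pls")
}

#' @export
print.summary.task_pls <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$bootstrap_ratios)) {
    cat("Features with |bootstrap ratio| >=", x$bsr_threshold, "per LV:\n")
    print(stats::setNames(x$n_stable, paste0("LV", seq_along(x$n_stable))))
  }
  if (length(x$fit$dropped_columns))
    cat(length(x$fit$dropped_columns), "feature column(s) dropped for missingness\n")
  invisible(x)
}

#' @export
coef.task_pls <- function(object, type = c("feature", "design"), ...) {
  type <- match.arg(type)
  if (type == "feature") object$feature_saliences else object$design_saliences
}

#' Heatmap of bootstrap ratios for one latent variable
#'
#' Requires a `feature_index` with columns `channel` and either `time_ms` or
#' `scale`; draws channels x time (or scale) bootstrap ratios as an image.
#'
#' @param x A fitted [task_pls()] object with bootstrap ratios.
#' @param lv Latent variable to plot.
#' @param ... Passed to [graphics::image()].
#' @export
plot.task_pls <- function(x, lv = 1, ...) {
  if (is.null(x$bootstrap_ratios)) stop("fit has no bootstrap ratios")
  fi <- x$feature_index
  if (is.null(fi) || !("channel" %in% names(fi)))
    stop("plotting needs a feature_index with a 'channel' column")
  poscol <- intersect(c("time_ms", "scale"), names(fi))[1]
  if (is.na(poscol)) stop("feature_index needs a 'time_ms' or 'scale' column")
  ch <- unique(fi$channel)
  pos <- sort(unique(fi[[poscol]]))
  z <- matrix(NA_real_, length(pos), length(ch))
  z[cbind(match(fi[[poscol]], pos), match(fi$channel, ch))] <-
    x$bootstrap_ratios[, lv]
  graphics::image(pos, seq_along(ch), z, xlab = poscol, ylab = "channel",
                  yaxt = "n", main = paste0("LV", lv, " bootstrap ratios"), ...)
  graphics::axis(2, at = seq_along(ch), labels = ch, las = 2, cex.axis = 0.5)
  invisible(x)
}

#' Extract stable feature windows from bootstrap ratios
#'
#' Per channel, finds the maximal contiguous runs (in time or scale) where
#' the magnitude of the bootstrap ratio meets the threshold, and reports
#' each run with the sign of the underlying saliences. Runs shorter than
#' `min_run` positions are discarded (for ERP features sampled at 2 ms, the
#' default 5-sample minimum corresponds to a 10 ms window; for scale
#' features use `min_run = 1`).
#'
#' @param fit A fitted [task_pls()] with bootstrap ratios and a
#'   `feature_index` containing `channel` plus `time_ms` or `scale`.
#' @param lv Latent variable.
#' @param threshold Bootstrap-ratio magnitude threshold (conventionally 2.0).
#' @param min_run Minimum run length in consecutive positions.
#' @return Data frame with columns lv, channel, start, end, n_points, sign,
#'   mean_bsr; one row per maximal run, non-overlapping within channel.
#' @export
stable_windows <- function(fit, lv = 1, threshold = 2, min_run = 5) {
  stopifnot(inherits(fit, "task_pls"))
  if (is.null(fit$bootstrap_ratios)) stop("fit has no bootstrap ratios")
  fi <- fit$feature_index
  if (is.null(fi) || !("channel" %in% names(fi)))
    stop("stable_windows needs a feature_index with a 'channel' column")
  poscol <- intersect(c("time_ms", "scale"), names(fi))[1]
  if (is.na(poscol)) stop("feature_index needs a 'time_ms' or 'scale' column")
  bsr <- fit$bootstrap_ratios[, lv]
  sal <- fit$feature_saliences[, lv]
  out <- list()
  for (ch in unique(fi$channel)) {
    idx <- which(fi$channel == ch)
    idx <- idx[order(fi[[poscol]][idx])]
    hit <- !is.na(bsr[idx]) & abs(bsr[idx]) >= threshold
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (seg in which(r$values & r$lengths >= min_run)) {
      ii <- idx[starts[seg]:ends[seg]]
      out[[length(out) + 1L]] <- data.frame(
        lv = lv, channel = ch,
        start = fi[[poscol]][ii[1]], end = fi[[poscol]][ii[length(ii)]],
        n_points = length(ii),
        sign = sign(mean(sal[ii])),
        mean_bsr = mean(bsr[ii]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(lv = integer(0), channel = character(0),
                      start = numeric(0), end = numeric(0),
                      n_points = integer(0), sign = numeric(0),
                      mean_bsr = numeric(0)))
  do.call(rbind, out)
}

#' Stack per-subject, per-condition feature maps into a PLS input
#'
#' `maps` is a nested list: `maps[[subject]][[condition]]` is a numeric
#' matrix (e.g. channels x timepoints for ERPs, channels x scales for MSE)
#' with identical dimensions throughout. Rows of the output are ordered
#' condition-major to match `task_pls`'s expectations, and a feature index
#' (channel plus `time_ms` or `scale`) is built from the supplied position
#' axis.
#'
#' @param maps Nested list of matrices, subjects then conditions.
#' @param channels Channel labels (rows of each matrix).
#' @param positions Position axis for the matrix columns.
#' @param position_name `"time_ms"` or `"scale"`.
#' @return List with `x`, `conditions`, `subjects`, `feature_index`,
#'   ready to splice into [task_pls()].
#' @export
stack_features <- function(maps, channels, positions,
                           position_name = c("time_ms", "scale")) {
  position_name <- match.arg(position_name)
  subjects <- names(maps)
  if (is.null(subjects)) subjects <- as.character(seq_along(maps))
  conds <- names(maps[[1]])
  if (is.null(conds)) conds <- as.character(seq_along(maps[[1]]))
  rows <- list()
  cond_col <- subj_col <- character(0)
  for (ci in seq_along(conds)) {
    for (si in seq_along(subjects)) {
      cn <- conds[ci]; sn <- subjects[si]
      m <- maps[[si]][[ci]]
      stopifnot(nrow(m) == length(channels), ncol(m) == length(positions))
      rows[[length(rows) + 1L]] <- as.vector(m)
      cond_col <- c(cond_col, cn)
      subj_col <- c(subj_col, sn)
    }
  }
  fi <- data.frame(channel = rep(channels, length(positions)),
                   pos = rep(positions, each = length(channels)),
                   stringsAsFactors = FALSE)
  names(fi)[2] <- position_name
  list(x = do.call(rbind, rows), conditions = cond_col, subjects = subj_col,
       feature_index = fi)
}
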