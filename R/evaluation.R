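# Discrimination and calibration machinery: midrank AUROC with DeLong
# variance/covariance, paired AUC tests, exact binomial per-score mortality,
# and bootstrap calibration curves.

# DeLong structural components via midranks, O(n log n).
# v10: placement of each case among controls; v01: of each control among
# cases. mean(v10) == mean(v01) == AUC, with ties counted 1/2.
delong_components <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels must be non-missing booleans", call. = FALSE)
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    stop("scores must be finite numeric", call. = FALSE)
  }
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos < 1 || n_neg < 1) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  r_all <- rank(scores, ties.method = "average")
  r_pos <- rank(scores[labels], ties.method = "average")
  r_neg <- rank(scores[!labels], ties.method = "average")
  v10 <- (r_all[labels] - r_pos) / n_neg
  v01 <- 1 - (r_all[!labels] - r_neg) / n_pos
  list(auc = mean(v10), v10 = v10, v01 = v01, n_pos = n_pos, n_neg = n_neg)
}

#' Midrank AUROC with DeLong variance
#'
#' Estimates the area under the ROC curve as the probability that a randomly
#' chosen case outranks a randomly chosen control, counting ties as one half
#' — the Mann-Whitney estimator computed through midranks in O(n log n),
#' which is required for heavily tied ordinal scores such as SOFA values.
#' The variance is DeLong's structural-component (two-sample jackknife)
#' estimator.
#'
#' Two confidence intervals are available: the DeLong normal-approximation
#' interval (default, matching the paired-test machinery) and a
#' Hanley-McNeil binomial-style interval using the classic exponential
#' approximation to the AUC variance. Both are clipped to [0, 1].
#'
#' @param scores Numeric (possibly ordinal, tied) risk scores.
#' @param labels Logical (or 0/1) outcomes; both classes must be present.
#' @param ci_mode `"delong"` or `"binomial_style"`.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `auc_estimate`: a list with `auc`, `variance`,
#'   `ci_low`, `ci_high`, `n_pos`, `n_neg`, `ci_mode`.
#' @examples
#' auc_midrank(c(1, 2, 2, 3), c(FALSE, TRUE, FALSE, TRUE))
#' @export
auc_midrank <- function(scores, labels,
                        ci_mode = c("delong", "binomial_style"),
                        conf = 0.95) {
  ci_mode <- match.arg(ci_mode)
  comp <- delong_components(scores, labels)
  s10 <- if (comp$n_pos > 1) stats::var(comp$v10) else 0
  s01 <- if (comp$n_neg > 1) stats::var(comp$v01) else 0
  variance <- s10 / comp$n_pos + s01 / comp$n_neg
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- if (ci_mode == "delong") {
    sqrt(variance)
  } else {
    a <- comp$auc
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    sqrt((a * (1 - a) + (comp$n_pos - 1) * (q1 - a^2) +
            (comp$n_neg - 1) * (q2 - a^2)) / (comp$n_pos * comp$n_neg))
  }
  structure(list(
    auc = comp$auc,
    variance = variance,
    ci_low = max(0, comp$auc - z * se),
    ci_high = min(1, comp$auc + z * se),
    n_pos = comp$n_pos,
    n_neg = comp$n_neg,
    ci_mode = ci_mode
  ), class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUROC %.4f (95%% CI %.4f-%.4f; %d cases, %d controls)\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong paired test for two correlated AUROCs
#'
#' Compares the AUROCs of two risk scores measured on the same patients
#' against the same outcome. The variance of the AUC difference is
#' \eqn{var(A) + var(B) - 2 cov(A, B)} from the DeLong structural
#' components; the z statistic is referred to the standard normal, two
#' sided. When the two scores induce an identical ranking the difference has
#' zero variance; the result is then flagged `degenerate` with p = 1.
#'
#' @param scores_a,scores_b Numeric score vectors, same patients, same order.
#' @param labels Logical (or 0/1) outcomes.
#' @param conf Confidence level for the per-score AUC intervals.
#' @return An object of class `auc_comparison`: list with `auc_a`, `auc_b`
#'   ([auc_midrank()] results), `delta` (`auc_a - auc_b`), `var_delta`, `z`,
#'   `p`, `degenerate`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels, conf = 0.95) {
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  m <- ca$n_pos
  n <- ca$n_neg
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- ca$auc - cb$auc
  degenerate <- !(var_delta > 0) || var_delta < 1e-24
  z <- if (degenerate) 0 else delta / sqrt(var_delta)
  p <- if (degenerate) 1 else 2 * stats::pnorm(-abs(z))
  structure(list(
    auc_a = auc_midrank(scores_a, labels, conf = conf),
    auc_b = auc_midrank(scores_b, labels, conf = conf),
    delta = delta,
    var_delta = var_delta,
    z = z,
    p = p,
    degenerate = degenerate
  ), class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("dAUROC %+.4f (z = %.3f, p = %.4g%s)\n", x$delta, x$z, x$p,
              if (x$degenerate) "; degenerate" else ""))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile closed form for the exact binomial interval of an event
#' proportion: the lower bound is the 2.5% quantile of Beta(k, n - k + 1)
#' (0 when k = 0) and the upper the 97.5% quantile of Beta(k + 1, n - k)
#' (1 when k = n).
#'
#' @param k Number of events, 0 <= k <= n.
#' @param n Number of trials, >= 1.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' exact_binomial_ci(1, 20)
#' @export
exact_binomial_ci <- function(k, n, conf = 0.95) {
  if (n < 1 || k < 0 || k > n) {
    stop("require 0 <= k <= n and n >= 1", call. = FALSE)
  }
  alpha <- 1 - conf
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Observed mortality by score level
#'
#' Tabulates, for each observed score level, the number of patients, the
#' number of deaths, the mortality proportion, and its exact binomial 95%
#' interval — the data behind a score-level calibration bar plot.
#'
#' @param scores Integer (or ordinal) scores, e.g. respiratory sub-scores
#'   0-4 or totals 0-24.
#' @param labels Logical (or 0/1) outcome indicator.
#' @param conf Confidence level.
#' @return A data frame with columns `score`, `n`, `deaths`, `rate`,
#'   `ci_low`, `ci_high`, one row per observed level.
#' @export
per_score_mortality <- function(scores, labels, conf = 0.95) {
  if (length(scores) == 0) stop("empty input", call. = FALSE)
  labels <- as.logical(labels)
  levels <- sort(unique(scores))
  rows <- lapply(levels, function(s) {
    idx <- scores == s
    n <- sum(idx)
    k <- sum(labels[idx])
    ci <- exact_binomial_ci(k, n, conf)
    data.frame(score = s, n = n, deaths = k, rate = k / n,
               ci_low = ci[["lower"]], ci_high = ci[["upper"]])
  })
  do.call(rbind, rows)
}

# Evaluate expr with a temporarily seeded RNG, restoring global state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Bootstrap calibration curve by score level
#'
#' Per-score-level observed event proportions with percentile confidence
#' intervals over plain (non-stratified) case resamples with replacement.
#' Levels absent from a replicate contribute nothing to that replicate's
#' quantile. Output is deterministic given `seed`.
#'
#' @param scores Ordinal risk scores.
#' @param labels Logical (or 0/1) outcomes; both classes required.
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Integer RNG seed (required; recorded in the result).
#' @param conf Confidence level for the percentile interval.
#' @return An object of class `calibration_result`: list with `table`
#'   (`score`, `n`, `observed`, `ci_low`, `ci_high`), `n_boot`, `seed`, and
#'   `degenerate` (TRUE when `n_boot` < 2, which yields zero-width
#'   intervals).
#' @export
calibration_bootstrap <- function(scores, labels, n_boot = 100, seed,
                                  conf = 0.95) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  levels <- sort(unique(scores))
  n <- length(scores)
  rate_by_level <- function(s, l) {
    vapply(levels, function(lv) {
      idx <- s == lv
      if (!any(idx)) NA_real_ else mean(l[idx])
    }, numeric(1))
  }
  observed <- rate_by_level(scores, labels)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      rate_by_level(scores[idx], labels[idx])
    }, numeric(length(levels)))
  })
  boot <- matrix(boot, nrow = length(levels))
  alpha <- 1 - conf
  ci <- apply(boot, 1, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
  structure(list(
    table = data.frame(
      score = levels,
      n = vapply(levels, function(lv) sum(scores == lv), integer(1)),
      observed = observed,
      ci_low = ci[1, ],
      ci_high = ci[2, ]
    ),
    n_boot = n_boot,
    seed = seed,
    degenerate = n_boot < 2
  ), class = "calibration_result")
}

#' Compare all scoring methods against the conventional reference
#'
#' Scores the cohort under every requested method, then, separately for the
#' respiratory sub-score and the total SOFA score, computes each method's
#' AUROC for in-hospital mortality with its 95% interval and the DeLong
#' paired p-value against the conventional method. No multiple-testing
#' correction is applied.
#'
#' @inheritParams score_cohort
#' @param ci_mode AUC interval construction, `"delong"` (default) or
#'   `"binomial_style"`.
#' @return A data frame keyed by (`score_type`, `method`) with columns
#'   `auc`, `ci_low`, `ci_high`, `delta`, `z`, `p_vs_conventional` (NA for
#'   the conventional rows).
#' @export
compare_methods <- function(cohort, methods = sofa_methods,
                            conv_mode = c("impute_pao2_100", "score_zero"),
                            ci_mode = c("delong", "binomial_style"),
                            fio2_lookup = NULL) {
  conv_mode <- match.arg(conv_mode)
  ci_mode <- match.arg(ci_mode)
  methods <- match.arg(methods, sofa_methods, several.ok = TRUE)
  if (!"CONV" %in% methods) methods <- c("CONV", methods)
  labels <- as.logical(cohort$died_in_hospital)
  if (length(unique(labels)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  breakdowns <- lapply(methods, function(m) {
    total_sofa(cohort, m, conv_mode, fio2_lookup)
  })
  names(breakdowns) <- methods
  rows <- list()
  for (score_type in c("respiratory", "total")) {
    ref <- breakdowns[["CONV"]][[score_type]]
    for (m in methods) {
      sc <- breakdowns[[m]][[score_type]]
      est <- auc_midrank(sc, labels, ci_mode = ci_mode)
      if (m == "CONV") {
        delta <- z <- p <- NA_real_
      } else {
        cmp <- delong_paired_test(sc, ref, labels)
        delta <- cmp$delta
        z <- cmp$z
        p <- cmp$p
      }
      rows[[length(rows) + 1]] <- data.frame(
        score_type = score_type, method = m,
        auc = est$auc, ci_low = est$ci_low, ci_high = est$ci_high,
        delta = delta, z = z, p_vs_conventional = p
      )
    }
  }
  do.call(rbind, rows)
}
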