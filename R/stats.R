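## Behavioural scoring and group-level statistics. The rank tests wrap the
## canonical base-R implementations; the module adds the conventions used
## throughout the pipeline (extreme-rate correction, single-pass outlier
## rule, pooled-SD effect size).

#' Signal-detection sensitivity d'
#'
#' `d' = qnorm(hit rate) - qnorm(false-alarm rate)` under the equal-variance
#' Gaussian model. Extreme rates of 0 or 1 are replaced by `1/(2N)` and
#' `1 - 1/(2N)` (N = trials in that class) so the quantiles stay finite.
#' Negative values (false-alarm rate above hit rate) are allowed.
#'
#' @param session a [simulate_behavior()]-style `behavioral_session`, or
#'   `NULL` if the counts are given directly.
#' @param hits,n_signal,false_alarms,n_noise raw counts (ignored when
#'   `session` is supplied).
#' @return d' (unitless).
#' @export
#' @examples
#' dprime(hits = 80, n_signal = 100, false_alarms = 20, n_noise = 100)
dprime <- function(session = NULL, hits, n_signal, false_alarms, n_noise) {
  if (!is.null(session)) {
    stop_if_not(inherits(session, "behavioral_session"),
                "`session` must be a behavioral_session")
    hits <- session$hits; n_signal <- session$n_signal_trials
    false_alarms <- session$false_alarms; n_noise <- session$n_noise_trials
  }
  stop_if_not(n_signal > 0 && n_noise > 0,
              "both trial classes need at least one trial")
  stop_if_not(hits >= 0 && hits <= n_signal &&
                false_alarms >= 0 && false_alarms <= n_noise,
              "counts must lie within their trial totals")
  rate <- function(k, n) {
    r <- k / n
    if (r <= 0) r <- 1 / (2 * n)
    if (r >= 1) r <- 1 - 1 / (2 * n)
    r
  }
  qnorm(rate(hits, n_signal)) - qnorm(rate(false_alarms, n_noise))
}

#' Single-pass SD outlier removal
#'
#' Flags subjects whose value lies `k` or more standard deviations from the
#' group mean (both computed once on the full group; the rule is not
#' iterated).
#'
#' @param values numeric vector (e.g. per-subject d').
#' @param k cutoff in SD units (default 1.5).
#' @return list with `kept` (values), `kept_idx`, `removed_idx`.
#' @export
remove_outliers <- function(values, k = 1.5) {
  stop_if_not(length(values) >= 3, "need at least 3 subjects")
  s <- sd(values)
  if (s == 0) {
    warning("zero variance; no outliers removed")
    return(list(kept = values, kept_idx = seq_along(values),
                removed_idx = integer()))
  }
  z <- abs(values - mean(values)) / s
  removed <- which(z >= k)
  kept <- setdiff(seq_along(values), removed)
  list(kept = values[kept], kept_idx = kept, removed_idx = removed)
}

test_result <- function(statistic, p_value, effect_size = NA_real_,
                        n_per_group = NA_integer_, method = "") {
  structure(list(statistic = statistic, p_value = p_value,
                 effect_size = effect_size, n_per_group = n_per_group,
                 method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s\n", x$method, x$statistic,
              x$p_value,
              if (is.na(x$effect_size)) "" else
                sprintf(", Cohen's d = %.2f", x$effect_size)))
  invisible(x)
}

#' Mann-Whitney U test between two groups
#'
#' Two-sided rank-sum test; exact for small tie-free samples (n <= 12 per
#' group), normal approximation with tie correction otherwise.
#'
#' @param a,b numeric vectors for the two groups.
#' @return a `test_result` with the U statistic, p-value and Cohen's d.
#' @export
mann_whitney <- function(a, b) {
  stop_if_not(length(a) >= 1 && length(b) >= 1, "both groups must be non-empty")
  exact <- length(a) <= 12 && length(b) <= 12 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
  d <- tryCatch(cohens_d(a, b), error = function(e) NA_real_)
  test_result(unname(wt$statistic), wt$p.value, d,
              c(length(a), length(b)), "Mann-Whitney U")
}

#' Kruskal-Wallis rank test across groups
#'
#' @param groups list of numeric vectors (>= 2 groups). All-tied input
#'   yields H = 0, p = 1.
#' @return a `test_result` with the tie-corrected H statistic.
#' @export
kruskal_wallis <- function(groups) {
  stop_if_not(is.list(groups) && length(groups) >= 2 &&
                all(lengths(groups) >= 1), "need >= 2 non-empty groups")
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1)
    return(test_result(0, 1, NA_real_, lengths(groups), "Kruskal-Wallis"))
  kt <- kruskal.test(x, g)
  d <- if (length(groups) == 2)
    tryCatch(cohens_d(groups[[1]], groups[[2]]), error = function(e) NA_real_)
  else NA_real_
  test_result(unname(kt$statistic), kt$p.value, d, lengths(groups),
              "Kruskal-Wallis")
}

#' Shapiro-Wilk normality gate
#'
#' Computes W and p; the pipeline uses it only to log why rank-based tests
#' are applied (the nonparametric path is always taken).
#'
#' @param values numeric, n >= 3, non-constant.
#' @return list with `W`, `p_value`, `normal` (at alpha = 0.05).
#' @export
shapiro_wilk_gate <- function(values) {
  stop_if_not(length(values) >= 3, "need n >= 3")
  stop_if_not(sd(values) > 0, "constant input; normality undefined")
  st <- shapiro.test(values)
  list(W = unname(st$statistic), p_value = st$p.value,
       normal = st$p.value > 0.05)
}

#' Pearson brain-behaviour correlation
#'
#' @param behavior,neural paired numeric vectors (n >= 3), e.g. hit rates
#'   against a coherence or tPDC index.
#' @return a `test_result` with r (in `statistic`) and the two-sided p.
#' @export
pearson_brain_behavior <- function(behavior, neural) {
  stop_if_not(length(behavior) == length(neural), "inputs must be paired")
  stop_if_not(length(behavior) >= 3, "need n >= 3 pairs")
  stop_if_not(sd(behavior) > 0 && sd(neural) > 0,
              "zero variance in one of the inputs")
  ct <- cor.test(behavior, neural, method = "pearson")
  test_result(unname(ct$estimate), ct$p.value, NA_real_,
              length(behavior), "Pearson correlation")
}

#' Cohen's d (pooled SD)
#'
#' @param a,b numeric vectors, each n >= 2.
#' @return standardized mean difference `(mean(a) - mean(b)) / s_pooled`.
#' @export
cohens_d <- function(a, b) {
  stop_if_not(length(a) >= 2 && length(b) >= 2, "each group needs n >= 2")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  stop_if_not(sp2 > 0, "pooled SD is zero")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Two-sided p-value from a t statistic
#'
#' @param t t statistic.
#' @param df degrees of freedom (>= 1).
#' @return `2 * (1 - F_t(|t|; df))`.
#' @export
#' @examples
#' round(t_to_p(0.86, 42), 2)   # 0.39
t_to_p <- function(t, df) {
  stop_if_not(df >= 1, "`df` must be >= 1")
  2 * pt(abs(t), df, lower.tail = FALSE)
}

#' Rank-based age residualization
#'
#' Optional covariate adjustment before the rank tests: replaces each value
#' by the residual of a linear fit of its rank on the covariate's rank.
#'
#' @param values numeric outcome per subject.
#' @param covariate numeric covariate (e.g. age).
#' @return residualized values (rank scale).
#' @export
residualize_by_rank <- function(values, covariate) {
  stop_if_not(length(values) == length(covariate), "inputs must be paired")
  rv <- rank(values); rc <- rank(covariate)
  as.numeric(stats::resid(stats::lm(rv ~ rc)))
}
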