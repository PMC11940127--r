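#' Trial validity filter
#'
#' Flags trials with a reaction time in the inclusive 300--1200 ms window as
#' valid. Responses faster than 300 ms are discarded as fast guesses and
#' responses slower than 1200 ms as attentional lapses; timeouts (no RT) are
#' never valid for RT analyses but remain in accuracy denominators as
#' incorrect.
#'
#' @param trials Data frame with columns `rt_ms` and `outcome` (as produced
#'   by [generate_behavior()]).
#' @return Logical validity mask, one entry per trial.
#' @export
filter_trials <- function(trials) {
  stopifnot(all(c("rt_ms", "outcome") %in% names(trials)))
  if (any(trials$rt_ms < 0, na.rm = TRUE)) stop("negative reaction time")
  if (any(is.na(trials$rt_ms) & trials$outcome != "timeout"))
    stop("rt_ms may be missing only for timeout trials")
  !is.na(trials$rt_ms) & trials$rt_ms >= 300 & trials$rt_ms <= 1200
}

#' Per-class behavioral summary
#'
#' Median reaction time over valid correct trials and percent correct over
#' all trials of the class (timeouts counted incorrect). Classes: `"all"`,
#' `"easy"` (high coherence, 37.5%), `"hard"` (low coherence, 32.5%),
#' `"face"`, `"car"`.
#'
#' @param trials Behavioral trial table.
#' @param trial_class One of `"all"`, `"easy"`, `"hard"`, `"face"`, `"car"`.
#' @return List with `trial_class`, `n_trials`, `median_rt_ms`,
#'   `accuracy_pct`.
#' @export
summarize_behavior <- function(trials,
                               trial_class = c("all", "easy", "hard",
                                               "face", "car")) {
  trial_class <- match.arg(trial_class)
  sel <- switch(trial_class,
                all = rep(TRUE, nrow(trials)),
                easy = trials$imCoh == 37.5,
                hard = trials$imCoh == 32.5,
                face = trials$imType == "face",
                car = trials$imType == "car")
  sub <- trials[sel, , drop = FALSE]
  if (nrow(sub) == 0L) stop("empty trial class: ", trial_class)
  valid <- filter_trials(sub)
  correct <- sub$outcome == "correct"
  rt <- sub$rt_ms[valid & correct]
  list(trial_class = trial_class,
       n_trials = nrow(sub),
       median_rt_ms = if (length(rt)) stats::median(rt) else NA_real_,
       accuracy_pct = 100 * mean(correct))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test between two groups, exact for small samples
#' without ties and normal-approximated (with tie correction) otherwise.
#' When every value across both groups is tied the test is uninformative and
#' p = 1 is returned with a warning.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @return List with `U` (the statistic for `group_a`) and `p`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  if (max(c(group_a, group_b)) == min(c(group_a, group_b))) {
    warning("all values tied across groups; returning p = 1")
    return(list(U = length(group_a) * length(group_b) / 2, p = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Bayesian prevalence of a within-participant effect
#'
#' Maps the count `k` of participants with an individually significant test
#' (at level `alpha`) out of `n` tested to the population prevalence `gamma`
#' of a true effect. Under the model the per-participant hit rate is
#' `theta = alpha + gamma * (1 - alpha)`; with a uniform prior the posterior
#' on `theta` is `Beta(k + 1, n - k + 1)`. The maximum a posteriori
#' prevalence is `max(0, (k/n - alpha) / (1 - alpha))` and the credible
#' interval is obtained from Monte Carlo draws of the posterior transformed
#' to the prevalence scale (truncated at 0).
#'
#' @param k Number of significant participants (0 <= k <= n).
#' @param n Number tested.
#' @param alpha Per-participant test level (default 0.05).
#' @param mc_runs Number of Monte Carlo posterior draws (default 10000).
#' @param seed Optional seed for the draws.
#' @return List with `k`, `n`, `alpha`, `gamma_map` and `interval`
#'   (95% credible bounds).
#' @export
bayesian_prevalence <- function(k, n, alpha = 0.05, mc_runs = 10000L,
                                seed = NULL) {
  if (k < 0 || k > n || n < 1) stop("invalid counts: need 0 <= k <= n")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  gamma_map <- max(0, (k / n - alpha) / (1 - alpha))
  theta <- stats::rbeta(mc_runs, k + 1, n - k + 1)
  gamma <- pmax(0, (theta - alpha) / (1 - alpha))
  interval <- unname(stats::quantile(gamma, c(0.025, 0.975)))
  interval[1] <- min(interval[1], gamma_map)
  interval[2] <- max(interval[2], gamma_map)
  list(k = k, n = n, alpha = alpha, gamma_map = gamma_map,
       interval = interval)
}
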