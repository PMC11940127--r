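#' Cohen's d between treatment and control values
#'
#' Standardized mean difference `d = (mu_t - mu_c) / s` with the pooled
#' standard deviation
#' `s = sqrt(((m_t - 1) s_t^2 + (m_c - 1) s_c^2) / (m_t + m_c - 2))`
#' (sample variances, denominator m - 1). Positive d means larger values in
#' the treatment group. If both groups are constant with equal means d = 0;
#' if s = 0 with unequal means a signed-infinity sentinel is returned with a
#' warning.
#'
#' @param treatment_values,control_values Numeric vectors (each >= 2 values).
#' @return Object of class `effect_size` with fields `d`, `mu_treatment`,
#'   `mu_control`, `s`, `m_treatment`, `m_control`.
#' @export
cohens_d <- function(treatment_values, control_values) {
  mt <- length(treatment_values); mc <- length(control_values)
  if (mt < 2L || mc < 2L) stop("each group needs at least 2 values")
  mu_t <- mean(treatment_values); mu_c <- mean(control_values)
  s2 <- ((mt - 1) * stats::var(treatment_values) +
           (mc - 1) * stats::var(control_values)) / (mt + mc - 2)
  s <- sqrt(s2)
  if (s == 0) {
    if (mu_t == mu_c) d <- 0
    else {
      warning("zero pooled SD with unequal means; returning signed infinity")
      d <- sign(mu_t - mu_c) * Inf
    }
  } else d <- (mu_t - mu_c) / s
  structure(list(d = d, mu_treatment = mu_t, mu_control = mu_c, s = s,
                 m_treatment = mt, m_control = mc), class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> d = %.4f (treatment %.4g vs control %.4g, s = %.4g)\n",
              x$d, x$mu_treatment, x$mu_control, x$s))
  invisible(x)
}

# Copula correlation matrix per participant, computed once and reused for
# every subset evaluation.
participant_correlations <- function(band_trials) {
  lapply(band_trials, copula_correlation)
}

# Measure values for a list of subsets across participants, from precomputed
# correlation matrices. Vectorized closed forms for orders 2 and 3 (the bulk
# of exhaustive seeding); generic determinant path above that.
# Returns a participants x subsets matrix.
subset_values <- function(Rlist, subsets, measure) {
  k <- length(subsets[[1L]])
  if (measure %in% c("O", "negO") && k == 2L)
    stop("O-information is identically zero for pairs; seed the search at order 3")
  S <- matrix(unlist(subsets), nrow = k)
  vals <- matrix(NA_real_, nrow = length(Rlist), ncol = length(subsets),
                 dimnames = list(names(Rlist), NULL))
  for (i in seq_along(Rlist)) {
    R <- Rlist[[i]]
    if (k == 2L) {
      r <- R[cbind(S[1L, ], S[2L, ])]
      if (any(1 - r^2 < 1e-12))
        stop("rank-deficient correlation matrix for subset {",
             paste(S[, which(1 - r^2 < 1e-12)[1L]], collapse = ","),
             "} (collinear channels)")
      vals[i, ] <- -0.5 * log2(1 - r^2)        # TC = DTC at order 2
    } else if (k == 3L) {
      r12 <- R[cbind(S[1L, ], S[2L, ])]
      r13 <- R[cbind(S[1L, ], S[3L, ])]
      r23 <- R[cbind(S[2L, ], S[3L, ])]
      det3 <- 1 + 2 * r12 * r13 * r23 - r12^2 - r13^2 - r23^2
      if (any(det3 < 1e-12))
        stop("rank-deficient correlation matrix for subset {",
             paste(S[, which(det3 < 1e-12)[1L]], collapse = ","),
             "} (collinear channels)")
      tc <- -0.5 * log2(det3)
      if (measure == "TC") vals[i, ] <- tc
      else {
        dtc <- 0.5 * (log2(1 - r23^2) + log2(1 - r13^2) + log2(1 - r12^2) -
                        2 * log2(det3))
        vals[i, ] <- switch(measure, DTC = dtc, O = tc - dtc,
                            negO = -(tc - dtc))
      }
    } else {
      vals[i, ] <- vapply(subsets, function(s)
        measure_from_correlation(R, s, measure), numeric(1))
    }
  }
  vals
}

#' Score channel subsets by group effect size
#'
#' Computes, for each subset, the per-participant measure values on the
#' supplied band trials and the Cohen's d contrast between treatment and
#' control participants.
#'
#' @param band_trials Named list of channels x time matrices, one per
#'   participant (typically follow-up-session band trials).
#' @param groups Character vector (`"treatment"` / `"control"`) named by, or
#'   aligned with, the participants in `band_trials`.
#' @param order Interaction order k, used when `subsets = "all"`.
#' @param measure One of `"TC"`, `"DTC"`, `"O"`, `"negO"`.
#' @param subsets `"all"` for every k-subset of the montage, or an explicit
#'   list of integer channel-index vectors.
#' @return Data frame with one row per subset: `subset` (channel indices
#'   joined by `"+"`), `order`, `d`, `mu_treatment`, `mu_control`, `s`.
#' @export
score_all_subsets <- function(band_trials, groups, order, measure,
                              subsets = "all") {
  groups <- align_groups(groups, band_trials)
  n <- nrow(band_trials[[1L]])
  if (identical(subsets, "all"))
    subsets <- combn_subsets(n, order)
  Rlist <- participant_correlations(band_trials)
  vals <- subset_values(Rlist, subsets, measure)
  eff <- apply(vals, 2L, function(v)
    cohens_d(v[groups == "treatment"], v[groups == "control"]))
  data.frame(
    subset = vapply(subsets, paste, character(1), collapse = "+"),
    order = lengths(subsets),
    d = vapply(eff, `[[`, numeric(1), "d"),
    mu_treatment = vapply(eff, `[[`, numeric(1), "mu_treatment"),
    mu_control = vapply(eff, `[[`, numeric(1), "mu_control"),
    s = vapply(eff, `[[`, numeric(1), "s"),
    stringsAsFactors = FALSE)
}

# All k-subsets of n channels, in lexicographic order, as a list of vectors.
combn_subsets <- function(n, k) {
  if (k > n) stop("order exceeds montage size")
  m <- utils::combn(n, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

align_groups <- function(groups, band_trials) {
  groups <- as.character(groups)
  if (!is.null(names(groups)) && !is.null(names(band_trials)))
    groups <- groups[names(band_trials)]
  if (length(groups) != length(band_trials) || anyNA(groups))
    stop("groups must align with the participants in band_trials")
  if (!all(groups %in% c("treatment", "control")))
    stop("groups must be 'treatment' or 'control'")
  groups
}

#' Candidate expansions of a channel subset
#'
#' All subsets obtained by adding exactly one new channel to `best`, in
#' lexicographic order. This is the candidate set the greedy search scores at
#' each step beyond the seed order.
#'
#' @param best Integer vector of channel indices.
#' @param montage_size Total number of channels.
#' @return List of `montage_size - length(best)` sorted integer vectors, each
#'   containing `best`.
#' @export
expand_candidates <- function(best, montage_size) {
  best <- sort(as.integer(best))
  if (length(best) >= montage_size)
    stop("subset already spans the montage")
  new <- setdiff(seq_len(montage_size), best)
  cands <- lapply(new, function(ch) sort(c(best, ch)))
  lex_order_subsets(cands)
}

# Order a list of equal-length sorted subsets lexicographically.
lex_order_subsets <- function(subsets) {
  m <- matrix(unlist(subsets), nrow = length(subsets[[1L]]))
  ord <- do.call(order, split(t(m), rep(seq_len(nrow(m)), each = ncol(m))))
  subsets[ord]
}

#' Greedy search for maximally discriminative networks
#'
#' Grows a channel subset from an exhaustively scored seed order up to
#' `max_order`, at each step keeping the candidate (one added channel) whose
#' per-participant measure values give the largest (direction `"maximize"`)
#' or smallest (`"minimize"`) Cohen's d between treatment and control. Ties
#' are broken deterministically in favour of the lexicographically smallest
#' subset. By default TC and DTC searches seed at pairs (order 2) while O and
#' negO searches seed at triplets, since the O-information of any pair is
#' identically zero.
#'
#' @inheritParams score_all_subsets
#' @param direction `"maximize"` or `"minimize"` the effect size.
#' @param start_order Seed order (2 or 3); default 2 for TC/DTC, 3 for
#'   O/negO.
#' @param max_order Largest interaction order to grow to (default 16, capped
#'   at the montage size).
#' @return Object of class `search_trace`: fields `measure`, `direction`,
#'   `band`, `start_order`, `max_order`, `eval_count` (number of subset
#'   evaluations per participant) and `steps`, a list with one entry per
#'   order holding `order`, `subset`, `effect` (an `effect_size`) and
#'   `values` (named per-participant measure values).
#' @export
run_gsa <- function(band_trials, groups, measure = c("TC", "DTC", "O", "negO"),
                    direction = c("maximize", "minimize"),
                    start_order = NULL, max_order = 16L, band = NA_character_) {
  measure <- match.arg(measure)
  direction <- match.arg(direction)
  groups <- align_groups(groups, band_trials)
  n <- nrow(band_trials[[1L]])
  if (is.null(start_order))
    start_order <- if (measure %in% c("O", "negO")) 3L else 2L
  if (!start_order %in% c(2L, 3L)) stop("start_order must be 2 or 3")
  if (n < start_order) stop("fewer channels than the seed order")
  max_order <- min(as.integer(max_order), n)
  if (max_order < start_order) stop("max_order below start_order")
  Rlist <- participant_correlations(band_trials)
  treat <- groups == "treatment"; ctrl <- groups == "control"
  pick <- function(d) if (direction == "maximize") which.max(d) else which.min(d)

  eval_count <- 0L
  steps <- list()
  subsets <- combn_subsets(n, start_order)
  for (k in start_order:max_order) {
    if (k > start_order)
      subsets <- expand_candidates(best, n)
    vals <- subset_values(Rlist, subsets, measure)
    eval_count <- eval_count + length(subsets)
    d <- apply(vals, 2L, function(v) cohens_d(v[treat], v[ctrl])$d)
    ix <- pick(d)
    best <- subsets[[ix]]
    steps[[as.character(k)]] <- list(
      order = k, subset = best,
      effect = cohens_d(vals[treat, ix], vals[ctrl, ix]),
      values = stats::setNames(vals[, ix], names(band_trials)))
  }
  structure(list(measure = measure, direction = direction, band = band,
                 start_order = start_order, max_order = max_order,
                 n_channels = n, eval_count = eval_count, steps = steps),
            class = "search_trace")
}

#' @export
print.search_trace <- function(x, ...) {
  cat(sprintf("<search_trace> %s/%s band=%s orders %d-%d (%d evaluations)\n",
              x$measure, x$direction, x$band, x$start_order, x$max_order,
              x$eval_count))
  for (s in x$steps)
    cat(sprintf("  k=%2d d=%+.3f {%s}\n", s$order, s$effect$d,
                paste(s$subset, collapse = ",")))
  invisible(x)
}

#' Reverse the sign of O-information values
#'
#' Relabels a measure-value table from `O` to `negO`, flipping the sign of
#' the `value` column (and `value_normalized` if present), so that the
#' greedy search maximizing the relabelled values targets synergy instead of
#' redundancy.
#'
#' @param values Data frame with columns `measure` (all `"O"`) and `value`.
#' @return The table with `measure = "negO"` and negated values.
#' @export
negate_o_information <- function(values) {
  if (!is.data.frame(values) || !all(c("measure", "value") %in% names(values)))
    stop("values must be a data frame with 'measure' and 'value' columns")
  if (!all(values$measure == "O"))
    stop("input measure must be 'O'")
  values$value <- -values$value
  if ("value_normalized" %in% names(values))
    values$value_normalized <- -values$value_normalized
  values$measure <- "negO"
  values
}
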