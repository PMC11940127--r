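#' Back-compute measure values on baseline data
#'
#' Evaluates, for every step of a follow-up search trace, the same measure on
#' the same channel subset but from baseline-session band trials. Subset
#' identity is preserved exactly; the measures are permutation-invariant in
#' the channel order.
#'
#' @param trace A [run_gsa()] `search_trace`.
#' @param baseline_band_trials Named list of channels x time matrices for the
#'   baseline session; must cover every participant in the trace.
#' @return Named list (one entry per order) of named per-participant values.
#' @export
baseline_backcompute <- function(trace, baseline_band_trials) {
  stopifnot(inherits(trace, "search_trace"))
  ids <- names(trace$steps[[1L]]$values)
  missing <- setdiff(ids, names(baseline_band_trials))
  if (length(missing))
    stop("missing baseline data for participants: ",
         paste(missing, collapse = ", "))
  Rlist <- participant_correlations(baseline_band_trials[ids])
  out <- lapply(trace$steps, function(s)
    stats::setNames(
      vapply(Rlist, measure_from_correlation, numeric(1),
             subset = s$subset, measure = trace$measure),
      ids))
  names(out) <- names(trace$steps)
  out
}

#' Baseline-adjusted ANCOVA group effect
#'
#' Ordinary least squares fit of `follow_up ~ group + baseline` with the
#' group coded control = 0, treatment = 1, so a positive `group_coef` means
#' higher baseline-adjusted follow-up values in the treatment group. The
#' group effect is the 1-degree-of-freedom F test of the group term
#' (equivalently the squared t statistic) with residual degrees of freedom
#' m - 3. A perfect fit (zero residual variance) is flagged with a
#' signed-infinite F sentinel rather than an error so that batch sweeps
#' complete.
#'
#' @param follow_up,baseline Numeric per-participant values.
#' @param groups Character vector `"treatment"` / `"control"`.
#' @return Object of class `ancova_result` with fields `F`, `p`, `df1`,
#'   `df2`, `group_coef`, `degenerate`, and the fitted `model`.
#' @export
ancova_group_effect <- function(follow_up, baseline, groups) {
  groups <- as.character(groups)
  m <- length(follow_up)
  if (length(baseline) != m || length(groups) != m)
    stop("follow_up, baseline and groups must have equal length")
  if (!all(groups %in% c("treatment", "control")))
    stop("groups must be 'treatment' or 'control'")
  if (min(table(groups)) < 3L) stop("need at least 3 participants per group")
  if (stats::sd(baseline) == 0)
    stop("singular design: baseline covariate is constant")
  g <- as.integer(groups == "treatment")
  fit <- stats::lm(follow_up ~ g + baseline)
  if (anyNA(stats::coef(fit))) stop("singular ANCOVA design")
  rdf <- fit$df.residual                      # m - 3
  rss <- sum(stats::residuals(fit)^2)
  coef_g <- stats::coef(fit)[["g"]]
  scale <- mean(follow_up^2) + 1e-300
  if (rss / scale < 1e-20) {
    # perfect fit: no residual variance left to test against
    if (abs(coef_g) < 1e-10 * sqrt(scale)) {
      res <- list(F = 0, p = 1, df1 = 1L, df2 = rdf, group_coef = 0,
                  degenerate = FALSE, model = fit)
    } else {
      res <- list(F = Inf, p = 0, df1 = 1L, df2 = rdf, group_coef = coef_g,
                  degenerate = TRUE, model = fit)
    }
  } else {
    X <- stats::model.matrix(fit)
    se_g <- sqrt(rss / rdf * solve(crossprod(X))[2L, 2L])
    tg <- coef_g / se_g
    res <- list(F = tg^2, p = 2 * stats::pt(-abs(tg), rdf), df1 = 1L,
                df2 = rdf, group_coef = coef_g, degenerate = FALSE,
                model = fit)
  }
  class(res) <- "ancova_result"
  res
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("<ancova_result> F(%d, %d) = %.4g, p = %.4g, group_coef = %.4g%s\n",
              x$df1, x$df2, x$F, x$p, x$group_coef,
              if (x$degenerate) " [degenerate fit]" else ""))
  invisible(x)
}

#' White's test for heteroskedasticity
#'
#' Lagrange-multiplier test regressing squared residuals on the model's
#' regressors, their squares and pairwise cross-products (dropping constant
#' and duplicated columns, e.g. the square of a 0/1 dummy). The statistic is
#' `LM = m * R^2` of the auxiliary regression, compared against a chi-square
#' distribution with as many degrees of freedom as auxiliary regressors.
#'
#' @param model An `lm` fit or an [ancova_group_effect()] result; or a
#'   numeric residual vector if `design` is supplied.
#' @param design Optional model matrix (used when `model` is a residual
#'   vector); an intercept column is ignored.
#' @return List with `statistic`, `df` and `p`.
#' @export
white_test <- function(model, design = NULL) {
  if (inherits(model, "ancova_result")) model <- model$model
  if (inherits(model, "lm")) {
    r <- stats::residuals(model)
    X <- stats::model.matrix(model)
  } else {
    r <- as.numeric(model)
    if (is.null(design)) stop("design matrix required with raw residuals")
    X <- as.matrix(design)
  }
  icpt <- apply(X, 2L, function(col) max(col) == min(col))
  X <- X[, !icpt, drop = FALSE]
  if (ncol(X) == 0L) stop("degenerate auxiliary design: no regressors")
  aux <- X
  for (j in seq_len(ncol(X)))
    for (l in j:ncol(X))
      aux <- cbind(aux, X[, j] * X[, l])
  keep <- !duplicated(lapply(seq_len(ncol(aux)), function(j) round(aux[, j], 12))) &
    apply(aux, 2L, function(col) max(col) - min(col) > 1e-12)
  aux <- aux[, keep, drop = FALSE]
  m <- length(r)
  if (m <= ncol(aux) + 1L) stop("too few observations for the auxiliary regression")
  r2sq <- r^2
  if (stats::var(r2sq) == 0)
    return(list(statistic = 0, df = ncol(aux), p = 1))
  afit <- stats::lm(r2sq ~ aux)
  R2 <- summary(afit)$r.squared
  stat <- m * R2
  df <- sum(!is.na(stats::coef(afit))) - 1L
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up FDR procedure
#'
#' Sorts the family's p values ascending, finds the largest rank `i` with
#' `p_(i) <= i * q / m`, and declares every p value up to `p_(i)`
#' significant. The family critical value is `p_(i)` (or `NA` when nothing
#' is significant).
#'
#' @param p_values Numeric p values in `[0, 1]`.
#' @param q Target false discovery rate in `(0, 1)`.
#' @return List with `significant` (logical mask in input order) and
#'   `critical_p`.
#' @export
benjamini_hochberg <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value family")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  m <- length(p_values)
  ord <- order(p_values)
  ps <- p_values[ord]
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok) == 0L)
    return(list(significant = rep(FALSE, m), critical_p = NA_real_))
  crit <- ps[max(ok)]
  list(significant = p_values <= crit, critical_p = crit)
}

#' Fit the ANCOVA grid over search traces and control FDR
#'
#' For every step of every search trace, back-computes baseline values for
#' the selected subset, fits the baseline-adjusted ANCOVA group model, runs
#' White's homoskedasticity check (reported, never used as a filter), and
#' finally applies Benjamini-Hochberg FDR control separately within each
#' (measure, direction) family across all bands and orders.
#'
#' Because each subset is selected to extremize the group contrast on the
#' same follow-up data the model is then fitted to, the p values are
#' anti-conservative under the null; the family-level false-positive rate of
#' the full pipeline on null cohorts is the meaningful calibration check.
#'
#' @param traces List of `search_trace` objects (any bands / measures /
#'   directions).
#' @param baseline_trials Nested list `band$participant` of baseline
#'   channels x time matrices.
#' @param groups Character vector named by participant id.
#' @param q FDR level per family (default 0.05).
#' @return Data frame with one row per (band, measure, direction, order):
#'   columns `band`, `measure`, `direction`, `order`, `subset`, `d`, `F`,
#'   `p`, `df1`, `df2`, `group_coef`, `degenerate`, `white_lm`, `white_p`,
#'   `fdr_critical_p`, `fdr_significant`.
#' @export
ancova_grid <- function(traces, baseline_trials, groups, q = 0.05) {
  rows <- list()
  for (tr in traces) {
    base_vals <- baseline_backcompute(tr, baseline_trials[[tr$band]])
    for (s in tr$steps) {
      fv <- s$values
      bv <- base_vals[[as.character(s$order)]]
      g <- groups[names(fv)]
      an <- ancova_group_effect(fv, bv, g)
      wt <- white_test(an)
      rows[[length(rows) + 1L]] <- data.frame(
        band = tr$band, measure = tr$measure, direction = tr$direction,
        order = s$order,
        subset = paste(s$subset, collapse = "+"),
        d = s$effect$d, F = an$F, p = an$p, df1 = an$df1, df2 = an$df2,
        group_coef = an$group_coef, degenerate = an$degenerate,
        white_lm = wt$statistic, white_p = wt$p,
        stringsAsFactors = FALSE)
    }
  }
  grid <- do.call(rbind, rows)
  grid$fdr_critical_p <- NA_real_
  grid$fdr_significant <- FALSE
  for (fam in split(seq_len(nrow(grid)),
                    paste(grid$measure, grid$direction))) {
    bh <- benjamini_hochberg(grid$p[fam], q)
    grid$fdr_significant[fam] <- bh$significant
    grid$fdr_critical_p[fam] <- bh$critical_p
  }
  grid
}
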