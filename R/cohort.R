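#' Cohort configuration
#'
#' Describes a two-group (treatment / control), two-session (baseline /
#' follow-up) EEG cohort. Defaults reproduce the study conditions this
#' package models: 17 treatment and 15 control participants, 64 channels at
#' 1000 Hz, 0--800 ms stimulus-locked epochs and 576 trials per session, with
#' the five conventional analysis bands.
#'
#' Background activity is independent band-limited Gaussian noise per
#' channel: each channel's trial-invariant evoked component is a sum of
#' unit-variance signals, one per analysis band, generated by filtering white
#' noise with the same zero-phase filter used by the analysis ([band_filter()]),
#' so planted and background structure live inside the analyzed bands. The
#' evoked component mixes a participant-stable waveform (drawn once per
#' participant) with a session-specific one in proportion
#' `session_stability : (1 - session_stability)` of variance, reflecting the
#' high across-session test-retest stability of trial-averaged stimulus-locked
#' responses -- the property that makes a baseline covariate informative. Each
#' trial adds independent white noise of standard deviation `noise_sd`; each
#' participant carries a session-stable multiplicative gain
#' (`1 + gain_jitter * z`).
#'
#' Behavioral defaults give a log-normal reaction-time distribution with a
#' baseline median of 600 ms, a 30 ms slowing at follow-up in both groups (no
#' group effect -- a null behavioral cohort), and accuracies of 90% on easy
#' (high-coherence) and 82% on hard (low-coherence) trials.
#'
#' @param n_treatment,n_control Group sizes (>= 2).
#' @param n_channels Montage size.
#' @param fs Sampling rate in Hz.
#' @param epoch_ms Epoch duration in ms; `epoch_ms * fs / 1000` must be an
#'   integer sample count.
#' @param n_trials Trials per session; must be divisible by 16 so that each
#'   of the 4 blocks balances the 2 image types x 2 coherence levels (with
#'   the 2 response keys tied to image type).
#' @param bands List of [band_spec()] objects.
#' @param planted_effects List of [plant_spec()] objects (default none).
#' @param noise_sd Per-trial additive noise standard deviation.
#' @param gain_jitter Relative SD of the per-participant gain (default 0.1).
#' @param session_stability Fraction of evoked variance shared between a
#'   participant's two sessions (default 0.9).
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   cohort.
#' @param rt_median_ms,rt_sdlog,session_slowing_ms,group_speedup_ms,acc_easy,acc_hard
#'   Behavioral generator parameters (see Details).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_treatment = 17L, n_control = 15L,
                          n_channels = 64L, fs = 1000, epoch_ms = 800,
                          n_trials = 576L, bands = default_bands(),
                          planted_effects = list(), noise_sd = 1,
                          gain_jitter = 0.1, session_stability = 0.9,
                          seed = 1L,
                          rt_median_ms = 600, rt_sdlog = 0.22,
                          session_slowing_ms = 30, group_speedup_ms = 0,
                          acc_easy = 0.90, acc_hard = 0.82) {
  if (n_treatment < 2L || n_control < 2L) stop("group sizes must be >= 2")
  n_time <- epoch_ms * fs / 1000
  if (abs(n_time - round(n_time)) > 1e-9)
    stop("epoch_ms * fs must yield an integer sample count (got ", n_time, ")")
  if (n_trials %% 16L != 0L)
    stop("n_trials must be divisible by 16 (4 blocks x imType x imCoh balance)")
  if (session_stability < 0 || session_stability > 1)
    stop("session_stability must lie in [0, 1]")
  bands <- lapply(bands, as_band_spec)
  for (b in bands) if (b$hi >= fs / 2) stop("band ", b$name, " exceeds Nyquist")
  for (p in planted_effects) {
    if (!inherits(p, "plant_spec")) stop("planted_effects must be plant_spec objects")
    if (any(p$target_channels > n_channels) || any(p$target_channels < 1L))
      stop("planted channel index out of range for ", n_channels, " channels")
    if (p$band$hi >= fs / 2) stop("planted band exceeds Nyquist")
  }
  structure(list(
    n_treatment = as.integer(n_treatment), n_control = as.integer(n_control),
    n_channels = as.integer(n_channels), fs = fs, epoch_ms = epoch_ms,
    n_time = as.integer(round(n_time)), n_trials = as.integer(n_trials),
    bands = bands, planted_effects = planted_effects, noise_sd = noise_sd,
    gain_jitter = gain_jitter, session_stability = session_stability,
    seed = as.integer(seed),
    rt_median_ms = rt_median_ms, rt_sdlog = rt_sdlog,
    session_slowing_ms = session_slowing_ms,
    group_speedup_ms = group_speedup_ms,
    acc_easy = acc_easy, acc_hard = acc_hard), class = "cohort_config")
}

#' Planted dependency structure
#'
#' Declares a ground-truth higher-order structure injected into one group and
#' session of a synthetic cohort, confined to one frequency band and channel
#' subset:
#'
#' * `common_driver`: one shared band-limited signal, scaled by `amplitude`,
#'   is added to every target channel. This equicorrelates the subset and
#'   raises TC and redundancy (positive O-information).
#' * `collider`: every target channel except the last receives a private
#'   band-limited signal scaled by `amplitude`, and the last target channel
#'   (the collider) receives the scaled sum of all those private signals.
#'   The non-collider channels stay mutually uncorrelated while each
#'   correlates with the collider, which drives the subset's O-information
#'   negative (synergy).
#'
#' `amplitude = 0` reproduces the unplanted cohort exactly.
#'
#' @param target_channels Integer channel indices (>= 2; >= 3 for collider).
#' @param band [band_spec()] the structure is confined to.
#' @param structure `"common_driver"` or `"collider"`.
#' @param amplitude Gain >= 0 applied to the planted signals, relative to the
#'   unit in-band background standard deviation (see [driver_amplitude()],
#'   [collider_amplitude()] to target a correlation level).
#' @param group,session Which cohort cell receives the structure.
#' @return Object of class `plant_spec`.
#' @export
plant_spec <- function(target_channels, band,
                       structure = c("common_driver", "collider"),
                       amplitude = 1,
                       group = c("treatment", "control"),
                       session = c("follow_up", "baseline")) {
  structure_kw <- match.arg(structure)
  group <- match.arg(group)
  session <- match.arg(session)
  target_channels <- as.integer(target_channels)
  if (length(target_channels) < 2L || anyDuplicated(target_channels))
    stop("target_channels must be >= 2 distinct channel indices")
  if (structure_kw == "collider" && length(target_channels) < 3L)
    stop("a collider needs at least 3 target channels")
  if (amplitude < 0) stop("amplitude must be >= 0")
  base::structure(list(
    target_channels = target_channels, band = as_band_spec(band),
    structure = structure_kw, amplitude = amplitude,
    group = group, session = session), class = "plant_spec")
}

# Unit-variance band-limited Gaussian noise of length n.
band_noise <- function(n, band, fs) {
  y <- band_filter(stats::rnorm(n), band$lo, band$hi, fs)
  y / stats::sd(y)
}

#' Amplitude for a target common-driver correlation
#'
#' Inverts the common-driver correlation model: with unit in-band background
#' variance and a shared signal of amplitude `a`, every pair of target
#' channels has in-band correlation `rho = a^2 / (1 + a^2)`.
#'
#' @param rho Desired pairwise equicorrelation, `0 <= rho < 1`.
#' @return Amplitude `a = sqrt(rho / (1 - rho))`.
#' @export
driver_amplitude <- function(rho) {
  stopifnot(rho >= 0, rho < 1)
  sqrt(rho / (1 - rho))
}

#' Amplitude for a target collider correlation
#'
#' Inverts the collider correlation model with `m` private source channels:
#' with `t = a^2`, each source correlates with the collider channel as
#' `rho = t / sqrt((1 + t) * (1 + m * t))` while sources stay mutually
#' uncorrelated. Solves for `a` given `rho`.
#'
#' @param rho Desired source-collider correlation; must be attainable,
#'   i.e. `rho < 1 / sqrt(m)`.
#' @param m Number of private source channels (target subset size minus 1).
#' @return Amplitude `a`.
#' @export
collider_amplitude <- function(rho, m = 2L) {
  stopifnot(rho >= 0, m >= 2L)
  if (rho >= 1 / sqrt(m))
    stop("collider correlation must be below 1/sqrt(m) = ", round(1 / sqrt(m), 4))
  if (rho == 0) return(0)
  # t^2 (1 - m rho^2) - (m + 1) rho^2 t - rho^2 = 0, positive root
  a2 <- (m + 1) * rho^2
  disc <- a2^2 + 4 * (1 - m * rho^2) * rho^2
  t <- (a2 + sqrt(disc)) / (2 * (1 - m * rho^2))
  sqrt(t)
}

#' Implied in-band correlation matrix of a planted structure
#'
#' Returns the correlation matrix that a [plant_spec()] induces among its
#' target channels within its band, given unit in-band background variance
#' per channel (the generator's convention).
#'
#' @param spec A [plant_spec()].
#' @return Correlation matrix of size `length(spec$target_channels)`.
#' @export
plant_correlation <- function(spec) {
  k <- length(spec$target_channels)
  t <- spec$amplitude^2
  R <- diag(k)
  if (spec$structure == "common_driver") {
    rho <- t / (1 + t)
    R[] <- rho
    diag(R) <- 1
  } else {
    m <- k - 1L
    rho <- t / sqrt((1 + t) * (1 + m * t))
    R[k, seq_len(m)] <- rho
    R[seq_len(m), k] <- rho
  }
  R
}

#' Inject a planted structure into an epoch array
#'
#' Adds the trial-invariant, band-limited signals described by a
#' [plant_spec()] to a channels x time x trials epoch array. Only the target
#' channels are modified, only within the planted band, identically on every
#' trial (so the structure survives trial averaging). With `amplitude = 0`
#' the input is returned unchanged and no random numbers are consumed.
#'
#' @param epochs A channels x time x trials array.
#' @param spec A [plant_spec()].
#' @param fs Sampling rate in Hz.
#' @return The modified epoch array.
#' @export
plant_structure <- function(epochs, spec, fs) {
  d <- dim(epochs)
  if (is.null(d) || length(d) != 3L)
    stop("epochs must be a channels x time x trials array")
  if (!inherits(spec, "plant_spec")) stop("spec must be a plant_spec")
  if (any(spec$target_channels > d[1]))
    stop("planted channel index out of range")
  if (spec$band$hi >= fs / 2) stop("planted band exceeds Nyquist")
  if (spec$amplitude == 0) return(epochs)
  n_time <- d[2]
  tgt <- spec$target_channels
  add <- matrix(0, nrow = length(tgt), ncol = n_time)
  if (spec$structure == "common_driver") {
    s <- spec$amplitude * band_noise(n_time, spec$band, fs)
    add <- add + matrix(s, nrow = length(tgt), ncol = n_time, byrow = TRUE)
  } else {
    m <- length(tgt) - 1L
    priv <- vapply(seq_len(m), function(i)
      spec$amplitude * band_noise(n_time, spec$band, fs), numeric(n_time))
    add[seq_len(m), ] <- t(priv)
    add[m + 1L, ] <- rowSums(priv)
  }
  for (i in seq_along(tgt))
    epochs[tgt[i], , ] <- epochs[tgt[i], , ] + add[i, ]
  epochs
}

#' Generate a synthetic two-group, two-session EEG cohort
#'
#' Draws, for every participant and session, a channels x time x trials epoch
#' array composed of a trial-invariant evoked background (independent
#' band-limited Gaussian noise per channel, one unit-variance component per
#' configured band), per-trial white noise, a session-stable per-participant
#' gain, and any planted structures whose group/session matches
#' (see [plant_structure()]). The generator is fully determined by
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return Object of class `hoi_cohort`: a list with `epochs` (named list
#'   `"<id>_<session>"` of arrays), `participants` (data frame with `id`,
#'   `group`), `sessions`, `channel_names` and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  ids <- c(sprintf("T%02d", seq_len(config$n_treatment)),
           sprintf("C%02d", seq_len(config$n_control)))
  groups <- rep(c("treatment", "control"),
                c(config$n_treatment, config$n_control))
  participants <- data.frame(id = ids, group = groups,
                             stringsAsFactors = FALSE)
  sessions <- c("baseline", "follow_up")
  nch <- config$n_channels; nt <- config$n_time; ntr <- config$n_trials
  gains <- 1 + config$gain_jitter * stats::rnorm(length(ids))
  gains <- pmax(gains, 0.1)
  epochs <- list()
  draw_evoked <- function() {
    ev <- matrix(0, nch, nt)
    for (b in config$bands)
      ev <- ev + t(vapply(seq_len(nch), function(ch)
        band_noise(nt, b, config$fs), numeric(nt)))
    ev
  }
  a_st <- sqrt(config$session_stability)
  a_se <- sqrt(1 - config$session_stability)
  for (i in seq_along(ids)) {
    stable <- draw_evoked()
    for (ses in sessions) {
      evoked <- a_st * stable + a_se * draw_evoked()
      e <- array(stats::rnorm(nch * nt * ntr, sd = config$noise_sd),
                 dim = c(nch, nt, ntr))
      e <- e + as.vector(gains[i] * evoked)
      for (p in config$planted_effects)
        if (p$group == groups[i] && p$session == ses)
          e <- plant_structure(e, p, config$fs)
      epochs[[paste0(ids[i], "_", ses)]] <- e
    }
  }
  structure(list(epochs = epochs, participants = participants,
                 sessions = sessions,
                 channel_names = sprintf("ch%02d", seq_len(nch)),
                 config = config), class = "hoi_cohort")
}

#' @export
print.hoi_cohort <- function(x, ...) {
  cat(sprintf("<hoi_cohort> %d treatment + %d control, %d channels, %d x %d x %d epochs\n",
              x$config$n_treatment, x$config$n_control, x$config$n_channels,
              x$config$n_channels, x$config$n_time, x$config$n_trials))
  invisible(x)
}

#' Generate a behavioral trial table
#'
#' Emits one session's trial table for the two-alternative categorization
#' task: 4 blocks of `n_trials / 4` trials, each block balanced across image
#' type (face / car) and phase coherence (high 37.5% / low 32.5%). Reaction
#' times are log-normal with a configurable median, slowed by
#' `session_slowing_ms` at follow-up and sped by `group_speedup_ms` in the
#' treatment group at follow-up; responses beyond the 1.25 s deadline time
#' out (no RT, counted incorrect). Accuracy is Bernoulli with higher success
#' on high-coherence trials.
#'
#' @param config A [cohort_config()].
#' @param group `"treatment"` or `"control"`.
#' @param session `"baseline"` or `"follow_up"`.
#' @return Data frame with columns `block`, `imType`, `imCoh`, `rt_ms`,
#'   `outcome` (`rt_ms` is `NA` iff `outcome == "timeout"`).
#' @export
generate_behavior <- function(config, group = c("treatment", "control"),
                              session = c("baseline", "follow_up")) {
  stopifnot(inherits(config, "cohort_config"))
  group <- match.arg(group)
  session <- match.arg(session)
  per_block <- config$n_trials %/% 4L
  per_cell <- per_block %/% 4L
  cell <- expand.grid(imType = c("face", "car"), imCoh = c(37.5, 32.5),
                      stringsAsFactors = FALSE)
  blocks <- lapply(seq_len(4L), function(b) {
    df <- cell[rep(seq_len(nrow(cell)), each = per_cell), ]
    df <- df[sample.int(nrow(df)), ]
    df$block <- b
    df
  })
  trials <- do.call(rbind, blocks)
  rownames(trials) <- NULL
  med <- config$rt_median_ms
  if (session == "follow_up") {
    med <- med + config$session_slowing_ms
    if (group == "treatment") med <- med - config$group_speedup_ms
  }
  n <- nrow(trials)
  rt <- exp(stats::rnorm(n, mean = log(med), sd = config$rt_sdlog))
  p_correct <- ifelse(trials$imCoh == 37.5, config$acc_easy, config$acc_hard)
  correct <- stats::rbinom(n, 1L, p_correct) == 1L
  timeout <- rt > 1250
  trials$rt_ms <- ifelse(timeout, NA_real_, rt)
  trials$outcome <- ifelse(timeout, "timeout",
                           ifelse(correct, "correct", "incorrect"))
  trials[, c("block", "imType", "imCoh", "rt_ms", "outcome")]
}
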