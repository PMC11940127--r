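#' Re-reference epochs to the channel average
#'
#' Subtracts, at every time point (and trial), the instantaneous mean across
#' channels, so that the channel mean is zero everywhere afterwards. This is
#' the standard average-reference montage for multichannel EEG.
#'
#' @param epochs A channels x time matrix or a channels x time x trials array.
#' @return Object of the same shape with zero channel mean at every sample.
#' @export
average_reference <- function(epochs) {
  d <- dim(epochs)
  if (is.null(d) || length(d) < 2L)
    stop("epochs must be a channels x time matrix or channels x time x trials array")
  if (d[1] < 2L) stop("average referencing needs at least 2 channels")
  if (length(d) == 2L) {
    return(sweep(epochs, 2L, colMeans(epochs), "-"))
  }
  if (length(d) == 3L) {
    m <- apply(epochs, c(2L, 3L), mean)
    return(epochs - aperm(array(m, dim = c(d[2], d[3], d[1])), c(3L, 1L, 2L)))
  }
  stop("epochs must have 2 or 3 dimensions")
}

#' Trial-averaged representative epoch
#'
#' Averages a channels x time x trials array over the trial axis, yielding the
#' participant's representative stimulus-locked response (the event-related
#' signal, with trial-to-trial noise suppressed by 1/n_trials in variance).
#'
#' @param epochs A channels x time x trials array (trials >= 1).
#' @return A channels x time matrix.
#' @export
representative_trial <- function(epochs) {
  d <- dim(epochs)
  if (is.null(d) || length(d) != 3L)
    stop("epochs must be a channels x time x trials array")
  if (d[3] < 1L) stop("at least one trial is required")
  out <- rowMeans(epochs, dims = 2L)
  dim(out) <- d[1:2]
  out
}

#' Zero-phase Butterworth band-pass filter (single channel)
#'
#' Applies the bidirectional (zero-phase) magnitude response of an order-`order`
#' Butterworth band-pass filter, |H(f)|^2 with
#' `|H(f)|^2 = 1 / (1 + ((f^2 - lo*hi) / (f * (hi - lo)))^(2*order))`,
#' exactly in the frequency domain. The epoch is extended by even (symmetric)
#' reflection at both ends before transforming, which keeps the periodic
#' extension continuous and confines edge transients to the pads. The response
#' is real and even, so the filter has exactly zero phase and zero group delay.
#'
#' @param x Numeric vector (one channel's samples).
#' @param lo,hi Band edges in Hz, `0 < lo < hi < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param order Butterworth order per pass (default 3).
#' @return Filtered vector, same length as `x`.
#' @export
band_filter <- function(x, lo, hi, fs, order = 3L) {
  n <- length(x)
  if (hi >= fs / 2) stop("upper band edge must be below the Nyquist frequency")
  if (lo <= 0 || lo >= hi) stop("band edges must satisfy 0 < lo < hi")
  if (n < 8L) stop("input too short to filter (need >= 8 samples)")
  pad <- n - 1L
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  N <- length(xp)
  k <- c(0:floor(N / 2), -(ceiling(N / 2) - 1L):-1L)
  f <- abs(k) * fs / N
  X <- (f^2 - lo * hi) / pmax(f, .Machine$double.eps) / (hi - lo)
  M <- 1 / (1 + X^(2L * order))
  M[f == 0] <- 0
  y <- Re(stats::fft(stats::fft(xp) * M, inverse = TRUE)) / N
  y[(pad + 1L):(pad + n)]
}

#' Band-filter a representative trial
#'
#' Filters every channel of a channels x time matrix into one frequency band
#' with the zero-phase Butterworth response of [band_filter()].
#'
#' @param trial A channels x time matrix (one representative trial).
#' @param band A [band_spec()] (or the name of a default band).
#' @param fs Sampling rate in Hz.
#' @param order Butterworth order per pass (default 3).
#' @return A channels x time matrix of band-limited signals, with attributes
#'   `band` and `fs`.
#' @export
bandpass_trial <- function(trial, band, fs, order = 3L) {
  if (is.null(dim(trial)) || length(dim(trial)) != 2L)
    stop("trial must be a channels x time matrix")
  band <- as_band_spec(band)
  out <- t(apply(trial, 1L, band_filter, lo = band$lo, hi = band$hi,
                 fs = fs, order = order))
  dimnames(out) <- dimnames(trial)
  attr(out, "band") <- band$name
  attr(out, "fs") <- fs
  out
}

#' Prepare per-band representative trials for a whole cohort
#'
#' Runs the preprocessing chain average reference -> trial average -> band
#' filter for every participant-session of a cohort, for each requested band.
#'
#' @param cohort A cohort from [generate_cohort()] or [load_external_epochs()].
#' @param bands List of [band_spec()] objects (default: the cohort's bands).
#' @return Nested list `band$session$participant` of channels x time matrices.
#' @export
prep_band_trials <- function(cohort, bands = NULL) {
  if (is.null(bands)) bands <- cohort$config$bands
  fs <- cohort$config$fs
  reps <- lapply(cohort$epochs, function(e) representative_trial(average_reference(e)))
  out <- list()
  for (b in bands) {
    out[[b$name]] <- list()
    for (ses in cohort$sessions) {
      keys <- paste0(cohort$participants$id, "_", ses)
      mats <- lapply(reps[keys], bandpass_trial, band = b, fs = fs)
      names(mats) <- cohort$participants$id
      out[[b$name]][[ses]] <- mats
    }
  }
  out
}
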