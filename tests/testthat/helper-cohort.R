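# Reduced-scale study conditions shared across tests: paper-sized groups
# (17 vs 15), a small montage, 250 Hz sampling of the same 800 ms epoch,
# 16 trials, and two bands (delta + beta).

reduced_bands <- function() {
  list(delta = band_spec("delta", 0.5, 4), beta = band_spec("beta", 12, 30))
}

reduced_config <- function(seed, n_channels = 16L, plants = list(), ...) {
  cohort_config(n_treatment = 17L, n_control = 15L, n_channels = n_channels,
                fs = 250, epoch_ms = 800, n_trials = 16L,
                bands = reduced_bands(), planted_effects = plants,
                seed = seed, ...)
}

cohort_groups <- function(cohort) {
  stats::setNames(cohort$participants$group, cohort$participants$id)
}

# Band trials for one session without re-referencing (module-level search
# tests; the average reference of a tiny montage mixes planted structure
# across all channels).
band_trials_noref <- function(cohort, band, session = "follow_up") {
  ids <- cohort$participants$id
  out <- lapply(ids, function(id)
    bandpass_trial(representative_trial(cohort$epochs[[paste0(id, "_", session)]]),
                   band, cohort$config$fs))
  stats::setNames(out, ids)
}

# Exact-correlation Gaussian samples: k x T data with population correlation R.
gaussian_subset <- function(R, T_, seed = 1) {
  set.seed(seed)
  t(MASS::mvrnorm(T_, rep(0, nrow(R)), R))
}

equicorr <- function(k, rho) {
  R <- matrix(rho, k, k); diag(R) <- 1; R
}

collider_R <- function(rho = 1 / sqrt(3)) {
  R <- diag(3)
  R[1, 3] <- R[3, 1] <- R[2, 3] <- R[3, 2] <- rho
  R
}
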