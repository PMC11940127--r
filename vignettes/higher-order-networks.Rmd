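---
title: "Higher-order brain-network interdependencies: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Higher-order brain-network interdependencies: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoinet)
```

## The problem

Randomized nootropic (or any treatment/placebo) EEG studies ask whether an
intervention changes how *groups of channels* share information, not merely
pairwise coupling. `hoinet` implements a complete analysis chain for that
question on two-group, two-session (baseline / follow-up) epoched EEG:

1. band-limited representative trials per participant,
2. Gaussian-copula estimates of higher-order information measures over
   channel subsets,
3. a greedy search for subsets whose measure values maximally discriminate
   treatment from control,
4. baseline-adjusted ANCOVA inference with false-discovery-rate control, and
5. the accompanying behavioral analysis of a two-alternative forced-choice
   task.

A synthetic cohort generator with *planted*, analytically characterized
higher-order structure provides ground truth for every stage.

## Information measures

For a subset $X^n = (X_1, \dots, X_n)$ of channels, the package estimates,
in bits:

* **Total correlation** $\mathrm{TC}(X^n) = \sum_j H(X_j) - H(X_1,\dots,X_n)$
  — the collective constraints: how much the channels repeat each other.
* **Dual total correlation (binding information)**
  $\mathrm{DTC}(X^n) = H(X_1,\dots,X_n) - \sum_j H(X_j \mid X^n_{-j})$
  — the shared randomness: information carried jointly.
* **O-information** $\Omega = \mathrm{TC} - \mathrm{DTC}$ — positive when
  redundancy dominates, negative when synergy dominates, identically zero
  for pairs.

Estimation uses the Gaussian copula: each channel is rank-transformed to
standard-normal marginals ($z_t = \Phi^{-1}(r_t/(T+1))$, average ranks for
ties), and the measures reduce to determinant formulas on the resulting
correlation matrix $R$:
$\mathrm{TC} = -\tfrac12 \log_2 \det R$ and
$\mathrm{DTC} = \tfrac12\big(\sum_j \log_2 \det R_{-j} - (n-1)\log_2 \det R\big)$.
These are lower-bound estimates of the underlying non-Gaussian quantities
and are exactly invariant under strictly increasing per-channel transforms.
No small-sample bias correction is applied: both groups share the bias, so
group contrasts are unbiased by construction, and the lower-bound character
of the estimates is preserved.

Degenerate inputs are hard errors, not silent repairs: constant channels
are rejected at the copula stage, and rank-deficient subset correlation
matrices (detected by a rank check, with a single $10^{-10}$ ridge retry
reserved for merely ill-conditioned Cholesky factorizations) raise an error
naming the offending subset.

```{r oracle}
R <- matrix(0.5, 3, 3); diag(R) <- 1        # equicorrelated triplet
X <- t(MASS::mvrnorm(10000, rep(0, 3), R))
c(TC = total_correlation(X), DTC = dual_total_correlation(X),
  O = o_information(X))
# closed forms: 0.5, 0.3774, +0.1226 bits
```

## Signal preparation

Epochs are average-referenced, averaged over trials into one representative
stimulus-locked trial per participant and session, and band-filtered into
the conventional delta (0.5–4), theta (4–8), alpha (8–12), beta (12–30) and
gamma (30–40 Hz) ranges. Averaging before filtering is equivalent to
filtering per trial, since both operations are linear.

The band filter realizes the bidirectional (zero-phase) magnitude response
of an order-3 Butterworth band-pass,
$|H(f)|^2$ with $|H(f)|^2 = \big(1 + ((f^2 - f_1 f_2)/(f\,(f_2-f_1)))^{6}\big)^{-1}$,
applied exactly in the frequency domain on an epoch extended by even
(symmetric) reflection. Three numerical findings drove this design, all
reproducible from the package's tests:

* transfer-function (`filtfilt`-style) realizations of the same filter are
  numerically unusable at delta-band normalized cutoffs on 1000 Hz data
  (stop-band leakage above 0.1);
* a cascade of separate order-3 high-pass and low-pass passes attenuates
  mid-band content (6 Hz in theta) below 0.8 after the four effective
  passes, which misrepresents the band;
* odd ("point-mirror") reflection padding injects a DC pedestal of height
  $2x_1$ into the extension, which swamps the delta band on 800 ms epochs;
  even reflection has no pedestal and leaves a 50 Hz tone at less than 0.01
  amplitude in the central half of a delta-filtered 800-sample epoch while
  preserving in-band sinusoids at $\ge 0.9$.

The response is real and even, so the filter has exactly zero phase, and
linearity holds to machine precision. An 800 ms epoch still only supports a
frequency resolution of 1.25 Hz; delta-band quantities therefore rest on
partially observed cycles, which inflates their estimation variance (see
*Limitations*).

## Greedy discriminative search

For each band, measure and direction the search starts from an exhaustive
scan of all subsets at the seed order — pairs for TC and DTC; triplets for
O-information and its sign reversal negO, because $\Omega \equiv 0$ for
pairs — and then repeatedly extends the current best subset by the single
channel that extremizes the between-group Cohen's d
$$d = \frac{\mu_{\text{treat}} - \mu_{\text{ctrl}}}{s}, \qquad
s = \sqrt{\frac{(m_t-1)s_t^2 + (m_c-1)s_c^2}{m_t + m_c - 2}},$$
up to order 16 (one quarter of a 64-channel montage). The printed form of
the pooled-variance denominator in the source literature contains an
obvious typographical slip; the standard pooled-SD convention above is
used. Ties in d are broken toward the lexicographically smallest subset so
runs are exactly reproducible. The evaluation count per participant is
$\binom{n}{k_0} + \sum_{k=k_0}^{15}(n-k)$ — verified by a counter — versus
$\binom{n}{16}$-scale costs for exhaustive enumeration. Both directions
(treatment above and below control) are always searched; synergy-favouring
networks are found by maximizing the sign-reversed O-information.

## Group inference

For every selected subset the same measure is back-computed from the
baseline session, and the follow-up values are modelled as
`follow_up ~ group + baseline` (control coded 0, treatment 1). The group
effect is the 1-df F test with residual df $m-3$; White's test of the
squared residuals on regressors, squares and cross-products is reported for
every model but never used as a filter. Benjamini–Hochberg FDR control is
applied separately within each (measure, direction) family across all bands
and orders; the family critical p value is an output of the step-up rule,
not an input. Perfectly fitting models are flagged with an infinite-F
sentinel (or F = 0 when the adjusted group difference is itself zero)
rather than raising, so batch sweeps complete.

**Selection and calibration.** The subsets entering these models were
chosen to extremize d on the very follow-up values being tested, so the
ANCOVA p values are anti-conservative under the null. This is a property of
the published analysis design, reproduced deliberately. The package
quantifies the consequence instead of hiding it: on null cohorts
(no planted effects) the full pipeline's per-family count of FDR-significant
models averages around 4 out of 10 at the reduced scale used by the test
suite — far above the nominal q = 0.05 — and no realistic degree of
across-session stability removes the bias, because the session-specific
sampling noise of band-limited correlation estimates is irreducible at
800 ms epochs. The run manifest carries this caveat, and the acceptance
outputs report the measured null rate. Discoveries from this pipeline
should be read as *selected-and-ranked candidates*, compelling only when
their F statistics dwarf the selection noise floor, as the large effects
reported in this literature do.

## The synthetic cohort

Each participant-session epoch array is built from:

* a trial-invariant evoked background per channel: one unit-variance
  band-limited Gaussian component per configured band, produced by the same
  zero-phase filter as the analysis so background and planted structure
  occupy exactly the analyzed bands;
* a participant-stable versus session-specific split of that evoked
  activity (`session_stability`, default 0.9 of evoked variance stable):
  trial-averaged stimulus-locked responses are highly stereotyped within a
  person across sessions, and this stability is what makes a baseline
  covariate informative. Amplitude-only stability (the per-participant gain
  jitter, default 10%) would be invisible to the copula measures, which are
  scale-invariant;
* independent per-trial white noise (`noise_sd`), suppressed by trial
  averaging;
* planted structures. A **common driver** adds one shared band-limited
  signal to every target channel, giving pairwise equicorrelation
  $\rho = a^2/(1+a^2)$ (invert with `driver_amplitude()`); a **collider**
  gives each non-final target channel a private band-limited signal and the
  final channel their scaled sum, giving source–collider correlation
  $\rho = t/\sqrt{(1+t)(1+mt)}$, $t = a^2$ (invert with
  `collider_amplitude()`), mutually uncorrelated sources, and negative
  O-information. Zero amplitude reproduces the null cohort bit-exactly.

Behavioral tables mirror the task design: 576 trials per session in 4
blocks, each block balancing 72 face/72 car and 72 high (37.5%)/72 low
(32.5%) coherence trials; log-normal reaction times (default median 600 ms,
dispersion 0.22 on the log scale, 30 ms slowing at follow-up in both
groups, i.e. a null group contrast), a 1.25 s response deadline producing
timeouts, and Bernoulli accuracy of 90% (easy) / 82% (hard), which keeps
overall accuracy above 80%. The source study reports behavioral
distributions only as figure-level medians, so these defaults are
conventions chosen to sit in the reported qualitative ranges, not
calibrated values.

## Behavioral statistics

Trials with reaction times outside the inclusive 300–1200 ms window are
discarded (fast guesses / attentional lapses); the boundary values
themselves are valid because the discard rule is stated with strict
inequalities. Timeouts never enter RT summaries but count as incorrect in
accuracy denominators. Summaries (median RT over valid correct trials,
percent correct) are computed for all/easy/hard/face/car trial classes and
compared between groups with Mann–Whitney U tests (exact for small
samples). Within-participant baseline-versus-follow-up RT effects feed a
Bayesian prevalence analysis: with $k$ of $n$ participants individually
significant at level $\alpha$, the posterior on the hit rate
$\theta = \alpha + \gamma(1-\alpha)$ is Beta($k+1$, $n-k+1$) under a
uniform prior; the maximum a posteriori prevalence is
$\max(0, (k/n - \alpha)/(1-\alpha))$ and the 95% credible interval is
formed from 10,000 Monte Carlo posterior draws transformed to the
prevalence scale. The per-participant test is a two-sided rank-sum test on
valid correct-trial RTs at $\alpha = 0.05$ (the source text does not name
the individual test; this is the natural nonparametric choice).

## Problem sizes used by the tests

The full-scale configuration (64 channels at 1000 Hz, five bands, four
measures, orders to 16, 576 trials) is supported but deliberately not what
the test suite runs. Tests use cohorts of 17 + 15 participants with 8- or
16-channel montages, 250 Hz sampling of the same 800 ms epoch, 16 trials,
two bands (delta + beta) and searches to order 6 — sizes chosen so the
entire suite, including twenty-cohort property checks, completes on a
single CPU in a few minutes while preserving the paper-sized group
contrast. Module-level search tests feed band trials that skip the average
reference: on an 8-channel montage the reference mixes 3/8 of any planted
driver into every channel and destroys the planted contrast, which is a
property of tiny montages rather than of the search. The end-to-end
recovery test keeps the full chain (including the reference) on 16
channels, and plants a collider with source–collider correlation 0.65
($\Omega \approx -0.55$ bits): recovery validation requires ground truth
well above the delta band's single-participant estimation noise floor
(SD ≈ 0.2–0.3 bits at 800 ms), which a correlation of $1/\sqrt{3}$
($\Omega \approx -0.21$ bits) does not clear from epochs this short.

## What the synthetic tests do and do not show

Passing tests demonstrate that the estimators match Gaussian closed forms,
that the search finds dominant planted structure and matches brute force,
that the inference machinery is calibrated where calibration is possible
(unselected ANCOVA, White's test, BH, prevalence), and that the pipeline is
bit-reproducible. They do not show that real EEG satisfies the generator's
assumptions: real background activity has 1/f structure, volume-conducted
cross-channel correlation, artifacts and non-stationarity, none of which
are simulated (the copula step removes sensitivity to marginal
distributions but not to those dependence structures). Nor do they remove
the selection anti-conservativeness discussed above.

## Known limitations

* Delta-band quantities from 800 ms epochs rest on partially observed
  cycles; their estimation variance dominates small planted effects.
* ANCOVA p values on greedy-selected subsets are anti-conservative; no
  post-selection correction is attempted (none is used in the source
  analysis).
* The O-information summarizes the redundancy–synergy balance only; no
  finer partial-information decomposition is provided.
* The generator plants second-order (Gaussian) structure only, which is
  exactly what copula-based estimators consume; effects carried purely by
  higher moments are out of scope.
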