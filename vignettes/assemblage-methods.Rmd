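---
title: "Detecting and validating hippocampal-prefrontal cell assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and validating hippocampal-prefrontal cell assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`assemblage` analyses simultaneously recorded dorsal CA1 (dCA1) and medial
prefrontal (mPFC) spike trains from delayed non-match to sample (DNMTS)
sessions: rats press a sample lever (left or right), wait out a 4/8/16 s
delay ended by a tone, and earn reward by pressing the opposite lever. The
pipeline asks which area carries the cue (sample side) at each moment, how
stable the delay code is, which groups of neurons co-fluctuate as cell
assemblies within and across the two areas, and which of these signatures
fail on error trials.

Because suitable raw recordings cannot be bundled with a package, every
stage is validated against a synthetic DNMTS session generator with planted
ground truth. The generator is first-class, tested code; its defaults are
the study conditions the analyses assume.

# The synthetic session generator

`simulate_session()` draws inhomogeneous-Poisson spike trains on a 5-ms
grid. The intensity of unit $i$ on trial $k$ is

$$\lambda_i(t) = b_i \cdot c_{ik}(t) \cdot g_{a(i)}(t) \cdot r_{ik}(t)$$

* **Baselines** $b_i$ are log-normal (median 2 Hz, $\sigma_{\log} = 0.5$),
  matching the skewed rate distributions of extracellular unit recordings;
  planted assembly members sit at 5 Hz so their co-fluctuations are visible
  at 50-ms resolution.
* **Cue tuning** $c_{ik}(t)$: about half the units are side-selective. dCA1
  units carry Gaussian bumps (SD 0.6 s, ~6 Hz amplitude) tied to the sample
  or choice press; mPFC units carry weaker (~3 Hz) bumps whose centres tile
  the delay (`delay_code = "sequential"`), or a constant delay offset
  (`"stable"`) used to plant a temporally stable code. dCA1 amplitudes are
  set higher than mPFC because that asymmetry in peak single-unit
  discrimination is a property the analyses must reproduce.
* **Assembly gain** $g_a(t)$: each planted assembly shares a multiplicative
  log-normal gain redrawn every 50 ms (SD 0.8 of the log, mean-corrected).
  This produces the ~0.15-0.2 pairwise count correlation between members
  that factor analysis is meant to pick up, without adding any
  trial-label (signal) correlation.
* **Rhythm** $r_{ik}(t) = 1 + m\cos(2\pi f t + \phi_k)$ with $f = 4.5$ Hz,
  $m = 0.3$ and a common phase per trial, applied to inter-area assembly
  members only, and only in the 4 s before the sample press. The planted
  rhythm therefore provides a positive control in the sample-preparatory
  window and a built-in negative control in the choice-preparatory window.
* **Errors**: outcomes are planted exactly per delay (defaults 10%/15%/35%
  for 4/8/16 s, echoing the strong delay dependence of real performance).
  On error trials the mPFC delay-tuning amplitude and the rhythm depth are
  multiplied by 0.3. Attenuation, not label flipping, is used so decoders
  trained on correct trials degrade on errors while dCA1 structure is
  untouched.
* **Schedule**: 150 trials (50 per delay, equal left/right counts per
  delay) in shuffled order; latencies between events are log-normal,
  independent of delay and outcome, and quantized to 0.25 s so that trial
  windows fall into a small number of exact-length classes (this matters
  for the trial-shuffle surrogate below).

What the generator does **not** emulate: bursting and refractoriness,
theta-phase precession, slow drift and electrode instability, behavioral
covariates (running, whisking), and realistic LFP coupling beyond the
simple planted oscillators of `simulate_lfp()`. Passing tests therefore
demonstrate that the estimators recover the structure they target under
Poisson variability at realistic rates and counts — not that real
recordings contain that structure.

# Firing-rate estimation

Rates are kernel density estimates: spike trains convolved with a Gaussian
of SD $h$, sampled at 50-ms bin left edges (bin $k$ covers
$[k\cdot 0.05, (k+1)\cdot 0.05)$ s, and offset 0 is the alignment event —
one convention everywhere prevents off-by-one-bin drift). The bandwidth is
chosen per unit by minimizing the unbiased least-squares cross-validation
error, for which Gaussian kernels admit a closed form:

$$\mathrm{CVE}(h) = \frac{1}{n^2}\sum_{i,j}\varphi_{\sqrt2 h}(d_{ij})
  - \frac{2}{n(n-1)}\sum_{i\neq j}\varphi_h(d_{ij}),$$

with $d_{ij}$ the spike-time differences. The implementation truncates
pairs beyond $12h$ (the $\sqrt2 h$ kernel's $8.5\sigma$) and is verified
against a direct numerical leave-one-out evaluation to $10^{-8}$ relative
error. Minimization is a 60-point log-spaced grid search over 1 ms-2 s with
ties broken toward the smaller bandwidth; the CVE can be flat, so a
deterministic rule is needed. For homogeneous trains the CVE valley is flat
at large $h$ and the argmin wanders within the upper plateau — stability to
within a grid step only holds when the train has temporal structure. One
bandwidth per unit (selected on the whole task period) is reused for every
alignment so tensors stay comparable across events. Several calibration-
style analyses instead fix the bandwidth (50-200 ms) where per-unit
selection is irrelevant to the question asked; this is a configuration
knob, not a change of method.

Event responsiveness uses the classic $|z| > 3$ rule in a 2-s post-event
window against a 500-ms pre-event baseline. The $z$ denominator is the
standard error of the trial-averaged rate (across-trial SD pooled over
baseline bins, divided by $\sqrt{n_\mathrm{trials}}$): estimating an SD
from the ten 50-ms baseline bins alone would roughly double the nominal
false-positive rate.

# Single-unit and population decoding

Per 50-ms bin, cue discrimination is the pooled-SD two-sample t statistic
between left- and right-trial rates; at the typical ~54 trials the p<0.05
criterion is $t > t_{0.95,52} = 1.67$. Significance masks come from label
shuffles shared across bins, with exact permutation p values
$p = (1 + \#\{|t|_\mathrm{null} \ge |t|\})/(B+1)$ and Bonferroni correction
over bins. Exact p values are conservative at any shuffle count; a
quantile-threshold rule at small $B$ silently inflates the false-positive
rate, which is visible in calibration runs. This means a Bonferroni-
corrected mask at level $\alpha$ over $n_b$ bins needs
$B \ge n_b/\alpha$ shuffles to have any power — calibration analyses size
their windows accordingly. A unit is *informative* when significant bins
within ±4 s of the sample or choice press total more than 50 ms (at least
2 bins; the ≥1-bin reading is available via `min_bins`). Encoding duration
is total significant time; a longest-run variant is exposed as an option.

Population decoding is a two-class linear discriminant on the trial ×
unit rate matrix of each bin, with the pooled covariance regularized toward
the identity, $\Sigma_\mathrm{reg} = \Sigma + \lambda I$, $\lambda = 0.05$
fixed without optimisation, equal priors, and the boundary through the
midpoint of the class means. Features are raw KDE rates (no per-unit
z-scoring) because the regularization is defined on the covariance, not the
correlation. Performance is leave-one-out cross-validated correct-
prediction fraction (CP = 1 − CVE). LOOCV LDA carries a small negative
bias at chance (~1/n), inherent to leave-one-out with plug-in means; the
calibration analysis accounts for it. Area comparisons equalize population
size by drawing K units (the smaller area's count) with replacement from
the larger area 10 times and averaging; CP differences are referred to a
Beta(k+1, n−k+1) reference built from the smaller CP. Hotelling's $T^2$
with the same regularized covariance provides the parametric cross-check,
with the usual F approximation (exact at $\lambda = 0$).

Correct-to-error generalization trains each bin's decoder on all correct
trials and evaluates on error trials. Within one session, a Bonferroni-
corrected per-bin permutation test on a handful of error trials is
hopelessly underpowered (the CP granularity alone exceeds the required
effect), so condition contrasts are run at the session level: per-session
window-averaged CP differences are tested by sign-flip permutation across
sessions (`paired_permutation_test()`), mirroring how multi-session data
are actually analysed.

# Cross-temporal decoding

Code stability over the delay is probed by training at one time and testing
at every other. Per resample, 8 trials per class are drawn; within the
draw, one trial per class is held out in turn (leave-one-pair-out), so
training and testing sets are disjoint while every decoder sees 7+7
trials. 500 resamples is the full-scale convention; reduced grids
(`stride`) and resample counts are used in tests. Resample-group means are
retained so that two conditions can be compared by group-label permutation
(`ct_difference()`). Cell-level significance uses label-shuffled grids.
The 250-ms Gaussian kernel applied for display is read as a FWHM
($\sigma = 250/2.355$ ms), applied after significance testing and never to
the mask.

# Factor-analysis assembly detection

The FA model for the units × bins rate matrix (concatenated task epochs:
cue − 5 s to choice + 5 s per completed trial, overlapping windows merged)
is $v_t = \mu + \Gamma z_t + \varepsilon$, $\varepsilon \sim N(0, \Psi)$
diagonal, $z \sim N(0, I)$. Fitting is EM on the ML covariance with
log-likelihood guaranteed non-decreasing; convergence at $10^{-6}$
relative log-likelihood or 500 iterations; Heywood cases are floored at
$10^{-6}$ of the unit variance and flagged.

Initialization deserves a note: a factor loading an isolated unit's
variance is likelihood-equivalent to putting that variance in $\Psi$, so EM
cannot move off such a ridge. Principal-axis initialization points factors
at the highest-variance single units and, on surrogate data, leaves
spurious single-unit loadings as large as a unit's SD, which wrecks the
bootstrap loading threshold. Factors are therefore initialized from the
eigenstructure of the *correlation* matrix (scaled back to the covariance
metric), so they start where correlation — the thing FA is for — lives.

Model selection and membership use the trial-shuffle bootstrap: for each
unit independently, whole-trial rate segments are permuted across trials,
preserving within-trial autocorrelation and the event-locked rate
structure while destroying instantaneous cross-unit dependencies. Trials of
exactly equal bin count exchange directly; remaining trials are permuted
within nearest-length blocks with donor segments truncated or recycled to
the recipient length. Note what this null removes and keeps: stimulus-
driven co-modulation (two units tuned to the same side) *is* destroyed by
the shuffle, so factors capturing strong shared tuning are genuine
detections for this method — which is why the assembly-recovery benchmarks
plant assemblies into otherwise untuned populations when the question is
specifically gain co-fluctuation.

The factor count is the largest $l$ such that every incremental
log-likelihood ratio $2(\ell_m - \ell_{m-1})$, $m \le l$, exceeds the 99th
percentile of the same statistic over 500 (reduced in tests) trial-shuffled
surrogates, stopping at the first failure. "Exceeds the 1% upper confidence
limit" is read as the 99th percentile of the bootstrap distribution; the
same reading applies to loadings: a unit joins a factor's assembly when its
|loading| exceeds the 99th percentile of the pooled bootstrap |loading|
distribution at the same factor count (a per-factor variant is available).
Factor signs are fixed so each factor's largest-|loading| unit is positive.
No rotation is applied — significance is bootstrap-calibrated per loading,
and rotations would detach loadings from their null distribution.

Assemblies need ≥ 2 significant members; they are typed by their members'
areas, and a within-area assembly whose member set is contained in an
inter-area assembly is reported as part of the larger one. Activation
significance projects trial-shuffled inputs through the fitted model and
thresholds factor scores at the shuffled 99th percentile. An independent
PCA/ICA route (Marchenko-Pastur eigenvalue bound on the z-scored
correlation matrix, fixed-point ICA on the retained subspace, membership at
weight > mean + 2.5 SD, ≥ 3 members) cross-checks FA; agreement is scored
as the mean best-pair Jaccard overlap $O = |A \cap B| / |A \cup B|$. The
2.5-SD weight rule is known to penalize large assemblies in small
populations (the members themselves inflate the weight SD), so convergent-
validity benchmarks use compact (≤ 4-unit) planted assemblies in full-size
populations.

Optimality benchmarking ranks units by individual peak CP and decodes
consecutive rank blocks of each size; a detected assembly is assigned the
rank of the closest-performing synthetic block of its size. Within-class
trial-order permutation (per unit, or per area) estimates the contribution
of noise correlations to the population code.

# Rhythmic physiology

Autocorrelograms are coincidence counts normalized by the homogeneous-
Poisson expectation (asymptote 1). The band modulation index — not defined
canonically anywhere — is the fraction of mean-removed ACG spectral power
(lags ≤ 1 s) in 3.5-5.5 Hz relative to 1-15 Hz; a (peak−trough)/(peak+trough)
alternative over 150-300-ms lags is provided. Pair coherence is multitaper
(Slepian tapers computed from the tridiagonal eigenproblem, NW = 3, 5
tapers) on mean-subtracted 10-ms binned counts over concatenated 4-s
epochs. Cross-correlograms rate-match the two trains per window by
subsampling the larger to the smaller count (100 draws), tally
coincidences, and divide by the per-draw matched total spike count;
positive lag means the dCA1 reference fires first. Both correlograms
correct for the finite analysis window (pairs at lag $\tau$ can only arise
over $T - |\tau|$ of a $T$-s window); without this the linear count decline
masquerades as low-frequency spectral mass. CCG and ACG spectra apply a
Hann taper before the FFT so sidelobe leakage from broad envelope
components cannot outcompete a genuine narrow-band peak. CCG spectra are
tested
between conditions by per-frequency permutation at the CCG's native
spectral resolution (zero-padded oversampling would multiply the Bonferroni
burden with no information gain), and condition comparisons subsample
epochs to equal counts because the CCG noise floor scales with 1/epochs.
The lead/lag balance is (Σ positive-lag − Σ negative-lag)/Σ all. LFP phase
locking band-passes with a zero-phase 4th-order Butterworth, takes the
FFT analytic-signal phase at spike times, and reports the mean resultant
length with the Rayleigh test (Zar's approximation); units under 50 spikes
are excluded.

# Numerical and design choices

* All times are absolute seconds from session start; alignment is by
  subtraction only.
* Miss trials are excluded from every analysis; sessions with < 67%
  completed trials are flagged by a warning rather than refused.
* Permutations are shared across bins within a run; every stochastic step
  is reproducible under `set.seed()` and the pipeline derives all stage
  seeds from one master seed.
* Problem sizes in tests and the validation script are deliberately small
  (8-24 units, 30-90 trials, 50-200 shuffles, 100 FA bootstraps); they were
  chosen as the smallest scales at which the planted effects are
  comfortably detectable, and the full-scale defaults (1000 shuffles, 500
  bootstraps, 500 resamples) remain the package defaults.

# Known limitations

* The trial-shuffle surrogate's nearest-length fallback leaves a seam where
  donor segments are recycled; with latencies quantized at 0.25 s this
  affects few trials, but data with wildly variable trial lengths would
  weaken the null slightly.
* EM-FA finds local optima; the correlation-based initialization makes the
  benchmarks reproducible but a different deterministic initialization can
  select a different (equally supported) factor count near the significance
  boundary.
* The beta-reference CP comparison treats bins independently and ignores
  LOOCV fold dependence; it matches common practice rather than an exact
  sampling distribution.
* `simulate_lfp()` plants phase locking by regenerating a unit's spikes
  from the target component's phase, so locked units lose their original
  task tuning; it is meant for validating the phase-locking estimators
  only.
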