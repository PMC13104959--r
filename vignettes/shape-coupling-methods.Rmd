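---
title: "Cycle-by-cycle respiration-neural shape coupling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cycle-by-cycle respiration-neural shape coupling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the screening and estimation procedures, their assumptions, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. What is being estimated

Coherence between a respiration trace and a neural channel demonstrates
frequency-locking averaged over a recording, but not that the *shape* of
each breath is reflected in the shape of the matched neural cycle. The
target estimand here is a standardized within-subject slope
$\beta_\mathrm{within}$: how many pooled-SD units a neural waveform
feature moves per pooled-SD unit of the matched breath's feature, after
removing subject-level means. A slope of 0 means cycle-shuffling the
breaths would change nothing; a slope of 1 means neural cycle shape copies
breath shape.

The analysis proceeds in three stages — screening, cycle matching with
feature extraction, and hierarchical estimation — each of which only
consumes the previous stage's output, so each is testable in isolation.

## 2. Preprocessing

* Neural channels are assumed bipolar re-referenced
  (`bipolar_rereference()`, contact $i$ minus contact $i+1$), which cancels
  far-field components but leaves the *sign* of each derivation arbitrary;
  the cross-correlation screen therefore estimates and reports a polarity
  that downstream extraction can apply.
* Respiration traces are low-pass filtered at 2 Hz with a linear-phase
  windowed-sinc FIR (Hamming window, 1 Hz transition band), group-delay
  compensated so the net delay is zero and the DC gain exactly 1.
* For the time-domain screens both signals are band-passed 0.01–2 Hz with
  a fifth-order Bessel filter applied forward-backward and then z-scored
  over the whole recording (not per epoch, so epoching cannot change the
  normalization). The Bessel family is chosen for its flat group delay,
  preserving waveform timing. A numerical note: the 0.01 Hz corner places
  poles within $4\times10^{-4}$ of the unit circle, and a time-domain
  recursion rings for minutes after any edge; the forward-backward pass is
  therefore applied spectrally — the padded signal's spectrum is multiplied
  by $|H(f)|^2$ of the second-order-section cascade, which is the exact
  steady state of forward-backward filtering with no transient. Pads are
  odd-reflected and cosine-tapered; the first and last 10 s of any
  filtered recording are flagged and excluded from cycle extraction.

## 3. Screening respiration-locked channels

**Breathing band.** The respiration PSD (Welch, 40 s Hann windows, 20 s
overlap, 0.025 Hz grid) is decomposed into an aperiodic
$\mathrm{offset} - \chi \log_{10} f$ component plus Gaussian peaks
(`spectrum_model()`). The highest peak within 0.05–1 Hz defines the
breathing frequency $f_\mathrm{resp}$, the fixed-width analysis band
$f_\mathrm{resp} \pm 0.1$ Hz, and the period $\tau = 1/f_\mathrm{resp}$.
Because breaths are strongly nonsinusoidal, their harmonics can rival the
fundamental in the flattened spectrum; each Gaussian is therefore fitted
on the local monotone window around its candidate maximum so neighboring
harmonic peaks are resolved separately rather than swallowed by one wide
Gaussian. Unstated-in-advance settings were fixed once: fit range
0.05–2 Hz, at most 4 peaks, FWHM limits 0.02–0.5 Hz, relative threshold 2
SD of the flattened spectrum, and an absolute height floor of 0.55
log-units calibrated so a pure aperiodic Welch spectrum at the default
segmentation essentially never yields a spurious peak (a participant with
no detectable respiratory rhythm is excluded with a classed error).

**Coherence screen.** Magnitude-squared coherence
$C(f) = |P_{xy}|^2/(P_{xx}P_{yy})$ is computed on 32 s segments with 27 s
overlap (0.03125 Hz grid). The selection statistic is the maximum
coherence within the breathing band; its null distribution comes from
phase-randomized surrogates of the *neural* signal (amplitude spectrum
preserved exactly, phases uniform with Hermitian symmetry), and the
channel must exceed the 99th percentile of 1,000 surrogate maxima. Using
the max-in-band statistic for the surrogates matches the selection
statistic and controls selection-level error across band bins. The dual
criterion additionally requires a spectral-parameterization peak of the
neural PSD inside the band, because harmonics of a nonsinusoidal breath
can drive coherence without any fundamental neural rhythm; such channels
fail the screen. Note the surrogate null is far above textbook coherence
significance: both signals are narrowband near $f_\mathrm{resp}$, so
surrogate coherence within a 32 s segment is high and only decorrelates
across segments — exactly why the empirical null is needed.

**Cross-correlation screen.** Both (band-passed, z-scored) signals are cut
into epochs centered on each inhale peak with window length $\tau$ — one
mean breath period, so the inhale peak and exhale trough both fall inside
(the window rule is our concretization of "calibrated to the breath
cycle"). Per epoch the normalized cross-correlation (divided by the
product of epoch norms, so values lie in $[-1,1]$) is averaged across
epochs, lags restricted to $|\ell| \le \tau/2$, and the maximum absolute
value extracted. The null re-pairs the real respiration epochs with
randomly placed neural segments drawn outside a 10 s margin around each
original window (500 permutations); polarity is flipped when the extremal
mean CCF is negative. Finite epochs imply a small zero-padding bias of
the extremal lag toward zero (a couple of samples at these settings); the
screen statistic is the maximum magnitude, which is unaffected in
practice.

**Phase monotonicity index.** Each respiration cycle is split at the
detected extrema into rising (trough to peak) and falling (peak to trough)
phases. A cycle's PMI is the unweighted mean of the fraction of positive
neural first differences in the rising phase and negative differences in
the falling phase (ties count as inconsistent in both directions —
conservative); the channel PMI is the median over cycles. The combination
rule (mean of the two fractions) is our choice where the procedure was
underdetermined; both components are retained in the result. The null
circularly shifts the neural signal by at least 10 s, preserving its
autocorrelation while destroying alignment; 500 shifts, 99th percentile.
A perfectly monotone channel scores 1, an unrelated one about 0.5 — both
limits are exercised in the tests.

All percentile thresholds use linear interpolation between order
statistics (quantile type 7) throughout.

## 4. Cycle matching and shape features

**Extrema.** Stage one finds candidate peaks above a base height (default:
the signal median, i.e. 0 after z-scoring) separated by at least
1.5 s; troughs identically on the negated signal. Stage two removes
extrema below 0.3 x the median extremum amplitude (the two thresholds are
named by the procedure but not valued; 0.3 is our default), then enforces
strict alternation by keeping the higher of consecutive peaks and the
deeper of consecutive troughs. Cycles whose within-cycle amplitude or RMS
exceeds median + 5 MAD are rejected as artifacts; with MAD = 0 the strict
inequality rejects nothing.

**Matching.** Respiration peaks are visited in time order and each claims
the temporally closest unmatched neural peak; a pair is kept when
$|\Delta t| < \tau$ and both cycles have both bounding troughs. The
contract is the greedy order, not global optimality — an earlier breath
may claim a neural peak a later breath is closer to — and ties resolve to
the earlier neural peak. `match_direction = "neural_after_resp"` restricts
candidates to delays $\ge 0$ for users reading "delayed" one-sidedly;
the default uses $|\Delta t|$.

**Features.** Per cycle (trough–peak–trough): rise time, decay time,
duration (their sum), amplitude (peak minus the mean of the two bounding
troughs), symmetry (rise/duration), sharpness (mean $|dx/dt|$ over the
contiguous window within half the local peak-to-trough amplitude of the
extremum, normalized by that amplitude), and AUC (trapezoidal integral of
the signal minus the cycle median over the contiguous region on the
extremum's side of the median). The exhale-trough windows may extend past
the cycle's end trough (capped at one cycle length), since the trough's
median crossing naturally falls in the next cycle's rise. The cycle
median — not the whole-recording median — sets the AUC boundaries (local
robustness; exposed as a documented choice). Feature-wise outlier
exclusion drops a row when any feature (amplitude excluded, mirroring the
listed metrics) exceeds its channel's median + 3 SD; the rule is
deliberately one-sided.

## 5. The hierarchical coupling model

For a feature pair, with $y_i$ the neural feature standardized by its
pooled SD and the respiration predictor split into within
($x^w_i$: subject-mean-centered, scaled by the pooled within-subject SD)
and between ($x^b_{s}$: grand-mean-centered subject means scaled by their
SD) components:

$$y_i \sim \mathrm{StudentT}(\nu,\ \mu_i,\ \sigma), \qquad
\mu_i = \alpha + (\beta_w + w_{s(i)}) x^w_i + \beta_b x^b_{s(i)} +
u_{s(i)} + v_{c(i)}$$

with priors $\beta_w, \beta_b \sim N(0,1)$, $\alpha \sim N(0,2)$, all SD
components and $\sigma \sim \mathrm{Exponential}(1)$, and
$\nu \sim \mathrm{Gamma}(2, 0.1)$. The Student-t likelihood absorbs
heavy-tailed cycles that survive outlier exclusion. The random-effects
structure — subject intercepts, channel-within-subject intercepts, and a
by-subject random within-slope — is one concrete instance of "hierarchical
nesting of participants and channels"; the random slope is dropped by
default below 5 subjects and the channel term when channels do not
outnumber subjects (identifiability), both switchable.

**Sampler.** The model is fitted by a blocked Gibbs sampler written for
this package, using the scale-mixture-of-normals representation of the
Student-t (per-observation Gamma weights $\lambda_i$), conjugate
multivariate-normal updates for the fixed effects and each random-effect
block, and univariate slice updates on the log scale for the SD
components, $\sigma$, and $\nu$ (bounded to $[1.5, 200]$). Interweaving
("sweep") moves resample the shared location between the intercept and
each random-intercept block, between $\beta_w$ and the random slopes, and
between $\beta_b$ and the subject intercepts along the between-predictor
direction; these leave the likelihood invariant and remove the posterior
correlations that otherwise stall single-site Gibbs in hierarchical
models. Convergence is monitored by split-Rhat over all chains with a
1.01 flag (warning, not fatal). The test suite cross-checks the sampler
against an independent JAGS implementation of the identical model on a
small fixture: posterior medians and quantiles of $\beta_w$, $\sigma$,
$\nu$ and the SD components agree.

Defaults are 4 chains x 3000 iterations (1500 warmup); equal-tailed 95%
credible intervals (2.5/97.5 percentiles of pooled post-warmup draws);
$P(\beta_w>0)$ is the fraction of positive draws. Posterior predictive
adequacy is summarized as the coverage of the observed outcome by the
central 50% and 90% predictive intervals (`ppc_coverage`).

**Null models** (`null = TRUE`) permute $x^w$ across cycles *within each
subject* — destroying cycle-level pairing while preserving the predictor's
distribution and the multilevel structure — and refit with identical
priors and sampler settings. Displacement of the real posterior from the
null posterior is the evidence that coupling is cycle-level rather than an
artifact of shared slow structure; `plot(fit, null = null_fit)` overlays
the two.

**Modality comparison.** `compare_modalities()` reduces each participant's
cycles to a median per feature and modality and applies the paired
two-sided Wilcoxon signed-rank test (exact for up to 25 pairs; all-zero
differences reported as degenerate with $p = 1$).

## 6. The synthetic-data generator

No recordings are distributed with the method, so the generator is
first-class, tested code defining the study conditions.

**Breaths.** A breath is two monotone half-cosine limbs: a rise from a
(negative) trough to the inhale peak, and a decay back through baseline,
holding *at baseline* for the post-expiratory pause before descending into
the next trough. Airflow-like biphasia matters: the trough is a unique
smooth minimum *below* the pause level, so the onset trough of each breath
is a well-defined landmark and extracted durations equal rendered
durations (a flat pause at trough level would make the trough location an
argmin over noise, injecting ~0.2 s of predictor measurement error and
attenuating recovered slopes by tens of percent — the decisive argument
for this template). Defaults: rise 1.6 +/- 0.25 s, decay (pause included)
2.2 +/- 0.3 s, pause 0.5 +/- 0.2 s, amplitude 1 +/- 0.15 (truncated below
at physiological floors), giving a ~0.26 Hz resting rhythm. Belt traces
use the same template with the pause damped (x 0.3) and the waveform
smoothed to ~1 Hz — blunter extrema and smaller AUC at identical cycle
durations, which the modality-comparison test confirms.

**Coupled LFP channels.** For each breath, a neural cycle is rendered from
the same template family with standardized rise, decay and amplitude equal
to $\beta_\mathrm{true} \cdot z(\text{breath feature}) + t_\nu \cdot s$
(defaults $\nu = 5$, $s = 0.74$, chosen so the standardized feature
variance is ~1 at moderate coupling and the recovered standardized slope
equals $\beta_\mathrm{true}$ up to a ~1% scale factor). The neural peak
sits ~`lag_s` (default 0.3 s, a free parameter — the typical physiological
lag is not pinned down by the literature this implements) after the breath
peak. Cycles chain through shared troughs; because durations are free
while peaks must track the breath train, the chain would otherwise drift,
so a proportional controller (gain 0.25) absorbs the accumulated drift
into the *flat mid-decay pause* of the current cycle. Two properties of
this arrangement are load-bearing: the correction depends only on past
cycles' noise, so the current cycle's rise-time coupling is exactly
unbiased (rise time is therefore the parameter-recovery feature used in
the acceptance suite); and the correction never touches trough-adjacent
limb shapes, so it cannot leak into extraction via extrema displacement.
Exact per-peak anchoring is impossible without bias: it would force
measured decay$_k$ + rise$_{k+1}$ to equal the breath's inter-peak
interval identically, dragging duration-feature slopes toward 1 regardless
of $\beta_\mathrm{true}$. Decay and duration therefore carry a small
amount of mechanical correction noise and are not used as recovery
targets. With $\beta_\mathrm{true}=1$ and zero noise the construction is
exactly self-consistent: neural durations copy breath durations and the
drift correction vanishes identically.

Aperiodic $1/f^2$ background (RMS 0.1 of the mean cycle amplitude — a
strongly entrained channel) is added; `generate_dataset()` also renders
background-only channels as the manifest's "uncoupled" role, used as the
negative control that fails every screen. Channels that are time-locked
but shape-uncoupled are available via `simulate_coupled_lfp()` with
$\beta_\mathrm{true}=0$. One global seed drives named per-stream
substreams, so adding subjects or channels never perturbs existing
recordings.

**A calibration note on raw posteriors.** Cycle landmarks are detected on
smoothed signals, and a smoothed V-shaped trough's apparent position
depends on the asymmetry of its flanks; those flank lengths weakly share
breath geometry between the two signals even when shapes are uncoupled.
The net effect, measured on uncoupled synthetic channels, is a tiny
positive lean of the raw within-slope posterior (about +0.01 standardized
units — roughly 1% of one SD — confirmed identically by pooled OLS, so it
is a data-level measurement interaction, not a property of the sampler or
priors). Credible-interval coverage of the ground truth is unaffected at
the study sizes used, but the raw $P(\beta_w>0)$ should not be read
against an assumed exact zero: inference about coupling is made against
the cycle-shuffled null model, which shares the same measurement geometry
and therefore absorbs this artifact — the design reason the null models
exist at all.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: cardiac and movement artifacts, apnea and
sighs, non-stationary breathing rate, volume conduction between channels,
epileptiform activity, and any harmonically structured neural background.
The generator's coupling is also feature-wise independent by construction,
whereas real breath features covary.

## 7. Problem sizes and conditions used by the checks

The test suite exercises: screen calibration on 200 independent
channel/respiration pairs (150 s at 100 Hz; 200 surrogates/permutations
for the coherence and CCF screens, the 500-permutation default for the
PMI screen) against the <= 2 x nominal 1% bar; and parameter recovery on
20 seeded replicates per $\beta_\mathrm{true} \in \{0, 0.3\}$ of 10
subjects x 2 channels x ~150 cycles (680 s at 100 Hz), fitted with 2
chains x 1500 iterations, requiring 95% CrI coverage of the truth in
>= 18/20 and real-vs-null separation at $\beta_\mathrm{true}=0.3$.
100 Hz generation amply samples dynamics below the 2 Hz analysis
band; 500 Hz (the preprocessing target rate for clinical recordings) is
used where single-sample fidelity is asserted. `scripts/acceptance.R`
re-derives the same quantities at reduced replication (100 calibration
pairs, 4 recovery replicates) from any `--seed`.

## 8. Known limitations

* The screens' empirical nulls make mild exchangeability assumptions
  (stationarity for circular shifts; sufficient recording length for the
  CCF margin rule). Recordings much shorter than ~2.5 min leave few
  coherence segments and the surrogate threshold rises accordingly.
* The PMI is rank-based within phases (invariant to monotone transforms)
  but assumes the breathing-band component dominates the band-passed
  neural trace; strong unrelated slow activity lowers it toward 0.5.
* The greedy matcher is order-dependent by contract; in pathological
  configurations a globally better assignment exists.
* Extremal-lag estimates from finite epochs are biased toward zero by a
  few samples (windowing); the screen uses magnitudes, and matching uses
  extrema times, so downstream results are unaffected.
* The Gibbs sampler's posterior-predictive simulation and
  `fitted()`/`residuals()` use posterior-mean random effects, a standard
  plug-in approximation.
* Single-subject designs estimate only the within-slope; the between
  component is zeroed with a warning.
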