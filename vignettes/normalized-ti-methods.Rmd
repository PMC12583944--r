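---
title: "Normalized total interdependence for EEG hyperscanning: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalized total interdependence for EEG hyperscanning: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In team-training simulations, several people work together while each wears a
mobile EEG headset.  A recurring question is whether the degree of
*brain-to-brain synchronization* -- statistical dependence between different
individuals' neural signals -- tracks how well the team works together, as
judged by structured behavioural ratings (here, the five-domain TeamSTEPPS
instrument scored by two independent raters).  `hyperti` implements the full
analysis chain for one session design: six participants, 15-channel EEG at
125 Hz, manually annotated communication events, and two-rater scores.

## The synchrony measure

For two signals with magnitude-squared coherence $C(f)$, the band **total
interdependence (TI)** is

$$\mathrm{TI} = -\sum_{f \in \text{band}} \log\big(1 - C(f)\big),$$

a nonnegative quantity (nats) that is additive over disjoint bands and grows
with linear dependence at any lag.  Coherence is estimated Welch-style over
1-second epochs: per-epoch linear detrend, Hann window, DFT at integer-Hz
bins (1-s epochs make the bin spacing exactly 1 Hz), cross- and auto-spectra
averaged over the $K$ commonly clean epochs.  Two bands are analysed:
*all* (1--20 Hz inclusive) and *alpha* (8--12 Hz inclusive).

The coherence estimate is biased upward by roughly $1/K$ under independence,
and raw TI grows with the number of epochs analysed, so raw values are not
comparable across communications of different length.  **Normalization**
replaces the raw TI with a z-score against a permutation null: the epoch
pairing of one subject is shuffled uniformly (no fixed-point constraint),
band TI is recomputed, and this is repeated `n_perm` times (default 1000).
Shuffling preserves each subject's own spectra while destroying
cross-subject alignment, which is the minimal exchangeable null for
coherence.  The z-score is $(\mathrm{TI} - \mu_{null})/\sigma_{null}$.  Each
null sample is audited for normality with a Kolmogorov-Smirnov test at
$\alpha = .05$ against a normal with the sample's own mean and SD; the
result is carried along as a flag, not used to discard values.  The
permutation TI null is mildly right-skewed by construction (it is a sum of
$-\log(1-\hat C)$ terms), so the choice of audit matters: the
estimated-parameter-corrected (Lilliefors) version has real power against
that skew and flags the majority of nulls at usual permutation counts,
whereas the plain KS statistic with fitted parameters is conservative and
flags only clear departures, at a rate consistent with what is reported in
practice for this pipeline.  The plain version is the default;
`ks_audit = "lilliefors"` selects the corrected one.

Because any affine rescaling of raw TI cancels in the z-score, downstream
results are insensitive to alternative normalization constants (for example
per-bin bandwidth factors) that some formulations attach to the TI sum.

## The pipeline

1. **I/O and preprocessing.**  Recordings are CSV (`unix_time` + 15 labelled
   channels, microvolts).  Signals are rereferenced to the common average and
   band-passed 1--40 Hz with a 4th-order Butterworth filter applied
   forward-backward (`signal::filtfilt`), i.e. zero-phase -- phase matters
   because cross-spectra are computed later.  The two operations are linear
   and commute (tested to 1e-6).
2. **Artifact rule.**  Per channel, a *golden SD* -- a robust variability
   estimate, $1.4826 \times$ the median absolute deviation of the filtered
   recording, unbiased for Gaussian data and resistant to up to tens of
   percent contamination -- anchors an amplitude threshold.  The recording is
   cut into contiguous 1-s epochs (trailing partial epoch dropped); an epoch
   is rejected when any sample on any channel exceeds 6 golden SDs.  Only
   epochs *commonly clean* for both members of a pair enter coherence
   estimation.  Manual component-based artifact correction used in lab
   practice is deliberately out of scope; the amplitude rule is the
   automated, machine-specifiable replacement, and this fidelity gap should
   be kept in mind when comparing with hand-cleaned analyses.
3. **Alignment.**  Devices start recording at slightly different moments.
   Per-subject lags are estimated from shared audio envelopes by normalized
   cross-correlation (search window ±5 s; the first subject is the
   reference, lag 0; a peak correlation below 0.2 raises an "unreliable"
   flag).  Recordings are trimmed onto a common sample grid before epoching,
   so both members of a pair share one epoch clock.
4. **Communication windows.**  Each annotated event (sender, receiver,
   start, end) is mapped to the half-open sample window
   $[\lceil t_0 f_s\rceil, \lfloor t_1 f_s \rfloor)$; events shorter than
   one epoch after clipping are marked invalid rather than raising.  TI is
   computed for **all** subject pairs within each communication window (the
   pairwise measure is symmetric, so no sender/receiver asymmetry is
   imposed), for each of the three regions and two bands.
5. **Regions.**  Channels are averaged within anterior
   {Fp1, Fp2, F3, Fz, F4}, central {C3, Cz, C4} and posterior
   {P7, P3, Pz, P4, P8, O1, O2} before spectral estimation -- one series per
   region, hence one TI per pair, region, band and communication.  Averaging
   before (rather than after) spectral estimation is a design choice; the
   map is configurable.
6. **Aggregation.**  Unweighted means at every level: a student's
   communication TI is the mean over all valid pair TIs including that
   student; the student TI is the mean over that student's valid
   communications; the group TI is the mean of the six student TIs and is
   defined only when all six exist.  A pair-communication TI is *valid* when
   it rests on at least `K_min = 10` commonly clean epochs -- below that the
   coherence estimate is dominated by its $1/K$ bias.
7. **Scores.**  The two raters' scores are averaged per (profession, topic)
   and min-max scaled by the instrument's declared per-profession ranges;
   the overall score is the *sum* of the five topic scores scaled by the
   overall range (not the mean of the five scaled topics).  The group score
   is the mean of the six professions' scaled overalls.  Interrater
   reliability is ICC(2,1): two-way random-effects, single-rater, absolute
   agreement, computed from the ANOVA mean squares; boundary values of the
   qualitative bands are assigned to the band whose printed range starts
   there (0.75 is "excellent" on the Cicchetti scale).
8. **Inference.**  The 36-case grid -- 6 scores (5 topics + overall) x 3
   regions x 2 bands -- of Pearson correlations, at the individual
   (subject-session) and group (session) levels separately.  Each case is
   screened for bivariate outliers with FastMCD (75% support), Pearson r and
   its exact-t two-sided p are computed on the survivors, and
   Benjamini-Hochberg correction is applied across exactly the 36 cases of
   that grid ($m = 36$ even when some cases are undefined); significance is
   adjusted $p < .05$.  Screening is skipped below 10 observations.

## The MCD cutoff: an honest small-sample correction

The asymptotic rule flags points whose robust squared Mahalanobis distance
exceeds $\chi^2_{2, 0.999} = 13.816$.  At session-level sample sizes
($n \approx 10$--$30$), however, raw MCD distances are strongly inflated by
the estimator's small-sample bias: simulation shows the $\chi^2$ rule flags
clean bivariate-normal points at dozens of times the nominal 0.1% rate, and
because trimming extremes from a null cloud biases the subsequent
correlation test, the per-case type-I error roughly doubles.  The default
cutoff is therefore *calibrated*: the package simulates 400 clean
bivariate-normal datasets of the same $n$ (fixed internal seed, memoized per
$n$), computes their robust distances with the identical FastMCD pipeline,
and uses the empirical $1-\alpha$ quantile as the threshold.  This restores
the false-flag rate to its nominal level while leaving gross outliers (which
sit far beyond either threshold) flagged.  `cutoff = "chisq"` recovers the
asymptotic rule for comparison.

## The synthetic-data generator

Raw multi-subject team-training EEG is rarely shareable, so the generator is
a first-class module producing sessions with known ground truth; every
downstream stage is tested against it.

* **Baseline signal.**  Per channel, spectrally synthesized pink ($1/f$)
  noise, globally scaled so the mean channel SD is 10 µV -- a realistic
  magnitude for band-passed scalp EEG.
* **Coherence injection.**  A *component* specifies a band, a target
  magnitude-squared coherence $C \in [0, 1)$, a region (or `"all"`) and a
  pair set.  Within the band, participating subjects carry
  $w\,S + (1-w)\,D_s$ (shared source $S$, subject-specific $D_s$, equal
  per-bin variance), giving cross-spectral correlation
  $w^2/(w^2 + (1-w)^2)$ and hence magnitude-squared coherence equal to its
  square; $w$ is solved from $\sqrt{C}$ so the measured coherence hits the
  target.  Because the pipeline rereferences to the common average, region
  means obey $5\,\mathrm{ant} + 3\,\mathrm{cen} + 7\,\mathrm{pos} = 0$ for
  every source, so single-region content cannot exist in isolation.
  Region-targeted components therefore use zero-sum spatial patterns: the
  target region carries the mixture at weight 1, a balancing region carries
  the counter-phase part, and independent masking noise routed through a
  second zero-sum pattern dilutes the balancing region's coherent leak to
  about 1/20 in amplitude while leaving the target region untouched.  This
  construction is exactly controllable but deliberately non-physiological:
  channels within a subject are perfectly correlated in-band, and the mask
  region carries elevated in-band power.
* **Artifacts.**  Poisson-planted per channel (rate per minute), 80% short
  spikes (3--5 samples) and 20% half-second square drifts, at
  `artifact_amplitude` (> 6, default 10) times the channel's robust SD; the
  touched epoch indices are recorded as ground truth.  Spikes are at least
  3 samples wide so the 1--40 Hz filter cannot attenuate them below the 6x
  threshold.  Zero-phase filter ringing can spill into the directly
  adjacent epoch, so "clean" in false-flag accounting means at least one
  epoch away from any planted artifact.
* **Lags.**  Each subject's device samples a common underlying signal with
  its own start offset; the audio envelope (smoothed rectified noise plus
  5% measurement noise) carries the same offset, which is what the
  cross-correlation stage recovers.
* **Scores.**  Two-way random-effects generator (subject, rater, error
  variance components) mapped linearly into each (profession, topic) range
  with ±3 SD spanning the range, then clipped; the implied single-rater ICC
  is $\sigma^2_s / (\sigma^2_s + \sigma^2_r + \sigma^2_e)$.  Scores are
  continuous rather than integer Likert sums -- a simplification that keeps
  the realized ICC exactly controllable.
* **Study link.**  Across sessions the designated component's target
  coherence is drawn uniformly from `coh_range`, and every profession's
  latent subject effect in a session is shifted by
  `link_slope` x (that session's coherence, centred), planting a monotone
  group-level association of known sign (or a null when the slope is 0).

What passing tests on these data do *not* show: robustness to volume
conduction, muscle/ocular artifacts with realistic spectra, non-stationary
coherence, integer-valued ratings, or imperfect event annotation.  The
generator is a correctness harness, not a physiological simulator.

## Numerical choices

* Coherence is clipped at $1 - 10^{-10}$ before the log so self-coherence
  stays finite.
* Band endpoints are inclusive (alpha = bins 8, 9, 10, 11, 12).
* The permutation engine precomputes per-epoch spectra once and recomputes
  only the cross-spectrum per draw (auto-spectra are permutation
  invariant); both analysis bands share one set of permutations.
* A permutation null with zero variance, coherence at $K = 1$, fewer than
  100 permutations, a flat channel, or a rank-deficient MCD cloud each
  raise an informative error; short communications and incomplete groups
  are *undefined markers*, not errors.
* Seeding: one master seed; per-communication substreams are derived
  deterministically from (session, communication, pair), so reruns are
  bit-identical and sessions are independent of each other's order.
* Epoch grids are fixed 1-s, 0-based half-open in sample units; trailing
  partial epochs are dropped.

## Problem sizes

The test-suite simulations use sessions of 45--120 s with one
communication window, 120--400 permutations, and studies of 15 sessions
with 20 seeded replicates per arm for the end-to-end recovery and null
checks; the acceptance script uses a 12-session study at 300 permutations
and 150 independent communications for null calibration.  These sizes keep
the full suite to minutes on one CPU while leaving every estimate's
sampling error well inside the tested tolerances.  The defaults users see
(`n_perm = 1000`, 30-session studies) are larger.

## Known limitations

* The amplitude-only artifact rule cannot remove stereotyped physiological
  artifacts (blinks, EMG) the way component-based cleaning does.
* Whether TI should be computed on region-averaged series or averaged over
  within-region channel pairs is not settled; the package averages first.
* The Monte-Carlo MCD cutoff calibrates the false-flag rate under a
  bivariate-normal null; heavy-tailed clean data would still be trimmed
  more often than nominal.
* Individual-level grids pool all professions into one 36-case grid;
  per-profession grids would need their own correction family.
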