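---
title: "Simulating and analysing a multifeature oddball ERP study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing a multifeature oddball ERP study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Children's cortical discrimination of speech-sound changes can be indexed
without a behavioural task by event-related potentials (ERPs) recorded in a
passive oddball paradigm. In a multifeature variant, a frequent standard
pseudoword (/tatata/) strictly alternates with rare deviants whose middle
syllable changes in one of five dimensions — an inserted gap, vowel
duration, vowel identity, fundamental frequency (F0), or intensity — so that
every other stimulus probes change detection while the standard keeps
re-establishing the reference memory trace. Difference waveforms
(deviant ERP minus standard ERP) over a frontocentral region of interest
(ROI: F3, Fz, F4, C3, Cz, C4) carry a characteristic sequence of deflections
in children: a positive mismatch response (pMMR), the mismatch negativity
(MMN), the P3a attention-orienting response, and the late differentiating
negativity (LDN).

`mferp` implements this design end to end for a longitudinal two-group
cohort — cochlear-implanted (CI) and normally hearing (NH) children, each
split into preschoolers and schoolchildren and measured twice (T1, T2) —
with a synthetic EEG generator whose ground truth is known, so every
analysis stage can be validated by parameter recovery.

## The stimulus sequence

The standard lasts 480 ms (three ~120 ms syllables separated by 60 ms
silences, middle-syllable F0 169 Hz); deviants change the middle syllable
at 198 ms after stimulus onset. The seven deviant conditions collapse onto
five types: gap (580 ms total), vowel duration (560 ms), vowel identity
(formants 560/1240/2750 Hz), F0 +15% (194 Hz) and +50% (254 Hz), and
intensity −6 and +6 dB. A run consists of 2,000 events at a 900 ms stimulus
onset asynchrony — 1,000 standards alternating with 200 deviants per type
(100 per magnitude for the split types), i.e. 30 minutes.

`generate_sequence()` shuffles the deviant multiset and then repairs it:
every third-or-later consecutive repetition of a deviant *type* is swapped
with a deviant at a uniformly random position, and the sequence is rescanned
until no run exceeds two (a scan cap guards termination; infeasible designs
are rejected up front by a counting argument). The constraint is enforced at
the five-type level, so the two magnitudes of a split type may alternate
freely. The sequence begins with a standard and no run-in is excluded from
averaging. All randomness is seeded and the seed is recorded on the output.

## The synthetic cohort

Each ERP component is modelled as a Gaussian deflection
$a\,e^{-(t-\ell)^2/2\sigma^2}$ with $\sigma = \mathrm{fwhm}/2.3548$;
defaults are fwhm 80 ms for pMMR, MMN and P3a and 120 ms for the broader
LDN, chosen so components at the published latency spacings remain
separable. Per (clinical group × age group × timepoint × deviant) cell the
generator takes a target peak latency and an amplitude mean and SD from the
published group tables (`default_response_norms()`); a subject's true
amplitude is drawn once per subject and timepoint from that cell's normal
distribution (so CI cells with positive-going "MMN" means produce
polarity-flipped responses, as observed), while latencies are fixed at the
cell value — the analysis quantifies amplitudes at group-level latencies, and
fixed cell latencies keep each cell's pMMR < MMN < P3a < LDN ordering intact.

Every trial carries a fixed small P1–N2-like standard-evoked base so that
difference waves isolate the injected components. The montage is the six
ROI electrodes (unit weight) plus two mastoids (0.2) and a nose reference
channel (0); a full 64-channel simulation would add nothing because the
analysis uses the ROI average. Background activity is white noise
(SD 8 µV), 1/f noise (SD 8 µV, spectrum shaped by $1/\sqrt{f}$) and a 10 Hz
sinusoid (3 µV) with an independent random phase per 900 ms trial segment.
A configurable fraction of trials (default 8%) receives a frontally
weighted Gaussian artifact pulse of 200–500 µV, which exercises both
rejection stages; the rate is capped at 0.27 so the 73% retention floor
remains attainable by design. Injected activity is aligned to the sample
nearest each event onset, which makes the noiseless median ERP reproduce
the injected signal *exactly* — the basis of the identity tests.

Singing-questionnaire scores (parental and child's own) are drawn uniformly
on the questionnaire scale at each timepoint, independent of age group, and
combined by averaging the two responses (`singing_score()`). The scale is a
parameter (`singing_scale`, default 0–5) because published descriptions of
the instrument give both 0–5 and 1–5.

What the generator does *not* emulate: realistic scalp topographies,
implant-specific electrical artifact spectra, ocular artifacts with their
own topography, latency jitter between subjects of a cell, or
trial-to-trial amplitude variability. Passing recovery tests therefore
demonstrate that the analysis machinery is correct under the stated model,
not that it would be unbiased on arbitrary real recordings.

## Preprocessing

The chain follows the study's stated order, each stage logged with its
parameters: 0.5 Hz zero-phase Butterworth high-pass; anti-aliased
downsampling 512 → 256 Hz (zero-phase low-pass at 0.45 × the target rate,
then integer decimation); re-referencing to the nose; an optional
`clean_hook` where externally computed artifact correction (e.g. ICA) can
be injected — its use is recorded in the audit log; epoching into
[−100, 700) ms windows (`floor(0.8 s × 256 Hz)` = 204 samples, 0-based
indexing, time 0 at the sample nearest stimulus onset); adaptive rejection,
which scans thresholds upward from ±300 to ±400 µV in 10 µV steps and
applies the smallest one retaining at least 85% of all epochs (if none
qualifies the maximum is applied and the subject flagged); final rejection
at ±150 µV; and baseline correction over [−50, 0) ms. Rejected trials are
never deleted — only the retention mask and reason codes change. A
condition retaining fewer than 73% of its presented epochs is flagged, and
a subject with any flagged deviant condition is marked for exclusion; the
floor is read as a fraction of presented trials per condition.

Filters are realised in the frequency domain for long recordings
(reflection padding, squared Butterworth magnitude response — the response
a forward–backward pass realises in time) and with `signal::filtfilt` for
short ERP-level waveforms. Passband and stopband behaviour is asserted
against analytic sinusoid gains in the test suite.

## ERP extraction and component quantification

ERPs use the per-sample *median* over accepted trials (even counts average
the two central order statistics), computed independently per channel and
sample; the median resists occasional extreme trials, e.g. residual implant
artifacts, with the usual 50% breakdown point (both properties are tested).
The ROI waveform is the unweighted six-electrode mean, taken after the
per-channel median — the ordering is an interpretation, flagged as such.
Difference waves subtract the standard ERP pointwise and a 20 Hz zero-phase
low-pass is applied at quantification time, to ERP-level waveforms only.

Detection follows the ordered window scheme on the low-passed ROI wave,
with "largest deflection" made reproducible as the largest-magnitude local
extremum of matching polarity and ties breaking to the earliest sample:

* **MMN** — most negative local extremum in 300–450 ms from stimulus onset
  (102–252 ms after the 198 ms change onset);
* **pMMR** — most positive local extremum in [250 ms, MMN peak); if none on
  the ROI, the six electrodes are searched in the fixed order Cz, Fz, F3,
  C3, F4, C4 (`fallback_electrode` flag); if still none, the latency is
  pinned to the 250 ms lower bound (52 ms post-change,
  `lower_bound_latency` flag);
* **P3a** — most positive local extremum in (MMN peak, 525 ms], same
  fallbacks, window extremum with `window_edge` flag as last resort;
* **LDN** — most negative local extremum from the P3a peak (or the MMN peak
  when the P3a was only a flagged window extremum) to 650 ms
  (452 ms post-change).

Amplitudes are means over a 50 ms window centred at the peak. For an
isolated Gaussian of fwhm 80 ms this windowed mean recovers
$\sigma\sqrt{2\pi}/(2h)\,(2\Phi(h/\sigma)-1) \approx 0.92$ of the true peak
(`window_attenuation()`); overlapping neighbours additionally bleed into
each other's windows, so recovery tests compare against the windowed mean
of the injected *composite*, which is exact. Latencies are reported in both
reference frames with `change latency = peak latency − 198 ms` enforced
exactly. The windows are not shifted for the vowel-duration deviant even
though its change becomes apparent only around 280 ms, matching the
published quantification. Two quantification modes exist: the group mode
(default, mirroring the study) first detects peaks on each cell's
grand-average difference wave and then measures every subject at those
group latencies; the individual mode detects per subject and is labelled as
such in outputs.

Two numerical caveats are documented rather than hidden. First, the
0.5 Hz high-pass, applied to a 1.1 Hz evoked train, deforms the slow
content of the ERP by up to a few tenths of a µV — so extracted amplitudes
differ from the raw injected templates by up to ~15% on the wide LDN — and
the deformation varies between trials because each trial's filter
neighbourhood (its surrounding deviants) differs. Second, a 900 ms onset
asynchrony is not an integer number of 256 Hz samples, so epochs align to
the grid with up to half a native sample of scatter. The pipeline-identity
tests therefore compare against the injected signal passed through the same
linear filter chain on a single-trial, single-channel path — isolating the
nonlinear machinery (median, rejection, ROI averaging, differencing,
detection, windowing) that the tests are about — and assert agreement to
documented bounds that cover both effects: 0.5 µV sample-wise on the
difference wave (worst case measured ≈0.43 µV across the seven deviants at
the published amplitude scale) and 0.3 µV on the 50 ms windowed amplitudes,
where the two deformations partly average out. The exact noiseless identity
(median ERP = injected signal, sample for sample) is asserted on the
unfiltered path, and the raw-template window attenuation separately at the
quantification level.

## Statistics

Per-cell amplitudes are tested against zero with two-sided one-sample
t-tests. A (deviant, component) response enters the clinical-group mixed
models iff it is significant (α = 0.05) *with the expected polarity* in at
least one CI and at least one NH age-group × timepoint cell; the singing
analysis pools the CI group (using age-group latencies) and requires
significance at T1 or T2. Polarity gating is configurable
(`require_polarity`), since opposite-polarity significant responses are
tracked but excluded from their nominal component's comparisons.

Group models fit `amplitude ~ clinical_group * age_group * timepoint +
(1 | subject)` by REML with Satterthwaite degrees of freedom, then prune in
stages: a non-significant three-way interaction is removed and the model
refitted; afterwards all non-significant two-way interactions are removed
and the model refitted once more. Main effects are never pruned, nothing is
pruned while the three-way term is significant, and the pruning history is
reported. With all factors at two levels, each interaction coefficient's
t-test equals the type-III F-test of that term, so coefficient p-values
drive the pruning. Factors are coded with reference levels NH,
schoolchildren and T2, so estimates read CI−NH, preschooler−schoolchild and
T1−T2 — the sign conventions of the published estimate table. Missing
timepoints are retained under likelihood-based estimation rather than
listwise deletion. Singular fits are reported and flagged unstable rather
than suppressed. Significant two-way interactions get simple-effect
post-hoc contrasts through estimated marginal means with Bonferroni
correction over that interaction's four-contrast family. Singing models fit
`amplitude ~ singing * time + (1 | subject)` on the CI rows, prune a
non-significant interaction, and refuse to fit when the covariate has no
variance; correlations among the two singing scores and age decide whether
age would enter as a covariate (it does not when they are non-significant).

Calibration uses the amplitude-level generator
(`simulate_amplitude_table()`), which skips EEG synthesis: under the null
the full-factorial fixed effects reject at the nominal 5%, and 95%
confidence intervals from the full model cover injected effects — a CI−NH
contrast of 1.888 µV and a parental-singing × time slope of −1.090 µV per
scale unit, the magnitudes the group analyses report — at nominal coverage.
Coverage is evaluated on the *full* (pre-pruning) model because pruning is
a selection step: conditional coverage after selection is a property of the
selection rule, not of the interval estimator. Between-subject and residual
SDs default to 1.4 µV each (total SD ≈ 2 µV, the scale of the published
cell SDs).

## Problem sizes

The test and acceptance suites choose sizes that keep single-core runs
short while leaving every property well-powered: sequencing properties over
100 seeds at the full 2,000-event design; detector ordering over 1,000
synthetic difference waves at the default difference-wave SNR (residual SD
0.45 µV on the ROI, the level the default cohort noise leaves after median
ERPs and ROI averaging); end-to-end EEG runs with 2 subjects per cell and
reduced event counts; and mixed-model calibration over 500 replicates at
the study's cell sizes (11/11/10/11). The analysis drivers under
`analysis/` run the full cohort with 500-event recordings for the same
reason; all sizes are parameters, and the full-length design is exercised
wherever it is cheap (sequence generation, single-subject recovery).

## Known limitations

* The Gaussian component model and fixed cell latencies are idealisations;
  real pediatric ERPs show latency jitter and non-Gaussian morphology.
* ICA-based artifact removal and bad-channel interpolation are delegated to
  the `clean_hook`; the built-in artifact model is a single amplitude
  mechanism designed to exercise rejection, not a physiological model.
* The published fixed-effect estimates derive from sensitive raw data that
  are not available; they serve here as simulation parameters and
  output-format targets, not as reproduction targets.
* The "clearly peaking electrode" rule of the original quantification is
  visual; the deterministic fallback chain is a surrogate, not a claim
  about the original procedure.
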