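---
title: "Methods: gap-ASSR ITPC and ERP analysis of simulated mouse EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gap-ASSR ITPC and ERP analysis of simulated mouse EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapassr)
```

`gapassr` implements a complete analysis chain for a two-channel mouse EEG
experiment on auditory temporal processing: a 40 Hz gap-in-noise auditory
steady-state response (gap-ASSR) paradigm quantified by inter-trial phase
clustering (ITPC), and an auditory event-related potential (ERP) paradigm
quantified by P1/N1/P2 peak amplitudes and latencies, followed by the
group-level statistical battery. Because no raw recordings ship with the
package, a synthetic-EEG generator with documented cohort presets stands in
for the animal data; it is a first-class, tested component, and this
vignette records what it emulates, what it deliberately does not, and every
numerical choice a maintainer might want to revisit.

## The stimuli

**ERP session.** Narrowband noise bursts (6–12 kHz, 100 ms, 5 ms
cosine-squared rise/fall ramps) are presented 120 times at a 0.25 Hz
repetition rate, i.e. one burst every 4 s. Waveforms are peak-normalized
and unitless; the nominal 75 dB SPL level is metadata only — no acoustic
calibration is in scope. Band-limiting is a brickwall DFT mask, which
keeps at least 90 % of spectral power inside the passband after ramping
(verified against a periodogram oracle in the tests).

**Gap-ASSR session.** The stimulus alternates 250 ms segments of plain
noise and gap-interrupted noise. Within a gapped segment, gaps recur every
25 ms — a 40 Hz presentation rate — and each segment draws one *parametric
pair* uniformly at random: gap width ∈ {2, 4, 6, 8, 10, 12} ms ×
modulation depth ∈ {75, 100} %. Depth is applied as a pure amplitude
scale with rectangular edges: 100 % depth produces bit-exact silence,
75 % scales in-gap samples by exactly 0.25. Sessions extend until every
pair has at least the requested trial count (default 101, so every pair
exceeds 100 trials).

Gap placement inside a segment was genuinely open: given the 25 ms period
and the 250 ms segment, we place the first gap onset 25 ms after segment
start, giving nine gaps per segment — a tenth onset would land exactly on
the segment boundary with no samples inside it. The 40 Hz periodicity is
preserved because the next 25 ms step coincides with the start of the
following noise segment. Whether noise-only segments share their noise
token with the neighbouring gapped segment was also open; they are
independent draws here.

## The synthetic EEG generator

Each channel (auditory cortex AC, frontal cortex FC) is a sum of three
parts:

1. **Background noise**: `1/f^α` noise synthesized by spectral shaping of
   Gaussian white noise, α = 1 and RMS = 15 µV by default — the canonical
   aperiodic slope and an amplitude typical of awake rodent epidural EEG.
2. **ERP components**: at every stimulus onset, Gaussian-windowed
   monophasic deflections (P1 +, N1 −, P2 +) with per-component latency,
   amplitude and width (`width_ms` is the Gaussian SD). Per-trial
   amplitude jitter is multiplicative log-normal (SD 0.1 by default);
   latency jitter is off. The baseline adult AC set is P1 +12 µV @ 25 ms
   (SD 5 ms), N1 −18 µV @ 60 ms (SD 10 ms), P2 +9 µV @ 150 ms (SD 25 ms),
   in the range of published mouse epidural ERPs.
3. **Gap-evoked 40 Hz bursts**: one sinusoidal burst spanning each gapped
   segment, amplitude 4 µV, with a common phase offset per segment drawn
   von Mises(0, κ). Jitter therefore operates at the segment level — the
   same level at which ITPC defines a "trial". κ is configured per
   parametric pair; the asymptotic ITPC of such trials is the mean
   resultant length `A(κ) = I₁(κ)/I₀(κ)`, which the package exposes as
   `kappa_to_expected_itpc()` and uses as a closed-form oracle in tests.

The generator's real-data gaps worth keeping in mind: no volume
conduction or channel correlation, no latency jitter or habituation, no
movement or chewing artifacts, noise is stationary, and the 40 Hz response
is a pure sinusoid rather than a superposition of transient onset
responses. Passing tests therefore demonstrate that the *analysis* is
correct and well calibrated, not that it is robust to every pathology of
awake-animal EEG; the artifact-screening stage exists but, like the
emulated study, flags rather than deletes, and clean synthetic data yield
zero flags.

## Cohort presets

`cohort_presets()` encodes one parameter set per genotype × sex × age cell
(WT/KO × M/F × p21/p30/p60). They are a *qualitative emulation* — numbers
chosen once to reproduce the direction of the reported group differences,
never fitted to data:

* Target mean ITPC grows with gap width as
  `0.12 + 0.45 (gap/12)^0.7`, is 15 % lower at 75 % depth, scales with age
  (0.70, 0.85, 1.00 at p21/p30/p60), and is 20 % lower in FC than AC.
  Targets convert to κ through the inverse of `A(κ)`.
* Phase-locking deficit cells multiply the FC target by 0.45: KO females
  at p21 only; KO males at p21 and p30 (the slower male maturation).
  AC is identical across genotypes; WT males and females are identical
  everywhere.
* ERP amplitudes scale with age by (0.70, 0.85, 1.00) in WT and (0.80,
  1.10, 1.50) in KO, so the KO−WT gap grows with age and peaks at p60;
  adult KO females get a further ×1.25 on N1 and P2 relative to KO males.
  FC amplitudes are 90 % of AC.

Per-trial response-amplitude variability in the real data is unknown; the
log-normal SD of 0.1 is a convention, flagged as such.

Female cell sizes follow the emulated study (WT 11/9/8, KO 8/9/8 at
p21/p30/p60). Male cell sizes live in a companion dataset and are not
restated; the default is 9 per cell.

## Preprocessing

Recordings are simulated at 4096 Hz by default (the acquisition hardware
rate is irrelevant above the Nyquist of the analysed band) and
down-sampled to the 1024 Hz analysis rate through a zero-phase FFT
low-pass — unity gain to 0.4 × the target rate, raised-cosine roll-off to
zero at the target Nyquist — so 40 Hz phase estimates suffer no filter
delay. Epochs are cut on TTL-style event times; ERP epochs span −250 to
+750 ms around sound onset (the emulated study fixes only the 250 ms
baseline; 750 ms covers P2 at all ages and is recorded in the output
metadata), are baseline-corrected by subtracting each trial's mean over
−250–0 ms, then linearly detrended, in that order. Gap-ASSR epochs span
−100 to +350 ms around gapped-segment onset: the segment itself plus
100 ms of context per side for wavelet edge handling.

## ITPC

The time–frequency transform is a convolution with unit-energy complex
Morlet wavelets. The "dynamic" cycle rule rises linearly from 3 cycles at
10 Hz to 8 at 100 Hz, trading temporal precision for spectral precision as
frequency grows; the default grid is 31 log-spaced frequencies over
10–100 Hz with the nearest point snapped to exactly 40 Hz. Wavelets are
truncated at ±4 SD; a time–frequency point is valid only if it is farther
from either epoch edge than both the 100 ms edge pad and the wavelet
half-support, so the transform errors out only when an epoch cannot hold
the longest wavelet at all.

ITPC at a point is the modulus of the mean unit phase vector across the N
trials of one parametric pair, `|mean_k exp(iφ_k)|` ∈ [0, 1]. It is
amplitude-invariant and rotation-invariant. The summary statistic is the
40 Hz row averaged over 50–250 ms after segment onset — the segment minus
its onset transient; the emulated study says only that 40 Hz values were
averaged, so the window is a package choice recorded in outputs. The
small-sample bias of plain ITPC (uniform phases give ≈ √π/(2√N), not 0)
is reported via the trial count and *not* corrected, matching the plain
statistic; a Rayleigh-based bias-corrected variant is available but off by
default. Below 100 trials per pair the summary warns.

## ERP peaks

Grand averages are pointwise means over trials (flagged trials excluded
only in strict mode). P1 is the maximum in 10–50 ms, N1 the minimum in
30–100 ms, P2 the maximum in 80–250 ms — windows are conventions (the
emulated study does not state its procedure), configuration-exposed and
recorded in outputs. Amplitudes are baseline-to-peak (not peak-to-peak),
since single-wave amplitudes are what the study reports; latency is the
extremum's time with ties broken toward the earlier sample, and when
reconfigured windows overlap, each search starts strictly after the
previous peak so P1 < N1 < P2 always holds.

## Statistics

The battery is implemented from matrix algebra rather than wrapped around
`aov()`, and is cross-checked in the tests against `car::Anova`,
`stats::anova.mlm`, `stats::mauchly.test` and `TukeyHSD`:

* **Two-way factorial ANOVA** (ERP measures): Type III sums of squares
  with sum-to-zero contrasts, chosen because the cohort cells are
  unbalanced (n = 8–11).
* **Repeated-measures ANOVA** (ITPC): classical split-plot strata with
  gap duration (6 levels) within subject and genotype × age (or sex)
  between. Sphericity of the within-level differences is tested with
  Mauchly's W (two-term asymptotic chi-square p); the Greenhouse–Geisser
  ε̂ (bounded by 1/(k−1) and 1) multiplies the within degrees of freedom.
  The default policy applies the correction only when Mauchly rejects at
  0.05 — "if necessary" — with an always/never override. One ε̂
  implementation serves both the two- and three-way variants; the
  distinction drawn in the emulated study's wording is not operational.
  Note the standard corrected p `pf(F, εdf₁, εdf₂)` exceeds the
  uncorrected p only in the rejection-relevant regime (F ≳ 1); for F < 1
  it is smaller, a property of the standard formula itself.
* **Post hocs**: Tukey (studentized range, Tukey–Kramer standard errors
  for unbalanced cells), Bonferroni `min(1, mp)` and Sidak `1−(1−p)^m`.
  Mirroring the emulated analyses, ERP contrasts use Tukey/Bonferroni and
  gap-ASSR contrasts use Sidak; the mapping is an argument of
  `run_paper_contrasts()`. Age-wise ITPC contrasts are computed on
  gap-collapsed per-subject means and tested against an age-local error
  variance: ITPC estimation noise shrinks as ITPC grows, so a pooled error
  term would be anti-conservative at the well-locked ages. A contrast is
  reported significant only when the omnibus ANOVA shows a significant
  effect involving that factor (protected testing).
* **Diagnostics**: Shapiro–Wilk, sample skewness and excess kurtosis
  against the ±2 screening rule, and sorted quantile–quantile pairs.
  Cortical regions and modulation depths are always analysed separately.

## Problem sizes and determinism

Every stochastic function takes a seed and leaves the caller's RNG stream
untouched; cohorts derive per-subject sub-seeds deterministically from one
master seed, and `run_all()` reruns byte-identically under a fixed
configuration. The test-suite simulations are scaled to desk size as
package choices: the directional pattern-recovery study
(`pattern_recovery_study()`) uses 20 replicate cohorts at the study's
female cell sizes plus 9 WT males per age, 60 trials per parametric pair
(scaled from the paradigm's >100, but kept high enough that the ITPC
small-sample bias floor, ≈ √π/(2√N), stays below the weakly locked
conditions it would otherwise mask), and simulates natively at the
1024 Hz analysis rate (the down-sampling path is exercised separately);
type-I calibration uses 2000 null
replicates per ANOVA variant; generator recovery checks use 1000 segments
or 200 trials as stated in each test. The pattern study scores direction
and significance, never specific F or p values, and the preset effect
sizes above were fixed before any recovery study was run.

## Known limitations

* The generator's two channels are independent; cross-regional coupling
  analyses would need a richer forward model.
* ITPC is the only phase statistic; evoked/total power and connectivity
  are out of scope, as is any circular inference beyond the mean
  resultant length.
* EDF/HDF5/WAV persistence is not provided; schedules, tables and
  manifests round-trip through JSON/TSV/CSV instead.
* Absolute sound level is nominal; no speaker transfer function or
  calibration is modelled.
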