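---
title: "Vocoded discourse recall: models, generator calibration, and design choices"
author: "vocrecall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vocoded discourse recall: models, generator calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocrecall)
```

This vignette documents the science inside `vocrecall`: the signal chain of
the noise-band vocoder, the counterbalanced design, the propositional
scoring convention, the generative model behind the synthetic data, and the
mixed-effects analysis — together with the numerical and design decisions
that were genuinely open, and what the package's tests do and do not
establish about real data.

## 1. The vocoder

Noise-band vocoding replaces the spectro-temporal fine structure of speech
inside each frequency band with band-limited noise carrying that band's
temporal envelope, approximating the percept delivered by a cochlear
implant. The chain, per channel:

1. **Analysis filter.** The 80–8000 Hz range is divided into
   `n_channels` bands with geometrically spaced edges
   $f_k = f_{lo}\,(f_{hi}/f_{lo})^{k/N}$, matching the cochlea's roughly
   logarithmic frequency map. Each band is isolated with a single-pass
   (causal) Butterworth band-pass of order 3, i.e. an asymptotic skirt of
   $6 \times 3 = 18$ dB/octave per side. Single-pass filtering is
   deliberate: zero-phase two-pass filtering would double the effective
   rolloff to 36 dB/octave and no longer match an 18 dB/octave
   description.
2. **Envelope.** The envelope detector is half-wave rectification followed
   by a single-pass Butterworth low-pass at 300 Hz (order 2 by default).
   Rectifier type and low-pass order are not pinned down by convention in
   the vocoding literature beyond "envelope smoothing", so both are
   configurable (`vocoder_config()`); half-wave + low-pass is the standard
   noise-band choice. Residual negative excursions of the causal low-pass
   are clamped at zero. Note that a 300 Hz cutoff leaves visible carrier
   ripple on low-frequency tones (about 10% coefficient of variation at
   1 kHz) — that is a property of the published design, not an artifact.
3. **Carrier and resynthesis.** Each envelope modulates white Gaussian
   noise filtered by *the same* band-pass that isolated the band. Each
   band uses an independent noise stream seeded from
   (`rng_seed`, band index), so output is bit-reproducible. By default
   each modulated band is rescaled to the RMS of its analysis band before
   summation (preserving the input's spectral profile — whether the
   original experiments did this per band is not documented, so
   `per_band_rms_match` can be turned off), and the summed output is
   rescaled to the input RMS, the documented global constraint.

**What confinement to expect.** With contiguous order-3 bands and a 300 Hz
envelope bandwidth, a channel's synthesized energy does *not* stay inside
the nominal channel edges: modulation sidebands spread the carrier by up
to ±300 Hz and the gentle skirts overlap neighboring bands. For
channel-confined input roughly 70–75% of output energy falls inside the
nominal channel and >95% inside the channel plus its two neighbors; the
tests assert exactly that neighborhood-confinement behavior. Over the full
80–8000 Hz analysis range, ≥95% of output energy is retained.

**Measuring the rolloff.** The dB-per-octave figure of a digital
(bilinear-transformed) filter cannot be read off its upper skirt at
44.1 kHz — frequency warping near Nyquist steepens it without bound.
`measure_rolloff()` therefore evaluates the analytic Butterworth band-pass
prototype magnitude
$|H|^2 = 1/(1 + ((f^2-f_0^2)/(Bf))^{2n})$
and walks outward from one octave beyond the upper band edge until the
per-octave slope stabilizes (change < 0.25 dB/octave). For the default
mid-channel design this converges at 18.10 dB/octave (order 3), 6.05
(order 1), 24.1 (order 4).

Nyquist handling: if the upper analysis edge reaches 95% of Nyquist it is
capped there with a warning (filter stability); steady-state measurements
discard a 50 ms settling transient.

## 2. Segmentation and the counterbalanced design

Self-paced listening presents a passage segment by segment, the listener
triggering each segment by keypress. Segment boundaries ("major clause and
sentence boundaries") are linguistic annotations supplied as input;
`suggest_boundaries()` is only an orthographic heuristic for building test
fixtures and is labeled as such. Boundaries are 0-based ("interrupt before
word *k*"), and segmentation is verified lossless.

The design assigns each participant all 8 passages: 2 per
format × clarity cell, one of each predictability class per cell.
`build_design()` uses a fixed 8-row rotation matrix — high-predictability
passage $i$ goes to cell $(i+r) \bmod 4$ in row $r$, low-predictability
passage $i$ to cell $(i+r+\lfloor r/4 \rfloor) \bmod 4$ — so that across
any block of 8 rows every passage occupies every cell exactly twice. The
seed permutes only which participant receives which row, which cannot
disturb the balance; the exact rotation scheme used in the original
procedure is not documented, and any scheme with the equal-exposure
property is equivalent for analysis.

The default synthetic passage set (`default_passages()`) is a stand-in for
the eight copyrighted experimental passages: it reproduces the class
structure (4 high / 4 low, mean cloze 0.67 / 0.51) and approximately the
segment counts (means 10.50 and 10.75; the printed low-predictability mean
of 10.62 is not attainable as a mean of four integers).

## 3. Propositional scoring

Propositions are predicate–argument units; since propositions can take
other propositions as arguments, a passage's bank is a DAG. Levels follow
the three-way rule: flagged roots are **main ideas**; a non-root that takes
any main proposition as an argument is **mid-level** (referencing any main
takes precedence over whatever else it references); everything else is a
**detail**. Scoring is binary with no half credit: a proposition is
recalled iff its predicate lemma and all atomic-argument lemmas occur in
the lemmatized transcript, each directly or via the bank's explicit
synonym list. Matching is bag-of-lemmas over the whole transcript — free
recall is scored for content, not order.

Two deliberate simplifications: (1) the lemmatizer is a small deterministic
suffix-stripper (plural *-s/-es/-ies*, verbal *-ed/-ing* with consonant
undoubling). It does not restore dropped final *e* ("making" → "mak");
irregular forms should be covered by synonym entries, and the lemmatizer is
swappable. (2) "Close synonyms" are an explicit per-bank lexicon. Human
scorers' synonym judgment is not reproducible algorithmically, and
proposition identification itself (a CPIDR-style analysis) is authored
input, not something this package infers from text.

## 4. The synthetic-data generator

Because no raw data from such studies are deposited, every downstream
stage is exercised against a generator whose truth is known exactly.

**Linear-probability construction.** Effects are reported in percentage
points, so the generator is linear on the percentage scale: the expected
recall percentage for a design cell is

$$\mu = b + c(\ell) + d_p[\text{high}] + d_f[\text{self-paced}]
      + d_c[\text{clear}] \pm \kappa\, g(\ell)$$

with level contribution $c = (0,\, d_{md},\, d_{md}+d_{mm})$ for
detail/mid/main, $g = c - \bar c$, $\kappa = (1-a)/(1+a)$ for attenuation
$a$, sign + for high and − for low predictability. Two properties follow
by construction and are verified symbolically in the tests:

* every **marginal contrast** (unweighted over the other factors) equals
  its calibration delta exactly — the printed effect sizes are generator
  parameters, not emergent quantities;
* the ratio of the expected hierarchy slope, low over high predictability,
  is exactly $a$ (the interaction's attenuation parameterization: only its
  existence and direction are reported, not its magnitude).

The double-centering of the interaction term is essential: attenuating the
level contribution only under low predictability would leak the
interaction into both the hierarchy and the predictability marginals
(e.g. the main−mid marginal would become $d_{mm}(1+a)/2$), breaking the
identity above. At $a = 1$ the term vanishes and the surface is purely
additive.

**Stochastic structure.** On top of the fixed surface: a participant
intercept $u_i$ (SD 8 pp) built from standardized R-span (loading 0.5),
the pause-tendency latent (loading 0.6) and an independent residual; item
intercepts (SD 5 pp) and item-by-level slopes (SD 2 pp); an optional
Gaussian residual (SD 0 by default — trial-level noise comes from the
binomial); and for self-paced trials a per-passage latent shared with the
pause generator, entering recall at 0.3 × SD~participant~ (2.4 pp) per
latent SD. Counts are then
$\mathrm{Binomial}(n_\ell,\ \mu/100)$ with $n_\ell$ = 10/15/20 propositions
for main/mid/detail. A feasibility guard rejects calibrations whose fixed
surface leaves [0, 100]; random-effect excursions are clamped at the
binomial step only.

None of base (40 pp), attenuation (0.55), the SDs, the loadings or
$n_\ell$ are reported quantities; they are documented, configurable
defaults chosen to be realistic for discourse recall at this scale.

**Participants.** R-span is a rounded normal (9.42, 2.98) censored to
[0, 15]; censoring rather than rejection sampling, because rejection at
the 15-point ceiling would shift the mean to ≈9.21 while censoring keeps
it at ≈9.39, matching the intended population mean. Vocabulary
(13.0, 1.8, censored to [0, 20]) and PTA (6.88, 4.12 dB HL) likewise.

**Pauses.** Inter-segment pauses are lognormal, moment-matched
analytically so the marginal mean and SD are exactly 2.43 s and 2.71 s
(the lognormal's positivity and right skew fit SD ≈ mean). The total
log-scale variance is split into between-participant (sdlog 0.35 — the
`pause_tendency` multiplier, unit median), between-passage-within-
participant (sdlog 0.25, the latent shared with recall) and within-passage
remainder; the split is a modeling choice (the marginal distribution is
identical for any split) sized so that between-person pause tendencies
vary by roughly a factor of 1.4. Clarity does not enter the pause model at
all — pause durations are insensitive to stimulus clarity in this
paradigm.

## 5. The analysis stage

The response is the recall percentage per
participant × passage × level cell (the scale on which results are
reported and plotted), not a trial-level binomial GLMM. Models are fit
with `lme4` by **maximum likelihood** — not REML — because all inference
is by likelihood-ratio tests between nested fixed-effect structures, for
which REML likelihoods are not comparable. The random structure is the
study design's: participant intercepts, item intercepts, and an
item-by-level slope (level scored −1/0/+1); if the slope term makes the
fit fail it is dropped with a warning and the simplification recorded.
Treatment coding with references detail / low / continuous / vocoded.

**Reverse selection** starts from all four main effects plus all two-way
interactions (the four-way is available as an optional check) and
repeatedly removes the least significant non-significant interaction by
drop-one LRT at α = 0.05, never a main effect; removal order and each
step's LRT are logged. **Per-predictor tests** compare the final model to
a null with the predictor removed — a main effect taking its retained
interactions with it, which is what produces 4 df for the hierarchy and
3 df for predictability when the hierarchy × predictability interaction is
retained. No multiple-testing correction is applied, matching the raw-LRT
reporting convention. Marginal effects are unweighted cell-mean contrasts
with participant-bootstrap CIs, and the hierarchy slope is the
$(\text{main}-\text{detail})/2$ contrast on cell means — deliberately
model-agnostic, so slope estimates do not depend on the fitted
random-effect structure. Whether reported percentage-point benefits are
model-based or raw-mean contrasts is ambiguous in the source convention;
the package computes raw-mean contrasts for effects (and the model
coefficients are available from the fit for comparison).

**Pause analyses.** Between participants: OLS of participant mean recall
on participant mean pause, F(1, n−2). Within participants: passage-level
recall on the within-participant-centered passage mean pause with
participant intercepts, LRT with 1 df. Degenerate regressors (constant
pauses) raise errors rather than returning zero slopes. Covariates
(R-span, vocabulary, PTA) enter the final model standardized, tested by
1-df LRT.

## 6. Problem sizes, tolerances, and known limitations

The test suite exercises the pipeline at the study's own scale — 24
participants × 8 passages × 3 levels (576 cells) — with 200 seeded
replicates for calibration-recovery, slope-direction and type-I-error
checks, and 20–40 replicates for the heavier reverse-selection and power
checks. Signal tests use 0.5–2 s fixtures at 22.05 or 44.1 kHz; RMS
matching is asserted at 0.1% relative, filterbank edges at 1e-9 relative,
rolloff at ±1.5 dB/octave.

Known limitations, found and quantified while validating:

* **Between-item LRTs are anticonservative at 8 items.** Under a null
  generator, ML likelihood-ratio tests reject hierarchy, format and
  clarity at ≈5% as they should, but *predictability* — the only factor
  varying **between** passages — rejects at ≈13%. This is the expected
  behavior of χ² reference distributions with so few item-level units, and
  it applies equally to the original analysis method this package
  re-implements; readers should treat predictability p-values near 0.05
  with caution at this design size.
* **Reverse-selection power at the default calibration is modest.** With
  attenuation 0.55 and the default random-effect SDs, the
  hierarchy × predictability interaction is retained in only ≈35% of
  24-participant replicates (vs. ≈95% at attenuation 0.3). The marginal,
  cell-mean *slope-direction* statistic is far more sensitive: the low
  slope is shallower than the high slope in >95% of replicates.
* **Null reverse-selection keeps a spurious interaction ≈25% of the
  time** — exactly what α = 0.05 over six candidate terms implies
  ($1 - 0.95^6$); backwards selection does not control family-wise error.
* The generator emulates the *statistical* structure of discourse-recall
  data, not its content: no audio, no transcripts, no serial-position or
  passage-topic effects, no floor compression for details under the
  hardest conditions (expected percentages stay inside [0, 100] by
  construction instead). Passing recovery tests therefore demonstrates
  that the analysis stage measures what the generator encodes — not that
  real recall data satisfy the generator's assumptions.
* The scorer's lemmatizer is intentionally crude; on real transcripts,
  synonym lists carry the burden the human scorers carried.

## 7. One run, end to end

```{r end-to-end}
sim <- simulate_study(n_participants = 24, seed = 1)
sel <- reverse_select(sim$trials)
sel$spec$interactions
marginal_effect(sim$trials, "predictability", n_boot = 100, seed = 2)
c(high = hierarchy_slope(sim$trials, predictability = "high"),
  low = hierarchy_slope(sim$trials, predictability = "low"))
pause_analyses(sim$trials, sim$pauses)
```
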