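# vocrecall

Noise-band vocoding and propositional discourse-recall simulation for
cochlear-implant-simulation listening experiments.

## What problem this addresses

Cochlear implants deliver speech with the equivalent of only a handful of
spectral channels. Listening experiments simulate that percept in
normal-hearing listeners with **noise-band vocoding** and then ask not just
*how much* of a spoken passage is recalled but *what kind* of content
survives: discourse recall reliably favors main ideas over mid-level
information over details (the **semantic hierarchy** or "levels" effect),
and the slope of that gradient indexes how well the listener understood the
passage. Experiments of this type cross spectral degradation (clear vs.
6-channel vocoded speech), passage predictability (high vs. low mean
inter-word cloze probability), and presentation format (continuous vs.
**self-paced listening**, where the listener triggers each successive
segment by keypress and the inter-segment pauses are recorded).

`vocrecall` implements the full computational chain for such studies, for
experimenters who need the stimulus processing and for methodologists who
want to study the design's statistical behavior on synthetic data:

1. **Vocoder** — band-pass analysis into `N` logarithmically spaced bands
   (Butterworth order 3, 80–8000 Hz by default), half-wave-rectified
   envelopes low-passed at 300 Hz, envelope-modulated band-limited white
   noise carriers, per-band and global RMS matching
   (`vocode()`, `rms_equalize()`, `measure_rolloff()`).
2. **Stimulus preparation** — lossless segmentation of passages at
   annotated clause/sentence boundaries and a counterbalanced
   within-subject design in which every participant hears all 8 passages,
   2 per format × clarity cell (one high- and one low-predictability), and
   every passage occupies every cell equally often across each block of 8
   participants (`segment_passage()`, `build_design()`).
3. **Propositional scoring** — a passage's propositions form a DAG; roots
   are *main ideas*, propositions taking a main proposition as an argument
   are *mid-level*, the rest are *details*. A free-recall transcript earns
   binary credit for a proposition when its predicate and atomic arguments
   all appear (directly or via a listed synonym) in the lemmatized
   transcript (`assign_levels()`, `score_transcript()`,
   `aggregate_scores()`).
4. **Synthetic data** — a linear-probability generator on the percentage
   scale whose marginal contrasts equal its calibration deltas by
   construction. The packaged defaults encode the study conditions this
   package emulates: effects of 7.85 (predictability), 9.78 (main−mid),
   5.61 (mid−detail), 6.83 (format) and 4.78 (clarity) percentage points,
   a hierarchy-slope attenuation of 0.55 under low predictability,
   participant/item random effects, covariate profiles (R-span,
   vocabulary, PTA), and lognormal inter-segment pauses with mean 2.43 s
   and SD 2.71 s coupled to recall between and within participants
   (`simulate_study()`, `effect_calibration()`).
5. **Analysis** — cell-level linear mixed models (`lme4`, ML fits) with
   participant and item random intercepts and a by-item hierarchy slope;
   reverse selection over interaction terms; per-predictor
   likelihood-ratio tests with the null-model df bookkeeping that yields
   df = 4 for the hierarchy and df = 3 for predictability when the
   hierarchy × predictability interaction is retained; marginal effects
   with participant-bootstrap CIs; hierarchy-slope estimates; pause and
   covariate analyses (`fit_recall_model()`, `reverse_select()`, `lrt()`,
   `marginal_effect()`, `hierarchy_slope()`, `pause_analyses()`,
   `covariate_predictors()`).

## The model at the core

For participant *i*, passage *j*, level *l* the generator draws

```
pct_ijl = mu(l, pred_j, format_ij, clarity_ij) + u_i + v_j + w_j s_l + e
n_recalled ~ Binomial(n_props_l, pct_ijl / 100)
```

with `u_i ~ N(0, sd_participant^2)` (loaded on R-span and pause tendency),
`v_j, w_j` item intercept/slope effects, `s_l` the level score (−1, 0, +1),
and the fixed surface

```
mu = b + c(l) + d_pred [high] + d_format [self-paced] + d_clarity [clear]
     ± kappa * g(l),     kappa = (1 − atten) / (1 + atten)
```

where `c(l)` is the cumulative level contribution (0, 5.61, 15.39), `g` is
`c` centered, and the sign is + for high / − for low predictability. The
double-centered interaction keeps every marginal contrast equal to its
delta while making the low/high hierarchy-slope ratio exactly `atten`.
The analysis stage estimates the same quantities from data: marginal
contrasts as unweighted cell-mean differences, the levels-effect slope as
`(main − detail)/2`, and inference via ML likelihood-ratio tests.

## Worked example

```r
library(vocrecall)

# vocode a tone complex and check RMS preservation
x <- audio_signal(sin(2 * pi * 440 * (0:44099) / 44100), 44100)
y <- vocode(x, vocoder_config(n_channels = 6, rng_seed = 1))
c(in_rms = signal_rms(x), out_rms = signal_rms(y))
#>    in_rms   out_rms
#> 0.7071068 0.7071068

# simulate one study and analyze it
sim <- simulate_study(n_participants = 24, seed = 1)
marginal_effect(sim$trials, "predictability", n_boot = 200, seed = 2)
#> Marginal effect [predictability: high - low]: 17.67 percentage points
#>   (CI 15.92 to 19.33, 200 bootstrap reps)

fit <- fit_recall_model(sim$trials,
                        model_spec(interactions = "hierarchy:predictability"))
lrt(sim$trials, fit$spec, "hierarchy")
#> LRT hierarchy: chisq(4) = 26.828, p = 2.154e-05

round(c(high = hierarchy_slope(sim$trials, predictability = "high"),
        low  = hierarchy_slope(sim$trials, predictability = "low")), 2)
#>  high   low
#>  11.25  3.62
```

A single replicate's predictability estimate is noisy (17.67 points here
against a generating 7.85): predictability varies *between* passages, so
with 4 passages per class and an item SD of 5 points, single-study
estimates scatter widely — averaged over 200 replicates the estimator
recovers 7.85 to within a fraction of a point (that is what
`scripts/acceptance.R` computes). The hierarchy slope is visibly shallower
for low-predictability passages (attenuation 0.55 in truth), and the
hierarchy's likelihood-ratio test uses the 4-df null-model comparison.

## Layout

```
R/                  implementation (audio, vocoder, stimulus, design,
                    scoring, calibration, simulate, model, effects, pauses)
inst/extdata/       packaged default calibration, toy proposition bank
inst/cli/vocode.R   command-line vocoder / RMS-equalizer
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R
vignettes/vocoded-discourse-pipeline.Rmd   methods vignette
```
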