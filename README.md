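# gazebias

Analysis of two-stimulus preferential-looking eye-tracking experiments on
emotional attention biases, from raw gaze samples to Bayesian posterior
summaries — with a seeded synthetic-gaze generator so the whole pipeline is
testable without any recordings.

**Who it is for.** Researchers running preferential-looking paradigms
(comparative cognition, infant studies, emotion research) in which a
subject sees an emotional and a neutral scene side by side for a few
seconds, and the questions are (i) whether the emotional scene holds gaze
longer (*sustained* attention bias) and (ii) whether it draws the first
fixation (*immediate* attention bias).

## What it computes

From tab-separated gaze logs (`trial_id, t_ms, x_px, y_px, valid`) and a
trial manifest, the pipeline:

1. detects fixations with a velocity-threshold (I-VT style) filter;
2. estimates and corrects per-session horizontal calibration drift by
   k-means clustering of fixation x-coordinates against the two ROI
   centres;
3. extracts per-trial, per-ROI Total Fixation Duration (TFD) and Time To
   First Fixation (TTFF), with validity flags;
4. applies the paradigm's sequential exclusion rules (no-gaze trials,
   fixation totals overrunning the 3 s presentation, failed pre-stimulus
   centre checks, anticipatory < 80 ms latencies, latency ties) with a
   fully accounted exclusion ledger;
5. scores each valid trial with the proportional looking duration

   `PLD = TFD_emotional / (TFD_emotional + TFD_neutral)`

   and an attention weight `w = trial looking time / subject mean looking
   time` (sustained measure), or the binary first-fixation location
   (immediate measure);
6. fits, by adaptive Metropolis-within-Gibbs MCMC written in the package,
   * a **weighted zero-one-inflated beta (ZOIB) mixed regression** for PLD —
     point masses `zoi·(1−coi)` at 0 and `zoi·coi` at 1, beta density
     `(1−zoi)·Beta(μφ, (1−μ)φ)` between, logit-linear sum-coded fixed
     effects (side + species × emotion) on μ, random intercepts for
     session nested in subject;
   * a **logistic mixed regression** for first-fixation location with
     random slopes for emotion and species;

   under Normal(0, 1) priors on coefficients and half-Student-t(3, 0, 2.5)
   priors on random-effect SDs;
7. reports each estimand as posterior median, 89% highest-density
   interval, probability of direction (pd), and split-chain Gelman–Rubin
   diagnostic, plus response-scale condition estimates and contrasts.

See `vignettes/attention-bias-methods.Rmd` for the model, the sampler and
every design decision.

## Worked example

```r
library(gazebias)

# Simulate a study: 4 subjects x 6 sessions x 10 trials, with a -141 px
# calibration drift injected into every subject's third session.
cfg <- gen_config(n_subjects = 4, sessions_per_subject = 6,
                  trials_per_session = 10,
                  drift_px_by_session = c("3" = -141), seed = 2026)
ds <- simulate_gaze(cfg)

fx <- detect_fixations(ds$gaze)
dr <- correct_drift(fx, ds$manifest, ds$geometry)
mt <- compute_metrics(dr$fixations, ds$geometry,
                      trial_ids = ds$manifest$trial_id)
st <- filter_tfd(mt, ds$manifest)
print(st$ledger)
#> TFD exclusion ledger: 240 trials
#>   - no_gaze                   23
#>   - overrun                    3
#>   valid: 214 (89.2%; 10.8% removed)

inc <- st$scored[!st$scored$excluded, ]
fit <- fit_zoib(inc, iter = 4000, warmup = 1000, chains = 2, seed = 2026)
condition_estimates(fit, data.frame(species_on_scene = c("bonobo", "human")))
#>   estimand median hdi_lo hdi_hi    pd rhat
#> 1   bonobo  0.509  0.441  0.587 0.602 1.01
#> 2    human  0.452  0.378  0.527 0.897 1.01
contrast(fit, data.frame(species_on_scene = "bonobo"),
         data.frame(species_on_scene = "human"))
#>         estimand median hdi_lo hdi_hi    pd
#> 1 bonobo - human 0.0557 0.0284 0.0856 0.999
```

Reading the output: the drift report (`dr$report`) shows the four injected
sessions recovered at offsets of roughly +135 to +152 px and corrected,
the others untouched. The condition estimates are response-scale mixture
means for each scene species marginal over emotion category and side, with
pd assessed against the 0.5 chance level: under this generator
(conspecific bias 0.52, heterospecific 0.48, 214 valid trials) neither
cell alone is resolved with certainty, but their *contrast* — bonobo-scene
minus human-scene PLD, the sharper estimand because cell posteriors are
correlated — is 0.056 with 89% HDI (0.028, 0.086) and pd ≈ 1.00, covering the
generator's true gap (0.9 × 0.04 = 0.036 after inflation) within interval.

The same run end-to-end, writing all intermediates, ledgers and summaries
to a directory:

```r
rc <- run_config(output_dir = "run1", simulate = cfg, seed = 2026)
report <- run_pipeline(rc)
```

or from a shell via the bundled CLI
(`system.file("scripts/gazebias-cli.R", package = "gazebias")`) with verbs
`simulate | preprocess | score | fit | report | all`.

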