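# bcidecode

Nested cross-validation hyperparameter optimization for imagined-speech
EEG decoding, as a tested, reusable R pipeline.

## The problem

Direct-speech brain–computer interfaces try to decode linguistic units
(imagined words, vowels) from non-invasive EEG. Typical studies in this
area record few channels and few trials per class, which makes two
methodological questions acute:

1. Do deep decoders (compact EEG CNNs) actually beat classical pipelines
   (SVM / random forest on wavelet features, regularized LDA on
   filter-bank CSP features) once both are given the same, honest
   hyperparameter (HP) optimization?
2. How should HPs be selected — per subject (intra-subject) or shared
   across the cohort (inter-subject) — and which HPs matter?

Answering either requires nested cross-validation: inner folds select HPs
by exhaustive grid search, outer folds estimate generalization with the
selected HPs, so test data never influence selection. For a dataset
`D` split into `k` folds, each HP combination θ in the grid Θ receives one
validation accuracy per inner fold; the selected combination is

    θ* = argmax_θ  mean over all inner folds of Acc(θ)

and the reported performance is the mean outer-fold test accuracy at θ*.
With `k = 4`, every outer fold is a 75/25 train/test split and every inner
split is again 75/25.

`bcidecode` implements the full study apparatus around a six-channel
(F3, F4, C3, C4, P3, P4), 1024 Hz, 4 s-trial imagined-speech protocol
(six Spanish words or five vowels, 40 imagined trials per class, 15
subjects): a seeded synthetic-EEG generator (1/f background band-limited
to 2–40 Hz, class-dependent band-power effects with tunable
signal-to-noise ratio, log-normal subject variability, Poisson eye-blink
artefacts), preprocessing (zero-phase FIR band-pass, FastICA blink
screening against a template topography at |r| ≥ 0.8, resampling to
128 Hz), relative wavelet energy (db4, levels D2–D5 + A5, 30 features per
trial) and FBCSP features (six canonical bands, CSP spatial filters,
log-variance, mutual-information selection), six decoders (shallow / deep
/ EEGNet-style CNNs trained with ADAM at batch 64, plus SVM, random
forest, shrinkage-regularized LDA), the nested-CV driver with intra- and
inter-subject selection modes over the study grids (128 HP combinations
per CNN family), and the statistical layer (repeated-measures ANOVA,
two-way ANOVA with interaction, Tukey HSD, precision scores, summary
tables).

The real recordings are not redistributable; the synthetic generator
reproduces their structure so every stage is testable offline. See the
methods vignette (`vignettes/hp-optimization-methods.Rmd`) for models,
defaults and design decisions.

## Worked example

A desk-scale run: three synthetic subjects, the rLDA-FBCSP pipeline, a
reduced grid, 4-fold nested CV.

```r
library(bcidecode)

protocol <- protocol_words(n_subjects = 3, fs = 128, trials_per_class = 20)
model    <- signal_model_spec(snr = 1, seed = 1)
dataset  <- generate_dataset(protocol, model)

grid <- hp_grid("rlda", list(nsf = c(2, 3), miql = 6, nof = c(8, 10)))
res  <- run_intra_subject(dataset, "rlda", grid, k = 4, seed = 1)

res[[1]]
#> <cv_result> rlda subject S01 (words): mean test acc 100.00%
#>   theta*: nsf=2,miql=6,nof=8
attr(res, "cohort")
#>        mean          sd max
#> 1 0.9972222 0.004811252   1
```

Per subject you get the full inner-fold table (`inner_table`), the
selected combination (`theta_star`), outer-fold accuracies and per-class
precision. At `snr = 1` the generator's class-specific band-power effects
are strong, so the pipeline separates the six classes far above the
16.67% chance level; with `snr = 0` the same pipeline returns chance
accuracy (that calibration is what the acceptance script measures).
`run_inter_subject()` selects one shared combination from the pooled
inner-fold accuracies; `run_experiment(experiment_config(...))` drives
the whole design (generation → preprocessing → nCV per family and mode →
CSV tables → statistics report) from one seeded, validated configuration,
and `read_config()` loads the packaged YAML configs
(`inst/configs/paper_words.yaml`, `paper_vowels.yaml`, `desk.yaml`).

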