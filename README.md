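# badchan

Automatic bad-channel detection for intracranial EEG (SEEG) recordings.

## The problem

Stereo-EEG records from hundreds of contacts on depth-electrode shafts
implanted in patients evaluated for epilepsy surgery. During 1 Hz direct
electrical stimulation, some channels carry no brain signal at all:
contacts detached from the amplifier, contacts drowned in 50 Hz line
noise, contacts with an intermittent electrical connection producing sharp
transients, and the two contacts of the stimulation pair themselves, whose
amplifier inputs are driven by the stimulator. Leaving these "bad
channels" in spoils every downstream analysis, and finding them by eye
across thousands of stimulation files is slow and poorly reproducible.
Scalp-EEG detectors that predict each channel from all the others do not
transfer, because intracranial signals have much weaker spatial
correlation.

`badchan` classifies each channel from seven signal features computed
against its *same-shaft neighborhood* — the other contacts on the same
electrode shaft within 5 contact positions — so every feature is local,
dimensionless (or in microvolts only where it should be), and robust to
montage gain and sampling rate:

| Feature | Definition |
|---|---|
| `corr` | mean Pearson correlation with the neighbors, μCorᵢ = (1/n) Σⱼ Cor(Xᵢ, Xⱼ) |
| `varn` | σ′ᵢ² = σᵢ² / median of neighbor variances |
| `devn` | ΔAᵢ = μAᵢ − mean of neighbor mean amplitudes (µV) |
| `ampl` | A′ᵢ = (max Xᵢ − min Xᵢ) / median of neighbor peak-to-peak ranges |
| `grad` | μG′ᵢ = mean&#124;ΔXᵢ&#124; / median of neighbor mean absolute gradients |
| `kurt` | kurtosis m₄/m₂² (Gaussian = 3) |
| `hurs` | single-window rescaled-range Hurst exponent, H = log(Rₙ/σₙ)/log(n/2) |

A bagged ensemble of 200 unpruned decision trees votes on each channel;
bagging is used because bad channels are a rare class (typically ~5% plus
the stimulation pair) and bootstrap aggregation handles that imbalance
without resampling tricks. Ties at a vote fraction of exactly 0.5 go to
"bad" — in quality control a false alarm is cheaper than a miss.

Because clinical SEEG cannot be redistributed, the package ships a
synthetic SEEG generator (`simulate_run()`, `simulate_cohort()`) that
emulates the acquisition envelope (8–17 shafts × 5–18 contacts, 256–4096
Hz, ≤40 s baseline plus a 1 Hz biphasic pulse train) and all four
bad-channel phenotypes at configurable severity, so the entire pipeline —
features, classifier, learning curve, per-center robustness — is testable
end to end.

## Worked example

Train on a small synthetic cohort, then screen a new recording:

```r
library(badchan)

cfg <- sim_config(n_shafts = 8, contacts_per_shaft = 8,
                  baseline = 4, stim_duration = 4, tail = 1,
                  fs = 256, seed = 42)
feats <- simulate_cohort_features(cfg, n_subjects = 12,
                                  runs_per_subject = 2, seed = 42)
train <- dplyr::filter(feats, subject <= 8)
attr(train, "conventions") <- attr(feats, "conventions")
fit <- train_detector(train, model_config(seed = 1))
fit
#> <badchan_model> 200 bagged trees, trained on 1024 channels (7.6% bad)
#>   features: corr, varn, devn, ampl, grad, kurt, hurs
#>   conventions: kurtosis=moment, hurst=rs

run <- simulate_run(sim_config(n_shafts = 8, contacts_per_shaft = 8,
                               baseline = 4, stim_duration = 4, tail = 1,
                               fs = 256, seed = 99))
report <- predict(fit, extract_features(run))
dplyr::filter(report, class == "bad")
#> # A tibble: 4 × 4
#>   channel label class vote_bad
#>     <int> <chr> <chr>    <dbl>
#> 1      19 c3    bad          1
#> 2      20 c4    bad          1
#> 3      44 f4    bad          1
#> 4      48 f8    bad          1

run$channel_labels[run$labels == "bad"]
#> [1] "c3" "c4" "e1" "f4" "f8"
```

All 200 trees vote "bad" for the stimulation pair `c3`/`c4` and the two
clearly artifacted contacts `f4`/`f8`. Channel `e1` — ground-truth bad —
is missed: it is an intermittent contact whose transients are too sparse
in this short run to leave a signature, exactly the kind of borderline
case that shrinks as the training cohort grows. `glance(fit)` reports the
out-of-bag accuracy (0.998 here) and `tidy(fit)` the per-feature
importances; `learning_curve()`, `grouped_accuracy()` and
`feature_ttests()` implement the full evaluation protocol, with
`autoplot()` methods for the curve.

A command-line front end wraps the same functions:

```sh
inst/cli/badchan detect --recording run.edf --model model.rds --out report.csv
inst/cli/badchan reproduce --out study/ --seed 7 --preset quick
```

File formats: EDF for interchange (16-bit, via the package's minimal
codec) and a bit-exact RDS "fixture" container (the `seeg_recording`
object serialized with `saveRDS()`) that also stores ground-truth labels
and metadata; `write_feature_csv()` exports the channels × 7 feature table
with its degeneracy-flag sibling.

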