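---
title: "Detecting bad channels in stereo-EEG: features, classifier, and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bad channels in stereo-EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(badchan)
```

## The detection model

A stereo-EEG implant carries 8–17 electrode shafts with 5–18 contacts
each, recorded in a referential (monopolar) montage at 256–4096 Hz. During
1 Hz direct electrical stimulation, each stimulation run produces one file
with up to 40 s of baseline, the pulse train, and a 3 s tail. Bad channels
— contacts detached from the amplifier, contacts dominated by mains noise,
contacts with a failing electrical connection, and the two stimulated
contacts themselves — must be flagged on the montage *as recorded*:
instrumental faults belong to physical channels, and any re-referencing
would smear them across linear combinations. `badchan` therefore never
re-references.

Detection is per channel. Each channel is summarized by seven features and
a bagged decision-tree ensemble votes good/bad. Five features are
normalized against the channel's *neighborhood*: the other contacts on the
same shaft within 5 contact positions (distance counted on nominal contact
indices, so a missing contact does not widen the window; contacts at shaft
ends simply have fewer neighbors). Intracranial signals correlate only
locally, so the neighborhood — not the whole montage — is the right
reference population: it makes each feature approximately 1 (or 0) for a
healthy channel regardless of brain region, amplifier gain, or sampling
rate.

The features, for channel $X_i$ with $n$ neighbors $X_j$:

* mean neighbor correlation $\mu Cor_i = \frac1n \sum_j Cor(X_i, X_j)$,
  signed — referential neighbors correlate positively, so anticorrelation
  is itself anomalous;
* normalized variance $\sigma'^2_i = \sigma^2_i / \tilde\sigma^2$, the
  channel variance over the *median* neighbor variance (the median keeps
  one monster neighbor from skewing the reference);
* amplitude deviation $\Delta A_i = \mu A_i - \overline{\mu A}$, the mean
  amplitude minus the mean of neighbor means, in microvolts — sensitive to
  electrode drift; a common offset cancels;
* normalized amplitude range $A'_i = (\max X_i - \min X_i)/\tilde A$, with
  $\tilde A$ the median of neighbor peak-to-peak ranges;
* normalized mean gradient $\mu G'_i = \mu G_i / \tilde\mu G$, where
  $\mu G_i$ is the mean *absolute* first difference (the signed mean would
  telescope to essentially zero); the ratio across channels sampled at the
  same rate cancels the sampling-rate dependence of the raw derivative;
* kurtosis $m_4/m_2^2$ (non-excess, Gaussian reference 3, no small-sample
  correction) — isolated transients from an intermittent contact push it
  far above 3;
* a single-window rescaled-range Hurst exponent: center the signal,
  cumulate it, take the range $R_n$ of the cumulated series over the
  population standard deviation $\sigma_n$, and read the exponent as
  $H = \log(R_n/\sigma_n)/\log(n/2)$. White noise lands near 0.5,
  integrated noise near 1, and 1/f EEG-like signals in between, around
  0.7–0.85; channels far from that band are suspicious.

The final Hurst expression is the one genuinely open design point: the
single-window rescaled-range literature admits a variant that divides by
$\sigma_n^{1/2}$ instead. We adopted the $R_n/\sigma_n$ reading because it
is scale invariant (a pure gain change cannot alter long-memory) and
because it alone satisfies the white-noise ≈ 0.5 anchor; the
$\sigma^{1/2}$ variant is implemented behind
`hurst_exponent(..., convention = "sqrt-sigma")` and both are tested
against a Monte-Carlo white-noise oracle. The convention used at feature
extraction is persisted inside every trained model and enforced at
prediction time, so a model can never silently consume features computed
under the other reading. The same applies to the kurtosis convention.

### Degenerate channels

Flat channels, channels with unparseable labels (hence empty
neighborhoods), and all-flat neighborhoods are not errors: a disconnected
or saturated contact is precisely what the classifier must learn to
recognize. Degenerate cells therefore receive finite sentinels — 0 where
the statistic's numerator vanishes (correlation, deviation, gradient of a
constant signal), and a cap of $10^6$ where a normalizing median is zero —
plus a per-cell flag carried alongside the table
(`feature_flags()`). The cap value is arbitrary by design; it only needs
to be far outside the physiological range so that trees split it off
cleanly.

## The classifier

Bad channels are a few percent of contacts, and the bad class is the class
of interest. We use bagging — bootstrap resamples at full sample size with
replacement, one unpruned CART tree per resample, majority vote — because
bootstrap aggregation is robust to class imbalance without explicit
rebalancing. Tree count (200), unpruned depth, and full-size bootstrap are
conventional defaults; held-out accuracy plateaus over a wide range of
these values, which the test suite checks by asserting that accuracy
variance across seeds shrinks from 10 to 200 trees. Inverse-prevalence
class weighting is available (`class_weighting = "balanced"`) but off by
default. Before the seeded bootstrap, training rows are put in a canonical
order so that the learned model is a function of the *set* of training
channels, not of the caller's row order. An exact 0.5 vote tie is resolved
to "bad" by default (`tie_break` in `model_config()`): flagging a good
channel costs a review glance, missing a bad one corrupts an analysis.

## The synthetic generator

No clinical recordings ship with the package, so the generator is
first-class, tested code that defines the study conditions for every
evaluation:

* **Good channels.** Each shaft carries a chain of 1/f (pink) processes
  built by recursive mixing, so adjacent contacts correlate at
  `neighbor_correlation` (default 0.6) with correlation decaying
  geometrically with contact distance — the weak, local spatial structure
  of intracranial EEG. Channel RMS is ~50 µV with per-subject and
  per-channel gain spread, plus a faint mains component (power ratio
  10⁻³–10⁻¹ of background), because real "good" channels are not mains-free.
* **Stimulation.** A biphasic pulse train (1 Hz, 2 ms per phase by
  default) is added to *every* channel — good and bad — so the artifact
  cannot become a classification shortcut. The two stimulated contacts are
  overwritten with a rail-saturated version (±3 mV) and are always
  labeled bad; the pair rotates across a subject's runs.
* **Phenotypes** (5% of channels by default, equal mix): *disconnected* =
  2–15 µV white noise with no physiological background and only weak
  capacitive coupling of the pulse; *line_noise* = good background plus a
  mains sinusoid at 10–100× the background power; *intermittent* = good
  background plus Poisson-timed exponential transients (0.05–1 events/s,
  300–3000 µV, 5–50 ms decay). Severities are drawn from deliberately wide
  ranges: a faint line hum or a transient rate so low that no event falls
  inside a short run produces genuinely hard, sometimes irreducible cases,
  which is what makes the learning curve rise gradually instead of
  saturating after two subjects — the qualitative behavior of expert-labeled
  clinical data. Phenotype assignments and severities are drawn once per
  subject and persist across that subject's runs.
* **Cohorts.** `simulate_cohort()` partitions subjects into tagged groups
  ("centers") with group-level nuisance parameters: sampling rate drawn
  from {256, 512, 1024, 4096} Hz, neighbor correlation 0.45–0.7, and a
  mains-amplitude scale, emulating inter-center acquisition differences.
  One master seed derives per-subject child seeds, so any subject is
  reproducible in isolation.

What the generator does **not** emulate: epileptiform activity, seizures
and after-discharges, realistic evoked potentials following each pulse,
electrode geometry, amplifier drift dynamics, or 50 Hz stimulation
protocols. Passing tests on this generator therefore demonstrate that the
pipeline recovers planted phenotypes under realistic amplitude ratios,
correlation structure and class imbalance — not that clinical accuracy
figures transfer to any particular hospital's data.

## Evaluation protocol

Accuracy is the channel-level ratio $(TP+TN)/(TP+FN+FP+TN)$ with bad as
the positive class, pooled over all test files. `learning_curve()`
reserves a fixed random half of the cohort's subjects as the test set,
then for each training size draws 19 random subject subsets from the
remaining pool, trains, and scores held-out channels. Splits are always by
subject, so no channel of a test subject can leak into training; the suite
verifies that shuffling channels within subjects changes nothing. Three
protocol details are not fully pinned down by the clinical description and
were fixed as follows: the test set is held fixed across repetitions and
sizes (rather than redrawn), which makes curve points comparable; the
per-center evaluation uses one model trained on center-mixed subjects
disjoint from the test subjects (rather than one model per center),
matching the single-model reading of the original protocol; and
`feature_ttests()` defaults to Welch's unequal-variance two-sample t-test
(bad-class feature variances are grossly larger by construction), with the
pooled Student variant behind `var_equal = TRUE` and no multiplicity
correction, since this is a filter-method ranking.

## Problem sizes used in the package's own studies

The clinical protocol spans 206 patients and ~10,000 files; the package's
bundled studies use scaled-down cohorts chosen to exercise the same
protocol shape: the learning-curve study uses a 60-subject cohort
(8 shafts × 5 contacts, 256 Hz, 7 s runs, two runs per subject) with 20
training sizes of 1–20 subjects × 19 repetitions; the headline accuracy
protocol in `scripts/acceptance.R` uses 240 subjects under the default
configuration (10 shafts × 12 contacts, 512 Hz, 23 s runs, one run per
subject) with training sizes 10 and 110; the per-center study uses 70
subjects across five groups; and the feature-discriminability gate uses 10
subjects × 5 runs, mirroring the 10-subject/466-run scale at which the
feature distributions were originally examined. Within each study the
fraction of hard, low-severity bad channels bounds achievable accuracy;
the 110-subject plateau sits near 99.7% on the default generator because
a small fraction of intermittent channels show no transient at all inside
a single short run and are unidentifiable in principle.

## Known limitations

* Labels are per channel and per run: time-resolved bad *segments* and
  artifact removal are out of scope — the tool excludes channels, it does
  not clean them.
* The EDF codec is minimal (continuous 16-bit EDF, one-second records,
  equal sampling rates across channels); vendor formats and EDF+
  annotations are not supported. The fixture container exists because EDF
  quantizes to 16 bits and tests need bit-exact round trips.
* The gradient feature is the known weak discriminator (as in the clinical
  filter-method ranking) and is kept for completeness; the deviation
  feature is similarly marginal on synthetic cohorts because the generator
  has no slow electrode drift.
* A model trained on one feature-convention pair refuses tables from the
  other; retrain rather than mix.
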