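Package: badchan
Title: Automatic Bad-Channel Detection for Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quality control for stereo-electroencephalography (SEEG)
    recordings acquired during 1 Hz direct electrical stimulation. Computes
    seven per-channel signal features (mean neighbor correlation, normalized
    variance, amplitude deviation, normalized amplitude range, normalized
    mean gradient, kurtosis and a rescaled-range Hurst exponent) against
    same-shaft contact neighborhoods, classifies channels as good or bad
    with a bagged decision-tree ensemble robust to class imbalance, and
    ships the full evaluation protocol (confusion counts and accuracy,
    learning curves over training-set size, per-center accuracy, per-feature
    t-tests) together with a synthetic SEEG stimulation-run generator so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
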