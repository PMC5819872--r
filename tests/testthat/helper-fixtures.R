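# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files are read.

# A recording with a random shaft layout and Gaussian signals; occasional
# primed shafts and an unparseable auxiliary channel exercise the label
# grammar.
random_recording <- function(seed, n_samples = 200, with_junk = FALSE) {
  withr::with_seed(seed, {
    n_shafts <- sample(2:4, 1)
    shafts <- sample(c(letters[1:6], "a'", "b'"), n_shafts)
    labels <- unlist(lapply(shafts, function(s) {
      paste0(s, seq_len(sample(4:10, 1)))
    }))
    if (with_junk) labels <- c(labels, "EKG")
    sig <- matrix(rnorm(length(labels) * n_samples, sd = 50), length(labels))
    recording(sig, fs = 256, channel_labels = labels)
  })
}

# A recording whose per-channel variances / means / ranges are controlled
# exactly: channel i = offset + gain * base, base standardized.
scaled_recording <- function(gains, offsets = rep(0, length(gains)),
                             n_samples = 256, seed = 1) {
  base <- withr::with_seed(seed, as.numeric(scale(rnorm(n_samples))))
  sig <- t(sapply(seq_along(gains), function(i) offsets[i] + gains[i] * base))
  recording(sig, fs = 256, channel_labels = paste0("a", seq_along(gains)))
}

# Small desk-scale simulator config used by most pipeline tests.
test_config <- function(seed = 1, ...) {
  sim_config(n_shafts = 8, contacts_per_shaft = 5, fs = 256,
             baseline = 3, stim_duration = 3, tail = 1, seed = seed, ...)
}

# A linearly separable two-class feature table for classifier contract tests.
separable_table <- function(n = 500, seed = 1) {
  withr::with_seed(seed, {
    n_bad <- round(n * 0.1)
    good <- tibble::tibble(
      corr = rnorm(n - n_bad, 0.5, 0.05), varn = rnorm(n - n_bad, 1, 0.1),
      devn = rnorm(n - n_bad, 0, 1), ampl = rnorm(n - n_bad, 1, 0.1),
      grad = rnorm(n - n_bad, 1, 0.1), kurt = rnorm(n - n_bad, 3, 0.2),
      hurs = rnorm(n - n_bad, 0.7, 0.03), class = "good"
    )
    bad <- tibble::tibble(
      corr = rnorm(n_bad, -0.2, 0.05), varn = rnorm(n_bad, 50, 5),
      devn = rnorm(n_bad, 30, 5), ampl = rnorm(n_bad, 8, 1),
      grad = rnorm(n_bad, 10, 1), kurt = rnorm(n_bad, 40, 5),
      hurs = rnorm(n_bad, 0.2, 0.05), class = "bad"
    )
    dplyr::bind_rows(good, bad)
  })
}

with_conventions <- function(tab, template) {
  attr(tab, "conventions") <- attr(template, "conventions", exact = TRUE)
  tab
}
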