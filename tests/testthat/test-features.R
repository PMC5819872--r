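test_that("mean neighbor correlation matches hand-built cases", {
  base <- withr::with_seed(1, rnorm(500))
  # four identical copies: perfect correlation with every neighbor
  rec <- recording(rbind(base, base, base, base), fs = 256,
                   channel_labels = paste0("a", 1:4))
  nb <- build_neighborhoods(rec)
  expect_equal(mean_neighbor_correlation(rec, nb, 1), 1.0)
  # single neighbor equal to -X: perfect anticorrelation
  rec2 <- recording(rbind(base, -base), fs = 256, channel_labels = c("a1", "a2"))
  expect_equal(mean_neighbor_correlation(rec2, build_neighborhoods(rec2), 1), -1.0)
  # independent white noise: null correlation bounded near zero
  sig <- withr::with_seed(7, matrix(rnorm(5 * 10000), 5))
  rec3 <- recording(sig, fs = 256, channel_labels = paste0("a", 1:5))
  v <- mean_neighbor_correlation(rec3, build_neighborhoods(rec3), 1)
  expect_lt(abs(v), 0.05)
})

test_that("normalized variance divides by the median neighbor variance", {
  rec <- scaled_recording(gains = c(2, 1, sqrt(2), sqrt(3)))
  nb <- build_neighborhoods(rec)
  expect_equal(normalized_variance(rec, nb, 1), 4 / 2, tolerance = 1e-12)
  # identical neighbors give exactly 1
  base <- withr::with_seed(2, rnorm(300))
  rec2 <- recording(rbind(base, base, base), fs = 256,
                    channel_labels = paste0("a", 1:3))
  expect_equal(normalized_variance(rec2, build_neighborhoods(rec2), 1), 1.0)
})

test_that("amplitude deviation is the difference of mean amplitudes", {
  rec <- scaled_recording(gains = rep(1, 4), offsets = c(10, 2, 4, 6))
  nb <- build_neighborhoods(rec)
  expect_equal(amplitude_deviation(rec, nb, 1), 10 - mean(c(2, 4, 6)), tolerance = 1e-12)
  # common offset cancels
  rec2 <- scaled_recording(gains = rep(1, 4), offsets = c(10, 2, 4, 6) + 100)
  expect_equal(amplitude_deviation(rec2, build_neighborhoods(rec2), 1), 6, tolerance = 1e-12)
  # equal means give zero
  rec3 <- scaled_recording(gains = rep(1, 4))
  expect_equal(amplitude_deviation(rec3, build_neighborhoods(rec3), 1), 0)
})

test_that("normalized amplitude range divides by the median neighbor range", {
  base <- withr::with_seed(1, as.numeric(scale(rnorm(256))))
  R <- max(base) - min(base)
  rec <- scaled_recording(gains = c(200, 40, 50, 60) / R)
  nb <- build_neighborhoods(rec)
  expect_equal(normalized_amplitude_range(rec, nb, 1), 4.0, tolerance = 1e-12)
  # global gain cancels
  rec2 <- scaled_recording(gains = 3.7 * c(200, 40, 50, 60) / R)
  expect_equal(normalized_amplitude_range(rec2, build_neighborhoods(rec2), 1), 4.0,
               tolerance = 1e-12)
})

test_that("normalized mean gradient divides by the median neighbor gradient", {
  base <- withr::with_seed(1, as.numeric(scale(rnorm(256))))
  G <- mean(abs(diff(base)))
  rec <- scaled_recording(gains = c(5, 2, 2.5, 3) / G)
  nb <- build_neighborhoods(rec)
  expect_equal(normalized_mean_gradient(rec, nb, 1), 2.0, tolerance = 1e-12)
  # constant channel has zero gradient
  sig <- rbind(rep(1, 256), matrix(rnorm(3 * 256), 3))
  rec2 <- recording(sig, fs = 256, channel_labels = paste0("a", 1:4))
  expect_equal(normalized_mean_gradient(rec2, build_neighborhoods(rec2), 1), 0)
  # high-frequency alternating channel among smooth sinusoids
  t <- seq_len(512) / 256
  sig3 <- rbind(rep(c(1, -1), 256), sin(2 * pi * 2 * t), sin(2 * pi * 3 * t),
                sin(2 * pi * 4 * t))
  rec3 <- recording(sig3, fs = 256, channel_labels = paste0("a", 1:4))
  expect_gt(normalized_mean_gradient(rec3, build_neighborhoods(rec3), 1), 10)
})

test_that("kurtosis uses the non-excess moment convention", {
  expect_equal(kurtosis(rep(c(-1, 1), 100)), 1.0)
  k <- withr::with_seed(3, kurtosis(rnorm(1e5)))
  expect_lt(abs(k - 3), 0.1)
  # single spike in a long flat signal: kurtosis of order n
  x <- c(rep(0, 10000), 1)
  expect_equal(kurtosis(x), oracle_kurt(x), tolerance = 1e-12)
  expect_lt(abs(kurtosis(x) - length(x)), 5)
})

test_that("hurst exponent behaves at its anchors and degenerates safely", {
  hw <- withr::with_seed(4, replicate(50, hurst_exponent(rnorm(8192))))
  expect_lt(abs(mean(hw) - 0.5), 0.1)
  hr <- withr::with_seed(5, replicate(50, hurst_exponent(cumsum(rnorm(8192)))))
  expect_gt(mean(hr), 0.85)
  expect_equal(hurst_exponent(rep(2, 100)), 0)
  # default convention is scale invariant; the sqrt-sigma reading is not
  x <- withr::with_seed(6, rnorm(4096))
  expect_equal(hurst_exponent(50 * x), hurst_exponent(x), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(hurst_exponent(50 * x, "sqrt-sigma"),
                                hurst_exponent(x, "sqrt-sigma"))))
})

test_that("feature table honors the shape and column-order contract", {
  run <- simulate_run(test_config(seed = 11))
  ft <- extract_features(run)
  expect_equal(names(ft), c("channel", "label", feature_columns(), "class"))
  expect_equal(nrow(ft), nrow(run$signals))
  # degenerate channels stay in the table
  sig <- run$signals
  sig[3, ] <- 0
  run2 <- recording(sig, run$fs, run$channel_labels, labels = run$labels)
  ft2 <- extract_features(run2)
  expect_equal(nrow(ft2), nrow(sig))
  expect_true(any(feature_flags(ft2)[3, ] == TRUE))
})

test_that("permuting channel order permutes feature rows identically", {
  run <- simulate_run(test_config(seed = 12))
  perm <- withr::with_seed(1, sample(nrow(run$signals)))
  run_p <- recording(run$signals[perm, ], run$fs, run$channel_labels[perm],
                     labels = run$labels[perm])
  ft <- extract_features(run)
  ft_p <- extract_features(run_p)
  reordered <- ft[perm, ]
  expect_equal(ft_p$corr, reordered$corr, tolerance = 1e-12)
  expect_equal(ft_p$hurs, reordered$hurs, tolerance = 1e-12)
  expect_equal(ft_p$label, reordered$label)
})

test_that("features are gain invariant and offset invariant (devn scales)", {
  run <- simulate_run(test_config(seed = 13))
  ft <- extract_features(run)
  g <- 7.3
  run_g <- recording(g * run$signals, run$fs, run$channel_labels)
  ft_g <- extract_features(run_g)
  for (f in c("corr", "varn", "ampl", "grad", "kurt", "hurs")) {
    expect_equal(ft_g[[f]], ft[[f]], tolerance = 1e-9, label = f)
  }
  expect_equal(ft_g$devn, g * ft$devn, tolerance = 1e-9)
  run_o <- recording(run$signals + 120, run$fs, run$channel_labels)
  ft_o <- extract_features(run_o)
  for (f in feature_columns()) {
    expect_equal(ft_o[[f]], ft[[f]], tolerance = 1e-9, label = f)
  }
})

test_that("degenerate neighborhoods produce capped, flagged sentinels", {
  sig <- rbind(withr::with_seed(1, rnorm(128)), matrix(0, 3, 128))
  rec <- recording(sig, fs = 256, channel_labels = paste0("a", 1:4))
  ft <- extract_features(rec)
  fl <- feature_flags(ft)
  expect_equal(ft$varn[1], 1e6)
  expect_equal(ft$ampl[1], 1e6)
  expect_equal(ft$grad[1], 1e6)
  expect_true(all(unlist(fl[1, c("varn", "ampl", "grad")])))
  # flat channels: zero-variance sentinels, flagged
  expect_equal(ft$kurt[2], 0)
  expect_equal(ft$hurs[2], 0)
  expect_true(all(unlist(fl[2, c("corr", "kurt", "hurs")])))
  # empty neighborhood: flagged zeros for corr/devn
  rec2 <- recording(rbind(sig[1, ], sig[1, ]), fs = 256,
                    channel_labels = c("a1", "EKG"))
  ft2 <- extract_features(rec2)
  expect_equal(ft2$corr[2], 0)
  expect_equal(ft2$devn[2], 0)
  expect_true(all(unlist(feature_flags(ft2)[2, c("corr", "devn")])))
})

test_that("normalized features are robust to the sampling rate", {
  cfg <- sim_config(n_shafts = 8, contacts_per_shaft = 8, fs = 1024,
                    baseline = 4, stim_duration = 4, tail = 1,
                    bad_fraction = 0, seed = 21)
  run <- simulate_run(cfg)
  keep <- run$meta$phenotype == "good"
  # band-limit below 80 Hz so 256 Hz sampling holds the same content,
  # then compare the same signals sampled at 1024 Hz and at 256 Hz
  bf <- signal::butter(4, 80 / (1024 / 2))
  bl <- t(apply(run$signals, 1, function(x) signal::filtfilt(bf, x)))
  run1024 <- recording(bl, 1024, run$channel_labels)
  run256 <- recording(bl[, seq(1, ncol(bl), by = 4)], 256, run$channel_labels)
  ft_hi <- extract_features(run1024)
  ft_lo <- extract_features(run256)
  for (f in c("corr", "varn", "ampl", "grad")) {
    rel <- abs(ft_lo[[f]][keep] - ft_hi[[f]][keep]) /
      pmax(abs(ft_hi[[f]][keep]), 1e-6)
    expect_lt(mean(rel), 0.10, label = f)
  }
})
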