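#' Per-channel signal features for bad-channel detection
#'
#' Seven features are computed per channel, five of them normalized against
#' the channel's same-shaft neighborhood (see [build_neighborhoods()]) so
#' that they sit near a common reference value for healthy channels
#' regardless of region, montage gain or sampling rate:
#'
#' * `corr` — mean Pearson correlation with the neighbors (signed; healthy
#'   referential SEEG neighbors correlate positively, so both uncorrelated
#'   and anticorrelated channels are anomalous).
#' * `varn` — channel variance over the median neighbor variance.
#' * `devn` — channel mean amplitude minus the mean of neighbor means
#'   (microvolts; sensitive to electrode drift/offset).
#' * `ampl` — channel peak-to-peak range over the median neighbor range.
#' * `grad` — mean absolute first difference over the median neighbor value
#'   (sensitive to high-frequency content).
#' * `kurt` — kurtosis, standardized fourth moment `m4/m2^2` (Gaussian
#'   reference 3; sensitive to isolated transients).
#' * `hurs` — single-window rescaled-range Hurst exponent (long-memory
#'   index; about 0.5 for white noise, about 0.7 for EEG-like signals).
#'
#' Degenerate situations (flat channels, empty neighborhoods, zero
#' normalizing medians) never error: they produce finite sentinel values —
#' 0 where the statistic's numerator vanishes, a cap of `1e6` where a ratio
#' explodes — plus a per-cell flag, because flat or disconnected channels
#' are precisely the bad channels the classifier must learn to see.
#'
#' @param recording A [recording()].
#' @param nbhd A neighborhood map from [build_neighborhoods()]; built on the
#'   fly when omitted.
#' @param channel Channel row index.
#' @return A single numeric value (individual feature functions), or a
#'   feature table (see [extract_features()]).
#' @name channel-features
NULL

# mean/var/range/gradient summaries used by several features
chan_mean <- function(x) mean(x)
chan_range <- function(x) max(x) - min(x)
chan_grad <- function(x) mean(abs(diff(x)))

ratio_or_cap <- function(num, den) {
  if (den <= 0 || !is.finite(den)) {
    list(value = if (num <= 0) 0 else DEGENERATE_CAP, flag = TRUE)
  } else {
    list(value = num / den, flag = FALSE)
  }
}

#' @rdname channel-features
#' @export
mean_neighbor_correlation <- function(recording, nbhd = build_neighborhoods(recording),
                                      channel) {
  nb <- nbhd$neighbors[[channel]]
  x <- recording$signals[channel, ]
  if (length(nb) == 0L || var(x) == 0) return(0)
  vals <- vapply(nb, function(j) {
    y <- recording$signals[j, ]
    if (var(y) == 0) return(NA_real_)
    cor(x, y)
  }, 1)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(0)
  mean(vals)
}

#' @rdname channel-features
#' @export
normalized_variance <- function(recording, nbhd = build_neighborhoods(recording),
                                channel) {
  nb <- nbhd$neighbors[[channel]]
  num <- var(recording$signals[channel, ])
  if (length(nb) == 0L) return(if (num <= 0) 0 else DEGENERATE_CAP)
  den <- median(vapply(nb, function(j) var(recording$signals[j, ]), 1))
  ratio_or_cap(num, den)$value
}

#' @rdname channel-features
#' @export
amplitude_deviation <- function(recording, nbhd = build_neighborhoods(recording),
                                channel) {
  nb <- nbhd$neighbors[[channel]]
  if (length(nb) == 0L) return(0)
  mean(recording$signals[channel, ]) -
    mean(vapply(nb, function(j) mean(recording$signals[j, ]), 1))
}

#' @rdname channel-features
#' @export
normalized_amplitude_range <- function(recording, nbhd = build_neighborhoods(recording),
                                       channel) {
  nb <- nbhd$neighbors[[channel]]
  num <- chan_range(recording$signals[channel, ])
  if (length(nb) == 0L) return(if (num <= 0) 0 else DEGENERATE_CAP)
  den <- median(vapply(nb, function(j) chan_range(recording$signals[j, ]), 1))
  ratio_or_cap(num, den)$value
}

#' @rdname channel-features
#' @export
normalized_mean_gradient <- function(recording, nbhd = build_neighborhoods(recording),
                                     channel) {
  nb <- nbhd$neighbors[[channel]]
  num <- chan_grad(recording$signals[channel, ])
  if (length(nb) == 0L) return(if (num <= 0) 0 else DEGENERATE_CAP)
  den <- median(vapply(nb, function(j) chan_grad(recording$signals[j, ]), 1))
  ratio_or_cap(num, den)$value
}

#' Rescaled-range Hurst exponent (single window)
#'
#' Estimates the long-memory index of one channel from the rescaled range:
#' the signal is mean-centered, cumulated, and the range of the cumulated
#' series `R_n` is divided by the population standard deviation `s_n`. The
#' default convention reads the estimator as `H = log(R_n / s_n) / log(n/2)`,
#' which sends white noise to about 0.5 and an integrated (random-walk)
#' signal towards 1, with EEG-like 1/f signals near 0.7 in between. The
#' `"sqrt-sigma"` convention divides the range by `sqrt(s_n)` instead and is
#' provided for comparison; it carries a signal-scale-dependent offset and
#' does not satisfy the white-noise anchor. The convention in force is
#' persisted with any trained model so training and prediction always agree.
#'
#' @param x Numeric signal vector, at least 4 samples.
#' @param convention `"rs"` (default) or `"sqrt-sigma"`.
#' @return The estimated exponent, or 0 (flagged degenerate upstream) for a
#'   flat signal.
#' @export
#' @examples
#' set.seed(1)
#' hurst_exponent(rnorm(4096))          # near 0.5
#' hurst_exponent(cumsum(rnorm(4096)))  # near 1
hurst_exponent <- function(x, convention = c("rs", "sqrt-sigma")) {
  convention <- match.arg(convention)
  n <- length(x)
  if (n < 4L) abort("Hurst exponent needs at least 4 samples.")
  mu <- mean(x)
  y <- x - mu
  z <- cumsum(y)
  rn <- max(z) - min(z)
  sn <- sqrt(mean(y^2))
  if (sn == 0 || rn == 0) return(0)
  den <- if (convention == "rs") sn else sqrt(sn)
  log(rn / den) / log(n / 2)
}

#' Kurtosis (standardized fourth moment)
#'
#' Non-excess sample kurtosis `m4 / m2^2` with population moments and no
#' small-sample bias correction; the Gaussian reference value is 3. Large
#' values indicate isolated outliers such as the sharp transients of an
#' intermittent electrical contact.
#'
#' @param x Numeric signal vector, at least 4 samples.
#' @return Kurtosis, or 0 (flagged degenerate upstream) for a flat signal.
#' @export
#' @examples
#' kurtosis(rep(c(-1, 1), 50))  # two-point distribution: 1
kurtosis <- function(x) {
  n <- length(x)
  if (n < 4L) abort("Kurtosis needs at least 4 samples.")
  y <- x - mean(x)
  m2 <- mean(y^2)
  if (m2 == 0) return(0)
  mean(y^4) / m2^2
}

#' Extract the seven-feature channel table
#'
#' Computes all features of [channel-features] for every channel of a
#' recording, in the fixed column order `corr, varn, devn, ampl, grad,
#' kurt, hurs`. When the recording carries expert labels, a `class` column
#' (`good` = 0, `bad` = 1, kept as the strings) is attached, giving the
#' classifier's 7-features-plus-class input contract. Degenerate channels
#' never drop out: the table always has one row per channel, with sentinel
#' values and per-cell flags retrievable via [feature_flags()].
#'
#' @param recording A [recording()].
#' @param nbhd Optional precomputed [build_neighborhoods()] map.
#' @param hurst_convention Passed to [hurst_exponent()]; recorded (with the
#'   kurtosis convention) in the table's `conventions` attribute, which
#'   trained models check at prediction time.
#' @return A tibble with columns `channel`, `label`, the seven features and
#'   optionally `class`; attributes `flags` (logical tibble of per-cell
#'   degeneracy) and `conventions`.
#' @export
#' @examples
#' run <- simulate_run(sim_config(n_shafts = 8, contacts_per_shaft = 5,
#'                                baseline = 2, stim_duration = 2, seed = 1))
#' extract_features(run)
extract_features <- function(recording, nbhd = NULL,
                             hurst_convention = c("rs", "sqrt-sigma")) {
  stopifnot(inherits(recording, "seeg_recording"))
  hurst_convention <- match.arg(hurst_convention)
  if (is.null(nbhd)) nbhd <- build_neighborhoods(recording)
  sig <- recording$signals
  n <- nrow(sig)

  # per-channel summaries shared across features
  mu <- rowMeans(sig)
  va <- apply(sig, 1L, var)
  rg <- apply(sig, 1L, function(x) max(x) - min(x))
  gr <- apply(sig, 1L, chan_grad)

  # per-shaft correlation blocks (only same-shaft pairs are ever needed)
  cormat <- matrix(NA_real_, n, n)
  for (s in unique(nbhd$shaft[nbhd$ok])) {
    idx <- which(nbhd$ok & nbhd$shaft == s)
    live <- idx[va[idx] > 0]
    if (length(live) >= 2L) {
      cormat[live, live] <- suppressWarnings(cor(t(sig[live, , drop = FALSE])))
    }
  }

  feat <- matrix(0, n, length(FEATURE_COLUMNS),
                 dimnames = list(NULL, FEATURE_COLUMNS))
  flags <- matrix(FALSE, n, length(FEATURE_COLUMNS),
                  dimnames = list(NULL, FEATURE_COLUMNS))
  for (i in seq_len(n)) {
    nb <- nbhd$neighbors[[i]]
    has_nb <- length(nb) > 0L

    if (!has_nb || va[i] == 0) {
      feat[i, "corr"] <- 0; flags[i, "corr"] <- TRUE
    } else {
      cv <- cormat[i, nb]
      cv <- cv[!is.na(cv)]
      if (length(cv) == 0L) { feat[i, "corr"] <- 0; flags[i, "corr"] <- TRUE }
      else feat[i, "corr"] <- mean(cv)
    }

    if (!has_nb) {
      feat[i, "varn"] <- if (va[i] <= 0) 0 else DEGENERATE_CAP
      flags[i, "varn"] <- TRUE
      feat[i, "devn"] <- 0; flags[i, "devn"] <- TRUE
      feat[i, "ampl"] <- if (rg[i] <= 0) 0 else DEGENERATE_CAP
      flags[i, "ampl"] <- TRUE
      feat[i, "grad"] <- if (gr[i] <= 0) 0 else DEGENERATE_CAP
      flags[i, "grad"] <- TRUE
    } else {
      rv <- ratio_or_cap(va[i], median(va[nb]))
      feat[i, "varn"] <- rv$value; flags[i, "varn"] <- rv$flag
      feat[i, "devn"] <- mu[i] - mean(mu[nb])
      ra <- ratio_or_cap(rg[i], median(rg[nb]))
      feat[i, "ampl"] <- ra$value; flags[i, "ampl"] <- ra$flag
      rgd <- ratio_or_cap(gr[i], median(gr[nb]))
      feat[i, "grad"] <- rgd$value; flags[i, "grad"] <- rgd$flag
    }

    if (va[i] == 0) {
      feat[i, "kurt"] <- 0; flags[i, "kurt"] <- TRUE
      feat[i, "hurs"] <- 0; flags[i, "hurs"] <- TRUE
    } else {
      feat[i, "kurt"] <- kurtosis(sig[i, ])
      feat[i, "hurs"] <- hurst_exponent(sig[i, ], convention = hurst_convention)
    }
  }

  out <- tibble::tibble(
    channel = seq_len(n),
    label = recording$channel_labels
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(feat))
  if (!is.null(recording$labels)) out$class <- recording$labels
  attr(out, "flags") <- tibble::as_tibble(flags)
  attr(out, "conventions") <- list(kurtosis = "moment", hurst = hurst_convention)
  out
}

#' Per-cell degeneracy flags of a feature table
#'
#' @param features A table from [extract_features()].
#' @return A logical tibble (channels x 7 features), or `NULL` if the table
#'   carries no flags (e.g. after round-tripping through CSV).
#' @export
feature_flags <- function(features) attr(features, "flags", exact = TRUE)
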