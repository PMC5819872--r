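#' Configuration of the synthetic SEEG generator
#'
#' The generator emulates referential-montage SEEG stimulation runs as
#' acquired during 1 Hz direct electrical stimulation: a baseline segment,
#' a train of biphasic stimulation pulses visible on every channel, and a
#' short tail after the last pulse. Good channels share a per-shaft 1/f
#' (pink) background mixed with channel-private pink noise so that adjacent
#' contacts on a shaft correlate at about `neighbor_correlation`, decaying
#' with contact distance; a faint amount of line noise is present on all
#' channels, as in real recordings. Bad channels follow three phenotypes:
#' `disconnected` (low-amplitude white noise, no physiological background,
#' only capacitively-coupled stimulation artifact), `line_noise` (good
#' background plus a dominant line-frequency sinusoid, at least 10x the
#' background power), and `intermittent` (good background plus sparse sharp
#' transients from a failing electrical contact). The two contacts of the
#' stimulation pair are always bad: they record the saturated rail-to-rail
#' stimulation signal, not brain activity. Phenotype severities are drawn
#' from wide ranges (faint line noise, rare faint transients) so that some
#' bad channels are genuinely hard and classification keeps improving with
#' more training subjects, as on clinical data.
#'
#' @param n_shafts Number of electrode shafts (clinical implants carry
#'   8-17).
#' @param contacts_per_shaft Contacts per shaft (5-18 clinically).
#' @param fs Sampling rate in Hz, one of 256, 512, 1024, 4096.
#' @param baseline Baseline duration before the first pulse, seconds
#'   (at most 40).
#' @param stim_duration Duration of the 1 Hz pulse train, seconds.
#' @param tail Seconds after the last pulse (3 in the acquisition
#'   protocol).
#' @param stim_rate Stimulation rate in Hz (1).
#' @param stim_pulse_width Per-phase pulse width in seconds (1-3 ms).
#' @param bad_fraction Fraction of channels made bad (excluding the
#'   stimulation pair), default 0.05.
#' @param bad_type_mix Named weights over the three phenotypes; must sum
#'   to 1.
#' @param line_freq Mains frequency in Hz (50 for European centers).
#' @param neighbor_correlation Target correlation of adjacent same-shaft
#'   good channels (default 0.6).
#' @param good_rms Typical good-channel RMS amplitude, microvolts.
#' @param saturation_rail Saturation rail of the amplifier, microvolts.
#' @param stim_artifact_amp Typical stimulation-artifact amplitude on
#'   non-stimulated channels, microvolts.
#' @param seed RNG seed used by [simulate_run()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_shafts = 10L, contacts_per_shaft = 12L, fs = 512,
                       baseline = 10, stim_duration = 10, tail = 3,
                       stim_rate = 1, stim_pulse_width = 0.002,
                       bad_fraction = 0.05,
                       bad_type_mix = c(disconnected = 1 / 3,
                                        line_noise = 1 / 3,
                                        intermittent = 1 / 3),
                       line_freq = 50, neighbor_correlation = 0.6,
                       good_rms = 50, saturation_rail = 3000,
                       stim_artifact_amp = 200, seed = 1L) {
  if (!fs %in% c(256, 512, 1024, 4096)) {
    abort("`fs` must be one of 256, 512, 1024, 4096 Hz (the acquisition envelope).")
  }
  if (baseline < 0 || baseline > 40) abort("`baseline` must be within [0, 40] s.")
  if (baseline + stim_duration + tail > 43) {
    abort("Total run duration must not exceed 43 s (40 s baseline + stimulation tail).")
  }
  if (bad_fraction < 0 || bad_fraction > 1) abort("`bad_fraction` must be in [0, 1].")
  if (abs(sum(bad_type_mix) - 1) > 1e-8) abort("`bad_type_mix` weights must sum to 1.")
  if (!all(names(bad_type_mix) %in% c("disconnected", "line_noise", "intermittent"))) {
    abort("`bad_type_mix` names must be disconnected, line_noise, intermittent.")
  }
  if (neighbor_correlation < 0 || neighbor_correlation >= 1) {
    abort("`neighbor_correlation` must be in [0, 1).")
  }
  if (n_shafts < 1 || n_shafts > 26) abort("`n_shafts` must be in 1..26.")
  if (contacts_per_shaft < 2) abort("`contacts_per_shaft` must be at least 2.")
  structure(
    list(
      n_shafts = as.integer(n_shafts),
      contacts_per_shaft = as.integer(contacts_per_shaft),
      fs = fs, baseline = baseline, stim_duration = stim_duration, tail = tail,
      stim_rate = stim_rate, stim_pulse_width = stim_pulse_width,
      bad_fraction = bad_fraction, bad_type_mix = bad_type_mix,
      line_freq = line_freq, neighbor_correlation = neighbor_correlation,
      good_rms = good_rms, saturation_rail = saturation_rail,
      stim_artifact_amp = stim_artifact_amp, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# 1/f (pink) noise of length n, unit RMS, via spectral shaping.
pink_noise <- function(n) {
  white <- rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))                 # avoid DC blowup
  f <- pmin(f, n - f + 1)                   # two-sided frequency index
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x / sqrt(mean(x^2))
}

# Subject-level state: montage, persistent bad channels and their severity.
draw_subject_state <- function(cfg) {
  shafts <- letters[seq_len(cfg$n_shafts)]
  addr <- expand.grid(contact = seq_len(cfg$contacts_per_shaft),
                      shaft = shafts, stringsAsFactors = FALSE)
  addr <- addr[order(match(addr$shaft, shafts), addr$contact), ]
  labels <- paste0(addr$shaft, addr$contact)
  n <- length(labels)

  n_bad <- round(cfg$bad_fraction * n)
  if (n_bad > n - 2L) abort("`bad_fraction` asks for more bad channels than available.")
  phenotype <- rep("good", n)
  if (n_bad > 0L) {
    idx <- sample.int(n, n_bad)
    kinds <- sample(names(cfg$bad_type_mix), n_bad, replace = TRUE,
                    prob = cfg$bad_type_mix)
    phenotype[idx] <- kinds
  }
  severity <- vector("list", n)
  for (i in seq_len(n)) {
    severity[i] <- list(switch(phenotype[[i]],
      disconnected = list(rms = runif(1, 2, 15),
                          stim_coupling = runif(1, 0.05, 0.2)),
      line_noise = list(power_ratio = 10^runif(1, 1, 2)),
      intermittent = list(rate = 10^runif(1, log10(0.05), 0),
                          amp = runif(1, 300, 3000) * sample(c(-1, 1), 1),
                          tau = runif(1, 0.005, 0.05)),
      NULL
    ))
  }
  list(
    shafts = shafts, addr = addr, labels = labels, n = n,
    phenotype = phenotype, severity = severity,
    subject_rms = runif(1, 0.7, 1.4) * cfg$good_rms,
    chan_gain = runif(n, 0.85, 1.15),
    good_line_ratio = 10^runif(n, -3, -1)   # faint mains on every channel
  )
}

# One stimulation run under an already-seeded RNG.
gen_run <- function(cfg, state, run_id = 1L) {
  n <- state$n
  ns <- round((cfg$baseline + cfg$stim_duration + cfg$tail) * cfg$fs)
  t <- (seq_len(ns) - 1L) / cfg$fs
  rho <- cfg$neighbor_correlation

  # shaft-shared background by recursive mixing of independent pink series:
  # adjacent-contact correlation rho, decaying as rho^distance
  sig <- matrix(0, n, ns)
  for (s in state$shafts) {
    idx <- which(state$addr$shaft == s)
    prev <- NULL
    for (i in idx) {
      e <- pink_noise(ns)
      cur <- if (is.null(prev)) e else rho * prev + sqrt(1 - rho^2) * e
      sig[i, ] <- cur
      prev <- cur
    }
  }
  rms <- state$subject_rms * state$chan_gain
  sig <- sig * rms

  # faint mains everywhere; group-level line_scale emulates center differences
  line_scale <- cfg$line_scale %||% 1
  phase <- runif(n, 0, 2 * pi)
  line_amp <- line_scale * rms * sqrt(2 * state$good_line_ratio)
  carrier <- 2 * pi * cfg$line_freq * t
  sig <- sig +
    t(vapply(seq_len(n), function(i) line_amp[i] * sin(carrier + phase[i]), numeric(ns)))

  # stimulation pulse train, biphasic, visible on every channel
  n_pulses <- max(0L, floor(cfg$stim_duration * cfg$stim_rate))
  w <- max(1L, round(cfg$stim_pulse_width * cfg$fs))
  pulse <- numeric(ns)
  if (n_pulses > 0L) {
    starts <- round((cfg$baseline + (seq_len(n_pulses) - 1L) / cfg$stim_rate) * cfg$fs) + 1L
    for (p in starts) {
      pos <- p:min(p + w - 1L, ns)
      neg <- (p + w):min(p + 2L * w - 1L, ns)
      pulse[pos] <- pulse[pos] + 1
      if (length(neg) && neg[1L] <= ns) pulse[neg] <- pulse[neg] - 1
    }
  }
  stim_gain <- runif(n, 0.5, 1.5) * cfg$stim_artifact_amp

  phenotype <- state$phenotype
  # stimulation pair for this run: two contiguous contacts on one shaft
  shaft <- sample(state$shafts, 1L)
  c0 <- sample.int(cfg$contacts_per_shaft - 1L, 1L)
  pair <- which(state$addr$shaft == shaft & state$addr$contact %in% c(c0, c0 + 1L))
  phenotype[pair] <- "stim_channel"

  for (i in seq_len(n)) {
    sv <- state$severity[[i]]
    sig[i, ] <- switch(phenotype[[i]],
      good = sig[i, ] + stim_gain[i] * pulse,
      line_noise = sig[i, ] + stim_gain[i] * pulse +
        line_scale * rms[i] * sqrt(2 * sv$power_ratio) * sin(carrier + runif(1, 0, 2 * pi)),
      intermittent = {
        x <- sig[i, ] + stim_gain[i] * pulse
        n_ev <- rpois(1L, sv$rate * ns / cfg$fs)
        if (n_ev > 0L) {
          t0 <- sort(runif(n_ev, 0, ns / cfg$fs))
          for (tt in t0) {
            k0 <- floor(tt * cfg$fs) + 1L
            klen <- min(ns - k0 + 1L, ceiling(10 * sv$tau * cfg$fs))
            kk <- k0:(k0 + klen - 1L)
            x[kk] <- x[kk] + sv$amp * exp(-(kk - k0) / (sv$tau * cfg$fs))
          }
        }
        x
      },
      disconnected = sv$rms * rnorm(ns) + sv$stim_coupling * stim_gain[i] * pulse,
      stim_channel = {
        # amplifier input driven past its rails by the stimulator
        drive <- 50 * sig[i, ] + 100 * cfg$saturation_rail * pulse
        pmax(pmin(drive, cfg$saturation_rail), -cfg$saturation_rail)
      }
    )
  }

  labels <- ifelse(phenotype == "good", "good", "bad")
  recording(
    sig, cfg$fs, state$labels, labels = labels,
    meta = list(
      run = run_id,
      phenotype = phenotype,
      stim_pair = state$labels[pair],
      config = cfg
    )
  )
}

#' Simulate one SEEG stimulation run
#'
#' Generates a labeled referential-montage recording under the model
#' described in [sim_config()]. The returned recording carries ground-truth
#' `good`/`bad` labels and a per-channel phenotype tag in
#' `meta$phenotype` (one of `good`, `disconnected`, `line_noise`,
#' `intermittent`, `stim_channel`); the two stimulation-pair contacts are
#' always labeled bad.
#'
#' @param config A [sim_config()]; its `seed` makes the run reproducible.
#' @return A labeled [recording()].
#' @export
#' @examples
#' run <- simulate_run(sim_config(n_shafts = 8, contacts_per_shaft = 5,
#'                                baseline = 2, stim_duration = 2, seed = 42))
#' table(run$meta$phenotype)
simulate_run <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    state <- draw_subject_state(config)
    gen_run(config, state)
  })
}

#' Simulate all stimulation runs of one subject
#'
#' A subject has one implantation: the montage, the set of persistently bad
#' channels and their severities are drawn once and shared by all runs,
#' while noise, transient timings and the stimulation pair are redrawn per
#' run (the pair rotates across runs, as stimulation sites do clinically).
#'
#' @param config A [sim_config()].
#' @param n_runs Number of stimulation runs.
#' @param seed Subject-level seed (defaults to the config seed).
#' @return A list of labeled [recording()]s sharing one montage.
#' @export
simulate_subject <- function(config, n_runs = 5L, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (n_runs < 1L) abort("`n_runs` must be at least 1.")
  withr::with_seed(seed, {
    state <- draw_subject_state(config)
    lapply(seq_len(n_runs), function(r) gen_run(config, state, run_id = r))
  })
}

# Per-group nuisance parameters emulating inter-center variability.
draw_group_params <- function(tags, cfg, seed) {
  withr::with_seed(seed, {
    lapply(seq_along(tags), function(g) {
      list(
        fs = sample(c(256, 512, 1024, 4096), 1L),
        neighbor_correlation = runif(1, 0.45, 0.7),
        line_scale = 10^runif(1, -0.5, 0.5)
      )
    }) |> stats::setNames(tags)
  })
}

resolve_groups <- function(n_subjects, group_tags) {
  if (is.null(group_tags)) return(rep("POOL", n_subjects))
  if (!is.null(names(group_tags)) && is.numeric(group_tags)) {
    if (sum(group_tags) != n_subjects) {
      abort("Named `group_tags` counts must sum to `n_subjects`.")
    }
    return(rep(names(group_tags), times = group_tags))
  }
  rep_len(as.character(group_tags), n_subjects)
}

#' Simulate a multi-subject (multi-center) cohort
#'
#' Subjects are partitioned into tagged groups emulating acquisition
#' centers; each group gets its own nuisance parameters (sampling rate
#' drawn from 256/512/1024/4096 Hz, neighbor correlation, line-noise
#' scale) so that cross-group robustness can be evaluated. With
#' `group_tags = NULL` all subjects form a single homogeneous group using
#' `config` as-is.
#'
#' @param config A [sim_config()] used as the base for every group.
#' @param n_subjects Number of subjects.
#' @param group_tags `NULL`, a character vector of group names (subjects
#'   are spread evenly), or a named integer vector of per-group subject
#'   counts.
#' @param runs_per_subject Stimulation runs per subject (default 5, a
#'   desk-scale stand-in for the dozens of runs of a clinical stimulation
#'   session).
#' @param seed Master seed; every subject gets a derived child seed.
#' @return A `badchan_cohort` tibble with columns `subject`, `group` and a
#'   list-column `runs` of labeled recordings.
#' @seealso [simulate_cohort_features()] for the memory-light variant that
#'   keeps only channel features.
#' @export
simulate_cohort <- function(config, n_subjects, group_tags = NULL,
                            runs_per_subject = 5L, seed = config$seed) {
  plan <- cohort_plan(config, n_subjects, group_tags, seed)
  runs <- purrr::map(seq_len(n_subjects), function(i) {
    cfg_i <- plan$configs[[i]]
    rs <- simulate_subject(cfg_i, n_runs = runs_per_subject,
                           seed = plan$subject_seeds[[i]])
    lapply(rs, function(r) {
      r$meta$subject <- i
      r$meta$group <- plan$groups[[i]]
      r
    })
  })
  out <- tibble::tibble(subject = seq_len(n_subjects), group = plan$groups,
                        runs = runs)
  class(out) <- c("badchan_cohort", class(out))
  attr(out, "seed") <- seed
  out
}

cohort_plan <- function(config, n_subjects, group_tags, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (n_subjects < 1L) abort("`n_subjects` must be at least 1.")
  groups <- resolve_groups(n_subjects, group_tags)
  tags <- unique(groups)
  seeds <- derive_seeds(seed, n_subjects + 1L)
  gp <- if (is.null(group_tags)) NULL else draw_group_params(tags, config, seeds[[n_subjects + 1L]])
  configs <- lapply(seq_len(n_subjects), function(i) {
    if (is.null(gp)) return(config)
    p <- gp[[groups[[i]]]]
    cfg <- config
    cfg$fs <- p$fs
    cfg$neighbor_correlation <- p$neighbor_correlation
    cfg$line_scale <- p$line_scale
    cfg
  })
  list(groups = groups, subject_seeds = seeds[seq_len(n_subjects)],
       configs = configs)
}

#' Extract features from every run of a cohort
#'
#' @param cohort A [simulate_cohort()] result.
#' @param ... Passed to [extract_features()].
#' @return A tibble of per-channel features with `subject`, `group`, `run`,
#'   `phenotype` and `class` columns.
#' @export
extract_cohort_features <- function(cohort, ...) {
  purrr::pmap(
    list(cohort$subject, cohort$group, cohort$runs),
    function(subject, group, runs) {
      purrr::map(runs, function(r) {
        ft <- extract_features(r, ...)
        conv <- attr(ft, "conventions")
        ft <- dplyr::mutate(ft, subject = subject, group = group,
                            run = r$meta$run, phenotype = r$meta$phenotype,
                            .before = 1)
        attr(ft, "conventions") <- conv
        ft
      }) |> bind_feature_rows()
    }
  ) |> bind_feature_rows()
}

# bind_rows drops attributes; keep the conventions contract
bind_feature_rows <- function(tabs) {
  conv <- attr(tabs[[1L]], "conventions", exact = TRUE)
  out <- dplyr::bind_rows(tabs)
  attr(out, "conventions") <- conv
  out
}

#' Simulate a cohort and keep only its channel features
#'
#' Equivalent to `extract_cohort_features(simulate_cohort(...))` but
#' generates and discards each subject's signals in turn, so cohorts of
#' hundreds of subjects fit in memory. Used by the learning-curve and
#' robustness protocols.
#'
#' @inheritParams simulate_cohort
#' @param ... Passed to [extract_features()].
#' @return The feature tibble of [extract_cohort_features()].
#' @export
simulate_cohort_features <- function(config, n_subjects, group_tags = NULL,
                                     runs_per_subject = 5L,
                                     seed = config$seed, ...) {
  plan <- cohort_plan(config, n_subjects, group_tags, seed)
  tabs <- purrr::map(seq_len(n_subjects), function(i) {
    runs <- simulate_subject(plan$configs[[i]], n_runs = runs_per_subject,
                             seed = plan$subject_seeds[[i]])
    purrr::map(runs, function(r) {
      ft <- extract_features(r, ...)
      conv <- attr(ft, "conventions")
      ft <- dplyr::mutate(ft, subject = i, group = plan$groups[[i]],
                          run = r$meta$run, phenotype = r$meta$phenotype,
                          .before = 1)
      attr(ft, "conventions") <- conv
      ft
    }) |> bind_feature_rows()
  })
  bind_feature_rows(tabs)
}
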