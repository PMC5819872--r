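test_that("a seeded run is reproducible bit for bit", {
  a <- simulate_run(test_config(seed = 7))
  b <- simulate_run(test_config(seed = 7))
  expect_identical(a$signals, b$signals)
  expect_identical(a$labels, b$labels)
  expect_identical(a$meta$phenotype, b$meta$phenotype)
  c <- simulate_run(test_config(seed = 8))
  expect_false(identical(a$signals, c$signals))
})

test_that("with bad_fraction 0 only the stimulation pair is bad", {
  run <- simulate_run(test_config(seed = 9, bad_fraction = 0))
  expect_equal(sum(run$labels == "bad"), 2)
  expect_setequal(run$channel_labels[run$labels == "bad"], run$meta$stim_pair)
  expect_true(all(run$meta$phenotype[run$labels == "bad"] == "stim_channel"))
  # the pair is contiguous on one shaft
  pr <- parse_channel_labels(run$meta$stim_pair)
  expect_equal(length(unique(pr$shaft)), 1L)
  expect_equal(abs(diff(pr$contact)), 1L)
})

test_that("asking for more bad channels than available is a config error", {
  expect_error(simulate_run(test_config(seed = 1, bad_fraction = 0.99)),
               "more bad channels")
  expect_error(sim_config(bad_fraction = 1.2), "bad_fraction")
  expect_error(sim_config(fs = 300), "256")
  expect_error(sim_config(baseline = 41), "40")
  expect_error(sim_config(bad_type_mix = c(disconnected = 0.5, line_noise = 0.2,
                                           intermittent = 0.2)), "sum to 1")
})

test_that("adjacent good channels hit the configured correlation target", {
  cfg <- sim_config(baseline = 37, stim_duration = 3, tail = 3, seed = 15)
  run <- simulate_run(cfg)
  nb <- build_neighborhoods(run)
  good <- which(run$meta$phenotype == "good")
  vals <- c()
  for (i in good) {
    adj <- intersect(nb$neighbors[[i]], good)
    adj <- adj[abs(nb$contact[adj] - nb$contact[i]) == 1 & adj > i]
    for (j in adj) vals <- c(vals, cor(run$signals[i, ], run$signals[j, ]))
  }
  expect_lt(abs(mean(vals) - cfg$neighbor_correlation), 0.1)
})

test_that("a subject's montage and persistent bad channels persist across runs", {
  runs <- simulate_subject(test_config(seed = 16), n_runs = 6)
  labs <- runs[[1]]$channel_labels
  for (r in runs) expect_identical(r$channel_labels, labs)
  persistent <- function(r) r$channel_labels[
    r$meta$phenotype %in% c("disconnected", "line_noise", "intermittent")]
  # the persistent set is fixed; a run may mask a member while stimulating it
  base <- unique(unlist(lapply(runs, persistent)))
  for (r in runs) {
    expect_true(all(setdiff(base, r$meta$stim_pair) %in% persistent(r)))
  }
  # the stimulation pair rotates and is bad only in its own run
  pairs <- lapply(runs, function(r) sort(r$meta$stim_pair))
  expect_gt(length(unique(pairs)), 1L)
  for (k in seq_along(runs)) {
    others <- setdiff(unlist(pairs[-k]), c(pairs[[k]], base))
    expect_true(all(runs[[k]]$labels[match(others, labs)] == "good"))
  }
})

test_that("many-run subjects share one montage", {
  runs <- simulate_subject(sim_config(n_shafts = 8, contacts_per_shaft = 5,
                                      fs = 256, baseline = 1, stim_duration = 1,
                                      tail = 0.5, seed = 17), n_runs = 51)
  expect_length(runs, 51)
  expect_length(unique(lapply(runs, function(r) r$channel_labels)), 1L)
})

test_that("cohorts are grouped, seeded, and group parameters stay in envelope", {
  tags <- c(BUC = 2L, GRE = 3L, LYO = 1L, NAN = 2L, ROT = 2L)
  cohort <- simulate_cohort(test_config(seed = 18), n_subjects = 10,
                            group_tags = tags, runs_per_subject = 1)
  expect_equal(as.integer(table(cohort$group)[names(tags)]), as.integer(tags))
  fss <- vapply(cohort$runs, function(rs) rs[[1]]$fs, 1)
  expect_true(all(fss %in% c(256, 512, 1024, 4096)))
  cohort2 <- simulate_cohort(test_config(seed = 18), n_subjects = 10,
                             group_tags = tags, runs_per_subject = 1)
  expect_identical(cohort$runs[[4]][[1]]$signals, cohort2$runs[[4]][[1]]$signals)
  expect_error(simulate_cohort(test_config(), 5, group_tags = c(A = 2L, B = 2L)),
               "sum to")
})

test_that("streamed cohort features equal extract-after-simulate", {
  cfg <- test_config(seed = 19)
  direct <- simulate_cohort_features(cfg, n_subjects = 3, runs_per_subject = 2,
                                     seed = 77)
  cohort <- simulate_cohort(cfg, n_subjects = 3, runs_per_subject = 2, seed = 77)
  via <- extract_cohort_features(cohort)
  expect_equal(direct, via, ignore_attr = TRUE)
})

test_that("phenotypes leave their expected feature signatures", {
  feats <- simulate_cohort_features(test_config(seed = 20), n_subjects = 8,
                                    runs_per_subject = 3, seed = 20)
  by_type <- function(f, type) feats[[f]][feats$phenotype == type]
  good_mean <- function(f) mean(feats[[f]][feats$phenotype == "good"])
  expect_lt(abs(mean(by_type("corr", "disconnected"))), 0.12)
  expect_gt(mean(by_type("varn", "line_noise")), 2 * good_mean("varn"))
  expect_gt(mean(by_type("grad", "line_noise")), 2 * good_mean("grad"))
  expect_gt(mean(by_type("kurt", "intermittent")), good_mean("kurt"))
  expect_gt(mean(by_type("ampl", "stim_channel")), 5 * good_mean("ampl"))
})
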