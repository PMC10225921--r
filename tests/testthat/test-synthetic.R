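test_that("degenerate rate sets produce degenerate streams and spec errors", {
  spec <- cohort_spec()
  lex <- default_lexicon()
  rates <- list(patient = c(i = 100, we = 0, you = 0, shehe = 0, they = 0,
                            nonfluent = 0),
                therapist = spec$rates$therapist)
  tr <- generate_transcript(spec, "d1", rates = rates,
                            aux_target = c(patient = 0, therapist = 0.005),
                            seed = 2)
  pat <- token_stream(tr, "patient")$token
  expect_true(all(pat %in% lex$i))

  expect_error(cohort_spec(rates = list(
    patient = c(i = 60, we = 50, you = 0, shehe = 0, they = 0, nonfluent = 0),
    therapist = spec$rates$therapist)), "infeasible")
})

test_that("emitted category rates land within binomial tolerance of the target", {
  spec <- cohort_spec()
  rates <- list(patient = c(i = 5, we = 1, you = 2, shehe = 1, they = 1,
                            nonfluent = 20),
                therapist = spec$rates$therapist)
  tr <- generate_transcript(spec, "d1", rates = rates,
                            n_tokens = c(patient = 10000, therapist = 100),
                            seed = 3)
  p <- category_percents(token_stream(tr, "patient"))
  se <- 100 * sqrt(0.2 * 0.8 / 10000)
  expect_lt(abs(p[["nonfluent"]] - 20), 3 * se)
})

test_that("transcript generation is deterministic under a fixed seed", {
  spec <- cohort_spec()
  t1 <- generate_transcript(spec, "d1", seed = 7)
  t2 <- generate_transcript(spec, "d1", seed = 7)
  expect_identical(write_transcript(t1), write_transcript(t2))
  expect_identical(t1$utterances$gold_tags, t2$utterances$gold_tags)
})

test_that("generated transcripts survive a serialization round trip cleanly", {
  tr <- generate_transcript(cohort_spec(), "d9", seed = 11)
  reparsed <- preprocess_transcript(
    parse_transcript(write_transcript(tr), "prefixed_lines", dyad_id = "d9"))
  expect_identical(reparsed$utterances$tokens, tr$utterances$tokens)
  expect_identical(reparsed$utterances$speaker_role, tr$utterances$speaker_role)
})

test_that("planted outcomes recover exactly at zero noise and stay constant at zero slopes", {
  co <- generate_cohort(cohort_spec(n_dyads = 12), seed = 21)
  flat <- cohort_spec(n_dyads = 12, slopes = c(patient_i_log = 0),
                      alliance_noise_sd = 0,
                      mediation = c(a = 0, b = 0, c_prime = 0), rf_sd = 0,
                      subscore_sd = 0, bond_shift = c(patient_i_log = 0))
  out0 <- plant_outcomes(co$features, flat, seed = 1)
  expect_true(all(out0$alliance_total == out0$alliance_total[1]))

  planted <- cohort_spec(n_dyads = 12, slopes = c(therapist_i_log = -5),
                         alliance_noise_sd = 0,
                         mediation = c(a = 0, b = 0, c_prime = 0), rf_sd = 0)
  out1 <- plant_outcomes(co$features, planted, seed = 1)
  fit <- univariate_f_regression(co$features$therapist_i_log,
                                 out1$alliance_total)
  expect_equal(fit$estimate, -5, tolerance = 1e-10)
})

test_that("a planted correlation of -0.6 at n=28 is recovered on average", {
  # slope and noise chosen so slope*sd(x) / sd(y) is about -0.6 given the
  # patient i log-feature's dispersion (rate jitter 0.25 plus counting noise)
  spec <- cohort_spec(slopes = c(patient_i_log = -5),
                      alliance_noise_sd = 1.78,
                      mediation = c(a = 0, b = 0, c_prime = 0), rf_sd = 0)
  rs <- vapply(1:100, function(s) {
    co <- generate_cohort(spec, seed = 1000 + s)
    cor(co$features$patient_i_log, co$outcomes$alliance_total)
  }, numeric(1))
  expect_lt(abs(mean(rs) - (-0.6)), 0.1)
})

test_that("cohort bundles are self-consistent and regenerate from the manifest", {
  spec <- cohort_spec(n_dyads = 28)
  co <- generate_cohort(spec, seed = 42)
  expect_equal(nrow(co$features), 28)
  expect_equal(nrow(co$outcomes), 28)

  # self-consistency: re-running extraction reproduces the stored features
  re <- extract_features(co$transcripts, tagger = "gold")
  expect_identical(re, co$features)

  # manifest round trip: same spec + seed regenerates the identical bundle
  co2 <- generate_cohort(co$manifest$spec, seed = co$manifest$seed)
  expect_identical(co2$features, co$features)
  expect_identical(co2$outcomes, co$outcomes)

  # alliance respects the instrument bounds; sessions conserve units
  expect_true(all(co$outcomes$alliance_total >= 12 &
                    co$outcomes$alliance_total <= 84))
  for (s in co$sessions)
    expect_equal(s$kept_total + sum(s$rounds$R), sum(3 * s$rounds$I))
  # realized session means track the planted repayment targets
  expect_lt(max(abs(co$outcomes$mean_RF_patient -
                      co$outcomes$rf_target_patient)), 0.05)
})

test_that("cohort-level category rates match the spec targets within 3 standard errors", {
  spec <- cohort_spec(n_dyads = 200)
  co <- generate_cohort(spec, seed = 77)
  for (role in c("patient", "therapist")) {
    for (cat in names(spec$rates[[role]])) {
      v <- co$features[[paste0(role, "_", cat)]]
      se <- sd(v) / sqrt(length(v))
      expect_lt(abs(mean(v) - spec$rates[[role]][[cat]]), 3 * se + 1e-8,
                label = paste(role, cat))
    }
  }
  # AUX-INTJ transition targets are hit as well
  for (role in c("patient", "therapist")) {
    v <- co$features[[paste0(role, "_AUX-INTJ")]]
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - spec$aux_intj_target[[role]]), 3 * se)
  }
})
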