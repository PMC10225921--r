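#!/usr/bin/env Rscript
# Stage 4: quasi-Bayesian mediation.
#
# Tests whether the patient's mean trust-game repayment fraction mediates
# the association between the therapist's first-person pronoun log-features
# and patient-rated alliance: 1,000 coefficient draws from the asymptotic
# normal of the two path fits, percentile interval on the a*b product, and
# the full-mediation significance rule (indirect interval excludes zero,
# total effect significant, direct effect not). Writes mediation.csv.

suppressPackageStartupMessages(library(alliancelang))

features <- read.csv("results/features.csv", check.names = FALSE)
outcomes <- read.csv("results/cohort/outcomes.csv", check.names = FALSE)
d <- merge(features, outcomes, by = "dyad_id")

rows <- list()
for (f in c("therapist_i_log", "therapist_we_log")) {
  md <- mediate(d[[f]], d$mean_RF_patient, d$alliance_total,
                iterations = 1000, seed = 20234, feature = f)
  print(md)
  rows[[f]] <- data.frame(feature = f, a = md$a, b = md$b, c = md$c,
                          c_prime = md$c_prime, indirect = md$indirect,
                          ci_low = md$ci_low, ci_high = md$ci_high,
                          p_indirect = md$p_indirect,
                          significant = md$significant)
}
write.csv(do.call(rbind, rows), "results/mediation.csv", row.names = FALSE)
message("wrote results/mediation.csv")
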