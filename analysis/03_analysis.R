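#!/usr/bin/env Rscript
# Stage 3: the statistical analysis.
#
# Joins the extracted features to the planted outcomes and runs the full
# layer: mass-univariate F-regressions of every feature on patient-rated
# alliance with Benjamini-Hochberg FDR, speaker-role comparisons (paired t
# on log dictionary features, Wilcoxon signed-rank on the skewed transition
# features), trust-game correlations, the treatment-duration-partialled
# Spearman correlation for patient AUX-INTJ, Steiger's Z across the
# goal/task/bond subscores, and Kruskal-Wallis across categorical
# covariates. Writes report.csv / report.json under results/.

suppressPackageStartupMessages(library(alliancelang))

features <- read.csv("results/features.csv", check.names = FALSE)
outcomes <- read.csv("results/cohort/outcomes.csv", check.names = FALSE)
cfg <- run_config(seed = 20233)

report <- run_analysis(features, outcomes, cfg)
write_report(report, "results")

reg <- report$regressions
sig <- reg[!is.na(reg$q) & reg$q < 0.05, ]
message(sprintf("%d of %d feature~alliance regressions FDR-significant:",
                nrow(sig), sum(!is.na(reg$p))))
for (i in seq_len(nrow(sig)))
  message(sprintf("  %-28s slope %8.3f  F = %6.2f  q = %.4f",
                  sig$feature[i], sig$estimate[i], sig$statistic[i], sig$q[i]))

rc <- report$role_comparisons
for (f in c("i", "we"))
  message(sprintf("role difference, %-3s (log %%): t = %6.2f, p = %.2g",
                  f, rc$statistic[rc$feature == f], rc$p[rc$feature == f]))

gc <- report$game_correlations
for (i in seq_len(nrow(gc)))
  message(sprintf("%-36s r = %6.3f  p = %.3g", gc$feature[i],
                  gc$estimate[i], gc$p[i]))
message(sprintf("partial (duration-controlled) %s: rho = %.3f, p = %.3g",
                report$partial$feature, report$partial$estimate,
                report$partial$p))
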