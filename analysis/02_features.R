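#!/usr/bin/env Rscript
# Stage 2: extract language features from the transcript files.
#
# Reads the prefixed-lines transcripts written by stage 1 the same way real
# session files would be read, and extracts the per-dyad feature table:
# dictionary category percentages (raw and log), the 33 interjection-
# adjacent transition features per role via the built-in rule tagger, and
# pronoun-anchored word bigrams. Dictionary features are tagger-independent
# and must agree exactly with the generation-time truth; transition
# features may differ slightly from the gold-tag truth where the rule
# tagger's filler-context rule fires on emitted (non-inserted) tokens.

suppressPackageStartupMessages(library(alliancelang))

paths <- list.files("results/cohort/transcripts", full.names = TRUE)
res <- run_features(paths, run_config(tagger = "rule"))
if (length(res$errors)) {
  message("files failing to parse:")
  for (nm in names(res$errors)) message("  ", nm, ": ", res$errors[nm])
}
write.csv(res$features, "results/features.csv", row.names = FALSE)

truth <- read.csv("results/cohort/features_truth.csv", check.names = FALSE)
lex_cols <- grep("^(patient|therapist)_[a-z]+$", names(truth), value = TRUE)
agree <- max(abs(as.matrix(res$features[lex_cols]) - as.matrix(truth[lex_cols])))
message(sprintf("extracted %d features for %d dyads", ncol(res$features) - 1,
                nrow(res$features)))
message(sprintf("max |file-based - truth| over dictionary percentages: %.3g",
                agree))
trans <- grep("AUX-INTJ$", names(truth), value = TRUE)
for (col in trans)
  message(sprintf("%s: rule-tagged mean %.5f vs gold %.5f", col,
                  mean(res$features[[col]]), mean(truth[[col]])))
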