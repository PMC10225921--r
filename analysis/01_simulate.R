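#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic 28-dyad cohort.
#
# Real psychotherapy transcripts are IRB-protected, so the whole analysis
# runs on a synthetic cohort with known planted structure: per-role
# dictionary rates centred on the reported cohort means, a planted
# mediation chain (therapist first-person-singular -> patient repayment ->
# alliance), and a simulated 10-round trust game per dyad. Writes the
# transcripts, outcomes, and game logs under results/cohort/.

suppressPackageStartupMessages(library(alliancelang))

seed <- 20230
out_dir <- "results/cohort"
dir.create(file.path(out_dir, "transcripts"), showWarnings = FALSE,
           recursive = TRUE)

spec <- cohort_spec()
co <- generate_cohort(spec, seed = seed)

for (id in names(co$transcripts))
  write_transcript(co$transcripts[[id]],
                   file.path(out_dir, "transcripts", paste0(id, ".txt")))

write.csv(co$outcomes, file.path(out_dir, "outcomes.csv"), row.names = FALSE)
write.csv(co$features, file.path(out_dir, "features_truth.csv"),
          row.names = FALSE)

game <- do.call(rbind, lapply(co$sessions, function(s)
  cbind(dyad_id = s$dyad_id, s$rounds)))
write.csv(game, file.path(out_dir, "trust_game_rounds.csv"), row.names = FALSE)

jsonlite::write_json(list(seed = seed, n_dyads = spec$n_dyads,
                          generated = nrow(co$features)),
                     file.path(out_dir, "manifest.json"), auto_unbox = TRUE)

message(sprintf("simulated %d dyads (seed %d)", nrow(co$features), seed))
message(sprintf("cohort means: patient_i %.2f%%, therapist_i %.2f%%, therapist_we %.2f%%",
                mean(co$features$patient_i), mean(co$features$therapist_i),
                mean(co$features$therapist_we)))
message(sprintf("mean patient repayment fraction %.3f; alliance mean %.1f (range %.0f-%.0f)",
                mean(co$outcomes$mean_RF_patient),
                mean(co$outcomes$alliance_total),
                min(co$outcomes$alliance_total),
                max(co$outcomes$alliance_total)))
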