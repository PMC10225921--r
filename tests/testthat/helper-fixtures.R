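# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

make_transcript <- function(lines, dyad_id = "t1") {
  preprocess_transcript(parse_transcript(lines, "prefixed_lines",
                                         dyad_id = dyad_id))
}

# A minimal two-role transcript used where content does not matter.
tiny_transcript <- function() {
  make_transcript(c("PATIENT: i was like, um, fine.",
                    "THERAPIST: let's talk about that.",
                    "PATIENT: when i talk to you i feel better."))
}

# Random token stream over a small vocabulary, as a plain character vector.
random_tokens <- function(n, vocab = c("i", "we", "um", "like", "the",
                                       "cat", "sat", "go", "let's", "fine")) {
  sample(vocab, n, replace = TRUE)
}

# Random UPOS tag sequence as a single-role tagged data frame.
random_tagged <- function(n, role = "patient",
                          tags = c("PRON", "AUX", "INTJ", "VERB", "NOUN",
                                   "ADV", "SCONJ", "DET")) {
  data.frame(token = paste0("w", seq_len(n)),
             tag = sample(tags, n, replace = TRUE),
             speaker_role = role,
             utterance_index = 0L,
             stringsAsFactors = FALSE)
}
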