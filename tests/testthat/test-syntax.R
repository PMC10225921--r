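test_that("rule tagger handles fillers, contexts and unknowns", {
  expect_equal(rule_tagger("um"), "INTJ")
  expect_equal(rule_tagger(c("i", "was", "like")), c("PRON", "AUX", "INTJ"))
  expect_equal(rule_tagger(c("just", "like")), c("ADV", "INTJ"))
  expect_equal(rule_tagger(c("i", "like", "cats")), c("PRON", "VERB", "X"))
  expect_equal(rule_tagger("zzzqx"), "X")
  expect_equal(rule_tagger(c("slowly", "walking", "kindness", "42")),
               c("ADV", "VERB", "NOUN", "NUM"))
})

test_that("tagged sequences keep one tag per token inside the UPOS inventory", {
  tr <- tiny_transcript()
  seq <- tag_stream(token_stream(tr, "dialogue"))
  expect_equal(nrow(seq), nrow(token_stream(tr, "dialogue")))
  expect_true(all(seq$tag %in% upos_tagset()))
  expect_error(tag_stream(token_stream(tr, "patient"),
                          tagger = function(x) "PRON"), "tagger returned")
  expect_error(tag_stream(token_stream(tr, "patient"),
                          tagger = function(x) rep("WORD", length(x))),
               "outside the UPOS inventory")
})

test_that("joint and conditional transition probabilities match hand counts", {
  seq <- data.frame(token = c("a", "b", "c", "d"),
                    tag = c("PRON", "AUX", "INTJ", "PRON"),
                    speaker_role = "patient", utterance_index = 0L)
  mj <- transition_matrix(seq, "joint")
  expect_equal(mj$total_bigrams, 3)
  expect_equal(mj$probabilities["AUX", "INTJ"], 1 / 3)
  expect_equal(mj$probabilities["INTJ", "PRON"], 1 / 3)
  expect_equal(sum(mj$probabilities), 1)

  mc <- transition_matrix(seq, "conditional")
  expect_equal(mc$probabilities["AUX", "INTJ"], 1)
  expect_error(transition_matrix(seq[1, ], "joint"), "too short")
})

test_that("dialogue-first-token attribution assigns talk-turn pairs to the first speaker", {
  tr <- make_transcript(c("PATIENT: as i can", "THERAPIST: yeah"))
  seq <- tag_stream(token_stream(tr, "dialogue"))
  # "can"(AUX) -> "yeah"(INTJ) crosses the turn; first token is the patient's
  mp <- transition_matrix(seq, "joint", "dialogue_first_token", role = "patient")
  expect_equal(mp$counts["AUX", "INTJ"], 1L)
  expect_equal(mp$total_bigrams, 3L)  # as-i, i-can, can-yeah
  # the per-speaker view of the patient has no AUX-INTJ pair
  ms <- transition_matrix(seq, "joint", "per_speaker", role = "patient")
  expect_equal(ms$counts["AUX", "INTJ"], 0L)
  expect_equal(ms$total_bigrams, 2L)
})

test_that("per-speaker pairs span the speaker's own consecutive utterances", {
  tr <- make_transcript(c("PATIENT: i can", "PATIENT: um yes"))
  seq <- tag_stream(token_stream(tr, "patient"))
  m <- transition_matrix(seq, "joint")
  expect_equal(m$counts["AUX", "INTJ"], 1L)  # can|um across the boundary
  expect_equal(m$total_bigrams, 3L)
})

test_that("transition counts match a naive double-loop counter on random sequences", {
  set.seed(31)
  tagset <- upos_tagset()
  for (rep in 1:100) {
    n <- sample(2:1000, 1)
    seq <- random_tagged(n, tags = sample(tagset, sample(3:17, 1)))
    m <- transition_matrix(seq, "joint")
    naive <- matrix(0L, 17, 17, dimnames = list(from = tagset, to = tagset))
    for (i in seq_len(n - 1)) {
      naive[seq$tag[i], seq$tag[i + 1]] <- naive[seq$tag[i], seq$tag[i + 1]] + 1L
    }
    expect_identical(m$counts, naive)
    expect_equal(m$total_bigrams, n - 1)
    expect_equal(sum(m$probabilities), 1)
  }
})

test_that("joint cells equal conditional times marginal", {
  set.seed(32)
  for (rep in 1:20) {
    seq <- random_tagged(sample(10:300, 1))
    mj <- transition_matrix(seq, "joint")
    mc <- transition_matrix(seq, "conditional")
    marg <- rowSums(mj$counts) / mj$total_bigrams
    expect_equal(mj$probabilities, mc$probabilities * marg,
                 tolerance = 1e-12)
  }
})

test_that("interjection features flatten the INTJ row and column, zeros included", {
  seq <- data.frame(token = c("is", "like"), tag = c("AUX", "INTJ"),
                    speaker_role = "patient", utterance_index = 0L)
  f <- interjection_features(transition_matrix(seq, "joint"))
  expect_length(f, 33)  # 17 X-INTJ + 16 INTJ-Y
  expect_equal(unname(f["patient_AUX-INTJ"]), 1)
  expect_equal(sum(f), 1)

  f0 <- interjection_features(transition_matrix(
    random_tagged(50, tags = c("NOUN", "VERB")), "joint"))
  expect_true(all(f0 == 0))
})

test_that("interjection features equal brute-force pair proportions on a long sequence", {
  set.seed(33)
  seq <- random_tagged(500)
  f <- interjection_features(transition_matrix(seq, "joint"))
  pairs <- paste(seq$tag[-500], seq$tag[-1])
  for (x in upos_tagset()) {
    expect_equal(unname(f[paste0("patient_", x, "-INTJ")]),
                 sum(pairs == paste(x, "INTJ")) / 499)
    if (x != "INTJ")
      expect_equal(unname(f[paste0("patient_INTJ-", x)]),
                   sum(pairs == paste("INTJ", x)) / 499)
  }
})

test_that("gold tags pass through unchanged", {
  tr <- generate_transcript(cohort_spec(), "g1", seed = 5)
  st <- token_stream(tr, "patient")
  expect_identical(tag_stream(st, "gold")$tag, st$gold_tag)
})
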