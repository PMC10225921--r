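#' @title Part-of-speech tagging and bigram transition matrices
#' @name syntax
#' @description Every token gets one of the 17 universal part-of-speech
#'   (UPOS) tags; contiguous tag pairs (bigrams) are counted into a
#'   per-speaker transition matrix whose entries starting or ending with
#'   INTJ (interjection) serve as multi-word non-fluency features. Tagging
#'   is pluggable: any function mapping a token vector to an equal-length
#'   UPOS vector can stand behind [tag_stream()]; the built-in rule tagger
#'   uses a closed word list with suffix fallbacks and a filler-context
#'   rule, and synthetic cohorts carry gold tags that bypass tagging.
NULL

#' The 17-tag universal part-of-speech inventory
#' @export
upos_tagset <- function() {
  c("ADJ", "ADP", "ADV", "AUX", "CCONJ", "DET", "INTJ", "NOUN", "NUM",
    "PART", "PRON", "PROPN", "PUNCT", "SCONJ", "SYM", "VERB", "X")
}

.rule_word_tags <- local({
  entries <- list(
    PRON = c("i", "i'm", "i've", "i'll", "i'd", "me", "my", "mine", "myself",
             "we", "we're", "we've", "we'll", "we'd", "our", "ours", "us",
             "you", "you're", "you've", "your", "yours", "yourself",
             "she", "she's", "her", "hers", "he", "he's", "him", "his",
             "they", "they're", "they've", "them", "their", "it", "it's",
             "this", "something", "anything", "nothing", "everything",
             "someone", "anyone", "what", "who", "myself", "themselves"),
    AUX = c("am", "is", "are", "was", "were", "be", "been", "being",
            "can", "could", "will", "would", "should", "shall", "might",
            "may", "must", "do", "does", "did", "have", "has", "had",
            "gonna", "gotta", "don't", "doesn't", "didn't", "can't",
            "couldn't", "won't", "wouldn't", "isn't", "wasn't", "aren't"),
    INTJ = c("uh", "uhh", "um", "umm", "er", "err", "hm", "hmm", "mm",
             "mmm", "eh", "ehh", "ehhh", "huh", "oh", "ooh", "ah", "yeah",
             "yep", "okay", "ok", "wow", "hey", "alright"),
    DET = c("the", "a", "an", "these", "those", "every", "each", "some",
            "any", "no"),
    SCONJ = c("that", "because", "cause", "if", "when", "while", "although",
              "since", "whether", "unless", "after", "before"),
    ADP = c("in", "on", "at", "of", "with", "from", "about", "for", "into",
            "over", "under", "through", "between", "by"),
    ADV = c("very", "really", "just", "so", "now", "here", "there", "then",
            "maybe", "otherwise", "again", "too", "also", "always", "never",
            "sometimes", "kind", "sort", "pretty", "still", "quite", "well",
            "how", "why", "where", "more", "less", "moderately"),
    PART = c("not", "to", "n't"),
    CCONJ = c("and", "or", "but", "nor"),
    VERB = c("go", "going", "went", "gone", "talk", "talked", "talking",
             "think", "thought", "know", "knew", "known", "want", "wanted",
             "feel", "felt", "get", "got", "gotten", "see", "saw", "seen",
             "say", "said", "like", "liked", "make", "made", "take", "took",
             "come", "came", "try", "tried", "work", "worked", "need",
             "needed", "tell", "told", "give", "gave", "look", "looked",
             "understand", "understood", "remind", "worry", "worrying",
             "figure", "deal", "bring", "brought", "suppose", "keep",
             "kept", "happen", "happened", "lose", "accommodate"),
    NOUN = c("time", "week", "day", "year", "thing", "things", "way",
             "session", "sessions", "therapy", "therapist", "work", "job",
             "family", "mother", "father", "friend", "friends", "people",
             "life", "home", "school", "medication", "medications",
             "frustration", "frustrations", "feelings", "thoughts",
             "snowstorm", "pay", "conditions", "control", "bit", "lot"),
    ADJ = c("good", "bad", "fine", "hard", "better", "worse", "dangerous",
            "important", "honest", "significant", "real", "little", "big",
            "inhumane", "nice", "happy", "sad", "anxious", "tired"),
    NUM = c("one", "two", "three", "four", "five", "six", "seven", "eight",
            "nine", "ten", "zero")
  )
  tags <- rep(names(entries), lengths(entries))
  words <- unlist(entries, use.names = FALSE)
  # first listing wins on duplicates (e.g. "that" SCONJ before any other)
  keep <- !duplicated(words)
  stats::setNames(tags[keep], words[keep])
})

#' Built-in deterministic rule tagger
#'
#' A closed word-to-tag lexicon with suffix fallbacks (-ly adverb,
#' -ing/-ed verb, noun-forming suffixes, digit strings as numerals) and the
#' unknown tag X otherwise. One context rule marks filler "like" as INTJ
#' when the previous tag is AUX or ADV ("was like", "just like"); elsewhere
#' "like" keeps its verb reading. Deterministic for a fixed input.
#'
#' @param tokens Character vector of cleaned lowercase tokens.
#' @return Character vector of UPOS tags, same length.
#' @export
rule_tagger <- function(tokens) {
  if (length(tokens) == 0L) return(character(0))
  tags <- unname(.rule_word_tags[tokens])
  miss <- is.na(tags)
  if (any(miss)) {
    tk <- tokens[miss]
    fb <- rep("X", length(tk))
    fb[grepl("^[0-9]+$", tk)] <- "NUM"
    fb[grepl("ly$", tk) & fb == "X"] <- "ADV"
    fb[grepl("(ing|ed)$", tk) & fb == "X"] <- "VERB"
    fb[grepl("(tion|ness|ment|ity)s?$", tk) & fb == "X"] <- "NOUN"
    tags[miss] <- fb
  }
  filler <- which(tokens == "like")
  filler <- filler[filler > 1L & tags[pmax(filler - 1L, 1L)] %in% c("AUX", "ADV")]
  tags[filler] <- "INTJ"
  tags
}

#' Tag a token stream
#'
#' @param stream A `token_stream`.
#' @param tagger Function mapping a token vector to an equal-length tag
#'   vector in [upos_tagset()]; default the built-in [rule_tagger()].
#'   Adapters to external neural taggers plug in here. Tags supplied in a
#'   `gold_tag` column pass through unchanged when `tagger = "gold"`.
#' @return A `tagged_sequence`: the stream's data frame with a `tag` column.
#' @export
tag_stream <- function(stream, tagger = rule_tagger) {
  stopifnot(inherits(stream, "token_stream") || is.data.frame(stream))
  if (nrow(stream) == 0L) stop("cannot tag an empty stream")
  if (identical(tagger, "gold")) {
    if (is.null(stream$gold_tag)) stop("no gold_tag column on this stream")
    tags <- stream$gold_tag
  } else {
    tags <- tagger(stream$token)
  }
  if (length(tags) != nrow(stream))
    stop("tagger returned ", length(tags), " tags for ", nrow(stream), " tokens")
  bad <- setdiff(unique(tags), upos_tagset())
  if (length(bad)) stop("tags outside the UPOS inventory: ", paste(bad, collapse = ", "))
  out <- stream
  out$tag <- tags
  class(out) <- unique(c("tagged_sequence", class(out)))
  out
}

#' Part-of-speech bigram transition matrix
#'
#' Counts contiguous tag pairs over the 17-tag inventory and normalizes
#' them jointly (each cell divided by the total bigram count — the default,
#' matching the magnitude of reported transition features) or conditionally
#' (each row divided by its outgoing count). Two attribution schemes:
#' `per_speaker` concatenates one speaker's utterances in session order and
#' counts pairs within that concatenation (pairs may span the speaker's own
#' consecutive utterances); `dialogue_first_token` counts pairs in the full
#' dialogue sequence and attributes each pair to the speaker of its first
#' token, so cross-speaker talk-turn transitions are captured.
#'
#' @param seq A `tagged_sequence` (per-speaker stream for `per_speaker`,
#'   whole-dialogue stream for `dialogue_first_token`).
#' @param mode `"joint"` or `"conditional"`.
#' @param attribution `"per_speaker"` or `"dialogue_first_token"`.
#' @param role The owner role (`"patient"`/`"therapist"`); required for
#'   `dialogue_first_token`, inferred from the stream otherwise.
#' @return A `transition_matrix`: list with `counts` (17 x 17 integer),
#'   `total_bigrams`, `probabilities`, `mode`, `attribution`, `role`.
#' @export
transition_matrix <- function(seq, mode = c("joint", "conditional"),
                              attribution = c("per_speaker", "dialogue_first_token"),
                              role = NULL) {
  mode <- match.arg(mode)
  attribution <- match.arg(attribution)
  stopifnot(is.data.frame(seq), !is.null(seq$tag))
  tagset <- upos_tagset()

  if (attribution == "per_speaker") {
    if (is.null(role)) {
      role <- unique(seq$speaker_role)
      if (length(role) != 1L)
        stop("per_speaker attribution needs a single-role stream or an explicit role")
    } else {
      seq <- seq[seq$speaker_role == role, , drop = FALSE]
    }
    if (nrow(seq) < 2L) stop("sequence too short: need at least two tokens")
    a <- seq$tag[-nrow(seq)]
    b <- seq$tag[-1L]
  } else {
    if (is.null(role)) stop("dialogue_first_token attribution requires a role")
    if (nrow(seq) < 2L) stop("sequence too short: need at least two tokens")
    a <- seq$tag[-nrow(seq)]
    b <- seq$tag[-1L]
    keep <- seq$speaker_role[-nrow(seq)] == role
    a <- a[keep]; b <- b[keep]
    if (length(a) == 0L) stop("no bigrams attributed to role '", role, "'")
  }

  counts <- table(factor(a, levels = tagset), factor(b, levels = tagset))
  counts <- matrix(as.integer(counts), nrow = length(tagset),
                   dimnames = list(from = tagset, to = tagset))
  total <- sum(counts)
  if (mode == "joint") {
    probs <- counts / total
  } else {
    out_deg <- rowSums(counts)
    probs <- counts / ifelse(out_deg > 0, out_deg, 1)
    probs[out_deg == 0, ] <- 0
  }
  structure(list(counts = counts, total_bigrams = total, probabilities = probs,
                 mode = mode, attribution = attribution, role = role),
            class = "transition_matrix")
}

#' Interjection-adjacent transition features
#'
#' Flattens every X-INTJ and INTJ-Y entry of a transition matrix into named
#' features `"<role>_<X>-INTJ"` / `"<role>_INTJ-<Y>"` (INTJ-INTJ appears
#' once). Absent transitions are reported as 0. These are the multi-word
#' non-fluency metrics; the four of clinical interest are AUX-INTJ,
#' ADV-INTJ, INTJ-PRON and INTJ-SCONJ.
#'
#' @param m A `transition_matrix`.
#' @return Named numeric vector of 33 probabilities.
#' @export
interjection_features <- function(m) {
  stopifnot(inherits(m, "transition_matrix"))
  p <- m$probabilities
  tagset <- rownames(p)
  into <- stats::setNames(p[, "INTJ"], paste0(m$role, "_", tagset, "-INTJ"))
  outof <- stats::setNames(p["INTJ", ], paste0(m$role, "_INTJ-", tagset))
  c(into, outof[names(outof) != paste0(m$role, "_INTJ-INTJ")])
}
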