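#' @title Dictionary-based word-category features
#' @name lexicon
#' @description Word-category frequencies in the style of closed-vocabulary
#'   psycholinguistic dictionaries: each category is a set of lowercase
#'   tokens, and a speaker's score for a category is the percentage of that
#'   speaker's total words falling in the category. The shipped default
#'   lexicon is a small open word list covering the personal-pronoun
#'   categories (first singular "i", first plural "we", "you", third
#'   singular "shehe", third plural "they") and a "nonfluent" filler
#'   category; users of licensed dictionaries can supply their own via
#'   [read_lexicon()].
NULL

#' Default open lexicon
#'
#' Closed word lists for the six categories used in the analysis. The
#' first-person plural category includes "let's"; contraction forms are
#' separate entries because tokenization keeps internal apostrophes.
#'
#' @return A `lexicon` object: a named list of character vectors with a
#'   `version` attribute.
#' @export
default_lexicon <- function() {
  lex <- list(
    i = c("i", "i'm", "i've", "i'll", "i'd", "me", "my", "mine", "myself"),
    we = c("we", "we're", "we've", "we'll", "we'd", "our", "ours", "us", "let's"),
    you = c("you", "you're", "you've", "you'll", "you'd", "your", "yours", "yourself"),
    shehe = c("she", "she's", "her", "hers", "herself",
              "he", "he's", "him", "his", "himself"),
    they = c("they", "they're", "they've", "they'll", "they'd",
             "them", "their", "theirs", "themselves"),
    nonfluent = c("uh", "uhh", "um", "umm", "er", "err", "hm", "hmm",
                  "mm", "mmm", "eh", "ehh", "ehhh", "huh")
  )
  as_lexicon(lex, version = "alliancelang-open-0.1")
}

#' Construct and validate a lexicon
#'
#' @param categories Named list of character vectors; entries must be
#'   lowercase, category names unique.
#' @param version Version tag stored on the object.
#' @return A `lexicon` object.
#' @export
as_lexicon <- function(categories, version = "custom") {
  stopifnot(is.list(categories), length(categories) > 0)
  nm <- names(categories)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    stop("lexicon categories must have unique non-empty names")
  categories <- lapply(categories, function(w) unique(tolower(as.character(w))))
  structure(categories, version = version, class = "lexicon")
}

#' Read a lexicon from a JSON file
#'
#' The file maps category name to word list, e.g.
#' `{"i": ["i", "me"], "nonfluent": ["um"]}`.
#'
#' @param path Path to a JSON file.
#' @return A `lexicon` object.
#' @export
read_lexicon <- function(path) {
  as_lexicon(jsonlite::fromJSON(path, simplifyVector = TRUE),
             version = basename(path))
}

#' Category usage percentages for a token stream
#'
#' For each lexicon category, the percentage of the stream's tokens that
#' belong to the category: `100 * count / total`. Matching is
#' case-insensitive exact whole-token matching (the stream is already
#' lowercase after preprocessing); no stemming or wildcards.
#'
#' @param stream A `token_stream`, or a character vector of tokens.
#' @param lex A `lexicon`; default [default_lexicon()].
#' @return Named numeric vector of percentages, one per category.
#' @export
category_percents <- function(stream, lex = default_lexicon()) {
  tokens <- if (inherits(stream, "token_stream")) stream$token else as.character(stream)
  if (length(tokens) == 0L) stop("empty token stream: no words to count")
  tokens <- tolower(tokens)
  vapply(lex, function(words) 100 * sum(tokens %in% words) / length(tokens),
         numeric(1))
}

#' Logarithmic transform of a percentage feature
#'
#' Natural log of `percent + epsilon`. The offset keeps zero frequencies
#' finite; the default 0.01 percentage points is an order of magnitude
#' below the smallest nonzero frequency a ~2,000-word speech can produce
#' (~0.05%), so the transform stays strictly increasing and near-log for
#' observed values.
#'
#' @param percent Non-negative numeric vector (percent scale).
#' @param epsilon Small positive offset in percentage points.
#' @return `log(percent + epsilon)`.
#' @export
log_transform <- function(percent, epsilon = 0.01) {
  if (any(!is.finite(percent) & !is.na(percent)) || any(percent < 0, na.rm = TRUE))
    stop("percent must be non-negative")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a single positive number")
  log(percent + epsilon)
}

#' Pronoun-anchored word-bigram frequencies
#'
#' Counts every contiguous word pair in the stream in which either member is
#' one of the anchor tokens (default first-person pronouns "i" and "we"),
#' scaled by the total number of word bigrams in the stream. In a dialogue
#' stream, bigrams never cross a change of speaker.
#'
#' @param stream A `token_stream` or character vector of tokens.
#' @param anchors Tokens anchoring a bigram.
#' @return Named numeric vector mapping `"w1 w2"` to its proportion of all
#'   word bigrams (empty when no anchored bigram occurs).
#' @export
pronoun_bigrams <- function(stream, anchors = c("i", "we")) {
  if (inherits(stream, "token_stream")) {
    tokens <- stream$token
    role <- stream$speaker_role
  } else {
    tokens <- as.character(stream)
    role <- rep("x", length(tokens))
  }
  if (length(tokens) < 2L)
    stop("stream too short: at least two tokens are needed for bigrams")
  first <- tokens[-length(tokens)]
  second <- tokens[-1L]
  same <- role[-length(role)] == role[-1L]
  first <- first[same]; second <- second[same]
  total <- length(first)
  if (total == 0L)
    stop("stream too short: no within-speaker bigram exists")
  hit <- first %in% anchors | second %in% anchors
  if (!any(hit)) return(stats::setNames(numeric(0), character(0)))
  tab <- table(paste(first[hit], second[hit]))
  out <- as.numeric(tab) / total
  names(out) <- names(tab)
  out[order(names(out))]
}
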