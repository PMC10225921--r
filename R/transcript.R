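#' @title Transcript parsing, cleaning and token streams
#' @name transcript
#' @description Two-speaker session transcripts are the unit of feature
#'   extraction: ordered utterances, each owned by one of two speaker roles
#'   (patient or therapist), carrying the raw line of text and, after
#'   cleaning, a lowercase token sequence. Supported on-disk dialects are
#'   `prefixed_lines` ("ROLE: text", one utterance per line) and
#'   `json_records` (a JSON array of `{speaker, text}` records).
NULL

.roles <- c("patient", "therapist")

.default_label_map <- c(PATIENT = "patient", THERAPIST = "therapist")

#' Parse a two-speaker session transcript
#'
#' @param source Path to a file, or a character vector of lines
#'   (`prefixed_lines`) / a JSON string (`json_records`).
#' @param dialect `"prefixed_lines"` (one `"ROLE: text"` utterance per line)
#'   or `"json_records"` (JSON array of `{speaker, text}` objects).
#' @param dyad_id Identifier for the dyad; defaults to the filename stem when
#'   `source` is a path, `"dyad"` otherwise.
#' @param label_map Named character vector mapping speaker labels (matched
#'   case-insensitively) to roles `"patient"` / `"therapist"`.
#' @param metadata Named list of per-dyad covariates (e.g.
#'   `treatment_duration_sessions`).
#' @return An object of class `transcript`: a list with `dyad_id`,
#'   `utterances` (data frame with `index`, `speaker_role`, `raw_text` and a
#'   `tokens` list column, empty until [preprocess_transcript()]) and
#'   `metadata`.
#' @export
parse_transcript <- function(source, dialect = c("prefixed_lines", "json_records"),
                             dyad_id = NULL, label_map = .default_label_map,
                             metadata = list()) {
  dialect <- match.arg(dialect)
  from_file <- length(source) == 1L && !grepl("[\n:{]", source) && file.exists(source)
  if (from_file) {
    if (is.null(dyad_id)) dyad_id <- sub("\\.[^.]*$", "", basename(source))
    source <- readLines(source, warn = FALSE, encoding = "UTF-8")
  }
  if (is.null(dyad_id)) dyad_id <- "dyad"

  if (dialect == "prefixed_lines") {
    lines <- unlist(strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE))
    keep <- nzchar(trimws(lines))
    if (!any(keep)) stop("empty transcript source for dyad '", dyad_id, "'")
    rows <- which(keep)
    speakers <- character(length(rows)); texts <- character(length(rows))
    for (j in seq_along(rows)) {
      ln <- lines[rows[j]]
      m <- regexec("^\\s*([^:]+?)\\s*:\\s*(.*)$", ln)[[1]]
      if (m[1] == -1L)
        stop("line ", rows[j], ": no 'ROLE: text' prefix found")
      label <- toupper(regmatches(ln, list(m))[[1]][2])
      role <- unname(label_map[match(label, toupper(names(label_map)))])
      if (is.na(role))
        stop("line ", rows[j], ": unrecognized speaker label '", label, "'")
      speakers[j] <- role
      texts[j] <- regmatches(ln, list(m))[[1]][3]
    }
  } else {
    txt <- paste(source, collapse = "\n")
    if (!nzchar(trimws(txt))) stop("empty transcript source for dyad '", dyad_id, "'")
    recs <- jsonlite::fromJSON(txt, simplifyDataFrame = TRUE)
    if (NROW(recs) == 0L) stop("empty transcript source for dyad '", dyad_id, "'")
    labels <- toupper(recs$speaker)
    role <- unname(label_map[match(labels, toupper(names(label_map)))])
    bad <- which(is.na(role))
    if (length(bad))
      stop("record ", bad[1], ": unrecognized speaker label '", recs$speaker[bad[1]], "'")
    speakers <- role
    texts <- as.character(recs$text)
  }

  utt <- data.frame(index = seq_along(speakers) - 1L,
                    speaker_role = speakers,
                    raw_text = texts,
                    stringsAsFactors = FALSE)
  utt$tokens <- rep(list(character(0)), nrow(utt))
  structure(list(dyad_id = dyad_id, utterances = utt, metadata = metadata),
            class = "transcript")
}

#' Clean one string into lowercase tokens
#'
#' Bracketed spans (redaction placeholders such as `[NAME]`) are removed,
#' text is lowercased, punctuation is stripped except apostrophes internal
#' to a token (so contractions like "let's" and "i'm" survive as single
#' tokens), and the result is split on whitespace. Numerals are kept.
#'
#' @param x Character vector of raw utterance text.
#' @return List of character vectors of tokens, one per element of `x`.
#' @export
clean_tokens <- function(x) {
  x <- gsub("[‘’ʼ]", "'", x)
  x <- gsub("\\[[^][]*\\]", " ", x)
  x <- tolower(x)
  x <- gsub("[^a-z0-9' ]", " ", x)
  lapply(strsplit(trimws(x), "\\s+"), function(tk) {
    tk <- gsub("^'+|'+$", "", tk)
    tk[nzchar(tk)]
  })
}

#' Preprocess a transcript into token sequences
#'
#' Populates the `tokens` column of every utterance using [clean_tokens()].
#' Idempotent: preprocessing an already-preprocessed transcript changes
#' nothing.
#'
#' @param t A `transcript` from [parse_transcript()].
#' @return The transcript with tokens populated.
#' @export
preprocess_transcript <- function(t) {
  stopifnot(inherits(t, "transcript"))
  t$utterances$tokens <- clean_tokens(t$utterances$raw_text)
  t
}

#' Extract a per-speaker or whole-dialogue token stream
#'
#' @param t A preprocessed `transcript`.
#' @param owner `"patient"`, `"therapist"` or `"dialogue"`.
#' @return An object of class `token_stream`: a data frame with columns
#'   `token`, `speaker_role`, `utterance_index`, in session order, with the
#'   owner stored as an attribute.
#' @export
token_stream <- function(t, owner = c("dialogue", "patient", "therapist")) {
  stopifnot(inherits(t, "transcript"))
  owner <- match.arg(owner)
  utt <- t$utterances
  if (owner != "dialogue") utt <- utt[utt$speaker_role == owner, , drop = FALSE]
  n <- vapply(utt$tokens, length, integer(1))
  if (sum(n) == 0L)
    stop("empty token stream for owner '", owner, "' in dyad '", t$dyad_id, "'")
  out <- data.frame(token = unlist(utt$tokens, use.names = FALSE),
                    speaker_role = rep(utt$speaker_role, n),
                    utterance_index = rep(utt$index, n),
                    stringsAsFactors = FALSE)
  if (!is.null(utt$gold_tags))
    out$gold_tag <- unlist(utt$gold_tags, use.names = FALSE)
  attr(out, "owner") <- owner
  class(out) <- c("token_stream", class(out))
  out
}

#' Serialize a transcript in the prefixed-lines dialect
#'
#' Writes one `"ROLE: text"` line per utterance. When tokens are populated
#' the cleaned token sequence is written (so a parse/preprocess round trip
#' is stable); otherwise the raw text is written. Output is byte-identical
#' for a fixed input.
#'
#' @param t A `transcript`.
#' @param path Optional file path; if `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
write_transcript <- function(t, path = NULL) {
  stopifnot(inherits(t, "transcript"))
  utt <- t$utterances
  text <- ifelse(lengths(utt$tokens) > 0L,
                 vapply(utt$tokens, paste, "", collapse = " "),
                 utt$raw_text)
  lines <- paste0(toupper(utt$speaker_role), ": ", text)
  if (is.null(path)) return(lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}
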