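#' @title Synthetic dyad cohorts with planted structure
#' @name synthetic
#' @description Because real session transcripts are protected, the
#'   pipeline is validated on synthetic cohorts generated from a template
#'   grammar with exact control over per-role word-category rates and
#'   part-of-speech structure. Gold tags are recorded at emission time,
#'   alliance scores are planted as a linear function of log-features plus
#'   Gaussian noise, and trust-game behavior carries a planted
#'   exposure -> repayment -> alliance mediation chain, so every pipeline
#'   stage has known ground truth.
NULL

# Content vocabulary: tag -> word list, with sampling weight per tag.
# Words deliberately avoid every lexicon-category entry so that the
# dictionary rates are controlled solely by the category emissions.
.content_vocab <- list(
  NOUN = list(w = 0.19, words = c("time", "week", "day", "year", "thing",
    "things", "way", "work", "family", "friend", "people", "life", "home",
    "school", "session", "frustration")),
  VERB = list(w = 0.21, words = c("go", "going", "talk", "think", "know",
    "want", "feel", "get", "see", "say", "make", "take", "come", "try",
    "need", "tell", "give", "look", "understand", "happen")),
  AUX = list(w = 0.09, words = c("am", "is", "are", "was", "were", "be",
    "been", "can", "could", "will", "would", "should", "have", "has",
    "had", "do", "does", "did")),
  DET = list(w = 0.10, words = c("the", "a", "an", "these", "those",
    "some", "any")),
  ADP = list(w = 0.10, words = c("in", "on", "at", "of", "with", "from",
    "about", "for", "into", "over")),
  ADV = list(w = 0.08, words = c("very", "really", "just", "so", "now",
    "here", "there", "then", "maybe", "again", "too", "also", "still")),
  ADJ = list(w = 0.07, words = c("good", "bad", "fine", "hard", "better",
    "important", "honest", "little", "big", "nice")),
  PRON = list(w = 0.05, words = c("it", "this", "something", "anything",
    "what")),
  SCONJ = list(w = 0.04, words = c("that", "because", "if", "when",
    "while", "since")),
  CCONJ = list(w = 0.04, words = c("and", "or", "but")),
  PART = list(w = 0.02, words = c("not", "to")),
  NUM = list(w = 0.01, words = c("one", "two", "three"))
)

.category_tag <- c(i = "PRON", we = "PRON", you = "PRON", shehe = "PRON",
                   they = "PRON", nonfluent = "INTJ")

#' Cohort generation specification
#'
#' Defaults mirror the study conditions: 28 dyads; per-role
#' lexicon-category target rates centred on the reported cohort means
#' (therapist "i" 3.30%, patient "i" 10.3%, therapist "we" 0.994%, patient
#' "we" 0.517%, nonfluent 2.79% / 2.12%) with pronoun categories not
#' reported in the source set to field-plausible values; per-role AUX-INTJ
#' joint transition targets 0.005 (therapist) and 0.007 (patient), realized
#' by filler-interjection insertion after auxiliaries; alliance bounded
#' 12..84 with 4..28 goal/task/bond subscores; and a planted mediation
#' chain from the therapist first-person-singular log-feature through the
#' patient's mean trust-game repayment fraction to alliance.
#'
#' @param n_dyads Number of dyads (>= 4).
#' @param token_mean,token_dispersion Per-role mean token counts and the
#'   lognormal dispersion of per-dyad counts.
#' @param rates Per-role category target rates in percent: a list with
#'   `patient` and `therapist` named numeric vectors over the lexicon
#'   categories. Row sums must stay below 100.
#' @param rate_sd Lognormal sd of the per-dyad multiplicative rate jitter
#'   (mean-one, so cohort means hit the targets).
#' @param aux_intj_target Per-role target joint AUX-INTJ transition
#'   probability.
#' @param aux_intj_sd Lognormal sd of its per-dyad jitter.
#' @param slopes Named numeric vector of planted alliance slopes over
#'   feature-table columns (log lexicon features or raw transition
#'   features).
#' @param alliance_mean,alliance_noise_sd Alliance intercept and residual
#'   sd (instrument scale 12..84).
#' @param mediation Named numeric vector `c(a, b, c_prime)`: exposure ->
#'   mean repayment fraction slope, repayment -> alliance slope, residual
#'   direct slope, for exposure `mediation_exposure`.
#' @param mediation_exposure Feature column carrying the planted chain.
#' @param rf_mean,rf_sd Mean and residual sd of the patient's planted mean
#'   repayment fraction.
#' @param subscore_sd Sd of goal/task subscore noise around a third of the
#'   total (bond takes the remainder so the three sum to the total).
#' @param bond_shift Differential loading of the bond subscore on the
#'   centred patient "i" log-feature (moved out of goal), exercising the
#'   dependent-correlation comparison.
#' @param duration_cor Correlation between log treatment duration and the
#'   patient AUX-INTJ log-feature (the confound that motivates the partial
#'   correlation).
#' @param knn_k Investor neighbour count for the simulated trust game.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_dyads = 28,
                        token_mean = c(patient = 1600, therapist = 900),
                        token_dispersion = 0.2,
                        rates = list(
                          patient = c(i = 10.3, we = 0.517, you = 2.0,
                                      shehe = 1.0, they = 1.2, nonfluent = 2.12),
                          therapist = c(i = 3.30, we = 0.994, you = 3.0,
                                        shehe = 0.8, they = 0.9, nonfluent = 2.79)),
                        rate_sd = 0.25,
                        aux_intj_target = c(patient = 0.007, therapist = 0.005),
                        aux_intj_sd = 0.3,
                        slopes = c(therapist_we_log = -5, patient_i_log = -7,
                                   patient_nonfluent_log = 4,
                                   `patient_AUX-INTJ` = 800),
                        alliance_mean = 70, alliance_noise_sd = 2,
                        mediation = c(a = -0.2, b = 15, c_prime = -1.5),
                        mediation_exposure = "therapist_i_log",
                        rf_mean = 0.55, rf_sd = 0.12,
                        subscore_sd = 1.2,
                        bond_shift = c(patient_i_log = -1.5),
                        duration_cor = 0.45,
                        knn_k = 5) {
  stopifnot(n_dyads >= 4, token_dispersion >= 0, rate_sd >= 0,
            aux_intj_sd >= 0, alliance_noise_sd >= 0, rf_sd >= 0,
            subscore_sd >= 0, abs(duration_cor) <= 1)
  for (role in c("patient", "therapist")) {
    r <- rates[[role]]
    if (any(r < 0) || any(r > 100)) stop("category rates must lie in [0, 100]")
    if (sum(r) > 100)
      stop("infeasible rate set: ", role, " category rates sum above 100%")
  }
  structure(list(n_dyads = as.integer(n_dyads), token_mean = token_mean,
                 token_dispersion = token_dispersion, rates = rates,
                 rate_sd = rate_sd, aux_intj_target = aux_intj_target,
                 aux_intj_sd = aux_intj_sd, slopes = slopes,
                 alliance_mean = alliance_mean,
                 alliance_noise_sd = alliance_noise_sd,
                 mediation = mediation,
                 mediation_exposure = mediation_exposure,
                 rf_mean = rf_mean, rf_sd = rf_sd,
                 subscore_sd = subscore_sd, bond_shift = bond_shift,
                 duration_cor = duration_cor, knn_k = knn_k),
            class = "cohort_spec")
}

# Emit one role's token + gold-tag stream at the requested rates.
.emit_role_stream <- function(n_tokens, rates_pct, aux_target, lex) {
  p_cat <- rates_pct / 100
  # inserted fillers dilute category rates by ~ the insertion fraction;
  # inflate the emission probabilities to compensate
  p_cat <- p_cat * (1 + aux_target)
  content_mass <- 1 - sum(p_cat)
  if (content_mass < 0) stop("infeasible rate set: categories exceed 100%")
  cats <- names(p_cat)
  tag_w <- vapply(.content_vocab, `[[`, numeric(1), "w")
  draw <- sample(c(cats, names(tag_w)), n_tokens, replace = TRUE,
                 prob = c(p_cat, content_mass * tag_w / sum(tag_w)))
  tokens <- character(n_tokens); tags <- character(n_tokens)
  for (cat in cats) {
    idx <- which(draw == cat)
    if (!length(idx)) next
    words <- lex[[cat]]
    tokens[idx] <- words[sample.int(length(words), length(idx), replace = TRUE)]
    tags[idx] <- .category_tag[[cat]]
  }
  for (tg in names(tag_w)) {
    idx <- which(draw == tg)
    if (!length(idx)) next
    words <- .content_vocab[[tg]]$words
    tokens[idx] <- words[sample.int(length(words), length(idx), replace = TRUE)]
    tags[idx] <- tg
  }
  # filler-interjection insertion after auxiliaries drives the AUX-INTJ
  # transition rate without touching the dictionary categories; the base
  # emission already yields chance AUX -> filler pairs at rate p_nf per
  # auxiliary, so the insertion supplies only the shortfall
  p_aux <- content_mass * tag_w[["AUX"]] / sum(tag_w)
  p_nf <- unname(p_cat["nonfluent"])
  if (is.na(p_nf)) p_nf <- 0
  q <- if (p_aux > 0 && aux_target > 0)
    min(1, max(0, (aux_target / p_aux - p_nf) / (1 - p_nf))) else 0
  if (q > 0) {
    aux_pos <- which(tags == "AUX")
    ins <- aux_pos[stats::runif(length(aux_pos)) < q]
    if (length(ins)) {
      keep <- order(c(seq_len(n_tokens), ins + 0.5))
      tokens <- c(tokens, rep("like", length(ins)))[keep]
      tags <- c(tags, rep("INTJ", length(ins)))[keep]
    }
  }
  list(tokens = tokens, tags = tags)
}

#' Generate one synthetic dyad transcript with gold tags
#'
#' Tokens are drawn from a template grammar: category words (pronoun and
#' filler dictionaries) at the requested per-role rates, remaining mass
#' from a tagged content vocabulary, and filler interjections inserted
#' after auxiliaries at the rate needed to hit the AUX-INTJ transition
#' target. The emitted tag of every token is recorded as its gold tag.
#' Utterances alternate between the two roles.
#'
#' @param spec A `cohort_spec`.
#' @param dyad_id Identifier.
#' @param rates,aux_target,n_tokens Optional per-dyad overrides of the
#'   spec targets (per-role lists/vectors), used by [generate_cohort()] to
#'   inject dyad-level heterogeneity.
#' @param lex Lexicon supplying the category word lists.
#' @param seed Optional seed.
#' @return A preprocessed `transcript` whose utterances carry a
#'   `gold_tags` list column.
#' @export
generate_transcript <- function(spec, dyad_id = "dyad01", rates = NULL,
                                aux_target = NULL, n_tokens = NULL,
                                lex = default_lexicon(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  local_rng(seed)
  if (is.null(rates)) rates <- spec$rates
  if (is.null(aux_target)) aux_target <- spec$aux_intj_target
  if (is.null(n_tokens)) {
    disp <- spec$token_dispersion
    n_tokens <- vapply(c(patient = "patient", therapist = "therapist"),
                       function(role) {
                         mu <- spec$token_mean[[role]]
                         max(20L, as.integer(round(stats::rlnorm(1,
                           log(mu) - disp^2 / 2, disp))))
                       }, integer(1))
  }
  streams <- list(
    patient = .emit_role_stream(n_tokens[["patient"]], rates$patient,
                                aux_target[["patient"]], lex),
    therapist = .emit_role_stream(n_tokens[["therapist"]], rates$therapist,
                                  aux_target[["therapist"]], lex))

  # chunk each role's stream into utterances and interleave the roles
  chunk <- function(n, mean_len) {
    lens <- integer(0)
    while (sum(lens) < n) lens <- c(lens, 1L + stats::rpois(1, mean_len - 1))
    lens[length(lens)] <- lens[length(lens)] - (sum(lens) - n)
    lens[lens > 0]
  }
  lens <- list(patient = chunk(length(streams$patient$tokens), 16),
               therapist = chunk(length(streams$therapist$tokens), 9))
  pos <- c(patient = 0L, therapist = 0L)
  used <- c(patient = 0L, therapist = 0L)
  role_seq <- character(0); tok_list <- list(); tag_list <- list()
  turn <- "patient"
  while (used[["patient"]] < length(lens$patient) ||
         used[["therapist"]] < length(lens$therapist)) {
    if (used[[turn]] >= length(lens[[turn]]))
      turn <- setdiff(c("patient", "therapist"), turn)
    used[[turn]] <- used[[turn]] + 1L
    L <- lens[[turn]][used[[turn]]]
    idx <- pos[[turn]] + seq_len(L)
    pos[[turn]] <- pos[[turn]] + L
    role_seq <- c(role_seq, turn)
    tok_list <- c(tok_list, list(streams[[turn]]$tokens[idx]))
    tag_list <- c(tag_list, list(streams[[turn]]$tags[idx]))
    turn <- setdiff(c("patient", "therapist"), turn)
  }

  utt <- data.frame(index = seq_along(role_seq) - 1L, speaker_role = role_seq,
                    raw_text = vapply(tok_list, paste, "", collapse = " "),
                    stringsAsFactors = FALSE)
  utt$tokens <- tok_list
  utt$gold_tags <- tag_list
  structure(list(dyad_id = dyad_id, utterances = utt, metadata = list()),
            class = "transcript")
}

#' Plant alliance and trust-game outcomes onto a feature table
#'
#' Adds outcome columns to an extracted feature table with known linear
#' structure: the patient's target mean repayment fraction follows the
#' mediation plant `rf = rf_mean + a * (exposure - mean) + noise` (clipped
#' to \[0, 1\]); alliance is `alliance_mean + sum(slope_j * centred
#' feature_j) + b * (rf - rf_mean) + c' * (exposure - mean) + noise`,
#' clipped to the 12..84 instrument range; goal/task/bond subscores sum to
#' the total, with a configurable differential loading on the bond
#' subscore; treatment duration is lognormal and correlated with the
#' patient AUX-INTJ log-feature; clinic and diagnosis covariates follow
#' the cohort composition of the emulated study.
#'
#' @param features Feature table from [extract_features()] (one row per
#'   dyad, named numeric columns).
#' @param spec A `cohort_spec`.
#' @param seed Optional seed.
#' @return Data frame of outcomes keyed by `dyad_id`: `alliance_total`,
#'   `goal`, `task`, `bond`, `rf_target_patient`, `duration`, `clinic`,
#'   `diagnosis`, plus `alliance_signal` (the noiseless linear predictor,
#'   kept as ground truth).
#' @export
plant_outcomes <- function(features, spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$alliance_noise_sd < 0) stop("noise sd must be non-negative")
  local_rng(seed)
  n <- nrow(features)
  centred <- function(col) {
    v <- features[[col]]
    if (is.null(v)) stop("planted slope names a missing feature column: ", col)
    v - mean(v)
  }
  expo <- centred(spec$mediation_exposure)
  a <- spec$mediation[["a"]]; b <- spec$mediation[["b"]]
  c_prime <- spec$mediation[["c_prime"]]
  rf <- spec$rf_mean + a * expo + stats::rnorm(n, 0, spec$rf_sd)
  rf <- pmin(1, pmax(0, rf))

  signal <- spec$alliance_mean + b * (rf - spec$rf_mean) + c_prime * expo
  for (col in names(spec$slopes)) signal <- signal + spec$slopes[[col]] * centred(col)
  alliance <- pmin(84, pmax(12, signal + stats::rnorm(n, 0, spec$alliance_noise_sd)))

  shift <- 0
  for (col in names(spec$bond_shift)) shift <- shift + spec$bond_shift[[col]] * centred(col)
  goal <- alliance / 3 - shift + stats::rnorm(n, 0, spec$subscore_sd)
  task <- alliance / 3 + stats::rnorm(n, 0, spec$subscore_sd)
  goal <- pmin(28, pmax(4, goal)); task <- pmin(28, pmax(4, task))
  bond <- pmin(28, pmax(4, alliance - goal - task))

  aux <- features[["patient_AUX-INTJ"]]
  z_aux <- if (!is.null(aux) && stats::sd(aux) > 0) {
    la <- log(aux + 1e-4); (la - mean(la)) / stats::sd(la)
  } else rep(0, n)
  rho <- spec$duration_cor
  ldur <- log(14.5) + 0.9 * (rho * z_aux + sqrt(1 - rho^2) * stats::rnorm(n))
  duration <- pmax(2, round(exp(ldur)))

  data.frame(dyad_id = features$dyad_id,
             alliance_total = alliance, goal = goal, task = task, bond = bond,
             alliance_signal = signal,
             rf_target_patient = rf,
             duration = duration,
             clinic = sample(c("general", "personality_specialized"), n,
                             replace = TRUE, prob = c(0.79, 0.21)),
             diagnosis = sample(c("personality", "mood", "anxiety_trauma"), n,
                                replace = TRUE, prob = c(0.54, 0.25, 0.21)),
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort bundle
#'
#' Generates `spec$n_dyads` transcripts with dyad-level rate heterogeneity,
#' extracts the feature table through the package's own extraction path
#' (gold tags), plants outcomes, and simulates a round-level trust-game
#' session per dyad whose trustee repays the planted target fraction of
#' each tripled offer (so the realized session mean matches the target
#' within per-round integer rounding). The manifest records the seed and
#' the generation spec so the bundle can be regenerated identically.
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer root seed; all randomness derives from it.
#' @param lex Lexicon for category word lists.
#' @return A `cohort` list: `transcripts` (named list), `features` (data
#'   frame), `outcomes` (data frame, including the realized
#'   `mean_RF_patient` / `mean_RF_therapist`), `sessions` (named list of
#'   patient `trust_game_session`s), `manifest` (seed + spec).
#' @export
generate_cohort <- function(spec, seed = 1, lex = default_lexicon()) {
  stopifnot(inherits(spec, "cohort_spec"))
  local_rng(seed)
  n <- spec$n_dyads
  ids <- sprintf("dyad%03d", seq_len(n))

  jitter_mult <- function(sd, k) exp(stats::rnorm(k, -sd^2 / 2, sd))
  transcripts <- vector("list", n); names(transcripts) <- ids
  for (j in seq_len(n)) {
    rates <- lapply(spec$rates, function(r) {
      v <- pmin(r * jitter_mult(spec$rate_sd, length(r)), 95)
      if (sum(v) > 100) v <- v * (95 / sum(v))
      v
    })
    aux <- spec$aux_intj_target * jitter_mult(spec$aux_intj_sd, 2)
    transcripts[[j]] <- generate_transcript(spec, ids[j], rates = rates,
                                            aux_target = aux, lex = lex)
  }

  features <- extract_features(transcripts, lex = lex, tagger = "gold")
  outcomes <- plant_outcomes(features, spec)

  ref <- investor_reference(seed = child_seed(seed, "investor_reference"))
  sessions <- vector("list", n); names(sessions) <- ids
  rf_real <- numeric(n); rf_ther <- numeric(n)
  for (j in seq_len(n)) {
    sessions[[j]] <- play_session(knn_investor(ref, k = spec$knn_k),
                                  proportional_trustee(outcomes$rf_target_patient[j]),
                                  dyad_id = ids[j], player_role = "patient")
    rf_real[j] <- sessions[[j]]$mean_RF
    ther_target <- min(1, max(0, stats::rnorm(1, spec$rf_mean, spec$rf_sd)))
    ther <- play_session(knn_investor(ref, k = spec$knn_k),
                         proportional_trustee(ther_target),
                         dyad_id = ids[j], player_role = "therapist")
    rf_ther[j] <- ther$mean_RF
  }
  outcomes$mean_RF_patient <- rf_real
  outcomes$mean_RF_therapist <- rf_ther

  structure(list(transcripts = transcripts, features = features,
                 outcomes = outcomes, sessions = sessions,
                 manifest = list(seed = as.integer(seed), spec = spec)),
            class = "cohort")
}
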