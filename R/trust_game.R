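#' @title Ten-round trust game with a k-nearest-neighbour investor
#' @name trust_game
#' @description The subject plays the trustee role against a simulated
#'   investor for ten rounds. Each round the investor offers an integer
#'   portion of a 20-unit endowment; the offer is tripled and sent to the
#'   trustee, who repays an integer amount out of what was received. The
#'   repayment fraction RF_t = R_t / (3 I_t) — repayment over the amount
#'   received — averaged over the defined rounds is the session-level proxy
#'   of the investor's perceived trustworthiness. The investor's first
#'   offer is random; later offers are sampled from a reference dataset of
#'   same-round plays via k nearest neighbours on the previous round's
#'   repayment fraction.
NULL

#' Synthetic investor reference dataset
#'
#' A seeded, synthetic stand-in for a behavioral dataset of investors'
#' round-by-round choices: for rounds 2..10, `n_per_round` records of
#' (round, previous-round repayment fraction, offer), with offers
#' increasing in the previous repayment (reciprocating investors) plus
#' integer noise, clamped to 0..20.
#'
#' @param n_per_round Records per round.
#' @param rounds Number of rounds (offers needed for rounds 2..rounds).
#' @param seed Integer seed.
#' @return Data frame with columns `round`, `prev_rf`, `offer`.
#' @export
investor_reference <- function(n_per_round = 60, rounds = 10, seed = 20210) {
  rng <- local_rng(seed)
  recs <- do.call(rbind, lapply(2:rounds, function(t) {
    prev_rf <- round(stats::runif(n_per_round), 3)
    base <- 20 * (0.15 + 0.75 * prev_rf)
    offer <- as.integer(pmin(20, pmax(0, round(base + stats::rnorm(n_per_round, 0, 2)))))
    data.frame(round = t, prev_rf = prev_rf, offer = offer)
  }))
  rownames(recs) <- NULL
  recs
}

#' Investor offer for the next round
#'
#' Round 1: a uniform integer draw over 0..20. Round t > 1: among reference
#' records for round t, the k records whose stored previous-round repayment
#' fraction is nearest (absolute difference) to the trustee's observed
#' RF_{t-1} are selected — distance ties at the k-th neighbour broken
#' uniformly at random — and one of the k offers is sampled uniformly. k is
#' clamped to the number of available records. If the previous round's RF
#' is undefined (zero offer), a neutral 0.5 is used for the lookup.
#'
#' @param history Data frame of completed rounds (columns `t`, `I`, `R`,
#'   `RF`), zero rows for the first round.
#' @param ref Reference data frame from [investor_reference()].
#' @param k Neighbour count.
#' @return Integer offer in 0..20.
#' @export
investor_offer <- function(history, ref, k = 5) {
  t_next <- nrow(history) + 1L
  if (t_next == 1L) return(sample(0:20, 1L))
  pool <- ref[ref$round == t_next, , drop = FALSE]
  if (nrow(pool) == 0L)
    stop("investor reference has no records for round ", t_next)
  prev <- history$RF[nrow(history)]
  if (is.na(prev)) prev <- 0.5
  d <- abs(pool$prev_rf - prev)
  k <- min(k, nrow(pool))
  # k nearest with uniform random tie-break at the boundary distance
  ord <- order(d, sample.int(nrow(pool)))
  as.integer(sample(rep(pool$offer[ord[seq_len(k)]], 2L), 1L))
}

#' Repayment fraction of one round
#'
#' `R / (3 I)` — the repayment over the tripled amount received — for a
#' positive offer; `NA` (undefined) when the offer is zero. Set
#' `tripled = FALSE` for the alternative reading that divides by the bare
#' offer.
#'
#' @param I Integer offer 0..20.
#' @param R Integer repayment, 0..3I.
#' @param tripled Divide by the tripled receipt (default) or the bare offer.
#' @return Fraction in \[0, 1\] (or \[0, 3\] when `tripled = FALSE`), or `NA`.
#' @export
repayment_fraction <- function(I, R, tripled = TRUE) {
  if (any(I < 0 | I > 20)) stop("offer out of range 0..20")
  if (any(R < 0 | R > 3 * I, na.rm = TRUE))
    stop("repayment outside 0..3*offer violates the game's budget")
  denom <- if (tripled) 3 * I else I
  ifelse(I > 0, R / denom, NA_real_)
}

#' Mean repayment fraction of a session
#'
#' Arithmetic mean of the defined per-round repayment fractions; rounds
#' with a zero offer are excluded from numerator and denominator.
#'
#' @param session A `trust_game_session` or its `rounds` data frame.
#' @return Mean repayment fraction in \[0, 1\].
#' @export
mean_repayment <- function(session) {
  rounds <- if (inherits(session, "trust_game_session")) session$rounds else session
  rf <- rounds$RF
  if (all(is.na(rf))) stop("undefined statistic: every round had a zero offer")
  mean(rf, na.rm = TRUE)
}

#' Play a full trust-game session
#'
#' Ten rounds generated sequentially: the investor policy produces the
#' offer given the history, the offer is tripled and sent, the trustee
#' policy chooses the integer repayment given the amount received and the
#' history. Conservation holds exactly: what the trustee kept plus all
#' repayments equals the sum of tripled offers.
#'
#' @param investor Function `(history, round)` returning an offer 0..20;
#'   default the k-NN policy against a fresh synthetic reference.
#' @param trustee Function `(received, history)` returning an integer
#'   repayment 0..received.
#' @param n_rounds Number of rounds (10 in the study design).
#' @param dyad_id,player_role Session labels.
#' @return A `trust_game_session`: list with `rounds` (columns `t`, `I`,
#'   `received`, `R`, `RF`), `mean_RF`, `kept_total`, `dyad_id`,
#'   `player_role`.
#' @export
play_session <- function(investor, trustee, n_rounds = 10,
                         dyad_id = "dyad", player_role = "patient") {
  hist <- data.frame(t = integer(0), I = integer(0), received = integer(0),
                     R = integer(0), RF = numeric(0))
  for (t in seq_len(n_rounds)) {
    I <- as.integer(investor(hist, t))
    if (is.na(I) || I < 0 || I > 20)
      stop("investor policy returned an out-of-range offer at round ", t)
    received <- 3L * I
    R <- as.integer(trustee(received, hist))
    if (is.na(R) || R < 0 || R > received)
      stop("trustee policy returned an out-of-range repayment at round ", t)
    hist <- rbind(hist, data.frame(t = t, I = I, received = received, R = R,
                                   RF = repayment_fraction(I, R)))
  }
  structure(list(dyad_id = dyad_id, player_role = player_role, rounds = hist,
                 mean_RF = mean_repayment(hist),
                 kept_total = sum(hist$received - hist$R)),
            class = "trust_game_session")
}

#' k-NN investor policy closure
#'
#' @param ref Reference data frame from [investor_reference()].
#' @param k Neighbour count.
#' @return A policy function usable as `investor` in [play_session()].
#' @export
knn_investor <- function(ref, k = 5) {
  function(history, round) investor_offer(history, ref, k = k)
}

#' Proportional trustee policy closure
#'
#' Repays a fixed fraction of the amount received, rounded to the nearest
#' integer — used by the synthetic cohort to realize a target mean
#' repayment fraction within rounding error.
#'
#' @param fraction Target repayment fraction in \[0, 1\].
#' @return A policy function usable as `trustee` in [play_session()].
#' @export
proportional_trustee <- function(fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  function(received, history) as.integer(round(fraction * received))
}
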