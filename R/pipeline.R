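#' @title End-to-end feature extraction and analysis
#' @name pipeline
#' @description Orchestration of the full analysis: a feature table (one
#'   row per dyad: dictionary percentages raw and log, interjection
#'   transition features, pronoun-anchored word bigrams, per-role totals)
#'   is extracted from transcripts, joined to per-dyad outcomes, and run
#'   through the statistical layer — mass-univariate F-regressions with
#'   FDR control, role comparisons, trust-game correlations, the
#'   duration-partialled correlation, dependent-correlation subscore
#'   comparisons, and mediation. All randomness flows from one root seed.
NULL

#' Run configuration
#'
#' @param tagger `"rule"` (built-in rule tagger), `"gold"` (use gold tags
#'   carried by synthetic transcripts), or a tagger function.
#' @param mode Transition probability normalization, `"joint"` (default)
#'   or `"conditional"`.
#' @param attribution `"per_speaker"` (default) or `"dialogue_first_token"`.
#' @param alpha Two-sided type-I error level.
#' @param fdr_method Multiple-testing method (Benjamini-Hochberg).
#' @param mediation_iterations Quasi-Bayesian draw count.
#' @param mediation_exposures Feature columns tested as mediation exposures.
#' @param steiger_features Feature columns compared across alliance
#'   subscores.
#' @param epsilon Offset of the log transform, percentage points.
#' @param bigram_min_share Keep a pronoun bigram as a column when it occurs
#'   in at least this share of dyads.
#' @param seed Root seed.
#' @return A `run_config` list.
#' @export
run_config <- function(tagger = "rule", mode = "joint",
                       attribution = "per_speaker", alpha = 0.05,
                       fdr_method = "BH", mediation_iterations = 1000,
                       mediation_exposures = c("therapist_i_log", "therapist_we_log"),
                       steiger_features = "patient_i_log",
                       epsilon = 0.01, bigram_min_share = 0.5, seed = 1) {
  stopifnot(alpha > 0, alpha < 1, mediation_iterations >= 100)
  structure(list(tagger = tagger, mode = mode, attribution = attribution,
                 alpha = alpha, fdr_method = fdr_method,
                 mediation_iterations = as.integer(mediation_iterations),
                 mediation_exposures = mediation_exposures,
                 steiger_features = steiger_features,
                 epsilon = epsilon, bigram_min_share = bigram_min_share,
                 seed = as.integer(seed)),
            class = "run_config")
}

.resolve_tagger <- function(tagger) {
  if (is.function(tagger)) return(tagger)
  switch(tagger, rule = rule_tagger, gold = "gold",
         stop("unknown tagger '", tagger, "'"))
}

#' Extract the per-dyad feature table
#'
#' One row per dyad: for each role the six dictionary category percentages
#' (`<role>_<cat>`) and their log transforms (`<role>_<cat>_log`), the
#' total word count (`<role>_total_words`), the 33 interjection-adjacent
#' transition features (`<role>_<X>-INTJ`, `<role>_INTJ-<Y>`), and the
#' pronoun-anchored word-bigram proportions (`<role>_bigram_<w1>_<w2>`)
#' for bigrams present in at least `bigram_min_share` of dyads (absent
#' occurrences are 0). Column order is stable for a fixed cohort.
#'
#' @param transcripts Named list of `transcript` objects (preprocessed or
#'   not), or a character vector of file paths in the prefixed-lines
#'   dialect.
#' @param lex Lexicon.
#' @param tagger As in [run_config()].
#' @param mode,attribution Transition-matrix options.
#' @param epsilon Log-transform offset.
#' @param bigram_min_share Bigram column inclusion threshold.
#' @return Data frame keyed by `dyad_id`.
#' @export
extract_features <- function(transcripts, lex = default_lexicon(),
                             tagger = "rule", mode = "joint",
                             attribution = "per_speaker", epsilon = 0.01,
                             bigram_min_share = 0.5) {
  if (is.character(transcripts))
    transcripts <- stats::setNames(lapply(transcripts, parse_transcript),
                                   vapply(transcripts, function(p)
                                     sub("\\.[^.]*$", "", basename(p)), ""))
  tg <- .resolve_tagger(tagger)
  roles <- c("patient", "therapist")
  rows <- vector("list", length(transcripts))
  bigram_maps <- vector("list", length(transcripts))
  for (j in seq_along(transcripts)) {
    tr <- transcripts[[j]]
    if (all(lengths(tr$utterances$tokens) == 0L)) tr <- preprocess_transcript(tr)
    row <- list(dyad_id = tr$dyad_id)
    bg <- list()
    dialogue <- if (attribution == "dialogue_first_token")
      tag_stream(token_stream(tr, "dialogue"), tg) else NULL
    for (role in roles) {
      stream <- token_stream(tr, role)
      pct <- category_percents(stream, lex)
      names(pct) <- paste0(role, "_", names(pct))
      row <- c(row, as.list(pct), as.list(stats::setNames(
        log_transform(pct, epsilon), paste0(names(pct), "_log"))))
      row[[paste0(role, "_total_words")]] <- nrow(stream)
      m <- if (attribution == "per_speaker")
        transition_matrix(tag_stream(stream, tg), mode, attribution)
      else transition_matrix(dialogue, mode, attribution, role = role)
      row <- c(row, as.list(interjection_features(m)))
      bg[[role]] <- tryCatch(pronoun_bigrams(stream),
                             error = function(e) stats::setNames(numeric(0), character(0)))
    }
    rows[[j]] <- row
    bigram_maps[[j]] <- bg
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)))

  # bigram columns: those present in enough dyads, zero-filled elsewhere
  n <- length(transcripts)
  for (role in roles) {
    all_names <- unlist(lapply(bigram_maps, function(b) names(b[[role]])))
    if (!length(all_names)) next
    keep <- names(which(table(all_names) >= bigram_min_share * n))
    for (nm in sort(keep)) {
      col <- vapply(bigram_maps, function(b) {
        v <- b[[role]][nm]; if (is.na(v)) 0 else unname(v)
      }, numeric(1))
      out[[paste0(role, "_bigram_", gsub(" ", "_", nm))]] <- col
    }
  }
  rownames(out) <- NULL
  out
}

#' Extract features from transcript files, tolerating bad inputs
#'
#' Parses each file, extracts the feature table from the transcripts that
#' parse, and records one error message per failing file; an empty input
#' set is an error.
#'
#' @param paths Character vector of transcript file paths (prefixed-lines
#'   dialect).
#' @param cfg A [run_config()].
#' @param lex Lexicon.
#' @return List with `features` (data frame over the good files) and
#'   `errors` (named character vector, one entry per failed file; empty on
#'   a clean run).
#' @export
run_features <- function(paths, cfg = run_config(), lex = default_lexicon()) {
  if (length(paths) == 0L) stop("empty input: no transcript files given")
  parsed <- list(); errors <- character(0)
  for (p in paths) {
    tr <- tryCatch(preprocess_transcript(parse_transcript(p)),
                   error = function(e) e)
    if (inherits(tr, "error")) errors[p] <- conditionMessage(tr)
    else parsed[[tr$dyad_id]] <- tr
  }
  if (!length(parsed)) stop("empty input: no transcript parsed successfully")
  feats <- extract_features(parsed, lex = lex, tagger = cfg$tagger,
                            mode = cfg$mode, attribution = cfg$attribution,
                            epsilon = cfg$epsilon,
                            bigram_min_share = cfg$bigram_min_share)
  list(features = feats, errors = errors)
}

.bind_stat_results <- function(results) {
  results <- Filter(Negate(is.null), results)
  if (!length(results)) return(NULL)
  do.call(rbind, results)
}

#' Run the full statistical analysis on a feature/outcome pair
#'
#' Joins features and outcomes on `dyad_id` and produces the report:
#' (i) mass-univariate F-regressions of every feature column on patient
#' alliance with FDR q-values (log dictionary features; raw transition and
#' bigram features; constant columns reported with NA statistics),
#' (ii) speaker-role comparisons (paired t on log dictionary features,
#' Wilcoxon signed-rank on transition features), (iii) trust-game
#' correlations (Pearson between repayment and the log pronoun features
#' and alliance; Spearman for the skewed transition feature),
#' (iv) the duration-partialled Spearman correlation for patient
#' AUX-INTJ, (v) Steiger's Z comparisons of each configured feature's
#' correlation across the goal/task/bond subscores, (vi) Kruskal-Wallis
#' of alliance across categorical covariates, and (vii) quasi-Bayesian
#' mediation for the configured exposures with the patient's mean
#' repayment fraction as mediator.
#'
#' @param features Feature table (from [extract_features()]).
#' @param outcomes Outcome table with `dyad_id`, `alliance_total`, `goal`,
#'   `task`, `bond`, `mean_RF_patient`, `mean_RF_therapist`, `duration`,
#'   and categorical covariates.
#' @param cfg A [run_config()].
#' @return An `analysis_report` list of result data frames plus a config
#'   fingerprint.
#' @export
run_analysis <- function(features, outcomes, cfg = run_config()) {
  miss_f <- setdiff(outcomes$dyad_id, features$dyad_id)
  miss_o <- setdiff(features$dyad_id, outcomes$dyad_id)
  if (length(miss_f) || length(miss_o))
    stop("join error: unmatched dyad_ids: ",
         paste(c(miss_f, miss_o), collapse = ", "))
  d <- merge(features, outcomes, by = "dyad_id", sort = TRUE)
  y <- d$alliance_total

  lex_cats <- sub("^patient_", "",
                  grep("^patient_[a-z]+$", names(features), value = TRUE))
  lex_cats <- setdiff(lex_cats, c("total"))
  log_cols <- grep("_log$", names(features), value = TRUE)
  trans_cols <- grep("INTJ", names(features), value = TRUE)
  bigram_cols <- grep("_bigram_", names(features), value = TRUE)
  predictors <- c(log_cols, trans_cols, bigram_cols)

  reg <- lapply(predictors, function(col) {
    x <- d[[col]]
    if (stats::sd(x) == 0)
      return(stat_result(col, "f_regression", NA_real_, NA_real_,
                         length(x), NA_real_))
    univariate_f_regression(x, y, feature = col)
  })
  regressions <- .bind_stat_results(reg)
  regressions$q <- NA_real_
  ok <- !is.na(regressions$p)
  regressions$q[ok] <- fdr_adjust(regressions$p[ok])

  role_cmp <- list()
  for (cat in lex_cats) {
    pcol <- paste0("patient_", cat, "_log"); tcol <- paste0("therapist_", cat, "_log")
    if (!pcol %in% names(d) || !tcol %in% names(d)) next
    role_cmp[[cat]] <- tryCatch(paired_t(d[[tcol]], d[[pcol]], feature = cat),
                                error = function(e) NULL)
  }
  base_trans <- unique(sub("^(patient|therapist)_", "", trans_cols))
  for (tr in base_trans) {
    pcol <- paste0("patient_", tr); tcol <- paste0("therapist_", tr)
    if (!pcol %in% names(d) || !tcol %in% names(d)) next
    role_cmp[[tr]] <- tryCatch(wilcoxon_paired(d[[pcol]], d[[tcol]], feature = tr),
                               error = function(e) NULL)
  }
  role_comparisons <- .bind_stat_results(role_cmp)

  gc <- list()
  safe_cor <- function(x, yv, method, label) tryCatch(
    correlation(x, yv, method, feature = label), error = function(e) NULL)
  gc$we <- safe_cor(d$therapist_we_log, d$mean_RF_patient, "pearson",
                    "therapist_we_log~mean_RF_patient")
  gc$i <- safe_cor(d$therapist_i_log, d$mean_RF_patient, "pearson",
                   "therapist_i_log~mean_RF_patient")
  gc$rf_all_p <- safe_cor(d$mean_RF_patient, y, "pearson",
                          "mean_RF_patient~alliance")
  gc$rf_all_t <- safe_cor(d$mean_RF_therapist, y, "pearson",
                          "mean_RF_therapist~alliance")
  gc$aux <- safe_cor(d[["patient_AUX-INTJ"]], d$mean_RF_patient, "spearman",
                     "patient_AUX-INTJ~mean_RF_patient")
  game_correlations <- .bind_stat_results(gc)

  partial <- tryCatch(
    partial_correlation(d[["patient_AUX-INTJ"]], y, log(d$duration),
                        method = "spearman",
                        feature = "patient_AUX-INTJ~alliance|log_duration"),
    error = function(e) NULL)

  subs <- c("goal", "task", "bond")
  st <- list()
  for (f in cfg$steiger_features) {
    if (!f %in% names(d)) next
    for (j in 1:2) for (h in (j + 1):3) {
      r_jk <- stats::cor(d[[f]], d[[subs[j]]])
      r_jh <- stats::cor(d[[f]], d[[subs[h]]])
      r_kh <- stats::cor(d[[subs[j]]], d[[subs[h]]])
      st[[paste(f, subs[j], subs[h], sep = "|")]] <-
        steiger_z(r_jk, r_jh, r_kh, nrow(d),
                  feature = paste0(f, ": ", subs[j], " vs ", subs[h]))
    }
  }
  steiger <- .bind_stat_results(st)

  kw <- list()
  for (v in intersect(c("clinic", "diagnosis"), names(d))) {
    if (length(unique(d[[v]])) >= 2)
      kw[[v]] <- kruskal_wallis(y, d[[v]], feature = paste0("alliance~", v))
  }
  kruskal <- .bind_stat_results(kw)

  med <- list()
  for (j in seq_along(cfg$mediation_exposures)) {
    f <- cfg$mediation_exposures[j]
    if (!f %in% names(d)) next
    med[[f]] <- tryCatch(
      mediate(d[[f]], d$mean_RF_patient, y,
              iterations = cfg$mediation_iterations, alpha = cfg$alpha,
              seed = child_seed(cfg$seed, paste0("mediate_", f)),
              feature = f),
      error = function(e) NULL)
    if (is.null(med[[f]])) med[[f]] <- NULL
  }
  mediation <- .bind_stat_results(lapply(med, function(m)
    data.frame(feature = m$feature, a = m$a, b = m$b, c = m$c,
               c_prime = m$c_prime, indirect = m$indirect,
               ci_low = m$ci_low, ci_high = m$ci_high,
               p_indirect = m$p_indirect, p_total = m$p_total,
               p_direct = m$p_direct, significant = m$significant,
               n = m$n, stringsAsFactors = FALSE)))

  structure(list(regressions = regressions,
                 role_comparisons = role_comparisons,
                 game_correlations = game_correlations,
                 partial = partial, steiger = steiger, kruskal = kruskal,
                 mediation = mediation, mediation_details = med,
                 config = list(seed = cfg$seed, alpha = cfg$alpha,
                               fdr_method = cfg$fdr_method,
                               transition_mode = cfg$mode,
                               attribution = cfg$attribution,
                               mediation_iterations = cfg$mediation_iterations),
                 n_dyads = nrow(d)),
            class = "analysis_report")
}

#' Write an analysis report to disk
#'
#' `report.json` holds every section plus the config fingerprint;
#' `report.csv` stacks the tabular sections with a `section` column.
#' Output bytes are deterministic for a fixed report.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sections <- c("regressions", "role_comparisons", "game_correlations",
                "steiger", "kruskal")
  tab <- do.call(rbind, lapply(sections, function(s) {
    df <- report[[s]]
    if (is.null(df)) return(NULL)
    cbind(section = s, as.data.frame(df))
  }))
  if (!is.null(report$partial))
    tab <- rbind(tab, cbind(section = "partial", as.data.frame(report$partial)))
  csv <- file.path(dir, "report.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  json <- file.path(dir, "report.json")
  payload <- report[c("regressions", "role_comparisons", "game_correlations",
                      "partial", "steiger", "kruskal", "mediation",
                      "config", "n_dyads")]
  jsonlite::write_json(payload, json, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(c(csv, json))
}
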