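# End-to-end orchestration: corpus analysis, enrollment modelling,
# validation statistics, file outputs and the run report.

#' Analyze a mixed tweet corpus
#'
#' The in-memory core of the pipeline: de-duplicates by tweet id, splits
#' the corpus into the keyword set (collection terms), the handle set
#' (marketplace `@handle` mentions, among tweets not already in the keyword
#' set) and the remaining random-sample comparators; scores every tweet
#' against the lexicon; Z-standardizes all scored tweets together (one
#' pooled standardization, so group contrasts share SD units); geocodes the
#' keyword set; aggregates keyword sentiment to state means; and computes
#' the group contrasts.
#'
#' @param tweets Tweet data frame from [read_tweets()].
#' @param lexicon A `sentiment_lexicon`.
#' @param gazetteer A `geo_gazetteer`.
#' @param terms Collection term table (see [default_terms()]).
#' @param handles Marketplace handle table (see [marketplace_handles()]).
#' @return List with `scores` (tweet_id, group, query_tag, raw, z, state),
#'   `state_table` (from [aggregate_by_state()]), `geo` (the keyword-set
#'   `geo_result`), `comparisons` (one row per group contrast, differences
#'   in SD units), and `counts` (per-stage record counts).
#' @export
analyze_corpus <- function(tweets, lexicon, gazetteer,
                           terms = default_terms(),
                           handles = marketplace_handles()) {
  n_read <- nrow(tweets)
  tweets <- dedupe_tweets(tweets)
  n_dedup <- nrow(tweets)
  kw <- filter_terms(tweets, terms)
  rest <- tweets[!(tweets$id %in% kw$id), , drop = FALSE]
  hd <- filter_mentions(rest, handles)
  rnd <- rest[!(rest$id %in% hd$id), , drop = FALSE]
  rnd$query_tag <- "random_sample"

  grp <- rbind(
    if (nrow(kw)) cbind(kw, group = "keyword", stringsAsFactors = FALSE),
    if (nrow(hd)) cbind(hd, group = "handle", stringsAsFactors = FALSE),
    if (nrow(rnd)) cbind(rnd, group = "random", stringsAsFactors = FALSE)
  )
  if (is.null(grp) || nrow(grp) == 0L) {
    stop("no tweets left after filtering", call. = FALSE)
  }
  raw <- score_tweets(grp$text, lexicon)
  scoreable <- !is.na(raw)
  n_unscoreable <- sum(!scoreable)
  scores <- data.frame(tweet_id = grp$id[scoreable],
                       group = grp$group[scoreable],
                       query_tag = grp$query_tag[scoreable],
                       raw = raw[scoreable], stringsAsFactors = FALSE)
  scores$z <- zscore_corpus(scores$raw)

  kw_scored <- grp[scoreable & grp$group == "keyword", , drop = FALSE]
  geo <- geocode_corpus(kw_scored, gazetteer)
  state_table <- aggregate_by_state(scores, geo$resolutions)
  scores <- merge(scores, geo$resolutions[c("tweet_id", "state")],
                  by = "tweet_id", all.x = TRUE, sort = FALSE)
  scores <- scores[order(scores$tweet_id), , drop = FALSE]
  rownames(scores) <- NULL

  cmp <- function(label, za, zb) {
    if (length(za) < 2L || length(zb) < 2L) return(NULL)
    g <- compare_groups(za, zb)
    data.frame(comparison = label, diff_sd = g$difference, t = g$t,
               df = g$df, p = g$p, n_a = g$n_a, n_b = g$n_b,
               stringsAsFactors = FALSE)
  }
  z_of <- function(sel) scores$z[sel]
  comparisons <- do.call(rbind, Filter(Negate(is.null), list(
    cmp("keyword_vs_random",
        z_of(scores$group == "keyword"), z_of(scores$group == "random")),
    cmp("aca_vs_obamacare",
        z_of(scores$query_tag == "aca"),
        z_of(scores$query_tag == "obamacare")),
    cmp("handle_federal_vs_state",
        z_of(scores$query_tag == "handle_federal"),
        z_of(scores$query_tag == "handle_state"))
  )))

  list(scores = scores, state_table = state_table, geo = geo,
       comparisons = comparisons,
       counts = list(n_read = n_read, n_after_dedup = n_dedup,
                     n_keyword = nrow(kw), n_handle = nrow(hd),
                     n_random = nrow(rnd), n_unscoreable = n_unscoreable,
                     n_scored = nrow(scores),
                     n_geocoded = geo$summary$n_resolved,
                     fraction_geocoded = geo$summary$fraction_resolved))
}

#' Bin state sentiment into quartiles
#'
#' Reproduces the choropleth's quartile presentation as data: states are
#' ranked by `mean_z` and binned into quartiles 1 (lowest sentiment) to 4
#' (highest); bin sizes differ by at most one and ties go to the lower bin.
#'
#' @param state_sentiment Data frame with `state` and `mean_z` (at least 4
#'   rows).
#' @param path Optional CSV output path.
#' @return The input with a `quartile` column appended.
#' @export
export_state_table <- function(state_sentiment, path = NULL) {
  stopifnot(is.data.frame(state_sentiment),
            all(c("state", "mean_z") %in% names(state_sentiment)))
  n <- nrow(state_sentiment)
  if (n < 4L) stop("need at least 4 states for quartile binning",
                   call. = FALSE)
  r <- rank(state_sentiment$mean_z, ties.method = "min")
  state_sentiment$quartile <- as.integer(floor((r - 1) * 4 / n) + 1)
  if (!is.null(path)) {
    write.csv(state_sentiment, path, row.names = FALSE, quote = FALSE)
  }
  state_sentiment
}

#' Assemble a pipeline configuration
#'
#' @param corpus,lexicon,enrollment Paths to the tweet JSON-lines file, the
#'   lexicon TSV, and the enrollment CSV (all required at run time).
#' @param ratings Optional path to a ratings CSV for rater validation.
#' @param out_dir Output directory (created if absent).
#' @param states_path,cities_path,polygons_path,handles_path Optional
#'   gazetteer / handle-table replacements.
#' @param outlier_k SD multiplier of the enrollment outlier rule.
#' @param outcome `"pct"` or `"log"` enrollment outcome scale.
#' @param seed Seed recorded in the run report (the analysis pipeline
#'   itself is deterministic; only synthetic generation draws random
#'   numbers).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(corpus, lexicon, enrollment, ratings = NULL,
                            out_dir = tempfile("acasent_run_"),
                            states_path = NULL, cities_path = NULL,
                            polygons_path = NULL, handles_path = NULL,
                            outlier_k = 2.5, outcome = c("pct", "log"),
                            seed = 1) {
  stopifnot(outlier_k > 0)
  structure(list(corpus = corpus, lexicon = lexicon,
                 enrollment = enrollment, ratings = ratings,
                 out_dir = out_dir, states_path = states_path,
                 cities_path = cities_path, polygons_path = polygons_path,
                 handles_path = handles_path, outlier_k = outlier_k,
                 outcome = match.arg(outcome), seed = seed),
            class = "pipeline_config")
}

fit_to_list <- function(fit) {
  fit[c("slope_per_unit", "effect_per_0p10", "robust_se",
        "robust_se_per_0p10", "ci95", "p", "n_states", "df", "covariates",
        "outcome", "coefficients")]
}

#' Run the full analysis pipeline
#'
#' Executes every stage on files named in the configuration and writes the
#' stage outputs plus a run report to the output directory:
#' `tweet_scores.csv`, `state_sentiment.csv` (with quartile bins),
#' `group_comparisons.csv`, `enrollment_model.json` (unadjusted model plus
#' one model per policy covariate and a both-covariates model),
#' `validation.json` (when ratings are supplied) and `run_report.json`
#' (input MD5 hashes, per-stage counts, package version). The analysis is
#' deterministic: rerunning the same configuration reproduces every output
#' byte for byte.
#'
#' @param config A [pipeline_config()], or the path to a JSON file with the
#'   same fields.
#' @return Invisibly, a list with `analysis` (see [analyze_corpus()]),
#'   `enrollment` (kept/excluded after the outlier rule), `models`,
#'   `validation` and `report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    cfg_list <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- do.call(pipeline_config, cfg_list)
  }
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("corpus", "lexicon", "enrollment")) {
    if (!is.character(config[[f]]) || !file.exists(config[[f]])) {
      stop("input file for '", f, "' not found: ", config[[f]],
           call. = FALSE)
    }
  }
  if (!is.null(config$ratings) && !file.exists(config$ratings)) {
    stop("ratings file not found: ", config$ratings, call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  gaz <- load_gazetteer(config$states_path, config$cities_path,
                        config$polygons_path)
  handles <- marketplace_handles(config$handles_path)
  lex <- load_lexicon(config$lexicon)
  tweets <- read_tweets(config$corpus)
  an <- analyze_corpus(tweets, lex, gaz, default_terms(), handles)

  enr <- read_enrollment(config$enrollment)
  excl <- exclude_outliers(enr, k = config$outlier_k)
  kept <- excl$kept
  no_sent <- setdiff(kept$state, an$state_table$state)
  if (length(no_sent)) {
    warning("dropping state(s) with no geocoded tweets from the model: ",
            paste(sort(no_sent), collapse = ", "), call. = FALSE)
    kept <- kept[!(kept$state %in% no_sent), , drop = FALSE]
  }
  models <- list(
    unadjusted = fit_enrollment_model(kept, an$state_table,
                                      outcome = config$outcome),
    medicaid_expansion = fit_enrollment_model(
      kept, an$state_table, covariates = "medicaid_expansion",
      outcome = config$outcome),
    state_based_marketplace = fit_enrollment_model(
      kept, an$state_table, covariates = "state_based_marketplace",
      outcome = config$outcome),
    both_covariates = fit_enrollment_model(
      kept, an$state_table,
      covariates = c("medicaid_expansion", "state_based_marketplace"),
      outcome = config$outcome)
  )

  validation <- NULL
  if (!is.null(config$ratings)) {
    m <- read_ratings(config$ratings)
    sc <- an$scores[match(rownames(m), an$scores$tweet_id), , drop = FALSE]
    if (anyNA(sc$raw)) {
      stop("ratings reference tweet ids absent from the scored corpus",
           call. = FALSE)
    }
    svh <- score_vs_human(sc$raw, rowMeans(m))
    validation <- list(n_rated = nrow(m),
                       icc2_1 = icc_two_rater(m, type = "ICC2"),
                       icc3_1 = icc_two_rater(m, type = "ICC3"),
                       r_score_vs_human = svh$r,
                       p_score_vs_human = svh$p)
  }

  out <- function(x) file.path(config$out_dir, x)
  write.csv(an$scores, out("tweet_scores.csv"), row.names = FALSE,
            quote = FALSE)
  state_tbl <- if (nrow(an$state_table) >= 4L) {
    export_state_table(an$state_table, out("state_sentiment.csv"))
  } else {
    an$state_table
  }
  if (!is.null(an$comparisons)) {
    write.csv(an$comparisons, out("group_comparisons.csv"),
              row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(lapply(models, fit_to_list),
                       out("enrollment_model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(validation)) {
    jsonlite::write_json(validation, out("validation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  inputs <- Filter(Negate(is.null),
                   config[c("corpus", "lexicon", "enrollment", "ratings")])
  report <- list(
    package_version = as.character(packageVersion("acasent")),
    seed = config$seed,
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    counts = c(an$counts,
               list(n_states_sentiment = nrow(an$state_table),
                    n_enrollment_states = nrow(enr),
                    n_outliers_excluded = nrow(excl$excluded),
                    outlier_states = excl$excluded$state,
                    n_states_model = models$unadjusted$n_states)),
    outlier_threshold = excl$threshold,
    outputs = list.files(config$out_dir)
  )
  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(analysis = c(an[setdiff(names(an), "state_table")],
                              list(state_table = state_tbl)),
                 enrollment = excl, models = models,
                 validation = validation, report = report))
}

#' Generate a complete synthetic scenario on disk
#'
#' Writes every pipeline input for a seeded scenario into a directory:
#' `lexicon.tsv`, `corpus.jsonl` (keyword + handle + random-sample
#' sub-corpora), `enrollment.csv` and `ratings.csv`, plus `scenario.json`
#' recording the configuration and the planted truth. Because enrollment is
#' generated from the realized state sentiment (scored with this package's
#' own pipeline stages), the planted enrollment slope is exact with respect
#' to the state sentiment a subsequent [run_pipeline()] will recompute.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if absent).
#' @return List with `paths` (named input paths), `truth` (planted
#'   quantities from [generate_tweets()] plus the true slope), `analysis`
#'   (the corpus analysis used to realize state sentiment) and `config`.
#' @export
simulate_scenario <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(corpus = file.path(dir, "corpus.jsonl"),
                lexicon = file.path(dir, "lexicon.tsv"),
                enrollment = file.path(dir, "enrollment.csv"),
                ratings = file.path(dir, "ratings.csv"),
                scenario = file.path(dir, "scenario.json"))
  gaz <- load_gazetteer()
  lx <- generate_lexicon(cfg, paths$lexicon)
  truth <- generate_tweets(cfg, lx, gaz, paths$corpus)
  tweets <- read_tweets(paths$corpus)
  an <- analyze_corpus(tweets, lx$lexicon, gaz)
  generate_enrollment(cfg, an$state_table, paths$enrollment)
  kw <- an$scores[an$scores$group == "keyword", , drop = FALSE]
  generate_ratings(cfg,
                   data.frame(tweet_id = kw$tweet_id, score = kw$raw,
                              stringsAsFactors = FALSE),
                   paths$ratings)
  truth$true_slope <- cfg$true_slope
  truth$enroll_intercept <- cfg$enroll_intercept
  jsonlite::write_json(list(config = unclass(cfg),
                            truth = truth[c("states", "state_mean_scores",
                                            "baseline_score_sd",
                                            "n_keyword", "n_random",
                                            "n_handle_federal",
                                            "n_handle_state",
                                            "n_resolvable", "true_slope")]),
                       paths$scenario, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(paths = paths, truth = truth, analysis = an, config = cfg)
}
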