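# Synthetic-data generation with planted ground truth.
#
# Every pipeline input (lexicon, tweet corpora, enrollment table, rater
# files) can be generated from a seeded configuration. Tweets are
# synthesized from the toy lexicon's word model rather than natural
# language, which makes expected tweet scores analytically computable:
# each tweet is a fixed number of independent category draws (positive,
# mildly positive, mildly negative, negative, neutral out-of-vocabulary)
# plus one tag token, so the expected score and its variance follow in
# closed form from the category probabilities. Planted state effects and
# group shifts tilt the category mixture; geolocation fields are planted
# deterministically so the resolvable fraction is exact by construction.

# Category weights and the two anchor mixtures. A tweet group's word
# distribution is the convex combination (1 - lambda) * p_neg + lambda *
# p_pos; the mean lexicon weight is linear in lambda, so any target mean in
# [E_neg, E_pos] maps to exactly one lambda.
word_model <- function() {
  weights <- c(pos2 = 2, pos1 = 1, neg1 = -1, neg3 = -3, neutral = 0)
  p_neg <- c(0.02, 0.08, 0.25, 0.25, 0.40)
  p_pos <- c(0.25, 0.25, 0.08, 0.02, 0.40)
  e_neg <- sum(weights * p_neg)
  e_pos <- sum(weights * p_pos)
  words <- list(
    pos2 = c("stellar", "superb", "wonderful", "fantastic"),
    pos1 = c("helpful", "pleased", "smooth", "useful"),
    neg1 = c("annoying", "glitchy", "costly", "slow"),
    neg3 = c("horrible", "nightmare", "dreadful", "furious"),
    neutral = c("website", "plan", "coverage", "policy", "people", "today",
                "phone", "form")
  )
  list(weights = weights, p_neg = p_neg, p_pos = p_pos,
       e_neg = e_neg, e_pos = e_pos, words = words)
}

# lambda for a target mean word weight; errors outside the feasible range.
lambda_for_mean <- function(mu_word, model) {
  if (any(mu_word < model$e_neg - 1e-12) || any(mu_word > model$e_pos + 1e-12)) {
    stop("target mean word weight ", fmt_num(max(abs(mu_word))),
         " outside the feasible range [", fmt_num(model$e_neg), ", ",
         fmt_num(model$e_pos), "]", call. = FALSE)
  }
  (mu_word - model$e_neg) / (model$e_pos - model$e_neg)
}

mixture_probs <- function(lambda, model) {
  (1 - lambda) * model$p_neg + lambda * model$p_pos
}

# SD of a single category draw's weight at mixture lambda.
mixture_sd <- function(lambda, model) {
  p <- mixture_probs(lambda, model)
  sqrt(sum(model$weights^2 * p) - sum(model$weights * p)^2)
}

#' Synthetic scenario configuration
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' describe the emulated study conditions: 50 states + DC; a keyword corpus
#' whose sentiment sits 0.44 within-group SD below an equally sized random
#' sample; an 0.46 ACA-vs-Obamacare gap within the keyword corpus (ACA
#' higher); marketplace-handle corpora with the federal handle 0.20 SD
#' below the state handles; 46% of keyword tweets carrying resolvable
#' geography; enrollment at mean 23.5% with a planted slope of 87
#' percentage points per sentiment-SD (8.7 per 0.10 units), Gaussian state
#' noise of 8 points, and one state (Vermont) planted 3 SD above the mean;
#' and a 300-tweet two-rater validation study with a score-human
#' correlation of 0.26.
#'
#' @param seed Master integer seed; every generator stage derives its own
#'   stream from it.
#' @param n_states Number of state units (the first `n_states` gazetteer
#'   codes in lexicographic order; 51 = 50 states + DC).
#' @param tweets_per_state Keyword tweets generated per state.
#' @param words_per_tweet Lexicon-model word draws per tweet (plus one tag
#'   token).
#' @param state_effect_range_sd Total range of the planted per-state mean
#'   raw scores, in units of the within-group score SD; states are evenly
#'   spaced over it in state-code order.
#' @param shift_aca_all_sd Mean shift of the whole keyword corpus relative
#'   to the random sample (SD units; negative = more negative sentiment).
#' @param aca_vs_obamacare_sd Planted gap between ACA-tagged and
#'   Obamacare-tagged tweets (SD units; positive = ACA higher).
#' @param handle_base_sd,federal_vs_state_handle_sd Mean shift of the
#'   handle corpora and the federal-minus-state-handle gap (SD units).
#' @param handle_fraction Handle-corpus size as a fraction of the keyword
#'   corpus (split evenly between the federal and state handles).
#' @param geo_resolvable_fraction Fraction of keyword tweets planted with
#'   resolvable geography (coordinates, "City, ST", or a full state name,
#'   cycled deterministically).
#' @param enroll_intercept,true_slope,noise_sd Enrollment model:
#'   `pct = intercept + slope * (mean_z - mean(mean_z)) + N(0, noise_sd)`,
#'   floored at 0.05%; the intercept is the mean rate across states.
#' @param outlier_states Named numeric vector of planted outliers: each
#'   state's enrollment is reset to `mean + offset * sd` of the remaining
#'   states (e.g. `c(VT = 3)`).
#' @param eligible_base,eligible_step Eligible-population counts per state
#'   (`base + step * state_index`; deterministic).
#' @param n_rated,target_score_human_corr,rater_noise_sd Rater study:
#'   number of sampled keyword tweets, target correlation between lexicon
#'   scores and the human consensus, and the per-rater noise SD (rating
#'   units) controlling interrater reliability. The default noise SD is
#'   calibrated by simulation so that after integer rounding and clipping
#'   of the ratings the population two-rater ICC(2,1) is about 0.72.
#' @return A `synthetic_config` list.
#' @seealso [scenario_recovery()] for a preset tuned to parameter-recovery
#'   validation rather than study emulation.
#' @export
synthetic_config <- function(seed = 1,
                             n_states = 51,
                             tweets_per_state = 1000,
                             words_per_tweet = 20,
                             state_effect_range_sd = 0.35,
                             shift_aca_all_sd = -0.44,
                             aca_vs_obamacare_sd = 0.46,
                             handle_base_sd = -0.30,
                             federal_vs_state_handle_sd = -0.20,
                             handle_fraction = 0.035,
                             geo_resolvable_fraction = 0.46,
                             enroll_intercept = 23.5,
                             true_slope = 87,
                             noise_sd = 8,
                             outlier_states = c(VT = 3),
                             eligible_base = 400000,
                             eligible_step = 23000,
                             n_rated = 300,
                             target_score_human_corr = 0.26,
                             rater_noise_sd = 0.87) {
  stopifnot(n_states >= 2, n_states <= 51, tweets_per_state >= 1,
            words_per_tweet >= 1,
            geo_resolvable_fraction >= 0, geo_resolvable_fraction <= 1,
            handle_fraction >= 0,
            abs(target_score_human_corr) < 1)
  structure(list(seed = seed, n_states = n_states,
                 tweets_per_state = tweets_per_state,
                 words_per_tweet = words_per_tweet,
                 state_effect_range_sd = state_effect_range_sd,
                 shift_aca_all_sd = shift_aca_all_sd,
                 aca_vs_obamacare_sd = aca_vs_obamacare_sd,
                 handle_base_sd = handle_base_sd,
                 federal_vs_state_handle_sd = federal_vs_state_handle_sd,
                 handle_fraction = handle_fraction,
                 geo_resolvable_fraction = geo_resolvable_fraction,
                 enroll_intercept = enroll_intercept,
                 true_slope = true_slope, noise_sd = noise_sd,
                 outlier_states = outlier_states,
                 eligible_base = eligible_base,
                 eligible_step = eligible_step,
                 n_rated = n_rated,
                 target_score_human_corr = target_score_human_corr,
                 rater_noise_sd = rater_noise_sd),
            class = "synthetic_config")
}

#' Parameter-recovery scenario preset
#'
#' A configuration tuned for recovery validation rather than study
#' emulation: 50 states, 5000 tweets per state, fully resolvable
#' geography, no group shifts, and planted state means spread over 3.8
#' within-group SDs end to end — the widest spacing the word model's
#' feasible mean range admits, and wide enough (adjacent-state gaps of
#' about four standard errors) that the state ranking is recovered with
#' near-certainty at this sample size. The enrollment slope and noise
#' are scaled so all generated rates stay well inside (0, 100).
#'
#' @param seed Master seed.
#' @return A `synthetic_config`.
#' @export
scenario_recovery <- function(seed = 1) {
  synthetic_config(seed = seed, n_states = 50, tweets_per_state = 5000,
                   state_effect_range_sd = 3.8,
                   shift_aca_all_sd = 0, aca_vs_obamacare_sd = 0,
                   handle_base_sd = 0, federal_vs_state_handle_sd = 0,
                   handle_fraction = 0.02,
                   geo_resolvable_fraction = 1.0,
                   enroll_intercept = 40, true_slope = 12, noise_sd = 6,
                   outlier_states = NULL)
}

set_stream <- function(cfg, stage) {
  set.seed(stage_seed(cfg$seed, stage), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

#' Generate the toy sentiment lexicon and its word-frequency model
#'
#' The lexicon holds 16 sentiment words over the weights +2, +1, -1, -3
#' (four words per weight); eight neutral filler words stay out of
#' vocabulary so they exercise the all-words denominator. The returned
#' model carries the category probabilities, which make every planted
#' group's expected tweet score analytically computable.
#'
#' @param cfg A [synthetic_config()].
#' @param path Optional path; when given, the lexicon is written there in
#'   the two-column TSV dialect.
#' @return List with `lexicon` (a `sentiment_lexicon`) and `model` (the
#'   category mixture: weights, anchor probabilities, word lists).
#' @export
generate_lexicon <- function(cfg, path = NULL) {
  model <- word_model()
  entries <- unlist(lapply(names(model$words)[1:4], function(cat) {
    setNames(rep(model$weights[[cat]], length(model$words[[cat]])),
             model$words[[cat]])
  }))
  lex <- new_lexicon(entries)
  if (!is.null(path)) write_lexicon(lex, path)
  list(lexicon = lex, model = model)
}

# States used by a config: the first n_states gazetteer codes.
config_states <- function(cfg, gazetteer) {
  sort(gazetteer$states$code)[seq_len(cfg$n_states)]
}

# Baseline within-group score SD (sigma of one tweet's score at the neutral
# mixture): sd(weight) * sqrt(n_words) / (n_words + 1), the +1 being the
# out-of-vocabulary tag token.
baseline_score_sd <- function(cfg, model) {
  lam0 <- lambda_for_mean(0, model)
  mixture_sd(lam0, model) * sqrt(cfg$words_per_tweet) /
    (cfg$words_per_tweet + 1)
}

# Draw n_tweets x n_words word tokens at mixture lambda.
draw_words <- function(n_tweets, n_words, lambda, model) {
  p <- mixture_probs(lambda, model)
  cat_idx <- sample.int(5L, n_tweets * n_words, replace = TRUE, prob = p)
  tok <- character(n_tweets * n_words)
  for (ci in 1:5) {
    sel <- cat_idx == ci
    if (any(sel)) {
      pool <- model$words[[ci]]
      tok[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
    }
  }
  matrix(tok, nrow = n_tweets)
}

# Planted per-state mean raw scores, evenly spaced in state-code order.
planted_state_means <- function(cfg, model) {
  sigma <- baseline_score_sd(cfg, model)
  half <- cfg$state_effect_range_sd / 2 * sigma
  seq(-half, half, length.out = cfg$n_states)
}

#' Generate the synthetic tweet corpus
#'
#' Writes one JSON-lines file containing three planted sub-corpora:
#' keyword tweets (one `ACA` or `Obamacare` term each, alternating, with
#' per-state sentiment tilts and planted geography), marketplace-handle
#' tweets (one `@handle` mention each), and random-sample comparator tweets
#' (a neutral filler token, no terms, no handles). The collection filters
#' therefore retain exactly the planted sets. Within each state, exactly
#' `round(geo_resolvable_fraction * tweets_per_state)` keyword tweets carry
#' resolvable geography, cycling coordinates (the state's representative
#' interior point), `"City, ST"` strings, and full state names; the rest
#' cycle junk strings and missing locations.
#'
#' @param cfg A [synthetic_config()].
#' @param lexmodel Result of [generate_lexicon()].
#' @param gazetteer A `geo_gazetteer`.
#' @param path Output JSON-lines path.
#' @return Invisibly, the planted truth: state codes, per-state mean raw
#'   scores, per-corpus sizes, the planted resolvable count, and the group
#'   mean scores.
#' @export
generate_tweets <- function(cfg, lexmodel, gazetteer, path) {
  model <- lexmodel$model
  states <- config_states(cfg, gazetteer)
  n_words <- cfg$words_per_tweet
  denom <- n_words + 1
  sigma <- baseline_score_sd(cfg, model)
  # score-unit shifts -> mean word weight: mu_word = mu_score * denom / n.
  to_word <- function(mu_score) mu_score * denom / n_words
  state_means <- planted_state_means(cfg, model)
  names(state_means) <- states

  set_stream(cfg, "tweets")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))

  junk <- c(NA, "Earth", "in my feelings", "somewhere out there", "worldwide")
  n_res_state <- round(cfg$geo_resolvable_fraction * cfg$tweets_per_state)

  # One planted city per state, skipping city names that contain a
  # *different* state's name ("Kansas City" would resolve to KS under the
  # state-name-first precedence): planted strings must be unambiguous.
  name_norm <- normalize_phrase(gazetteer$states$name)
  other_state_in <- function(city, s) {
    cn <- normalize_phrase(city)
    hits <- vapply(name_norm, function(p) grepl(p, cn, fixed = TRUE),
                   logical(1))
    any(hits & gazetteer$states$code != s)
  }
  state_city <- setNames(rep(NA_character_, length(states)), states)
  for (s in states) {
    cand <- gazetteer$cities$city[gazetteer$cities$state == s]
    cand <- cand[!vapply(cand, other_state_in, logical(1), s = s)]
    if (length(cand)) state_city[s] <- cand[1]
  }
  state_name <- setNames(gazetteer$states$name, gazetteer$states$code)
  rep_lat <- setNames(gazetteer$states$rep_lat, gazetteer$states$code)
  rep_lon <- setNames(gazetteer$states$rep_lon, gazetteer$states$code)

  esc <- function(x) gsub('"', '\\\\"', x)
  kw_counter <- 0L
  group_sums <- c(aca = 0, obamacare = 0)
  group_ns <- c(aca = 0L, obamacare = 0L)

  half_gap <- cfg$aca_vs_obamacare_sd / 2
  paste_rows <- function(wmat) {
    do.call(paste, as.data.frame(wmat, stringsAsFactors = FALSE))
  }
  for (si in seq_along(states)) {
    s <- states[si]
    nt <- cfg$tweets_per_state
    # geo plan: tweet positions 1..n_res_state (within the state) are
    # resolvable; forms cycle deterministically by position.
    pos <- seq_len(nt)
    geo_all <- character(nt)
    res <- pos <= n_res_state
    form <- pos %% 3L
    coord_geo <- sprintf('"coordinates":[%.5f,%.5f],"user":{"location":null}',
                         rep_lon[s], rep_lat[s])
    city_str <- if (!is.na(state_city[s])) {
      sprintf("%s, %s", state_city[s], s)
    } else {
      sprintf("Smallville, %s", s)
    }
    geo_all[res & form == 1L] <- coord_geo
    geo_all[res & form == 2L] <-
      sprintf('"coordinates":null,"user":{"location":"%s"}', esc(city_str))
    geo_all[res & form == 0L] <-
      sprintf('"coordinates":null,"user":{"location":"%s"}',
              esc(state_name[s]))
    jk <- junk[(pos %% length(junk)) + 1L]
    geo_all[!res] <- ifelse(is.na(jk[!res]),
                            '"coordinates":null,"user":{"location":null}',
                            sprintf('"coordinates":null,"user":{"location":"%s"}',
                                    jk[!res]))
    tag <- rep(c("aca", "obamacare"), length.out = nt)
    for (g in c("aca", "obamacare")) {
      idx <- which(tag == g)
      shift_sd <- cfg$shift_aca_all_sd + if (g == "aca") half_gap else -half_gap
      mu_score <- state_means[si] + shift_sd * sigma
      lam <- lambda_for_mean(to_word(mu_score), model)
      wmat <- draw_words(length(idx), n_words, lam, model)
      term <- if (g == "aca") "ACA" else "Obamacare"
      texts <- paste(term, paste_rows(wmat))
      ids <- sprintf("kw%07d", kw_counter + idx)
      writeLines(sprintf('{"id":"%s","text":"%s",%s}',
                         ids, esc(texts), geo_all[idx]), con)
      group_sums[g] <- group_sums[g] + length(idx) * mu_score
      group_ns[g] <- group_ns[g] + length(idx)
    }
    kw_counter <- kw_counter + nt
  }

  # Marketplace-handle corpora.
  n_handle <- round(cfg$handle_fraction * cfg$n_states * cfg$tweets_per_state)
  n_fed <- n_handle %/% 2L
  n_sta <- n_handle - n_fed
  handles <- marketplace_handles()
  state_handles <- handles$handle[handles$group == "state"]
  hd_counter <- 0L
  for (g in c("federal", "state")) {
    ng <- if (g == "federal") n_fed else n_sta
    if (ng == 0L) next
    shift_sd <- cfg$handle_base_sd +
      (if (g == "federal") 0.5 else -0.5) * cfg$federal_vs_state_handle_sd
    lam <- lambda_for_mean(to_word(shift_sd * sigma), model)
    wmat <- draw_words(ng, n_words, lam, model)
    hh <- if (g == "federal") rep("@HealthCareGov", ng) else
      rep(state_handles, length.out = ng)
    texts <- paste(hh, paste_rows(wmat))
    ids <- sprintf("hd%07d", hd_counter + seq_len(ng))
    writeLines(sprintf(
      '{"id":"%s","text":"%s","coordinates":null,"user":{"location":null}}',
      ids, esc(texts)), con)
    hd_counter <- hd_counter + ng
  }

  # Random-sample comparator corpus, same size as the keyword corpus.
  n_rand <- cfg$n_states * cfg$tweets_per_state
  lam0 <- lambda_for_mean(0, model)
  block <- 50000L
  done <- 0L
  while (done < n_rand) {
    nb <- min(block, n_rand - done)
    wmat <- draw_words(nb, n_words, lam0, model)
    texts <- paste("brunch", paste_rows(wmat))
    ids <- sprintf("rs%07d", done + seq_len(nb))
    writeLines(sprintf(
      '{"id":"%s","text":"%s","coordinates":null,"user":{"location":null}}',
      ids, esc(texts)), con)
    done <- done + nb
  }

  invisible(list(
    states = states,
    state_mean_scores = state_means,
    baseline_score_sd = sigma,
    n_keyword = cfg$n_states * cfg$tweets_per_state,
    n_random = n_rand,
    n_handle_federal = n_fed,
    n_handle_state = n_sta,
    n_resolvable = n_res_state * cfg$n_states,
    n_resolvable_per_state = n_res_state,
    group_mean_scores = as.list(group_sums / pmax(group_ns, 1L))
  ))
}

#' Generate a synthetic state enrollment table
#'
#' Enrollment is generated from the realized state sentiment:
#' `pct = intercept + true_slope * (mean_z - mean(mean_z)) + N(0, noise_sd)`,
#' floored at 0.05% (enrollment rates are strictly positive; the centering
#' anchors the intercept at the average state sentiment), then converted to
#' integer plan-selection / eligible-population pairs. Planted outlier
#' states are reset to `mean + offset * sd` of the other states after the
#' base draw. Medicaid-expansion and marketplace-type flags are assigned at
#' random (independently of sentiment).
#'
#' @param cfg A [synthetic_config()].
#' @param state_sentiment Data frame with `state` and `mean_z` covering all
#'   configured states.
#' @param path Optional CSV output path.
#' @return Data frame with columns `state`, `plan_selections`, `eligible`,
#'   `medicaid_expansion`, `state_based_marketplace`, `pct_enrolled`
#'   (the exact generated percent, before integer conversion), and
#'   attribute `true_slope`.
#' @export
generate_enrollment <- function(cfg, state_sentiment, path = NULL) {
  stopifnot(all(c("state", "mean_z") %in% names(state_sentiment)))
  ss <- state_sentiment[order(state_sentiment$state), , drop = FALSE]
  n <- nrow(ss)
  set_stream(cfg, "enrollment")
  # The intercept is anchored at the average state sentiment, so
  # enroll_intercept is the mean enrollment rate across states regardless
  # of where the corpus sits on the pooled Z scale.
  x <- ss$mean_z - mean(ss$mean_z)
  pct <- cfg$enroll_intercept + cfg$true_slope * x +
    rnorm(n, sd = cfg$noise_sd)
  pct <- pmax(pct, 0.05)
  out_states <- names(cfg$outlier_states)
  out_states <- intersect(out_states, ss$state)
  if (length(out_states)) {
    for (s in out_states) {
      others <- pct[ss$state != s]
      pct[ss$state == s] <- mean(others) +
        cfg$outlier_states[[s]] * sd(others)
    }
  }
  eligible <- cfg$eligible_base + cfg$eligible_step * seq_len(n)
  selections <- pmax(round(pct / 100 * eligible), 0L)
  flags <- matrix(rbinom(2L * n, 1L, 0.5) == 1L, ncol = 2L)
  d <- data.frame(state = ss$state,
                  plan_selections = as.integer(selections),
                  eligible = as.integer(eligible),
                  medicaid_expansion = flags[, 1],
                  state_based_marketplace = flags[, 2],
                  pct_enrolled = pct,
                  stringsAsFactors = FALSE)
  attr(d, "true_slope") <- cfg$true_slope
  if (!is.null(path)) {
    write.csv(d[, c("state", "plan_selections", "eligible",
                    "medicaid_expansion", "state_based_marketplace")],
              path, row.names = FALSE, quote = FALSE)
  }
  d
}

#' Generate synthetic two-rater validation ratings
#'
#' Each sampled tweet gets a latent human consensus correlated with its
#' lexicon score at `target_score_human_corr`; the two raters observe the
#' consensus plus independent Gaussian noise (`rater_noise_sd`), scaled to
#' the rating range and rounded to integers in -3..3. With zero rater noise
#' the raters agree exactly (ICC = 1).
#'
#' @param cfg A [synthetic_config()].
#' @param scores Data frame with `tweet_id` and raw or standardized `score`
#'   for the candidate tweets; `cfg$n_rated` of them are sampled.
#' @param path Optional CSV output path (long format: `tweet_id`,
#'   `rater_id`, `rating`).
#' @return Long-format ratings data frame with attribute `latent`
#'   (data frame of sampled `tweet_id`, `score`, latent consensus).
#' @export
generate_ratings <- function(cfg, scores, path = NULL) {
  stopifnot(all(c("tweet_id", "score") %in% names(scores)))
  n <- min(cfg$n_rated, nrow(scores))
  if (n < 3L) stop("need at least 3 tweets to rate", call. = FALSE)
  set_stream(cfg, "ratings")
  pick <- sort(sample.int(nrow(scores), n))
  s <- scores$score[pick]
  z <- (s - mean(s)) / pop_sd(s)
  rho <- cfg$target_score_human_corr
  latent <- rho * z + sqrt(1 - rho^2) * rnorm(n)
  signal <- 1.5 * latent
  clip <- function(x) pmin(3L, pmax(-3L, as.integer(round(x))))
  r1 <- clip(signal + rnorm(n, sd = cfg$rater_noise_sd))
  r2 <- clip(signal + rnorm(n, sd = cfg$rater_noise_sd))
  d <- data.frame(tweet_id = rep(scores$tweet_id[pick], 2L),
                  rater_id = rep(c("rater1", "rater2"), each = n),
                  rating = c(r1, r2), stringsAsFactors = FALSE)
  attr(d, "latent") <- data.frame(tweet_id = scores$tweet_id[pick],
                                  score = s, latent = latent,
                                  stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write.csv(d, path, row.names = FALSE, quote = FALSE)
  }
  d
}
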