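# Tweet tokenization, lexicon scoring, Z-standardization, state
# aggregation and group contrasts.
#
# The per-tweet score is the frequency-weighted sum of lexicon weights:
#
#   score(tweet) = sum_{word in tweet} weight(word) * n(word) / n_total
#
# where n(word) is the word's occurrence count in the tweet and n_total the
# total (non-unique) token count. Out-of-vocabulary tokens carry weight 0
# but still inflate n_total: the denominator is the number of words in the
# tweet, not the number of lexicon words.

#' Tokenize tweet text
#'
#' Splits on whitespace, strips leading/trailing punctuation (keeping a
#' leading `#` or `@`), and optionally lowercases. Each hashtag token
#' `#tag` additionally yields the bare token `tag`, so lexicon matching
#' works with or without the `#`; both forms count in the all-words total.
#' `@handle` tokens and URLs are kept as single tokens (they score 0 against
#' a word lexicon but count in the denominator).
#'
#' @param text Character vector of tweet texts.
#' @param lower Lowercase tokens? Scoring uses lowercased tokens; the
#'   collection filters use `lower = FALSE` to honour case-sensitive terms.
#' @return A list of character token vectors, one per input text. Empty
#'   texts yield `character(0)` (such tweets are unscoreable).
#' @examples
#' tokenize("Good GOOD bad.")
#' tokenize("#ACAworks")
#' @export
tokenize <- function(text, lower = TRUE) {
  f <- flat_tokenize(text, lower = lower)
  unname(split(f$tokens, factor(f$id, levels = seq_len(f$n))))
}

# Vectorized tokenizer over a whole corpus: returns the flat token vector,
# the index of the owning text, and the number of texts. Hashtag
# expansions are appended at the end of each tweet's token run.
flat_tokenize <- function(text, lower = TRUE) {
  stopifnot(is.character(text))
  n <- length(text)
  if (lower) text <- tolower(text)
  raw <- strsplit(text, "[[:space:]]+")
  lens <- lengths(raw)
  flat <- unlist(raw, use.names = FALSE)
  id <- rep.int(seq_len(n), lens)
  keep <- nzchar(flat)
  flat <- flat[keep]; id <- id[keep]
  if (length(flat)) {
    is_url <- grepl("^(https?://|www\\.)", flat, ignore.case = TRUE)
    flat[!is_url] <- sub("^[^[:alnum:]#@]+", "", flat[!is_url])
    flat[!is_url] <- sub("[^[:alnum:]]+$", "", flat[!is_url])
    keep <- nzchar(flat)
    flat <- flat[keep]; id <- id[keep]
    is_tag <- grepl("^#[[:alnum:]_]+$", flat)
    if (any(is_tag)) {
      ord <- order(c(id, id[is_tag]),
                   c(seq_along(id), which(is_tag) + 0.5))
      flat <- c(flat, sub("^#", "", flat[is_tag]))[ord]
      id <- c(id, id[is_tag])[ord]
    }
  }
  list(tokens = flat, id = id, n = n)
}

#' Score one tokenized tweet against a lexicon
#'
#' @param tokens Character vector of (lowercased) tokens for one tweet,
#'   as produced by [tokenize()].
#' @param lexicon A `sentiment_lexicon`.
#' @return The raw sentiment score, or `NA_real_` for an empty token vector
#'   (unscoreable tweet).
#' @details The score is invariant to token order and to duplicating every
#'   token, because it depends only on relative frequencies.
#' @examples
#' lex <- load_lexicon(system.file("extdata", "toy_lexicon.tsv",
#'                                 package = "acasent"))
#' score_tweet(c("good", "good", "awful"), lex)
#' @export
score_tweet <- function(tokens, lexicon) {
  stopifnot(is.character(tokens), inherits(lexicon, "sentiment_lexicon"))
  n <- length(tokens)
  if (n == 0L) return(NA_real_)
  sum(get_weight(lexicon, tokens)) / n
}

#' Score many tweets at once
#'
#' Vectorized equivalent of [tokenize()] + [score_tweet()] over a corpus.
#'
#' @param text Character vector of tweet texts.
#' @param lexicon A `sentiment_lexicon`.
#' @return Numeric vector of raw scores (`NA` for unscoreable tweets).
#' @export
score_tweets <- function(text, lexicon) {
  f <- flat_tokenize(text, lower = TRUE)
  out <- rep(NA_real_, f$n)
  if (!length(f$tokens)) return(out)
  w <- get_weight(lexicon, f$tokens)
  lens <- tabulate(f$id, nbins = f$n)
  sums <- rowsum(w, f$id, reorder = TRUE)
  idx <- as.integer(rownames(sums))
  out[idx] <- as.numeric(sums) / lens[idx]
  out
}

#' Z-standardize raw scores across a corpus
#'
#' Centers and scales raw per-tweet scores to mean 0 and population
#' (divide-by-n) standard deviation 1 across the corpus, so downstream
#' contrasts are in corpus standard-deviation units. The population SD is
#' used for determinism; at corpus scale the sample/population distinction
#' is immaterial.
#'
#' @param raw Numeric vector of raw scores (no `NA`s; drop unscoreable
#'   tweets first).
#' @return Numeric vector of Z scores in input order.
#' @export
zscore_corpus <- function(raw) {
  stopifnot(is.numeric(raw))
  if (anyNA(raw)) stop("raw scores contain NA; drop unscoreable tweets first",
                       call. = FALSE)
  if (length(raw) < 2L) stop("need at least 2 scores to standardize",
                             call. = FALSE)
  s <- pop_sd(raw)
  if (s == 0) stop("degenerate corpus: zero variance in raw scores",
                   call. = FALSE)
  (raw - mean(raw)) / s
}

#' Aggregate standardized tweet scores to state means
#'
#' @param scores Data frame with columns `tweet_id` and `z`.
#' @param resolutions Data frame with columns `tweet_id` and `state`
#'   (`NA` for unresolved), as returned by [geocode_corpus()].
#' @return Data frame (one row per state with at least one resolved, scored
#'   tweet) with columns `state`, `mean_z`, `n_tweets`, ordered by state
#'   code. Unresolved or unscoreable tweets are excluded.
#' @export
aggregate_by_state <- function(scores, resolutions) {
  stopifnot(all(c("tweet_id", "z") %in% names(scores)),
            all(c("tweet_id", "state") %in% names(resolutions)))
  m <- merge(scores[c("tweet_id", "z")],
             resolutions[c("tweet_id", "state")], by = "tweet_id")
  m <- m[!is.na(m$state) & !is.na(m$z), , drop = FALSE]
  if (nrow(m) == 0L) {
    return(data.frame(state = character(0), mean_z = numeric(0),
                      n_tweets = integer(0), stringsAsFactors = FALSE))
  }
  agg <- aggregate(m$z, by = list(state = m$state),
                   FUN = function(v) c(mean(v), length(v)))
  out <- data.frame(state = agg$state,
                    mean_z = agg$x[, 1],
                    n_tweets = as.integer(agg$x[, 2]),
                    stringsAsFactors = FALSE)
  out[order(out$state), , drop = FALSE]
}

#' Compare the sentiment of two tweet groups
#'
#' Welch's unpaired two-sample t test on standardized scores. The mean
#' difference is reported in corpus standard-deviation units (the scores'
#' own units after Z-standardization). The groups compared here (e.g. an
#' ACA keyword corpus versus a random-sample corpus) have different sizes
#' and no pairing structure, so an unpaired test with unequal variances is
#' the appropriate comparison.
#'
#' @param a,b Numeric vectors of (standardized) scores, each of length >= 2.
#' @return List with `difference` (`mean(a) - mean(b)`), `t`, `df`, `p`
#'   (two-sided), `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(difference = mean(a) - mean(b),
       t = unname(tt$statistic),
       df = unname(tt$parameter),
       p = tt$p.value,
       n_a = length(a),
       n_b = length(b))
}
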