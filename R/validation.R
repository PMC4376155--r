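# Rater-based validation of the lexicon scores: interrater reliability
# between two human raters, and correlation of lexicon scores with the
# human consensus (mean of the raters).

#' Intraclass correlation for a two-rater design
#'
#' Computes the single-rater intraclass correlation from the two-way ANOVA
#' mean squares. The default form is ICC(2,1) — two-way random effects,
#' absolute agreement — which treats the raters as a random sample and
#' penalizes systematic rater mean differences. ICC(3,1) (two-way mixed,
#' consistency) is available behind the `type` flag; it is invariant to a
#' rater mean shift, which ICC(2,1) deliberately is not.
#'
#' @param ratings Numeric matrix (or data frame) with one row per rated
#'   item and one column per rater; `n >= 3` rows, two or more columns.
#' @param type `"ICC2"` (default; absolute agreement) or `"ICC3"`
#'   (consistency).
#' @return The ICC, a number in `[-1, 1]`.
#' @details With zero between-subject variance the coefficient is undefined;
#'   it is reported as 0 with a warning.
#' @examples
#' m <- cbind(r1 = c(1, 2, 3, 4, 5), r2 = c(2, 2, 4, 4, 5))
#' icc_two_rater(m)
#' @export
icc_two_rater <- function(ratings, type = c("ICC2", "ICC3")) {
  type <- match.arg(type)
  m <- as.matrix(ratings)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("ratings contain NA; every item needs a rating from ",
                     "each rater", call. = FALSE)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3L || k < 2L) {
    stop("need at least 3 items and 2 raters", call. = FALSE)
  }
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_row <- k * sum((row_means - grand)^2)
  ss_col <- n * sum((col_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_row - ss_col
  msr <- ss_row / (n - 1)
  msc <- ss_col / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (ss_row == 0) {
    warning("zero between-subject variance; ICC undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  if (type == "ICC3") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
}

#' Correlate lexicon scores with human consensus ratings
#'
#' Pearson correlation (with two-sided p value) between per-tweet lexicon
#' scores and the mean of the human ratings for the same tweets.
#'
#' @param lexicon_scores Numeric vector of per-tweet lexicon scores.
#' @param human_means Numeric vector of per-tweet mean human ratings,
#'   same length.
#' @return List with `r` (Pearson correlation), `p` (two-sided), `n`.
#' @export
score_vs_human <- function(lexicon_scores, human_means) {
  stopifnot(is.numeric(lexicon_scores), is.numeric(human_means),
            length(lexicon_scores) == length(human_means))
  if (length(lexicon_scores) < 3L) {
    stop("need at least 3 paired values", call. = FALSE)
  }
  if (sd(lexicon_scores) == 0 || sd(human_means) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  ct <- cor.test(lexicon_scores, human_means, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(lexicon_scores))
}

#' Read a long-format ratings file into a rater matrix
#'
#' @param path CSV with columns `tweet_id`, `rater_id`, `rating` (integers
#'   in -3..3: -3 extremely negative, 0 neutral, 3 extremely positive).
#' @return Numeric matrix, rows = tweets (rownames = tweet ids), columns =
#'   raters. Every tweet must be rated by every rater; ratings must lie in
#'   \[-3, 3\].
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("ratings file not found: ", path,
                               call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tweet_id", "rater_id", "rating")
  if (!all(need %in% names(d))) {
    stop("ratings table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(d$rating < -3 | d$rating > 3)) {
    stop("ratings out of the -3..3 range", call. = FALSE)
  }
  m <- tapply(d$rating, list(as.character(d$tweet_id),
                             as.character(d$rater_id)), identity)
  if (anyNA(m)) stop("incomplete ratings: every tweet needs a rating from ",
                     "each rater", call. = FALSE)
  storage.mode(m) <- "double"
  m
}
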