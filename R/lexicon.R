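# Sentiment lexicon: loading and lookup.
#
# The lexicon dialect is the two-column (word, weight) format of the NRC
# hashtag sentiment lexicon: one entry per line, tab-separated (whitespace
# accepted as a fallback), positive weights for positive sentiment.

#' Load a word-sentiment lexicon
#'
#' Reads a two-column delimited file of `word<TAB>weight` pairs into a
#' `sentiment_lexicon` object. Words are case-folded to lowercase on load;
#' tweets are case-noisy and lexicon matching is therefore case-insensitive
#' throughout the package.
#'
#' @param path Path to a delimited file. Each non-empty line must contain a
#'   token field and a numeric weight field, separated by a tab (or, as a
#'   fallback, any run of whitespace).
#' @return A `sentiment_lexicon`: a named numeric vector mapping lowercased
#'   words to finite real-valued sentiment weights.
#' @details Duplicate words (after lowercasing) with conflicting weights are
#'   an input error; exact duplicates are collapsed silently. Malformed lines
#'   (non-numeric weight, missing field) raise an error naming the line
#'   number.
#' @examples
#' lex <- load_lexicon(system.file("extdata", "toy_lexicon.tsv",
#'                                 package = "acasent"))
#' get_weight(lex, "relief")
#' @seealso [get_weight()], [write_lexicon()]
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) {
    stop("lexicon file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    return(new_lexicon(numeric(0)))
  }
  words <- character(length(keep))
  weights <- numeric(length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    parts <- strsplit(trimws(lines[ln]), "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      parts <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    }
    if (length(parts) < 2L) {
      stop("lexicon parse error at line ", ln, ": expected 'word<TAB>weight'",
           call. = FALSE)
    }
    w <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(w) || !is.finite(w)) {
      stop("lexicon parse error at line ", ln, ": non-numeric weight '",
           parts[2], "'", call. = FALSE)
    }
    words[i] <- tolower(parts[1])
    weights[i] <- w
  }
  if (anyDuplicated(words)) {
    dup <- unique(words[duplicated(words)])
    for (d in dup) {
      ws <- weights[words == d]
      if (length(unique(ws)) > 1L) {
        stop("duplicate lexicon word '", d, "' with conflicting weights: ",
             paste(unique(ws), collapse = ", "), call. = FALSE)
      }
    }
    keep2 <- !duplicated(words)
    words <- words[keep2]
    weights <- weights[keep2]
  }
  new_lexicon(setNames(weights, words))
}

new_lexicon <- function(x) {
  stopifnot(is.numeric(x))
  structure(x, class = "sentiment_lexicon")
}

#' Look up the sentiment weight of a word
#'
#' Lookup is total: out-of-vocabulary words return exactly 0, so they
#' contribute nothing to a tweet's score numerator while still counting in
#' the all-words denominator. Lookup is case-folded.
#'
#' @param lexicon A `sentiment_lexicon` from [load_lexicon()].
#' @param word Character vector of tokens.
#' @return Numeric vector of weights (0 for words not in the lexicon).
#' @export
get_weight <- function(lexicon, word) {
  stopifnot(inherits(lexicon, "sentiment_lexicon"))
  idx <- match(tolower(word), names(lexicon))
  out <- as.numeric(lexicon)[idx]
  out[is.na(idx)] <- 0
  out
}

#' Write a lexicon back to the two-column TSV dialect
#'
#' @param lexicon A `sentiment_lexicon`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "sentiment_lexicon"))
  writeLines(sprintf("%s\t%s", names(lexicon),
                     formatC(as.numeric(lexicon), format = "fg", digits = 15)),
             path)
  invisible(path)
}

#' @export
print.sentiment_lexicon <- function(x, ...) {
  cat("<sentiment_lexicon> ", length(x), " words\n", sep = "")
  if (length(x)) {
    rng <- range(as.numeric(x))
    cat("  weight range: [", fmt_num(rng[1]), ", ", fmt_num(rng[2]), "]\n",
        sep = "")
  }
  invisible(x)
}

#' @export
length.sentiment_lexicon <- function(x) length(unclass(x))
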