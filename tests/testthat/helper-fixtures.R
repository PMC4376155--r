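# Shared fixtures, built in code at test time.

toy_lexicon <- function() {
  load_lexicon(system.file("extdata", "toy_lexicon.tsv",
                           package = "acasent"))
}

# Write a small lexicon file and return its path.
write_tmp_lexicon <- function(lines, dir = withr::local_tempdir(.local_envir =
                                                                  parent.frame())) {
  path <- file.path(dir, "lex.tsv")
  writeLines(lines, path)
  path
}

# Write a JSON-lines corpus and return its path.
write_tmp_jsonl <- function(lines, dir = withr::local_tempdir(.local_envir =
                                                                parent.frame())) {
  path <- file.path(dir, "corpus.jsonl")
  writeLines(lines, path)
  path
}

# A tweet data frame in the shape read_tweets() produces.
make_tweets <- function(text, id = sprintf("t%03d", seq_along(text)),
                        lat = NA_real_, lon = NA_real_,
                        profile_location = NA_character_) {
  data.frame(id = id, text = text, lat = lat, lon = lon,
             profile_location = profile_location,
             query_tag = NA_character_, stringsAsFactors = FALSE)
}

# Independent brute-force scorer: explicit loop over tokens, kept free of
# the package's vectorized machinery (only the tokenizer is shared, since
# the tokenization rule itself is fixed by contract).
brute_force_score <- function(tokens, lexicon_df) {
  if (length(tokens) == 0L) return(NA_real_)
  total <- 0
  for (tk in tokens) {
    hit <- which(lexicon_df$word == tk)
    if (length(hit) == 1L) total <- total + lexicon_df$weight[hit]
  }
  total / length(tokens)
}

# Random synthetic tweet texts mixing lexicon words, OOV words, hashtags,
# handles and URLs.
random_texts <- function(n, lexicon_words) {
  extras <- c("the", "a", "zzz", "@someone", "http://x.co/1", "#tag",
              "#GoodDay", "so", "very", "meh")
  vapply(seq_len(n), function(i) {
    k <- sample(1:12, 1)
    paste(sample(c(lexicon_words, extras), k, replace = TRUE),
          collapse = " ")
  }, character(1))
}

# Welch t statistic and two-sided p computed from first principles.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}
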