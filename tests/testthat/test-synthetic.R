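small_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 5, n_states = 8, tweets_per_state = 100,
         handle_fraction = 0.05, n_rated = 40),
    list(...))
  do.call(synthetic_config, args)
}

test_that("the generated lexicon has the documented weight classes", {
  lx <- generate_lexicon(small_cfg())
  w <- as.numeric(unclass(lx$lexicon))
  expect_gte(length(w), 12L)
  expect_setequal(unique(w), c(2, 1, -1, -3))
  # neutral words stay out of vocabulary
  expect_identical(get_weight(lx$lexicon, lx$model$words$neutral),
                   rep(0, length(lx$model$words$neutral)))
  # deterministic construction
  lx2 <- generate_lexicon(small_cfg(seed = 99))
  expect_identical(unclass(lx$lexicon), unclass(lx2$lexicon))
})

test_that("planted group means are recovered within Monte-Carlo error", {
  cfg <- small_cfg(seed = 6, tweets_per_state = 400)
  dir <- withr::local_tempdir()
  lx <- generate_lexicon(cfg)
  gaz <- load_gazetteer()
  truth <- generate_tweets(cfg, lx, gaz, file.path(dir, "c.jsonl"))
  tw <- read_tweets(file.path(dir, "c.jsonl"))
  kw <- filter_terms(tw)
  raw <- score_tweets(kw$text, lx$lexicon)
  # per-tag group means against the planted analytic means
  for (g in c("aca", "obamacare")) {
    got <- mean(raw[kw$query_tag == g])
    want <- truth$group_mean_scores[[g]]
    mc_sd <- sd(raw[kw$query_tag == g]) / sqrt(sum(kw$query_tag == g))
    expect_lt(abs(got - want), 4 * mc_sd + 1e-12)
  }
  # random-sample corpus centers on zero
  rs <- tw[grepl("^rs", tw$id), ]
  raw_rs <- score_tweets(rs$text, lx$lexicon)
  expect_lt(abs(mean(raw_rs)), 4 * sd(raw_rs) / sqrt(length(raw_rs)))
})

test_that("planted filter and geolocation counts are exact", {
  cfg <- small_cfg(seed = 7)
  dir <- withr::local_tempdir()
  lx <- generate_lexicon(cfg)
  gaz <- load_gazetteer()
  truth <- generate_tweets(cfg, lx, gaz, file.path(dir, "c.jsonl"))
  tw <- read_tweets(file.path(dir, "c.jsonl"))
  kw <- filter_terms(tw)
  expect_equal(nrow(kw), truth$n_keyword)
  hd <- filter_mentions(tw[!(tw$id %in% kw$id), ])
  expect_equal(nrow(hd), truth$n_handle_federal + truth$n_handle_state)
  expect_equal(sum(hd$query_tag == "handle_federal"),
               truth$n_handle_federal)
  geo <- geocode_corpus(kw, gaz)
  expect_equal(geo$summary$n_resolved, truth$n_resolvable)
  expect_equal(geo$summary$fraction_resolved,
               cfg$geo_resolvable_fraction)
  # a corpus with no planted keyword tweets yields an empty keyword set
  rs_only <- tw[grepl("^rs", tw$id), ]
  expect_equal(nrow(filter_terms(rs_only)), 0L)
})

test_that("planted state sentiment ordering is recovered", {
  cfg <- scenario_recovery(seed = 8)
  cfg$tweets_per_state <- 400  # scaled-down structural check
  dir <- withr::local_tempdir()
  sim <- simulate_scenario(cfg, dir)
  st <- sim$analysis$state_table
  expect_equal(nrow(st), 50L)
  expect_true(all(st$n_tweets == 400L))
  truth <- sim$truth$state_mean_scores[match(st$state, sim$truth$states)]
  expect_gt(cor(st$mean_z, truth), 0.99)
})

test_that("noiseless enrollment recovers the planted slope exactly", {
  cfg <- small_cfg(noise_sd = 0, outlier_states = NULL)
  # sentiment spread on the scale realized state means actually have, so
  # the generated rates stay inside (0, 100) and untouched by the floor
  ss <- data.frame(state = sprintf("s%02d", 1:20),
                   mean_z = seq(-0.15, 0.15, length.out = 20))
  enr <- generate_enrollment(cfg, ss)
  fit <- suppressWarnings(fit_enrollment_model(enr, ss))  # exact fit
  expect_equal(fit$slope_per_unit, cfg$true_slope, tolerance = 1e-8)
  expect_equal(attr(enr, "true_slope"), cfg$true_slope)
})

test_that("a planted outlier state is exactly the one excluded", {
  # masking bounds the rule at small n (max standardized deviation is
  # (n-1)/sqrt(n)), so the planted offset must clear the inflated SD:
  # 5 SD over 20 states does comfortably
  cfg <- small_cfg(seed = 9, n_states = 20, outlier_states = c(AZ = 5))
  ss <- data.frame(state = sort(c(state.abb, "DC"))[1:20],
                   mean_z = seq(-0.2, 0.2, length.out = 20))
  enr <- generate_enrollment(cfg, ss)
  out <- exclude_outliers(enr, k = 2.5)
  expect_identical(out$excluded$state, "AZ")
  # and with no planted outlier, nothing is excluded
  enr2 <- generate_enrollment(small_cfg(seed = 9, n_states = 20,
                                        outlier_states = NULL), ss)
  expect_equal(nrow(exclude_outliers(enr2, 2.5)$excluded), 0L)
})

test_that("rater generation hits its reliability and correlation targets", {
  cfg <- small_cfg(seed = 10, n_rated = 300, rater_noise_sd = 0)
  withr::local_seed(1)
  sc <- data.frame(tweet_id = sprintf("t%04d", 1:500), score = rnorm(500))
  d <- generate_ratings(cfg, sc)
  m <- read_ratings_from_df <- tapply(d$rating,
                                      list(d$tweet_id, d$rater_id), identity)
  storage.mode(m) <- "double"
  expect_equal(icc_two_rater(m), 1)  # no rater noise -> perfect agreement
  # zero target correlation centers r on zero
  cfg0 <- small_cfg(seed = 11, n_rated = 300,
                    target_score_human_corr = 0)
  d0 <- generate_ratings(cfg0, sc)
  m0 <- tapply(d0$rating, list(d0$tweet_id, d0$rater_id), identity)
  storage.mode(m0) <- "double"
  sc0 <- sc[match(rownames(m0), sc$tweet_id), ]
  expect_lt(abs(score_vs_human(sc0$score, rowMeans(m0))$r), 0.15)
})

test_that("a fixed seed reproduces every generated file byte for byte", {
  cfg <- small_cfg(seed = 12)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_scenario(cfg, d1)
  s2 <- simulate_scenario(cfg, d2)
  for (f in c("corpus.jsonl", "lexicon.tsv", "enrollment.csv",
              "ratings.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # a different seed changes the corpus
  s3 <- simulate_scenario(small_cfg(seed = 13), withr::local_tempdir())
  expect_false(identical(
    unname(tools::md5sum(s1$paths$corpus)),
    unname(tools::md5sum(s3$paths$corpus))))
})
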