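test_that("percent eligible enrolled is 100 * selections / eligible", {
  expect_equal(compute_pct_enrolled(235, 1000), 23.5)
  expect_equal(compute_pct_enrolled(0, 500), 0)
  expect_equal(compute_pct_enrolled(c(10, 20), c(100, 50)), c(10, 40))
  expect_error(compute_pct_enrolled(10, 0), "positive")
})

test_that("the enrollment reader computes pct and validates columns", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "enr.csv")
  write.csv(data.frame(state = c("PA", "TX"), plan_selections = c(235, 100),
                       eligible = c(1000, 400), medicaid_expansion = c(1, 0),
                       state_based_marketplace = c(0, 0)),
            path, row.names = FALSE)
  d <- read_enrollment(path)
  expect_equal(d$pct_enrolled, c(23.5, 25))
  expect_identical(d$medicaid_expansion, c(TRUE, FALSE))
  write.csv(data.frame(state = "PA", plan_selections = 1), path,
            row.names = FALSE)
  expect_error(read_enrollment(path), "missing columns")
})

test_that("the outlier rule excludes only upper-tail states beyond k SD", {
  withr::local_seed(301)
  d <- data.frame(state = sprintf("s%02d", 1:50),
                  pct_enrolled = rnorm(50, 23.5, 5),
                  stringsAsFactors = FALSE)
  # plant one state at mean + 3 SD of the others
  d$pct_enrolled[50] <- mean(d$pct_enrolled[1:49]) +
    3 * sd(d$pct_enrolled[1:49])
  out <- exclude_outliers(d, k = 2.5)
  expect_identical(out$excluded$state, "s50")
  expect_equal(nrow(out$kept), 49L)
  # nothing excluded when everything is within 2.5 SD
  out2 <- exclude_outliers(d[1:49, ], k = 2.5)
  expect_equal(nrow(out2$excluded), 0L)
  # a symmetric low outlier is never excluded (upper tail only)
  d$pct_enrolled[50] <- mean(d$pct_enrolled[1:49]) -
    4 * sd(d$pct_enrolled[1:49])
  expect_equal(nrow(exclude_outliers(d, 2.5)$excluded), 0L)
  expect_error(exclude_outliers(d[1:2, ], 2.5), "at least 3")
})

make_model_inputs <- function(x, y, states = sprintf("s%03d", seq_along(x)),
                              medicaid = rep(c(TRUE, FALSE),
                                             length.out = length(x)),
                              sbm = rep(c(FALSE, TRUE, TRUE, FALSE),
                                        length.out = length(x))) {
  list(enrollment = data.frame(state = states, pct_enrolled = y,
                               medicaid_expansion = medicaid,
                               state_based_marketplace = sbm,
                               stringsAsFactors = FALSE),
       sentiment = data.frame(state = states, mean_z = x,
                              stringsAsFactors = FALSE))
}

test_that("HC1 robust SEs match the sandwich definition on a 10-state fixture", {
  withr::local_seed(302)
  x <- seq(-0.4, 0.5, length.out = 10)
  y <- 20 + 40 * x + rnorm(10, sd = c(rep(2, 5), rep(9, 5)))
  mi <- make_model_inputs(x, y)
  fit <- fit_enrollment_model(mi$enrollment, mi$sentiment)
  # sandwich oracle from the definition: (X'X)^-1 X' diag(e^2) X (X'X)^-1
  # with the HC1 small-sample factor n/(n - k)
  X <- cbind(1, x)
  bread <- solve(t(X) %*% X)
  beta <- bread %*% t(X) %*% y
  e <- as.numeric(y - X %*% beta)
  n <- length(y); k <- ncol(X)
  vc <- n / (n - k) * bread %*% (t(X) %*% diag(e^2) %*% X) %*% bread
  expect_equal(fit$slope_per_unit, unname(beta[2, 1]), tolerance = 1e-10)
  expect_equal(fit$robust_se, sqrt(vc[2, 2]), tolerance = 1e-10)
  # CI on the per-0.10 scale uses t with n - k degrees of freedom
  expect_equal(fit$ci95[2] - fit$ci95[1],
               2 * qt(0.975, n - k) * sqrt(vc[2, 2]) / 10,
               tolerance = 1e-10)
})

test_that("noiseless data recover the planted slope exactly", {
  x <- seq(-1, 1, length.out = 20)
  mi <- make_model_inputs(x, 10 + 50 * x)
  # an exact fit makes summary.lm grumble inside the sandwich estimator
  fit <- suppressWarnings(fit_enrollment_model(mi$enrollment, mi$sentiment))
  expect_equal(fit$slope_per_unit, 50, tolerance = 1e-8)
  expect_equal(fit$effect_per_0p10, 5.0, tolerance = 1e-9)
  expect_lt(fit$robust_se, 1e-6)
})

test_that("effect per 0.10 units is exactly slope / 10, with covariates too", {
  withr::local_seed(303)
  x <- rnorm(30)
  mi <- make_model_inputs(x, 15 + 8 * x + rnorm(30))
  for (cov in list(character(0), "medicaid_expansion",
                   c("medicaid_expansion", "state_based_marketplace"))) {
    fit <- fit_enrollment_model(mi$enrollment, mi$sentiment,
                                covariates = cov)
    expect_identical(fit$effect_per_0p10, fit$slope_per_unit / 10)
    expect_identical(fit$covariates, cov)
  }
})

test_that("an uncorrelated covariate barely moves the sentiment slope", {
  withr::local_seed(304)
  n <- 400
  x <- rnorm(n)
  mi <- make_model_inputs(x, 20 + 6 * x + rnorm(n),
                          medicaid = rbinom(n, 1, 0.5) == 1)
  f0 <- fit_enrollment_model(mi$enrollment, mi$sentiment)
  f1 <- fit_enrollment_model(mi$enrollment, mi$sentiment,
                             covariates = "medicaid_expansion")
  expect_lt(abs(f1$slope_per_unit - f0$slope_per_unit),
            3 * f0$robust_se / sqrt(n) * 10 + 0.05)
})

test_that("model input errors are specific", {
  x <- seq(-1, 1, length.out = 10)
  mi <- make_model_inputs(x, 10 + 5 * x)
  expect_error(
    fit_enrollment_model(mi$enrollment, mi$sentiment[1:8, ]),
    "s009, s010")
  expect_error(
    fit_enrollment_model(mi$enrollment, mi$sentiment, covariates = "nope"),
    "unknown covariate")
  mi$enrollment$medicaid_expansion <- TRUE  # constant -> collinear
  expect_error(
    fit_enrollment_model(mi$enrollment, mi$sentiment,
                         covariates = "medicaid_expansion"),
    "rank-deficient")
  expect_error(
    fit_enrollment_model(mi$enrollment[1:2, ], mi$sentiment[1:2, ]),
    "too few states")
})

test_that("the log-outcome variant fits log percent enrolled", {
  withr::local_seed(305)
  x <- rnorm(25)
  y <- exp(3 + 0.4 * x)
  mi <- make_model_inputs(x, y)
  fit <- suppressWarnings(  # exact fit on the log scale
    fit_enrollment_model(mi$enrollment, mi$sentiment, outcome = "log"))
  expect_equal(fit$slope_per_unit, 0.4, tolerance = 1e-8)
  expect_identical(fit$outcome, "log")
})
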