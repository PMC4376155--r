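# Marketplace enrollment: percent-eligible-enrolled, the upper-tail
# outlier rule, and the robust-SE linear model of enrollment on state
# sentiment.

#' Percent of eligible consumers who selected a marketplace plan
#'
#' @param plan_selections Count of persons who selected a marketplace plan.
#' @param eligible Count of consumers eligible to enroll (must be > 0).
#' @return `100 * plan_selections / eligible`, a percent on the 0-100 scale.
#' @export
compute_pct_enrolled <- function(plan_selections, eligible) {
  stopifnot(is.numeric(plan_selections), is.numeric(eligible))
  if (any(eligible <= 0)) {
    stop("eligible population must be positive", call. = FALSE)
  }
  100 * plan_selections / eligible
}

#' Read a state enrollment table
#'
#' @param path CSV with columns `state`, `plan_selections`, `eligible`,
#'   `medicaid_expansion`, `state_based_marketplace` (logical or 0/1).
#' @return Data frame with those columns plus computed `pct_enrolled`.
#'   Records with `pct_enrolled > 100` are pathological and flagged with a
#'   warning (they are kept; the outlier rule usually removes them).
#' @export
read_enrollment <- function(path) {
  if (!file.exists(path)) {
    stop("enrollment file not found: ", path, call. = FALSE)
  }
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("state", "plan_selections", "eligible", "medicaid_expansion",
            "state_based_marketplace")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("enrollment table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d$medicaid_expansion <- as.logical(d$medicaid_expansion)
  d$state_based_marketplace <- as.logical(d$state_based_marketplace)
  d$pct_enrolled <- compute_pct_enrolled(d$plan_selections, d$eligible)
  if (any(d$pct_enrolled > 100)) {
    warning("pct_enrolled exceeds 100% for: ",
            paste(d$state[d$pct_enrolled > 100], collapse = ", "),
            call. = FALSE)
  }
  d
}

#' Exclude high-enrollment outlier states
#'
#' Removes states whose enrollment rate lies more than `k` standard
#' deviations above the mean (upper tail only, mean and SD computed over
#' all records). This is the rule under which a state like Vermont, with an
#' enrollment rate over 2.5 SD above the mean, is dropped before model
#' fitting.
#'
#' @param records Enrollment data frame with a `pct_enrolled` column.
#' @param k SD multiplier (default 2.5).
#' @return List with `kept` and `excluded` data frames and the numeric
#'   `threshold` used.
#' @export
exclude_outliers <- function(records, k = 2.5) {
  stopifnot(is.data.frame(records), "pct_enrolled" %in% names(records),
            k > 0)
  if (nrow(records) < 3L) {
    stop("need at least 3 records to apply the outlier rule", call. = FALSE)
  }
  m <- mean(records$pct_enrolled)
  s <- sd(records$pct_enrolled)
  threshold <- m + k * s
  out <- records$pct_enrolled > threshold
  list(kept = records[!out, , drop = FALSE],
       excluded = records[out, , drop = FALSE],
       threshold = threshold)
}

#' Linear model of enrollment on state sentiment with robust SEs
#'
#' Fits ordinary least squares of percent-eligible-enrolled on the state
#' mean standardized sentiment score (plus optional policy covariates) and
#' reports heteroskedasticity-robust (HC1 sandwich) standard errors, the
#' convention of the common "robust" regression default. The headline
#' effect is expressed per 0.10 sentiment units: `effect_per_0p10 =
#' slope / 10`. The 95% CI uses the t distribution with `n - p` degrees of
#' freedom, which matters at n of about 50 states.
#'
#' @param enrollment Enrollment data frame (`state`, `pct_enrolled`,
#'   covariate columns), typically after [exclude_outliers()].
#' @param state_sentiment Data frame with `state` and `mean_z` columns from
#'   [aggregate_by_state()].
#' @param covariates Character vector of covariate column names in
#'   `enrollment` (e.g. `"medicaid_expansion"`,
#'   `"state_based_marketplace"`); default none (unadjusted model).
#' @param outcome `"pct"` (default) models percentage points;
#'   `"log"` models `log(pct_enrolled)` (effects then on the log scale).
#' @return An `enrollment_fit` list: `slope_per_unit`, `effect_per_0p10`,
#'   `robust_se` (per sentiment unit), `robust_se_per_0p10`, `ci95`
#'   (on the per-0.10 scale), `p`, `n_states`, `covariates`, `outcome`,
#'   `coefficients` (full robust coefficient table), and the underlying
#'   `lm` fit.
#' @details States present in `enrollment` but absent from
#'   `state_sentiment` are an error listing the states (join both inputs to
#'   a common state set first). The design must be full rank.
#' @export
fit_enrollment_model <- function(enrollment, state_sentiment,
                                 covariates = character(0),
                                 outcome = c("pct", "log")) {
  outcome <- match.arg(outcome)
  stopifnot(all(c("state", "pct_enrolled") %in% names(enrollment)),
            all(c("state", "mean_z") %in% names(state_sentiment)))
  missing_states <- setdiff(enrollment$state, state_sentiment$state)
  if (length(missing_states)) {
    stop("no sentiment available for state(s): ",
         paste(sort(missing_states), collapse = ", "), call. = FALSE)
  }
  bad_cov <- setdiff(covariates, names(enrollment))
  if (length(bad_cov)) {
    stop("unknown covariate column(s): ", paste(bad_cov, collapse = ", "),
         call. = FALSE)
  }
  d <- merge(enrollment, state_sentiment[c("state", "mean_z")], by = "state")
  n <- nrow(d)
  p <- 2L + length(covariates)
  if (n < p + 1L) {
    stop("too few states (", n, ") for ", p, " parameters", call. = FALSE)
  }
  d$.y <- if (outcome == "log") log(d$pct_enrolled) else d$pct_enrolled
  rhs <- paste(c("mean_z", covariates), collapse = " + ")
  fml <- stats::as.formula(paste(".y ~", rhs))
  fit <- lm(fml, data = d)
  if (fit$rank < p) {
    stop("rank-deficient design (collinear covariates?)", call. = FALSE)
  }
  vc <- sandwich::vcovHC(fit, type = "HC1")
  est <- coef(fit)
  se <- sqrt(diag(vc))
  dfree <- n - p
  tval <- est / se
  pval <- 2 * pt(abs(tval), df = dfree, lower.tail = FALSE)
  slope <- unname(est["mean_z"])
  slope_se <- unname(se["mean_z"])
  effect <- slope / 10
  effect_se <- slope_se / 10
  crit <- qt(0.975, df = dfree)
  structure(list(
    slope_per_unit = slope,
    effect_per_0p10 = effect,
    robust_se = slope_se,
    robust_se_per_0p10 = effect_se,
    ci95 = c(effect - crit * effect_se, effect + crit * effect_se),
    p = unname(pval["mean_z"]),
    n_states = n,
    df = dfree,
    covariates = covariates,
    outcome = outcome,
    coefficients = data.frame(term = names(est), estimate = unname(est),
                              robust_se = unname(se), t = unname(tval),
                              p = unname(pval), stringsAsFactors = FALSE),
    fit = fit
  ), class = "enrollment_fit")
}

#' @export
print.enrollment_fit <- function(x, ...) {
  cat("Enrollment ~ state sentiment (OLS, HC1 robust SEs)\n")
  cat("  outcome: ", if (x$outcome == "pct") "percent eligible enrolled"
      else "log(percent eligible enrolled)", "\n", sep = "")
  cat("  states:  ", x$n_states, if (length(x$covariates))
    paste0("   adjusted for: ", paste(x$covariates, collapse = ", ")) else
      "   (unadjusted)", "\n", sep = "")
  cat(sprintf("  effect per 0.10 sentiment: %.2f (95%% CI %.2f to %.2f; P=%.3g)\n",
              x$effect_per_0p10, x$ci95[1], x$ci95[2], x$p))
  invisible(x)
}
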