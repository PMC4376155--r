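# Internal helpers shared across modules.

#' Derive a per-stage RNG seed from a master seed
#'
#' Each synthetic-generation stage draws from its own stream, seeded
#' deterministically from the master seed and the stage name, so changing one
#' stage's parameters never reshuffles another stage's draws.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) + h * 7919) %% 2147483647)
}

# Population (divide-by-n) standard deviation.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# File path of a packaged data file.
acasent_file <- function(...) {
  system.file("extdata", ..., package = "acasent", mustWork = TRUE)
}

# Consistent numeric formatting for reports.
fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "fg")
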