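#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

stop2 <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop2(sprintf("'%s' must be a single finite number", name))
  if (x < lower || x > upper)
    stop2(sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x))
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop2(sprintf("'%s' must be TRUE or FALSE", name))
  invisible(x)
}

## Draw from a normal truncated to (lower, upper) by inverse-CDF sampling.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

## Derive reproducible per-stage sub-seeds from one master seed: seeding the
## master stream and drawing one integer per named stage keeps stages
## independently re-runnable while the whole run stays a pure function of the
## master seed.
derive_seeds <- function(seed, stages) {
  check_number(seed, "seed")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(as.numeric(seed) %% .Machine$integer.max))
  s <- sample.int(.Machine$integer.max - 1L, length(stages))
  names(s) <- stages
  s
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(as.numeric(seed) %% .Machine$integer.max))
  expr
}
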