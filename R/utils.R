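# Internal helpers shared across modules.

# Closed-form simple OLS; returns c(slope, intercept).
# Used in hot paths (bilinear split search, bootstrap refits) where lm()
# overhead matters.
.ols <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0) stop("singular design: all x values identical", call. = FALSE)
  a <- sum((x - mx) * (y - my)) / sxx
  c(a, my - a * mx)
}

.is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x == round(x))

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Run `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards so library calls do not perturb user code.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# FNV-1a hash over the serialized object; used to make pipeline outputs
# traceable to their inputs without a hashing dependency.
.object_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

.signif6 <- function(x) {
  if (is.numeric(x)) signif(x, 6) else x
}
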