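# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed error constructors so callers can distinguish failure modes.
stop_rs <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "respshape_error")))
}
stop_invalid <- function(msg) stop_rs(msg, "rs_invalid_argument")

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (length(seed) != 1L || !is.finite(seed)) {
    stop_invalid("seed must be a single finite integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# One global seed plus a stream label gives a reproducible child seed.
# Adding unrelated streams never perturbs existing ones.
substream_seed <- function(seed, stream) {
  h <- 0
  for (k in utf8ToInt(as.character(stream))) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Linear-interpolation percentile (quantile type 7), the package-wide
# definition used for all surrogate/permutation thresholds.
percentile <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

next_pow2 <- function(n) 2^ceiling(log2(max(n, 1)))

trapz_int <- function(y, fs) {
  if (length(y) < 2L) return(0)
  (sum(y) - (y[1L] + y[length(y)]) / 2) / fs
}
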