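#' @keywords internal
"_PACKAGE"

# Geometric mean of positive values.
geomean <- function(x) exp(mean(log(x)))

# Deterministic per-operation RNG substream derived from a master seed, so
# adding or reordering one generation step never perturbs the draws of
# another. Keeps derived seeds inside the 32-bit integer range.
substream_seed <- function(seed, op) {
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  as.integer((as.double(seed) * 48271 + h * 9973) %% 2147483563L)
}

with_substream <- function(seed, op, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(substream_seed(seed, op))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
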