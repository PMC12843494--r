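#' @keywords internal
"_PACKAGE"

#' @importFrom stats prcomp kmeans predict rnorm runif setNames aggregate dist quantile
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## half-up rounding to `digits` decimals; R's round() is half-even, which is
## the wrong convention for report tables
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## deterministic child seed from a global seed and a stage tag; keeps every
## random stage reproducible from one --seed while decoupling their streams.
## Result stays below 2^31 - 1.
derive_seed <- function(seed, tag) {
  h <- 5381
  for (cp in utf8ToInt(paste0(tag, ":", seed))) h <- (h * 33 + cp) %% 2147483647
  as.integer(h)
}

## run expr with a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## 31-bit string hash (FNV-style), exact in double arithmetic
hash_string <- function(s) {
  h <- 2166136261 %% 2147483647
  for (cp in utf8ToInt(s)) h <- ((h * 16777619) %% 2147483647 + cp) %% 2147483647
  h
}

## combine non-negative integer codes into one 31-bit code; order-sensitive
hash_codes <- function(codes) {
  h <- 17
  for (v in codes) h <- (h * 1048573 + v) %% 2147483647
  h
}
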