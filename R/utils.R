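## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

expit <- function(x) plogis(x)

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_cfg("non-finite values in %s", what)
  invisible(x)
}

## Deterministic sub-seed derivation so the generator modules can be driven
## from one master seed yet remain independently reproducible.  Kept below
## 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 69069 + h * 9973) %% 2147483629L)
}

## Local RNG scope: runs expr under set.seed(seed) without disturbing the
## caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## Quantile with a documented default convention (type 7, linear
## interpolation); tertile assignment uses type 1 separately.
quantile7 <- function(x, probs) unname(quantile(x, probs, type = 7, names = FALSE))
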