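# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a key
#'
#' Folds the master seed and any number of integer/character key components
#' into a single seed below 2^31 so each (region, year, channel) gets its own
#' RNG stream: adding regions or years never perturbs existing streams.
#'
#' @param seed master integer seed.
#' @param ... key components (integers or strings).
#' @return an integer in `[1, 2147483628]`.
#' @keywords internal
sub_seed <- function(seed, ...) {
  keys <- list(...)
  # modular polynomial hash; all intermediates stay below 2^53 so doubles
  # represent them exactly
  mod <- 2147483629
  acc <- as.numeric(seed) %% mod
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    for (v in as.numeric(k)) {
      acc <- (acc * 1000003 + (v %% mod)) %% mod
    }
  }
  as.integer(acc %% 2147483628) + 1L
}

# deterministic rolling hash of an R object's serialisation, hex string.
# Used for provenance blocks; not cryptographic.
object_hash <- function(x) {
  raw <- as.integer(serialize(x, connection = NULL, version = 2))
  mod <- 2147483647
  h <- 0
  for (b in raw) h <- (h * 257 + b + 1) %% mod
  sprintf("%08x", as.integer(h))
}

stopf <- function(fmt, ..., class = "chumphen_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}
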