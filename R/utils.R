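#' Derive a child seed from a master seed
#'
#' Reproducible seed splitting used throughout the package: every source of
#' randomness (genotype simulation, CV00 splits, per-replicate chains) draws
#' its own child seed from one master seed plus a string key, so whole studies
#' replay bit-identically from a single integer.
#'
#' The rule is `child = (master * 48271 + h) mod 2147483629`, where `h` is the
#' position-weighted sum of the UTF-8 code points of the key parts joined with
#' `"|"`. The modulus keeps children inside the 32-bit integer range.
#'
#' @param seed Master seed (integer-like scalar).
#' @param ... Key parts (coerced to character) identifying the consumer.
#' @return An integer seed in `[0, 2147483628]`.
#' @examples
#' derive_seed(42, "cv00", 1, "IA_2013")
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  key <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                      character(1)), collapse = "|")
  cp <- utf8ToInt(key)
  h <- if (length(cp)) sum(cp * seq_along(cp)) else 0
  as.integer((abs(seed) * 48271 + h) %% 2147483629)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  code
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Symmetry check used by kernel validators; tolerance per the container contract.
check_symmetric <- function(K, tol = 1e-10, label = "kernel") {
  if (!is.matrix(K) || nrow(K) != ncol(K)) {
    stop(label, " must be a square matrix", call. = FALSE)
  }
  if (max(abs(K - t(K))) > tol * max(1, max(abs(K)))) {
    stop(label, " is not symmetric", call. = FALSE)
  }
  invisible(K)
}
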