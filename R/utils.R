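# Internal utilities: stable ordering, deterministic hashing, seed scoping.

# Stable descending order: ties broken by original position, so rankings are
# invariant to permutations of equal values being re-sorted (documented tie
# policy across the package).
.stableOrderDesc <- function(x) {
  order(-xtfrm(x), seq_along(x), method = "radix")
}

# Deterministic polynomial string hash, mod 2^31 - 1. All intermediates stay
# below 2^53 so the result is exact in double arithmetic on every platform.
.hashString <- function(s) {
  vapply(s, function(one) {
    bytes <- as.integer(charToRaw(one))
    h <- 0
    for (b in bytes) h <- (h * 131 + b) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Deterministic hash of a configuration object
#'
#' Used to stamp output files with a short provenance fingerprint of the
#' run configuration. Not cryptographic.
#'
#' @param x any R object; it is deparsed canonically before hashing.
#' @return A character scalar (hex digits).
#' @export
#' @examples
#' configHash(list(lambda = 1, fraction = 0.1))
configHash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger")), collapse = "")
  sprintf("%08x", .hashString(txt))
}

# Evaluate expr with a local RNG state; the caller's .Random.seed is restored
# afterwards so library code never perturbs user-level randomness.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Log line to stderr (machine-readable outputs go to files only).
.log <- function(fmt, ...) message(sprintf(fmt, ...))

.assertFlag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(what, " must be TRUE or FALSE", call. = FALSE)
}
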