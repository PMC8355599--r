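# Internal helpers shared across modules.

#' Deterministic 31-bit string hash
#'
#' Polynomial rolling hash over the UTF-8 bytes of a string, reduced modulo
#' 2^31 - 1. Used to derive per-gene random seeds that do not depend on gene
#' iteration order, and to fingerprint pipeline configurations. Stable across
#' platforms and R sessions (no dependence on R's internal hashing).
#'
#' @param x character vector
#' @return integer vector in [0, 2^31 - 2]
#' @keywords internal
hash_string <- function(x) {
  mod <- 2147483647
  vapply(x, function(s) {
    bytes <- as.integer(charToRaw(enc2utf8(s)))
    h <- 0
    for (b in bytes) h <- (h * 31 + b) %% mod
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

#' Derive a per-gene seed from a global seed
#'
#' @param seed global integer seed
#' @param gene_id gene identifier
#' @return integer seed in [0, 2^31 - 2]
#' @keywords internal
gene_seed <- function(seed, gene_id) {
  as.integer((as.numeric(seed) %% 2147483647 + hash_string(gene_id)) %% 2147483647)
}

# Canonical key for an unordered node pair; vectorised.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Canonical key for a directed edge; vectorised.
edge_key <- function(tf, target) paste(tf, target, sep = "\r")

# Run code with the RNG seeded, restoring the caller's RNG state afterwards,
# so library functions do not silently consume or clobber the user's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("grnprune_config_error", "error")))
}

stop_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("grnprune_parse_error", "error")))
}
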