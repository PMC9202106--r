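#' Canonical key for an unordered gene pair
#'
#' Edges of co-expression networks are unordered; a canonical string key
#' (lexicographically smaller gene first, separated by `"|"`) makes set
#' operations on edges exact and fast.
#'
#' @param a,b Character vectors of gene ids (recycled to common length).
#' @return Character vector of canonical pair keys.
#' @keywords internal
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Derive a stage-specific seed from a master seed
#'
#' All randomness in the package flows from one master seed; each stage gets
#' a deterministic child seed so stages can be re-run independently and still
#' reproduce. The derivation is a fixed integer hash of the stage label,
#' folded into the master seed modulo 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param stage Character scalar naming the stage.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483645 + 1)
}

stop2 <- function(...) stop(..., call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x
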