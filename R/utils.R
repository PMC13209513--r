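# small shared helpers

#' Round half away from zero
#'
#' Base \code{round()} rounds halves to even; screening summaries here follow
#' the convention of rounding halves away from zero (so 37.5 -> 38), which is
#' what printed percent tables use.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Euclidean distance between two 3-vectors
vdist <- function(a, b) sqrt(sum((a - b)^2))

# all pairwise distances between rows of A and rows of B
cross_dist <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# deterministic sub-seed for a named fixture stream; keeps within 32-bit range
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(seed) * 7919 + h) %% 2147483647L)
}
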