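#' Shannon entropy of a probability vector
#'
#' `-sum(p * log2(p))` with the convention `0 * log(0) = 0`; reported in
#' bits.
#'
#' @param p Probability vector (non-negative, summing to 1 within 1e-8).
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(0.5, 0.5)) # 1 bit
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    abort("p must be a normalized probability vector")
  }
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Renyi entropy of a probability vector
#'
#' `log2(sum(p^q)) / (1 - q)` for weighting parameter `q > 0`, `q != 1`;
#' reported in bits. For `q < 1` rare outcomes are up-weighted, for `q > 1`
#' frequent ones; as `q -> 1` it converges to the Shannon entropy.
#'
#' @inheritParams shannon_entropy
#' @param q Weighting parameter (> 0, != 1).
#' @return Entropy in bits.
#' @examples
#' renyi_entropy(c(0.75, 0.25), q = 2) # -log2(0.625)
#' @export
renyi_entropy <- function(p, q) {
  if (!is_scalar_num(q) || q <= 0) abort("q must be > 0")
  if (q == 1) abort("q = 1 is the Shannon limit; use shannon_entropy()")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    abort("p must be a normalized probability vector")
  }
  log2(sum(p[p > 0]^q)) / (1 - q)
}
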