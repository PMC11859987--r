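#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats quantile sd fft prcomp rbinom rnorm runif rpois setNames
#' @importFrom utils head tail
NULL

# Canonical order of the eight eco-acoustic indices; used for column layout
# and for deterministic tie-breaking when selecting representatives.
INDEX_NAMES <- c("H", "ACI", "ADI", "AEI", "NDSI", "BI", "DSC", "ZCR")

#' Derive a child seed from a master seed
#'
#' All stochastic generators in the package draw their randomness from a
#' single integer seed; independent stages receive distinct child seeds via a
#' fixed affine map so that changing one stage never perturbs another.
#'
#' @param seed Master integer seed.
#' @param offset Non-negative integer identifying the consumer.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) + 48271 * (offset + 1)) %% 2147483647)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# dBFS with a full-scale sine (amplitude 1) as the 0 dB reference.
# `x` is a linear amplitude; the full-scale sine has RMS 1/sqrt(2).
amp_to_dbfs <- function(x) {
  20 * log10(pmax(x, .Machine$double.xmin) / (1 / sqrt(2)))
}
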