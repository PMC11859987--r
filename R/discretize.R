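#' Discretize a real-valued series into symbols by quantile boundaries
#'
#' Bin edges are the requested quantile levels of the series' own finite
#' values (type-7 linear interpolation); the default boundaries at the 5th
#' and 95th percentiles yield 3 symbols emphasizing the distribution tails.
#' Values falling exactly on an edge go to the lower bin, so the coding is
#' invariant under monotone transforms of the values. Flagged missing values
#' are removed and split contiguity blocks.
#'
#' @param x Numeric series (NAs allowed; they split blocks).
#' @param boundaries Quantile levels in percent, strictly increasing within
#'   (0, 100). `k` boundaries give `k + 1` symbols.
#' @param blocks Optional integer vector (same length as `x`) of contiguity
#'   block ids; transitions are only formed within a block.
#' @return A `symbolic_series`: list with `symbols` (integer codes in
#'   `0..alphabet_size-1`), `alphabet_size`, `edges`, and `blocks` (one id
#'   per retained symbol).
#' @examples
#' s <- discretize(1:100)
#' table(s$symbols) # 5 / 90 / 5
#' @export
discretize <- function(x, boundaries = c(5, 95), blocks = NULL) {
  if (any(diff(boundaries) <= 0) || any(boundaries <= 0) ||
    any(boundaries >= 100)) {
    abort("boundaries must be strictly increasing within (0, 100)")
  }
  finite <- is.finite(x)
  if (sum(finite) < 20L) abort("need at least 20 finite values")
  if (length(unique(x[finite])) < length(boundaries) + 1L) {
    abort("fewer distinct values than bins; use fewer boundaries")
  }
  edges <- quantile(x[finite], boundaries / 100, names = FALSE, type = 7)
  if (anyDuplicated(edges)) {
    abort("tied quantile edges; the series is too concentrated for this many bins, use fewer boundaries")
  }
  blocks <- blocks %||% rep(1L, length(x))
  if (length(blocks) != length(x)) abort("blocks must match x in length")
  # missing values split blocks: renumber runs of finite values
  run <- cumsum(!finite | c(TRUE, diff(as.integer(factor(blocks))) != 0))
  symbols <- rowSums(outer(x[finite], edges, `>`))
  symbolic_series(
    symbols = as.integer(symbols),
    alphabet_size = length(boundaries) + 1L,
    blocks = as.integer(factor(run[finite])),
    edges = edges
  )
}

#' Construct a symbolic series
#'
#' @param symbols Integer codes in `0..alphabet_size-1`.
#' @param alphabet_size Number of distinct symbols the coding allows.
#' @param blocks Integer contiguity-block id per symbol (non-decreasing).
#' @param edges Optional numeric bin edges recorded for provenance.
#' @param site_id,index_name,period Optional provenance labels.
#' @return A list of class `symbolic_series`.
#' @export
symbolic_series <- function(symbols, alphabet_size = max(symbols) + 1L,
                            blocks = rep(1L, length(symbols)), edges = NULL,
                            site_id = NULL, index_name = NULL, period = NULL) {
  symbols <- as.integer(symbols)
  if (any(symbols < 0L) || any(symbols >= alphabet_size)) {
    abort("symbols must lie in [0, alphabet_size)")
  }
  if (length(blocks) != length(symbols)) abort("blocks must match symbols in length")
  structure(
    list(
      symbols = symbols, alphabet_size = as.integer(alphabet_size),
      blocks = as.integer(blocks), edges = edges,
      site_id = site_id, index_name = index_name, period = period
    ),
    class = "symbolic_series"
  )
}

#' @export
print.symbolic_series <- function(x, ...) {
  cat("<symbolic_series> ", length(x$symbols), " symbols, alphabet ",
    x$alphabet_size, ", ", length(unique(x$blocks)), " block(s)\n",
    sep = ""
  )
  invisible(x)
}

as_symbolic <- function(x) {
  if (inherits(x, "symbolic_series")) {
    x
  } else {
    symbolic_series(as.integer(x))
  }
}
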