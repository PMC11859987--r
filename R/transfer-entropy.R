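# Plug-in Shannon and Renyi transfer entropy between symbolic series.
#
# With target history y_t^n and source history x_t^m, the Shannon transfer
# entropy from X to Y is the Kullback-Leibler departure from the Markov
# condition p(y_{t+1} | y_t^n, x_t^m) = p(y_{t+1} | y_t^n):
#
#   STE(X->Y) = sum p(y+, yh, xh) log2[ p(y+ | yh, xh) / p(y+ | yh) ]
#
# evaluated on the empirical joint distribution of transition tuples. The
# Renyi variant weights contexts by the escort distribution
# phi_q(j) = p(j)^q / sum p(j)^q:
#
#   RTE_q(X->Y) = 1/(1-q) log2 [ sum_yh phi_q(yh) sum_y+ p^q(y+|yh) /
#                                sum_yh,xh phi_q(yh,xh) sum_y+ p^q(y+|yh,xh) ]
#
# Both are reported in bits; RTE may legitimately be negative and is never
# clipped. Transitions never span contiguity-block boundaries.

# Empirical joint counts over (y_{t+1}, y-history, x-history) tuples as a
# 3-d array of dimension (Ay, Ay^n, Ax^m). Histories are encoded base-A with
# the most recent symbol in the lowest digit.
joint_counts <- function(x, y, m = 1L, n = 1L) {
  x <- as_symbolic(x)
  y <- as_symbolic(y)
  if (length(x$symbols) != length(y$symbols)) {
    abort("x and y must have equal length")
  }
  if (!identical(x$blocks, y$blocks)) {
    abort("x and y must share contiguity blocks")
  }
  if (!is_count(m) || m < 1 || !is_count(n) || n < 1) {
    abort("Markov orders m and n must be >= 1")
  }
  ax <- x$alphabet_size
  ay <- y$alphabet_size
  k <- max(m, n)
  yn <- integer(0)
  yh <- integer(0)
  xh <- integer(0)
  for (b in unique(y$blocks)) {
    sel <- which(y$blocks == b)
    len <- length(sel)
    if (len < k + 1L) next
    xs <- x$symbols[sel]
    ys <- y$symbols[sel]
    t_idx <- (k + 1L):len # positions of y_{t+1}
    yn_b <- ys[t_idx]
    yh_b <- integer(length(t_idx))
    for (j in seq_len(n)) yh_b <- yh_b + ys[t_idx - j] * ay^(j - 1L)
    xh_b <- integer(length(t_idx))
    for (j in seq_len(m)) xh_b <- xh_b + xs[t_idx - j] * ax^(j - 1L)
    yn <- c(yn, yn_b)
    yh <- c(yh, yh_b)
    xh <- c(xh, xh_b)
  }
  dims <- c(ay, ay^n, ax^m)
  if (length(yn) == 0L) {
    return(structure(array(0L, dims), n_transitions = 0L, m = m, n = n))
  }
  idx <- 1L + yn + dims[1] * yh + dims[1] * dims[2] * xh
  counts <- array(tabulate(idx, nbins = prod(dims)), dims)
  structure(counts, n_transitions = length(yn), m = as.integer(m), n = as.integer(n))
}

# Shannon TE from a joint (counts or probability) array over (y+, yh, xh).
ste_from_joint <- function(joint) {
  tot <- sum(joint)
  if (tot == 0) return(0)
  p3 <- joint / tot
  p_yx <- apply(p3, c(2, 3), sum) # p(yh, xh)
  p_yy <- apply(p3, c(1, 2), sum) # p(y+, yh)
  p_y <- colSums(p_yy) # p(yh)
  nz <- which(p3 > 0, arr.ind = TRUE)
  terms <- p3[nz] * log2(
    (p3[nz] / p_yx[nz[, 2:3, drop = FALSE]]) /
      (p_yy[nz[, 1:2, drop = FALSE]] / p_y[nz[, 2]])
  )
  sum(terms)
}

# Renyi TE (escort-weighted) from a joint array over (y+, yh, xh).
rte_from_joint <- function(joint, q) {
  if (!is_scalar_num(q) || q <= 0) abort("q must be > 0")
  if (q == 1) abort("q = 1 is the Shannon limit; use the shannon estimator")
  tot <- sum(joint)
  if (tot == 0) return(0)
  p3 <- joint / tot
  p_yx <- apply(p3, c(2, 3), sum) # p(yh, xh) contexts
  p_yy <- apply(p3, c(1, 2), sum) # p(y+, yh)
  p_y <- colSums(p_yy) # p(yh) contexts
  # numerator: escort over y-history contexts, q-moments of p(y+ | yh)
  phi_y <- p_y^q
  phi_y <- phi_y / sum(phi_y[p_y > 0])
  num <- 0
  for (j in which(p_y > 0)) {
    cond <- p_yy[, j] / p_y[j]
    num <- num + phi_y[j] * sum(cond[cond > 0]^q)
  }
  # denominator: escort over (y-history, x-history) contexts
  phi_yx <- p_yx^q
  phi_yx <- phi_yx / sum(phi_yx[p_yx > 0])
  den <- 0
  ctx <- which(p_yx > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(ctx))) {
    j <- ctx[r, 1]
    kk <- ctx[r, 2]
    cond <- p3[, j, kk] / p_yx[j, kk]
    den <- den + phi_yx[j, kk] * sum(cond[cond > 0]^q)
  }
  log2(num / den) / (1 - q)
}

te_warn_small <- function(counts) {
  n_tr <- attr(counts, "n_transitions")
  cells <- prod(dim(counts))
  if (n_tr < cells) {
    warn(paste0(
      "only ", n_tr, " transitions for ", cells,
      " joint cells; the plug-in estimate may be strongly biased"
    ))
  }
}

new_te_estimate <- function(value, estimator, q, m, n, n_transitions,
                            direction = NULL, null_summary = NULL) {
  structure(
    list(
      value = value, estimator = estimator, q = q, m = m, n = n,
      n_transitions = n_transitions, direction = direction,
      null_summary = null_summary
    ),
    class = "te_estimate"
  )
}

#' @export
print.te_estimate <- function(x, ...) {
  lab <- if (x$estimator == "shannon") "STE" else paste0("RTE(q=", x$q, ")")
  cat("<te_estimate> ", lab, " = ", format(x$value, digits = 6), " bits (",
    x$n_transitions, " transitions)\n",
    sep = ""
  )
  invisible(x)
}

#' Shannon transfer entropy between two symbolic series
#'
#' Plug-in estimate in bits of the information flow from source `x` to
#' target `y`, with Markov orders `m` (source) and `n` (target); transitions
#' never span contiguity-block boundaries. The estimate is non-negative and
#' is exactly 0 when `x` and `y` are the same series (with `m = n`).
#'
#' @param x,y Source and target: `symbolic_series` objects or integer
#'   vectors.
#' @param m,n Markov order of the source and target histories (default 1).
#' @return A `te_estimate` (value in bits, `n_transitions`, parameters).
#' @examples
#' set.seed(1)
#' x <- rbinom(500, 1, 0.5)
#' y <- c(0L, x[-500]) # y copies x one step later
#' shannon_te(x, y)$value # close to 1 bit
#' @export
shannon_te <- function(x, y, m = 1L, n = 1L) {
  counts <- joint_counts(x, y, m, n)
  te_warn_small(counts)
  val <- ste_from_joint(counts)
  # the plug-in STE is a conditional mutual information, hence >= 0; guard
  # against negative floating-point dust only
  val <- max(val, 0)
  new_te_estimate(val, "shannon", NA_real_, m, n, attr(counts, "n_transitions"))
}

#' Renyi transfer entropy between two symbolic series
#'
#' Escort-weighted plug-in estimate in bits. For `q < 1` rare contexts carry
#' more weight, for `q > 1` frequent ones; as `q -> 1` the value converges
#' to the Shannon transfer entropy. Negative values are legitimate and never
#' clipped.
#'
#' @inheritParams shannon_te
#' @param q Weighting parameter (> 0, != 1); conventional choices here are
#'   0.1 and 0.5.
#' @return A `te_estimate`.
#' @export
renyi_te <- function(x, y, q, m = 1L, n = 1L) {
  counts <- joint_counts(x, y, m, n)
  te_warn_small(counts)
  val <- rte_from_joint(counts, q)
  new_te_estimate(val, "renyi", q, m, n, attr(counts, "n_transitions"))
}

#' Transfer entropy from an exact joint distribution
#'
#' Evaluates the Shannon or Renyi transfer-entropy functional directly on a
#' known joint probability array over `(y_next, y_history, x_history)`
#' rather than on empirical counts — useful for closed-form checks such as
#' the binary copy process, whose exact STE is 1 bit.
#'
#' @param joint 3-d array of probabilities (or unnormalized weights) with
#'   dimensions (next-symbol, target-history, source-history).
#' @param estimator `"shannon"` or `"renyi"`.
#' @param q Weighting parameter for the Renyi case.
#' @return Transfer entropy in bits.
#' @export
te_from_joint <- function(joint, estimator = c("shannon", "renyi"), q = NULL) {
  estimator <- match.arg(estimator)
  if (!is.array(joint) || length(dim(joint)) != 3L || any(joint < 0)) {
    abort("joint must be a non-negative 3-d array")
  }
  if (estimator == "shannon") {
    ste_from_joint(joint)
  } else {
    rte_from_joint(joint, q)
  }
}

#' Shuffle-based null distribution for a transfer-entropy estimate
#'
#' Recomputes the estimate on `reps` block-respecting permutations of the
#' source series (symbols shuffled within each contiguity block, destroying
#' the temporal alignment while preserving the marginal symbol distribution
#' and the block structure). Finite-sample plug-in TE is positively biased;
#' the null summary calibrates an observed value against that bias.
#'
#' @inheritParams shannon_te
#' @param estimator `"shannon"` or `"renyi"`.
#' @param q Weighting parameter for the Renyi case.
#' @param reps Number of permutations (>= 19).
#' @param seed Integer seed for the permutations.
#' @return A list with `observed`, `null_mean`, `null_sd`, `percentile`
#'   (fraction of null values strictly below the observed one) and `reps`.
#' @export
shuffle_null <- function(x, y, estimator = c("shannon", "renyi"), q = NULL,
                         m = 1L, n = 1L, reps = 100L, seed = 1L) {
  estimator <- match.arg(estimator)
  if (!is_count(reps) || reps < 19) abort("reps must be >= 19")
  x <- as_symbolic(x)
  y <- as_symbolic(y)
  est_fun <- function(xs) {
    counts <- joint_counts(xs, y, m, n)
    if (estimator == "shannon") ste_from_joint(counts) else rte_from_joint(counts, q)
  }
  observed <- est_fun(x)
  null_vals <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      shuffled <- x$symbols
      for (b in unique(x$blocks)) {
        sel <- which(x$blocks == b)
        shuffled[sel] <- shuffled[sample(sel)]
      }
      est_fun(symbolic_series(shuffled, x$alphabet_size, x$blocks))
    }, numeric(1))
  })
  list(
    observed = observed, null_mean = mean(null_vals), null_sd = sd(null_vals),
    percentile = mean(null_vals < observed), reps = as.integer(reps)
  )
}

#' Pairwise transfer-entropy matrix across sites
#'
#' Discretizes one index series per site (quantile boundaries on each
#' site's own values, computed on the full series so symbols are comparable
#' across day periods), optionally restricts to one period of the day
#' (cutting contiguity blocks at every period boundary), and estimates the
#' transfer entropy for every ordered site pair.
#'
#' @param index_matrix A tibble with `site_id`, `timestamp` and the index
#'   column (from [gen_index_series()] or [assemble_series()]).
#' @param index Name of the index column to analyze (e.g. `"H"` or `"BI"`).
#' @param estimator `"shannon"` or `"renyi"`.
#' @param q Weighting parameter for the Renyi case.
#' @param m,n Markov orders (default 1).
#' @param period `"all"`, `"dawn"`, `"day"` or `"night"`.
#' @param boundaries Quantile levels in percent for [discretize()].
#' @return A tibble with one row per ordered pair: `from_site`, `to_site`,
#'   `estimator`, `q`, `m`, `n`, `period`, `te_bits`, `n_transitions`.
#'   Sites whose series cannot be discretized are dropped with a message.
#' @examples
#' im <- gen_index_series(soundscape_spec(river_park_sites(), days = 2))
#' tem <- te_matrix(im, "BI", period = "dawn")
#' head(tem)
#' @export
te_matrix <- function(index_matrix, index, estimator = c("shannon", "renyi"),
                      q = NULL, m = 1L, n = 1L,
                      period = c("all", "dawn", "day", "night"),
                      boundaries = c(5, 95)) {
  estimator <- match.arg(estimator)
  period <- match.arg(period)
  if (!index %in% names(index_matrix)) {
    abort(paste0("no column `", index, "` in index_matrix"))
  }
  df <- dplyr::arrange(as_tibble(index_matrix), .data$site_id, .data$timestamp)
  sites <- unique(df$site_id)
  if (length(sites) < 2L) abort("need at least 2 sites")
  series <- list()
  for (s in sites) {
    sub <- df[df$site_id == s, ]
    sym <- tryCatch(discretize(sub[[index]], boundaries),
      error = function(e) NULL
    )
    if (is.null(sym)) {
      rlang::inform(paste0("site ", s, " dropped: series cannot be discretized"))
      next
    }
    if (period != "all") {
      labels <- split_periods(sub$timestamp)
      keep <- which(labels == period)
      if (length(keep) < 20L) {
        rlang::inform(paste0("site ", s, " dropped: too few ", period, " windows"))
        next
      }
      # cut blocks wherever retained windows are not adjacent in the series
      new_blocks <- cumsum(c(1L, as.integer(
        diff(keep) > 1L | diff(sym$blocks[keep]) != 0L
      )))
      sym <- symbolic_series(sym$symbols[keep], sym$alphabet_size, new_blocks,
        edges = sym$edges
      )
    }
    series[[s]] <- sym
  }
  kept <- names(series)
  if (length(kept) < 2L) abort("fewer than 2 sites survived filtering")
  pairs <- tidyr::expand_grid(from_site = kept, to_site = kept)
  pairs <- pairs[pairs$from_site != pairs$to_site, ]
  est <- purrr::map2(pairs$from_site, pairs$to_site, function(a, b) {
    counts <- joint_counts(series[[a]], series[[b]], m, n)
    val <- if (estimator == "shannon") {
      max(ste_from_joint(counts), 0)
    } else {
      rte_from_joint(counts, q)
    }
    list(te = val, n_tr = attr(counts, "n_transitions"))
  })
  q_val <- if (estimator == "renyi") q else NA_real_
  tibble(
    from_site = pairs$from_site, to_site = pairs$to_site,
    estimator = estimator, q = q_val,
    m = as.integer(m), n = as.integer(n), period = period,
    te_bits = purrr::map_dbl(est, "te"),
    n_transitions = purrr::map_int(est, ~ as.integer(.x$n_tr))
  )
}

#' Reshape a pairwise TE tibble into a square matrix
#'
#' @param te_tbl Output of [te_matrix()].
#' @return A square numeric matrix (rows = source, columns = target) with a
#'   zero diagonal.
#' @export
te_to_matrix <- function(te_tbl) {
  sites <- sort(unique(c(te_tbl$from_site, te_tbl$to_site)))
  m <- matrix(0, length(sites), length(sites), dimnames = list(sites, sites))
  m[cbind(te_tbl$from_site, te_tbl$to_site)] <- te_tbl$te_bits
  m
}
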