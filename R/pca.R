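# PCA over the pooled (site, window) observations of the eight indices:
# explained-variance fractions, per-index contributions, retention and
# representative-index selection.

#' Standardize an index matrix for PCA
#'
#' Drops rows containing flagged missing values (counting them), then
#' centres and scales every index column to zero mean and unit variance.
#'
#' @param index_matrix A data frame with the eight index columns (extra
#'   columns such as `site_id`/`timestamp` are ignored for scaling and not
#'   returned).
#' @param columns Index columns to use (default the canonical eight).
#' @return A numeric matrix with attributes `n_dropped` (incomplete rows
#'   removed) and `center`/`scale`.
#' @export
standardize_indices <- function(index_matrix, columns = INDEX_NAMES) {
  missing_cols <- setdiff(columns, names(index_matrix))
  if (length(missing_cols) > 0L) {
    abort(paste0("missing index columns: ", paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(index_matrix[columns])
  complete <- stats::complete.cases(m)
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    rlang::inform(paste0(n_dropped, " incomplete rows dropped before PCA"))
  }
  m <- m[complete, , drop = FALSE]
  if (nrow(m) <= length(columns)) {
    abort("need more complete observations than variables")
  }
  sds <- apply(m, 2L, sd)
  if (any(sds == 0)) {
    abort(paste0(
      "constant column(s): ",
      paste(columns[sds == 0], collapse = ", ")
    ))
  }
  out <- scale(m)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "center") <- attr(out, "scaled:center")
  attr(out, "scale") <- attr(out, "scaled:scale")
  out
}

#' Principal component analysis of an index matrix
#'
#' Runs a PCA on the standardized pooled observations and reports, for each
#' dimension, its explained-variance fraction `V_i` (summing to 1), the
#' cumulative explained variance, the loadings, and the percentage
#' contribution of each index to each dimension
#' (`100 * loading^2 / sum(loading^2)` per dimension). Each loading vector
#' is oriented so its largest-magnitude entry is positive, making signs
#' deterministic.
#'
#' @param index_matrix A data frame with the eight index columns, or an
#'   already-standardized matrix from [standardize_indices()].
#' @param columns Index columns to use.
#' @return An object of class `index_pca` with elements `eigenvalues`,
#'   `explained_variance` (the `V_i`), `cumulative_ev`, `loadings`,
#'   `contributions` (percent, columns sum to 100), `scores` and `n_obs`.
#' @examples
#' im <- gen_index_series(soundscape_spec(river_park_sites(), days = 2))
#' fit <- index_pca(im)
#' glance(fit)
#' @export
index_pca <- function(index_matrix, columns = INDEX_NAMES) {
  m <- if (is.matrix(index_matrix)) {
    index_matrix
  } else {
    standardize_indices(index_matrix, columns)
  }
  fit <- prcomp(m, center = FALSE, scale. = FALSE)
  flip <- apply(fit$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(fit$rotation, 2L, flip, `*`)
  scores <- sweep(fit$x, 2L, flip, `*`)
  eig <- fit$sdev^2
  v <- eig / sum(eig)
  contrib <- sweep(loadings^2, 2L, colSums(loadings^2), `/`) * 100
  dims <- paste0("Dim", seq_along(eig))
  colnames(loadings) <- colnames(contrib) <- colnames(scores) <- dims
  structure(
    list(
      eigenvalues = setNames(eig, dims),
      explained_variance = setNames(v, dims),
      cumulative_ev = setNames(cumsum(v), dims),
      loadings = loadings, contributions = contrib,
      scores = scores, n_obs = nrow(m),
      n_dropped = attr(m, "n_dropped") %||% 0L
    ),
    class = "index_pca"
  )
}

#' @export
print.index_pca <- function(x, ...) {
  cat("<index_pca> ", x$n_obs, " observations, ",
    length(x$eigenvalues), " dimensions\n",
    sep = ""
  )
  ev <- round(100 * x$explained_variance, 1)
  cat("explained variance [%]:", paste(ev, collapse = " "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an index PCA
#'
#' One row per (index, dimension) pair with the loading and the percentage
#' contribution.
#'
#' @param x An `index_pca` object.
#' @param ... Unused.
#' @return A tibble with columns `index`, `dimension`, `loading`,
#'   `contribution_pct`.
#' @export
tidy.index_pca <- function(x, ...) {
  long <- as_tibble(x$loadings, rownames = "index")
  long <- tidyr::pivot_longer(long, -"index",
    names_to = "dimension", values_to = "loading"
  )
  contrib <- as_tibble(x$contributions, rownames = "index")
  contrib <- tidyr::pivot_longer(contrib, -"index",
    names_to = "dimension", values_to = "contribution_pct"
  )
  dplyr::left_join(long, contrib, by = c("index", "dimension"))
}

#' @rdname tidy.index_pca
#' @return For `glance`: a one-row-per-dimension tibble with eigenvalue,
#'   explained-variance fraction and cumulative explained variance.
#' @export
glance.index_pca <- function(x, ...) {
  tibble(
    dimension = names(x$eigenvalues),
    eigenvalue = unname(x$eigenvalues),
    explained_variance = unname(x$explained_variance),
    cumulative_ev = unname(x$cumulative_ev),
    n_obs = x$n_obs
  )
}

#' Scree / contribution plot for an index PCA
#'
#' @param object An `index_pca` object.
#' @param dimension Dimension to show contributions for (default `"Dim1"`).
#' @param ... Unused.
#' @return A ggplot object: per-index contribution bars with the uniform
#'   reference level (100 / n indices) as a horizontal line.
#' @export
autoplot.index_pca <- function(object, dimension = "Dim1", ...) {
  d <- tidy(object)
  d <- d[d$dimension == dimension, ]
  d$index <- factor(d$index, levels = d$index[order(-d$contribution_pct)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$contribution_pct)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 100 / nrow(d), linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = "contribution [%]",
      title = paste0(
        dimension, " (",
        round(100 * object$explained_variance[[dimension]], 1),
        "% of variance)"
      )
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Decide how many dimensions to retain
#'
#' Default policy keeps the top `k` dimensions (k = 2); the alternative
#' `"threshold"` policy keeps dimensions whose explained-variance fraction
#' exceeds `threshold_frac` times the mean fraction.
#'
#' @param pca An `index_pca` object.
#' @param policy `"top_k"` or `"threshold"`.
#' @param k Number of dimensions for `"top_k"` (default 2).
#' @param threshold_frac Multiplier of the mean `V_i` for `"threshold"`
#'   (default 1).
#' @return A list with `retained` (dimension count) and `cumulative_ev`.
#' @export
retain_dimensions <- function(pca, policy = c("top_k", "threshold"), k = 2L,
                              threshold_frac = 1) {
  policy <- match.arg(policy)
  v <- pca$explained_variance
  retained <- switch(policy,
    top_k = min(as.integer(k), length(v)),
    threshold = sum(v > threshold_frac * mean(v))
  )
  retained <- max(retained, 1L)
  list(retained = retained, cumulative_ev = unname(pca$cumulative_ev[retained]))
}

#' Select one representative index per retained dimension
#'
#' Default policy picks the index with the largest contribution to each
#' dimension, breaking exact ties by the canonical index order
#' (H, ACI, ADI, AEI, NDSI, BI, DSC, ZCR). Manual overrides are accepted and
#' recorded as such (interpretability can justify choosing, say, BI over a
#' marginally higher contributor).
#'
#' @param pca An `index_pca` object.
#' @param retained Number of dimensions to cover (default 2).
#' @param overrides Named list/character, e.g. `list(Dim2 = "BI")`.
#' @return A tibble with `dimension`, `chosen_index`, `policy`,
#'   `contribution_pct`.
#' @export
select_representatives <- function(pca, retained = 2L, overrides = NULL) {
  dims <- paste0("Dim", seq_len(retained))
  overrides <- as.list(overrides %||% list())
  bad <- setdiff(unlist(overrides), rownames(pca$contributions))
  if (length(bad) > 0L) {
    abort(paste0("override names unknown index: ", paste(bad, collapse = ", ")))
  }
  purrr::map_dfr(dims, function(dim) {
    contrib <- pca$contributions[, dim]
    if (!is.null(overrides[[dim]])) {
      chosen <- overrides[[dim]]
      pol <- "manual"
    } else {
      ord <- order(-contrib, match(names(contrib), INDEX_NAMES))
      chosen <- names(contrib)[ord[1L]]
      pol <- "top_contribution"
    }
    tibble(
      dimension = dim, chosen_index = chosen, policy = pol,
      contribution_pct = unname(contrib[chosen])
    )
  })
}
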