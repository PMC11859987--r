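# From pairwise TE values to directed flow networks: oriented TE differences
# (the arrow between two sites points toward the site receiving more
# information than it sends back), percentile thresholds, geometry and the
# spatial summary statistics (arrow density, normalized distance index).

#' Label timestamps with the period of the day
#'
#' Half-open intervals in local time: dawn `[05:00, 08:00)`, day
#' `[08:00, 18:00)`, night `[18:00, 05:00)` (wrapping midnight).
#'
#' @param timestamps POSIXct vector.
#' @return Character vector of labels `"dawn"`, `"day"`, `"night"`.
#' @examples
#' split_periods(as.POSIXct(c("2022-04-13 05:00", "2022-04-13 02:30"), tz = "UTC"))
#' @export
split_periods <- function(timestamps) {
  hour <- as.numeric(format(timestamps, "%H", tz = "UTC")) +
    as.numeric(format(timestamps, "%M", tz = "UTC")) / 60 +
    as.numeric(format(timestamps, "%S", tz = "UTC")) / 3600
  dplyr::case_when(
    hour >= 5 & hour < 8 ~ "dawn",
    hour >= 8 & hour < 18 ~ "day",
    .default = "night"
  )
}

#' Oriented transfer-entropy difference for one site pair
#'
#' The difference between the two directional TE values; the arrow points in
#' the direction of the larger one. An exact tie produces no edge.
#'
#' @param te_forward TE from X to Y (bits).
#' @param te_reverse TE from Y to X (bits).
#' @return A list with `dtem` (non-negative oriented magnitude), `signed`
#'   (forward minus reverse) and `direction` (`"forward"`, `"reverse"` or
#'   `"tie"`).
#' @export
dtem <- function(te_forward, te_reverse) {
  signed <- te_forward - te_reverse
  list(
    dtem = abs(signed), signed = signed,
    direction = if (signed > 0) "forward" else if (signed < 0) "reverse" else "tie"
  )
}

#' Percentile threshold of a pool of values
#'
#' Linear-interpolation (type-7) percentile of the pooled oriented DTEM
#' values of one estimator configuration.
#'
#' @param values Numeric pool (>= 2 values).
#' @param p Percentile in `[0, 100]`.
#' @return The cutoff value.
#' @examples
#' percentile_threshold(1:100, 95) # 95.05
#' @export
percentile_threshold <- function(values, p) {
  if (length(values) < 2L) abort("need at least 2 values")
  quantile(values, p / 100, names = FALSE, type = 7)
}

#' Build a directed flow network from a TE matrix
#'
#' Every unordered site pair is oriented by [dtem()]; edges whose oriented
#' difference lies strictly above the percentile cutoff are kept (exact ties
#' are logged and never become edges). The cutoff defaults to the given
#' percentile of this matrix's own oriented DTEM pool; supplying `cutoff`
#' directly supports pooling across day periods of one configuration.
#'
#' @param te_tbl Output of [te_matrix()] (one estimator configuration).
#' @param sites A [site_map()] covering all sites in `te_tbl`.
#' @param percentile Percentile threshold (default 95, as used for the flow
#'   maps; 75 gives the denser network).
#' @param cutoff Optional explicit threshold value in bits overriding the
#'   percentile computation.
#' @return A `flow_network`: list with `edges` (tibble `source`, `target`,
#'   `dtem`, `te_forward`, `te_reverse`, `d_i`), `n_bar`, `d_max`, `d_n`
#'   (normalized distance index), `threshold_value`, `percentile_used`,
#'   `densities` (per-group arrows/site), `period`, `sites`.
#' @export
build_network <- function(te_tbl, sites, percentile = 95, cutoff = NULL) {
  if (!inherits(sites, "site_map")) abort("sites must be a site_map")
  te_sites <- unique(c(te_tbl$from_site, te_tbl$to_site))
  missing_sites <- setdiff(te_sites, sites$site_id)
  if (length(missing_sites) > 0L) {
    abort(paste0(
      "sites missing coordinates: ",
      paste(missing_sites, collapse = ", ")
    ))
  }
  if (length(unique(te_tbl$estimator)) > 1L ||
    length(unique(te_tbl$period)) > 1L) {
    abort("te_tbl mixes estimator configurations; build one network per configuration")
  }
  m <- te_to_matrix(te_tbl)
  ids <- rownames(m)
  pairs <- utils::combn(ids, 2L)
  oriented <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]
    b <- pairs[2L, i]
    d <- dtem(m[a, b], m[b, a])
    tibble(
      source = if (d$direction == "reverse") b else a,
      target = if (d$direction == "reverse") a else b,
      dtem = d$dtem,
      te_forward = if (d$direction == "reverse") m[b, a] else m[a, b],
      te_reverse = if (d$direction == "reverse") m[a, b] else m[b, a],
      tie = d$direction == "tie"
    )
  })
  n_ties <- sum(oriented$tie)
  if (n_ties > 0L) {
    rlang::inform(paste0(n_ties, " exact tie(s) dropped from the arrow pool"))
  }
  oriented <- oriented[!oriented$tie, ]
  threshold_value <- cutoff %||% percentile_threshold(oriented$dtem, percentile)
  # strict inequality at the cutoff, except at the degenerate 0th percentile
  # where the cutoff is the pool minimum and every non-tie pair is an arrow
  keep <- if (is.null(cutoff) && percentile <= 0) {
    oriented$dtem >= threshold_value
  } else {
    oriented$dtem > threshold_value
  }
  edges <- oriented[keep, , drop = FALSE]
  xy <- setNames(
    lapply(c("x", "y"), function(cc) setNames(sites[[cc]], sites$site_id)),
    c("x", "y")
  )
  edges$d_i <- unname(sqrt(
    (xy$x[edges$source] - xy$x[edges$target])^2 +
      (xy$y[edges$source] - xy$y[edges$target])^2
  ))
  edges$tie <- NULL
  n_bar <- nrow(edges)
  d_max <- if (n_bar > 0L) max(edges$d_i) else NA_real_
  d_n <- if (n_bar > 0L) mean(edges$d_i / d_max) else NA_real_
  groups <- unique(sites$group)
  densities <- setNames(vapply(groups, function(g) {
    members <- sites$site_id[sites$group == g]
    sum(edges$source %in% members) / length(members)
  }, numeric(1)), groups)
  structure(
    list(
      edges = as_tibble(edges), n_bar = n_bar, d_max = d_max, d_n = d_n,
      threshold_value = unname(threshold_value), percentile_used = percentile,
      densities = densities, period = unique(te_tbl$period),
      estimator = unique(te_tbl$estimator), q = unique(te_tbl$q),
      sites = sites
    ),
    class = "flow_network"
  )
}

#' @export
print.flow_network <- function(x, ...) {
  cat("<flow_network> ", x$n_bar, " arrows above ",
    format(x$threshold_value, digits = 4), " bits (",
    x$percentile_used, "th pct), period ", x$period, "\n",
    sep = ""
  )
  if (x$n_bar > 0L) {
    cat(
      "d_max =", round(x$d_max, 1), "m; d_n =", round(x$d_n, 3), "\n"
    )
  }
  invisible(x)
}

#' @rdname tidy.index_pca
#' @export
tidy.flow_network <- function(x, ...) x$edges

#' @rdname tidy.index_pca
#' @export
glance.flow_network <- function(x, ...) {
  tibble(
    period = x$period, estimator = x$estimator, q = x$q,
    n_bar = x$n_bar, d_max = x$d_max, d_n = x$d_n,
    threshold_value = x$threshold_value, percentile_used = x$percentile_used
  )
}

#' Plot a flow network over the site coordinates
#'
#' @param object A `flow_network`.
#' @param ... Unused.
#' @return A ggplot object: sites as points (colored by group), arrows for
#'   every above-threshold edge.
#' @export
autoplot.flow_network <- function(object, ...) {
  sites <- object$sites
  e <- object$edges
  xy <- setNames(
    lapply(c("x", "y"), function(cc) setNames(sites[[cc]], sites$site_id)),
    c("x", "y")
  )
  p <- ggplot2::ggplot(sites, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$group), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$site_id),
      nudge_y = 12, size = 3
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x [m]", y = "y [m]",
      title = paste0(
        "flow network (", object$period, ", ",
        object$percentile_used, "th pct)"
      )
    )
  if (nrow(e) > 0L) {
    seg <- tibble(
      x = xy$x[e$source], y = xy$y[e$source],
      xend = xy$x[e$target], yend = xy$y[e$target]
    )
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(
        x = .data$x, y = .data$y,
        xend = .data$xend, yend = .data$yend
      ),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      alpha = 0.7
    )
  }
  p
}

#' Per-site emission and reception profile
#'
#' Total TE emitted from each site (row sums), received at each site (column
#' sums), and their difference. The nets are computed from the exactly
#' antisymmetric pairwise difference matrix, so they sum to zero exactly;
#' sites with positive net are biophonic "hot" (predominantly emitting)
#' sites, negative net "cold" (predominantly receiving).
#'
#' @param te_tbl Output of [te_matrix()] (complete for the site set).
#' @return A tibble with `site_id`, `emitted`, `received`, `net`,
#'   `classification`.
#' @export
emission_reception <- function(te_tbl) {
  m <- te_to_matrix(te_tbl)
  d <- m - t(m) # exactly antisymmetric
  net <- unname(rowSums(d))
  tibble(
    site_id = rownames(m),
    emitted = unname(rowSums(m)),
    received = unname(colSums(m)),
    net = net,
    classification = dplyr::case_when(
      net > 0 ~ "hot", net < 0 ~ "cold", .default = "neutral"
    )
  )
}

#' Arrow density per site group
#'
#' Number of above-threshold arrows attributed to each group divided by the
#' group's site count. Arrows are assigned by their source site (an arrow
#' represents information emitted).
#'
#' @param network A `flow_network`.
#' @param groups Optional named list mapping group labels to site-id
#'   vectors; defaults to the `group` column of the network's site map.
#' @return A tibble with `group`, `n_arrows`, `n_sites`, `density`.
#' @export
arrow_density <- function(network, groups = NULL) {
  sites <- network$sites
  if (is.null(groups)) {
    groups <- split(sites$site_id, sites$group)
  }
  if (any(lengths(groups) == 0L)) abort("empty group")
  purrr::imap_dfr(groups, function(members, g) {
    n_arrows <- sum(network$edges$source %in% members)
    tibble(
      group = g, n_arrows = n_arrows, n_sites = length(members),
      density = n_arrows / length(members)
    )
  })
}

#' Normalized distance index (NDI) of a flow network
#'
#' Mean of the drawn arrows' lengths divided by the maximum drawn length:
#' `d_n = (1/n_bar) * sum(d_i / d_max)`, in `(0, 1]`. `d_max` is taken over
#' the drawn arrows (so a single-arrow network has `d_n = 1`); set
#' `d_max = "pairs"` to normalize by the maximum distance over all site
#' pairs instead.
#'
#' @param network A `flow_network`.
#' @param d_max `"arrows"` (default) or `"pairs"`.
#' @return `d_n`, or flagged `NA` when the network has no arrows.
#' @export
ndi <- function(network, d_max = c("arrows", "pairs")) {
  d_max <- match.arg(d_max)
  if (network$n_bar == 0L) {
    warn("network has no arrows: NDI undefined (NA)")
    return(NA_real_)
  }
  dm <- if (d_max == "arrows") {
    max(network$edges$d_i)
  } else {
    sites <- network$sites
    max(stats::dist(cbind(sites$x, sites$y)))
  }
  mean(network$edges$d_i / dm)
}
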