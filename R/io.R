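# Delimited-text and JSON readers/writers for the pipeline artifacts. All
# writers embed the configuration that produced the numbers, and none embed
# wall-clock timestamps, so re-running a configuration reproduces the files
# byte for byte.

#' Read and write index matrices as delimited text
#'
#' Schema: `site_id`, `timestamp` (ISO-8601, UTC), then the eight index
#' columns `H, ACI, ADI, AEI, NDSI, BI, DSC, ZCR`.
#'
#' @param index_matrix A tibble as produced by [gen_index_series()] or
#'   [assemble_series()].
#' @param path File path (CSV).
#' @return `read_index_matrix` returns the tibble; `write_index_matrix`
#'   returns `path` invisibly.
#' @export
write_index_matrix <- function(index_matrix, path) {
  out <- as_tibble(index_matrix)
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_index_matrix
#' @export
read_index_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  df$site_id <- as.character(df$site_id)
  df$timestamp <- as.POSIXct(df$timestamp,
    format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"
  )
  df
}

#' Read a site map from delimited text
#'
#' Expected columns: `site_id`, `x`, `y` and optionally `group`.
#'
#' @param path File path (CSV).
#' @param ... Passed to [site_map()] (e.g. `exclude`, `road`).
#' @return A [site_map()].
#' @export
read_site_map <- function(path, ...) {
  site_map(readr::read_csv(path, show_col_types = FALSE), ...)
}

#' Write a TE table or flow network to disk
#'
#' The TE table goes to CSV with its full configuration columns; the flow
#' network to JSON with an edge list and a summary block (n_bar, d_max,
#' d_n, densities, threshold and configuration).
#'
#' @param te_tbl Output of [te_matrix()].
#' @param network A `flow_network`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_te_table <- function(te_tbl, path) {
  readr::write_csv(te_tbl, path)
  invisible(path)
}

#' @rdname write_te_table
#' @export
write_network_json <- function(network, path) {
  payload <- list(
    summary = list(
      period = network$period, estimator = network$estimator,
      q = network$q, percentile_used = network$percentile_used,
      threshold_value = network$threshold_value,
      n_bar = network$n_bar, d_max = network$d_max, d_n = network$d_n,
      densities = as.list(network$densities)
    ),
    edges = network$edges
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(path)
}

#' Write audio segments for a synthetic deployment
#'
#' One 16-bit mono WAV per (site, window), named
#' `<site_id>_<ISO timestamp>.wav`.
#'
#' @param spec A [soundscape_spec()].
#' @param dir Output directory (created if needed).
#' @param windows Window numbers to render (default the first).
#' @param site_ids Sites to render (default all usable sites).
#' @return Tibble of written files, invisibly.
#' @export
write_audio_segments <- function(spec, dir, windows = 1L, site_ids = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  site_ids <- site_ids %||% spec$site_map$site_id
  grid <- tidyr::expand_grid(site_id = site_ids, window = windows)
  files <- purrr::pmap_chr(grid, function(site_id, window) {
    seg <- gen_audio_segment(spec, site_id, window)
    stamp <- format(seg$start_time, "%Y%m%dT%H%M%SZ", tz = "UTC")
    path <- file.path(dir, paste0("site", site_id, "_", stamp, ".wav"))
    write_wav(seg$samples, path, seg$sample_rate)
    path
  })
  invisible(tibble(grid, path = files))
}
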