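# End-to-end orchestration: index series -> PCA -> representative indices ->
# TE matrices per (index, estimator, period) -> flow networks -> summaries.

#' Configure a full analysis run
#'
#' @param spec A [soundscape_spec()] to generate inputs from, or `NULL` when
#'   `index_matrix` is supplied directly.
#' @param index_matrix Optional pre-computed index tibble (overrides `spec`
#'   as data source; `spec` is then only used for survey labels if given).
#' @param representatives `"auto"` (top-contribution policy on the retained
#'   dimensions) or a named character vector of manual overrides, e.g.
#'   `c(Dim1 = "H", Dim2 = "BI")`.
#' @param keep Number of PCA dimensions to retain (default 2).
#' @param estimators Tibble with columns `estimator` and `q`; default
#'   Shannon plus Renyi at q = 0.1 and q = 0.5.
#' @param periods Periods to analyze: any of `"all"`, `"dawn"`, `"day"`,
#'   `"night"`. Default: the three day periods for duty-cycle protocols,
#'   `"all"` for continuous ones.
#' @param percentile Arrow threshold percentile (default 95).
#' @param boundaries Discretization quantile levels (default `c(5, 95)`).
#' @param m,n Markov orders (default 1).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(spec = NULL, index_matrix = NULL,
                            representatives = "auto", keep = 2L,
                            estimators = default_estimators(),
                            periods = NULL, percentile = 95,
                            boundaries = c(5, 95), m = 1L, n = 1L) {
  if (is.null(spec) && is.null(index_matrix)) {
    abort("config needs a soundscape spec or an index matrix")
  }
  if (is.null(periods)) {
    protocol <- if (!is.null(spec)) spec$protocol else attr(index_matrix, "protocol")
    periods <- if (identical(protocol, "duty_cycle")) {
      c("dawn", "day", "night")
    } else {
      "all"
    }
  }
  structure(
    list(
      spec = spec, index_matrix = index_matrix,
      representatives = representatives, keep = as.integer(keep),
      estimators = estimators, periods = periods, percentile = percentile,
      boundaries = boundaries, m = as.integer(m), n = as.integer(n)
    ),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @export
default_estimators <- function() {
  tibble(
    estimator = c("shannon", "renyi", "renyi"),
    q = c(NA_real_, 0.1, 0.5)
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage `", stage, "` failed: ", conditionMessage(e)))
  })
}

#' Run the whole analysis pipeline
#'
#' Executes every stage on one configuration: build (or accept) the index
#' matrix, run the PCA and pick representative indices, estimate TE matrices
#' for every (representative index, estimator, period) combination,
#' threshold the oriented TE differences into flow networks — pooling the
#' percentile cutoff across periods within each (index, estimator, q)
#' configuration so period networks are comparable — and summarize
#' emission/reception, arrow densities, NDI and the aural survey (when the
#' generator's drivers are available). Re-running the same configuration
#' reproduces all outputs exactly.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, every artifact is also
#'   written there (CSV/JSON, no embedded wall-clock timestamps).
#' @return A `soundflow_run` list: `index_matrix`, `pca`, `retention`,
#'   `representatives`, `te_tables` (one bound tibble), `networks` (named
#'   list of `flow_network`s), `network_summary`, `emission`,
#'   `survey_summary` (or `NULL`), `config`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(
#'   soundscape_spec(river_park_sites(), days = 2, seed = 1),
#'   estimators = tibble::tibble(estimator = "shannon", q = NA_real_)
#' )
#' run <- run_pipeline(cfg)
#' run$network_summary
#' }
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (!inherits(config, "pipeline_config")) abort("config must be a pipeline_config")
  im <- run_stage("index_matrix", {
    config$index_matrix %||% gen_index_series(config$spec)
  })
  pca <- run_stage("dimension_reduction", index_pca(im))
  retention <- retain_dimensions(pca, k = config$keep)
  reps <- run_stage("representative_selection", {
    if (identical(config$representatives, "auto")) {
      select_representatives(pca, retention$retained)
    } else {
      select_representatives(pca, retention$retained,
        overrides = as.list(config$representatives)
      )
    }
  })
  grid <- tidyr::expand_grid(
    index = unique(reps$chosen_index),
    config$estimators,
    period = config$periods
  )
  te_tables <- run_stage("transfer_entropy", {
    purrr::pmap(grid, function(index, estimator, q, period) {
      te_matrix(im, index,
        estimator = estimator, q = if (is.na(q)) NULL else q,
        m = config$m, n = config$n, period = period,
        boundaries = config$boundaries
      )
    })
  })
  te_all <- dplyr::bind_rows(purrr::map2(
    te_tables, grid$index,
    function(tb, idx) dplyr::mutate(tb, index = idx, .before = 1L)
  ))
  networks <- run_stage("flow_network", {
    sm <- if (!is.null(config$spec)) config$spec$site_map else attr(im, "spec")$site_map
    if (is.null(sm)) abort("no site map available for network construction")
    out <- list()
    cfg_key <- paste(grid$index, grid$estimator, grid$q)
    for (key_i in unique(cfg_key)) {
      sel <- which(cfg_key == key_i)
      # pool oriented DTEMs across this configuration's periods
      pool <- unlist(lapply(sel, function(j) {
        mt <- te_to_matrix(te_tables[[j]])
        up <- upper.tri(mt)
        abs(mt[up] - t(mt)[up])
      }))
      cutoff <- percentile_threshold(pool, config$percentile)
      for (j in sel) {
        key <- paste(grid$index[j], grid$estimator[j],
          ifelse(is.na(grid$q[j]), "", grid$q[j]), grid$period[j],
          sep = "_"
        )
        out[[key]] <- build_network(te_tables[[j]], sm,
          percentile = config$percentile, cutoff = cutoff
        )
      }
    }
    out
  })
  network_summary <- dplyr::bind_cols(
    tibble(configuration = names(networks)),
    purrr::map_dfr(networks, glance)
  )
  emission <- run_stage("emission_reception", {
    keys <- dplyr::distinct(grid)
    purrr::map_dfr(seq_along(te_tables), function(j) {
      dplyr::bind_cols(keys[j, ], emission_reception(te_tables[[j]]))
    })
  })
  survey_summary <- NULL
  if (!is.null(attr(im, "drivers"))) {
    survey_summary <- run_stage(
      "survey",
      summarize_survey(gen_survey_labels(im))
    )
  }
  run <- structure(
    list(
      index_matrix = im, pca = pca, retention = retention,
      representatives = reps, te_tables = te_all, networks = networks,
      network_summary = network_summary, emission = emission,
      survey_summary = survey_summary, config = config
    ),
    class = "soundflow_run"
  )
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

#' @export
print.soundflow_run <- function(x, ...) {
  cat("<soundflow_run>\n")
  cat(
    " index matrix:", nrow(x$index_matrix), "rows,",
    length(unique(x$index_matrix$site_id)), "sites\n"
  )
  ev <- round(100 * x$retention$cumulative_ev, 1)
  cat(
    " PCA:", x$retention$retained, "dimensions retained (cumulative EV",
    paste0(ev, "%)"), "\n"
  )
  cat(
    " representatives:",
    paste(x$representatives$chosen_index, collapse = ", "), "\n"
  )
  cat(" networks:", length(x$networks), "configurations\n")
  invisible(x)
}

# Persist every artifact of a run under `dir`.
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_index_matrix(run$index_matrix, file.path(dir, "index_matrix.csv"))
  jsonlite::write_json(
    list(
      eigenvalues = run$pca$eigenvalues,
      explained_variance = run$pca$explained_variance,
      contributions = as.data.frame(run$pca$contributions),
      representatives = run$representatives,
      retained = run$retention$retained
    ),
    file.path(dir, "pca.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  write_te_table(run$te_tables, file.path(dir, "te_matrices.csv"))
  for (key in names(run$networks)) {
    write_network_json(
      run$networks[[key]],
      file.path(dir, paste0("network_", key, ".json"))
    )
  }
  readr::write_csv(run$network_summary, file.path(dir, "network_summary.csv"))
  readr::write_csv(run$emission, file.path(dir, "emission.csv"))
  if (!is.null(run$survey_summary)) {
    readr::write_csv(run$survey_summary, file.path(dir, "survey_summary.csv"))
  }
  invisible(dir)
}
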