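SURVEY_VOCAB <- list(
  birds_singing = c("none", "few", "many"),
  bird_species = c("none", "<=2", ">2"),
  singing_activity = c("0", "(0,25]", "(25,50]", "(50,75]", "(75,100]"),
  traffic_characteristics = c("none", "continuous", "intermittent"),
  traffic_intensity = c("none", "low", "high"),
  other_sources = c("none", "presence")
)

#' Summarize an aural-survey table per site
#'
#' Validates every label against the closed survey vocabulary and computes,
#' for each site, the fraction of recordings with many birds singing and
#' with high traffic intensity. Fractions are stored at full precision;
#' round only for display (two decimals is the conventional table format).
#'
#' @param survey A data frame with columns `site_id` and the survey
#'   categories (as produced by [gen_survey_labels()]).
#' @return A tibble with `site_id`, `n_recordings`, `frac_many_birds`,
#'   `frac_high_traffic`.
#' @export
summarize_survey <- function(survey) {
  survey <- as_tibble(survey)
  if (nrow(survey) == 0L) abort("survey table is empty")
  for (cat_name in intersect(names(SURVEY_VOCAB), names(survey))) {
    bad <- which(!survey[[cat_name]] %in% SURVEY_VOCAB[[cat_name]])
    if (length(bad) > 0L) {
      abort(paste0(
        "unknown ", cat_name, " label `", survey[[cat_name]][bad[1]],
        "` at row ", bad[1]
      ))
    }
  }
  needed <- c("site_id", "birds_singing", "traffic_intensity")
  missing_cols <- setdiff(needed, names(survey))
  if (length(missing_cols) > 0L) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  out <- dplyr::summarise(
    dplyr::group_by(survey, .data$site_id),
    n_recordings = dplyr::n(),
    frac_many_birds = mean(.data$birds_singing == "many"),
    frac_high_traffic = mean(.data$traffic_intensity == "high"),
    .groups = "drop"
  )
  out
}
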