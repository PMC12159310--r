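# Small in-code fixtures shared across test files.

# Tiny hand-built long dataset: two families (one MZ, one DZ), one measure
# per trait, fully observed.
tiny_dataset <- function() {
  grid <- expand.grid(family_id = 1:2, twin_index = 1:2,
                      measure_id = c("cbcl_aggression", "peq_nurturance"),
                      stringsAsFactors = FALSE)
  grid$zygosity <- ifelse(grid$family_id == 1, "MZ", "DZ")
  grid$informant_id <- ifelse(grid$measure_id == "peq_nurturance",
                              "mother", "mother")
  grid$value <- seq_len(nrow(grid))
  tibble::as_tibble(grid[c("family_id", "zygosity", "twin_index",
                           "measure_id", "informant_id", "value")])
}

# Perfect-measurement battery covering one checklist measure, the
# interview, and all nurturance reports: reliability 1, no skew, no
# missingness, so observed scores are affine images of the latents.
perfect_battery <- function() {
  dplyr::bind_rows(
    measurement_model("cbcl_aggression", "mother", "asb", 1, 0, 0, 0, 36),
    measurement_model("interview", "twin", "asb", 1, 0, 0, 0, 46),
    measurement_model("peq_nurturance", "mother", "nurturance", 1, 0, 0,
                      0, 36))
}

# Minimal one-cell curve configuration matching perfect_battery().
one_cell_config <- function() {
  curve_config(asb_measures = "cbcl_aggression",
               cbcl_informants = "mother",
               nurturance_informants = "mother",
               normalizations = "raw")
}

# Analysis table of a small simulated study, cached per session.
small_study_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      study <- simulate_twin_study("scenario1_environmental", n_mz = 120,
                                   n_dz = 150, seed = 7)
      cache <<- build_analysis_table(study$dataset)
    }
    cache
  }
})
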