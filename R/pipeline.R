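#' Full twin-differences specification-curve analysis
#'
#' Runs the complete pipeline on a long twin dataset: derives the analysis
#' variables, assigns A/B labels, executes the phenotypic and
#' twin-difference multiverses, aggregates each (overall and within MZ /
#' DZ pairs), applies the four-indicator decision rule, and classifies the
#' etiologic scenario.
#'
#' @param dataset A long twin dataset (see [render_observed()] /
#'   [read_twin_dataset()]) or a prebuilt [build_analysis_table()] output.
#' @param config [curve_config()] for the twin-difference multiverse (and,
#'   by default, the phenotypic one).
#' @param phenotypic_config Optional separate [curve_config()] for the
#'   phenotypic level (the multilevel models are the expensive part of the
#'   pipeline; a reduced phenotypic grid is useful in simulation studies).
#' @param seed Integer seed for the A/B assignment.
#' @param alpha,z_crit Decision thresholds, see [decide_significance()].
#' @return A list of class `twin_curve_analysis`: `results` (per-spec
#'   estimates), `summaries` (overall phenotypic / MZ / DZ), `decisions`,
#'   `scenario` (a [classify_scenario()] label), plus the configuration
#'   and seed.
#' @examples
#' study <- simulate_twin_study("scenario2_genetic", n_mz = 80, n_dz = 80,
#'                              seed = 3)
#' cfg <- curve_config(asb_measures = "cbcl_aggression",
#'                     cbcl_informants = "mother",
#'                     nurturance_informants = "mother",
#'                     normalizations = "raw")
#' analyze_twin_dataset(study$dataset, config = cfg, seed = 3)$scenario
#' @export
analyze_twin_dataset <- function(dataset, config = default_curve_config(),
                                 phenotypic_config = NULL, seed = 1,
                                 alpha = 0.05, z_crit = 1.96) {
  analysis <- if ("measure_id" %in% names(dataset)) {
    build_analysis_table(dataset)
  } else {
    dataset
  }
  if (is.null(phenotypic_config)) phenotypic_config <- config
  assignment <- assign_twin_labels(analysis, seed)
  specs <- dplyr::bind_rows(
    enumerate_specifications(phenotypic_config, "phenotypic"),
    enumerate_specifications(config, "twin_difference"))
  results <- run_spec_curve(analysis, specs, assignment = assignment)
  pick <- function(level, zyg) {
    results[results$analysis_level == level & results$zygosity == zyg, ]
  }
  summaries <- list(
    phenotypic = summarize_curve(pick("phenotypic", "not_applicable")),
    mz = summarize_curve(pick("twin_difference", "MZ")),
    dz = summarize_curve(pick("twin_difference", "DZ")))
  decisions <- lapply(summaries, decide_significance,
                      alpha = alpha, z_crit = z_crit)
  scenario <- classify_scenario(decisions$phenotypic, decisions$mz,
                                decisions$dz)
  structure(list(results = results, summaries = summaries,
                 decisions = decisions, scenario = scenario,
                 config = config, phenotypic_config = phenotypic_config,
                 seed = seed),
            class = "twin_curve_analysis")
}

#' @export
print.twin_curve_analysis <- function(x, ...) {
  cat("Twin-differences specification-curve analysis\n")
  fmt <- function(s, d) {
    sprintf("median %.3f [%.3f, %.3f], mean %.3f [%.3f, %.3f], median p %.3g, %%p<.05 %.1f, avg z %.2f, k %d -> %s",
            s$median_es, s$median_ci_low, s$median_ci_high, s$mean_es,
            s$mean_ci_low, s$mean_ci_high, s$median_p, s$pct_p_lt_05,
            s$avg_z, s$k,
            if (d$significant) "significant" else "nonsignificant")
  }
  cat("  phenotypic:      ", fmt(x$summaries$phenotypic,
                                 x$decisions$phenotypic), "\n")
  cat("  MZ differences:  ", fmt(x$summaries$mz, x$decisions$mz), "\n")
  cat("  DZ differences:  ", fmt(x$summaries$dz, x$decisions$dz), "\n")
  print(x$scenario)
  invisible(x)
}

#' Grouped curve summaries in the layout of the study tables
#'
#' For each analysis level (and zygosity at the twin-difference level),
#' summarizes the curve overall and within each level of each
#' specification axis: antisocial-behavior measure, antisocial-behavior
#' informant, nurturance informant, and normalization. Every row is
#' exactly [summarize_curve()] applied to the corresponding subset.
#'
#' @param results Results tibble from [run_spec_curve()].
#' @return A tibble with `analysis_level`, `zygosity`, `group_type`,
#'   `group_value`, and the summary columns.
#' @export
grouped_summaries <- function(results) {
  blocks <- unique(results[c("analysis_level", "zygosity")])
  axes <- c(overall = NA, asb_measure = "asb_measure",
            asb_informant = "asb_informant",
            nurturance_informant = "nurturance_informant",
            normalization = "normalization")
  rows <- list()
  for (b in seq_len(nrow(blocks))) {
    sub <- results[results$analysis_level == blocks$analysis_level[b] &
                     results$zygosity == blocks$zygosity[b], ]
    for (ax in names(axes)) {
      if (ax == "overall") {
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          blocks[b, ], tibble::tibble(group_type = "overall",
                                      group_value = "overall"),
          summarize_curve(sub))
      } else {
        for (val in unique(sub[[axes[[ax]]]])) {
          rows[[length(rows) + 1]] <- dplyr::bind_cols(
            blocks[b, ], tibble::tibble(group_type = ax,
                                        group_value = val),
            summarize_curve(sub[sub[[axes[[ax]]]] == val, ]))
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Contrast two parenting dimensions against the same outcome
#'
#' Applies the dependent-correlation test ([steiger_dependent_z()]) to
#' matched specification results for two parenting dimensions (e.g.,
#' nurturance and harshness) sharing the antisocial-behavior variable:
#' per matched specification, and at the summary level using the median
#' and the sample-size-weighted mean correlations with the median
#' per-spec sample size.
#'
#' The correlation between the two parenting difference scores (`r23`) and
#' the per-comparison sample size are not part of the per-dimension
#' results and must be supplied (scalar or per-spec vector).
#'
#' @param results_dim1,results_dim2 Results tibbles from
#'   [run_spec_curve()] for the two dimensions; rows must be matched
#'   (same antisocial-behavior specification, aligned parenting
#'   informants, same zygosity and order).
#' @param r23 Correlation(s) between the two parenting variables.
#' @param n Sample size(s); defaults to the pairwise minimum of the two
#'   dimensions' per-spec sample sizes.
#' @param alpha Flagging threshold.
#' @return A list with `per_spec` (tibble: spec id, the two correlations,
#'   `z`, `p`, `significant`) and `summary` (median- and mean-based
#'   comparisons).
#' @export
compare_parenting_dimensions <- function(results_dim1, results_dim2, r23,
                                         n = NULL, alpha = 0.05) {
  if (nrow(results_dim1) != nrow(results_dim2)) {
    stop("the two results sets must contain the same specifications",
         call. = FALSE)
  }
  match_cols <- intersect(c("asb_measure", "asb_informant",
                            "normalization", "zygosity"),
                          intersect(names(results_dim1),
                                    names(results_dim2)))
  for (cl in match_cols) {
    if (!identical(results_dim1[[cl]], results_dim2[[cl]])) {
      stop("specification lists are not matched on `", cl, "`",
           call. = FALSE)
    }
  }
  k <- nrow(results_dim1)
  r23 <- rep_len(r23, k)
  if (is.null(n)) n <- pmin(results_dim1$n, results_dim2$n)
  n <- rep_len(n, k)
  per <- vector("list", k)
  for (i in seq_len(k)) {
    st <- steiger_dependent_z(results_dim1$estimate[i],
                              results_dim2$estimate[i], r23[i], n[i])
    per[[i]] <- tibble::tibble(
      spec_id = if ("spec_id" %in% names(results_dim1))
        results_dim1$spec_id[i] else as.character(i),
      r_dim1 = results_dim1$estimate[i], r_dim2 = results_dim2$estimate[i],
      r23 = r23[i], n = n[i], z = st$z, p = st$p,
      significant = st$p < alpha)
  }
  per <- dplyr::bind_rows(per)
  s1 <- summarize_curve(results_dim1)
  s2 <- summarize_curve(results_dim2)
  n_sum <- stats::median(n)
  r23_sum <- stats::median(r23)
  med <- steiger_dependent_z(s1$median_es, s2$median_es, r23_sum, n_sum)
  mea <- steiger_dependent_z(s1$mean_es, s2$mean_es, r23_sum, n_sum)
  summary <- tibble::tibble(
    statistic = c("median", "mean"),
    r_dim1 = c(s1$median_es, s1$mean_es),
    r_dim2 = c(s2$median_es, s2$mean_es),
    r23 = r23_sum, n = n_sum,
    z = c(med$z, mea$z), p = c(med$p, mea$p),
    significant = c(med$p, mea$p) < alpha)
  list(per_spec = per, summary = summary)
}

#' Specification-curve plot
#'
#' Estimates sorted by magnitude with 95% confidence intervals, colored by
#' per-spec significance, faceted by analysis level and zygosity.
#'
#' @param results Results tibble from [run_spec_curve()].
#' @return A ggplot object.
#' @export
plot_spec_curve <- function(results) {
  r <- results[!is.na(results$estimate), ]
  r$panel <- ifelse(r$analysis_level == "phenotypic", "phenotypic",
                    paste0("twin_difference (", r$zygosity, ")"))
  r <- dplyr::mutate(dplyr::group_by(r, .data$panel),
                     rank = rank(.data$estimate, ties.method = "first"))
  ggplot2::ggplot(r, ggplot2::aes(x = .data$rank, y = .data$estimate,
                                  color = .data$p < 0.05)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0, alpha = 0.4) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#D55E00",
                                           `FALSE` = "grey30"),
                                name = "p < 0.05") +
    ggplot2::labs(x = "specification (sorted by estimate)",
                  y = "effect size") +
    ggplot2::theme_minimal()
}

#' Write the analysis report to disk
#'
#' Writes (i) the per-specification results CSV, (ii) grouped curve
#' summary tables CSV, (iii) a JSON file with the three curve decisions
#' and the etiologic classification, and (iv) a specification-curve plot
#' (PDF). Re-running on the same analysis produces byte-identical CSV and
#' JSON files.
#'
#' @param analysis A [analyze_twin_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "twin_curve_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(results = file.path(dir, "results.csv"),
             summaries = file.path(dir, "summary_tables.csv"),
             decisions = file.path(dir, "decisions.json"),
             plot = file.path(dir, "speccurve.pdf"))
  readr::write_csv(analysis$results, paths[["results"]], na = "")
  readr::write_csv(grouped_summaries(analysis$results),
                   paths[["summaries"]], na = "")
  jsonlite::write_json(
    list(decisions = lapply(analysis$decisions, function(d)
      list(significant = d$significant,
           indicators = as.list(d$indicators))),
      scenario = analysis$scenario$label,
      seed = analysis$seed),
    paths[["decisions"]], auto_unbox = TRUE, digits = NA)
  grDevices::pdf(paths[["plot"]], width = 9, height = 5)
  print(plot_spec_curve(analysis$results))
  grDevices::dev.off()
  invisible(paths)
}

#' Scenario-recovery simulation study
#'
#' Repeatedly simulates study-scale studies under each etiologic scenario
#' preset, runs the analysis pipeline, and records the recovered
#' classification. The twin-difference multiverse uses the full default
#' grid (difference correlations are cheap); the phenotypic level uses a
#' small two-specification grid (all-informant checklist composite and
#' the interview, all-informant nurturance, raw scores) because the
#' individual-level association is strongly powered at study scale and
#' each multilevel model is comparatively expensive.
#'
#' @param scenarios Scenario labels to simulate.
#' @param n_rep Replicates per scenario.
#' @param n_mz,n_dz,effect_size,sign Study conditions passed to
#'   [simulate_twin_study()].
#' @param reliability Informant reliability for the measurement battery.
#' @param config Twin-difference curve configuration.
#' @param phenotypic_config Phenotypic curve configuration.
#' @param seed Master seed; each replicate derives its own substream.
#' @return A tibble with `scenario`, `replicate`, `label`, and the three
#'   level decisions.
#' @export
scenario_recovery <- function(scenarios = c("scenario1_environmental",
                                            "scenario2_genetic",
                                            "scenario3_genetic_shared"),
                              n_rep = 100, n_mz = 426, n_dz = 604,
                              effect_size = 0.10, sign = -1,
                              reliability = 0.7,
                              config = default_curve_config(),
                              phenotypic_config = recovery_phenotypic_config(),
                              seed = 1) {
  battery <- default_measurement_models(reliability = reliability)
  rows <- list()
  for (si in seq_along(scenarios)) {
    for (rep in seq_len(n_rep)) {
      rep_seed <- substream_seed(seed, 10000L * si + rep)
      study <- simulate_twin_study(scenarios[[si]], n_mz = n_mz,
                                   n_dz = n_dz,
                                   effect_size = effect_size, sign = sign,
                                   measurement = battery, seed = rep_seed)
      an <- analyze_twin_dataset(study$dataset, config = config,
                                 phenotypic_config = phenotypic_config,
                                 seed = rep_seed)
      rows[[length(rows) + 1]] <- tibble::tibble(
        scenario = scenarios[[si]], replicate = rep,
        label = an$scenario$label,
        phenotypic_sig = an$decisions$phenotypic$significant,
        mz_sig = an$decisions$mz$significant,
        dz_sig = an$decisions$dz$significant)
    }
  }
  dplyr::bind_rows(rows)
}

#' @rdname scenario_recovery
#' @export
recovery_phenotypic_config <- function() {
  curve_config(asb_measures = c("cbcl_aggression", "interview"),
               cbcl_informants = "all",
               nurturance_informants = "all",
               normalizations = "raw")
}
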