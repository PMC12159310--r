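test_that("the default grid couples measures and informants as printed counts require", {
  ph <- enumerate_specifications(default_curve_config(), "phenotypic")
  td <- enumerate_specifications(default_curve_config(), "twin_difference")
  expect_equal(nrow(ph), 130)
  expect_equal(nrow(td), 260)
  expect_true(all(ph$zygosity == "not_applicable"))
  expect_equal(sort(unique(td$zygosity)), c("DZ", "MZ"))
  # interview pairs only with the twin informant
  expect_true(all(ph$asb_informant[ph$asb_measure == "interview"] ==
                    "twin"))
  expect_false(any(ph$asb_informant == "twin" &
                     ph$asb_measure != "interview"))
  expect_false(anyDuplicated(ph$spec_id) > 0)
})

test_that("enumeration is a pure function of the configuration", {
  cfg <- curve_config(asb_measures = c("interview", "cbcl_rulebreaking"),
                      cbcl_informants = c("mother", "adults"),
                      nurturance_informants = c("twin", "father"),
                      normalizations = "log")
  expect_identical(enumerate_specifications(cfg, "phenotypic"),
                   enumerate_specifications(cfg, "phenotypic"))
  expect_equal(nrow(enumerate_specifications(cfg, "phenotypic")),
               (2 + 1) * 2 * 1)
  one <- curve_config(asb_measures = "cbcl_aggression",
                      cbcl_informants = "mother",
                      nurturance_informants = "mother",
                      normalizations = "raw")
  expect_equal(nrow(enumerate_specifications(one, "phenotypic")), 1)
  expect_error(curve_config(asb_measures = character(0)), "nonempty")
  expect_error(curve_config(cbcl_informants = "grandparent"), "unknown")
})

test_that("specifications referencing unavailable data raise configuration errors", {
  p <- scenario_preset("scenario1_environmental", 0.10, -1)
  pairs <- simulate_biometric_pairs(p, 60, 60, seed = 1)
  at <- build_analysis_table(render_observed(pairs, perfect_battery(),
                                             seed = 1))
  spec <- enumerate_specifications(
    curve_config(asb_measures = "cbcl_aggression",
                 cbcl_informants = "teacher",
                 nurturance_informants = "mother",
                 normalizations = "raw"), "phenotypic")
  expect_error(run_specification(at, spec),
               class = "twindiffcurve_config_error")
  expect_error(run_spec_curve(at, spec),
               class = "twindiffcurve_config_error")
  td <- enumerate_specifications(one_cell_config(), "twin_difference")
  expect_error(run_specification(at, td[1, ]), "assignment")
})

test_that("specification runs recover the generating association", {
  # one-cell grid with perfect measurement on latent data with known
  # individual-level slope -0.10 and MZ-difference correlation 0
  p <- scenario_preset("scenario3_genetic_shared", 0.10, -1)
  pairs <- simulate_biometric_pairs(p, 5000, 5000, seed = 14)
  at <- build_analysis_table(render_observed(pairs, perfect_battery(),
                                             seed = 14))
  asg <- assign_twin_labels(at, seed = 14)
  ph <- run_specification(
    at, enumerate_specifications(one_cell_config(), "phenotypic"))
  expect_lt(abs(ph$estimate - (-0.10)), 0.04)
  td <- enumerate_specifications(one_cell_config(), "twin_difference")
  mz <- run_specification(at, td[td$zygosity == "MZ", ], assignment = asg)
  expect_lt(abs(mz$estimate), 0.03)
})

test_that("batched curve execution matches single-specification runs", {
  at <- small_study_table()
  asg <- assign_twin_labels(at, seed = 7)
  specs <- dplyr::bind_rows(
    enumerate_specifications(one_cell_config(), "phenotypic"),
    enumerate_specifications(one_cell_config(), "twin_difference"))
  batch <- run_spec_curve(at, specs, assignment = asg)
  for (i in seq_len(nrow(specs))) {
    single <- run_specification(at, specs[i, ], assignment = asg)
    expect_equal(batch$estimate[i], single$estimate, tolerance = 1e-12)
    expect_equal(batch$p[i], single$p, tolerance = 1e-12)
    expect_equal(batch$n[i], single$n)
  }
})

test_that("curve summaries aggregate with weighted means and unweighted medians", {
  single <- tibble::tibble(estimate = 0.2, ci_low = 0.1, ci_high = 0.3,
                           p = 0.01, n = 50L)
  s <- summarize_curve(single)
  expect_equal(s$median_es, 0.2)
  expect_equal(s$mean_es, 0.2)
  expect_equal(s$pct_p_lt_05, 100)
  expect_equal(s$k, 1)

  two <- tibble::tibble(estimate = c(0.1, 0.3), ci_low = c(0, 0.2),
                        ci_high = c(0.2, 0.4), p = c(0.01, 0.20),
                        n = c(100L, 100L))
  s2 <- summarize_curve(two)
  expect_equal(s2$mean_es, 0.2)
  expect_equal(s2$pct_p_lt_05, 50)
  unequal <- tibble::tibble(estimate = c(0.0, 0.4), ci_low = c(-0.1, 0.3),
                            ci_high = c(0.1, 0.5), p = c(0.5, 0.01),
                            n = c(100L, 300L))
  expect_equal(summarize_curve(unequal)$mean_es, 0.3)
  # medians stay unweighted under unequal n
  expect_equal(summarize_curve(unequal)$median_es, 0.2)
  # strict inequality at the 0.05 boundary
  tie <- tibble::tibble(estimate = 0.1, ci_low = 0, ci_high = 0.2,
                        p = 0.05, n = 10L)
  expect_equal(summarize_curve(tie)$pct_p_lt_05, 0)
  expect_error(summarize_curve(tie[0, ]), "empty")
})

test_that("the signed average z reflects the effect direction", {
  neg <- tibble::tibble(estimate = c(-0.2, -0.1), ci_low = -0.3,
                        ci_high = -0.05, p = c(0.001, 0.02),
                        n = c(100L, 100L))
  expect_lt(summarize_curve(neg)$avg_z, -1.96)
})

test_that("significance requires all four indicators (full truth table)", {
  mk <- function(mean_ci, median_ci, med_p, avg_z) {
    tibble::tibble(
      mean_ci_low = if (mean_ci) -0.14 else -0.10,
      mean_ci_high = if (mean_ci) -0.05 else 0.10,
      median_ci_low = if (median_ci) -0.15 else -0.10,
      median_ci_high = if (median_ci) -0.06 else 0.10,
      median_p = if (med_p) 0.001 else 0.10,
      avg_z = if (avg_z) -4.39 else -0.63)
  }
  grid <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                      c = c(TRUE, FALSE), d = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid))) {
    dec <- decide_significance(mk(grid$a[i], grid$b[i], grid$c[i],
                                  grid$d[i]))
    expect_identical(dec$significant,
                     all(unlist(grid[i, ])),
                     info = paste(unlist(grid[i, ]), collapse = ","))
  }
})

test_that("the decision rule is monotone in evidence strength", {
  set.seed(26)
  n_sig <- 0
  for (i in 1:50) {
    sgn <- sample(c(-1, 1), 1)
    est <- sgn * runif(1, 0.05, 0.3)
    half <- runif(1, 0.01, 0.3)
    s <- tibble::tibble(mean_ci_low = est - half, mean_ci_high = est + half,
                        median_ci_low = est - half * 1.1,
                        median_ci_high = est + half * 1.1,
                        median_p = runif(1, 0, 0.2),
                        avg_z = sgn * runif(1, 0, 5))
    shrink <- tibble::tibble(
      mean_ci_low = est - half / 4, mean_ci_high = est + half / 4,
      median_ci_low = est - half / 4, median_ci_high = est + half / 4,
      median_p = s$median_p / 10,
      avg_z = s$avg_z * 3)
    if (decide_significance(s)$significant) {
      n_sig <- n_sig + 1
      expect_true(decide_significance(shrink)$significant)
    }
  }
  expect_gt(n_sig, 0)
})

test_that("the scenario classifier maps decision patterns to etiologies", {
  expect_equal(classify_scenario(TRUE, TRUE, TRUE)$label, "environmental")
  expect_equal(classify_scenario(TRUE, FALSE, TRUE)$label, "genetic")
  expect_equal(classify_scenario(TRUE, FALSE, FALSE)$label,
               "genetic_plus_shared_environmental")
  expect_equal(classify_scenario(FALSE, TRUE, TRUE)$label,
               "no_association")
  expect_equal(classify_scenario(TRUE, TRUE, FALSE)$label, "inconsistent")
})

test_that("grouped summaries equal summarize_curve on every subset", {
  at <- small_study_table()
  cfg <- curve_config(asb_measures = c("cbcl_aggression", "interview"),
                      cbcl_informants = c("mother", "all"),
                      nurturance_informants = c("mother", "all"),
                      normalizations = c("raw", "log"))
  specs <- dplyr::bind_rows(
    enumerate_specifications(cfg, "phenotypic"),
    enumerate_specifications(cfg, "twin_difference"))
  res <- run_spec_curve(at, specs, seed = 7)
  g <- grouped_summaries(res)
  for (i in seq_len(nrow(g))) {
    sub <- res[res$analysis_level == g$analysis_level[i] &
                 res$zygosity == g$zygosity[i], ]
    if (g$group_type[i] != "overall") {
      sub <- sub[sub[[g$group_type[i]]] == g$group_value[i], ]
    }
    expect_equal(g$median_es[i], summarize_curve(sub)$median_es,
                 tolerance = 1e-12)
    expect_equal(g$avg_z[i], summarize_curve(sub)$avg_z,
                 tolerance = 1e-12)
  }
})

test_that("reports are complete and byte-identical across re-runs", {
  study <- simulate_twin_study("scenario2_genetic", n_mz = 60, n_dz = 60,
                               seed = 15)
  cfg <- curve_config(asb_measures = "cbcl_aggression",
                      cbcl_informants = c("mother", "all"),
                      nurturance_informants = c("mother", "all"),
                      normalizations = "raw")
  an <- analyze_twin_dataset(study$dataset, config = cfg, seed = 15)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_report(an, d1)
  p2 <- write_report(analyze_twin_dataset(study$dataset, config = cfg,
                                          seed = 15), d2)
  res <- readr::read_csv(p1[["results"]], show_col_types = FALSE)
  expect_equal(nrow(res), 4 + 8)  # 4 phenotypic + 4 specs x 2 zygosities
  expect_identical(readLines(p1[["results"]]), readLines(p2[["results"]]))
  expect_identical(readLines(p1[["decisions"]]),
                   readLines(p2[["decisions"]]))
  dec <- jsonlite::read_json(p1[["decisions"]])
  expect_true(dec$scenario %in% c("environmental", "genetic",
                                  "genetic_plus_shared_environmental",
                                  "no_association", "inconsistent"))
  g <- readr::read_csv(p1[["summaries"]], show_col_types = FALSE)
  overall <- g[g$group_type == "overall" &
                 g$analysis_level == "phenotypic", ]
  expect_equal(overall$median_es,
               summarize_curve(res[res$analysis_level == "phenotypic", ])$
                 median_es, tolerance = 1e-12)
})

test_that("curve configurations load from JSON with validation", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"asb_measures": ["interview"], "alpha": 0.01}', path)
  cfg <- read_curve_config(path)
  expect_equal(cfg$config$asb_measures, "interview")
  expect_equal(cfg$alpha, 0.01)
  expect_equal(cfg$z_crit, 1.96)
  writeLines('{"asb_informants": ["mother"]}', path)
  expect_error(read_curve_config(path), "unknown configuration field")
  writeLines('{"normalizations": ["sqrt"]}', path)
  expect_error(read_curve_config(path), "unknown value")
})
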