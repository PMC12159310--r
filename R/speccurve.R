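#' Configuration of the specification grid
#'
#' Defines the axes of the analytic multiverse. The antisocial-behavior
#' measure and informant axes are coupled: checklist measures
#' (`cbcl_aggression`, `cbcl_rulebreaking`) cross with the checklist
#' informant variants, while the `interview` measure has the twin as its
#' only informant. With all defaults the grid therefore contains
#' `(2*6 + 1) * 5 * 2 = 130` phenotypic specifications and twice that
#' (separately by zygosity) at the twin-difference level.
#'
#' @param asb_measures Antisocial-behavior measures, a subset of
#'   `c("cbcl_aggression", "cbcl_rulebreaking", "interview")`.
#' @param cbcl_informants Informant variants for the checklist measures, a
#'   subset of `c("mother", "father", "teacher", "family", "adults",
#'   "all")`.
#' @param nurturance_informants Subset of `c("mother", "father", "twin",
#'   "adults", "all")`.
#' @param normalizations Subset of `c("raw", "log")`.
#' @return A list of class `curve_config`.
#' @export
curve_config <- function(asb_measures = c("cbcl_aggression",
                                          "cbcl_rulebreaking", "interview"),
                         cbcl_informants = c("mother", "father", "teacher",
                                             "family", "adults", "all"),
                         nurturance_informants = c("mother", "father",
                                                   "twin", "adults", "all"),
                         normalizations = c("raw", "log")) {
  check_axis <- function(x, allowed, name) {
    if (length(x) == 0) {
      stop("configuration axis `", name, "` must be nonempty",
           call. = FALSE)
    }
    bad <- setdiff(x, allowed)
    if (length(bad) > 0) {
      stop("unknown value(s) in `", name, "`: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    x
  }
  cfg <- list(
    asb_measures = check_axis(asb_measures,
                              c("cbcl_aggression", "cbcl_rulebreaking",
                                "interview"), "asb_measures"),
    cbcl_informants = check_axis(cbcl_informants,
                                 c("mother", "father", "teacher", "family",
                                   "adults", "all"), "cbcl_informants"),
    nurturance_informants = check_axis(nurturance_informants,
                                       c("mother", "father", "twin",
                                         "adults", "all"),
                                       "nurturance_informants"),
    normalizations = check_axis(normalizations, c("raw", "log"),
                                "normalizations"))
  structure(cfg, class = "curve_config")
}

#' @rdname curve_config
#' @export
default_curve_config <- function() curve_config()

#' Read a curve configuration from JSON
#'
#' The JSON object may contain the four grid axes (`asb_measures`,
#' `cbcl_informants`, `nurturance_informants`, `normalizations`; missing
#' axes take the full defaults) and the decision thresholds `alpha` and
#' `z_crit`. Unknown axis values are rejected with an explicit error.
#'
#' @param path Path to a JSON file.
#' @return A list with elements `config` (a [curve_config()]), `alpha`,
#'   and `z_crit`.
#' @export
read_curve_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("asb_measures", "cbcl_informants", "nurturance_informants",
             "normalizations", "alpha", "z_crit")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration field(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults <- unclass(default_curve_config())
  axes <- defaults
  for (ax in names(defaults)) {
    if (!is.null(raw[[ax]])) axes[[ax]] <- as.character(raw[[ax]])
  }
  list(config = do.call(curve_config, axes),
       alpha = if (is.null(raw$alpha)) 0.05 else as.numeric(raw$alpha),
       z_crit = if (is.null(raw$z_crit)) 1.96 else as.numeric(raw$z_crit))
}

#' Enumerate the analytic multiverse
#'
#' Expands a [curve_config()] into the ordered list of specifications for
#' one analysis level. The order is deterministic and lexicographic in
#' (measure, ASB informant, nurturance informant, normalization,
#' zygosity), so repeated calls give identical lists.
#'
#' @param config A [curve_config()].
#' @param analysis_level `"phenotypic"` (individual-level multilevel
#'   models) or `"twin_difference"` (family-level difference correlations,
#'   enumerated separately for MZ and DZ pairs).
#' @return A tibble with columns `spec_id`, `analysis_level`,
#'   `asb_measure`, `asb_informant`, `nurturance_informant`,
#'   `normalization`, `zygosity` (`"not_applicable"` at the phenotypic
#'   level).
#' @export
enumerate_specifications <- function(config = default_curve_config(),
                                     analysis_level = c("phenotypic",
                                                        "twin_difference")) {
  stopifnot(inherits(config, "curve_config"))
  analysis_level <- match.arg(analysis_level)
  rows <- list()
  zygs <- if (analysis_level == "phenotypic") "not_applicable"
          else c("MZ", "DZ")
  for (measure in config$asb_measures) {
    informants <- if (measure == "interview") "twin" else
      config$cbcl_informants
    for (inf in informants) {
      for (nurt in config$nurturance_informants) {
        for (nrm in config$normalizations) {
          for (zyg in zygs) {
            rows[[length(rows) + 1]] <- tibble::tibble(
              analysis_level = analysis_level, asb_measure = measure,
              asb_informant = inf, nurturance_informant = nurt,
              normalization = nrm, zygosity = zyg)
          }
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$spec_id <- paste(out$analysis_level, out$zygosity, out$asb_measure,
                       out$asb_informant, out$nurturance_informant,
                       out$normalization, sep = "|")
  out[c("spec_id", "analysis_level", "asb_measure", "asb_informant",
        "nurturance_informant", "normalization", "zygosity")]
}

.config_error <- function(msg) {
  stop(structure(class = c("twindiffcurve_config_error", "error",
                           "condition"),
                 list(message = msg, call = NULL)))
}

.spec_columns <- function(analysis_table, spec) {
  xcol <- nurt_column(spec$nurturance_informant)
  ycol <- asb_column(spec$asb_measure, spec$asb_informant,
                     spec$normalization)
  for (cl in c(xcol, ycol)) {
    if (!cl %in% names(analysis_table) ||
        all(is.na(analysis_table[[cl]]))) {
      .config_error(paste0("specification ", spec$spec_id,
                           " references an unavailable analysis column: ",
                           cl))
    }
  }
  list(x = xcol, y = ycol)
}

# Shared estimator for a difference correlation given complete-case
# difference vectors; used by both the single-spec and the batched path.
# Returns a plain list for speed (the batched path runs hundreds of these).
.diff_cor_stat <- function(dx, dy) {
  n <- length(dx)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    return(list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p = NA_real_, n = n, degenerate = TRUE))
  }
  r <- max(-1, min(1, sum(dx * dy) / sqrt(sxx * syy)))
  zr <- atanh(r)
  se <- 1 / sqrt(n - 3)
  list(estimate = r, ci_low = tanh(zr - 1.96 * se),
       ci_high = tanh(zr + 1.96 * se),
       p = 2 * stats::pnorm(-abs(zr) / se), n = n, degenerate = FALSE)
}

#' Run a single specification
#'
#' Dispatches one cell of the multiverse: phenotypic specifications fit
#' [mlm_phenotypic()] (antisocial behavior regressed on nurturance with a
#' family random intercept); twin-difference specifications compute
#' [compute_difference_scores()] followed by [diff_correlation()] for the
#' specification's zygosity. Normalization, composites, and
#' standardization are applied beforehand by [build_analysis_table()].
#'
#' @param analysis_table Output of [build_analysis_table()].
#' @param spec A one-row specification tibble (see
#'   [enumerate_specifications()]).
#' @param assignment A/B labels from [assign_twin_labels()]; required for
#'   twin-difference specifications.
#' @return A one-row tibble: the specification columns plus the effect
#'   estimate.
#' @export
run_specification <- function(analysis_table, spec, assignment = NULL) {
  spec <- tibble::as_tibble(spec)
  stopifnot(nrow(spec) == 1)
  cols <- .spec_columns(analysis_table, spec)
  if (spec$analysis_level == "phenotypic") {
    est <- mlm_phenotypic(analysis_table[[cols$x]],
                          analysis_table[[cols$y]],
                          analysis_table$family_id)
  } else {
    if (is.null(assignment)) {
      stop("twin-difference specifications require an A/B `assignment`",
           call. = FALSE)
    }
    diffs <- compute_difference_scores(analysis_table, cols$x, cols$y,
                                       assignment)
    est <- diff_correlation(diffs, spec$zygosity)
  }
  dplyr::bind_cols(spec, est)
}

#' Run a set of specifications
#'
#' Executes every row of `specs` against the analysis table. Family
#' differences of all analysis columns are computed once per assignment,
#' so large twin-difference grids are cheap. Specifications that fail for
#' statistical reasons (too few complete families, non-convergence) yield
#' a flagged `NA` row with the failure message in `note`; configuration
#' errors (references to unavailable columns) are raised immediately.
#'
#' @inheritParams run_specification
#' @param specs Specification tibble from [enumerate_specifications()]
#'   (levels may be mixed).
#' @param seed Used to create the A/B assignment when `assignment` is not
#'   supplied and twin-difference specifications are present.
#' @return A results tibble, one row per specification.
#' @export
run_spec_curve <- function(analysis_table, specs, assignment = NULL,
                           seed = 1) {
  specs <- tibble::as_tibble(specs)
  need_diff <- any(specs$analysis_level == "twin_difference")
  if (need_diff && is.null(assignment)) {
    assignment <- assign_twin_labels(analysis_table, seed)
  }
  diff_env <- NULL
  if (need_diff) {
    cols <- setdiff(names(analysis_table),
                    c("family_id", "zygosity", "twin_index"))
    sgn <- ifelse(analysis_table$twin_index ==
                    assignment$twin_a[match(analysis_table$family_id,
                                            assignment$family_id)],
                  1, -1)
    D <- rowsum(as.matrix(analysis_table[cols]) * sgn,
                analysis_table$family_id)
    fam_ids <- sort(unique(analysis_table$family_id))
    zyg <- analysis_table$zygosity[match(fam_ids,
                                         analysis_table$family_id)]
    diff_env <- list(D = D, zyg = zyg)
  }
  k <- nrow(specs)
  est <- tibble::tibble(
    estimate = rep(NA_real_, k), ci_low = NA_real_, ci_high = NA_real_,
    p = NA_real_, n = 0L,
    kind = ifelse(specs$analysis_level == "phenotypic", "mlm_beta",
                  "diff_correlation"),
    degenerate = FALSE, note = NA_character_)
  for (i in seq_len(k)) {
    spec <- list(spec_id = specs$spec_id[i],
                 analysis_level = specs$analysis_level[i],
                 asb_measure = specs$asb_measure[i],
                 asb_informant = specs$asb_informant[i],
                 nurturance_informant = specs$nurturance_informant[i],
                 normalization = specs$normalization[i],
                 zygosity = specs$zygosity[i])
    row <- tryCatch({
      cols_i <- .spec_columns(analysis_table, spec)
      if (spec$analysis_level == "phenotypic") {
        mlm_phenotypic(analysis_table[[cols_i$x]],
                       analysis_table[[cols_i$y]],
                       analysis_table$family_id)
      } else {
        sel <- diff_env$zyg == spec$zygosity
        dx <- diff_env$D[sel, cols_i$x]
        dy <- diff_env$D[sel, cols_i$y]
        ok <- !is.na(dx) & !is.na(dy)
        if (sum(ok) < 4) {
          stop("fewer than 4 complete ", spec$zygosity, " families",
               call. = FALSE)
        }
        .diff_cor_stat(dx[ok], dy[ok])
      }
    },
    error = function(e) {
      if (inherits(e, "twindiffcurve_config_error")) stop(e)
      list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           p = NA_real_, n = 0L, degenerate = TRUE,
           note = conditionMessage(e))
    })
    est$estimate[i] <- row$estimate
    est$ci_low[i] <- row$ci_low
    est$ci_high[i] <- row$ci_high
    est$p[i] <- row$p
    est$n[i] <- row$n
    est$degenerate[i] <- row$degenerate
    if ("note" %in% names(row)) est$note[i] <- row$note
  }
  dplyr::bind_cols(specs, est)
}

#' Aggregate a set of specification results
#'
#' Summary statistics across the curve: unweighted medians of the
#' estimates, confidence bounds, and p-values; sample-size-weighted means
#' of the estimates, confidence bounds, and signed z-scores (each p-value
#' converted with [p_to_signed_z()] using the sign of its estimate); and
#' the (unweighted) percentage of specifications with p < 0.05 (strict
#' inequality). Medians are deliberately unweighted: the weighting the
#' design calls for applies to averages. Flagged/degenerate results are
#' dropped with their count recorded in `k_dropped`.
#'
#' @param results Results tibble from [run_spec_curve()] (or any tibble
#'   with `estimate`, `ci_low`, `ci_high`, `p`, `n`).
#' @return A one-row tibble: `median_es`, `mean_es`, `median_ci_low`,
#'   `median_ci_high`, `mean_ci_low`, `mean_ci_high`, `median_p`,
#'   `pct_p_lt_05`, `avg_z`, `k`, `k_dropped`, `n_median`, `n_total`.
#' @export
summarize_curve <- function(results) {
  if (nrow(results) == 0) {
    stop("cannot summarize an empty set of specification results",
         call. = FALSE)
  }
  keep <- !is.na(results$estimate)
  r <- results[keep, ]
  if (nrow(r) == 0) {
    stop("all specification results are missing or degenerate",
         call. = FALSE)
  }
  w <- r$n
  z <- p_to_signed_z(r$p, sign(r$estimate))
  tibble::tibble(
    median_es = stats::median(r$estimate),
    mean_es = stats::weighted.mean(r$estimate, w),
    median_ci_low = stats::median(r$ci_low),
    median_ci_high = stats::median(r$ci_high),
    mean_ci_low = stats::weighted.mean(r$ci_low, w),
    mean_ci_high = stats::weighted.mean(r$ci_high, w),
    median_p = stats::median(r$p),
    pct_p_lt_05 = 100 * mean(r$p < 0.05),
    avg_z = stats::weighted.mean(z, w),
    k = nrow(r),
    k_dropped = sum(!keep),
    n_median = stats::median(r$n),
    n_total = sum(r$n))
}

#' Four-indicator significance decision for a curve summary
#'
#' An aggregate effect is deemed significantly different from zero only
#' when all four indicators agree: the sample-size-weighted mean
#' confidence interval excludes 0, the median confidence interval excludes
#' 0, the median p-value is below 0.05, and the magnitude of the average
#' signed z-score exceeds 1.96. Disagreement among the indicators is
#' conservatively read as nonsignificant.
#'
#' @param summary A one-row tibble from [summarize_curve()].
#' @param alpha P-value threshold (default 0.05).
#' @param z_crit Critical z magnitude (default 1.96).
#' @return A list of class `curve_decision` with `significant` and the
#'   named logical vector `indicators`.
#' @export
decide_significance <- function(summary, alpha = 0.05, z_crit = 1.96) {
  excludes0 <- function(lo, hi) (lo > 0 && hi > 0) || (lo < 0 && hi < 0)
  ind <- c(
    mean_ci_excludes_0 = excludes0(summary$mean_ci_low,
                                   summary$mean_ci_high),
    median_ci_excludes_0 = excludes0(summary$median_ci_low,
                                     summary$median_ci_high),
    median_p_lt_05 = summary$median_p < alpha,
    avg_abs_z_gt_196 = abs(summary$avg_z) > z_crit)
  structure(list(significant = all(ind), indicators = ind),
            class = "curve_decision")
}

#' @export
print.curve_decision <- function(x, ...) {
  cat("Curve-level decision:",
      if (x$significant) "SIGNIFICANT" else "nonsignificant", "\n")
  for (nm in names(x$indicators)) {
    cat(sprintf("  %-22s %s\n", nm, x$indicators[[nm]]))
  }
  invisible(x)
}

#' Classify the etiologic scenario from three decisions
#'
#' Maps the significance pattern of the phenotypic, MZ-difference, and
#' DZ-difference aggregate effects to an etiologic label. A significant
#' association at every level indicates an environmental pathway (it
#' survives full genetic and shared-environmental control in MZ pairs);
#' significance at the individual and DZ levels only indicates purely
#' genetic mediation (evocative gene-environment correlation); an
#' individual-level association absent within both MZ and DZ pairs
#' indicates mediation by genetic influences plus shared-environmental
#' confounds; no individual-level association means there is nothing to
#' decompose; significance in MZ but not DZ pairs does not correspond to
#' any coherent etiologic pattern and is labeled inconsistent.
#'
#' @param pheno,mz,dz [decide_significance()] decisions (or logicals).
#' @return A list of class `scenario_label` with `label` (one of
#'   `"environmental"`, `"genetic"`,
#'   `"genetic_plus_shared_environmental"`, `"no_association"`,
#'   `"inconsistent"`) and the three supporting decisions.
#' @export
classify_scenario <- function(pheno, mz, dz) {
  sig <- function(d) {
    if (inherits(d, "curve_decision")) d$significant else isTRUE(d)
  }
  p <- sig(pheno); m <- sig(mz); z <- sig(dz)
  label <- if (!p) "no_association"
    else if (m && z) "environmental"
    else if (!m && z) "genetic"
    else if (!m && !z) "genetic_plus_shared_environmental"
    else "inconsistent"
  structure(list(label = label,
                 decisions = list(phenotypic = p, mz = m, dz = z)),
            class = "scenario_label")
}

#' @export
print.scenario_label <- function(x, ...) {
  cat(sprintf("Etiologic classification: %s\n", x$label))
  cat(sprintf("  (phenotypic %s, MZ %s, DZ %s)\n",
              ifelse(x$decisions$phenotypic, "sig", "ns"),
              ifelse(x$decisions$mz, "sig", "ns"),
              ifelse(x$decisions$dz, "sig", "ns")))
  invisible(x)
}
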