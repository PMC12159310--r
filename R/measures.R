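#' Sample skewness (adjusted Fisher--Pearson estimator)
#'
#' Standardized third central moment with the small-sample adjustment
#' `sqrt(n*(n-1))/(n-2)` used by mainstream statistics software.
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @return Scalar skewness.
#' @export
skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("skewness requires at least 3 nonmissing values",
                  call. = FALSE)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) stop("skewness undefined for zero-variance input",
                    call. = FALSE)
  g1 <- mean((x - mean(x))^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Log-normalize right-skewed nonnegative scores
#'
#' `log(1 + x)`: order-preserving, maps 0 to 0, and strictly reduces the
#' skewness of right-skewed score distributions.
#'
#' @param x Nonnegative numeric vector (`NA` allowed and preserved).
#' @return Transformed vector.
#' @export
log_normalize <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    stop("log_normalize requires nonnegative input", call. = FALSE)
  }
  log1p(x)
}

#' Standardize a column to z-scores
#'
#' Centers and scales over nonmissing entries using the sample standard
#' deviation (denominator `n - 1`); missing values are preserved.
#'
#' @param x Numeric vector.
#' @param label Optional column name used in error messages.
#' @return Standardized vector.
#' @export
standardize <- function(x, label = deparse(substitute(x))) {
  ok <- !is.na(x)
  if (sum(ok) < 2) {
    stop("cannot standardize `", label, "`: fewer than 2 nonmissing values",
         call. = FALSE)
  }
  s <- stats::sd(x[ok])
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize `", label, "`: zero variance", call. = FALSE)
  }
  (x - mean(x[ok])) / s
}

#' Composite rules for multi-informant scores
#'
#' `composite_rule()` builds a rule; `composite_rules()` returns the study
#' defaults: for antisocial behavior, *adults* = mother, father, teacher;
#' *family* = mother, father, child; *all* = mother, father, teacher,
#' child; for nurturance, *adults* = mother, father and *all* = mother,
#' father, child.
#'
#' @param composite_id One of `"adults"`, `"family"`, `"all"`.
#' @param members Ordered character vector of member informants.
#' @param trait `"asb"` or `"nurturance"`.
#' @return A list of class `composite_rule`, or (for
#'   `composite_rules()`) a named list of them per trait.
#' @export
composite_rule <- function(composite_id, members, trait) {
  if (length(members) == 0) {
    stop("composite members must be nonempty", call. = FALSE)
  }
  structure(list(composite_id = composite_id, members = members,
                 trait = trait), class = "composite_rule")
}

#' @rdname composite_rule
#' @export
composite_rules <- function() {
  list(
    asb = list(
      adults = composite_rule("adults", c("mother", "father", "teacher"),
                              "asb"),
      family = composite_rule("family", c("mother", "father", "child"),
                              "asb"),
      all = composite_rule("all", c("mother", "father", "teacher", "child"),
                           "asb")),
    nurturance = list(
      adults = composite_rule("adults", c("mother", "father"), "nurturance"),
      all = composite_rule("all", c("mother", "father", "child"),
                           "nurturance")))
}

#' Average informant reports into a composite score
#'
#' Mean of the available member scores per row; when only one member is
#' available that report is used; when none is available the composite is
#' missing. Permutation-invariant in its members.
#'
#' @param scores A data frame / tibble with one column per informant.
#' @param rule A [composite_rule()] or a character vector of member
#'   column names.
#' @return Numeric vector of composite scores.
#' @examples
#' build_composite(data.frame(mother = 2, father = 4, teacher = 6),
#'                 c("mother", "father", "teacher"))
#' @export
build_composite <- function(scores, rule) {
  members <- if (inherits(rule, "composite_rule")) rule$members else rule
  missing_cols <- setdiff(members, names(scores))
  if (length(missing_cols) > 0) {
    stop("composite members absent from `scores`: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(scores[members])
  out <- rowMeans(m, na.rm = TRUE)
  out[rowSums(!is.na(m)) == 0] <- NA_real_
  out
}

#' Combine a twin's reports of maternal and paternal nurturance
#'
#' The two reports index one construct (the twin's overall perception of
#' parental involvement) and are averaged; if only one is present it is
#' used; both missing gives missing.
#'
#' @param of_mother,of_father Numeric vectors of the twin's reports.
#' @return Numeric vector.
#' @export
combine_twin_parent_reports <- function(of_mother, of_father) {
  build_composite(data.frame(of_mother = of_mother, of_father = of_father),
                  c("of_mother", "of_father"))
}

#' Co-twin discordance relative to phenotypic variability
#'
#' Expresses a mean absolute co-twin difference as a percentage of the
#' phenotypic standard deviation of the same measure -- a descriptive index
#' of how much within-pair variation in exposure the twin-differences
#' design has to work with.
#'
#' @param mean_abs_diff Mean absolute co-twin difference.
#' @param phenotypic_sd Standard deviation of the measure across all twins.
#' @return Percentage (0--100+ scale).
#' @examples
#' discordance_ratio(2.73, 3.56)  # ~77%
#' @export
discordance_ratio <- function(mean_abs_diff, phenotypic_sd) {
  if (phenotypic_sd <= 0) stop("`phenotypic_sd` must be positive",
                               call. = FALSE)
  100 * mean_abs_diff / phenotypic_sd
}

# Standardize-if-possible helper used when building analysis columns from
# observed data: columns that are entirely missing stay missing rather
# than erroring (a spec referencing them fails later with a clear message).
.std_or_na <- function(x, label) {
  ok <- !is.na(x)
  if (sum(ok) < 2 || stats::sd(x[ok]) == 0) return(rep(NA_real_, length(x)))
  standardize(x, label = label)
}

#' Build the analysis table of derived variables
#'
#' Pivots a long twin dataset to one row per twin and derives every
#' analysis variable of the specification grid: per-informant antisocial
#' behavior scores under raw and log(1 + x) normalization, informant
#' composites (*adults*, *family*, *all*; the child member of the family /
#' all composites is the interview score), per-informant nurturance, the
#' combined twin-perceived nurturance score, and nurturance composites.
#' Composites average the members' standardized scores (informant reports
#' come from different instruments with different scales) and are then
#' restandardized; every analysis column is standardized over the pooled
#' sample (both zygosities) before any difference scoring.
#'
#' Column naming: `asb.<measure>.<informant>.<normalization>` and
#' `nurt.<informant>`; see [asb_column()] / [nurt_column()].
#'
#' @param dataset Long twin dataset (see [render_observed()]).
#' @return A tibble with `family_id`, `zygosity`, `twin_index` and one
#'   column per analysis variable.
#' @export
build_analysis_table <- function(dataset) {
  wide <- tidyr::pivot_wider(
    dataset,
    id_cols = c("family_id", "zygosity", "twin_index"),
    names_from = c("measure_id", "informant_id"),
    values_from = "value", names_sep = ".")
  out <- wide[c("family_id", "zygosity", "twin_index")]

  raw_col <- function(nm) {
    if (nm %in% names(wide)) wide[[nm]] else rep(NA_real_, nrow(wide))
  }
  norm_fun <- list(raw = identity, log = log_normalize)

  for (measure in c("cbcl_aggression", "cbcl_rulebreaking")) {
    for (nrm in c("raw", "log")) {
      singles <- list()
      for (inf in c("mother", "father", "teacher")) {
        v <- norm_fun[[nrm]](raw_col(paste(measure, inf, sep = ".")))
        singles[[inf]] <- .std_or_na(v, paste(measure, inf, nrm))
        out[[asb_column(measure, inf, nrm)]] <- singles[[inf]]
      }
      child <- .std_or_na(norm_fun[[nrm]](raw_col("interview.twin")),
                          paste("interview", nrm))
      members <- c(singles, list(child = child))
      for (cid in c("adults", "family", "all")) {
        rule <- composite_rules()$asb[[cid]]
        comp <- build_composite(tibble::as_tibble(members), rule)
        out[[asb_column(measure, cid, nrm)]] <-
          .std_or_na(comp, paste(measure, cid, nrm))
      }
    }
  }
  for (nrm in c("raw", "log")) {
    v <- norm_fun[[nrm]](raw_col("interview.twin"))
    out[[asb_column("interview", "twin", nrm)]] <-
      .std_or_na(v, paste("interview", nrm))
  }

  twin_combined <- combine_twin_parent_reports(
    raw_col("peq_nurturance.twin_about_mother"),
    raw_col("peq_nurturance.twin_about_father"))
  nurt <- list(
    mother = .std_or_na(raw_col("peq_nurturance.mother"), "nurt mother"),
    father = .std_or_na(raw_col("peq_nurturance.father"), "nurt father"),
    child = .std_or_na(twin_combined, "nurt twin"))
  out[[nurt_column("mother")]] <- nurt$mother
  out[[nurt_column("father")]] <- nurt$father
  out[[nurt_column("twin")]] <- nurt$child
  for (cid in c("adults", "all")) {
    rule <- composite_rules()$nurturance[[cid]]
    comp <- build_composite(tibble::as_tibble(nurt), rule)
    out[[nurt_column(cid)]] <- .std_or_na(comp, paste("nurt", cid))
  }
  out
}

#' Analysis-column naming helpers
#'
#' Map a specification's axes to the column names produced by
#' [build_analysis_table()].
#'
#' @param measure,informant,normalization Specification axes.
#' @return A column name string.
#' @export
asb_column <- function(measure, informant, normalization) {
  paste("asb", measure, informant, normalization, sep = ".")
}

#' @rdname asb_column
#' @export
nurt_column <- function(informant) {
  paste("nurt", informant, sep = ".")
}
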