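# Consistent schema for every estimate the pipeline produces.
effect_estimate <- function(estimate, ci_low, ci_high, p, n, kind,
                            degenerate = FALSE) {
  tibble::tibble(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 p = p, n = as.integer(n), kind = kind,
                 degenerate = degenerate)
}

#' Randomly assign co-twins to labels A and B
#'
#' Each family is independently assigned which of its two twins is "Twin
#' A"; difference scores are then A minus B. The labels are arbitrary, so
#' analyses downstream must not depend on the assignment (see
#' [diff_correlation()] for the invariance this implies).
#'
#' @param data A tibble with `family_id` and `twin_index` columns (one row
#'   per twin, exactly two twins per family).
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return A tibble with `family_id` and `twin_a` (the `twin_index`
#'   assigned to label A), carrying the seed in attribute `seed`.
#' @export
assign_twin_labels <- function(data, seed) {
  fam <- unique(data[c("family_id", "twin_index")])
  counts <- table(fam$family_id)
  if (any(counts != 2)) {
    bad <- names(counts)[counts != 2]
    stop("each family must have exactly two twins; offending family_id(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  ids <- sort(unique(fam$family_id))
  set.seed(substream_seed(seed, "twin_order"))
  out <- tibble::tibble(family_id = ids,
                        twin_a = sample(c(1L, 2L), length(ids),
                                        replace = TRUE))
  attr(out, "seed") <- seed
  out
}

#' Compute co-twin difference scores for one variable pair
#'
#' For each family with both twins observed on both variables, returns
#' `dx = x_A - x_B` and `dy = y_A - y_B` under the supplied A/B
#' assignment. Families with any of the four values missing are excluded;
#' the number excluded is attached as attribute `n_excluded`.
#'
#' @param data Analysis table (one row per twin) containing the two
#'   variable columns.
#' @param x_column,y_column Column names (exposure and outcome).
#' @param assignment Output of [assign_twin_labels()].
#' @return A tibble with `family_id`, `zygosity`, `dx`, `dy`.
#' @export
compute_difference_scores <- function(data, x_column, y_column, assignment) {
  for (cl in c(x_column, y_column)) {
    if (!cl %in% names(data)) {
      stop("column not found in data: ", cl, call. = FALSE)
    }
  }
  d <- data[c("family_id", "zygosity", "twin_index", x_column, y_column)]
  names(d)[4:5] <- c("x", "y")
  d <- dplyr::left_join(d, assignment, by = "family_id")
  d$sign <- ifelse(d$twin_index == d$twin_a, 1, -1)
  diffs <- dplyr::summarise(
    dplyr::group_by(d, .data$family_id, .data$zygosity),
    dx = sum(.data$sign * .data$x), dy = sum(.data$sign * .data$y),
    .groups = "drop")
  n_all <- nrow(diffs)
  diffs <- diffs[!is.na(diffs$dx) & !is.na(diffs$dy), ]
  attr(diffs, "n_excluded") <- n_all - nrow(diffs)
  diffs
}

#' Correlation between co-twin difference scores
#'
#' Pearson-type correlation of `dx` and `dy` over families of one
#' zygosity. Because the A/B labeling is arbitrary, the population mean of
#' each difference score is exactly zero; the correlation is therefore
#' computed about the origin (`sum(dx*dy) / sqrt(sum(dx^2) * sum(dy^2))`),
#' which makes the estimate invariant, to machine precision, to the A/B
#' assignment seed (each family's `(dx, dy)` flips sign jointly). The 95%
#' confidence interval uses the Fisher transform
#' (`atanh(r) +/- 1.96 / sqrt(n - 3)`, back-transformed) and the two-sided
#' p-value comes from the Fisher z statistic `atanh(r) * sqrt(n - 3)`.
#'
#' @param diffs A difference table from [compute_difference_scores()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A one-row effect-estimate tibble (`estimate`, `ci_low`,
#'   `ci_high`, `p`, `n`, `kind = "diff_correlation"`, `degenerate`). A
#'   zero-variance difference column (no discordance) yields an `NA`
#'   estimate flagged `degenerate = TRUE`.
#' @export
diff_correlation <- function(diffs, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  d <- diffs[diffs$zygosity == zygosity, ]
  n <- nrow(d)
  if (n < 4) {
    stop("diff_correlation requires at least 4 complete families of ",
         "zygosity ", zygosity, " (got ", n, ")", call. = FALSE)
  }
  st <- .diff_cor_stat(d$dx, d$dy)
  effect_estimate(st$estimate, st$ci_low, st$ci_high, st$p, st$n,
                  "diff_correlation", degenerate = st$degenerate)
}

#' Random-intercept phenotypic association
#'
#' Fits `y = b0 + b1*x + u_family + e` by maximum likelihood with a normal
#' random intercept per family ([lme4::lmer()]), after standardizing both
#' variables over the analyzed (complete-case) twins, so `b1` is a
#' standardized beta. Returns a Wald 95% confidence interval and two-sided
#' normal p-value. When the between-family variance is zero the estimate
#' coincides with the pooled regression slope (the Pearson correlation of
#' standardized `x` and `y`).
#'
#' @param x,y Numeric vectors (exposure, outcome), one entry per twin.
#' @param family_ids Family identifier per twin.
#' @return A one-row effect-estimate tibble with `kind = "mlm_beta"`;
#'   `n` is the number of analyzed twins.
#' @export
mlm_phenotypic <- function(x, y, family_ids) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; fam <- family_ids[ok]
  if (length(unique(fam)) < 2 || length(x) < 4) {
    stop("mlm_phenotypic requires at least 2 families and 4 twins",
         call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("mlm_phenotypic: zero-variance exposure", call. = FALSE)
  }
  xs <- standardize(x, "x")
  ys <- standardize(y, "y")
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(ys ~ xs + (1 | fam),
                 REML = FALSE,
                 control = lme4::lmerControl(
                   calc.derivs = FALSE,
                   check.conv.singular = "ignore")))),
    error = function(e) {
      stop("mlm_phenotypic failed to converge: ", conditionMessage(e),
           call. = FALSE)
    })
  est <- lme4::fixef(fit)[["xs"]]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[["xs"]]
  z <- est / se
  effect_estimate(est, est - 1.96 * se, est + 1.96 * se,
                  2 * stats::pnorm(-abs(z)), length(xs), "mlm_beta")
}

#' Convert a two-sided p-value to a signed z-score
#'
#' `|z|` is the upper-tail standard-normal quantile of `p/2` (so p = 0.05
#' maps to |z| = 1.96 and p = 1 to z = 0); the sign of the underlying
#' effect is attached. P-values are floored at 1e-15 to avoid infinite
#' z-scores in aggregation.
#'
#' @param p Two-sided p-value(s) in `(0, 1]`.
#' @param effect_sign Sign(s) of the effect: -1, 0, or +1 (recycled).
#' @return Signed z-score(s).
#' @examples
#' p_to_signed_z(0.05, -1)  # -1.96
#' @export
p_to_signed_z <- function(p, effect_sign) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (!all(effect_sign %in% c(-1, 0, 1))) {
    stop("`effect_sign` must be -1, 0, or +1", call. = FALSE)
  }
  p <- pmax(p, 1e-15)
  effect_sign * stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Compare two dependent correlations sharing a common variable
#'
#' Steiger-type Z1* statistic with the pooled estimate
#' `rbar = (r12 + r13)/2`: with `z1j = atanh(r1j)`,
#' `z = (z12 - z13) * sqrt(n - 3) / sqrt(2 - 2*s)` where
#' `s = psi / (1 - rbar^2)^2` and
#' `psi = r23*(1 - 2*rbar^2) - 0.5*rbar^2*(1 - 2*rbar^2 - r23^2)`.
#' Used to test whether variable 1 (e.g., a co-twin difference in
#' antisocial behavior) correlates differently with variables 2 and 3
#' (e.g., differences in two parenting dimensions).
#'
#' @param r12,r13 The two dependent correlations being compared.
#' @param r23 Correlation between variables 2 and 3.
#' @param n Sample size (>= 4).
#' @return A list with `z` and two-sided `p`.
#' @export
steiger_dependent_z <- function(r12, r13, r23, n) {
  rs <- c(r12, r13, r23)
  if (any(!is.finite(rs)) || any(abs(c(r12, r13)) >= 1) || abs(r23) > 1) {
    stop("correlations must lie in (-1, 1)", call. = FALSE)
  }
  if (!is.finite(n) || n < 4) {
    stop("`n` must be at least 4", call. = FALSE)
  }
  R <- matrix(c(1, r12, r13,
                r12, 1, r23,
                r13, r23, 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-12) {
    stop("the correlation triple (r12, r13, r23) is not positive ",
         "semi-definite", call. = FALSE)
  }
  dz <- atanh(r12) - atanh(r13)
  if (dz == 0) {
    return(list(z = 0, p = 1))
  }
  rbar <- (r12 + r13) / 2
  psi <- r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)
  s <- psi / (1 - rbar^2)^2
  denom <- 2 - 2 * s
  if (denom <= 0) {
    stop("degenerate correlation structure: nonpositive variance of the ",
         "difference of Fisher z's", call. = FALSE)
  }
  z <- dz * sqrt(n - 3) / sqrt(denom)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
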