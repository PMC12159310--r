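#' Path coefficients of a bivariate ACE generating model
#'
#' Defines the generating model for two latent child traits -- parenting
#' received (trait X) and antisocial behavior (trait Y) -- each decomposed
#' into additive genetic (A), shared environmental (C), and nonshared
#' environmental (E) components with unit total variance, plus cross-trait
#' correlations between like components.
#'
#' Each trait is constructed as `a*A + c*C + e*E` from standard-normal
#' factors. Co-twins share the A factor completely (MZ) or with weight 0.5
#' (DZ), share the C factor completely, and have independent E factors. The
#' cross-trait correlations `r_A`, `r_C`, `r_E` are imposed pairwise between
#' like factors of the two traits.
#'
#' @param a_x,c_x,e_x Path coefficients for trait X (parenting received).
#'   Squared coefficients must sum to 1.
#' @param a_y,c_y,e_y Path coefficients for trait Y (antisocial behavior).
#' @param r_A,r_C,r_E Cross-trait correlations between the A, C, and E
#'   factors of the two traits, each in `[-1, 1]`.
#' @return An object of class `biometric_params`.
#' @examples
#' p <- biometric_params(a_x = sqrt(0.5), c_x = 0, e_x = sqrt(0.5),
#'                       a_y = sqrt(0.5), c_y = 0, e_y = sqrt(0.5),
#'                       r_A = 0.5)
#' expected_individual_cor(p)
#' @export
biometric_params <- function(a_x, c_x, e_x, a_y, c_y, e_y,
                             r_A = 0, r_C = 0, r_E = 0) {
  vals <- c(a_x = a_x, c_x = c_x, e_x = e_x,
            a_y = a_y, c_y = c_y, e_y = e_y,
            r_A = r_A, r_C = r_C, r_E = r_E)
  if (!all(is.finite(vals))) {
    stop("all biometric parameters must be finite numbers", call. = FALSE)
  }
  if (any(vals[1:6] < 0) || any(vals[1:6] > 1)) {
    stop("path coefficients must lie in [0, 1]", call. = FALSE)
  }
  if (abs(a_x^2 + c_x^2 + e_x^2 - 1) > 1e-9 ||
      abs(a_y^2 + c_y^2 + e_y^2 - 1) > 1e-9) {
    stop("squared path coefficients must sum to 1 for each trait ",
         "(unit latent variance)", call. = FALSE)
  }
  if (any(abs(c(r_A, r_C, r_E)) > 1)) {
    stop("cross-trait correlations must lie in [-1, 1]", call. = FALSE)
  }
  if (e_x <= 0 || e_y <= 0) {
    stop("nonshared environmental paths e_x and e_y must be positive",
         call. = FALSE)
  }
  structure(as.list(vals), class = "biometric_params")
}

#' @export
print.biometric_params <- function(x, ...) {
  cat("Bivariate ACE generating model\n")
  cat(sprintf("  trait X (parenting): a^2 = %.3f, c^2 = %.3f, e^2 = %.3f\n",
              x$a_x^2, x$c_x^2, x$e_x^2))
  cat(sprintf("  trait Y (ASB):       a^2 = %.3f, c^2 = %.3f, e^2 = %.3f\n",
              x$a_y^2, x$c_y^2, x$e_y^2))
  cat(sprintf("  cross-trait: r_A = %.3f, r_C = %.3f, r_E = %.3f\n",
              x$r_A, x$r_C, x$r_E))
  cat(sprintf("  expected individual-level correlation: %.4f\n",
              expected_individual_cor(x)))
  invisible(x)
}

#' Closed-form expected correlations under the generating model
#'
#' `expected_individual_cor()` gives the population cross-trait correlation
#' at the individual level, `a_x*a_y*r_A + c_x*c_y*r_C + e_x*e_y*r_E`.
#' `expected_diff_cor()` gives the population correlation between co-twin
#' difference scores: `r_E` for MZ pairs (genes and shared environment drop
#' out of an MZ difference) and
#' `(a_x*a_y*r_A + 2*e_x*e_y*r_E) / sqrt((a_x^2 + 2*e_x^2)*(a_y^2 + 2*e_y^2))`
#' for DZ pairs. `expected_cotwin_cor()` gives the within-trait co-twin
#' correlation, `a^2 + c^2` (MZ) or `0.5*a^2 + c^2` (DZ).
#'
#' These closed forms serve as oracles for the simulator: sampled
#' correlations converge to them as the number of pairs grows.
#'
#' @param params A [biometric_params()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param trait `"x"` (parenting) or `"y"` (antisocial behavior).
#' @return A correlation (scalar).
#' @export
expected_individual_cor <- function(params) {
  stopifnot(inherits(params, "biometric_params"))
  with(params, a_x * a_y * r_A + c_x * c_y * r_C + e_x * e_y * r_E)
}

#' @rdname expected_individual_cor
#' @export
expected_diff_cor <- function(params, zygosity = c("MZ", "DZ")) {
  stopifnot(inherits(params, "biometric_params"))
  zygosity <- match.arg(zygosity)
  if (zygosity == "MZ") {
    return(params$r_E)
  }
  with(params,
       (a_x * a_y * r_A + 2 * e_x * e_y * r_E) /
         sqrt((a_x^2 + 2 * e_x^2) * (a_y^2 + 2 * e_y^2)))
}

#' @rdname expected_individual_cor
#' @export
expected_cotwin_cor <- function(params, trait = c("x", "y"),
                                zygosity = c("MZ", "DZ")) {
  stopifnot(inherits(params, "biometric_params"))
  trait <- match.arg(trait)
  zygosity <- match.arg(zygosity)
  a <- if (trait == "x") params$a_x else params$a_y
  c_ <- if (trait == "x") params$c_x else params$c_y
  w <- if (zygosity == "MZ") 1 else 0.5
  w * a^2 + c_^2
}

# Latent ACE variance shares used by the etiologic scenario presets.
# Parenting received by a child: roughly 30% child-driven genetic, 40%
# shared environmental, 30% child-specific, in line with meta-analytic
# estimates for parental warmth/positivity (Klahr & Burt, 2014). Childhood
# antisocial behavior: strongly heritable with moderate shared environment.
.scenario_paths <- function(label) {
  if (label == "scenario2_genetic") {
    # purely genetic transmission: no shared-environment paths at all
    list(a_x = sqrt(0.5), c_x = 0, e_x = sqrt(0.5),
         a_y = sqrt(0.5), c_y = 0, e_y = sqrt(0.5))
  } else {
    list(a_x = sqrt(0.30), c_x = sqrt(0.40), e_x = sqrt(0.30),
         a_y = sqrt(0.55), c_y = sqrt(0.25), e_y = sqrt(0.20))
  }
}

#' Etiologic scenario presets
#'
#' Returns a generating model in which the cross-trait association is (1)
#' purely nonshared-environmental (`scenario1_environmental`: only `r_E`
#' nonzero), (2) purely genetic (`scenario2_genetic`: only `r_A` nonzero),
#' or (3) both genetic and shared-environmental in origin
#' (`scenario3_genetic_shared`: `r_A` and `r_C` nonzero, `r_E = 0`). The
#' relevant cross-trait correlations are scaled so that the expected
#' individual-level correlation equals `sign * effect_size`; for scenario 3
#' the genetic and shared-environmental routes each carry half the effect.
#'
#' The default effect size of 0.10 matches the modest magnitude typical of
#' parenting--antisocial-behavior associations; the default sign is
#' negative because higher nurturance accompanies lower antisocial
#' behavior.
#'
#' @param label One of `"scenario1_environmental"`, `"scenario2_genetic"`,
#'   `"scenario3_genetic_shared"`.
#' @param effect_size Magnitude of the expected individual-level
#'   correlation (positive).
#' @param sign Direction of the association, `+1` or `-1`.
#' @return A list with elements `label`, `params` (a [biometric_params()]
#'   object), `sign`, and `effect_size`, of class `scenario_preset`.
#' @examples
#' scenario_preset("scenario1_environmental", effect_size = 0.10, sign = -1)
#' @export
scenario_preset <- function(label = c("scenario1_environmental",
                                      "scenario2_genetic",
                                      "scenario3_genetic_shared"),
                            effect_size = 0.10, sign = -1) {
  label <- match.arg(label)
  if (!is.numeric(effect_size) || length(effect_size) != 1 ||
      !is.finite(effect_size) || effect_size <= 0) {
    stop("`effect_size` must be a single positive number", call. = FALSE)
  }
  if (!sign %in% c(-1, 1)) {
    stop("`sign` must be +1 or -1", call. = FALSE)
  }
  pth <- .scenario_paths(label)
  target <- sign * effect_size
  r_A <- r_C <- r_E <- 0
  if (label == "scenario1_environmental") {
    r_E <- target / (pth$e_x * pth$e_y)
  } else if (label == "scenario2_genetic") {
    r_A <- target / (pth$a_x * pth$a_y)
  } else {
    r_A <- (target / 2) / (pth$a_x * pth$a_y)
    r_C <- (target / 2) / (pth$c_x * pth$c_y)
  }
  if (any(abs(c(r_A, r_C, r_E)) > 1)) {
    stop("`effect_size` is infeasible for these path coefficients ",
         "(a required cross-trait correlation exceeds 1 in magnitude)",
         call. = FALSE)
  }
  params <- biometric_params(pth$a_x, pth$c_x, pth$e_x,
                             pth$a_y, pth$c_y, pth$e_y,
                             r_A = r_A, r_C = r_C, r_E = r_E)
  structure(list(label = label, params = params, sign = sign,
                 effect_size = effect_size),
            class = "scenario_preset")
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat(sprintf("Scenario preset '%s' (effect %s%.3f)\n", x$label,
              if (x$sign < 0) "-" else "+", x$effect_size))
  print(x$params)
  invisible(x)
}
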