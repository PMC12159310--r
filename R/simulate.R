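#' Derive a deterministic substream seed from a master seed
#'
#' A single master seed spawns one seed per pipeline stage (latents,
#' measurement noise, missingness, twin ordering, replicates) so that
#' stages draw from independent, reproducible streams. The arithmetic is
#' exact in doubles and the result stays below 2^31 (a valid R integer).
#'
#' @param seed Master seed (single finite number).
#' @param stage A stage name (`"latents"`, `"noise"`, `"missingness"`,
#'   `"twin_order"`, `"replicate"`) or an integer offset.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1, is.finite(seed))
  offsets <- c(latents = 11L, noise = 211L, missingness = 431L,
               twin_order = 617L, replicate = 1009L)
  if (is.character(stage)) {
    if (!stage %in% names(offsets)) {
      stop("unknown substream stage: ", stage, call. = FALSE)
    }
    stage <- offsets[[stage]]
  }
  as.integer((abs(as.numeric(seed)) * 48271 + 69621 * as.numeric(stage)) %%
               2147483629)
}

# Pair of standard-normal vectors with correlation r.
.corr_pair <- function(n, r) {
  u <- stats::rnorm(n)
  v <- r * u + sqrt(1 - r^2) * stats::rnorm(n)
  list(u = u, v = v)
}

.simulate_zygosity_block <- function(params, n, zygosity, id_offset) {
  w <- if (zygosity == "MZ") 1 else 0.5
  # Shared and twin-specific genetic parts: the cross-trait correlation r_A
  # is imposed within each part, so cor(A_x, A_y) = r_A within a twin and
  # cor(A_x1, A_y2) = w * r_A across co-twins.
  As <- .corr_pair(n, params$r_A)
  A1 <- .corr_pair(n, params$r_A)
  A2 <- .corr_pair(n, params$r_A)
  Cs <- .corr_pair(n, params$r_C)
  E1 <- .corr_pair(n, params$r_E)
  E2 <- .corr_pair(n, params$r_E)
  mix <- function(shared, own) sqrt(w) * shared + sqrt(1 - w) * own
  build <- function(A, C, E, a, c_, e) a * A + c_ * C + e * E
  x1 <- build(mix(As$u, A1$u), Cs$u, E1$u, params$a_x, params$c_x, params$e_x)
  y1 <- build(mix(As$v, A1$v), Cs$v, E1$v, params$a_y, params$c_y, params$e_y)
  x2 <- build(mix(As$u, A2$u), Cs$u, E2$u, params$a_x, params$c_x, params$e_x)
  y2 <- build(mix(As$v, A2$v), Cs$v, E2$v, params$a_y, params$c_y, params$e_y)
  fam <- id_offset + seq_len(n)
  tibble::tibble(
    family_id = rep(fam, each = 2),
    zygosity = zygosity,
    twin_index = rep(c(1L, 2L), times = n),
    x = as.vector(rbind(x1, x2)),
    y = as.vector(rbind(y1, y2))
  )
}

#' Simulate latent twin pairs under a bivariate ACE model
#'
#' Draws family-clustered MZ and DZ twin pairs with two standardized latent
#' traits per twin: parenting received (`x`) and antisocial behavior (`y`).
#' Co-twins share the additive genetic factor completely (MZ) or with
#' weight 0.5 (DZ, implemented by splitting A into shared and twin-specific
#' parts of equal variance), share the C factor completely, and have
#' independent E factors; cross-trait correlations are imposed between like
#' factors. Sampled correlations converge to the closed forms in
#' [expected_individual_cor()], [expected_diff_cor()], and
#' [expected_cotwin_cor()].
#'
#' @param params A [biometric_params()] object (or a
#'   [scenario_preset()], whose `params` element is used).
#' @param n_mz,n_dz Number of MZ and DZ pairs (non-negative).
#' @param seed Integer seed; output is bit-reproducible given the seed.
#' @return A tibble with one row per twin: `family_id`, `zygosity`,
#'   `twin_index` (1 or 2), and latent values `x`, `y`.
#' @examples
#' pairs <- simulate_biometric_pairs(
#'   scenario_preset("scenario2_genetic", 0.25, +1), 500, 500, seed = 1)
#' @export
simulate_biometric_pairs <- function(params, n_mz, n_dz, seed) {
  if (inherits(params, "scenario_preset")) params <- params$params
  if (!inherits(params, "biometric_params")) {
    stop("`params` must be a biometric_params or scenario_preset object",
         call. = FALSE)
  }
  if (any(c(n_mz, n_dz) < 0) || any(c(n_mz, n_dz) %% 1 != 0)) {
    stop("`n_mz` and `n_dz` must be non-negative integers", call. = FALSE)
  }
  set.seed(substream_seed(seed, "latents"))
  out <- list()
  if (n_mz > 0) out$mz <- .simulate_zygosity_block(params, n_mz, "MZ", 0L)
  if (n_dz > 0) out$dz <- .simulate_zygosity_block(params, n_dz, "DZ", n_mz)
  if (length(out) == 0) {
    return(tibble::tibble(family_id = integer(), zygosity = character(),
                          twin_index = integer(), x = double(), y = double()))
  }
  dplyr::bind_rows(out)
}
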