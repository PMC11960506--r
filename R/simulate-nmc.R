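#' Generate synthetic observations from the competition model
#'
#' Forward-simulates a normalized dosage-response curve from the
#' TF-nucleosome competition model (optionally with additive Gaussian
#' noise), for parameter-recovery testing of the `fit_nmc_*` routines.
#'
#' @param L,c Model parameters.
#' @param alpha_max Effective TF concentration at dosage 1.
#' @param n_ha,n_la Site multiplicities (set `n_la = 0` for the homotypic
#'   case).
#' @param k_ratio Low/high K_D ratio (ignored when `n_la = 0`).
#' @param dosages Dosage grid.
#' @param noise_sd SD of additive noise on the response.
#' @param normalize Divide by the response at dosage 1 (the convention the
#'   `fit_nmc_*` targets use)? With the default `FALSE` the raw model
#'   accessibility is returned.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#'
#' @return A list with `curve` (tibble `dosage`, `response`) and `truth`
#'   (one-row tibble of the generating parameters). The curve carries
#'   `truth` as attribute `ground_truth`.
#' @export
generate_nmc_observations <- function(L = 1000, c, alpha_max, n_ha = 3,
                                      n_la = 0, k_ratio = 10,
                                      dosages = seq(0, 1, length.out = 50),
                                      noise_sd = 0, normalize = FALSE,
                                      seed = 1L) {
  check_nmc_params(L, c)
  check_number(alpha_max, "alpha_max", lower = .Machine$double.eps)
  check_number(noise_sd, "noise_sd", lower = 0)
  a <- alpha_max * dosages
  acc <- if (n_la > 0) {
    accessibility_mixed(a, L, c, k_ha = 1, k_la = k_ratio,
                        n_ha = n_ha, n_la = n_la)
  } else {
    accessibility_homotypic(a, L, c, n = n_ha)
  }
  resp <- if (normalize) acc / acc[which.max(dosages)] else acc
  if (noise_sd > 0) {
    set.seed(seed)
    resp <- resp + rnorm(length(resp), 0, noise_sd)
  }
  truth <- tibble(L = L, c = c, alpha_max = alpha_max, n_ha = n_ha,
                  n_la = n_la, k_ratio = if (n_la > 0) k_ratio else NA_real_,
                  noise_sd = noise_sd)
  curve <- tibble(dosage = dosages, response = resp)
  attr(curve, "ground_truth") <- truth
  list(curve = curve, truth = truth)
}
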