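#' Configuration for synthetic TF-dosage titration series
#'
#' Defaults emulate the study design the package targets: five dosage levels
#' spanning no TF to full TF with four biological replicates at each level,
#' lognormal replicate noise, additive log-scale batch offsets, and rare
#' extreme outliers.
#'
#' @param n_res Number of regulatory elements.
#' @param dosages Relative dosage levels in `[0, 1]`; must include 0 and 1.
#' @param replicates_per_dosage Biological replicates per dosage level.
#' @param n_batches Number of differentiation batches; replicates at each
#'   dosage are spread across batches round-robin.
#' @param batch_sd Log-scale SD of per-(RE, batch) offsets.
#' @param noise_sd Log-scale SD of per-sample multiplicative noise.
#' @param outlier_rate Probability that a sample value is replaced by an
#'   extreme value (a 4-6 SD shift, so the Z > 3 filter is exercised).
#' @param ed50_range Range for the true raw Hill half-max `K`, in dosage
#'   units `(0, 1]`.
#' @param hill_range Range for the true Hill exponent.
#' @param baseline_range Range for the true baseline as a fraction of the
#'   plateau.
#' @param ymax_range Range (CPM) for the true plateau accessibility,
#'   sampled log-uniformly.
#' @param seed RNG seed.
#'
#' @return A list of class `synthetic_dose_config`.
#' @export
synthetic_dose_config <- function(n_res = 200,
                                  dosages = c(0, 0.22, 0.45, 0.75, 1),
                                  replicates_per_dosage = 4,
                                  n_batches = 2,
                                  batch_sd = 0.1,
                                  noise_sd = 0.1,
                                  outlier_rate = 0,
                                  ed50_range = c(0.1, 0.9),
                                  hill_range = c(1, 4),
                                  baseline_range = c(0.02, 0.25),
                                  ymax_range = c(50, 500),
                                  seed = 1L) {
  check_number(n_res, "n_res", lower = 1)
  if (!any(dosages == 0) || !any(dosages == 1)) {
    abort("`dosages` must include 0 and 1.")
  }
  check_number(replicates_per_dosage, "replicates_per_dosage", lower = 1)
  check_number(n_batches, "n_batches", lower = 1)
  check_number(batch_sd, "batch_sd", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(outlier_rate, "outlier_rate", lower = 0, upper = 1)
  for (nm in c("ed50_range", "hill_range", "baseline_range", "ymax_range")) {
    r <- get(nm)
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
      abort(sprintf("`%s` must be an increasing positive range.", nm))
    }
  }
  if (ed50_range[2] > 1) abort("`ed50_range` values must lie in (0, 1].")
  if (baseline_range[2] >= 1) abort("`baseline_range` must stay below 1.")
  structure(
    list(n_res = as.integer(n_res), dosages = dosages,
         replicates_per_dosage = as.integer(replicates_per_dosage),
         n_batches = as.integer(n_batches), batch_sd = batch_sd,
         noise_sd = noise_sd, outlier_rate = outlier_rate,
         ed50_range = ed50_range, hill_range = hill_range,
         baseline_range = baseline_range, ymax_range = ymax_range,
         seed = as.integer(seed)),
    class = "synthetic_dose_config"
  )
}

# closed-form modified ED50 (percent) of a true Hill curve
true_modified_ed50 <- function(K, h, y_min, y_max) {
  k <- K^h
  A <- y_max - y_min
  t <- 0.5 / (k + 1) - 0.5 * y_min / A
  ifelse(t <= 0, NA_real_, 100 * (k * t / (1 - t))^(1 / h))
}

#' Simulate a TF-dosage titration series with known ground truth
#'
#' Each RE's expected value at dosage `d` follows the increasing Hill form
#' `y(d) = y_min + (y_max - y_min) d^h / (K^h + d^h)` with parameters drawn
#' from the configured ranges. Multiplicative lognormal noise and additive
#' log-scale batch offsets are applied, and outliers are injected at
#' `outlier_rate` as 4-6 SD shifts.
#'
#' @param config A [synthetic_dose_config()].
#'
#' @return A list with `data` (a [dosage_matrix()]) and `truth` (a tibble of
#'   per-RE true parameters: `K`, `h`, `y_min`, `y_max`, `ed50_mod`, plus a
#'   list-column `outliers` of injected outlier sample indices). The
#'   `dosage_matrix` also carries `truth` as attribute `ground_truth`.
#' @export
simulate_dose_response <- function(config = synthetic_dose_config()) {
  stopifnot(inherits(config, "synthetic_dose_config"))
  set.seed(config$seed)
  n_samp <- length(config$dosages) * config$replicates_per_dosage
  samples <- tibble(
    sample = sprintf("s%03d", seq_len(n_samp)),
    dosage = rep(config$dosages, each = config$replicates_per_dosage),
    batch = sprintf("b%d", rep_len(seq_len(config$n_batches), n_samp))
  )
  n <- config$n_res
  K <- runif(n, config$ed50_range[1], config$ed50_range[2])
  h <- runif(n, config$hill_range[1], config$hill_range[2])
  y_max <- exp(runif(n, log(config$ymax_range[1]), log(config$ymax_range[2])))
  y_min <- y_max * runif(n, config$baseline_range[1], config$baseline_range[2])
  mu <- vapply(seq_len(n_samp), function(j) {
    hill_mean(samples$dosage[j], K, h, y_min, y_max)
  }, numeric(n))
  batch_idx <- as.integer(factor(samples$batch))
  b_off <- matrix(rnorm(n * config$n_batches, 0, config$batch_sd), nrow = n)
  noise <- matrix(rnorm(n * n_samp, 0, config$noise_sd), nrow = n)
  values <- mu * exp(b_off[, batch_idx, drop = FALSE] + noise)
  out_flag <- matrix(runif(n * n_samp) < config$outlier_rate, nrow = n)
  if (any(out_flag)) {
    row_sd <- apply(values, 1, sd)
    row_sd[row_sd == 0] <- 0.2 * rowMeans(values)[row_sd == 0]
    idx <- which(out_flag, arr.ind = TRUE)
    shift <- sample(c(-1, 1), nrow(idx), replace = TRUE) *
      runif(nrow(idx), 4, 6) * row_sd[idx[, 1]]
    values[out_flag] <- pmax(values[out_flag] + shift, 0)
  }
  rownames(values) <- sprintf("re_%05d", seq_len(n))
  truth <- tibble(
    re_id = rownames(values), K = K, h = h, y_min = y_min, y_max = y_max,
    ed50_mod = true_modified_ed50(K, h, y_min, y_max),
    outliers = purrr::map(seq_len(n), function(i) which(out_flag[i, ]))
  )
  dm <- dosage_matrix(values, samples)
  attr(dm, "ground_truth") <- truth
  list(data = dm, truth = truth)
}
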