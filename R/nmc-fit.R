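# direct-space accessibility used inside optimizers: tolerates the
# exploratory c < 0 region (where log-space evaluation is undefined) and is
# overflow-safe within the fit bounds (alpha <= 1e6, n <= 7)
acc_fit_eval <- function(alpha_mat, nvec, L, c) {
  num <- rep(1, nrow(alpha_mat))
  bound <- rep(1, nrow(alpha_mat))
  for (s in seq_along(nvec)) {
    num <- num * (1 + alpha_mat[, s])^nvec[s]
    bound <- bound * (1 + c * alpha_mat[, s])^nvec[s]
  }
  num / (num + L * bound)
}

nmc_objective <- function(target, model_fn) {
  d <- target$dosage
  y <- target$response
  function(par) {
    pred <- model_fn(d, par)
    if (any(!is.finite(pred))) return(1e6)
    top <- pred[which.max(d)]
    if (!is.finite(top) || top <= 0) return(1e6)
    mean((pred / top - y)^2)
  }
}

run_nmc_optim <- function(obj, starts, lower, upper) {
  cands <- list()
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 1000, factr = 10)),
      error = function(e) NULL
    )
    if (!is.null(res)) cands[[length(cands) + 1]] <- res
  }
  if (length(cands) == 0) return(NULL)
  # the (c, K_ratio) likelihood surface is nearly flat along a trade-off
  # direction; polish the best basins with a derivative-free pass before a
  # final bounded refinement
  ord <- order(purrr::map_dbl(cands, "value"))
  best <- cands[[ord[1]]]
  for (j in head(ord, 3)) {
    pol <- tryCatch(
      optim(cands[[j]]$par, function(p) {
        if (any(p < lower) || any(p > upper)) return(1e6)
        obj(p)
      }, method = "Nelder-Mead",
      control = list(maxit = 5000, reltol = 1e-15)),
      error = function(e) NULL
    )
    if (is.null(pol)) next
    fin <- tryCatch(
      optim(pmin(pmax(pol$par, lower), upper), obj, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 1000, factr = 10)),
      error = function(e) NULL
    )
    for (r in list(pol, fin)) {
      if (!is.null(r) && r$value < best$value) best <- r
    }
  }
  best
}

new_nmc_fit <- function(type, params, n, mse, mse_by_n, passed_filter, L,
                        mse_threshold) {
  structure(
    list(type = type, params = params, n = n, mse = mse, mse_by_n = mse_by_n,
         passed_filter = passed_filter, L = L, mse_threshold = mse_threshold),
    class = "nmc_fit"
  )
}

#' Fit the homotypic competition model to a dosage-response curve
#'
#' Fits the normalized n-site homotypic accessibility curve
#' `Acc(alpha_max d) / Acc(alpha_max)` to a target response curve (1 at
#' dosage 1) by bounded least squares over the competition parameter `c` and
#' the effective concentration at full dosage `alpha_max`, for each
#' candidate site number `n`. The fit with the smallest mean squared error
#' across candidates is chosen. Fits with `mse > mse_threshold` or fitted
#' `c < 0` fail the quality filter (the lower bound on `c` sits below zero
#' precisely so that negative fits are observable and removable).
#'
#' @param target A tibble with columns `dosage` and `response`, response 1
#'   at dosage 1 (see [dosage_curve_from_hill()]).
#' @param L Nucleosome/open equilibrium constant, fixed during fitting.
#' @param n_candidates Candidate effective site numbers.
#' @param mse_threshold Filter threshold on the mean squared error.
#'
#' @return An `nmc_fit` with elements `type`, `params` (named vector with
#'   `c` and `alpha_max`), `n`, `mse`, `mse_by_n` (per-candidate tibble),
#'   and `passed_filter`.
#' @export
fit_nmc_homotypic <- function(target, L = 1000, n_candidates = 1:7,
                              mse_threshold = 0.001) {
  stopifnot(all(c("dosage", "response") %in% names(target)))
  starts <- expand.grid(c = c(0.005, 0.1), la = c(0.5, 2.5))
  lower <- c(-0.5, -2)
  upper <- c(1, 6)
  per_n <- purrr::map(n_candidates, function(n) {
    obj <- nmc_objective(target, function(d, par) {
      acc_fit_eval(cbind(10^par[2] * d), n, L, par[1])
    })
    best <- run_nmc_optim(obj, starts, lower, upper)
    if (is.null(best)) return(NULL)
    list(n = n, c = best$par[1], alpha_max = 10^best$par[2], mse = best$value)
  })
  per_n <- purrr::compact(per_n)
  if (length(per_n) == 0) {
    return(new_nmc_fit("homotypic", c(c = NA_real_, alpha_max = NA_real_),
                       NA_integer_, NA_real_, tibble(), FALSE, L, mse_threshold))
  }
  mse_by_n <- bind_rows(purrr::map(per_n, as_tibble))
  best <- per_n[[which.min(mse_by_n$mse)]]
  new_nmc_fit("homotypic",
              c(c = best$c, alpha_max = best$alpha_max),
              as.integer(best$n), best$mse, mse_by_n,
              best$mse <= mse_threshold && best$c >= 0, L, mse_threshold)
}

#' Fit the mixed high/low-affinity competition model
#'
#' Holds the number of high-affinity sites fixed (3 by default) and fits the
#' competition parameter `c`, the effective concentration `alpha_max` and
#' the low/high dissociation-constant ratio `k_ratio` for a given number of
#' low-affinity sites.
#'
#' @inheritParams fit_nmc_homotypic
#' @param n_ha Fixed number of high-affinity sites.
#' @param n_la Number of low-affinity sites (1-3 in typical use).
#'
#' @return An `nmc_fit` whose `params` also carries `k_ratio`.
#' @export
fit_nmc_mixed <- function(target, n_ha = 3, n_la = 1, L = 1000,
                          mse_threshold = 0.001) {
  stopifnot(all(c("dosage", "response") %in% names(target)))
  starts <- expand.grid(c = c(0.01, 0.1), la = c(1, 2.5),
                        lk = c(0.25, 0.75, 1.25, 1.75, 2.5))
  lower <- c(-0.5, -2, 0)
  upper <- c(1, 6, 5)
  obj <- nmc_objective(target, function(d, par) {
    a <- 10^par[2] * d
    acc_fit_eval(cbind(a, a / 10^par[3]), c(n_ha, n_la), L, par[1])
  })
  best <- run_nmc_optim(obj, starts, lower, upper)
  if (is.null(best)) {
    return(new_nmc_fit("mixed", c(c = NA_real_, alpha_max = NA_real_,
                                  k_ratio = NA_real_),
                       NA_integer_, NA_real_, tibble(), FALSE, L, mse_threshold))
  }
  params <- c(c = best$par[1], alpha_max = 10^best$par[2], k_ratio = 10^best$par[3])
  new_nmc_fit("mixed", params, as.integer(n_ha + n_la), best$value,
              tibble(n_ha = n_ha, n_la = n_la, mse = best$value),
              best$value <= mse_threshold && params[["c"]] >= 0, L, mse_threshold)
}

#' Fit the two-TF (heterotypic) competition model
#'
#' The perturbed TF contributes `n1` sites whose effective concentration
#' scales with dosage; an optional single site for a second, unperturbed TF
#' is held at a fitted constant effective concentration `alpha2`. Without a
#' second motif the fit reduces to the homotypic path with `n = n1`. The
#' quality filter threshold is 0.01 for this model class.
#'
#' @inheritParams fit_nmc_homotypic
#' @param n1 Number of sites for the perturbed TF.
#' @param second_motif Is a second-TF site present?
#'
#' @return An `nmc_fit`; with a second motif `params` carries `alpha2`.
#' @export
fit_nmc_heterotypic <- function(target, n1 = 2, second_motif = TRUE, L = 1000,
                                mse_threshold = 0.01) {
  if (!second_motif) {
    fit <- fit_nmc_homotypic(target, L = L, n_candidates = n1,
                             mse_threshold = mse_threshold)
    fit$type <- "heterotypic"
    return(fit)
  }
  stopifnot(all(c("dosage", "response") %in% names(target)))
  starts <- expand.grid(c = c(0.005, 0.05), la = 1.5, la2 = c(0, 2))
  lower <- c(-0.5, -2, -3)
  upper <- c(1, 6, 5)
  obj <- nmc_objective(target, function(d, par) {
    acc_fit_eval(cbind(10^par[2] * d, 10^par[3]), c(n1, 1), L, par[1])
  })
  best <- run_nmc_optim(obj, starts, lower, upper)
  if (is.null(best)) {
    return(new_nmc_fit("heterotypic", c(c = NA_real_, alpha_max = NA_real_,
                                        alpha2 = NA_real_),
                       NA_integer_, NA_real_, tibble(), FALSE, L, mse_threshold))
  }
  params <- c(c = best$par[1], alpha_max = 10^best$par[2], alpha2 = 10^best$par[3])
  new_nmc_fit("heterotypic", params, as.integer(n1), best$value,
              tibble(n1 = n1, n2 = 1, mse = best$value),
              best$value <= mse_threshold && params[["c"]] >= 0, L, mse_threshold)
}

#' @export
print.nmc_fit <- function(x, ...) {
  cat(sprintf("<nmc_fit:%s> n = %s, mse = %.3g, filter %s\n", x$type,
              ifelse(is.na(x$n), "?", x$n), x$mse,
              ifelse(isTRUE(x$passed_filter), "passed", "FAILED")))
  print(round(x$params, 5))
  invisible(x)
}

#' @rdname fit_nmc_homotypic
#' @param x An `nmc_fit`.
#' @param ... Unused.
#' @method tidy nmc_fit
#' @export
tidy.nmc_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname fit_nmc_homotypic
#' @method glance nmc_fit
#' @export
glance.nmc_fit <- function(x, ...) {
  tibble(type = x$type, n = x$n, mse = x$mse, L = x$L,
         passed_filter = x$passed_filter)
}

#' Summarize a population of competition-model fits
#'
#' Medians of the fitted competition parameter and (where present) K_D
#' ratio across a set of fits that passed the quality filter, with
#' percentile bootstrap confidence intervals.
#'
#' @param fits A list of `nmc_fit` objects.
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param seed RNG seed for the bootstrap.
#'
#' @return A tibble with one row per parameter: `term`, `median`, `lo`,
#'   `hi`, `n_fits`.
#' @export
summarize_nmc_fits <- function(fits, n_boot = 200, conf = 0.95, seed = 1L) {
  keep <- purrr::keep(fits, ~ isTRUE(.x$passed_filter))
  if (length(keep) == 0) {
    return(tibble(term = character(), median = numeric(), lo = numeric(),
                  hi = numeric(), n_fits = integer()))
  }
  set.seed(seed)
  terms <- intersect(c("c", "k_ratio", "alpha_max"),
                     unique(unlist(purrr::map(keep, ~ names(.x$params)))))
  bind_rows(purrr::map(terms, function(tm) {
    v <- purrr::map_dbl(keep, function(f) {
      if (tm %in% names(f$params)) f$params[[tm]] else NA_real_
    })
    v <- v[!is.na(v)]
    boots <- purrr::map_dbl(seq_len(n_boot),
                            ~ median(sample(v, length(v), replace = TRUE)))
    qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    tibble(term = tm, median = median(v), lo = qs[1], hi = qs[2],
           n_fits = length(v))
  }))
}
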