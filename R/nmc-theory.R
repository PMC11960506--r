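#' TF-nucleosome competition accessibility curves
#'
#' Equilibrium accessibility of a DNA region whose open and nucleosome-bound
#' states compete for TF binding. With per-site effective TF concentrations
#' `a_s` (concentration divided by the site's K_D), site multiplicities
#' `n_s`, nucleosome/open equilibrium constant `L` and competition parameter
#' `c` (the fold suppression of TF binding on nucleosomal DNA),
#'
#'   `Acc = prod_s (1 + a_s)^n_s / [ prod_s (1 + a_s)^n_s + L prod_s (1 + c a_s)^n_s ]`
#'
#' Evaluated in log space so large `a * n` cannot overflow. At `a = 0` every
#' configuration gives `1 / (1 + L)`; at `c = 1` the curve is flat.
#'
#' @param alpha Effective TF concentration(s); vectorized.
#' @param L Nucleosome/open equilibrium constant (`> 0`).
#' @param c Competition parameter in `[0, 1]`.
#' @param n Number of binding sites (homotypic case).
#'
#' @return Accessibility values in `(0, 1)`.
#' @name nmc_accessibility
NULL

acc_core <- function(log_num_terms, log_bound_terms, L) {
  # both arguments: matrices (grid x sites) of n_s*log1p(alpha_s) and
  # n_s*log1p(c*alpha_s)
  ln <- rowSums(log_num_terms)
  lb <- log(L) + rowSums(log_bound_terms)
  exp(ln - logsumexp2(ln, lb))
}

check_nmc_params <- function(L, c) {
  check_number(L, "L", lower = .Machine$double.eps)
  check_number(c, "c", lower = 0, upper = 1)
}

#' @rdname nmc_accessibility
#' @export
accessibility_homotypic <- function(alpha, L, c, n) {
  check_nmc_params(L, c)
  check_number(n, "n", lower = 0)
  if (any(alpha < 0)) abort("`alpha` must be nonnegative.")
  acc_core(cbind(n * log1p(alpha)), cbind(n * log1p(c * alpha)), L)
}

#' @rdname nmc_accessibility
#' @param k_ha,k_la Dissociation constants of the high- and low-affinity
#'   site classes (the TF concentration scale is set by `k_ha`; only the
#'   ratio matters).
#' @param n_ha,n_la Site multiplicities of the two classes.
#' @export
accessibility_mixed <- function(alpha, L, c, k_ha = 1, k_la, n_ha, n_la) {
  check_nmc_params(L, c)
  if (k_ha <= 0 || k_la <= 0) abort("dissociation constants must be positive.")
  if (any(alpha < 0)) abort("`alpha` must be nonnegative.")
  a_ha <- alpha / k_ha
  a_la <- alpha / k_la
  acc_core(cbind(n_ha * log1p(a_ha), n_la * log1p(a_la)),
           cbind(n_ha * log1p(c * a_ha), n_la * log1p(c * a_la)), L)
}

#' @rdname nmc_accessibility
#' @param alpha1,alpha2 Effective concentrations of the two TFs (vectorized
#'   over `alpha1`).
#' @param n1,n2 Site multiplicities of the two TFs.
#' @export
accessibility_heterotypic <- function(alpha1, alpha2, L, c, n1, n2) {
  check_nmc_params(L, c)
  if (any(alpha1 < 0) || any(alpha2 < 0)) abort("`alpha` must be nonnegative.")
  acc_core(cbind(n1 * log1p(alpha1), n2 * log1p(alpha2)),
           cbind(n1 * log1p(c * alpha1), n2 * log1p(c * alpha2)), L)
}

#' Log-spaced effective-concentration grid
#'
#' The standard titration grid: 20 points per decade over `[1e-5, 1e5]`.
#'
#' @param lo,hi Grid range.
#' @param points_per_decade Grid density.
#' @export
nmc_alpha_grid <- function(lo = 1e-5, hi = 1e5, points_per_decade = 20) {
  10^seq(log10(lo), log10(hi), by = 1 / points_per_decade)
}

#' Theoretical ED50 of an accessibility curve
#'
#' The effective concentration at which accessibility reaches halfway
#' between its value at the bottom and at the top of the titration window -
#' the theory-side analogue of the data-side modified ED50 (half of the
#' response at the top of the titration). Located on the log-spaced grid and
#' refined by root bisection between the bracketing grid points.
#'
#' @param f A function of `alpha` returning accessibility, or a data frame
#'   with columns `alpha` and `acc` (then log-linear interpolation is used).
#' @param alpha_range Titration window.
#' @param points_per_decade Grid density for bracketing.
#' @param tol Relative bisection tolerance on `alpha`.
#'
#' @return The ED50 concentration. Flat curves (e.g. `c = 1`) are an error.
#' @export
curve_ed50 <- function(f, alpha_range = c(1e-5, 1e5), points_per_decade = 20,
                       tol = 1e-12) {
  if (is.data.frame(f)) {
    stopifnot(all(c("alpha", "acc") %in% names(f)))
    dat <- f[order(f$alpha), ]
    fn <- function(a) {
      exp(stats::approx(log(dat$alpha), log(dat$acc), xout = log(a), rule = 2)$y)
    }
    alpha_range <- range(dat$alpha)
  } else {
    fn <- f
  }
  grid <- nmc_alpha_grid(alpha_range[1], alpha_range[2], points_per_decade)
  acc <- fn(grid)
  if (any(diff(acc) < -1e-9 * max(abs(acc)))) {
    abort("ED50 undefined: accessibility curve is not monotone nondecreasing.")
  }
  span <- acc[length(acc)] - acc[1]
  if (span <= 1e-12 * max(acc[1], .Machine$double.xmin)) {
    abort("ED50 undefined: accessibility curve is flat over the titration window.")
  }
  level <- acc[1] + 0.5 * span
  i <- which(acc >= level)[1]
  if (i == 1) return(grid[1])
  uniroot(function(a) fn(a) - level, c(grid[i - 1], grid[i]),
          tol = tol * grid[i])$root
}

#' Minimal K_D ratio at which a second binding site sensitizes
#'
#' Starting from a single high-affinity site, scans the dissociation-constant
#' ratio of an added second site over a log-spaced grid (decades by default,
#' matching the order-of-magnitude resolution at which the competition model
#' is usually interrogated) and reports the smallest ratio at which the
#' two-site theoretical ED50 exceeds the single-site ED50 by more than
#' `margin` (relative). The margin guards against edge-of-titration
#' artifacts when the second site's K_D approaches the top of the
#' concentration window; genuine sensitizing shifts are orders of magnitude
#' larger. With `refine = TRUE` the grid answer is sharpened to the
#' continuous crossover ratio by bisection in log ratio.
#'
#' @param L Nucleosome/open equilibrium constant.
#' @param c Competition parameter (`< 1`).
#' @param ratios K_D ratio grid (second site relative to the first).
#' @param margin Relative ED50 increase required to call sensitization.
#' @param refine Also compute the continuous crossover ratio?
#' @param alpha_range,points_per_decade Titration window and density passed
#'   to [curve_ed50()].
#'
#' @return A list of class `sensitizing_scan`: `threshold` (smallest
#'   sensitizing ratio on the grid, or `NA` when no ratio sensitizes, as at
#'   `c = 0`), `crossover` (continuous refinement, when requested),
#'   `single_ed50`, and `scan`, a tibble of per-ratio ED50s.
#' @export
sensitizing_threshold <- function(L = 1000, c, ratios = 10^(0:5), margin = 0.01,
                                  refine = FALSE, alpha_range = c(1e-5, 1e5),
                                  points_per_decade = 20) {
  check_nmc_params(L, c)
  if (c >= 1) abort("`c` must be < 1 for a non-flat dosage response.")
  ed50_at <- function(r) {
    curve_ed50(function(a) accessibility_mixed(a, L, c, k_ha = 1, k_la = r,
                                               n_ha = 1, n_la = 1),
               alpha_range, points_per_decade)
  }
  e1 <- curve_ed50(function(a) accessibility_homotypic(a, L, c, n = 1),
                   alpha_range, points_per_decade)
  ratios <- sort(ratios)
  e2 <- vapply(ratios, ed50_at, numeric(1))
  sens <- e2 > e1 * (1 + margin)
  idx <- which(sens)[1]
  threshold <- if (is.na(idx)) NA_real_ else ratios[idx]
  crossover <- NA_real_
  if (refine && !is.na(idx)) {
    lo <- if (idx > 1) log10(ratios[idx - 1]) else log10(ratios[idx]) - 1
    g <- function(lr) ed50_at(10^lr) - e1 * (1 + margin)
    crossover <- if (g(lo) >= 0) 10^lo else {
      10^uniroot(g, c(lo, log10(ratios[idx])), tol = 1e-7)$root
    }
  }
  structure(
    list(threshold = threshold, crossover = crossover, single_ed50 = e1,
         L = L, c = c, margin = margin,
         scan = tibble(ratio = ratios, ed50 = e2, sensitizing = sens)),
    class = "sensitizing_scan"
  )
}

#' @export
print.sensitizing_scan <- function(x, ...) {
  cat(sprintf("<sensitizing_scan> L = %g, c = %g; single-site ED50 = %.4g\n",
              x$L, x$c, x$single_ed50))
  if (is.na(x$threshold)) {
    cat("  no K_D ratio on the grid sensitizes (every second site buffers)\n")
  } else {
    cat(sprintf("  minimal sensitizing K_D ratio: %g\n", x$threshold))
    if (!is.na(x$crossover)) cat(sprintf("  continuous crossover: %.4g\n", x$crossover))
  }
  invisible(x)
}

#' Closed-form two-TF ED50
#'
#' For one site per TF (`n1 = n2 = 1`), the ED50 of TF1's dosage-response
#' curve while TF2 is held at effective concentration `alpha2` has a closed
#' form under the half-of-titration-top convention used by [curve_ed50()].
#' With `A = 1 + alpha2`, `B = L (1 + c alpha2)` and half-level
#' `m = (Acc(alpha_min) + Acc(alpha_max)) / 2`, solving `Acc(alpha) = m`
#' gives `alpha* = (R - 1) / (1 - R c)` where `R = m B / (A (1 - m))`.
#' Strictly decreasing in `alpha2` for `c < 1`: a second TF always buffers.
#'
#' @param alpha2 Effective concentration of the held-constant TF.
#' @param L,c Model parameters.
#' @param alpha_range Titration window defining the reference level.
#'
#' @return ED50 of TF1, or `NA` (flagged with a warning) when no root lies
#'   in the window.
#' @export
analytic_ed50_two_tf <- function(alpha2, L = 1000, c, alpha_range = c(1e-5, 1e5)) {
  check_nmc_params(L, c)
  if (c >= 1) abort("`c` must be < 1.")
  check_number(alpha2, "alpha2", lower = 0)
  A <- 1 + alpha2
  B <- L * (1 + c * alpha2)
  f <- function(a1) accessibility_heterotypic(a1, alpha2, L, c, n1 = 1, n2 = 1)
  m <- (f(alpha_range[1]) + f(alpha_range[2])) / 2
  R <- m * B / (A * (1 - m))
  if (R <= 1 || R * c >= 1) {
    warn("no ED50 root in this parameter regime.")
    return(NA_real_)
  }
  (R - 1) / (1 - R * c)
}

#' Hill-shaped target curve for competition-model fitting
#'
#' Builds the normalized dosage-response curve implied by a fitted modified
#' ED50 (percent) and Hill exponent: an increasing Hill curve scaled so the
#' response at dosage 1 is exactly 1 and the response at `ed50_mod / 100` is
#' exactly 0.5 - the same convention under which the ED50 was estimated.
#' A Hill curve with zero baseline can realize this only when
#' `(ed50_mod / 100)^h < 1/2`; at the boundary the limiting curve `d^h` is
#' used and beyond it the pair is not representable and an error is raised.
#'
#' @param ed50_mod Modified ED50 in percent, `(0, 100]`.
#' @param h Hill exponent.
#' @param dosages Dosage grid for the target curve.
#'
#' @return A tibble with columns `dosage` and `response` (response at
#'   dosage 1 equal to 1), carrying `ed50_mod` and `h` as attributes.
#' @export
dosage_curve_from_hill <- function(ed50_mod, h, dosages = seq(0, 1, length.out = 50)) {
  check_number(ed50_mod, "ed50_mod", lower = 1e-12, upper = 100)
  check_number(h, "h", lower = 1e-12)
  e <- ed50_mod / 100
  E <- e^h
  if (abs(2 * E - 1) < 1e-9) {
    resp <- dosages^h
  } else if (E > 0.5) {
    abort(sprintf(
      "ED50 = %.3g%% with h = %.3g is not representable by a zero-baseline Hill curve (need (ed50/100)^h < 1/2).",
      ed50_mod, h))
  } else {
    k <- E / (1 - 2 * E)
    resp <- (dosages^h / (k + dosages^h)) * (k + 1)
  }
  out <- tibble(dosage = dosages, response = resp)
  attr(out, "ed50_mod") <- ed50_mod
  attr(out, "h") <- h
  out
}
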