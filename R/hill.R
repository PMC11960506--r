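#' Scale a response vector and mask outlier samples
#'
#' Divides a per-RE vector of (batch-corrected) CPM values by its maximum
#' absolute value, then masks samples whose Z score (sample SD, computed on
#' the scaled values) exceeds 3 in magnitude.
#'
#' @param values Numeric vector of per-sample values for one RE.
#' @param z_cutoff Z-score magnitude beyond which a sample is masked.
#'
#' @return A list with `values` (scaled vector), `keep` (logical mask of
#'   retained samples), `n_outliers`, and `reason` (`NA` or a string when the
#'   RE is degenerate and should be skipped).
#' @export
preprocess_for_fit <- function(values, z_cutoff = 3) {
  if (length(values) < 4) abort("need at least 4 samples per RE.")
  m <- max(abs(values))
  if (!is.finite(m) || m == 0) {
    return(list(values = values, keep = rep(FALSE, length(values)),
                n_outliers = 0L, reason = "all-zero or non-finite response"))
  }
  scaled <- values / m
  s <- sd(scaled)
  z <- if (is.na(s) || s == 0) rep(0, length(scaled)) else (scaled - mean(scaled)) / s
  keep <- abs(z) <= z_cutoff
  list(values = scaled, keep = keep, n_outliers = sum(!keep), reason = NA_character_)
}

hill_mean <- function(d, K, h, y_min, y_max) {
  y_min + (y_max - y_min) * d^h / (K^h + d^h)
}

# profiled-Gaussian AIC for a least-squares fit: n*log(RSS/n) + 2k,
# k counting the fitted curve parameters plus the noise variance
aic_ls <- function(rss, n, p) n * log(rss / n) + 2 * (p + 1)

fit_hill_one <- function(d, y, free_ymax, y_min, y_max0,
                         starts_K = c(0.1, 0.3, 0.5, 0.7), starts_h = c(1, 3)) {
  dat <- data.frame(d = d, y = y)
  best <- NULL
  for (K0 in starts_K) {
    for (h0 in starts_h) {
      fit <- tryCatch({
        if (free_ymax) {
          minpack.lm::nlsLM(
            y ~ y_min + (ymax - y_min) * d^h / (K^h + d^h),
            data = dat, start = list(K = K0, h = h0, ymax = y_max0),
            lower = c(K = 1e-4, h = 0.05, ymax = y_min),
            upper = c(K = 100, h = 50, ymax = Inf),
            control = minpack.lm::nls.lm.control(maxiter = 200)
          )
        } else {
          minpack.lm::nlsLM(
            y ~ y_min + (y_max0 - y_min) * d^h / (K^h + d^h),
            data = dat, start = list(K = K0, h = h0),
            lower = c(K = 1e-4, h = 0.05), upper = c(K = 100, h = 50),
            control = minpack.lm::nls.lm.control(maxiter = 200)
          )
        }
      }, error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) {
        cf <- stats::coef(fit)
        best <- list(K = unname(cf["K"]), h = unname(cf["h"]),
                     y_max = if (free_ymax) unname(cf["ymax"]) else y_max0,
                     rss = rss)
      }
    }
  }
  best
}

#' Fit a Hill dose-response curve to one RE
#'
#' Fits the increasing Hill form
#' `y(d) = y_min + (y_max - y_min) d^h / (K^h + d^h)` to scaled accessibility
#' values by bounded Levenberg-Marquardt least squares with multi-start
#' initialization. Two candidate models are fitted: a two-parameter model
#' with both endpoints fixed to the mean response at dosage 0 (`y_min`) and
#' dosage 1 (`y_max`), and a three-parameter model with `y_min` fixed but
#' `y_max` free. The three-parameter model is adopted only when its AIC
#' (Gaussian likelihood with the variance profiled out) improves on the
#' two-parameter model by more than `aic_gap`.
#'
#' @param values Scaled response values (see [preprocess_for_fit()]).
#' @param dosages Relative TF dosage per value, in `[0, 1]`; dosages 0 and 1
#'   must both be present.
#' @param aic_gap Minimum AIC decrease required to adopt the three-parameter
#'   model.
#'
#' @return An object of class `hill_fit` with elements `model`
#'   (`"two_param"` or `"three_param"`), `K`, `h`, `y_min`, `y_max`, `aic2`,
#'   `aic3`, `rss`, `converged`, and `reason` when not converged.
#' @export
fit_hill <- function(values, dosages, aic_gap = 2) {
  if (length(values) != length(dosages)) abort("`values` and `dosages` lengths differ.")
  if (!any(dosages == 0) || !any(dosages == 1)) {
    abort("both endpoint dosages (0 and 1) are required.")
  }
  y_min <- mean(values[dosages == 0])
  y_max0 <- mean(values[dosages == 1])
  out <- structure(
    list(model = NA_character_, K = NA_real_, h = NA_real_,
         y_min = y_min, y_max = NA_real_, aic2 = NA_real_, aic3 = NA_real_,
         rss = NA_real_, converged = FALSE, reason = NA_character_),
    class = "hill_fit"
  )
  span <- y_max0 - y_min
  if (!is.finite(span) || abs(span) < 1e-8 * max(abs(values), 1e-12)) {
    out$reason <- "flat response: endpoints indistinguishable"
    return(out)
  }
  n <- length(values)
  f2 <- fit_hill_one(dosages, values, free_ymax = FALSE, y_min = y_min, y_max0 = y_max0)
  f3 <- fit_hill_one(dosages, values, free_ymax = TRUE, y_min = y_min, y_max0 = y_max0)
  if (is.null(f2) && is.null(f3)) {
    out$reason <- "optimizer failed on all starts"
    return(out)
  }
  # RSS floor at numerical-zero scale: on essentially perfect fits the
  # profiled-Gaussian AIC would otherwise amplify meaningless RSS ratios and
  # defeat parsimony
  rss_floor <- 1e-12
  aic2 <- if (!is.null(f2)) aic_ls(max(f2$rss, rss_floor), n, 2) else Inf
  aic3 <- if (!is.null(f3)) aic_ls(max(f3$rss, rss_floor), n, 3) else Inf
  use3 <- !is.null(f3) && (aic2 - aic3 > aic_gap)
  chosen <- if (use3) f3 else if (!is.null(f2)) f2 else f3
  out$model <- if (use3) "three_param" else "two_param"
  out$K <- chosen$K
  out$h <- chosen$h
  out$y_max <- chosen$y_max
  out$aic2 <- aic2
  out$aic3 <- aic3
  out$rss <- chosen$rss
  out$converged <- TRUE
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<hill_fit> not converged:", x$reason, "\n")
  } else {
    cat(sprintf("<hill_fit> %s: K = %.4g, h = %.4g, y_min = %.4g, y_max = %.4g\n",
                x$model, x$K, x$h, x$y_min, x$y_max))
  }
  invisible(x)
}

#' Evaluate a fitted Hill curve
#'
#' @param object A `hill_fit`.
#' @param newdata Optional data frame with a `d` column of dosages; defaults
#'   to a fine grid on `[0, 1]`.
#' @param ... Unused.
#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) seq(0, 1, length.out = 101) else newdata$d
  hill_mean(d, object$K, object$h, object$y_min, object$y_max)
}

#' Modified, capped ED50 of a fitted Hill curve
#'
#' The TF dosage (as a percent) at which the fitted curve reaches 50% of its
#' fitted value at 100% dosage - not of the theoretical plateau. Because the
#' root is sought on dosage `(0, 1]`, the value is capped at 100 by
#' construction. Found by bisection to `tol` in dosage units.
#'
#' @param fit A converged `hill_fit`.
#' @param tol Bisection tolerance in dosage units.
#'
#' @return ED50 in percent (`(0, 100]`), or `NA` with attribute `reason`
#'   when the baseline already exceeds the half-level.
#' @export
modified_ed50 <- function(fit, tol = 1e-9) {
  stopifnot(inherits(fit, "hill_fit"))
  if (!isTRUE(fit$converged)) abort("ED50 undefined: fit did not converge.")
  if (fit$y_max < fit$y_min) {
    abort("fitted curve is decreasing beyond tolerance; fit rejected.")
  }
  f <- function(d) hill_mean(d, fit$K, fit$h, fit$y_min, fit$y_max)
  target <- 0.5 * f(1)
  lo <- 1e-6
  if (f(lo) >= target) {
    return(structure(NA_real_, reason = "baseline at or above half of top response"))
  }
  root <- uniroot(function(d) f(d) - target, c(lo, 1), tol = tol)$root
  100 * root
}

#' Classify an RE response as buffered or sensitive
#'
#' @param ed50_mod Modified ED50 in percent.
#' @param threshold Class boundary in percent (default 30): `buffered` when
#'   `ed50_mod < threshold`, `sensitive` otherwise; exact ties go to
#'   `sensitive` and are reported via a message.
#'
#' @return Character vector of labels.
#' @export
classify_response <- function(ed50_mod, threshold = 30) {
  ties <- sum(ed50_mod == threshold, na.rm = TRUE)
  if (ties > 0) {
    inform(sprintf("%d ED50 value(s) exactly at the %g threshold assigned 'sensitive'.",
                   ties, threshold))
  }
  ifelse(is.na(ed50_mod), NA_character_,
         ifelse(ed50_mod < threshold, "buffered", "sensitive"))
}

#' Fit dose-response curves for every RE in a dosage matrix
#'
#' Runs the full per-RE recipe: batch correction (optional, on by default),
#' max-absolute-value scaling, Z > 3 outlier masking, two- versus
#' three-parameter Hill fitting with AIC selection, the modified capped
#' ED50, and buffered/sensitive classification.
#'
#' @param x A [dosage_matrix()].
#' @param threshold Buffered/sensitive ED50 boundary in percent.
#' @param batch_correct Apply [correct_batch()] first?
#' @param aic_gap AIC gap for adopting the three-parameter model.
#'
#' @return A tibble with one row per RE: `re_id`, `model`, `K`, `h`,
#'   `y_min`, `y_max`, `aic2`, `aic3`, `ed50_mod`, `class`, `n_outliers`,
#'   `converged`, `reason`.
#' @export
fit_dose_response <- function(x, threshold = 30, batch_correct = TRUE, aic_gap = 2) {
  stopifnot(inherits(x, "dosage_matrix"))
  if (batch_correct) x <- correct_batch(x)
  d_all <- x$samples$dosage
  rows <- purrr::map(seq_len(nrow(x$values)), function(i) {
    v <- x$values[i, ]
    prep <- preprocess_for_fit(v)
    if (!is.na(prep$reason)) {
      return(tibble(re_id = rownames(x$values)[i], model = NA_character_,
                    K = NA_real_, h = NA_real_, y_min = NA_real_, y_max = NA_real_,
                    aic2 = NA_real_, aic3 = NA_real_, ed50_mod = NA_real_,
                    class = NA_character_, n_outliers = prep$n_outliers,
                    converged = FALSE, reason = prep$reason))
    }
    keep <- prep$keep
    fit <- fit_hill(prep$values[keep], d_all[keep], aic_gap = aic_gap)
    ed <- if (fit$converged) {
      e <- tryCatch(modified_ed50(fit), error = function(e) NA_real_)
      as.numeric(e)
    } else NA_real_
    tibble(re_id = rownames(x$values)[i], model = fit$model, K = fit$K, h = fit$h,
           y_min = fit$y_min, y_max = fit$y_max, aic2 = fit$aic2, aic3 = fit$aic3,
           ed50_mod = ed, class = NA_character_, n_outliers = prep$n_outliers,
           converged = fit$converged, reason = fit$reason)
  })
  out <- bind_rows(rows)
  out$class <- classify_response(out$ed50_mod, threshold)
  out
}

#' @rdname fit_hill
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("K", "h", "y_min", "y_max"),
         estimate = c(x$K, x$h, x$y_min, x$y_max),
         fixed = c(FALSE, FALSE, TRUE, x$model == "two_param"))
}

#' @rdname fit_hill
#' @method glance hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(model = x$model, rss = x$rss, aic2 = x$aic2, aic3 = x$aic3,
         converged = x$converged)
}
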