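#' Configuration for an end-to-end synthetic run
#'
#' Assembles every tunable threshold of the pipeline in one place, with the
#' package defaults: ED50 class boundary 30 (percent), AIC adoption gap 2,
#' outlier Z cutoff 3, CWM Jaccard/contribution percentiles 10 and 0.5,
#' competition-model MSE filters 0.001 (homotypic/mixed) and 0.01
#' (heterotypic), and L fixed at 1000. A single run seed is fanned out into
#' independent per-stage seeds so stages are individually reproducible.
#'
#' @param seed Run seed.
#' @param dose_config A [synthetic_dose_config()]; its seed is derived from
#'   `seed` unless supplied explicitly.
#' @param ed50_threshold Buffered/sensitive boundary (percent).
#' @param aic_gap AIC gap for three-parameter adoption.
#' @param jaccard_percentile,contrib_percentile CWM mapping thresholds.
#' @param L Nucleosome/open equilibrium constant for competition fits.
#' @param mse_threshold Homotypic/mixed fit filter.
#' @param n_nmc_fits Number of REs whose fitted Hill curves are refit with
#'   the competition model (capped for desk-scale runs).
#' @param stages Character vector of stages to run, in order, among
#'   `"simulate"`, `"dose"`, `"nmc"`, `"cwm"`.
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, dose_config = NULL, ed50_threshold = 30,
                       aic_gap = 2, jaccard_percentile = 10,
                       contrib_percentile = 0.5, L = 1000,
                       mse_threshold = 0.001, n_nmc_fits = 50,
                       stages = c("simulate", "dose", "nmc", "cwm")) {
  if (is.null(dose_config)) {
    dose_config <- synthetic_dose_config(seed = derive_seed(seed, "simulate"))
  }
  bad <- setdiff(stages, c("simulate", "dose", "nmc", "cwm"))
  if (length(bad)) abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  structure(list(seed = as.integer(seed), dose_config = dose_config,
                 ed50_threshold = ed50_threshold, aic_gap = aic_gap,
                 jaccard_percentile = jaccard_percentile,
                 contrib_percentile = contrib_percentile, L = L,
                 mse_threshold = mse_threshold, n_nmc_fits = n_nmc_fits,
                 stages = stages),
            class = "run_config")
}

demo_cwms <- function() {
  box <- function(seqs, width, strength = 1) {
    m <- matrix(-0.05, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_along(seqs)) {
      m[seqs[j], j] <- strength
    }
    m
  }
  list(
    coordinator_hi = cwm("coordinator_hi",
                         box(c(2, 1, 4, 4, 3, 2, 1, 1, 1, 3, 3, 1), 12, 1.2),
                         polarity = "buffering"),
    ebox_lo = cwm("ebox_lo", box(c(2, 1, 4, 4, 3, 2), 6, 0.5),
                  polarity = "sensitizing")
  )
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the configured stages in order - simulate a titration series,
#' fit per-RE dose-response curves and classify them, refit a subset with
#' the TF-nucleosome competition model, and map planted CWM instances in
#' simulated contribution tracks - writing every table (TSV), the stage
#' summaries (JSON) and a manifest into `out_dir`. Stages only consume
#' artifacts of earlier stages; a missing upstream artifact fails fast
#' naming the stage.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#'
#' @return Invisibly, a list with the in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  if ("simulate" %in% config$stages) {
    sim <- simulate_dose_response(config$dose_config)
    res$sim <- sim
    readr::write_tsv(as_tibble(sim$data), file.path(out_dir, "dose_matrix.tsv"))
    readr::write_tsv(sim$data$samples, file.path(out_dir, "samples.tsv"))
    readr::write_tsv(select(sim$truth, -"outliers"),
                     file.path(out_dir, "ground_truth.tsv"))
    note("simulate: %d REs x %d samples", nrow(sim$data$values),
         ncol(sim$data$values))
  }

  if ("dose" %in% config$stages) {
    if (is.null(res$sim)) abort("stage 'dose' requires stage 'simulate'.")
    fits <- fit_dose_response(res$sim$data, threshold = config$ed50_threshold,
                              aic_gap = config$aic_gap)
    res$fits <- fits
    readr::write_tsv(fits, file.path(out_dir, "hill_fits.tsv"))
    note("dose: %d/%d REs converged, %d without defined ED50",
         sum(fits$converged), nrow(fits),
         sum(fits$converged & is.na(fits$ed50_mod)))
  }

  if ("nmc" %in% config$stages) {
    if (is.null(res$fits)) abort("stage 'nmc' requires stage 'dose'.")
    usable <- filter(res$fits, .data$converged, !is.na(.data$ed50_mod),
                     (.data$ed50_mod / 100)^.data$h < 0.5 - 1e-9)
    skipped <- nrow(res$fits) - nrow(usable)
    usable <- head(usable, config$n_nmc_fits)
    nmc_fits <- purrr::map(seq_len(nrow(usable)), function(i) {
      target <- dosage_curve_from_hill(usable$ed50_mod[i], usable$h[i])
      fit_nmc_homotypic(target, L = config$L,
                        mse_threshold = config$mse_threshold)
    })
    names(nmc_fits) <- usable$re_id
    res$nmc <- nmc_fits
    nmc_tbl <- bind_rows(purrr::imap(nmc_fits, function(f, id) {
      mutate(glance(f), re_id = id, c = f$params[["c"]],
             alpha_max = f$params[["alpha_max"]])
    }))
    res$nmc_table <- nmc_tbl
    readr::write_tsv(nmc_tbl, file.path(out_dir, "nmc_fits.tsv"))
    summ <- summarize_nmc_fits(nmc_fits, seed = derive_seed(config$seed, "nmc"))
    readr::write_tsv(summ, file.path(out_dir, "nmc_summary.tsv"))
    note("nmc: fitted %d REs (%d skipped as non-representable or unconverged), %d passed filter",
         nrow(usable), skipped, sum(nmc_tbl$passed_filter))
  }

  if ("cwm" %in% config$stages) {
    cwms <- demo_cwms()
    cwm_seed <- derive_seed(config$seed, "cwm")
    set.seed(cwm_seed)
    tracks <- purrr::map(1:12, function(i) {
      w1 <- cwm_width(cwms$coordinator_hi)
      w2 <- cwm_width(cwms$ebox_lo)
      planted <- tibble(
        cwm_id = c("coordinator_hi", "ebox_lo"),
        offset = c(sample(120:(180 - w1), 1), sample(c(10:60, 240:280), 1)),
        strand = sample(c("+", "-"), 2, replace = TRUE), scale = 1)
      simulate_contribution_track(300, cwms, planted, noise_sd = 0.03,
                                  region_id = sprintf("region_%02d", i),
                                  seed = cwm_seed + i)
    })
    truth <- bind_rows(purrr::map(tracks, function(t) {
      mutate(t$truth, region_id = t$track$region_id)
    }))
    inst <- scan_cwm(purrr::map(tracks, "track"), cwms,
                     jaccard_percentile = config$jaccard_percentile,
                     contrib_percentile = config$contrib_percentile) |>
      resolve_overlaps()
    stats <- summit_distance_stats(inst, cwms)
    res$cwm <- list(instances = stats$instances, truth = truth,
                    by_polarity = stats$by_polarity)
    readr::write_tsv(stats$instances, file.path(out_dir, "cwm_instances.tsv"))
    readr::write_tsv(truth, file.path(out_dir, "cwm_truth.tsv"))
    note("cwm: %d instances mapped over %d tracks", nrow(stats$instances),
         length(tracks))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dosegrammar")),
    seed = config$seed,
    stages = config$stages,
    parameters = config[c("ed50_threshold", "aic_gap", "jaccard_percentile",
                          "contrib_percentile", "L", "mse_threshold")],
    dose_config = unclass(config$dose_config),
    log = log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

#' Summary plots for a completed run
#'
#' Builds the standard report panels from a run directory: example fitted
#' dose-response curves, theoretical ED50 versus second-site K_D ratio at
#' several competition strengths, and the distribution of fitted competition
#' parameters. Empty results yield an empty-but-valid report.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param save Also write PDFs into `run_dir`?
#'
#' @return A named list of ggplot objects (possibly empty slots) plus a
#'   `notes` character vector.
#' @export
make_report <- function(run_dir, save = FALSE) {
  plots <- list()
  notes <- character()
  fits_path <- file.path(run_dir, "hill_fits.tsv")
  if (file.exists(fits_path)) {
    fits <- readr::read_tsv(fits_path, show_col_types = FALSE)
    mat_path <- file.path(run_dir, "dose_matrix.tsv")
    if (file.exists(mat_path)) {
      dat <- readr::read_tsv(mat_path, show_col_types = FALSE)
      ok <- filter(fits, .data$converged, !is.na(.data$ed50_mod))
      show <- head(arrange(ok, .data$ed50_mod), 3) |>
        bind_rows(head(arrange(ok, dplyr::desc(.data$ed50_mod)), 3))
      plots$dose_response <- plot_dose_response(
        filter(dat, .data$re_id %in% show$re_id), show)
    }
  } else {
    notes <- c(notes, "no dose-response fits found")
  }
  plots$theory <- plot_theory_ed50(c_values = c(0, 0.001, 0.01))
  nmc_path <- file.path(run_dir, "nmc_fits.tsv")
  if (file.exists(nmc_path)) {
    nmc <- readr::read_tsv(nmc_path, show_col_types = FALSE)
    nmc_ok <- filter(nmc, .data$passed_filter)
    if (nrow(nmc_ok) > 0) {
      plots$nmc_params <- ggplot2::ggplot(nmc_ok, ggplot2::aes(x = .data$type,
                                                               y = .data$c)) +
        ggplot2::geom_boxplot() +
        ggplot2::labs(x = NULL, y = "fitted competition parameter c") +
        ggplot2::theme_minimal()
    } else {
      notes <- c(notes, "no competition fits passed the filter; boxplot omitted")
    }
  }
  if (save) {
    for (nm in names(plots)) {
      ggplot2::ggsave(file.path(run_dir, paste0("report_", nm, ".pdf")),
                      plots[[nm]], width = 6, height = 4)
    }
  }
  plots$notes <- notes
  plots
}
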