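#' Positional statistics of motif instances relative to RE summits
#'
#' Computes signed and absolute distances from each instance midpoint to its
#' region's accessibility summit, flags central instances (within 50 bp of
#' the summit, i.e. the central 100 bp), and summarizes by CWM polarity. If
#' both sensitizing and buffering instances are present, the positional
#' difference is tested by a two-sided Wilcoxon rank-sum test on absolute
#' distances.
#'
#' @param instances Tibble from [scan_cwm()]/[resolve_overlaps()].
#' @param cwms List of [cwm()] objects supplying polarities.
#' @param central_halfwidth Half-width (bp) of the central window.
#'
#' @return A list: `instances` (input plus `polarity`, `abs_dist`,
#'   `central`), `by_polarity` (per-polarity summaries), `test` (the
#'   Wilcoxon result or `NULL`).
#' @export
summit_distance_stats <- function(instances, cwms, central_halfwidth = 50) {
  if (inherits(cwms, "cwm")) cwms <- list(cwms)
  pol <- purrr::map_chr(cwms, "polarity")
  names(pol) <- purrr::map_chr(cwms, "id")
  inst <- instances |>
    mutate(polarity = unname(pol[.data$cwm_id]),
           abs_dist = abs(.data$summit_dist),
           central = .data$abs_dist <= central_halfwidth)
  by_pol <- inst |>
    group_by(.data$polarity) |>
    summarise(n = dplyr::n(),
              median_abs_dist = median(.data$abs_dist),
              frac_central = mean(.data$central), .groups = "drop")
  test <- NULL
  if (all(c("sensitizing", "buffering") %in% inst$polarity)) {
    test <- stats::wilcox.test(
      abs_dist ~ polarity, exact = FALSE,
      data = filter(inst, .data$polarity %in% c("buffering", "sensitizing"))
    )
  }
  list(instances = inst, by_polarity = by_pol, test = test)
}

#' Shuffled positional controls for motif instances
#'
#' Places width-matched intervals uniformly at random within the same
#' region set, discarding placements that overlap any true instance - the
#' location-shuffled null used to benchmark positional or conservation
#' signals of real instances.
#'
#' @param instances True instances (tibble with `region_id`, `start`,
#'   `end`).
#' @param regions Tibble with `region_id`, `length`, and optionally
#'   `summit`.
#' @param n Number of controls to draw (defaults to `nrow(instances)`).
#' @param seed RNG seed.
#' @param max_tries Rejection-sampling budget per control.
#'
#' @return A tibble of control intervals (`region_id`, `start`, `end`,
#'   `cwm_id` of the width donor, `summit_dist` when summits are given);
#'   fewer rows than requested (with a warning) when space runs out.
#' @export
shuffle_instances <- function(instances, regions, n = nrow(instances),
                              seed = 1L, max_tries = 50) {
  stopifnot(all(c("region_id", "length") %in% names(regions)))
  set.seed(seed)
  widths <- instances$end - instances$start
  donor <- sample.int(nrow(instances), n, replace = n > nrow(instances))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    w <- widths[donor[i]]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      r <- regions[sample.int(nrow(regions), 1), ]
      if (r$length < w) next
      s <- sample.int(r$length - w + 1, 1) - 1L
      hit <- filter(instances, .data$region_id == r$region_id,
                    .data$start < s + w, .data$end > s)
      if (nrow(hit) == 0) { ok <- TRUE; break }
    }
    if (!ok) next
    out[[i]] <- tibble(region_id = r$region_id, start = s, end = s + w,
                       cwm_id = instances$cwm_id[donor[i]])
  }
  res <- bind_rows(purrr::compact(out))
  if (nrow(res) < n) {
    warn(sprintf("only %d of %d requested shuffled controls could be placed.",
                 nrow(res), n))
  }
  if ("summit" %in% names(regions) && nrow(res) > 0) {
    su <- regions$summit
    names(su) <- regions$region_id
    res$summit_dist <- (res$start + res$end - 1) %/% 2 - unname(su[res$region_id])
  }
  res
}
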