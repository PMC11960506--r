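#' Contribution weight matrices and contribution tracks
#'
#' A CWM is a signed 4-by-width matrix of per-base contribution scores
#' (rows A, C, G, T) summarizing a motif learned from model attributions; a
#' contribution track is the 4-by-length matrix of per-base, per-nucleotide
#' contribution scores over one regulatory element, with the accessibility
#' summit recorded.
#'
#' @param id Motif identifier.
#' @param matrix Numeric 4-by-width matrix; rows are taken as A, C, G, T.
#' @param polarity `"sensitizing"`, `"buffering"` or `"unlabeled"`.
#'
#' @return `cwm()` returns an object of class `cwm`.
#' @export
cwm <- function(id, matrix, polarity = c("unlabeled", "sensitizing", "buffering")) {
  polarity <- match.arg(polarity)
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4 || ncol(matrix) < 4 || any(!is.finite(matrix))) {
    abort("a CWM must be a finite 4-row matrix with width >= 4.")
  }
  rownames(matrix) <- c("A", "C", "G", "T")
  structure(list(id = id, matrix = matrix, polarity = polarity), class = "cwm")
}

#' @export
print.cwm <- function(x, ...) {
  cat(sprintf("<cwm> %s (%s), width %d\n", x$id, x$polarity, ncol(x$matrix)))
  invisible(x)
}

#' @rdname cwm
#' @param x A `cwm`.
#' @export
cwm_width <- function(x) ncol(x$matrix)

#' Reverse complement of a CWM (or any 4-by-width score matrix)
#'
#' Reverses positions and swaps the A/T and C/G rows; contribution signs are
#' preserved.
#'
#' @param m A `cwm` or a 4-row matrix.
#' @export
cwm_revcomp <- function(m) {
  if (inherits(m, "cwm")) {
    out <- m
    out$matrix <- cwm_revcomp(m$matrix)
    return(out)
  }
  r <- m[4:1, ncol(m):1, drop = FALSE]
  rownames(r) <- c("A", "C", "G", "T")
  r
}

#' @rdname cwm
#' @param region_id Region identifier.
#' @param scores 4-by-length matrix of per-base contribution scores.
#' @param summit 0-based offset of the accessibility summit within the
#'   region.
#' @return `contribution_track()` returns an object of class
#'   `contribution_track`.
#' @export
contribution_track <- function(region_id, scores, summit) {
  scores <- as.matrix(scores)
  if (nrow(scores) != 4) abort("track scores must have 4 rows (A, C, G, T).")
  check_number(summit, "summit", lower = 0, upper = ncol(scores) - 1)
  rownames(scores) <- c("A", "C", "G", "T")
  structure(list(region_id = region_id, scores = scores,
                 summit = as.integer(summit)),
            class = "contribution_track")
}

#' @export
print.contribution_track <- function(x, ...) {
  cat(sprintf("<contribution_track> %s: %d bp, summit at %d\n",
              x$region_id, ncol(x$scores), x$summit))
  invisible(x)
}

#' Simulate a contribution track with planted motif instances
#'
#' Gaussian background noise plus, at each planted offset, the CWM's score
#' matrix (reverse-complemented for the minus strand) times a scale factor.
#' Overlapping planted instances are allowed but flagged in the ground
#' truth.
#'
#' @param length Track length in bases.
#' @param cwms Named list of [cwm()] objects.
#' @param planted Tibble/data frame with columns `cwm_id`, `offset`
#'   (0-based), `strand` (`"+"`/`"-"`), and optionally `scale` (default 1).
#' @param noise_sd SD of the Gaussian background, in score units.
#' @param summit Summit offset; defaults to the track midpoint.
#' @param region_id Region identifier.
#' @param seed RNG seed.
#'
#' @return A list with `track` (a [contribution_track()]) and `truth` (the
#'   planted table with an `overlapping` flag).
#' @export
simulate_contribution_track <- function(length, cwms, planted, noise_sd = 0.05,
                                        summit = NULL, region_id = "region_1",
                                        seed = 1L) {
  planted <- as_tibble(planted)
  if (!"scale" %in% names(planted)) planted$scale <- 1
  if (is.null(names(cwms))) names(cwms) <- purrr::map_chr(cwms, "id")
  widths <- purrr::map_int(cwms[planted$cwm_id], cwm_width)
  if (any(planted$offset < 0) || any(planted$offset + widths > length)) {
    abort("planted instances must fit within the track.")
  }
  set.seed(seed)
  scores <- matrix(rnorm(4 * length, 0, noise_sd), nrow = 4)
  for (i in seq_len(nrow(planted))) {
    m <- cwms[[planted$cwm_id[i]]]$matrix
    if (planted$strand[i] == "-") m <- cwm_revcomp(m)
    cols <- planted$offset[i] + seq_len(ncol(m))
    scores[, cols] <- scores[, cols] + m * planted$scale[i]
  }
  ivl_start <- planted$offset
  ivl_end <- planted$offset + widths
  overlapping <- purrr::map_lgl(seq_len(nrow(planted)), function(i) {
    any(ivl_start[-i] < ivl_end[i] & ivl_end[-i] > ivl_start[i])
  })
  truth <- mutate(planted, width = widths, overlapping = overlapping)
  track <- contribution_track(region_id, scores,
                              summit %||% (length %/% 2))
  attr(track, "ground_truth") <- truth
  list(track = track, truth = truth)
}

#' Sign-aware continuous Jaccard similarity between score windows
#'
#' For equal-size score matrices `a` and `b`,
#' `sum(min(|a|, |b|) * s) / sum(max(|a|, |b|))` over all entries, where `s`
#' is +1 where the signs agree and -1 where they disagree. Equals 1 iff
#' `a == b` elementwise and -1 for `b == -a`; zero-magnitude windows score 0
#' by convention.
#'
#' @param a,b Numeric matrices (or vectors) of equal size.
#' @return A scalar in `[-1, 1]`.
#' @export
cwm_jaccard <- function(a, b) {
  if (length(a) != length(b)) abort("windows must have equal size.")
  aa <- abs(a); ab <- abs(b)
  den <- sum(pmax(aa, ab))
  if (den == 0) return(0)
  s <- ifelse(a * b >= 0, 1, -1)
  sum(pmin(aa, ab) * s) / den
}

scan_one <- function(track, cw, strand) {
  m <- if (strand == "-") cwm_revcomp(cw$matrix) else cw$matrix
  w <- ncol(m)
  L <- ncol(track$scores)
  if (L < w) return(NULL)
  offs <- 0:(L - w)
  jac <- vapply(offs, function(o) {
    cwm_jaccard(m, track$scores[, o + seq_len(w), drop = FALSE])
  }, numeric(1))
  contrib <- vapply(offs, function(o) {
    sum(abs(track$scores[, o + seq_len(w), drop = FALSE]))
  }, numeric(1))
  tibble(region_id = track$region_id, start = offs, end = offs + w,
         strand = strand, cwm_id = cw$id, jaccard = jac,
         lw_score = jac * w, contrib = contrib)
}

#' Map CWM instances in contribution tracks
#'
#' Slides each CWM (both strands) across each track, scoring every window by
#' sign-aware continuous Jaccard similarity and by total absolute
#' contribution. A window becomes an instance when its Jaccard score is at
#' or above the `jaccard_percentile` of all windows scanned for that CWM
#' (across all tracks and both strands) and its contribution is at or above
#' the `contrib_percentile` of the same reference population. The permissive
#' defaults (10 and 0.5) deliberately admit low-affinity instances; run
#' [resolve_overlaps()] afterwards to deduplicate.
#'
#' @param tracks A [contribution_track()] or list of them.
#' @param cwms A [cwm()] or list of them.
#' @param jaccard_percentile,contrib_percentile Percentile thresholds in
#'   `[0, 100]`.
#'
#' @return A tibble of candidate instances: `region_id`, `start`, `end`
#'   (0-based half-open, region-relative), `strand`, `cwm_id`, `jaccard`,
#'   `lw_score` (jaccard times width), `contrib`, `summit_dist` (instance
#'   midpoint minus summit), `central` (|summit_dist| <= 50).
#' @export
scan_cwm <- function(tracks, cwms, jaccard_percentile = 10,
                     contrib_percentile = 0.5) {
  if (inherits(tracks, "contribution_track")) tracks <- list(tracks)
  if (inherits(cwms, "cwm")) cwms <- list(cwms)
  summits <- purrr::map_int(tracks, "summit")
  names(summits) <- purrr::map_chr(tracks, "region_id")
  out <- purrr::map(cwms, function(cw) {
    wins <- bind_rows(purrr::map(tracks, function(tr) {
      short <- ncol(tr$scores) < cwm_width(cw)
      if (short) {
        inform(sprintf("track %s shorter than CWM %s: skipped.",
                       tr$region_id, cw$id))
        return(NULL)
      }
      bind_rows(scan_one(tr, cw, "+"), scan_one(tr, cw, "-"))
    }))
    if (nrow(wins) == 0) return(NULL)
    jac_thr <- quantile(wins$jaccard, jaccard_percentile / 100, names = FALSE)
    con_thr <- quantile(wins$contrib, contrib_percentile / 100, names = FALSE)
    filter(wins, .data$jaccard >= jac_thr, .data$contrib >= con_thr)
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) return(out)
  mid <- (out$start + out$end - 1) %/% 2
  out$summit_dist <- mid - unname(summits[out$region_id])
  out$central <- abs(out$summit_dist) <= 50
  arrange(out, .data$region_id, .data$start, .data$cwm_id)
}

#' Resolve overlapping CWM instances
#'
#' Among instances whose intervals overlap within a region, keeps the one
#' with the highest length-weighted score (Jaccard similarity times CWM
#' width, so short motifs do not win on score inflation alone); ties break
#' toward the lower start, then the lexicographically smaller CWM id.
#' Palindromic double counts - the same CWM matching the same interval on
#' both strands - are collapsed to the plus strand first.
#'
#' @param instances A tibble from [scan_cwm()].
#' @return The deduplicated tibble; output intervals are pairwise
#'   non-overlapping within each region.
#' @export
resolve_overlaps <- function(instances) {
  if (nrow(instances) == 0) return(instances)
  # same CWM, same interval, both strands: keep the better-scoring strand,
  # collapsing true palindromes (equal scores) to "+"
  strand_rank <- ifelse(instances$strand == "+", 0L, 1L)
  inst <- instances[order(instances$region_id, instances$start,
                          instances$end, instances$cwm_id,
                          -instances$lw_score, strand_rank), ]
  dup <- duplicated(inst[, c("region_id", "start", "end", "cwm_id")])
  inst <- inst[!dup, ]
  keep_one_region <- function(df) {
    ord <- order(-df$lw_score, df$start, df$cwm_id)
    df <- df[ord, ]
    kept <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      overl <- kept & df$start < df$end[i] & df$end > df$start[i]
      if (!any(overl)) kept[i] <- TRUE
    }
    df[kept, ]
  }
  out <- inst |>
    dplyr::group_split(.data$region_id) |>
    purrr::map(keep_one_region) |>
    bind_rows()
  arrange(out, .data$region_id, .data$start)
}
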