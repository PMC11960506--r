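test_that("continuous Jaccard matches the naive oracle and its fixed points", {
  cw <- make_box_cwm("m", c(1, 2, 3, 4), 4)
  a <- cw$matrix
  expect_equal(cwm_jaccard(a, a), 1)
  expect_equal(cwm_jaccard(a, -a), -1)
  expect_equal(cwm_jaccard(matrix(0, 4, 4), matrix(0, 4, 4)), 0)
  set.seed(9)
  for (i in 1:20) {
    x <- matrix(rnorm(24), 4)
    y <- matrix(rnorm(24), 4)
    expect_equal(cwm_jaccard(x, y), jaccard_brute(as.vector(x), as.vector(y)),
                 tolerance = 1e-12)
  }
})

test_that("reverse complement is an involution that swaps A/T and C/G", {
  cw <- make_box_cwm("m", c(1, 3, 2, 4), 4, strength = 2)
  rc <- cwm_revcomp(cw)
  expect_equal(cwm_revcomp(rc)$matrix, cw$matrix)
  expect_equal(unname(rc$matrix["T", 4]), unname(cw$matrix["A", 1]))
  expect_equal(unname(rc$matrix["C", 2]), unname(cw$matrix["G", 3]))
})

test_that("scanning recovers planted instances at exact offsets", {
  cwms <- list(
    big = make_box_cwm("big", c(2, 1, 4, 4, 3, 2, 1, 1), 8, 1,
                       polarity = "buffering"),
    small = make_box_cwm("small", c(3, 3, 1, 2, 1, 4), 6, 0.6,
                         polarity = "sensitizing")
  )
  set.seed(13)
  planted_all <- list()
  tracks <- lapply(1:25, function(i) {
    planted <- tibble::tibble(
      cwm_id = c("big", "small"),
      offset = c(sample(5:80, 1), sample(110:180, 1)),
      strand = sample(c("+", "-"), 2, replace = TRUE), scale = 1)
    sim <- simulate_contribution_track(200, cwms, planted, noise_sd = 0.03,
                                       region_id = sprintf("r%02d", i),
                                       seed = 1000 + i)
    planted_all[[i]] <<- dplyr::mutate(sim$truth, region_id = sprintf("r%02d", i))
    sim$track
  })
  truth <- dplyr::bind_rows(planted_all)
  inst <- resolve_overlaps(scan_cwm(tracks, cwms))
  hits <- dplyr::inner_join(
    truth, inst, by = c("region_id", "cwm_id", "offset" = "start"))
  recall <- nrow(hits) / nrow(truth)
  expect_gte(recall, 0.95)
  # strand of recovered instances matches the planted strand
  expect_true(all(hits$strand.x == hits$strand.y))
})

test_that("thresholds behave monotonically and extremes keep at most one window", {
  cw <- make_box_cwm("m", c(1, 2, 3, 4, 1, 2), 6)
  sim <- simulate_contribution_track(
    120, list(m = cw), tibble::tibble(cwm_id = "m", offset = 50, strand = "+"),
    noise_sd = 0.05, seed = 7)
  n_at <- function(jp) nrow(scan_cwm(sim$track, cw, jaccard_percentile = jp))
  counts <- vapply(c(0, 25, 50, 75, 100), n_at, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_lte(counts[length(counts)], 2)  # one window per strand at most
  inst100 <- resolve_overlaps(scan_cwm(sim$track, cw, jaccard_percentile = 100))
  expect_lte(nrow(inst100), 1)
})

test_that("overlap resolution keeps the best length-weighted candidate", {
  inst <- tibble::tibble(
    region_id = "r1", start = c(10, 12), end = c(16, 24),
    strand = "+", cwm_id = c("short", "long"),
    jaccard = c(0.9, 0.5), lw_score = c(0.9 * 6, 0.5 * 12),
    contrib = 1, summit_dist = 0L, central = TRUE)
  kept <- resolve_overlaps(inst)
  expect_identical(kept$cwm_id, "long")  # 6.0 beats 5.4
  # non-overlapping instances all survive
  inst2 <- dplyr::mutate(inst, start = c(10, 30), end = c(16, 42))
  expect_identical(nrow(resolve_overlaps(inst2)), 2L)
  # palindromic double counts collapse to the plus strand
  pal <- tibble::tibble(
    region_id = "r1", start = 5, end = 11, strand = c("+", "-"),
    cwm_id = "pal", jaccard = 0.8, lw_score = 4.8, contrib = 1,
    summit_dist = 0L, central = TRUE)
  res <- resolve_overlaps(pal)
  expect_identical(nrow(res), 1L)
  expect_identical(res$strand, "+")
})

test_that("resolved instances are pairwise non-overlapping", {
  cw1 <- make_box_cwm("a", c(1, 2, 3, 4, 1), 5)
  cw2 <- make_box_cwm("b", c(1, 2, 3, 4, 1, 2, 3), 7)
  sim <- simulate_contribution_track(
    150, list(a = cw1, b = cw2),
    tibble::tibble(cwm_id = c("a", "b", "a"), offset = c(20, 22, 100),
                   strand = "+"),
    noise_sd = 0.05, seed = 3)
  out <- resolve_overlaps(scan_cwm(sim$track, list(cw1, cw2)))
  out <- dplyr::arrange(out, start)
  if (nrow(out) > 1) {
    expect_true(all(out$start[-1] >= out$end[-nrow(out)]))
  }
})

test_that("summit distances, central flags and polarity contrasts are computed", {
  cwms <- list(
    buf = make_box_cwm("buf", c(2, 1, 4, 4, 3, 2, 1, 1), 8, 1,
                       polarity = "buffering"),
    sen = make_box_cwm("sen", c(3, 3, 1, 2, 1, 4), 6, 0.8,
                       polarity = "sensitizing")
  )
  # buffering planted central, sensitizing peripheral, across tracks
  set.seed(27)
  tracks <- lapply(1:15, function(i) {
    simulate_contribution_track(
      300, cwms,
      tibble::tibble(cwm_id = c("buf", "sen"),
                     offset = c(146, sample(c(5:40, 250:290), 1)),
                     strand = "+"),
      noise_sd = 0.02, summit = 150, region_id = sprintf("r%02d", i),
      seed = 500 + i)$track
  })
  # keep only high-similarity instances so the planted geometry is assessed
  # without background windows
  inst <- resolve_overlaps(scan_cwm(tracks, cwms)) |>
    dplyr::filter(jaccard > 0.8)
  stats <- summit_distance_stats(inst, cwms)
  buf <- dplyr::filter(stats$instances, polarity == "buffering")
  expect_true(all(buf$central))
  expect_true(all(abs(buf$summit_dist) <= 5))
  expect_lt(stats$test$p.value, 1e-4)
  # arithmetic of the central flag
  one <- tibble::tibble(region_id = "r01", start = 86, end = 94, strand = "+",
                        cwm_id = "buf", jaccard = 1, lw_score = 8, contrib = 1,
                        summit_dist = -61L, central = FALSE)
  st <- summit_distance_stats(one, cwms)
  expect_false(st$instances$central)
  expect_equal(st$instances$abs_dist, 61)
})

test_that("shuffled controls stay inside regions and off true instances", {
  regions <- tibble::tibble(region_id = c("r1", "r2"), length = c(300, 300),
                            summit = c(150, 150))
  inst <- tibble::tibble(region_id = c("r1", "r1", "r2"),
                         start = c(50, 200, 120), end = c(62, 212, 132),
                         cwm_id = "m")
  for (seed in 1:5) {
    ctrl <- shuffle_instances(inst, regions, n = 40, seed = seed)
    expect_true(all(ctrl$start >= 0))
    expect_true(all(ctrl$end <= 300))
    clash <- dplyr::inner_join(ctrl, inst, by = "region_id",
                               suffix = c("", ".true"), relationship = "many-to-many") |>
      dplyr::filter(start < end.true, end > start.true)
    expect_identical(nrow(clash), 0L)
  }
  expect_identical(shuffle_instances(inst, regions, n = 10, seed = 3),
                   shuffle_instances(inst, regions, n = 10, seed = 3))
  # with no true instances in a region, placements there are uniform
  inst_far <- tibble::tibble(region_id = "r2", start = 120, end = 132,
                             cwm_id = "m")
  ctrl0 <- shuffle_instances(inst_far, regions, n = 1200, seed = 11)
  r1_starts <- dplyr::filter(ctrl0, region_id == "r1")$start
  bins <- cut(r1_starts, breaks = seq(0, 289, length.out = 8),
              include.lowest = TRUE)
  expect_gt(chisq.test(table(bins))$p.value, 0.01)
})
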