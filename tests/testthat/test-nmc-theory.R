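test_that("accessibility limits and degeneracies hold for every configuration", {
  # TF-free limit is 1/(1+L) regardless of sites
  expect_equal(accessibility_homotypic(0, 1000, 0.5, 3), 1 / 1001, tolerance = 1e-12)
  expect_equal(accessibility_mixed(0, 1000, 0.2, k_la = 50, n_ha = 3, n_la = 2),
               1 / 1001, tolerance = 1e-12)
  expect_equal(accessibility_heterotypic(0, 0, 1000, 0.1, 2, 1), 1 / 1001,
               tolerance = 1e-12)
  # c = 1 cancels the competition: flat at 1/(1+L)
  a <- nmc_alpha_grid()
  expect_equal(accessibility_homotypic(a, 1000, 1, 2), rep(1 / 1001, length(a)),
               tolerance = 1e-12)
  # saturation: n = 1, c = 0.01, L = 1000 gives 1/(1+Lc) = 1/11
  expect_equal(accessibility_homotypic(1e8, 1000, 0.01, 1), 1 / 11,
               tolerance = 1e-5)
})

test_that("mixed-site accessibility reduces to the homotypic form", {
  a <- nmc_alpha_grid(points_per_decade = 5)
  expect_equal(accessibility_mixed(a, 1000, 0.05, k_la = 30, n_ha = 3, n_la = 0),
               accessibility_homotypic(a, 1000, 0.05, 3), tolerance = 1e-12)
  expect_equal(accessibility_mixed(a, 1000, 0.05, k_ha = 1, k_la = 1,
                                   n_ha = 2, n_la = 3),
               accessibility_homotypic(a, 1000, 0.05, 5), tolerance = 1e-12)
})

test_that("two-TF accessibility is symmetric and reduces correctly", {
  a <- nmc_alpha_grid(points_per_decade = 5)
  expect_equal(accessibility_heterotypic(a, 0, 1000, 0.01, 2, 1),
               accessibility_homotypic(a, 1000, 0.01, 2), tolerance = 1e-12)
  # swap symmetry at matched concentrations
  expect_equal(accessibility_heterotypic(3, 7, 1000, 0.02, 2, 1),
               accessibility_heterotypic(7, 3, 1000, 0.02, 1, 2),
               tolerance = 1e-14)
  # two TFs at equal K_D equal the mixed evaluation with matching K's
  expect_equal(accessibility_heterotypic(a, a / 20, 1000, 0.03, 2, 1),
               accessibility_mixed(a, 1000, 0.03, k_ha = 1, k_la = 20,
                                   n_ha = 2, n_la = 1),
               tolerance = 1e-12)
})

test_that("accessibility is monotone in concentration whenever c < 1", {
  set.seed(31)
  a <- nmc_alpha_grid(points_per_decade = 10)
  for (i in 1:20) {
    L <- 10^runif(1, 1, 4)
    cc <- runif(1, 0, 0.99)
    n <- sample(1:5, 1)
    acc <- accessibility_homotypic(a, L, cc, n)
    expect_true(all(diff(acc) >= -1e-12))
    expect_true(all(acc > 0 & acc < 1))
  }
})

test_that("theoretical ED50 matches a dense brute-force grid and scales with K_D", {
  f <- function(a) accessibility_homotypic(a, 1000, 0, 1)
  ed <- curve_ed50(f)
  expect_rel(ed, ed50_brute(f), 1e-3)
  # flat curve (c = 1) is an error
  expect_error(curve_ed50(function(a) accessibility_homotypic(a, 1000, 1, 1)),
               "flat")
  # scaling every K_D by 10 multiplies the ED50 by 10
  f1 <- function(a) accessibility_mixed(a, 1000, 0.01, k_ha = 1, k_la = 10,
                                        n_ha = 1, n_la = 1)
  f10 <- function(a) accessibility_mixed(a, 1000, 0.01, k_ha = 10, k_la = 100,
                                         n_ha = 1, n_la = 1)
  # covariance holds when the titration window is scaled along with the K_D's
  expect_rel(curve_ed50(f10, alpha_range = c(1e-4, 1e6)), 10 * curve_ed50(f1),
             1e-6)
  # tabulated curves go through the interpolation path
  grid <- nmc_alpha_grid()
  tab <- data.frame(alpha = grid, acc = f(grid))
  expect_rel(curve_ed50(tab), ed, 1e-3)
})

test_that("a second site sensitizes only under competition, at decade thresholds", {
  s_strong <- sensitizing_threshold(L = 1000, c = 0.01)
  expect_equal(s_strong$threshold, 10)
  s_weak <- sensitizing_threshold(L = 1000, c = 0.001)
  expect_equal(s_weak$threshold, 1000)
  # without competition every second site buffers
  s0 <- sensitizing_threshold(L = 1000, c = 0)
  expect_true(is.na(s0$threshold))
  expect_false(any(s0$scan$sensitizing))
  # continuous refinement lies below the decade answer
  s_ref <- sensitizing_threshold(L = 1000, c = 0.01, refine = TRUE)
  expect_lt(s_ref$crossover, 10)
  expect_gt(s_ref$crossover, 1)
})

test_that("the sensitizing threshold decreases with competition strength", {
  thr <- vapply(c(0.001, 0.003, 0.01, 0.03), function(cc) {
    sensitizing_threshold(L = 1000, c = cc)$threshold
  }, numeric(1))
  expect_true(all(diff(thr) <= 0))
})

test_that("closed-form two-TF ED50 equals the numeric root and decreases in alpha2", {
  set.seed(17)
  for (i in 1:12) {
    L <- 10^runif(1, 2, 4)
    cc <- runif(1, 0.001, 0.05)
    a2 <- 10^runif(1, -1, 2)
    an <- analytic_ed50_two_tf(a2, L = L, c = cc)
    nu <- curve_ed50(function(a) accessibility_heterotypic(a, a2, L, cc, 1, 1))
    expect_rel(an, nu, 1e-8)
  }
  # alpha2 = 0 reduces to the single-site ED50
  expect_rel(analytic_ed50_two_tf(0, L = 1000, c = 0.01),
             curve_ed50(function(a) accessibility_homotypic(a, 1000, 0.01, 1)),
             1e-8)
  # strictly decreasing in the second TF's concentration for c < 1
  for (cc in c(0, 0.003, 0.02, 0.3)) {
    eds <- vapply(10^seq(-2, 3, by = 0.5), analytic_ed50_two_tf,
                  numeric(1), L = 1000, c = cc)
    expect_true(all(diff(eds) < 0))
  }
})

test_that("Hill-derived fitting targets honour the half-of-top convention", {
  tgt <- dosage_curve_from_hill(50, 1, dosages = c(0, 0.5, 1))
  expect_equal(tgt$response[3], 1)
  expect_equal(tgt$response[2], 0.5 * tgt$response[3], tolerance = 1e-9)
  # steep exponent approaches a step at the ED50
  tgt_steep <- dosage_curve_from_hill(40, 60, dosages = c(0, 0.35, 0.45, 1))
  expect_lt(tgt_steep$response[2], 0.01)
  expect_gt(tgt_steep$response[3], 0.95)
  # round-trip: the generated curve's own modified ED50 returns the input
  set.seed(5)
  for (i in 1:10) {
    h <- runif(1, 1, 5)
    ed <- runif(1, 10, 99 * 0.5^(1 / h))
    fine <- dosage_curve_from_hill(ed, h, dosages = seq(0, 1, length.out = 20001))
    half <- 0.5 * fine$response[nrow(fine)]
    back <- 100 * fine$dosage[which(fine$response >= half)[1]]
    expect_equal(back, ed, tolerance = 0.02)
  }
  # pairs outside the representable region are refused loudly
  expect_error(dosage_curve_from_hill(80, 1), "not representable")
})
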