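sample_sheet <- function(dosages, reps = 1, batches = 1) {
  n <- length(dosages) * reps
  tibble::tibble(sample = sprintf("s%02d", seq_len(n)),
                 dosage = rep(dosages, each = reps),
                 batch = sprintf("b%d", rep_len(seq_len(batches), n)))
}

test_that("CPM normalization follows its definition and is scale invariant", {
  ss <- sample_sheet(c(0, 1))
  counts <- matrix(c(250, 999750, 500, 1999500), ncol = 2,
                   dimnames = list(c("re1", "re2"), NULL))
  dm <- normalize_to_cpm(counts, ss)
  expect_equal(unname(dm$values["re1", 1]), 250)
  # doubling the library with proportional counts leaves CPM unchanged
  expect_equal(unname(dm$values[, 1]), unname(dm$values[, 2]))
  expect_error(normalize_to_cpm(matrix(0, 2, 2), ss), "positive library")
})

test_that("TMM factors match a brute-force trimmed-mean computation", {
  skip_if_not_installed("edgeR")
  tmm_pair <- function(obs, ref, logratioTrim = 0.3, sumTrim = 0.05) {
    nO <- sum(obs); nR <- sum(ref)
    keep <- obs > 0 & ref > 0
    obs <- obs[keep]; ref <- ref[keep]
    logR <- log2((obs / nO) / (ref / nR))
    absE <- (log2(obs / nO) + log2(ref / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
    n <- length(logR)
    loL <- floor(n * logratioTrim) + 1
    loS <- floor(n * sumTrim) + 1
    keep2 <- rank(logR) >= loL & rank(logR) <= n + 1 - loL &
      rank(absE) >= loS & rank(absE) <= n + 1 - loS
    2^(sum(logR[keep2] / v[keep2]) / sum(1 / v[keep2]))
  }
  set.seed(3)
  counts <- matrix(rnbinom(400, mu = 100, size = 10), ncol = 2)
  counts[1, 1] <- 5000  # one strongly differential row
  uq <- apply(counts, 2, function(x) quantile(x, 0.75) / sum(x))
  refcol <- which.min(abs(uq - mean(uq)))
  raw <- vapply(1:2, function(j) tmm_pair(counts[, j], counts[, refcol]),
                numeric(1))
  expected <- raw / exp(mean(log(raw)))
  ss <- sample_sheet(c(0, 1))
  dm <- normalize_to_cpm(counts, ss, method = "TMM")
  lib <- colSums(counts)
  implied <- counts[2, ] * 1e6 / dm$values[2, ] / lib
  expect_equal(unname(implied), expected, tolerance = 1e-10)
})

test_that("batch correction equalizes batch means and is identity for one batch", {
  ss <- sample_sheet(c(0, 0.5, 1), reps = 4, batches = 2)
  vals <- rbind(rep(c(10, 20, 30), each = 4),
                2 * rep(c(10, 20, 30), each = 4))
  delta <- 7
  vals[, ss$batch == "b2"] <- vals[, ss$batch == "b2"] + delta
  dm <- dosage_matrix(vals, ss)
  corr <- correct_batch(dm)
  for (i in 1:2) {
    m1 <- mean(corr$values[i, ss$batch == "b1"])
    m2 <- mean(corr$values[i, ss$batch == "b2"])
    expect_equal(m1, m2, tolerance = 1e-10)
  }
  # overall level preserved
  expect_equal(unname(rowMeans(corr$values)), rowMeans(vals), tolerance = 1e-10)
  ss1 <- sample_sheet(c(0, 0.5, 1), reps = 2, batches = 1)
  dm1 <- dosage_matrix(vals[, 1:6], ss1)
  expect_identical(correct_batch(dm1)$values, dm1$values)
})

test_that("batch correction drives the residual batch F-statistic to zero", {
  cfg <- synthetic_dose_config(n_res = 30, noise_sd = 0.1, batch_sd = 0.4,
                               n_batches = 2, seed = 8)
  sim <- simulate_dose_response(cfg)
  corr <- correct_batch(sim$data)
  batch <- factor(corr$samples$batch)
  fstats <- apply(corr$values, 1, function(v) {
    anova(lm(v ~ batch))[["F value"]][1]
  })
  expect_lt(max(fstats), 1e-10)
})

test_that("a batch confounded with a dosage level triggers a warning", {
  ss <- tibble::tibble(sample = sprintf("s%d", 1:6),
                       dosage = c(0, 0, 1, 1, 0.5, 0.5),
                       batch = c("b1", "b1", "b1", "b1", "b2", "b2"))
  dm <- dosage_matrix(matrix(1:12, nrow = 2), ss)
  expect_warning(correct_batch(dm), "confounded")
})

test_that("preprocessing scales to unit max magnitude and masks constructed outliers", {
  v <- c(rep(8, 7), -8)
  prep <- preprocess_for_fit(v)
  expect_equal(max(abs(prep$values)), 1)
  expect_true(all(prep$keep))
  # 19 near-identical values and one at 10x: exactly that one masked
  v2 <- c(rnorm(19, 1, 0.01), 10)
  prep2 <- preprocess_for_fit(v2)
  expect_identical(which(!prep2$keep), 20L)
  expect_identical(prep2$n_outliers, 1L)
  # degenerate all-zero vector is flagged, not fitted
  prep3 <- preprocess_for_fit(rep(0, 6))
  expect_false(is.na(prep3$reason))
})

test_that("Hill fitting recovers noiseless curves and selects models sensibly", {
  d <- rep(c(0, 0.22, 0.45, 0.75, 1), each = 4)
  # data from the fixed-endpoint family: plateau parameters match the means
  y2 <- 0.1 + 0.8 * d^2 / (0.5^2 + d^2)
  f2 <- fit_hill(y2, d)
  expect_true(f2$converged)
  expect_rel(f2$K, 0.5, 1e-6)
  expect_rel(f2$h, 2, 1e-6)
  # plateau well above the dosage-1 mean forces the free-maximum model
  y3 <- 2 * d / (0.8 + d)
  f3 <- fit_hill(y3, d)
  expect_identical(f3$model, "three_param")
  expect_lte(f3$aic3, f3$aic2 - 2)
  expect_rel(f3$K, 0.8, 1e-4)
  expect_rel(f3$y_max, 2, 1e-4)
  # a flat response never returns a silent number
  ff <- fit_hill(rep(0.7, length(d)), d)
  expect_false(ff$converged)
  expect_match(ff$reason, "flat")
})

test_that("modified ED50 matches closed forms and stays capped at 100", {
  d <- rep(c(0, 0.25, 0.5, 0.75, 1), each = 2)
  # K = 0.5, h = 1, y_min = 0: y(1) = 2/3, half-level 1/3, root at 0.25
  f <- fit_hill(d / (0.5 + d), d)
  expect_equal(modified_ed50(f), 25, tolerance = 1e-6)
  # steep curve approaches a step at K: ED50 -> 100 K
  fs <- fit_hill(d^30 / (0.4^30 + d^30), d)
  expect_equal(modified_ed50(fs), 40, tolerance = 0.5)
  # property: capped at 100 for random convergent fits, and equal to a
  # brute-force dense grid root
  set.seed(42)
  for (i in 1:25) {
    K <- runif(1, 0.05, 5)
    h <- runif(1, 0.5, 6)
    b <- runif(1, 0, 0.2)
    fit <- fit_hill(b + (1 - b) * d^h / (K^h + d^h), d)
    if (!fit$converged) next
    ed <- modified_ed50(fit)
    if (is.na(ed)) next
    expect_lte(ed, 100)
    grid <- seq(1e-6, 1, length.out = 100001)
    yy <- predict(fit, data.frame(d = grid))
    brute <- 100 * grid[which(yy >= 0.5 * yy[length(yy)])[1]]
    expect_equal(ed, brute, tolerance = 2e-3)
  }
})

test_that("responses are classified buffered below 30 and sensitive at or above", {
  expect_identical(classify_response(19.8), "buffered")
  expect_identical(classify_response(45.3), "sensitive")
  expect_message(cl <- classify_response(30), "threshold")
  expect_identical(cl, "sensitive")
  expect_identical(classify_response(c(10, NA, 50)),
                   c("buffered", NA, "sensitive"))
})

test_that("replicate-split ED50 reproducibility improves as noise shrinks", {
  split_cor <- function(noise) {
    cfg <- synthetic_dose_config(n_res = 30, noise_sd = noise, batch_sd = 0,
                                 seed = 11)
    sim <- simulate_dose_response(cfg)
    s <- sim$data$samples
    halves <- lapply(split(seq_len(nrow(s)), s$dosage), function(i) {
      list(i[c(1, 2)], i[c(3, 4)])
    })
    fit_half <- function(k) {
      idx <- unlist(lapply(halves, `[[`, k))
      fit_dose_response(dosage_matrix(sim$data$values[, idx], s[idx, ]),
                        batch_correct = FALSE)$ed50_mod
    }
    e1 <- fit_half(1)
    e2 <- fit_half(2)
    ok <- !is.na(e1) & !is.na(e2)
    cor(e1[ok], e2[ok])
  }
  cors <- vapply(c(0.3, 0.1, 0.02), split_cor, numeric(1))
  expect_true(all(diff(cors) > 0))
})
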