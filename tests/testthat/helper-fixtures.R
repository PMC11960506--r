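# small motif fixtures and brute-force oracles used across test files

make_box_cwm <- function(id, base_rows, width, strength = 1, bg = -0.05,
                         polarity = "unlabeled") {
  m <- matrix(bg, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(base_rows)) m[base_rows[j], j] <- strength
  cwm(id, m, polarity = polarity)
}

# a PWM concentrated on a consensus with probability p_major
make_sharp_pwm <- function(id, consensus, p_major = 0.85) {
  w <- nchar(consensus)
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix((1 - p_major) / 3, 4, w)
  for (j in seq_len(w)) m[idx[j], j] <- p_major
  pwm(id, m)
}

# naive double-loop continuous Jaccard, the oracle for cwm_jaccard()
jaccard_brute <- function(a, b) {
  num <- 0
  den <- 0
  for (i in seq_along(a)) {
    s <- if (a[i] * b[i] >= 0) 1 else -1
    num <- num + min(abs(a[i]), abs(b[i])) * s
    den <- den + max(abs(a[i]), abs(b[i]))
  }
  if (den == 0) 0 else num / den
}

# exhaustive enumeration of all w-mers with their background probabilities
# and lattice-quantized PWM log-odds scores: the oracle for the
# score-distribution DP (same per-position integer lattice)
pwm_enumerate <- function(p, granularity = 1e-4) {
  m <- pmax(p$matrix, 1e-4)
  m <- sweep(m, 2, colSums(m), `/`)
  S <- log(sweep(m, 1, p$background, `/`))
  w <- ncol(S)
  mins <- apply(S, 2, min)
  ints <- round(sweep(S, 2, mins, `-`) / granularity)
  combos <- expand.grid(rep(list(1:4), w))
  qscore <- apply(combos, 1, function(ii) {
    sum(ints[cbind(ii, seq_len(w))]) * granularity + sum(mins)
  })
  prob <- apply(combos, 1, function(ii) prod(p$background[ii]))
  list(score = qscore, prob = prob)
}

# dense-grid brute-force theoretical ED50, the oracle for curve_ed50()
ed50_brute <- function(f, lo = 1e-5, hi = 1e5, n_grid = 200001) {
  a <- 10^seq(log10(lo), log10(hi), length.out = n_grid)
  acc <- f(a)
  level <- acc[1] + 0.5 * (acc[length(acc)] - acc[1])
  a[which(acc >= level)[1]]
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
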