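#' Simulate background sequences with planted PWM sites
#'
#' Generates i.i.d. background sequences and inserts motif sites - either
#' the PWM consensus or draws from the PWM - at random non-overlapping
#' positions, recording every insertion.
#'
#' @param pwms A [pwm()] or list of them.
#' @param n_seq Number of sequences.
#' @param length Sequence length.
#' @param planted_per_seq Insertions per sequence (cycled over the PWMs).
#' @param background Base frequencies (A, C, G, T); must sum to 1.
#' @param mode `"consensus"` inserts the per-column argmax base;
#'   `"sample"` draws each base from the PWM column.
#' @param seed RNG seed.
#'
#' @return A list with `sequences` (named character vector) and `truth`
#'   (tibble: `seq_id`, `pwm_id`, `offset` (0-based), `width`).
#' @export
simulate_sequences <- function(pwms, n_seq = 10, length = 200,
                               planted_per_seq = 1,
                               background = rep(0.25, 4),
                               mode = c("consensus", "sample"), seed = 1L) {
  mode <- match.arg(mode)
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (abs(sum(background) - 1) > 1e-6) abort("`background` must sum to 1.")
  widths <- purrr::map_int(pwms, ~ ncol(.x$matrix))
  if (planted_per_seq > 0 && max(widths) > length) {
    abort("planted motif wider than the sequence.")
  }
  bases <- c("A", "C", "G", "T")
  set.seed(seed)
  truth <- list()
  seqs <- character(n_seq)
  for (i in seq_len(n_seq)) {
    x <- sample(bases, length, replace = TRUE, prob = background)
    placed <- integer(0)
    placed_w <- integer(0)
    k <- 0
    while (k < planted_per_seq) {
      pw <- pwms[[(k %% length(pwms)) + 1]]
      w <- ncol(pw$matrix)
      ok <- FALSE
      for (try in 1:200) {
        off <- sample.int(length - w + 1, 1) - 1L
        if (!any(placed < off + w & placed + placed_w > off)) { ok <- TRUE; break }
      }
      if (!ok) break
      ins <- if (mode == "consensus") {
        bases[apply(pw$matrix, 2, which.max)]
      } else {
        vapply(seq_len(w), function(j) sample(bases, 1, prob = pw$matrix[, j]),
               character(1))
      }
      x[off + seq_len(w)] <- ins
      placed <- c(placed, off)
      placed_w <- c(placed_w, w)
      truth[[base::length(truth) + 1]] <- tibble(
        seq_id = sprintf("seq_%03d", i), pwm_id = pw$id,
        offset = off, width = w)
      k <- k + 1
    }
    seqs[i] <- paste(x, collapse = "")
  }
  names(seqs) <- sprintf("seq_%03d", seq_len(n_seq))
  truth <- if (base::length(truth)) bind_rows(truth) else
    tibble(seq_id = character(), pwm_id = character(),
           offset = integer(), width = integer())
  list(sequences = seqs, truth = truth)
}
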