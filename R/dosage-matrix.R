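#' Construct a dosage matrix
#'
#' Container for an RE-by-sample matrix of normalized chromatin accessibility
#' (CPM scale) together with the per-sample relative TF dosage and batch
#' labels. This is the unit of data consumed by [correct_batch()] and
#' [fit_dose_response()].
#'
#' @param values Numeric matrix, regulatory elements (rows) by samples
#'   (columns). Row names are RE identifiers; column names are sample ids.
#' @param samples Data frame with one row per column of `values` and columns
#'   `sample`, `dosage` (relative TF dosage in `[0, 1]`) and `batch`.
#'
#' @return An object of class `dosage_matrix`: a list with elements `values`
#'   (the matrix) and `samples` (a tibble).
#' @export
dosage_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (REs x samples).")
  }
  samples <- as_tibble(samples)
  req <- c("sample", "dosage", "batch")
  if (!all(req %in% names(samples))) {
    abort("`samples` must have columns `sample`, `dosage`, `batch`.")
  }
  if (nrow(samples) != ncol(values)) {
    abort("`samples` must have one row per column of `values`.")
  }
  if (any(samples$dosage < 0 | samples$dosage > 1)) {
    abort("`dosage` must lie in [0, 1].")
  }
  if (!any(samples$dosage == 0) || !any(samples$dosage == 1)) {
    abort("both endpoint dosages (0 and 1) must be present for fixed-endpoint fitting.")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("re_%05d", seq_len(nrow(values)))
  }
  colnames(values) <- samples$sample
  structure(list(values = values, samples = samples), class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix> %d REs x %d samples\n", nrow(x$values), ncol(x$values)))
  cat(sprintf("  dosages: %s\n", paste(sort(unique(x$samples$dosage)), collapse = ", ")))
  cat(sprintf("  batches: %s\n", paste(unique(x$samples$batch), collapse = ", ")))
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$values)

#' @rdname dosage_matrix
#' @param x A `dosage_matrix`.
#' @param ... Unused.
#' @method as_tibble dosage_matrix
#' @export
as_tibble.dosage_matrix <- function(x, ...) {
  tibble(
    re_id = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(x$samples$sample, each = nrow(x$values)),
    dosage = rep(x$samples$dosage, each = nrow(x$values)),
    batch = rep(x$samples$batch, each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' Normalize raw ATAC counts to CPM
#'
#' Scales each sample (column) to counts per million, optionally with
#' trimmed-mean-of-M-values (TMM) effective library sizes. Column `j` is
#' scaled by `1e6 / (library_size_j * factor_j)`; with `method = "none"` all
#' factors are 1 (plain CPM).
#'
#' @param raw_counts Nonnegative integer matrix, REs by samples.
#' @param samples Sample sheet as for [dosage_matrix()].
#' @param method `"none"` for plain CPM or `"TMM"` for trimmed-mean-of-M
#'   normalization factors (computed with edgeR).
#' @param scale_factors Optional explicit per-sample factors, overriding
#'   `method`.
#'
#' @return A [dosage_matrix()] of CPM values.
#' @export
normalize_to_cpm <- function(raw_counts, samples, method = c("none", "TMM"),
                             scale_factors = NULL) {
  method <- match.arg(method)
  raw_counts <- as.matrix(raw_counts)
  if (any(raw_counts < 0)) abort("counts must be nonnegative.")
  lib <- colSums(raw_counts)
  if (any(lib <= 0)) abort("every sample must have a positive library size.")
  f <- if (!is.null(scale_factors)) {
    if (length(scale_factors) != ncol(raw_counts)) {
      abort("`scale_factors` must have one entry per sample.")
    }
    scale_factors
  } else if (method == "TMM") {
    if (!requireNamespace("edgeR", quietly = TRUE)) {
      abort("TMM normalization requires the edgeR package.")
    }
    edgeR::calcNormFactors(raw_counts, method = "TMM")
  } else {
    rep(1, ncol(raw_counts))
  }
  cpm <- sweep(raw_counts, 2, 1e6 / (lib * f), `*`)
  dosage_matrix(cpm, samples)
}

#' Remove differentiation-batch effects by linear regression
#'
#' Per RE, replaces values by the residuals of a least-squares regression on
#' batch indicators plus the RE's grand mean, so that batch means are
#' equalized while the overall level is preserved. With a single batch this
#' is the identity.
#'
#' @param x A [dosage_matrix()].
#'
#' @return A `dosage_matrix` of corrected values.
#' @export
correct_batch <- function(x) {
  stopifnot(inherits(x, "dosage_matrix"))
  batch <- factor(x$samples$batch)
  if (nlevels(batch) < 2) return(x)
  # a batch observed at exactly one dosage level that occurs nowhere else is
  # confounded: regressing it out removes dose signal
  tab <- table(batch, x$samples$dosage)
  conf <- vapply(seq_len(nrow(tab)), function(i) {
    j <- which(tab[i, ] > 0)
    length(j) == 1 && sum(tab[, j] > 0) == 1
  }, logical(1))
  if (any(conf)) {
    warn(sprintf(
      "batch(es) %s are confounded 1:1 with a dosage level; correction removes dose signal there.",
      paste(levels(batch)[conf], collapse = ", ")
    ))
  }
  design <- stats::model.matrix(~batch)
  qrd <- qr(design)
  # residuals of every RE against the batch design, plus the grand mean
  res <- t(qr.resid(qrd, t(x$values)))
  corrected <- res + rowMeans(x$values)
  dimnames(corrected) <- dimnames(x$values)
  dosage_matrix(corrected, x$samples)
}
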