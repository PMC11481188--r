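#' Filter transcripts with low total counts
#'
#' Removes transcripts whose count sum over all samples is strictly below
#' `min_total` (default 30), the usual expression floor before network
#' analysis. Row order of the survivors is preserved.
#'
#' @param counts Non-negative numeric matrix, transcripts x samples.
#' @param min_total Minimum row sum to retain a transcript.
#' @return The filtered count matrix.
#' @export
filter_low_counts <- function(counts, min_total = 30) {
  assert_matrix(counts, "counts")
  if (any(counts < 0)) stop_invalid("counts must be non-negative")
  counts[rowSums(counts) >= min_total, , drop = FALSE]
}

#' TMM normalization of a count matrix
#'
#' Computes per-sample scaling factors by the trimmed mean of M-values
#' (weighted mean of gene-wise log-ratios against a reference sample after
#' trimming the most extreme 30% of M values and 5% of A values, with
#' inverse-variance weights), then returns log2 normalized expression
#' `log2((count + pseudocount) / (library size x factor) * 1e6)`.
#' Factor computation is delegated to [edgeR::calcNormFactors()]; factors are
#' scaled so their geometric mean is 1.
#'
#' @param counts Count matrix with >= 2 samples, each with a positive total.
#' @param pseudocount Added to counts before the log (default 0.5).
#' @return Object of class `normalized_expression`: list with `matrix`
#'   (log2 normalized values), `scaling_factors`, `lib_sizes`,
#'   `kept_transcripts`.
#' @export
tmm_normalize <- function(counts, pseudocount = 0.5) {
  assert_matrix(counts, "counts")
  if (ncol(counts) < 2) stop_invalid("TMM needs >= 2 samples")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop_invalid("every sample needs a positive library size")
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  if (any(!is.finite(f) | f <= 0))
    stop_degenerate("TMM factors undefined: a sample shares no positively ",
                    "expressed transcripts with the reference")
  norm <- log2(sweep(counts + pseudocount, 2, lib * f, "/") * 1e6)
  structure(list(matrix = norm, scaling_factors = f, lib_sizes = lib,
                 kept_transcripts = rownames(counts)),
            class = "normalized_expression")
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat("Normalized expression:", nrow(x$matrix), "transcripts x",
      ncol(x$matrix), "samples\n")
  cat("TMM factors:", paste(sprintf("%.3f", head(x$scaling_factors, 6)),
                            collapse = " "),
      if (length(x$scaling_factors) > 6) "...\n" else "\n")
  invisible(x)
}

#' Scale each transcript to mean 0, standard deviation 1
#'
#' Uses the population (divide by n) convention; constant rows map to zero.
#' Scaling is idempotent up to floating-point tolerance.
#'
#' @param mat Numeric matrix, transcripts x samples (>= 2 samples).
#' @return Matrix of the same shape with standardized rows.
#' @export
scale_per_transcript <- function(mat) {
  assert_matrix(mat, "matrix")
  if (ncol(mat) < 2) stop_invalid("scaling needs >= 2 samples")
  mu <- rowMeans(mat)
  s <- sqrt(rowMeans((mat - mu)^2))
  out <- (mat - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out
}

#' Full preprocessing step: filter then normalize
#'
#' @param counts Raw count matrix.
#' @param min_total Low-count filter threshold (see [filter_low_counts()]).
#' @param pseudocount Passed to [tmm_normalize()].
#' @return A `normalized_expression` object restricted to kept transcripts.
#' @export
preprocess_counts <- function(counts, min_total = 30, pseudocount = 0.5) {
  tmm_normalize(filter_low_counts(counts, min_total), pseudocount = pseudocount)
}
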