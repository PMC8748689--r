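#' Single-sample GSEA scores for a gene signature
#'
#' For each sample, genes are ranked by expression (average ranks for ties;
#' higher expression = higher rank) and the raw enrichment score is the sum,
#' over all list positions, of the difference between the weighted empirical
#' CDF of signature genes (weights \code{rank^alpha}) and the unweighted CDF
#' of the remaining genes. Because only within-sample ranks enter, the raw
#' ES is invariant under any strictly monotone transform of a sample's
#' expression values. Raw scores are normalized across the cohort by the
#' range (max - min) of raw ES to give the NES.
#'
#' @param expr Numeric gene x sample matrix with dimnames; >= 2 samples.
#' @param signature Character vector of signature genes (or a
#'   \code{gene_set}); at least one must be present in the matrix.
#' @param alpha Rank-weighting exponent, default 0.25.
#' @return Data frame with columns \code{sample}, \code{es} (raw) and
#'   \code{nes}; attributes \code{alpha} and \code{n_signature} (overlap
#'   size used).
#' @export
ssgsea_scores <- function(expr, signature, alpha = 0.25) {
  if (inherits(signature, "gene_set")) signature <- signature$members
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (ncol(expr) < 2L) stop("ssGSEA normalization needs >= 2 samples")
  in_sig <- rownames(expr) %in% signature
  k <- sum(in_sig)
  N <- nrow(expr)
  if (k == 0L) stop("empty signature overlap with expression matrix")
  if (k >= N) stop("signature cannot cover the whole gene universe")
  raw <- vapply(seq_len(ncol(expr)), function(j) {
    x <- expr[, j]
    r <- rank(x, ties.method = "average")
    # walk the list from highest to lowest expression; deterministic ties
    ord <- order(-r, rownames(expr))
    hit <- in_sig[ord]
    w <- r[ord]^alpha
    w[!hit] <- 0
    cdf_hit <- cumsum(w) / sum(w)
    cdf_miss <- cumsum(!hit) / (N - k)
    sum(cdf_hit - cdf_miss)
  }, numeric(1))
  names(raw) <- colnames(expr)
  rng <- max(raw) - min(raw)
  nes <- if (rng > 0) raw / rng else rep(0, length(raw))
  out <- data.frame(sample = colnames(expr), es = unname(raw),
                    nes = unname(nes), stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "n_signature") <- k
  out
}
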