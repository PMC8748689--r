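#' Tag an expression matrix with its unit
#'
#' @param mat Numeric gene x sample matrix.
#' @param unit One of \code{"counts"}, \code{"TPM"}, \code{"normalized"}.
#' @return The matrix with a \code{unit} attribute.
#' @export
expression_matrix <- function(mat, unit = c("counts", "TPM", "normalized")) {
  unit <- match.arg(unit)
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(mat))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample ids")
  if (unit %in% c("counts", "TPM") && any(mat < 0, na.rm = TRUE)) {
    stop(sprintf("negative entries not allowed for unit '%s'", unit))
  }
  attr(mat, "unit") <- unit
  mat
}

expr_unit <- function(mat) {
  u <- attr(mat, "unit")
  if (is.null(u)) "normalized" else u
}

#' Convert raw counts to transcripts per million
#'
#' \code{TPM = 1e6 * (count / length) / sum(count / length)} per sample, so
#' every sample column sums to one million.
#'
#' @param counts Gene x sample count matrix.
#' @param gene_lengths Named numeric vector of gene lengths in bases,
#'   covering every gene in \code{counts}.
#' @return TPM matrix (unit attribute \code{"TPM"}).
#' @export
counts_to_tpm <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  missing <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing) > 0L) {
    stop(sprintf("missing gene length(s): %s",
                 paste(utils::head(missing, 10), collapse = ", ")))
  }
  len <- gene_lengths[rownames(counts)]
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("gene lengths must be positive")
  }
  rate <- counts / len
  tpm <- sweep(rate, 2L, colSums(rate), "/") * 1e6
  expression_matrix(tpm, "TPM")
}

#' Correlate each gene's expression with an immune-infiltration score
#'
#' Computes, across the samples shared between the expression matrix and
#' the immune score vector, the correlation of each gene's expression with
#' the score. Spearman rank correlation is the default. Raw counts/TPM are
#' quantile-normalized across samples before correlating (skipped for
#' pre-normalized input); zero-variance genes are returned as NA with a
#' missing flag.
#'
#' @param expr Gene x sample matrix (ideally from
#'   \code{\link{expression_matrix}}).
#' @param immune Named numeric vector of per-sample immune scores
#'   (externally computed, e.g. ESTIMATE).
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @param quantile_normalize Override the unit-based default for quantile
#'   normalization.
#' @return Data frame (class \code{immune_correlation_profile}) with
#'   columns \code{gene}, \code{correlation}, \code{missing}; attributes
#'   \code{method}, \code{n_samples}, \code{quantile_normalized}.
#' @export
immune_correlation <- function(expr, immune,
                               method = c("spearman", "pearson"),
                               quantile_normalize = NULL) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  shared <- intersect(colnames(expr), names(immune))
  if (length(shared) < 3L) stop("fewer than 3 shared samples")
  if (any(!is.finite(immune[shared]))) stop("immune scores must be finite")
  if (is.null(quantile_normalize)) {
    quantile_normalize <- expr_unit(expr) %in% c("counts", "TPM")
  }
  m <- expr[, shared, drop = FALSE]
  if (quantile_normalize) m <- limma::normalizeQuantiles(m)
  v <- apply(m, 1L, stats::var)
  cc <- rep(NA_real_, nrow(m))
  ok <- is.finite(v) & v > 0
  if (any(ok)) {
    cc[ok] <- as.numeric(stats::cor(t(m[ok, , drop = FALSE]),
                                    immune[shared], method = method))
  }
  out <- data.frame(gene = rownames(m), correlation = cc, missing = !ok,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "n_samples") <- length(shared)
  attr(out, "quantile_normalized") <- quantile_normalize
  class(out) <- c("immune_correlation_profile", "data.frame")
  out
}

corr_vector <- function(corr) {
  if (inherits(corr, "immune_correlation_profile") || is.data.frame(corr)) {
    v <- corr$correlation
    names(v) <- corr$gene
    v
  } else {
    v <- corr
    if (is.null(names(v))) stop("correlations must be named by gene")
    v
  }
}

assoc_frame <- function(assoc) {
  if (inherits(assoc, "association_scores")) assoc <- assoc$scores
  if (!is.data.frame(assoc)) assoc <- rank_and_percentile(assoc)
  assoc
}

#' Select immune-positive and immune-negative associated genes
#'
#' Restricts to the top fraction of the association ranking and splits it by
#' immune correlation: genes with correlation at or above +threshold form
#' the immune-positive set, those at or below -threshold the immune-negative
#' set. Ties at the top-fraction boundary are broken lexicographically.
#'
#' @param assoc A \code{ranked_list} (or named association score vector).
#' @param corr An \code{immune_correlation_profile} (or named correlation
#'   vector).
#' @param top_fraction Fraction of the association ranking retained,
#'   default 0.10.
#' @param corr_threshold Absolute correlation cutoff, default 0.2.
#' @return An object of class \code{immune_gene_selection}: list with
#'   \code{positive}, \code{negative} (character vectors), \code{top_genes}
#'   and the parameters.
#' @export
select_immune_genes <- function(assoc, corr, top_fraction = 0.10,
                                corr_threshold = 0.2) {
  assoc <- assoc_frame(assoc)
  cv <- corr_vector(corr)
  shared <- intersect(assoc$gene, names(cv))
  if (length(shared) == 0L) stop("empty shared gene universe")
  a <- assoc[assoc$gene %in% shared, , drop = FALSE]
  a <- a[order(-a$score, a$gene), , drop = FALSE]
  n_top <- max(1L, floor(top_fraction * nrow(a)))
  top_genes <- a$gene[seq_len(n_top)]
  cc <- cv[top_genes]
  pos <- top_genes[!is.na(cc) & cc >= corr_threshold]
  neg <- top_genes[!is.na(cc) & cc <= -corr_threshold]
  if (length(pos) == 0L && length(neg) == 0L) {
    message("select_immune_genes: no gene passed the correlation threshold")
  }
  structure(list(positive = sort(pos), negative = sort(neg),
                 top_genes = top_genes, top_fraction = top_fraction,
                 corr_threshold = corr_threshold),
            class = "immune_gene_selection")
}

#' @export
print.immune_gene_selection <- function(x, ...) {
  cat(sprintf(
    "immune_gene_selection: %d positive, %d negative (top %.0f%%, |corr| >= %g)\n",
    length(x$positive), length(x$negative), 100 * x$top_fraction,
    x$corr_threshold))
  invisible(x)
}

#' Select the MIAS gene signature by rank product
#'
#' Merges, for every gene of the shared universe, its rank in the network
#' association prediction (r1, 1 = most associated) and its rank by immune
#' correlation (r2, 1 = most positively correlated) into the rank-product
#' score \code{MR = sqrt(r1 * r2)}. The signature is the \code{n_signature}
#' genes with the smallest MR; boundary ties are broken lexicographically.
#'
#' @param assoc A \code{ranked_list} or named association score vector.
#' @param corr An \code{immune_correlation_profile} or named correlation
#'   vector.
#' @param n_signature Signature size, default 100.
#' @return An object of class \code{mias_signature}: data frame with
#'   columns \code{gene}, \code{r1}, \code{r2}, \code{mr}, sorted by
#'   ascending \code{mr}.
#' @export
select_mias_signature <- function(assoc, corr, n_signature = 100L) {
  assoc <- assoc_frame(assoc)
  cv <- corr_vector(corr)
  shared <- intersect(assoc$gene, names(cv)[!is.na(cv)])
  if (length(shared) < n_signature) {
    stop(sprintf("shared universe (%d) smaller than signature size (%d)",
                 length(shared), n_signature))
  }
  sc <- assoc$score
  names(sc) <- assoc$gene
  sc <- sc[shared]
  cc <- cv[shared]
  r1 <- rank(-sc, ties.method = "average")
  r2 <- rank(-cc, ties.method = "average")
  mr <- sqrt(r1 * r2)
  ord <- order(mr, shared)
  idx <- ord[seq_len(n_signature)]
  out <- data.frame(gene = shared[idx], r1 = unname(r1[idx]),
                    r2 = unname(r2[idx]), mr = unname(mr[idx]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("mias_signature", "data.frame")
  out
}

#' Score samples with the MIAS immunoscore
#'
#' The MIAS of a sample is the ssGSEA normalized enrichment score of the
#' signature genes in that sample's expression profile; a higher MIAS
#' predicts a higher likelihood of anti-PD-1 response. When comparing
#' cohorts profiled on different platforms, restrict \code{universe} to the
#' genes covered by all platforms.
#'
#' @param expr Gene x sample matrix (TPM or normalized).
#' @param signature A \code{mias_signature}, \code{gene_set} or character
#'   vector of signature genes.
#' @param universe Optional character vector restricting the gene universe.
#' @param min_overlap Minimum fraction of signature genes that must be
#'   present in the (restricted) matrix, default 0.5.
#' @param alpha ssGSEA weighting exponent, default 0.25.
#' @return Data frame with columns \code{sample}, \code{mias}; attribute
#'   \code{n_signature_used}.
#' @export
mias_score <- function(expr, signature, universe = NULL,
                       min_overlap = 0.5, alpha = 0.25) {
  if (inherits(signature, "mias_signature")) signature <- signature$gene
  if (inherits(signature, "gene_set")) signature <- signature$members
  expr <- as.matrix(expr)
  if (!is.null(universe)) {
    expr <- expr[intersect(rownames(expr), universe), , drop = FALSE]
  }
  present <- intersect(signature, rownames(expr))
  frac <- length(present) / length(signature)
  if (frac < min_overlap) {
    stop(sprintf(
      "signature overlap too small: %d/%d genes (%.0f%%) present, need >= %.0f%%",
      length(present), length(signature), 100 * frac, 100 * min_overlap))
  }
  ss <- ssgsea_scores(expr, present, alpha = alpha)
  out <- data.frame(sample = ss$sample, mias = ss$nes,
                    stringsAsFactors = FALSE)
  attr(out, "n_signature_used") <- length(present)
  out
}

#' Integrate two per-sample predictors by rank product
#'
#' Both score vectors must be oriented so that a higher score predicts
#' response. Each sample's ranks under the two predictors (1 = highest
#' score) are merged as \code{sqrt(rank_a * rank_b)}; a smaller merged rank
#' means a more confident response prediction.
#'
#' @param scores_a,scores_b Named numeric per-sample score vectors.
#' @return Data frame with columns \code{sample}, \code{rank_a},
#'   \code{rank_b}, \code{rank_product}, sorted ascending by
#'   \code{rank_product}.
#' @export
integrate_predictions <- function(scores_a, scores_b) {
  if (is.null(names(scores_a)) || is.null(names(scores_b))) {
    stop("scores must be named by sample")
  }
  shared <- intersect(names(scores_a), names(scores_b))
  if (length(shared) < 2L) stop("need >= 2 shared samples")
  ra <- rank(-scores_a[shared], ties.method = "average")
  rb <- rank(-scores_b[shared], ties.method = "average")
  rp <- sqrt(ra * rb)
  out <- data.frame(sample = shared, rank_a = unname(ra),
                    rank_b = unname(rb), rank_product = unname(rp),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank_product, out$sample), , drop = FALSE]
  rownames(out) <- NULL
  out
}
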