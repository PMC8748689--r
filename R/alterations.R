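#' Call copy-number states from log2 ratios
#'
#' Gene-level log2 copy-number ratios strictly above 0.5 are called gains
#' and strictly below -0.5 losses; everything else (including the
#' boundaries) is neutral.
#'
#' @param cnv Numeric gene x sample matrix (or vector) of log2 ratios.
#' @return Character object of the same shape with entries in
#'   \code{c("loss", "neutral", "gain")}.
#' @export
call_cnv_states <- function(cnv) {
  if (any(!is.finite(as.numeric(cnv)))) stop("log2 ratios must be finite")
  states <- ifelse(cnv > 0.5, "gain", ifelse(cnv < -0.5, "loss", "neutral"))
  if (is.matrix(cnv)) {
    dim(states) <- dim(cnv)
    dimnames(states) <- dimnames(cnv)
  } else {
    names(states) <- names(cnv)
  }
  states
}

#' Recurrently altered genes among the immune gene selection
#'
#' Counts, for each immune-positive or immune-negative gene, the samples
#' carrying a mutation, a copy-number gain (Amp) or a loss (Del), and keeps
#' genes with at least \code{min_samples} altered samples in at least one
#' alteration type.
#'
#' @param selection An \code{immune_gene_selection}.
#' @param mutations Data frame with columns \code{gene}, \code{sample}
#'   (one row per mutation call); may be NULL.
#' @param cnv_states Character gene x sample matrix from
#'   \code{\link{call_cnv_states}}; may be NULL.
#' @param min_samples Recurrence threshold, default 3.
#' @return Data frame with columns \code{gene}, \code{direction}
#'   (\code{"immune_positive"}/\code{"immune_negative"}), \code{n_mut},
#'   \code{n_amp}, \code{n_del}.
#' @export
recurrent_alterations <- function(selection, mutations = NULL,
                                  cnv_states = NULL, min_samples = 3L) {
  stopifnot(inherits(selection, "immune_gene_selection"))
  genes <- c(selection$positive, selection$negative)
  direction <- rep(c("immune_positive", "immune_negative"),
                   c(length(selection$positive), length(selection$negative)))
  n_mut <- n_amp <- n_del <- integer(length(genes))
  if (!is.null(mutations) && nrow(mutations) > 0L) {
    mut <- unique(mutations[, c("gene", "sample")])
    tab <- table(mut$gene)
    hit <- genes %in% names(tab)
    n_mut[hit] <- as.integer(tab[genes[hit]])
  }
  if (!is.null(cnv_states)) {
    present <- intersect(genes, rownames(cnv_states))
    amp <- rowSums(cnv_states[present, , drop = FALSE] == "gain")
    del <- rowSums(cnv_states[present, , drop = FALSE] == "loss")
    n_amp[match(present, genes)] <- as.integer(amp)
    n_del[match(present, genes)] <- as.integer(del)
  }
  out <- data.frame(gene = genes, direction = direction,
                    n_mut = n_mut, n_amp = n_amp, n_del = n_del,
                    stringsAsFactors = FALSE)
  keep <- pmax(out$n_mut, out$n_amp, out$n_del) >= min_samples
  out <- out[keep, , drop = FALSE]
  out <- out[order(-pmax(out$n_mut, out$n_amp, out$n_del), out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map drugs onto immune-negative associated genes
#'
#' Joins a drug-target table against the immune-negative gene set (the
#' candidate therapeutic targets: genes whose high expression tracks low
#' immune infiltration), optionally annotating each target with its
#' association percentile and immune correlation.
#'
#' @param selection An \code{immune_gene_selection}.
#' @param drug_targets Data frame with columns \code{drug}, \code{target}.
#' @param assoc Optional \code{ranked_list} for percentile annotation.
#' @param corr Optional \code{immune_correlation_profile} for correlation
#'   annotation.
#' @return Data frame with columns \code{drug}, \code{target},
#'   \code{immune_correlation}, \code{association_percentile}.
#' @export
map_drug_targets <- function(selection, drug_targets, assoc = NULL,
                             corr = NULL) {
  stopifnot(inherits(selection, "immune_gene_selection"))
  stopifnot(all(c("drug", "target") %in% colnames(drug_targets)))
  hit <- drug_targets[drug_targets$target %in% selection$negative, ,
                      drop = FALSE]
  out <- data.frame(drug = as.character(hit$drug),
                    target = as.character(hit$target),
                    stringsAsFactors = FALSE)
  out$immune_correlation <- rep(NA_real_, nrow(out))
  out$association_percentile <- rep(NA_real_, nrow(out))
  if (!is.null(corr) && nrow(out) > 0L) {
    cv <- corr_vector(corr)
    out$immune_correlation <- unname(cv[out$target])
  }
  if (!is.null(assoc) && nrow(out) > 0L) {
    a <- assoc_frame(assoc)
    out$association_percentile <-
      a$percentile[match(out$target, a$gene)]
  }
  out <- out[order(out$target, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}
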