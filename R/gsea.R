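# Weighted Kolmogorov-Smirnov running-sum machinery shared by the preranked
# association analysis and the two-group deregulation analysis.

# Evaluate both scopes of the RNG: run expr under a fixed seed without
# disturbing the caller's RNG stream.
with_rng_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic descending order of a named score vector; ties broken
# lexicographically by gene so that all downstream walks are reproducible.
ordered_universe <- function(scores) {
  if (inherits(scores, "ranked_list")) {
    s <- scores$score
    names(s) <- scores$gene
    scores <- s
  }
  if (is.null(names(scores))) stop("scores must be named by gene")
  ord <- order(-scores, names(scores))
  scores[ord]
}

# ES from sorted hit positions and per-hit weights in a universe of size N.
# The running sum increments by w/sum(w) at hits and decrements by 1/(N-k)
# at misses; extrema only occur adjacent to hits, so it suffices to examine
# the value just before and just after each hit.
es_from_hits <- function(pos, w, N) {
  k <- length(pos)
  if (k == 0L) stop("gene set absent from universe")
  if (k >= N) stop("ranked universe must be strictly larger than the overlap")
  if (sum(w) <= 0) w <- rep(1, k)  # all-zero hit scores: fall back to KS
  total_w <- sum(w)
  miss_step <- 1 / (N - k)
  cw <- cumsum(w) / total_w
  misses_before <- pos - seq_len(k)
  after <- cw - misses_before * miss_step
  before <- c(0, cw[-k]) - misses_before * miss_step
  hi <- max(after)
  lo <- min(before)
  if (hi >= -lo) hi else lo
}

#' Preranked enrichment score
#'
#' Classic weighted Kolmogorov-Smirnov running-sum statistic over a ranked
#' gene list: the running sum increments by \code{|score|^weight_exponent}
#' (normalized over set hits) at set members and decrements by
#' \code{1/(N - N_hits)} at non-members; the ES is the signed extremum.
#'
#' @param scores Named numeric vector of per-gene scores, or a
#'   \code{ranked_list}. Sorted internally by descending score with
#'   lexicographic tie-breaks.
#' @param set_members Character vector of gene-set members.
#' @param weight_exponent Nonnegative exponent on |score| for hit weights;
#'   0 gives the unweighted KS statistic. Default 1.
#' @return The enrichment score in [-1, 1], with attribute \code{size}
#'   (overlap with the universe).
#' @export
preranked_es <- function(scores, set_members, weight_exponent = 1) {
  stopifnot(weight_exponent >= 0)
  s <- ordered_universe(scores)
  N <- length(s)
  pos <- which(names(s) %in% set_members)
  if (length(pos) == 0L) stop("gene set absent from universe")
  w <- abs(s[pos])^weight_exponent
  es <- es_from_hits(pos, w, N)
  attr(es, "size") <- length(pos)
  es
}

# Shared permutation engine: observed ES per set plus gene-label permutation
# null, same-sign NES and nominal p with add-one smoothing.
gsea_core <- function(s, sets, n_perm, rng_seed, weight_exponent,
                      min_size, max_size) {
  N <- length(s)
  wvec <- abs(s)^weight_exponent
  rows <- list()
  set_index <- 0L
  for (gs in sets) {
    set_index <- set_index + 1L
    pos <- which(names(s) %in% gs$members)
    k <- length(pos)
    if (k < min_size || k > max_size || k >= N) {
      message(sprintf(
        "gsea: skipping set '%s' (overlap %d outside [%d, %d])",
        gs$name, k, min_size, max_size))
      next
    }
    es <- es_from_hits(pos, wvec[pos], N)
    # per-set substream keeps p-values independent across sets
    perm_es <- with_rng_seed(rng_seed + set_index, {
      vapply(seq_len(n_perm), function(i) {
        p <- sort.int(sample.int(N, k))
        es_from_hits(p, wvec[p], N)
      }, numeric(1))
    })
    same <- perm_es[sign(perm_es) == sign(es)]
    nes <- if (length(same) > 0) es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    rows[[length(rows) + 1L]] <- data.frame(
      set = gs$name, size = k, es = es, nes = nes, p = p,
      n_perm = n_perm, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(set = character(), size = integer(), es = numeric(),
               nes = numeric(), p = numeric(), n_perm = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' GSEA association analysis on a ranked gene list
#'
#' Tests each gene set for enrichment toward the top (or bottom) of a ranked
#' list, e.g. genes ordered by network association score with the MHC I seed
#' set. The null distribution reassigns set labels to random genes of the
#' universe (gene-label permutation); NES divides the observed ES by the mean
#' |ES| of same-sign permutations and the nominal p-value is the same-sign
#' tail fraction with add-one smoothing.
#'
#' @param ranked A \code{ranked_list} or named score vector.
#' @param sets A \code{gene_set_collection} (or list of \code{gene_set}).
#' @param n_perm Number of permutations (>= 100). Default 1000.
#' @param rng_seed Integer seed making permutations reproducible.
#' @param weight_exponent Hit-weight exponent, default 1.
#' @param min_size,max_size Overlap bounds outside which a set is skipped
#'   with a message. Defaults 5 and 2000.
#' @return Data frame with columns \code{set}, \code{size}, \code{es},
#'   \code{nes}, \code{p}, \code{n_perm}; attributes record the permutation
#'   scheme, weight exponent and seed.
#' @export
gsea_association <- function(ranked, sets, n_perm = 1000L, rng_seed = 1L,
                             weight_exponent = 1, min_size = 5L,
                             max_size = 2000L) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  s <- ordered_universe(ranked)
  out <- gsea_core(s, sets, n_perm, rng_seed, weight_exponent,
                   min_size, max_size)
  attr(out, "permutation") <- "gene-label"
  attr(out, "weight_exponent") <- weight_exponent
  attr(out, "rng_seed") <- rng_seed
  out
}

# Signal-to-noise ratio per gene between two groups, with each group SD
# floored at 0.2 * |group mean| (classic GSEA convention).
signal_to_noise <- function(expr, positive, negative) {
  m1 <- rowMeans(expr[, positive, drop = FALSE])
  m0 <- rowMeans(expr[, negative, drop = FALSE])
  s1 <- apply(expr[, positive, drop = FALSE], 1L, stats::sd)
  s0 <- apply(expr[, negative, drop = FALSE], 1L, stats::sd)
  if (all(s1 + s0 == 0)) {
    stop("degenerate group: zero variance in all genes")
  }
  s1 <- pmax(s1, 0.2 * abs(m1))
  s0 <- pmax(s0, 0.2 * abs(m0))
  denom <- s1 + s0
  if (all(denom == 0)) stop("degenerate group: zero variance in all genes")
  denom[denom == 0] <- min(denom[denom > 0])
  (m1 - m0) / denom
}

#' GSEA deregulation analysis between two sample groups
#'
#' Ranks genes by a two-group differential statistic (signal-to-noise ratio
#' by default, log2 fold-change as an alternative) and applies the preranked
#' enrichment machinery with gene-label permutations. Positive ES means the
#' set is up-regulated in the first (positive) group.
#'
#' @param expr Numeric gene x sample matrix with dimnames.
#' @param groups Binary labels aligned with \code{colnames(expr)}: a logical
#'   vector (TRUE = positive group) or a two-level factor/character whose
#'   first sorted level is taken as the negative group unless a
#'   \code{positive_level} is given.
#' @param sets A \code{gene_set_collection}.
#' @param n_perm,rng_seed,weight_exponent,min_size,max_size As in
#'   \code{\link{gsea_association}}.
#' @param ranking \code{"s2n"} (default) or \code{"log2fc"}.
#' @param positive_level For factor/character \code{groups}, the level
#'   treated as the positive group.
#' @return Data frame as in \code{\link{gsea_association}}.
#' @export
gsea_deregulation <- function(expr, groups, sets, n_perm = 1000L,
                              rng_seed = 1L, weight_exponent = 1,
                              min_size = 5L, max_size = 2000L,
                              ranking = c("s2n", "log2fc"),
                              positive_level = NULL) {
  ranking <- match.arg(ranking)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  expr <- as.matrix(expr)
  if (length(groups) != ncol(expr)) {
    stop("groups must align with expression columns")
  }
  if (is.logical(groups)) {
    positive <- groups
  } else {
    lev <- sort(unique(as.character(groups)))
    if (length(lev) != 2L) stop("groups must have exactly two levels")
    if (is.null(positive_level)) positive_level <- lev[2L]
    positive <- as.character(groups) == positive_level
  }
  if (sum(positive) < 3L || sum(!positive) < 3L) {
    stop("each group needs >= 3 samples")
  }
  stat <- switch(ranking,
    s2n = signal_to_noise(expr, positive, !positive),
    log2fc = log2(rowMeans(expr[, positive, drop = FALSE]) + 1) -
      log2(rowMeans(expr[, !positive, drop = FALSE]) + 1))
  names(stat) <- rownames(expr)
  s <- ordered_universe(stat)
  out <- gsea_core(s, sets, n_perm, rng_seed, weight_exponent,
                   min_size, max_size)
  attr(out, "permutation") <- "gene-label"
  attr(out, "ranking") <- ranking
  attr(out, "weight_exponent") <- weight_exponent
  attr(out, "rng_seed") <- rng_seed
  out
}
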