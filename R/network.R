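#' Build a gene network from an edge list
#'
#' Constructs a simple undirected gene network: self-loops are dropped,
#' duplicate edges (in either orientation) are collapsed, and nodes are kept
#' in lexicographic order so that all derived matrices are reproducible.
#'
#' @param edge_records A two-column matrix or data frame of gene identifier
#'   pairs, or a list of length-2 character vectors.
#' @return An object of class \code{gene_network} with elements
#'   \code{nodes} (sorted character vector) and \code{edges} (two-column
#'   character matrix, each row an unordered pair stored with the
#'   lexicographically smaller gene first).
#' @examples
#' net <- build_network(rbind(c("A", "B"), c("B", "C")))
#' net$nodes
#' @export
build_network <- function(edge_records) {
  if (is.list(edge_records) && !is.data.frame(edge_records)) {
    edge_records <- do.call(rbind, edge_records)
  }
  edge_records <- as.matrix(edge_records)
  if (length(edge_records) == 0L || nrow(edge_records) == 0L) {
    stop("empty network")
  }
  if (ncol(edge_records) != 2L) {
    stop("edge records must have exactly two columns")
  }
  a <- trimws(as.character(edge_records[, 1L]))
  b <- trimws(as.character(edge_records[, 2L]))
  if (any(a == "" | b == "" | is.na(a) | is.na(b))) {
    stop("blank gene identifier in edge list")
  }
  self <- a == b
  if (any(self)) {
    message(sprintf("build_network: dropped %d self-loop(s)", sum(self)))
    a <- a[!self]
    b <- b[!self]
  }
  if (length(a) == 0L) stop("empty network")
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  keep <- !duplicated(key)
  n_dup <- sum(!keep)
  if (n_dup > 0L) {
    message(sprintf("build_network: collapsed %d duplicate edge(s)", n_dup))
  }
  edges <- cbind(gene_a = lo[keep], gene_b = hi[keep])
  ord <- order(edges[, 1L], edges[, 2L])
  edges <- edges[ord, , drop = FALSE]
  nodes <- sort(unique(c(edges)))
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Sparse adjacency matrix of a gene network
#'
#' @param net A \code{gene_network}.
#' @return A symmetric sparse 0/1 matrix over \code{net$nodes} (dgCMatrix).
#' @export
adjacency_matrix <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  n <- length(net$nodes)
  i <- match(net$edges[, 1L], net$nodes)
  j <- match(net$edges[, 2L], net$nodes)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                       dims = c(n, n),
                       dimnames = list(net$nodes, net$nodes))
}

#' Column-normalized transition matrix
#'
#' Divides each column of the adjacency matrix by the node's degree, giving
#' the transition matrix of a simple random walk. Columns of isolated
#' (degree-0) nodes are left all-zero and reported with a warning; during a
#' restart walk such nodes can only carry restart-injected mass.
#'
#' @param net A \code{gene_network}.
#' @return A sparse column-stochastic matrix (zero columns for isolated
#'   nodes) with an attribute \code{isolated} naming degree-0 nodes.
#' @export
column_normalize <- function(net) {
  A <- adjacency_matrix(net)
  deg <- Matrix::colSums(A)
  isolated <- colnames(A)[deg == 0]
  if (length(isolated) > 0) {
    warning(sprintf("column_normalize: %d isolated node(s): %s",
                    length(isolated),
                    paste(utils::head(isolated, 5), collapse = ", ")))
  }
  scale <- ifelse(deg > 0, 1 / deg, 0)
  W <- A %*% Matrix::Diagonal(x = scale)
  dimnames(W) <- dimnames(A)
  attr(W, "isolated") <- isolated
  W
}

#' Random walk with restart association scores
#'
#' Iterates \code{p <- (1 - gamma) * W \%*\% p + gamma * p0} from an initial
#' vector placing equal mass on each seed gene, until the L1 change between
#' successive probability vectors falls below \code{tol}. The stationary
#' vector is the per-gene association score with the seed set: genes closer
#' to the seeds in the network receive more probability mass.
#'
#' @param W Column-stochastic transition matrix (from
#'   \code{\link{column_normalize}}) with gene identifiers as dimnames.
#' @param seeds Character vector of seed genes; all must be matrix columns.
#' @param gamma Restart probability in (0, 1). Default 0.5.
#' @param tol L1 convergence threshold (> 0). Default 1e-10.
#' @param max_iter Maximum number of iterations before erroring.
#' @return An object of class \code{association_scores}: a list with
#'   \code{scores} (named numeric, sums to 1 when no isolated sinks),
#'   \code{gamma}, \code{tol}, \code{iterations}, \code{residual},
#'   \code{seeds}.
#' @export
random_walk_with_restart <- function(W, seeds, gamma = 0.5, tol = 1e-10,
                                     max_iter = 10000L) {
  if (!(is.numeric(gamma) && length(gamma) == 1L && gamma > 0 && gamma < 1)) {
    stop("gamma must be a single number in (0, 1)")
  }
  if (!(is.numeric(tol) && tol > 0)) stop("tol must be > 0")
  nodes <- colnames(W)
  if (is.null(nodes)) stop("transition matrix must carry gene dimnames")
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) stop("seed set is empty")
  missing <- setdiff(seeds, nodes)
  if (length(missing) > 0L) {
    stop(sprintf("seed gene(s) not in network: %s",
                 paste(missing, collapse = ", ")))
  }
  p0 <- numeric(length(nodes))
  names(p0) <- nodes
  p0[seeds] <- 1 / length(seeds)
  p <- p0
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric((1 - gamma) * (W %*% p)) + gamma * p0
    resid <- sum(abs(p_new - p))
    p <- p_new
    if (resid < tol) {
      names(p) <- nodes
      return(structure(list(scores = p, gamma = gamma, tol = tol,
                            iterations = it, residual = resid,
                            seeds = seeds),
                       class = "association_scores"))
    }
  }
  stop(sprintf(
    "random walk did not converge in %d iterations (last L1 residual %.3e)",
    max_iter, resid))
}

#' @export
print.association_scores <- function(x, ...) {
  cat(sprintf(
    "association_scores: %d genes, gamma = %g, converged in %d iterations (L1 residual %.2e)\n",
    length(x$scores), x$gamma, x$iterations, x$residual))
  invisible(x)
}

#' Rank a score vector and attach percentiles
#'
#' Sorts genes by descending score, assigns average ranks to ties and a
#' percentile \code{100 * rank / n} so that the best gene of \code{n} has
#' percentile \code{100/n} and the worst has 100.
#'
#' @param scores Named numeric vector (or \code{association_scores}).
#' @return A data frame (class \code{ranked_list}) with columns
#'   \code{gene}, \code{score}, \code{rank}, \code{percentile}, ordered by
#'   ascending rank with lexicographic gene order inside ties.
#' @export
rank_and_percentile <- function(scores) {
  if (inherits(scores, "association_scores")) scores <- scores$scores
  if (length(scores) == 0L) stop("empty score vector")
  if (is.null(names(scores))) stop("scores must be named by gene")
  n <- length(scores)
  r <- rank(-scores, ties.method = "average")
  out <- data.frame(gene = names(scores),
                    score = unname(scores),
                    rank = unname(r),
                    percentile = unname(100 * r / n),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranked_list", "data.frame")
  out
}

# igraph view of a gene_network; node order preserved
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
}

#' Default MHC class I seed gene set
#'
#' The default bait genes for the association walk: the classical MHC class
#' I loci plus the checkpoint axis genes PD-1 (PDCD1) and PD-L1 (CD274).
#' Fully configurable; genes commonly reported as top predictions (TAP1,
#' B2M, ...) are deliberately not seeds.
#'
#' @return Character vector of gene symbols.
#' @export
default_mhc_seeds <- function() {
  c("HLA-A", "HLA-B", "HLA-C", "PDCD1", "CD274")
}
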