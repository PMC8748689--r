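#' Degree centrality
#'
#' Number of distinct neighbors of each gene in the network.
#'
#' @param net A \code{gene_network}.
#' @return Named integer vector over all nodes, with attribute
#'   \code{method = "degree"}.
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  d <- integer(length(net$nodes))
  names(d) <- net$nodes
  tab <- table(c(net$edges[, 1L], net$edges[, 2L]))
  d[names(tab)] <- as.integer(tab)
  attr(d, "method") <- "degree"
  d
}

#' Betweenness centrality
#'
#' For each gene, the sum over unordered pairs \{s, t\} (s, t distinct from
#' the gene) of the fraction of shortest s-t paths passing through it.
#' Disconnected pairs contribute 0. Computed with Brandes' algorithm via
#' igraph.
#'
#' @param net A \code{gene_network}.
#' @return Named numeric vector, attribute \code{method = "betweenness"}.
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  g <- as_igraph(net)
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  b <- b[net$nodes]
  attr(b, "method") <- "betweenness"
  b
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the adjacency matrix of the largest connected
#' component, entrywise nonnegative and max-normalized to 1; genes outside
#' that component score 0. For components below 500 nodes a dense symmetric
#' eigendecomposition is used; larger components use deterministic power
#' iteration started from the all-ones vector.
#'
#' @param net A \code{gene_network} with at least one edge.
#' @return Named numeric vector in [0, 1], attribute
#'   \code{method = "eigenvector"}.
#' @export
eigenvector_centrality <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  if (nrow(net$edges) == 0L) stop("eigenvector centrality needs >= 1 edge")
  g <- as_igraph(net)
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  members <- net$nodes[comp$membership == main]
  A <- adjacency_matrix(net)[members, members, drop = FALSE]
  n <- length(members)
  if (n < 500L) {
    ev <- eigen(as.matrix(A), symmetric = TRUE)
    v <- ev$vectors[, 1L]
    # Perron vector of a connected nonnegative matrix has one sign
    if (sum(v) < 0) v <- -v
    v[v < 0] <- 0
  } else {
    v <- rep(1, n)
    for (it in seq_len(10000L)) {
      v_new <- as.numeric(A %*% v)
      v_new <- v_new / sqrt(sum(v_new^2))
      if (sum(abs(v_new - v)) < 1e-13) {
        v <- v_new
        break
      }
      v <- v_new
    }
  }
  v <- v / max(v)
  e <- numeric(length(net$nodes))
  names(e) <- net$nodes
  e[members] <- v
  attr(e, "method") <- "eigenvector"
  e
}

#' Compute a centrality measure by name
#'
#' @param net A \code{gene_network}.
#' @param method One of \code{"degree"}, \code{"betweenness"},
#'   \code{"eigenvector"}.
#' @return Named numeric vector of centrality values.
#' @export
centrality <- function(net, method = c("degree", "betweenness",
                                       "eigenvector")) {
  method <- match.arg(method)
  switch(method,
         degree = degree_centrality(net),
         betweenness = betweenness_centrality(net),
         eigenvector = eigenvector_centrality(net))
}
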