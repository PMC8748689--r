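# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Random simple edge list over n nodes: each unordered pair kept with prob p.
rand_edge_list <- function(n, p, ids = sprintf("n%02d", seq_len(n))) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  cbind(ids[pairs[keep, 1]], ids[pairs[keep, 2]])
}

# Dense 0/1 adjacency matrix from a gene_network, node order preserved.
dense_adjacency <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  A[cbind(net$edges[, 1], net$edges[, 2])] <- 1
  A[cbind(net$edges[, 2], net$edges[, 1])] <- 1
  A
}

# BFS shortest-path counts from source s: distances and path multiplicities.
bfs_paths <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n)
  sig <- numeric(n)
  d[s] <- 0
  sig[s] <- 1
  cur <- s
  while (length(cur) > 0) {
    nxt <- integer(0)
    for (u in cur) {
      for (v in which(A[u, ] > 0)) {
        if (is.infinite(d[v])) {
          d[v] <- d[u] + 1
          nxt <- c(nxt, v)
        }
        if (d[v] == d[u] + 1) sig[v] <- sig[v] + sig[u]
      }
    }
    cur <- unique(nxt)
  }
  list(d = d, sigma = sig)
}

# Exhaustive betweenness: sum over unordered pairs {s,t} (both != i) of the
# fraction of shortest s-t paths through i.
brute_betweenness <- function(A) {
  n <- nrow(A)
  bf <- lapply(seq_len(n), function(s) bfs_paths(A, s))
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (is.infinite(bf[[s]]$d[t])) next
      for (i in seq_len(n)) {
        if (i == s || i == t) next
        if (bf[[s]]$d[i] + bf[[i]]$d[t] == bf[[s]]$d[t]) {
          b[i] <- b[i] +
            bf[[s]]$sigma[i] * bf[[i]]$sigma[t] / bf[[s]]$sigma[t]
        }
      }
    }
  }
  names(b) <- rownames(A)
  b
}

# Explicit position-by-position running-sum walk, independent of the
# package's cumulative-sum shortcut. Returns both extrema so tests can
# apply the signed-extremum selection rule explicitly.
slow_running_extrema <- function(scores, members, weight = 1) {
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  hit <- names(s) %in% members
  w <- abs(s)^weight
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1
  inc <- w / sum(w)
  dec <- 1 / sum(!hit)
  run <- 0
  hi <- 0
  lo <- 0
  for (i in seq_along(s)) {
    run <- if (hit[i]) run + inc[i] else run - dec
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  list(hi = unname(hi), lo = unname(lo))
}

slow_preranked_es <- function(scores, members, weight = 1) {
  ex <- slow_running_extrema(scores, members, weight)
  if (ex$hi >= -ex$lo) ex$hi else ex$lo
}

# AUC by exhaustive pair counting (ties credited one half).
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Small fixed-topology networks used in several files.
path_net <- function(labels = c("A", "B", "C")) {
  build_network(cbind(labels[-length(labels)], labels[-1]))
}

# Shuffle a vector under a local seed without disturbing the test RNG.
with_seed_sample <- function(x, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(x)
}
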