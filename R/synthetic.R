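# Synthetic fixtures with planted ground truth. Each generator is a pure
# function of its parameters and seed, so regeneration is bit-identical.

default_gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Simulate a scale-free gene network with a planted seed-proximal module
#'
#' A preferential-attachment backbone over \code{n_nodes} genes, plus a
#' densely interconnected module (every within-module pair drawn with
#' probability \code{p_module}) containing the seed genes. Mirrors the
#' structure a guilt-by-association method exploits: seeds sit inside a
#' community whose members should receive high association scores.
#'
#' @param n_nodes Total genes, default 1000.
#' @param attach_m Edges added per node in the backbone, default 3.
#' @param module_size Planted module size, default 50.
#' @param seeds_in_module Number of module genes used as seeds, default 5.
#' @param rng_seed Integer seed.
#' @param p_module Within-module edge probability, default 0.6.
#' @return List with \code{network} (\code{gene_network}), \code{seeds}
#'   (character), \code{truth} (list: \code{module_genes},
#'   \code{seed_genes}, \code{rng_seed}).
#' @export
simulate_network <- function(n_nodes = 1000L, attach_m = 3L,
                             module_size = 50L, seeds_in_module = 5L,
                             rng_seed = 1L, p_module = 0.6) {
  if (module_size >= n_nodes) stop("module_size must be < n_nodes")
  if (attach_m < 1L) stop("attach_m must be >= 1")
  if (seeds_in_module < 1L || seeds_in_module > module_size) {
    stop("seeds_in_module must be in [1, module_size]")
  }
  ids <- default_gene_ids(n_nodes)
  with_rng_seed(rng_seed, {
    g <- igraph::sample_pa(n_nodes, m = attach_m, directed = FALSE)
    backbone <- igraph::as_edgelist(g, names = FALSE)
    module_idx <- sort(sample.int(n_nodes, module_size))
    pairs <- utils::combn(module_idx, 2L)
    keep <- stats::runif(ncol(pairs)) < p_module
    module_edges <- t(pairs[, keep, drop = FALSE])
    edges <- rbind(backbone, module_edges)
    edges <- cbind(ids[edges[, 1L]], ids[edges[, 2L]])
    net <- suppressMessages(build_network(edges))
    module_genes <- ids[module_idx]
    seeds <- sort(sample(module_genes, seeds_in_module))
    list(network = net, seeds = seeds,
         truth = list(module_genes = module_genes, seed_genes = seeds,
                      rng_seed = rng_seed))
  })
}

#' Simulate an expression cohort with a latent immune axis
#'
#' Draws a latent per-sample immune-infiltration axis z ~ N(0, 1) and gives
#' immune-positive genes log-expression \code{a * z + noise} (immune-negative
#' genes \code{-a * z + noise}) with \code{a} chosen so the population
#' Pearson correlation with z on the log scale is \code{rho_target}; the
#' remaining genes are independent noise. Log-expression gets a gene-specific
#' baseline and is exponentiated (base 2), giving nonnegative, log-normal
#' values. The immune score returned is the latent axis itself.
#'
#' @param n_genes,n_samples Cohort dimensions, defaults 2000 x 200.
#' @param frac_immune_pos,frac_immune_neg Fractions of immune-correlated
#'   genes (defaults 0.05 each; must sum below 1). Ignored for a group when
#'   an explicit gene list is supplied.
#' @param rho_target Target |correlation| in (0, 1), default 0.5.
#' @param rng_seed Integer seed.
#' @param gene_ids Optional gene identifiers (length \code{n_genes}).
#' @param immune_pos_genes,immune_neg_genes Optional explicit, disjoint
#'   subsets of \code{gene_ids} to plant as immune-positive/-negative
#'   (used to tie the cohort to a simulated network's module).
#' @return List with \code{expr} (unit \code{"normalized"}),
#'   \code{immune} (named numeric), \code{truth} (list:
#'   \code{immune_pos_genes}, \code{immune_neg_genes}, \code{rho_target},
#'   \code{rng_seed}).
#' @export
simulate_expression_cohort <- function(n_genes = 2000L, n_samples = 200L,
                                       frac_immune_pos = 0.05,
                                       frac_immune_neg = 0.05,
                                       rho_target = 0.5, rng_seed = 1L,
                                       gene_ids = NULL,
                                       immune_pos_genes = NULL,
                                       immune_neg_genes = NULL) {
  if (!(rho_target > 0 && rho_target < 1)) stop("rho_target must be in (0,1)")
  if (frac_immune_pos + frac_immune_neg >= 1) {
    stop("immune fractions must sum below 1")
  }
  if (is.null(gene_ids)) gene_ids <- default_gene_ids(n_genes)
  stopifnot(length(gene_ids) == n_genes)
  with_rng_seed(rng_seed, {
    if (is.null(immune_pos_genes) || is.null(immune_neg_genes)) {
      n_pos <- round(frac_immune_pos * n_genes)
      n_neg <- round(frac_immune_neg * n_genes)
      pick <- sample(gene_ids, n_pos + n_neg)
      if (is.null(immune_pos_genes)) immune_pos_genes <- pick[seq_len(n_pos)]
      if (is.null(immune_neg_genes)) {
        immune_neg_genes <- setdiff(pick, immune_pos_genes)[seq_len(n_neg)]
      }
    }
    stopifnot(all(immune_pos_genes %in% gene_ids),
              all(immune_neg_genes %in% gene_ids),
              !anyDuplicated(c(immune_pos_genes, immune_neg_genes)))
    a <- rho_target / sqrt(1 - rho_target^2)
    z <- stats::rnorm(n_samples)
    samples <- sprintf("s%04d", seq_len(n_samples))
    loading <- numeric(n_genes)
    names(loading) <- gene_ids
    loading[immune_pos_genes] <- a
    loading[immune_neg_genes] <- -a
    baseline <- stats::rnorm(n_genes, mean = 4, sd = 1)
    logx <- outer(loading, z) +
      matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples) +
      baseline
    expr <- expression_matrix(
      matrix(2^logx, n_genes, n_samples,
             dimnames = list(gene_ids, samples)),
      unit = "normalized")
    immune <- stats::setNames(z, samples)
    list(expr = expr, immune = immune,
         truth = list(immune_pos_genes = sort(immune_pos_genes),
                      immune_neg_genes = sort(immune_neg_genes),
                      rho_target = rho_target, rng_seed = rng_seed))
  })
}

#' Simulate a responder/non-responder cohort with a planted signature
#'
#' All genes are exchangeable log-normal noise except the signature genes,
#' whose log-expression is shifted by \code{effect_sd} standard deviations
#' in responders. Emulates a treated cohort in which a response-associated
#' signature is truly up-regulated in responders.
#'
#' @param signature Character vector of signature genes (or a
#'   \code{gene_set}/\code{mias_signature}).
#' @param n_resp,n_nonresp Group sizes, defaults 30/30.
#' @param effect_sd Shift in SD units (>= 0), default 1.5.
#' @param rng_seed Integer seed.
#' @param n_genes Universe size, default 2000 (expanded if the signature is
#'   larger).
#' @param gene_ids Optional explicit gene universe containing the signature.
#' @param timing Treatment timing label for all samples, default "on".
#' @return List with \code{expr}, \code{labels} (data frame \code{sample},
#'   \code{response}, \code{timing}), \code{truth}.
#' @export
simulate_response_cohort <- function(signature, n_resp = 30L,
                                     n_nonresp = 30L, effect_sd = 1.5,
                                     rng_seed = 1L, n_genes = 2000L,
                                     gene_ids = NULL, timing = "on") {
  if (inherits(signature, "mias_signature")) signature <- signature$gene
  if (inherits(signature, "gene_set")) signature <- signature$members
  if (effect_sd < 0) stop("effect_sd must be >= 0")
  if (is.null(gene_ids)) {
    gene_ids <- sort(unique(c(signature, default_gene_ids(n_genes))))
  }
  stopifnot(all(signature %in% gene_ids))
  n_g <- length(gene_ids)
  n_s <- n_resp + n_nonresp
  with_rng_seed(rng_seed, {
    samples <- sprintf("p%04d", seq_len(n_s))
    responder <- c(rep(TRUE, n_resp), rep(FALSE, n_nonresp))
    baseline <- stats::rnorm(n_g, mean = 4, sd = 1)
    logx <- matrix(stats::rnorm(n_g * n_s), n_g, n_s) + baseline
    sig_rows <- gene_ids %in% signature
    logx[sig_rows, responder] <- logx[sig_rows, responder] + effect_sd
    expr <- expression_matrix(
      matrix(2^logx, n_g, n_s, dimnames = list(gene_ids, samples)),
      unit = "normalized")
    labels <- data.frame(
      sample = samples,
      response = ifelse(responder, "response", "non-response"),
      timing = timing, stringsAsFactors = FALSE)
    list(expr = expr, labels = labels,
         truth = list(signature_genes = sort(signature),
                      effect_sd = effect_sd, rng_seed = rng_seed))
  })
}

#' Simulate a coherent network-plus-expression study
#'
#' Composes the network and expression generators so that the planted
#' immune-positive genes partially coincide with the network module: the
#' intersection (\code{n_overlap} genes, excluding the seeds) is the true
#' response signature, while the rest of the module is seed-proximal but
#' immune-uncorrelated and the rest of the immune-positive genes is
#' immune-correlated but network-distant. This reproduces the situation the
#' rank-product signature is designed for, where neither network proximity
#' nor immune correlation alone identifies the signature.
#'
#' @param n_genes Gene universe, default 1500.
#' @param n_samples Expression cohort size, default 150.
#' @param module_size Network module size, default 250.
#' @param n_immune_pos Total immune-positive genes, default 250.
#' @param n_overlap Module genes that are also immune-positive (the true
#'   signature), default 100.
#' @param n_immune_neg Immune-negative genes, default 100.
#' @param attach_m,seeds_in_module,rho_target,rng_seed Passed through to
#'   the underlying generators.
#' @return List with \code{network}, \code{seeds}, \code{expr},
#'   \code{immune}, \code{truth} (including \code{signature_genes}).
#' @export
simulate_study <- function(n_genes = 1500L, n_samples = 150L,
                           module_size = 250L, n_immune_pos = 250L,
                           n_overlap = 100L, n_immune_neg = 100L,
                           attach_m = 3L, seeds_in_module = 5L,
                           rho_target = 0.5, rng_seed = 1L) {
  stopifnot(n_overlap <= module_size - seeds_in_module,
            n_overlap <= n_immune_pos)
  sim_net <- simulate_network(n_nodes = n_genes, attach_m = attach_m,
                              module_size = module_size,
                              seeds_in_module = seeds_in_module,
                              rng_seed = rng_seed)
  ids <- sim_net$network$nodes
  with_rng_seed(rng_seed + 1L, {
    module_nonseed <- setdiff(sim_net$truth$module_genes, sim_net$seeds)
    signature <- sort(sample(module_nonseed, n_overlap))
    off_module <- setdiff(ids, sim_net$truth$module_genes)
    extra_pos <- sample(off_module, n_immune_pos - n_overlap)
    immune_pos <- sort(c(signature, extra_pos))
    immune_neg <- sort(sample(setdiff(off_module, extra_pos), n_immune_neg))
    sim_expr <- simulate_expression_cohort(
      n_genes = length(ids), n_samples = n_samples,
      rho_target = rho_target, rng_seed = rng_seed + 2L,
      gene_ids = ids, immune_pos_genes = immune_pos,
      immune_neg_genes = immune_neg)
    truth <- c(sim_net$truth, sim_expr$truth,
               list(signature_genes = signature))
    list(network = sim_net$network, seeds = sim_net$seeds,
         expr = sim_expr$expr, immune = sim_expr$immune, truth = truth)
  })
}
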