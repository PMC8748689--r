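test_that("counts_to_tpm normalizes by length and library size", {
  one <- matrix(57, 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_true(all(counts_to_tpm(one, c(g1 = 500)) == 1e6))

  two <- matrix(c(10, 10, 40, 40), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  tpm <- counts_to_tpm(two, c(g1 = 1000, g2 = 1000))
  expect_true(all(tpm == 5e5))

  set.seed(50)
  cnt <- matrix(rpois(200, 50), 20, 10,
                dimnames = list(sprintf("g%02d", 1:20),
                                sprintf("s%02d", 1:10)))
  len <- setNames(runif(20, 300, 5000), rownames(cnt))
  tpm2 <- counts_to_tpm(cnt, len)
  expect_equal(unname(colSums(tpm2)), rep(1e6, 10), tolerance = 1e-6)
  # invariant under uniform scaling of one sample's counts
  cnt2 <- cnt
  cnt2[, 3] <- cnt2[, 3] * 17
  expect_equal(counts_to_tpm(cnt2, len)[, 3], tpm2[, 3])

  expect_error(counts_to_tpm(cnt, len[-1]), "missing gene length")
})

test_that("immune correlation recovers exact and simulated relationships", {
  set.seed(51)
  z <- rnorm(30)
  expr <- rbind(gpos = z, gneg = exp(-z), gnull = rnorm(30),
                gflat = rep(1, 30))
  colnames(expr) <- sprintf("s%02d", 1:30)
  ic <- immune_correlation(expr, setNames(z, colnames(expr)),
                           method = "spearman", quantile_normalize = FALSE)
  cc <- setNames(ic$correlation, ic$gene)
  expect_equal(unname(cc["gpos"]), 1)
  expect_equal(unname(cc["gneg"]), -1)
  expect_true(ic$missing[ic$gene == "gflat"])

  # known rho = 0.6 at n = 500: estimate within +/- 0.1
  set.seed(52)
  n <- 500
  z2 <- rnorm(n)
  a <- 0.6 / sqrt(1 - 0.6^2)
  expr2 <- rbind(g1 = a * z2 + rnorm(n))
  colnames(expr2) <- sprintf("s%03d", 1:n)
  ic2 <- immune_correlation(expr2, setNames(z2, colnames(expr2)),
                            method = "pearson", quantile_normalize = FALSE)
  expect_lt(abs(ic2$correlation[1] - 0.6), 0.1)

  expect_error(immune_correlation(expr[, 1:2], setNames(z[1:2],
                                                        colnames(expr)[1:2])),
               "shared samples")
})

test_that("immune gene selection applies the two-predicate filter", {
  genes <- sprintf("g%03d", 1:100)
  assoc <- setNames(seq(100, 1, length.out = 100), genes)
  corr <- setNames(rep(0, 100), genes)
  corr[genes[1:3]] <- c(0.5, 0.2, 0.9)      # in top decile, positive
  corr[genes[4:5]] <- c(-0.3, -0.2)         # in top decile, negative
  corr[genes[50]] <- 0.9                    # outside top decile
  sel <- select_immune_genes(assoc, corr)
  expect_setequal(sel$positive, genes[1:3])
  expect_setequal(sel$negative, genes[4:5])

  sel_none <- suppressMessages(
    select_immune_genes(assoc, setNames(rep(0, 100), genes)))
  expect_length(sel_none$positive, 0)
  expect_length(sel_none$negative, 0)

  # randomized inputs equal the brute-force filter
  set.seed(53)
  for (rep in 1:10) {
    a <- setNames(rnorm(200), sprintf("r%03d", 1:200))
    cc <- setNames(runif(200, -1, 1), names(a))
    sel2 <- suppressMessages(select_immune_genes(a, cc,
                                                 top_fraction = 0.2,
                                                 corr_threshold = 0.3))
    top <- names(sort(a, decreasing = TRUE))[1:40]
    expect_setequal(sel2$positive, top[cc[top] >= 0.3])
    expect_setequal(sel2$negative, top[cc[top] <= -0.3])
  }
})

test_that("MIAS signature selection implements the rank product", {
  # MR arithmetic: r1 = 4, r2 = 9 -> MR = 6
  expect_equal(sqrt(4 * 9), 6)
  genes <- sprintf("g%03d", 1:50)
  assoc <- setNames(50:1, genes)
  corr <- setNames(seq(1, -1, length.out = 50), genes)
  sig <- select_mias_signature(assoc, corr, n_signature = 10)
  expect_equal(sig$gene[1], "g001")  # r1 = r2 = 1
  expect_equal(sig$mr[1], 1)
  expect_equal(sig$mr, sqrt(sig$r1 * sig$r2))

  # brute-force MR sort oracle under random ranks
  set.seed(54)
  for (rep in 1:10) {
    a <- setNames(rnorm(120), sprintf("r%03d", 1:120))
    cc <- setNames(runif(120, -1, 1), names(a))
    sig2 <- select_mias_signature(a, cc, n_signature = 25)
    mr_all <- sqrt(rank(-a) * rank(-cc))
    # boundary ties resolve lexicographically, as the package documents
    ord <- order(mr_all, names(a))
    expect_setequal(sig2$gene, names(a)[ord][1:25])
    expect_equal(sort(sig2$mr), unname(sort(mr_all)[1:25]))
  }

  # permutation invariance w.r.t. input order
  perm <- sample(names(assoc))
  sig3 <- select_mias_signature(assoc[perm], corr[perm], n_signature = 10)
  expect_equal(sig3, sig)
  expect_error(select_mias_signature(assoc, corr, n_signature = 100),
               "smaller than")
})

test_that("mias_score delegates to ssGSEA and respects the universe", {
  set.seed(55)
  expr <- matrix(2^rnorm(400, 4), 100, 4,
                 dimnames = list(sprintf("g%03d", 1:100),
                                 sprintf("s%d", 1:4)))
  sig <- sprintf("g%03d", 1:10)
  m <- mias_score(expr, sig)
  ss <- ssgsea_scores(expr, sig)
  expect_equal(m$mias, ss$nes)
  # restricting the universe changes the ranking baseline
  m2 <- mias_score(expr, sig, universe = rownames(expr)[1:60])
  expect_equal(attr(m2, "n_signature_used"), 10L)
  expect_error(mias_score(expr, c(sig[1], "absent1", "absent2")),
               "overlap too small")
})

test_that("rank-product integration merges predictors", {
  a <- c(s1 = 10, s2 = 5, s3 = 1)
  r <- integrate_predictions(a, a)
  expect_equal(r$sample, c("s1", "s2", "s3"))  # idempotent ordering
  expect_equal(r$rank_product, c(1, 2, 3))

  set.seed(56)
  for (rep in 1:5) {
    x <- setNames(rnorm(20), sprintf("s%02d", 1:20))
    y <- setNames(rnorm(20), names(x))
    r2 <- integrate_predictions(x, y)
    oracle <- sqrt(rank(-x) * rank(-y))
    expect_equal(setNames(r2$rank_product, r2$sample)[names(x)],
                 oracle)
  }
  expect_error(integrate_predictions(a, c(zz = 1)), "shared samples")
})

test_that("CNV calls follow the strict +/-0.5 thresholds", {
  x <- c(-0.6, -0.5, 0, 0.5, 0.6)
  expect_equal(unname(call_cnv_states(x)),
               c("loss", "neutral", "neutral", "neutral", "gain"))
  m <- matrix(c(0.51, -0.51, 0.49, -0.49), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  st <- call_cnv_states(m)
  expect_equal(st["g1", "s1"], "gain")
  expect_equal(st["g2", "s1"], "loss")
  expect_true(all(st[, 2] == "neutral"))
  # every entry falls in exactly one state
  set.seed(57)
  y <- rnorm(1000)
  expect_true(all(call_cnv_states(y) %in% c("gain", "neutral", "loss")))
  expect_error(call_cnv_states(c(1, NA)), "finite")
})

test_that("recurrent alterations count and filter per type", {
  sel <- structure(list(positive = c("gp1", "gp2"),
                        negative = c("gn1", "gn2"),
                        top_genes = c("gp1", "gp2", "gn1", "gn2"),
                        top_fraction = 0.1, corr_threshold = 0.2),
                   class = "immune_gene_selection")
  mut <- data.frame(gene = c(rep("gn1", 5), rep("gp1", 2)),
                    sample = c(sprintf("s%d", 1:5), "s1", "s2"))
  cnv <- matrix(c(0.6, 0.6, 0.6, 0, 0,
                  -0.7, -0.7, 0, 0, 0), 2, 5, byrow = TRUE,
                dimnames = list(c("gp2", "gn2"), sprintf("s%d", 1:5)))
  alt <- recurrent_alterations(sel, mut, call_cnv_states(cnv),
                               min_samples = 3)
  expect_setequal(alt$gene, c("gn1", "gp2"))  # gn1 Mut:5, gp2 Amp:3
  expect_equal(alt$n_mut[alt$gene == "gn1"], 5L)
  expect_equal(alt$n_amp[alt$gene == "gp2"], 3L)
  # below threshold excluded (gp1 mutated twice, gn2 two losses)
  expect_false("gp1" %in% alt$gene)
  expect_false("gn2" %in% alt$gene)
})

test_that("drug mapping joins only the immune-negative set", {
  sel <- structure(list(positive = "gp1", negative = c("gn1", "gn2"),
                        top_genes = c("gp1", "gn1", "gn2"),
                        top_fraction = 0.1, corr_threshold = 0.2),
                   class = "immune_gene_selection")
  drugs <- data.frame(drug = c("d1", "d2", "d3", "d4"),
                      target = c("gn1", "gp1", "gn1", "zz"))
  assoc <- rank_and_percentile(c(gp1 = 3, gn1 = 2, gn2 = 1, other = 0.5))
  corr <- setNames(c(0.5, -0.4, -0.3, 0), c("gp1", "gn1", "gn2", "other"))
  r <- map_drug_targets(sel, drugs, assoc = assoc, corr = corr)
  expect_equal(nrow(r), 2L)
  expect_true(all(r$target == "gn1"))
  expect_equal(unique(r$immune_correlation), -0.4)
  expect_equal(unique(r$association_percentile), 50)
  # drugs hitting only the positive set produce no rows
  r2 <- map_drug_targets(sel, drugs[drugs$target == "gp1", , drop = FALSE])
  expect_equal(nrow(r2), 0L)
})
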