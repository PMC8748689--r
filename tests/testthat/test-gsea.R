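test_that("preranked ES matches hand-computed running sums", {
  s <- c(a = 4, b = 3, c = 2, d = 1)
  # set = top gene: running sum jumps to 1 at the first position
  expect_equal(as.numeric(preranked_es(s, "a")), 1)
  # set = bottom gene only: deepest point is just before the terminal hit,
  # after three miss decrements of 1/3 each
  expect_equal(as.numeric(preranked_es(s, "d")), -1)
  # two-gene set, weight 1: hand walk
  # order a,b,c,d; hits {a,c} weights 4,2 (norm 6); misses decrement 1/2
  # running: 4/6, 4/6-1/2=1/6, 1/6+2/6=1/2, 0 -> extremum 2/3
  expect_equal(as.numeric(preranked_es(s, c("a", "c"))), 2 / 3)
  expect_error(preranked_es(s, c("x", "y")), "absent")
})

test_that("preranked ES equals the slow position-by-position oracle", {
  set.seed(20)
  for (rep in 1:25) {
    n <- sample(20:80, 1)
    scores <- setNames(rnorm(n), sprintf("g%03d", seq_len(n)))
    members <- sample(names(scores), sample(3:10, 1))
    for (w in c(0, 1, 1.5)) {
      a <- as.numeric(preranked_es(scores, members, w))
      ex <- slow_running_extrema(scores, members, w)
      if (abs(ex$hi + ex$lo) < 1e-9) {
        # extremum tie: either signed extremum is a valid ES
        expect_equal(abs(a), ex$hi, tolerance = 1e-12)
      } else {
        expect_equal(a, slow_preranked_es(scores, members, w),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("unweighted ES is invariant under monotone score rescaling", {
  set.seed(21)
  scores <- setNames(rnorm(50), sprintf("g%02d", 1:50))
  members <- sample(names(scores), 8)
  es1 <- preranked_es(scores, members, weight_exponent = 0)
  es2 <- preranked_es(exp(3 * scores) + 7, members, weight_exponent = 0)
  expect_equal(as.numeric(es1), as.numeric(es2))
})

test_that("preranked ES agrees with fgsea's statistic", {
  skip_if_not_installed("fgsea")
  set.seed(22)
  scores <- setNames(sort(rnorm(100), decreasing = TRUE),
                     sprintf("g%03d", 1:100))
  members <- sample(names(scores), 12)
  es_ref <- fgsea::calcGseaStat(stats = scores,
                                selectedStats = which(names(scores) %in%
                                                        members),
                                gseaParam = 1, scoreType = "std")
  expect_equal(as.numeric(preranked_es(scores, members, 1)), es_ref,
               tolerance = 1e-12)
})

test_that("association GSEA is deterministic and flags extreme sets", {
  set.seed(23)
  scores <- setNames(sort(rnorm(300), decreasing = TRUE),
                     sprintf("g%03d", 1:300))
  sets <- gene_set_collection(list(
    gene_set("top", names(scores)[1:10]),
    gene_set("rand", sample(names(scores), 10)),
    gene_set("tiny", names(scores)[1:2])))
  r1 <- suppressMessages(
    gsea_association(scores, sets, n_perm = 200, rng_seed = 5))
  r2 <- suppressMessages(
    gsea_association(scores, sets, n_perm = 200, rng_seed = 5))
  expect_identical(r1, r2)
  # undersized set skipped
  expect_false("tiny" %in% r1$set)
  # perfectly top-loaded set: no permutation can beat ES = 1, so the
  # smoothed p is the smallest attainable for its same-sign count
  top <- r1[r1$set == "top", ]
  expect_equal(top$es, 1)
  expect_lte(top$p, 1 / 100)
  expect_error(gsea_association(scores, sets, n_perm = 10), "n_perm")
})

test_that("deregulation GSEA finds a planted up-shift and is antisymmetric", {
  set.seed(24)
  n_g <- 400; n_s <- 16
  expr <- matrix(2^rnorm(n_g * n_s, 4), n_g, n_s,
                 dimnames = list(sprintf("g%03d", 1:n_g),
                                 sprintf("s%02d", 1:n_s)))
  grp <- rep(c(TRUE, FALSE), each = 8)
  planted <- sprintf("g%03d", 1:20)
  expr[planted, grp] <- expr[planted, grp] * 2^2
  sets <- gene_set_collection(list(
    gene_set("planted", planted),
    gene_set("null", sprintf("g%03d", 101:120))))
  r <- gsea_deregulation(expr, grp, sets, n_perm = 500, rng_seed = 2)
  expect_lt(r$p[r$set == "planted"], 0.01)
  expect_gt(r$es[r$set == "planted"], 0)
  # swapping group labels flips the ES sign exactly
  r_sw <- gsea_deregulation(expr, !grp, sets, n_perm = 500, rng_seed = 2)
  expect_equal(r_sw$es, -r$es, tolerance = 1e-12)

  const <- matrix(5, 10, 8, dimnames = list(sprintf("g%02d", 1:10),
                                            sprintf("s%02d", 1:8)))
  expect_error(
    gsea_deregulation(const, rep(c(TRUE, FALSE), each = 4), sets,
                      n_perm = 100),
    "degenerate")
  expect_error(
    gsea_deregulation(expr, rep(c(TRUE, FALSE), c(2, 14)), sets,
                      n_perm = 100),
    ">= 3 samples")
})

test_that("random sets give null-calibrated nominal p-values", {
  set.seed(25)
  N <- 600
  scores <- setNames(sort(rnorm(N), decreasing = TRUE),
                     sprintf("g%03d", 1:N))
  sets <- gene_set_collection(lapply(1:100, function(i)
    gene_set(paste0("S", i), sample(names(scores), 15))))
  r <- gsea_association(scores, sets, n_perm = 200, rng_seed = 31)
  frac <- mean(r$p < 0.05)
  # binomial 99% CI around 0.05 for 100 draws
  expect_lt(frac, 0.05 + 2.576 * sqrt(0.05 * 0.95 / 100))
})
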