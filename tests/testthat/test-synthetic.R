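test_that("generators are pure functions of their seed", {
  a <- simulate_network(n_nodes = 300, module_size = 20, rng_seed = 9)
  b <- simulate_network(n_nodes = 300, module_size = 20, rng_seed = 9)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$seeds, b$seeds)

  e1 <- simulate_expression_cohort(n_genes = 200, n_samples = 40,
                                   rng_seed = 9)
  e2 <- simulate_expression_cohort(n_genes = 200, n_samples = 40,
                                   rng_seed = 9)
  expect_identical(e1$expr, e2$expr)
  expect_identical(e1$immune, e2$immune)

  r1 <- simulate_response_cohort(sprintf("g%05d", 1:20), n_genes = 200,
                                 rng_seed = 9)
  r2 <- simulate_response_cohort(sprintf("g%05d", 1:20), n_genes = 200,
                                 rng_seed = 9)
  expect_identical(r1$expr, r2$expr)
  expect_identical(r1$labels, r2$labels)
})

test_that("planted module is much denser than the backbone", {
  sim <- simulate_network(n_nodes = 400, module_size = 30, rng_seed = 3)
  net <- sim$network
  in_module <- net$edges[, 1] %in% sim$truth$module_genes &
    net$edges[, 2] %in% sim$truth$module_genes
  n_mod <- length(sim$truth$module_genes)
  dens_mod <- sum(in_module) / choose(n_mod, 2)
  n_out <- length(net$nodes)
  dens_all <- sum(!in_module) / choose(n_out, 2)
  expect_gt(dens_mod, 5 * dens_all)
  expect_true(all(sim$seeds %in% sim$truth$module_genes))
})

test_that("generated objects satisfy their type invariants", {
  sim <- simulate_network(n_nodes = 200, module_size = 15, rng_seed = 5)
  expect_s3_class(sim$network, "gene_network")
  expect_identical(sim$network$nodes, sort(sim$network$nodes))
  expect_false(any(sim$network$edges[, 1] == sim$network$edges[, 2]))

  e <- simulate_expression_cohort(n_genes = 150, n_samples = 30,
                                  rng_seed = 5)
  expect_true(all(e$expr >= 0))
  expect_identical(colnames(e$expr), names(e$immune))
  expect_true(all(e$truth$immune_pos_genes %in% rownames(e$expr)))
})

test_that("expression cohort hits the target immune correlation", {
  e <- simulate_expression_cohort(n_genes = 1000, n_samples = 500,
                                  frac_immune_pos = 0.05,
                                  frac_immune_neg = 0.05,
                                  rho_target = 0.5, rng_seed = 7)
  ic <- immune_correlation(e$expr, e$immune, method = "pearson",
                           quantile_normalize = FALSE)
  # correlate on the log scale where the generator's rho is defined
  ic_log <- immune_correlation(log2(e$expr + 1e-9), e$immune,
                               method = "pearson",
                               quantile_normalize = FALSE)
  cc <- setNames(ic_log$correlation, ic_log$gene)
  expect_lt(abs(mean(cc[e$truth$immune_pos_genes]) - 0.5), 0.05)
  expect_lt(abs(mean(cc[e$truth$immune_neg_genes]) + 0.5), 0.05)
  null_genes <- setdiff(names(cc), c(e$truth$immune_pos_genes,
                                     e$truth$immune_neg_genes))
  expect_gte(mean(abs(cc[null_genes]) < 0.2), 0.95)
})

test_that("response cohort plants the signature shift only in responders", {
  sig <- sprintf("g%05d", 1:50)
  rc <- simulate_response_cohort(sig, n_resp = 25, n_nonresp = 25,
                                 effect_sd = 2, rng_seed = 11,
                                 n_genes = 500)
  resp <- rc$labels$response == "response"
  lx <- log2(rc$expr)
  shift_sig <- mean(lx[sig, resp]) - mean(lx[sig, !resp])
  other <- setdiff(rownames(rc$expr), sig)
  shift_other <- mean(lx[other, resp]) - mean(lx[other, !resp])
  expect_gt(shift_sig, 1.5)
  expect_lt(abs(shift_other), 0.2)
  expect_identical(unique(rc$labels$timing), "on")
})

test_that("coherent study links module, immune axis and signature", {
  st <- simulate_study(n_genes = 600, module_size = 80, n_immune_pos = 80,
                       n_overlap = 40, n_immune_neg = 40, rng_seed = 13)
  expect_true(all(st$truth$signature_genes %in% st$truth$module_genes))
  expect_true(all(st$truth$signature_genes %in%
                    st$truth$immune_pos_genes))
  expect_false(any(st$seeds %in% st$truth$signature_genes))
  expect_length(st$truth$signature_genes, 40)
  expect_identical(rownames(st$expr), st$network$nodes)
})

test_that("generator parameter validation", {
  expect_error(simulate_network(n_nodes = 10, module_size = 10), "module")
  expect_error(simulate_expression_cohort(rho_target = 1.5,
                                          n_genes = 50, n_samples = 10),
               "rho_target")
  expect_error(simulate_response_cohort(sprintf("g%05d", 1:5),
                                        effect_sd = -1, n_genes = 50),
               "effect_sd")
})
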