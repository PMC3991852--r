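test_that("design generator hits its noiseless limit and normalisation", {
  d0 <- generateDesign(n_replicates = 3, radius_cv = 0, seed = 11)
  expect_equal(d0$relative_radius,
               rep(c(1.0, 1.05, 1.3, 2.5), each = 3))

  d <- generateDesign(n_replicates = 5, radius_cv = 0.1, seed = 11)
  ref <- d$genotype == "control" & d$timepoint == "pre"
  expect_equal(mean(d$relative_radius[ref]), 1.0)
  expect_true(all(d$relative_radius > 0))

  expect_identical(generateDesign(3, seed = 4), generateDesign(3, seed = 4))
  expect_error(generateDesign(0), ">= 1")
  expect_error(generateDesign(3, group_radii = c(1, 2, 3, -1)), "positive")
})

test_that("noiseless matrices recover planted slopes exactly downstream", {
  d <- generateDesign(n_replicates = 2, radius_cv = 0, seed = 1)
  g <- generateMatrix(d, n_features = 10,
                      class_props = c(positive = 0.3, negative = 0.2,
                                      null = 0.5),
                      noise_sd = 0, seed = 2)
  ct <- correlateFeatures(g$experiment, log2_transform = TRUE,
                          pseudocount = 0)
  pos <- g$truth$scaling_class == "positive"
  neg <- g$truth$scaling_class == "negative"
  nul <- g$truth$scaling_class == "null"
  expect_equal(ct$r[pos], rep(1, sum(pos)))
  expect_equal(ct$r[neg], rep(-1, sum(neg)))
  # pure null features are constant -> flagged missing
  expect_true(all(is.na(ct$r[nul])))
  expect_true(all(is.na(ct$p_adj[nul])))
  # perfect correlations keep a positive, vanishing p
  expect_true(all(ct$p[pos] > 0))
  expect_lt(max(ct$p[pos]), 1e-12)
})

test_that("recovered negative-class correlations sit below the null class", {
  d <- generateDesign(n_replicates = 3, radius_cv = 0.05, seed = 5)
  g <- generateMatrix(d, n_features = 1000, noise_sd = 0.25, seed = 5)
  ct <- correlateFeatures(g$experiment)
  mean_neg <- mean(ct$r[g$truth$scaling_class == "negative"])
  mean_null <- mean(ct$r[g$truth$scaling_class == "null"], na.rm = TRUE)
  expect_lt(mean_neg, mean_null)
  expect_gt(mean_null, -0.2)
  expect_lt(mean_null, 0.2)

  # Monte-Carlo oracle at 10x replicates pins the class mean the 3-replicate
  # run should fluctuate around
  d10 <- generateDesign(n_replicates = 30, radius_cv = 0.05, seed = 6)
  g10 <- generateMatrix(d10, n_features = 1000, noise_sd = 0.25, seed = 6)
  ct10 <- correlateFeatures(g10$experiment)
  oracle_neg <- mean(ct10$r[g10$truth$scaling_class == "negative"])
  expect_lt(abs(mean_neg - oracle_neg), 0.15)

  # Mann-Whitney style separation of the recovered distributions
  w <- wilcox.test(ct$r[g$truth$scaling_class == "negative"],
                   ct$r[g$truth$scaling_class == "null"],
                   alternative = "less")
  expect_lt(w$p.value, 1e-10)
})

test_that("generators are deterministic under a fixed seed", {
  s1 <- simulateStudy(seed = 9)
  s2 <- simulateStudy(seed = 9)
  expect_identical(s1$design, s2$design)
  expect_identical(SummarizedExperiment::assay(s1$genes),
                   SummarizedExperiment::assay(s2$genes))
  expect_identical(networkEdges(s1$network), networkEdges(s2$network))
  expect_identical(geneSets(s1$gene_sets), geneSets(s2$gene_sets))
})

test_that("annotation sets respect class anchoring and disjointness", {
  d <- generateDesign(2, radius_cv = 0, seed = 1)
  g <- generateMatrix(d, n_features = 500, noise_sd = 0, seed = 1)
  gsc <- generateAnnotations(g$truth,
                             planted_sizes = c(mito_like = 40,
                                               cyto_like = 40),
                             decoy_sizes = c(30, 30),
                             purity = 1, seed = 2)
  sets <- geneSets(gsc)
  cls <- setNames(g$truth$scaling_class, g$truth$feature_id)
  expect_true(all(cls[sets$mito_like] == "negative"))
  expect_true(all(cls[sets$cyto_like] == "positive"))
  expect_true(all(cls[sets$decoy_1] == "null"))
  # sets never share members
  all_members <- unlist(sets, use.names = FALSE)
  expect_false(anyDuplicated(all_members) > 0)

  expect_error(
    generateAnnotations(g$truth,
                        planted_sizes = c(mito_like = 5000, cyto_like = 10),
                        purity = 1, seed = 1),
    "exceeds available")
})

test_that("network generator obeys its edge-probability limits", {
  d <- generateDesign(2, radius_cv = 0, seed = 1)
  g <- generateMatrix(d, n_features = 40,
                      class_props = c(positive = 0.25, negative = 0.25,
                                      null = 0.5),
                      noise_sd = 0, seed = 1)
  empty <- generateNetwork(g$truth, 0, 0, seed = 1)
  expect_equal(numEdges(empty), 0L)
  expect_equal(numNodes(empty), 40L)  # isolated nodes retained

  full <- generateNetwork(g$truth, 1, 0, seed = 1)
  module <- g$truth$feature_id[g$truth$scaling_class == "negative"]
  m <- length(module)
  expect_equal(numEdges(full), m * (m - 1) / 2)
  expect_true(all(c(networkEdges(full)) %in% module))

  expect_error(generateNetwork(g$truth, 0.1, 0.5), "p_background")

  # analytic edge-density oracle: observed module enrichment ratio near
  # p_within / mixture expectation
  g2 <- generateMatrix(d, n_features = 500,
                       class_props = c(positive = 0.3, negative = 0.1,
                                       null = 0.6),
                       noise_sd = 0, seed = 3)
  net <- generateNetwork(g2$truth, 0.3, 0.02, seed = 3)
  mod <- g2$truth$feature_id[g2$truth$scaling_class == "negative"]
  obs <- connectivity(net, mod)$edges_per_gene
  k <- length(mod); n <- 500
  # expected edges/gene of the module vs of a random k-set:
  exp_mod <- 0.3 * (k - 1) / 2
  p_pair_mixture <- 0.3 * choose(k, 2) / choose(n, 2) +
    0.02 * (1 - choose(k, 2) / choose(n, 2))
  exp_rand <- p_pair_mixture * (k - 1) / 2
  cn <- connectivityTest(net, mod, n_iterations = 2000, seed = 4)
  expect_lt(abs(obs - exp_mod) / exp_mod, 0.15)
  expect_lt(abs(enrichmentRatio(cn) - exp_mod / exp_rand) /
              (exp_mod / exp_rand), 0.25)
})
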