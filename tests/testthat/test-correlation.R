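test_that("radius normalisation rescales to the reference group", {
  d <- toyDesign()
  d$relative_radius <- rep(c(2, 3, 5, 2), each = 2)
  norm <- normalizeRadius(d)   # reference: control/pre, mean 2
  expect_equal(norm$relative_radius, rep(c(1, 1.5, 2.5, 1), each = 2))
  expect_equal(normalizeRadius(norm), norm)   # idempotent
  expect_error(normalizeRadius(d[d$genotype == "knockout", ], "control",
                               "pre"),
               "no samples")
})

test_that("per-feature statistics match the cor.test oracle", {
  # fixed printed abundance vector on the duplicated radius design
  se <- toyExperiment(c(5.1, 4.8, 6.2, 5.9, 7.4, 7.0, 12.1, 12.9))
  ct <- correlateFeatures(se, ci_level = 0.90)
  orc <- pearsonOracle(c(5.1, 4.8, 6.2, 5.9, 7.4, 7.0, 12.1, 12.9),
                       relativeRadius(se), 0.90)
  expect_equal(ct$r, orc$r, tolerance = 1e-10)
  expect_equal(ct$p, orc$p, tolerance = 1e-10)
  expect_equal(ct$ci_low, orc$ci_low, tolerance = 1e-10)
  expect_equal(ct$ci_high, orc$ci_high, tolerance = 1e-10)

  # 100 random small instances
  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:15, 1)
    x <- runif(n, 0.5, 3)
    y <- abs(rnorm(n, 10, 4)) + 0.01
    d <- data.frame(sample_id = paste0("s", 1:n),
                    genotype = rep_len(c("control", "knockout"), n),
                    timepoint = rep_len(c("pre", "pre", "post", "post"), n),
                    replicate = seq_len(n), relative_radius = x)
    m <- matrix(y, nrow = 1, dimnames = list("f1", d$sample_id))
    res <- correlateFeatures(SizeExperiment(m, d, "gene"))
    orc <- pearsonOracle(y, x)
    expect_equal(res$r, orc$r, tolerance = 1e-10)
    expect_equal(res$p, orc$p, tolerance = 1e-10)
    expect_equal(res$ci_low, orc$ci_low, tolerance = 1e-10)
    expect_equal(res$ci_high, orc$ci_high, tolerance = 1e-10)
  }
})

test_that("correlation handles exact linearity and degenerate features", {
  r <- rep(c(1.00, 1.05, 1.30, 2.50), each = 2)
  se <- toyExperiment(c(3 * r,            # perfectly proportional
                        rep(7, 8)))       # constant
  ct <- correlateFeatures(se)
  expect_equal(ct$r[1], 1.0)
  expect_equal(ct$p[1], .Machine$double.xmin)
  expect_true(ct$ci_low[1] <= 1 && ct$ci_high[1] >= 1)
  expect_true(is.na(ct$r[2]) && is.na(ct$p[2]) && is.na(ct$p_adj[2]))
  expect_error(correlateFeatures(toyExperiment(rep(1, 8))),
               "zero variance")
})

test_that("r is invariant to positive affine maps and flips sign on negation", {
  se <- toyExperiment(c(5.1, 4.8, 6.2, 5.9, 7.4, 7.0, 12.1, 12.9))
  base <- correlateFeatures(se)$r
  d <- toyDesign()
  m <- SummarizedExperiment::assay(se)
  scaled <- correlateFeatures(SizeExperiment(3.7 * m + 2, d, "gene"))$r
  expect_equal(scaled, base, tolerance = 1e-12)
  d2 <- d; d2$relative_radius <- 0.5 * d2$relative_radius + 0.1
  expect_equal(correlateFeatures(SizeExperiment(m, d2, "gene"))$r, base,
               tolerance = 1e-12)
  d3 <- d; d3$relative_radius <- max(d3$relative_radius) + 1 -
    d3$relative_radius   # order-reversing affine map
  expect_equal(correlateFeatures(SizeExperiment(m, d3, "gene"))$r, -base,
               tolerance = 1e-12)
})

test_that("BH adjustment matches the brute-force step-up", {
  expect_equal(adjustPvalues(0.03), 0.03)
  expect_equal(adjustPvalues(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_error(adjustPvalues(c(0.5, 0)), "0, 1")
  expect_error(adjustPvalues(c(0.5, 1.2)), "0, 1")

  set.seed(7)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    adj <- adjustPvalues(p)
    expect_equal(adj, bhOracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    for (alpha in c(0.01, 0.05, 0.2)) {
      # rejection set equals the literal step-up rule
      m <- length(p); ord <- order(p)
      k <- which(p[ord] <= alpha * seq_len(m) / m)
      brute <- if (length(k)) ord[seq_len(max(k))] else integer()
      expect_setequal(which(adj <= alpha), brute)
    }
  }
})

test_that("size fold change uses extreme-radius groups and a pseudocount", {
  se <- toyExperiment(c(rep(2, 6), 8, 8))      # smallest grp mean 2, largest 8
  expect_equal(unname(sizeFoldChange(se, pseudocount = 0))[1], 2.0)
  expect_equal(unname(sizeFoldChange(toyExperiment(rep(4, 8)),
                                     pseudocount = 0))[1], 0.0)
  # smallest-cell group mean 4, largest-cell group mean 0
  se0 <- toyExperiment(c(rep(4, 6), 0, 0))
  expect_equal(unname(sizeFoldChange(se0, pseudocount = 1))[1], log2(1 / 5))

  # antisymmetry when the largest and smallest groups swap roles
  d <- toyDesign()
  d_rev <- d; d_rev$relative_radius <- rev(d$relative_radius)
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), nrow = 1,
              dimnames = list("f1", d$sample_id))
  fc <- sizeFoldChange(SizeExperiment(m, d, "gene"), pseudocount = 0)
  fc_rev <- sizeFoldChange(SizeExperiment(m, d_rev, "gene"), pseudocount = 0)
  expect_equal(unname(fc), -unname(fc_rev))

  d_tie <- d; d_tie$relative_radius <- rep(c(1, 2, 2, 1), each = 2)
  expect_error(sizeFoldChange(SizeExperiment(m, d_tie, "gene")), "tie")
})

test_that("correlation density obeys the bin convention and a null median", {
  tab <- data.frame(feature_id = c("a", "b", "c"), r = c(-1, 0, 1))
  dens <- correlationDensity(tab, bin_width = 0.1)
  expect_equal(dens$median_r, 0)
  expect_equal(sum(dens$counts), 3L)
  expect_equal(dens$counts[1], 1L)            # r = -1 in the first bin
  expect_equal(dens$counts[20], 1L)           # r = +1 in the closed last bin
  expect_equal(dens$counts[11], 1L)           # r = 0 in [0, 0.1)

  tab2 <- data.frame(feature_id = letters[1:4], r = rep(0.5, 4))
  dens2 <- correlationDensity(tab2)
  expect_equal(sum(dens2$counts > 0), 1L)
  expect_equal(dens2$median_r, 0.5)

  expect_error(correlationDensity(data.frame(r = NA_real_)), "no features")

  # 1000 simulated null features: median within Monte-Carlo error of 0
  d <- generateDesign(3, radius_cv = 0.05, seed = 21)
  g <- generateMatrix(d, n_features = 1000,
                      class_props = c(positive = 0, negative = 0, null = 1),
                      noise_sd = 0.25, seed = 21)
  ct <- correlateFeatures(g$experiment)
  expect_lt(abs(correlationDensity(ct)$median_r), 0.05)
})

test_that("abundance strata are stable and recover planted structure", {
  tab <- data.frame(feature_id = sprintf("f%02d", 1:10),
                    r = seq(-0.9, 0.9, length.out = 10),
                    log2_fc_size = seq(-2, 2, length.out = 10),
                    mean_abundance = 10:1)
  s <- abundanceStratifiedSummary(tab, n_strata = 5)
  expect_equal(s$n, rep(2L, 5))
  # abundance 10:1 reverses the order: stratum 5 holds f01, f02
  expect_equal(s$mean_r[5], mean(tab$r[1:2]))

  # all-tied abundances: stable tie-break by table order
  tab$mean_abundance <- 1
  s_tie <- abundanceStratifiedSummary(tab, n_strata = 5)
  expect_equal(s_tie$mean_r[1], mean(tab$r[1:2]))
  expect_equal(s_tie$mean_r[5], mean(tab$r[9:10]))

  expect_error(abundanceStratifiedSummary(tab[1:3, ], n_strata = 5),
               "fewer features")

  # planted: high-abundance features carry negative slopes
  tab2 <- data.frame(feature_id = sprintf("g%03d", 1:100),
                     r = c(rep(0.8, 80), rep(-0.6, 20)),
                     log2_fc_size = c(rep(1, 80), rep(-0.8, 20)),
                     mean_abundance = c(runif(80, 1, 10),
                                        runif(20, 1000, 2000)))
  s2 <- abundanceStratifiedSummary(tab2, n_strata = 5)
  expect_lt(s2$mean_r[5], s2$mean_r[1])
  expect_lt(s2$mean_log2_fc[5], s2$mean_log2_fc[1])
})
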