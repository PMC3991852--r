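test_that("KS comparison matches the ECDF enumeration oracle", {
  ks <- ksCompare(1:5, 1:5)
  expect_equal(ks$D, 0)
  expect_equal(ks$p, 1)
  expect_equal(ksCompare(1:5, 11:20)$D, 1)
  expect_equal(ksCompare(c(0.1, 0.4, 0.6), c(0.2, 0.3, 0.9))$D, 1 / 3)
  expect_equal(ksDOracle(c(0.1, 0.4, 0.6), c(0.2, 0.3, 0.9)), 1 / 3)

  set.seed(31)
  for (i in 1:100) {
    a <- rnorm(sample(3:30, 1))
    b <- rnorm(sample(3:40, 1), mean = runif(1, -1, 1))
    ks <- ksCompare(a, b)
    expect_equal(ks$D, ksDOracle(a, b), tolerance = 1e-12)
    # symmetry and invariance under a common monotone transform
    expect_equal(ksCompare(b, a)$D, ks$D, tolerance = 1e-12)
    expect_equal(ksCompare(exp(a), exp(b))$D, ks$D, tolerance = 1e-12)
    expect_equal(ksCompare(b, a)$p, ks$p, tolerance = 1e-12)
  }
  expect_error(ksCompare(numeric(), 1:3), "non-empty")
})

test_that("scaling profiles normalise the background and spot planted sets", {
  stat <- data.frame(feature_id = paste0("g", 1:40),
                     r = seq(-0.95, 0.95, length.out = 40))
  # a set identical to the whole background: normalised background equals
  # the set counts exactly
  gsc <- GeneSetCollection(list(all = paste0("g", 1:40)))
  prof <- setScalingProfiles(stat, gsc, background = "annotated_union")$all
  expect_equal(prof@backgroundCounts, as.numeric(prof@setCounts))
  expect_equal(prof@ksD, 0)

  gsc2 <- GeneSetCollection(list(two = c("g1", "g2"),
                                 rest = paste0("g", 1:40)))
  prof2 <- setScalingProfiles(stat, gsc2)$two
  expect_equal(prof2@medianStat,
               median(stat$r[1:2]))   # (-0.95 - 0.9013)/2 = -0.8506...
  # conservation: normalised background counts sum to the measured set size
  expect_equal(sum(prof2@backgroundCounts), 2)
  expect_equal(sum(prof2@setCounts), prof2@nMembers)

  # sets smaller than the minimum are skipped with a warning
  gsc3 <- GeneSetCollection(list(lonely = "g1", ok = paste0("g", 1:5)))
  expect_warning(p3 <- setScalingProfiles(stat, gsc3), "lonely")
  expect_named(p3, "ok")

  # members missing from the table are dropped (intersection semantics)
  gsc4 <- GeneSetCollection(list(mixed = c("g1", "g2", "phantom")))
  p4 <- setScalingProfiles(stat, gsc4)
  expect_equal(p4$mixed@nMembers, 2L)
})

test_that("planted sets separate from the background in both statistic modes", {
  study <- simulateStudy(seed = 17)
  ct <- correlateFeatures(study$genes)
  profs <- setScalingProfiles(ct, study$gene_sets)
  summ <- profileSummary(profs)

  bg_ids <- intersect(unlist(geneSets(study$gene_sets)), ct$feature_id)
  bg_median <- median(ct$r[ct$feature_id %in% bg_ids], na.rm = TRUE)
  expect_lt(summ$median[summ$set == "mito_like"], bg_median)
  expect_gt(summ$median[summ$set == "cyto_like"], bg_median)
  expect_lt(summ$ks_p[summ$set == "mito_like"], 0.05)

  # profile mass shifts into negative bins relative to the background
  mito <- profs$mito_like
  neg_bins <- mito@binEdges[-length(mito@binEdges)] < 0
  expect_gt(sum(mito@setCounts[neg_bins]),
            sum(mito@backgroundCounts[neg_bins]))

  # log2fc mode ranks the planted sets the same way
  profs_fc <- setScalingProfiles(ct, study$gene_sets,
                                 statistic_mode = "log2fc")
  summ_fc <- profileSummary(profs_fc)
  expect_equal(summ_fc$set[which.min(summ_fc$median)], "mito_like")
  expect_equal(summ_fc$set[which.max(summ_fc$median)], "cyto_like")
  expect_equal(summ$set[which.min(summ$median)], "mito_like")
})

test_that("KS p-values are calibrated for random subsets of the background", {
  set.seed(53)
  background <- rnorm(2000)
  stat <- data.frame(feature_id = paste0("g", seq_along(background)),
                     r = background)
  pvals <- replicate(500, {
    members <- sample(stat$feature_id, 30)
    ksCompare(stat$r[stat$feature_id %in% members], stat$r)$p
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.02)
})

test_that("lipid-class summary filters small classes and ranks the planted one", {
  tab <- data.frame(feature_id = paste0("m", 1:14),
                    r = c(rep(0.7, 6), rep(0.1, 4), rep(-0.5, 4)),
                    log2_fc_size = c(rep(1.2, 6), rep(0, 4), rep(-0.7, 4)))
  cmap <- data.frame(feature_id = paste0("m", 1:14),
                     class = c(rep("storage", 6), rep("membrane", 4),
                               rep("sterol", 4)))
  s <- lipidClassSummary(tab, cmap, min_class_size = 5)
  expect_equal(s$class, "storage")          # only class with > 4 members
  expect_equal(s$median_r, 0.7)
  expect_equal(s$mean_log2_fc, 1.2)
  expect_warning(empty <- lipidClassSummary(tab, cmap, min_class_size = 10),
                 "no lipid class")
  expect_equal(nrow(empty), 0L)

  study <- simulateStudy(seed = 29)
  mc <- correlateFeatures(study$metabolites)
  ls <- lipidClassSummary(mc, study$lipid_classes)
  expect_equal(ls$class[1], "TAG_like")     # storage lipids rank first
  expect_false("tiny_class" %in% ls$class)  # 4 members < "more than four"
  expect_gt(ls$median_r[1], 0.5)
})

test_that("surface-to-volume expectation is 1/r with its reference at 1", {
  expect_equal(surfaceVolumeExpectation(1), 1.0)
  expect_equal(surfaceVolumeExpectation(2), 0.5)
  expect_equal(surfaceVolumeExpectation(2.5), 0.4)
  expect_equal(surfaceVolumeExpectation(c(a = 1, b = 4)),
               c(a = 1, b = 0.25))
  expect_error(surfaceVolumeExpectation(c(1, 0)), "> 0")
  expect_error(surfaceVolumeExpectation(-2), "> 0")
})
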