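## Synthetic study generator: emulates a 2x2 genotype x hepatectomy design in
## which one genotype cannot divide and regenerates by hypertrophy, producing
## a cell-size gradient spanning roughly 1x to 2.5x relative nuclear radius,
## with planted size-coupled expression signal on top of a majority-null
## background.

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## independent, named substreams derived from one global seed, so each
## artifact can be regenerated on its own
.subSeeds <- function(seed, n = 6L) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.SCALING_CLASSES <- c("positive", "negative", "null")

#' Generate a 2x2 genotype x hepatectomy sample design
#'
#' Creates `4 * n_replicates` samples over (control, knockout) x
#' (pre, post) with per-sample relative nuclear radii drawn lognormally
#' around the group means with coefficient of variation `radius_cv`, then
#' renormalised so the control/pre group mean is exactly 1 (the reference
#' of the size gradient). The default group radii (1, 1.05, 1.3, 2.5)
#' encode an essentially unchanged control liver after hepatectomy, a
#' modestly enlarged knockout before, and knockout cells with radii in the
#' 2-3x range after regeneration by hypertrophy.
#'
#' @param n_replicates samples per group (>= 1).
#' @param group_radii mean relative radii for control/pre, control/post,
#'   knockout/pre, knockout/post (all > 0).
#' @param radius_cv coefficient of variation of the per-sample radius
#'   around its group mean; 0 gives exactly the group means.
#' @param seed integer seed.
#' @return validated sample table data.frame (see [readSampleTable()]).
#' @examples
#' generateDesign(n_replicates = 2, radius_cv = 0, seed = 1)
#' @export
generateDesign <- function(n_replicates = 3L,
                           group_radii = c(1.0, 1.05, 1.3, 2.5),
                           radius_cv = 0.05, seed = 1L) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (length(group_radii) != 4L || any(group_radii <= 0))
    stop("group_radii must be four positive values")
  if (radius_cv < 0) stop("radius_cv must be non-negative")
  grp <- data.frame(
    genotype = rep(c("control", "control", "knockout", "knockout"),
                   each = n_replicates),
    timepoint = rep(c("pre", "post", "pre", "post"), each = n_replicates),
    mean_radius = rep(group_radii, each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = 4L))
  radii <- .withSeed(seed, {
    if (radius_cv == 0) grp$mean_radius else {
      sdlog <- sqrt(log(1 + radius_cv^2))
      meanlog <- log(grp$mean_radius) - sdlog^2 / 2
      stats::rlnorm(nrow(grp), meanlog = meanlog, sdlog = sdlog)
    }
  })
  ref <- grp$genotype == "control" & grp$timepoint == "pre"
  radii <- radii / mean(radii[ref])
  short <- ifelse(grp$genotype == "control", "ctrl", "ko")
  validateSampleTable(data.frame(
    sample_id = paste(short, grp$timepoint, grp$replicate, sep = "_"),
    genotype = grp$genotype, timepoint = grp$timepoint,
    replicate = grp$replicate, relative_radius = radii))
}

#' Generate an abundance matrix with planted size-coupled signal
#'
#' Each feature follows `log2(abundance) = baseline + slope * radius
#' [+ shift * knockout] + Normal(0, noise_sd)`: positive-class features get
#' positive slopes, negative-class features negative slopes, null features
#' slope 0. Baselines are drawn from a normal on the log2 scale (a
#' lognormal abundance distribution) so that abundance strata exist.
#' Optionally, a number of null-class features receive a genotype-only
#' log2 shift, planting differential expression that is independent of the
#' size gradient: because genotype and size are confounded in this design
#' (the knockout cells are the enlarged ones), the shift is applied along
#' the knockout indicator residualised against radius, so these features
#' carry a genotype contrast but no size correlation in the noiseless
#' limit.
#'
#' @param design sample table from [generateDesign()].
#' @param n_features total feature count.
#' @param class_props named proportions for positive/negative/null; the
#'   default 30/12/58 echoes the observed asymmetry of positive over
#'   negative strong size correlators in liver.
#' @param slope_range absolute slope magnitudes are drawn uniformly from
#'   this range (per unit relative radius, log2 scale).
#' @param noise_sd residual standard deviation on the log2 scale.
#' @param baseline_mean,baseline_sd parameters of the log2 baseline
#'   distribution.
#' @param n_genotype_shift number of null-class features given a pure
#'   genotype effect; `genotype_shift` is its log2 magnitude (random sign).
#' @param genotype_shift log2 shift magnitude for those features.
#' @param kind `"gene"` or `"metabolite"` (feature ids are prefixed
#'   accordingly).
#' @param seed integer seed.
#' @return list with `experiment` (a [SizeExperiment-class]) and `truth`
#'   (data.frame: feature_id, scaling_class, true_slope, baseline_log2,
#'   noise_sd, genotype_shift).
#' @export
generateMatrix <- function(design, n_features = 1000L,
                           class_props = c(positive = 0.30,
                                           negative = 0.12,
                                           null = 0.58),
                           slope_range = c(0.5, 1.5), noise_sd = 0.25,
                           baseline_mean = 6, baseline_sd = 2,
                           n_genotype_shift = 0L, genotype_shift = 2,
                           kind = c("gene", "metabolite"), seed = 1L) {
  kind <- match.arg(kind)
  design <- validateSampleTable(design)
  if (nrow(design) < 2L) stop("need at least 2 samples")
  if (n_features < 1L) stop("n_features must be >= 1")
  stopifnot(all(.SCALING_CLASSES %in% names(class_props)))
  props <- class_props[.SCALING_CLASSES]
  if (any(props < 0) || abs(sum(props) - 1) > 1e-8)
    stop("class_props must be non-negative and sum to 1")
  counts <- floor(props * n_features)
  counts["null"] <- n_features - counts["positive"] - counts["negative"]
  if (n_genotype_shift > counts["null"])
    stop("n_genotype_shift exceeds the number of null-class features")
  prefix <- if (kind == "gene") "gene" else "met"
  ids <- sprintf("%s_%04d", prefix, seq_len(n_features))
  cls <- rep(.SCALING_CLASSES, times = counts)
  .withSeed(seed, {
    mag <- stats::runif(n_features, slope_range[1L], slope_range[2L])
    slope <- ifelse(cls == "positive", mag,
                    ifelse(cls == "negative", -mag, 0))
    baseline <- stats::rnorm(n_features, baseline_mean, baseline_sd)
    shift <- numeric(n_features)
    if (n_genotype_shift > 0L) {
      idx <- sample(which(cls == "null"), n_genotype_shift)
      shift[idx] <- genotype_shift * sample(c(-1, 1), n_genotype_shift,
                                            replace = TRUE)
    }
    r <- design$relative_radius
    ko <- as.numeric(design$genotype == "knockout")
    ## genotype-only effects are planted orthogonally to the size gradient
    ## (the knockout indicator residualised against radius): genotype is
    ## confounded with size in this design, and a raw indicator shift would
    ## be a size effect too
    w <- if (stats::var(ko) > 0 && any(shift != 0))
      stats::residuals(stats::lm(ko ~ r)) else ko
    log2a <- outer(slope, r) + outer(shift, w) + baseline
    if (noise_sd > 0)
      log2a <- log2a + matrix(stats::rnorm(length(log2a), 0, noise_sd),
                              nrow = n_features)
    m <- 2^log2a
    dimnames(m) <- list(ids, design$sample_id)
    list(experiment = SizeExperiment(m, design, kind = kind),
         truth = data.frame(feature_id = ids, scaling_class = cls,
                            true_slope = slope, baseline_log2 = baseline,
                            noise_sd = noise_sd, genotype_shift = shift))
  })
}

.drawSet <- function(truth, size, class, purity, seed_pool) {
  ## seed_pool: environment carrying the remaining-feature bookkeeping
  main <- seed_pool$available[[class]]
  n_main <- round(size * purity)
  n_fill <- size - n_main
  if (n_main > length(main))
    stop("requested set size ", size, " exceeds available '", class,
         "' features (", length(main), " left)")
  picked <- sample(main, n_main)
  seed_pool$available[[class]] <- setdiff(main, picked)
  if (n_fill > 0L) {
    filler <- seed_pool$available[["null"]]
    if (n_fill > length(filler))
      stop("requested set size ", size, " exceeds available null features")
    fill <- sample(filler, n_fill)
    seed_pool$available[["null"]] <- setdiff(filler, fill)
    picked <- c(picked, fill)
  }
  sort(picked)
}

#' Generate gene sets anchored on the planted scaling classes
#'
#' Builds a mitochondria-like set drawn mostly from negative-class
#' features, a cytoskeleton-like set mostly from positive-class features,
#' and decoy sets from the null background. With `purity = 1` and decoys
#' only, all sets are disjoint; `purity < 1` mixes in null-class members.
#' Sets never reuse a feature, so decoys are always disjoint from the
#' planted sets and from each other.
#'
#' @param truth truth data.frame from [generateMatrix()].
#' @param planted_sizes named sizes for `mito_like` and `cyto_like`.
#' @param decoy_sizes integer vector of decoy set sizes (members drawn from
#'   the null class).
#' @param purity fraction of a planted set drawn from its anchor class
#'   (remainder from the null class).
#' @param seed integer seed.
#' @return a [GeneSetCollection-class] with category
#'   `subcellular_component`.
#' @export
generateAnnotations <- function(truth,
                                planted_sizes = c(mito_like = 80L,
                                                  cyto_like = 80L),
                                decoy_sizes = c(60L, 60L, 60L),
                                purity = 0.9, seed = 1L) {
  stopifnot(all(c("mito_like", "cyto_like") %in% names(planted_sizes)))
  if (purity < 0 || purity > 1) stop("purity must lie in [0, 1]")
  pool <- new.env()
  pool$available <- split(truth$feature_id, truth$scaling_class)
  for (cl in .SCALING_CLASSES)
    if (is.null(pool$available[[cl]])) pool$available[[cl]] <- character()
  .withSeed(seed, {
    sets <- list(
      mito_like = .drawSet(truth, planted_sizes[["mito_like"]], "negative",
                           purity, pool),
      cyto_like = .drawSet(truth, planted_sizes[["cyto_like"]], "positive",
                           purity, pool))
    for (i in seq_along(decoy_sizes)) {
      sets[[paste0("decoy_", i)]] <-
        .drawSet(truth, decoy_sizes[i], "null", 1, pool)
    }
    GeneSetCollection(sets, category = "subcellular_component")
  })
}

#' Generate a lipid-class map with a planted storage-lipid class
#'
#' Assigns metabolite features to LIPID MAPS-style classes: a
#' triacylglyceride-analog class (`TAG_like`) drawn mostly from
#' positive-slope metabolites (storage lipids accumulate in larger cells),
#' a sterol-analog class from negative-slope metabolites, phospholipid-like
#' and fatty-acid-like classes from the null background, and a deliberately
#' tiny class to exercise the minimum-class-size filter.
#'
#' @param truth truth data.frame from a metabolite [generateMatrix()] run.
#' @param class_sizes named class sizes; names become class labels.
#' @param purity fraction of the TAG-like and sterol-like classes drawn
#'   from their anchor class.
#' @param seed integer seed.
#' @return data.frame with columns `feature_id`, `class`.
#' @export
generateLipidClasses <- function(truth,
                                 class_sizes = c(TAG_like = 30L,
                                                 sterol_like = 20L,
                                                 PL_like = 40L,
                                                 FA_like = 30L,
                                                 tiny_class = 4L),
                                 purity = 0.9, seed = 1L) {
  pool <- new.env()
  pool$available <- split(truth$feature_id, truth$scaling_class)
  for (cl in .SCALING_CLASSES)
    if (is.null(pool$available[[cl]])) pool$available[[cl]] <- character()
  anchor <- c(TAG_like = "positive", sterol_like = "negative")
  .withSeed(seed, {
    rows <- lapply(names(class_sizes), function(nm) {
      cl <- if (nm %in% names(anchor)) anchor[[nm]] else "null"
      pur <- if (nm %in% names(anchor)) purity else 1
      data.frame(feature_id = .drawSet(truth, class_sizes[[nm]], cl, pur,
                                       pool),
                 class = nm)
    })
    do.call(rbind, rows)
  })
}

#' Generate an interaction network with a connected planted module
#'
#' Samples an Erdos-Renyi-style undirected network over all features in
#' `truth`: node pairs inside the planted module (the negative scaling
#' class, emulating a densely interacting mitochondrial cluster) are
#' connected with probability `p_within_module`; all other pairs with
#' probability `p_background`.
#'
#' @param truth truth data.frame from [generateMatrix()].
#' @param p_within_module edge probability inside the module.
#' @param p_background edge probability elsewhere.
#' @param seed integer seed.
#' @return an [InteractionNetwork-class] whose node set covers all
#'   features (isolated nodes included).
#' @export
generateNetwork <- function(truth, p_within_module = 0.3,
                            p_background = 0.02, seed = 1L) {
  if (p_background < 0 || p_within_module > 1 ||
      p_background > p_within_module)
    stop("need 0 <= p_background <= p_within_module <= 1")
  ids <- truth$feature_id
  n <- length(ids)
  module <- truth$scaling_class == "negative"
  ## upper-triangle pair indices
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  p <- ifelse(module[i] & module[j], p_within_module, p_background)
  keep <- .withSeed(seed, stats::runif(length(p)) < p)
  InteractionNetwork(cbind(ids[i[keep]], ids[j[keep]]), nodes = ids)
}

#' Simulate a complete synthetic study
#'
#' One call producing every artifact the pipeline consumes: the 2x2
#' design, gene and metabolite matrices with planted size-coupled signal
#' (plus genotype-only shifted genes disjoint from the size-coupled ones),
#' gene-set annotations, a lipid-class map and an interaction network with
#' a module on the negative class. One global seed drives independent,
#' named substreams so artifacts can be regenerated individually.
#'
#' @param seed global integer seed.
#' @param n_replicates samples per design group.
#' @param n_genes,n_metabolites feature counts.
#' @param noise_sd residual log2 standard deviation for both matrices.
#' @param radius_cv per-sample radius coefficient of variation.
#' @param group_radii the four group mean radii.
#' @param n_genotype_shift genes given a genotype-only planted effect.
#' @param p_within_module,p_background network edge probabilities.
#' @param ... further arguments passed to [generateMatrix()].
#' @return list with elements `design`, `genes`, `gene_truth`,
#'   `metabolites`, `metabolite_truth`, `gene_sets`, `lipid_classes`,
#'   `network`, `seed`.
#' @export
simulateStudy <- function(seed = 1L, n_replicates = 3L,
                          n_genes = 1000L, n_metabolites = 300L,
                          noise_sd = 0.25, radius_cv = 0.05,
                          group_radii = c(1.0, 1.05, 1.3, 2.5),
                          n_genotype_shift = 50L,
                          p_within_module = 0.3, p_background = 0.02, ...) {
  s <- .subSeeds(seed, 6L)
  design <- generateDesign(n_replicates, group_radii, radius_cv,
                           seed = s[1L])
  genes <- generateMatrix(design, n_features = n_genes,
                          noise_sd = noise_sd,
                          n_genotype_shift = n_genotype_shift,
                          kind = "gene", seed = s[2L], ...)
  mets <- generateMatrix(design, n_features = n_metabolites,
                         noise_sd = noise_sd, kind = "metabolite",
                         seed = s[3L], ...)
  sets <- generateAnnotations(genes$truth, seed = s[4L])
  lipids <- generateLipidClasses(mets$truth, seed = s[5L])
  network <- generateNetwork(genes$truth,
                             p_within_module = p_within_module,
                             p_background = p_background, seed = s[6L])
  list(design = design, genes = genes$experiment,
       gene_truth = genes$truth, metabolites = mets$experiment,
       metabolite_truth = mets$truth, gene_sets = sets,
       lipid_classes = lipids, network = network, seed = seed)
}

#' Write every artifact of a simulated study to a directory
#'
#' Emits the sample table, both matrices, the GMT annotations, the
#' lipid-class map, the network edge list and truth TSVs
#' (feature_id, scaling_class, true_slope) for test harnesses.
#'
#' @param study list from [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSampleTable(study$design, file.path(dir, "samples.tsv"))
  writeFeatureMatrix(study$genes, file.path(dir, "gene_matrix.tsv"))
  writeFeatureMatrix(study$metabolites,
                     file.path(dir, "metabolite_matrix.tsv"))
  writeGeneSets(study$gene_sets, file.path(dir, "gene_sets.gmt"))
  writeResultTable(study$lipid_classes, file.path(dir, "lipid_classes.tsv"))
  writeNetwork(study$network, file.path(dir, "network.tsv"))
  writeResultTable(study$gene_truth[, c("feature_id", "scaling_class",
                                        "true_slope")],
                   file.path(dir, "gene_truth.tsv"))
  writeResultTable(study$metabolite_truth[, c("feature_id", "scaling_class",
                                              "true_slope")],
                   file.path(dir, "metabolite_truth.tsv"))
  invisible(dir)
}
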