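## One-shot orchestration: validated flat config, staged execution, result
## tables, a machine-readable summary and a run log.

.configDefaults <- function() list(
  mode = "simulate",                 # "simulate" or "files"
  seed = 1L,
  # generator (simulate mode)
  n_replicates = 3L, n_genes = 1000L, n_metabolites = 300L,
  noise_sd = 0.25, radius_cv = 0.05,
  group_radii = c(1.0, 1.05, 1.3, 2.5),
  n_genotype_shift = 50L,
  p_within_module = 0.3, p_background = 0.02,
  # inputs (files mode)
  sample_table = NULL, gene_matrix = NULL, metabolite_matrix = NULL,
  gene_sets = NULL, lipid_classes = NULL, network = NULL,
  network_min_score = 0,
  # analysis parameters
  reference_genotype = "control", reference_timepoint = "pre",
  ci_level = 0.90, alpha = 0.05, bin_width = 0.1,
  log2_transform = FALSE,
  pseudocount_gene = 1, pseudocount_metabolite = 0,
  set_background = "annotated_union", min_set_size = 2L,
  min_class_size = 5L,
  n_iterations = 1000L,
  genotype_timepoint = "pre", fc_threshold = log2(1.5))

#' Validate and normalise a pipeline configuration
#'
#' Fills defaults, checks types and ranges, and rejects unknown keys; all
#' problems are reported at once. The normalised config is echoed into the
#' run directory by [runPipeline()], and re-running from that echo
#' reproduces the run.
#'
#' @param config named list of configuration values (may be empty).
#' @return the normalised config list.
#' @export
validateConfig <- function(config = list()) {
  defaults <- .configDefaults()
  problems <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)],
                           keep.null = TRUE)
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  chk(cfg$mode %in% c("simulate", "files"),
      "mode must be 'simulate' or 'files'")
  chk(num1(cfg$seed), "seed must be a single number")
  chk(num1(cfg$n_replicates) && cfg$n_replicates >= 1,
      "n_replicates must be >= 1")
  chk(num1(cfg$n_genes) && cfg$n_genes >= 1, "n_genes must be >= 1")
  chk(num1(cfg$n_metabolites) && cfg$n_metabolites >= 1,
      "n_metabolites must be >= 1")
  chk(num1(cfg$noise_sd) && cfg$noise_sd >= 0, "noise_sd must be >= 0")
  chk(num1(cfg$radius_cv) && cfg$radius_cv >= 0, "radius_cv must be >= 0")
  chk(is.numeric(cfg$group_radii) && length(cfg$group_radii) == 4L &&
        all(cfg$group_radii > 0), "group_radii must be 4 positive values")
  chk(num1(cfg$p_background) && num1(cfg$p_within_module) &&
        cfg$p_background >= 0 &&
        cfg$p_background <= cfg$p_within_module &&
        cfg$p_within_module <= 1,
      "need 0 <= p_background <= p_within_module <= 1")
  chk(num1(cfg$ci_level) && cfg$ci_level > 0 && cfg$ci_level < 1,
      "ci_level must lie in (0, 1)")
  chk(num1(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1,
      "alpha must lie in (0, 1)")
  chk(num1(cfg$bin_width) && cfg$bin_width > 0 && cfg$bin_width <= 2,
      "bin_width must lie in (0, 2]")
  chk(num1(cfg$n_iterations) && cfg$n_iterations >= 1,
      "n_iterations must be >= 1")
  chk(num1(cfg$min_class_size) && cfg$min_class_size >= 1,
      "min_class_size must be >= 1")
  chk(num1(cfg$fc_threshold) && cfg$fc_threshold >= 0,
      "fc_threshold must be >= 0")
  chk(cfg$set_background %in% c("annotated_union", "all_features"),
      "set_background must be 'annotated_union' or 'all_features'")
  chk(cfg$genotype_timepoint %in% c("pre", "post", "both"),
      "genotype_timepoint must be pre/post/both")
  if (cfg$mode == "files") {
    for (key in c("sample_table", "gene_matrix", "metabolite_matrix",
                  "gene_sets", "lipid_classes", "network")) {
      chk(!is.null(cfg[[key]]),
          paste0("mode 'files' requires input path '", key, "'"))
    }
  }
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  for (key in c("seed", "n_replicates", "n_genes", "n_metabolites",
                "n_genotype_shift", "n_iterations", "min_set_size",
                "min_class_size"))
    cfg[[key]] <- as.integer(cfg[[key]])
  cfg
}

#' Read a flat YAML configuration file
#'
#' @param path path to a flat `key: value` YAML file.
#' @return validated config list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validateConfig(yaml::read_yaml(path))
}

.stage <- function(name, log, expr) {
  msg <- paste0("[stage ", name, "] ")
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full cell-size scaling pipeline
#'
#' Executes every stage in order — radius normalisation, per-feature
#' correlation (genes and metabolites), correlation density, gene-set
#' scaling profiles, lipid-class summary, network connectivity null,
#' genotype/size overlap, and the surface-area/volume expectation — on
#' simulated or file-based inputs, writing every result table, a
#' normalised config echo, a run log and a flat JSON summary into
#' `out_dir`. With a fixed seed the run is fully deterministic
#' (byte-identical summary).
#'
#' @param config named list or path to a YAML config (see
#'   [validateConfig()] for keys and defaults).
#' @param out_dir output directory (created).
#' @param seed optional override of the config seed.
#' @return the summary list, invisibly.
#' @export
runPipeline <- function(config = list(), out_dir, seed = NULL) {
  cfg <- if (is.character(config)) readConfig(config)
  else validateConfig(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    line <- paste0(...)
    message(line)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  cat("", file = log_path)
  yaml::write_yaml(cfg, file.path(out_dir, "config_echo.yaml"),
                   precision = 15L)

  ## partial outputs stay on disk; a marker flags an aborted run
  done <- FALSE
  on.exit(if (!done)
    writeLines("pipeline aborted; outputs are partial (see run.log)",
               file.path(out_dir, "FAILED")))

  ## -- inputs ---------------------------------------------------------
  if (cfg$mode == "simulate") {
    study <- .stage("simulate", logf, simulateStudy(
      seed = cfg$seed, n_replicates = cfg$n_replicates,
      n_genes = cfg$n_genes, n_metabolites = cfg$n_metabolites,
      noise_sd = cfg$noise_sd, radius_cv = cfg$radius_cv,
      group_radii = cfg$group_radii,
      n_genotype_shift = cfg$n_genotype_shift,
      p_within_module = cfg$p_within_module,
      p_background = cfg$p_background))
    design <- study$design; genes <- study$genes
    mets <- study$metabolites; sets <- study$gene_sets
    lipids <- study$lipid_classes; network <- study$network
    logf("simulated study: ", nrow(design), " samples, ",
         nrow(genes), " genes, ", nrow(mets), " metabolites")
  } else {
    design <- .stage("read_inputs", logf, readSampleTable(cfg$sample_table))
    sets <- readGeneSets(cfg$gene_sets)
    lipids <- readLipidClasses(cfg$lipid_classes)
    network <- readNetwork(cfg$network, min_score = cfg$network_min_score)
    genes <- NULL; mets <- NULL   # matrices need the normalised design
  }

  ## -- normalise ------------------------------------------------------
  design <- .stage("normalize", logf, normalizeRadius(
    design, cfg$reference_genotype, cfg$reference_timepoint))
  if (cfg$mode == "files") {
    genes <- .stage("read_inputs", logf, readFeatureMatrix(
      cfg$gene_matrix, kind = "gene", samples = design))
    mets <- readFeatureMatrix(cfg$metabolite_matrix, kind = "metabolite",
                              samples = design)
  } else {
    genes <- SizeExperiment(SummarizedExperiment::assay(genes, "abundance"),
                            design, kind = "gene")
    mets <- SizeExperiment(SummarizedExperiment::assay(mets, "abundance"),
                           design, kind = "metabolite")
  }
  writeSampleTable(design, file.path(out_dir, "samples_normalized.tsv"))

  ## -- correlate ------------------------------------------------------
  gene_cor <- .stage("correlate", logf, correlateFeatures(
    genes, ci_level = cfg$ci_level, log2_transform = cfg$log2_transform,
    pseudocount = cfg$pseudocount_gene))
  met_cor <- correlateFeatures(mets, ci_level = cfg$ci_level,
                               log2_transform = cfg$log2_transform,
                               pseudocount = cfg$pseudocount_metabolite)
  writeResultTable(gene_cor, file.path(out_dir, "gene_correlations.tsv"))
  writeResultTable(met_cor,
                   file.path(out_dir, "metabolite_correlations.tsv"))
  logf("correlated ", sum(!is.na(gene_cor$r)), " of ", nrow(gene_cor),
       " genes and ", sum(!is.na(met_cor$r)), " of ", nrow(met_cor),
       " metabolites")

  ## -- density + strata ----------------------------------------------
  dens <- .stage("density", logf,
                 correlationDensity(gene_cor, cfg$bin_width))
  writeResultTable(data.frame(bin_left = utils::head(dens$bin_edges, -1),
                              bin_right = dens$bin_edges[-1],
                              count = dens$counts),
                   file.path(out_dir, "correlation_density.tsv"))
  strata <- abundanceStratifiedSummary(gene_cor)
  writeResultTable(strata, file.path(out_dir, "abundance_strata.tsv"))

  ## -- set profiles ---------------------------------------------------
  profiles <- .stage("set_profiles", logf, withCallingHandlers(
    setScalingProfiles(gene_cor, sets, background = cfg$set_background,
                       bin_width = cfg$bin_width,
                       min_set_size = cfg$min_set_size),
    warning = function(w) {
      logf("WARN set_profiles: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }))
  prof_sum <- profileSummary(profiles)
  writeResultTable(prof_sum, file.path(out_dir, "profile_summary.tsv"))
  writeResultTable(do.call(rbind, lapply(profiles, as.data.frame)),
                   file.path(out_dir, "profiles.tsv"))

  ## -- lipid classes --------------------------------------------------
  lipid_sum <- .stage("lipid_classes", logf, lipidClassSummary(
    met_cor, lipids, min_class_size = cfg$min_class_size))
  writeResultTable(lipid_sum, file.path(out_dir, "lipid_classes.tsv"))

  ## -- network connectivity ------------------------------------------
  neg <- .stage("network", logf, selectSignificant(
    gene_cor, "negative", cfg$alpha))
  pos <- selectSignificant(gene_cor, "positive", cfg$alpha)
  logf("significant size-correlated genes: ", length(pos), " positive, ",
       length(neg), " negative (p_adj < ", cfg$alpha, ")")
  universe <- intersect(networkNodes(network), gene_cor$feature_id)
  conn <- .stage("network", logf, connectivityTest(
    network, neg, n_iterations = cfg$n_iterations, universe = universe,
    seed = cfg$seed, set_name = "negative_correlating"))
  writeResultTable(conn, file.path(out_dir, "connectivity.tsv"))
  writeResultTable(data.frame(null_edges_per_gene = nullValues(conn)),
                   file.path(out_dir, "connectivity_null.tsv"))

  ## -- genotype/size overlap -----------------------------------------
  geno <- .stage("overlap", logf, genotypeEffectGenes(
    genes, timepoint = cfg$genotype_timepoint,
    fc_threshold = cfg$fc_threshold, alpha = cfg$alpha,
    pseudocount = cfg$pseudocount_gene))
  logf("genotype-affected genes: ", length(geno))
  ov_pos <- overlapStats(geno, pos, "genotype_affected",
                         "positive_correlating")
  ov_neg <- overlapStats(geno, neg, "genotype_affected",
                         "negative_correlating")
  writeResultTable(rbind(as.data.frame(ov_pos), as.data.frame(ov_neg)),
                   file.path(out_dir, "overlap.tsv"))

  ## -- geometry -------------------------------------------------------
  sv <- .stage("geometry", logf, data.frame(
    sample_id = design$sample_id,
    relative_radius = design$relative_radius,
    expected_membrane_per_volume =
      surfaceVolumeExpectation(design$relative_radius)))
  writeResultTable(sv, file.path(out_dir, "surface_volume.tsv"))

  ## -- summary --------------------------------------------------------
  summary <- list(
    seed = cfg$seed,
    n_samples = nrow(design),
    n_genes_measured = sum(!is.na(gene_cor$r)),
    n_metabolites_measured = sum(!is.na(met_cor$r)),
    median_r_genes = dens$median_r,
    median_r_metabolites = stats::median(met_cor$r, na.rm = TRUE),
    n_positive_significant = length(pos),
    n_negative_significant = length(neg),
    set_medians = stats::setNames(as.list(prof_sum$median), prof_sum$set),
    set_ks_p = stats::setNames(as.list(prof_sum$ks_p), prof_sum$set),
    top_lipid_class = if (nrow(lipid_sum)) lipid_sum$class[1L] else NA,
    top_lipid_median_r = if (nrow(lipid_sum)) lipid_sum$median_r[1L] else NA,
    connectivity_enrichment_ratio = enrichmentRatio(conn),
    connectivity_empirical_p = empiricalP(conn),
    n_genotype_affected = length(geno),
    overlap_pct_positive = as.data.frame(ov_pos)$pct_of_b,
    overlap_pct_negative = as.data.frame(ov_neg)$pct_of_b,
    parameters = cfg)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  logf("pipeline complete; summary written to ",
       file.path(out_dir, "summary.json"))
  done <- TRUE
  invisible(summary)
}
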