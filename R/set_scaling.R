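## Gene-set level scaling: per-set medians, binned profiles against a
## size-normalised whole-background profile, KS comparison, lipid-class
## summaries and the geometric surface-area/volume expectation.

#' Binned scaling profiles for a gene-set collection
#'
#' For every set, intersects its members with the measured features,
#' takes the per-feature statistic (size correlation r, or the log2 fold
#' change for two-condition designs), bins it, and overlays the background
#' distribution rescaled so its counts sum to the set's measured size
#' (making set and whole-background profiles directly comparable). Set
#' versus background is additionally compared by a two-sample
#' Kolmogorov-Smirnov test.
#'
#' @param table a result of [correlateFeatures()] (or any data.frame with
#'   `feature_id` plus `r` / `log2_fc_size`).
#' @param sets a [GeneSetCollection-class].
#' @param background `"annotated_union"` (default): only features
#'   belonging to at least one set in the collection form the background;
#'   `"all_features"`: every measured feature does.
#' @param bin_width profile bin width (default 0.1).
#' @param statistic_mode `"correlation"` (bins tile \[-1, 1\]) or
#'   `"log2fc"` (bins tile the observed range).
#' @param min_set_size sets with fewer measured members are skipped with a
#'   warning (default 2).
#' @param exclude_set_from_background drop the tested set's members from
#'   its own background (sensitivity analysis; default keeps them, i.e.
#'   the whole-cell profile is the same for every set).
#' @return named list of [ScalingProfile-class] objects.
#' @examples
#' study <- simulateStudy(seed = 1, n_genes = 400, n_metabolites = 20)
#' ct <- correlateFeatures(study$genes)
#' profs <- setScalingProfiles(ct, study$gene_sets)
#' profileSummary(profs)
#' @export
setScalingProfiles <- function(table, sets,
                               background = c("annotated_union",
                                              "all_features"),
                               bin_width = 0.1,
                               statistic_mode = c("correlation", "log2fc"),
                               min_set_size = 2L,
                               exclude_set_from_background = FALSE) {
  background <- match.arg(background)
  statistic_mode <- match.arg(statistic_mode)
  stopifnot(methods::is(sets, "GeneSetCollection"))
  col <- if (statistic_mode == "correlation") "r" else "log2_fc_size"
  tab <- table[!is.na(table[[col]]), , drop = FALSE]
  stat <- stats::setNames(tab[[col]], tab$feature_id)

  bg_ids <- if (background == "annotated_union")
    intersect(unique(unlist(geneSets(sets), use.names = FALSE)),
              names(stat))
  else names(stat)
  if (!length(bg_ids)) stop("background is empty")

  edges <- if (statistic_mode == "correlation") {
    .correlationBinEdges(bin_width)
  } else {
    lo <- floor(min(stat[bg_ids]) / bin_width) * bin_width
    hi <- ceiling(max(stat[bg_ids]) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    seq(lo, hi, by = bin_width)
  }

  out <- list()
  for (nm in names(geneSets(sets))) {
    members <- intersect(geneSets(sets)[[nm]], names(stat))
    if (length(members) < min_set_size) {
      warning("skipping set '", nm, "': only ", length(members),
              " measured member(s)")
      next
    }
    bg <- if (exclude_set_from_background)
      setdiff(bg_ids, members) else bg_ids
    if (!length(bg)) stop("background is empty for set '", nm, "'")
    sv <- stat[members]
    bv <- stat[bg]
    ks <- ksCompare(sv, bv)
    set_counts <- .binCounts(sv, edges)
    bg_counts <- .binCounts(bv, edges) * (length(sv) / length(bv))
    out[[nm]] <- methods::new("ScalingProfile", setName = nm,
                              nMembers = length(sv),
                              medianStat = stats::median(sv),
                              binEdges = edges,
                              setCounts = set_counts,
                              backgroundCounts = bg_counts,
                              ksD = ks$D, ksP = ks$p,
                              statMode = statistic_mode)
  }
  out
}

#' Per-set summary table of scaling profiles
#'
#' @param profiles list of [ScalingProfile-class] from
#'   [setScalingProfiles()].
#' @return data.frame with one row per set: `set`, `n`, `median`, `ks_D`,
#'   `ks_p` and BH-adjusted `ks_p_adj` (adjusted across the sets in the
#'   collection), sorted by median.
#' @export
profileSummary <- function(profiles) {
  if (!length(profiles)) return(data.frame(
    set = character(), n = integer(), median = numeric(),
    ks_D = numeric(), ks_p = numeric(), ks_p_adj = numeric()))
  df <- data.frame(
    set = vapply(profiles, methods::slot, character(1), "setName"),
    n = vapply(profiles, methods::slot, integer(1), "nMembers"),
    median = vapply(profiles, methods::slot, numeric(1), "medianStat"),
    ks_D = vapply(profiles, methods::slot, numeric(1), "ksD"),
    ks_p = vapply(profiles, methods::slot, numeric(1), "ksP"),
    row.names = NULL)
  df$ks_p_adj <- adjustPvalues(df$ks_p)
  df[order(df$median), , drop = FALSE]
}

#' Two-sample two-sided Kolmogorov-Smirnov comparison
#'
#' D is the supremum absolute difference of the two empirical CDFs; the
#' p-value uses the asymptotic two-sample distribution, switching to the
#' exact small-sample computation when both samples have at most 25
#' values and carry no ties.
#'
#' @param set_values,background_values numeric samples (non-empty).
#' @param exact override the automatic exact/asymptotic choice.
#' @return list with elements `D` and `p`.
#' @export
ksCompare <- function(set_values, background_values, exact = NULL) {
  if (!length(set_values) || !length(background_values))
    stop("both samples must be non-empty")
  if (is.null(exact))
    exact <- length(set_values) <= 25L &&
      length(background_values) <= 25L &&
      !anyDuplicated(c(set_values, background_values))
  kt <- suppressWarnings(
    stats::ks.test(set_values, background_values,
                   alternative = "two.sided", exact = exact))
  ## a vanishing asymptotic tail is reported as the smallest positive
  ## double so downstream adjustment and log-scale summaries stay defined
  list(D = unname(kt$statistic),
       p = min(max(kt$p.value, .Machine$double.xmin), 1))
}

#' Lipid-class scaling summary
#'
#' Groups metabolite features by lipid class and reports, for every class
#' with at least `min_class_size` measured members (default 5, i.e. "more
#' than four"), the median size correlation and the mean log2 fold change
#' between the largest and smallest cells, sorted by median correlation
#' (the storage-lipid class is expected on top in enlarged hepatocytes).
#'
#' @param table a metabolite result of [correlateFeatures()].
#' @param class_map data.frame with `feature_id`, `class` (see
#'   [readLipidClasses()]).
#' @param min_class_size minimum measured members per reported class.
#' @return data.frame: `class`, `n`, `median_r`, `mean_log2_fc`, sorted by
#'   `median_r` decreasing; empty (with a warning) when no class passes.
#' @export
lipidClassSummary <- function(table, class_map, min_class_size = 5L) {
  tab <- merge(table[!is.na(table$r), c("feature_id", "r", "log2_fc_size")],
               class_map, by = "feature_id")
  counts <- table(tab$class)
  keep <- names(counts)[counts >= min_class_size]
  if (!length(keep)) {
    warning("no lipid class has >= ", min_class_size, " measured members")
    return(data.frame(class = character(), n = integer(),
                      median_r = numeric(), mean_log2_fc = numeric()))
  }
  out <- do.call(rbind, lapply(keep, function(cl) {
    sel <- tab$class == cl
    data.frame(class = cl, n = sum(sel),
               median_r = stats::median(tab$r[sel]),
               mean_log2_fc = mean(tab$log2_fc_size[sel]))
  }))
  out <- out[order(-out$median_r), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expected surface-area-to-volume scaling
#'
#' With volume growing as r^3 but surface area only as r^2, the membrane
#' demand per unit volume of a cell of relative radius r falls as
#' r^2 / r^3 = 1/r. Returns that expectation normalised so radius 1 maps
#' to 1 — the reference curve against which measured membrane-lipid
#' levels are judged.
#'
#' @param relative_radii positive relative radii.
#' @return numeric vector `1 / relative_radii` (names preserved).
#' @examples
#' surfaceVolumeExpectation(c(1, 2, 2.5))  # 1.0 0.5 0.4
#' @export
surfaceVolumeExpectation <- function(relative_radii) {
  if (any(!is.finite(relative_radii)) || any(relative_radii <= 0))
    stop("relative radii must be finite and > 0")
  relative_radii^2 / relative_radii^3
}
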