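## Disentangling genotype effects from size effects: per-feature Welch
## screening of knockout versus control at a fixed timepoint, and overlap
## statistics between the resulting set and the size-correlated sets.

#' Per-feature genotype contrast (Welch screen)
#'
#' For each feature, a Welch two-sample t-test of `log2(abundance +
#' pseudocount)` between knockout and control samples at the chosen
#' timepoint, with BH adjustment. The pre-hepatectomy contrast is the
#' default: it isolates the effect of the gene deletion from the
#' regeneration response. With 2-3 replicates per group this is a
#' screening statistic, not an inferential claim.
#'
#' @param x a [SizeExperiment-class].
#' @param timepoint `"pre"` (default), `"post"` or `"both"`.
#' @param pseudocount added before the log (default 1 for genes, 0 for
#'   metabolites).
#' @return data.frame: `feature_id`, `log2_fc` (knockout minus control),
#'   `p`, `p_adj`.
#' @export
genotypeEffectTable <- function(x, timepoint = c("pre", "post", "both"),
                                pseudocount = NULL) {
  stopifnot(methods::is(x, "SizeExperiment"))
  timepoint <- match.arg(timepoint)
  if (is.null(pseudocount))
    pseudocount <- if (featureKind(x) == "gene") 1 else 0
  cd <- SummarizedExperiment::colData(x)
  sel <- if (timepoint == "both") rep(TRUE, ncol(x))
  else as.character(cd$timepoint) == timepoint
  ko <- sel & cd$genotype == "knockout"
  ct <- sel & cd$genotype == "control"
  if (sum(ko) < 2L || sum(ct) < 2L)
    stop("need >= 2 replicates per genotype at timepoint '", timepoint,
         "' (got ", sum(ct), " control, ", sum(ko), " knockout)")
  a <- log2(SummarizedExperiment::assay(x, "abundance") + pseudocount)
  m1 <- rowMeans(a[, ko, drop = FALSE]); n1 <- sum(ko)
  m2 <- rowMeans(a[, ct, drop = FALSE]); n2 <- sum(ct)
  v1 <- apply(a[, ko, drop = FALSE], 1L, stats::var)
  v2 <- apply(a[, ct, drop = FALSE], 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  ## degenerate: zero variance in both groups
  flat <- se2 == 0
  p[flat] <- ifelse(m1[flat] == m2[flat], 1, .Machine$double.xmin)
  p[p == 0] <- .Machine$double.xmin
  data.frame(feature_id = rownames(a), log2_fc = m1 - m2, p = p,
             p_adj = adjustPvalues(p), row.names = NULL)
}

#' Features affected by the genotype contrast
#'
#' Applies the significance and effect-size thresholds to
#' [genotypeEffectTable()].
#'
#' @inheritParams genotypeEffectTable
#' @param fc_threshold minimum absolute log2 fold change
#'   (default `log2(1.5)`).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return character vector of selected feature ids.
#' @export
genotypeEffectGenes <- function(x, timepoint = c("pre", "post", "both"),
                                fc_threshold = log2(1.5), alpha = 0.05,
                                pseudocount = NULL) {
  tab <- genotypeEffectTable(x, timepoint = timepoint,
                             pseudocount = pseudocount)
  tab$feature_id[tab$p_adj < alpha & abs(tab$log2_fc) >= fc_threshold]
}

#' Overlap between two feature sets
#'
#' Reports the shared member count and the percentage of set B that is
#' shared — the "x% (a of b)" framing used to argue that genotype effects
#' and size effects concern different genes. The shared count is
#' symmetric; the percentage refers to B.
#'
#' @param set_a,set_b character vectors of feature ids; `set_b` must be
#'   non-empty.
#' @param name_a,name_b labels carried into the result.
#' @return an [OverlapResult-class].
#' @examples
#' a <- paste0("g", 1:22); b <- paste0("g", 1:526)
#' overlapStats(a, b)  # 22 of 526 = 4%
#' @export
overlapStats <- function(set_a, set_b, name_a = "A", name_b = "B") {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (!length(set_b)) stop("set B is empty; percentage undefined")
  shared <- length(intersect(set_a, set_b))
  methods::new("OverlapResult", nameA = name_a, nameB = name_b,
               sizeA = length(set_a), sizeB = length(set_b),
               nShared = as.integer(shared),
               pctOfB = 100 * shared / length(set_b))
}
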