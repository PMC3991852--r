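## Per-feature size-correlation statistics: Pearson r of abundance against
## relative nuclear radius over all samples, Fisher-z confidence intervals,
## t-based p-values, BH adjustment, and the largest-vs-smallest-cell fold
## change.

#' Renormalise the size gradient to a reference group
#'
#' Divides every sample's relative radius by the mean radius of the
#' reference genotype x timepoint group, so the reference group mean
#' becomes exactly 1. Idempotent once normalised.
#'
#' @param samples sample table data.frame.
#' @param genotype,timepoint the reference group (default control/pre,
#'   the unperturbed liver).
#' @return the sample table with rescaled `relative_radius`.
#' @export
normalizeRadius <- function(samples, genotype = "control",
                            timepoint = "pre") {
  samples <- validateSampleTable(samples)
  ref <- samples$genotype == genotype & samples$timepoint == timepoint
  if (!any(ref))
    stop("reference group ", genotype, "/", timepoint,
         " has no samples")
  samples$relative_radius <-
    samples$relative_radius / mean(samples$relative_radius[ref])
  samples
}

#' Correlate every feature with the cell-size gradient
#'
#' For each feature, the Pearson correlation of abundance with the
#' per-sample relative nuclear radius, computed over all samples. The
#' p-value comes from the t statistic `r * sqrt((n-2) / (1-r^2))` on
#' `n - 2` degrees of freedom (two-sided); the confidence interval from
#' the Fisher z transform at `ci_level` (default 90%, matching the bands
#' a size-scaling analysis typically draws). Features with zero abundance
#' variance get missing r/CI/p and are excluded from the BH adjustment.
#' For a perfect correlation the p-value is reported as the smallest
#' positive double rather than 0, keeping log-scale summaries finite.
#'
#' @param x a [SizeExperiment-class].
#' @param ci_level two-sided confidence level for the Fisher-z interval.
#' @param log2_transform correlate `log2(abundance + pseudocount)` instead
#'   of the linear-scale abundance (default off: expression-versus-radius
#'   trends are near-linear on the measurement scale).
#' @param pseudocount added inside the log and in the size fold change;
#'   default 1 for gene matrices and 0 for metabolite intensities
#'   (strictly positive by construction).
#' @return data.frame with columns `feature_id`, `r`, `ci_low`, `ci_high`,
#'   `p`, `p_adj`, `log2_fc_size`, `mean_abundance`.
#' @examples
#' study <- simulateStudy(seed = 1, n_genes = 50, n_metabolites = 20)
#' head(correlateFeatures(study$genes))
#' @export
correlateFeatures <- function(x, ci_level = 0.90, log2_transform = FALSE,
                              pseudocount = NULL) {
  stopifnot(methods::is(x, "SizeExperiment"))
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must lie in (0, 1)")
  if (is.null(pseudocount))
    pseudocount <- if (featureKind(x) == "gene") 1 else 0
  a <- SummarizedExperiment::assay(x, "abundance")
  n <- ncol(a)
  if (n < 3L) stop("need at least 3 samples to correlate")
  y <- if (log2_transform) log2(a + pseudocount) else a
  radius <- relativeRadius(x)

  yc <- y - rowMeans(y)
  xc <- radius - mean(radius)
  ssy <- rowSums(yc^2)
  ssx <- sum(xc^2)
  r <- as.numeric(yc %*% xc) / sqrt(ssy * ssx)
  r[ssy == 0] <- NA_real_
  if (all(is.na(r))) stop("all features have zero variance")
  r <- pmin(pmax(r, -1), 1)

  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[is.finite(r) & (abs(r) == 1 | p == 0)] <- .Machine$double.xmin

  eps <- .Machine$double.eps
  z <- atanh(pmin(pmax(r, -1 + eps), 1 - eps))
  hw <- stats::qnorm(1 - (1 - ci_level) / 2) / sqrt(n - 3)
  ci_low <- pmin(tanh(z - hw), r)
  ci_high <- pmax(tanh(z + hw), r)

  p_adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_adj[ok] <- adjustPvalues(p[ok])

  data.frame(feature_id = rownames(a), r = r,
             ci_low = ci_low, ci_high = ci_high,
             p = p, p_adj = p_adj,
             log2_fc_size = sizeFoldChange(x, pseudocount = pseudocount),
             mean_abundance = rowMeans(a), row.names = NULL)
}

#' Benjamini-Hochberg adjustment of p-values
#'
#' Step-up false-discovery-rate control; output is monotone in rank,
#' capped at 1 and elementwise no smaller than the input.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param method only `"BH"` is offered.
#' @return adjusted p-values in input order.
#' @export
adjustPvalues <- function(p, method = c("BH")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = method)
}

#' Log2 fold change between the largest and the smallest cells
#'
#' Identifies the design groups with the largest and smallest mean
#' relative radius and returns, per feature,
#' `log2((mean_largest + pseudocount) / (mean_smallest + pseudocount))`
#' using group means over replicates.
#'
#' @param x a [SizeExperiment-class].
#' @param pseudocount stabiliser added to both group means; default 1 for
#'   genes, 0 for metabolites.
#' @return named numeric vector, one value per feature.
#' @export
sizeFoldChange <- function(x, pseudocount = NULL) {
  stopifnot(methods::is(x, "SizeExperiment"))
  if (is.null(pseudocount))
    pseudocount <- if (featureKind(x) == "gene") 1 else 0
  grp <- sampleGroup(x)
  radius <- relativeRadius(x)
  grp_radius <- tapply(radius, grp, mean)
  if (max(grp_radius) == min(grp_radius) ||
      sum(grp_radius == max(grp_radius)) > 1L ||
      sum(grp_radius == min(grp_radius)) > 1L)
    stop("tie for largest/smallest group mean radius; ",
         "select the groups explicitly by subsetting the experiment")
  a <- SummarizedExperiment::assay(x, "abundance")
  largest <- grp == names(which.max(grp_radius))
  smallest <- grp == names(which.min(grp_radius))
  ml <- rowMeans(a[, largest, drop = FALSE])
  ms <- rowMeans(a[, smallest, drop = FALSE])
  stats::setNames(log2((ml + pseudocount) / (ms + pseudocount)),
                  rownames(a))
}

## Shared binning convention: left-closed/right-open bins with a closed
## terminal bin, so a value equal to the last edge is counted exactly once.
.binCounts <- function(values, edges) {
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  idx <- idx[idx >= 1L & idx <= length(edges) - 1L]
  tabulate(idx, nbins = length(edges) - 1L)
}

.correlationBinEdges <- function(bin_width) {
  nb <- ceiling(2 / bin_width)
  seq(-1, by = bin_width, length.out = nb + 1L)
}

#' Histogram and median of the size-correlation distribution
#'
#' Bins the defined per-feature correlations over \[-1, 1\]
#' (left-closed/right-open, final bin closed) and reports the median r —
#' the single-number summary of global transcriptome scaling with cell
#' size.
#'
#' @param table a result of [correlateFeatures()].
#' @param bin_width histogram bin width (default 0.1).
#' @return list with `bin_edges`, `counts`, `median_r`, `n`.
#' @export
correlationDensity <- function(table, bin_width = 0.1) {
  r <- table$r[!is.na(table$r)]
  if (!length(r)) stop("no features with a defined correlation")
  edges <- .correlationBinEdges(bin_width)
  list(bin_edges = edges, counts = .binCounts(r, edges),
       median_r = stats::median(r), n = length(r))
}

#' Mean correlation and fold change by abundance stratum
#'
#' Ranks features by mean abundance (ties broken by table order, stable),
#' splits them into `n_strata` quantile strata and reports mean r and mean
#' size fold change per stratum — the check that a global positive
#' correlation is not driven by downregulation of a few abundant genes.
#'
#' @param table a result of [correlateFeatures()]; rows with missing r are
#'   ignored.
#' @param n_strata number of abundance strata (default 5).
#' @return data.frame: `stratum` (1 = least abundant), `n`,
#'   `mean_abundance`, `mean_r`, `mean_log2_fc`.
#' @export
abundanceStratifiedSummary <- function(table, n_strata = 5L) {
  tab <- table[!is.na(table$r), , drop = FALSE]
  n <- nrow(tab)
  if (n < n_strata)
    stop("fewer features with defined r (", n, ") than strata (",
         n_strata, ")")
  ord <- order(tab$mean_abundance)          # stable: ties keep table order
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  stratum <- floor((rank - 1L) * n_strata / n) + 1L
  out <- do.call(rbind, lapply(seq_len(n_strata), function(s) {
    sel <- stratum == s
    data.frame(stratum = s, n = sum(sel),
               mean_abundance = mean(tab$mean_abundance[sel]),
               mean_r = mean(tab$r[sel]),
               mean_log2_fc = mean(tab$log2_fc_size[sel]))
  }))
  rownames(out) <- NULL
  out
}
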