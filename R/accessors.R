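#' @rdname SizeExperiment-class
#' @param x a `SizeExperiment`
#' @return `relativeRadius` returns the named per-sample relative nuclear
#'   radius; `featureKind` returns `"gene"` or `"metabolite"`;
#'   `sampleGroup` returns the `genotype.timepoint` factor.
#' @export
relativeRadius <- function(x) {
  stopifnot(methods::is(x, "SizeExperiment"))
  stats::setNames(SummarizedExperiment::colData(x)$relative_radius,
                  colnames(x))
}

#' @rdname SizeExperiment-class
#' @export
featureKind <- function(x) {
  stopifnot(methods::is(x, "SizeExperiment"))
  S4Vectors::metadata(x)$kind
}

#' @rdname SizeExperiment-class
#' @export
sampleGroup <- function(x) {
  stopifnot(methods::is(x, "SizeExperiment"))
  cd <- SummarizedExperiment::colData(x)
  interaction(cd$genotype, cd$timepoint, drop = TRUE, sep = ".")
}

#' @rdname SizeExperiment-class
#' @export
sampleTable <- function(x) {
  stopifnot(methods::is(x, "SizeExperiment"))
  cd <- SummarizedExperiment::colData(x)
  data.frame(sample_id = rownames(cd),
             genotype = as.character(cd$genotype),
             timepoint = as.character(cd$timepoint),
             replicate = cd$replicate,
             relative_radius = cd$relative_radius,
             row.names = NULL)
}

#' @rdname GeneSetCollection-class
#' @param x a `GeneSetCollection`
#' @return `geneSets` returns the named list of member id vectors;
#'   `setCategories` the named category vector; `setSizes` the named member
#'   counts.
#' @export
geneSets <- function(x) {
  stopifnot(methods::is(x, "GeneSetCollection"))
  x@sets
}

#' @rdname GeneSetCollection-class
#' @export
setCategories <- function(x) {
  stopifnot(methods::is(x, "GeneSetCollection"))
  stats::setNames(x@category, names(x@sets))
}

#' @rdname GeneSetCollection-class
#' @export
setSizes <- function(x) {
  stopifnot(methods::is(x, "GeneSetCollection"))
  vapply(x@sets, length, integer(1))
}

#' @rdname InteractionNetwork-class
#' @param x an `InteractionNetwork`
#' @return `networkEdges` returns the canonical two-column edge matrix;
#'   `networkNodes` the node ids; `numEdges`/`numNodes` their counts.
#' @export
networkEdges <- function(x) {
  stopifnot(methods::is(x, "InteractionNetwork"))
  x@edges
}

#' @rdname InteractionNetwork-class
#' @export
networkNodes <- function(x) {
  stopifnot(methods::is(x, "InteractionNetwork"))
  x@nodes
}

#' @rdname InteractionNetwork-class
#' @export
numEdges <- function(x) nrow(networkEdges(x))

#' @rdname InteractionNetwork-class
#' @export
numNodes <- function(x) length(networkNodes(x))

#' @rdname ConnectivityResult-class
#' @param x a `ConnectivityResult`
#' @return `enrichmentRatio` returns observed / null-mean edges-per-gene
#'   (`Inf` flags a zero null mean with a non-zero observation);
#'   `empiricalP` the add-one empirical p; `nullValues` the null
#'   edges-per-gene draws.
#' @export
enrichmentRatio <- function(x) {
  stopifnot(methods::is(x, "ConnectivityResult"))
  x@enrichmentRatio
}

#' @rdname ConnectivityResult-class
#' @export
empiricalP <- function(x) {
  stopifnot(methods::is(x, "ConnectivityResult"))
  x@empiricalP
}

#' @rdname ConnectivityResult-class
#' @export
nullValues <- function(x) {
  stopifnot(methods::is(x, "ConnectivityResult"))
  x@nullValues
}

#' Coerce results to one-row data.frames for writing
#'
#' @param x a `ConnectivityResult`, `OverlapResult` or `ScalingProfile`.
#' @param ... ignored.
#' @return a data.frame representation suitable for [writeResultTable()];
#'   for `ScalingProfile` a long format with one row per bin.
#' @name result-coercion
NULL

#' @rdname result-coercion
#' @export
setMethod("as.data.frame", "ConnectivityResult", function(x, ...) {
  data.frame(set = x@setName, set_size = x@setSize,
             observed_edges = x@observedEdges,
             observed_edges_per_gene = x@observedEdgesPerGene,
             null_mean_edges_per_gene = x@nullMean,
             enrichment_ratio = x@enrichmentRatio,
             empirical_p = x@empiricalP,
             n_iterations = x@nIterations,
             exhaustive = x@exhaustive,
             statistic = x@statistic,
             seed = x@seed)
})

#' @rdname result-coercion
#' @export
setMethod("as.data.frame", "OverlapResult", function(x, ...) {
  data.frame(set_a = x@nameA, size_a = x@sizeA,
             set_b = x@nameB, size_b = x@sizeB,
             n_shared = x@nShared,
             pct_of_b = x@pctOfB,
             pct_of_b_rounded = round(x@pctOfB))
})

#' @rdname result-coercion
#' @export
setMethod("as.data.frame", "ScalingProfile", function(x, ...) {
  nb <- length(x@binEdges) - 1L
  data.frame(set = x@setName,
             bin_left = x@binEdges[-(nb + 1L)],
             bin_right = x@binEdges[-1L],
             set_count = x@setCounts,
             background_normalized = x@backgroundCounts)
})

setMethod("show", "SizeExperiment", function(object) {
  cat("SizeExperiment (", featureKind(object), "): ",
      nrow(object), " features x ", ncol(object), " samples\n", sep = "")
  rr <- relativeRadius(object)
  cat("  relative radius range: [", format(min(rr), digits = 3), ", ",
      format(max(rr), digits = 3), "]\n", sep = "")
  cat("  groups:", paste(levels(sampleGroup(object)), collapse = ", "), "\n")
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "set(s)\n")
  if (length(object@sets)) {
    n <- utils::head(names(object@sets), 5L)
    cat("  ", paste0(n, " (", setSizes(object)[n], ")", collapse = ", "),
        if (length(object@sets) > 5L) ", ..." else "", "\n", sep = "")
  }
})

setMethod("show", "InteractionNetwork", function(object) {
  cat("InteractionNetwork:", numNodes(object), "nodes,",
      numEdges(object), "undirected edges\n")
})

setMethod("show", "ScalingProfile", function(object) {
  cat("ScalingProfile '", object@setName, "' (", object@statMode, "): ",
      object@nMembers, " measured members, median ",
      format(object@medianStat, digits = 4), ", KS D = ",
      format(object@ksD, digits = 3), ", p = ",
      format(object@ksP, digits = 3), "\n", sep = "")
})

setMethod("show", "ConnectivityResult", function(object) {
  cat("ConnectivityResult '", object@setName, "': ", object@observedEdges,
      " edges over ", object@setSize, " genes (",
      format(object@observedEdgesPerGene, digits = 4), " per gene)\n",
      "  null mean ", format(object@nullMean, digits = 4),
      ", enrichment ratio ", format(object@enrichmentRatio, digits = 4),
      ", empirical p ", format(object@empiricalP, digits = 3),
      if (object@exhaustive) " (exhaustive null)" else
        paste0(" (", object@nIterations, " iterations)"), "\n", sep = "")
})

setMethod("show", "OverlapResult", function(object) {
  cat("OverlapResult: ", object@nShared, " of ", object@sizeB, " (",
      round(object@pctOfB), "%) of '", object@nameB,
      "' shared with '", object@nameA, "'\n", sep = "")
})
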