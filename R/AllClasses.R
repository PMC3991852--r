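#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

.GENOTYPE_LEVELS <- c("control", "knockout")
.TIMEPOINT_LEVELS <- c("pre", "post")
.FEATURE_KINDS <- c("gene", "metabolite")
.SET_CATEGORIES <- c("subcellular_component", "transcription_factor_family",
                     "lipid_class", "other")

#' SizeExperiment: abundance matrix tied to a cell-size design
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose columns are samples
#' from a genotype x timepoint design carrying a per-sample relative nuclear
#' radius (the cell-size proxy), and whose rows are features (genes or
#' metabolite ions). The single assay `"abundance"` holds non-negative
#' normalised abundances in arbitrary units. The feature kind is stored in
#' `metadata(x)$kind`.
#'
#' Validity requires: unique feature ids; finite, non-negative abundances;
#' colData columns `genotype` (control/knockout), `timepoint` (pre/post),
#' `replicate` (positive integer) and `relative_radius` (positive, with at
#' least two distinct values across samples); unique sample ids; and every
#' genotype x timepoint combination present in the data non-empty.
#'
#' @seealso [SizeExperiment()] for construction from a matrix and sample
#'   table, [relativeRadius()], [featureKind()].
#' @export
setClass("SizeExperiment", contains = "SummarizedExperiment")

setValidity("SizeExperiment", function(object) {
  msgs <- character()
  a <- SummarizedExperiment::assay(object, "abundance")
  if (is.null(rownames(a)) || anyDuplicated(rownames(a)))
    msgs <- c(msgs, "feature ids (rownames) must be present and unique")
  if (any(!is.finite(a)))
    msgs <- c(msgs, "all abundance values must be finite")
  else if (any(a < 0))
    msgs <- c(msgs, "abundance values must be non-negative")
  cd <- SummarizedExperiment::colData(object)
  needed <- c("genotype", "timepoint", "replicate", "relative_radius")
  miss <- setdiff(needed, colnames(cd))
  if (length(miss)) {
    msgs <- c(msgs, paste0("colData is missing column(s): ",
                           paste(miss, collapse = ", ")))
  } else {
    if (is.null(rownames(cd)) || anyDuplicated(rownames(cd)))
      msgs <- c(msgs, "sample ids (colnames) must be present and unique")
    if (!all(as.character(cd$genotype) %in% .GENOTYPE_LEVELS))
      msgs <- c(msgs, "genotype must be 'control' or 'knockout'")
    if (!all(as.character(cd$timepoint) %in% .TIMEPOINT_LEVELS))
      msgs <- c(msgs, "timepoint must be 'pre' or 'post'")
    rr <- cd$relative_radius
    if (!is.numeric(rr) || any(!is.finite(rr)) || any(rr <= 0))
      msgs <- c(msgs, "relative_radius must be finite and > 0 for all samples")
    else if (length(unique(rr)) < 2)
      msgs <- c(msgs, "need at least two distinct relative_radius values")
  }
  kind <- S4Vectors::metadata(object)$kind
  if (is.null(kind) || !kind %in% .FEATURE_KINDS)
    msgs <- c(msgs, "metadata(x)$kind must be 'gene' or 'metabolite'")
  if (length(msgs)) msgs else TRUE
})

#' GeneSetCollection: named sets of feature ids
#'
#' A lightweight container for gene-set (or metabolite-class) collections:
#' a named list of character vectors plus an optional category per set
#' (subcellular_component, transcription_factor_family, lipid_class, other).
#' Set names are unique and members non-empty and deduplicated.
#'
#' @seealso [readGeneSets()], [geneSets()], [setCategories()]
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", category = "character"))

setValidity("GeneSetCollection", function(object) {
  msgs <- character()
  s <- object@sets
  if (length(s)) {
    if (is.null(names(s)) || any(names(s) == "") || anyDuplicated(names(s)))
      msgs <- c(msgs, "set names must be present and unique")
    if (!all(vapply(s, is.character, logical(1))))
      msgs <- c(msgs, "each set must be a character vector of feature ids")
    else {
      if (any(vapply(s, length, integer(1)) == 0L))
        msgs <- c(msgs, "sets must be non-empty")
      if (any(vapply(s, anyDuplicated, integer(1)) > 0L))
        msgs <- c(msgs, "set members must be unique within a set")
    }
  }
  if (length(object@category) != length(s))
    msgs <- c(msgs, "category must have one entry per set (NA allowed)")
  else if (!all(is.na(object@category) | object@category %in% .SET_CATEGORIES))
    msgs <- c(msgs, paste0("category values must be NA or one of: ",
                           paste(.SET_CATEGORIES, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' InteractionNetwork: an undirected interaction network
#'
#' Stores a STRING-like undirected network as a canonical two-column edge
#' matrix: each edge appears once, endpoints sorted lexicographically, no
#' self-loops. The node set is the union of edge endpoints plus any isolated
#' nodes supplied at construction.
#'
#' @seealso [readNetwork()], [networkEdges()], [networkNodes()]
#' @export
setClass("InteractionNetwork",
         representation(edges = "matrix", nodes = "character"))

setValidity("InteractionNetwork", function(object) {
  e <- object@edges
  msgs <- character()
  if (!is.character(e) || ncol(e) != 2L)
    return("edges must be a two-column character matrix")
  if (nrow(e)) {
    if (any(e[, 1L] == e[, 2L]))
      msgs <- c(msgs, "self-loops are not allowed")
    if (any(e[, 1L] > e[, 2L]))
      msgs <- c(msgs, "edge endpoints must be stored in sorted order")
    if (anyDuplicated(paste(e[, 1L], e[, 2L], sep = "\r")))
      msgs <- c(msgs, "duplicate edges are not allowed")
    if (!all(c(e) %in% object@nodes))
      msgs <- c(msgs, "all edge endpoints must be in the node set")
  }
  if (anyDuplicated(object@nodes))
    msgs <- c(msgs, "node ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' ScalingProfile: binned size-scaling profile of one gene set
#'
#' Per-set summary produced by [setScalingProfiles()]: the median of the
#' per-feature statistic (correlation r or log2 fold change) over measured
#' set members, the binned counts of that statistic, the whole-background
#' counts rescaled to the set size, and a two-sample Kolmogorov-Smirnov
#' comparison of set versus background.
#'
#' @export
setClass("ScalingProfile",
         representation(setName = "character", nMembers = "integer",
                        medianStat = "numeric", binEdges = "numeric",
                        setCounts = "integer",
                        backgroundCounts = "numeric",
                        ksD = "numeric", ksP = "numeric",
                        statMode = "character"))

setValidity("ScalingProfile", function(object) {
  msgs <- character()
  nb <- length(object@binEdges) - 1L
  if (length(object@setCounts) != nb || length(object@backgroundCounts) != nb)
    msgs <- c(msgs, "counts must have one entry per bin")
  if (sum(object@setCounts) != object@nMembers)
    msgs <- c(msgs, "set counts must sum to the number of measured members")
  if (abs(sum(object@backgroundCounts) - object@nMembers) > 1e-8)
    msgs <- c(msgs, "normalised background counts must sum to the set size")
  if (object@ksD < 0 || object@ksD > 1)
    msgs <- c(msgs, "ks D must lie in [0, 1]")
  if (!object@statMode %in% c("correlation", "log2fc"))
    msgs <- c(msgs, "statMode must be 'correlation' or 'log2fc'")
  if (length(msgs)) msgs else TRUE
})

#' ConnectivityResult: network connectivity versus a random-set null
#'
#' Result of [connectivityTest()]: the induced edge count and edges-per-gene
#' of a gene set on an [InteractionNetwork], the null distribution of
#' edges-per-gene for random same-size sets, the enrichment ratio
#' (observed / null mean) and an empirical p-value.
#'
#' @export
setClass("ConnectivityResult",
         representation(setName = "character", setSize = "integer",
                        observedEdges = "integer",
                        observedEdgesPerGene = "numeric",
                        nullValues = "numeric", nullMean = "numeric",
                        enrichmentRatio = "numeric", empiricalP = "numeric",
                        nIterations = "integer", exhaustive = "logical",
                        statistic = "character", seed = "integer"))

setValidity("ConnectivityResult", function(object) {
  msgs <- character()
  if (object@setSize > 0 &&
      abs(object@observedEdgesPerGene -
          object@observedEdges / object@setSize) > 1e-12)
    msgs <- c(msgs, "edges-per-gene must equal edges / set size")
  if (object@empiricalP <= 0 || object@empiricalP > 1)
    msgs <- c(msgs, "empirical p must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' OverlapResult: overlap between two feature sets
#'
#' Result of [overlapStats()]: the shared member count and the percentage of
#' the second set that is shared (the paper-style "x% (a of b)" statement).
#' The shared count is symmetric in the two sets; the percentage is not.
#'
#' @export
setClass("OverlapResult",
         representation(nameA = "character", nameB = "character",
                        sizeA = "integer", sizeB = "integer",
                        nShared = "integer", pctOfB = "numeric"))

setValidity("OverlapResult", function(object) {
  msgs <- character()
  if (object@nShared > min(object@sizeA, object@sizeB))
    msgs <- c(msgs, "shared count cannot exceed either set size")
  if (object@pctOfB < 0 || object@pctOfB > 100)
    msgs <- c(msgs, "percentage must lie in [0, 100]")
  if (length(msgs)) msgs else TRUE
})
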