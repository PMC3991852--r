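#' Build a SizeExperiment from an abundance matrix and a sample table
#'
#' Aligns the matrix columns to the sample table rows (by sample id),
#' attaches the design as colData and validates the result. The sample
#' table is the data.frame produced by [readSampleTable()] or
#' [generateDesign()]: columns `sample_id`, `genotype`, `timepoint`,
#' `replicate`, `relative_radius`.
#'
#' @param abundance numeric matrix, features x samples, with rownames
#'   (feature ids) and colnames (sample ids).
#' @param samples sample table data.frame (see [readSampleTable()]).
#' @param kind `"gene"` or `"metabolite"`.
#' @return A validated [SizeExperiment-class] with columns in sample-table
#'   order.
#' @examples
#' design <- generateDesign(n_replicates = 2, seed = 1)
#' m <- matrix(runif(5 * nrow(design), 1, 10), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), design$sample_id))
#' se <- SizeExperiment(m, design, kind = "gene")
#' relativeRadius(se)
#' @export
SizeExperiment <- function(abundance, samples, kind = c("gene", "metabolite")) {
  kind <- match.arg(kind)
  samples <- validateSampleTable(samples)
  if (is.null(colnames(abundance)))
    stop("abundance matrix must carry sample ids as colnames")
  extra <- setdiff(colnames(abundance), samples$sample_id)
  missing <- setdiff(samples$sample_id, colnames(abundance))
  if (length(extra) || length(missing)) {
    stop("sample ids differ between matrix and sample table; ",
         "only in matrix: [", paste(extra, collapse = ", "),
         "]; only in sample table: [", paste(missing, collapse = ", "), "]")
  }
  abundance <- abundance[, samples$sample_id, drop = FALSE]
  cd <- S4Vectors::DataFrame(
    genotype = factor(samples$genotype, levels = .GENOTYPE_LEVELS),
    timepoint = factor(samples$timepoint, levels = .TIMEPOINT_LEVELS),
    replicate = as.integer(samples$replicate),
    relative_radius = as.numeric(samples$relative_radius),
    row.names = samples$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance), colData = cd,
    metadata = list(kind = kind))
  methods::new("SizeExperiment", se)
}

#' Construct a GeneSetCollection from a named list
#'
#' @param sets named list of character vectors of feature ids; duplicate
#'   members within a set are removed.
#' @param category optional character vector (recycled NA) giving one of
#'   `subcellular_component`, `transcription_factor_family`, `lipid_class`,
#'   `other` per set.
#' @return A [GeneSetCollection-class].
#' @export
GeneSetCollection <- function(sets = list(), category = NULL) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(category)) category <- rep(NA_character_, length(sets))
  if (length(category) == 1L && length(sets) > 1L)
    category <- rep(category, length(sets))
  methods::new("GeneSetCollection", sets = sets,
               category = as.character(category))
}

#' Construct an InteractionNetwork from an edge table
#'
#' Edges are undirected: both orientations of a pair collapse to one edge,
#' self-loops are dropped (with a message giving the count), and duplicates
#' are removed.
#'
#' @param edges two-column character matrix or data.frame of endpoint pairs.
#' @param nodes optional additional (possibly isolated) node ids.
#' @return An [InteractionNetwork-class].
#' @examples
#' net <- InteractionNetwork(rbind(c("a", "b"), c("b", "a"), c("a", "a")))
#' numEdges(net)  # 1
#' @export
InteractionNetwork <- function(edges = NULL, nodes = character()) {
  if (is.null(edges) || NROW(edges) == 0L) {
    e <- matrix(character(), ncol = 2L)
  } else {
    e <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(e) <- "character"
    loops <- e[, 1L] == e[, 2L]
    if (any(loops)) {
      message("dropped ", sum(loops), " self-loop(s)")
      e <- e[!loops, , drop = FALSE]
    }
    e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    e <- e[!duplicated(paste(e[, 1L], e[, 2L], sep = "\r")), , drop = FALSE]
    e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  }
  dimnames(e) <- list(NULL, c("node1", "node2"))
  methods::new("InteractionNetwork", edges = e,
               nodes = sort(unique(c(c(e), as.character(nodes)))))
}
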