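#' Validate a sample table data.frame
#'
#' Checks the design invariants: required columns, unique sample ids,
#' genotype/timepoint levels (mapped case-insensitively), positive integer
#' replicates, strictly positive radii and at least two distinct radii.
#'
#' @param samples data.frame with columns `sample_id`, `genotype`,
#'   `timepoint`, `replicate`, `relative_radius`.
#' @return the normalised sample table (lower-case enum values, numeric
#'   radius), invisibly usable anywhere a sample table is expected.
#' @export
validateSampleTable <- function(samples) {
  needed <- c("sample_id", "genotype", "timepoint", "replicate",
              "relative_radius")
  miss <- setdiff(needed, colnames(samples))
  if (length(miss))
    stop("sample table is missing column(s): ", paste(miss, collapse = ", "))
  samples <- as.data.frame(samples)[, needed]
  samples$sample_id <- as.character(samples$sample_id)
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup))
    stop("duplicate sample_id(s): ", paste(unique(dup), collapse = ", "))
  samples$genotype <- tolower(as.character(samples$genotype))
  samples$timepoint <- tolower(as.character(samples$timepoint))
  badg <- which(!samples$genotype %in% .GENOTYPE_LEVELS)
  if (length(badg))
    stop("invalid genotype in row(s) ", paste(badg, collapse = ", "),
         " (expected control/knockout)")
  badt <- which(!samples$timepoint %in% .TIMEPOINT_LEVELS)
  if (length(badt))
    stop("invalid timepoint in row(s) ", paste(badt, collapse = ", "),
         " (expected pre/post)")
  samples$replicate <- as.integer(samples$replicate)
  if (any(is.na(samples$replicate) | samples$replicate < 1L))
    stop("replicate must be a positive integer")
  samples$relative_radius <- as.numeric(samples$relative_radius)
  badr <- which(!is.finite(samples$relative_radius) |
                  samples$relative_radius <= 0)
  if (length(badr))
    stop("non-positive or non-numeric relative_radius in row(s) ",
         paste(badr, collapse = ", "), " (sample ",
         paste(samples$sample_id[badr], collapse = ", "), ")")
  if (length(unique(samples$relative_radius)) < 2L)
    stop("need at least two distinct relative_radius values")
  rownames(samples) <- NULL
  samples
}

#' Read a sample design table from TSV
#'
#' The TSV must have a header with columns `sample_id`, `genotype`
#' (control/knockout, case-insensitive), `timepoint` (pre/post),
#' `replicate` and `relative_radius` (the per-sample relative nuclear
#' radius, unitless, reference group mean = 1).
#'
#' @param path path to the TSV file.
#' @return validated sample table data.frame.
#' @export
readSampleTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validateSampleTable(df)
}

#' Read a feature x sample abundance matrix from TSV
#'
#' First column holds feature ids; remaining columns are samples. If a
#' sample table is supplied, columns are checked against it and reordered
#' to match, and a [SizeExperiment-class] is returned; otherwise the bare
#' matrix is returned.
#'
#' @param path path to the TSV file.
#' @param kind `"gene"` or `"metabolite"`.
#' @param samples optional sample table for alignment.
#' @param na_action `"error"` (default) fails on any missing cell, naming
#'   its coordinates; `"drop"` removes features with missing values and
#'   reports how many were dropped.
#' @return a [SizeExperiment-class] when `samples` is given, else a numeric
#'   matrix with a `kind` attribute.
#' @export
readFeatureMatrix <- function(path, kind = c("gene", "metabolite"),
                              samples = NULL,
                              na_action = c("error", "drop")) {
  kind <- match.arg(kind)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("matrix TSV needs a feature_id column plus samples")
  fid <- as.character(df[[1L]])
  dup <- fid[duplicated(fid)]
  if (length(dup))
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  rownames(m) <- fid
  bad <- which(is.na(m), arr.ind = TRUE)
  if (nrow(bad)) {
    if (na_action == "error") {
      stop("non-numeric or missing value at (feature '",
           rownames(m)[bad[1L, 1L]], "', sample '",
           colnames(m)[bad[1L, 2L]], "')",
           if (nrow(bad) > 1L) paste0(" and ", nrow(bad) - 1L, " more cell(s)"))
    }
    drop <- unique(bad[, 1L])
    message("dropping ", length(drop), " feature(s) with missing values")
    m <- m[-drop, , drop = FALSE]
  }
  if (is.null(samples)) {
    attr(m, "kind") <- kind
    return(m)
  }
  SizeExperiment(m, samples, kind = kind)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member ids. Duplicate members within a set are
#' stored once. An optional category can be carried in the description
#' field (one of subcellular_component, transcription_factor_family,
#' lipid_class, other); anything else becomes `NA`.
#'
#' @param path path to the GMT file.
#' @return a [GeneSetCollection-class].
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(GeneSetCollection())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(short))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(short, collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  category <- ifelse(desc %in% .SET_CATEGORIES, desc, NA_character_)
  GeneSetCollection(sets, category)
}

#' Write a gene-set collection to a GMT file
#'
#' @param x a [GeneSetCollection-class].
#' @param path output path.
#' @export
writeGeneSets <- function(x, path) {
  stopifnot(methods::is(x, "GeneSetCollection"))
  desc <- ifelse(is.na(x@category), "na", x@category)
  lines <- mapply(function(nm, d, members)
    paste(c(nm, d, members), collapse = "\t"),
    names(x@sets), desc, x@sets)
  writeLines(unlist(lines, use.names = FALSE), path)
}

#' Read an undirected interaction network from an edge list
#'
#' Whitespace- or tab-delimited lines `node1 node2 [score]`. Edges listed
#' in both orientations collapse to one; self-loops are dropped with a
#' message; edges with a score below `min_score` are discarded. Lines with
#' fewer than two fields are an error (with the line number).
#'
#' @param path path to the edge-list file.
#' @param min_score minimum confidence score to retain an edge (default 0,
#'   keep everything; scoreless lines are always kept).
#' @return an [InteractionNetwork-class].
#' @export
readNetwork <- function(path, min_score = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  short <- which(vapply(fields, length, integer(1)) < 2L)
  if (length(short))
    stop("edge-list line(s) with fewer than 2 fields: line ",
         paste(idx[short], collapse = ", "))
  if (!length(fields)) return(InteractionNetwork())
  n1 <- vapply(fields, `[[`, character(1), 1L)
  n2 <- vapply(fields, `[[`, character(1), 2L)
  score <- vapply(fields, function(f)
    if (length(f) >= 3L) suppressWarnings(as.numeric(f[3L])) else NA_real_,
    numeric(1))
  ok <- is.na(score) | score >= min_score
  InteractionNetwork(cbind(n1[ok], n2[ok]))
}

#' Write a network as a canonical edge list
#'
#' @param x an [InteractionNetwork-class].
#' @param path output path.
#' @export
writeNetwork <- function(x, path) {
  stopifnot(methods::is(x, "InteractionNetwork"))
  e <- networkEdges(x)
  writeLines(paste(e[, 1L], e[, 2L], sep = "\t"), path)
}

#' Read a lipid-class map from TSV
#'
#' Two columns: `feature_id` (metabolite ion id) and `class` (a LIPID
#' MAPS-style class label such as triacylglycerides).
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `feature_id`, `class`.
#' @export
readLipidClasses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("feature_id", "class") %in% colnames(df)))
    stop("lipid-class TSV needs columns feature_id and class")
  df$feature_id <- as.character(df$feature_id)
  df$class <- as.character(df$class)
  if (anyDuplicated(df$feature_id))
    stop("duplicate feature_id(s) in lipid-class map")
  df[, c("feature_id", "class")]
}

#' Write a result table (or S4 result) as TSV
#'
#' Numeric columns are serialised with 6 significant digits, a stable
#' column order (as given) and a header; reading the file back reproduces
#' the table to serialisation precision. S4 results (`ConnectivityResult`,
#' `OverlapResult`, `ScalingProfile`) are converted with `as.data.frame`
#' first.
#'
#' @param x data.frame or supported S4 result object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(x, path) {
  if (!is.data.frame(x)) x <- as.data.frame(x)
  out <- x
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 6, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a result table written by [writeResultTable()]
#'
#' @param path path to the TSV.
#' @return data.frame.
#' @export
readResultTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a sample table to TSV
#'
#' @param samples sample table data.frame.
#' @param path output path.
#' @export
writeSampleTable <- function(samples, path) {
  samples <- validateSampleTable(samples)
  writeResultTable(samples, path)
}

#' Write the abundance assay of a SizeExperiment to TSV
#'
#' @param x a [SizeExperiment-class] or a features x samples matrix.
#' @param path output path.
#' @export
writeFeatureMatrix <- function(x, path) {
  m <- if (methods::is(x, "SizeExperiment"))
    SummarizedExperiment::assay(x, "abundance") else x
  df <- data.frame(feature_id = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
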