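## Connectivity of size-correlated gene sets on an interaction network,
## tested against a null of uniformly drawn random gene sets of equal size.

#' Select significantly size-correlated features
#'
#' Features with adjusted p below `alpha` whose correlation sign matches
#' the requested direction.
#'
#' @param table a result of [correlateFeatures()].
#' @param direction `"positive"` or `"negative"`.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return character vector of feature ids (possibly empty, with a
#'   message).
#' @export
selectSignificant <- function(table, direction = c("positive", "negative"),
                              alpha = 0.05) {
  direction <- match.arg(direction)
  sgn <- if (direction == "positive") 1 else -1
  sel <- !is.na(table$p_adj) & table$p_adj < alpha &
    sign(table$r) == sgn
  ids <- table$feature_id[sel]
  if (!length(ids))
    message("no features pass p_adj < ", alpha, " with ", direction,
            " correlation")
  ids
}

#' Induced edge count of a gene set
#'
#' Counts network edges with both endpoints in the set. Genes absent from
#' the network contribute no edges but remain in the denominator of
#' edges-per-gene (conservative).
#'
#' @param network an [InteractionNetwork-class].
#' @param genes non-empty character vector of feature ids.
#' @return list with `edges` (integer) and `edges_per_gene`.
#' @export
connectivity <- function(network, genes) {
  stopifnot(methods::is(network, "InteractionNetwork"))
  genes <- unique(genes)
  if (!length(genes)) stop("gene set is empty")
  absent <- sum(!genes %in% networkNodes(network))
  if (absent > 0L)
    message(absent, " gene(s) absent from the network ",
            "(kept in the denominator)")
  e <- networkEdges(network)
  inset <- e[, 1L] %in% genes & e[, 2L] %in% genes
  edges <- sum(inset)
  list(edges = as.integer(edges), edges_per_gene = edges / length(genes))
}

#' Connectivity enrichment against a random-gene-set null
#'
#' Compares the observed edges-per-gene of `genes` with the distribution
#' obtained for random sets of the same size drawn uniformly without
#' replacement from the universe. The enrichment ratio is observed over
#' null mean; the empirical p uses the add-one rule
#' `(1 + #\{null >= observed\}) / (n_iterations + 1)`, so it is never 0.
#' With `exhaustive = TRUE` every subset of the universe is enumerated
#' instead (feasible for small universes) and the p-value is the exact
#' tail fraction without the add-one correction.
#'
#' @param network an [InteractionNetwork-class].
#' @param genes the observed feature set (non-empty).
#' @param n_iterations Monte Carlo draws (default 1000).
#' @param universe ids to draw null sets from: `NULL` (default) uses the
#'   network's node set; a character vector restricts it (e.g. network
#'   nodes intersected with measured features).
#' @param seed integer seed for the null draws.
#' @param exhaustive enumerate all `choose(|universe|, |genes|)` subsets
#'   (guarded to at most 500000 subsets).
#' @param set_name label carried into the result.
#' @return a [ConnectivityResult-class].
#' @examples
#' net <- InteractionNetwork(rbind(c("a","b"), c("b","c"), c("a","c")),
#'                           nodes = c("a","b","c","d","e"))
#' connectivityTest(net, c("a","b","c"), exhaustive = TRUE)
#' @export
connectivityTest <- function(network, genes, n_iterations = 1000L,
                             universe = NULL, seed = 1L,
                             exhaustive = FALSE, set_name = "selected") {
  stopifnot(methods::is(network, "InteractionNetwork"))
  genes <- unique(genes)
  obs <- connectivity(network, genes)
  k <- length(genes)
  if (is.null(universe)) universe <- networkNodes(network)
  universe <- unique(universe)
  if (k > length(universe))
    stop("set size (", k, ") exceeds the universe (", length(universe), ")")

  ## edges as integer endpoint indices into the universe; endpoints outside
  ## the universe can never be in a null set
  e <- networkEdges(network)
  i1 <- match(e[, 1L], universe)
  i2 <- match(e[, 2L], universe)
  keep <- !is.na(i1) & !is.na(i2)
  i1 <- i1[keep]; i2 <- i2[keep]
  nu <- length(universe)

  countFor <- function(idx) {
    m <- logical(nu)
    m[idx] <- TRUE
    sum(m[i1] & m[i2])
  }

  if (exhaustive) {
    if (choose(nu, k) > 5e5)
      stop("exhaustive enumeration infeasible: choose(", nu, ", ", k,
           ") subsets")
    subsets <- utils::combn(nu, k)
    null_epg <- apply(subsets, 2L, countFor) / k
    n_it <- ncol(subsets)
    emp_p <- sum(null_epg >= obs$edges_per_gene) / n_it
    emp_p <- max(emp_p, 1 / (n_it + 1))    # exact tail; keep p > 0
  } else {
    null_epg <- .withSeed(seed, vapply(seq_len(n_iterations), function(b)
      countFor(sample.int(nu, k)), numeric(1))) / k
    n_it <- n_iterations
    emp_p <- (1 + sum(null_epg >= obs$edges_per_gene)) / (n_it + 1)
  }
  null_mean <- mean(null_epg)
  ratio <- if (null_mean == 0) {
    if (obs$edges_per_gene > 0) Inf else NaN
  } else obs$edges_per_gene / null_mean

  methods::new("ConnectivityResult", setName = set_name,
               setSize = as.integer(k),
               observedEdges = obs$edges,
               observedEdgesPerGene = obs$edges_per_gene,
               nullValues = null_epg, nullMean = null_mean,
               enrichmentRatio = ratio, empiricalP = emp_p,
               nIterations = as.integer(n_it),
               exhaustive = exhaustive,
               statistic = "induced_edges_per_gene",
               seed = as.integer(seed))
}
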