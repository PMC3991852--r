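# Independent brute-force oracles, kept deliberately naive and separate from
# the package's vectorised implementations.

# Benjamini-Hochberg step-up, literal definition: adjusted p for the i-th
# smallest p is min over j >= i of min(m * p_(j) / j, 1).
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(vapply(i:m, function(j) min(m * ps[j] / j, 1), numeric(1)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Two-sample KS D by evaluating both ECDFs at every observed point.
ksDOracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

# Pearson r / p / Fisher-z CI via stats::cor.test (an implementation
# entirely separate from the package's matrix-algebra route).
pearsonOracle <- function(y, x, ci_level = 0.90) {
  ct <- stats::cor.test(y, x, method = "pearson", conf.level = ci_level)
  list(r = unname(ct$estimate), p = ct$p.value,
       ci_low = ct$conf.int[1], ci_high = ct$conf.int[2])
}

# Induced edge count by exhaustive enumeration over all pairs in the set.
inducedEdgesOracle <- function(edges, genes) {
  cnt <- 0L
  if (length(genes) < 2L) return(0L)
  key <- paste(pmin(edges[, 1], edges[, 2]),
               pmax(edges[, 1], edges[, 2]), sep = "|")
  cmb <- utils::combn(sort(genes), 2L)
  for (k in seq_len(ncol(cmb))) {
    if (paste(cmb[1, k], cmb[2, k], sep = "|") %in% key) cnt <- cnt + 1L
  }
  cnt
}

# Exhaustive connectivity null: edges-per-gene for every k-subset.
exhaustiveNullOracle <- function(edges, universe, k) {
  subsets <- utils::combn(universe, k)
  apply(subsets, 2L, function(s)
    inducedEdgesOracle(edges, s) / k)
}

# A small fixed design used across unit tests: the four group radii
# duplicated over two replicates each.
toyDesign <- function() {
  data.frame(
    sample_id = paste0("s", 1:8),
    genotype = rep(c("control", "control", "knockout", "knockout"),
                   each = 2),
    timepoint = rep(c("pre", "post", "pre", "post"), each = 2),
    replicate = rep(1:2, times = 4),
    relative_radius = rep(c(1.00, 1.05, 1.30, 2.50), each = 2))
}

toyExperiment <- function(values, kind = "gene") {
  d <- toyDesign()
  m <- matrix(values, ncol = nrow(d), byrow = TRUE)
  rownames(m) <- sprintf("f%02d", seq_len(nrow(m)))
  colnames(m) <- d$sample_id
  SizeExperiment(m, d, kind = kind)
}
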