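# sizeScaling

Cell-size scaling analysis of transcriptomes and metabolomes.

## The problem

When hepatocytes cannot divide (a liver-specific *Cdk1* knockout) and the
liver regenerates after partial hepatectomy, cells grow by hypertrophy.
Together with the control genotype before and after surgery this yields
four nearly isogenic sample groups spanning roughly a 1x–2.5x range of
relative nuclear radius — an in vivo cell-size gradient, with nuclear
radius as the size proxy. `sizeScaling` asks which transcripts,
metabolites, gene sets and network modules scale with that gradient and
which fall behind, for researchers analysing expression or metabolite
matrices against any continuous per-sample size covariate.

## What it computes

For abundances $y_{ij}$ and per-sample relative radii $r_j$:

* **Per-feature statistics** — Pearson $\rho_i = \mathrm{cor}(y_{i\cdot},
  r_\cdot)$ over all samples; two-sided p from
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df; 90% Fisher-z confidence
  intervals; Benjamini–Hochberg adjustment; and the
  largest-versus-smallest-cell fold change
  $\log_2\big((\bar y_\mathrm{largest}+c)/(\bar y_\mathrm{smallest}+c)\big)$.
* **Gene-set scaling profiles** — binned correlation distributions per
  set, overlaid on the whole-background histogram rescaled to the set
  size, plus a two-sample Kolmogorov–Smirnov comparison.
* **Network connectivity** — induced edges-per-gene of the significantly
  size-correlated genes on a STRING-like interaction network, against a
  null of uniformly drawn same-size gene sets (enrichment ratio and
  add-one empirical p).
* **Lipid-class summaries** — median correlation and mean fold change for
  every class with more than four measured metabolites.
* **Genotype/size overlap** — a Welch screen of knockout versus control
  at a fixed timepoint, overlapped with the size-correlated sets as
  "x% (a of b)".
* **Geometry** — the expected membrane-per-volume curve $1/r$ from the
  $r^2$ versus $r^3$ surface/volume scaling argument.

A synthetic-data generator (`simulateStudy()`) emulates the full study
design with planted signal, so the whole pipeline is testable without
any external data. See `vignette("size-scaling-methods")` for the model,
parameter defaults and limitations.

## Worked example

```r
library(sizeScaling)
study <- simulateStudy(seed = 1)              # 1000 genes, 300 metabolites,
ct <- correlateFeatures(study$genes)          # 4 groups x 3 replicates
median(ct$r, na.rm = TRUE)
#> [1] 0.107
profileSummary(setScalingProfiles(ct, study$gene_sets))
#>         set  n  median  ks_D      ks_p  ks_p_adj
#> 1 mito_like 80 -0.8833 0.679 2.23e-308 5.56e-308
#> 3   decoy_1 60 -0.0719 0.220  1.46e-02  1.83e-02
#> 4   decoy_2 60 -0.0296 0.212  2.06e-02  2.06e-02
#> 5   decoy_3 60  0.0707 0.242  5.05e-03  8.42e-03
#> 2 cyto_like 80  0.9476 0.685 2.23e-308 5.56e-308
```

The planted mitochondria-like set scales negatively (median r = −0.88)
and the cytoskeleton-like set positively (0.95), both far from the
annotated background (KS p at the double floor); the global median
(0.107) reflects the planted positive/negative asymmetry. Connectivity
of the significantly negative genes on the simulated network:

```r
neg <- selectSignificant(ct, "negative")
connectivityTest(study$network, neg,
                 universe = intersect(networkNodes(study$network),
                                      ct$feature_id), seed = 1)
#> ConnectivityResult 'selected': 2204 edges over 125 genes (17.63 per gene)
#>   null mean 1.491, enrichment ratio 11.83, empirical p 0.000999 (1000 iterations)
```

i.e. the selected genes carry ~12 times more connections per gene than
random same-size sets. The metabolite side ranks the planted
storage-lipid class first:

```r
lipidClassSummary(correlateFeatures(study$metabolites), study$lipid_classes)
#>         class  n median_r mean_log2_fc
#> 1    TAG_like 30    0.938        1.445
#> 2     FA_like 30    0.107        0.032
#> 3     PL_like 40   -0.168       -0.058
#> 4 sterol_like 20   -0.872       -1.281
```

`runPipeline(list(), out_dir = "run1")` executes every stage in order and
writes all result tables, a config echo, a run log and `summary.json`;
`inst/scripts/run_pipeline.R` wraps it for shell use.

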