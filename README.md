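# regiospec

Comparative transcriptomics of a tissue sampled at several anatomical
regions — e.g. the five commercial beef cuts (tenderloin, longissimus
lumborum, rump, neck, chuck), each with six biological replicates — asks two
questions: which individual genes are *region-specific*, and which
co-expression *modules* track a region as a whole. `regiospec` implements
that analysis as a tidy, fully tested R pipeline, together with a
synthetic-data generator that plants known region markers and modules so
every stage can be benchmarked against ground truth.

## The method

**Expression filtering.** Counts are converted to FPKM
(`10^9 · c_ij / (N_j · L_i)`) and genes are retained when FPKM > 1 in *all*
biological replicates of at least one region, so region-restricted genes
survive the filter.

**Region-specific genes (RSGs).** With `m[g, r]` the mean FPKM of gene *g*
in region *r*, gene *g* is an RSG for focal region *r* when

1. `m[g, r] > 3 · m[g, s]` for every other region *s* (fold criterion),
2. `m[g, r] > 0.5 · mean_{s≠r} m[g, s]` (ratio criterion), and
3. `m[g, r]` lies at or above the 75th percentile of all genes' means in
   region *r* (abundance criterion).

With a fold factor above 1, a gene can be an RSG for at most one region.

**Co-expression modules.** A weighted network is built from scratch:
Pearson correlation on `log2(FPKM + 1)`, soft-power adjacency
`a_ij = |cor_ij|^β` (β = 5 by default, or selected by scale-free fit),
topological overlap `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
average-linkage clustering of `1 − TOM` with a minimum module size, and
eigengene-based merging. Each module is summarised by its eigengene — the
first principal component of the module's standardised expression across
samples.

**Region-specific modules.** A one-hot design matrix **X** (samples ×
regions) is correlated with each eigengene; two-tailed p-values come from
the Student-t transform `t = r·√(n−2)/√(1−r²)`. A (module, region) pair is
called region-specific when `|r| > 0.60` and `p < 1e-2`; negative
associations are retained with their direction.

**Candidates and validation.** Candidate genes are the union of RSGs and
the top hub genes (by |kME|, the gene–eigengene correlation) of each
region-specific module, with provenance. qPCR validation support includes
the `2^−ΔΔCt` transform, Kruskal–Wallis comparison across regions, and
rank concordance between platforms.

## Worked example

The package ships a generator whose defaults emulate the study design
(5 regions × 6 replicates, ~60 % of genes below the expression filter,
6 planted markers per region at 8-fold elevation, 5 planted modules):

```r
library(regiospec)

res <- run_pipeline(pipeline_config(seed = 42), out_dir = tempfile("demo"))

glance(res$network)
#>   n_genes n_modules n_unassigned  beta type
#> 1     798         5          244     5 unsigned

dplyr::filter(res$calls, is_region_specific)
#>   module               region          r            p direction
#> 1      1                 rump  0.9454490 3.619575e-15  positive
#> 2      2           tenderloin  0.9679832 2.394594e-18  positive
#> 3      3                 neck -0.9487924 1.524491e-15  negative
#> 4      4                chuck  0.9635067 1.455322e-17  positive
#> 5      5 longissimus_lumborum -0.9435902 5.719532e-15  negative

res$recovery
#>   rsg_precision rsg_recall module_ari region_call_accuracy
#> 1             1          1          1                    1
```

798 of 2000 simulated genes pass the FPKM > 1 filter; the network recovers
all five planted modules (adjusted Rand index 1 against the planted
labels), each called for its planted region with the planted sign — the two
negatively coupled modules are reported as `negative`, which is why calling
uses |r|. All 30 planted markers are recovered with no false detections
among unplanted genes.

Individual stages compose with the pipe as well:

```r
ds   <- generate_dataset(sim_config(seed = 1))
rsgs <- ds$expr |>
  filter_expressed(ds$meta, threshold = 1) |>
  region_means(ds$meta) |>
  detect_rsgs(fold = 3, quantile = 0.75)
rsg_region_counts(rsgs)
```

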