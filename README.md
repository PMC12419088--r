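# ablayers

Depth-resolved proteome analysis of serially ablated tissue layers.

`ablayers` implements the statistical workflow for spatial proteomics data in
which a nanosecond infrared laser ablates consecutive ~40 µm tissue layers
from the skin surface down into the embryonic mouse cerebral cortex, and each
layer is quantified by label-free LC-MS/MS. The study design it targets has
four genotypes — CTRL (control), GL (LIN28A overexpression), GB (stabilized
CTNNB1), GBL (both) — sampled at two developmental timepoints (E14.5 with 9
layers per hemisphere, E18.5 with 18), in hemisphere replicates, processed in
two nested batch systems (laser-ablation batches and MS measurement batches).

It is written for proteomics analysts who want the depth-profiling analysis as
reusable, tested functions rather than a one-off script collection. No real
data are required: a synthetic-data module generates manifests, abundance
matrices with planted ground truth, gene sets and per-cell histology tables
emulating the study design, so every downstream stage can be exercised and
verified offline.

## What the pipeline computes

Given a log2 abundance matrix (proteins × samples, missing values allowed) and
a sample manifest:

1. **Preprocessing** — per-sample median subtraction (`normalize_median`);
   two-pass batch correction (`batch_correct`): ablation batches corrected per
   protein via class-mean-centred residuals of genotype × layer-block
   reference classes, measurement batches via a linear model with class
   covariates; validity filtering at 70 % (testing) or 100 % (enrichment)
   observed values (`filter_by_validity`).
2. **Layer clusters** — resampling consensus clustering of control samples
   (`consensus_cluster`): subsample 80 % of samples 250 times, Ward-link
   hierarchical clustering on pairwise-complete Euclidean distances, consensus
   = co-clustering fraction among co-selections. The number of clusters k is
   the largest one whose consensus stays unambiguous (PAC ≤ 0.05); each layer
   joins the cluster holding most of its replicates, giving contiguous
   clusters C1, C2, … from the surface inward. Anatomical identity is
   annotated with marker panels (skin FLG/KRT14/LOR, bone
   COL1A1/COL1A2/SERPINF1, meninges CDH11/CRABP2/TAGLN, cortex
   TBR1/MAP2/BCL11B; `marker_panel_profile`).
3. **Layer signatures** — per layer Lₙ, a moderated one-vs-rest test of Lₙ
   against L_all−n (`moderated_layer_de`): empirical-Bayes variance shrinkage
   (inverse-gamma moment matching), moderated t with augmented df, BH
   adjustment. The unique top-10 signature (`unique_top_signatures`) walks
   layers superficial→deep, ranking significantly high-abundant proteins
   (logFC > 0, p < 0.05) by logFC; proteins claimed by an earlier layer are
   skipped — first come, first serve — so signatures are disjoint. Layer
   identity across genotypes is mapped by Pearson correlation of
   signature-protein layer means against every control layer
   (`signature_correlation_map`).
4. **Gene-set depth gradients** — per gene z-scores across layers; a set of m
   quantified genes scores Σzᵢ/√m per layer (`ssgsea_zscore`); OLS of the
   score on layer index over the cortex layers keeps terms with p < 0.05 and
   R² > 0.1 (`gradient_filter`), compared across timepoints
   (`cross_timepoint_direction`).
5. **Term deconvolution** — for precomputed GO:BP parent-term tables,
   `best_match` finds the (genotype, layer) with the highest −log10 mean
   adjusted p, and `diff_score` measures representation spread: per genotype
   the sum of represented layer indices (absent genotypes get
   −n(n+1)/2, i.e. −45 at E14.5 and −171 at E18.5), DiffScore = max − min.
6. **ANCOVA screen** — per layer cluster, abundance ~ layer × genotype for
   CTRL vs one genotype (`ancova_fit`): the interaction term tests slope
   (rate-of-change) differences, the additive model's group term tests
   intercept (level) differences; significant at p < 0.05 with full-model
   R² > 0.1. A three-way Venn over the GL/GB/GBL contrasts yields
   genotype-specific proteins (`model_specific_sets`), optionally annotated
   with LIN28A-partner and literature categories (`annotate_candidates`).
7. **Histomorphometry** — 50 µm distance binning with a closed last edge and
   explicit overflow (`bin_distances`), one-way ANOVA + Tukey HSD on replicate
   means and two-way genotype × bin ANOVA (`migration_summary`), proliferation
   rate = cells⁺/100 µm (`proliferation_rate`), and the BrdU⁺/Ki67⁺
   cell-cycle re-entry 2×2 chi-square with Yates correction (`reentry_test`).

## Worked example

```r
library(ablayers)

man <- build_manifest()          # study design incl. printed QC exclusions
manifest_counts(man, "timepoint")
#>   timepoint   n
#> 1     E14.5 124
#> 2     E18.5 243

sim  <- simulate_abundance(generator_config(), man, seed = 1)
norm <- normalize_median(sim$matrix)
corr <- batch_correct(norm, man, "la_batch", references = reference_classes(man))
corr <- batch_correct(corr, man, "m_batch")

ctrl18 <- man$sample_id[!man$excluded & man$model == "CTRL" & man$timepoint == "E18.5"]
consensus_cluster(corr[, ctrl18], man, k_range = 2:6, seed = 1)
#> Consensus clustering over k = 2, 3, 4, 5, 6 ( 250 resamples )
#> PAC: k=2 0.000  k=3 0.000  k=4 0.126  k=5 0.178  k=6 0.287
#> Selected k = 3
#> Layer clusters:
#>  timepoint cluster layer_index
#>      E18.5      C1       L1-L2
#>      E18.5      C2       L3-L9
#>      E18.5      C3     L10-L18
```

The three recovered clusters are the planted superficial (skin/bone),
meningeal and cortical layer blocks. Building the unique control signatures
and mapping GBL layers onto them shows the planted identity shift — GBL's
superficial layers carry deep-layer proteomes:

```r
tabs <- lapply(1:18, function(L)
  moderated_layer_de(corr, man, L, model = "CTRL", timepoint = "E18.5"))
sig <- unique_top_signatures(tabs)
map <- signature_correlation_map(sig,
  layer_means(corr, man, "CTRL", "E18.5"),
  layer_means(corr, man, "GBL",  "E18.5"))
head(map, 3)
#>   query_layer best_ref_layer    best_r
#> 1           1             15 0.9677157
#> 2           2             15 0.9749450
#> 3           3             11 0.9700328
```

Query layers 1–3 of GBL correlate best with control layers 15, 15 and 11 —
deep cortex (cluster C3) — instead of their own superficial indices. The
DiffScore arithmetic on a term represented in control layers 4, 5 and 7 only:

```r
diff_score(data.frame(term = "t", model = "CTRL", layer = c(4, 5, 7),
                      adj_p = 0.01), n_layers = 9)
#>   term CTRL  GL  GB GBL diff_score
#> 1    t   16 -45 -45 -45         61
```

CTRL sums to 4+5+7 = 16, the three absent genotypes receive the placeholder
−45, and the spread is 61.

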