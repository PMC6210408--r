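# segcca

Global-to-local multivariate genotype–phenotype association for spatially
dense 3D landmark shape data.

`segcca` is for geneticists and morphometricians who have (i) dense landmark
configurations in point-to-point correspondence across individuals — e.g.
facial surface scans mapped with a common symmetric template — (ii) candidate
SNP genotypes coded as additive minor-allele counts, and (iii) standard
covariates, and who want to ask: *does this variant shift shape, and where?*
Instead of preselecting distances or single principal components, the package
tests every variant against a hierarchy of data-driven shape segments, from
the full configuration down to small local patches, in a multivariate
framework.

## The method

For cohorts \(c = 1, 2, 3\) with landmark configurations
\(X_i \in \mathbb{R}^{L \times 3}\) and genotypes \(g \in \{0, 1, 2\}\):

1. **Preprocessing** — generalized Procrustes superimposition (rotation +
   translation; centroid size recorded as the size covariate), symmetrization
   (average of each configuration with its reflected-relabelled copy after
   joint superimposition), Mahalanobis Z-score quality report.
2. **Confounder correction** — shape (flattened) and each genotype are
   residualized on age, age², sex, weight, height, centroid size and four
   ancestry axes by partial least squares (SIMPLS; with as many components as
   covariates this is the exact linear projection), per cohort.
3. **Segmentation** — pairwise landmark covariation is measured with
   Escoufier's RV coefficient,
   \(\mathrm{RV}(X, Y) = \operatorname{tr}(S_{xy} S_{yx}) /
   \sqrt{\operatorname{tr}(S_{xx}^2) \operatorname{tr}(S_{yy}^2)}\),
   and the landmark graph (RV weights on template-adjacent pairs) is
   recursively bipartitioned by normalized-Laplacian spectral clustering into
   a binary tree of depth 5: 63 nested, spatially contiguous segments.
4. **Per-segment shape space** — each segment is re-superimposed across the
   pooled cohorts and summarized by PCA; components are retained by parallel
   analysis (observed eigenvalue above the 95th percentile of
   column-permutation nulls).
5. **Association** — per SNP, segment and cohort, canonical correlation
   analysis between the segment's PC scores and the genotype. With a single
   genotype the canonical correlation is the multiple correlation \(r\),
   Wilks' \(\Lambda = 1 - r^2\), and significance uses Rao's F
   approximation (right tail), \(F = \frac{1 - \Lambda}{\Lambda}
   \cdot \frac{n - p - 1 - c}{p}\) with \(c\) the confounder count.
6. **Round-robin meta-analysis** — each cohort serves once as discovery; the
   other two are projected onto the discovered loadings and tested by
   one-sided linear regression. Each discovery row's three independent
   p-values are combined by Stouffer's method
   \(Z = \sum_i \Phi^{-1}(1 - p_i) / \sqrt{3}\): nine constituent p-values
   and three meta p-values per (SNP, segment).
7. **Multiple testing** — Li–Ji effective numbers of independent segments and
   SNPs from the eigenvalues of their correlation matrices; the adjusted
   threshold is \(\alpha / (M_{seg} \times M_{snp} \times 3)\)
   (e.g. \(0.05 / (37 \times 56 \times 3) = 8.04 \times 10^{-6}\)).

Because raw cohorts of this kind are access-restricted, the package ships a
first-class synthetic-data module: a bilaterally symmetric dense template,
Hardy–Weinberg genotypes, smooth covariate effect fields, and localized
additive SNP displacement fields (pure shape-space effects), over three
cohorts that differ only in size and random stream.

## Worked example

```r
library(segcca)

tpl <- make_template(100, seed = 2)
cfg <- sim_config(n_per_cohort = c(300, 300, 300), L = 100,
                  mafs = c(rs_effect = 0.3, rs_null = 0.4),
                  effect_segments = list(rs_effect = 30:38),
                  effect_size = c(rs_effect = 2),
                  seed = 7)
sim <- simulate_cohorts(tpl, cfg)
res <- run_pipeline(sim, depth = 4, pa_reps = 30, seed = 8)

res$threshold
#> <threshold_spec> 0.05 / (19 x 2 x 3) = 0.000439
nrow(res$tree$nodes)
#> [1] 31
res$significant_snps
#> [1] "rs_effect"
min(res$meta_table$p_meta_cohort_1[res$meta_table$snp_id == "rs_effect"])
#> [1] 0
min(res$meta_table$p_meta_cohort_1[res$meta_table$snp_id == "rs_null"])
#> [1] 0.0958115
```

The tree has 31 segments at depth 4; the Li–Ji effective counts (19
independent segments, 2 independent SNPs) set the adjusted threshold. The
planted variant is significant far below it — its strongest meta p-value
underflows double precision to 0 in the segments overlapping landmarks
30–38 — while the null variant never comes close. The
per-allele displacement for any record can be rendered with
`effect_visualization()`, which exaggerates the mean segment shape along the
minor- and major-allele directions.

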