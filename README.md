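# rdcnv — common CNV association and genotyping from exome read depth

`rdcnv` finds common copy number variants (CNVs) associated with
case-control status in exome capture sequencing data, and produces
absolute copy-number genotypes (CN 0–4) at the loci it flags. It is
aimed at statistical geneticists analysing case-control exome cohorts
where array-based CNV genotyping is unavailable or unreliable, and at
methodologists who need a fully simulated test bed for depth-based CNV
association.

The obstacle to depth-based CNV association is technical structure:
hybridization capture responds to batches, reagent lots and GC content
per region, so a naive scan of depth against phenotype is grossly
inflated. `rdcnv` addresses this with a two-level principal-component
decomposition:

1. **Normalization** — per-base depth divided by sample mean coverage
   over the capture footprint: $r_{ijk} = d_{ijk} / \bar d_k$.
2. **Local PC** — for each capture region $i$, the first principal
   component $\mathrm{FPC}_i$ across samples of the centered
   bases-by-samples matrix $R_i$, computed by a streaming power
   iteration ($t \gets R v$; $v \gets R^\top t/\lVert R^\top t\rVert$)
   that never forms a covariance matrix. It summarizes each sample's
   relative depth in that region.
3. **Global PCs** — the first $K = 50$ right singular vectors
   $g_1, \dots, g_K$ of the stacked (standardized) local PCs: the
   cohort-wide technical directions.
4. **Adjustment** — $\mathrm{FPC}_i^{(H)} = \mathrm{FPC}_i -
   \sum_{h \le H} \frac{\langle \mathrm{FPC}_i, g_h\rangle}
   {\langle g_h, g_h\rangle}\, g_h$ for a grid of $H$.
5. **Association** — logistic regression of phenotype on
   $\mathrm{FPC}_i^{(H)}$ per region, with the genomic-control factor
   $\lambda = \mathrm{median}(\chi^2_{\mathrm{Wald}})/0.4549$,
   quantile-quantile and GC-bias diagnostics along the $H$ grid.
6. **Genotyping** — at a flagged locus, 100-bp window depths (adjusted
   the same way) are fitted with a population hidden Markov model:
   Gaussian emission clusters per copy number initialized at
   $0, 0.5, 1, 1.5, 2$ shared across all samples, sticky transitions
   along windows, 20 rounds of EM; each sample's copy number is its
   maximum mean-posterior state, with calls under a certainty threshold
   set missing.

A synthetic-cohort generator (`simulate_cohort`) produces
Hardy-Weinberg deletion genotypes, phenotypes under a logistic disease
model, and per-base depths with latent-factor batch structure,
two-sample capture arrays, GC sensitivity and negative-binomial noise —
so the entire pipeline is testable end to end without external data.
The methods vignette (`vignettes/read-depth-cnv-pipeline.Rmd`)
documents the model, the parameter choices and the generator's scope.

## Worked example

Simulate a confounded 300-sample cohort (400 regions, every sample's
batch determined by its phenotype's processing wave) carrying one
common deletion (allele frequency 0.6, odds ratio 2) at region
`R00123`, scan it, and genotype a 32.2-kb deletion locus:

```r
library(rdcnv)

cfg <- sim_config(n_case = 150, n_control = 150, n_regions = 400,
                  batch_phenotype_confounding = 1,
                  causal_region_ids = "R00123", odds_ratio = 2, seed = 7)
cohort <- simulate_cohort(cfg)

scan <- run_scan(cohort, H_grid = c(0, 10), K = 40,
                 max_iter = 100, tol = 1e-6)
print(scan)
#> rdcnv scan: 400 regions x 300 samples; K = 40
#>   H0   lambda = 2.498 over 400 regions
#>   H10  lambda = 0.964 over 400 regions
```

Uncorrected, the scan is inflated ($\lambda = 2.5$: the median
association statistic is 2.5 times its null expectation, purely from
batch structure). Projecting out 10 global PCs restores calibration
($\lambda = 0.96$) — and the causal region rises to rank 1:

```r
res <- scan$by_H$H10$results
head(res[order(res$rank), c("region_id", "beta", "wald_chi2",
                            "p_value", "rank")], 3)
#>        region_id  beta wald_chi2  p_value rank
#> R00123    R00123 -12.1     12.66 0.000373    1
#> R00019    R00019  29.6      7.33 0.006772    2
#> R00205    R00205 -23.7      5.68 0.017136    3
```

The negative coefficient says cases sit lower on the adjusted depth
summary — a deletion raising disease risk. Genotyping the wide locus
(322 windows of 100 bp) against the simulator's truth:

```r
locus <- simulate_locus_depth(cohort, 32200)
geno <- run_genotype(locus$depth, locus$interval,
                     scan$local$mean_depths, gpcs = scan$gpcs,
                     H = 10, truth = locus$truth)
unlist(geno$metrics)
#>     accuracy missing_rate     n_called
#>   0.99658703   0.02333333 293.00000000
round(geno$fit$model$means, 3)
#> [1] 0.018 0.491 0.954 1.500 2.000
table(called = geno$calls$copy_number, truth = locus$truth)
#>       truth
#> called   0   1   2
#>      0  95   0   0
#>      1   0 147   0
#>      2   0   1  50
```

The fitted emission clusters sit at normalized depths ~0, 0.5 and 1
(homozygous deletion, heterozygous, diploid; the CN 3–4 clusters hold
no samples and stay frozen at their initial positions), 99.7% of
confident calls match truth, and 2.3% of samples are set missing
rather than called at low certainty.

A command-line wrapper over the same functions is installed at
`inst/scripts/rdcnv.R` with subcommands `simulate`, `scan` and
`genotype`.

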