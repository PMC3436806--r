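---
title: "Detecting and genotyping common CNVs from exome read depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and genotyping common CNVs from exome read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Exome capture sequencing reads a region in proportion to its copy number
in the source DNA, so per-base read depth carries copy-number variant
(CNV) signal. It also carries everything else that perturbs capture
efficiency: array batches, reagent lots, DNA source, GC composition.
A naive depth-phenotype association scan on a case-control cohort is
therefore badly inflated, and the inflation is not removable by a simple
per-sample normalization because the technical effects differ per region.

`rdcnv` implements a two-level principal-component treatment of this
problem, a logistic association scan with genomic-control diagnostics,
and an absolute copy-number genotyper for loci the scan flags.

## The model

**Normalization.** For capture region $i$, base $j$, sample $k$, the
normalized depth is $r_{ijk} = d_{ijk} / \bar d_k$ where $\bar d_k$ is
the sample's mean depth over the capture footprint. We use the footprint
(the union of capture regions) rather than a genome-wide average because
off-target depth is not consistently observed; for a captured cohort the
two are proportional, and the proportionality constant cancels in every
downstream statistic.

**Local first PC.** Within region $i$, the matrix $R_i$ (bases $\times$
samples) is column-centered and its dominant right singular direction
$\mathrm{FPC}_i$ (one loading per sample) is computed by power
iteration: starting from a vector uniform on $(0,1)$, repeat
$t \gets R v$, $v \gets R^\top t / \lVert R^\top t\rVert$ until the
change in $v$ falls below tolerance. This streams one column at a time
and never forms $R R^\top$ or $R^\top R$. The iterate is an application
of a positive semi-definite operator, so its orientation cannot
oscillate. The local PC works because capture efficiency has a strong
per-base profile along each region that is shared across samples: each
sample's column is approximately its relative depth times that profile,
so the covariance of shape recovers per-sample relative depth — the
region's one-number depth summary. The returned vector has unit norm
(the scale of a singular direction is arbitrary; fixing it makes
regression coefficients comparable across regions) and is sign-flipped
to have non-negative inner product with the per-sample mean of the
uncentered matrix, so it is positively oriented with relative copy
number and genotype cluster order is stable.

**Global PCs.** The local PCs are stacked into a regions $\times$
samples matrix; its first $K$ right singular vectors (default $K = 50$)
are the global PCs — cohort-wide technical directions in sample space
(batches, GC sensitivity). These are computed by dense SVD, which is
slower than the iterative scheme but more accurate for the lower-order
components that matter here.

**Row standardization before the global SVD.** The scan pipeline
standardizes every stack row (centers and rescales it to unit norm
across samples) before the SVD. This is a deliberate design choice with
two effects. First, unstandardized rows have wildly different residual
norms once the shared mean-depth component is removed — and a region
carrying a strong common CNV keeps a large-norm row all of its own, so
its genotype direction can surface as a global PC at desk-scale region
counts and the correction then deletes the very signal the scan is
looking for. Equal row weights confine the global PCs to structure
shared across many regions. Second, standardized rows are exactly
orthogonal to the constant vector, hence so are the global PCs, and
projecting them out of a depth profile can never disturb the cohort-wide
mean level — which matters when the same components are projected out of
window depths during genotyping. The module-level SVD
(`compute_global_pcs`) defaults to the plain column-centered contract;
`run_scan` enables `scale_rows`.

**Projection.** The adjusted summary is
$\mathrm{FPC}_i^{(H)} = \mathrm{FPC}_i - \sum_{h\le H}
\frac{\langle \mathrm{FPC}_i, g_h\rangle}{\langle g_h, g_h\rangle} g_h$.
The Rayleigh-quotient form keeps the operator exact for non-normalized
components; with orthonormal components it is the usual projection. It
is idempotent, and the residual is orthogonal to the removed components
to numerical precision.

**Association.** For each region, logistic regression of phenotype on
$\mathrm{FPC}_i^{(H)}$; the Wald $\chi^2_1$ from $\hat\beta/\widehat{se}$
gives the p-value. The predictor is standardized internally (the Wald
statistic is invariant, the IRLS is better conditioned, and the
separation guard — log-odds per standard deviation exceeding 15 —
is meaningful regardless of raw scale). Zero-variance and separated
regions are non-estimable: excluded from ranking and from the inflation
factor rather than assigned an artificial p-value. The genomic-control
factor is $\lambda = \mathrm{median}(\chi^2) / 0.454936423120$, with the
$\chi^2_1$ median fixed to twelve digits for bit-stable output. Ranks
break p-value ties by region id so the scan is independent of input
order.

**Genotyping.** At a flagged locus, depth is averaged in non-overlapping
100-bp windows (anchored at the locus start, trailing partial window
dropped), normalized by sample mean depth, and the first $H$ global PCs
are projected out of every window row. A population hidden Markov model
assigns each sample a copy number in $0..4$: Gaussian emissions per
copy-number state, shared across all samples (every sample informs every
cluster), initial means at $\mathrm{CN}/2 = 0, 0.5, 1, 1.5, 2$, initial
variances $0.01$, a sticky transition matrix (stay probability 0.99 per
100-bp step — a common CNV spans hundreds of windows), and 20 rounds of
expectation maximization updating each state's mean and variance from
posterior-weighted window values pooled over the cohort. A sample's
genotype is the state maximizing its mean posterior across windows; that
maximum is the call's certainty, and calls under a threshold (default
0.9) are set missing — trading call rate for accuracy.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `K` | 50 | components | upper bound on removable structure; needs $\ge K$ samples and regions |
| `H_grid` | 0, 5, 20, 40, 50 | components | inflation is inspected along the grid; use the smallest $H$ with $\lambda \approx 1$ |
| `window_size` | 100 | bp | genotyping resolution vs per-window counting noise |
| `em_iterations` | 20 | — | enough for the cluster means at a common CNV; early-stops on $<10^{-6}$ log-likelihood gain |
| `stay_prob` | 0.99 | per window | CNV segments are long relative to 100 bp |
| `call_threshold` | 0.9 | posterior | below it a call is missing, not guessed |
| `tol`, `max_iter` | 1e-8, 1000 | — | power-iteration stopping; see numerical notes |

**Choosing $H$.** Correction should remove the shared technical
directions and no more. With a few hundred samples, each additional
projected component costs roughly $1/N$ of every region's variance and,
during genotyping, adds per-sample jitter proportional to the component
entries ($\sim 1/\sqrt N$); far beyond the number of real technical
factors this over-projection first erodes genotype cluster separation
and eventually mis-calibrates the scan. At modest region counts there is
a second, subtler cost: a region carrying a strong common CNV slightly
tilts many sub-threshold noise components of the stack toward its
genotype direction even after row standardization, so the cumulative
overlap of a large-$H$ projection with that direction grows well beyond
the $H/N$ random-overlap expectation. Both effects shrink as the number
of stacked regions grows and are negligible at full exome scale
($\sim 10^5$ regions). At desk-scale cohorts we
therefore genotype at moderate $H$ (10–20); cohorts in the thousands of
samples tolerate $H = 40$–$50$ comfortably. The package reports
$\lambda$ along the whole grid precisely so this choice is made on the
inflation trajectory, not by convention.

## What the synthetic cohorts emulate

`simulate_cohort` generates truth genotypes, phenotypes and per-base
depths so that every stage of the pipeline is testable without external
data:

* **Genotypes**: Hardy-Weinberg draws for a biallelic deletion, default
  allele frequency 0.6 — a common deletion at which both heterozygous
  and homozygous carriers are plentiful.
* **Phenotypes**: a per-allele logistic disease model, default odds
  ratio 1.38; the intercept is tuned by root finding so the expected
  case count matches the target, and whole vectors are redrawn until the
  case count is exact (the case-control conditional distribution).
  Default cohort 700 cases / 800 controls at 12–18$\times$ coverage.
* **Technical structure**, hierarchical on the log-depth scale, drawn at
  capture-probe resolution (probes are `region_length_bp` = 200 bp; a
  wide locus spans many probes and averages these effects exactly as
  real capture data do):
  * ten latent factors with strengths $0.1/\sqrt f$ — reagent lots,
    chemistry, processing waves; the low-rank structure global PCs can
    find;
  * iid per-(capture-array, probe) effects (sd 0.03) with two samples
    per array — a high-dimensional noise floor that no small number of
    PCs absorbs, and that keeps any single region's own direction from
    surfacing as a global PC;
  * iid per-(sample, probe) capture noise (sd 0.15) — the unclustered
    residual left after correction;
  * a per-base log-normal capture profile (sd 0.3) shared across
    samples — the covariance-of-shape signal the local PC feeds on;
  * optional per-sample GC sensitivity acting through a quadratic
    response peaking at mid-GC content.
* **Confounding**: with probability `batch_phenotype_confounding` a
  sample is processed in its phenotype's wave; arrays are filled within
  wave and the wave shifts the loadings of the three leading factors.
  Confounded structure is therefore low-rank and removable — which is
  what makes the scan's correction a fair test rather than an impossible
  one.
* **Counting noise**: negative-binomial per base (overdispersion 0.15;
  Poisson when 0).

The magnitudes were chosen once so that a fully confounded 400-sample,
2000-region cohort shows uncorrected inflation of the order reported for
real exome case-control scans (several-fold) while correction restores
$\lambda \approx 1$ — the regime this method exists for.

What the generator does **not** emulate: read-level artifacts
(mappability, duplicates, alignment errors), segmental-duplication
homology, multi-allelic or recurrent CNVs, population stratification,
and correlated noise between adjacent regions. Passing tests show the
statistical machinery behaves as designed under the stated noise model;
they do not certify performance on any particular real dataset.

## Numerical choices

* Power iteration: convergence is the Euclidean change of the normalized
  iterate, tolerance $10^{-8}$, cap 1000 iterations by default. A region
  with two near-equal top singular values converges slowly and is
  returned flagged `converged = FALSE` rather than hidden. Genome-scale
  scans may cap iterations lower (the acceptance-scale runs in this
  package use 75 with tolerance $10^{-6}$): structured regions converge
  in far fewer, and a noise-only region has no preferred direction worth
  resolving — its summary is exchangeable with respect to phenotype
  either way.
* Per-region RNG streams are derived as `seed XOR hash(region_id)`, so
  local PCs do not depend on region processing order.
* Logistic IRLS: deviance tolerance $10^{-12}$ (tight, so Wald standard
  errors are evaluated at the maximum), 25 iterations.
* The EM freezes any state whose posterior occupancy drops below 1% of
  windows $\times$ samples: an unoccupied copy-number state otherwise
  accumulates tail mass and drifts into an occupied cluster over the
  iterations, splitting it and shifting every label above it. Freezing
  is a partial (generalized) EM update, so the log-likelihood remains
  non-decreasing. A variance floor of $10^{-6}$ prevents collapse on
  literally constant clusters (e.g. homozygous deletions with zero
  depth).
* Cluster means are re-sorted after every M-step so the state-to-copy-
  number mapping keeps strictly increasing means.
* Degenerate regions (no depth variance) are dropped from the scan with
  a warning; all-zero samples are an error, not a silent NaN.

## Problem sizes used in the packaged runs

The test suite exercises the full pipeline on simulated cohorts of
2000 regions $\times$ 400 samples (scan behavior), 600–1000 regions for
the genotyping and GC diagnostics, and a 32.2-kb locus (322 windows) for
copy-number calls. The acceptance script runs 2000 regions at the full
700-case / 800-control cohort size. Real exome designs have on the order
of $10^5$ capture regions; all algorithms here are linear in the number
of regions and stream region by region, so the scaling is in wall time,
not memory.

## Known limitations

* The genotyper targets a supplied locus; it does not discover CNV
  boundaries genome-wide (the Viterbi path over windows is exposed for
  segmentation audits, but the per-locus call is the mean posterior).
* Copy numbers above 4 are not modelled.
* The certainty is a max mean posterior; it is well calibrated only as
  far as the Gaussian emission model holds.
* With $H$ approaching the sample count, projection provably removes
  real signal; inspect the $\lambda$ trajectory and cluster-fit trace
  before trusting a heavily corrected result.
* A single cohort-wide association per region is computed; there is no
  multiple-CNV or haplotype modelling.
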