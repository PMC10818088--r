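---
title: "Kinship-aware differential methylation analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinship-aware differential methylation analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinmeth)
```

## The problem kinmeth addresses

Reduced representation bisulfite sequencing (RRBS) measures DNA methylation
as paired counts at each cytosine: methylated reads and total reads. In
small, intensively pedigreed populations — ex situ breeding programmes are
the motivating case — the scientific question is whether per-CpG methylation
covaries with an individual phenotype (lifetime average litter size, sperm
count, seasonal testes firmness) once age and shared ancestry are accounted
for. Two properties of such data drive the design:

* counts are over-dispersed relative to a binomial, because biological
  replicates of the same site differ in their underlying methylation
  fraction; and
* individuals are related, so per-site methylation levels are correlated
  across samples through the pedigree.

`kinmeth` therefore fits, at every CpG site, a **binomial mixed model**

$$y_j \sim \mathrm{Binomial}(r_j, \pi_j), \qquad
\mathrm{logit}(\pi_j) = \mu + \gamma\,\mathrm{age}_j + \beta x_j + g_j + e_j,$$

where $x$ is the phenotype of interest, $g \sim N(0, \sigma_g^2 K)$ is a
genetic random effect with $K$ the pedigree-based additive relationship
matrix, and $e_j \sim N(0, \sigma_e^2)$ is independent residual
over-dispersion. Downstream, extreme sites are called differentially
methylated (DMS) by a dual-percentile rule, aggregated into distance-based
DMclusters, annotated against a gene model, and carried into gene-set
enrichment and interaction-network summaries.

## Fitting: penalized quasi-likelihood

The per-site model is fitted by penalized quasi-likelihood (PQL) rather
than MCMC. Each iteration linearises the model at the current
$\eta = \mathrm{logit}(\pi)$: the working response is
$z = \eta + (y/r - \pi)/(\pi(1-\pi))$ with weights $w = r\pi(1-\pi)$, and
the resulting linear mixed model
$z = X b + u$, $\mathrm{Var}(u) = \sigma_g^2 K + \sigma_e^2 I + W^{-1}$
is solved by generalized least squares. Variance components are
re-estimated at each iteration by restricted likelihood over a bounded
log scale ($[10^{-8}, 10]$): a coarse log-spaced grid locates the basin and
a bounded quasi-Newton step refines it. Iteration stops when the largest
fixed-effect change falls below the tolerance (default $10^{-5}$, cap 50
iterations); non-converged sites are *retained and flagged*, because the
outlier rule below is percentile-based and silently dropping sites would
shift every percentile.

Numerical safeguards: probabilities are clipped to $[10^{-6}, 1-10^{-6}]$
before forming weights, which stabilises sites adjacent to fixation;
monomorphic sites (all $y=0$ or all $y=r$) and constant predictors are
skipped with explicit flags rather than fitted. Predictors are standardised
internally (mean 0, SD 1) so effect sizes are comparable across phenotypes
with very different units; the raw-scale effect is reported alongside
(`beta_raw = beta / sd(x)`).

PQL is deterministic and fast at the scale this pipeline targets (tens of
samples), and its approximation error matters little for a rank-based
outlier rule. Two guards in the test suite quantify the approximation:
with the variance components pinned to zero the fit reproduces ordinary
IRLS binomial regression to $10^{-4}$, and on six-sample kinship toys the
PQL $\hat\beta$ stays within 0.2 of the full maximum-likelihood estimate
obtained by numerically integrating over the joint random effect.

The Wald test uses a **t reference with residual degrees of freedom**
rather than a standard normal. At the sample sizes this package is built
for ($n \le 22$ per analysis) the normal reference is visibly
anti-conservative — on a 20-sample null simulation it yields a type-I rate
of 0.068 and a QQ slope of 1.12, versus 0.050 and 1.00 under the t
reference. The two coincide as $n$ grows.

The random-effect covariance is the additive relationship matrix $A$
itself (diagonal $1+F$), not $A/2$: the scale difference is absorbed by
$\sigma_g^2$, and $A$ keeps the diagonal interpretable. Users with their
own relatedness estimates can pass any positive semi-definite matrix.

## DMS calling, clusters, and annotation

Per analysis (one tissue × phenotype combination), significant DMS are the
joint extremes: effect $\beta$ in the 1st or 99th percentile tails **and**
p-value in the lowest 1st percentile. Quantiles are linear-interpolation
order statistics (R type 7); the definition is configurable because
"percentile" is ambiguous at the margins, and a strict rank cutoff is
available behind a flag. Ties at a threshold are included (≤/≥
comparisons). Quantiles are computed within each analysis over its
non-skipped sites only.

DMclusters are maximal runs of DMS on one scaffold whose consecutive
inter-cytosine distances are strictly below 40 bp; a gap of exactly 40
starts a new cluster. A single linear scan suffices because chaining any
pair closer than 40 bp is equivalent to chaining consecutive sites (the
test suite verifies this against an $O(n^2)$ pairwise-chaining oracle).
Clusters with at least three member DMS feed the network stage. Distances
are simple coordinate differences, strand-agnostic.

Annotation labels each site promoter / exon / intron / intergenic with
precedence promoter > exon > intron. The promoter is the 2 kb window
strictly *upstream* of each transcription start site on the transcript's
strand, clipped at the scaffold start; a symmetric ±2 kb window is
available via a flag since either reading of "within 2 kb of a TSS" is
defensible. Intron means inside a gene span but in no exon of that gene's
(unioned) transcripts. Coordinates are 1-based inclusive at every user
surface and converted to 0-based half-open only inside interval queries
and BED exports.

Enrichment is a one-sided upper-tail hypergeometric test per term
(over-representation), with Benjamini–Hochberg control at FDR 0.05 and the
union of the gene-set collection as the default universe; the universe is
always explicit and overridable, since enrichment backgrounds are the most
common source of irreproducible GO results. Interaction networks keep
edges with confidence ≥ 0.7 (inclusive) from a user-supplied undirected
edge list; seeds absent from the filtered graph remain as isolated nodes
so that "no known interactions" is visible rather than silent.

## The synthetic-data generator

No raw sequence data ships with the package; `simulate_dataset()` generates
CGmap methylomes with the statistical structure the analysis assumes, plus
a truth table for recovery tests. Its defaults emulate the motivating
study design:

* 22 samples from 9 pedigreed individuals across three tissues (8 blood,
  9 testes, 5 sperm), read depth ~25× (truncated Poisson, ≥ 1);
* CG methylation centred at 0.50 with site-to-site logit SD 1.0, against
  near-zero CHG/CHH methylation (0.003);
* tissue logit shifts (blood −0.2, testes 0, sperm +0.4) reproducing the
  sperm-hypermethylation pattern while keeping the grand CG mean at the
  baseline; the age effect enters on centred age for the same reason;
* bisulfite conversion efficiency 99.4%, modelled as a per-read Bernoulli
  misread of unmethylated cytosines, and an unmethylated lambda spike-in
  chromosome from which `conversion_efficiency()` recovers the rate as one
  minus the mean apparent methylation;
* kinship and residual variance components $\sigma_g^2 = \sigma_e^2 =
  0.25$ on the logit scale. These two are free parameters: the motivating
  study reports no per-site dispersion magnitudes, so the values are a
  deliberate, documented choice of "visible but not dominating"
  over-dispersion, not a calibration to any dataset.

Phenotypes follow the shapes of the study's metadata table: lifetime
average litter size is zero-inflated on 0–5 kits (30% zeros), sperm count
per mL is log-normal around 400 million, firmness is Bernoulli(2/3), ages
are 2–6 years. Draws come from a single seeded stream in a fixed
generation order, so identical configurations and seeds give byte-identical
CGmap files; subsetting sites changes downstream draws and is not a
stability contract.

What the generator does **not** emulate — and hence what green tests do not
establish about real RRBS data: fragment-selection clustering of covered
CpGs (sites are uniform on each scaffold), SNP–methylation confounding,
cell-type mixtures within bulk tissues, alignment and mapping error, and
spatial correlation of methylation along the genome beyond what kinship
induces.

## Problem sizes and reproducibility

The calibration checks in the test suite and acceptance script use
simulation sizes chosen to make their statistical tolerances meaningful on
a desk machine: 500 null sites at $n = 20$ for the type-I rate (binomial
SE ≈ 0.01 at $\alpha = 0.05$), 200 causal sites at $n = 50$ and 30× depth
for effect recovery within 20%, and 100-trial randomized comparisons
against brute-force oracles for every combinatorial step. The five-analysis
pipeline demonstration runs 150 CpGs per scaffold on the emulated 22-sample
design. All, from pedigree to BED output, are driven by one integer seed.

## Known limitations

* PQL underestimates variance components for strongly over-dispersed
  binary-like data; with depths ≥ 10× (the default coverage filter) this
  is mild, and the quadrature cross-check bounds the effect on $\beta$.
* The dual-percentile rule always calls ~the configured fraction of sites
  per analysis; it ranks, it does not test. Counts of DMS are therefore
  not comparable across datasets with different site totals.
* Replicate resolution assumes replicate pairs share an individual and
  tissue and that conversion efficiencies are available for both members.
* GFF3 handling expects gene/mRNA (or transcript)/exon features with
  `ID`/`Parent` links; exotic annotation dialects should be converted
  first.
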