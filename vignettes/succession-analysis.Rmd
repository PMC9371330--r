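---
title: "Modelling seasonal succession in phyllosphere fungal communities"
author: "mycodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seasonal succession in phyllosphere fungal communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycodyn)
```

## The scientific problem

Leaf-surface (phyllosphere) fungal communities assemble anew every growing
season. Three forces shape that assembly: the calendar (directional
succession from early colonisers to a late-season climax), the host's
genotype (subpopulations and individual loci that favour or suppress
particular taxa), and fungus–fungus interactions (pathogens, yeasts and the
mycoparasites that attack pathogens covary in networks). `mycodyn`
implements the complete analysis stack needed to quantify these forces in
an OTU count table from a host diversity panel sampled repeatedly through a
season, together with a synthetic data generator that plants all three
signals with known ground truth so that every stage of the pipeline can be
validated end to end.

## The data model

The central object is an `otu_table`: a samples x OTUs count matrix, sample
metadata (genotype, genetic subpopulation, site, timepoint, infection flag,
negative-control flag) and optional per-OTU annotation (taxonomic Class and
functional guild). Negative controls share the sample schema with a boolean
flag rather than living in a separate file; this keeps the decontamination
interface to a single object.

Decontamination scores each OTU with a one-sided Fisher exact test on the
2x2 presence table (controls vs true samples); an OTU is flagged when the
test is significant *and* its control prevalence exceeds its sample
prevalence. The threshold defaults to 0.1. The score is a p-value used as a
ranking statistic, not an inference: the directionality condition is what
prevents abundant real taxa from being discarded.

The normalisation path is fixed as decontaminate, then cumulative sum
scaling (CSS, quantile 0.5), then the Hellinger transform, then Bray-Curtis
dissimilarity. One consequence worth knowing: per-sample CSS scaling
cancels inside the Hellinger relative abundance, so the distances are
identical with or without the CSS step. CSS output is still exposed (and
independently tested) because count-scale output is useful on its own; the
pipeline keeps the full order so each intermediate is available.

## Ordination and permutational inference

* `pcoa()` is classical metric scaling of the Gower-centred matrix
  \(-\tfrac12 J D^2 J\). Negative eigenvalues are dropped and reported;
  variance explained is computed over the positive spectrum.
* `nmds()` minimises Kruskal's stress-1 by alternating weak (primary-tie)
  monotone regression of configuration distances on dissimilarity ranks
  with a Guttman majorization update, over 20 random starts plus one
  PCoA-seeded start (tolerance 1e-6 on the relative stress change, guarded
  so the reported stress sequence never increases). The returned stress
  always equals an independent recomputation from the returned coordinates;
  `shepard()` exposes the (dissimilarity, distance, fitted) triples.
* `permanova()` implements the McArdle–Anderson partition with sequential
  (Type I) sums of squares via incremental orthonormal bases, permuting raw
  sample identities — freely, or within `strata` for paired designs such as
  infected vs symptomless leaves from the same plant. p-values are
  \((b+1)/(n_{perm}+1)\). Marginal (Type III) tests are out of scope.
* `dispersion_homogeneity()` measures distances to group centroids in the
  full principal-coordinate space, subtracting squared contributions of
  negative-eigenvalue axes, with a permutation F test.
* `mantel()` correlates lower triangles of two distance matrices with joint
  row/column permutation.

## Community trajectories

`build_trajectories()` orders each genotype's ordination coordinates by
timepoint. Geometry follows movement ecology: path length, net
displacement, directionality (their ratio), turning angles, and reversals,
where a reversal is a segment whose projection on the subject's net
displacement is negative — a geometric reading of "returning toward an
earlier community state". Group comparisons use one-way ANOVA with Tukey
HSD on path length and on the angle of each subject's net displacement
relative to the grand-mean direction (first two axes by default;
full-dimensional cosines behind a flag).

`trajectory_distance()` is the symmetrised mean point-to-segment distance
between two paths. `otu_removal_influence()` deletes each OTU in turn,
re-runs the fixed protocol (CSS, Hellinger, Bray-Curtis, PCoA), recomputes
mean group trajectories and scores the OTU by the mean trajectory distance
to the originals. Two design choices matter here:

* Trajectories for influence live in the *full positive-eigenvalue PCoA
  space*, because trajectory geometry needs a metric embedding and a
  truncated space makes the score hostage to which axis a noise direction
  lands on.
* Each recomputed ordination is aligned to the original by orthogonal
  Procrustes (rotation/reflection plus translation, no scaling) on the
  shared samples before comparison. PCoA axes are only defined up to
  rotation and sign; without alignment the score measures axis relabelling
  rather than community change.

Significance is a z-score against the all-OTU influence distribution
(flagged at z > 2). This is the package's own rule; the empirical
distribution is heavy-tailed, so the flag should be read as "far outside
the bulk", not as a calibrated error rate.

## Host genetics

Genetic distance is Nei's pi: the expected allele mismatch probability
\((g_i(2-g_j)+g_j(2-g_i))/4\) averaged over pairwise-complete loci. Kinship
is the VanRaden standardised cross-product with missing dosages imputed to
twice the allele frequency. Pseudo-heritability uses single-random-effect
REML on the eigenbasis of the kinship matrix — a one-dimensional profile
optimisation over \(h^2\) that is exact, fast and deterministic; the
standard error comes from the curvature at the optimum. A field-position
random effect is deliberately omitted: it keeps the spectral trick exact
and spatial structure is not part of what the generator plants. The GWAS
scan is single-marker OLS with the top 10 singular vectors of the centred
dosage matrix (or the double-centred genetic distance matrix) as structure
covariates, with Benjamini-Hochberg and Bonferroni thresholds reported
side by side.

## Core taxa, time explainability, indicators

The core selector ranks OTUs by occupancy (ties by mean relative
abundance, then id) and walks down the ranking. The published "2% increase
in beta diversity" rule is stated operationally here: at rank \(k\) the
partial between-group Bray-Curtis \(BC_k\) is the top-\(k\) OTUs' share of
the Bray-Curtis numerator over the full denominator, so \(BC_k\) rises
monotonically to the full between-group dissimilarity and the marginal
contributions \((BC_k - BC_{k-1})/BC_{full}\) are nonnegative and sum to
exactly one. The core is everything up to the last rank contributing at
least the increment (default 0.02). This formulation guarantees the two
limit behaviours a user expects — increment 0 keeps every contributing
OTU, an increment above 1 keeps none — and makes cores nested across
increments. The overall core is the intersection of the subpopulation core
and the timepoint core, in ranking order.

Time explainability (TE) asks, per taxon, how much of its standardised
relative abundance at times \(t > 1\) is explained by the whole community
at the preceding timepoint(s). The previous-community matrix (per-OTU
z-scored, built from earlier timepoints only, so no information leaks
backwards) defines a "community kinship", and the same spectral REML
machinery yields \(TE = \sigma^2_b/(\sigma^2_b+\sigma^2_e)\) with a
\(\tfrac12\chi^2_0 + \tfrac12\chi^2_1\) boundary likelihood-ratio test and
Bonferroni correction. The Markov order defaults to 1 and is a parameter.
One property of compositional data is worth emphasising: when a few
dominant taxa trend strongly through the season, *every* relative
abundance inherits a trend through the shared denominator, so with
realistic power most taxa test significant and the interesting contrast is
the magnitude of TE, not the binary flag. The test suite asserts exactly
that: planted drivers are all significant *and* their TE magnitudes are
enriched over the rest.

Indicator species analysis combines specificity (A, a group's share of the
mean relative abundance) and fidelity (B, within-group occupancy) as
\(IndVal = \sqrt{AB}\), with the max-group statistic tested by label
permutation and summarised both as a z-score and a permutation p-value.

## Covariance networks

Networks are inferred on centred log-ratio (CLR) transformed counts
(pseudocount 1) by stability-selected correlation: an edge is kept when
|r| >= 0.35 in at least 80% of fifty 80% subsamples, signed and weighted
by the full-data correlation. This is a deterministic, dependency-light
surrogate for inverse-covariance (neighbourhood selection) network
inference, not a re-implementation of it; the interface accepts any
samples x OTUs matrix so other backends can be swapped in. Modules come
from greedy modularity maximisation on absolute weights; node roles use
the classical Zi–Pi thresholds (module/network hubs at Zi >= 2.5,
connectors at Pi >= 0.62). Guild summaries report betweenness (unweighted
skeleton), degree and within-module fraction per functional guild; the
two-network comparison statistic is one minus the Spearman correlation of
edge weights over the union of edges, with a permutation null (samples
reassigned to timepoints) and a within-timepoint bootstrap CI.

## What the generator plants, and what it does not

`sim_config()` defaults describe a single-site seasonal survey: 60
genotypes from 3 subpopulations (10% admixed), 5 timepoints, 100 real OTUs
in five guilds plus 5 control-exclusive contaminant OTUs, 500 SNPs at
Fst 0.3, mean depth 5,000, and two negative controls per date. Latent
log-abundances add:

* a per-OTU baseline (the abundance hierarchy);
* directional drift: eight pathogen-guild drivers with alternating-sign
  loadings (early decliners, late bloomers) scaled by `time_shift` (0.8
  per step, well above the latent noise sd of 0.5). Drivers are drawn as
  dominant community members — in real phyllosphere successions the strong
  temporal trends belong to the abundant pathogens — and non-driver taxa
  carry no planted temporal loading, so the recorded driver set is exactly
  the set of temporally structured taxa;
* a subpopulation displacement growing linearly through the season, and a
  polygenic host axis with the same temporal ramp, both supported on
  prevalent non-driver taxa (weights proportional to the square root of
  mean share) so the genetic signal is visible to Bray-Curtis and
  separable from succession — this reproduces the late-season peak in
  host-genetic association;
* one causal SNP (MAF 0.2–0.45) shifting five yeast-guild target OTUs;
* guild-block correlated Gaussian noise (within-guild correlation 0.5),
  and an infection shift along a pathogen-guild direction for the paired
  infected leaves collected from 20% of genotypes at the last two dates.

Counts are multinomial at Poisson depths (compositional closure; no extra
zero inflation), controls carry the contaminants plus sparse low-depth
carryover of the mean community at one tenth of the sample depth, and the
ground-truth record stores the causal SNP, target/driver/contaminant ids,
latent values, per-subpopulation centroids and the realised heritability
of the latent host axis at the final date.

What the generator does *not* emulate: read-level error, chimeras,
over-dispersed (zero-inflated) counts, multiple sites' climates (site is a
categorical label only), temporal autocorrelation in the noise, and
taxonomy strings. Passing tests therefore demonstrate that the algorithms
recover planted structure through multinomial compositional sampling — not
that they are robust to every artefact of real amplicon data.

## Numerical choices and degenerate inputs

All permutation p-values are \((b+1)/(n_{perm}+1)\) with ties counted as
exceedances. Distances are double precision with no snapping. All-zero
samples are dropped with a warning by CSS; all-zero rows map to zeros in
the Hellinger transform; pairs of all-zero rows get Bray-Curtis 0. NMDS
handles ties by primary (weak) monotone regression, pre-sorting tied
dissimilarities by configuration distance — at stress 0 tied recovered
distances may appear in either order, which is the correct weak-tie
semantics. PERMANOVA refuses saturated designs (no residual df), constant
terms, and strata with singleton blocks. REML estimates within
\(10^{-3}\) of 0 or 1 are flagged as boundary estimates. Per-stage seeds
derive from the global seed by stable string hashing, so enabling or
disabling one pipeline stage never shifts another stage's random stream.

Default problem sizes throughout the test suite (and the acceptance
script) are the generator defaults above; calibration checks use 200–500
replicates of small (n = 30) null datasets with 199 permutations, which
characterise the rejection rate to within about one percentage point.

## Known limitations

* The network backend is correlation-based; strong indirect correlations
  can survive stability selection where an inverse-covariance method would
  remove them. Planted-block precision, not exact edge recovery, is the
  tested contract.
* The influence z-score is descriptive, as discussed above.
* TE's binary significance saturates under strong compositional trends;
  compare magnitudes.
* Pseudo-heritability of an ordination axis underestimates the latent-axis
  heritability whenever the axis mixes host-driven and noise directions;
  the acceptance report therefore prints both the realised latent
  heritability and the axis-level REML estimate without equating them.
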