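# mycodyn

Succession analysis for phyllosphere (leaf-associated) fungal microbiomes.

Leaf fungal communities reassemble every growing season, shaped by the
calendar, by host genetics, and by fungus–fungus interactions. `mycodyn`
is an R package for quantifying all three forces in OTU count tables from
host diversity panels sampled repeatedly through a season — the kind of
design where ~100 host genotypes from several genetic subpopulations are
each sampled at ~5 dates, with per-date negative controls and paired
infected/symptomless leaves.

It provides, as one coherent toolkit:

* **Community table management** — TSV/BIOM-JSON I/O, Fisher-exact
  decontamination against negative controls, CSS and Hellinger
  normalisation, Bray–Curtis distances.
* **Ordination and permutational inference** — PCoA; NMDS minimising
  Kruskal stress-1 by monotone regression + majorization; sequential
  (Type I) PERMANOVA via the McArdle–Anderson partition
  (SS(term) = tr(H G), G the Gower-centred matrix), with restricted
  permutations within strata for paired designs; multivariate dispersion
  homogeneity; Mantel tests.
* **Community trajectory analysis** — per-genotype paths through
  ordination space (length, net displacement, directionality, turning
  angles, reversals), group ANOVA + Tukey HSD, mean trajectories, and a
  leave-one-OTU-out influence screen that measures how much deleting each
  taxon moves the mean group trajectories (symmetrised point-to-segment
  trajectory distance, Procrustes-aligned ordinations, z-score flags).
* **Host genetics** — Nei's π genetic distance
  d(i,j) = mean over loci of (gᵢ(2−gⱼ)+gⱼ(2−gᵢ))/4, VanRaden kinship,
  pseudo-heritability h² = σ²g/(σ²g+σ²e) by exact spectral REML,
  single-marker GWAS with SVD population-structure covariates, BH and
  Bonferroni thresholds.
* **Core and temporal screens** — occupancy-ranked core selection under
  the 2% beta-diversity-contribution rule, per-taxon time explainability
  TE = σ²b/(σ²b+σ²e) from sequential linear mixed models on the previous
  timepoint's community, and IndVal indicator species analysis.
* **Covariance networks** — CLR transform, stability-selected correlation
  networks, greedy modularity modules, Zi–Pi node roles (network hubs,
  module hubs, connectors, peripherals), per-guild statistics,
  bootstrap–permutation comparison of timepoint networks, and Class-level
  edge proportions.
* **A synthetic successional-community generator** with recorded ground
  truth (drivers, contaminants, causal SNP, target taxa, latent host
  axis), so every stage above is testable end to end without any external
  data.

## Worked example

Simulate the default study design (60 genotypes × 5 dates, 3 genetic
subpopulations, 100 OTUs + 5 planted contaminants, negative controls,
paired infected leaves), decontaminate, and partition community variation:

```r
library(mycodyn)

ds  <- simulate_dataset(sim_config(seed = 42))
ds$table
#> otu_table: 334 samples x 105 OTUs (10 control samples)

tab <- decontaminate(ds$table)          # drops flagged OTUs + controls
tab
#> otu_table: 324 samples x 100 OTUs (0 control samples)

tab <- subset_table(tab, samples = !tab$sample_meta$infected)
d   <- bray_curtis(hellinger_transform(css_normalize(tab)))

permanova(d ~ timepoint + subpopulation, data = tab$sample_meta,
          n_perm = 999, seed = 1)
#> PERMANOVA (sequential SS, 999 permutations, strata: none)
#>           term  Df SumOfSqs      R2       F     p
#>      timepoint   1   4.7457 0.50297 314.521 0.001
#>  subpopulation   3   0.2385 0.02528   5.269 0.001
#>       Residual 295   4.4512 0.47175      NA    NA
#>          Total 299   9.4354 1.00000      NA    NA

nmds(d, n_restarts = 5, seed = 1)
#> ordination (nmds): 300 samples, 2 axes, stress-1 = 0.1011

select_core(tab, "timepoint")
#> core_set: 68 of 100 OTUs (factor: timepoint, increment 0.020)
```

Half the community variation here is the planted seasonal succession
(`timepoint`, R² = 0.50), a few percent is host subpopulation — growing
through the season by construction — and the NMDS embeds the Bray–Curtis
structure at stress ≈ 0.10. The five planted contaminants were flagged and
removed, and the core selector keeps the OTUs that carry at least 2% of
the between-date Bray–Curtis signal each.

Downstream, `otu_removal_influence()` ranks taxa by how much their removal
bends the mean subpopulation trajectories, `pseudo_heritability()` and
`gwas_scan()` attribute ordination-axis variation to kinship and to
individual SNPs, `time_explainability()` screens for temporally contingent
taxa, and `infer_network()` + `zi_pi()` classify hub taxa in the
covariance network. `run_pipeline()` / `mycodyn_cli()` (and the
`inst/cli/mycodyn` Rscript) orchestrate all stages with per-stage seeds
derived from one global seed.

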