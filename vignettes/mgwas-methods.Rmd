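---
title: "Methods: from gene counts to hypertension-associated MLGs"
author: "gutmgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from gene counts to hypertension-associated MLGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`gutmgwas` re-implements, as a tested R package plus a numbered analysis
workflow (`analysis/01_simulate.R` ... `analysis/06_classification.R`), a
shotgun-metagenomics case/control analysis of the gut microbiome in primary
hypertension: 60 hypertensive patients against 60 matched normotensive
controls. The entry point is a gene × sample matrix of uniquely-mapped read
counts against a reference gene catalog, together with per-gene lengths,
per-sample read totals, gene-level taxonomy and KO annotations, and a
phenotype table. Everything upstream of that matrix — read QC, catalog
alignment, sequence-level functional annotation — is out of scope and
treated as input.

The analysis chain is:

1. **Relative abundance.** For gene $g$ in sample $s$,
   $a_{gs} \propto c_{gs} / (\ell_g \, N_s)$ (count over gene length times
   sample read total), renormalised so each sample sums to 1. Dividing by
   length removes gene-size bias; renormalising makes samples comparable and
   is required for Shannon diversity on "gene relative abundance profiles".
   Renormalisation conditions on mapped reads; samples with no mapped reads
   are kept as flagged zero columns so phenotype alignment never breaks.
2. **Alpha diversity.** Gene count at a fixed rarefied depth (a single
   seeded draw without replacement — multivariate hypergeometric — with an
   optional replicate average), and Shannon index $H = -\sum p \ln p$
   (natural log, the common convention in gut metagenomics).
3. **Beta diversity and ordination.** Bray-Curtis distances between genus
   profiles; distance-based redundancy analysis implemented as principal
   coordinates (Gower-centred $-d^2/2$, eigendecomposition, negative
   eigenvalues discarded) followed by redundancy analysis of the embedding
   on the group indicator. Constrained eigenvalues are sums of squares, the
   same scale `vegan` uses; the tests verify exact agreement with
   `vegan::capscale` and `stats::cmdscale` without calling them in the
   implementation. Taxa loadings are correlations of taxon abundances with
   the two display axes (first constrained, first residual).
4. **Marker genes (MGWAS).** Per-gene Mann-Whitney tests with
   Benjamini-Hochberg FDR; genes with $q < 0.05$ become markers, with an
   enrichment direction from the arithmetic group means. Genes observed in
   fewer than 10% of samples are excluded before testing: rank tests on
   almost-all-zero rows are degenerate and only dilute the FDR budget.
5. **MLGs.** Within each direction stratum, greedy canopy clustering on
   Spearman correlations: the gene with the most neighbours at
   $\rho \ge 0.7$ seeds a cluster, which is re-centred on its medoid and
   re-gathered until stable (≤ 20 rounds); clusters under the minimum size
   dissolve back into the pool. Taxonomy is assigned by voting over member
   genes (≥ 90% agreement for species, else ≥ 80% for genus, else
   unclassified); MLG abundance is the sum of member-gene abundances.
6. **Network, severity, function, classification.** Spearman co-occurrence
   edges at $|\rho| > 0.4$ (strict, no p-value filter), exported as
   SIF/GraphML/TSV; gross abundance of each direction's MLGs tested across
   hypertension stages (all stage pairs, Mann-Whitney + BH, Spearman trend);
   KO and pathway profiles by summing member-gene abundances, with named
   panels for TMA production (cutC, K20038) and SCFA production (K00193,
   K00194, K00197, K14138, K01034, K01035, K00929); random-forest
   classification of disease status from MLG profiles under stratified
   5-fold cross-validation, with AUC computed on pooled out-of-fold
   probabilities.

# Key parameters

| parameter | default | unit | why |
|---|---|---|---|
| rarefaction depth | 50,000 | reads | half the synthetic cohort's mean depth; the real-data analogue is 10 million |
| marker q threshold | 0.05 | — | conventional FDR level |
| prevalence filter | 0.10 | fraction of samples | keeps rank tests non-degenerate |
| genus abundance filter | 5×10⁻⁴ | mean relative abundance | 0.05% display threshold for genus contrasts |
| MLG correlation | 0.70 | Spearman ρ | co-abundance tightness of genes from one genome |
| MLG minimum size | 20 (synthetic) / 100 (catalog scale) | genes | below this, clusters are unstable noise |
| network threshold | 0.40 | \|ρ\|, strict | magnitude-only edge rule |
| forest size | 10,000 | trees | cohort-scale convention; CV-based tests use fewer trees, which changes runtime, not logic |
| bootstrap resamples | 2,000 | — | stratified bootstrap for the AUC CI |

Severity stages follow the classical two-stage clinical bands — stage 1:
SBP 140–159 or DBP 90–99 mm Hg; stage 2: SBP ≥ 160 or DBP ≥ 100 — the only
scheme consistent with a ≥ 140/90 case-entry criterion; the boundaries are
encoded in `assign_stage()` and deliberately not configurable elsewhere, so
every stage-labelled output means the same thing.

# The synthetic cohort generator

Real marker-gene cohorts cannot be shipped with a package, so every claim
the tests make is grounded in `generate_cohort()`, whose ground truth object
is the acceptance surface for recovery tests. The generative model is:

- Species abundance for sample $s$:
  $\log A_{is} = \mu_i + \mathbb{1}\{\text{group matches direction}_i\}\ln f_i
  + \varepsilon_{is}$, $\varepsilon \sim N(0, \sigma^2_{\text{species}})$
  with $\sigma_{\text{species}} = 1$ — log-normal, heavy-tailed, the
  standard picture for gut taxa.
- Member-gene expected share: $A_{is} \, w_g \, e^{\eta_{gs}}$ with fixed
  per-gene weights $w_g \sim \text{lognormal}(0, 0.25)$ and per-sample gene
  noise $\eta \sim N(0, 0.3^2)$. Genes of one species therefore co-vary
  like genes of one genome — the premise the MLG concept rests on.
- Counts: multinomial at a negative-binomial depth
  (mean 100,000 reads, size 5); gene lengths uniform on 300–3,000 bp,
  fixed per gene. Column sums equal drawn depths exactly.
- Phenotypes: SBP/DBP match the cohort-table marginals (cases 165 ± 20 /
  101 ± 11, controls 111 ± 6 / 71 ± 7 mm Hg, truncated to the entry
  criteria), gender 25/35 vs 28/32, smoking 31.7% vs 40.0%, with age, BMI
  and triglycerides at their table means. Case blood pressure is
  rank-coupled to the gross abundance of case-direction species (default
  on), so the severity analysis has a real monotone signal to find.
- KO placement: K20038 on one designated case-direction species; K01034,
  K01035 and K00929 on one control-direction species; generic KOs
  (K10001–K10200, outside any named panel) on a third of remaining genes.

The standard study-condition objects are `planted_truth()` (10 differential
species × 100 genes at fold change 4 — 5 per direction — plus 20 null
species and 500 independent background genes, 60 vs 60) and `null_truth()`
(30 null species, 3,000 genes, 30 vs 30).

**Why the planted design is mass-balanced.** Relative abundances are
compositionally closed: if the planted mass expected in cases exceeds that
in controls, every null gene's relative abundance shifts the other way, and
the marker test will flag genuinely null genes — not a test artifact but a
real property of compositional data. With case- and control-enriched
species paired on base abundance, the expected planted mass cancels between
groups and Benjamini-Hochberg behaves nominally on the null genes (the
suite checks empirical FDR against twice the nominal level). An unbalanced
design is still expressible through `synthetic_truth()`; users probing
compositional artifacts can build one deliberately.

**What the generator does not emulate:** strain-level variation, read-level
errors, correlated species (beyond the group effect — real gut taxa form
guilds, which is why real co-occurrence networks have many positive
within-direction edges while the synthetic ones are dominated by
cross-direction negative edges), unmapped-read loss, a planted alpha- or
beta-diversity difference between groups, and the 5.3-million-gene scale of
a real catalog. Passing recovery tests therefore demonstrates correctness
of the pipeline's logic under a favourable, known model — not field
performance on real cohorts.

# Numerical choices and degenerate inputs

- **Mann-Whitney mode switch**: exact null distribution when the combined
  sample size is ≤ 20 and there are no ties; tie-corrected normal
  approximation (no continuity correction) otherwise. Completely tied data
  returns $p = 1$ rather than NaN. The exact mode is verified against full
  permutation enumeration.
- **Categorical cohort-table test**: Fisher's exact test. On the printed
  gender split (25/35 vs 28/32) Fisher and Yates-corrected chi-square agree
  at 0.713, but on the smoking split (19/41 vs 24/36) the continuity
  -corrected chi-square gives 0.446 while Fisher reproduces the reference
  0.447 at three decimals; both tests are exported, Fisher is the default
  reading. Continuous cohort-table p-values need per-subject raw values and
  are not reproducible from printed summaries.
- **Spearman on constant input** raises an error instead of returning 0: an
  undefined correlation must not masquerade as "no association". Constant
  MLG profiles are excluded from network pairing with a warning.
- **Rarefaction** refuses depths above the sample total (no silent
  with-replacement fallback); samples shallower than the requested depth get
  `NA` richness and are excluded from richness contrasts by the drivers.
- **PCoA negative eigenvalues** are discarded, not Lingoes/Cailliez
  corrected — the axes serve display and group projection only.
- **Canopy tie-breaks**: genes are sorted by id within a direction stratum
  before seeding, and seeds are chosen by neighbour count with first-index
  tie-break, so clustering is invariant to input row order.
- **Determinism**: every stochastic step (generator, rarefaction, CV folds,
  forests, bootstrap) takes a seed and restores the caller's RNG state;
  the pipeline is a pure function of (inputs, config, seed), which the
  suite checks byte-for-byte on re-runs.

# Problem sizes

The shipped workflow and tests run at a deliberately desk-sized scale:
3,500-gene, 120-sample cohorts at ~100,000 reads; 20-seed null
calibrations; 10-seed recovery ensembles; 200-tree forests inside
cross-validated ensembles (10,000 trees in the single-cohort driver).
These sizes make the whole analysis reproducible in minutes while leaving
every algorithmic path identical to a catalog-scale run, where the same
code applies with the minimum MLG size raised to ~100 and the rarefaction
depth to 10 million reads.

# Known limitations

- Rank tests on relative abundances inherit compositional effects; no
  log-ratio or compositional correction is applied, matching the analysis
  being reproduced. SparCC-style network corrections are likewise out of
  scope.
- MLG clustering parameters at catalog scale are not identifiable from a
  printed cluster count alone; they are exposed as configuration and
  validated by planted-partition recovery instead.
- The classifier is evaluated by internal cross-validation only; no
  external-cohort transfer is attempted.
- Covariates (age, BMI, medication) are not adjusted for anywhere, again
  matching the reproduced analysis.
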