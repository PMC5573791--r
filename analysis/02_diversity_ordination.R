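#!/usr/bin/env Rscript
# Stage 2: community structure.
#
# Alpha diversity (rarefied gene count at 50,000 reads, Shannon index on
# gene relative abundances), Bray-Curtis distances between genus
# profiles, dbRDA ordination constrained by disease group, and per-genus
# Mann-Whitney contrasts (mean abundance >= 0.05%, BH-corrected).

library(gutmgwas)

cohort <- read_cohort("results/cohort")
prof <- relative_abundance(cohort$counts)
groups <- cohort$phenotypes$group

div <- suppressWarnings(alpha_diversity(cohort$counts, depth = 50000L, seed = 2L))
write_phenotypes(div, "results/diversity.tsv")
# samples shallower than the rarefaction depth are excluded from the
# richness contrast (their gene count is not defined at this depth)
ok <- !is.na(div$gene_count)
gc_p <- mann_whitney_test(div$gene_count[ok & groups == "case"],
                          div$gene_count[ok & groups == "control"])$p_value
sh_p <- mann_whitney_test(div$shannon[groups == "case"],
                          div$shannon[groups == "control"])$p_value
message(sprintf("alpha diversity (%d samples at depth): gene-count MWU p = %.3g, Shannon MWU p = %.3g",
                sum(ok), gc_p, sh_p))

genus_prof <- aggregate_by_annotation(prof, taxonomy_map(cohort$taxonomy, "genus"),
                                      "genus")
bc <- bray_curtis(genus_prof[rownames(genus_prof) != "unclassified", ,
                             drop = FALSE])
write_matrix(bc, "results/bray_curtis.tsv")

ord <- dbrda_group(bc, groups, genus_prof)
write_matrix(ord$site_scores, "results/ordination_sites.tsv")
write_matrix(ord$taxa_loadings, "results/ordination_loadings.tsv")
message(sprintf("dbRDA: group explains %.1f%% of Bray-Curtis variation",
                100 * ord$constrained_fraction))

genus_tests <- compare_taxa(genus_prof, groups, min_mean_abundance = 5e-4)
write_annotations(genus_tests, "results/genus_tests.tsv")
message(sprintf("genus contrasts: %d/%d genera at q < 0.05",
                sum(genus_tests$q < 0.05), nrow(genus_tests)))
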