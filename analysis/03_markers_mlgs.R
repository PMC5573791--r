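#!/usr/bin/env Rscript
# Stage 3: metagenome-wide association and MLG construction.
#
# Calls marker genes (Mann-Whitney, BH FDR q < 0.05, prevalence >= 10%),
# clusters co-abundant markers into metagenomic linkage groups within
# each enrichment direction (Spearman rho >= 0.7, minimum 20 genes),
# assigns MLG taxonomy by constituent-gene voting, and writes the MLG
# table, memberships and abundance profile.

library(gutmgwas)

cohort <- read_cohort("results/cohort")
prof <- relative_abundance(cohort$counts)
groups <- cohort$phenotypes$group

markers <- identify_markers(prof, groups, q_threshold = 0.05,
                            prevalence_min = 0.1)
write_annotations(as.data.frame(markers), "results/markers.tsv")
message(sprintf("markers: %d of %d tested genes at q < 0.05 (%d case-, %d control-enriched)",
                nrow(markers), attr(markers, "n_tested"),
                sum(markers$direction == "case_enriched"),
                sum(markers$direction == "control_enriched")))

mlgs <- cluster_mlgs(prof[markers$gene_id, , drop = FALSE], markers,
                     corr_threshold = 0.7, min_size = 20L)
mlgs <- annotate_mlgs(mlgs, cohort$taxonomy)
tab <- mlg_table(mlgs)
write_annotations(tab, "results/mlg_table.tsv")
write_annotations(do.call(rbind, lapply(mlgs, function(x)
  data.frame(mlg_id = x$mlg_id, gene_id = x$member_genes))),
  "results/mlg_members.tsv")
write_matrix(mlg_profile(mlgs, prof), "results/mlg_abundance.tsv")
clustered <- sum(tab$size)
message(sprintf("MLGs: %d (%d higher in patients, %d in controls); %.0f%% of markers clustered",
                nrow(tab), sum(tab$direction == "case_enriched"),
                sum(tab$direction == "control_enriched"),
                100 * clustered / nrow(markers)))
message(sprintf("taxonomy: %d at species rank, %d at genus, %d unclassified",
                sum(tab$taxon_rank == "species"),
                sum(tab$taxon_rank == "genus"),
                sum(tab$taxon_rank == "unclassified")))
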