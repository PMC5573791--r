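#!/usr/bin/env Rscript
# Stage 4: MLG co-occurrence network and severity association.
#
# Builds the Spearman co-occurrence network over MLG abundance profiles
# (edge iff |rho| > 0.4), exports it in SIF/GraphML/TSV for network
# viewers, and tests whether the gross abundance of case- and
# control-enriched MLGs tracks the hypertension stage (0 = control,
# 1 = 140-159/90-99, 2 = >=160/>=100 mm Hg).

library(gutmgwas)

cohort <- read_cohort("results/cohort")
prof <- relative_abundance(cohort$counts)
mp <- rel_abundance(read_matrix("results/mlg_abundance.tsv"), "MLG")
tab <- read_annotations("results/mlg_table.tsv")
members <- read_annotations("results/mlg_members.tsv")
mlgs <- structure(lapply(seq_len(nrow(tab)), function(i) {
  structure(list(mlg_id = tab$mlg_id[i],
                 member_genes = members$gene_id[members$mlg_id == tab$mlg_id[i]],
                 direction = tab$direction[i], taxon_name = tab$taxon_name[i],
                 taxon_rank = tab$taxon_rank[i],
                 abundance = mp[tab$mlg_id[i], ]), class = "mlg")
}), class = "mlg_set")

edges <- build_network(mp, threshold = 0.4)
export_network(edges, mlgs, "results/network.sif", "sif")
export_network(edges, mlgs, "results/network.graphml", "graphml")
export_network(edges, mlgs, "results/network_edges.tsv", "tsv")
dirs <- setNames(tab$direction, tab$mlg_id)
same <- dirs[edges$mlg_a] == dirs[edges$mlg_b]
message(sprintf("network: %d edges (%d positive / %d negative); %d/%d within-direction edges positive",
                nrow(edges), sum(edges$sign == "positive"),
                sum(edges$sign == "negative"),
                sum(edges$sign[same] == "positive"), sum(same)))

stages <- cohort$phenotypes$stage
for (dir in c("case_enriched", "control_enriched")) {
  sub <- mlgs_by_direction(mlgs, dir)
  if (!length(sub)) next
  gross <- gross_abundance(sub, prof)
  sa <- stage_association(gross, stages)
  write_annotations(sa$pairs, sprintf("results/severity_%s.tsv", dir))
  message(sprintf("severity (%s): trend rho = %.2f; stage-pair q: %s",
                  dir, sa$trend_rho,
                  paste(sprintf("%d-%d %.2g", sa$pairs$stage_a,
                                sa$pairs$stage_b, sa$pairs$q), collapse = ", ")))
}
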