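#!/usr/bin/env Rscript
# Stage 5: functional contrasts.
#
# Aggregates gene abundances to KEGG orthologs and pathways, then tests
# the pathway categories and the named enzyme panels between groups:
# TMA production (choline-trimethylamine lyase cutC, K20038) and SCFA
# production (acetyl-CoA decarbonylase/synthase, butyryl-CoA:acetate
# CoA-transferase, butyrate kinase).

library(gutmgwas)

cohort <- read_cohort("results/cohort")
prof <- relative_abundance(cohort$counts)
groups <- cohort$phenotypes$group

kp <- ko_profile(prof, cohort$ko_map)
pw <- pathway_profile(kp, cohort$ko_pathway)
pw_tests <- compare_features(as.matrix(pw), groups, "pathway")
write_annotations(pw_tests, "results/pathway_tests.tsv")
message(sprintf("pathways: %d/%d at q < 0.05",
                sum(pw_tests$q < 0.05), nrow(pw_tests)))

panels <- compare_panels(kp, default_panels(), groups)
write_annotations(panels$panels, "results/panel_tests.tsv")
write_annotations(panels$kos, "results/panel_ko_tests.tsv")
for (i in seq_len(nrow(panels$panels))) {
  r <- panels$panels[i, ]
  message(sprintf("%s: %s (q = %.2g, %d KO present)",
                  r$panel, r$direction, r$q, r$n_ko_present))
}
miss <- unlist(panels$missing)
if (length(miss))
  message("panel KOs absent from this cohort: ", paste(miss, collapse = ", "))
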