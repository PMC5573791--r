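#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates a synthetic 60-case / 60-control marker-gene cohort with ten
# differential species (5 enriched in hypertensive cases, 5 in controls,
# fold change 4), twenty null species, and 500 background genes, with
# blood pressure rank-coupled to the case-direction species load. Writes
# the cohort tables (counts, lengths, taxonomy, KO maps, phenotypes,
# ground truth) under results/cohort/.

library(gutmgwas)

seed <- 1L
truth <- planted_truth(seed = seed)
cohort <- generate_cohort(truth)

dir.create("results", showWarnings = FALSE)
write_cohort(cohort, "results/cohort")

cnt <- cohort$counts$counts
message(sprintf("cohort: %d genes x %d samples, median depth %s reads",
                nrow(cnt), ncol(cnt),
                format(median(colSums(cnt)), big.mark = ",")))
message(sprintf("planted: %d differential species (%d case-, %d control-enriched)",
                sum(truth$species_table$direction != "null"),
                sum(truth$species_table$direction == "case"),
                sum(truth$species_table$direction == "control")))
message(sprintf("stages among cases: %s",
                paste(names(table(cohort$phenotypes$stage[
                  cohort$phenotypes$group == "case"])),
                  table(cohort$phenotypes$stage[
                    cohort$phenotypes$group == "case"]),
                  sep = "=", collapse = ", ")))
message("written: results/cohort/")
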