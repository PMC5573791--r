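# markers table shaped like identify_markers() output
fake_markers <- function(gene_ids, direction) {
  structure(data.frame(gene_id = gene_ids, p_value = 1e-6, q_value = 1e-5,
                       direction = direction, mean_case = 1, mean_control = 0,
                       stringsAsFactors = FALSE),
            class = c("marker_genes", "data.frame"))
}

test_that("perfectly co-abundant genes form a single MLG", {
  set.seed(61)
  base <- rlnorm(40)
  # 25 genes on one trajectory with mild per-sample gene noise (a pure
  # rank-one profile would renormalise to constant rows)
  m <- outer(rlnorm(25, 0, 0.05), base) * rlnorm(25 * 40, 0, 0.1)
  dimnames(m) <- list(paste0("g", 1:25), paste0("s", 1:40))
  prof <- rel_abundance(m, "gene")
  mk <- fake_markers(rownames(m), "case_enriched")
  mlgs <- cluster_mlgs(prof, mk, min_size = 5)
  expect_length(mlgs, 1)
  expect_setequal(mlgs[[1]]$member_genes, rownames(m))
  expect_equal(mlgs[[1]]$direction, "case_enriched")
})

test_that("independent planted species are recovered as separate MLGs (ARI 1)", {
  set.seed(62)
  t1 <- rlnorm(50); t2 <- rlnorm(50)       # independent trajectories
  m <- rbind(outer(rlnorm(20, 0, 0.05), t1), outer(rlnorm(20, 0, 0.05), t2))
  m <- m * rlnorm(length(m), 0, 0.1)
  dimnames(m) <- list(paste0("g", 1:40), paste0("s", 1:50))
  prof <- rel_abundance(sweep(m, 2, colSums(m), "/"), "gene")
  mk <- fake_markers(rownames(m), "case_enriched")
  mlgs <- cluster_mlgs(prof, mk, min_size = 5)
  expect_length(mlgs, 2)
  truth <- rep(1:2, each = 20)
  found <- integer(40)
  for (i in seq_along(mlgs))
    found[match(mlgs[[i]]$member_genes, rownames(m))] <- i
  expect_equal(mclust::adjustedRandIndex(truth[found > 0], found[found > 0]), 1)
})

test_that("mutually independent genes yield no MLGs", {
  set.seed(63)
  m <- matrix(rlnorm(30 * 60), 30, 60,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:60)))
  prof <- rel_abundance(sweep(m, 2, colSums(m), "/"), "gene")
  mk <- fake_markers(rownames(m), "control_enriched")
  expect_length(cluster_mlgs(prof, mk, min_size = 5), 0)
  expect_error(cluster_mlgs(prof, mk, corr_threshold = 1.2), "corr_threshold")
})

test_that("clusters are disjoint, direction-pure and internally correlated", {
  run <- planted_run(1)
  mlgs <- run$mlgs
  expect_gt(length(mlgs), 0)
  all_members <- unlist(lapply(mlgs, `[[`, "member_genes"))
  expect_equal(anyDuplicated(all_members), 0)
  expect_true(all(all_members %in% run$markers$gene_id))
  m <- as.matrix(run$profile)
  for (mlg in mlgs) {
    dirs <- run$markers$direction[match(mlg$member_genes, run$markers$gene_id)]
    expect_true(all(dirs == mlg$direction))
    rho <- cor(apply(m[mlg$member_genes, ], 1, rank))
    expect_gte(mean(rho[upper.tri(rho)]), 0.7 - 0.05)
  }
})

test_that("taxonomic voting follows the species/genus fraction thresholds", {
  tax <- data.frame(gene_id = paste0("g", 1:10),
                    phylum = "p", genus = "G",
                    species = c(rep("X", 9), "Y"),
                    stringsAsFactors = FALSE)
  mlg <- structure(list(mlg_id = "MLG_001", member_genes = paste0("g", 1:10),
                        direction = "case_enriched",
                        taxon_name = "unclassified",
                        taxon_rank = "unclassified", abundance = numeric()),
                   class = "mlg")
  # unanimity and 9/10 at species_frac 0.9 both give species X
  expect_equal(assign_taxonomy(mlg, within(tax, species <- "X"))$taxon_name, "X")
  got <- assign_taxonomy(mlg, tax)
  expect_equal(got$taxon_name, "X"); expect_equal(got$taxon_rank, "species")
  # 6/10 species X but 9/10 genus G -> genus fallback
  tax2 <- tax
  tax2$species <- c(rep("X", 6), rep("Y", 4))
  tax2$genus <- c(rep("G", 9), "H")
  got2 <- assign_taxonomy(mlg, tax2)
  expect_equal(got2$taxon_name, "G"); expect_equal(got2$taxon_rank, "genus")
  # no annotation at all -> unclassified
  got3 <- assign_taxonomy(mlg, tax[0, ])
  expect_equal(got3$taxon_rank, "unclassified")
})

test_that("MLG abundance is the additive sum of member genes", {
  prof <- rel_abundance(matrix(c(0.1, 0.2, 0.7), 3, 2,
                               dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
  single <- structure(list(mlg_id = "m", member_genes = "b",
                           direction = "case_enriched", taxon_name = "u",
                           taxon_rank = "unclassified", abundance = numeric()),
                      class = "mlg")
  expect_equal(mlg_abundance(single, prof), prof["b", ])
  pair <- single; pair$member_genes <- c("a", "b")
  expect_equal(unname(mlg_abundance(pair, prof)), c(0.3, 0.3))
  bad <- single; bad$member_genes <- c("a", "zz")
  expect_error(mlg_abundance(bad, prof), "zz")
})

test_that("recovered MLGs track true species abundance and taxonomy", {
  run <- planted_run(1)
  st <- run$truth$species_table
  n_diff <- sum(st$direction != "null")
  expect_lte(abs(length(run$mlgs) - n_diff), 2)
  tab <- mlg_table(run$mlgs)
  correct <- vapply(run$mlgs, function(mlg) {
    sp <- run$cohort$taxonomy$species[match(mlg$member_genes,
                                            run$cohort$taxonomy$gene_id)]
    modal <- names(sort(table(sp), decreasing = TRUE))[1]
    mlg$taxon_rank == "species" && mlg$taxon_name == modal
  }, logical(1))
  expect_gte(mean(correct), 0.8)

  # zero-gene-noise check: MLG abundance tracks the species' read share
  st0 <- data.frame(species_id = "spZ", genus = "gZ", phylum = "p",
                    n_genes = 30L, base_log_abundance = 0, fold_change = 1,
                    direction = "null", stringsAsFactors = FALSE)
  co <- generate_cohort(synthetic_truth(st0, background_genes = 200L,
                                        gene_noise_sigma = 0,
                                        n_case = 20, n_control = 20, seed = 64))
  prof <- relative_abundance(co$counts)
  sp_genes <- grep("^spZ", rownames(co$counts$counts), value = TRUE)
  mk <- fake_markers(sp_genes, "case_enriched")
  mlgs <- cluster_mlgs(prof[sp_genes, , drop = FALSE], mk, min_size = 10)
  expect_length(mlgs, 1)
  species_share <- colSums(co$counts$counts[sp_genes, ]) /
    colSums(co$counts$counts)
  expect_gt(spearman_rho(mlg_abundance(mlgs[[1]], prof), species_share), 0.99)
})
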