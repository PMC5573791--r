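test_that("truth constructor enforces its invariants", {
  st <- data.frame(species_id = "a", genus = "g", phylum = "p", n_genes = 5L,
                   base_log_abundance = 0, fold_change = 2,
                   direction = "case", stringsAsFactors = FALSE)
  expect_s3_class(synthetic_truth(st), "synthetic_truth")
  bad <- st; bad$fold_change <- 1        # fold 1 must mean null
  expect_error(synthetic_truth(bad), "fold_change")
  bad <- st; bad$direction <- "null"     # null must mean fold 1
  expect_error(synthetic_truth(bad), "fold_change")
  expect_error(synthetic_truth(st, n_case = 1), "2 samples")
  expect_error(synthetic_truth(st, depth_mean = 0), "1 read")
})

test_that("zero-noise single-species cohort follows the multinomial expectation", {
  st <- data.frame(species_id = "a", genus = "g", phylum = "p", n_genes = 10L,
                   base_log_abundance = 0, fold_change = 1,
                   direction = "null", stringsAsFactors = FALSE)
  tr <- synthetic_truth(st, gene_noise_sigma = 0, sigma_species = 0,
                        n_case = 2L, n_control = 2L,
                        depth_mean = 200000L, seed = 4L)
  co <- generate_cohort(tr)
  counts <- co$counts$counts[, 1]
  # recover gene weights from truth RNG order: weights drawn first
  w <- gutmgwas:::.seeded(4L, stats::rlnorm(10, 0, 0.25))
  expected <- sum(counts) * w / sum(w)
  gof <- suppressWarnings(chisq.test(counts, p = w / sum(w)))
  expect_gt(gof$p.value, 0.01)
  expect_lt(max(abs(counts - expected) / expected), 0.2)
})

test_that("generation is deterministic under the truth seed", {
  tr <- null_truth(seed = 9, n_case = 3, n_control = 3)
  a <- generate_cohort(tr); b <- generate_cohort(tr)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$ko_map, b$ko_map)
})

test_that("column sums equal the drawn depths exactly", {
  co <- generate_cohort(planted_truth(seed = 2, n_case = 5, n_control = 5))
  expect_identical(unname(colSums(co$counts$counts)),
                   as.numeric(co$counts$sample_totals))
})

test_that("planted fold changes are recovered in species-level mean abundance", {
  ok <- vapply(1:20, function(s) {
    tr <- planted_truth(seed = 100 + s)
    co <- generate_cohort(tr)
    prof <- relative_abundance(co$counts)
    sp_prof <- aggregate_by_annotation(prof, taxonomy_map(co$taxonomy, "species"),
                                       "species")
    st <- tr$species_table
    is_case <- co$phenotypes$group == "case"
    n_ok <- 0L
    for (i in which(st$direction != "null")) {
      ab <- as.matrix(sp_prof)[st$species_id[i], ]
      ratio <- mean(ab[is_case]) / mean(ab[!is_case])
      if (st$direction[i] == "control") ratio <- 1 / ratio
      if (ratio >= 2.5 && ratio <= 6) n_ok <- n_ok + 1L
    }
    n_ok
  }, integer(1))
  expect_gte(median(ok), 8)
})

test_that("within-species gene correlation exceeds between-species correlation", {
  run <- planted_run(1)
  m <- as.matrix(run$profile)
  tx <- run$cohort$taxonomy
  g1 <- tx$gene_id[!is.na(tx$species) & tx$species == "sp01"][1:20]
  g2 <- tx$gene_id[!is.na(tx$species) & tx$species == "sp03"][1:20]
  r1 <- cor(apply(m[g1, ], 1, rank))
  r12 <- cor(apply(m[g1, ], 1, rank), apply(m[g2, ], 1, rank))
  expect_gt(mean(r1[upper.tri(r1)]), mean(r12))
  expect_gt(mean(r1[upper.tri(r1)]), 0.5)
})

test_that("phenotypes respect the cohort entry criteria and marginals", {
  co <- generate_cohort(planted_truth(seed = 3))
  ph <- co$phenotypes
  case <- ph[ph$group == "case", ]; ctl <- ph[ph$group == "control", ]
  expect_true(all(case$sbp >= 140 | case$dbp >= 90))
  expect_true(all(ctl$sbp <= 120 & ctl$dbp <= 80))
  expect_true(all(ctl$stage == 0))
  expect_true(all(case$stage %in% 1:2))
  expect_equal(sum(case$gender == "F"), 25)
  expect_equal(sum(ctl$gender == "F"), 28)
  expect_equal(sum(case$smoke), 19)
  expect_equal(sum(ctl$smoke), 24)
  expect_gt(mean(case$sbp), mean(ctl$sbp) + 30)
})

test_that("case blood pressure is coupled to case-direction species load", {
  run <- planted_run(1)
  st <- run$truth$species_table
  case_sp <- st$species_id[st$direction == "case"]
  sp_prof <- aggregate_by_annotation(run$profile,
                                     taxonomy_map(run$cohort$taxonomy, "species"),
                                     "species")
  gross <- colSums(as.matrix(sp_prof)[case_sp, ])
  is_case <- run$cohort$phenotypes$group == "case"
  expect_gt(spearman_rho(gross[is_case], run$cohort$phenotypes$sbp[is_case]), 0.5)
})

test_that("a cohort round-trips through TSV/JSON bit-exactly", {
  dir <- withr::local_tempdir()
  tr <- planted_truth(seed = 5, n_case = 4, n_control = 4)
  co <- generate_cohort(tr)
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_identical(back$counts$counts, co$counts$counts)
  expect_identical(back$counts$gene_lengths, co$counts$gene_lengths)
  expect_identical(back$counts$sample_totals, co$counts$sample_totals)
  expect_equal(back$taxonomy, co$taxonomy)
  expect_equal(back$ko_map, co$ko_map)
  expect_equal(back$phenotypes, co$phenotypes)
  expect_equal(back$truth$species_table, co$truth$species_table)
  expect_identical(back$truth$seed, co$truth$seed)
})

test_that("a cohort without background genes still writes valid files", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(null_truth(seed = 6, n_case = 3, n_control = 3))
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_identical(back$counts$counts, co$counts$counts)
  expect_equal(ncol(read_matrix(file.path(dir, "counts.tsv"))), 6)
})
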