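mini_gcm <- function(counts, lengths, totals = NULL) {
  if (is.null(totals)) totals <- colSums(counts)
  gene_count_matrix(counts,
                    setNames(lengths, rownames(counts)),
                    setNames(totals, colnames(counts)))
}

test_that("gene count matrix validates its invariants", {
  cm <- matrix(c(1L, 2L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_s3_class(mini_gcm(cm, c(100L, 200L)), "gene_count_matrix")
  expect_error(mini_gcm(cm, c(0L, 200L)), "positive length")
  expect_error(mini_gcm(cm, c(100L, 200L), totals = 2L), "exceed")
  dup <- matrix(1L, 2, 1, dimnames = list(c("g1", "g1"), "s1"))
  expect_error(gene_count_matrix(dup, c(g1 = 1L), c(s1 = 5L)), "duplicate")
})

test_that("relative abundance normalises by length and depth then renormalises", {
  cm <- matrix(c(10L, 20L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  prof <- relative_abundance(mini_gcm(cm, c(100L, 400L)))
  expect_equal(unname(prof[, 1]), c(2 / 3, 1 / 3))

  one <- matrix(7L, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(unname(relative_abundance(mini_gcm(one, 500L))[, 1]), 1)

  eq <- matrix(5L, 4, 2, dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  expect_equal(unname(relative_abundance(mini_gcm(eq, rep(100L, 4)))[, 1]),
               rep(0.25, 4))
})

test_that("relative abundance is scale-invariant in depth and flags empty samples", {
  cm <- matrix(c(3L, 9L, 0L, 0L), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  gcm1 <- mini_gcm(cm, c(100L, 300L), totals = c(12L, 10L))
  gcm2 <- mini_gcm(cm * c(5L, 5L), c(100L, 300L), totals = c(60L, 10L))
  p1 <- relative_abundance(gcm1); p2 <- relative_abundance(gcm2)
  expect_equal(p1[, "s1"], p2[, "s1"])
  expect_equal(unname(p1[, "s2"]), c(0, 0))
  expect_identical(attr(p1, "zero_samples"), "s2")
})

test_that("annotation aggregation sums members and conserves mass", {
  prof <- rel_abundance(matrix(c(0.2, 0.3, 0.5), 3, 2,
                               dimnames = list(paste0("g", 1:3), c("s1", "s2"))))
  ann <- c(g1 = "A", g2 = "A", g3 = "B")
  agg <- aggregate_by_annotation(prof, ann, "genus")
  expect_equal(unname(agg["A", ]), c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(unname(agg["B", ]), c(0.5, 0.5), ignore_attr = TRUE)

  # single label absorbs everything
  all_one <- aggregate_by_annotation(prof, c(g1 = "G", g2 = "G", g3 = "G"), "genus")
  expect_equal(unname(all_one["G", ]), c(1, 1), ignore_attr = TRUE)

  # half unannotated -> unclassified bucket, totals conserved
  half <- aggregate_by_annotation(prof, c(g1 = "A", g2 = NA, g3 = NA), "genus")
  expect_equal(unname(half["unclassified", ]), c(0.8, 0.8), ignore_attr = TRUE)
  expect_equal(colSums(half), colSums(prof), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("aggregation warns on unknown genes and errors on empty overlap", {
  prof <- toy_profile()
  expect_warning(aggregate_by_annotation(prof, c(f1 = "A", zz = "B"), "genus"),
                 "absent")
  expect_error(
    suppressWarnings(aggregate_by_annotation(prof, c(zz = "B"), "genus")),
    "no overlap")
})

test_that("mass conservation holds for random partitions", {
  prof <- toy_profile(20, 5, seed = 9)
  set.seed(10)
  for (i in 1:20) {
    labels <- sample(c("A", "B", "C", NA), 20, replace = TRUE)
    names(labels) <- rownames(prof)
    agg <- aggregate_by_annotation(prof, labels, "genus")
    expect_equal(colSums(agg), colSums(prof), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("genus aggregation tracks true species abundance on a noiseless cohort", {
  st <- data.frame(species_id = c("spA", "spB"), genus = c("gA", "gB"),
                   phylum = "p", n_genes = 50L,
                   base_log_abundance = c(0, 0.5), fold_change = 1,
                   direction = "null", stringsAsFactors = FALSE)
  tr <- synthetic_truth(st, gene_noise_sigma = 0, n_case = 15, n_control = 15,
                        seed = 12)
  co <- generate_cohort(tr)
  prof <- relative_abundance(co$counts)
  gp <- aggregate_by_annotation(prof, taxonomy_map(co$taxonomy, "genus"), "genus")
  cnt <- co$counts$counts
  spA_count_share <- colSums(cnt[grep("^spA", rownames(cnt)), ]) / colSums(cnt)
  expect_gt(spearman_rho(as.matrix(gp)["gA", ], spA_count_share), 0.95)
})
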