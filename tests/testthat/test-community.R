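test_that("rarefied gene count honours depth bounds and degenerate cases", {
  cc <- c(5L, 0L, 3L, 2L)
  expect_equal(rarefied_gene_count(cc, depth = 10, seed = 1), 3)  # full depth
  expect_equal(rarefied_gene_count(c(50L), depth = 7, seed = 1), 1)
  expect_error(rarefied_gene_count(cc, depth = 11, seed = 1), "exceeds")
  expect_identical(rarefied_gene_count(cc, 4, seed = 9),
                   rarefied_gene_count(cc, 4, seed = 9))
})

test_that("mean rarefied count matches the hypergeometric closed form", {
  set.seed(21)
  cc <- rpois(40, 8)
  n_tot <- sum(cc)
  d <- 60L
  expected <- sum(1 - choose(n_tot - cc, d) / choose(n_tot, d))
  draws <- vapply(1:200, function(s) rarefied_gene_count(cc, d, seed = s),
                  integer(1))
  expect_equal(mean(draws), expected, tolerance = 0.02)
})

test_that("mean rarefied count is non-decreasing in depth", {
  set.seed(22)
  cc <- rpois(60, 5)
  means <- vapply(c(20L, 60L, 120L), function(d)
    mean(vapply(1:50, function(s) rarefied_gene_count(cc, d, seed = s),
                integer(1))), numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("Shannon index matches closed forms and is maximal at uniform", {
  expect_equal(shannon_index(rep(1, 100)), log(100), tolerance = 1e-12)
  expect_equal(shannon_index(c(0, 7, 0)), 0)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.03972, tolerance = 1e-5)
  set.seed(2)
  for (i in 1:10) {
    p <- rexp(30)
    expect_lte(shannon_index(p), log(30) + 1e-12)
    expect_equal(shannon_index(p), shannon_index(sample(p)))
  }
  expect_error(shannon_index(c(0, 0)), "all-zero")
})

test_that("Bray-Curtis matches hand values and metric-boundedness on fuzz", {
  same <- rel_abundance(matrix(c(0.3, 0.7, 0.3, 0.7), 2, 2,
                               dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_equal(bray_curtis(same)["s1", "s2"], 0)
  disjoint <- rel_abundance(matrix(c(1, 0, 0, 1), 2, 2,
                                   dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_equal(bray_curtis(disjoint)["s1", "s2"], 1)
  pair <- rel_abundance(matrix(c(0.5, 0.5, 0, 0.25, 0.25, 0.5), 3, 2,
                               dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
  expect_equal(bray_curtis(pair)["s1", "s2"], 0.5)

  set.seed(31)
  for (i in 1:25) {
    m <- matrix(rexp(8 * 5), 8, 5,
                dimnames = list(paste0("f", 1:8), paste0("s", 1:5)))
    d <- bray_curtis(rel_abundance(sweep(m, 2, colSums(m), "/")))
    expect_true(all(diag(d) == 0))
    expect_equal(d, t(d))
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("PCoA embedding matches cmdscale eigendecomposition", {
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  emb <- pcoa_embed(d3)
  cm <- cmdscale(as.dist(d3), k = 2, eig = TRUE)
  expect_equal(emb$eigenvalues[seq_along(cm$eig)], cm$eig, tolerance = 1e-9)
  prof <- toy_profile(12, 9, seed = 41)
  d <- bray_curtis(prof)
  emb <- pcoa_embed(d)
  cm <- cmdscale(as.dist(d), k = 8, eig = TRUE)
  expect_equal(emb$eigenvalues, cm$eig, tolerance = 1e-9)
  # embedding reproduces distances up to discarded negative part
  expect_equal(abs(emb$points[, 1]), abs(cm$points[, 1]), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("dbRDA agrees with vegan's capscale on the constrained fraction", {
  set.seed(42)
  m <- matrix(rexp(30 * 20), 30, 20,
              dimnames = list(paste0("t", 1:30), paste0("s", 1:20)))
  m[1:5, 1:10] <- m[1:5, 1:10] * 4
  prof <- rel_abundance(sweep(m, 2, colSums(m), "/"), "genus")
  groups <- rep(c("case", "control"), each = 10)
  bc <- bray_curtis(prof)
  o <- dbrda_group(bc, groups, prof)
  cs <- vegan::capscale(as.dist(bc) ~ g, data = data.frame(g = groups))
  expect_equal(o$constrained_fraction,
               cs$CCA$tot.chi / (cs$CCA$tot.chi + cs$CA$tot.chi),
               tolerance = 1e-8)
  expect_equal(o$constrained_eig[1], unname(cs$CCA$eig[1]), tolerance = 1e-8)
  expect_true(all(diff(o$unconstrained_eig) <= 1e-12))
  expect_true(!is.null(o$taxa_loadings))
})

test_that("dbRDA separates planted groups and finds nothing under the null", {
  null_fracs <- vapply(1:20, function(s) {
    set.seed(500 + s)
    m <- matrix(rexp(25 * 24), 25, 24,
                dimnames = list(paste0("t", 1:25), paste0("s", 1:24)))
    prof <- rel_abundance(sweep(m, 2, colSums(m), "/"), "genus")
    dbrda_group(bray_curtis(prof), rep(c("case", "control"), each = 12))$constrained_fraction
  }, numeric(1))
  expect_lt(median(null_fracs), 0.05)

  set.seed(43)
  m <- matrix(rexp(20 * 30), 20, 30,
              dimnames = list(paste0("t", 1:20), paste0("s", 1:30)))
  m[1, 1:15] <- m[1, 1:15] + 20          # one genus fully separates
  prof <- rel_abundance(sweep(m, 2, colSums(m), "/"), "genus")
  groups <- rep(c("case", "control"), each = 15)
  o <- dbrda_group(bray_curtis(prof), groups, prof)
  cap1 <- o$site_scores[, "CAP1"]
  expect_true(max(cap1[groups == "case"]) < min(cap1[groups == "control"]) ||
              min(cap1[groups == "case"]) > max(cap1[groups == "control"]))
  expect_error(dbrda_group(bray_curtis(prof), rep("case", 30)), "2 group")
})

test_that("genus contrasts apply the mean-abundance filter before testing", {
  set.seed(44)
  m <- matrix(rexp(5 * 40, rate = 1), 5, 40,
              dimnames = list(paste0("t", 1:5), paste0("s", 1:40)))
  m <- sweep(m, 2, colSums(m), "/")
  m["t5", ] <- 4e-4                       # below the 0.05% default filter
  m["t1", 1:20] <- m["t1", 1:20] * 6      # strong planted shift
  prof <- rel_abundance(sweep(m, 2, colSums(m), "/"), "genus")
  groups <- rep(c("case", "control"), each = 20)
  res <- compare_taxa(prof, groups)
  expect_false("t5" %in% res$taxon)
  expect_true(res$q[res$taxon == "t1"] < 0.05)
  expect_equal(res$direction[res$taxon == "t1"], "case_enriched")
})
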