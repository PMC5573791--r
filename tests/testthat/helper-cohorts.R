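# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

# standard planted cohort analysed through markers + MLGs
planted_run <- function(seed) {
  cached(paste0("planted_", seed), {
    tr <- planted_truth(seed = seed)
    co <- generate_cohort(tr)
    prof <- relative_abundance(co$counts)
    mk <- identify_markers(prof, co$phenotypes$group)
    mlgs <- annotate_mlgs(
      cluster_mlgs(prof[mk$gene_id, , drop = FALSE], mk, min_size = 20L),
      co$taxonomy)
    list(truth = tr, cohort = co, profile = prof, markers = mk, mlgs = mlgs)
  })
}

# ids of genes belonging to differential (non-null) planted species
planted_gene_ids <- function(run) {
  st <- run$truth$species_table
  diff_sp <- st$species_id[st$direction != "null"]
  run$cohort$taxonomy$gene_id[run$cohort$taxonomy$species %in% diff_sp]
}

# expected marker direction for a planted gene, from the truth
planted_direction <- function(run, gene_ids) {
  st <- run$truth$species_table
  sp <- run$cohort$taxonomy$species[match(gene_ids, run$cohort$taxonomy$gene_id)]
  dir <- st$direction[match(sp, st$species_id)]
  ifelse(dir == "case", "case_enriched",
         ifelse(dir == "control", "control_enriched", NA_character_))
}

# small deterministic relative-abundance matrix
toy_profile <- function(n_feat = 6, n_samp = 8, seed = 7) {
  set.seed(seed)
  m <- matrix(rexp(n_feat * n_samp), n_feat, n_samp,
              dimnames = list(paste0("f", seq_len(n_feat)),
                              paste0("s", seq_len(n_samp))))
  rel_abundance(sweep(m, 2, colSums(m), "/"), level = "gene")
}

# brute-force two-sided exact Mann-Whitney p by full enumeration
enumerate_mwu_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  idx <- utils::combn(n + m, n)
  u_all <- apply(idx, 2, function(i) sum(r[i]) - n * (n + 1) / 2)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}
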