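#' Specify the ground truth of a synthetic marker-gene cohort
#'
#' The truth object fixes everything the generator needs: a species table
#' (blocks of co-abundant genes with an optional group effect), background
#' genes with independent trajectories, noise scales, the case/control
#' design, the sequencing-depth model, and a seed. Downstream recovery
#' tests compare pipeline output against this object.
#'
#' @param species_table data.frame with columns `species_id`, `genus`,
#'   `phylum`, `n_genes` (>= 1), `base_log_abundance`,
#'   `fold_change` (> 0), `direction` (one of `"case"`, `"control"`,
#'   `"null"`; `fold_change` must be exactly 1 iff direction is `"null"`).
#' @param background_genes Number of independent singleton genes outside
#'   any species block.
#' @param gene_noise_sigma Log-scale sd of per-gene, per-sample noise around
#'   the species trajectory.
#' @param sigma_species Log-scale sd of between-sample species abundance.
#' @param n_case,n_control Group sizes (each >= 2).
#' @param depth_mean,depth_dispersion Negative-binomial sequencing-depth
#'   model: mean reads per sample and NB size parameter.
#' @param couple_sbp If `TRUE` (default) case blood pressure is
#'   rank-coupled to the gross abundance of case-direction species, so
#'   severity stages carry a real microbiome gradient.
#' @param seed Integer seed; the cohort is a pure function of the truth.
#' @return A `synthetic_truth` object.
#' @export
synthetic_truth <- function(species_table, background_genes = 0L,
                            gene_noise_sigma = 0.3, sigma_species = 1.0,
                            n_case = 60L, n_control = 60L,
                            depth_mean = 100000L, depth_dispersion = 5,
                            couple_sbp = TRUE, seed = 1L) {
  st <- as.data.frame(species_table, stringsAsFactors = FALSE)
  need <- c("species_id", "genus", "phylum", "n_genes",
            "base_log_abundance", "fold_change", "direction")
  if (!all(need %in% names(st)))
    stop("species_table missing columns: ",
         paste(setdiff(need, names(st)), collapse = ", "), call. = FALSE)
  if (any(st$n_genes < 1L)) stop("n_genes must be >= 1", call. = FALSE)
  if (any(st$fold_change <= 0)) stop("fold_change must be > 0", call. = FALSE)
  if (!all(st$direction %in% c("case", "control", "null")))
    stop("direction must be case/control/null", call. = FALSE)
  if (any((st$direction == "null") != (st$fold_change == 1)))
    stop("fold_change must equal 1 exactly when direction is null",
         call. = FALSE)
  if (anyDuplicated(st$species_id)) stop("duplicate species_id", call. = FALSE)
  if (n_case < 2L || n_control < 2L)
    stop("need at least 2 samples per group", call. = FALSE)
  if (depth_mean < 1) stop("depth_mean must be at least 1 read", call. = FALSE)
  if (gene_noise_sigma < 0 || sigma_species < 0)
    stop("noise sigmas must be >= 0", call. = FALSE)
  structure(list(species_table = st,
                 background_genes = as.integer(background_genes),
                 gene_noise_sigma = gene_noise_sigma,
                 sigma_species = sigma_species,
                 sample_design = c(n_case = as.integer(n_case),
                                   n_control = as.integer(n_control)),
                 depth_model = list(mean_reads = as.integer(depth_mean),
                                    dispersion = depth_dispersion),
                 couple_sbp = isTRUE(couple_sbp),
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Convenience truth objects for standard study conditions
#'
#' `planted_truth()` emulates the study cohort: 10 differential species
#' (5 enriched in cases, 5 in controls) of 100 genes each at fold change 4,
#' 20 null species, 500 independent background genes, 60 cases vs 60
#' controls. The case- and control-enriched species are paired on base
#' abundance so the expected planted mass is balanced between groups:
#' relative-abundance profiles are compositionally closed, and an
#' unbalanced design would push every null gene systematically in the
#' opposite direction. `null_truth()` is a no-effect cohort (30 null
#' species, 3,000 genes, 30 vs 30) for false-positive calibration.
#'
#' @param seed Integer seed.
#' @param fold_change Fold change of the differential species (planted only).
#' @param n_case,n_control Group sizes.
#' @return A `synthetic_truth`.
#' @export
planted_truth <- function(seed = 1L, fold_change = 4,
                          n_case = 60L, n_control = 60L) {
  n_sp <- 30L
  base_diff <- .seeded(seed * 7L + 1L, stats::rnorm(5L, 0, 1))
  base_null <- .seeded(seed * 7L + 3L, stats::rnorm(20L, 0, 1))
  dir <- c(rep("case", 5L), rep("control", 5L), rep("null", 20L))
  st <- data.frame(
    species_id = sprintf("sp%02d", seq_len(n_sp)),
    genus = sprintf("genus%02d", c(1:10, 10 + ((1:20 - 1) %% 15) + 1)),
    phylum = sprintf("phylum%d", ((seq_len(n_sp) - 1) %% 4) + 1),
    n_genes = 100L,
    base_log_abundance = c(base_diff, base_diff, base_null),
    fold_change = ifelse(dir == "null", 1, fold_change),
    direction = dir,
    stringsAsFactors = FALSE)
  synthetic_truth(st, background_genes = 500L,
                  n_case = n_case, n_control = n_control, seed = seed)
}

#' @rdname planted_truth
#' @export
null_truth <- function(seed = 1L, n_case = 30L, n_control = 30L) {
  n_sp <- 30L
  base <- .seeded(seed * 7L + 2L, stats::rnorm(n_sp, 0, 1))
  st <- data.frame(
    species_id = sprintf("sp%02d", seq_len(n_sp)),
    genus = sprintf("genus%02d", ((seq_len(n_sp) - 1) %% 15) + 1),
    phylum = sprintf("phylum%d", ((seq_len(n_sp) - 1) %% 4) + 1),
    n_genes = 100L,
    base_log_abundance = base,
    fold_change = 1,
    direction = "null",
    stringsAsFactors = FALSE)
  synthetic_truth(st, background_genes = 0L,
                  n_case = n_case, n_control = n_control, seed = seed)
}

# run expr under a local RNG state so helpers do not disturb callers
.seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

#' Generate a synthetic cohort from a truth specification
#'
#' Per sample, each species' relative abundance is drawn log-normally around
#' its base log abundance, shifted by `log(fold_change)` in the group
#' matching its direction; member-gene expected shares are the species
#' abundance times a fixed log-normal gene weight times per-sample
#' log-normal gene noise; read counts are multinomial at a
#' negative-binomially drawn depth. Gene lengths are uniform on
#' \[300, 3000\] bp and fixed per gene. Phenotypes follow the cohort-table
#' marginals (case SBP 165 +/- 20, DBP 101 +/- 11; control SBP 111 +/- 6,
#' DBP 71 +/- 7 mm Hg; gender, age, BMI, TG, smoking), with case blood
#' pressure optionally rank-coupled to case-direction species load.
#'
#' @param truth A [synthetic_truth()] object.
#' @return A `synthetic_cohort` list: `counts` ([gene_count_matrix()]),
#'   `taxonomy`, `ko_map`, `ko_pathway`, `phenotypes`, `truth`.
#' @export
generate_cohort <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  .seeded(truth$seed, .generate_cohort_impl(truth))
}

.generate_cohort_impl <- function(truth) {
  st <- truth$species_table
  n_sp <- nrow(st)
  n_bg <- truth$background_genes
  n_case <- truth$sample_design[["n_case"]]
  n_ctl <- truth$sample_design[["n_control"]]
  n_samp <- n_case + n_ctl

  gene_species <- rep(st$species_id, st$n_genes)
  gene_ids <- unlist(lapply(seq_len(n_sp), function(i)
    sprintf("%s_g%03d", st$species_id[i], seq_len(st$n_genes[i]))))
  if (n_bg > 0L) {
    gene_ids <- c(gene_ids, sprintf("bg_g%04d", seq_len(n_bg)))
    gene_species <- c(gene_species, rep(NA_character_, n_bg))
  }
  n_gene <- length(gene_ids)

  # fixed per-gene quantities
  weights <- stats::rlnorm(n_gene, 0, 0.25)        # within-species gene weight
  lengths <- as.integer(round(stats::runif(n_gene, 300, 3000)))
  bg_base <- stats::rnorm(n_bg, 0, 1)              # background genes: own base

  groups <- c(rep("case", n_case), rep("control", n_ctl))
  sample_ids <- sprintf("S%03d", seq_len(n_samp))

  # species log-abundance per sample (n_sp x n_samp)
  eff <- matrix(0, n_sp, n_samp)
  eff[st$direction == "case", groups == "case"] <-
    rep(log(st$fold_change[st$direction == "case"]), sum(groups == "case"))
  eff[st$direction == "control", groups == "control"] <-
    rep(log(st$fold_change[st$direction == "control"]), sum(groups == "control"))
  sp_log <- matrix(st$base_log_abundance, n_sp, n_samp) + eff +
    matrix(stats::rnorm(n_sp * n_samp, 0, truth$sigma_species), n_sp, n_samp)

  bg_log <- if (n_bg > 0L)
    matrix(bg_base, n_bg, n_samp) +
      matrix(stats::rnorm(n_bg * n_samp, 0, truth$sigma_species), n_bg, n_samp)
  else matrix(0, 0L, n_samp)

  sp_index <- match(gene_species, st$species_id)   # NA for background
  is_bg <- is.na(sp_index)
  bg_row <- cumsum(is_bg)                          # index into bg_log

  depth <- stats::rnbinom(n_samp, mu = truth$depth_model$mean_reads,
                          size = truth$depth_model$dispersion)
  depth <- as.integer(pmax(depth, 1L))

  counts <- matrix(0L, n_gene, n_samp,
                   dimnames = list(gene_ids, sample_ids))
  for (s in seq_len(n_samp)) {
    gl <- numeric(n_gene)
    gl[!is_bg] <- sp_log[sp_index[!is_bg], s]
    if (n_bg > 0L) gl[is_bg] <- bg_log[bg_row[is_bg], s]
    share <- exp(gl) * weights *
      exp(stats::rnorm(n_gene, 0, truth$gene_noise_sigma))
    counts[, s] <- stats::rmultinom(1L, depth[s], share / sum(share))[, 1L]
  }

  gcm <- gene_count_matrix(counts, gene_lengths = stats::setNames(lengths, gene_ids),
                           sample_totals = stats::setNames(depth, sample_ids))

  taxonomy <- data.frame(
    gene_id = gene_ids,
    phylum = ifelse(is_bg, NA_character_, st$phylum[sp_index]),
    genus = ifelse(is_bg, NA_character_, st$genus[sp_index]),
    species = ifelse(is_bg, NA_character_, st$species_id[sp_index]),
    stringsAsFactors = FALSE)

  # gross case-direction species abundance per sample, for SBP coupling
  case_sp <- st$species_id[st$direction == "case"]
  gross_case <- if (length(case_sp))
    colSums(exp(sp_log[st$direction == "case", , drop = FALSE])) else
    rep(0, n_samp)

  phenotypes <- .synth_phenotypes(groups, sample_ids, gross_case,
                                  truth$couple_sbp)

  list_out <- structure(list(counts = gcm,
                             taxonomy = taxonomy,
                             ko_map = .synth_ko_map(gene_ids, gene_species, st),
                             ko_pathway = .synth_ko_pathway(),
                             phenotypes = phenotypes,
                             truth = truth),
                        class = "synthetic_cohort")
  list_out
}

# KO placement: cutC (K20038) on the first case-direction species, the
# SCFA enzymes on the first control-direction species, generic KOs on a
# third of remaining genes; the rest unannotated.
.synth_ko_map <- function(gene_ids, gene_species, st) {
  ko <- rep(NA_character_, length(gene_ids))
  case_sp <- st$species_id[st$direction == "case"]
  ctl_sp <- st$species_id[st$direction == "control"]
  if (length(case_sp)) {
    idx <- which(gene_species == case_sp[1L])
    ko[idx[seq_len(min(10L, length(idx)))]] <- "K20038"
  }
  scfa <- c("K01034", "K01035", "K00929")
  if (length(ctl_sp)) {
    idx <- which(gene_species == ctl_sp[1L])
    take <- idx[seq_len(min(12L, length(idx)))]
    ko[take] <- rep(scfa, length.out = length(take))
  }
  open <- which(is.na(ko))
  pick <- open[seq_along(open) %% 3L == 0L]
  ko[pick] <- sprintf("K%05d", 10000L + ((seq_along(pick) - 1L) %% 200L) + 1L)
  data.frame(gene_id = gene_ids[!is.na(ko)], ko = ko[!is.na(ko)],
             stringsAsFactors = FALSE)
}

.synth_ko_pathway <- function() {
  generic <- sprintf("K%05d", 10001:10200)
  data.frame(ko = c("K20038", "K01034", "K01035", "K00929", generic),
             pathway = c("Choline metabolism", "Butanoate metabolism",
                         "Butanoate metabolism", "Butanoate metabolism",
                         sprintf("pathway_%02d", ((seq_along(generic) - 1L) %% 10L) + 1L)),
             stringsAsFactors = FALSE)
}

.synth_phenotypes <- function(groups, sample_ids, gross_case, couple_sbp) {
  n <- length(groups)
  is_case <- groups == "case"
  n_case <- sum(is_case); n_ctl <- sum(!is_case)

  draw_trunc <- function(n, mean, sd, ok) {
    x <- stats::rnorm(n, mean, sd)
    for (i in seq_len(50L)) {
      bad <- !ok(x)
      if (!any(bad)) break
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    }
    x
  }
  sbp <- dbp <- numeric(n)
  # cases must satisfy >=140/90, controls <=120/80 (cohort entry criteria)
  case_sbp <- draw_trunc(n_case, 165, 20, function(x) x >= 125)
  case_dbp <- draw_trunc(n_case, 101, 11, function(x) x >= 75)
  bad <- case_sbp < 140 & case_dbp < 90
  case_sbp[bad] <- pmax(case_sbp[bad], 140)
  if (couple_sbp && n_case > 1L) {
    r <- rank(gross_case[is_case], ties.method = "first")  # high load -> high BP
    case_sbp <- sort(case_sbp)[r]
    case_dbp <- sort(case_dbp)[r]
  }
  sbp[is_case] <- round(case_sbp); dbp[is_case] <- round(case_dbp)
  sbp[!is_case] <- round(draw_trunc(n_ctl, 111, 6, function(x) x <= 120 & x >= 85))
  dbp[!is_case] <- round(draw_trunc(n_ctl, 71, 7, function(x) x <= 80 & x >= 50))
  dbp[is_case] <- ifelse(sbp[is_case] < 140, pmax(dbp[is_case], 90), dbp[is_case])

  n_f_case <- round(25 / 60 * n_case); n_f_ctl <- round(28 / 60 * n_ctl)
  gender <- character(n)
  gender[is_case] <- sample(c(rep("F", n_f_case), rep("M", n_case - n_f_case)))
  gender[!is_case] <- sample(c(rep("F", n_f_ctl), rep("M", n_ctl - n_f_ctl)))
  n_s_case <- round(0.317 * n_case); n_s_ctl <- round(0.400 * n_ctl)
  smoke <- integer(n)
  smoke[is_case] <- sample(c(rep(1L, n_s_case), rep(0L, n_case - n_s_case)))
  smoke[!is_case] <- sample(c(rep(1L, n_s_ctl), rep(0L, n_ctl - n_s_ctl)))

  ph <- data.frame(
    sample_id = sample_ids,
    group = groups,
    sbp = sbp, dbp = dbp,
    stage = NA_integer_,
    gender = gender,
    age = round(ifelse(is_case, stats::rnorm(n, 57, 9.6), stats::rnorm(n, 56, 8.6))),
    bmi = round(ifelse(is_case, stats::rnorm(n, 23.5, 2.9), stats::rnorm(n, 23.4, 2.6)), 1),
    tg = round(pmax(0.3, ifelse(is_case, stats::rnorm(n, 1.87, 0.85),
                                stats::rnorm(n, 1.52, 0.69))), 2),
    smoke = smoke,
    stringsAsFactors = FALSE)
  ph$stage <- mapply(assign_stage, ph$sbp, ph$dbp, ph$group)
  ph
}

#' Write / read a synthetic cohort as plain TSV + JSON
#'
#' Emits `counts.tsv`, `gene_lengths.tsv`, `taxonomy.tsv`, `ko_map.tsv`,
#' `ko_pathway.tsv`, `phenotypes.tsv` and `truth.json` into `directory`;
#' [read_cohort()] round-trips them exactly.
#'
#' @param cohort A `synthetic_cohort`.
#' @param directory Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory, call. = FALSE)
  gcm <- cohort$counts
  paths <- c(
    counts = file.path(directory, "counts.tsv"),
    gene_lengths = file.path(directory, "gene_lengths.tsv"),
    taxonomy = file.path(directory, "taxonomy.tsv"),
    ko_map = file.path(directory, "ko_map.tsv"),
    ko_pathway = file.path(directory, "ko_pathway.tsv"),
    phenotypes = file.path(directory, "phenotypes.tsv"),
    truth = file.path(directory, "truth.json"))
  write_matrix(gcm$counts, paths["counts"])
  .write_tsv(data.frame(gene_id = names(gcm$gene_lengths),
                        length = unname(gcm$gene_lengths),
                        total_reads = NA_integer_,
                        stringsAsFactors = FALSE)[, 1:2], paths["gene_lengths"])
  .write_tsv(data.frame(sample_id = names(gcm$sample_totals),
                        total_reads = unname(gcm$sample_totals)),
             file.path(directory, "sample_totals.tsv"))
  .write_tsv(cohort$taxonomy, paths["taxonomy"])
  .write_tsv(cohort$ko_map, paths["ko_map"])
  .write_tsv(cohort$ko_pathway, paths["ko_pathway"])
  .write_tsv(cohort$phenotypes, paths["phenotypes"])
  tr <- unclass(cohort$truth)
  tr$sample_design <- as.list(tr$sample_design)  # keep names in JSON
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(paths, sample_totals = file.path(directory, "sample_totals.tsv")))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  counts <- read_matrix(file.path(directory, "counts.tsv"))
  gl <- .read_tsv(file.path(directory, "gene_lengths.tsv"))
  stt <- .read_tsv(file.path(directory, "sample_totals.tsv"))
  tr <- jsonlite::read_json(file.path(directory, "truth.json"),
                            simplifyVector = TRUE)
  truth <- synthetic_truth(as.data.frame(tr$species_table),
                           background_genes = tr$background_genes,
                           gene_noise_sigma = tr$gene_noise_sigma,
                           sigma_species = tr$sigma_species,
                           n_case = tr$sample_design$n_case,
                           n_control = tr$sample_design$n_control,
                           depth_mean = tr$depth_model$mean_reads,
                           depth_dispersion = tr$depth_model$dispersion,
                           couple_sbp = tr$couple_sbp, seed = tr$seed)
  structure(list(
    counts = gene_count_matrix(
      matrix(as.integer(counts), nrow(counts), ncol(counts),
             dimnames = dimnames(counts)),
      gene_lengths = stats::setNames(as.integer(gl$length), gl$gene_id),
      sample_totals = stats::setNames(as.integer(stt$total_reads), stt$sample_id)),
    taxonomy = .read_tsv(file.path(directory, "taxonomy.tsv")),
    ko_map = .read_tsv(file.path(directory, "ko_map.tsv")),
    ko_pathway = .read_tsv(file.path(directory, "ko_pathway.tsv")),
    phenotypes = .read_tsv(file.path(directory, "phenotypes.tsv")),
    truth = truth), class = "synthetic_cohort")
}
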