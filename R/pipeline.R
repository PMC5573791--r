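#' Pipeline configuration
#'
#' Collects input paths and stage parameters. `pipeline_config()` builds a
#' validated config from arguments or a YAML file.
#'
#' @param input_dir Directory holding `counts.tsv`, `gene_lengths.tsv`,
#'   `sample_totals.tsv`, `taxonomy.tsv`, `ko_map.tsv`, `ko_pathway.tsv`,
#'   `phenotypes.tsv` (the layout [write_cohort()] emits).
#' @param out_dir Output directory.
#' @param rarefaction_depth Reads per sample for the rarefied gene count.
#' @param q_threshold Marker FDR threshold.
#' @param prevalence_min Marker prevalence filter.
#' @param corr_threshold MLG clustering Spearman threshold.
#' @param network_threshold Co-occurrence |rho| cutoff.
#' @param min_mlg_size Minimum MLG size.
#' @param min_mean_abundance Genus-contrast abundance filter.
#' @param n_trees,n_folds Classifier settings.
#' @param seed Integer seed recorded in every output header.
#' @param yaml_file Optional YAML file whose keys override the defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            rarefaction_depth = 50000L,
                            q_threshold = 0.05, prevalence_min = 0.1,
                            corr_threshold = 0.7, network_threshold = 0.4,
                            min_mlg_size = 20L, min_mean_abundance = 5e-4,
                            n_trees = 1000L, n_folds = 5L, seed = 1L,
                            yaml_file = NULL) {
  cfg <- list(input_dir = input_dir, out_dir = out_dir,
              rarefaction_depth = rarefaction_depth,
              q_threshold = q_threshold, prevalence_min = prevalence_min,
              corr_threshold = corr_threshold,
              network_threshold = network_threshold,
              min_mlg_size = min_mlg_size,
              min_mean_abundance = min_mean_abundance,
              n_trees = n_trees, n_folds = n_folds, seed = seed)
  if (!is.null(yaml_file)) {
    ov <- yaml::read_yaml(yaml_file)
    cfg[names(ov)] <- ov
  }
  stopifnot(cfg$q_threshold > 0, cfg$q_threshold <= 1,
            cfg$corr_threshold > 0, cfg$corr_threshold < 1,
            cfg$network_threshold > 0, cfg$network_threshold < 1,
            cfg$prevalence_min >= 0, cfg$prevalence_min <= 1,
            cfg$min_mlg_size >= 1, cfg$n_trees >= 1, cfg$n_folds >= 2)
  structure(cfg, class = "pipeline_config")
}

.config_hash <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), c("input_dir", "out_dir"))] # paths are volatile
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(cfg), vapply(cfg, function(x)
    paste(format(x), collapse = ","), character(1L)), sep = "="), f)
  unname(tools::md5sum(f))
}

.provenance <- function(cfg) {
  c(paste("gutmgwas", as.character(utils::packageVersion("gutmgwas"))),
    paste("seed", cfg$seed),
    paste("config_hash", .config_hash(cfg)))
}

#' Run the full analysis pipeline
#'
#' Executes the study's analysis order on a cohort directory: abundance
#' profiles, alpha diversity, Bray-Curtis dbRDA, genus contrasts, marker
#' genes, MLG clustering and taxonomy, co-occurrence network, severity
#' staging, KO/pathway/panel contrasts, and random-forest classification.
#' Each stage logs its timing and record count to stderr, and every output
#' TSV carries a provenance header (package version, seed, config hash).
#' A stage failure stops the run with a stage-named error.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the main in-memory results and the
#'   output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  hdr <- .provenance(config)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  inp <- stage("read_inputs", {
    counts <- read_matrix(file.path(config$input_dir, "counts.tsv"))
    gl <- .read_tsv(file.path(config$input_dir, "gene_lengths.tsv"))
    stt <- .read_tsv(file.path(config$input_dir, "sample_totals.tsv"))
    ph <- read_phenotypes(file.path(config$input_dir, "phenotypes.tsv"))
    gcm <- gene_count_matrix(
      counts, stats::setNames(gl$length, gl$gene_id),
      stats::setNames(stt$total_reads, stt$sample_id))
    offenders <- c(setdiff(colnames(counts), ph$sample_id),
                   setdiff(ph$sample_id, colnames(counts)))
    if (length(offenders))
      stop("sample ids mismatch between counts and phenotypes: ",
           paste(offenders, collapse = ", "))
    ph <- ph[match(colnames(counts), ph$sample_id), ]
    list(gcm = gcm, phenotypes = ph,
         taxonomy = .read_tsv(file.path(config$input_dir, "taxonomy.tsv")),
         ko_map = .read_tsv(file.path(config$input_dir, "ko_map.tsv")),
         ko_pathway = .read_tsv(file.path(config$input_dir, "ko_pathway.tsv")))
  })
  groups <- inp$phenotypes$group

  prof <- stage("profiles", relative_abundance(inp$gcm))
  genus_prof <- stage("genus_profile",
    aggregate_by_annotation(prof, taxonomy_map(inp$taxonomy, "genus"), "genus"))

  div <- stage("diversity", {
    d <- alpha_diversity(inp$gcm, depth = config$rarefaction_depth,
                         seed = config$seed)
    write_phenotypes(d, file.path(out, "diversity.tsv"), hdr)
    d
  })

  ord <- stage("ordination", {
    bc <- bray_curtis(genus_prof[rownames(genus_prof) != "unclassified", ,
                                 drop = FALSE])
    write_matrix(bc, file.path(out, "bray_curtis.tsv"), hdr)
    o <- dbrda_group(bc, groups, genus_prof)
    write_matrix(o$site_scores, file.path(out, "ordination_sites.tsv"), hdr)
    if (!is.null(o$taxa_loadings))
      write_matrix(o$taxa_loadings, file.path(out, "ordination_loadings.tsv"), hdr)
    o
  })

  taxa_tests <- stage("genus_contrasts", {
    tt <- compare_taxa(genus_prof, groups,
                       min_mean_abundance = config$min_mean_abundance)
    .write_tsv(tt, file.path(out, "genus_tests.tsv"), hdr)
    tt
  })

  markers <- stage("markers", {
    mk <- identify_markers(prof, groups, q_threshold = config$q_threshold,
                           prevalence_min = config$prevalence_min)
    .write_tsv(as.data.frame(mk), file.path(out, "markers.tsv"), hdr)
    mk
  })

  mlgs <- stage("mlg", {
    mm <- cluster_mlgs(prof[markers$gene_id, , drop = FALSE], markers,
                       corr_threshold = config$corr_threshold,
                       min_size = config$min_mlg_size)
    mm <- annotate_mlgs(mm, inp$taxonomy)
    .write_tsv(mlg_table(mm), file.path(out, "mlg_table.tsv"), hdr)
    .write_tsv(do.call(rbind, lapply(mm, function(x)
      data.frame(mlg_id = x$mlg_id, gene_id = x$member_genes))),
      file.path(out, "mlg_members.tsv"), hdr)
    mm
  })
  mprof <- stage("mlg_profile", {
    mp <- mlg_profile(mlgs, prof)
    write_matrix(mp, file.path(out, "mlg_abundance.tsv"), hdr)
    mp
  })

  net <- stage("network", {
    ed <- build_network(mprof, threshold = config$network_threshold)
    export_network(ed, mlgs, file.path(out, "network.sif"), "sif")
    export_network(ed, mlgs, file.path(out, "network.graphml"), "graphml")
    export_network(ed, mlgs, file.path(out, "network_edges.tsv"), "tsv")
    ed
  })

  sev <- stage("severity", {
    stages <- inp$phenotypes$stage
    if (is.null(stages) || anyNA(stages))
      stages <- mapply(assign_stage, inp$phenotypes$sbp, inp$phenotypes$dbp,
                       inp$phenotypes$group)
    res <- list()
    for (dir in c("case_enriched", "control_enriched")) {
      sub <- mlgs_by_direction(mlgs, dir)
      if (!length(sub)) next
      gr <- gross_abundance(sub, prof)
      res[[dir]] <- stage_association(gr, stages)
      .write_tsv(res[[dir]]$pairs,
                 file.path(out, paste0("severity_", dir, ".tsv")), hdr)
    }
    res
  })

  fun <- stage("functional", {
    kp <- ko_profile(prof, inp$ko_map)
    pw <- pathway_profile(kp, inp$ko_pathway)
    pw_tests <- compare_features(as.matrix(pw), groups, "pathway")
    panels <- compare_panels(kp, default_panels(), groups)
    .write_tsv(pw_tests, file.path(out, "pathway_tests.tsv"), hdr)
    .write_tsv(panels$panels, file.path(out, "panel_tests.tsv"), hdr)
    list(ko_profile = kp, pathway_tests = pw_tests, panels = panels)
  })

  cls <- stage("classify", {
    rep <- train_and_evaluate(mprof, groups, n_trees = config$n_trees,
                              n_folds = config$n_folds, seed = config$seed)
    .write_tsv(rep$importance, file.path(out, "rf_importance.tsv"), hdr)
    rc <- roc_curve(rep$oob_scores, groups)
    .write_tsv(rc, file.path(out, "roc_curve.tsv"), hdr)
    jsonlite::write_json(
      list(cv_error = rep$cv_error, auc = rep$auc,
           auc_ci = as.list(rep$auc_ci), n_trees = rep$n_trees,
           seed = rep$seed),
      file.path(out, "classification.json"), auto_unbox = TRUE, digits = NA)
    rep
  })

  invisible(list(diversity = div, ordination = ord, taxa_tests = taxa_tests,
                 markers = markers, mlgs = mlgs, mlg_profile = mprof,
                 network = net, severity = sev, functional = fun,
                 classification = cls, out_dir = out))
}
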