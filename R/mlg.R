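#' Cluster co-abundant marker genes into metagenomic linkage groups
#'
#' Within each enrichment-direction stratum, marker genes are clustered by
#' greedy canopy clustering on the Spearman correlation of their abundance
#' profiles: the unclustered gene with the most neighbours at
#' `rho >= corr_threshold` seeds a cluster of itself plus those
#' neighbours; the cluster is then re-centred on its medoid (the member
#' with the highest total correlation to the others) and re-gathered from
#' the unclustered pool until membership is stable (at most `max_iter`
#' rounds). Clusters smaller than `min_size` are dissolved back into the
#' pool. Members of one MLG therefore co-vary like genes of one genome,
#' which is what lets an MLG stand in for a species.
#'
#' @param marker_profile `rel_abundance` restricted to marker genes.
#' @param markers `marker_genes` table from [identify_markers()] (supplies
#'   the direction stratification).
#' @param corr_threshold Spearman threshold for neighbourhood (default 0.7).
#' @param min_size Minimum cluster size (default 20, suited to synthetic
#'   cohorts; catalog-scale runs conventionally use 100).
#' @param max_iter Medoid-refinement iteration cap.
#' @return An `mlg_set`: list of `mlg` objects with fields `mlg_id`,
#'   `member_genes`, `direction`, `taxon_name`, `taxon_rank`, `abundance`.
#' @export
cluster_mlgs <- function(marker_profile, markers, corr_threshold = 0.7,
                         min_size = 20L, max_iter = 20L) {
  if (corr_threshold <= 0 || corr_threshold >= 1)
    stop("corr_threshold must be in (0, 1)", call. = FALSE)
  m <- as.matrix(marker_profile)
  miss <- setdiff(markers$gene_id, rownames(m))
  if (length(miss))
    stop("marker gene(s) absent from profile: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  clusters <- list()
  for (dir in c("case_enriched", "control_enriched")) {
    genes <- sort(markers$gene_id[markers$direction == dir])
    if (length(genes) < min_size) next
    sub <- m[genes, , drop = FALSE]
    keep <- apply(sub, 1L, stats::sd) > 0
    sub <- sub[keep, , drop = FALSE]
    if (nrow(sub) < min_size) next
    # apply() returns samples x genes; cor() then correlates genes
    rho <- stats::cor(apply(sub, 1L, rank))      # Spearman via mid-ranks
    dimnames(rho) <- list(rownames(sub), rownames(sub))
    cl <- .canopy(rho, corr_threshold, min_size, max_iter)
    for (members in cl)
      clusters[[length(clusters) + 1L]] <-
        list(members = rownames(sub)[members], direction = dir)
  }
  if (length(clusters))
    clusters <- clusters[order(-vapply(clusters, function(x)
      length(x$members), numeric(1L)),
      vapply(clusters, function(x) x$members[1L], character(1L)))]
  out <- lapply(seq_along(clusters), function(i) {
    ab <- colSums(m[clusters[[i]]$members, , drop = FALSE])
    structure(list(mlg_id = sprintf("MLG_%03d", i),
                   member_genes = clusters[[i]]$members,
                   direction = clusters[[i]]$direction,
                   taxon_name = "unclassified",
                   taxon_rank = "unclassified",
                   abundance = ab), class = "mlg")
  })
  structure(out, class = "mlg_set")
}

# greedy canopy over a correlation matrix; returns list of index vectors
.canopy <- function(rho, threshold, min_size, max_iter) {
  n <- nrow(rho)
  adj <- rho >= threshold
  diag(adj) <- TRUE
  pool <- rep(TRUE, n)
  ineligible <- rep(FALSE, n)
  clusters <- list()
  repeat {
    cand <- which(pool & !ineligible)
    if (!length(cand)) break
    counts <- rowSums(adj[cand, pool, drop = FALSE])
    seed <- cand[which.max(counts)]
    members <- which(pool & adj[seed, ])
    for (it in seq_len(max_iter)) {
      medoid <- members[which.max(rowSums(
        rho[members, members, drop = FALSE]))]
      new_members <- which(pool & adj[medoid, ])
      new_members <- sort(union(new_members, medoid))
      if (identical(new_members, sort(members))) break
      members <- new_members
    }
    if (length(members) >= min_size) {
      clusters[[length(clusters) + 1L]] <- sort(members)
      pool[members] <- FALSE
      ineligible[] <- FALSE
    } else {
      ineligible[seed] <- TRUE
    }
  }
  clusters
}

#' Assign a taxon to an MLG by voting over its constituent genes
#'
#' Among members with a taxonomic annotation: if at least `species_frac`
#' agree on one species, that species is assigned at species rank; failing
#' that, if at least `genus_frac` agree on one genus, the genus is
#' assigned (genus- or higher-rank MLGs are conventionally starred in
#' displays); otherwise the MLG stays unclassified.
#'
#' @param mlg An `mlg` object.
#' @param taxonomy data.frame: gene_id, phylum, genus, species.
#' @param species_frac,genus_frac Agreement fractions (defaults 0.9, 0.8).
#' @return The `mlg` with `taxon_name`/`taxon_rank` filled.
#' @export
assign_taxonomy <- function(mlg, taxonomy, species_frac = 0.9,
                            genus_frac = 0.8) {
  stopifnot(inherits(mlg, "mlg"))
  tx <- taxonomy[taxonomy$gene_id %in% mlg$member_genes, , drop = FALSE]
  annotated <- tx[!(is.na(tx$species) & is.na(tx$genus)), , drop = FALSE]
  mlg$taxon_name <- "unclassified"; mlg$taxon_rank <- "unclassified"
  if (nrow(annotated) == 0L) return(mlg)
  vote <- function(labels, frac) {
    labels <- labels[!is.na(labels)]
    if (!length(labels)) return(NULL)
    tab <- sort(table(labels), decreasing = TRUE)
    if (tab[1L] / nrow(annotated) >= frac) names(tab)[1L] else NULL
  }
  sp <- vote(annotated$species, species_frac)
  if (!is.null(sp)) {
    mlg$taxon_name <- sp; mlg$taxon_rank <- "species"
    return(mlg)
  }
  ge <- vote(annotated$genus, genus_frac)
  if (!is.null(ge)) {
    mlg$taxon_name <- ge; mlg$taxon_rank <- "genus"
  }
  mlg
}

#' @rdname assign_taxonomy
#' @param mlgs An `mlg_set`.
#' @export
annotate_mlgs <- function(mlgs, taxonomy, species_frac = 0.9,
                          genus_frac = 0.8) {
  structure(lapply(mlgs, assign_taxonomy, taxonomy = taxonomy,
                   species_frac = species_frac, genus_frac = genus_frac),
            class = "mlg_set")
}

#' Per-sample MLG abundance
#'
#' The MLG's abundance in each sample is the sum of its member genes'
#' relative abundances (additive, mass-conserving).
#'
#' @param mlg An `mlg` object.
#' @param gene_profile `rel_abundance` at gene level containing every
#'   member gene.
#' @return Named per-sample numeric vector.
#' @export
mlg_abundance <- function(mlg, gene_profile) {
  stopifnot(inherits(mlg, "mlg"))
  m <- as.matrix(gene_profile)
  miss <- setdiff(mlg$member_genes, rownames(m))
  if (length(miss))
    stop("member gene(s) missing from profile: ",
         paste(miss, collapse = ", "), call. = FALSE)
  colSums(m[mlg$member_genes, , drop = FALSE])
}

#' MLG x sample abundance profile
#'
#' @param mlgs An `mlg_set`.
#' @param gene_profile Gene-level `rel_abundance`.
#' @return `rel_abundance` at MLG level.
#' @export
mlg_profile <- function(mlgs, gene_profile) {
  stopifnot(inherits(mlgs, "mlg_set"), length(mlgs) > 0L)
  vals <- t(vapply(mlgs, mlg_abundance, gene_profile = gene_profile,
                   numeric(ncol(gene_profile))))
  rownames(vals) <- vapply(mlgs, `[[`, character(1L), "mlg_id")
  colnames(vals) <- colnames(gene_profile)
  rel_abundance(vals, level = "MLG",
                zero_samples = attr(gene_profile, "zero_samples"))
}

#' Summary table of an MLG set
#'
#' @param mlgs An `mlg_set`.
#' @return data.frame: mlg_id, size, direction, taxon_name, taxon_rank.
#' @export
mlg_table <- function(mlgs) {
  data.frame(
    mlg_id = vapply(mlgs, `[[`, character(1L), "mlg_id"),
    size = vapply(mlgs, function(x) length(x$member_genes), integer(1L)),
    direction = vapply(mlgs, `[[`, character(1L), "direction"),
    taxon_name = vapply(mlgs, `[[`, character(1L), "taxon_name"),
    taxon_rank = vapply(mlgs, `[[`, character(1L), "taxon_rank"),
    stringsAsFactors = FALSE)
}

#' @export
print.mlg_set <- function(x, ...) {
  cat(sprintf("mlg_set: %d MLGs (%d case-enriched, %d control-enriched)\n",
              length(x),
              sum(vapply(x, `[[`, character(1L), "direction") == "case_enriched"),
              sum(vapply(x, `[[`, character(1L), "direction") == "control_enriched")))
  invisible(x)
}
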