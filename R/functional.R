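#' KEGG-ortholog abundance profile
#'
#' A KO's abundance is the summed relative abundance of the genes assigned
#' to it (each gene maps to at most one KO, its best hit). Genes without a
#' KO contribute to no KO, so per-sample KO mass is at most the gene mass.
#'
#' @param gene_profile Gene-level `rel_abundance`.
#' @param gene_to_ko data.frame (gene_id, ko) or named vector gene -> KO.
#' @return `rel_abundance` at KO level.
#' @export
ko_profile <- function(gene_profile, gene_to_ko) {
  if (is.data.frame(gene_to_ko) && anyDuplicated(gene_to_ko[[1L]]))
    stop("a gene maps to at most one KO", call. = FALSE)
  prof <- aggregate_by_annotation(gene_profile, gene_to_ko,
                                  target_level = "KO",
                                  keep_unclassified = FALSE)
  prof
}

#' Pathway abundance profile from a KO profile
#'
#' KO-to-pathway is one-to-many: a KO contributes to every pathway it
#' belongs to, so pathway mass is not conserved.
#'
#' @param ko_prof KO-level `rel_abundance`.
#' @param ko_to_pathway data.frame (ko, pathway), repeats allowed.
#' @return `rel_abundance` at pathway level.
#' @export
pathway_profile <- function(ko_prof, ko_to_pathway) {
  aggregate_by_annotation(ko_prof, ko_to_pathway, target_level = "pathway",
                          keep_unclassified = FALSE)
}

#' Named enzyme panels for functional contrasts
#'
#' `TMA_production` holds choline-trimethylamine lyase (cutC, K20038),
#' the microbial route from dietary choline to trimethylamine.
#' `SCFA_production` holds the short-chain-fatty-acid producer enzymes:
#' acetyl-CoA decarbonylase/synthase (K00193, K00194, K00197, K14138),
#' butyryl-CoA:acetate CoA-transferase (K01034, K01035) and butyrate
#' kinase (K00929). Propionyl-CoA:succinate-CoA transferase belongs to
#' this functional family but has no assigned KO identifier, so it is not
#' in the default panel.
#'
#' @return Named list of KO-id character vectors.
#' @export
default_panels <- function() {
  list(TMA_production = "K20038",
       SCFA_production = c("K00193", "K00194", "K00197", "K14138",
                           "K01034", "K01035", "K00929"))
}

#' Two-group contrasts of enzyme panels and their member KOs
#'
#' Each panel's abundance is the per-sample sum over its member KOs; panels
#' are tested by Mann-Whitney with BH correction across panels, and each
#' present member KO is also tested individually (BH across KOs). Panel
#' KOs absent from the profile are treated as zero rows and reported; a
#' panel with no KO present at all is an error.
#'
#' @param ko_prof KO-level `rel_abundance`.
#' @param panels Named list of KO-id vectors (default [default_panels()]);
#'   ids must look like `K` + 5 digits.
#' @param groups Two-level grouping aligned with samples.
#' @return List: `panels` data.frame (panel, statistic, p, q, mean_case,
#'   mean_control, direction, n_ko_present), `kos` per-KO data.frame,
#'   `missing` named list of absent KO ids.
#' @export
compare_panels <- function(ko_prof, panels = default_panels(), groups) {
  stopifnot(is.list(panels), length(panels) > 0L)
  bad <- unlist(panels)[!grepl("^K[0-9]{5}$", unlist(panels))]
  if (length(bad))
    stop("malformed KO id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  m <- as.matrix(ko_prof)
  missing <- lapply(panels, setdiff, y = rownames(m))
  present <- mapply(intersect, panels, list(rownames(m)), SIMPLIFY = FALSE)
  empty <- names(present)[vapply(present, length, integer(1L)) == 0L]
  if (length(empty))
    stop("no panel KO present in profile for: ",
         paste(empty, collapse = ", "), call. = FALSE)
  panel_mat <- t(vapply(present, function(kos)
    colSums(m[kos, , drop = FALSE]), numeric(ncol(m))))
  rownames(panel_mat) <- names(panels)
  panel_res <- compare_features(panel_mat, groups, feature_name = "panel")
  panel_res$n_ko_present <- vapply(present[panel_res$panel], length,
                                   integer(1L))
  member_kos <- unique(unlist(present))
  ko_res <- compare_features(m[member_kos, , drop = FALSE], groups,
                             feature_name = "ko")
  list(panels = panel_res, kos = ko_res, missing = missing)
}
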