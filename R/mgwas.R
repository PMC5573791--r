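#' Metagenome-wide association: call marker genes
#'
#' Per-gene two-group Mann-Whitney testing with Benjamini-Hochberg FDR on
#' the gene relative-abundance profile. Genes observed (nonzero) in fewer
#' than `prevalence_min` of samples are excluded before testing —
#' low-prevalence genes make rank tests degenerate and dilute the FDR
#' budget. Genes passing `q < q_threshold` are returned with an enrichment
#' direction from the arithmetic group means.
#'
#' @param gene_profile `rel_abundance` at gene level.
#' @param groups Two-level grouping aligned with samples ("case" level
#'   treated as case).
#' @param q_threshold FDR threshold (default 0.05).
#' @param prevalence_min Minimum fraction of samples in which a gene must
#'   be nonzero (default 0.1).
#' @return A `marker_genes` data.frame: gene_id, p_value, q_value,
#'   direction, mean_case, mean_control. Attribute `n_tested` records how
#'   many genes entered testing.
#' @export
identify_markers <- function(gene_profile, groups, q_threshold = 0.05,
                             prevalence_min = 0.1) {
  m <- as.matrix(gene_profile)
  g <- .two_groups(groups)
  n1 <- sum(g$is_case); n2 <- sum(!g$is_case)
  if (n1 == 0L || n2 == 0L) stop("a group is empty", call. = FALSE)
  if (min(n1, n2) < 10L)
    warning("fewer than 10 samples in a group; rank tests will be weak")
  prevalence <- rowMeans(m > 0)
  tested <- m[prevalence >= prevalence_min, , drop = FALSE]
  res <- compare_features(tested, groups, feature_name = "gene_id")
  out <- res[res$q < q_threshold, , drop = FALSE]
  out <- data.frame(gene_id = out$gene_id, p_value = out$p, q_value = out$q,
                    direction = out$direction, mean_case = out$mean_case,
                    mean_control = out$mean_control,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$q_value, out$p_value, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_tested = nrow(tested), class = c("marker_genes", "data.frame"))
}
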