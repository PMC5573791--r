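#' Gene count matrix container
#'
#' Uniquely-mapped read counts per gene per sample, with per-gene lengths
#' (bp) and per-sample total read counts. This is the pipeline's entry
#' point: counts are later converted to length- and depth-normalised
#' relative abundances.
#'
#' @param counts Non-negative integer matrix, genes x samples, with
#'   dimnames.
#' @param gene_lengths Named positive integer vector (bp), one per gene.
#' @param sample_totals Named positive integer vector, one per sample; each
#'   must be at least the corresponding column sum (reads can map nowhere,
#'   never to more genes than there are reads).
#' @return A `gene_count_matrix` list.
#' @export
gene_count_matrix <- function(counts, gene_lengths, sample_totals) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene and sample names", call. = FALSE)
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("duplicate gene or sample ids", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  gene_lengths <- gene_lengths[rownames(counts)]
  sample_totals <- sample_totals[colnames(counts)]
  if (anyNA(gene_lengths) || any(gene_lengths <= 0))
    stop("every gene needs a positive length", call. = FALSE)
  if (anyNA(sample_totals) || any(sample_totals <= 0))
    stop("every sample needs a positive read total", call. = FALSE)
  if (any(colSums(counts) > sample_totals))
    stop("column sums exceed sample totals", call. = FALSE)
  structure(list(counts = counts,
                 gene_lengths = gene_lengths,
                 sample_totals = sample_totals),
            class = "gene_count_matrix")
}

#' @export
print.gene_count_matrix <- function(x, ...) {
  cat(sprintf("gene_count_matrix: %d genes x %d samples, median depth %s\n",
              nrow(x$counts), ncol(x$counts),
              format(stats::median(x$sample_totals), big.mark = ",")))
  invisible(x)
}

#' Length- and depth-normalised gene relative abundance
#'
#' The relative abundance of gene g in sample s is its uniquely-mapped
#' read count divided by the gene length and by the sample's total reads,
#' then renormalised so each sample sums to one. Samples with no mapped
#' reads are retained as all-zero columns and flagged (attribute
#' `zero_samples`) so sample sets stay aligned with phenotypes.
#'
#' @param counts A [gene_count_matrix()].
#' @return A numeric matrix (class `rel_abundance`) with attribute
#'   `level = "gene"`; columns sum to 1 (or 0 for flagged empty samples).
#' @export
relative_abundance <- function(counts) {
  stopifnot(inherits(counts, "gene_count_matrix"))
  raw <- counts$counts / counts$gene_lengths          # recycles by row
  raw <- sweep(raw, 2L, counts$sample_totals, `/`)
  cs <- colSums(raw)
  zero <- cs == 0
  cs[zero] <- 1
  out <- sweep(raw, 2L, cs, `/`)
  rel_abundance(out, level = "gene", zero_samples = colnames(out)[zero])
}

#' @rdname relative_abundance
#' @param values Non-negative feature x sample matrix.
#' @param level One of gene, phylum, genus, species, KO, pathway, MLG.
#' @param zero_samples Sample ids flagged as empty.
#' @export
rel_abundance <- function(values, level = "gene", zero_samples = character()) {
  values <- as.matrix(values)
  level <- match.arg(level, c("gene", "phylum", "genus", "species",
                              "KO", "pathway", "MLG"))
  if (any(values < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids", call. = FALSE)
  structure(values, level = level, zero_samples = zero_samples,
            class = c("rel_abundance", "matrix", "array"))
}

#' @export
print.rel_abundance <- function(x, ...) {
  cat(sprintf("rel_abundance (%s level): %d features x %d samples\n",
              attr(x, "level"), nrow(x), ncol(x)))
  invisible(x)
}

#' Aggregate a gene-level profile by annotation
#'
#' A label's abundance in a sample is the sum of its member genes'
#' abundances. Genes without a label (or with a missing rank) are pooled
#' into an `"unclassified"` bucket so per-sample mass is conserved. With a
#' one-to-one annotation (taxonomy, gene-to-KO) the output columns sum to
#' the input columns; a many-to-many map (KO-to-pathway) is also accepted,
#' in which case a feature contributes to every label it carries.
#'
#' @param profile A `rel_abundance` matrix.
#' @param annotation Either a named character vector (names = feature ids,
#'   values = labels, `NA` allowed) or a two-column data.frame
#'   (feature_id, label), possibly with repeated feature ids.
#' @param target_level Level tag of the output profile.
#' @param keep_unclassified Keep the pooled unlabelled bucket (default
#'   `TRUE`; set `FALSE` for partial annotations such as KO where
#'   unannotated mass is simply absent).
#' @return A `rel_abundance` matrix at `target_level`.
#' @export
aggregate_by_annotation <- function(profile, annotation, target_level,
                                    keep_unclassified = TRUE) {
  stopifnot(inherits(profile, "rel_abundance"))
  if (is.data.frame(annotation)) {
    ann <- data.frame(feature_id = as.character(annotation[[1L]]),
                      label = as.character(annotation[[2L]]),
                      stringsAsFactors = FALSE)
  } else {
    ann <- data.frame(feature_id = names(annotation),
                      label = as.character(annotation),
                      stringsAsFactors = FALSE)
  }
  unknown <- setdiff(ann$feature_id, rownames(profile))
  if (length(unknown)) {
    warning(length(unknown), " annotated feature(s) absent from profile, ignored")
    ann <- ann[!ann$feature_id %in% unknown, , drop = FALSE]
  }
  ann <- ann[!is.na(ann$label), , drop = FALSE]
  if (nrow(ann) == 0L)
    stop("annotation has no overlap with the profile", call. = FALSE)
  labelled <- profile[ann$feature_id, , drop = FALSE]
  agg <- rowsum(labelled, group = ann$label)
  if (keep_unclassified) {
    covered <- unique(ann$feature_id)
    rest <- setdiff(rownames(profile), covered)
    uncl <- if (length(rest))
      colSums(profile[rest, , drop = FALSE]) else rep(0, ncol(profile))
    agg <- rbind(agg, unclassified = uncl)
  }
  rel_abundance(agg[order(rownames(agg) == "unclassified",
                          rownames(agg)), , drop = FALSE],
                level = target_level,
                zero_samples = attr(profile, "zero_samples"))
}

#' Extract a rank map from a taxonomy table
#'
#' @param taxonomy data.frame with columns `gene_id`, `phylum`, `genus`,
#'   `species` (ranks may be `NA`).
#' @param rank Which rank to map to.
#' @return Named character vector gene_id -> rank label (`NA` if missing).
#' @export
taxonomy_map <- function(taxonomy, rank = c("species", "genus", "phylum")) {
  rank <- match.arg(rank)
  stats::setNames(as.character(taxonomy[[rank]]), taxonomy$gene_id)
}
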