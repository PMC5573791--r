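# TSV readers/writers shared by every stage. All files are UTF-8,
# tab-delimited, header row, "." decimal; lines starting with '#' are
# provenance comments and are skipped on read.

.write_tsv <- function(df, path, header_lines = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a feature x sample matrix as TSV
#'
#' First column is the feature id; remaining columns are samples. Duplicate
#' ids and non-numeric cells are reported with the offending id/line.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path File path.
#' @param header_lines Optional provenance comment lines (written with a
#'   leading `#`, skipped on read).
#' @return `write_matrix`: the path, invisibly. `read_matrix`: the matrix.
#' @export
write_matrix <- function(mat, path, header_lines = character()) {
  # built column-wise so a 0-row matrix keeps its id column
  df <- data.frame(feature_id = if (is.null(rownames(mat)))
    character() else rownames(mat), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mat))) df[[colnames(mat)[j]]] <- mat[, j]
  .write_tsv(df, path, header_lines)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- .read_tsv(path)
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate feature id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  vals <- df[, -1L, drop = FALSE]
  # a zero-row table reads every column as logical NA; coerce explicitly
  if (nrow(vals) == 0L) vals[] <- lapply(vals, as.numeric)
  bad <- !vapply(vals, is.numeric, logical(1L))
  if (any(bad))
    stop("non-numeric column(s) in ", path, ": ",
         paste(names(vals)[bad], collapse = ", "), call. = FALSE)
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Write / read a phenotype table
#'
#' Columns: sample_id, group, sbp, dbp, stage, gender, age, bmi, tg, smoke.
#'
#' @param phenotypes data.frame as produced by [generate_cohort()].
#' @param path File path.
#' @param header_lines Optional provenance comments.
#' @export
write_phenotypes <- function(phenotypes, path, header_lines = character()) {
  .write_tsv(phenotypes, path, header_lines)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  ph <- .read_tsv(path)
  need <- c("sample_id", "group", "sbp", "dbp")
  miss <- setdiff(need, names(ph))
  if (length(miss))
    stop("phenotype table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ph$sample_id))
    stop("duplicate sample_id in ", path, call. = FALSE)
  ph
}

#' Write / read a two-column annotation table (gene to label)
#'
#' @param annotation data.frame, first column feature id, second the label.
#' @param path File path.
#' @param header_lines Optional provenance comments.
#' @export
write_annotations <- function(annotation, path, header_lines = character()) {
  .write_tsv(annotation, path, header_lines)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2L) stop("annotation needs at least 2 columns", call. = FALSE)
  df
}
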