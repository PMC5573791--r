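#' Build the MLG co-occurrence network
#'
#' Spearman correlation between every unordered pair of MLG abundance
#' vectors; an edge is emitted iff `|rho|` strictly exceeds `threshold`
#' (default 0.4). Positive edges tie co-occurring MLGs, negative edges tie
#' mutually exclusive ones. No p-value filter is applied (magnitude only);
#' constant profiles are excluded from pairing with a warning.
#'
#' @param mlg_profile `rel_abundance` at MLG level (>= 2 MLGs, >= 10
#'   samples recommended).
#' @param threshold Absolute-correlation cutoff (strict inequality).
#' @return A `network_edges` data.frame: mlg_a, mlg_b (canonical a < b
#'   order), rho, sign.
#' @export
build_network <- function(mlg_profile, threshold = 0.4) {
  m <- as.matrix(mlg_profile)
  if (nrow(m) < 2L) stop("need at least 2 MLGs", call. = FALSE)
  if (ncol(m) < 10L)
    warning("fewer than 10 samples; correlations will be unstable")
  const <- apply(m, 1L, stats::sd) == 0
  if (any(const)) {
    warning("constant MLG profile(s) excluded: ",
            paste(rownames(m)[const], collapse = ", "))
    m <- m[!const, , drop = FALSE]
  }
  ids <- rownames(m)
  rho <- stats::cor(t(m), method = "spearman")
  pairs <- which(upper.tri(rho) & abs(rho) > threshold, arr.ind = TRUE)
  edges <- data.frame(
    mlg_a = ids[pmin(pairs[, 1L], pairs[, 2L])],
    mlg_b = ids[pmax(pairs[, 1L], pairs[, 2L])],
    rho = rho[pairs],
    stringsAsFactors = FALSE)
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  edges <- edges[order(edges$mlg_a, edges$mlg_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, class = c("network_edges", "data.frame"))
}

#' Export a co-occurrence network for external viewers
#'
#' `sif` writes `a pp b` interaction lines (isolated nodes as single-token
#' lines); `graphml` writes an igraph GraphML file carrying `rho`/`sign`
#' edge attributes and `direction`/`taxon`/`size` node attributes;
#' `tsv` writes the edge table plus a companion `<path>.nodes.tsv`.
#'
#' @param edges `network_edges` from [build_network()].
#' @param nodes An `mlg_set` (or a data.frame with columns mlg_id, size,
#'   direction, taxon_name).
#' @param path Output file path.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return The path, invisibly.
#' @export
export_network <- function(edges, nodes, path,
                           format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  nd <- if (inherits(nodes, "mlg_set")) mlg_table(nodes) else
    as.data.frame(nodes, stringsAsFactors = FALSE)
  unknown <- setdiff(unique(c(edges$mlg_a, edges$mlg_b)), nd$mlg_id)
  if (length(unknown))
    stop("edge references unknown node(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (format == "sif") {
    lines <- if (nrow(edges))
      paste(edges$mlg_a, "pp", edges$mlg_b) else character()
    isolated <- setdiff(nd$mlg_id, unique(c(edges$mlg_a, edges$mlg_b)))
    writeLines(c(lines, isolated), path)
  } else if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      edges[, c("mlg_a", "mlg_b", "rho", "sign")], directed = FALSE,
      vertices = nd[, c("mlg_id", "size", "direction", "taxon_name")])
    igraph::write_graph(g, path, format = "graphml")
  } else {
    .write_tsv(as.data.frame(edges), path)
    .write_tsv(nd, paste0(path, ".nodes.tsv"))
  }
  invisible(path)
}

#' Read back a GraphML network export
#'
#' @param path GraphML file written by [export_network()].
#' @return List: `edges` (`network_edges`-shaped data.frame), `nodes`
#'   data.frame.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g)
  edges <- data.frame(
    mlg_a = pmin(el[, 1L], el[, 2L]),
    mlg_b = pmax(el[, 1L], el[, 2L]),
    rho = if (igraph::ecount(g)) igraph::E(g)$rho else numeric(),
    sign = if (igraph::ecount(g)) igraph::E(g)$sign else character(),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$mlg_a, edges$mlg_b), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(mlg_id = igraph::V(g)$name,
                      size = igraph::V(g)$size,
                      direction = igraph::V(g)$direction,
                      taxon_name = igraph::V(g)$taxon_name,
                      stringsAsFactors = FALSE)
  list(edges = edges, nodes = nodes)
}
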