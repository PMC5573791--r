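#' Rarefied gene count (gene richness at fixed depth)
#'
#' Draws `depth` reads without replacement from a sample's read-to-gene
#' multiset and counts the distinct genes hit — the catalog-scale analogue
#' of rarefied richness, here at a stated depth so sequencing-effort
#' differences cannot masquerade as diversity differences.
#'
#' @param counts_column Non-negative integer vector of per-gene read counts.
#' @param depth Number of reads to draw; must not exceed the column total
#'   (no silent with-replacement fallback).
#' @param seed Integer seed; a single draw is taken per call.
#' @return Integer: number of distinct genes observed.
#' @export
rarefied_gene_count <- function(counts_column, depth, seed = 1L) {
  cc <- as.numeric(counts_column)
  if (any(cc < 0) || any(cc != round(cc)))
    stop("counts must be non-negative integers", call. = FALSE)
  total <- sum(cc)
  if (depth < 1L) stop("depth must be at least 1", call. = FALSE)
  if (depth > total)
    stop("depth (", depth, ") exceeds total reads (", total, ")", call. = FALSE)
  .seeded(seed, {
    # sequential multivariate hypergeometric: one rhyper per gene
    remaining <- total
    left <- depth
    hit <- 0L
    for (g in seq_along(cc)) {
      if (left == 0L) break
      if (cc[g] == 0) { next }
      x <- stats::rhyper(1L, m = cc[g], n = remaining - cc[g], k = left)
      if (x > 0L) hit <- hit + 1L
      left <- left - x
      remaining <- remaining - cc[g]
    }
    hit
  })
}

#' Alpha diversity per sample: rarefied gene count and Shannon index
#'
#' @param counts A [gene_count_matrix()].
#' @param depth Rarefaction depth (reads); samples shallower than `depth`
#'   get `NA` gene count with a warning.
#' @param seed Base seed; sample i uses `seed + i`.
#' @param replicates Number of rarefaction draws to average (default 1,
#'   a single seeded draw).
#' @return data.frame: sample_id, gene_count, shannon.
#' @export
alpha_diversity <- function(counts, depth = 50000L, seed = 1L,
                            replicates = 1L) {
  stopifnot(inherits(counts, "gene_count_matrix"))
  prof <- relative_abundance(counts)
  tot <- colSums(counts$counts)
  gc <- vapply(seq_len(ncol(counts$counts)), function(i) {
    if (tot[i] < depth) return(NA_real_)
    mean(vapply(seq_len(replicates), function(r)
      rarefied_gene_count(counts$counts[, i], depth,
                          seed = seed + i * 1000L + r), numeric(1L)))
  }, numeric(1L))
  if (anyNA(gc))
    warning(sum(is.na(gc)), " sample(s) shallower than the rarefaction depth")
  sh <- vapply(seq_len(ncol(prof)), function(i) shannon_index(prof[, i]),
               numeric(1L))
  data.frame(sample_id = colnames(counts$counts),
             gene_count = gc, shannon = sh, stringsAsFactors = FALSE)
}

#' Shannon diversity index (natural log)
#'
#' H = -sum p log p over the renormalised relative-abundance column.
#'
#' @param abundance_column Non-negative vector with positive sum.
#' @return H >= 0.
#' @export
shannon_index <- function(abundance_column) {
  x <- as.numeric(abundance_column)
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (sum(x) <= 0) stop("all-zero abundance column", call. = FALSE)
  unname(vegan::diversity(x / sum(x), index = "shannon"))
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(a, b) = 1 - 2 sum min(x_a, x_b) / sum (x_a + x_b), computed on the
#' columns of a relative-abundance profile.
#'
#' @param profile A `rel_abundance` matrix (features x samples, >= 2
#'   samples).
#' @return Symmetric sample x sample matrix, zero diagonal, values in
#'   \[0, 1\].
#' @export
bray_curtis <- function(profile) {
  m <- as.matrix(profile)
  if (ncol(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  zero <- colSums(m) == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(colnames(m)[zero], collapse = ", "),
         call. = FALSE)
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

#' Principal-coordinates embedding of a distance matrix
#'
#' Gower-centers -d^2/2 and eigendecomposes it; axes with eigenvalues below
#' `tol` (including all negative ones) are discarded. Used as the metric
#' embedding step of [dbrda_group()].
#'
#' @param dist Square symmetric distance matrix.
#' @param tol Eigenvalue cutoff relative to the largest eigenvalue.
#' @return List: `points` (samples x kept axes, scaled by sqrt eigenvalue),
#'   `eigenvalues` (all, decreasing), `kept` (logical).
#' @export
pcoa_embed <- function(dist, tol = 1e-9) {
  d <- as.matrix(dist)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be square and symmetric", call. = FALSE)
  n <- nrow(d)
  a <- -0.5 * d^2
  j <- diag(n) - matrix(1 / n, n, n)
  b <- j %*% a %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values))
  pts <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  list(points = pts, eigenvalues = e$values, kept = keep)
}

#' Distance-based redundancy analysis constrained by group
#'
#' Embeds the distance matrix by principal coordinates (negative
#' eigenvalues discarded), then performs redundancy analysis of the
#' embedding on the group indicator: the constrained axes are the
#' principal axes of the group-mean projection of the embedding, and the
#' constrained fraction is the share of embedded variance explained by
#' group membership. Taxa loadings are correlations of each taxon's
#' abundance with the two display axes (first constrained axis and first
#' residual axis), mirroring how genera are overlaid as the main
#' contributors on such ordinations.
#'
#' @param dist Sample x sample distance matrix (e.g. [bray_curtis()]).
#' @param groups Factor-like vector with >= 2 levels, aligned with the
#'   distance matrix.
#' @param taxa_profile Optional `rel_abundance` (taxa x samples) for
#'   loadings.
#' @return An `ordination_result` list: `site_scores` (samples x 2:
#'   CAP1, MDS1), `constrained_eig`, `unconstrained_eig`,
#'   `constrained_fraction`, `taxa_loadings` (or `NULL`).
#' @export
dbrda_group <- function(dist, groups, taxa_profile = NULL) {
  d <- as.matrix(dist)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop("need at least 2 group levels to constrain", call. = FALSE)
  if (length(groups) != nrow(d))
    stop("groups length does not match distance matrix", call. = FALSE)
  emb <- pcoa_embed(d)
  y <- scale(emb$points, center = TRUE, scale = FALSE)
  x <- stats::model.matrix(~ groups)[, -1L, drop = FALSE]
  x <- scale(x, center = TRUE, scale = FALSE)
  # hat-matrix projection of the embedding onto the group space
  qx <- qr(x)
  fitted <- qr.fitted(qx, y)
  resid <- y - fitted
  sv <- svd(fitted)
  # eigenvalues as sums of squares, the convention of vegan ordinations
  pos <- sv$d^2 > 1e-12 * max(sv$d^2, 1e-300)
  cap_scores <- y %*% sv$v[, pos, drop = FALSE]       # wa-style scores
  sv_r <- svd(resid)
  mds_scores <- resid %*% sv_r$v[, 1L, drop = FALSE]
  site <- cbind(CAP1 = cap_scores[, 1L], MDS1 = mds_scores[, 1L])
  rownames(site) <- rownames(d)
  loadings <- NULL
  if (!is.null(taxa_profile)) {
    tp <- as.matrix(taxa_profile)
    keep <- apply(tp, 1L, stats::sd) > 0
    loadings <- t(apply(tp[keep, , drop = FALSE], 1L, function(r)
      c(CAP1 = stats::cor(r, site[, 1L]), MDS1 = stats::cor(r, site[, 2L]))))
  }
  structure(list(site_scores = site,
                 constrained_eig = sv$d[pos]^2,
                 unconstrained_eig = sv_r$d[sv_r$d^2 > 1e-12 * max(sv_r$d^2, 1e-300)]^2,
                 constrained_fraction = sum(fitted^2) / sum(y^2),
                 taxa_loadings = loadings),
            class = "ordination_result")
}

#' Per-taxon case/control contrasts
#'
#' Mann-Whitney test per taxon with Benjamini-Hochberg correction; taxa
#' whose mean relative abundance across all samples is below
#' `min_mean_abundance` (default 0.05% of total) are excluded before
#' testing, matching the display convention for genus-level comparisons.
#'
#' @param taxa_profile `rel_abundance`, taxa x samples.
#' @param groups Two-level grouping aligned with samples; the level named
#'   `"case"` (if present, else the first level) is treated as case.
#' @param min_mean_abundance Mean-abundance inclusion threshold.
#' @return data.frame: taxon, statistic, p, q, mean_case, mean_control,
#'   direction.
#' @export
compare_taxa <- function(taxa_profile, groups, min_mean_abundance = 5e-4) {
  m <- as.matrix(taxa_profile)
  keep <- rowMeans(m) >= min_mean_abundance
  compare_features(m[keep, , drop = FALSE], groups, feature_name = "taxon")
}

#' Generic per-feature two-group contrast
#'
#' @param mat Feature x sample matrix.
#' @param groups Two-level grouping.
#' @param feature_name Name for the id column of the result.
#' @return data.frame with per-feature Mann-Whitney statistics, BH q-values
#'   and enrichment direction by arithmetic mean.
#' @export
compare_features <- function(mat, groups, feature_name = "feature") {
  g <- .two_groups(groups)
  if (sum(g$is_case) < 2L || sum(!g$is_case) < 2L)
    stop("need at least 2 samples per group", call. = FALSE)
  if (nrow(mat) == 0L)
    return(stats::setNames(data.frame(character(), numeric(), numeric(),
                                      numeric(), numeric(), numeric(),
                                      character(), stringsAsFactors = FALSE),
                           c(feature_name, "statistic", "p", "q",
                             "mean_case", "mean_control", "direction")))
  res <- apply(mat, 1L, function(r) {
    ht <- mann_whitney_test(r[g$is_case], r[!g$is_case])
    c(ht$statistic, ht$p_value)
  })
  p <- res[2L, ]
  q <- bh_fdr(p)$q_values
  mc <- rowMeans(mat[, g$is_case, drop = FALSE])
  mk <- rowMeans(mat[, !g$is_case, drop = FALSE])
  out <- data.frame(id = rownames(mat), statistic = res[1L, ],
                    p = p, q = q, mean_case = mc, mean_control = mk,
                    direction = ifelse(mc >= mk, "case_enriched",
                                       "control_enriched"),
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[1L] <- feature_name
  out
}

# resolve a two-level grouping; "case" (or "HT"-style first level) is case
.two_groups <- function(groups) {
  g <- as.character(groups)
  lev <- unique(g)
  if (length(lev) != 2L) stop("need exactly 2 groups", call. = FALSE)
  case_level <- if ("case" %in% lev) "case" else lev[1L]
  list(is_case = g == case_level, case_level = case_level,
       control_level = setdiff(lev, case_level))
}
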