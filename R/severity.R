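#' Hypertension severity stage from blood pressure
#'
#' Classical two-stage clinical bands: controls are stage 0; cases are
#' stage 1 when SBP 140-159 or DBP 90-99 mm Hg (and below both stage-2
#' cutoffs), stage 2 when SBP >= 160 or DBP >= 100. A "case" whose
#' pressures are below both hypertension cutoffs is a validation error.
#'
#' @param sbp,dbp Systolic / diastolic pressure (mm Hg, positive).
#' @param group `"case"` or `"control"`.
#' @return Integer stage in {0, 1, 2}.
#' @export
assign_stage <- function(sbp, dbp, group) {
  if (sbp <= 0 || dbp <= 0) stop("pressures must be positive", call. = FALSE)
  if (group == "control") return(0L)
  if (group != "case") stop("group must be case or control", call. = FALSE)
  if (sbp < 140 && dbp < 90)
    stop("case with SBP < 140 and DBP < 90 mm Hg", call. = FALSE)
  if (sbp >= 160 || dbp >= 100) 2L else 1L
}

#' Gross abundance of an MLG set
#'
#' Per sample, the summed abundance of all MLGs in the set — typically all
#' case-enriched or all control-enriched MLGs, giving the total microbial
#' load attributable to one enrichment direction.
#'
#' @param mlgs Non-empty `mlg_set` (pre-filtered by direction if desired).
#' @param gene_profile Gene-level `rel_abundance`.
#' @return Named per-sample numeric vector.
#' @export
gross_abundance <- function(mlgs, gene_profile) {
  if (!inherits(mlgs, "mlg_set") || length(mlgs) == 0L)
    stop("need a non-empty mlg_set", call. = FALSE)
  Reduce(`+`, lapply(mlgs, mlg_abundance, gene_profile = gene_profile))
}

#' Filter an MLG set by enrichment direction
#'
#' @param mlgs `mlg_set`.
#' @param direction `"case_enriched"` or `"control_enriched"`.
#' @return `mlg_set` subset.
#' @export
mlgs_by_direction <- function(mlgs, direction) {
  keep <- vapply(mlgs, `[[`, character(1L), "direction") == direction
  structure(mlgs[keep], class = "mlg_set")
}

#' Association of gross MLG abundance with severity stage
#'
#' All stage-pair Mann-Whitney contrasts with BH correction across pairs,
#' plus a Spearman trend of gross abundance against stage. Pairs where a
#' stage has fewer than 2 samples are skipped with a warning.
#'
#' @param gross Per-sample gross abundance vector.
#' @param stages Integer stage vector aligned with `gross`.
#' @return List: `pairs` data.frame (stage_a, stage_b, statistic, p, q),
#'   `trend_rho` Spearman correlation of abundance with stage.
#' @export
stage_association <- function(gross, stages) {
  stopifnot(length(gross) == length(stages))
  lev <- sort(unique(stages))
  if (length(lev) < 2L) stop("need at least 2 stages", call. = FALSE)
  combos <- utils::combn(lev, 2L)
  rows <- list()
  for (k in seq_len(ncol(combos))) {
    a <- combos[1L, k]; b <- combos[2L, k]
    xa <- gross[stages == a]; xb <- gross[stages == b]
    if (length(xa) < 2L || length(xb) < 2L) {
      warning(sprintf("stage pair %s-%s skipped: fewer than 2 samples", a, b))
      next
    }
    ht <- mann_whitney_test(xa, xb)
    rows[[length(rows) + 1L]] <- data.frame(
      stage_a = a, stage_b = b, statistic = ht$statistic, p = ht$p_value)
  }
  if (!length(rows)) stop("no testable stage pairs", call. = FALSE)
  pairs <- do.call(rbind, rows)
  pairs$q <- bh_fdr(pairs$p)$q_values
  trend <- spearman_rho(gross, stages)
  list(pairs = pairs, trend_rho = trend)
}
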