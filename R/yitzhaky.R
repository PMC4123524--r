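# Consensus-ROC baseline for edge-map selection: potential ground truths by
# vote counting, averaged correspondence rates, the correspondence-threshold
# ROC curve, an estimated ground truth, and best-map selection against it.

check_map_list <- function(maps, min_n = 2L) {
  if (!is.list(maps) || length(maps) < min_n)
    stopf("need at least %d candidate edge maps", min_n)
  maps <- lapply(maps, as_edge_map)
  d1 <- dim(maps[[1]])
  for (m in maps[-1]) {
    if (!identical(dim(m), d1))
      stopf("candidate edge maps must share one shape (%d x %d vs %d x %d)",
            d1[1], d1[2], nrow(m), ncol(m))
  }
  maps
}

#' Potential ground truths by consensus voting
#'
#' `PGT_i` is true wherever a pixel is marked as edge by at least `i` of the
#' `N` candidate maps, so the levels are nested:
#' `PGT_1 >= PGT_2 >= ... >= PGT_N`.
#'
#' @param maps List of `N >= 2` logical edge maps of one shape.
#' @return List of `N` logical masks, level `i` at position `i`.
#' @export
potential_ground_truths <- function(maps) {
  maps <- check_map_list(maps)
  votes <- Reduce(`+`, lapply(maps, function(m) m * 1L))
  lapply(seq_along(maps), function(i) votes >= i)
}

confusion_vs <- function(map, ref) {
  tp <- sum(map & ref)
  fp <- sum(map & !ref)
  fn <- sum(!map & ref)
  tn <- sum(!map & !ref)
  pos <- tp + fn
  neg <- fp + tn
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       tpr = if (pos > 0) tp / pos else 0,
       fpr = if (neg > 0) fp / neg else 0,
       tnr = if (neg > 0) tn / neg else 0,
       fnr = if (pos > 0) fn / pos else 0,
       degenerate = pos == 0 || neg == 0)
}

#' Average correspondence rates against one potential ground truth
#'
#' Each candidate map's confusion matrix is computed against the consensus
#' mask and the normalized rates (`TPR = TP / (TP + FN)`,
#' `FPR = FP / (FP + TN)`, ...) are averaged over the maps. When the
#' reference has no positives (or no negatives) the undefined rate is
#' reported as 0 and `degenerate` is flagged, so whole-grid sweeps never
#' abort.
#'
#' @param maps List of logical edge maps.
#' @param pgt Logical consensus mask of the same shape.
#' @return List with `tpr`, `fpr`, `tnr`, `fnr` (means over maps) and a
#'   `degenerate` flag.
#' @export
correspondence_rates <- function(maps, pgt) {
  maps <- check_map_list(maps, min_n = 1L)
  pgt <- as_edge_map(pgt, expected_shape = dim(maps[[1]]))
  conf <- lapply(maps, confusion_vs, ref = pgt)
  list(tpr = mean(vapply(conf, `[[`, numeric(1), "tpr")),
       fpr = mean(vapply(conf, `[[`, numeric(1), "fpr")),
       tnr = mean(vapply(conf, `[[`, numeric(1), "tnr")),
       fnr = mean(vapply(conf, `[[`, numeric(1), "fnr")),
       degenerate = any(vapply(conf, `[[`, logical(1), "degenerate")))
}

#' Correspondence-threshold ROC curve
#'
#' One averaged `(FPR, TPR)` point per consensus level, ordered by level.
#'
#' @param maps List of `N >= 2` logical edge maps.
#' @return Data frame with columns `level`, `FPR`, `TPR`, `degenerate`.
#' @export
ct_roc <- function(maps) {
  maps <- check_map_list(maps)
  pgts <- potential_ground_truths(maps)
  rates <- lapply(pgts, function(p) correspondence_rates(maps, p))
  data.frame(level = seq_along(maps),
             FPR = vapply(rates, `[[`, numeric(1), "fpr"),
             TPR = vapply(rates, `[[`, numeric(1), "tpr"),
             degenerate = vapply(rates, `[[`, logical(1), "degenerate"))
}

#' Estimate the consensus ground truth
#'
#' Picks the consensus level whose averaged `(FPR, TPR)` point lies closest
#' (Euclidean) to the ideal corner `(0, 1)` of the correspondence-threshold
#' ROC; ties go to the smaller level.
#'
#' @param maps List of `N >= 2` logical edge maps.
#' @return List with `level` (selected consensus level) and `mask` (the
#'   estimated ground-truth edge map).
#' @export
estimate_ground_truth <- function(maps) {
  maps <- check_map_list(maps)
  roc <- ct_roc(maps)
  d2 <- roc$FPR^2 + (1 - roc$TPR)^2
  lvl <- which.min(d2) # first minimum = smallest level on ties
  list(level = lvl, mask = potential_ground_truths(maps)[[lvl]])
}

f1_score <- function(map, ref) {
  tp <- sum(map & ref)
  fp <- sum(map & !ref)
  fn <- sum(!map & ref)
  den <- 2 * tp + fp + fn
  if (den == 0) 1 else 2 * tp / den
}

#' Select the candidate map closest to the estimated ground truth
#'
#' The best match is the candidate maximizing the F1 score against the
#' estimated ground truth. Exact F1 ties are broken by the lexicographically
#' smallest mask content (so the selected map's *mask* never depends on the
#' input order), then by the lower index among identical masks. If the
#' estimated ground truth is empty, the candidate with the fewest
#' false-positive pixels is chosen and the result is flagged.
#'
#' @param maps List of `N >= 2` logical edge maps.
#' @return Selected 1-based index, with attributes `level` (consensus level
#'   used), `f1` (per-map scores) and `degenerate`.
#' @export
select_best_map <- function(maps) {
  maps <- check_map_list(maps)
  gt <- estimate_ground_truth(maps)
  if (sum(gt$mask) == 0) {
    fp <- vapply(maps, function(m) sum(m & !gt$mask), numeric(1))
    idx <- which.min(fp)
    return(structure(idx, level = gt$level, f1 = rep(NA_real_, length(maps)),
                     degenerate = TRUE))
  }
  f1 <- vapply(maps, f1_score, numeric(1), ref = gt$mask)
  best <- which(f1 >= max(f1) - 1e-12)
  if (length(best) > 1) {
    keys <- vapply(best, function(i) paste(as.integer(maps[[i]]), collapse = ""),
                   character(1))
    best <- best[order(keys)]
  }
  structure(best[1], level = gt$level, f1 = f1, degenerate = FALSE)
}

#' Rank candidate maps with the consensus-ROC baseline
#'
#' Companion to [rank_candidates()]: reports, for each candidate, its rates
#' and F1 against the estimated consensus ground truth, with the selected
#' map first-ranked.
#'
#' @param candidates Named list of `N >= 2` logical edge maps.
#' @return Data frame with columns `candidate_id`, `Ne` (raw edge pixels),
#'   `TPR`, `FPR`, `F1`, `selected`, plus attribute `level`.
#' @export
yitzhaky_rank <- function(candidates) {
  maps <- check_map_list(candidates)
  ids <- names(candidates)
  if (is.null(ids)) ids <- sprintf("candidate_%d", seq_along(maps))
  gt <- estimate_ground_truth(maps)
  sel <- select_best_map(maps)
  conf <- lapply(maps, confusion_vs, ref = gt$mask)
  tab <- data.frame(
    candidate_id = ids,
    Ne = vapply(maps, sum, numeric(1)),
    TPR = vapply(conf, `[[`, numeric(1), "tpr"),
    FPR = vapply(conf, `[[`, numeric(1), "fpr"),
    F1 = vapply(maps, f1_score, numeric(1), ref = gt$mask),
    selected = seq_along(maps) == as.integer(sel),
    stringsAsFactors = FALSE
  )
  attr(tab, "level") <- gt$level
  tab
}
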