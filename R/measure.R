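# The composite no-reference edge-map score: gradient structural similarity
# of the edge-guided reconstruction, discounted by edge-pixel density, plus
# the two selection tasks built on it (detector ranking, threshold sweep).

#' Scoring configuration
#'
#' @param alpha_nrem Exponent on MGSSIM (default 1).
#' @param beta_nrem Exponent on the density penalty (default 3). The (1, 3)
#'   defaults are the experimentally chosen operating point.
#' @param reconstruction A [reconstruction_config()].
#' @param similarity A [similarity_config()].
#' @param dilation_radius Square structuring-element radius used to build the
#'   grayscale edge map (default 1).
#' @return An `nrem_config` object.
#' @export
nrem_config <- function(alpha_nrem = 1, beta_nrem = 3,
                        reconstruction = reconstruction_config(),
                        similarity = similarity_config(),
                        dilation_radius = 1L) {
  if (!is_scalar_num(alpha_nrem) || alpha_nrem <= 0)
    stopf("`alpha_nrem` must be > 0")
  if (!is_scalar_num(beta_nrem) || beta_nrem <= 0)
    stopf("`beta_nrem` must be > 0")
  stopifnot(inherits(reconstruction, "reconstruction_config"),
            inherits(similarity, "similarity_config"))
  structure(list(alpha_nrem = alpha_nrem, beta_nrem = beta_nrem,
                 reconstruction = reconstruction, similarity = similarity,
                 dilation_radius = as.integer(dilation_radius)),
            class = "nrem_config")
}

#' Edge-density penalty factor
#'
#' `f_p = 1 / (1 + Ne / MN)`: strictly decreasing in the dilated edge-pixel
#' count, equal to 1 for an empty map and 0.5 for a saturated one. It
#' counterbalances the similarity term's bias toward dense edge maps (denser
#' maps hand more of the original image to the reconstruction).
#'
#' @param ne Number of edge pixels after dilation, `0 <= ne <= mn`.
#' @param mn Total number of image pixels (> 0).
#' @return Scalar penalty in `(0.5, 1]` for `ne < mn`.
#' @examples
#' penalty_factor(0, 100)    # 1
#' penalty_factor(100, 100)  # 0.5
#' @export
penalty_factor <- function(ne, mn) {
  if (!is_scalar_num(mn) || mn <= 0) stopf("`mn` must be positive")
  if (!is_scalar_num(ne) || ne < 0 || ne > mn)
    stopf("`ne` must satisfy 0 <= ne <= mn (got ne = %s, mn = %s)",
          format(ne), format(mn))
  1 / (1 + ne / mn)
}

#' Score one edge map
#'
#' Runs the full pipeline: dilate the candidate map and retain original
#' intensities, reconstruct every off-mask pixel, compare reconstruction and
#' original with MGSSIM, and combine with the density penalty:
#' `score = MGSSIM^alpha * f_p^beta`. All intermediates are returned.
#'
#' @param image A [gray_image].
#' @param edges Logical candidate edge map (before dilation).
#' @param cfg An [nrem_config()].
#' @param candidate_id Label stored in the result (detector name, threshold,
#'   ...).
#' @param keep_reconstruction If `TRUE` the reconstructed image is attached
#'   to the result.
#' @return An `nrem_result`: list with `candidate_id`, `ne` (edge pixels
#'   after dilation), `mgssim`, `penalty`, `nrem`, and optionally
#'   `reconstruction`.
#' @examples
#' ph <- make_phantom(shapes_phantom_spec(noise_sigma = 10, seed = 1))
#' nrem_score(ph$image, ph$truth)
#' @export
nrem_score <- function(image, edges, cfg = nrem_config(),
                       candidate_id = NA_character_,
                       keep_reconstruction = FALSE) {
  image <- as_gray_image(image)
  edges <- as_edge_map(edges, expected_shape = dim(image))
  gem <- make_grayscale_edge_map(image, edges, cfg$dilation_radius)
  rec <- reconstruct_from_gem(image, gem, cfg$reconstruction)
  mg <- mgssim(image, rec, cfg$similarity)
  fp <- penalty_factor(gem$ne, length(image$pixels))
  res <- list(candidate_id = candidate_id,
              ne = gem$ne,
              mgssim = mg,
              penalty = fp,
              nrem = signed_pow(mg, cfg$alpha_nrem) * fp^cfg$beta_nrem)
  if (keep_reconstruction) res$reconstruction <- rec
  class(res) <- "nrem_result"
  res
}

#' @export
print.nrem_result <- function(x, ...) {
  cat(sprintf("<nrem_result> %s: NREM %.6f (MGSSIM %.6f, Ne %d, penalty %.6f)\n",
              if (is.na(x$candidate_id)) "(unnamed)" else x$candidate_id,
              x$nrem, x$mgssim, x$ne, x$penalty))
  invisible(x)
}

# deterministic score order: higher score first, ties to the sparser map,
# then to earlier input position
score_order <- function(nrem, ne) order(-nrem, ne, seq_along(nrem))

#' Rank candidate edge maps
#'
#' Scores every candidate and returns the result table sorted by score
#' (descending); ties go to the candidate with fewer dilated edge pixels,
#' then to earlier input order.
#'
#' @param image A [gray_image].
#' @param candidates Named list of logical edge maps (names are the
#'   candidate ids; unnamed lists get positional ids).
#' @param cfg An [nrem_config()].
#' @return A `result_table` sorted by `NREM` descending.
#' @export
rank_candidates <- function(image, candidates, cfg = nrem_config()) {
  if (!is.list(candidates) || length(candidates) == 0L)
    stopf("`candidates` must be a nonempty list of edge maps")
  ids <- names(candidates)
  if (is.null(ids) || any(ids == ""))
    ids <- if (is.null(ids)) sprintf("candidate_%d", seq_along(candidates)) else
      ifelse(ids == "", sprintf("candidate_%d", seq_along(candidates)), ids)
  results <- Map(function(e, id) nrem_score(image, e, cfg, candidate_id = id),
                 candidates, ids)
  tab <- result_table(unname(results))
  tab <- tab[score_order(tab$NREM, tab$Ne), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("result_table", "data.frame")
  tab
}

#' Sweep a detector's threshold
#'
#' Runs a detector over an increasing threshold grid, scores each resulting
#' edge map, and reports the scores in grid order together with the
#' best-scoring threshold.
#'
#' @param image A [gray_image].
#' @param detector A [detector_spec()] template; its threshold is replaced by
#'   each grid value.
#' @param thresholds Strictly increasing nonnegative thresholds.
#' @param cfg An [nrem_config()].
#' @return A `result_table` in threshold order, with attributes
#'   `argmax_threshold` and `argmax_index` giving the winning grid point
#'   (score ties resolved as in [rank_candidates()]).
#' @export
sweep_threshold <- function(image, detector, thresholds, cfg = nrem_config()) {
  if (!inherits(detector, "detector_spec")) stopf("`detector` must be a detector_spec")
  if (length(thresholds) == 0L) stopf("`thresholds` must be nonempty")
  if (any(thresholds < 0)) stopf("thresholds must be >= 0")
  if (length(thresholds) > 1 && any(diff(thresholds) <= 0))
    stopf("thresholds must be strictly increasing")
  image <- as_gray_image(image)
  results <- lapply(thresholds, function(thr) {
    spec <- detector
    spec$threshold <- thr
    e <- detect_edges(image, spec)
    nrem_score(image, e, cfg, candidate_id = format(thr))
  })
  tab <- result_table(results)
  best <- score_order(tab$NREM, tab$Ne)[1]
  attr(tab, "argmax_threshold") <- thresholds[best]
  attr(tab, "argmax_index") <- best
  tab
}
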