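# Replicate-based optional functionalities: correlation weighting of
# overlapping isotopic distributions, correlated-candidate removal, and
# region-wise correction of replicate misalignment.  Both exploit the fact
# that peaks of one species co-vary across replicates while peaks of
# different species do not.

#' Cross-replicate correlation weights for TID evaluation points
#'
#' For every queried grid position, the Pearson correlation across
#' replicates between the intensities at the reference-peak position and at
#' that position, clamped to [0, 1].  Positions belonging to an overlapping
#' foreign species co-vary weakly with the reference and receive low weight,
#' so their (large) fit differences barely contribute to the score.
#'
#' @param rs A `replicate_set` with at least 3 replicates.
#' @param ref_index Grid index of the reference peak.
#' @param pos_index Grid indices of the TID peak positions.
#' @return Numeric weights in [0, 1], one per position; the reference
#'   position itself gets weight 1, as do zero-variance positions (with a
#'   warning).
#' @export
correlation_weights <- function(rs, ref_index, pos_index) {
  stopifnot(inherits(rs, "replicate_set"))
  if (ncol(rs$matrix) < 3L)
    stop("correlation weights need at least 3 replicates")
  ref <- rs$matrix[ref_index, ]
  ref_const <- stats::sd(ref) == 0
  degenerate <- FALSE
  w <- vapply(pos_index, function(p) {
    if (p == ref_index) return(1)
    v <- rs$matrix[p, ]
    if (ref_const || stats::sd(v) == 0) {
      degenerate <<- TRUE
      return(1)
    }
    max(0, stats::cor(ref, v))
  }, numeric(1))
  if (degenerate)
    warning("zero-variance position(s); weight set to 1")
  w
}

#' Remove candidates correlated with an accepted reference peak
#'
#' After an isotopic distribution is accepted, candidates that co-vary
#' strongly with its reference peak across replicates belong to the same
#' species (e.g. satellite isotopic peaks) and are removed together with it.
#'
#' @param candidates Grid indices of the remaining candidate peaks.
#' @param ref_index Grid index of the reference peak.
#' @param rs A `replicate_set` with at least 3 replicates.
#' @param corr_cut Correlation at or above which a candidate is removed
#'   (default 0.8).
#' @return The pruned candidate indices; the reference itself is removed
#'   (it has just been accepted and fitted).
#' @export
overlap_aware_removal <- function(candidates, ref_index, rs, corr_cut = 0.8) {
  if (length(candidates) == 0L) return(candidates)
  w <- correlation_weights(rs, ref_index, candidates)
  candidates[w < corr_cut & candidates != ref_index]
}

#' Correct replicate misalignment within a region
#'
#' Each replicate is shifted by an integer number of grid steps (bounded by
#' `max_shift`, about one FWHM) so as to maximise its correlation with the
#' representative spectrum over the most correlated points of the region
#' (the top half of region points ranked by how strongly their
#' cross-replicate intensities track the per-replicate total ion current).
#' A shift is only applied when it does not decrease the replicate's
#' full-region correlation with the representative; the representative is
#' then recomputed in the region.  Shifts are recovered relative to the
#' consensus of the replicates: when no subset of replicates anchors the
#' representative at the true position, all recovered shifts share a common
#' offset.
#'
#' @param rs A `replicate_set` with at least 2 replicates.
#' @param region Integer vector of (contiguous) grid indices.
#' @param max_shift Maximum shift in grid steps.
#' @param point_fraction Fraction of region points used for the correlation
#'   (default 0.5).
#' @return The updated `replicate_set`, with attribute `"shifts"` (applied
#'   shift per replicate, in grid steps).
#' @export
align_replicates <- function(rs, region, max_shift = 5L,
                             point_fraction = 0.5) {
  stopifnot(inherits(rs, "replicate_set"))
  m <- ncol(rs$matrix)
  if (m < 2L) stop("alignment needs at least 2 replicates")
  region <- sort(as.integer(region))
  if (length(region) < 2L * max_shift + 2L) {
    warning("region too short for alignment; skipped")
    attr(rs, "shifts") <- rep(0L, m)
    return(rs)
  }
  n <- length(rs$grid)
  mat <- rs$matrix
  repv <- rs$representative
  # rank region points by how well they track the per-replicate ion current
  tic <- colSums(mat[region, , drop = FALSE])
  pt_score <- suppressWarnings(
    apply(mat[region, , drop = FALSE], 1L, stats::cor, y = tic))
  pt_score[is.na(pt_score)] <- -Inf
  n_sel <- max(4L, ceiling(point_fraction * length(region)))
  sel <- region[order(pt_score, decreasing = TRUE)[seq_len(min(n_sel,
                                                length(region)))]]
  shifts <- integer(m)
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    stats::cor(a, b)
  }
  for (j in seq_len(m)) {
    cand_shifts <- order(abs(-max_shift:max_shift))  # prefer small |s|
    cand_shifts <- (-max_shift:max_shift)[cand_shifts]
    best_s <- 0L; best_c <- -Inf
    for (s in cand_shifts) {
      src <- pmin(pmax(sel - s, 1L), n)
      cc <- safe_cor(mat[src, j], repv[sel])
      if (cc > best_c + 1e-12) { best_c <- cc; best_s <- s }
    }
    if (best_s != 0L) {
      # accept only if the full-region correlation does not decrease
      src_all <- pmin(pmax(region - best_s, 1L), n)
      c_new <- safe_cor(mat[src_all, j], repv[region])
      c_old <- safe_cor(mat[region, j], repv[region])
      if (is.finite(c_new) && c_new >= c_old) {
        mat[region, j] <- rs$matrix[src_all, j]
        shifts[j] <- best_s
      }
    }
  }
  out <- new_replicate_set(rs$grid, mat)
  attr(out, "shifts") <- shifts
  out
}
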