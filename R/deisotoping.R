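# Monoisotoping and charge-state determination: for every candidate peak,
# theoretical isotopic distributions (TIDs) are rendered as Gaussian combs
# for every charge and reference residue, shifted coarsely (whole isotope
# positions) and finely (grid resolution), scored against the representative
# spectrum, and the best fit below the score threshold is subtracted and
# reported as one peak-list entry.

#' Fit parameters for monoisotoping
#'
#' @param score_threshold Acceptance threshold on the (dimensionless,
#'   reference-peak-normalised) fitting score; fits scoring at or above it
#'   are rejected (default 0.35).
#' @param tid_prune_ratio TID peaks below this fraction of the TID maximum
#'   are dropped before rendering (default 1/1000).
#' @param removal_fit_ratio Candidate peaks where the fitted TID explains
#'   more than this fraction of the observed intensity are removed from the
#'   candidate vector after an accepted fit (default 0.8).
#' @param charge_prior_lambda ESI charge-prior weight: with `esi_mode` the
#'   score is multiplied by `1 + lambda * (z_max - Z) / z_max`, penalising
#'   low charges, which are less probable under electrospray ionisation
#'   (default 0.05 per charge step).
#' @param fine_shift_halfwidth Half-width of the fine shift scan as a
#'   fraction of the peak FWHM (default 0.5).
#' @param esi_mode Apply the ESI charge prior (default FALSE).
#' @param max_fine_points Cap on the number of fine-shift evaluations per
#'   coarse shift (default 25).
#' @param overlap_corr_cut Cross-replicate correlation above which a
#'   candidate is considered part of the same species as the reference peak
#'   and removed with it (default 0.8; used with `use_replicates`).
#' @return A `fit_params` list.
#' @export
fit_params <- function(score_threshold = 0.35, tid_prune_ratio = 1e-3,
                       removal_fit_ratio = 0.8, charge_prior_lambda = 0.05,
                       fine_shift_halfwidth = 0.5, esi_mode = FALSE,
                       max_fine_points = 25L, overlap_corr_cut = 0.8) {
  stopifnot(score_threshold > 0, removal_fit_ratio > 0,
            removal_fit_ratio <= 1, tid_prune_ratio > 0)
  structure(list(score_threshold = score_threshold,
                 tid_prune_ratio = tid_prune_ratio,
                 removal_fit_ratio = removal_fit_ratio,
                 charge_prior_lambda = charge_prior_lambda,
                 fine_shift_halfwidth = fine_shift_halfwidth,
                 esi_mode = esi_mode,
                 max_fine_points = as.integer(max_fine_points),
                 overlap_corr_cut = overlap_corr_cut),
            class = "fit_params")
}

#' Choose the reference peak model for a candidate
#'
#' Isotopic peaks at m/z are separated by `1/Z`; the instrument resolves
#' them when the peak FWHM `mz / rp` is below that spacing.  In that case
#' the reference peak of the fit is taken to be the monoisotopic one;
#' otherwise only the envelope apex is resolvable and the most likely peak
#' becomes the reference, with the monoisotopic mass recovered by the
#' inverse regression of [fit_most_likely_model()] (the "double model").
#'
#' @param mz Candidate peak m/z (Da).
#' @param z Charge under test.
#' @param rp Estimated resolution power.
#' @return `"monoisotopic"` if `mz / rp < 1 / z` (strict), else
#'   `"most_likely"`.
#' @export
choose_reference_model <- function(mz, z, rp) {
  stopifnot(mz > 0, z >= 1, rp > 0)
  if (mz / rp < 1 / z) "monoisotopic" else "most_likely"
}

#' Render a theoretical isotopic distribution as a Gaussian comb
#'
#' TID peaks below `prune_ratio` of the TID maximum are dropped; each kept
#' isotope position becomes a Gaussian with standard deviation
#' `ref_mz / (2.35482 * rp)` (from RP = m / FWHM), peaks spaced
#' `position_spacing / z` apart and anchored so that isotope position
#' `ref_position` sits at `ref_mz`.  The whole comb is scaled so its value
#' at the anchor equals `ref_intensity`, on top of `baseline_offset` (the
#' lowest intensity of the fitted region, treated as local residual
#' baseline).
#'
#' @param tid An `isotopic_distribution`.
#' @param z Charge.
#' @param ref_mz Anchor m/z (Da).
#' @param ref_intensity Spectrum intensity at the anchor.
#' @param rp Resolution power.
#' @param grid m/z values at which to evaluate the curve.
#' @param ref_position Isotope position (0-based) anchored at `ref_mz`.
#' @param baseline_offset Local residual baseline added to the curve.
#' @param prune_ratio Pruning threshold relative to the TID maximum.
#' @return A list with `curve` (over `grid`), `positions` and `heights` of
#'   the kept peaks, `kept` (0-based positions), `sigma` and `scale`; or
#'   `NULL` when the anchor position was pruned away or carries no
#'   abundance.
#' @export
render_tid <- function(tid, z, ref_mz, ref_intensity, rp, grid,
                       ref_position = 0L, baseline_offset = 0,
                       prune_ratio = 1e-3) {
  ab <- tid$abundances
  keep <- which(ab >= max(ab) * prune_ratio)
  if (length(keep) == 0L) stop("TID empty after pruning")
  k <- keep - 1L
  if (!(ref_position %in% k)) return(NULL)
  spacing <- tid$position_spacing / z
  positions <- ref_mz + (k - ref_position) * spacing
  sigma <- ref_mz / (fwhm_sigma_ratio() * rp)
  u <- ab[keep] / ab[ref_position + 1L]
  curve <- numeric(length(grid))
  for (j in seq_along(positions)) {
    lo <- findInterval(positions[j] - 5 * sigma, grid) + 1L
    hi <- findInterval(positions[j] + 5 * sigma, grid)
    if (hi < lo) next
    seg <- lo:hi
    curve[seg] <- curve[seg] +
      u[j] * exp(-((grid[seg] - positions[j])^2) / (2 * sigma^2))
  }
  v <- sum(u * exp(-((ref_mz - positions)^2) / (2 * sigma^2)))
  if (v <= 0) return(NULL)
  scale <- (ref_intensity - baseline_offset) / v
  if (scale <= 0) return(NULL)
  list(curve = baseline_offset + scale * curve,
       positions = positions, heights = scale * u,
       kept = k, sigma = sigma, scale = scale,
       baseline_offset = baseline_offset)
}

#' Goodness-of-fit score of a rendered TID against the spectrum
#'
#' Weighted mean of absolute differences between the rendered curve and the
#' spectrum at the evaluation points, after both are normalised by the
#' reference-peak intensity (making the score dimensionless, so one
#' acceptance threshold transfers across spectra).  With `esi_mode` the
#' score is multiplied by `1 + lambda * (z_max - z) / z_max`.
#'
#' @param curve Rendered curve values at the evaluation points.
#' @param observed Spectrum values at the evaluation points.
#' @param weights Non-negative weights, one per point.
#' @param ref_intensity Reference-peak intensity used for normalisation.
#' @param z Charge of the fit; `z_max` the configured maximum.
#' @param esi_mode,lambda ESI charge prior (see [fit_params()]).
#' @return The score (>= 0; 0 for a perfect fit).
#' @export
fit_score <- function(curve, observed, weights, ref_intensity, z = 1L,
                      z_max = 1L, esi_mode = FALSE, lambda = 0.05) {
  stopifnot(length(curve) == length(observed),
            length(weights) == length(curve))
  if (length(curve) == 0L) stop("no evaluation points")
  sw <- sum(weights)
  if (sw <= 0) {
    warning("all evaluation weights are zero; score set to 0")
    return(0)
  }
  score <- sum(weights * abs(curve - observed)) / (sw * ref_intensity)
  if (esi_mode) score <- score * (1 + lambda * (z_max - z) / z_max)
  score
}

# Lazy provider of TID tables + most-likely models per residue.  Extends to
# `extended_limit` only when a queried mass exceeds the default table.
make_tid_provider <- function(residues, isotope_table = default_isotope_table(),
                              default_limit = 20000,
                              extended_limit = 170000, cache_dir = NULL) {
  residues <- lapply(residues, reference_residue, table = isotope_table)
  names(residues) <- vapply(residues, `[[`, character(1), "name")
  env <- new.env(parent = emptyenv())
  fetch <- function(residue_name, m0) {
    res <- residues[[residue_name]]
    key <- residue_name
    tm <- if (exists(key, env)) get(key, env) else {
      x <- get_reference_tid(res, default_limit, isotope_table, cache_dir)
      assign(key, x, env); x
    }
    rng <- range(tm$table$masses)
    if (m0 < rng[1L]) return(NULL)
    if (m0 > rng[2L]) {
      if (m0 > extended_limit) return(NULL)
      tm <- get_reference_tid(res, extended_limit, isotope_table, cache_dir)
      assign(key, tm, env)
    }
    tm
  }
  list(fetch = fetch, residues = names(residues))
}

# Evaluation points for scoring.  z_max > 1: apex grid point of every kept
# TID peak plus its two neighbours, and the midpoints between adjacent
# peaks -- the whole TID must be checked to pin the charge, and the
# midpoints are where a fit at half the true charge is betrayed by the
# interleaved isotope peaks it cannot explain.  z_max == 1: the
# reference-peak stencil plus 3 points spaced FWHM/2 to the left of the
# estimated monoisotopic peak, avoiding errors from overlap on the right.
eval_points <- function(positions, ref_pos_index, grid, region_idx, z_max,
                        mono_mz, fwhm) {
  nearest <- function(mzs) {
    i <- findInterval(mzs, grid)
    i <- pmin(pmax(i, 1L), length(grid) - 1L)
    ifelse(mzs - grid[i] > grid[i + 1L] - mzs, i + 1L, i)
  }
  lo <- region_idx[1L]; hi <- region_idx[length(region_idx)]
  if (z_max > 1L) {
    apex <- nearest(positions)
    pts <- as.vector(vapply(apex, function(a) c(a - 1L, a, a + 1L),
                            integer(3)))
    owner <- rep(seq_along(positions), each = 3L)
    if (length(positions) > 1L) {
      mid <- nearest((positions[-1L] + positions[-length(positions)]) / 2)
      pts <- c(pts, mid)
      owner <- c(owner, -seq_along(mid))   # negative: midpoint index
    }
  } else {
    apex <- nearest(positions[ref_pos_index])
    left <- nearest(mono_mz - (1:3) * fwhm / 2)
    pts <- c(apex - 1L, apex, apex + 1L, left)
    owner <- c(rep(ref_pos_index, 3L), rep(NA_integer_, 3L))
  }
  ok <- pts >= lo & pts <= hi
  list(idx = pts[ok], owner = owner[ok])
}

# Fit one candidate peak: loop over charges, residues, coarse shifts (whole
# isotope positions, per the double model) and fine shifts (grid
# resolution), returning the best-scoring TID fit or NULL.
fit_candidate <- function(repvec, grid, idx, rp, z_max, residues, tables,
                          params, rs = NULL, use_overlap = FALSE) {
  mz_i <- grid[idx]
  I_i <- repvec[idx]
  if (I_i <= 0) return(NULL)
  spacing0 <- ISOTOPE_SPACING
  best <- NULL
  step <- if (idx < length(grid)) grid[idx + 1L] - grid[idx]
          else grid[idx] - grid[idx - 1L]
  for (z in seq_len(z_max)) {
    model_type <- choose_reference_model(mz_i, z, rp)
    m_obs <- z * (mz_i - PROTON_MASS)
    if (m_obs <= 0) next
    fwhm <- mz_i / rp
    sigma <- mz_i / (fwhm_sigma_ratio() * rp)
    hw <- params$fine_shift_halfwidth * fwhm
    nside <- floor(hw / step)
    offs <- if (nside < 1L) 0 else
      if (2L * nside + 1L > params$max_fine_points) {
        m <- params$max_fine_points %/% 2L
        seq(-hw, hw, length.out = 2L * m + 1L)
      } else (-nside:nside) * step
    for (res in residues) {
      tm <- tables$fetch(res, m_obs)
      if (is.null(tm)) next
      m0 <- if (model_type == "monoisotopic") m_obs
            else tm$model$predict_monoisotopic(m_obs)
      if (m0 < tm$table$masses[1L]) next
      tid <- tid_at_mass(tm$table, m0)
      kst <- tm$model$k_star_at(m0)
      ref_positions <- if (model_type == "monoisotopic") 0:kst
                       else unique(pmax(kst + (-1:1), 0L))
      for (rp_pos in ref_positions) {
        ab <- tid$abundances
        keep0 <- which(ab >= max(ab) * params$tid_prune_ratio) - 1L
        if (!(rp_pos %in% keep0)) next
        pos0 <- mz_i + (keep0 - rp_pos) * spacing0 / z
        r_lo <- findInterval(min(pos0) - 3 * sigma - hw, grid) + 1L
        r_hi <- findInterval(max(pos0) + 3 * sigma + hw, grid)
        r_lo <- max(r_lo, 1L); r_hi <- min(r_hi, length(grid))
        if (r_hi - r_lo < 2L) next
        region_idx <- r_lo:r_hi
        offset <- min(repvec[region_idx])
        weights_pos <- NULL; weights_mid <- NULL
        if (use_overlap && !is.null(rs) && ncol(rs$matrix) >= 3L) {
          pos_idx <- pmin(pmax(findInterval(pos0, grid), 1L), length(grid))
          weights_pos <- correlation_weights(rs, idx, pos_idx)
          if (length(pos0) > 1L) {
            mid_idx <- pmin(pmax(findInterval(
              (pos0[-1L] + pos0[-length(pos0)]) / 2, grid), 1L),
              length(grid))
            weights_mid <- correlation_weights(rs, idx, mid_idx)
          }
        }
        for (dd in offs) {
          rend <- render_tid(tid, z, mz_i + dd, I_i, rp, grid[region_idx],
                             ref_position = rp_pos, baseline_offset = offset,
                             prune_ratio = params$tid_prune_ratio)
          if (is.null(rend)) next
          ref_pos_index <- match(rp_pos, rend$kept)
          mono_mz <- (mz_i + dd) - rp_pos * spacing0 / z
          ep <- eval_points(rend$positions, ref_pos_index, grid, region_idx,
                            z_max, mono_mz, fwhm)
          if (length(ep$idx) == 0L) next
          w <- rep(1, length(ep$idx))
          if (!is.null(weights_pos)) {
            pk_pt <- !is.na(ep$owner) & ep$owner > 0
            w[pk_pt] <- weights_pos[ep$owner[pk_pt]]
            if (!is.null(weights_mid)) {
              mid_pt <- !is.na(ep$owner) & ep$owner < 0
              w[mid_pt] <- weights_mid[-ep$owner[mid_pt]]
            }
          }
          sc <- fit_score(rend$curve[ep$idx - r_lo + 1L], repvec[ep$idx],
                          w, I_i, z = z, z_max = z_max,
                          esi_mode = params$esi_mode,
                          lambda = params$charge_prior_lambda)
          if (is.null(best) || sc < best$score) {
            best <- list(score = sc, z = z, residue = res,
                         model_type = model_type, ref_position = rp_pos,
                         shift = dd, region_idx = region_idx,
                         render = rend,
                         monoisotopic_mass = z * (mono_mz - PROTON_MASS),
                         intensity = sum(rend$heights),
                         eval_idx = ep$idx)
          }
        }
      }
    }
  }
  best
}

#' Iterative peak-list extraction from a prepared replicate set
#'
#' Runs the monoisotoping/charge-determination loop on a detected candidate
#' list: repeatedly take the lowest-m/z surviving candidate, reject it if
#' below the intensity threshold, fit TIDs over all charges, residues and
#' shifts, and either discard the candidate (best score at or above the
#' threshold) or emit a peak-list entry, subtract the rendered TID from the
#' representative spectrum, and drop every candidate the TID explains
#' (and, with `use_overlap`, every candidate strongly correlated with the
#' reference across replicates).  Most users should call [extract_peaks()],
#' which prepares all inputs.
#'
#' @param rs A baseline-corrected `replicate_set`.
#' @param rp Estimated resolution power.
#' @param peaks Candidate data frame from [find_peaks()].
#' @param threshold A `threshold_curve` from [build_threshold()].
#' @param tables TID provider (internal; built by [extract_peaks()]).
#' @param z_max Maximum charge.
#' @param params [fit_params()].
#' @param use_overlap Weight scores and removals by cross-replicate
#'   correlation (needs >= 3 replicates).
#' @param use_align Correct replicate misalignment per fitted region
#'   (needs >= 2 replicates).
#' @return A list with `peaks` (data frame: monoisotopic_mass, charge,
#'   intensity, residue, score), `residual` (representative after all
#'   subtractions) and `counts` (candidates partitioned into
#'   below_threshold, rejected, absorbed by an accepted fit, extracted).
#' @export
extract_peak_list <- function(rs, rp, peaks, threshold, tables,
                              z_max = 1L, params = fit_params(),
                              use_overlap = FALSE, use_align = FALSE) {
  grid <- rs$grid
  n <- length(grid)
  sub <- numeric(n)                 # cumulative subtracted signal
  base_rep <- rowSums(rs$matrix)
  repvec <- pmax(base_rep - sub, 0)
  thr <- threshold$at(grid)
  cand <- peaks$grid_index          # sorted by m/z
  spacing0 <- ISOTOPE_SPACING
  entries <- list()
  n_below <- 0L; n_rejected <- 0L; n_absorbed <- 0L
  while (length(cand) > 0L) {
    idx <- cand[1L]
    if (repvec[idx] < thr[idx]) {
      cand <- cand[-1L]; n_below <- n_below + 1L; next
    }
    if (use_align && ncol(rs$matrix) >= 2L) {
      span <- 35 * spacing0
      reg <- which(grid >= grid[idx] - span & grid <= grid[idx] + span)
      max_shift <- max(1L, round((grid[idx] / rp) /
                                   stats::median(diff(grid[reg]))))
      rs <- align_replicates(rs, reg, max_shift = max_shift)
      base_rep[reg] <- rowSums(rs$matrix[reg, , drop = FALSE])
      repvec[reg] <- pmax(base_rep[reg] - sub[reg], 0)
    }
    fit <- fit_candidate(repvec, grid, idx, rp, z_max, tables$residues,
                         tables, params, rs = rs, use_overlap = use_overlap)
    if (is.null(fit) || fit$score >= params$score_threshold) {
      cand <- cand[-1L]; n_rejected <- n_rejected + 1L; next
    }
    entries[[length(entries) + 1L]] <-
      data.frame(monoisotopic_mass = fit$monoisotopic_mass,
                 charge = fit$z, intensity = fit$intensity,
                 residue = fit$residue, score = fit$score,
                 stringsAsFactors = FALSE)
    # remove candidates the accepted TID explains
    reg <- fit$region_idx
    in_region <- cand[cand >= reg[1L] & cand <= reg[length(reg)]]
    drop <- idx
    if (length(in_region) > 0L) {
      curve_at <- fit$render$curve[in_region - reg[1L] + 1L] -
        fit$render$baseline_offset
      obs_at <- repvec[in_region] - fit$render$baseline_offset
      near <- vapply(grid[in_region], function(m)
        min(abs(m - fit$render$positions)), numeric(1)) <=
        spacing0 / (2 * fit$z)
      expl <- near & obs_at > 0 & curve_at > params$removal_fit_ratio * obs_at
      drop <- union(drop, in_region[expl])
      if (use_overlap && ncol(rs$matrix) >= 3L) {
        cw <- correlation_weights(rs, idx, in_region)
        drop <- union(drop, in_region[cw >= params$overlap_corr_cut &
                                        in_region != idx])
      }
    }
    # subtract the rendered TID (without its baseline offset), clamped
    sub[reg] <- sub[reg] + (fit$render$curve - fit$render$baseline_offset)
    repvec[reg] <- pmax(base_rep[reg] - sub[reg], 0)
    n_absorbed <- n_absorbed + length(drop) - 1L
    cand <- setdiff(cand, drop)
  }
  peaks_df <- if (length(entries) > 0L) do.call(rbind, entries) else
    data.frame(monoisotopic_mass = numeric(0), charge = integer(0),
               intensity = numeric(0), residue = character(0),
               score = numeric(0), stringsAsFactors = FALSE)
  list(peaks = peaks_df, residual = repvec,
       counts = c(candidates = nrow(peaks), below_threshold = n_below,
                  rejected = n_rejected, absorbed = n_absorbed,
                  extracted = nrow(peaks_df)))
}
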