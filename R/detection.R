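# Peak detection and noise handling: the maximal curve with a mass-dependent
# moving window, estimation of the effective resolution power, and the
# signal-dependent intensity threshold (mu + 2*sigma of the local noise
# maxima).

# sparse table for O(1) range-maximum queries; lo/hi are index vectors
range_max <- function(y, lo, hi) {
  n <- length(y)
  maxlen <- max(hi - lo + 1L)
  levels <- max(1L, floor(log2(maxlen)) + 1L)
  tab <- vector("list", levels)
  tab[[1L]] <- y
  len <- 1L
  for (k in seq_len(levels - 1L)) {
    prev <- tab[[k]]
    m <- n - 2L * len + 1L
    tab[[k + 1L]] <- pmax(prev[seq_len(max(m, 0L))],
                          prev[seq_len(max(m, 0L)) + len])
    len <- 2L * len
  }
  span <- hi - lo + 1L
  k <- floor(log2(span))
  p <- 2L^k
  top <- tab[[k[1L] + 1L]]
  if (length(unique(k)) == 1L) {
    pmax(top[lo], top[hi - p + 1L])
  } else {
    out <- numeric(length(lo))
    for (kk in unique(k)) {
      sel <- k == kk
      t2 <- tab[[kk + 1L]]
      out[sel] <- pmax(t2[lo[sel]], t2[hi[sel] - 2L^kk + 1L])
    }
    out
  }
}

#' Maximal curve of a spectrum
#'
#' For every grid point the maximum intensity within a moving window of
#' width m/z / RP centred on it; the set of these maxima forms the maximal
#' curve, which is everywhere >= the spectrum and equal to it at window
#' maxima.
#'
#' @param spectrum A `mass_spectrum`.
#' @param rp Resolution power defining the window width.
#' @return Numeric vector of the maximal curve over the grid.
#' @export
maximal_curve <- function(spectrum, rp) {
  stopifnot(rp > 0)
  mz <- spectrum$mz
  w <- mz / rp
  lo <- findInterval(mz - w / 2, mz, left.open = TRUE) + 1L
  hi <- findInterval(mz + w / 2, mz)
  hi <- pmax(hi, seq_along(mz))
  lo <- pmin(lo, seq_along(mz))
  range_max(spectrum$intensity, lo, hi)
}

#' Detect candidate isotopic peaks via the maximal curve
#'
#' Local maxima of the maximal curve are located as the central point of
#' each plateau region bounded by a positive-to-nonpositive and a
#' nonnegative-to-negative derivative change (ties resolved towards lower
#' m/z).  Every local maximum is a candidate isotopic peak; noise candidates
#' are filtered later by the intensity threshold.
#'
#' @param spectrum The representative `mass_spectrum`.
#' @param rp Estimated resolution power.
#' @return A data frame with columns `grid_index`, `mz`, `intensity`,
#'   sorted by m/z.
#' @export
find_peaks <- function(spectrum, rp) {
  mc <- maximal_curve(spectrum, rp)
  runs <- rle(mc)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  v <- runs$values
  k <- length(v)
  if (k == 1L)           # flat spectrum: no local maxima
    return(data.frame(grid_index = integer(0), mz = numeric(0),
                      intensity = numeric(0)))
  is_peak <- rep(FALSE, k)
  left_ok <- c(FALSE, v[-1L] > v[-k])    # boundary runs are not maxima
  right_ok <- c(v[-k] > v[-1L], FALSE)
  is_peak <- left_ok & right_ok
  idx <- starts[is_peak] + (runs$lengths[is_peak] - 1L) %/% 2L
  data.frame(grid_index = idx, mz = spectrum$mz[idx],
             intensity = spectrum$intensity[idx])
}

#' Bundled proteome mass-density model
#'
#' Log-normal approximation of the mass density of peptides/proteins in a
#' proteome database, used to scale the threshold-window width (wider
#' windows where database mass density is low).  Replaceable by a
#' two-column (mass, density) text file.
#'
#' @param density_file Optional path to a two-column (mass Da, density)
#'   table.
#' @return A function mass (Da) -> relative density.
#' @export
mass_density_model <- function(density_file = NULL) {
  if (!is.null(density_file)) {
    dat <- utils::read.table(density_file, header = FALSE,
                             col.names = c("mass", "density"))
    f <- stats::approxfun(dat$mass, dat$density, rule = 2)
    return(function(m) pmax(f(m), 1e-12))
  }
  function(m) stats::dlnorm(pmax(m, 1), meanlog = log(1500), sdlog = 0.9)
}

#' Signal-dependent intensity threshold
#'
#' The intensities of the detected local maxima in a moving window are
#' assumed to be dominated by noise spread in a Gaussian way; a Gaussian
#' (mu, sigma) is fitted robustly per window (median and MAD, so that real
#' signal peaks do not inflate sigma) and the threshold at the window centre
#' is mu + 2*sigma, chosen to keep false-positive noise peaks low.  Window
#' width is inversely proportional to the proteome mass density at the
#' window centre, clamped to [200 grid points, 10\% of the spectrum]; the
#' full curve is the linear interpolation of the window thresholds.
#'
#' @param peaks Data frame from [find_peaks()].
#' @param spectrum The representative `mass_spectrum`.
#' @param density Density model from [mass_density_model()].
#' @param min_window,max_window_fraction Window clamps (points, fraction).
#' @param min_maxima Windows with fewer local maxima are merged with their
#'   neighbour (default 30, enough for the noise maxima to dominate the
#'   robust Gaussian fit even inside an isotopic envelope).
#' @return A `threshold_curve`: list with `at(mz)` evaluating the curve,
#'   plus `centers`, `mu`, `sigma`, `threshold` per window.
#' @export
build_threshold <- function(peaks, spectrum, density = mass_density_model(),
                            min_window = 200L, max_window_fraction = 0.1,
                            min_maxima = 30L) {
  n <- length(spectrum$mz)
  max_w <- max(min_window, ceiling(max_window_fraction * n))
  if (nrow(peaks) < 20L) {
    bounds <- c(1L, n)                    # single global window
  } else {
    d <- density(spectrum$mz)
    dmax <- max(d)
    bounds <- 1L
    i <- 1L
    while (i <= n) {
      w <- as.integer(min(max(min_window * dmax / d[i], min_window), max_w))
      i <- i + w
      bounds <- c(bounds, min(i, n))
    }
    if (length(bounds) < 2L) bounds <- c(1L, n)
  }
  # assign maxima to windows, merging sparse windows with the next
  centers <- numeric(0); mus <- numeric(0); sigmas <- numeric(0)
  pend_idx <- integer(0); pend_lo <- NA_integer_
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- bounds[k]; hi <- bounds[k + 1L]
    sel <- which(peaks$grid_index >= lo & peaks$grid_index < hi |
                   (k == length(bounds) - 1L & peaks$grid_index == hi))
    pend_idx <- c(pend_idx, sel)
    if (is.na(pend_lo)) pend_lo <- lo
    if (length(pend_idx) < min_maxima && k < length(bounds) - 1L)
      next
    vals <- peaks$intensity[pend_idx]
    if (length(vals) == 0L) { pend_idx <- integer(0); pend_lo <- NA; next }
    mu <- stats::median(vals)
    sigma <- stats::mad(vals)
    centers <- c(centers, (spectrum$mz[pend_lo] + spectrum$mz[hi]) / 2)
    mus <- c(mus, mu); sigmas <- c(sigmas, sigma)
    pend_idx <- integer(0); pend_lo <- NA_integer_
  }
  if (length(centers) == 0L) {           # no maxima at all: zero threshold
    centers <- stats::median(spectrum$mz); mus <- 0; sigmas <- 0
  }
  thr <- mus + 2 * sigmas
  at <- if (length(centers) == 1L) {
    function(mz) rep(thr, length(mz))
  } else {
    function(mz) stats::approx(centers, thr, xout = mz, rule = 2)$y
  }
  structure(list(centers = centers, mu = mus, sigma = sigmas,
                 threshold = thr, at = at),
            class = "threshold_curve")
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat("Intensity threshold (mu + 2*sigma):", length(x$centers),
      "window(s), threshold range",
      format(min(x$threshold)), "-", format(max(x$threshold)), "\n")
  invisible(x)
}

#' Estimate the effective resolution power of a spectrum
#'
#' The nominal RP of an instrument rarely matches the data (drift, replicate
#' misalignment), so the observed RP is estimated: the representative
#' spectrum is divided into `n_intervals` intervals of equal point counts,
#' the maximum-intensity m/z of each interval is treated as the most likely
#' peak of an isotopic distribution, and the monoisotoping fit is run on it
#' for a grid of RP values around `rp_in`; the RP minimising the mean
#' fitting score is returned.
#'
#' @param rs A `replicate_set` (baseline-corrected).
#' @param rp_in Initial resolution-power guess.
#' @param tables Reference TID tables, as built by [extract_peaks()]
#'   internals; an environment keyed by residue name.
#' @param z_max Maximum charge considered in the trial fits.
#' @param residues Residue names used for the trial fits.
#' @param n_intervals Number of intervals (default 4).
#' @param rp_grid Multipliers applied to `rp_in`; default 15 log-spaced
#'   values in [1/2, 2].
#' @param params Fit parameters ([fit_params()]).
#' @return The estimated RP, with attribute `"scores"` (mean score per grid
#'   value).
#' @export
estimate_rp <- function(rs, rp_in, tables, z_max = 1L,
                        residues = "averagine", n_intervals = 4L,
                        rp_grid = exp(seq(log(0.5), log(2), length.out = 15)),
                        params = fit_params()) {
  stopifnot(rp_in > 0, n_intervals >= 1L)
  rep_s <- representative_spectrum(rs)
  n <- length(rep_s$mz)
  if (n < n_intervals) stop("spectrum too short for RP estimation")
  edges <- as.integer(floor(seq(0L, n, length.out = n_intervals + 1L)))
  cand <- vapply(seq_len(n_intervals), function(k) {
    i0 <- edges[k] + 1L; i1 <- edges[k + 1L]
    i0 + which.max(rep_s$intensity[i0:i1]) - 1L
  }, integer(1))
  rps <- rp_in * rp_grid
  mean_scores <- vapply(rps, function(rp) {
    sc <- vapply(cand, function(idx) {
      fit <- fit_candidate(rep_s$intensity, rep_s$mz, idx, rp,
                           z_max = z_max, residues = residues,
                           tables = tables, params = params)
      if (is.null(fit)) NA_real_ else fit$score
    }, numeric(1))
    mean(sc, na.rm = TRUE)
  }, numeric(1))
  if (all(is.nan(mean_scores))) {
    warning("RP estimation failed on all intervals; returning rp_in")
    return(structure(rp_in, scores = mean_scores))
  }
  best <- which.min(mean_scores)
  rp_est <- rps[best]
  if (min(mean_scores, na.rm = TRUE) >= params$score_threshold)
    warning("low-confidence RP estimate: no trial fit scored below the ",
            "acceptance threshold (possibly a noise-only spectrum)")
  structure(rp_est, scores = mean_scores)
}
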