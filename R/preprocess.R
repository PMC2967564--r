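# Preprocessing: baseline correction (applied twice by the pipeline) and
# optional smoothing.  Normalization is deliberately never applied, so each
# replicate's contribution stays proportional to its total ion current.

#' Baseline correction of a profile spectrum
#'
#' Estimates the slowly varying baseline as the moving-window minimum of the
#' intensity trace, smooths that minima envelope with a running mean of the
#' same width, and subtracts it; negative residuals are clamped to zero.
#' The pipeline applies this twice (`baseline_passes = 2`), which removes
#' both a broad offset and the residual envelope the first pass leaves under
#' wide humps.
#'
#' @param spectrum A `mass_spectrum`.
#' @param window_fraction Width of the moving window as a fraction of the
#'   number of grid points (default 0.05).
#' @param passes Number of correction passes applied here (default 1; the
#'   pipeline calls it with its own `baseline_passes`).
#' @return The corrected `mass_spectrum`.
#' @export
baseline_correct <- function(spectrum, window_fraction = 0.05, passes = 1L) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  n <- length(spectrum$intensity)
  w <- max(3L, as.integer(round(window_fraction * n)))
  if (w > n)
    stop("baseline window (", w, " points) larger than the spectrum (",
         n, " points)")
  y <- spectrum$intensity
  for (p in seq_len(passes)) {
    env <- running_extremum(y, w, pmin)
    env <- running_mean(env, w)
    y <- pmax(y - env, 0)
  }
  mass_spectrum(spectrum$mz, y)
}

# moving-window extremum with centred window of half-width (w-1)/2;
# `fun` must be an elementwise pair reducer (pmin/pmax)
running_extremum <- function(y, w, fun) {
  n <- length(y)
  h <- (w - 1L) %/% 2L
  out <- y
  for (d in seq_len(h)) {
    out <- fun(out, c(y[-seq_len(d)], rep(y[n], d)))
    out <- fun(out, c(rep(y[1L], d), y[seq_len(n - d)]))
  }
  out
}

running_mean <- function(y, w) {
  h <- (w - 1L) %/% 2L
  n <- length(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Optional smoothing of a spectrum
#'
#' Lowess or Savitzky-Golay smoothing on the unchanged m/z grid.  Off by
#' default in the pipeline: summing replicates already performs an implicit
#' smoothing, and envelope fitting prefers unaltered signal.
#'
#' @param spectrum A `mass_spectrum`.
#' @param method `"lowess"` or `"savitzky_golay"`.
#' @param span Lowess smoother span (fraction of points, default 0.01).
#' @param window Savitzky-Golay window length in points (odd, default 11).
#' @param order Savitzky-Golay polynomial order (less than `window`,
#'   default 2).
#' @return The smoothed `mass_spectrum` on the same grid.
#' @export
smooth_spectrum <- function(spectrum,
                            method = c("lowess", "savitzky_golay"),
                            span = 0.01, window = 11L, order = 2L) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  method <- match.arg(method)
  y <- switch(method,
    lowess = stats::lowess(spectrum$mz, spectrum$intensity, f = span)$y,
    savitzky_golay = {
      if (window %% 2L == 0L) stop("Savitzky-Golay window must be odd")
      if (order >= window) stop("polynomial order must be below the window")
      if (window > length(spectrum$intensity))
        stop("smoothing window larger than the spectrum")
      as.numeric(signal::sgolayfilt(spectrum$intensity, p = order, n = window))
    })
  mass_spectrum(spectrum$mz, y)
}
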