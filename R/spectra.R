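# Spectrum containers and I/O: reading profile-mode spectra (two-column
# ASCII or mzXML), assembling the replicate matrix and its representative
# spectrum, correlation-based quality control, and peak-list output.

#' Construct a profile-mode mass spectrum
#'
#' @param mz Numeric vector of m/z values (Da), strictly increasing after
#'   sorting/deduplication.
#' @param intensity Numeric vector of intensities, same length as `mz`.
#' @return A `mass_spectrum` object (list with `mz`, `intensity`).
#' @export
mass_spectrum <- function(mz, intensity) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length")
  if (length(mz) < 2L)
    stop("a profile-mode spectrum needs at least 2 points")
  if (is.unsorted(mz)) {
    warning("m/z values not monotone; sorting")
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
  }
  if (anyDuplicated(mz)) {
    keep <- !duplicated(mz)
    grp <- factor(match(mz, mz[keep]), levels = seq_len(sum(keep)))
    intensity <- vapply(split(intensity, grp), max, numeric(1), USE.NAMES = FALSE)
    mz <- mz[keep]
  }
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat("Mass spectrum:", length(x$mz), "points, m/z",
      format(min(x$mz)), "-", format(max(x$mz)), "\n")
  invisible(x)
}

#' @export
plot.mass_spectrum <- function(x, ...) {
  graphics::plot(x$mz, x$intensity, type = "l", xlab = "m/z",
                 ylab = "intensity", ...)
  invisible(x)
}

#' Read a profile-mode spectrum from disk
#'
#' ASCII spectra are two columns (m/z, intensity), whitespace- or
#' comma-separated, optionally with a header line; mzXML files are read
#' through the `mzR` package (all MS1 profile scans in the file are summed
#' on the first scan's grid, following the replicate model in which scans of
#' one sample accumulate into a representative trace).
#'
#' @param path File path.
#' @param format `"ascii"` or `"mzxml"`; default guesses from the extension.
#' @return A `mass_spectrum`.
#' @export
read_spectrum <- function(path, format = c("auto", "ascii", "mzxml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mzxml$", path, ignore.case = TRUE))
      "mzxml" else "ascii"
  if (format == "mzxml") {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("reading mzXML requires the mzR package")
    handle <- mzR::openMSfile(path)
    on.exit(mzR::close(handle))
    hd <- mzR::header(handle)
    scans <- which(hd$msLevel == 1L)
    if (length(scans) == 0L) stop("no MS1 scans in ", path)
    pk <- mzR::peaks(handle, scans[1L])
    if (nrow(pk) < 2L) stop("scan in ", path, " looks centroided or empty")
    s <- mass_spectrum(pk[, 1L], pk[, 2L])
    if (length(scans) > 1L) {
      reps <- lapply(scans, function(i) {
        p <- mzR::peaks(handle, i)
        mass_spectrum(p[, 1L], p[, 2L])
      })
      s <- representative_spectrum(build_replicate_set(reps))
    }
    return(s)
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  dat <- utils::read.table(path, sep = sep, header = FALSE,
                           comment.char = "#",
                           colClasses = "character", fill = TRUE)
  # tolerate a header line of column names
  suppressWarnings({
    col1 <- as.numeric(dat[[1L]]); col2 <- as.numeric(dat[[2L]])
  })
  if (is.na(col1[1L])) { col1 <- col1[-1L]; col2 <- col2[-1L] }
  if (anyNA(col1) || anyNA(col2))
    stop("could not parse two numeric columns from ", path)
  if (length(col1) < 2L)
    stop(path, " has fewer than 2 points; not a profile-mode spectrum")
  mass_spectrum(col1, col2)
}

#' Write a spectrum as two-column ASCII
#'
#' @param spectrum A `mass_spectrum`.
#' @param path Output file.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(data.frame(spectrum$mz, spectrum$intensity), path,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble a replicate set on a common m/z grid
#'
#' The common grid is the first spectrum's grid clipped to the intersection
#' of all m/z ranges; every other replicate is linearly resampled onto it.
#' The representative spectrum is the row sum of the intensity matrix (no
#' normalization: each replicate contributes in proportion to its total ion
#' current).
#'
#' @param spectra A list of `mass_spectrum` objects (or a single one).
#' @return A `replicate_set`: list with `grid` (N m/z values), `matrix`
#'   (N x M intensities) and `representative` (row sums).
#' @export
build_replicate_set <- function(spectra) {
  if (inherits(spectra, "mass_spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1L)
  lo <- max(vapply(spectra, function(s) min(s$mz), numeric(1)))
  hi <- min(vapply(spectra, function(s) max(s$mz), numeric(1)))
  if (lo >= hi)
    stop("replicate m/z ranges do not overlap")
  grid <- spectra[[1L]]$mz
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) < 2L)
    stop("common m/z range contains fewer than 2 grid points")
  mat <- vapply(spectra, function(s) {
    stats::approx(s$mz, s$intensity, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  new_replicate_set(grid, mat)
}

new_replicate_set <- function(grid, mat) {
  structure(list(grid = grid, matrix = mat,
                 representative = rowSums(mat)),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat("Replicate set:", ncol(x$matrix), "replicates x",
      length(x$grid), "grid points, m/z",
      format(min(x$grid)), "-", format(max(x$grid)), "\n")
  invisible(x)
}

#' Representative spectrum of a replicate set
#'
#' @param rs A `replicate_set`.
#' @return The row-sum representative as a `mass_spectrum`.
#' @export
representative_spectrum <- function(rs) {
  mass_spectrum(rs$grid, rs$representative)
}

#' Quality control of replicates by correlation with the representative
#'
#' Replicates whose Pearson correlation with the representative spectrum is
#' below `min_corr` are dropped and the representative is recomputed once.
#'
#' @param rs A `replicate_set` with at least 2 replicates.
#' @param min_corr Correlation threshold (default 0.4).
#' @param iterate Recompute and re-filter until stable instead of the single
#'   default pass.
#' @return The filtered `replicate_set`, with attribute `"dropped"` holding
#'   the indices of removed replicates.
#' @export
qc_filter <- function(rs, min_corr = 0.4, iterate = FALSE) {
  stopifnot(inherits(rs, "replicate_set"))
  if (ncol(rs$matrix) < 2L)
    stop("quality control needs at least 2 replicates")
  dropped <- integer(0)
  idx <- seq_len(ncol(rs$matrix))
  repeat {
    cors <- suppressWarnings(
      apply(rs$matrix, 2L, stats::cor, y = rs$representative))
    cors[is.na(cors)] <- 0
    bad <- which(cors < min_corr)
    if (length(bad) == 0L) break
    if (length(bad) == ncol(rs$matrix))
      stop("quality control would drop every replicate")
    dropped <- c(dropped, idx[bad])
    idx <- idx[-bad]
    rs <- new_replicate_set(rs$grid, rs$matrix[, -bad, drop = FALSE])
    if (!iterate) break
  }
  attr(rs, "dropped") <- dropped
  rs
}

#' Write a peak list as tab-separated text
#'
#' Columns: monoisotopic_mass, charge, intensity, residue, score.
#'
#' @param peaks A data frame as found in the `peaks` element of an
#'   [extract_peaks()] result (or the result itself).
#' @param path Output file.
#' @export
write_peaklist <- function(peaks, path) {
  if (inherits(peaks, "peak_list")) peaks <- peaks$peaks
  utils::write.table(peaks[, c("monoisotopic_mass", "charge", "intensity",
                               "residue", "score")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
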