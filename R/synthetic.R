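# Synthetic profile-mode spectra with known ground truth: peptide-like
# species rendered as Gaussian isotopic envelopes at a stated resolution
# power, an additive slowly varying baseline, Gaussian noise, and replicate
# sets with per-replicate intensity variation and integer-grid m/z jitter.
# Every pipeline stage is testable against the recorded truth tables.

#' Specify species for a synthetic spectrum
#'
#' @param mass Monoisotopic masses (Da).
#' @param charge Charges (>= 1).
#' @param abundance Relative intensities (amplitude of the most likely
#'   isotope peak).
#' @param residue Residue model for the envelope shape (default
#'   `"averagine"`).
#' @return A data frame with one row per species.
#' @export
species_spec <- function(mass, charge = 1L, abundance = 1,
                         residue = "averagine") {
  stopifnot(all(mass > 0), all(charge >= 1), all(abundance > 0))
  data.frame(mass = mass, charge = as.integer(charge),
             abundance = abundance, residue = residue,
             stringsAsFactors = FALSE)
}

# noiseless envelope of one species on the grid; returns the curve and apex
render_species <- function(grid, mass, charge, abundance, residue, rp,
                           prune_ratio = 1e-4) {
  tm <- get_reference_tid(residue,
                          mass_limit = if (mass > 19900) 170000 else 20000)
  tid <- tid_at_mass(tm$table, mass)
  ab <- tid$abundances
  keep <- which(ab >= max(ab) * prune_ratio)
  k <- keep - 1L
  pos <- (mass + k * tid$position_spacing + charge * PROTON_MASS) / charge
  if (min(pos) < min(grid) || max(pos) > max(grid))
    stop(sprintf("species at %.1f Da (charge %d) falls outside the grid",
                 mass, charge))
  apex_mz <- pos[which.max(ab[keep])]
  sigma <- apex_mz / (fwhm_sigma_ratio() * rp)
  amp <- abundance * ab[keep] / max(ab)
  curve <- numeric(length(grid))
  for (j in seq_along(pos)) {
    lo <- findInterval(pos[j] - 6 * sigma, grid) + 1L
    hi <- findInterval(pos[j] + 6 * sigma, grid)
    if (hi < lo) next
    seg <- lo:hi
    curve[seg] <- curve[seg] +
      amp[j] * exp(-((grid[seg] - pos[j])^2) / (2 * sigma^2))
  }
  list(curve = curve, apex_mz = apex_mz)
}

#' Simulate a profile-mode mass spectrum with known ground truth
#'
#' Each species' theoretical isotopic distribution is rendered as a Gaussian
#' comb at the stated resolution power (abundance = height of the most
#' likely isotope peak); an exponentially decaying baseline and i.i.d.
#' Gaussian noise are added.
#'
#' @param species Data frame from [species_spec()].
#' @param rp Resolution power of the simulated instrument.
#' @param grid Numeric vector of m/z values (the acquisition grid).
#' @param baseline `NULL`, or `list(amplitude =, decay =)` for
#'   `amplitude * exp(-(mz - min(mz)) / decay)`.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param seed Random seed (`NULL` leaves the RNG state alone).
#' @return List with `spectrum` (a `mass_spectrum`) and `truth` (the
#'   species table plus the rendered envelope apex m/z).
#' @export
simulate_spectrum <- function(species, rp, grid, baseline = NULL,
                              noise_sigma = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- sort(grid)
  signal <- numeric(length(grid))
  apex <- numeric(nrow(species))
  for (i in seq_len(nrow(species))) {
    r <- render_species(grid, species$mass[i], species$charge[i],
                        species$abundance[i], species$residue[i], rp)
    signal <- signal + r$curve
    apex[i] <- r$apex_mz
  }
  if (!is.null(baseline))
    signal <- signal + baseline$amplitude *
      exp(-(grid - grid[1L]) / baseline$decay)
  if (noise_sigma > 0)
    signal <- signal + stats::rnorm(length(grid), 0, noise_sigma)
  truth <- species
  truth$apex_mz <- apex
  list(spectrum = mass_spectrum(grid, signal), truth = truth)
}

#' Simulate a replicate set with intensity variation and m/z jitter
#'
#' Emulates the scan spectra (e.g. laser shots) accumulated into one
#' representative spectrum: per replicate, every species' abundance is
#' multiplied by an independent log-normal factor of the given coefficient
#' of variation (independent across species, which is what makes
#' cross-replicate overlap weights informative), and the whole replicate is
#' shifted by a rounded Gaussian number of grid steps.
#'
#' @inheritParams simulate_spectrum
#' @param n_replicates Number of replicates M.
#' @param jitter_sd Standard deviation of the per-replicate shift, in grid
#'   steps (rounded to integers).
#' @param intensity_cv Coefficient of variation of the per-species
#'   log-normal abundance factors (default 0.3).
#' @param noise_sigma Per-replicate additive Gaussian noise.
#' @return List with `replicates` (a `replicate_set`), `truth` (species
#'   table), `shifts` (applied integer shift per replicate) and
#'   `abundances` (species x replicate matrix of realised abundances).
#' @export
simulate_replicates <- function(species, rp, grid, n_replicates,
                                jitter_sd = 0, intensity_cv = 0.3,
                                noise_sigma = 0, baseline = NULL,
                                seed = NULL) {
  stopifnot(n_replicates >= 1L)
  if (!is.null(seed)) set.seed(seed)
  grid <- sort(grid)
  n <- length(grid)
  ns <- nrow(species)
  sdlog <- sqrt(log(1 + intensity_cv^2))
  # noiseless unit envelope per species, reused across replicates
  parts <- lapply(seq_len(ns), function(i)
    render_species(grid, species$mass[i], species$charge[i],
                   1, species$residue[i], rp))
  base <- if (is.null(baseline)) numeric(n) else
    baseline$amplitude * exp(-(grid - grid[1L]) / baseline$decay)
  abund <- matrix(0, ns, n_replicates)
  shifts <- integer(n_replicates)
  mat <- matrix(0, n, n_replicates)
  for (r in seq_len(n_replicates)) {
    f <- if (intensity_cv > 0)
      stats::rlnorm(ns, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    else rep(1, ns)
    abund[, r] <- species$abundance * f
    y <- base
    for (i in seq_len(ns))
      y <- y + abund[i, r] * parts[[i]]$curve
    s <- if (jitter_sd > 0) as.integer(round(stats::rnorm(1, 0, jitter_sd)))
         else 0L
    shifts[r] <- s
    if (s != 0L)
      y <- y[pmin(pmax(seq_len(n) - s, 1L), n)]
    if (noise_sigma > 0)
      y <- y + stats::rnorm(n, 0, noise_sigma)
    mat[, r] <- y
  }
  truth <- species
  truth$apex_mz <- vapply(parts, `[[`, numeric(1), "apex_mz")
  list(replicates = new_replicate_set(grid, mat), truth = truth,
       shifts = shifts, abundances = abund)
}

#' Score an extracted peak list against a simulation truth table
#'
#' A truth species is recovered when an extracted entry matches its
#' monoisotopic mass within the tolerance (and its charge, unless
#' `require_charge = FALSE`); the false discovery rate is the fraction of
#' extracted entries matching no truth species.
#'
#' @param peaks Peak data frame (or [extract_peaks()] result).
#' @param truth Truth table from the simulators.
#' @param mass_tol Absolute mass tolerance (Da); or
#' @param rel_tol relative tolerance (e.g. 0.01 for the +/-1\% window used
#'   with known mixtures).  Exactly one must be given.
#' @param require_charge Match charges too (default TRUE).
#' @return List with `recovered` (logical per truth row), `recovery`
#'   (fraction), `fdr`, and `mass_errors` (Da, NA where unrecovered).
#' @export
score_peaklist <- function(peaks, truth, mass_tol = NULL, rel_tol = NULL,
                           require_charge = TRUE) {
  if (inherits(peaks, "peak_list")) peaks <- peaks$peaks
  stopifnot(xor(is.null(mass_tol), is.null(rel_tol)))
  tol_of <- function(m) if (!is.null(mass_tol)) mass_tol else rel_tol * m
  recovered <- logical(nrow(truth))
  mass_errors <- rep(NA_real_, nrow(truth))
  matched_peak <- rep(FALSE, nrow(peaks))
  for (i in seq_len(nrow(truth))) {
    err <- abs(peaks$monoisotopic_mass - truth$mass[i])
    ok <- err <= tol_of(truth$mass[i])
    if (require_charge) ok <- ok & peaks$charge == truth$charge[i]
    if (any(ok)) {
      j <- which(ok)[which.min(err[ok])]
      recovered[i] <- TRUE
      mass_errors[i] <- peaks$monoisotopic_mass[j] - truth$mass[i]
      matched_peak[j] <- TRUE
    }
  }
  # FDR over all extracted peaks: any entry near some truth mass (charge
  # ignored) is not counted as false
  false_peak <- vapply(seq_len(nrow(peaks)), function(j)
    all(abs(peaks$monoisotopic_mass[j] - truth$mass) >
          tol_of(peaks$monoisotopic_mass[j])), logical(1))
  list(recovered = recovered, recovery = mean(recovered),
       fdr = if (nrow(peaks) == 0L) 0 else mean(false_peak),
       mass_errors = mass_errors)
}
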