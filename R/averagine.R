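# Reference residues and precomputed theoretical isotopic distributions
# (TIDs).  The ID of a detected biomolecule of unknown sequence is
# approximated by the ID of an artificial sequence of identical "reference"
# residues with the same monoisotopic mass.  Tables of TIDs for sequences of
# n = 1, 2, ... residues are computed once and interpolated at query time.

# water terminus added to every artificial sequence (peptide convention)
WATER_FORMULA <- c(H = 2, O = 1)

#' Built-in reference residues
#'
#' Three residue models are available for building theoretical isotopic
#' distributions:
#' \describe{
#'   \item{`averagine`}{Senko's Averagine, the classical average amino-acid
#'     residue (C4.9384 H7.7583 N1.3577 O1.4773 S0.0417, 111.054 Da).}
#'   \item{`leucine`}{Leucine (C6 H11 N O), the most frequent real residue,
#'     sharing its formula with isoleucine.}
#'   \item{`averagine_swissprot`}{An updated average residue recomputed from
#'     a recent SwissProt release (C4.949 H7.833 O1.473 N1.361 S0.038).}
#' }
#'
#' @param name One of `"averagine"`, `"leucine"`, `"averagine_swissprot"`,
#'   or a custom residue created with [custom_residue()].
#' @param table Isotope table used to evaluate the residue mass.
#' @return A `reference_residue` object: list with `name`, `formula`
#'   (named counts, possibly fractional) and `residue_mass` (monoisotopic, Da).
#' @export
#' @examples
#' reference_residue("leucine")$residue_mass # 113.084
reference_residue <- function(name = c("averagine", "leucine",
                                       "averagine_swissprot"),
                              table = default_isotope_table()) {
  if (inherits(name, "reference_residue")) return(name)
  name <- match.arg(name)
  formula <- switch(name,
    averagine = c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417),
    leucine = c(C = 6, H = 11, N = 1, O = 1),
    averagine_swissprot = c(C = 4.949, H = 7.833, O = 1.473, N = 1.361,
                            S = 0.038))
  custom_residue(name, formula, table)
}

#' Define a custom reference residue
#'
#' @param name Residue label used in peak lists.
#' @param formula Named element counts (fractional allowed).
#' @inheritParams reference_residue
#' @return A `reference_residue` object.
#' @export
custom_residue <- function(name, formula, table = default_isotope_table()) {
  formula <- validate_formula(formula)
  structure(list(name = name, formula = formula,
                 residue_mass = monoisotopic_mass(formula, table)),
            class = "reference_residue")
}

#' Precompute the TID table of a reference residue
#'
#' Computes and stores the isotopic distributions of all artificial
#' sequences of n residues, n = 1 .. N with N the smallest count whose
#' sequence mass reaches `mass_limit`.  Each sequence receives one water
#' terminus (switchable off) and its distribution is truncated to the first
#' `max_positions` isotope positions.
#'
#' @param residue A `reference_residue` or a name accepted by
#'   [reference_residue()].
#' @param mass_limit Upper mass bound to cover (Da); 20000 by default,
#'   extended automatically by the pipeline when a spectrum requires more.
#' @param table Isotope table.
#' @param max_positions Isotope positions stored per row (default 30).
#' @param water_terminus Add H2O to every artificial sequence (default TRUE).
#' @return A `tid_table` object: list with `residue`, `mass_limit`,
#'   `masses` (monoisotopic mass per row, strictly increasing) and
#'   `abundances` (N x `max_positions` matrix, rows padded with 0).
#' @export
build_tid_table <- function(residue, mass_limit = 20000,
                            table = default_isotope_table(),
                            max_positions = 30L, water_terminus = TRUE) {
  residue <- reference_residue(residue, table)
  if (mass_limit <= residue$residue_mass)
    stop("mass_limit must exceed the residue mass")
  n_max <- ceiling(mass_limit / residue$residue_mass)
  terminus <- if (water_terminus) WATER_FORMULA else c(H = 0)
  terminus_mass <- if (water_terminus)
    monoisotopic_mass(WATER_FORMULA, table) else 0

  # cache of repeated-squaring powers per element, shared across rows
  pow_cache <- new.env(parent = emptyenv())
  atom_dist <- function(el) {
    iso <- element_isotopes(el, table)
    shifts <- round(iso$masses - iso$masses[1L])
    atom <- numeric(max(shifts) + 1L)
    atom[shifts + 1L] <- iso$abundances
    atom
  }
  powers_of <- function(el, upto) {
    key <- el
    have <- if (exists(key, pow_cache)) get(key, pow_cache) else list(atom_dist(el))
    while (length(have) < upto) {
      nxt <- convolve_abundances(have[[length(have)]], have[[length(have)]])
      if (length(nxt) > max_positions) nxt <- nxt[seq_len(max_positions)]
      have[[length(have) + 1L]] <- nxt
    }
    assign(key, have, pow_cache)
    have
  }
  element_power <- function(el, n) {
    n <- as.integer(n)
    if (n == 0L) return(1.0)
    bits <- which(intToBits(n)[1:31] == as.raw(1))
    pw <- powers_of(el, max(bits))
    out <- 1.0
    for (b in bits) {
      out <- convolve_abundances(out, pw[[b]])
      if (length(out) > max_positions) out <- out[seq_len(max_positions)]
    }
    out
  }

  masses <- numeric(n_max)
  abundances <- matrix(0, nrow = n_max, ncol = max_positions)
  for (n in seq_len(n_max)) {
    frac <- residue$formula * n
    for (el in names(terminus))
      frac[el] <- (if (el %in% names(frac)) frac[[el]] else 0) + terminus[[el]]
    masses[n] <- n * residue$residue_mass + terminus_mass
    counts <- integerize_formula(frac, table)
    dist <- 1.0
    for (el in names(counts)) {
      dist <- convolve_abundances(dist, element_power(el, counts[[el]]))
      if (length(dist) > max_positions) dist <- dist[seq_len(max_positions)]
    }
    abundances[n, seq_along(dist)] <- dist
  }
  structure(list(residue = residue, mass_limit = mass_limit,
                 max_positions = as.integer(max_positions),
                 water_terminus = water_terminus,
                 masses = masses, abundances = abundances),
            class = "tid_table")
}

#' @export
print.tid_table <- function(x, ...) {
  cat("TID table:", x$residue$name, "-", nrow(x$abundances), "rows,",
      format(x$masses[1]), "to", format(x$masses[length(x$masses)]), "Da\n")
  invisible(x)
}

#' Theoretical isotopic distribution at an arbitrary monoisotopic mass
#'
#' Interpolates the stored table rows position-wise (linearly in mass)
#' between the two bracketing artificial-sequence rows.
#'
#' @param table A `tid_table` from [build_tid_table()].
#' @param m0 Monoisotopic mass (Da); must lie within the table's mass range.
#' @return An `isotopic_distribution` with `monoisotopic_mass = m0`.
#' @export
tid_at_mass <- function(table, m0) {
  masses <- table$masses
  if (m0 < masses[1L] || m0 > masses[length(masses)])
    stop(sprintf("mass %.3f Da outside TID table range [%.3f, %.3f]",
                 m0, masses[1L], masses[length(masses)]))
  i <- findInterval(m0, masses)
  if (i == length(masses)) {
    ab <- table$abundances[i, ]
  } else {
    w <- (m0 - masses[i]) / (masses[i + 1L] - masses[i])
    ab <- (1 - w) * table$abundances[i, ] + w * table$abundances[i + 1L, ]
  }
  isotopic_distribution(m0, ab)
}

#' Fit the most-likely-peak model of a TID table
#'
#' For every table row, records the index of the most abundant isotope
#' position (`k_star`) and the mass of that most-likely peak, and builds the
#' inverse mapping from a most-likely-peak mass back to the monoisotopic
#' mass as a piecewise-linear interpolation through the table pairs.  This
#' is the regression used when the spectrum resolves only the envelope apex
#' (low-resolution / high-mass regime).
#'
#' @param table A `tid_table`.
#' @return A `most_likely_model`: list with `k_star_at(m0)` (most-likely
#'   position index at a monoisotopic mass) and
#'   `predict_monoisotopic(ml_mass)` (monoisotopic mass from a most-likely
#'   peak mass), plus the underlying knots.
#' @export
fit_most_likely_model <- function(table) {
  k_star <- apply(table$abundances, 1L, which.max) - 1L
  spacing <- ISOTOPE_SPACING
  ml_mass <- table$masses + k_star * spacing
  mono <- table$masses
  structure(list(
    residue = table$residue$name,
    mono_masses = mono,
    k_star = k_star,
    ml_masses = ml_mass,
    k_star_at = function(m0) {
      i <- findInterval(m0, mono, all.inside = TRUE)
      k_star[i]
    },
    predict_monoisotopic = function(ml) {
      stats::approx(ml_mass, mono, xout = ml, rule = 2)$y
    }
  ), class = "most_likely_model")
}

#' @export
print.most_likely_model <- function(x, ...) {
  cat("Most-likely-peak model (", x$residue, "): k* ranges ",
      min(x$k_star), "..", max(x$k_star), " over ",
      format(min(x$mono_masses)), "-", format(max(x$mono_masses)),
      " Da\n", sep = "")
  invisible(x)
}

#' Write / read a TID table as plain text
#'
#' Tab-separated: a `#` header carrying the residue, mass limit and options,
#' then one row per artificial sequence (mass followed by abundances).
#'
#' @param table A `tid_table`.
#' @param path File path.
#' @return `write_tid_table` returns `path` invisibly; `read_tid_table`
#'   returns the `tid_table`.
#' @export
write_tid_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tid_table v1\t%s\t%.6f\t%d\t%d",
                     table$residue$name, table$mass_limit,
                     table$max_positions, as.integer(table$water_terminus)),
             con)
  writeLines(sprintf("# residue_formula\t%s",
                     paste(names(table$residue$formula),
                           table$residue$formula,
                           sep = "=", collapse = "\t")), con)
  utils::write.table(cbind(mass = table$masses, table$abundances), con,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_tid_table
#' @export
read_tid_table <- function(path) {
  hdr <- readLines(path, n = 2L)
  h1 <- strsplit(sub("^# tid_table v1\t", "", hdr[1L]), "\t")[[1L]]
  fparts <- strsplit(strsplit(sub("^# residue_formula\t", "", hdr[2L]),
                              "\t")[[1L]], "=")
  formula <- vapply(fparts, function(p) as.numeric(p[2L]), numeric(1))
  names(formula) <- vapply(fparts, `[`, character(1), 1L)
  dat <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  structure(list(residue = custom_residue(h1[1L], formula),
                 mass_limit = as.numeric(h1[2L]),
                 max_positions = as.integer(h1[3L]),
                 water_terminus = as.logical(as.integer(h1[4L])),
                 masses = dat[, 1L],
                 abundances = unname(dat[, -1L, drop = FALSE])),
            class = "tid_table")
}

# In-session cache: tables are expensive enough to build once per residue
# and mass limit.
.tid_cache <- new.env(parent = emptyenv())

#' Retrieve (building and caching if needed) a TID table and its model
#'
#' @inheritParams build_tid_table
#' @param cache_dir Optional directory for on-disk caching of built tables.
#' @return List with elements `table` (`tid_table`) and `model`
#'   (`most_likely_model`).
#' @export
get_reference_tid <- function(residue, mass_limit = 20000,
                              table = default_isotope_table(),
                              cache_dir = NULL) {
  residue <- reference_residue(residue, table)
  key <- sprintf("%s_%d", residue$name, as.integer(mass_limit))
  if (exists(key, .tid_cache))
    return(get(key, .tid_cache))
  tid <- NULL
  cache_file <- if (!is.null(cache_dir))
    file.path(cache_dir, paste0("tid_", key, ".tsv")) else NULL
  if (!is.null(cache_file) && file.exists(cache_file))
    tid <- read_tid_table(cache_file)
  if (is.null(tid)) {
    tid <- build_tid_table(residue, mass_limit, table)
    if (!is.null(cache_file)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      write_tid_table(tid, cache_file)
    }
  }
  out <- list(table = tid, model = fit_most_likely_model(tid))
  assign(key, out, .tid_cache)
  out
}
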