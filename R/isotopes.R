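# Isotopic-distribution engine: elemental isotope tables, molecular formulas
# and the iterative matrix-convolution algorithm that builds the isotopic
# distribution (ID) of a molecule atom by atom.

#' Ratio between FWHM and standard deviation of a Gaussian
#'
#' Peak widths are specified throughout as resolution power RP = m / FWHM,
#' while peaks are rendered as Gaussians; the conversion is
#' FWHM = 2 * sqrt(2 * log(2)) * sigma.
#'
#' @return The constant 2 * sqrt(2 * log(2)), approximately 2.35482.
#' @export
fwhm_sigma_ratio <- function() 2 * sqrt(2 * log(2))

# Average spacing between successive isotope positions (Da), dominated by
# the 13C-12C mass difference in peptides.
ISOTOPE_SPACING <- 1.00235

# Mass of a proton (Da); positive ions are treated as proton adducts,
# observed m/z = (M0 + Z * PROTON_MASS) / Z.
PROTON_MASS <- 1.00728

#' Built-in elemental isotope abundance table
#'
#' IUPAC-style isotope masses (Da) and natural abundances for C, H, N, O
#' and S, the elements of the peptide residue models.  A user table in the
#' same shape (see [read_isotope_table()]) may be supplied anywhere a table
#' is accepted.
#'
#' @return A data frame with columns `element`, `mass`, `abundance`, one row
#'   per isotope, isotopes of each element ordered by increasing mass.
#' @export
#' @examples
#' default_isotope_table()
default_isotope_table <- function() {
  tab <- data.frame(
    element = c("H", "H",
                "C", "C",
                "N", "N",
                "O", "O", "O",
                "S", "S", "S", "S"),
    mass = c(1.0078250319, 2.0141017779,
             12.0, 13.0033548378,
             14.0030740052, 15.0001088984,
             15.9949146221, 16.9991315, 17.9991604,
             31.97207069, 32.9714585, 33.96786683, 35.96708088),
    abundance = c(0.999885, 0.000115,
                  0.9893, 0.0107,
                  0.99636, 0.00364,
                  0.99757, 0.00038, 0.00205,
                  0.9499, 0.0075, 0.0425, 0.0001),
    stringsAsFactors = FALSE
  )
  validate_isotope_table(tab)
  tab
}

#' Read an elemental isotope table from a text file
#'
#' One line per isotope: element symbol, isotope mass (Da), abundance
#' (fraction), whitespace separated.  Lines starting with `#` are ignored.
#'
#' @param path Path to the table file.
#' @return A data frame as returned by [default_isotope_table()].
#' @export
read_isotope_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("element", "mass", "abundance"),
                           stringsAsFactors = FALSE)
  tab <- tab[order(tab$element, tab$mass), ]
  rownames(tab) <- NULL
  validate_isotope_table(tab)
  tab
}

validate_isotope_table <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("element", "mass", "abundance") %in% names(tab)))
  for (el in unique(tab$element)) {
    rows <- tab[tab$element == el, ]
    if (any(rows$abundance < 0) || any(rows$abundance > 1))
      stop("isotope abundances of ", el, " must lie in [0, 1]")
    if (abs(sum(rows$abundance) - 1) > 1e-9)
      stop("isotope abundances of ", el, " must sum to 1")
    if (any(diff(rows$mass) <= 0))
      stop("isotope masses of ", el, " must be strictly increasing")
  }
  invisible(tab)
}

# Per-element view used internally: list(masses =, abundances =).
element_isotopes <- function(element, table) {
  rows <- table[table$element == element, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("unknown element: ", element)
  list(masses = rows$mass, abundances = rows$abundance)
}

#' Convolve two isotope abundance vectors
#'
#' One step of the iterative algorithm that builds the isotopic distribution
#' of a molecule atom by atom: the matrix of the joint distribution of the
#' current molecule (`a`) and the next atom (`b`) is formed, and
#' configurations with the same total mass shift (the anti-diagonals) are
#' summed.
#'
#' @param a,b Numeric vectors of abundances at successive isotope positions
#'   (position 0 first); non-empty, non-negative.
#' @return Numeric vector of length `length(a) + length(b) - 1` with
#'   `result[k] = sum(a[i] * b[j])` over `i + j = k` (0-based positions).
#' @export
#' @examples
#' convolve_abundances(c(0.99, 0.01), c(0.99, 0.01)) # 0.9801 0.0198 0.0001
convolve_abundances <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("abundance vectors must be non-empty")
  if (any(a < 0) || any(b < 0))
    stop("abundance vectors must be non-negative")
  out <- numeric(length(a) + length(b) - 1L)
  # accumulate anti-diagonals of the joint matrix, vectorised over `a`
  for (j in seq_along(b)) {
    idx <- j:(j + length(a) - 1L)
    out[idx] <- out[idx] + a * b[j]
  }
  out
}

# Distribution of n identical atoms, by binary exponentiation of the
# single-atom distribution; truncation to max_positions is exact for the
# retained positions (higher positions only ever feed positions beyond the cut).
element_power_distribution <- function(abundances, n, max_positions = 30L) {
  stopifnot(n >= 0)
  result <- 1.0
  base <- abundances
  n <- as.integer(n)
  while (n > 0L) {
    if (n %% 2L == 1L) {
      result <- convolve_abundances(result, base)
      if (length(result) > max_positions) result <- result[seq_len(max_positions)]
    }
    n <- n %/% 2L
    if (n > 0L) {
      base <- convolve_abundances(base, base)
      if (length(base) > max_positions) base <- base[seq_len(max_positions)]
    }
  }
  result
}

#' Monoisotopic mass of a molecular formula
#'
#' Linear in the (possibly fractional) element counts: the sum over elements
#' of count times the mass of the lightest isotope.  Fractional counts arise
#' from average-residue (Averagine-type) compositions and are used as-is.
#'
#' @param formula Named numeric vector of element counts,
#'   e.g. `c(C = 6, H = 11, N = 1, O = 1)`.
#' @param table Isotope table (see [default_isotope_table()]).
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass(c(C = 6, H = 11, N = 1, O = 1)) # leucine residue, 113.084
monoisotopic_mass <- function(formula, table = default_isotope_table()) {
  formula <- validate_formula(formula)
  sum(vapply(names(formula), function(el) {
    formula[[el]] * element_isotopes(el, table)$masses[1L]
  }, numeric(1)))
}

validate_formula <- function(formula) {
  if (is.null(names(formula)) || any(names(formula) == ""))
    stop("formula must be a named numeric vector of element counts")
  formula <- formula[formula != 0]
  if (any(formula < 0))
    stop("element counts must be non-negative")
  if (length(formula) == 0L)
    stop("formula must contain at least one atom")
  formula
}

# Resolve fractional element counts to integers: round every count to the
# nearest integer, then adjust the hydrogen count so that the integerised
# monoisotopic mass matches the fractional-formula mass within half a
# hydrogen mass (the standard fractional-Averagine convention).
integerize_formula <- function(formula, table = default_isotope_table()) {
  formula <- validate_formula(formula)
  if (all(formula == round(formula)))
    return(formula)
  target <- monoisotopic_mass(formula, table)
  rounded <- round(formula)
  h_mass <- element_isotopes("H", table)$masses[1L]
  got <- sum(vapply(names(rounded), function(el) {
    rounded[[el]] * element_isotopes(el, table)$masses[1L]
  }, numeric(1)))
  dh <- round((target - got) / h_mass)
  rounded[["H"]] <- max(0, (if ("H" %in% names(rounded)) rounded[["H"]] else 0) + dh)
  rounded[rounded > 0]
}

#' Isotopic distribution of a molecular formula
#'
#' Builds the molecule atom by atom with the matrix-convolution step of
#' [convolve_abundances()], grouping isotopologues by nominal mass shift
#' (integer neutron count).  Fractional counts (Averagine-type residues) are
#' first resolved to an integer formula whose monoisotopic mass matches the
#' fractional one within half a hydrogen mass; the reported monoisotopic
#' mass is that of the fractional formula itself.
#'
#' @inheritParams monoisotopic_mass
#' @param max_positions Maximum number of isotope positions retained
#'   (default 30).
#' @return An object of class `isotopic_distribution`: a list with
#'   `monoisotopic_mass` (Da), `abundances` (relative abundance per isotope
#'   position, position 0 first) and `position_spacing` (Da per position).
#' @export
#' @examples
#' formula_distribution(c(H = 2, O = 1)) # water
formula_distribution <- function(formula, table = default_isotope_table(),
                                 max_positions = 30L) {
  formula <- validate_formula(formula)
  mono <- monoisotopic_mass(formula, table)
  counts <- integerize_formula(formula, table)
  dist <- 1.0
  for (el in names(counts)) {
    iso <- element_isotopes(el, table)
    # abundance per nominal mass shift of one atom
    shifts <- round(iso$masses - iso$masses[1L])
    atom <- numeric(max(shifts) + 1L)
    atom[shifts + 1L] <- iso$abundances
    dist <- convolve_abundances(dist,
                                element_power_distribution(atom, counts[[el]],
                                                           max_positions))
    if (length(dist) > max_positions) dist <- dist[seq_len(max_positions)]
  }
  isotopic_distribution(mono, dist)
}

isotopic_distribution <- function(monoisotopic_mass, abundances,
                                  position_spacing = ISOTOPE_SPACING) {
  stopifnot(length(abundances) >= 1L, all(abundances >= -1e-15))
  structure(list(monoisotopic_mass = monoisotopic_mass,
                 abundances = pmax(abundances, 0),
                 position_spacing = position_spacing),
            class = "isotopic_distribution")
}

#' @export
print.isotopic_distribution <- function(x, ...) {
  cat("Isotopic distribution: monoisotopic mass", format(x$monoisotopic_mass),
      "Da,", length(x$abundances), "positions\n")
  cat("  most likely position:", which.max(x$abundances) - 1L,
      " total abundance:", format(sum(x$abundances)), "\n")
  invisible(x)
}
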