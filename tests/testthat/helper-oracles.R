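# Independent oracles and fixture builders shared across the test files.

# all length-k vectors of non-negative integers summing to n
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1L))
  out <- NULL
  for (i in 0:n)
    out <- rbind(out, cbind(i, compositions(n - i, k - 1L)))
  unname(out)
}

# Exhaustive isotopologue enumeration: every assignment of isotopes to atoms
# (grouped into per-element multinomial compositions), probability from the
# closed-form multinomial, aggregated by total nominal mass shift.  Fully
# independent of the package's iterative convolution.
enum_distribution <- function(counts, table = default_isotope_table()) {
  per_el <- lapply(names(counts), function(el) {
    rows <- table[table$element == el, ]
    shifts <- round(rows$mass - rows$mass[1L])
    comp <- compositions(counts[[el]], nrow(rows))
    prob <- apply(comp, 1L, function(m) dmultinom(m, prob = rows$abundance))
    shift <- as.vector(comp %*% shifts)
    list(prob = prob, shift = shift)
  })
  idx <- expand.grid(lapply(per_el, function(x) seq_along(x$prob)))
  prob <- rep(1, nrow(idx))
  shift <- rep(0, nrow(idx))
  for (j in seq_along(per_el)) {
    prob <- prob * per_el[[j]]$prob[idx[[j]]]
    shift <- shift + per_el[[j]]$shift[idx[[j]]]
  }
  out <- numeric(max(shift) + 1L)
  agg <- tapply(prob, shift, sum)
  out[as.integer(names(agg)) + 1L] <- agg
  out
}

# minimal mzXML writer (32-bit network-order m/z-intensity pairs), enough
# for round-trip tests of the mzXML reading path
write_test_mzxml <- function(spectrum, path) {
  pairs <- as.numeric(rbind(spectrum$mz, spectrum$intensity))
  raw <- writeBin(pairs, raw(), size = 4L, endian = "big")
  b64 <- gsub("\n", "", jsonlite::base64_enc(raw))
  xml <- sprintf(paste0(
    '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/',
    'mzXML_3.2">\n <msRun scanCount="1">\n',
    '  <scan num="1" msLevel="1" peaksCount="%d" retentionTime="PT1S">\n',
    '   <peaks compressionType="none" compressedLen="0" precision="32"',
    ' byteOrder="network" contentType="m/z-int">%s</peaks>\n',
    '  </scan>\n </msRun>\n</mzXML>'),
    length(spectrum$mz), b64)
  writeLines(xml, path)
  path
}

# standard small fixture: one species on a clean grid
fixture_single_species <- function(mass = 2000, charge = 1L, rp = 10000,
                                   step = 0.02, pad = c(50, 100),
                                   noise = 0, seed = NULL) {
  mz_lo <- (mass + charge * 1.00728) / charge - pad[1L]
  mz_hi <- (mass + charge * 1.00728) / charge + pad[2L]
  simulate_spectrum(species_spec(mass, charge), rp = rp,
                    grid = seq(mz_lo, mz_hi, by = step),
                    noise_sigma = noise, seed = seed)
}
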