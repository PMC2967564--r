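test_that("convolution reproduces the two-atom worked example", {
  out <- convolve_abundances(c(0.99, 0.01), c(0.99, 0.01))
  expect_equal(out, c(0.9801, 0.0198, 0.0001), tolerance = 1e-12)
})

test_that("convolution against a brute-force double loop", {
  set.seed(11)
  for (rep in 1:5) {
    a <- runif(sample(1:6, 1))
    b <- runif(sample(1:6, 1))
    brute <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a))
      for (j in seq_along(b))
        brute[i + j - 1L] <- brute[i + j - 1L] + a[i] * b[j]
    expect_equal(convolve_abundances(a, b), brute, tolerance = 1e-14)
  }
})

test_that("convolution properties: identity, commutativity, mass conservation", {
  a <- c(0.7, 0.2, 0.1)
  b <- c(0.5, 0.5)
  expect_equal(convolve_abundances(a, 1), a)
  expect_equal(convolve_abundances(a, b), convolve_abundances(b, a))
  expect_equal(sum(convolve_abundances(a, b)), sum(a) * sum(b))
  expect_error(convolve_abundances(numeric(0), a), "non-empty")
  expect_error(convolve_abundances(a, c(0.5, -0.1)), "non-negative")
})

test_that("element powers match repeated convolution", {
  atom <- c(0.9893, 0.0107)
  direct <- 1.0
  for (i in 1:13) direct <- convolve_abundances(direct, atom)
  expect_equal(element_power_distribution(atom, 13), direct,
               tolerance = 1e-14)
  expect_equal(element_power_distribution(atom, 0), 1.0)
})

test_that("truncation is exact for the retained positions", {
  atom <- c(0.95, 0.04, 0.01)
  full <- element_power_distribution(atom, 40, max_positions = 100L)
  cut <- element_power_distribution(atom, 40, max_positions = 10L)
  expect_equal(cut, full[1:10], tolerance = 1e-14)
})

test_that("monoisotopic masses of the reference formulas", {
  expect_equal(monoisotopic_mass(c(C = 6, H = 11, N = 1, O = 1)),
               113.084, tolerance = 5e-4)
  expect_equal(monoisotopic_mass(c(C = 4.9384, H = 7.7583, N = 1.3577,
                                   O = 1.4773, S = 0.0417)),
               111.054, tolerance = 5e-4)
  # linearity in the counts
  f <- c(C = 2, H = 6, O = 1)
  expect_equal(monoisotopic_mass(f * 3), 3 * monoisotopic_mass(f))
})

test_that("formula validation catches malformed input", {
  expect_error(monoisotopic_mass(c(1, 2)), "named")
  expect_error(monoisotopic_mass(c(C = -1)), "non-negative")
  expect_error(monoisotopic_mass(c(C = 0)), "at least one atom")
  expect_error(monoisotopic_mass(c(Xx = 1)), "unknown element")
})

test_that("integerization preserves the fractional monoisotopic mass", {
  tab <- default_isotope_table()
  ave <- reference_residue("averagine")$formula
  for (n in c(1, 7, 40)) {
    frac <- ave * n + c(C = 0, H = 2, N = 0, O = 1, S = 0)
    ints <- integerize_formula(frac, tab)
    expect_true(all(ints == round(ints)))
    h_mass <- 1.0078250319
    expect_lt(abs(monoisotopic_mass(ints, tab) -
                    monoisotopic_mass(frac, tab)), h_mass / 2 + 1e-9)
  }
  # already integral formulas pass through unchanged
  expect_identical(integerize_formula(c(C = 6, H = 11, N = 1, O = 1)),
                   c(C = 6, H = 11, N = 1, O = 1))
})

test_that("formula_distribution matches the enumeration oracle on water", {
  got <- formula_distribution(c(H = 2, O = 1))
  want <- enum_distribution(c(H = 2, O = 1))
  expect_equal(got$abundances[seq_along(want)], want, tolerance = 1e-12)
  expect_equal(got$monoisotopic_mass, 18.0105646859, tolerance = 1e-6)
})

test_that("formula_distribution matches the oracle on larger molecules", {
  cases <- list(c(C = 6, H = 12, O = 6),              # glucose
                c(C = 6, H = 11, N = 1, O = 1),       # leucine residue
                c(C = 10, H = 16, N = 5, O = 13, S = 2),
                c(S = 4))
  for (f in cases) {
    got <- formula_distribution(f)$abundances
    want <- enum_distribution(f)
    k <- min(length(got), length(want))
    expect_equal(got[1:k], want[1:k], tolerance = 1e-12)
  }
})

test_that("single-element distributions follow the closed binomial form", {
  tab <- default_isotope_table()
  p13 <- tab$abundance[tab$element == "C" & tab$mass > 13]
  got <- formula_distribution(c(C = 25))$abundances
  want <- dbinom(0:25, 25, p13)
  expect_equal(got[1:26], want, tolerance = 1e-12)
})

test_that("distribution abundances are a probability vector", {
  d <- formula_distribution(c(C = 50, H = 80, N = 10, O = 15, S = 1))
  expect_true(all(d$abundances >= 0))
  expect_lte(sum(d$abundances), 1 + 1e-12)
  expect_gt(sum(d$abundances), 0.999)    # 30 positions cover the mass range
})

test_that("FWHM/sigma conversion constant", {
  expect_equal(fwhm_sigma_ratio(), 2 * sqrt(2 * log(2)))
  # a rendered Gaussian with sigma from the constant has the right FWHM
  sigma <- 1 / fwhm_sigma_ratio()
  half <- exp(-((0.5)^2) / (2 * sigma^2))
  expect_equal(half, 0.5, tolerance = 1e-12)
})

test_that("user isotope tables round-trip and are validated", {
  tab <- default_isotope_table()
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(c("# element mass abundance",
               sprintf("%s %.10f %.10f", tab$element, tab$mass,
                       tab$abundance)), tf)
  back <- read_isotope_table(tf)         # reader sorts by element symbol
  o <- order(tab$element, tab$mass)
  expect_equal(back$mass, tab$mass[o], tolerance = 1e-9)
  expect_equal(back$abundance, tab$abundance[o], tolerance = 1e-9)

  bad <- tab
  bad$abundance[2] <- bad$abundance[2] + 0.1   # sums break, range does not
  expect_error(validate_isotope_table(bad), "sum to 1")
  bad2 <- tab
  bad2$abundance[1] <- 1.2
  expect_error(validate_isotope_table(bad2), "lie in")
})
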