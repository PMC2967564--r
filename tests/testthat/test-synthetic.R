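test_that("simulation is deterministic under a seed", {
  sp <- species_spec(c(1200, 1500), abundance = c(1, 0.5))
  g <- seq(1150, 1600, by = 0.05)
  a <- simulate_spectrum(sp, 5000, g, noise_sigma = 0.01, seed = 99)
  b <- simulate_spectrum(sp, 5000, g, noise_sigma = 0.01, seed = 99)
  c <- simulate_spectrum(sp, 5000, g, noise_sigma = 0.01, seed = 100)
  expect_identical(a$spectrum$intensity, b$spectrum$intensity)
  expect_false(identical(a$spectrum$intensity, c$spectrum$intensity))
})

test_that("the envelope apex sits at the recorded truth position", {
  sim <- simulate_spectrum(species_spec(1300), 8000,
                           seq(1250, 1350, by = 0.01))
  s <- sim$spectrum
  expect_equal(s$mz[which.max(s$intensity)], sim$truth$apex_mz,
               tolerance = 0.01)
  # charge 1, light peptide: the apex is the protonated monoisotopic peak
  expect_equal(sim$truth$apex_mz, 1300 + 1.00728, tolerance = 1e-6)
  # abundance is the apex height (up to the grid sampling of the apex)
  expect_equal(max(s$intensity), 1, tolerance = 1e-2)
})

test_that("abundance scales the envelope linearly", {
  g <- seq(1250, 1350, by = 0.01)
  a <- simulate_spectrum(species_spec(1300, abundance = 1), 8000, g)
  b <- simulate_spectrum(species_spec(1300, abundance = 2.5), 8000, g)
  expect_equal(b$spectrum$intensity, 2.5 * a$spectrum$intensity,
               tolerance = 1e-12)
})

test_that("charge compresses the envelope onto m/z = (M0 + Z mp) / Z", {
  g <- seq(600, 700, by = 0.005)
  sim <- simulate_spectrum(species_spec(1300, charge = 2L), 8000, g)
  expect_equal(sim$truth$apex_mz, (1300 + 2 * 1.00728) / 2,
               tolerance = 1e-6)
  s <- sim$spectrum
  pk <- find_peaks(s, rp = 8000)
  pk <- pk[pk$intensity > 0.05, ]
  expect_equal(median(diff(pk$mz)), 1.00235 / 2, tolerance = 0.01)
})

test_that("baseline and noise are added as specified", {
  g <- seq(1000, 1200, by = 0.1)
  sim <- simulate_spectrum(species_spec(1100), 3000, g,
                           baseline = list(amplitude = 4, decay = 100))
  # at the left edge the baseline is its full amplitude
  expect_equal(sim$spectrum$intensity[1L], 4, tolerance = 1e-6)
  expect_equal(sim$spectrum$intensity[length(g)],
               4 * exp(-200 / 100), tolerance = 0.01)
  set.seed(1)
  noisy <- simulate_spectrum(species_spec(1100), 3000, g,
                             noise_sigma = 0.3, seed = 17)
  tail_pts <- g > 1150
  expect_equal(sd(noisy$spectrum$intensity[tail_pts]), 0.3, tolerance = 0.05)
})

test_that("species outside the grid are rejected", {
  expect_error(simulate_spectrum(species_spec(5000), 5000,
                                 seq(1000, 1100, by = 0.05)),
               "outside the grid")
})

test_that("replicates: no jitter and no variation means identical copies", {
  sp <- species_spec(1300)
  sim <- simulate_replicates(sp, 8000, seq(1250, 1350, by = 0.02),
                             n_replicates = 4, jitter_sd = 0,
                             intensity_cv = 0, seed = 1)
  expect_identical(sim$shifts, rep(0L, 4))
  expect_true(all(sim$abundances == 1))
  for (j in 2:4)
    expect_equal(sim$replicates$matrix[, j], sim$replicates$matrix[, 1L])
})

test_that("log-normal abundance factors have unit mean", {
  sp <- species_spec(1300)
  sim <- simulate_replicates(sp, 8000, seq(1250, 1350, by = 0.05),
                             n_replicates = 400, intensity_cv = 0.3,
                             seed = 2)
  expect_equal(mean(sim$abundances), 1, tolerance = 0.05)
  expect_equal(sd(sim$abundances) / mean(sim$abundances), 0.3,
               tolerance = 0.05)
})

test_that("applied jitter moves the apex by the recorded grid steps", {
  sp <- species_spec(1300)
  g <- seq(1250, 1350, by = 0.02)
  sim <- simulate_replicates(sp, 8000, g, n_replicates = 6,
                             jitter_sd = 2, intensity_cv = 0,
                             seed = 31)
  ref_apex <- which.max(sim$replicates$matrix[, which(sim$shifts == 0L)[1L]])
  for (j in seq_along(sim$shifts)) {
    apex_j <- which.max(sim$replicates$matrix[, j])
    expect_equal(apex_j - ref_apex, sim$shifts[j])
  }
})

test_that("score_peaklist counts recovery, charge and false discoveries", {
  truth <- species_spec(c(1000, 2000), charge = c(1L, 2L))
  peaks <- data.frame(monoisotopic_mass = c(1000.05, 2000.4, 5000),
                      charge = c(1L, 1L, 1L), intensity = 1,
                      residue = "averagine", score = 0.1)
  sc <- score_peaklist(peaks, truth, mass_tol = 0.5)
  expect_equal(sc$recovered, c(TRUE, FALSE))   # wrong charge at 2000
  expect_equal(sc$recovery, 0.5)
  expect_equal(sc$fdr, 1 / 3)                  # only 5000 matches nothing
  expect_equal(sc$mass_errors, c(0.05, NA))
  sc2 <- score_peaklist(peaks, truth, mass_tol = 0.5,
                        require_charge = FALSE)
  expect_equal(sc2$recovery, 1)
  # relative tolerance variant
  sc3 <- score_peaklist(peaks, truth, rel_tol = 0.01)
  expect_true(sc3$recovered[1L])
  expect_error(score_peaklist(peaks, truth), "is not TRUE")
})
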