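test_that("reference model switches exactly at FWHM = isotope spacing", {
  # resolved: peak width below the 1/z spacing
  expect_equal(choose_reference_model(1000, 1, rp = 1500), "monoisotopic")
  expect_equal(choose_reference_model(1000, 1, rp = 999), "most_likely")
  expect_equal(choose_reference_model(1000, 1, rp = 1000), "most_likely")
  # higher charge halves the spacing: needs twice the RP
  expect_equal(choose_reference_model(1000, 2, rp = 1500), "most_likely")
  expect_equal(choose_reference_model(1000, 2, rp = 2500), "monoisotopic")
})

test_that("rendered TID has the documented width, spacing and anchoring", {
  tid <- isotopic_distribution(2000, c(1, 0.8, 0.4, 0.1))
  grid <- seq(1990, 2010, by = 0.002)
  r <- render_tid(tid, z = 1L, ref_mz = 2001, ref_intensity = 50,
                  rp = 10000, grid = grid)
  expect_equal(r$sigma, 2001 / (2 * sqrt(2 * log(2)) * 10000),
               tolerance = 1e-12)
  expect_equal(diff(r$positions), rep(tid$position_spacing, 3),
               tolerance = 1e-12)
  expect_equal(r$positions[1L], 2001)
  # curve at the anchor equals the reference intensity
  at_ref <- approx(grid, r$curve, xout = 2001)$y
  expect_equal(at_ref, 50, tolerance = 1e-3)
  # charge 2 halves the peak spacing
  r2 <- render_tid(tid, z = 2L, ref_mz = 2001, ref_intensity = 50,
                   rp = 10000, grid = grid)
  expect_equal(diff(r2$positions), rep(tid$position_spacing / 2, 3),
               tolerance = 1e-12)
})

test_that("TID pruning and anchoring edge cases", {
  tid <- isotopic_distribution(2000, c(1, 0.5, 1e-5))
  grid <- seq(1995, 2010, by = 0.01)
  r <- render_tid(tid, 1L, 2000, 10, 5000, grid, prune_ratio = 1e-3)
  expect_equal(r$kept, c(0L, 1L))        # third position pruned
  # anchoring on a pruned position is impossible
  expect_null(render_tid(tid, 1L, 2002, 10, 5000, grid,
                         ref_position = 2L, prune_ratio = 1e-3))
  # anchoring on a non-monoisotopic kept position works
  r1 <- render_tid(tid, 1L, 2001.00235, 10, 5000, grid, ref_position = 1L)
  expect_equal(r1$positions[1L], 2000, tolerance = 1e-9)
})

test_that("baseline offset shifts the rendered curve, not its shape", {
  tid <- isotopic_distribution(1500, c(1, 0.6))
  grid <- seq(1495, 1505, by = 0.005)
  r0 <- render_tid(tid, 1L, 1500, 20, 8000, grid)
  r5 <- render_tid(tid, 1L, 1500, 20, 8000, grid, baseline_offset = 5)
  # same anchor intensity, smaller amplitude above the offset
  expect_equal(max(r0$curve), 20, tolerance = 1e-6)
  expect_equal(max(r5$curve), 20, tolerance = 1e-6)
  expect_equal(r5$scale / r0$scale, 15 / 20, tolerance = 1e-9)
})

test_that("fit score is zero for perfect fits and scales as documented", {
  expect_equal(fit_score(c(1, 2, 3), c(1, 2, 3), rep(1, 3),
                         ref_intensity = 3), 0)
  # hand-computed: mean |diff| = 1, normalised by ref intensity 2 -> 0.5
  expect_equal(fit_score(c(2, 4), c(3, 3), c(1, 1), ref_intensity = 2), 0.5)
  # weights re-weight the mean
  expect_equal(fit_score(c(2, 4), c(3, 3), c(3, 1), ref_intensity = 2), 0.5)
  expect_equal(fit_score(c(2, 3), c(3, 3), c(1, 0), ref_intensity = 1), 1)
  # ESI prior penalises low charge multiplicatively
  s1 <- fit_score(c(2), c(3), 1, 1, z = 1L, z_max = 3L, esi_mode = TRUE,
                  lambda = 0.06)
  expect_equal(s1, 1 * (1 + 0.06 * 2 / 3), tolerance = 1e-12)
  expect_warning(s0 <- fit_score(c(1), c(5), 0, 1), "zero")
  expect_equal(s0, 0)
})

test_that("a clean single species is extracted with the right mass", {
  sim <- fixture_single_species(mass = 1500, rp = 10000, noise = 0)
  fit <- extract_peaks(sim$spectrum, rp_in = 10000, rp_grid = 1,
                       residues = "averagine")
  expect_equal(nrow(fit$peaks), 1L)
  expect_equal(fit$peaks$charge, 1L)
  expect_lt(abs(fit$peaks$monoisotopic_mass - 1500), 0.01)
  expect_lt(fit$peaks$score, 0.05)
  # intensity reports the whole envelope, not just the apex
  expect_gt(fit$peaks$intensity, 1)
})

test_that("charge states are told apart by the envelope spacing", {
  sp <- species_spec(c(2399.2, 2400.8), charge = c(1L, 2L))
  sim <- simulate_spectrum(sp, rp = 10000,
                           grid = seq(1150, 2500, by = 0.02),
                           noise_sigma = 0.002, seed = 12)
  fit <- extract_peaks(sim$spectrum, rp_in = 10000, rp_grid = 1, z_max = 2L,
                       residues = "averagine")
  sc <- score_peaklist(fit, sim$truth, mass_tol = 0.25)
  expect_true(all(sc$recovered))
})

test_that("the double model recovers high-mass monoisotopic masses", {
  # at RP 500 a 20 kDa envelope shows only its apex; the inverse
  # regression still reports the monoisotopic mass
  sim <- simulate_spectrum(species_spec(20000), rp = 500,
                           grid = seq(19800, 20250, by = 0.5))
  # envelope FWHM is 40 Da here: the baseline window must be wider
  fit <- extract_peaks(sim$spectrum, rp_in = 500, rp_grid = 1,
                       residues = "averagine", baseline_window = 0.3)
  expect_gte(nrow(fit$peaks), 1L)
  best <- which.min(abs(fit$peaks$monoisotopic_mass - 20000))
  expect_lt(abs(fit$peaks$monoisotopic_mass[best] - 20000), 1.5)
})

test_that("noise-only input keeps false fits to a small candidate fraction", {
  # pure noise still produces occasional chance fits (the method trades
  # some precision for recall); the threshold must keep them scarce
  set.seed(13)
  g <- seq(1000, 1400, by = 0.05)
  s <- mass_spectrum(g, abs(rnorm(length(g), 1, 0.2)))
  fit <- suppressWarnings(
    extract_peaks(s, rp_in = 5000, rp_grid = 1, residues = "averagine"))
  expect_lt(fit$counts[["extracted"]] / fit$counts[["candidates"]], 0.1)
  expect_gt(fit$counts[["below_threshold"]] / fit$counts[["candidates"]],
            0.9)
})

test_that("extraction bookkeeping: scores below threshold, counts add up", {
  sim <- simulate_spectrum(species_spec(c(1300, 1700)), rp = 8000,
                           grid = seq(1250, 1800, by = 0.02),
                           noise_sigma = 0.01, seed = 14)
  fit <- extract_peaks(sim$spectrum, rp_in = 8000, rp_grid = 1,
                       residues = "averagine")
  expect_true(all(fit$peaks$score < fit$params$score_threshold))
  expect_true(all(fit$residual >= 0))
  cnt <- fit$counts
  expect_equal(unname(cnt["below_threshold"] + cnt["rejected"] +
                        cnt["absorbed"] + cnt["extracted"]),
               unname(cnt["candidates"]))
  # the fitted envelopes were subtracted from the residual
  expect_lt(max(fit$residual), 0.5 * max(fit$representative))
})

test_that("S3 methods of the fitted object work", {
  sim <- fixture_single_species(mass = 1200, rp = 5000, step = 0.05)
  fit <- extract_peaks(sim$spectrum, rp_in = 5000, rp_grid = 1,
                       residues = "averagine")
  expect_s3_class(fit, "peak_list")
  expect_output(print(fit), "isotopic distributions extracted")
  expect_output(summary(fit), "estimated RP")
  expect_identical(as.data.frame(fit), fit$peaks)
  tf <- tempfile(fileext = ".png")
  on.exit(unlink(tf))
  grDevices::png(tf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tf))
})
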