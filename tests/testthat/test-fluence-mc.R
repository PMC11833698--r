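mc_small <- function(seed, n = 1e4) mc_config(n_photons = n, seed = seed)

test_that("energy ledger balances: absorbed + escaped = launched", {
  ph <- slab_phantom(absorber_spec(1, musp = 15), n = c(12, 12, 16),
                     voxel_mm = 0.5)
  fm <- simulate_fluence(ph, beam_spec(0.4, 1), 1000, mc_small(11))
  expect_lt(abs(fm$absorbed_fraction + fm$escaped_fraction - 1), 1e-6)
  expect_equal(fm$truncated_fraction, 0)
  # mu_a = 0 everywhere: nothing absorbed, everything escapes, exactly
  ph0 <- slab_phantom(tissue_spec("sc", musp_a = 5, musp_b = 0, g = 0.8),
                      n = c(10, 10, 10), voxel_mm = 0.5)
  fm0 <- simulate_fluence(ph0, beam_spec(0.4, 1), 1000, mc_small(3, 2000))
  expect_identical(fm0$absorbed_fraction, 0)
  expect_identical(fm0$escaped_fraction, 1)
})

test_that("non-scattering slab reproduces Beer-Lambert within 3 SE", {
  mu_a <- 2
  ph <- slab_phantom(absorber_spec(mu_a, musp = 0), n = c(16, 16, 20),
                     voxel_mm = 0.5)
  # in-beam column, voxel-averaged analytic value at each depth
  dz <- 0.05
  z0 <- (0:19) * dz; z1 <- z0 + dz
  bl <- (exp(-mu_a * z0) - exp(-mu_a * z1)) / (mu_a * dz)
  prof <- function(seed) {
    fm <- simulate_fluence(ph, beam_spec(0.6, 1), 1000, mc_small(seed, 5e3))
    apply(fm$phi[7:10, 7:10, ], 3, mean)
  }
  runs <- sapply(101:106, prof)
  se <- apply(runs, 1, stats::sd) / sqrt(ncol(runs))
  m <- rowMeans(runs)
  keep <- 1:10  # depths with decent statistics
  expect_true(all(abs(m - bl)[keep] <= 3 * se[keep] + 1e-12))
  # track-length estimator agrees too
  fm <- simulate_fluence(ph, beam_spec(0.6, 1), 1000, mc_small(107, 2e4))
  trk <- apply(fm$phi_track[7:10, 7:10, ], 3, mean)
  expect_lt(max(abs(trk - bl)[1:6] / bl[1:6]), 0.1)
})

test_that("fluence maps are bit-reproducible given the seed", {
  ph <- slab_phantom(absorber_spec(0.5, musp = 10), n = c(10, 10, 12),
                     voxel_mm = 0.5)
  a <- simulate_fluence(ph, beam_spec(0.4, 1), 1000, mc_small(77, 3000))
  b <- simulate_fluence(ph, beam_spec(0.4, 1), 1000, mc_small(77, 3000))
  expect_identical(a$phi, b$phi)
  expect_identical(a$phi_track, b$phi_track)
  expect_identical(a$escaped_fraction, b$escaped_fraction)
  c <- simulate_fluence(ph, beam_spec(0.4, 1), 1000, mc_small(78, 3000))
  expect_false(identical(a$phi, c$phi))
})

test_that("Henyey-Greenstein sampling has the right mean cosine", {
  set.seed(5)
  x0 <- paoxy:::.hg_sample(20000L, 0)
  expect_lt(abs(mean(x0)), 3 * stats::sd(x0) / sqrt(length(x0)))
  set.seed(6)
  x9 <- paoxy:::.hg_sample(20000L, 0.9)
  expect_lt(abs(mean(x9) - 0.9), 3 * stats::sd(x9) / sqrt(length(x9)))
})

test_that("roi standard error scales as 1/sqrt(n_photons)", {
  ph <- slab_phantom(absorber_spec(1, musp = 5), n = c(10, 10, 10),
                     voxel_mm = 0.5)
  roi <- array(FALSE, c(10, 10, 10)); roi[4:7, 4:7, 3:5] <- TRUE
  est <- function(n, seeds) vapply(seeds, function(s)
    local_fluence(simulate_fluence(ph, beam_spec(0.5, 1), 1000,
                                   mc_small(s, n)), roi, 1), 0)
  sd_small <- stats::sd(est(300, 1:10))
  sd_large <- stats::sd(est(30000, 11:20))
  ratio <- sd_small / sd_large          # expected sqrt(100) = 10
  expect_gt(ratio, 5); expect_lt(ratio, 20)
})

test_that("two-layer on-axis fluence matches an independent brute-force walker", {
  d <- c(14, 14, 16); vox_mm <- 0.5
  labels <- array(1L, d); labels[, , 7:16] <- 2L
  top <- absorber_spec(0.5, musp = 4, g = 0.6, name = "top")
  bot <- absorber_spec(1.5, musp = 2, g = 0.3, name = "bot")
  ph <- voxel_phantom(labels, vox_mm, list(top, bot))
  pr <- paoxy:::resolve_properties(ph, 1000, tab)
  block <- function(phi) mean(phi[6:9, 6:9, 8:9])       # on-axis, fixed depth
  main <- vapply(1:10, function(s)
    block(simulate_fluence(ph, beam_spec(0.5, 1), 1000, mc_small(s, 1e4))$phi),
    0)
  ref <- vapply(1:8, function(s)
    block(ref_walker(labels, vox_mm / 10, pr$mua, pr$mus, pr$g,
                     0.25, 6000, seed = 100 + s)), 0)
  se <- sqrt(stats::sd(main)^2 / 10 + stats::sd(ref)^2 / 8)
  # 3 standard errors, padded slightly for the noise of the SE estimates
  # themselves at these replicate counts
  expect_lt(abs(mean(main) - mean(ref)), 3.5 * se)
})

test_that("local fluence handles surfaces, zeros and bad rois", {
  ph <- slab_phantom(vacuum_spec, n = c(10, 10, 10), voxel_mm = 0.5)
  fm <- simulate_fluence(ph, beam_spec(0.4, 1), 800, mc_small(1, 2e4))
  surf <- array(FALSE, c(10, 10, 10)); surf[5:6, 5:6, 1] <- TRUE
  # vacuum: unit normalized fluence inside the beam at the surface
  # (binomial noise in the per-column photon counts sets the tolerance)
  expect_equal(local_fluence(fm, surf, 5, estimator = "track_length"), 5,
               tolerance = 0.05)
  expect_equal(local_fluence(fm, surf, 0, estimator = "track_length"), 0)
  expect_error(local_fluence(fm, array(FALSE, c(10, 10, 10)), 1), "empty")
  # collision estimator refuses an all-vacuum roi with a warning trail
  expect_warning(expect_error(local_fluence(fm, surf, 1), "no voxels"),
                 "mu_a = 0")
})

test_that("fluence spectra are order-independent and follow attenuation", {
  ph <- slab_phantom(tissues$porcine_muscle, n = c(16, 16, 22),
                     voxel_mm = 0.5)
  roi <- array(FALSE, dim(ph$labels)); roi[6:11, 6:11, 21:22] <- TRUE
  # single-wavelength grid equals local_fluence (analytic mode, exact)
  f1 <- fluence_spectrum(ph, beam_spec(0.5, 25), 808, roi,
                         mode = "analytic_1d")
  m <- analytic_fluence_map(ph, 808, tab)
  expect_equal(unname(f1), local_fluence(m, roi, 25))
  # 1064 nm penetrates 10 mm of porcine muscle better than 690 nm
  # (a transport effect: the 1D diffusion surrogate does not show it)
  f2 <- fluence_spectrum(ph, beam_spec(0.5, 25), c(690, 1064), roi,
                         cfg = mc_small(9, 1e4), mode = "mc")
  expect_gt(f2["1064"], f2["690"])
  # ordering on a two-point grid constructed with ordered mu_eff (surrogate)
  ph2 <- slab_phantom(tissues$kidney, n = c(16, 16, 22), voxel_mm = 0.5)
  fb <- fluence_spectrum(ph2, beam_spec(0.5, 25), c(808, 1300), roi,
                         mode = "analytic_1d")
  mueff <- function(l) sqrt(3 * mu_a_from_spec(tissues$kidney, l, tab) *
                              (mu_a_from_spec(tissues$kidney, l, tab) +
                                 reduced_scattering(tissues$kidney, l)))
  expect_equal(order(c(mueff(808), mueff(1300))),
               order(-c(fb["808"], fb["1300"])))
  # evaluation order does not matter (per-wavelength substreams)
  f3 <- fluence_spectrum(ph, beam_spec(0.5, 25), c(1064, 690), roi,
                         cfg = mc_small(9, 1e4), mode = "mc")
  expect_equal(f2, f3[names(f2)])
})
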