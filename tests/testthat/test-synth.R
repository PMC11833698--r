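test_that("tube phantom carries the requested blood composition", {
  ph <- build_tube_phantom(1)
  expect_true(all(ph$truth$c_Hb == 0))
  expect_equal(ph$truth$regions$tube_lumen$so2, 1)

  ph5 <- build_tube_phantom(0.5)
  lum <- ph5$scene$regions$tube_lumen$mask
  expect_equal(unique(ph5$truth$c_HbO2[lum]), 1.15e-3)
  expect_equal(unique(ph5$truth$c_Hb[lum]), 1.15e-3)
  expect_equal(unique(ph5$truth$so2[lum]), 0.5)

  pbs <- build_tube_phantom(0, lumen_content = "PBS")
  expect_true(pbs$truth$regions$tube_lumen$hemoglobin_free)
  expect_true(is.na(pbs$truth$regions$tube_lumen$so2))
  expect_true(all(is.na(pbs$truth$so2)))

  expect_error(build_tube_phantom(0.5, slab_thickness_mm = 9,
                                  size_mm = c(12, 8, 10)), "deeper")
  expect_error(build_tube_phantom(1.2), "blood_so2")

  # lumen centroid depth matches the construction
  d <- dim(lum)
  cz <- (seq_len(d[3]) - 0.5) * 0.2
  depth <- mean(cz[apply(lum, 3, any)])
  expect_lt(abs(depth - ph5$scene$regions$tube_lumen$depth_mm), 0.2)
})

test_that("abdomen phantom stratifies layers and regions by depth", {
  ab <- build_abdomen_phantom(0.8)
  for (nm in names(ab$scene$regions)) {
    reg <- ab$scene$regions[[nm]]
    d <- dim(reg$mask)
    cz <- (seq_len(d[3]) - 0.5) * 0.2
    centroid <- mean(cz[which(reg$mask, arr.ind = TRUE)[, 3]])
    expect_lt(abs(centroid - reg$depth_mm), 0.21)  # within one voxel
  }
  kid <- ab$scene$phantom$labels == 3L
  expect_equal(unique(ab$truth$so2[kid & ab$truth$c_HbO2 > 0]), 0.8)

  bl <- build_abdomen_phantom(0.8, hemoglobin_bleached = TRUE)
  expect_true(all(bl$truth$c_HbO2[kid] == 0) && all(bl$truth$c_Hb[kid] == 0))
  z0 <- build_abdomen_phantom(0)
  expect_true(all(z0$truth$c_HbO2[kid] == 0))
  expect_error(build_abdomen_phantom(0.5, skin_mm = 8, fat_mm = 9,
                                     size_mm = c(16, 8, 16)), "overlap")
  expect_error(build_abdomen_phantom(0.5, roi_depths_mm = c(2, 9)), "kidney")
})

test_that("forward model is linear in Gamma and noiseless frames repeat", {
  ph <- build_tube_phantom(1, voxel_mm = 0.4, size_mm = c(8, 6, 8))
  grid <- c(808, 1064)
  st1 <- simulate_pa_stack(ph$scene, grid, beam_spec(0.5, 25),
                           forward_config(gamma = 1, noise_sd = 0),
                           fluence_mode = "analytic_1d")
  expect_equal(st1$amplitude[, 1, , ], st1$amplitude[, 5, , ])
  st2 <- simulate_pa_stack(ph$scene, grid, beam_spec(0.5, 25),
                           forward_config(gamma = 2, noise_sd = 0),
                           fluence_mode = "analytic_1d")
  expect_equal(st2$amplitude, 2 * st1$amplitude)
})

test_that("single absorbing voxel under vacuum matches the closed form", {
  n <- c(7, 7, 10)
  labels <- array(1L, n)
  labels[4, 4, 6] <- 2L
  sp <- absorber_spec(0.8, musp = 6)
  phantom <- voxel_phantom(labels, 1, list(vacuum_spec, sp))
  mask <- labels == 2L
  scene <- structure(list(phantom = phantom,
                          regions = list(spot = list(mask = mask,
                                                     depth_mm = 5.5)),
                          id = "spot"), class = "phantom_scene")
  st <- simulate_pa_stack(scene, 1000, beam_spec(0.5, 1),
                          forward_config(gamma = 3, noise_sd = 0),
                          fluence_mode = "analytic_1d",
                          plane_halfwidth_mm = 0)
  mueff <- sqrt(3 * 0.8 * (0.8 + 6))
  # vacuum above; the voxel's own first half contributes mueff * dz/2
  expected <- 3 * 1 * 0.8 * exp(-mueff * 0.1 / 2)
  expect_equal(st$amplitude[1, 1, 6, 4], expected, tolerance = 1e-10)
})

test_that("noiseless amplitudes equal Gamma * mu_a * Phi pixel by pixel", {
  ph <- build_tube_phantom(0.4, voxel_mm = 0.4, size_mm = c(8, 6, 8))
  grid <- c(808, 1230)
  sf <- 25
  st <- simulate_pa_stack(ph$scene, grid, beam_spec(0.5, sf),
                          forward_config(gamma = 1.7, noise_sd = 0),
                          fluence_mode = "analytic_1d")
  labs <- ph$scene$phantom$labels[, st$plane_y_index, ]
  for (j in 1:2) {
    mua <- vapply(ph$scene$phantom$tissues, mu_a_from_spec, 0,
                  lambda = grid[j], table = tab)
    mua_sl <- t(matrix(mua[labs], dim(labs)[1], dim(labs)[2]))
    expect_equal(st$amplitude[j, 1, , ], 1.7 * sf * mua_sl * st$phi[j, , ],
                 tolerance = 1e-12)
  }
})

test_that("sweep datasets jitter reproducibly and reject duplicate seeds", {
  base <- build_tube_phantom(1)
  sw <- so2_sweep_dataset(so2_levels = 1, replicates = 1, seed = 4,
                          jitter_frac = 0, simulate = FALSE)
  expect_identical(sw[[1]]$so2_1$scene$phantom$labels,
                   base$scene$phantom$labels)
  expect_equal(sw[[1]]$c_tHb_M, 2.3e-3)
  expect_error(so2_sweep_dataset(replicates = 2, seeds = c(7, 7),
                                 simulate = FALSE), "duplicate")
  sw2 <- so2_sweep_dataset(so2_levels = 1, replicates = 100, seed = 1,
                           jitter_frac = 0.05, simulate = FALSE)
  slabs <- vapply(sw2, `[[`, 0, "slab_mm")
  expect_lt(abs(stats::sd(slabs) - 0.15), 0.2 * 0.15 + 1e-9)
})

test_that("spectral coloring appears through the slab and not without it", {
  grid <- c(690, 808, 950)
  # dilute blood so the lumen's own absorption does not color the spectrum;
  # the property under test is the coloring by the overburden
  shape <- function(lib, np = 6000, seed = 21) {
    ph <- build_tube_phantom(0, tissues = lib, c_tHb_M = 2.3e-4)
    st <- simulate_pa_stack(ph$scene, grid, beam_spec(0.5, 25),
                            forward_config(noise_sd = 0),
                            mc_config(n_photons = np, seed = seed), "mc")
    s <- roi_spectrum(st, scene_roi(ph$scene, "tube_lumen"))
    mua <- mu_a_from_spec(ph$scene$phantom$tissues[[4]], grid, tab)
    r <- s$mean / mua
    r / r[2]
  }
  colored <- shape(tissues)
  # transparent overburden: same geometry, no attenuation above the tube
  lib <- tissues
  for (nm in c("porcine_muscle", "gelatin", "tube_wall"))
    lib[[nm]] <- tissue_spec(nm)
  lib$blood$musp_a <- 0   # remove blood self-scattering as well
  flat <- shape(lib)
  dev_col <- max(abs(colored - 1))
  dev_flat <- max(abs(flat - 1))
  expect_gt(dev_col, 5 * dev_flat)
  expect_gt(dev_col, 0.5)     # strong coloring through the slab
})

test_that("bleached kidney loses its 1064 nm amplitude", {
  mk <- function(bleached) {
    ab <- build_abdomen_phantom(1, hemoglobin_bleached = bleached)
    st <- simulate_pa_stack(ab$scene, 1064, beam_spec(1.3, 5.5),
                            forward_config(noise_sd = 0),
                            fluence_mode = "analytic_1d")
    roi <- scene_roi(ab$scene, "roi_9mm")
    roi_spectrum(st, roi)$mean
  }
  expect_lt(mk(TRUE), mk(FALSE))
})
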