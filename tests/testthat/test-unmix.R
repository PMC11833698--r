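test_that("design matrix rows are extinctions scaled by fluence", {
  A <- design_matrix(nir1_set(), tab)
  expect_equal(unname(A[, "HbO2"]), extinction("HbO2", c(690, 808, 950), tab))
  expect_equal(unname(A[, "Hb"]), extinction("Hb", c(690, 808, 950), tab))
  # doubling a flat fluence cancels under isosbestic column normalization
  phi1 <- stats::setNames(c(0.4, 0.5, 0.6), c(690, 808, 950))
  A1 <- design_matrix(nir1_set(), tab, phi1, list(lambda_iso = 808))
  A2 <- design_matrix(nir1_set(), tab, 2 * phi1, list(lambda_iso = 808))
  expect_equal(A1, A2, ignore_attr = TRUE)  # the scale lives in col_scale
  # NIR-II matrix is well conditioned but not orthonormal
  k <- kappa(design_matrix(nir2_set(), tab), exact = TRUE)
  expect_true(is.finite(k) && k > 1)
  # lambda_iso outside the set still works through the table + fluence
  phi2 <- stats::setNames(c(1, 1, 1), c(1064, 1230, 808))
  A3 <- design_matrix(nir2_set(), tab, phi2, list(lambda_iso = 808))
  expect_equal(dim(A3), c(2L, 2L))
  expect_error(design_matrix(nir2_set(), tab,
                             stats::setNames(c(1, 1), c(1064, 1230)),
                             list(lambda_iso = 808)), "808")
})

test_that("compute_so2 is the concentration ratio with a guarded domain", {
  expect_equal(compute_so2(1, 1), 0.5)
  expect_equal(compute_so2(3, 0), 1)
  expect_equal(compute_so2(0, 2), 0)
  expect_error(compute_so2(0, 0), class = "paoxy_undefined_so2")
})

test_that("unmixing solves consistent systems and respects scale", {
  A <- design_matrix(nir1_set(), tab)
  m <- as.numeric(A %*% c(2, 1))
  s <- make_spectrum(c(690, 808, 950), m)
  u <- linear_unmix(s, nir1_set(), tab)
  expect_equal(c(u$c_HbO2, u$c_Hb), c(2, 1), tolerance = 1e-9)
  expect_lt(u$residual_norm, 1e-9)
  # a pure-oxy spectrum gives c_Hb = 0, sO2 = 1
  s1 <- make_spectrum(c(690, 808, 950), as.numeric(A[, 1]))
  u1 <- linear_unmix(s1, nir1_set(), tab)
  expect_equal(u1$so2, 1)
  expect_equal(u1$c_Hb, 0)
  # scale equivariance
  uk <- linear_unmix(make_spectrum(c(690, 808, 950), 5 * m), nir1_set(), tab)
  expect_equal(c(uk$c_HbO2, uk$c_Hb), 5 * c(2, 1), tolerance = 1e-9)
  expect_equal(uk$so2, u$so2)
  expect_error(linear_unmix(make_spectrum(c(690, 808, 950), rep(0, 3)),
                            nir1_set(), tab), "all-zero")
})

test_that("nonnegative solve matches a brute-force saturation scan", {
  # colored spectrum: true mix distorted by a smooth multiplicative ramp
  wl <- c(808, 1064, 1230)
  set <- nir2_set()
  eO <- extinction("HbO2", set$wavelengths, tab)
  eH <- extinction("Hb", set$wavelengths, tab)
  for (strue in c(0.15, 0.6, 0.92)) {
    m <- (strue * eO + (1 - strue) * eH) *
      exp(0.25 * seq(-1, 1, length.out = 2))   # spectral coloring
    s <- make_spectrum(set$wavelengths, m)
    u <- linear_unmix(s, set, tab)
    # oracle: scan sO2, fitting the free scale, minimizing the residual
    scan <- vapply(seq(0, 1, by = 1e-3), function(sv) {
      shape <- sv * eO + (1 - sv) * eH
      k <- sum(shape * m) / sum(shape^2)
      sum((m - k * shape)^2)
    }, 0)
    s_scan <- seq(0, 1, by = 1e-3)[which.min(scan)]
    expect_lt(abs(u$so2 - s_scan), 1e-3 + 1e-9)
  }
})

test_that("ordinary solver reports unclamped saturation and flags the clamp", {
  set <- nir2_set()
  eO <- extinction("HbO2", set$wavelengths, tab)
  eH <- extinction("Hb", set$wavelengths, tab)
  m <- 1.3 * eO - 0.25 * eH            # outside the physical cone
  u <- linear_unmix(make_spectrum(set$wavelengths, m), set, tab,
                    solver = "ols")
  expect_true(u$clamped)
  expect_gt(u$so2_unclamped, 1)
  expect_equal(u$so2, 1)
  un <- linear_unmix(make_spectrum(set$wavelengths, m), set, tab,
                     solver = "nnls")
  expect_gte(un$c_HbO2, 0); expect_gte(un$c_Hb, 0)
})

test_that("saturation is recovered exactly with oracle fluence and no noise", {
  sets <- list(nir1_set(), nir2_set())
  grid <- c(690, 808, 950, 1064, 1230)
  for (strue in c(0, 0.25, 0.5, 0.75, 1)) {
    ph <- build_tube_phantom(strue)
    st <- simulate_pa_stack(ph$scene, grid, beam_spec(0.5, 25),
                            forward_config(noise_sd = 0),
                            fluence_mode = "analytic_1d")
    roi <- scene_roi(ph$scene, "tube_lumen")
    s <- roi_spectrum(st, roi)
    phi <- vapply(seq_along(grid), function(j)
      mean(st$phi[j, , ][which(roi$mask)]), 0)
    s <- isosbestic_normalize(fluence_correct(s, phi, "oracle"))
    for (set in sets)
      expect_lt(abs(linear_unmix(s, set, tab)$so2 - strue), 1e-3)
  }
})

test_that("pixelwise unmixing maps uniform input to uniform output", {
  set <- nir2_set()
  A <- design_matrix(set, tab)
  m <- as.numeric(A %*% c(1.5, 0.5))
  amp <- array(0, dim = c(2, 3, 4, 5))
  for (j in 1:2) amp[j, , , ] <- m[j]
  amp[, , 4, 5] <- 0                    # a dead pixel
  st <- make_stack(amp, set$wavelengths)
  img <- unmix_image(st, set, tab)
  expect_equal(unname(img$so2[1:3, 1:4]),
               matrix(1.5 / 2, 3, 4), tolerance = 1e-9)
  expect_true(is.na(img$so2[4, 5]))
  expect_false(img$defined[4, 5])
})

test_that("pixelwise unmixing with oracle fluence recovers lumen truth", {
  ph <- build_tube_phantom(0.7, voxel_mm = 0.4, size_mm = c(8, 6, 8))
  grid <- c(690, 808, 950)
  st <- simulate_pa_stack(ph$scene, grid, beam_spec(0.5, 25),
                          forward_config(noise_sd = 0),
                          fluence_mode = "analytic_1d")
  img <- unmix_image(st, wavelength_set(grid, "NIR1"), tab,
                     phi_map = "oracle", min_amplitude = 1e-12)
  roi <- scene_roi(ph$scene, "tube_lumen")
  vals <- img$so2[roi$mask]
  expect_lt(abs(mean(vals, na.rm = TRUE) - 0.7), 1e-3)
})
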