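# Builds the packaged chromophore spectra (inst/extdata/*.csv) and the tissue
# optical-property library (inst/extdata/tissues.yaml).
#
# The hemoglobin table is a synthetic compilation: anchor nodes at
# literature-scale values (compiled pure-hemoglobin molar extinction below
# 1000 nm; effective whole-blood molar extinction above 1000 nm, i.e. the
# water content of whole blood is folded into the per-hemoglobin effective
# extinction so that mu_a(blood) = ln(10) * eps * c_tHb across the full
# range), interpolated to a 2-nm grid with a monotone Hermite spline.
# Water and lipid absorption are anchored the same way.
#
# NIR-II hemoglobin anchors place the deoxyhemoglobin overtone band near
# 1135 nm with a second oxy/deoxy crossing near 1100-1130 nm, so that above
# ~1300 nm oxygenated whole blood becomes indistinguishable from water/PBS
# while deoxygenated blood retains excess absorption.
#
# Rerun with:  Rscript data-raw/make_spectra.R

grid <- seq(650, 1800, by = 2)

dense <- function(anchors) {
  f <- splinefun(anchors$wl, anchors$val, method = "monoH.FC")
  v <- f(grid)
  stopifnot(all(v > 0))
  v
}

# --- oxyhemoglobin: effective molar extinction, cm^-1 M^-1 ------------------
hbo2 <- data.frame(wl = c(650, 660, 680, 690, 700, 720, 740, 760, 780, 800,
                          810, 820, 840, 860, 880, 900, 920, 940, 950, 970,
                          1000, 1030, 1064, 1100, 1150, 1200, 1230, 1270,
                          1300, 1350, 1400, 1450, 1500, 1600, 1700, 1800),
                   val = c(368, 320, 288, 276, 290, 362, 446, 586, 710, 816,
                           864, 916, 1022, 1092, 1154, 1198, 1240, 1262, 1250,
                           1180, 1102, 1010, 852, 676, 456, 340, 243, 193,
                           214, 418, 1887, 4319, 3111, 1052, 926, 1238))

# --- deoxyhemoglobin --------------------------------------------------------
hb <- data.frame(wl = c(650, 660, 680, 690, 700, 720, 740, 760, 780, 800,
                        810, 820, 840, 860, 880, 900, 920, 940, 950, 970,
                        1000, 1030, 1064, 1100, 1135, 1150, 1200, 1230, 1270,
                        1300, 1350, 1400, 1450, 1500, 1600, 1700, 1800),
                 val = c(3750, 3227, 2730, 2407, 1794, 1540, 1464, 1600,
                         1180, 850, 805, 770, 720, 700, 700, 750, 740, 710,
                         700, 660, 734, 590, 382, 446, 590, 586, 490, 393,
                         313, 314, 493, 1952, 4384, 3146, 1072, 946, 1258))

# --- water absorption, cm^-1 (pure water) -----------------------------------
water <- data.frame(wl = c(650, 700, 750, 800, 850, 900, 950, 970, 1000,
                           1030, 1064, 1100, 1150, 1200, 1230, 1270, 1300,
                           1350, 1400, 1440, 1450, 1500, 1550, 1600, 1650,
                           1700, 1750, 1800),
                    val = c(0.0032, 0.0060, 0.0262, 0.0220, 0.0430, 0.0680,
                            0.388, 0.450, 0.363, 0.200, 0.144, 0.170, 0.570,
                            1.060, 0.950, 0.880, 1.150, 2.60, 12.4, 26.0,
                            28.5, 20.5, 12.0, 6.70, 5.50, 5.90, 6.80, 8.00))

# --- lipid absorption, cm^-1 (pure lipid) -----------------------------------
lipid <- data.frame(wl = c(650, 700, 750, 800, 850, 900, 930, 950, 1000,
                           1040, 1064, 1100, 1150, 1200, 1210, 1230, 1300,
                           1350, 1400, 1450, 1500, 1600, 1700, 1720, 1750,
                           1800),
                    val = c(0.005, 0.007, 0.012, 0.007, 0.012, 0.040, 0.115,
                            0.090, 0.035, 0.055, 0.050, 0.040, 0.080, 0.300,
                            0.340, 0.280, 0.100, 0.120, 0.50, 1.10, 0.90,
                            0.60, 3.00, 4.00, 2.80, 1.00))

out <- file.path("inst", "extdata")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

hdr_hb <- c(
  "# Synthetic compilation of hemoglobin molar extinction spectra.",
  "# eps in cm^-1 M^-1. Below 1000 nm: compiled pure-hemoglobin scale;",
  "# above 1000 nm: effective whole-blood scale (blood water folded in,",
  "# so mu_a(whole blood) = ln(10) * eps * c_tHb over the full range).",
  "# Generated by data-raw/make_spectra.R; monotone spline through anchors.")
con <- file(file.path(out, "hemoglobin_extinction.csv"), "w")
writeLines(hdr_hb, con)
write.csv(data.frame(wavelength_nm = grid,
                     eps_HbO2_cm1M1 = round(dense(hbo2), 3),
                     eps_Hb_cm1M1 = round(dense(hb), 3)),
          con, row.names = FALSE, quote = FALSE)
close(con)

wr_abs <- function(df, name, what) {
  con <- file(file.path(out, name), "w")
  writeLines(c(sprintf("# Synthetic compilation of %s absorption, cm^-1.", what),
               "# Generated by data-raw/make_spectra.R."), con)
  write.csv(data.frame(wavelength_nm = grid, mu_a_cm1 = round(dense(df), 5)),
            con, row.names = FALSE, quote = FALSE)
  close(con)
}
wr_abs(water, "water_absorption.csv", "pure water")
wr_abs(lipid, "lipid_absorption.csv", "pure lipid")

# --- tissue library ---------------------------------------------------------
# Reduced scattering follows mu_s' = a * (lambda/500)^(-b). The porcine slab
# is calibrated so the NIR-I (690-950 nm) mean of mu_a + mu_s' is 50 cm^-1
# while the NIR-II (1200-1300 nm) mean stays below 10 cm^-1 (the reported
# attenuation contrast of washed porcine muscle); b = 5 realizes the steep
# scattering decay that contrast implies, and a is solved for numerically.
musp <- function(a, b, wl) a * (wl / 500)^(-b)
eps_w <- splinefun(water$wl, water$val, method = "monoH.FC")
eps_l <- splinefun(lipid$wl, lipid$val, method = "monoH.FC")
pork_fw <- 0.72; pork_fl <- 0.10; pork_b <- 5
nir1 <- seq(690, 950, by = 2)
mua1 <- mean(pork_fw * eps_w(nir1) + pork_fl * eps_l(nir1))
pork_a <- uniroot(function(a) mean(musp(a, pork_b, nir1)) + mua1 - 50,
                  c(100, 3000))$root
nir2 <- seq(1200, 1300, by = 2)
att2 <- mean(musp(pork_a, pork_b, nir2) + pork_fw * eps_w(nir2) +
             pork_fl * eps_l(nir2))
message(sprintf("porcine a = %.2f; NIR-II mean attenuation = %.2f cm^-1",
                pork_a, att2))
stopifnot(att2 < 10)

tissues <- list(
  gelatin       = list(f_water = 0.95, f_lipid = 0.0, c_HbO2_M = 0.0,
                       c_Hb_M = 0.0, musp_a = 3.0, musp_b = 1.0,
                       g = 0.90, n = 1.35),
  porcine_muscle = list(f_water = pork_fw, f_lipid = pork_fl, c_HbO2_M = 0.0,
                        c_Hb_M = 0.0, musp_a = round(pork_a, 1),
                        musp_b = pork_b, g = 0.90, n = 1.37),
  skin          = list(f_water = 0.60, f_lipid = 0.10, c_HbO2_M = 2e-5,
                       c_Hb_M = 2e-5, musp_a = 45.0, musp_b = 1.4,
                       g = 0.90, n = 1.40),
  fat           = list(f_water = 0.15, f_lipid = 0.75, c_HbO2_M = 0.0,
                       c_Hb_M = 0.0, musp_a = 32.0, musp_b = 0.7,
                       g = 0.90, n = 1.44),
  kidney        = list(f_water = 0.65, f_lipid = 0.03, c_HbO2_M = 0.0,
                       c_Hb_M = 0.0, musp_a = 23.0, musp_b = 1.5,
                       g = 0.90, n = 1.37),
  blood         = list(f_water = 0.0, f_lipid = 0.0, c_HbO2_M = 0.0,
                       c_Hb_M = 0.0, musp_a = 7.0, musp_b = 1.0,
                       g = 0.98, n = 1.36),
  PBS           = list(f_water = 1.0, f_lipid = 0.0, c_HbO2_M = 0.0,
                       c_Hb_M = 0.0, musp_a = 0.1, musp_b = 1.0,
                       g = 0.0, n = 1.33),
  tube_wall     = list(f_water = 0.0, f_lipid = 0.0, c_HbO2_M = 0.0,
                       c_Hb_M = 0.0, musp_a = 30.0, musp_b = 0.5,
                       g = 0.90, n = 1.35)
)
yaml::write_yaml(tissues, file.path(out, "tissues.yaml"))
message("wrote inst/extdata/{hemoglobin_extinction,water_absorption,lipid_absorption}.csv and tissues.yaml")
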