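# paoxy

Spectral photoacoustic (PA) oximetry estimates hemoglobin oxygen saturation
(sO2) from multi-wavelength PA images. Its accuracy is limited by *spectral
coloring*: light reaching a deep target has been attenuated by the overlying
tissue in a wavelength-dependent way, so the target's measured PA spectrum is
a distorted version of its absorption spectrum. Imaging in the second
near-infrared window (NIR-II, ~950-1400 nm), where tissue scattering is much
weaker and skin exposure limits are higher, reduces that distortion compared
with the conventional first window (NIR-I, 690-950 nm).

`paoxy` is an R package for studying this quantitatively on synthetic data.
It provides, end to end:

* packaged chromophore spectra — oxy/deoxyhemoglobin effective molar
  extinction, water and lipid absorption, 650-1800 nm (a synthetic
  literature-scale compilation, see `data-raw/make_spectra.R`) — plus a
  tissue optical-property library with a porcine-muscle entry calibrated to
  the reported window contrast (mean mu_a + mu_s' of ~50 cm^-1 in NIR-I vs
  under 10 cm^-1 in NIR-II);
* a voxelized weighted-photon **Monte Carlo transport solver** (Rcpp) with
  Henyey-Greenstein scattering, Russian roulette, collision and track-length
  fluence estimators, and an exact energy ledger, plus a 1D diffusion
  surrogate `analytic_fluence_1d()`;
* a **synthetic-data generator**: a digital blood-tube phantom (3 mm porcine
  slab over a 1.5/2.0 mm tube of whole blood in gelatin) and a layered rat
  abdomen (skin, fat, kidney with regions at 6/9/12 mm depth), imaged by a
  forward model `p0 = Gamma * mu_a * Phi` with per-pulse multiplicative
  noise and 5 frames per wavelength;
* **preprocessing**: ROI/frame averaging, isosbestic normalization at
  808 nm, fluence correction;
* **linear spectral unmixing** of the two hemoglobin species
  (`p0(lambda) = Gamma [eps_HbO2 c_HbO2 + eps_Hb c_Hb] Phi`), nonnegative or
  ordinary least squares, with `sO2 = c_HbO2 / (c_HbO2 + c_Hb)`;
* **evaluation**: the total absolute error metric (sum of the absolute sO2
  errors of the oxygenated and deoxygenated conditions), replicated
  phantom and depth-stratified experiments comparing the NIR-I set
  {690, 808, 950} against the NIR-II set {1064, 1230}, one-way ANOVA, and a
  config-driven `run_pipeline()`;
* an ANSI-style nanosecond-pulse skin exposure limit calculator
  (`mpe_skin()`: 20 mJ/cm^2 at 690 nm, 100 mJ/cm^2 above ~1050 nm).

## Worked example

```r
library(paoxy)

# a tube phantom filled with deoxygenated whole blood
ph <- build_tube_phantom(blood_so2 = 0)

# fluence at the tube, Monte Carlo, 690 vs 1064 nm
roi3d <- ph$scene$regions$tube_lumen$mask
f <- fluence_spectrum(ph$scene$phantom, beam_spec(0.5, 25), c(690, 1064),
                      roi3d, cfg = mc_config(n_photons = 2e4, seed = 1),
                      mode = "mc")
round(f, 3)
#>   690  1064
#> 0.300 3.164
```

The tube sits under 3 mm of porcine muscle; the local fluence at 1064 nm
(3.2 mJ/cm^2 out of 25 delivered) is roughly ten times that at 690 nm
(0.30 mJ/cm^2) — the penetration advantage of the second window.

```r
# image the phantom, extract and normalize the tube spectrum, unmix
st  <- simulate_pa_stack(ph$scene, c(690, 808, 950, 1064, 1230),
                         beam_spec(0.5, 25), forward_config(seed = 1),
                         mc_config(n_photons = 2e4, seed = 1), "mc")
s   <- isosbestic_normalize(roi_spectrum(st, scene_roi(ph$scene)))
linear_unmix(s, nir2_set())
#> <unmixing_result> set NIR2 (nnls): sO2 = 0.0000
linear_unmix(s, nir1_set())
#> <unmixing_result> set NIR1 (nnls): sO2 = 0.7793
```

Without fluence correction the NIR-I estimate of this fully deoxygenated
sample (true sO2 = 0) is badly colored (0.78), while the NIR-II estimate
stays at truth (0.00). The full replicated comparison, including the
perturbed fluence correction used in the headline experiment, is run by

```r
report <- run_phantom_experiment(experiment_config(seed = 1))
report
```

which prints the mean total absolute error per wavelength set with
quartiles, and the percent error reduction of NIR-II versus NIR-I.

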