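# shared tiny fixtures; everything is built in code at test time

tab <- extinction_table()
tissues <- tissue_library()

# a minimal image stack with known amplitudes, bypassing the simulator
make_stack <- function(amplitude, wavelengths, voxel_mm = 0.2) {
  stopifnot(length(dim(amplitude)) == 4, dim(amplitude)[1] == length(wavelengths))
  structure(list(amplitude = amplitude, wavelengths = wavelengths,
                 frames = dim(amplitude)[2], voxel_mm = voxel_mm,
                 plane_y_index = 1L,
                 phi = array(1, dim = dim(amplitude)[c(1, 3, 4)]),
                 fluence_mode = "manual", scene_id = "fixture",
                 seed = 0L, beam = NULL, gamma = 1, noise_sd = 0),
            class = "pa_stack")
}

# spectrum with given means (sd zero), as if measured on `wl`
make_spectrum <- function(wl, mean, sd = rep(0, length(mean))) {
  structure(list(wavelengths = wl, mean = mean, sd = sd, state = "raw",
                 meta = list()),
            class = "spectrum_measurement")
}

# transparent tissue (no absorption, no scattering)
vacuum_spec <- tissue_spec("vacuum")

# homogeneous single-tissue phantom
slab_phantom <- function(spec, n = c(16, 16, 30), voxel_mm = 0.5)
  voxel_phantom(array(1L, n), voxel_mm, list(spec))

# absorber with exact mu_a at a reference wavelength (b = 0 power law);
# realized through a hemoglobin concentration so any mu_a is reachable
absorber_spec <- function(mu_a, musp = 0, at = 1000, g = 0.9, name = "abs")
  tissue_spec(name, c_HbO2_M = mu_a / (log(10) * extinction("HbO2", at)),
              musp_a = musp, musp_b = 0, g = g)
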