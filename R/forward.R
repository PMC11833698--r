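#' Forward-model settings
#'
#' @param gamma Grueneisen factor (arbitrary units, > 0). Absorbed into the
#'   arbitrary amplitude scale.
#' @param noise_sd multiplicative pulse-to-pulse noise standard deviation as
#'   a fraction of the amplitude (default 0.05, the laser's stated < 5%
#'   pulse-to-pulse output variation).
#' @param frames frames acquired per wavelength (default 5).
#' @param seed RNG seed for the noise draws.
#' @return object of class \code{forward_config}.
#' @export
forward_config <- function(gamma = 1, noise_sd = 0.05, frames = 5L,
                           seed = 1L) {
  stopifnot(gamma > 0, noise_sd >= 0, frames >= 1)
  structure(list(gamma = gamma, noise_sd = noise_sd,
                 frames = as.integer(frames), seed = as.integer(seed)),
            class = "forward_config")
}

#' Simulate a multi-wavelength photoacoustic image stack
#'
#' Initial-pressure forward model: per voxel and wavelength the noiseless
#' amplitude is Gamma * mu_a,total(voxel, lambda) * Phi(voxel, lambda), with
#' Phi either a Monte Carlo fluence map or the 1D analytic surrogate. The
#' "image" is the mid-plane (x, z) slice of the field (the transducer plane
#' containing the target axis); each frame carries an independent
#' multiplicative pulse-energy factor max(0, 1 + N(0, noise_sd)). Acoustic
#' propagation and reconstruction are out of scope.
#'
#' @param scene a \code{phantom_scene} (see \code{\link{build_tube_phantom}}).
#' @param grid wavelengths, nm (a \code{\link{wavelength_grid}} or numeric).
#' @param beam a \code{\link{beam_spec}}.
#' @param fcfg a \code{\link{forward_config}}.
#' @param mccfg an \code{\link{mc_config}} (used in \code{"mc"} mode).
#' @param fluence_mode \code{"mc"} or \code{"analytic_1d"}.
#' @param plane_halfwidth_mm half-width of the slab of y slices averaged
#'   into the image-plane fluence (default 1 mm). The scenes built by this
#'   package are translation-invariant near the mid-plane, so the average
#'   suppresses Monte Carlo tally noise without bias; set 0 to use the
#'   single mid-plane slice (e.g. for scenes without that symmetry).
#' @param table an \code{\link{extinction_table}}.
#' @return object of class \code{pa_stack}: \code{amplitude} array indexed
#'   (wavelength, frame, z, x) in arbitrary pressure units, the wavelength
#'   grid, pixel geometry, the per-wavelength ROI-resolved fluence maps'
#'   mid-plane slices (\code{phi}, wavelength x z x x, for oracle
#'   correction), and provenance.
#' @export
simulate_pa_stack <- function(scene, grid, beam, fcfg = forward_config(),
                              mccfg = mc_config(),
                              fluence_mode = c("analytic_1d", "mc"),
                              plane_halfwidth_mm = 1,
                              table = the_table()) {
  fluence_mode <- match.arg(fluence_mode)
  stopifnot(inherits(scene, "phantom_scene"), inherits(beam, "beam_spec"))
  grid <- wavelength_grid(grid, table)
  phantom <- scene$phantom
  d <- dim(phantom$labels)
  iy <- ceiling(d[2] / 2)
  iys <- which(abs((seq_len(d[2]) - 0.5) - d[2] / 2) * phantom$voxel_mm <=
                 plane_halfwidth_mm)
  if (length(iys) == 0) iys <- iy
  nl <- length(grid)

  pr_all <- lapply(as.numeric(grid), function(l)
    resolve_properties(phantom, l, table))
  lab_slice <- phantom$labels[, iy, ]  # nx x nz

  amp0 <- array(0, dim = c(nl, d[3], d[1]))   # lambda x z x x, noiseless
  phi_slice <- array(0, dim = c(nl, d[3], d[1]))
  for (j in seq_len(nl)) {
    l <- as.numeric(grid)[j]
    map <- if (fluence_mode == "mc") {
      cfg_l <- mccfg
      cfg_l$seed <- stream_seed(mccfg$seed, paste0("mc", l))
      simulate_fluence(phantom, beam, l, cfg_l, table)
    } else analytic_fluence_map(phantom, l, table)
    mua_sl <- matrix(pr_all[[j]]$mua[lab_slice], d[1], d[3])
    phi_plane <- apply(map$phi_track[, iys, , drop = FALSE], c(1, 3), mean)
    amp0[j, , ] <- t(fcfg$gamma * beam$surface_fluence_mJcm2 *
                       mua_sl * phi_plane)
    phi_slice[j, , ] <- t(phi_plane)
  }

  set.seed(stream_seed(fcfg$seed, paste0("noise_", scene$id)))
  factors <- matrix(pmax(0, 1 + stats::rnorm(nl * fcfg$frames, 0,
                                             fcfg$noise_sd)),
                    nl, fcfg$frames)
  amp <- array(0, dim = c(nl, fcfg$frames, d[3], d[1]))
  for (j in seq_len(nl)) for (f in seq_len(fcfg$frames))
    amp[j, f, , ] <- amp0[j, , ] * factors[j, f]

  structure(list(amplitude = amp, wavelengths = as.numeric(grid),
                 frames = fcfg$frames, voxel_mm = phantom$voxel_mm,
                 plane_y_index = iy, phi = phi_slice,
                 plane_halfwidth_mm = plane_halfwidth_mm,
                 fluence_mode = fluence_mode,
                 scene_id = scene$id, seed = fcfg$seed,
                 beam = beam, gamma = fcfg$gamma,
                 noise_sd = fcfg$noise_sd),
            class = "pa_stack")
}

#' @export
print.pa_stack <- function(x, ...) {
  d <- dim(x$amplitude)
  cat("<pa_stack> ", x$scene_id, ": ", d[1], " wavelengths x ", d[2],
      " frames x ", d[3], " z x ", d[4], " x (", x$fluence_mode, ")\n",
      sep = "")
  invisible(x)
}

#' Replicated oxygenation sweep
#'
#' Generates the replicated two-condition experiment: for each replicate a
#' freshly "prepared" tube phantom per saturation level, with slab thickness
#' and total hemoglobin jittered by a multiplicative factor
#' 1 + N(0, jitter_frac) to emulate inter-phantom variability, and an
#' independent noise substream. Geometry is shared across levels within a
#' replicate (the same phantom is loaded with each solution in turn).
#'
#' @param so2_levels saturations to generate (default 1.0 and 0.0).
#' @param replicates number of independently prepared phantoms (default 3).
#' @param seed global seed; per-replicate seeds are derived substreams.
#' @param seeds optional explicit per-replicate seeds (distinct; overrides
#'   \code{seed} fan-out).
#' @param jitter_frac inter-phantom variability fraction (default 0.05).
#' @param grid,beam,fcfg,mccfg,fluence_mode,table forwarded to
#'   \code{\link{simulate_pa_stack}}.
#' @param simulate if FALSE, only the jittered scenes and truths are built
#'   (no image stacks).
#' @param ... forwarded to \code{\link{build_tube_phantom}}.
#' @return list of replicates; each has \code{seed}, \code{slab_mm},
#'   \code{c_tHb_M} and one \code{list(scene, truth, stack)} per level
#'   (named by level).
#' @export
so2_sweep_dataset <- function(so2_levels = c(1, 0), replicates = 3,
                              seed = 1L, seeds = NULL, jitter_frac = 0.05,
                              grid = NULL, beam = NULL,
                              fcfg = forward_config(),
                              mccfg = mc_config(),
                              fluence_mode = c("analytic_1d", "mc"),
                              table = the_table(), simulate = TRUE, ...) {
  fluence_mode <- match.arg(fluence_mode)
  if (is.null(seeds))
    seeds <- vapply(seq_len(replicates), function(r)
      stream_seed(seed, paste0("replicate", r)), 0L)
  if (anyDuplicated(seeds)) stop("duplicate replicate seeds rejected")
  if (length(seeds) != replicates) stop("need one seed per replicate")
  base <- list(...)
  slab0 <- if (!is.null(base$slab_thickness_mm)) base$slab_thickness_mm else 3
  cthb0 <- if (!is.null(base$c_tHb_M)) base$c_tHb_M else 2.3e-3

  lapply(seq_len(replicates), function(r) {
    set.seed(stream_seed(seeds[r], "jitter"))
    slab <- slab0 * (1 + stats::rnorm(1, 0, jitter_frac))
    cthb <- cthb0 * (1 + stats::rnorm(1, 0, jitter_frac))
    levels <- lapply(so2_levels, function(s) {
      args <- base
      args$blood_so2 <- s
      args$slab_thickness_mm <- slab
      args$c_tHb_M <- cthb
      ph <- do.call(build_tube_phantom, args)
      stack <- NULL
      if (simulate) {
        fc <- fcfg
        fc$seed <- stream_seed(seeds[r], paste0("noise", s))
        stack <- simulate_pa_stack(ph$scene, grid, beam, fc, mccfg,
                                   fluence_mode, table = table)
      }
      list(scene = ph$scene, truth = ph$truth, stack = stack)
    })
    names(levels) <- sprintf("so2_%g", so2_levels)
    c(list(seed = seeds[r], slab_mm = slab, c_tHb_M = cthb), levels)
  })
}
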