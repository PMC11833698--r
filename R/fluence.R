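#' Voxelized tissue phantom
#'
#' A labeled 3D voxel grid with a tissue spec per label. Axes are (x, y, z)
#' with z the depth from the illumination surface (z = 0 face); voxel centers
#' sit at (i - 0.5) * voxel_mm along each axis (1-based R indices).
#'
#' @param labels 3D integer array of tissue labels (values 1..K).
#' @param voxel_mm voxel edge length, mm (> 0).
#' @param tissues list of \code{\link{tissue_spec}} of length K, indexed by
#'   label value.
#' @param origin_mm physical offset of the grid corner, length-3 (default 0).
#' @return object of class \code{voxel_phantom}.
#' @export
voxel_phantom <- function(labels, voxel_mm, tissues, origin_mm = c(0, 0, 0)) {
  stopifnot(length(dim(labels)) == 3, voxel_mm > 0, length(labels) > 0)
  used <- sort(unique(as.integer(labels)))
  if (any(used < 1L) || any(used > length(tissues)))
    stop("phantom labels must all resolve to an entry of `tissues`")
  if (!all(vapply(tissues, inherits, TRUE, "tissue_spec")))
    stop("`tissues` must be tissue_spec objects")
  structure(list(labels = labels, voxel_mm = voxel_mm, tissues = tissues,
                 origin_mm = origin_mm),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat("<voxel_phantom> ", paste(dim(x$labels), collapse = " x "),
      " voxels @ ", x$voxel_mm, " mm; tissues: ",
      paste(vapply(x$tissues, `[[`, "", "name"), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Illumination beam
#'
#' Circular flat-top beam at normal incidence on the z = 0 face.
#'
#' @param diameter_cm beam diameter, cm (> 0).
#' @param surface_fluence_mJcm2 delivered surface fluence, mJ/cm^2 (>= 0).
#' @param center_mm (x, y) beam center, mm; \code{NULL} = grid center.
#' @return object of class \code{beam_spec}.
#' @export
beam_spec <- function(diameter_cm, surface_fluence_mJcm2, center_mm = NULL) {
  stopifnot(diameter_cm > 0, surface_fluence_mJcm2 >= 0)
  structure(list(diameter_cm = diameter_cm,
                 surface_fluence_mJcm2 = surface_fluence_mJcm2,
                 center_mm = center_mm),
            class = "beam_spec")
}

#' Monte Carlo transport settings
#'
#' @param n_photons photons to launch (>= 1). The default 2e5 resolves a
#'   desk-scale fluence map in seconds.
#' @param seed RNG seed for this simulation.
#' @param roulette_threshold Russian-roulette weight threshold (0 < t < 1).
#' @param roulette_survival survival multiplier (> 1).
#' @param max_events hard cap on scattering events per photon (safeguard).
#' @return object of class \code{mc_config}.
#' @export
mc_config <- function(n_photons = 2e5, seed = 1L, roulette_threshold = 1e-5,
                      roulette_survival = 10, max_events = 1e6) {
  stopifnot(n_photons >= 1, roulette_threshold > 0, roulette_threshold < 1,
            roulette_survival > 1)
  structure(list(n_photons = as.integer(n_photons), seed = as.integer(seed),
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 max_events = max_events),
            class = "mc_config")
}

resolve_properties <- function(phantom, lambda, table = the_table()) {
  specs <- phantom$tissues
  list(mua = vapply(specs, mu_a_from_spec, 0, lambda = lambda, table = table),
       mus = vapply(specs, mu_s_from_spec, 0, lambda = lambda),
       g = vapply(specs, `[[`, 0, "g"))
}

#' Monte Carlo fluence simulation
#'
#' Weighted-photon transport of a circular flat-top beam through the phantom
#' at one wavelength. Returns the fluence normalized per unit delivered
#' surface fluence (dimensionless), with an energy ledger. Refractive-index
#' boundaries are matched (no Fresnel reflection). Bit-reproducible given the
#' seed in \code{cfg}.
#'
#' @param phantom a \code{\link{voxel_phantom}}.
#' @param beam a \code{\link{beam_spec}}.
#' @param lambda wavelength, nm (scalar).
#' @param cfg an \code{\link{mc_config}}.
#' @param table an \code{\link{extinction_table}}.
#' @return object of class \code{fluence_map}: normalized fluence arrays
#'   \code{phi} (collision estimator) and \code{phi_track} (track-length
#'   estimator; lower variance and defined also where mu_a = 0), logical
#'   \code{valid} (voxels with mu_a > 0, where the collision estimator is
#'   defined), the energy ledger, and provenance.
#' @export
simulate_fluence <- function(phantom, beam, lambda, cfg = mc_config(),
                             table = the_table()) {
  stopifnot(inherits(phantom, "voxel_phantom"), inherits(beam, "beam_spec"),
            length(lambda) == 1)
  pr <- resolve_properties(phantom, lambda, table)
  if (anyNA(pr$mua) || anyNA(pr$mus))
    stop("unresolvable tissue properties at ", lambda, " nm")
  d <- dim(phantom$labels)
  vox_cm <- phantom$voxel_mm / 10
  ctr <- if (is.null(beam$center_mm)) c(d[1], d[2]) * vox_cm / 2
         else beam$center_mm / 10
  set.seed(cfg$seed)
  res <- .mc_transport(as.integer(phantom$labels), as.integer(d), vox_cm,
                       pr$mua, pr$mus, pr$g, ctr[1], ctr[2],
                       beam$diameter_cm / 2, cfg$n_photons,
                       cfg$roulette_threshold, cfg$roulette_survival,
                       cfg$max_events)
  beam_area <- pi * (beam$diameter_cm / 2)^2
  mua_vox <- array(pr$mua[phantom$labels], dim = d)
  valid <- mua_vox > 0
  phi <- array(0, dim = d)
  vol <- vox_cm^3
  phi[valid] <- array(res$dep, dim = d)[valid] * beam_area /
    (cfg$n_photons * mua_vox[valid] * vol)
  phi_track <- array(res$tlen, dim = d) * beam_area / (cfg$n_photons * vol)
  structure(list(phi = phi, phi_track = phi_track, valid = valid,
                 absorbed_fraction = res$absorbed / cfg$n_photons,
                 escaped_fraction = res$escaped / cfg$n_photons,
                 truncated_fraction = res$truncated / cfg$n_photons,
                 roulette_net = res$roulette_net / cfg$n_photons,
                 lambda = lambda, voxel_mm = phantom$voxel_mm,
                 n_photons = cfg$n_photons, seed = cfg$seed,
                 method = "mc"),
            class = "fluence_map")
}

#' @export
print.fluence_map <- function(x, ...) {
  cat("<fluence_map> ", paste(dim(x$phi), collapse = " x "), " @ ",
      x$voxel_mm, " mm, ", x$lambda, " nm (", x$method, "); absorbed ",
      signif(x$absorbed_fraction, 4), ", escaped ",
      signif(x$escaped_fraction, 4), "\n", sep = "")
  invisible(x)
}

#' One-dimensional diffusion surrogate for fluence
#'
#' Depth profile Phi(z)/Phi0 = exp(-sum_i mu_eff,i d_i(z)) through a stack of
#' layers, with mu_eff = sqrt(3 mu_a (mu_a + mu_s')). A fast surrogate for
#' the Monte Carlo solver in quick-look pipelines and as a forward model for
#' tests; it ignores beam geometry and backscatter buildup.
#'
#' @param layers list of layers, each \code{list(spec = tissue_spec,
#'   thickness_mm = ...)}.
#' @param lambda wavelength(s), nm.
#' @param z_mm depths at which to evaluate, mm.
#' @param table an \code{\link{extinction_table}}.
#' @return matrix of Phi/Phi0, \code{length(z_mm)} x \code{length(lambda)}
#'   (dropped to a vector for scalar lambda).
#' @export
analytic_fluence_1d <- function(layers, lambda, z_mm, table = the_table()) {
  th <- vapply(layers, `[[`, 0, "thickness_mm")
  if (any(th < 0)) stop("negative layer thickness rejected")
  mueff <- vapply(lambda, function(l) {
    vapply(layers, function(ly) {
      mua <- mu_a_from_spec(ly$spec, l, table)
      musp <- reduced_scattering(ly$spec, l)
      sqrt(3 * mua * (mua + musp))
    }, 0)
  }, numeric(length(layers)))  # layers x lambda
  mueff <- matrix(mueff, nrow = length(layers))
  bounds <- c(0, cumsum(th))
  out <- vapply(seq_along(lambda), function(j) {
    vapply(z_mm, function(z) {
      d_mm <- pmax(0, pmin(z, bounds[-1]) - bounds[-length(bounds)])
      exp(-sum(mueff[, j] * d_mm / 10))
    }, 0)
  }, numeric(length(z_mm)))
  out <- matrix(out, nrow = length(z_mm))
  if (length(lambda) == 1L) drop(out) else out
}

#' Analytic fluence map on a phantom
#'
#' Applies the 1D surrogate column-by-column down the phantom: each voxel
#' center receives exp(-integral of mu_eff along its own z column). Shares
#' the \code{fluence_map} container with the Monte Carlo solver.
#'
#' @inheritParams simulate_fluence
#' @return a \code{fluence_map} (ledger fields are NA: the surrogate does
#'   not track energy).
#' @export
analytic_fluence_map <- function(phantom, lambda, table = the_table()) {
  stopifnot(length(lambda) == 1)
  pr <- resolve_properties(phantom, lambda, table)
  musp <- vapply(phantom$tissues, reduced_scattering, 0, lambda = lambda)
  mueff_lab <- sqrt(3 * pr$mua * (pr$mua + musp))
  d <- dim(phantom$labels)
  mueff <- array(mueff_lab[phantom$labels], dim = d)
  dz_cm <- phantom$voxel_mm / 10
  # optical depth to each voxel center: full voxels above + half of own
  tau <- apply(mueff, c(1, 2), function(col) cumsum(col) - col / 2) * dz_cm
  phi <- exp(-aperm(tau, c(2, 3, 1)))
  structure(list(phi = phi, phi_track = phi, valid = array(TRUE, d),
                 absorbed_fraction = NA_real_, escaped_fraction = NA_real_,
                 truncated_fraction = NA_real_, roulette_net = NA_real_,
                 lambda = lambda, voxel_mm = phantom$voxel_mm,
                 n_photons = NA_integer_, seed = NA_integer_,
                 method = "analytic_1d"),
            class = "fluence_map")
}

#' Mean local fluence over a region
#'
#' Mean normalized fluence over the region, scaled by the delivered surface
#' fluence. Voxels where the collision estimator is undefined (mu_a = 0) are
#' excluded with a warning.
#'
#' @param map a \code{\link[=simulate_fluence]{fluence_map}}.
#' @param roi logical array congruent with the map, or an index vector/matrix.
#' @param surface_fluence_mJcm2 delivered surface fluence, mJ/cm^2.
#' @param estimator \code{"collision"} (default; voxels with mu_a = 0 are
#'   excluded with a warning) or \code{"track_length"}.
#' @return scalar local fluence, mJ/cm^2.
#' @export
local_fluence <- function(map, roi, surface_fluence_mJcm2,
                          estimator = c("collision", "track_length")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(map, "fluence_map"))
  if (is.logical(roi)) {
    if (!identical(dim(roi), dim(map$phi)))
      stop("roi shape does not match the fluence map")
    idx <- which(roi)
  } else idx <- roi
  if (length(idx) == 0) stop("empty roi")
  if (estimator == "track_length")
    return(mean(map$phi_track[idx]) * surface_fluence_mJcm2)
  ok <- map$valid[idx]
  if (!all(ok)) {
    warning("excluding ", sum(!ok), " mu_a = 0 voxel(s) from the roi mean")
    idx <- idx[ok]
    if (length(idx) == 0) stop("roi contains no voxels with defined fluence")
  }
  mean(map$phi[idx]) * surface_fluence_mJcm2
}

#' Per-wavelength local fluence spectrum
#'
#' Maps \code{\link{simulate_fluence}} (or the analytic surrogate) plus
#' \code{\link{local_fluence}} over a wavelength grid. Each wavelength runs
#' on its own named RNG substream, so results are independent of evaluation
#' order.
#'
#' @inheritParams simulate_fluence
#' @param grid a \code{\link{wavelength_grid}} (or numeric vector).
#' @param roi region passed to \code{\link{local_fluence}}.
#' @param mode \code{"mc"} or \code{"analytic_1d"}.
#' @return named numeric vector of local fluence (mJ/cm^2) per wavelength.
#' @export
fluence_spectrum <- function(phantom, beam, grid, roi, cfg = mc_config(),
                             mode = c("mc", "analytic_1d"),
                             table = the_table()) {
  mode <- match.arg(mode)
  grid <- as.numeric(grid)
  out <- vapply(grid, function(l) {
    map <- if (mode == "mc") {
      cfg_l <- cfg
      cfg_l$seed <- stream_seed(cfg$seed, paste0("mc", l))
      simulate_fluence(phantom, beam, l, cfg_l, table)
    } else analytic_fluence_map(phantom, l, table)
    local_fluence(map, roi, beam$surface_fluence_mJcm2)
  }, 0)
  names(out) <- grid
  out
}
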