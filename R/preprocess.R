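#' Region-of-interest mask
#'
#' A 2D boolean mask aligned to the stack's (z, x) plane.
#'
#' @param mask logical matrix (z rows, x columns) with at least one TRUE.
#' @param label region name.
#' @param depth_mm nominal region depth below the surface, mm.
#' @return object of class \code{roi_mask}.
#' @export
roi_mask <- function(mask, label = "roi", depth_mm = NA_real_) {
  stopifnot(is.logical(mask), length(dim(mask)) == 2)
  if (!any(mask)) stop("empty roi")
  structure(list(mask = mask, label = label, depth_mm = depth_mm),
            class = "roi_mask")
}

#' Midplane ROI of a scene region
#'
#' Extracts the (z, x) mid-plane slice of a named 3D target region of a
#' scene, aligned with the image plane of \code{\link{simulate_pa_stack}}.
#'
#' @param scene a \code{phantom_scene}.
#' @param region region name (default the first).
#' @return an \code{\link{roi_mask}}.
#' @export
scene_roi <- function(scene, region = names(scene$regions)[1]) {
  reg <- scene$regions[[region]]
  if (is.null(reg)) stop("unknown region: ", region)
  iy <- ceiling(dim(reg$mask)[2] / 2)
  roi_mask(t(reg$mask[, iy, ]), label = region, depth_mm = reg$depth_mm)
}

#' ROI spectrum of an image stack
#'
#' Averages the pixels inside the region, then the frames; the
#' frame-to-frame standard deviation of the ROI mean is retained.
#'
#' @param stack a \code{\link[=simulate_pa_stack]{pa_stack}}.
#' @param roi an \code{\link{roi_mask}} aligned to the stack's (z, x) plane.
#' @return object of class \code{spectrum_measurement} with fields
#'   \code{wavelengths}, \code{mean}, \code{sd}, append-only normalization
#'   \code{state} (starting at \code{"raw"}) and normalization metadata.
#' @export
roi_spectrum <- function(stack, roi) {
  stopifnot(inherits(stack, "pa_stack"), inherits(roi, "roi_mask"))
  d <- dim(stack$amplitude)
  if (!identical(dim(roi$mask), c(d[3], d[4])))
    stop("roi shape does not match the stack image plane")
  idx <- which(roi$mask)
  nl <- d[1]; nf <- d[2]
  per_frame <- vapply(seq_len(nl), function(j)
    vapply(seq_len(nf), function(f) mean(stack$amplitude[j, f, , ][idx]), 0),
    numeric(nf))  # frames x lambda
  per_frame <- matrix(per_frame, nrow = nf)
  structure(list(wavelengths = stack$wavelengths,
                 mean = colMeans(per_frame),
                 sd = apply(per_frame, 2, stats::sd),
                 state = "raw",
                 meta = list(roi = roi$label, depth_mm = roi$depth_mm,
                             scene_id = stack$scene_id)),
            class = "spectrum_measurement")
}

#' @export
print.spectrum_measurement <- function(x, ...) {
  cat("<spectrum_measurement> ", length(x$wavelengths), " wavelengths (",
      min(x$wavelengths), "-", max(x$wavelengths), " nm); state: ",
      paste(x$state, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Isosbestic normalization
#'
#' Divides the spectrum by its amplitude at the isosbestic wavelength
#' (default 808 nm), which must be an exact member of the grid -- no
#' interpolation, to avoid silent shape distortion. The divisor is recorded
#' in the metadata so the unmixing design matrix can be transformed
#' identically. Idempotent.
#'
#' @param s a \code{spectrum_measurement}.
#' @param lambda_iso isosbestic wavelength, nm.
#' @return the normalized \code{spectrum_measurement}.
#' @export
isosbestic_normalize <- function(s, lambda_iso = 808) {
  stopifnot(inherits(s, "spectrum_measurement"))
  i <- match(lambda_iso, s$wavelengths)
  if (is.na(i))
    stop(lambda_iso, " nm is not a member of the measurement grid")
  div <- s$mean[i]
  if (!is.finite(div) || div <= 0)
    stop("non-positive amplitude at the isosbestic wavelength")
  s$mean <- s$mean / div
  s$sd <- s$sd / div
  s$state <- c(s$state, "isosbestic")
  s$meta$lambda_iso <- lambda_iso
  s$meta$iso_divisor <- if (is.null(s$meta$iso_divisor)) div
                        else s$meta$iso_divisor * div
  s
}

#' Fluence correction of a spectrum
#'
#' Divides the measured amplitudes by a per-wavelength local fluence,
#' removing (to the accuracy of the supplied fluence) the spectral coloring
#' of the overburden. Applied before isosbestic normalization in the
#' standard pipeline; the normalization state records the order.
#'
#' @param s a \code{spectrum_measurement}.
#' @param phi per-wavelength local fluence: numeric vector congruent with
#'   the grid (optionally named by wavelength), all > 0.
#' @param source label recorded in the metadata (e.g. "mc", "analytic_1d",
#'   "oracle", "perturbed").
#' @return the corrected \code{spectrum_measurement}.
#' @export
fluence_correct <- function(s, phi, source = "unspecified") {
  stopifnot(inherits(s, "spectrum_measurement"))
  if (length(phi) != length(s$wavelengths))
    stop("fluence vector not congruent with the wavelength grid")
  if (any(!is.finite(phi)) || any(phi <= 0))
    stop("non-positive fluence")
  if ("isosbestic" %in% s$state)
    warning("fluence correction applied after isosbestic normalization; ",
            "the standard pipeline corrects first")
  s$mean <- s$mean / phi
  s$sd <- s$sd / phi
  s$state <- c(s$state, "fluence_corrected")
  s$meta$fluence <- stats::setNames(phi, s$wavelengths)
  s$meta$fluence_source <- source
  s
}

#' Shape comparison against a reference absorption spectrum
#'
#' Scales both the measurement and a reference absorption spectrum to 1 at
#' the isosbestic wavelength so their shapes are comparable, and returns the
#' per-wavelength shape residual (measurement minus reference).
#'
#' @param s a \code{spectrum_measurement}.
#' @param mu_a_ref reference absorption spectrum on the same grid, cm^-1.
#' @param lambda_iso normalization wavelength, nm (grid member).
#' @return list with the scaled \code{measurement} and \code{reference}
#'   vectors and the \code{residual}.
#' @export
absorption_normalize_pair <- function(s, mu_a_ref, lambda_iso = 808) {
  stopifnot(inherits(s, "spectrum_measurement"),
            length(mu_a_ref) == length(s$wavelengths))
  i <- match(lambda_iso, s$wavelengths)
  if (is.na(i)) stop(lambda_iso, " nm is not a member of the grid")
  if (s$mean[i] <= 0 || mu_a_ref[i] <= 0)
    stop("non-positive amplitude at the isosbestic wavelength")
  m <- s$mean / s$mean[i]
  r <- mu_a_ref / mu_a_ref[i]
  list(measurement = m, reference = r, residual = m - r,
       wavelengths = s$wavelengths)
}
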