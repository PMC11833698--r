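#' Packaged chromophore spectra
#'
#' Loads the tabulated chromophore spectra shipped with the package: molar
#' extinction of oxy- and deoxyhemoglobin (cm^-1 M^-1) and absorption of pure
#' water and pure lipid (cm^-1), all on a common 650-1800 nm grid. Below
#' 1000 nm the hemoglobin values follow the usual compiled pure-hemoglobin
#' scale; above 1000 nm they are effective whole-blood values, i.e. the water
#' content of whole blood is folded into the per-hemoglobin extinction so
#' that \code{mu_a(blood) = log(10) * eps * c_tHb} holds across the full
#' range (see the methods vignette).
#'
#' @param path directory containing the spectra CSVs; defaults to the copies
#'   installed with the package.
#' @return An object of class \code{extinction_table}: a list with the node
#'   grid \code{wavelength_nm}, one numeric spectrum per chromophore
#'   (\code{HbO2}, \code{Hb}, \code{water}, \code{lipid}) and a provenance
#'   string per chromophore.
#' @export
extinction_table <- function(path = system.file("extdata", package = "paoxy")) {
  read1 <- function(file) {
    f <- file.path(path, file)
    lines <- readLines(f)
    prov <- paste(sub("^# ?", "", grep("^#", lines, value = TRUE)),
                  collapse = " ")
    df <- utils::read.csv(f, comment.char = "#")
    list(df = df, prov = prov)
  }
  hb <- read1("hemoglobin_extinction.csv")
  wa <- read1("water_absorption.csv")
  li <- read1("lipid_absorption.csv")
  wl <- hb$df$wavelength_nm
  stopifnot(identical(wl, wa$df$wavelength_nm),
            identical(wl, li$df$wavelength_nm),
            !is.unsorted(wl, strictly = TRUE))
  tab <- structure(list(
    wavelength_nm = wl,
    HbO2  = hb$df$eps_HbO2_cm1M1,
    Hb    = hb$df$eps_Hb_cm1M1,
    water = wa$df$mu_a_cm1,
    lipid = li$df$mu_a_cm1,
    provenance = c(HbO2 = hb$prov, Hb = hb$prov,
                   water = wa$prov, lipid = li$prov)
  ), class = "extinction_table")
  for (ch in c("HbO2", "Hb", "water", "lipid"))
    if (any(tab[[ch]] <= 0)) stop("non-positive value in packaged spectrum ", ch)
  tab
}

the_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- extinction_table()
    cache
  }
})

#' @export
print.extinction_table <- function(x, ...) {
  cat("<extinction_table> ", length(x$wavelength_nm), " nodes, ",
      min(x$wavelength_nm), "-", max(x$wavelength_nm), " nm; chromophores: ",
      paste(c("HbO2", "Hb", "water", "lipid"), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Validate a wavelength grid
#'
#' @param wavelengths numeric vector of wavelengths (nm), strictly increasing
#'   and inside the packaged table range.
#' @param table an \code{\link{extinction_table}}.
#' @return the validated numeric vector, classed \code{wavelength_grid}.
#' @export
wavelength_grid <- function(wavelengths, table = the_table()) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 1L || anyNA(wavelengths))
    stop("wavelength grid must be non-empty and finite")
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelength grid must be strictly increasing")
  rng <- range(table$wavelength_nm)
  if (any(wavelengths < rng[1] | wavelengths > rng[2]))
    stop("wavelengths outside the packaged table range (",
         rng[1], "-", rng[2], " nm)")
  structure(wavelengths, class = "wavelength_grid")
}

#' Interpolated chromophore extinction/absorption
#'
#' Piecewise-linear interpolation between the packaged table nodes, exact at
#' the nodes. No extrapolation: wavelengths outside the table range are an
#' error.
#'
#' @param chromophore one of \code{"HbO2"}, \code{"Hb"}, \code{"water"},
#'   \code{"lipid"}.
#' @param lambda wavelength(s), nm.
#' @param table an \code{\link{extinction_table}}.
#' @return numeric vector; cm^-1 M^-1 for hemoglobin, cm^-1 for water/lipid.
#' @export
extinction <- function(chromophore, lambda, table = the_table()) {
  chromophore <- match.arg(chromophore, c("HbO2", "Hb", "water", "lipid"))
  rng <- range(table$wavelength_nm)
  if (any(lambda < rng[1] | lambda > rng[2]))
    stop("lambda outside table range (", rng[1], "-", rng[2], " nm)")
  stats::approx(table$wavelength_nm, table[[chromophore]], xout = lambda,
                method = "linear", rule = 1)$y
}

#' Tissue optical-property specification
#'
#' A named tissue class with chromophore composition and a reduced-scattering
#' power law mu_s'(lambda) = a * (lambda/500 nm)^(-b).
#'
#' @param name tissue class label.
#' @param f_water,f_lipid volume fractions in [0, 1].
#' @param c_HbO2_M,c_Hb_M hemoglobin concentrations, mol/L (>= 0).
#' @param musp_a reduced scattering at the 500 nm reference, cm^-1 (>= 0).
#' @param musp_b scattering power-law exponent.
#' @param g scattering anisotropy in [-1, 1].
#' @param n refractive index (>= 1).
#' @return object of class \code{tissue_spec}.
#' @export
tissue_spec <- function(name, f_water = 0, f_lipid = 0,
                        c_HbO2_M = 0, c_Hb_M = 0,
                        musp_a = 0, musp_b = 0, g = 0.9, n = 1.37) {
  if (f_water < 0 || f_water > 1 || f_lipid < 0 || f_lipid > 1)
    stop("volume fractions must be in [0, 1]")
  if (c_HbO2_M < 0 || c_Hb_M < 0) stop("negative concentrations rejected")
  if (musp_a < 0) stop("musp_a must be >= 0")
  if (g < -1 || g > 1) stop("g must be in [-1, 1]")
  if (n < 1) stop("n must be >= 1")
  structure(list(name = name, f_water = f_water, f_lipid = f_lipid,
                 c_HbO2_M = c_HbO2_M, c_Hb_M = c_Hb_M,
                 musp_a = musp_a, musp_b = musp_b, g = g, n = n),
            class = "tissue_spec")
}

#' Packaged tissue library
#'
#' Reads the YAML tissue library shipped with the package (gelatin,
#' porcine_muscle, skin, fat, kidney, blood, PBS, tube_wall). The porcine
#' entry is calibrated so that its NIR-I mean total attenuation is about
#' 50 cm^-1 and its NIR-II mean is below 10 cm^-1.
#'
#' @param file YAML file; defaults to the packaged library.
#' @return named list of \code{\link{tissue_spec}} objects.
#' @export
tissue_library <- function(file = system.file("extdata", "tissues.yaml",
                                              package = "paoxy")) {
  raw <- yaml::read_yaml(file)
  out <- lapply(names(raw), function(nm) do.call(tissue_spec, c(list(name = nm), raw[[nm]])))
  names(out) <- names(raw)
  out
}

#' Absorption coefficient of a tissue spec
#'
#' mu_a = ln(10) * (eps_HbO2 * c_HbO2 + eps_Hb * c_Hb)
#'        + f_water * mu_a,water(lambda) + f_lipid * mu_a,lipid(lambda).
#'
#' @param spec a \code{\link{tissue_spec}}.
#' @param lambda wavelength(s), nm.
#' @param table an \code{\link{extinction_table}}.
#' @return mu_a, cm^-1.
#' @export
mu_a_from_spec <- function(spec, lambda, table = the_table()) {
  stopifnot(inherits(spec, "tissue_spec"))
  if (spec$c_HbO2_M < 0 || spec$c_Hb_M < 0)
    stop("negative concentrations rejected")
  hb <- if (spec$c_HbO2_M > 0 || spec$c_Hb_M > 0)
    log(10) * (extinction("HbO2", lambda, table) * spec$c_HbO2_M +
               extinction("Hb", lambda, table) * spec$c_Hb_M)
  else rep(0, length(lambda))
  wa <- if (spec$f_water > 0) spec$f_water * extinction("water", lambda, table)
        else rep(0, length(lambda))
  li <- if (spec$f_lipid > 0) spec$f_lipid * extinction("lipid", lambda, table)
        else rep(0, length(lambda))
  hb + wa + li
}

#' Reduced and unreduced scattering of a tissue spec
#'
#' mu_s'(lambda) = a * (lambda/500)^(-b); mu_s = mu_s' / (1 - g).
#'
#' @inheritParams mu_a_from_spec
#' @return \code{reduced_scattering}: mu_s' (cm^-1); \code{mu_s_from_spec}:
#'   mu_s (cm^-1).
#' @export
reduced_scattering <- function(spec, lambda) {
  stopifnot(inherits(spec, "tissue_spec"))
  spec$musp_a * (lambda / 500)^(-spec$musp_b)
}

#' @rdname reduced_scattering
#' @export
mu_s_from_spec <- function(spec, lambda) {
  if (spec$g >= 1) stop("degenerate anisotropy: g = 1")
  reduced_scattering(spec, lambda) / (1 - spec$g)
}

#' Total attenuation mu_a + mu_s'
#'
#' @inheritParams mu_a_from_spec
#' @return cm^-1.
#' @export
total_attenuation <- function(spec, lambda, table = the_table()) {
  mu_a_from_spec(spec, lambda, table) + reduced_scattering(spec, lambda)
}

#' Optical properties of a tissue spec at one wavelength
#'
#' @inheritParams mu_a_from_spec
#' @return list with mu_a, mu_s (both cm^-1), g, n.
#' @export
tissue_properties <- function(spec, lambda, table = the_table()) {
  structure(list(mu_a = mu_a_from_spec(spec, lambda, table),
                 mu_s = mu_s_from_spec(spec, lambda),
                 g = spec$g, n = spec$n),
            class = "tissue_optical_properties")
}

#' Maximum permissible single-pulse skin exposure
#'
#' ANSI-style nanosecond-pulse skin limit: 20 mJ/cm^2 for 400-700 nm, rising
#' as 20 * 10^(0.002 (lambda - 700)) mJ/cm^2 beyond 700 nm, and capped at
#' the 100 mJ/cm^2 plateau that applies through 1400 nm (the cap keeps the
#' rule continuous and non-decreasing; the exponential branch reaches it
#' just below 1050 nm). Repetitive-pulse and extended-exposure corrections
#' are out of scope.
#'
#' @param lambda wavelength(s) in nm, 400-1400.
#' @return mJ/cm^2.
#' @export
mpe_skin <- function(lambda) {
  if (any(lambda < 400 | lambda > 1400))
    stop("mpe_skin supports 400-1400 nm only")
  ifelse(lambda <= 700, 20,
         pmin(100, 20 * 10^(0.002 * (lambda - 700))))
}

#' Locate the hemoglobin isosbestic point
#'
#' Finds the root of the linearly interpolated eps_HbO2 - eps_Hb difference
#' inside a window. The window must contain exactly one sign change of the
#' difference at the table nodes; zero or multiple crossings are an
#' ambiguity error. Diagnostic only: pipeline normalizations use the
#' configured 808 nm regardless of where the packaged table crosses.
#'
#' @param table an \code{\link{extinction_table}}.
#' @param window length-2 numeric, nm.
#' @return crossing wavelength, nm.
#' @export
find_isosbestic <- function(table = the_table(), window = c(750, 850)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  rng <- range(table$wavelength_nm)
  if (window[1] < rng[1] || window[2] > rng[2])
    stop("window outside table range")
  keep <- table$wavelength_nm >= window[1] & table$wavelength_nm <= window[2]
  wl <- table$wavelength_nm[keep]
  d <- table$HbO2[keep] - table$Hb[keep]
  if (any(d == 0)) return(wl[which(d == 0)[1]])
  flips <- which(diff(sign(d)) != 0)
  if (length(flips) != 1L)
    stop("ambiguous isosbestic search: ", length(flips),
         " sign changes in window")
  i <- flips[1]
  wl[i] + (wl[i + 1] - wl[i]) * (0 - d[i]) / (d[i + 1] - d[i])
}
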