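#' Wavelength sets for unmixing
#'
#' A named set of at least two wavelengths inside the packaged table range.
#' The built-ins are \code{NIR1} = \{690, 808, 950\} nm and \code{NIR2} =
#' \{1064, 1230\} nm.
#'
#' @param wavelengths member wavelengths, nm.
#' @param name set label.
#' @param table an \code{\link{extinction_table}}.
#' @return object of class \code{wavelength_set}.
#' @export
wavelength_set <- function(wavelengths, name = "custom",
                           table = the_table()) {
  if (length(wavelengths) < 2) stop("a wavelength set needs >= 2 members")
  structure(list(wavelengths = as.numeric(wavelength_grid(sort(wavelengths),
                                                          table)),
                 name = name),
            class = "wavelength_set")
}

#' @rdname wavelength_set
#' @export
nir1_set <- function() wavelength_set(c(690, 808, 950), "NIR1")

#' @rdname wavelength_set
#' @export
nir2_set <- function() wavelength_set(c(1064, 1230), "NIR2")

#' Unmixing design matrix
#'
#' Builds the n_lambda x 2 matrix with rows
#' [eps_HbO2(lambda) phi(lambda), eps_Hb(lambda) phi(lambda)], then applies
#' exactly the normalization recorded for the measurement so model and data
#' are commensurate. For isosbestic-normalized measurements each column is
#' divided by its own value at lambda_iso (computed from the table and
#' phi(lambda_iso), so lambda_iso need not belong to the set -- the NIR-II
#' case); the divisors are attached as \code{attr(, "col_scale")} and undone
#' by \code{\link{linear_unmix}} before saturation is computed.
#'
#' @param set a \code{\link{wavelength_set}}.
#' @param table an \code{\link{extinction_table}}.
#' @param phi per-wavelength fluence: NULL (flat), a function of wavelength,
#'   or a numeric vector named by wavelength covering the set (and
#'   lambda_iso when isosbestic normalization is requested).
#' @param normalization NULL, or a list with \code{lambda_iso} indicating the
#'   measurement was isosbestic-normalized.
#' @return the design matrix with columns \code{HbO2}, \code{Hb}.
#' @export
design_matrix <- function(set, table = the_table(), phi = NULL,
                          normalization = NULL) {
  stopifnot(inherits(set, "wavelength_set"))
  wl <- set$wavelengths
  phi_at <- function(l) {
    if (is.null(phi)) return(rep(1, length(l)))
    if (is.function(phi)) return(phi(l))
    v <- phi[as.character(l)]
    if (anyNA(v)) stop("fluence not supplied at ", paste(l[is.na(v)],
                                                         collapse = ", "),
                       " nm")
    as.numeric(v)
  }
  pv <- phi_at(wl)
  if (any(pv <= 0)) stop("non-positive fluence")
  A <- cbind(HbO2 = extinction("HbO2", wl, table) * pv,
             Hb = extinction("Hb", wl, table) * pv)
  rownames(A) <- wl
  col_scale <- c(HbO2 = 1, Hb = 1)
  if (!is.null(normalization) && !is.null(normalization$lambda_iso)) {
    li <- normalization$lambda_iso
    p_iso <- phi_at(li)
    if (p_iso <= 0) stop("non-positive fluence at lambda_iso")
    col_scale <- c(HbO2 = extinction("HbO2", li, table) * p_iso,
                   Hb = extinction("Hb", li, table) * p_iso)
    A <- sweep(A, 2, col_scale, "/")
  }
  attr(A, "col_scale") <- col_scale
  A
}

#' Oxygen saturation from concentrations
#'
#' sO2 = c_HbO2 / (c_HbO2 + c_Hb). A zero (or non-positive) total
#' concentration has no defined saturation and raises a classed error
#' (\code{paoxy_undefined_so2}) rather than returning 0.
#'
#' @param c_HbO2,c_Hb chromophore concentrations (any common unit).
#' @return saturation fraction.
#' @export
compute_so2 <- function(c_HbO2, c_Hb) {
  tot <- c_HbO2 + c_Hb
  if (any(tot <= 0))
    stop(errorCondition("sO2 undefined: total hemoglobin is not positive",
                        class = "paoxy_undefined_so2"))
  c_HbO2 / tot
}

# exact nonnegative least squares for a 2-column design: enumerate the four
# active sets and keep the feasible solution with the smallest residual
nnls2 <- function(A, m) {
  best <- NULL
  cand <- list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE),
               c(FALSE, FALSE))
  for (act in cand) {
    c_hat <- c(0, 0)
    if (any(act)) {
      Aa <- A[, act, drop = FALSE]
      fit <- tryCatch(qr.solve(qr(Aa), m), error = function(e) NULL)
      if (is.null(fit)) next
      c_hat[act] <- fit
    }
    if (any(c_hat < -1e-12)) next
    c_hat <- pmax(c_hat, 0)
    rss <- sum((m - A %*% c_hat)^2)
    if (is.null(best) || rss < best$rss - 1e-15)
      best <- list(c = c_hat, rss = rss)
  }
  best
}

#' Linear spectral unmixing of a measured spectrum
#'
#' Least-squares estimation of relative oxy- and deoxyhemoglobin
#' concentrations from a multi-wavelength measurement, followed by the
#' saturation ratio. The Grueneisen factor and any surface-fluence scale are
#' absorbed into the arbitrary concentration units (saturation is scale
#' invariant). The default solver constrains concentrations to be
#' nonnegative; the ordinary solver reports unconstrained estimates with the
#' saturation clamped to [0, 1] and the clamp flagged (unclamped saturation
#' retained as \code{so2_unclamped}).
#'
#' @param s a \code{spectrum_measurement} covering the set.
#' @param set a \code{\link{wavelength_set}}.
#' @param table an \code{\link{extinction_table}}.
#' @param phi fluence assumption for the design matrix (see
#'   \code{\link{design_matrix}}); use NULL for flat (e.g. when the
#'   measurement is already fluence-corrected).
#' @param solver \code{"nnls"} (default) or \code{"ols"}.
#' @return object of class \code{unmixing_result}: \code{c_HbO2},
#'   \code{c_Hb} (relative units), \code{so2}, \code{residual_norm},
#'   \code{condition_number}, set and fluence-assumption labels, flags.
#' @export
linear_unmix <- function(s, set, table = the_table(), phi = NULL,
                         solver = c("nnls", "ols")) {
  solver <- match.arg(solver)
  stopifnot(inherits(s, "spectrum_measurement"),
            inherits(set, "wavelength_set"))
  idx <- match(set$wavelengths, s$wavelengths)
  if (anyNA(idx))
    stop("measurement does not cover the wavelength set")
  m <- s$mean[idx]
  if (all(m == 0)) stop("all-zero spectrum")
  norm_meta <- if ("isosbestic" %in% s$state)
    list(lambda_iso = s$meta$lambda_iso) else NULL
  A <- design_matrix(set, table, phi, norm_meta)
  kappa_A <- kappa(A, exact = TRUE)
  if (!is.finite(kappa_A) || kappa_A > 1e12)
    stop("rank-deficient design matrix")
  clamped <- FALSE
  so2_unclamped <- NA_real_
  if (solver == "nnls") {
    fit <- nnls2(A, m)
    c_hat <- fit$c
  } else {
    c_hat <- as.numeric(qr.solve(qr(A), m))
  }
  resid <- sqrt(sum((m - A %*% c_hat)^2))
  # undo the column normalization so concentrations are commensurate
  c_phys <- unname(c_hat / attr(A, "col_scale"))
  so2 <- tryCatch(compute_so2(c_phys[1], c_phys[2]),
                  paoxy_undefined_so2 = function(e) NA_real_)
  if (solver == "ols" && !is.na(so2)) {
    so2_unclamped <- so2
    if (so2 < 0 || so2 > 1) {
      so2 <- min(1, max(0, so2))
      clamped <- TRUE
    }
  }
  exact_system <- nrow(A) == ncol(A)
  structure(list(c_HbO2 = c_phys[1], c_Hb = c_phys[2], so2 = so2,
                 so2_unclamped = so2_unclamped, clamped = clamped,
                 residual_norm = if (exact_system) NA_real_ else resid,
                 condition_number = kappa_A, set = set$name,
                 solver = solver,
                 fluence_assumption = if (is.null(phi)) "flat" else "supplied",
                 degenerate = is.na(so2)),
            class = "unmixing_result")
}

#' @export
print.unmixing_result <- function(x, ...) {
  cat("<unmixing_result> set ", x$set, " (", x$solver, "): sO2 = ",
      if (is.na(x$so2)) "undefined" else sprintf("%.4f", x$so2),
      if (isTRUE(x$clamped)) " (clamped)" else "", "\n", sep = "")
  invisible(x)
}

#' Pixelwise unmixing of an image stack
#'
#' Applies \code{\link{linear_unmix}} to every pixel of the frame-averaged
#' stack. Pixels whose saturation is undefined (no hemoglobin signal) are
#' returned as NA and flagged in the mask, not as 0.
#'
#' @param stack a \code{pa_stack}.
#' @param set a \code{\link{wavelength_set}}.
#' @param table an \code{\link{extinction_table}}.
#' @param phi_map \code{NULL} for a flat fluence assumption, or
#'   \code{"oracle"} to use the stack's own per-pixel forward fluence.
#' @param solver passed to the per-pixel solve.
#' @param min_amplitude pixels whose peak frame-averaged amplitude across the
#'   set falls at or below this are masked as undefined.
#' @return list of matrices (z, x): \code{so2}, \code{c_HbO2}, \code{c_Hb},
#'   logical \code{defined}.
#' @export
unmix_image <- function(stack, set, table = the_table(), phi_map = NULL,
                        solver = c("nnls", "ols"), min_amplitude = 0) {
  solver <- match.arg(solver)
  stopifnot(inherits(stack, "pa_stack"))
  idx <- match(set$wavelengths, stack$wavelengths)
  if (anyNA(idx)) stop("stack does not cover the wavelength set")
  d <- dim(stack$amplitude)
  avg <- apply(stack$amplitude[idx, , , , drop = FALSE], c(1, 3, 4), mean)
  use_oracle <- identical(phi_map, "oracle")
  if (!is.null(phi_map) && !use_oracle)
    stop("phi_map must be NULL or \"oracle\"")
  A_flat <- design_matrix(set, table)
  nz <- d[3]; nx <- d[4]
  so2 <- matrix(NA_real_, nz, nx)
  c1 <- matrix(NA_real_, nz, nx)
  c2 <- matrix(NA_real_, nz, nx)
  for (i in seq_len(nz)) for (k in seq_len(nx)) {
    m <- avg[, i, k]
    if (max(m) <= min_amplitude) next
    A <- if (use_oracle) {
      p <- stack$phi[idx, i, k]
      if (any(p <= 0)) next
      A_flat * p
    } else A_flat
    fit <- if (solver == "nnls") nnls2(A, m)$c
           else as.numeric(qr.solve(qr(A), m))
    tot <- fit[1] + fit[2]
    if (tot <= 0) next
    c1[i, k] <- fit[1]; c2[i, k] <- fit[2]
    s <- fit[1] / tot
    so2[i, k] <- if (solver == "ols") min(1, max(0, s)) else s
  }
  list(so2 = so2, c_HbO2 = c1, c_Hb = c2, defined = !is.na(so2))
}
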