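#' Total absolute saturation error
#'
#' The study's headline metric: the linear sum of absolute errors in
#' estimated saturation of the oxygenated and deoxygenated conditions,
#' in percent. An undefined estimate propagates as NA, never as 0.
#'
#' @param est length-2 numeric: estimated sO2 (oxygenated, deoxygenated).
#' @param truth length-2 numeric: true (probe) sO2 for the same conditions.
#' @return percent error (can exceed 100 for unclamped estimates).
#' @export
total_absolute_error <- function(est, truth) {
  stopifnot(length(est) == 2, length(truth) == 2)
  if (anyNA(est) || anyNA(truth)) return(NA_real_)
  100 * (abs(est[1] - truth[1]) + abs(est[2] - truth[2]))
}

#' Percent error reduction
#'
#' 100 * (err_nir1 - err_nir2) / err_nir1; negative when the second set is
#' worse.
#'
#' @param err_nir1,err_nir2 total absolute errors, percent.
#' @return percent reduction.
#' @export
error_reduction <- function(err_nir1, err_nir2) {
  if (any(err_nir1 <= 0)) stop("err_nir1 must be > 0")
  100 * (err_nir1 - err_nir2) / err_nir1
}

#' One-way ANOVA on error groups
#'
#' Classical equal-variance one-way ANOVA via \code{stats::oneway.test}.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return list with \code{F}, \code{p}, \code{df}.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, 0L) < 2)) stop("each group needs >= 2 values")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 0L)))
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value),
       df = unname(ft$parameter))
}

#' Experiment configuration
#'
#' Settings shared by the phantom and depth experiments. The acquisition
#' grids follow the imaging protocol: NIR-I 690-950 nm at 20-nm increments
#' plus the 808 nm isosbestic wavelength; NIR-II 1064 nm plus 1200-1400 nm
#' (phantom) or 1200-1300 nm (in vivo) at 10-nm increments.
#'
#' @param replicates independently prepared phantoms / animals (default 3).
#' @param seed global seed; all substreams derive from it.
#' @param fluence_correction \code{"perturbed"} (default: correction fluence
#'   computed with overburden mu_a and mu_s' mis-specified),
#'   \code{"oracle"} (the forward model's own fluence) or \code{"flat"} (no
#'   correction -- the maximal-coloring stress test).
#' @param perturbation fractional mis-specification of the assumed optical
#'   properties (default 0.25; the sign of the mu_a and mu_s' factors is
#'   drawn independently per replicate).
#' @param noise_sd,frames forwarded to \code{\link{forward_config}}.
#' @param fluence_mode forward fluence: \code{"mc"} (default; the transport
#'   model that resolves scattering-driven coloring in the high-albedo
#'   slab) or \code{"analytic_1d"} (fast diffusion surrogate for quick
#'   looks; it understates first-window coloring -- see the methods
#'   vignette). In MC mode the acquisition grid is restricted to the
#'   unmixing wavelengths plus 808 nm to keep runtimes at desk scale.
#' @param solver unmixing solver.
#' @param jitter_frac inter-replicate variability fraction (default 0.05).
#' @param mccfg \code{\link{mc_config}} for \code{"mc"} mode.
#' @return object of class \code{experiment_config}.
#' @export
experiment_config <- function(replicates = 3, seed = 1L,
                              fluence_correction = c("perturbed", "oracle",
                                                     "flat"),
                              perturbation = 0.25, noise_sd = 0.05,
                              frames = 5L,
                              fluence_mode = c("mc", "analytic_1d"),
                              solver = c("nnls", "ols"),
                              jitter_frac = 0.05, mccfg = mc_config()) {
  stopifnot(replicates >= 1, perturbation >= 0)
  structure(list(replicates = as.integer(replicates), seed = as.integer(seed),
                 fluence_correction = match.arg(fluence_correction),
                 perturbation = perturbation, noise_sd = noise_sd,
                 frames = as.integer(frames),
                 fluence_mode = match.arg(fluence_mode),
                 solver = match.arg(solver), jitter_frac = jitter_frac,
                 mccfg = mccfg),
            class = "experiment_config")
}

#' Acquisition wavelength grids
#'
#' \code{phantom_grid}: NIR-I 690-950 nm at 20-nm increments plus 808 nm,
#' and NIR-II 1064 plus 1200-1400 nm at 10-nm increments (the phantom
#' protocol). \code{invivo_grid}: the same but with NIR-II stopping at
#' 1300 nm (the in vivo protocol).
#'
#' @return a \code{\link{wavelength_grid}}.
#' @export
phantom_grid <- function() {
  wavelength_grid(sort(unique(c(seq(690, 950, by = 20), 808, 1064,
                                seq(1200, 1400, by = 10)))))
}

#' @rdname phantom_grid
#' @export
invivo_grid <- function() {
  wavelength_grid(sort(unique(c(seq(690, 950, by = 20), 808, 1064,
                                seq(1200, 1300, by = 10)))))
}

# multiply the overburden tissues' absorbers and scattering amplitude by
# fixed factors (the "assumed" optical properties used for fluence
# correction); the target's own tissue (labels in `skip`) is left at truth
perturb_phantom <- function(phantom, f_mua, f_musp, skip = integer()) {
  for (i in seq_along(phantom$tissues)) {
    if (i %in% skip) next
    sp <- phantom$tissues[[i]]
    sp$f_water <- min(1, sp$f_water * f_mua)
    sp$f_lipid <- min(1, sp$f_lipid * f_mua)
    sp$c_HbO2_M <- sp$c_HbO2_M * f_mua
    sp$c_Hb_M <- sp$c_Hb_M * f_mua
    sp$musp_a <- sp$musp_a * f_musp
    phantom$tissues[[i]] <- sp
  }
  phantom
}

# ROI-mean normalized fluence per wavelength on the stack's image plane
roi_phi <- function(stack, roi) {
  idx <- which(roi$mask)
  vapply(seq_along(stack$wavelengths), function(j)
    mean(stack$phi[j, , ][idx]), 0)
}

# assumed correction fluence: fluence maps recomputed on the (possibly
# perturbed) phantom with the same model and, in MC mode, the same RNG
# substreams as the forward simulation (common random numbers, so the
# correction residual reflects the property mismatch, not MC noise),
# averaged over the same roi pixels
assumed_phi <- function(phantom, roi, wavelengths, table, beam,
                        mode = "analytic_1d", mccfg = mc_config(),
                        halfwidth_mm = 1) {
  d <- dim(phantom$labels)
  iys <- which(abs((seq_len(d[2]) - 0.5) - d[2] / 2) * phantom$voxel_mm <=
                 halfwidth_mm)
  if (length(iys) == 0) iys <- ceiling(d[2] / 2)
  idx <- which(roi$mask)
  vapply(wavelengths, function(l) {
    map <- if (mode == "mc") {
      cfg_l <- mccfg
      cfg_l$seed <- stream_seed(mccfg$seed, paste0("mc", l))
      simulate_fluence(phantom, beam, l, cfg_l, table)
    } else analytic_fluence_map(phantom, l, table)
    plane <- apply(map$phi_track[, iys, , drop = FALSE], c(1, 3), mean)
    mean(t(plane)[idx])
  }, 0)
}

preprocess_spectrum <- function(stack, roi, scene, cfg, rep_seed,
                                region = names(scene$regions)[1],
                                table = the_table()) {
  s <- roi_spectrum(stack, roi)
  if (cfg$fluence_correction == "oracle") {
    s <- fluence_correct(s, roi_phi(stack, roi), source = "oracle")
  } else if (cfg$fluence_correction == "perturbed") {
    set.seed(stream_seed(rep_seed, "perturbation"))
    f_mua <- 1 + cfg$perturbation * sample(c(-1, 1), 1)
    f_musp <- 1 + cfg$perturbation * sample(c(-1, 1), 1)
    target <- unique(scene$phantom$labels[scene$regions[[region]]$mask])
    assumed <- perturb_phantom(scene$phantom, f_mua, f_musp, skip = target)
    phi <- assumed_phi(assumed, roi, s$wavelengths, table, beam = stack$beam,
                       mode = stack$fluence_mode, mccfg = cfg$mccfg,
                       halfwidth_mm = stack$plane_halfwidth_mm)
    s <- fluence_correct(s, phi, source = "perturbed")
  }
  isosbestic_normalize(s, 808)
}

#' Phantom wavelength-set comparison experiment
#'
#' Runs the synthetic analogue of the blood-tube phantom study: for each
#' replicate, oxygenated (sO2 = 1) and deoxygenated (sO2 = 0) tube stacks
#' are generated (25 mJ/cm^2 surface fluence, 0.5 cm beam), tube-lumen
#' spectra extracted, fluence-corrected per the configured mode,
#' isosbestic-normalized at 808 nm, and unmixed with the NIR-I and NIR-II
#' sets. Reports per-replicate total absolute errors, summary statistics,
#' the percent error reduction of NIR-II versus NIR-I, and a one-way ANOVA
#' across sets. Deterministic given the config (including its seed).
#'
#' @param cfg an \code{\link{experiment_config}}.
#' @param table an \code{\link{extinction_table}}.
#' @return object of class \code{error_report}.
#' @export
run_phantom_experiment <- function(cfg = experiment_config(),
                                   table = the_table()) {
  grid <- if (cfg$fluence_mode == "mc")
    wavelength_grid(c(690, 808, 950, 1064, 1230)) else phantom_grid()
  beam <- beam_spec(0.5, 25)
  sweep <- so2_sweep_dataset(so2_levels = c(1, 0),
                             replicates = cfg$replicates, seed = cfg$seed,
                             jitter_frac = cfg$jitter_frac, grid = grid,
                             beam = beam,
                             fcfg = forward_config(noise_sd = cfg$noise_sd,
                                                   frames = cfg$frames),
                             mccfg = cfg$mccfg,
                             fluence_mode = cfg$fluence_mode, table = table)
  sets <- list(NIR1 = nir1_set(), NIR2 = nir2_set())
  rows <- list()
  for (r in seq_along(sweep)) {
    rep <- sweep[[r]]
    est <- lapply(c("so2_1", "so2_0"), function(lv) {
      roi <- scene_roi(rep[[lv]]$scene, "tube_lumen")
      s <- preprocess_spectrum(rep[[lv]]$stack, roi, rep[[lv]]$scene, cfg,
                               rep$seed, region = "tube_lumen", table = table)
      lapply(sets, function(st)
        linear_unmix(s, st, table, solver = cfg$solver))
    })
    for (nm in names(sets)) {
      e_oxy <- est[[1]][[nm]]$so2
      e_deo <- est[[2]][[nm]]$so2
      rows[[length(rows) + 1]] <- data.frame(
        set = nm, replicate = r, seed = rep$seed,
        so2_oxy_est = e_oxy, so2_deoxy_est = e_deo,
        so2_oxy_true = 1, so2_deoxy_true = 0,
        error_pct = total_absolute_error(c(e_oxy, e_deo), c(1, 0)))
    }
  }
  finish_report(do.call(rbind, rows), cfg, experiment = "phantom")
}

finish_report <- function(tab, cfg, experiment) {
  by_set <- split(tab$error_pct, tab$set)
  summ <- do.call(rbind, lapply(names(by_set), function(nm) {
    v <- by_set[[nm]]
    data.frame(set = nm, mean = mean(v, na.rm = TRUE),
               q25 = unname(stats::quantile(v, .25, na.rm = TRUE)),
               q75 = unname(stats::quantile(v, .75, na.rm = TRUE)),
               n = sum(!is.na(v)))
  }))
  red <- if (all(c("NIR1", "NIR2") %in% summ$set) &&
             summ$mean[summ$set == "NIR1"] > 0)
    error_reduction(summ$mean[summ$set == "NIR1"],
                    summ$mean[summ$set == "NIR2"]) else NA_real_
  an <- tryCatch(one_way_anova(by_set), error = function(e) NULL)
  structure(list(experiment = experiment, table = tab, summary = summ,
                 error_reduction_pct = red, anova = an, config = cfg),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat("<error_report> ", x$experiment, " experiment, ",
      x$config$replicates, " replicates, fluence correction: ",
      x$config$fluence_correction, "\n", sep = "")
  print(x$summary, row.names = FALSE)
  if (!is.na(x$error_reduction_pct))
    cat(sprintf("NIR-II vs NIR-I error reduction: %.1f%%\n",
                x$error_reduction_pct))
  invisible(x)
}

#' Depth-stratified in vivo emulation
#'
#' Runs the synthetic analogue of the rat-kidney study: layered abdomen
#' scenes pre-euthanasia (kidney sO2 = 1, the probe condition) and
#' post-euthanasia (sO2 = 0) at 5.5 mJ/cm^2 with a 1.3 cm beam, kidney
#' regions at three depths, unmixed with both wavelength sets. Per-region
#' total absolute errors, a monotone-depth summary, and per-region ANOVA
#' across sets (the shallowest region is flagged as underpowered and
#' excluded from significance testing). A hemoglobin-bleached kidney is
#' generated alongside and its degenerate unmixing excluded from the error
#' statistics (reported separately).
#'
#' @inheritParams run_phantom_experiment
#' @return an \code{error_report}; the per-region table carries a
#'   \code{roi} column, and \code{$bleached} records the flagged bleached
#'   result.
#' @export
run_depth_experiment <- function(cfg = experiment_config(),
                                 table = the_table()) {
  grid <- if (cfg$fluence_mode == "mc")
    wavelength_grid(c(690, 808, 950, 1064, 1230)) else invivo_grid()
  beam <- beam_spec(1.3, 5.5)
  sets <- list(NIR1 = nir1_set(), NIR2 = nir2_set())
  rows <- list()
  bleached_flags <- list()
  for (r in seq_len(cfg$replicates)) {
    rep_seed <- stream_seed(cfg$seed, paste0("animal", r))
    set.seed(stream_seed(rep_seed, "jitter"))
    skin <- 1 * (1 + stats::rnorm(1, 0, cfg$jitter_frac))
    fat <- 3 * (1 + stats::rnorm(1, 0, cfg$jitter_frac))
    bvf <- 0.2 * (1 + stats::rnorm(1, 0, cfg$jitter_frac))
    conditions <- list(so2_1 = 1, so2_0 = 0)
    scenes <- lapply(conditions, function(s)
      build_abdomen_phantom(s, skin_mm = skin, fat_mm = fat,
                            blood_volume_fraction = bvf, tissues = tissue_library()))
    stacks <- lapply(names(scenes), function(lv) {
      fc <- forward_config(noise_sd = cfg$noise_sd, frames = cfg$frames,
                           seed = stream_seed(rep_seed, paste0("noise", lv)))
      simulate_pa_stack(scenes[[lv]]$scene, grid, beam, fc, cfg$mccfg,
                        cfg$fluence_mode, table = table)
    })
    names(stacks) <- names(scenes)
    for (roi_nm in names(scenes$so2_1$scene$regions)) {
      ests <- lapply(names(scenes), function(lv) {
        roi <- scene_roi(scenes[[lv]]$scene, roi_nm)
        s <- preprocess_spectrum(stacks[[lv]], roi, scenes[[lv]]$scene, cfg,
                                 rep_seed, region = roi_nm, table = table)
        lapply(sets, function(st)
          linear_unmix(s, st, table, solver = cfg$solver))
      })
      names(ests) <- names(scenes)
      depth <- scenes$so2_1$scene$regions[[roi_nm]]$depth_mm
      for (nm in names(sets)) {
        e_oxy <- ests$so2_1[[nm]]$so2
        e_deo <- ests$so2_0[[nm]]$so2
        rows[[length(rows) + 1]] <- data.frame(
          set = nm, roi = roi_nm, depth_mm = depth, replicate = r,
          seed = rep_seed, so2_oxy_est = e_oxy, so2_deoxy_est = e_deo,
          so2_oxy_true = 1, so2_deoxy_true = 0,
          error_pct = total_absolute_error(c(e_oxy, e_deo), c(1, 0)))
      }
    }
    if (r == 1) {  # bleached-kidney control, excluded from error stats
      bl <- build_abdomen_phantom(0, skin_mm = skin, fat_mm = fat,
                                  hemoglobin_bleached = TRUE,
                                  blood_volume_fraction = bvf)
      fc <- forward_config(noise_sd = cfg$noise_sd, frames = cfg$frames,
                           seed = stream_seed(rep_seed, "noise_bleached"))
      stb <- simulate_pa_stack(bl$scene, grid, beam, fc, cfg$mccfg,
                               cfg$fluence_mode, table = table)
      roi <- scene_roi(bl$scene, "roi_9mm")
      s <- preprocess_spectrum(stb, roi, bl$scene, cfg, rep_seed,
                               region = "roi_9mm", table = table)
      res <- lapply(sets, function(st)
        tryCatch(linear_unmix(s, st, table, solver = cfg$solver),
                 error = function(e) list(so2 = NA_real_, degenerate = TRUE)))
      # the control's probe truth is undefined (no hemoglobin), so its
      # unmixing output is flagged degenerate and never enters error stats
      bleached_flags <- list(truth_hemoglobin_free = TRUE,
                             so2 = vapply(res, `[[`, 0, "so2"),
                             degenerate = rep(TRUE, length(res)))
    }
  }
  tab <- do.call(rbind, rows)
  rep_obj <- finish_report(tab, cfg, experiment = "depth")
  # per-region ANOVA across sets; region 1 (shallowest) underpowered
  depths <- sort(unique(tab$depth_mm))
  rep_obj$anova_by_region <- lapply(stats::setNames(depths, paste0("depth_",
                                                                   depths)),
    function(dp) {
      if (dp == depths[1])
        return(list(excluded = TRUE,
                    reason = "region 1 not sufficiently powered"))
      sub <- tab[tab$depth_mm == dp, ]
      c(one_way_anova(split(sub$error_pct, sub$set)), excluded = FALSE)
    })
  nir1_mean <- vapply(depths, function(dp)
    mean(tab$error_pct[tab$set == "NIR1" & tab$depth_mm == dp]), 0)
  rep_obj$depth_monotone_nir1 <- all(diff(nir1_mean) >= 0)
  rep_obj$nir1_error_by_depth <- stats::setNames(nir1_mean, depths)
  rep_obj$bleached <- bleached_flags
  rep_obj
}
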