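#' Digital tube phantom
#'
#' Builds a digital replica of the blood-tube phantom: a porcine muscle slab
#' of configurable thickness resting on a gelatin mold with an embedded
#' horizontal tube (default 1.5/2.0 mm inner/outer diameter, axis along y)
#' filled with whole blood at a prescribed oxygen saturation, or with PBS.
#' Lumen voxels carry c_HbO2 = sO2 * c_tHb and c_Hb = (1 - sO2) * c_tHb.
#'
#' @param blood_so2 lumen oxygen saturation, in [0, 1].
#' @param slab_thickness_mm porcine slab thickness (default 3 mm).
#' @param tube_id_mm,tube_od_mm tube inner/outer diameter, mm.
#' @param lumen_content \code{"blood"} or \code{"PBS"}.
#' @param c_tHb_M total hemoglobin in the lumen, mol/L (default 2.3 mM,
#'   about 150 g/L whole blood).
#' @param gap_mm gelatin above the tube's outer wall, mm.
#' @param voxel_mm voxel edge (default 0.2 mm).
#' @param size_mm domain size (x, y, z), mm.
#' @param tissues tissue library (see \code{\link{tissue_library}}).
#' @return list with \code{scene} (class \code{phantom_scene}: the
#'   \code{\link{voxel_phantom}}, named target regions with nominal depths)
#'   and \code{truth} (class \code{ground_truth}: per-voxel concentrations
#'   and sO2, per-region probe sO2; the sO2 of a hemoglobin-free lumen is NA
#'   and flagged).
#' @export
build_tube_phantom <- function(blood_so2, slab_thickness_mm = 3,
                               tube_id_mm = 1.5, tube_od_mm = 2.0,
                               lumen_content = c("blood", "PBS"),
                               c_tHb_M = 2.3e-3, gap_mm = 0.2,
                               voxel_mm = 0.2, size_mm = c(12, 8, 10),
                               tissues = tissue_library()) {
  lumen_content <- match.arg(lumen_content)
  if (blood_so2 < 0 || blood_so2 > 1) stop("blood_so2 must be in [0, 1]")
  if (tube_id_mm >= tube_od_mm) stop("tube inner diameter must be < outer")
  n <- round(size_mm / voxel_mm)
  zc_mm <- slab_thickness_mm + gap_mm + tube_od_mm / 2  # tube axis depth
  if (zc_mm + tube_od_mm / 2 >= size_mm[3])
    stop("tube deeper than the grid")

  cx <- (seq_len(n[1]) - 0.5) * voxel_mm
  cz <- (seq_len(n[3]) - 0.5) * voxel_mm
  xc_mm <- size_mm[1] / 2
  r2 <- outer((cx - xc_mm)^2, (cz - zc_mm)^2, `+`)  # nx x nz
  ring <- function(r2mat, rmax) r2mat <= rmax^2
  lab2d <- matrix(2L, n[1], n[3])                      # gelatin
  lab2d[, cz < slab_thickness_mm] <- 1L                # porcine slab
  lab2d[ring(r2, tube_od_mm / 2)] <- 3L                # tube wall
  lab2d[ring(r2, tube_id_mm / 2)] <- 4L                # lumen
  labels <- aperm(array(lab2d, dim = c(n[1], n[3], n[2])), c(1, 3, 2))
  storage.mode(labels) <- "integer"

  blood <- tissues$blood
  if (lumen_content == "blood") {
    blood$c_HbO2_M <- blood_so2 * c_tHb_M
    blood$c_Hb_M <- (1 - blood_so2) * c_tHb_M
    lumen_spec <- blood
  } else lumen_spec <- tissues$PBS
  lumen_spec$name <- paste0("lumen_", lumen_content)

  phantom <- voxel_phantom(labels, voxel_mm,
                           list(tissues$porcine_muscle, tissues$gelatin,
                                tissues$tube_wall, lumen_spec))
  lumen_mask <- labels == 4L
  scene <- structure(list(
    phantom = phantom,
    regions = list(tube_lumen = list(mask = lumen_mask, depth_mm = zc_mm)),
    overburden = list(list(spec = tissues$porcine_muscle,
                           thickness_mm = slab_thickness_mm),
                      list(spec = tissues$gelatin, thickness_mm = gap_mm),
                      list(spec = tissues$tube_wall,
                           thickness_mm = (tube_od_mm - tube_id_mm) / 2),
                      list(spec = lumen_spec, thickness_mm = tube_id_mm / 2)),
    id = sprintf("tube_%s_so2_%.3f", lumen_content, blood_so2)
  ), class = "phantom_scene")

  has_hb <- lumen_content == "blood" && c_tHb_M > 0
  c1 <- array(0, n); c2 <- array(0, n)
  if (has_hb) {
    c1[lumen_mask] <- blood_so2 * c_tHb_M
    c2[lumen_mask] <- (1 - blood_so2) * c_tHb_M
  }
  so2 <- array(NA_real_, n)
  so2[c1 + c2 > 0] <- (c1 / (c1 + c2))[c1 + c2 > 0]
  truth <- structure(list(
    c_HbO2 = c1, c_Hb = c2, so2 = so2,
    regions = list(tube_lumen = list(
      so2 = if (has_hb) blood_so2 else NA_real_,
      hemoglobin_free = !has_hb))
  ), class = "ground_truth")
  list(scene = scene, truth = truth)
}

#' Digital layered rat abdomen
#'
#' Planar skin and subcutaneous fat layers over a kidney block, with target
#' regions at configurable depths below the illumination surface. Kidney
#' voxels are perfused with whole blood at a configurable blood volume
#' fraction; the bleached variant zeroes the hemoglobin (the
#' hydrogen-peroxide-bleached kidney condition).
#'
#' @param kidney_so2 saturation of kidney blood, in [0, 1].
#' @param skin_mm,fat_mm layer thicknesses (defaults 1 and 3 mm).
#' @param roi_depths_mm region depths below the surface (default 6, 9, 12).
#' @param hemoglobin_bleached if TRUE the kidney carries no hemoglobin.
#' @param blood_volume_fraction kidney blood volume fraction (default 0.2).
#' @param c_tHb_M whole-blood total hemoglobin, mol/L.
#' @param roi_radius_mm lateral radius and half-height of each region.
#' @inheritParams build_tube_phantom
#' @return as \code{\link{build_tube_phantom}}; regions are named
#'   \code{roi_6mm} etc.
#' @export
build_abdomen_phantom <- function(kidney_so2, skin_mm = 1, fat_mm = 3,
                                  roi_depths_mm = c(6, 9, 12),
                                  hemoglobin_bleached = FALSE,
                                  blood_volume_fraction = 0.2,
                                  c_tHb_M = 2.3e-3, roi_radius_mm = 1.2,
                                  voxel_mm = 0.2, size_mm = c(16, 8, 16),
                                  tissues = tissue_library()) {
  if (kidney_so2 < 0 || kidney_so2 > 1) stop("kidney_so2 must be in [0, 1]")
  if (skin_mm <= 0 || fat_mm <= 0) stop("layers must have positive thickness")
  kidney_top <- skin_mm + fat_mm
  if (kidney_top >= size_mm[3]) stop("overlapping layers: no room for kidney")
  if (any(roi_depths_mm <= kidney_top | roi_depths_mm >= size_mm[3]))
    stop("roi depths must lie within the kidney extent")
  n <- round(size_mm / voxel_mm)
  cz <- (seq_len(n[3]) - 0.5) * voxel_mm
  lab_z <- ifelse(cz < skin_mm, 1L, ifelse(cz < kidney_top, 2L, 3L))
  labels <- array(rep(lab_z, each = n[1] * n[2]), dim = n)

  kid <- tissues$kidney
  c_blood <- if (hemoglobin_bleached) 0 else blood_volume_fraction * c_tHb_M
  kid$c_HbO2_M <- kidney_so2 * c_blood
  kid$c_Hb_M <- (1 - kidney_so2) * c_blood
  phantom <- voxel_phantom(labels, voxel_mm,
                           list(tissues$skin, tissues$fat, kid))

  cx <- (seq_len(n[1]) - 0.5) * voxel_mm
  cy <- (seq_len(n[2]) - 0.5) * voxel_mm
  ctr <- size_mm / 2
  regions <- lapply(roi_depths_mm, function(zd) {
    mask <- array(FALSE, n)
    inz <- abs(cz - zd) <= roi_radius_mm / 2
    inx <- abs(cx - ctr[1]) <= roi_radius_mm
    iny <- abs(cy - ctr[2]) <= roi_radius_mm
    mask[inx, iny, inz] <- TRUE
    list(mask = mask, depth_mm = zd)
  })
  names(regions) <- sprintf("roi_%gmm", roi_depths_mm)

  scene <- structure(list(
    phantom = phantom, regions = regions,
    overburden = list(list(spec = tissues$skin, thickness_mm = skin_mm),
                      list(spec = tissues$fat, thickness_mm = fat_mm),
                      list(spec = kid, thickness_mm = NA_real_)),
    id = sprintf("abdomen_so2_%.3f%s", kidney_so2,
                 if (hemoglobin_bleached) "_bleached" else "")
  ), class = "phantom_scene")

  c1 <- array(0, n); c2 <- array(0, n)
  kidney_mask <- labels == 3L
  c1[kidney_mask] <- kid$c_HbO2_M
  c2[kidney_mask] <- kid$c_Hb_M
  skin_mask <- labels == 1L
  c1[skin_mask] <- tissues$skin$c_HbO2_M
  c2[skin_mask] <- tissues$skin$c_Hb_M
  so2 <- array(NA_real_, n)
  so2[c1 + c2 > 0] <- (c1 / (c1 + c2))[c1 + c2 > 0]
  truth <- structure(list(
    c_HbO2 = c1, c_Hb = c2, so2 = so2,
    regions = lapply(regions, function(r) list(
      so2 = if (c_blood > 0) kidney_so2 else NA_real_,
      hemoglobin_free = c_blood == 0))
  ), class = "ground_truth")
  list(scene = scene, truth = truth)
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat("<phantom_scene> ", x$id, "; regions: ",
      paste(names(x$regions), collapse = ", "), "\n", sep = "")
  invisible(x)
}
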