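# Independent brute-force photon walker (analog absorption, no weighting),
# coded separately from the package's transport kernel. Used as a
# physics oracle on tiny two-layer problems: same geometry conventions
# (voxel grid, z = depth, matched boundaries), different algorithm.

ref_walker <- function(labels, voxel_cm, mua, mus, g, beam_radius_cm,
                       n_photons, seed) {
  set.seed(seed)
  d <- dim(labels)
  lx <- d[1] * voxel_cm; ly <- d[2] * voxel_cm; lz <- d[3] * voxel_cm
  absorbed <- array(0, d)
  for (p in seq_len(n_photons)) {
    r <- beam_radius_cm * sqrt(runif(1)); th <- 2 * pi * runif(1)
    pos <- c(lx / 2 + r * cos(th), ly / 2 + r * sin(th), 1e-9)
    dir <- c(0, 0, 1)
    for (step in 1:10000) {
      if (any(pos < 0) || pos[1] >= lx || pos[2] >= ly || pos[3] >= lz) break
      vox <- pmin(pmax(floor(pos / voxel_cm) + 1, 1), d)
      lab <- labels[vox[1], vox[2], vox[3]]
      mt <- mua[lab] + mus[lab]
      # distance to the nearest voxel face along dir
      db <- Inf
      for (k in 1:3) {
        if (dir[k] > 0) db <- min(db, ((vox[k]) * voxel_cm - pos[k]) / dir[k])
        if (dir[k] < 0) db <- min(db, ((vox[k] - 1) * voxel_cm - pos[k]) / dir[k])
      }
      if (mt <= 0) { pos <- pos + (db + 1e-9) * dir; next }
      s <- rexp(1, mt)
      if (s >= db) { pos <- pos + (db + 1e-9) * dir; next }
      pos <- pos + s * dir
      if (runif(1) < mua[lab] / mt) {  # analog absorption
        absorbed[vox[1], vox[2], vox[3]] <- absorbed[vox[1], vox[2], vox[3]] + 1
        break
      }
      gg <- g[lab]
      ct <- if (abs(gg) < 1e-8) 1 - 2 * runif(1) else {
        tmp <- (1 - gg^2) / (1 - gg + 2 * gg * runif(1))
        max(-1, min(1, (1 + gg^2 - tmp^2) / (2 * gg)))
      }
      st <- sqrt(max(0, 1 - ct^2)); phi <- 2 * pi * runif(1)
      if (abs(dir[3]) > 0.99999) {
        dir <- c(st * cos(phi), st * sin(phi), ct * sign(dir[3]))
      } else {
        den <- sqrt(1 - dir[3]^2)
        nd <- c(st * (dir[1] * dir[3] * cos(phi) - dir[2] * sin(phi)) / den +
                  dir[1] * ct,
                st * (dir[2] * dir[3] * cos(phi) + dir[1] * sin(phi)) / den +
                  dir[2] * ct,
                -st * cos(phi) * den + dir[3] * ct)
        dir <- nd / sqrt(sum(nd^2))
      }
    }
  }
  # fluence per unit delivered surface fluence, collision-type estimator
  beam_area <- pi * beam_radius_cm^2
  mua_vox <- array(mua[labels], d)
  phi <- array(0, d)
  ok <- mua_vox > 0
  phi[ok] <- absorbed[ok] * beam_area / (n_photons * mua_vox[ok] * voxel_cm^3)
  phi
}
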