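#' Equiangular coplanar beam set
#'
#' Gantry angles `start_deg + k * 360/n_beams`, k = 0..n-1, reduced mod 360
#' and sorted increasing. Beams are coplanar: they rotate in the axial (y-x)
#' plane about the z axis through the isocenter. Angle 0 is anterior (the
#' beam enters through the anterior surface and travels toward +y).
#'
#' @param n_beams number of beams, >= 1 (9 for a typical pelvic IMRT protocol)
#' @param start_deg angle of the first beam in degrees
#' @param isocenter_mm optional 3-vector (z, y, x) in mm; `NULL` means the
#'   PTV centroid, resolved when the influence matrix is computed
#' @param beamlet_size_mm beamlet (width, height) in mm: width is the in-plane
#'   lateral extent, height the axial extent
#' @param field_margin_mm margin added around the PTV beam's-eye-view
#'   footprint when laying out beamlets, mm
#' @return a `beam_set` object
#' @export
make_equiangular_beams <- function(n_beams, start_deg = 0,
                                   isocenter_mm = NULL,
                                   beamlet_size_mm = c(10, 10),
                                   field_margin_mm = 5) {
  if (!is.numeric(n_beams) || length(n_beams) != 1L || n_beams < 1) {
    abort_argument("`n_beams` must be an integer >= 1")
  }
  n_beams <- as.integer(n_beams)
  angles <- sort((start_deg + (seq_len(n_beams) - 1) * 360 / n_beams) %% 360)
  structure(list(
    gantry_angles_deg = angles,
    isocenter_mm = isocenter_mm,
    beamlet_size_mm = as.numeric(beamlet_size_mm),
    field_margin_mm = field_margin_mm
  ), class = "beam_set")
}

#' Pencil-beam engine parameters
#'
#' The engine is a parallel pencil-beam model: per beamlet,
#' `dose = fluence * exp(-mu * radiological_depth) * exp(-r^2 / (2 sigma^2))`
#' for voxels within `cutoff_sigma * sigma` of the beamlet axis, where the
#' radiological depth is the density-weighted path length from the body
#' surface to the voxel along the beam direction. Defaults give a plausible
#' megavoltage-photon-like falloff; they are free engine parameters, not
#' commissioned beam data.
#'
#' @param mu_mm linear attenuation per mm of radiological (water-equivalent) path
#' @param sigma_mm lateral Gaussian penumbra sigma, mm
#' @param cutoff_sigma lateral cutoff in units of sigma
#' @param step_mm ray-marching step for radiological depth, mm
#' @param drop_rel sparsity threshold: per beamlet, entries below
#'   `drop_rel * max(entry)` are removed
#' @return an `engine_params` list
#' @export
engine_params <- function(mu_mm = 0.005, sigma_mm = 5, cutoff_sigma = 3,
                          step_mm = 2, drop_rel = 1e-3) {
  structure(list(mu_mm = mu_mm, sigma_mm = sigma_mm,
                 cutoff_sigma = cutoff_sigma, step_mm = step_mm,
                 drop_rel = drop_rel),
            class = "engine_params")
}

# Radiological depth (mm of water-equivalent path) for voxel centres at mm
# coordinates (y, x) with fixed axial index iz_vec, along in-plane travel
# direction u = (uy, ux). Marches K fixed steps of `step` mm back toward the
# source, sampling the density at the nearest voxel; density is 0 outside the
# body, so the fixed step count integrates exactly the in-body path.
radiological_depth <- function(density, origin, spacing, iz, yc, xc, uy, ux, step) {
  d <- dim(density)
  extent <- sqrt((d[2] * spacing[2])^2 + (d[3] * spacing[3])^2)
  K <- ceiling(extent / step)
  acc <- numeric(length(yc))
  nz <- d[1]; ny <- d[2]
  for (k in seq_len(K)) {
    s <- (k - 0.5) * step
    py <- yc - s * uy
    px <- xc - s * ux
    iy <- floor((py - origin[2]) / spacing[2]) + 1
    ix <- floor((px - origin[3]) / spacing[3]) + 1
    ok <- iy >= 1 & iy <= d[2] & ix >= 1 & ix <= d[3]
    if (any(ok)) {
      flat <- iz[ok] + nz * (iy[ok] - 1) + nz * ny * (ix[ok] - 1)
      acc[ok] <- acc[ok] + density[flat]
    }
  }
  acc * step
}

#' Compute the dose-influence matrix
#'
#' Builds the sparse nonnegative linear operator A mapping beamlet fluences
#' to voxel doses (Gy per unit fluence) over the body voxels, for every beam
#' in the beam set. Beamlets are laid out per beam on a regular grid covering
#' the PTV beam's-eye-view footprint plus the field margin; beamlets whose
#' entries all fall below the drop tolerance are removed. After assembly the
#' matrix is globally rescaled so that a uniform unit fluence delivers a mean
#' PTV dose of 1 Gy, which makes objective weights transferable across
#' phantoms.
#'
#' @param p a [phantom()]
#' @param beams a [make_equiangular_beams()] beam set
#' @param params an [engine_params()] list
#' @return an `influence_matrix`: sparse matrix `A` (body voxels x beamlets),
#'   the flat voxel indices it maps to, per-beamlet provenance, and the
#'   normalization factor applied
#' @export
compute_influence <- function(p, beams, params = engine_params()) {
  shape <- dim(p$density); spacing <- p$spacing; origin <- p$origin
  iso <- beams$isocenter_mm
  if (is.null(iso)) {
    if (!any(p$masks$ptv)) abort_geometry("cannot place isocenter: empty PTV mask")
    idx <- which(p$masks$ptv, arr.ind = TRUE)
    iso <- origin + (colMeans(idx) - 0.5) * spacing
  }
  iso_idx <- floor((iso - origin) / spacing) + 1
  if (any(iso_idx < 1) || any(iso_idx > shape) ||
      !p$masks$body[iso_idx[1], iso_idx[2], iso_idx[3]]) {
    abort_geometry("isocenter lies outside the body")
  }

  body_flat <- which(p$masks$body)
  nb <- length(body_flat)
  ind <- arrayInd(body_flat, shape)
  zc <- origin[1] + (ind[, 1] - 0.5) * spacing[1] - iso[1]
  yc <- origin[2] + (ind[, 2] - 0.5) * spacing[2] - iso[2]
  xc <- origin[3] + (ind[, 3] - 0.5) * spacing[3] - iso[3]

  ptv_flat <- which(p$masks$ptv)
  ptv_local <- match(ptv_flat, body_flat)
  pind <- arrayInd(ptv_flat, shape)
  ptv_z <- origin[1] + (pind[, 1] - 0.5) * spacing[1] - iso[1]
  ptv_y <- origin[2] + (pind[, 2] - 0.5) * spacing[2] - iso[2]
  ptv_x <- origin[3] + (pind[, 3] - 0.5) * spacing[3] - iso[3]

  sig2 <- params$sigma_mm^2
  cut <- params$cutoff_sigma * params$sigma_mm
  w_mm <- beams$beamlet_size_mm[1]; h_mm <- beams$beamlet_size_mm[2]

  trip_i <- list(); trip_j <- list(); trip_x <- list()
  beamlet_tab <- list()
  jofs <- 0L
  for (ang in beams$gantry_angles_deg) {
    th <- ang * pi / 180
    uy <- cos(th); ux <- sin(th)        # travel direction (anterior at 0 deg)
    vy <- -ux; vx <- uy                 # in-plane lateral axis
    depth <- radiological_depth(p$density, origin - iso, spacing, ind[, 1],
                                yc, xc, uy, ux, params$step_mm)
    att <- exp(-params$mu_mm * depth)
    lat <- yc * vy + xc * vx

    ptv_l <- ptv_y * vy + ptv_x * vx
    centers_l <- beamlet_centers(range(ptv_l), beams$field_margin_mm, w_mm)
    centers_z <- beamlet_centers(range(ptv_z), beams$field_margin_mm, h_mm)

    for (zb in centers_z) {
      dz2 <- (zc - zb)^2
      near_z <- dz2 <= cut^2
      for (lb in centers_l) {
        r2 <- (lat - lb)^2 + dz2
        sel <- which(near_z & r2 <= cut^2)
        if (!length(sel)) next
        val <- att[sel] * exp(-r2[sel] / (2 * sig2))
        keep <- val >= params$drop_rel * max(val)
        sel <- sel[keep]; val <- val[keep]
        if (!length(sel)) next
        jofs <- jofs + 1L
        trip_i[[jofs]] <- sel
        trip_j[[jofs]] <- rep.int(jofs, length(sel))
        trip_x[[jofs]] <- val
        beamlet_tab[[jofs]] <- c(angle_deg = ang, lat_mm = lb, z_mm = zb)
      }
    }
  }
  if (jofs == 0L) abort_geometry("no beamlet deposits dose inside the body")

  A <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
    dims = c(nb, jofs)
  )
  # Normalize: uniform unit fluence -> mean PTV dose 1 Gy.
  unit_dose <- as.vector(A %*% rep(1, jofs))
  scale <- 1 / mean(unit_dose[ptv_local])
  A <- A * scale

  structure(list(
    A = A, voxel_index = body_flat, grid_dim = shape,
    spacing = spacing, origin = origin, isocenter_mm = iso,
    n_beamlets = jofs,
    beamlets = do.call(rbind, beamlet_tab),
    beams = beams, params = params, scale = scale,
    case_id = p$case_id
  ), class = "influence_matrix")
}

# Beamlet centre positions covering [rng] +/- margin at pitch `size`,
# symmetric about the interval midpoint.
beamlet_centers <- function(rng, margin, size) {
  half <- diff(rng) / 2 + margin
  n <- max(1L, ceiling(2 * half / size))
  mean(rng) + (seq_len(n) - (n + 1) / 2) * size
}

#' @exportS3Method base::print
print.influence_matrix <- function(x, ...) {
  cat(sprintf("<influence_matrix '%s'> %d body voxels x %d beamlets, %d nonzeros\n",
              x$case_id, nrow(x$A), x$n_beamlets, Matrix::nnzero(x$A)))
  invisible(x)
}

#' Forward dose calculation
#'
#' `dose = A %*% w` mapped back onto the phantom grid; voxels outside the
#' body receive 0 by construction.
#'
#' @param infl an [compute_influence()] influence matrix
#' @param w nonnegative fluence vector, one entry per beamlet
#' @return a [dose_grid()]
#' @export
compute_dose <- function(infl, w) {
  if (length(w) != infl$n_beamlets) {
    abort_argument(sprintf("fluence has length %d but the matrix has %d beamlets",
                           length(w), infl$n_beamlets))
  }
  if (any(w < 0)) abort_argument("fluence components must be nonnegative")
  vals <- array(0, dim = infl$grid_dim)
  vals[infl$voxel_index] <- as.vector(infl$A %*% w)
  dose_grid(vals, infl$spacing, infl$origin)
}
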