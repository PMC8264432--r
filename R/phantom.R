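#' Phantom generation configuration
#'
#' Geometry defaults for the synthetic pelvic phantom: an elliptic-cylinder
#' body spanning the full axial extent, a posterior-central ellipsoidal PTV,
#' an anterior ellipsoidal bladder abutting the PTV, and two lateral spherical
#' femoral heads. Structure sizes and positions are jittered per case from a
#' seeded RNG so cohorts show anatomical variability while every case remains
#' reproducible.
#'
#' The grid uses axis order (z, y, x) with 5 mm slices and 4 mm in-plane
#' voxels by default. Coordinates are in mm; +y is posterior, +x is patient
#' left, z is axial. The origin is the mm offset of the corner of voxel
#' (0,0,0) and defaults to centring the grid on (0,0,0).
#'
#' Structure-geometry defaults scale with the grid half-extents, so reduced
#' test grids still contain every structure; explicit mm values override the
#' scaling. On the default 24x64x64 grid at (5, 4, 4) mm the defaults give a
#' ~100x118 mm body, a PTV of ~30 mm semi-axes centred ~38 mm posterior, and
#' ~20 mm femoral heads ~82 mm lateral.
#'
#' @param shape integer grid shape `(nz, ny, nx)`; must be at least (16,32,32)
#' @param spacing voxel spacing `(dz, dy, dx)` in mm, all > 0
#' @param origin mm offset of the corner of voxel (0,0,0); default centres the grid
#' @param body_semiaxes_mm in-plane body semi-axes (y, x) in mm before jitter
#' @param body_jitter_rel relative jitter applied to the body semi-axes
#' @param ptv_center_mm nominal PTV centre (z, y, x) in mm (posterior-central)
#' @param ptv_semiaxes_mm nominal PTV semi-axes (z, y, x) in mm
#' @param ptv_jitter_rel relative jitter on PTV semi-axes
#' @param ptv_shift_mm maximum absolute jitter of structure centres, mm
#' @param bladder_semiaxes_mm nominal bladder semi-axes (z, y, x) in mm
#' @param bladder_gap_mm gap between the anterior PTV surface and the bladder, mm
#' @param femhead_radius_mm nominal femoral-head radius, mm
#' @param femhead_offset_mm femoral-head centre offsets `(z, y, |x|)` in mm
#' @param density_body,density_femhead relative densities (water = 1.0)
#' @return a `phantom_config` list
#' @export
phantom_config <- function(shape = c(24L, 64L, 64L),
                           spacing = c(5, 4, 4),
                           origin = NULL,
                           body_semiaxes_mm = NULL,
                           body_jitter_rel = 0.04,
                           ptv_center_mm = NULL,
                           ptv_semiaxes_mm = NULL,
                           ptv_jitter_rel = 0.10,
                           ptv_shift_mm = NULL,
                           bladder_semiaxes_mm = NULL,
                           bladder_gap_mm = 2,
                           femhead_radius_mm = NULL,
                           femhead_offset_mm = NULL,
                           density_body = 1.0,
                           density_femhead = 1.5) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < c(16L, 32L, 32L))) {
    abort_argument("`shape` must be (nz, ny, nx) with nz >= 16, ny >= 32, nx >= 32")
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort_argument("`spacing` must be three positive numbers (dz, dy, dx) in mm")
  }
  if (is.null(origin)) origin <- -shape * spacing / 2
  ref <- shape * spacing / 2            # grid half-extents (z, y, x), mm
  if (is.null(body_semiaxes_mm)) body_semiaxes_mm <- c(0.78, 0.92) * ref[2:3]
  if (is.null(ptv_center_mm)) ptv_center_mm <- c(0, 0.30 * ref[2], 0)
  if (is.null(ptv_semiaxes_mm)) {
    ptv_semiaxes_mm <- c(0.50 * ref[1], 0.20 * ref[2], 0.23 * ref[3])
  }
  if (is.null(ptv_shift_mm)) ptv_shift_mm <- 0.04 * ref[2]
  if (is.null(bladder_semiaxes_mm)) {
    bladder_semiaxes_mm <- c(0.40 * ref[1], 0.16 * ref[2], 0.20 * ref[3])
  }
  if (is.null(femhead_radius_mm)) femhead_radius_mm <- 0.16 * ref[3]
  if (is.null(femhead_offset_mm)) {
    femhead_offset_mm <- c(0, -0.09 * ref[2], 0.64 * ref[3])
  }
  structure(list(
    shape = shape, spacing = as.numeric(spacing), origin = as.numeric(origin),
    body_semiaxes_mm = body_semiaxes_mm, body_jitter_rel = body_jitter_rel,
    ptv_center_mm = ptv_center_mm, ptv_semiaxes_mm = ptv_semiaxes_mm,
    ptv_jitter_rel = ptv_jitter_rel, ptv_shift_mm = ptv_shift_mm,
    bladder_semiaxes_mm = bladder_semiaxes_mm, bladder_gap_mm = bladder_gap_mm,
    femhead_radius_mm = femhead_radius_mm, femhead_offset_mm = femhead_offset_mm,
    density_body = density_body, density_femhead = density_femhead
  ), class = "phantom_config")
}

#' Construct and validate a phantom
#'
#' Low-level constructor: checks all anatomical invariants (masks congruent
#' with the density grid, every structure inside the body, PTV disjoint from
#' both femoral heads, density zero outside the body and nonnegative inside).
#'
#' @param density 3D numeric array (z, y, x), relative density, water = 1
#' @param masks named list of logical arrays: body, ptv, bladder,
#'   femoral_head_l, femoral_head_r
#' @param spacing,origin grid geometry in mm
#' @param case_id character case identifier
#' @return a `phantom` object
#' @export
phantom <- function(density, masks, spacing, origin, case_id = "case") {
  required <- c("body", "ptv", "bladder", "femoral_head_l", "femoral_head_r")
  missing_masks <- setdiff(required, names(masks))
  if (length(missing_masks)) {
    abort_format(sprintf("phantom is missing mask(s): %s",
                         paste(missing_masks, collapse = ", ")))
  }
  masks <- lapply(masks[required], as_mask)
  for (nm in required) {
    if (!same_dim(masks[[nm]], density)) {
      abort_format(sprintf("mask '%s' shape does not match the density grid", nm))
    }
  }
  body <- masks$body
  for (nm in setdiff(required, "body")) {
    if (any(masks[[nm]] & !body)) {
      abort_geometry(sprintf("structure '%s' extends outside the body", nm))
    }
    if (!any(masks[[nm]])) {
      abort_geometry(sprintf("structure '%s' is empty on this grid", nm))
    }
  }
  if (any(masks$ptv & masks$femoral_head_l) || any(masks$ptv & masks$femoral_head_r)) {
    abort_geometry("PTV overlaps a femoral head")
  }
  if (any(density < 0)) abort_geometry("negative density voxels")
  if (any(density[!body] != 0)) abort_geometry("nonzero density outside the body")
  structure(list(
    density = density, masks = masks,
    spacing = as.numeric(spacing), origin = as.numeric(origin),
    case_id = as.character(case_id)
  ), class = "phantom")
}

#' @exportS3Method base::print
print.phantom <- function(x, ...) {
  d <- dim(x$density)
  cat(sprintf("<phantom '%s'> grid %dx%dx%d (z,y,x), spacing %s mm\n",
              x$case_id, d[1], d[2], d[3],
              paste(x$spacing, collapse = "x")))
  for (nm in names(x$masks)) {
    cat(sprintf("  %-15s %6d voxels (%.1f cc)\n", nm, sum(x$masks[[nm]]),
                mask_volume_cc(x$masks[[nm]], x$spacing)))
  }
  invisible(x)
}

# Voxel-centre coordinate vectors (mm) along each axis for a config grid.
grid_axes <- function(shape, spacing, origin) {
  list(
    z = origin[1] + (seq_len(shape[1]) - 0.5) * spacing[1],
    y = origin[2] + (seq_len(shape[2]) - 0.5) * spacing[2],
    x = origin[3] + (seq_len(shape[3]) - 0.5) * spacing[3]
  )
}

# Voxelize an axis-aligned ellipsoid by centre-of-voxel inclusion.
ellipsoid_mask <- function(shape, ax, center, semi) {
  z2 <- ((ax$z - center[1]) / semi[1])^2
  y2 <- ((ax$y - center[2]) / semi[2])^2
  x2 <- ((ax$x - center[3]) / semi[3])^2
  arr <- outer(outer(z2, y2, `+`), x2, `+`)
  array(arr <= 1, dim = shape)
}

#' Volume of a mask in cubic centimetres
#'
#' @param mask logical 3D array
#' @param spacing voxel spacing (dz, dy, dx) in mm
#' @return volume in cc
#' @export
mask_volume_cc <- function(mask, spacing) {
  sum(mask) * prod(spacing) / 1000
}

#' Generate one synthetic pelvic phantom
#'
#' Deterministic given `(config, seed)`: all structure jitters come from a
#' seeded RNG stream local to the call. Raises a geometry error (never a
#' silently clipped phantom) if the jittered structures cannot be placed
#' inside the body while keeping the PTV clear of both femoral heads.
#'
#' @param config a [phantom_config()]
#' @param seed integer seed
#' @param case_id optional case identifier; defaults to one derived from the seed
#' @return a [phantom()] object
#' @export
#' @examples
#' p <- generate_phantom(phantom_config(), seed = 1)
#' mask_volume_cc(p$masks$ptv, p$spacing)
generate_phantom <- function(config = phantom_config(), seed,
                             case_id = sprintf("case_s%d", seed)) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  if (missing(seed)) abort_argument("`seed` is required")
  shape <- config$shape; spacing <- config$spacing; origin <- config$origin
  ax <- grid_axes(shape, spacing, origin)

  j <- with_seed(seed, {
    list(
      body = 1 + stats::runif(2, -config$body_jitter_rel, config$body_jitter_rel),
      ptv_semi = 1 + stats::runif(3, -config$ptv_jitter_rel, config$ptv_jitter_rel),
      ptv_shift = stats::runif(3, -config$ptv_shift_mm, config$ptv_shift_mm),
      bladder_semi = 1 + stats::runif(3, -config$ptv_jitter_rel, config$ptv_jitter_rel),
      fem_r = 1 + stats::runif(2, -0.08, 0.08),
      fem_shift = stats::runif(2, -config$ptv_shift_mm, config$ptv_shift_mm)
    )
  })

  body_semi <- config$body_semiaxes_mm * j$body
  body <- {
    y2 <- (ax$y / body_semi[1])^2
    x2 <- (ax$x / body_semi[2])^2
    inplane <- outer(y2, x2, `+`) <= 1
    array(rep(inplane, each = shape[1]), dim = shape)
  }

  ptv_center <- config$ptv_center_mm + j$ptv_shift
  ptv_semi <- config$ptv_semiaxes_mm * j$ptv_semi
  ptv <- ellipsoid_mask(shape, ax, ptv_center, ptv_semi)

  bladder_semi <- config$bladder_semiaxes_mm * j$bladder_semi
  # Anterior of the PTV, abutting it across the configured gap.
  bladder_center <- c(ptv_center[1],
                      ptv_center[2] - ptv_semi[2] - config$bladder_gap_mm - bladder_semi[2],
                      ptv_center[3])
  bladder <- ellipsoid_mask(shape, ax, bladder_center, bladder_semi)

  fem_masks <- lapply(1:2, function(k) {
    side <- if (k == 1) 1 else -1     # +x = patient left
    r <- config$femhead_radius_mm * j$fem_r[k]
    center <- c(config$femhead_offset_mm[1],
                config$femhead_offset_mm[2] + j$fem_shift[k],
                side * config$femhead_offset_mm[3])
    ellipsoid_mask(shape, ax, center, rep(r, 3))
  })

  density <- array(0, dim = shape)
  density[body] <- config$density_body
  density[fem_masks[[1]] | fem_masks[[2]]] <- config$density_femhead
  density[!body] <- 0

  phantom(density,
          masks = list(body = body, ptv = ptv, bladder = bladder,
                       femoral_head_l = fem_masks[[1]],
                       femoral_head_r = fem_masks[[2]]),
          spacing = spacing, origin = origin, case_id = case_id)
}

#' Generate a cohort of phantoms
#'
#' Per-case seeds are derived as `seed + case_index - 1`, so the first `k`
#' cases of a size-`n` cohort are identical to a size-`k` cohort generated
#' with the same base seed (prefix stability).
#'
#' @param n number of cases, >= 1
#' @param config a [phantom_config()]
#' @param seed integer base seed
#' @return list of [phantom()] objects with distinct `case_id`s
#' @export
generate_cohort <- function(n, config = phantom_config(), seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort_argument("`n` must be an integer >= 1")
  }
  n <- as.integer(n)
  lapply(seq_len(n), function(i) {
    generate_phantom(config, seed = seed + i - 1L,
                     case_id = sprintf("case_%03d", i))
  })
}

#' Split case ids into train / validation / test sets
#'
#' Seeded uniform shuffle followed by contiguous partition, mirroring a
#' random cohort division such as 180 cases into 160 training, 10 validation
#' and 10 test cases.
#'
#' @param ids character or integer vector of case ids
#' @param n_train,n_val,n_test partition sizes; must sum to `length(ids)`
#' @param seed integer seed for the shuffle
#' @return a `cohort_split` list with `train_ids`, `val_ids`, `test_ids`, `seed`
#' @export
split_cohort <- function(ids, n_train, n_val, n_test, seed) {
  if (n_train + n_val + n_test != length(ids)) {
    abort_argument(sprintf(
      "split sizes %d+%d+%d do not sum to the number of ids (%d)",
      n_train, n_val, n_test, length(ids)))
  }
  shuffled <- with_seed(seed, sample(ids, length(ids), replace = FALSE))
  structure(list(
    train_ids = shuffled[seq_len(n_train)],
    val_ids = shuffled[seq_len(n_val) + n_train],
    test_ids = shuffled[seq_len(n_test) + n_train + n_val],
    seed = seed
  ), class = "cohort_split")
}

#' Write a phantom to disk
#'
#' Layout: one NIfTI volume per grid (`density.nii.gz`, `mask_<name>.nii.gz`)
#' plus a JSON sidecar `case.json` carrying spacing, origin, case id and the
#' mask names. The round trip through [read_phantom()] is lossless.
#'
#' @param p a [phantom()]
#' @param path directory to create/write into
#' @return `path`, invisibly
#' @export
write_phantom <- function(p, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(p$density, file.path(path, "density.nii.gz"),
                     datatype = "double")
  for (nm in names(p$masks)) {
    m <- p$masks[[nm]]
    storage.mode(m) <- "integer"
    RNifti::writeNifti(m, file.path(path, sprintf("mask_%s.nii.gz", nm)),
                       datatype = "uint8")
  }
  sidecar <- list(case_id = p$case_id, spacing = p$spacing, origin = p$origin,
                  masks = names(p$masks))
  jsonlite::write_json(sidecar, file.path(path, "case.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phantom written by [write_phantom()]
#'
#' @param path directory containing `case.json` and the NIfTI volumes
#' @return a [phantom()]
#' @export
read_phantom <- function(path) {
  sidecar_path <- file.path(path, "case.json")
  if (!file.exists(sidecar_path)) {
    abort_format(sprintf("no case.json sidecar found under '%s'", path))
  }
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  as_plain_array <- function(img) array(as.vector(img), dim = dim(img))
  density <- as_plain_array(RNifti::readNifti(file.path(path, "density.nii.gz")))
  masks <- lapply(sidecar$masks, function(nm) {
    f <- file.path(path, sprintf("mask_%s.nii.gz", nm))
    if (!file.exists(f)) {
      abort_format(sprintf("missing mask file for structure '%s'", nm))
    }
    m <- as_plain_array(RNifti::readNifti(f))
    if (!same_dim(m, density)) {
      abort_format(sprintf("mask '%s' shape does not match the density grid", nm))
    }
    as_mask(m)
  })
  names(masks) <- sidecar$masks
  phantom(density, masks, spacing = sidecar$spacing, origin = sidecar$origin,
          case_id = sidecar$case_id)
}
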