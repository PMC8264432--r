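#' Dose grid container
#'
#' Per-voxel absorbed dose in Gy on a phantom grid, stored as a plain 3D
#' array (z, y, x) with spacing and origin attributes so it can be written
#' to NIfTI alongside the phantom volumes.
#'
#' @param values nonnegative finite 3D numeric array, Gy
#' @param spacing,origin grid geometry in mm
#' @return a `dose_grid` object
#' @export
dose_grid <- function(values, spacing, origin) {
  if (any(!is.finite(values))) abort_argument("dose grid contains non-finite values")
  if (any(values < 0)) abort_argument("dose grid contains negative values")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "dose_grid")
}

#' @exportS3Method base::print
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %dx%dx%d (z,y,x), max %.2f Gy, mean %.2f Gy\n",
              d[1], d[2], d[3], max(x$values), mean(x$values)))
  invisible(x)
}

# Accept either a dose_grid or a bare array wherever doses are consumed.
dose_values <- function(dose) {
  if (inherits(dose, "dose_grid")) dose$values else dose
}

#' Write a dose grid to NIfTI
#'
#' @param dose a [dose_grid()]
#' @param path output file path (`.nii` or `.nii.gz`)
#' @return `path`, invisibly
#' @export
write_dose <- function(dose, path) {
  RNifti::writeNifti(dose$values, path, datatype = "double")
  invisible(path)
}

#' Geometric reference-dose surrogate
#'
#' Deterministic stand-in for a learned voxel-wise dose prediction: the
#' prescription everywhere inside the PTV, an exponential falloff with
#' Euclidean distance from the PTV surface inside the body, and zero outside
#' the body. Continuous across the PTV boundary (distance 0 gives exactly the
#' prescription).
#'
#' @param p a [phantom()]
#' @param prescription_gy prescription dose in Gy (> 0); default 50
#' @param falloff_mm exponential falloff length in mm (> 0); default 30
#' @return a [dose_grid()]
#' @export
#' @examples
#' p <- generate_phantom(phantom_config(), seed = 1)
#' d <- geometric_predictor(p, prescription_gy = 50)
#' max(d$values)  # 50 Gy, attained on the PTV
geometric_predictor <- function(p, prescription_gy = 50, falloff_mm = 30) {
  stopifnot_scalar_number(prescription_gy, "prescription_gy", positive = TRUE)
  stopifnot_scalar_number(falloff_mm, "falloff_mm", positive = TRUE)
  if (!any(p$masks$ptv)) abort_geometry("phantom has an empty PTV mask")
  dist_mm <- distance_transform(p$masks$ptv, p$spacing)
  vals <- prescription_gy * exp(-dist_mm / falloff_mm)
  vals[!p$masks$body] <- 0
  dose_grid(vals, p$spacing, p$origin)
}
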