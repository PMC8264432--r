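#' Objective weights for fluence optimization
#'
#' Weights combining the voxel mean-square-error term with the clinical
#' homogeneity-index (HI) and conformity-index (CI) objectives into the
#' total objective `F_total = alpha * F_MSE + W_HI * F_HI + W_CI * F_CI`.
#' Terms are normalized to be commensurate: the MSE term by
#' `|V| * prescription^2`, the HI term by `prescription^2`, and the CI term
#' is dimensionless by construction.
#'
#' @param alpha weight of the MSE term
#' @param w_hi weight of the homogeneity objective
#' @param w_ci weight of the conformity objective
#' @param c_index target conformity constant, in (0, 1]; 1 is ideal
#' @param reference_isodose_gy dose level defining the reference isodose
#'   volume for conformity (the prescription level)
#' @param hi_percentiles the three D_X percentiles entering the homogeneity
#'   objective, default (98, 50, 2)
#' @param tau logistic smoothing temperature for the isodose indicator, Gy
#' @return an `objective_weights` list
#' @export
objective_weights <- function(alpha = 1, w_hi = 10, w_ci = 10,
                              c_index = 1, reference_isodose_gy = 50,
                              hi_percentiles = c(98, 50, 2), tau = 0.5) {
  for (nm in c("alpha", "w_hi", "w_ci")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0) abort_argument(sprintf("`%s` must be >= 0", nm))
  }
  if (c_index <= 0 || c_index > 1) abort_argument("`c_index` must be in (0, 1]")
  stopifnot_scalar_number(reference_isodose_gy, "reference_isodose_gy", positive = TRUE)
  stopifnot_scalar_number(tau, "tau", positive = TRUE)
  structure(list(alpha = alpha, w_hi = w_hi, w_ci = w_ci, c_index = c_index,
                 reference_isodose_gy = reference_isodose_gy,
                 hi_percentiles = hi_percentiles, tau = tau),
            class = "objective_weights")
}

#' Voxel mean-square-error objective
#'
#' `F_MSE = sum_{i in V} (d_i_calc - d_i_pred)^2`, optionally normalized by
#' `|V| * prescription^2` so it is commensurate with the clinical terms. The
#' voxel domain V is given by `mask` (the body, in the planning pipeline:
#' air voxels carry no dose and are excluded).
#'
#' @param d_calc,d_pred congruent dose grids (or bare arrays), Gy
#' @param mask logical array selecting the voxel domain V
#' @param prescription_gy if given, value and gradient are divided by
#'   `|V| * prescription_gy^2`; if `NULL`, the raw voxel sum is returned
#' @return list with `value` and `gradient` (array, nonzero only on `mask`)
#' @export
f_mse <- function(d_calc, d_pred, mask, prescription_gy = NULL) {
  dc <- dose_values(d_calc); dp <- dose_values(d_pred)
  if (!same_dim(dc, dp) || !same_dim(dc, mask)) {
    abort_argument("dose grids and mask must have identical shapes")
  }
  if (!any(mask)) abort_geometry("voxel domain mask is empty")
  norm <- if (is.null(prescription_gy)) 1 else sum(mask) * prescription_gy^2
  diff <- dc - dp
  value <- sum(diff[mask]^2) / norm
  grad <- array(0, dim = dim(dc))
  grad[mask] <- 2 * diff[mask] / norm
  list(value = value, gradient = grad)
}

#' Dose at volume, D_X (nearest-rank convention)
#'
#' The minimum dose received by the hottest X% of a structure: structure
#' voxel doses are sorted descending and D_X is the value at 1-based rank
#' `ceiling(x/100 * N)`, i.e. the dose such that at least X% of the
#' structure receives at least it.
#'
#' @param dose a [dose_grid()] or array, Gy
#' @param mask logical structure mask
#' @param x_percent percentile in (0, 100]
#' @return D_X in Gy
#' @export
dose_at_volume <- function(dose, mask, x_percent) {
  dose_at_volume_idx(dose, mask, x_percent)$value
}

# Internal variant also returning the flat voxel index realizing the rank
# (ties broken toward the lowest flat index) for subgradient routing.
dose_at_volume_idx <- function(dose, mask, x_percent) {
  if (!any(mask)) abort_geometry("D_X of an empty structure mask")
  if (!is.numeric(x_percent) || x_percent <= 0 || x_percent > 100) {
    abort_argument("`x_percent` must be in (0, 100]")
  }
  vals <- dose_values(dose)
  flat <- which(mask)
  dvals <- vals[flat]
  rank <- ceiling(x_percent / 100 * length(dvals))
  dx <- sort(dvals, decreasing = TRUE, method = "quick")[rank]
  list(value = dx, voxel = min(flat[dvals == dx]))
}

#' Homogeneity objective on the PTV
#'
#' `F_HI = W_HI * [(D98 - D50)^2 + (D2 - D50)^2]`, divided by
#' `prescription^2` when given. Zero exactly when the PTV dose is flat at
#' the three percentiles. The subgradient routes each D_X term to the single
#' voxel realizing its nearest rank (ties to the lowest flat index); D50
#' appears in both squared terms and accumulates both contributions.
#'
#' @param dose a [dose_grid()] or array
#' @param ptv_mask logical PTV mask
#' @param w_hi objective weight
#' @param prescription_gy optional normalization (divides by its square)
#' @param percentiles the three percentiles, default (98, 50, 2)
#' @return list with `value`, `gradient` (array), and the realized `d_x` values
#' @export
f_hi <- function(dose, ptv_mask, w_hi = 1, prescription_gy = NULL,
                 percentiles = c(98, 50, 2)) {
  q <- lapply(percentiles, function(x) dose_at_volume_idx(dose, ptv_mask, x))
  d98 <- q[[1]]$value; d50 <- q[[2]]$value; d2 <- q[[3]]$value
  norm <- if (is.null(prescription_gy)) 1 else prescription_gy^2
  value <- w_hi * ((d98 - d50)^2 + (d2 - d50)^2) / norm
  grad <- array(0, dim = dim(dose_values(dose)))
  coef <- w_hi / norm
  grad[q[[1]]$voxel] <- grad[q[[1]]$voxel] + coef * 2 * (d98 - d50)
  grad[q[[3]]$voxel] <- grad[q[[3]]$voxel] + coef * 2 * (d2 - d50)
  grad[q[[2]]$voxel] <- grad[q[[2]]$voxel] -
    coef * (2 * (d98 - d50) + 2 * (d2 - d50))
  list(value = value, gradient = grad,
       d_x = c(d98 = d98, d50 = d50, d2 = d2))
}

#' Smoothed conformity objective
#'
#' Differentiable surrogate of the conformity objective
#' `F = W_CI * (F_CI - C_index)^2` with
#' `F_CI = TV_RI^2 / (V_RI * TV)`: the hard isodose indicator
#' `d_i >= reference` is replaced by the logistic
#' `s_i = 1 / (1 + exp(-(d_i - reference)/tau))`, so `TV_RI` is the smooth
#' count of PTV voxels above the reference isodose and `V_RI` the smooth
#' count over the body. The hard-threshold evaluation is returned alongside
#' for honest reporting. The `V_RI` denominator is guarded with
#' `1e-8 * |PTV|`; a guarded evaluation is flagged.
#'
#' @param dose a [dose_grid()] or array
#' @param ptv_mask,body_mask logical masks (PTV inside body)
#' @param reference_isodose dose level defining the reference isodose, Gy
#' @param c_index target conformity constant
#' @param w_ci objective weight
#' @param tau logistic temperature, Gy (> 0)
#' @return list with `value`, `gradient` (array), the smooth and hard `f_ci`,
#'   and a `guarded` flag
#' @export
f_ci_smooth <- function(dose, ptv_mask, body_mask, reference_isodose,
                        c_index = 1, w_ci = 1, tau = 0.5) {
  stopifnot_scalar_number(tau, "tau", positive = TRUE)
  if (!any(ptv_mask) || !any(body_mask)) abort_geometry("empty PTV or body mask")
  vals <- dose_values(dose)
  tv <- sum(ptv_mask)

  s_body <- 1 / (1 + exp(-(vals[body_mask] - reference_isodose) / tau))
  in_ptv <- ptv_mask[body_mask]
  tv_ri <- sum(s_body[in_ptv])
  v_ri <- sum(s_body)
  eps <- 1e-8 * tv
  guarded <- v_ri < eps
  v_ri_g <- v_ri + eps
  fci <- tv_ri^2 / (v_ri_g * tv)
  value <- w_ci * (fci - c_index)^2

  # chain rule: d value / d s_i, split by PTV membership
  dval_dfci <- 2 * w_ci * (fci - c_index)
  dfci_ds <- numeric(length(s_body))
  dfci_ds[in_ptv] <- 2 * tv_ri / (v_ri_g * tv)
  dfci_ds <- dfci_ds - tv_ri^2 / (v_ri_g^2 * tv)   # every body voxel is in V_RI
  ds_dd <- s_body * (1 - s_body) / tau
  grad <- array(0, dim = dim(vals))
  grad[body_mask] <- dval_dfci * dfci_ds * ds_dd

  hard_tvri <- sum(vals[ptv_mask] >= reference_isodose)
  hard_vri <- sum(vals[body_mask] >= reference_isodose)
  fci_hard <- if (hard_vri > 0) hard_tvri^2 / (hard_vri * tv) else 0

  list(value = value, gradient = grad, f_ci_smooth = fci,
       f_ci_hard = fci_hard, guarded = guarded)
}

#' Total planning objective over beamlet fluences
#'
#' `F_total = alpha * F_MSE + W_HI * F_HI + W_CI * F_CI` evaluated at
#' `d_calc = A %*% w`; the clinical HI and CI terms are included only in
#' mode `"mse_plus_clinical"`. Dose-space gradients are mapped to fluence
#' space through the transpose of the influence matrix.
#'
#' @param w nonnegative fluence vector
#' @param infl an [compute_influence()] influence matrix
#' @param d_pred reference dose grid driving the MSE term
#' @param weights an [objective_weights()] list
#' @param mode `"mse_only"` or `"mse_plus_clinical"`
#' @param masks list with logical `ptv` and `body` masks
#' @return list with `value`, fluence-space `gradient`, and per-term `terms`
#' @export
total_objective <- function(w, infl, d_pred, weights, mode, masks) {
  mode <- match.arg(mode, c("mse_only", "mse_plus_clinical"))
  presc <- weights$reference_isodose_gy
  d_calc <- compute_dose(infl, w)
  mse <- f_mse(d_calc, d_pred, masks$body, prescription_gy = presc)
  value <- weights$alpha * mse$value
  gdose <- weights$alpha * mse$gradient
  terms <- c(mse = weights$alpha * mse$value, hi = 0, ci = 0)
  if (mode == "mse_plus_clinical") {
    hi <- f_hi(d_calc, masks$ptv, w_hi = weights$w_hi,
               prescription_gy = presc,
               percentiles = weights$hi_percentiles)
    ci <- f_ci_smooth(d_calc, masks$ptv, masks$body,
                      reference_isodose = weights$reference_isodose_gy,
                      c_index = weights$c_index, w_ci = weights$w_ci,
                      tau = weights$tau)
    value <- value + hi$value + ci$value
    gdose <- gdose + hi$gradient + ci$gradient
    terms["hi"] <- hi$value
    terms["ci"] <- ci$value
  }
  gvec <- gdose[infl$voxel_index]
  gradient <- as.vector(Matrix::crossprod(infl$A, gvec))
  list(value = value, gradient = gradient, terms = terms)
}
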