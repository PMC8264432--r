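#' Cumulative dose-volume histogram
#'
#' Fraction (%) of structure voxels receiving at least each dose bin edge.
#' Starts at 100% at 0 Gy and is non-increasing in dose.
#'
#' @param dose a [dose_grid()] or array, Gy
#' @param mask logical structure mask (nonempty)
#' @param bin_width_gy dose bin width, Gy (> 0)
#' @param structure structure name carried on the curve
#' @return a `dvh_curve`: `dose_gy` bin edges and `volume_pct`
#' @export
compute_dvh <- function(dose, mask, bin_width_gy = 0.1, structure = "structure") {
  if (!any(mask)) abort_geometry("DVH of an empty structure mask")
  stopifnot_scalar_number(bin_width_gy, "bin_width_gy", positive = TRUE)
  vals <- sort(dose_values(dose)[mask])
  n <- length(vals)
  edges <- seq(0, max(vals) + bin_width_gy, by = bin_width_gy)
  # voxels with dose >= edge: n minus the count strictly below the edge
  pct <- 100 * (n - findInterval(edges, vals, left.open = TRUE)) / n
  structure(list(structure = structure, dose_gy = edges, volume_pct = pct),
            class = "dvh_curve")
}

#' @exportS3Method base::print
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve '%s'> %d bins up to %.1f Gy\n",
              x$structure, length(x$dose_gy), max(x$dose_gy)))
  invisible(x)
}

#' Volume at dose, V_D
#'
#' Percent of structure voxels receiving at least `d_gy` Gy.
#'
#' @param dose a [dose_grid()] or array
#' @param mask logical structure mask (nonempty)
#' @param d_gy dose threshold, Gy
#' @return percent in [0, 100]
#' @export
volume_at_dose <- function(dose, mask, d_gy) {
  if (!any(mask)) abort_geometry("V_D of an empty structure mask")
  100 * mean(dose_values(dose)[mask] >= d_gy)
}

#' Homogeneity index, HI = D5 / D95
#'
#' Evaluated on the PTV with the nearest-rank D_X convention shared with the
#' optimizer ([dose_at_volume()]). 1 is ideal; HI >= 1 always. If D95 is 0
#' the result is `Inf` with attribute `flagged = TRUE`.
#'
#' @param dose a [dose_grid()] or array
#' @param ptv_mask logical PTV mask
#' @return HI (dimensionless)
#' @export
homogeneity_index <- function(dose, ptv_mask) {
  d5 <- dose_at_volume(dose, ptv_mask, 5)
  d95 <- dose_at_volume(dose, ptv_mask, 95)
  if (d95 == 0) {
    return(structure(Inf, flagged = TRUE))
  }
  d5 / d95
}

#' Conformity index, CI = V_R^2 / (V_PTV * V_P)
#'
#' Hard-threshold conformity at the prescription level: `V_R` is the PTV
#' volume covered by the prescription isodose, `V_PTV` the PTV volume and
#' `V_P` the total prescription-isodose volume, counted over the body.
#' 1 is ideal; 0 <= CI <= 1 always. If no body voxel reaches the
#' prescription, returns 0 with attribute `flagged = TRUE`.
#'
#' @param dose a [dose_grid()] or array
#' @param ptv_mask,body_mask logical masks
#' @param prescription_gy prescription dose, Gy
#' @return CI (dimensionless)
#' @export
conformity_index <- function(dose, ptv_mask, body_mask, prescription_gy) {
  if (!any(ptv_mask)) abort_geometry("CI of an empty PTV mask")
  vals <- dose_values(dose)
  v_r <- sum(vals[ptv_mask] >= prescription_gy)
  v_p <- sum(vals[body_mask] >= prescription_gy)
  if (v_p == 0) {
    return(structure(0, flagged = TRUE))
  }
  v_r^2 / (sum(ptv_mask) * v_p)
}

#' Full dosimetric metrics report for one plan
#'
#' The standard index battery: Dmean for every structure; D2, D5, D95 and
#' D98 for the PTV; V15, V25, V35 and V50 for each OAR; HI; CI; and the
#' global maximum dose over the body.
#'
#' @param plan a `plan` (or any object with a `dose` field) to evaluate
#' @param phantom the [phantom()] the plan was computed on
#' @return a `plan_metrics` list; `as.data.frame()` gives one row per metric
#' @export
metrics_report <- function(plan, phantom) {
  dose <- if (inherits(plan, "dose_grid")) plan else plan$dose
  vals <- dose_values(dose)
  if (!same_dim(vals, phantom$density)) {
    abort_argument("plan dose is not congruent with the phantom grid")
  }
  oars <- c("bladder", "femoral_head_l", "femoral_head_r")
  for (nm in c("ptv", "body", oars)) {
    if (is.null(phantom$masks[[nm]])) {
      abort_format(sprintf("phantom is missing structure '%s'", nm))
    }
  }
  presc <- if (!is.null(plan$weights)) plan$weights$reference_isodose_gy else 50

  ptv <- phantom$masks$ptv
  structures <- list(
    ptv = list(
      Dmean = mean(vals[ptv]),
      D2 = dose_at_volume(vals, ptv, 2), D5 = dose_at_volume(vals, ptv, 5),
      D95 = dose_at_volume(vals, ptv, 95), D98 = dose_at_volume(vals, ptv, 98)
    )
  )
  for (nm in oars) {
    m <- phantom$masks[[nm]]
    structures[[nm]] <- list(
      Dmean = mean(vals[m]),
      V15 = volume_at_dose(vals, m, 15), V25 = volume_at_dose(vals, m, 25),
      V35 = volume_at_dose(vals, m, 35), V50 = volume_at_dose(vals, m, 50)
    )
  }
  structure(list(
    structures = structures,
    HI = as.numeric(homogeneity_index(vals, ptv)),
    CI = as.numeric(conformity_index(vals, ptv, phantom$masks$body, presc)),
    global_max = max(vals[phantom$masks$body]),
    plan_id = phantom$case_id,
    mode = if (!is.null(plan$mode)) plan$mode else NA_character_
  ), class = "plan_metrics")
}

#' @export
as.data.frame.plan_metrics <- function(x, ...) {
  rows <- list()
  for (nm in names(x$structures)) {
    for (idx in names(x$structures[[nm]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        plan_id = x$plan_id, mode = x$mode, structure = nm,
        metric = idx, value = x$structures[[nm]][[idx]],
        stringsAsFactors = FALSE)
    }
  }
  for (idx in c("HI", "CI", "global_max")) {
    rows[[length(rows) + 1L]] <- data.frame(
      plan_id = x$plan_id, mode = x$mode, structure = "plan",
      metric = idx, value = x[[idx]], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @exportS3Method base::print
print.plan_metrics <- function(x, ...) {
  cat(sprintf("<plan_metrics '%s' mode %s> HI %.3f, CI %.3f, global max %.1f Gy\n",
              x$plan_id, x$mode, x$HI, x$CI, x$global_max))
  print(utils::head(as.data.frame(x), 20))
  invisible(x)
}

# Pull a named scalar index out of a plan_metrics: "HI", "CI", "global_max",
# or "<structure>_<metric>" such as "ptv_D95" or "bladder_V50".
metric_value <- function(m, index_name) {
  if (index_name %in% c("HI", "CI", "global_max")) return(m[[index_name]])
  parts <- regmatches(index_name, regexpr("_[^_]*$", index_name))
  st <- sub("_[^_]*$", "", index_name)
  idx <- sub("^_", "", parts)
  if (is.null(m$structures[[st]]) || is.null(m$structures[[st]][[idx]])) {
    abort_argument(sprintf("unknown metric '%s'", index_name))
  }
  m$structures[[st]][[idx]]
}

#' Paired cohort comparison of one dosimetric index
#'
#' Two-sided paired-samples t-test of `index_name` between two cohorts of
#' plan metrics, paired by position (case). Significance is declared at
#' p < 0.05. If the paired differences have zero standard deviation the
#' result is degenerate: `t = 0, p = 1` when the cohorts are identical on
#' the index, otherwise a flagged result with `p = NA`.
#'
#' @param metrics_a,metrics_b equal-length lists of [metrics_report()]
#'   results (length >= 2), paired by case
#' @param index_name index to compare, e.g. `"HI"`, `"CI"`, `"ptv_D95"`,
#'   `"bladder_V50"`
#' @return list with `t`, `p`, `significant`, `mean_diff` (a - b), `flagged`
#' @export
compare_cohorts <- function(metrics_a, metrics_b, index_name) {
  if (length(metrics_a) != length(metrics_b)) {
    abort_argument("cohorts must have equal length (paired by case)")
  }
  if (length(metrics_a) < 2L) abort_argument("need at least 2 paired cases")
  a <- vapply(metrics_a, metric_value, numeric(1), index_name = index_name)
  b <- vapply(metrics_b, metric_value, numeric(1), index_name = index_name)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p = 1, significant = FALSE, mean_diff = 0,
                  flagged = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, p = NA_real_, significant = NA,
                mean_diff = mean(d), flagged = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < 0.05, mean_diff = mean(d), flagged = FALSE)
}
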