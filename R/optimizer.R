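#' Optimizer options
#'
#' @param max_iter maximum accepted iterations (default 500)
#' @param gtol convergence tolerance on the infinity norm of the projected
#'   gradient, relative to its value at the initial fluence
#' @param init optional initial fluence; default is uniform fluence scaled so
#'   the mean PTV dose equals the prescription (the influence matrix is
#'   normalized so uniform unit fluence gives mean PTV dose 1 Gy)
#' @param armijo_c sufficient-decrease constant of the backtracking line search
#' @param max_backtracks line-search halvings before giving up on an iteration
#' @return an `optimizer_opts` list
#' @export
optimizer_opts <- function(max_iter = 500, gtol = 1e-6, init = NULL,
                           armijo_c = 1e-4, max_backtracks = 40) {
  structure(list(max_iter = max_iter, gtol = gtol, init = init,
                 armijo_c = armijo_c, max_backtracks = max_backtracks),
            class = "optimizer_opts")
}

#' Optimize beamlet fluences against a reference dose
#'
#' Monotone spectral projected-gradient descent with nonnegativity bounds:
#' each iterate takes a Barzilai–Borwein-scaled gradient step, projects onto
#' `w >= 0`, and is accepted only if the total objective decreases
#' (Armijo backtracking otherwise), so the recorded objective trace is
#' non-increasing by construction. Subgradient steps arising from the
#' order-statistic HI term are handled by the same accepted-step rule.
#'
#' @param infl an [compute_influence()] influence matrix
#' @param d_pred reference dose grid (the "predicted" dose)
#' @param weights an [objective_weights()] list
#' @param mode `"mse_only"` or `"mse_plus_clinical"`
#' @param masks list with logical `ptv` and `body` masks
#' @param opts an [optimizer_opts()] list
#' @return a `plan` object: `fluence`, `dose` (exactly `A %*% fluence`),
#'   `mode`, `weights`, per-iteration `trace` and `term_trace`, `iterations`,
#'   `converged`
#' @export
optimize_fluence <- function(infl, d_pred, weights = objective_weights(),
                             mode = c("mse_only", "mse_plus_clinical"),
                             masks, opts = optimizer_opts()) {
  mode <- match.arg(mode)
  w <- opts$init
  if (is.null(w)) {
    w <- rep(weights$reference_isodose_gy, infl$n_beamlets)
  }
  if (length(w) != infl$n_beamlets || any(w < 0)) {
    abort_argument("initial fluence must be nonnegative with one entry per beamlet")
  }

  ev <- total_objective(w, infl, d_pred, weights, mode, masks)
  if (!is.finite(ev$value)) abort_argument("objective is non-finite at the initial fluence")
  trace <- ev$value
  term_trace <- list(ev$terms)
  alpha <- 1 / max(abs(ev$gradient), 1e-12)
  pg0 <- max(abs(w - pmax(0, w - ev$gradient)))
  converged <- FALSE
  it <- 0L

  while (it < opts$max_iter) {
    accepted <- FALSE
    a <- alpha
    for (bt in seq_len(opts$max_backtracks)) {
      w_new <- pmax(0, w - a * ev$gradient)
      step <- w - w_new
      if (all(step == 0)) break
      ev_new <- total_objective(w_new, infl, d_pred, weights, mode, masks)
      if (is.finite(ev_new$value) &&
          ev_new$value <= ev$value - opts$armijo_c * sum(ev$gradient * step)) {
        accepted <- TRUE
        break
      }
      a <- a / 2
    }
    if (!accepted) { converged <- TRUE; break }

    it <- it + 1L
    s <- w_new - w
    y <- ev_new$gradient - ev$gradient
    sy <- sum(s * y)
    alpha <- if (sy > 0) min(max(sum(s * s) / sy, 1e-10), 1e10) else a
    w <- w_new
    ev <- ev_new
    trace <- c(trace, ev$value)
    term_trace[[length(term_trace) + 1L]] <- ev$terms

    pg <- max(abs(w - pmax(0, w - ev$gradient)))
    if (pg <= opts$gtol * pg0) { converged <- TRUE; break }
  }

  structure(list(
    fluence = w,
    dose = compute_dose(infl, w),
    mode = mode,
    weights = weights,
    trace = trace,
    term_trace = do.call(rbind, term_trace),
    iterations = it,
    converged = converged,
    case_id = infl$case_id
  ), class = "plan")
}

#' @exportS3Method base::print
print.plan <- function(x, ...) {
  cat(sprintf("<plan '%s'> mode %s, %d iterations (%s), F = %.3e\n",
              x$case_id, x$mode, x$iterations,
              if (x$converged) "converged" else "max_iter",
              x$trace[length(x$trace)]))
  invisible(x)
}

#' Planning configuration
#'
#' Defaults mirror a standard pelvic protocol: 50 Gy in 25 fractions
#' delivered with 9 equiangular coplanar beams.
#'
#' @param n_beams number of equiangular beams
#' @param start_deg gantry angle of the first beam
#' @param prescription_gy prescription dose, Gy
#' @param fractions number of fractions
#' @param predictor `"geometric"` (deterministic surrogate, default) or
#'   `"unet"` (requires `unet` to be supplied)
#' @param falloff_mm falloff length of the geometric predictor, mm
#' @param engine an [engine_params()] list
#' @param weights an [objective_weights()] list; its reference isodose is
#'   kept in step with `prescription_gy`
#' @param opts an [optimizer_opts()] list
#' @param unet optional trained [build_unet()] handle for the U-Net predictor
#' @return a `plan_config` list
#' @export
plan_config <- function(n_beams = 9, start_deg = 0,
                        prescription_gy = 50, fractions = 25,
                        predictor = c("geometric", "unet"),
                        falloff_mm = 30,
                        engine = engine_params(),
                        weights = objective_weights(reference_isodose_gy = prescription_gy),
                        opts = optimizer_opts(),
                        unet = NULL) {
  predictor <- match.arg(predictor)
  stopifnot_scalar_number(prescription_gy, "prescription_gy", positive = TRUE)
  if (fractions < 1) abort_argument("`fractions` must be >= 1")
  structure(list(n_beams = n_beams, start_deg = start_deg,
                 prescription_gy = prescription_gy, fractions = fractions,
                 predictor = predictor, falloff_mm = falloff_mm,
                 engine = engine, weights = weights, opts = opts,
                 unet = unet),
            class = "plan_config")
}

with_stage <- function(stage, expr) {
  withCallingHandlers(expr, error = function(e) {
    if (inherits(e, "autoplan_error")) {
      stop(errorCondition(sprintf("[stage %s] %s", stage, conditionMessage(e)),
                          class = class(e)))
    }
  })
}

#' End-to-end automated planning for one phantom
#'
#' Runs the full workflow: beam setup, influence matrix, reference-dose
#' prediction, and fluence optimization in the requested mode. Deterministic
#' given the phantom and configuration. A precomputed influence matrix or
#' reference dose can be injected to share work between the two modes.
#'
#' @param p a [phantom()]
#' @param mode `"mse_only"` or `"mse_plus_clinical"`
#' @param config a [plan_config()]
#' @param influence optional precomputed [compute_influence()] result
#' @param d_pred optional precomputed reference dose grid
#' @return a `plan` with provenance (`config`, predictor used)
#' @export
#' @examples
#' \donttest{
#' p <- generate_phantom(phantom_config(), seed = 1)
#' pl <- auto_plan(p, "mse_plus_clinical")
#' metrics_report(pl, p)
#' }
auto_plan <- function(p, mode = c("mse_only", "mse_plus_clinical"),
                      config = plan_config(), influence = NULL,
                      d_pred = NULL) {
  mode <- match.arg(mode)
  beams <- with_stage("beams", make_equiangular_beams(config$n_beams, config$start_deg))
  if (is.null(influence)) {
    influence <- with_stage("influence", compute_influence(p, beams, config$engine))
  }
  if (is.null(d_pred)) {
    d_pred <- with_stage("predict", {
      if (config$predictor == "geometric") {
        geometric_predictor(p, config$prescription_gy, config$falloff_mm)
      } else {
        if (is.null(config$unet)) abort_argument("predictor 'unet' needs `config$unet`")
        predict_dose(config$unet, p)
      }
    })
  }
  plan <- with_stage("optimize", optimize_fluence(
    influence, d_pred, weights = config$weights, mode = mode,
    masks = list(ptv = p$masks$ptv, body = p$masks$body),
    opts = config$opts))
  plan$config <- config
  plan$predictor <- config$predictor
  plan
}
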