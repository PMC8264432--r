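#' Dose per fraction
#'
#' @param prescription_gy total prescription dose, Gy
#' @param n_fractions number of fractions, >= 1
#' @return Gy per fraction (e.g. 50 Gy / 25 fx = 2 Gy)
#' @export
fraction_dose <- function(prescription_gy, n_fractions) {
  stopifnot_scalar_number(prescription_gy, "prescription_gy", positive = TRUE)
  if (!is.numeric(n_fractions) || length(n_fractions) != 1L || n_fractions < 1) {
    abort_argument("`n_fractions` must be an integer >= 1")
  }
  prescription_gy / n_fractions
}

#' Experiment configuration
#'
#' One self-describing configuration for a full cohort experiment:
#' phantom geometry, cohort size and train/validation/test split, beam and
#' prescription protocol, predictor choice, objective weights, optimizer
#' options and the master seed. Defaults mirror the pelvic protocol
#' (50 Gy / 25 fractions, 9 beams); the 160/10/10 cohort split is scaled by
#' `scale_factor` so a desk-scale run keeps the same proportions.
#'
#' @param n_cases total number of phantoms
#' @param n_train,n_val,n_test split sizes (must sum to `n_cases`)
#' @param scale_factor divides the clinical 180 = 160/10/10 cohort layout;
#'   only used when explicit counts are not given
#' @param phantom a [phantom_config()]
#' @param plan a [plan_config()]
#' @param seed master seed
#' @param out_dir optional output directory for [run_experiment()]
#' @return a `run_config` list
#' @export
run_config <- function(n_cases = NULL, n_train = NULL, n_val = NULL,
                       n_test = NULL, scale_factor = 20,
                       phantom = phantom_config(), plan = plan_config(),
                       seed = 1L, out_dir = NULL) {
  if (is.null(n_cases)) {
    n_train <- max(1L, 160L %/% scale_factor)
    n_val <- max(1L, 10L %/% scale_factor)
    n_test <- max(2L, 10L %/% scale_factor)
    n_cases <- n_train + n_val + n_test
  }
  if (n_train + n_val + n_test != n_cases) {
    abort_argument("split counts must sum to `n_cases`")
  }
  structure(list(n_cases = n_cases, n_train = n_train, n_val = n_val,
                 n_test = n_test, phantom = phantom, plan = plan,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run a full cohort experiment
#'
#' Generates the phantom cohort, splits it into train/validation/test, and
#' for every test case produces both plan modes (MSE-only and
#' MSE-plus-clinical), their metric reports, and — when at least two test
#' cases exist — the paired index-by-index cohort comparison. Deterministic
#' given the configuration. When `config$out_dir` is set, the config
#' snapshot, per-plan metrics and the comparison table are written there as
#' JSON/CSV.
#'
#' @param config a [run_config()]
#' @return an `experiment_report`: `split`, `plans` (per case, both modes),
#'   `metrics` (long data frame), `comparison` (data frame or NULL)
#' @export
run_experiment <- function(config = run_config()) {
  cohort <- generate_cohort(config$n_cases, config$phantom, config$seed)
  ids <- vapply(cohort, function(p) p$case_id, character(1))
  split <- split_cohort(ids, config$n_train, config$n_val, config$n_test,
                        seed = config$seed)
  test_cases <- cohort[match(split$test_ids, ids)]

  plans <- list(); metrics_mse <- list(); metrics_clin <- list()
  for (p in test_cases) {
    infl <- compute_influence(p,
                              make_equiangular_beams(config$plan$n_beams,
                                                     config$plan$start_deg),
                              config$plan$engine)
    pl_mse <- auto_plan(p, "mse_only", config$plan, influence = infl)
    pl_clin <- auto_plan(p, "mse_plus_clinical", config$plan, influence = infl)
    plans[[p$case_id]] <- list(mse_only = pl_mse, mse_plus_clinical = pl_clin)
    metrics_mse[[p$case_id]] <- metrics_report(pl_mse, p)
    metrics_clin[[p$case_id]] <- metrics_report(pl_clin, p)
  }

  metrics_df <- do.call(rbind, c(lapply(metrics_mse, as.data.frame),
                                 lapply(metrics_clin, as.data.frame)))
  rownames(metrics_df) <- NULL

  comparison <- NULL
  if (length(test_cases) >= 2L) {
    index_names <- c("HI", "CI", "global_max",
                     "ptv_Dmean", "ptv_D2", "ptv_D5", "ptv_D95", "ptv_D98",
                     unlist(lapply(c("bladder", "femoral_head_l", "femoral_head_r"),
                                   function(s) paste0(s, "_", c("Dmean", "V15", "V25", "V35", "V50")))))
    comparison <- do.call(rbind, lapply(index_names, function(idx) {
      cmp <- compare_cohorts(metrics_clin, metrics_mse, idx)
      data.frame(index = idx,
                 mean_clinical = mean(vapply(metrics_clin, metric_value,
                                             numeric(1), index_name = idx)),
                 mean_mse = mean(vapply(metrics_mse, metric_value,
                                        numeric(1), index_name = idx)),
                 t = cmp$t, p = cmp$p, significant = cmp$significant,
                 stringsAsFactors = FALSE)
    }))
  }

  report <- structure(list(split = split, plans = plans, metrics = metrics_df,
                           comparison = comparison, config = config),
                      class = "experiment_report")
  if (!is.null(config$out_dir)) write_experiment(report, config$out_dir)
  report
}

write_experiment <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  snapshot <- list(
    n_cases = cfg$n_cases, n_train = cfg$n_train, n_val = cfg$n_val,
    n_test = cfg$n_test, seed = cfg$seed,
    prescription_gy = cfg$plan$prescription_gy, fractions = cfg$plan$fractions,
    n_beams = cfg$plan$n_beams, predictor = cfg$plan$predictor,
    weights = unclass(cfg$plan$weights))
  jsonlite::write_json(snapshot, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(report$comparison)) {
    utils::write.csv(report$comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
  }
  for (cid in names(report$plans)) {
    for (md in names(report$plans[[cid]])) {
      pl <- report$plans[[cid]][[md]]
      utils::write.csv(
        data.frame(iteration = seq_along(pl$trace) - 1L, objective = pl$trace,
                   pl$term_trace),
        file.path(out_dir, sprintf("trace_%s_%s.csv", cid, md)),
        row.names = FALSE)
    }
  }
  invisible(out_dir)
}

#' @exportS3Method base::print
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d cases (%d/%d/%d split), %d test plans x 2 modes\n",
              x$config$n_cases, x$config$n_train, x$config$n_val,
              x$config$n_test, length(x$plans)))
  if (!is.null(x$comparison)) {
    cat("clinical vs MSE-only comparison (paired t):\n")
    print(utils::head(x$comparison, 8))
  }
  invisible(x)
}
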