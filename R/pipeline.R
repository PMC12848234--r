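# End-to-end comparison of the statistical and optimality tracks on one
# site table, mirroring the cross-model evaluation design: all models are
# scored on both Vcmax at growing-season temperature and Vcmax25, plus the
# agreement between the optimality-constant and kinetics-only predictions.

#' Run the full model comparison
#'
#' Fits the kinetics-only (level-1) and kinetics-plus-regression (level-2)
#' statistical models, the optimality-constant model, and the
#' optimality-dynamic model for each requested cost scenario, on one site
#' table; assembles a metrics table (r2, bias, RMSE, AIC for both targets)
#' and the cross-model prediction agreement (r2 between optimality-constant
#' and kinetics-only predicted Vcmax_Tg). A single top-level seed fans out
#' to per-stage seeds by fixed offsets.
#'
#' @param table a `site_table` (aggregated to site means internally).
#' @param scenarios character vector of dynamic-cost scenarios to calibrate
#'   (possibly empty).
#' @param predictors covariates for the empirical track.
#' @param cv a [cv_scheme()]; its seed is re-derived from `seed`.
#' @param ga a [ga_config()].
#' @param seed top-level integer seed.
#' @param kinetics,params parameter objects.
#' @return List of class `vcmax_comparison`: `metrics` (data frame: model,
#'   target, r2, bias, rmse, aic, n), `agreement_r2`, `models` (the fitted
#'   [vcmax_model()] objects).
#' @export
run_comparison <- function(table, scenarios = "edaphic", predictors = NULL,
                           cv = cv_scheme(), ga = ga_config(), seed = 1,
                           kinetics = kinetics_params(),
                           params = optimality_params()) {
  if (!is.null(attr(table, "level")) && attr(table, "level") == "measurement")
    table <- aggregate_site_means(table)
  cv_emp <- cv; cv_emp$seed <- as.integer(seed * 131L + 1L)
  cv_dyn <- cv; cv_dyn$seed <- as.integer(seed * 131L + 2L)
  models <- list()
  models$kinetics <- vcmax_model(table, "kinetics", kinetics = kinetics)
  models$empirical <- tryCatch(
    vcmax_model(table, "empirical", predictors = predictors, cv = cv_emp,
                kinetics = kinetics),
    error = function(e) e)
  models$optimality_constant <- tryCatch(
    vcmax_model(table, "optimality", kinetics = kinetics, params = params),
    error = function(e) e)
  for (sc in scenarios) {
    models[[paste0("optimality_dynamic_", sc)]] <- tryCatch(
      vcmax_model(table, "optimality_dynamic", scenario = sc, cv = cv_dyn,
                  ga = ga, kinetics = kinetics, params = params),
      error = function(e) e)
  }
  rows <- list()
  for (nm in names(models)) {
    m <- models[[nm]]
    if (inherits(m, "error")) {
      rows[[length(rows) + 1L]] <-
        data.frame(model = nm, target = NA, r2 = NA, bias = NA, rmse = NA,
                   aic = NA, n = NA, status = conditionMessage(m))
      next
    }
    for (tg in c("vcmax_tg", "vcmax25")) {
      mt <- m$metrics[[tg]]
      rows[[length(rows) + 1L]] <-
        data.frame(model = nm, target = tg, r2 = mt$r2, bias = mt$bias,
                   rmse = mt$rmse, aic = mt$aic, n = mt$n, status = "ok")
    }
  }
  metrics <- do.call(rbind, rows)
  agreement_r2 <- NA_real_
  if (!inherits(models$optimality_constant, "error")) {
    po <- models$optimality_constant$predictions
    pk <- models$kinetics$predictions
    common <- intersect(po$site_id, pk$site_id)
    agreement_r2 <- stats::cor(
      po$predicted_vcmax_tg[match(common, po$site_id)],
      pk$predicted_vcmax_tg[match(common, pk$site_id)])^2
  }
  structure(list(metrics = metrics, agreement_r2 = agreement_r2,
                 models = models, seed = seed),
            class = "vcmax_comparison")
}

#' @export
print.vcmax_comparison <- function(x, ...) {
  cat("Model comparison (seed", x$seed, ")\n")
  print(x$metrics, row.names = FALSE, digits = 3)
  cat(sprintf("Agreement r2 (optimality-constant vs kinetics-only): %.3f\n",
              x$agreement_r2))
  invisible(x)
}
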