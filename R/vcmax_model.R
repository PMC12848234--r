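# Front-end fitting interface: one function, four methods, one classed
# object with the usual accessors.

#' Fit a Vcmax model to a site table
#'
#' Unified interface to the four model tracks for site-level photosynthetic
#' capacity:
#' \describe{
#'   \item{`"kinetics"`}{enzyme kinetics alone -- one global-mean Vcmax25
#'     scaled to each site's growing-season temperature.}
#'   \item{`"empirical"`}{kinetics plus an OLS regression of Vcmax25 on
#'     environmental and leaf-trait covariates, evaluated by out-of-fold
#'     ensemble prediction under repeated k-fold cross-validation.}
#'   \item{`"optimality"`}{the eco-evolutionary optimality model with a
#'     globally constant unit carbon cost (default 0.053); no fitting.}
#'   \item{`"optimality_dynamic"`}{the optimality model with a site-specific
#'     cost, a linear function of covariates calibrated by genetic algorithm
#'     under the same cross-validation.}
#' }
#' Measurement-level tables are aggregated to site means first.
#'
#' @param data a `site_table` (measurement or site-mean level).
#' @param method model track (see above).
#' @param predictors covariates for the `"empirical"` track (default: all
#'   complete covariates).
#' @param scenario cost scenario for `"optimality_dynamic"` (see
#'   [cost_model()]).
#' @param cost constant unit cost for the `"optimality"` track.
#' @param cv a [cv_scheme()] for the cross-validated tracks.
#' @param ga a [ga_config()] for the dynamic-cost calibration.
#' @param kinetics a [kinetics_params()] object.
#' @param params an [optimality_params()] object.
#' @return An object of class `vcmax_model` with components `method`, `fit`
#'   (track-specific fit object), `predictions` (per-site observed and
#'   predicted Vcmax at growing-season temperature and at 25 C) and
#'   `metrics` (a list of [compute_metrics()] results for both targets).
#' @examples
#' sim <- generate_sites(generator_config(n_sites = 40), seed = 1)
#' fit <- vcmax_model(sim$table, method = "kinetics")
#' print(fit)
#' @export
vcmax_model <- function(data,
                        method = c("kinetics", "empirical", "optimality",
                                   "optimality_dynamic"),
                        predictors = NULL, scenario = "edaphic",
                        cost = 0.053, cv = cv_scheme(), ga = ga_config(),
                        kinetics = kinetics_params(),
                        params = optimality_params()) {
  method <- match.arg(method)
  if (!is.null(attr(data, "level")) && attr(data, "level") == "measurement")
    data <- aggregate_site_means(data)
  df <- as.data.frame(data)
  obs <- observed_vcmax(df, kinetics)
  dS <- entropy_term(df$t_g, kinetics)
  f_tg25 <- temperature_scalar(df$t_g, 25, dS, kinetics)
  k_par <- 1
  if (method == "kinetics") {
    fit <- fit_level1(data, kinetics)
    pred_tg <- fit$predictions$predicted_vcmax_tg
    pred_25 <- fit$predictions$predicted_vcmax25
    k_par <- 1
  } else if (method == "empirical") {
    fit <- fit_level2(data, predictors = predictors, cv = cv,
                      kinetics = kinetics)
    pred_tg <- fit$predictions$predicted_vcmax_tg
    pred_25 <- fit$predictions$predicted_vcmax25
    df <- df[match(fit$predictions$site_id, df$site_id), , drop = FALSE]
    obs <- observed_vcmax(df, kinetics)
    f_tg25 <- f_tg25[match(fit$predictions$site_id,
                           as.data.frame(data)$site_id)]
    k_par <- length(fit$predictors) + 1
  } else if (method == "optimality") {
    need <- c("t_g", "par", "vpd", "ca", "elevation")
    ok <- stats::complete.cases(df[need]) & is.finite(obs$vcmax_tg)
    df <- df[ok, , drop = FALSE]
    obs <- lapply(obs, `[`, ok)
    f_tg25 <- f_tg25[ok]
    opt <- optimal_vcmax(df$t_g, df$par, df$vpd, df$ca, df$elevation,
                         cost = cost, params = params)
    fit <- list(cost = cost, internals = opt)
    pred_tg <- opt$vcmax
    pred_25 <- pred_tg * f_tg25
    k_par <- 1
  } else {
    fit <- fit_cost_ga(data, scenario = scenario, ga = ga, cv = cv,
                       kinetics = kinetics, params = params)
    df <- df[match(fit$predictions$site_id, df$site_id), , drop = FALSE]
    obs <- observed_vcmax(df, kinetics)
    dS <- entropy_term(df$t_g, kinetics)
    f_tg25 <- temperature_scalar(df$t_g, 25, dS, kinetics)
    pred_tg <- fit$predictions$predicted_vcmax_tg
    pred_25 <- pred_tg * f_tg25
    k_par <- length(scenario_covariates(scenario)) + 1
  }
  predictions <- data.frame(site_id = df$site_id,
                            observed_vcmax_tg = obs$vcmax_tg,
                            predicted_vcmax_tg = pred_tg,
                            observed_vcmax25 = obs$vcmax25,
                            predicted_vcmax25 = pred_25)
  # a constant predictor (kinetics-only Vcmax25) has undefined r2; record
  # the remaining metrics with r2 = NA rather than failing
  safe_metrics <- function(o, p, k) {
    tryCatch(compute_metrics(o, p, k = k), error = function(e) {
      resid <- p - o
      structure(list(r2 = NA_real_, bias = mean(resid),
                     rmse = sqrt(mean(resid^2)),
                     aic = 2 * k + length(o) * log(mean(resid^2)),
                     n = length(o), k = k), class = "vcmax_metrics")
    })
  }
  metrics <- list(
    vcmax_tg = safe_metrics(obs$vcmax_tg, pred_tg, k_par),
    vcmax25 = safe_metrics(obs$vcmax25, pred_25, k_par))
  structure(list(method = method, fit = fit, predictions = predictions,
                 metrics = metrics, kinetics = kinetics, params = params,
                 call = match.call()),
            class = "vcmax_model")
}

#' @export
print.vcmax_model <- function(x, ...) {
  cat("Vcmax model -- method:", x$method, "\n")
  cat(sprintf("  %d sites\n", nrow(x$predictions)))
  cat("  Vcmax_Tg : "); print(x$metrics$vcmax_tg)
  cat("  Vcmax_25 : "); print(x$metrics$vcmax25)
  invisible(x)
}

#' @export
summary.vcmax_model <- function(object, ...) {
  out <- list(method = object$method, metrics = object$metrics,
              n = nrow(object$predictions),
              coefficients = stats::coef(object))
  class(out) <- "summary.vcmax_model"
  out
}

#' @export
print.summary.vcmax_model <- function(x, ...) {
  cat("Vcmax model summary -- method:", x$method, "(", x$n, "sites )\n")
  cat("Vcmax_Tg : "); print(x$metrics$vcmax_tg)
  cat("Vcmax_25 : "); print(x$metrics$vcmax25)
  if (!is.null(x$coefficients)) {
    cat("Coefficients:\n")
    print(x$coefficients)
  }
  invisible(x)
}

#' @export
coef.vcmax_model <- function(object, ...) {
  switch(object$method,
         kinetics = c(global_mean_vcmax25 = object$fit$global_mean_vcmax25),
         empirical = object$fit$coefficients,
         optimality = c(cost = object$fit$cost),
         optimality_dynamic = {
           cm <- do.call(rbind, lapply(object$fit$models, function(m)
             c(beta0 = m$beta0, m$betas)))
           colMeans(cm)
         })
}

#' @export
fitted.vcmax_model <- function(object, ...) {
  stats::setNames(object$predictions$predicted_vcmax_tg,
                  object$predictions$site_id)
}

#' @export
residuals.vcmax_model <- function(object, ...) {
  stats::setNames(object$predictions$observed_vcmax_tg -
                    object$predictions$predicted_vcmax_tg,
                  object$predictions$site_id)
}

#' Predict Vcmax for new sites
#'
#' @param object a fitted [vcmax_model()].
#' @param newdata a `site_table` or data frame with the covariates the
#'   method needs; omitted returns the in-sample (out-of-fold where
#'   applicable) predictions.
#' @param ... unused.
#' @return Data frame with `site_id`, `predicted_vcmax_tg`,
#'   `predicted_vcmax25`.
#' @export
predict.vcmax_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(object$predictions[c("site_id", "predicted_vcmax_tg",
                                "predicted_vcmax25")])
  df <- as.data.frame(newdata)
  kin <- object$kinetics
  dS <- entropy_term(df$t_g, kin)
  f25tg <- temperature_scalar(25, df$t_g, dS, kin)
  if (object$method == "kinetics") {
    v25 <- rep(object$fit$global_mean_vcmax25, nrow(df))
    vtg <- v25 * f25tg
  } else if (object$method == "empirical") {
    cf <- object$fit$coefficients
    X <- cbind(1, as.matrix(df[object$fit$predictors]))
    v25 <- drop(X %*% cf)
    vtg <- v25 * f25tg
  } else if (object$method == "optimality") {
    vtg <- optimal_vcmax(df$t_g, df$par, df$vpd, df$ca, df$elevation,
                         cost = object$fit$cost, object$params)$vcmax
    v25 <- vtg / f25tg
  } else {
    preds <- vapply(object$fit$models, function(m) {
      ci <- site_cost(m, df)
      optimal_vcmax(df$t_g, df$par, df$vpd, df$ca, df$elevation,
                    cost = as.numeric(ci), object$params,
                    na_infeasible = TRUE)$vcmax
    }, numeric(nrow(df)))
    preds <- matrix(preds, nrow(df))
    vtg <- rowMeans(preds, na.rm = TRUE)
    v25 <- vtg / f25tg
  }
  data.frame(site_id = if ("site_id" %in% names(df)) df$site_id
             else seq_len(nrow(df)),
             predicted_vcmax_tg = vtg, predicted_vcmax25 = v25)
}

#' Observed-versus-predicted plot
#'
#' @param x a fitted [vcmax_model()].
#' @param target `"vcmax_tg"` or `"vcmax25"`.
#' @param ... passed to [plot()].
#' @export
plot.vcmax_model <- function(x, target = c("vcmax_tg", "vcmax25"), ...) {
  target <- match.arg(target)
  p <- x$predictions
  if (target == "vcmax_tg") {
    obs <- p$observed_vcmax_tg; pred <- p$predicted_vcmax_tg
    lab <- expression(V[c * ",max"] ~ "at" ~ T[g] ~ "(umol m"^-2 ~ s^-1 * ")")
  } else {
    obs <- p$observed_vcmax25; pred <- p$predicted_vcmax25
    lab <- expression(V[c * ",max25"] ~ "(umol m"^-2 ~ s^-1 * ")")
  }
  graphics::plot(obs, pred, xlab = "Observed", ylab = "Predicted",
                 main = paste(x$method, "-", target), ...)
  graphics::abline(0, 1, lty = 2)
  m <- x$metrics[[target]]
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("r2 = %.2f  RMSE = %.2f", m$r2, m$rmse))
  invisible(x)
}
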