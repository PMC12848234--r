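# Two-level statistical track: (1) enzyme kinetics with one global-mean
# Vcmax25; (2) kinetics plus a site-specific OLS regression of Vcmax25 on
# environment and leaf traits, evaluated by out-of-fold ensemble prediction
# under repeated k-fold cross-validation.

#' Kinetics-only (level-1) statistical model
#'
#' Derives site Vcmax25 from field measurements, averages it across all
#' sites, and predicts each site's Vcmax at growing-season temperature as
#' this global mean times the peaked-Arrhenius scalar f(25, Tg).
#'
#' @param table site-mean `site_table`.
#' @param kinetics a [kinetics_params()] object.
#' @return List of class `level1_fit`: `global_mean_vcmax25`, and a
#'   `predictions` data frame with observed/predicted Vcmax_Tg and Vcmax25.
#' @export
fit_level1 <- function(table, kinetics = kinetics_params()) {
  df <- as.data.frame(table)
  obs <- observed_vcmax(df, kinetics)
  mu <- mean(obs$vcmax25, na.rm = TRUE)
  dS <- entropy_term(df$t_g, kinetics)
  pred_tg <- mu * temperature_scalar(25, df$t_g, dS, kinetics)
  structure(list(
    global_mean_vcmax25 = mu,
    predictions = data.frame(site_id = df$site_id,
                             observed_vcmax25 = obs$vcmax25,
                             predicted_vcmax25 = mu,
                             observed_vcmax_tg = obs$vcmax_tg,
                             predicted_vcmax_tg = pred_tg)),
    class = "level1_fit")
}

#' Kinetics + covariate regression (level-2) statistical model
#'
#' Ordinary least-squares regression of site Vcmax25 on environmental and
#' leaf-trait covariates, fitted per repetition x fold of a repeated k-fold
#' cross-validation. Out-of-fold Vcmax25 predictions are averaged across
#' repetitions into the ensemble prediction, which is then carried to
#' growing-season temperature with f(25, Tg). With an empty predictor list
#' the model collapses to the level-1 global mean.
#'
#' @param table site-mean `site_table`.
#' @param predictors character vector of covariate names (default: all
#'   climate + edaphic + trait covariates present and complete in the table).
#' @param cv a [cv_scheme()].
#' @param kinetics a [kinetics_params()] object.
#' @param target `"vcmax_tg"` (default) evaluates against Vcmax at
#'   growing-season temperature; `"vcmax_tmeas"` evaluates against the raw
#'   measurement-temperature values (spurious-correlation check).
#' @return List of class `level2_fit`: `coefficients` (mean over fold
#'   models), `models` (per-fold coefficient vectors), `predictions` data
#'   frame, `predictors`.
#' @export
fit_level2 <- function(table, predictors = NULL, cv = cv_scheme(),
                       kinetics = kinetics_params(),
                       target = c("vcmax_tg", "vcmax_tmeas")) {
  target <- match.arg(target)
  df <- as.data.frame(table)
  if (is.null(predictors)) {
    predictors <- intersect(site_covariates("all"), names(df))
    predictors <- predictors[colSums(is.na(df[predictors])) == 0]
    if (length(predictors) > 1) {
      # drop exactly aliased columns (e.g. sand = 100 - silt - clay) once,
      # in input order, before cross-validation
      Xc <- cbind(1, as.matrix(df[predictors]))
      q <- qr(Xc)
      if (q$rank < ncol(Xc)) {
        keep_idx <- sort(q$pivot[seq_len(q$rank)])
        dropped <- setdiff(predictors, predictors[keep_idx[-1] - 1])
        predictors <- predictors[keep_idx[-1] - 1]
        warning("dropping aliased predictor(s): ",
                paste(dropped, collapse = ", "), call. = FALSE)
      }
    }
  }
  if (length(predictors)) {
    ok <- stats::complete.cases(df[predictors])
    df <- df[ok, , drop = FALSE]
  }
  n <- nrow(df)
  if (n < cv$n_folds * 2) stop("too few sites for the CV scheme", call. = FALSE)
  obs <- observed_vcmax(df, kinetics)
  y <- obs$vcmax25
  assigns <- .cv_assignments(n, cv)
  pred_sum <- numeric(n); pred_cnt <- integer(n)
  models <- list()
  fml <- if (length(predictors))
    stats::reformulate(predictors, response = ".y") else stats::formula(.y ~ 1)
  dat <- cbind(.y = y, df[intersect(predictors, names(df))])
  for (r in seq_len(cv$n_repetitions)) {
    folds <- assigns[[r]]
    for (k in seq_len(cv$n_folds)) {
      cal <- folds != k
      fit <- suppressWarnings(stats::lm(fml, data = dat[cal, , drop = FALSE]))
      cf <- stats::coef(fit)
      if (anyNA(cf)) {
        warning("rank-deficient design; aliased coefficient(s) dropped: ",
                paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
        cf[is.na(cf)] <- 0
        fit$coefficients <- cf
      }
      pv <- stats::predict(fit, newdata = dat[!cal, , drop = FALSE])
      idx <- which(!cal)
      pred_sum[idx] <- pred_sum[idx] + pv
      pred_cnt[idx] <- pred_cnt[idx] + 1L
      models[[length(models) + 1L]] <- cf
    }
  }
  ens25 <- pred_sum / pred_cnt
  dS <- entropy_term(df$t_g, kinetics)
  pred_tg <- ens25 * temperature_scalar(25, df$t_g, dS, kinetics)
  cmat <- do.call(rbind, models)
  preds <- data.frame(site_id = df$site_id,
                      observed_vcmax25 = y, predicted_vcmax25 = ens25,
                      observed_vcmax_tg = obs$vcmax_tg,
                      predicted_vcmax_tg = pred_tg)
  if (target == "vcmax_tmeas") {
    dSm <- entropy_term(df$t_g, kinetics)
    preds$observed_vcmax_tmeas <- df$vcmax_tmeas
    preds$predicted_vcmax_tmeas <-
      ens25 * temperature_scalar(25, df$t_meas, dSm, kinetics)
  }
  structure(list(coefficients = colMeans(cmat), models = models,
                 predictions = preds, predictors = predictors,
                 target = target, cv = cv),
            class = "level2_fit")
}
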