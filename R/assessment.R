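# Model assessment: the four evaluation metrics (r2, bias, RMSE, AIC with
# the RMSE-based natural-log convention), iterative VIF pruning, exhaustive
# corrected-AIC subset selection with Akaike-weight variable importance, and
# partial-regression diagnostics.

#' Performance metrics of a prediction
#'
#' Computes the four assessment metrics: `r2` (squared Pearson correlation),
#' `bias` (mean of predicted minus observed), `rmse`, and
#' `aic = 2*k + n*log(rmse^2)` with the natural logarithm.
#'
#' @param observed,predicted equal-length numeric vectors.
#' @param k number of model parameters entering the AIC.
#' @return List of class `vcmax_metrics` with `r2`, `bias`, `rmse`, `aic`,
#'   `n`, `k`.
#' @examples
#' compute_metrics(1:10, 1:10 + 0.1, k = 2)
#' @export
compute_metrics <- function(observed, predicted, k = 1) {
  ok <- is.finite(observed) & is.finite(predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  n <- length(observed)
  if (n == 0L || n != length(predicted))
    stop("observed and predicted must be equal-length non-empty vectors",
         call. = FALSE)
  resid <- predicted - observed
  rmse <- sqrt(mean(resid^2))
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    if (rmse == 0) {
      r2 <- 1  # perfect reproduction of a constant
    } else stop("r2 undefined: zero-variance vector", call. = FALSE)
  } else r2 <- stats::cor(observed, predicted)^2
  structure(list(r2 = r2, bias = mean(resid), rmse = rmse,
                 aic = 2 * k + n * log(rmse^2), n = n, k = k),
            class = "vcmax_metrics")
}

#' @export
print.vcmax_metrics <- function(x, ...) {
  cat(sprintf("r2 = %.3f  bias = %.3f  RMSE = %.3f  AIC = %.1f  (n = %d, k = %d)\n",
              x$r2, x$bias, x$rmse, x$aic, x$n, x$k))
  invisible(x)
}

# VIF of each candidate by regressing it on the others: 1/(1 - R2)
.vif <- function(X) {
  p <- ncol(X)
  vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    1 / max(1 - r2, .Machine$double.eps)
  }, 0)
}

#' Iterative collinearity pruning by VIF and pairwise correlation
#'
#' First removes, one at a time, the candidate with the largest variance
#' inflation factor while any VIF is at or above `vif_cutoff`; then, while
#' any surviving pair has absolute Pearson correlation at or above
#' `cor_cutoff`, removes from the worst-offending pair the member with the
#' larger mean absolute correlation to all remaining variables (ties broken
#' by input order). Returns the retained set and an ordered removal log.
#'
#' @param table `site_table` or data frame.
#' @param candidates character vector of candidate columns (>= 2).
#' @param vif_cutoff VIF threshold (default 10).
#' @param cor_cutoff absolute-correlation threshold (default 0.7).
#' @return List with `retained` (character), `removed` (data frame: variable,
#'   reason, value), `vif` (final VIFs).
#' @export
vif_prune <- function(table, candidates, vif_cutoff = 10, cor_cutoff = 0.7) {
  df <- as.data.frame(table)
  stopifnot(length(candidates) >= 2, all(candidates %in% names(df)))
  X <- as.matrix(df[candidates])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) <= length(candidates))
    stop("too few complete rows for VIF pruning", call. = FALSE)
  keep <- candidates
  removed <- data.frame(variable = character(0), reason = character(0),
                        value = numeric(0))
  repeat {
    if (length(keep) < 2) break
    v <- .vif(X[, keep, drop = FALSE])
    if (max(v) < vif_cutoff) break
    worst <- keep[which.max(v)]
    removed <- rbind(removed, data.frame(variable = worst, reason = "vif",
                                         value = max(v)))
    keep <- setdiff(keep, worst)
  }
  repeat {
    if (length(keep) < 2) break
    cm <- abs(stats::cor(X[, keep, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm) < cor_cutoff) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- keep[idx]
    meanabs <- rowMeans(abs(stats::cor(X[, keep, drop = FALSE])))[idx]
    drop_var <- if (meanabs[2] > meanabs[1]) pair[2] else pair[1]
    removed <- rbind(removed, data.frame(variable = drop_var, reason = "cor",
                                         value = max(cm)))
    keep <- setdiff(keep, drop_var)
  }
  final_vif <- if (length(keep) >= 2) .vif(X[, keep, drop = FALSE])
  else stats::setNames(rep(1, length(keep)), keep)
  list(retained = keep, removed = removed,
       vif = stats::setNames(final_vif, keep))
}

#' Exhaustive subset selection with corrected AIC and Akaike weights
#'
#' Fits every subset of the candidate predictors by OLS, scores each with
#' the small-sample corrected AIC (`AICc = AIC + 2k(k+1)/(n-k-1)` on the
#' RMSE-based AIC, or on the Gaussian log-likelihood AIC when
#' `ic = "loglik"`), converts scores to Akaike weights
#' `w_i = exp(-Delta_i/2) / sum exp(-Delta_j/2)`, and sums weights over the
#' models containing each variable to obtain its relative importance, with
#' the `important` flag set at `cutoff` (default 0.8).
#'
#' @param table `site_table` or data frame.
#' @param response response column name.
#' @param candidates candidate predictor names (at most 20).
#' @param cutoff importance cutoff flagging important variables.
#' @param ic `"rmse"` (default) scores models with the RMSE-based AIC;
#'   `"loglik"` uses the Gaussian likelihood AIC.
#' @param include_null include the intercept-only model in the set.
#' @return List of class `importance_fit`: `models` (data frame: formula
#'   terms, k, rmse, aic, aicc, delta, weight), `importance` (data frame:
#'   variable, importance, important, sign of the full-model partial
#'   effect).
#' @export
exhaustive_selection <- function(table, response, candidates, cutoff = 0.8,
                                 ic = c("rmse", "loglik"),
                                 include_null = TRUE) {
  ic <- match.arg(ic)
  df <- as.data.frame(table)
  p <- length(candidates)
  stopifnot(p >= 1, p <= 20, response %in% names(df),
            all(candidates %in% names(df)))
  df <- df[stats::complete.cases(df[c(response, candidates)]), , drop = FALSE]
  n <- nrow(df)
  y <- df[[response]]
  X <- as.matrix(df[candidates])
  subsets <- seq.int(if (include_null) 0L else 1L, 2^p - 1L)
  rows <- lapply(subsets, function(mask) {
    inc <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    k <- length(inc) + 1L              # coefficients incl. intercept
    if (n - k - 1 <= 0) return(NULL)   # AICc undefined; skip with log entry
    fit <- stats::lm.fit(cbind(1, X[, inc, drop = FALSE]), y)
    rmse <- sqrt(mean(fit$residuals^2))
    aic <- if (ic == "rmse") 2 * k + n * log(rmse^2)
    else {
      ll <- -n / 2 * (log(2 * pi) + log(rmse^2) + 1)
      2 * (k + 1) - 2 * ll             # +1 for sigma
    }
    data.frame(terms = paste(candidates[inc], collapse = "+"),
               mask = mask, k = k, rmse = rmse, aic = aic,
               aicc = aic + 2 * k * (k + 1) / (n - k - 1))
  })
  models <- do.call(rbind, rows)
  if (is.null(models) || !nrow(models))
    stop("no admissible models (n too small)", call. = FALSE)
  models$delta <- models$aicc - min(models$aicc)
  w <- exp(-models$delta / 2)
  models$weight <- w / sum(w)
  imp <- vapply(seq_len(p), function(j) {
    inmod <- bitwAnd(models$mask, bitwShiftL(1L, j - 1L)) != 0L
    sum(models$weight[inmod])
  }, 0)
  full <- stats::lm.fit(cbind(1, X), y)
  signs <- sign(full$coefficients[-1])
  importance <- data.frame(variable = candidates, importance = imp,
                           important = imp >= cutoff,
                           effect_sign = unname(signs))
  importance <- importance[order(-importance$importance), ]
  rownames(importance) <- NULL
  structure(list(models = models[order(models$aicc), ],
                 importance = importance, n = n, cutoff = cutoff, ic = ic),
            class = "importance_fit")
}

#' Partial-regression diagnostics
#'
#' Residualizes both the response and the focal predictor on the remaining
#' predictors; the slope of the residual-on-residual regression equals the
#' focal variable's coefficient in the full OLS model (Frisch-Waugh), and a
#' pointwise 95 percent confidence band around the fitted partial
#' relationship is returned for plotting.
#'
#' @param table `site_table` or data frame.
#' @param response response column name.
#' @param focal focal predictor name.
#' @param others character vector of the remaining predictors (may be empty).
#' @return List of class `partial_regression`: `x_resid`, `y_resid`,
#'   `slope`, `se`, `conf_band` (data frame x, fit, lwr, upr).
#' @export
partial_regression <- function(table, response, focal, others = character(0)) {
  df <- as.data.frame(table)
  stopifnot(!(focal %in% others))
  cols <- c(response, focal, others)
  df <- df[stats::complete.cases(df[cols]), , drop = FALSE]
  y <- df[[response]]; x <- df[[focal]]
  if (length(others)) {
    Z <- cbind(1, as.matrix(df[others]))
    if (qr(Z)$rank < ncol(Z))
      stop("aliased columns among the conditioning predictors", call. = FALSE)
    y_res <- stats::lm.fit(Z, y)$residuals
    x_res <- stats::lm.fit(Z, x)$residuals
  } else {
    y_res <- y - mean(y); x_res <- x - mean(x)
  }
  fit <- stats::lm(y_res ~ x_res)
  xs <- seq(min(x_res), max(x_res), length.out = 100)
  pr <- stats::predict(fit, newdata = data.frame(x_res = xs),
                       interval = "confidence", level = 0.95)
  structure(list(x_resid = x_res, y_resid = y_res,
                 slope = unname(stats::coef(fit)[2]),
                 se = summary(fit)$coefficients[2, 2],
                 conf_band = data.frame(x = xs, fit = pr[, 1],
                                        lwr = pr[, 2], upr = pr[, 3])),
            class = "partial_regression")
}
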