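# Dynamic unit-cost model: the total unit carbon cost of photosynthetic
# machinery at site i is a linear function of site covariates,
# c_i = beta0 + sum_j beta_j x_ij, calibrated by a real-coded genetic
# algorithm minimizing the RMSE of optimality-predicted Vcmax at
# growing-season temperature under repeated k-fold cross-validation.

#' Cost-model specification
#'
#' @param scenario one of `"constant"` (globally fixed cost),
#'   `"edaphic"` (ten soil covariates), `"env_traits"` (six climate + ten
#'   edaphic covariates + LMA + leaf N), or `"top5"` (leaf N, VPD, soil pH,
#'   precipitation, elevation).
#' @param beta0 intercept; for `"constant"` this is the cost itself
#'   (default 0.053).
#' @param betas named numeric vector of covariate coefficients (on the
#'   standardized scale when `center`/`scale` are set). Empty for
#'   `"constant"`.
#' @param center,scale optional named vectors standardizing covariates before
#'   the linear combination (as stored by [fit_cost_ga()] from calibration
#'   folds).
#' @param feasible_c_bounds unitless (low, high) range outside which site
#'   costs are flagged.
#' @return An object of class `cost_model`.
#' @export
cost_model <- function(scenario = c("constant", "edaphic", "env_traits", "top5"),
                       beta0 = 0.053, betas = numeric(0),
                       center = NULL, scale = NULL,
                       feasible_c_bounds = c(0.001, 0.5)) {
  scenario <- match.arg(scenario)
  if (scenario == "constant" && length(betas))
    stop("constant scenario takes no covariate coefficients", call. = FALSE)
  if (length(betas)) {
    want <- scenario_covariates(scenario)
    if (!all(names(betas) %in% want))
      stop("betas name covariates outside the scenario: ",
           paste(setdiff(names(betas), want), collapse = ", "), call. = FALSE)
  }
  structure(list(scenario = scenario, beta0 = beta0, betas = betas,
                 center = center, scale = scale,
                 feasible_c_bounds = feasible_c_bounds),
            class = "cost_model")
}

#' Covariate set of a cost scenario
#'
#' @param scenario scenario name (see [cost_model()]).
#' @return Ordered character vector of canonical covariate names: ten edaphic
#'   fields for `"edaphic"`, all climate + edaphic + trait fields for
#'   `"env_traits"`, and the five most important variables (leaf N, VPD, soil
#'   pH, precipitation, elevation) for `"top5"`.
#' @export
scenario_covariates <- function(scenario = c("constant", "edaphic",
                                             "env_traits", "top5")) {
  scenario <- match.arg(scenario)
  switch(scenario,
         constant = character(0),
         edaphic = site_covariates("edaphic"),
         env_traits = c(site_covariates("climate"), site_covariates("edaphic"),
                        site_covariates("traits")),
         top5 = c("na", "vpd", "soil_ph", "precipitation", "elevation"))
}

#' Site-specific unit cost
#'
#' Evaluates `c_i = beta0 + sum_j beta_j x_ij` for each row of a site table
#' (standardizing covariates first when the model carries `center`/`scale`).
#' Values outside `feasible_c_bounds` are flagged via the `"infeasible"`
#' attribute, never clamped.
#'
#' @param model a [cost_model()].
#' @param table a `site_table` or data frame holding the model's covariates.
#' @return Numeric vector of site costs with logical attribute
#'   `"infeasible"`.
#' @export
site_cost <- function(model, table) {
  df <- as.data.frame(table)
  vars <- names(model$betas)
  ci <- rep(model$beta0, max(nrow(df), 1L))
  if (length(vars)) {
    missing_cov <- setdiff(vars, names(df))
    if (length(missing_cov))
      stop("schema error: covariate(s) absent from table: ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    X <- as.matrix(df[vars])
    if (any(is.na(X)))
      stop("schema error: missing covariate values for site cost", call. = FALSE)
    if (!is.null(model$center)) X <- sweep(X, 2, model$center[vars], "-")
    if (!is.null(model$scale)) X <- sweep(X, 2, model$scale[vars], "/")
    ci <- ci + drop(X %*% model$betas)
  }
  attr(ci, "infeasible") <- ci < model$feasible_c_bounds[1] |
    ci > model$feasible_c_bounds[2]
  ci
}

#' Cross-validation scheme
#'
#' @param n_folds number of folds (>= 2).
#' @param n_repetitions number of independent repetitions of the k-fold
#'   split.
#' @param seed integer seed governing all fold assignments.
#' @return An object of class `cv_scheme`.
#' @export
cv_scheme <- function(n_folds = 5, n_repetitions = 100, seed = 1) {
  stopifnot(n_folds >= 2, n_repetitions >= 1)
  structure(list(n_folds = n_folds, n_repetitions = n_repetitions,
                 seed = as.integer(seed)), class = "cv_scheme")
}

# fold assignments: list (one per repetition) of integer vectors in 1..k;
# every record lands in a validation fold exactly once per repetition.
.cv_assignments <- function(n, cv) {
  rs <- .local_rng(cv$seed)
  lapply(seq_len(cv$n_repetitions), function(r) {
    perm <- rs$sample(n)
    folds <- integer(n)
    folds[perm] <- rep_len(seq_len(cv$n_folds), n)
    folds
  })
}

# Small self-contained RNG scope so CV/GA draws do not disturb the global
# stream beyond their own seed.
.local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    f()
  }
  list(sample = function(n, size = n) with_state(function() sample.int(n, size)),
       runif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
       rnorm = function(n, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd)),
       rint = function(n, max) with_state(function() sample.int(max, n, replace = TRUE)))
}

#' Genetic-algorithm configuration
#'
#' Real-coded GA defaults: population 100, 200 generations, tournament
#' selection of size 3, blend (BLX) crossover with rate 0.7, Gaussian
#' mutation with standard deviation 10 percent of each bound range, and one
#' elite carried over per generation. Site costs outside the feasible
#' interval are clamped to its boundary for prediction and contribute a
#' graded penalty proportional to the violation, keeping the search surface
#' continuous rather than disqualifying the candidate.
#'
#' @param population_size individuals per generation (>= 10).
#' @param n_generations generations to evolve.
#' @param crossover_rate probability a pair undergoes blend crossover.
#' @param mutation_scale mutation SD as a fraction of each bound range.
#' @param mutation_rate per-gene mutation probability.
#' @param tournament_size tournament selection size.
#' @param elitism elites preserved unchanged each generation.
#' @param penalty fitness penalty per unit of summed cost-feasibility
#'   violation.
#' @param beta_bound symmetric bound on standardized covariate coefficients.
#' @param beta0_bounds bounds on the intercept.
#' @param polish refine the GA's best candidate with a bounded quasi-Newton
#'   step (L-BFGS-B) on the same objective.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 100, n_generations = 200,
                      crossover_rate = 0.7, mutation_scale = 0.1,
                      mutation_rate = 0.2, tournament_size = 3, elitism = 1,
                      penalty = 1000, beta_bound = 0.2,
                      beta0_bounds = c(0.005, 0.3), polish = TRUE) {
  stopifnot(population_size >= 10, n_generations >= 1)
  structure(list(population_size = population_size,
                 n_generations = n_generations,
                 crossover_rate = crossover_rate,
                 mutation_scale = mutation_scale,
                 mutation_rate = mutation_rate,
                 tournament_size = tournament_size, elitism = elitism,
                 penalty = penalty, beta_bound = beta_bound,
                 beta0_bounds = beta0_bounds, polish = polish),
            class = "ga_config")
}

#' Real-coded genetic-algorithm minimizer
#'
#' Generic bounded minimizer used for cost-model calibration: tournament
#' selection, blend crossover, Gaussian mutation and elitism. `fitness`
#' receives the whole population as a matrix (one row per candidate) and
#' returns one value per row, so vectorized objectives are evaluated in a
#' single call per generation.
#'
#' @param fitness function(matrix) -> numeric vector to minimize.
#' @param lower,upper bound vectors, one entry per decision variable.
#' @param config a [ga_config()].
#' @param seed integer seed.
#' @return List with `par` (best candidate), `value` (its fitness) and
#'   `trace` (best fitness per generation).
#' @export
ga_optimize <- function(fitness, lower, upper, config = ga_config(), seed = 1) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  rs <- .local_rng(seed)
  np <- config$population_size
  span <- upper - lower
  pop <- matrix(rs$runif(np * d), np, d)
  pop <- sweep(sweep(pop, 2, span, "*"), 2, lower, "+")
  fit <- fitness(pop)
  trace <- numeric(config$n_generations)
  for (gen in seq_len(config$n_generations)) {
    # tournament selection (vectorized): per slot, best of k random rows
    k <- config$tournament_size
    cand <- matrix(rs$rint(np * k, np), np, k)
    sel <- cand[cbind(seq_len(np),
                      max.col(-matrix(fit[cand], np, k), ties.method = "first"))]
    parents <- pop[sel, , drop = FALSE]
    # blend crossover on consecutive pairs
    off <- parents
    do_cx <- rs$runif(np %/% 2) < config$crossover_rate
    a <- matrix(rs$runif((np %/% 2) * d, -0.5, 1.5), np %/% 2, d)
    i1 <- seq(1, np - 1, by = 2); i2 <- i1 + 1
    p1 <- parents[i1, , drop = FALSE]; p2 <- parents[i2, , drop = FALSE]
    c1 <- a * p1 + (1 - a) * p2
    c2 <- a * p2 + (1 - a) * p1
    off[i1[do_cx], ] <- c1[do_cx, , drop = FALSE]
    off[i2[do_cx], ] <- c2[do_cx, , drop = FALSE]
    # Gaussian mutation
    mut <- matrix(rs$runif(np * d) < config$mutation_rate, np, d)
    noise <- matrix(rs$rnorm(np * d), np, d) *
      matrix(span * config$mutation_scale, np, d, byrow = TRUE)
    off[mut] <- off[mut] + noise[mut]
    off <- pmin(pmax(off, matrix(lower, np, d, byrow = TRUE)),
                matrix(upper, np, d, byrow = TRUE))
    # elitism: keep the current best unchanged
    if (config$elitism > 0) {
      eli <- order(fit)[seq_len(config$elitism)]
      off[seq_len(config$elitism), ] <- pop[eli, , drop = FALSE]
    }
    pop <- off
    fit <- fitness(pop)
    trace[gen] <- min(fit)
  }
  best <- which.min(fit)
  par <- pop[best, ]; val <- fit[best]
  if (isTRUE(config$polish)) {
    pol <- tryCatch(
      stats::optim(par, function(p) fitness(matrix(p, 1)),
                   method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(pol) && is.finite(pol$value) && pol$value < val) {
      par <- pol$par; val <- pol$value
    }
  }
  list(par = par, value = val, trace = trace)
}

# Precompute environment-dependent optimality terms that do not involve the
# cost, so GA fitness reduces to the omega recomputation per candidate.
.optimality_precompute <- function(table, params = optimality_params()) {
  df <- as.data.frame(table)
  press <- atmospheric_pressure(df$elevation)
  co <- photosynthesis_coefficients(df$t_g, press, params)
  ch <- optimal_chi(co$gammastar, co$K, co$eta_star,
                    df$ca * 1e-6 * press, df$vpd * 1000, params)
  list(m = ch$m, mc = ch$mc, amp = params$phi0 * df$par,
       theta = params$theta)
}

# predicted Vcmax_Tg for a matrix of candidate coefficient vectors.
# B: pop x (1+p) (intercept first); Xs: n x p standardized covariates.
# With clamp = TRUE, site costs outside the feasible interval
# (c_lo, m/(8 theta)) are clamped to its edge and the violation magnitude is
# returned, so the calibration objective stays continuous; with
# clamp = FALSE infeasible entries come back NA.
.vcmax_tg_matrix <- function(B, Xs, pre, clamp = FALSE) {
  cmat <- matrix(B[, 1], nrow(Xs), nrow(B), byrow = TRUE)
  if (ncol(B) > 1)
    cmat <- cmat + Xs %*% t(B[, -1, drop = FALSE])
  m <- pre$m; theta <- pre$theta
  viol <- NULL
  if (clamp) {
    c_lo <- 1e-4
    c_hi <- m / (8 * theta) * 0.9999
    viol <- pmax(cmat - c_hi, 0) + pmax(c_lo - cmat, 0)
    cmat <- pmin(pmax(cmat, c_lo), c_hi)
  }
  om <- .omega(theta, as.vector(cmat), rep(m, ncol(cmat)))
  om <- matrix(om, nrow(Xs), ncol(cmat))
  omst <- 1 + om - sqrt((1 + om)^2 - 4 * theta * om)
  V <- (pre$amp * (pre$m / pre$mc) / (8 * theta)) * omst
  if (clamp) list(V = V, viol = viol) else V
}

#' Observed Vcmax at growing-season temperature
#'
#' Derives the field-based response of the calibration: Vcmax at measurement
#' temperature is first standardized to 25 C and then brought to the site's
#' growing-season temperature, both with the entropy term acclimated to
#' growing-season temperature.
#'
#' @param table a `site_table` with `vcmax_tmeas`, `t_meas`, `t_g`.
#' @param kinetics a [kinetics_params()] object.
#' @return List with numeric vectors `vcmax25` and `vcmax_tg`.
#' @export
observed_vcmax <- function(table, kinetics = kinetics_params()) {
  df <- as.data.frame(table)
  v25 <- convert_vcmax(df$vcmax_tmeas, df$t_meas, 25, df$t_g, kinetics)
  vtg <- convert_vcmax(v25, 25, df$t_g, df$t_g, kinetics)
  list(vcmax25 = v25, vcmax_tg = vtg)
}

#' Calibrate the dynamic cost model by GA under repeated cross-validation
#'
#' For each repetition x fold, fits the cost coefficients (Eq.-style linear
#' model of the unit cost on standardized covariates) by minimizing the RMSE
#' between observed and optimality-modelled Vcmax at growing-season
#' temperature on the calibration folds, then predicts the held-out fold.
#' Per-site predictions are averaged across repetitions into the ensemble
#' out-of-fold prediction. Covariates are z-scored with means/SDs from the
#' calibration folds only.
#'
#' @param table site-mean `site_table` with complete covariates for the
#'   scenario.
#' @param scenario cost scenario (see [cost_model()]).
#' @param ga a [ga_config()].
#' @param cv a [cv_scheme()].
#' @param kinetics a [kinetics_params()] object.
#' @param params an [optimality_params()] object.
#' @param covariates optional explicit covariate subset overriding the
#'   scenario's list (e.g. for low-dimensional calibration experiments).
#' @return List of class `cost_fit`: `models` (per rep x fold
#'   [cost_model()]s), `predictions` (data frame: site_id, observed and
#'   ensemble-predicted Vcmax_Tg), `fold_rmse` (calibration RMSE per fold),
#'   `failed_folds`.
#' @export
fit_cost_ga <- function(table, scenario = "edaphic", ga = ga_config(),
                        cv = cv_scheme(), kinetics = kinetics_params(),
                        params = optimality_params(), covariates = NULL) {
  df <- as.data.frame(table)
  if (!is.null(attr(table, "level")) && attr(table, "level") != "site-mean")
    stop("fit_cost_ga expects a site-mean table", call. = FALSE)
  vars <- if (is.null(covariates)) scenario_covariates(scenario)
  else covariates
  need <- c("vcmax_tmeas", "t_meas", "t_g", "par", "vpd", "ca", "elevation", vars)
  ok <- stats::complete.cases(df[unique(need)])
  if (!all(ok)) df <- df[ok, , drop = FALSE]
  n <- nrow(df)
  if (n < cv$n_folds) stop("fewer sites than folds", call. = FALSE)
  obs <- observed_vcmax(df, kinetics)$vcmax_tg
  pre <- .optimality_precompute(df, params)
  X <- if (length(vars)) as.matrix(df[vars]) else matrix(0, n, 0)
  p <- ncol(X)
  lower <- c(ga$beta0_bounds[1], rep(-ga$beta_bound, p))
  upper <- c(ga$beta0_bounds[2], rep(ga$beta_bound, p))
  assigns <- .cv_assignments(n, cv)
  pred_sum <- numeric(n); pred_cnt <- integer(n)
  models <- list(); fold_rmse <- numeric(0); failed <- 0L; total <- 0L
  for (r in seq_len(cv$n_repetitions)) {
    folds <- assigns[[r]]
    for (k in seq_len(cv$n_folds)) {
      total <- total + 1L
      cal <- folds != k
      if (p) {
        ctr <- colMeans(X[cal, , drop = FALSE])
        scl <- apply(X[cal, , drop = FALSE], 2, stats::sd)
        scl[scl == 0 | !is.finite(scl)] <- 1
        Xs_cal <- sweep(sweep(X[cal, , drop = FALSE], 2, ctr), 2, scl, "/")
        Xs_val <- sweep(sweep(X[!cal, , drop = FALSE], 2, ctr), 2, scl, "/")
      } else {
        ctr <- scl <- NULL
        Xs_cal <- matrix(0, sum(cal), 0); Xs_val <- matrix(0, sum(!cal), 0)
      }
      pre_cal <- list(m = pre$m[cal], mc = pre$mc[cal], amp = pre$amp[cal],
                      theta = pre$theta)
      obs_cal <- obs[cal]
      fitness <- function(B) {
        r <- .vcmax_tg_matrix(B, Xs_cal, pre_cal, clamp = TRUE)
        rmse <- sqrt(colMeans((r$V - obs_cal)^2))
        rmse + ga$penalty * colSums(r$viol)
      }
      res <- ga_optimize(fitness, lower, upper, ga,
                         seed = (cv$seed * 1000L + r * 97L + k) %% .Machine$integer.max)
      best <- res$par
      mdl <- cost_model(scenario = scenario, beta0 = best[1],
                        betas = if (p) stats::setNames(best[-1], vars) else numeric(0),
                        center = if (p) stats::setNames(ctr, vars) else NULL,
                        scale = if (p) stats::setNames(scl, vars) else NULL)
      mdl$repetition <- r; mdl$fold <- k
      pre_val <- list(m = pre$m[!cal], mc = pre$mc[!cal], amp = pre$amp[!cal],
                      theta = pre$theta)
      rv <- .vcmax_tg_matrix(matrix(best, 1), Xs_val, pre_val, clamp = TRUE)
      pv <- drop(rv$V)
      if (all(is.na(pv))) {
        failed <- failed + 1L
        next
      }
      val_idx <- which(!cal)
      fin <- is.finite(pv)
      pred_sum[val_idx[fin]] <- pred_sum[val_idx[fin]] + pv[fin]
      pred_cnt[val_idx[fin]] <- pred_cnt[val_idx[fin]] + 1L
      models[[length(models) + 1L]] <- mdl
      fold_rmse <- c(fold_rmse, res$value)
    }
  }
  if (failed > 0.1 * total)
    stop(sprintf("calibration aborted: %d of %d folds produced only infeasible costs",
                 failed, total), call. = FALSE)
  ensemble <- ifelse(pred_cnt > 0, pred_sum / pred_cnt, NA_real_)
  preds <- data.frame(site_id = df$site_id, observed_vcmax_tg = obs,
                      predicted_vcmax_tg = ensemble, n_reps = pred_cnt)
  structure(list(scenario = scenario, models = models, predictions = preds,
                 fold_rmse = fold_rmse, failed_folds = failed,
                 n_folds_total = total, cv = cv, ga = ga),
            class = "cost_fit")
}
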