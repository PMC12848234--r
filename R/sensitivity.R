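# Variance-based global sensitivity analysis: Sobol' quasi-random sampling
# over the optimality model's environmental inputs and Saltelli-style
# first-order variance partitioning of the model output.

# Joe & Kuo primitive polynomials and initial direction numbers for the
# first 13 Sobol' dimensions (dimension 1 is the van der Corput sequence).
.SOBOL_DIRS <- list(
  list(s = 1, a = 0,  m = c(1)),
  list(s = 2, a = 1,  m = c(1, 3)),
  list(s = 3, a = 1,  m = c(1, 3, 1)),
  list(s = 3, a = 2,  m = c(1, 1, 1)),
  list(s = 4, a = 1,  m = c(1, 1, 3, 3)),
  list(s = 4, a = 4,  m = c(1, 3, 5, 13)),
  list(s = 5, a = 2,  m = c(1, 1, 5, 5, 17)),
  list(s = 5, a = 4,  m = c(1, 1, 5, 5, 5)),
  list(s = 5, a = 7,  m = c(1, 1, 7, 11, 19)),
  list(s = 5, a = 11, m = c(1, 1, 5, 1, 1)),
  list(s = 5, a = 13, m = c(1, 1, 1, 3, 11)),
  list(s = 5, a = 14, m = c(1, 3, 5, 5, 31))
)
.SOBOL_BITS <- 30L

# direction integers for one dimension, scaled to 2^.SOBOL_BITS
.sobol_directions <- function(dim, nbits = .SOBOL_BITS) {
  v <- integer(nbits)
  if (dim == 1L) {
    for (k in seq_len(nbits)) v[k] <- bitwShiftL(1L, nbits - k)
    return(v)
  }
  dd <- .SOBOL_DIRS[[dim - 1L]]
  s <- dd$s; a <- dd$a; m <- dd$m
  for (k in seq_len(min(s, nbits))) v[k] <- bitwShiftL(m[k], nbits - k)
  if (nbits > s) {
    for (k in (s + 1L):nbits) {
      vk <- bitwXor(v[k - s], bitwShiftR(v[k - s], s))
      if (s > 1) for (i in seq_len(s - 1L)) {
        if (bitwAnd(bitwShiftR(a, s - 1L - i), 1L) == 1L)
          vk <- bitwXor(vk, v[k - i])
      }
      v[k] <- vk
    }
  }
  v
}

# first n points of the d-dimensional Sobol' sequence in [0,1)^d
# (Gray-code order, including the initial origin point), optionally with a
# seeded random digital shift per dimension.
.sobol_unit <- function(n, d, seed = NULL) {
  stopifnot(d >= 1, d <= length(.SOBOL_DIRS) + 1L)
  X <- matrix(0L, n, d)
  for (j in seq_len(d)) {
    v <- .sobol_directions(j)
    x <- 0L
    col <- integer(n)
    col[1] <- 0L
    if (n > 1) for (i in 2:n) {
      ii <- i - 2L
      c_ <- 1L
      while (bitwAnd(ii, 1L) == 1L) { ii <- bitwShiftR(ii, 1L); c_ <- c_ + 1L }
      x <- bitwXor(x, v[c_])
      col[i] <- x
    }
    X[, j] <- col
  }
  if (!is.null(seed)) {
    rs <- .local_rng(seed)
    shift <- as.integer(floor(rs$runif(d) * 2^.SOBOL_BITS))
    for (j in seq_len(d)) X[, j] <- bitwXor(X[, j], shift[j])
  }
  X / 2^.SOBOL_BITS
}

#' Input ranges for sensitivity analysis
#'
#' Lower/upper bounds in native units for the five environmental inputs of
#' the optimality model. Defaults span broad global conditions: growing
#' season temperature 0-30 C, PAR 100-2400 umol m-2 s-1, VPD 0.1-4 kPa,
#' ambient CO2 360-420 ppm, elevation 0-4500 m. An input may be frozen by
#' setting lower = upper.
#'
#' @param t_g,par,vpd,ca,elevation length-2 numeric `c(lower, upper)`
#'   vectors.
#' @return Named list of class `input_ranges`.
#' @export
input_ranges <- function(t_g = c(0, 30), par = c(100, 2400),
                         vpd = c(0.1, 4), ca = c(360, 420),
                         elevation = c(0, 4500)) {
  rng <- list(t_g = t_g, par = par, vpd = vpd, ca = ca, elevation = elevation)
  for (nm in names(rng)) {
    r <- rng[[nm]]
    if (length(r) != 2 || !all(is.finite(r)) || r[1] > r[2])
      stop("invalid bounds for ", nm, call. = FALSE)
  }
  structure(rng, class = "input_ranges")
}

#' Sobol' quasi-random sample over input ranges
#'
#' Draws `n` low-discrepancy points mapped to the given ranges. Frozen
#' inputs (lower = upper) yield constant columns. A seeded random digital
#' shift makes distinct seeds give distinct (still low-discrepancy) point
#' sets.
#'
#' @param ranges an [input_ranges()] object or any named list of
#'   `c(lower, upper)` bounds.
#' @param n number of sample points (powers of 2 recommended).
#' @param seed integer seed for the digital shift; `NULL` gives the raw
#'   sequence.
#' @return Matrix `n x d` with one named column per input.
#' @export
sobol_sample <- function(ranges, n, seed = NULL) {
  d <- length(ranges)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || !all(is.finite(r)) || r[1] > r[2])
      stop("invalid bounds for ", nm, call. = FALSE)
  }
  U <- .sobol_unit(n, d, seed)
  lo <- vapply(ranges, `[`, 0, 1); hi <- vapply(ranges, `[`, 0, 2)
  X <- sweep(sweep(U, 2, hi - lo, "*"), 2, lo, "+")
  colnames(X) <- names(ranges)
  X
}

#' First-order variance partition by the Saltelli estimator
#'
#' Estimates first-order Sobol' indices of a scalar model over independent
#' inputs: two base matrices A and B are drawn from a 2d-dimensional Sobol'
#' sequence, the model is evaluated on A, B and the d radial matrices
#' AB(i) (A with column i taken from B), and
#' `S_i = mean(f(B) * (f(AB_i) - f(A))) / Var(f)`. Indices are also
#' rescaled to relative contributions summing to 100 percent (frozen inputs
#' contribute zero).
#'
#' @param model function taking a named data frame of inputs (one row per
#'   sample) and returning a numeric vector.
#' @param ranges an [input_ranges()]-style named list of bounds.
#' @param n_base base sample size N (the model is run N*(d+2) times; powers
#'   of 2 recommended).
#' @param seed integer seed for the digital shift.
#' @return List of class `sensitivity_result`: `indices` data frame
#'   (variable, S1, contribution_pct), `total_variance`, `n_base`.
#' @export
variance_partition <- function(model, ranges, n_base = 2^14, seed = 1) {
  d <- length(ranges)
  U <- .sobol_unit(n_base, 2 * d, seed)
  lo <- vapply(ranges, `[`, 0, 1); hi <- vapply(ranges, `[`, 0, 2)
  scale_cols <- function(M) {
    X <- sweep(sweep(M, 2, hi - lo, "*"), 2, lo, "+")
    colnames(X) <- names(ranges)
    as.data.frame(X)
  }
  A <- scale_cols(U[, seq_len(d), drop = FALSE])
  B <- scale_cols(U[, d + seq_len(d), drop = FALSE])
  run <- function(X) {
    y <- model(X)
    bad <- !is.finite(y)
    if (mean(bad) > 0.001) {
      stop("model failed on more than 0.1% of samples; first offending input: ",
           paste(names(X), unlist(X[which(bad)[1], ]), sep = "=",
                 collapse = ", "), call. = FALSE)
    }
    y[bad] <- mean(y[!bad])
    y
  }
  yA <- run(A); yB <- run(B)
  V <- stats::var(c(yA, yB))
  frozen <- hi == lo
  S1 <- numeric(d)
  for (i in seq_len(d)) {
    if (frozen[i]) next
    ABi <- A; ABi[[i]] <- B[[i]]
    yABi <- run(ABi)
    S1[i] <- mean(yB * (yABi - yA)) / V
  }
  contrib <- if (sum(pmax(S1, 0)) > 0) 100 * pmax(S1, 0) / sum(pmax(S1, 0))
  else rep(0, d)
  structure(list(indices = data.frame(variable = names(ranges), S1 = S1,
                                      contribution_pct = contrib),
                 total_variance = V, n_base = n_base, seed = seed),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("First-order Sobol' variance partition (N = %d, total var = %.4g)\n",
              x$n_base, x$total_variance))
  print(x$indices, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Sensitivity of the optimality-constant model
#'
#' Convenience wrapper partitioning the variance of optimality-modelled
#' Vcmax25 over the five environmental inputs.
#'
#' @param ranges an [input_ranges()] object.
#' @param n_base base Sobol' sample size.
#' @param seed integer seed.
#' @param cost unit carbon cost (default 0.053).
#' @param params,kinetics model parameter objects.
#' @return A `sensitivity_result`.
#' @export
sensitivity_optimality <- function(ranges = input_ranges(), n_base = 2^14,
                                   seed = 1, cost = 0.053,
                                   params = optimality_params(),
                                   kinetics = kinetics_params()) {
  mdl <- function(X) predict_vcmax25_optimality(
    X$t_g, X$par, X$vpd, X$ca, X$elevation, cost = cost,
    params = params, kinetics = kinetics, na_infeasible = TRUE)
  variance_partition(mdl, ranges, n_base = n_base, seed = seed)
}
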