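test_that("metrics behave on exact and controlled predictions", {
  m <- compute_metrics(1:10, 1:10, k = 2)
  expect_equal(m$r2, 1); expect_equal(m$bias, 0); expect_equal(m$rmse, 0)
  # k = 2, n = 10, RMSE = 1 -> AIC = 4 (log 1 = 0)
  obs <- rep(c(0, 10), 5)
  pred <- obs + rep(c(1, -1), 5)
  m2 <- compute_metrics(obs, pred, k = 2)
  expect_equal(m2$rmse, 1)
  expect_equal(m2$aic, 4)
  expect_error(compute_metrics(rep(1, 5), c(1, 2, 1, 2, 1)), "zero-variance")
  # AIC decreases with RMSE at fixed k, n
  m3 <- compute_metrics(obs, obs + rep(c(0.5, -0.5), 5), k = 2)
  expect_lt(m3$aic, m2$aic)
})

test_that("VIF pruning keeps orthogonal designs and removes exact combinations", {
  n <- 64
  X <- withr::with_seed(1, {
    M <- qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n, 4))))[, -1]
    as.data.frame(M)
  })
  names(X) <- paste0("x", 1:4)
  res <- vif_prune(X, names(X))
  expect_setequal(res$retained, names(X))
  expect_true(all(abs(res$vif - 1) < 1e-8))
  # exact linear combination has the largest VIF and goes first
  X$x5 <- X$x1 + X$x2 + withr::with_seed(2, rnorm(n, sd = 1e-4))
  res2 <- vif_prune(X, names(X))
  expect_equal(res2$removed$variable[1], "x5")
  expect_equal(res2$removed$reason[1], "vif")
  # duplicated variable: exactly one copy survives
  Y <- X[paste0("x", 1:3)]
  Y$x1b <- Y$x1
  res3 <- vif_prune(Y, names(Y))
  expect_equal(sum(c("x1", "x1b") %in% res3$retained), 1)
  # survivor set satisfies both thresholds
  expect_true(all(res3$vif < 10))
  cm <- abs(stats::cor(Y[res3$retained])); diag(cm) <- 0
  expect_true(all(cm < 0.7))
})

test_that("Akaike weights are a proper partition with the stated ratios", {
  n <- 100
  dat <- withr::with_seed(3, {
    x1 <- rnorm(n)
    data.frame(x1 = x1, x2 = -x1 + rnorm(n, sd = 1e-9),
               y = 2 * x1 + rnorm(n))
  })
  sel <- exhaustive_selection(dat, "y", c("x1", "x2"))
  expect_equal(sum(sel$models$weight), 1)
  # x1 and x2 carry identical information: the two single-variable models tie
  w1 <- sel$models$weight[sel$models$terms == "x1"]
  w2 <- sel$models$weight[sel$models$terms == "x2"]
  expect_equal(w1, w2, tolerance = 1e-4)
  # weight ratios follow exp(-delta/2) exactly
  expect_equal(sel$models$weight,
               exp(-sel$models$delta / 2) / sum(exp(-sel$models$delta / 2)))
  # a delta of 2 gives the 0.731 / 0.269 split between two models
  expect_equal(exp(0) / (exp(0) + exp(-1)), 0.731, tolerance = 1e-3)
  expect_equal(exp(-1) / (exp(0) + exp(-1)), 0.269, tolerance = 1e-3)
})

test_that("a planted predictor is flagged important; noise is not", {
  dat <- withr::with_seed(5, {
    X <- as.data.frame(matrix(rnorm(200 * 6), 200, 6))
    names(X) <- paste0("x", 1:6)
    X$y <- X$x3 + rnorm(200, sd = 0.5)
    X
  })
  sel <- exhaustive_selection(dat, "y", paste0("x", 1:6))
  imp <- stats::setNames(sel$importance$importance, sel$importance$variable)
  expect_gt(imp["x3"], 0.8)
  expect_true(all(imp[paste0("x", c(1, 2, 4, 5, 6))] < 0.8))
  expect_true(sel$importance$important[sel$importance$variable == "x3"])
  expect_equal(sel$importance$effect_sign[sel$importance$variable == "x3"], 1)
  # importance of a variable in every model equals 1
  sel_all <- exhaustive_selection(dat, "y", c("x3"), include_null = FALSE)
  expect_equal(sel_all$importance$importance, 1)
})

test_that("partial regression matches simple regression for orthogonal focal", {
  dat <- withr::with_seed(7, {
    M <- qr.Q(qr(cbind(1, matrix(rnorm(80 * 3), 80, 3))))[, -1]
    d <- as.data.frame(M); names(d) <- c("f", "o1", "o2")
    d$y <- 3 * d$f + 0.5 * d$o1 + rnorm(80, sd = 0.2)
    d
  })
  pr <- partial_regression(dat, "y", "f", c("o1", "o2"))
  simple <- stats::coef(stats::lm(y ~ f, dat))[2]
  expect_equal(pr$slope, unname(simple), tolerance = 1e-8)
  full <- stats::coef(stats::lm(y ~ f + o1 + o2, dat))["f"]
  expect_equal(pr$slope, unname(full), tolerance = 1e-10)
  expect_error(partial_regression(dat, "y", "f", c("f")), ".")
})

test_that("partial-regression CIs cover the true coefficient", {
  covered <- withr::with_seed(11, {
    vapply(1:100, function(i) {
      n <- 60
      x <- rnorm(n); z <- 0.5 * x + rnorm(n)
      y <- 1.5 * x + 0.8 * z + rnorm(n)
      pr <- partial_regression(data.frame(x = x, z = z, y = y), "y", "x", "z")
      abs(pr$slope - 1.5) <= 1.96 * pr$se
    }, TRUE)
  })
  expect_gte(mean(covered), 0.9)
})
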