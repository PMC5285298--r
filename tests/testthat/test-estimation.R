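# Core estimators: OLS/LPM, probit, inverse Mills ratio, random intercepts.

test_that("ols_fit reproduces exact and oracle solutions", {
  # noiseless line: coefficients to machine precision
  df <- data.frame(y = 2 + 3 * (1:30), x = 1:30)
  f <- suppressWarnings(ols_fit(model_spec("y", "x", group = "none"), df))
  expect_equal(unname(f$coefficients), c(2, 3), tolerance = 1e-12)

  # random design against an independent normal-equations oracle
  set.seed(33)
  n <- 200
  X <- cbind(1, rnorm(n), runif(n))
  beta <- c(0.5, -1.2, 2)
  y <- as.numeric(X %*% beta + rnorm(n))
  df2 <- data.frame(y = y, x1 = X[, 2], x2 = X[, 3])
  f2 <- ols_fit(model_spec("y", c("x1", "x2"), group = "none"), df2)
  oracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_lt(max(abs(f2$coefficients - as.numeric(oracle))), 1e-8)

  # duplicated column: collinearity error naming the offender
  df2$x3 <- df2$x1
  expect_error(ols_fit(model_spec("y", c("x1", "x3"), group = "none"), df2),
               "x3")
})

test_that("the linear probability model reports its out-of-range share
           without clipping", {
  set.seed(35)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(2 * x))
  f <- ols_fit(model_spec("y", "x", group = "none"), data.frame(y, x))
  expect_gt(f$out_of_range_share, 0)
  expect_true(any(fitted(f$lm) < 0 | fitted(f$lm) > 1))
})

test_that("clustered standard errors differ from conventional ones under
           within-cluster correlation", {
  set.seed(36)
  g <- rep(1:40, each = 10)
  x <- rnorm(40)[g]
  y <- x + rnorm(40, 0, 2)[g] + rnorm(400, 0, 0.2)
  df <- data.frame(y, x, practice_id = g)
  plain <- ols_fit(model_spec("y", "x", group = "none"), df)
  clus <- ols_fit(model_spec("y", "x", group = "none"), df,
                  cluster = "practice_id")
  expect_gt(unname(clus$se["x"]) / unname(plain$se["x"]), 1.5)
})

test_that("probit recovers a known slope and refuses degenerate inputs", {
  set.seed(37)
  n <- 5000
  x <- rnorm(n)
  y <- as.integer(0.7 * x + rnorm(n) > 0)
  f <- probit_fit(model_spec("y", "x", group = "none"), data.frame(y, x))
  expect_lt(abs(f$coefficients["x"] - 0.7), 3 * f$se["x"])
  # balanced symmetric design: intercept near zero
  expect_lt(abs(f$coefficients["(Intercept)"]),
            3 * f$se["(Intercept)"])

  expect_error(probit_fit(model_spec("y", "x", group = "none"),
                          data.frame(y = rep(1, 50), x = rnorm(50))),
               "single class")
  # perfectly separated data must error, not silently diverge
  xs <- c(rnorm(50, -3), rnorm(50, 3))
  ys <- rep(c(0L, 1L), each = 50)
  suppressWarnings(
    expect_error(probit_fit(model_spec("y", "x", group = "none"),
                            data.frame(y = ys, x = xs)),
                 "separation"))
})

test_that("inverse Mills ratio matches closed form, tails and oracles", {
  expect_equal(inverse_mills(0), sqrt(2 / pi), tolerance = 1e-12)
  expect_lt(inverse_mills(8), 1e-10)
  # strictly decreasing
  grid <- seq(-40, 8, by = 0.5)
  vals <- inverse_mills(grid)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0))
  # quadrature oracle on moderate indices (quadrature itself degrades in
  # the far tail, where the continued fraction takes over)
  for (x in seq(-5, 8, by = 0.5)) {
    expect_lt(abs(inverse_mills(x) - imr_quad(x)), 1e-10)
  }
  # continued-fraction oracle in the left tail
  for (x in c(-5, -10, -20, -35)) {
    expect_lt(abs(inverse_mills(x) - imr_cf(x)) / imr_cf(x), 1e-10)
  }
})

test_that("random-intercept ML collapses to OLS when sigma_u is zero", {
  set.seed(41)
  g <- rep(1:50, each = 6)
  x <- rnorm(300)
  y <- 1 + 2 * x + rnorm(300)  # no group component
  df <- data.frame(y, x, practice_id = g)
  ri <- random_intercept_fit(model_spec("y", "x", group = "practice"), df)
  ols <- ols_fit(model_spec("y", "x", group = "none"), df)
  expect_lt(max(abs(ri$coefficients - ols$coefficients)), 1e-6)
  expect_lt(ri$sigma_u2, 0.05)
})

test_that("random-intercept fixed effects equal the closed-form GLS slope
           when the regressor is within-group centred", {
  # with zero between-group variation in x the GLS slope is the within
  # estimator for every variance ratio, a closed-form anchor
  set.seed(43)
  g <- rep(1:40, each = 5)
  x <- rnorm(200)
  x <- x - ave(x, g)
  y <- 2 + 1.3 * x + rnorm(40, 0, 1.5)[g] + rnorm(200, 0, 0.7)
  df <- data.frame(y, x, practice_id = g)
  ri <- random_intercept_fit(model_spec("y", "x", group = "practice"), df)
  within_slope <- sum((x) * (y - ave(y, g))) / sum(x^2)
  expect_equal(unname(ri$coefficients["x"]), within_slope,
               tolerance = 1e-6)
  expect_equal(unname(ri$coefficients["(Intercept)"]), mean(y),
               tolerance = 1e-6)
})

test_that("the random-intercept likelihood nests the OLS likelihood", {
  set.seed(44)
  g <- rep(1:30, each = 8)
  y <- rnorm(30, 0, 1)[g] + rnorm(240)
  x <- rnorm(240)
  df <- data.frame(y, x, practice_id = g)
  ri <- random_intercept_fit(model_spec("y", "x", group = "practice"), df)
  ols <- ols_fit(model_spec("y", "x", group = "none"), df)
  expect_gte(ri$loglik, ols$loglik - 1e-6)
})

test_that("random-intercept ML recovers known parameters", {
  res <- ri_recovery_study(reps = 20, n_groups = 200, per_group = 8,
                           seed = 45)
  truth <- attr(res, "truth")
  for (p in names(truth)) {
    mc_se <- sd(res[[p]]) / sqrt(nrow(res))
    expect_lt(abs(mean(res[[p]]) - truth[[p]]), 3 * mc_se + 1e-8,
              label = sprintf("recovery of %s", p))
  }
})

test_that("estimators are invariant to row order and equivariant to affine
           rescaling", {
  pan <- small_panel(seed = 47)
  spec <- model_spec("fte", c("age", "lisi"), group = "practice")
  base <- random_intercept_fit(spec, pan)
  shuf <- pan[sample(nrow(pan)), ]
  expect_equal(random_intercept_fit(spec, shuf)$coefficients,
               base$coefficients, tolerance = 1e-6)

  pan2 <- pan
  pan2$lisi <- 2 * pan$lisi + 5
  resc <- random_intercept_fit(spec, pan2)
  expect_equal(unname(resc$coefficients["lisi"]),
               unname(base$coefficients["lisi"]) / 2, tolerance = 1e-4)

  ospec <- model_spec("fte", c("age", "lisi"), group = "none")
  o1 <- ols_fit(ospec, pan)
  o2 <- ols_fit(ospec, pan[rev(seq_len(nrow(pan))), ])
  expect_equal(o1$coefficients, o2$coefficients, tolerance = 1e-10)
})
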