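# Independent oracles and shared fixtures for the test suite.

# Hand-coded Vincenty inverse solution on WGS-84 (scalar), in miles.
# Independent of the implementation path used by the package.
vincenty_ref <- function(lat1, lon1, lat2, lon2) {
  a <- 6378137; f <- 1 / 298.257223563; b <- a * (1 - f)
  L <- (lon2 - lon1) * pi / 180
  U1 <- atan((1 - f) * tan(lat1 * pi / 180))
  U2 <- atan((1 - f) * tan(lat2 * pi / 180))
  sU1 <- sin(U1); cU1 <- cos(U1); sU2 <- sin(U2); cU2 <- cos(U2)
  lambda <- L
  sinSigma <- cosSigma <- sigma <- cos2a <- cos2sm <- 0
  for (i in 1:200) {
    sL <- sin(lambda); cL <- cos(lambda)
    sinSigma <- sqrt((cU2 * sL)^2 + (cU1 * sU2 - sU1 * cU2 * cL)^2)
    if (sinSigma == 0) return(0)
    cosSigma <- sU1 * sU2 + cU1 * cU2 * cL
    sigma <- atan2(sinSigma, cosSigma)
    sinAlpha <- cU1 * cU2 * sL / sinSigma
    cos2a <- 1 - sinAlpha^2
    cos2sm <- if (cos2a == 0) 0 else cosSigma - 2 * sU1 * sU2 / cos2a
    C <- f / 16 * cos2a * (4 + f * (4 - 3 * cos2a))
    lam_prev <- lambda
    lambda <- L + (1 - C) * f * sinAlpha *
      (sigma + C * sinSigma *
         (cos2sm + C * cosSigma * (-1 + 2 * cos2sm^2)))
    if (abs(lambda - lam_prev) < 1e-12) break
  }
  u2 <- cos2a * (a^2 - b^2) / b^2
  A <- 1 + u2 / 16384 * (4096 + u2 * (-768 + u2 * (320 - 175 * u2)))
  B <- u2 / 1024 * (256 + u2 * (-128 + u2 * (74 - 47 * u2)))
  dSigma <- B * sinSigma *
    (cos2sm + B / 4 * (cosSigma * (-1 + 2 * cos2sm^2) -
                         B / 6 * cos2sm * (-3 + 4 * sinSigma^2) *
                         (-3 + 4 * cos2sm^2)))
  b * A * (sigma - dSigma) / 1609.344
}

# Mills-ratio oracle, continued-fraction form (accurate for index <= -3):
# phi(t)/Q(t) = t + 1/(t + 2/(t + 3/(...))) with t = -index.
imr_cf <- function(index, depth = 400L) {
  t <- -index
  stopifnot(t >= 3)
  acc <- 0
  for (k in depth:1) acc <- k / (t + acc)
  t + acc
}

# Mills-ratio oracle by adaptive quadrature of the normal density
# (independent of pnorm); usable for moderate indices.
imr_quad <- function(index) {
  Phi <- stats::integrate(function(z) exp(-z^2 / 2) / sqrt(2 * pi),
                          -Inf, index, rel.tol = 1e-13)$value
  stats::dnorm(index) / Phi
}

# Rejection-sample parameter draws inside region S (optionally S_hat).
draw_params_in_region <- function(n, seed = 1, shat = FALSE) {
  set.seed(seed)
  out <- vector("list", n)
  got <- 0
  while (got < n) {
    pars <- model_params(m = runif(1, 0, 2), p = runif(1, 0.2, 4),
                         pi = runif(1, 0.02, 0.98),
                         gamma_v = runif(1, 0.1, 0.9),
                         t = runif(1, 0.05, 1.5),
                         b1 = runif(1, 0, 2), b2 = runif(1, 0, 2))
    reg <- region_membership(pars, pars$gamma_v)
    ok <- if (shat) reg$in_S_hat else reg$in_S
    if (ok) {
      got <- got + 1
      out[[got]] <- pars
    }
  }
  out
}

# Three-indicator registry fixture with hand-checkable numbers.
fixture_registry <- function(price = 100) {
  qof_registry(2004, list(
    qof_indicator("A1", "CVD", max_points = 10,
                  lower_threshold = 0.40, upper_threshold = 0.90),
    qof_indicator("A2", "general", max_points = 4,
                  lower_threshold = 0.25, upper_threshold = 0.75),
    qof_indicator("A3", "general", max_points = 6,
                  lower_threshold = 0.40, upper_threshold = 0.70)
  ), price_per_point = price)
}

fixture_records <- function(practice = "P1") {
  data.frame(practice_id = practice,
             indicator_id = c("A1", "A2", "A3"),
             numerator = c(65, 50, 28),
             denominator = c(100, 100, 40))
}

# small, fast panel for estimation tests
small_panel <- function(seed = 1, n_practices = 80) {
  simulate_panel(dgp_config(n_practices = n_practices, seed = seed))
}
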