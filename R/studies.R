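## Monte-Carlo studies of the estimators: parameter recovery for the
## random-intercept model, selection-bias correction for the stacked-IMR
## Heckman procedure, and fixed-effect bias for the first-difference
## estimator. Shared by the test suite and the acceptance script.

#' Recovery study for the random-intercept model
#'
#' Repeatedly simulates a balanced two-level Gaussian panel with known
#' fixed slope and variance components and refits it by maximum
#' likelihood.
#'
#' @param reps Number of replications.
#' @param n_groups,per_group Panel dimensions (groups x observations).
#' @param beta True slope; the intercept is 1.
#' @param sigma_u,sigma_e True intercept and residual standard deviations.
#' @param seed RNG seed.
#' @return Data frame with one row per replication: `beta`, `beta_se`,
#'   `sigma_u2`, `sigma_e2`; truth in `attr(, "truth")`.
#' @export
ri_recovery_study <- function(reps = 100L, n_groups = 500L, per_group = 8L,
                              beta = 1.5, sigma_u = 2, sigma_e = 1,
                              seed = 1L) {
  set.seed(seed)
  spec <- model_spec("y", "x", group = "practice")
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    g <- rep(seq_len(n_groups), each = per_group)
    x <- stats::rnorm(n_groups * per_group)
    y <- 1 + beta * x + stats::rnorm(n_groups, 0, sigma_u)[g] +
      stats::rnorm(n_groups * per_group, 0, sigma_e)
    fit <- random_intercept_fit(spec, data.frame(y = y, x = x,
                                                 practice_id = g))
    out[[r]] <- data.frame(beta = unname(fit$coefficients["x"]),
                           beta_se = unname(fit$se["x"]),
                           sigma_u2 = fit$sigma_u2,
                           sigma_e2 = fit$sigma_e2)
  }
  res <- do.call(rbind, out)
  attr(res, "truth") <- c(beta = beta, sigma_u2 = sigma_u^2,
                          sigma_e2 = sigma_e^2)
  res
}

# one synthetic two-year selection panel: everyone is observed in year one
# (stay decision, exclusion variable shifts it); only stayers appear in
# year two, where the outcome depends on x with selection correlation rho
heckman_study_panel <- function(n_doctors = 1500L, n_practices = 50L,
                                rho = 0.5, beta = 1) {
  pid <- sample(sprintf("P%03d", seq_len(n_practices)), n_doctors,
                replace = TRUE)
  x <- stats::rnorm(n_doctors)
  z <- stats::rnorm(n_doctors)  # years-to-retirement style excluded shifter
  u1 <- stats::rnorm(n_doctors)
  idx <- 0.3 + 1.0 * z - 0.5 * x
  stayed <- as.integer(idx + u1 > 0)
  u2 <- rho * u1 + sqrt(1 - rho^2) * stats::rnorm(n_doctors)
  grp <- stats::rnorm(n_practices, 0, 0.5)
  y <- 0.5 + beta * x + grp[match(pid, sort(unique(pid)))] + u2
  y1 <- data.frame(doctor_id = sprintf("D%05d", seq_len(n_doctors)),
                   practice_id = pid, year = 2004L, stayed = stayed,
                   years_to_retirement = z, x = x, y = NA_real_)
  keep <- stayed == 1L
  y2 <- data.frame(doctor_id = y1$doctor_id[keep],
                   practice_id = pid[keep], year = 2005L,
                   stayed = 1L, years_to_retirement = z[keep],
                   x = x[keep], y = y[keep])
  rbind(y1, y2)
}

#' Selection-bias study for the stacked-IMR Heckman estimator
#'
#' Simulates panels in which market exit and the second-stage outcome share
#' a correlated error (`rho`), then compares the naive random-intercept fit
#' on the selected rows against the two-stage fit with the stacked inverse
#' Mills ratio.
#'
#' @param reps Replications.
#' @param rho Selection correlation of the generating process.
#' @param n_doctors,n_practices Panel dimensions per replication.
#' @param beta True slope on `x`.
#' @param seed RNG seed.
#' @return Data frame per replication: `naive`, `corrected` (slope
#'   estimates), `imr_coef`, `imr_p`; truth in `attr(, "truth")`.
#' @export
heckman_bias_study <- function(reps = 200L, rho = 0.5, n_doctors = 1500L,
                               n_practices = 50L, beta = 1, seed = 1L) {
  set.seed(seed)
  stay_spec <- model_spec("stayed", c("years_to_retirement", "x"),
                          group = "none")
  out_spec <- model_spec("y", "x", group = "practice")
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    pan <- heckman_study_panel(n_doctors, n_practices, rho, beta)
    sel <- heckman_selection_fit(stay_spec, out_spec, pan)
    naive <- random_intercept_fit(out_spec, pan[pan$year == 2005L, ])
    ct <- coef_table(sel$second_stage)
    out[[r]] <- data.frame(
      naive = unname(naive$coefficients["x"]),
      corrected = unname(sel$second_stage$coefficients["x"]),
      imr_coef = ct["imr", "estimate"],
      imr_p = ct["imr", "p"])
  }
  res <- do.call(rbind, out)
  attr(res, "truth") <- c(beta = beta)
  res
}

#' Fixed-effect bias study for the first-difference estimator
#'
#' Simulates a two-period panel whose doctor fixed effect is correlated
#' with the regressor, so pooled OLS is biased while the within-doctor
#' first difference is not.
#'
#' @param reps Replications.
#' @param n Doctors per replication.
#' @param beta True slope.
#' @param alpha_corr Strength of the fixed-effect/regressor correlation.
#' @param seed RNG seed.
#' @return Data frame per replication: `pooled`, `fd`; truth in
#'   `attr(, "truth")`.
#' @export
fd_bias_study <- function(reps = 100L, n = 500L, beta = 0.8,
                          alpha_corr = 1, seed = 1L) {
  set.seed(seed)
  spec <- model_spec("y", "x", group = "none")
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    alpha <- stats::rnorm(n)
    x1 <- alpha_corr * alpha + stats::rnorm(n)
    x2 <- alpha_corr * alpha + stats::rnorm(n)
    y1 <- alpha + beta * x1 + stats::rnorm(n)
    y2 <- 0.3 + alpha + beta * x2 + stats::rnorm(n)
    pan <- data.frame(
      doctor_id = rep(sprintf("D%04d", seq_len(n)), 2L),
      year = rep(c(2005L, 2006L), each = n),
      y = c(y1, y2), x = c(x1, x2))
    pooled <- ols_fit(spec, pan)
    fd <- first_difference_fit(spec, pan, shock_var = NULL)
    out[[r]] <- data.frame(pooled = unname(pooled$coefficients["x"]),
                           fd = unname(fd$coefficients["d_x"]))
  }
  res <- do.call(rbind, out)
  attr(res, "truth") <- c(beta = beta)
  res
}
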