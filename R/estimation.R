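## Estimators for the empirical strategy: pooled OLS / linear probability
## models, probit, two-level random-intercept linear models, and the
## selection-corrected and first-difference variants built on top of them.

#' Specify one empirical model
#'
#' A light container naming the outcome, the covariates (which must exist as
#' panel columns; the generator already stores them lagged where the design
#' lags them), the random-intercept level, year dummies, and an optional
#' row filter.
#'
#' @param outcome Outcome column name.
#' @param covariates Character vector of covariate column names.
#' @param group Random-intercept level: `"practice"`, `"doctor"` or
#'   `"none"`. Practice-level grouping is the default (doctors are nested
#'   in practices and group counts are reported at practice level);
#'   doctor-level grouping is available by flag.
#' @param year_dummies Include year fixed effects (factor of `year`).
#' @param filter Optional expression (as a one-sided formula or character)
#'   evaluated in the panel to subset rows, e.g. `~ year %in% 2004:2005`.
#' @return A `"model_spec"`.
#' @export
model_spec <- function(outcome, covariates,
                       group = c("practice", "doctor", "none"),
                       year_dummies = FALSE, filter = NULL) {
  group <- match.arg(group)
  stopifnot(is.character(outcome), length(outcome) == 1L,
            is.character(covariates), length(covariates) >= 1L)
  if (!is.null(filter) && !inherits(filter, "formula"))
    stop("filter must be NULL or a one-sided formula", call. = FALSE)
  structure(list(outcome = outcome, covariates = covariates, group = group,
                 year_dummies = year_dummies, filter = filter),
            class = "model_spec")
}

# apply a spec's filter and check the panel has what the spec needs
spec_frame <- function(spec, panel) {
  need <- c(spec$outcome, spec$covariates,
            if (spec$year_dummies) "year",
            switch(spec$group, practice = "practice_id",
                   doctor = "doctor_id", none = NULL))
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols))
    stop("panel lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(panel)
  if (!is.null(spec$filter)) {
    keep <- eval(spec$filter[[2]], envir = df, enclos = parent.frame())
    df <- df[keep & !is.na(keep), , drop = FALSE]
  }
  df <- df[stats::complete.cases(df[, need, drop = FALSE]), , drop = FALSE]
  if (nrow(df) < length(spec$covariates) + 2L)
    stop("filter leaves too few rows to fit the model", call. = FALSE)
  df
}

spec_formula <- function(spec) {
  rhs <- spec$covariates
  if (spec$year_dummies) rhs <- c(rhs, "factor(year)")
  stats::reformulate(rhs, response = spec$outcome)
}

new_fit_result <- function(kind, coefficients, se, sigma_u2 = NA_real_,
                           sigma_e2 = NA_real_, loglik = NA_real_,
                           n_obs, n_groups = NA_integer_, extra = list()) {
  stopifnot(length(coefficients) == length(se))
  structure(c(list(kind = kind, coefficients = coefficients, se = se,
                   sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                   loglik = loglik, n_obs = n_obs, n_groups = n_groups),
              extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: n = %d%s\n", x$kind, x$n_obs,
              if (!is.na(x$n_groups))
                sprintf(", groups = %d", x$n_groups) else ""))
  tab <- coef_table(x)
  print(round(tab, 4))
  if (!is.na(x$sigma_u2))
    cat(sprintf("variance components: sigma_u^2 = %.4f, sigma_e^2 = %.4f\n",
                x$sigma_u2, x$sigma_e2))
  invisible(x)
}

#' Coefficient table of a fit
#'
#' @param fit A `"fit_result"`.
#' @return Matrix with estimate, SE, z value and p value.
#' @export
coef_table <- function(fit) {
  z <- fit$coefficients / fit$se
  cbind(estimate = fit$coefficients, se = fit$se, z = z,
        p = 2 * stats::pnorm(-abs(z)))
}

#' Pooled least-squares / linear probability fit
#'
#' Ordinary least squares on the specified design. For binary outcomes this
#' is the linear probability model: fitted values are deliberately not
#' clipped to `[0, 1]`, and the share of out-of-range fitted values is
#' reported instead (`out_of_range_share`).
#'
#' @param spec A [model_spec()].
#' @param panel The doctor-year panel (any data.frame with the columns).
#' @param cluster Optional column name for cluster-robust standard errors
#'   (e.g. `"practice_id"`); conventional OLS standard errors otherwise.
#' @return A `"fit_result"`.
#' @export
ols_fit <- function(spec, panel, cluster = NULL) {
  df <- spec_frame(spec, panel)
  fo <- spec_formula(spec)
  X <- stats::model.matrix(fo, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("collinear design; offending column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(fo, data = df)
  if (is.null(cluster)) {
    se <- sqrt(diag(stats::vcov(fit)))
  } else {
    se <- sqrt(diag(sandwich::vcovCL(fit, cluster = df[[cluster]])))
  }
  fitted <- stats::fitted(fit)
  y <- df[[spec$outcome]]
  oor <- if (all(y %in% c(0, 1))) mean(fitted < 0 | fitted > 1) else NA_real_
  new_fit_result("OLS", stats::coef(fit), se,
                 sigma_e2 = summary(fit)$sigma^2,
                 loglik = as.numeric(stats::logLik(fit)),
                 n_obs = nrow(df),
                 n_groups = if (!is.null(cluster))
                   length(unique(df[[cluster]])) else NA_integer_,
                 extra = list(out_of_range_share = oor, lm = fit))
}

#' Probit fit by maximum likelihood
#'
#' Latent-index model for binary outcomes (partnership, mobility, market
#' entry/stay). Errors on one-class outcomes and on (quasi-)complete
#' separation rather than returning a silently divergent fit.
#'
#' @inheritParams ols_fit
#' @return A `"fit_result"` with element `glm` holding the underlying fit.
#' @export
probit_fit <- function(spec, panel) {
  df <- spec_frame(spec, panel)
  y <- df[[spec$outcome]]
  if (!all(y %in% c(0, 1)))
    stop("probit requires a 0/1 outcome", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; probit is not identified",
         call. = FALSE)
  fo <- spec_formula(spec)
  fit <- withCallingHandlers(
    stats::glm(fo, data = df, family = stats::binomial(link = "probit")),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop("probit did not converge; check for separation or scaling",
         call. = FALSE)
  eta <- abs(stats::predict(fit, type = "link"))
  if (max(abs(stats::coef(fit))) > 50 || all(eta > 8))
    stop("(quasi-)complete separation detected in probit fit",
         call. = FALSE)
  new_fit_result("probit", stats::coef(fit),
                 sqrt(diag(stats::vcov(fit))),
                 loglik = as.numeric(stats::logLik(fit)),
                 n_obs = nrow(df), extra = list(glm = fit))
}

#' Inverse Mills ratio
#'
#' `phi(x)/Phi(x)`, the standard-normal selection-correction term from a
#' first-stage probit; strictly positive and strictly decreasing. Computed
#' on the log scale (`exp(log phi - log Phi)`), which stays accurate far
#' into the left tail where the naive ratio underflows to 0/0.
#'
#' @param index Linear-predictor value(s).
#' @return `dnorm(index)/pnorm(index)`, numerically stable.
#' @examples
#' inverse_mills(0)  # sqrt(2/pi)
#' @export
inverse_mills <- function(index) {
  stopifnot(is.numeric(index), all(is.finite(index)))
  exp(stats::dnorm(index, log = TRUE) - stats::pnorm(index, log.p = TRUE))
}

#' Two-level random-intercept linear model
#'
#' Maximum-likelihood fit of a linear model with one random intercept at
#' the doctor or practice level (doctors are nested in practices; the
#' practice level is the default grouping). Fitting is delegated to lme4;
#' variance components and the log-likelihood are extracted into the common
#' `fit_result` contract.
#'
#' @inheritParams ols_fit
#' @return A `"fit_result"` with `sigma_u2` (intercept variance),
#'   `sigma_e2` (residual variance) and element `lmer` holding the fit.
#' @export
random_intercept_fit <- function(spec, panel) {
  if (spec$group == "none")
    stop("random_intercept_fit needs group = 'practice' or 'doctor'",
         call. = FALSE)
  df <- spec_frame(spec, panel)
  gvar <- if (spec$group == "practice") "practice_id" else "doctor_id"
  if (length(unique(df[[gvar]])) < 2L)
    stop("need at least two groups for a random intercept", call. = FALSE)
  rhs <- c(spec$covariates, if (spec$year_dummies) "factor(year)",
           sprintf("(1 | %s)", gvar))
  fo <- stats::as.formula(paste(spec$outcome, "~", paste(rhs, collapse = " + ")))
  fit <- lme4::lmer(fo, data = df, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u2 <- vc$vcov[vc$grp == gvar]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  new_fit_result("random-intercept ML", beta, se,
                 sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                 loglik = as.numeric(stats::logLik(fit)),
                 n_obs = nrow(df),
                 n_groups = length(unique(df[[gvar]])),
                 extra = list(lmer = fit))
}
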