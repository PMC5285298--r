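## Selection correction (two-stage Heckman with stacked inverse Mills
## ratios), first-difference estimation with the exogenous price shock, and
## the exclusion-restriction diagnostic.

#' Two-stage Heckman selection model with stacked inverse Mills ratios
#'
#' Stage one fits, separately for each census year, a probit of remaining
#' in the healthcare job market; its exclusion restriction is the number of
#' years to statutory retirement, which shifts exit but (by assumption) not
#' the practice-change decision. The inverse Mills ratio from each year's
#' fit is stacked into a single time-varying series and joined to the rows
#' at risk in the following year -- the doctors who stayed -- where it
#' enters the second-stage random-intercept model of mobility as an
#' additional covariate.
#'
#' @param stay_spec A [model_spec()] for the stay-in-market probit; its
#'   covariates must include `years_to_retirement`.
#' @param outcome_spec A [model_spec()] for the mobility equation; must not
#'   contain the exclusion variable.
#' @param panel The doctor-year panel.
#' @return A `"selection_result"`: `first_stage` (per-year `fit_result`s),
#'   `imr` (the stacked series, one value per surviving second-stage row,
#'   all positive), `second_stage` (a `fit_result` including the `imr`
#'   coefficient), and `skipped_years`.
#' @export
heckman_selection_fit <- function(stay_spec, outcome_spec, panel) {
  stopifnot(inherits(stay_spec, "model_spec"),
            inherits(outcome_spec, "model_spec"))
  if (!"years_to_retirement" %in% stay_spec$covariates)
    stop("the stay equation must include the exclusion variable ",
         "'years_to_retirement'", call. = FALSE)
  if ("years_to_retirement" %in% outcome_spec$covariates)
    stop("the outcome equation must exclude 'years_to_retirement'",
         call. = FALSE)
  df <- as.data.frame(panel)
  years <- sort(unique(df$year))

  first_stage <- list()
  skipped <- integer(0)
  imr_by <- list()  # doctor-year keyed IMR, joined to the following year
  for (y in years[-length(years)]) {
    sub <- df[df$year == y, , drop = FALSE]
    ycls <- unique(sub[[stay_spec$outcome]])
    if (length(ycls) < 2L) {
      warning("year ", y, " has a single-class stay outcome; excluded",
              call. = FALSE)
      skipped <- c(skipped, y)
      next
    }
    spec_y <- stay_spec
    spec_y$filter <- NULL
    fit <- probit_fit(spec_y, sub)
    eta <- stats::predict(fit$glm, newdata = sub, type = "link")
    first_stage[[as.character(y)]] <- fit
    imr_by[[as.character(y)]] <- data.frame(
      doctor_id = sub$doctor_id, year = y + 1L,
      imr = inverse_mills(eta))
  }
  if (!length(imr_by))
    stop("no year permitted a first-stage fit", call. = FALSE)
  imr_tab <- do.call(rbind, imr_by)

  key <- paste(df$doctor_id, df$year)
  df$imr <- imr_tab$imr[match(key, paste(imr_tab$doctor_id, imr_tab$year))]
  second <- df[!is.na(df$imr), , drop = FALSE]

  spec2 <- outcome_spec
  spec2$covariates <- c(outcome_spec$covariates, "imr")
  fit2 <- if (outcome_spec$group == "none") {
    ols_fit(spec2, second)
  } else {
    random_intercept_fit(spec2, second)
  }
  structure(list(first_stage = first_stage,
                 imr = second$imr,
                 second_stage = fit2,
                 skipped_years = skipped,
                 panel_with_imr = second),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Heckman two-stage fit: %d first-stage year(s), %d second-stage rows\n",
              length(x$first_stage), length(x$imr)))
  ct <- coef_table(x$second_stage)
  cat(sprintf("IMR coefficient: %.4f (SE %.4f, p = %.3f)\n",
              ct["imr", "estimate"], ct["imr", "se"], ct["imr", "p"]))
  invisible(x)
}

#' First-difference estimator with an exogenous price shock
#'
#' Differences each doctor's outcome and covariates between two consecutive
#' years, removing the time-invariant doctor component, and regresses the
#' change on the changed covariates plus the price shock in levels.
#' Covariates that are constant after differencing (gender, and age, whose
#' yearly change is identical for everyone) are dropped with a warning.
#' Optionally restricts to the bottom or top quintile of pre-period
#' practice performance, the design used for the mobility response, in
#' which case an `imr` column (if present) is retained in levels.
#'
#' @param spec A [model_spec()]; its covariates are differenced.
#' @param panel The doctor-year panel.
#' @param shock_var Column holding the price shock (entered in levels of
#'   the later year). Use `NULL` to omit.
#' @param years The two consecutive years to difference (default
#'   2005/2006).
#' @param quintile Optional: `"bottom"` or `"top"` quintile of
#'   `performance_var` measured in `performance_year`, ties assigned to the
#'   lower quintile.
#' @param performance_var,performance_year Practice performance measure and
#'   year used for the quintile split.
#' @return A `"fit_result"` on the differenced design, with element
#'   `dropped` listing covariates removed as constant.
#' @export
first_difference_fit <- function(spec, panel, shock_var = "price_shock",
                                 years = c(2005L, 2006L),
                                 quintile = NULL,
                                 performance_var = "prop_qof_points",
                                 performance_year = 2004L) {
  stopifnot(length(years) == 2L, diff(years) == 1L)
  df <- as.data.frame(panel)
  a <- df[df$year == years[1], , drop = FALSE]
  b <- df[df$year == years[2], , drop = FALSE]
  common <- intersect(a$doctor_id, b$doctor_id)
  if (!length(common))
    stop("no doctor observed in both years", call. = FALSE)
  a <- a[match(common, a$doctor_id), ]
  b <- b[match(common, b$doctor_id), ]

  if (!is.null(quintile)) {
    quintile <- match.arg(quintile, c("bottom", "top"))
    perf <- df[df$year == performance_year,
               c("practice_id", performance_var)]
    perf <- perf[!duplicated(perf$practice_id), ]
    qs <- stats::quantile(perf[[performance_var]],
                          probs = seq(0, 1, 0.2), names = FALSE)
    # ties to the lower quintile: right-closed intervals
    band <- findInterval(perf[[performance_var]], qs[2:5],
                         left.open = TRUE) + 1L
    wanted <- perf$practice_id[if (quintile == "bottom") band == 1L
                               else band == 5L]
    keep <- b$practice_id %in% wanted
    a <- a[keep, ]; b <- b[keep, ]
  }

  dd <- data.frame(doctor_id = a$doctor_id)
  dd[[paste0("d_", spec$outcome)]] <- b[[spec$outcome]] - a[[spec$outcome]]
  dropped <- character(0)
  kept <- character(0)
  for (cv in spec$covariates) {
    d <- b[[cv]] - a[[cv]]
    if (stats::var(d) < .Machine$double.eps * 100) {
      dropped <- c(dropped, cv)
    } else {
      dd[[paste0("d_", cv)]] <- d
      kept <- c(kept, cv)
    }
  }
  if (length(dropped))
    warning("dropped covariate(s) constant after differencing: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  rhs <- paste0("d_", kept)
  if (!is.null(shock_var)) {
    dd$shock <- b[[shock_var]]
    names(dd)[names(dd) == "shock"] <- shock_var
    rhs <- c(shock_var, rhs)
  }
  if (!is.null(quintile) && "imr" %in% names(b) && !all(is.na(b$imr))) {
    dd$imr <- b$imr
    rhs <- c(rhs, "imr")
  }
  fd_spec <- model_spec(paste0("d_", spec$outcome), rhs, group = "none")
  fit <- ols_fit(fd_spec, dd)
  fit$kind <- "first-difference OLS"
  fit$dropped <- dropped
  fit
}

#' Exclusion-restriction diagnostic for the selection model
#'
#' Refits the mobility equation with the first-stage exclusion variable
#' (years to statutory retirement) added directly as a covariate. If the
#' exclusion restriction holds -- retirement proximity shifts exit but not
#' practice changes -- its coefficient should be indistinguishable from
#' zero.
#'
#' @param mobility_spec A [model_spec()] for the mobility equation (without
#'   the exclusion variable).
#' @param panel The doctor-year panel.
#' @return A `"fit_result"` with extra elements `exclusion_coef`,
#'   `exclusion_se` and `exclusion_p`.
#' @export
exclusion_restriction_check <- function(mobility_spec, panel) {
  stopifnot(inherits(mobility_spec, "model_spec"))
  df <- as.data.frame(panel)
  if (stats::var(df$years_to_retirement) < .Machine$double.eps * 100) {
    warning("years_to_retirement is constant; dropped from the check",
            call. = FALSE)
    fit <- if (mobility_spec$group == "none")
      ols_fit(mobility_spec, df) else random_intercept_fit(mobility_spec, df)
    fit$exclusion_coef <- NA_real_
    fit$exclusion_se <- NA_real_
    fit$exclusion_p <- NA_real_
    return(fit)
  }
  spec2 <- mobility_spec
  spec2$covariates <- c(mobility_spec$covariates, "years_to_retirement")
  fit <- if (spec2$group == "none") ols_fit(spec2, df)
  else random_intercept_fit(spec2, df)
  ct <- coef_table(fit)
  fit$exclusion_coef <- ct["years_to_retirement", "estimate"]
  fit$exclusion_se <- ct["years_to_retirement", "se"]
  fit$exclusion_p <- ct["years_to_retirement", "p"]
  fit
}
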