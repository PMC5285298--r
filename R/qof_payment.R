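## QOF revenue engine: indicator achievement -> threshold-ramped points ->
## price-per-point revenue, plus the 2005->2006 exogenous price-shock
## construction used as the empirical price-decrease experiment.

#' Define a QOF indicator
#'
#' A clinical indicator rewarded on reported coverage ("achievement"): no
#' points at or below the lower threshold, the full `max_points` at or above
#' the upper threshold, and a linear ramp in between.
#'
#' @param id Indicator identifier (unique within a registry year).
#' @param disease_domain Clinical domain label, e.g. `"CVD"`.
#' @param max_points Maximum points available (> 0).
#' @param lower_threshold,upper_threshold Achievement thresholds as fractions,
#'   `0 <= lower < upper <= 1`.
#' @return A `"qof_indicator"` (named list).
#' @export
qof_indicator <- function(id, disease_domain = "general", max_points,
                          lower_threshold = 0.40, upper_threshold = 0.90) {
  stopifnot(is.character(id), length(id) == 1L,
            is.numeric(max_points), length(max_points) == 1L, max_points > 0,
            lower_threshold >= 0, lower_threshold < 1,
            upper_threshold > 0, upper_threshold <= 1)
  if (lower_threshold >= upper_threshold)
    stop("lower_threshold must be strictly below upper_threshold",
         call. = FALSE)
  structure(list(id = id, disease_domain = disease_domain,
                 max_points = max_points,
                 lower_threshold = lower_threshold,
                 upper_threshold = upper_threshold),
            class = "qof_indicator")
}

#' Assemble a year's indicator registry
#'
#' @param year Calendar year of the scheme.
#' @param indicators List of [qof_indicator()] objects with unique ids.
#' @param price_per_point Money per point (> 0); the scheme's empirical
#'   price: GBP 76 in 2004, rising to GBP 125 in 2005.
#' @return A `"qof_registry"`.
#' @export
qof_registry <- function(year, indicators, price_per_point) {
  stopifnot(is.numeric(year), length(year) == 1L,
            is.list(indicators), length(indicators) > 0L,
            is.numeric(price_per_point), price_per_point > 0)
  ids <- vapply(indicators, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("indicator ids must be unique within a registry year", call. = FALSE)
  names(indicators) <- ids
  structure(list(year = year, indicators = indicators,
                 price_per_point = price_per_point),
            class = "qof_registry")
}

#' @export
print.qof_registry <- function(x, ...) {
  cat(sprintf("QOF registry %d: %d indicators, price %.2f per point, %g max points\n",
              x$year, length(x$indicators), x$price_per_point,
              sum(vapply(x$indicators, `[[`, 0, "max_points"))))
  invisible(x)
}

#' Default synthetic indicator registries (2004--2006)
#'
#' Builds the registry used throughout the synthetic study: 146 indicators
#' (the scheme's first-two-years count) with a 40% lower threshold
#' everywhere, deterministic synthetic upper thresholds cycling over
#' {0.70, 0.80, 0.90}, and small point values. Four indicators form a
#' cardiovascular-disease (CVD) control subset; in the 2006 registry their
#' upper thresholds are raised, which is the threshold-only change behind
#' the exogenous price shock. Price per point is 76 in 2004 and 125 from
#' 2005 on.
#'
#' @param year One of 2004, 2005, 2006.
#' @return A `"qof_registry"`; the CVD subset ids are in
#'   `attr(registry, "cvd_subset")`.
#' @export
default_registry <- function(year) {
  stopifnot(year %in% 2004:2006)
  n <- 146L
  uppers <- rep(c(0.70, 0.80, 0.90), length.out = n)
  points <- rep(c(5, 7, 9, 6), length.out = n)
  domains <- rep("general", n)
  cvd_idx <- 1:4
  domains[cvd_idx] <- "CVD"
  uppers[cvd_idx] <- 0.70
  if (year == 2006) uppers[cvd_idx] <- 0.85  # raised CVD thresholds
  inds <- lapply(seq_len(n), function(i) {
    qof_indicator(id = sprintf("IND%03d", i), disease_domain = domains[i],
                  max_points = points[i], lower_threshold = 0.40,
                  upper_threshold = uppers[i])
  })
  price <- if (year == 2004) 76 else 125
  reg <- qof_registry(year, inds, price)
  attr(reg, "cvd_subset") <- sprintf("IND%03d", cvd_idx)
  reg
}

#' Achievement rate of one indicator record
#'
#' The proportion of eligible patients for whom the indicator's quality
#' measure was achieved.
#'
#' @param numerator,denominator Non-negative counts with
#'   `numerator <= denominator` and `denominator > 0`.
#' @return Fraction in `[0, 1]`.
#' @export
achievement_rate <- function(numerator, denominator) {
  stopifnot(is.numeric(numerator), is.numeric(denominator),
            length(numerator) == length(denominator))
  if (any(denominator == 0))
    stop("achievement is undefined for a zero denominator; drop the record",
         call. = FALSE)
  if (any(numerator < 0) || any(denominator < 0) ||
      any(numerator > denominator))
    stop("counts must satisfy 0 <= numerator <= denominator", call. = FALSE)
  numerator / denominator
}

#' Points earned on an indicator at a given achievement
#'
#' Zero at or below the lower threshold, the full `max_points` at or above
#' the upper threshold, linear in between: a continuous piecewise-linear
#' ramp with kinks exactly at the two thresholds.
#'
#' @param A Achievement fraction(s) in `[0, 1]`.
#' @param ind A [qof_indicator()].
#' @return Points earned (vectorised over `A`).
#' @examples
#' ind <- qof_indicator("X", max_points = 10, lower_threshold = 0.40,
#'                      upper_threshold = 0.90)
#' points_earned(c(0.40, 0.65, 0.90), ind)  # 0, 5, 10
#' @export
points_earned <- function(A, ind) {
  stopifnot(inherits(ind, "qof_indicator"), all(A >= 0 & A <= 1))
  ramp <- (A - ind$lower_threshold) /
    (ind$upper_threshold - ind$lower_threshold)
  ind$max_points * pmin(1, pmax(0, ramp))
}

# internal: records data.frame -> per-indicator points under a registry
points_table <- function(records, registry, subset = NULL) {
  stopifnot(is.data.frame(records),
            all(c("practice_id", "indicator_id", "numerator", "denominator")
                %in% names(records)))
  if (!is.null(subset)) {
    missing_ids <- setdiff(subset, names(registry$indicators))
    if (length(missing_ids))
      stop("indicator id(s) not in registry: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    records <- records[records$indicator_id %in% subset, , drop = FALSE]
  }
  unknown <- setdiff(unique(records$indicator_id), names(registry$indicators))
  if (length(unknown))
    stop("indicator id(s) not in registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  A <- achievement_rate(records$numerator, records$denominator)
  pts <- vapply(seq_len(nrow(records)), function(i)
    points_earned(A[i], registry$indicators[[records$indicator_id[i]]]),
    numeric(1))
  data.frame(practice_id = records$practice_id,
             indicator_id = records$indicator_id,
             achievement = A, points = pts,
             revenue = pts * registry$price_per_point)
}

#' Practice revenue under a registry
#'
#' Sums points earned across a practice's achievement records and converts
#' them to money at the registry's price per point.
#'
#' @param records Data frame with columns `practice_id`, `indicator_id`,
#'   `numerator`, `denominator` (one practice or many).
#' @param registry A [qof_registry()] containing every referenced indicator.
#' @return A list with `total` (named by practice) and `breakdown`, the
#'   per-indicator table whose revenue column sums exactly to the totals.
#' @export
practice_revenue <- function(records, registry) {
  stopifnot(inherits(registry, "qof_registry"))
  tab <- points_table(records, registry)
  total <- tapply(tab$revenue, tab$practice_id, sum)
  list(total = total, breakdown = tab)
}

#' Proportion of total QOF points achieved
#'
#' The practice performance measure: 100 x (points earned) / (points
#' available), on a 0--100 scale. Only indicators with records enter the
#' denominator (records with zero denominators must be dropped upstream).
#'
#' @inheritParams practice_revenue
#' @return Named numeric vector of percentages by practice.
#' @export
proportion_total_points <- function(records, registry) {
  stopifnot(inherits(registry, "qof_registry"))
  tab <- points_table(records, registry)
  maxp <- vapply(registry$indicators, `[[`, 0, "max_points")
  earned <- tapply(tab$points, tab$practice_id, sum)
  avail <- tapply(maxp[tab$indicator_id], tab$practice_id, sum)
  100 * earned / avail
}

#' Exogenous price shock from a threshold change
#'
#' The counterfactual revenue change on a subset of indicators: what a
#' practice would have received had it delivered its 2005 achievement under
#' the 2006 thresholds, minus what it actually received in 2005. Raising
#' thresholds makes it harder to earn the same money for unchanged
#' performance, so the shock is non-positive under a threshold-only
#' tightening. Reported both in money and as a percentage of the practice's
#' total 2005 revenue (the empirical regressor).
#'
#' @param records_2005 Achievement records for the base year.
#' @param registry_2005,registry_2006 The two years' registries; the price
#'   per point of the base year is used for both sides, isolating the
#'   threshold change.
#' @param subset Character vector of indicator ids (present in both
#'   registries) over which the shock is computed, e.g. the CVD subset.
#' @return A data.frame of class `"price_shock"` with columns `practice_id`,
#'   `shock_money`, `shock_pct` and attribute `"indicator_subset"`.
#' @export
price_shock <- function(records_2005, registry_2005, registry_2006, subset) {
  stopifnot(inherits(registry_2005, "qof_registry"),
            inherits(registry_2006, "qof_registry"),
            is.character(subset), length(subset) > 0L)
  # threshold change only: hold the price at the base year's level
  registry_cf <- registry_2006
  registry_cf$price_per_point <- registry_2005$price_per_point

  got <- points_table(records_2005, registry_2005, subset = subset)
  would <- points_table(records_2005, registry_cf, subset = subset)
  got_tot <- tapply(got$revenue, got$practice_id, sum)
  would_tot <- tapply(would$revenue, would$practice_id, sum)
  total_2005 <- tapply(points_table(records_2005, registry_2005)$revenue,
                       records_2005$practice_id, sum)
  ids <- names(got_tot)
  shock_money <- as.numeric(would_tot[ids] - got_tot[ids])
  out <- data.frame(practice_id = ids,
                    shock_money = shock_money,
                    shock_pct = 100 * shock_money / as.numeric(total_2005[ids]))
  attr(out, "indicator_subset") <- subset
  class(out) <- c("price_shock", "data.frame")
  out
}

#' Write/read a registry as JSON
#'
#' @param registry A [qof_registry()].
#' @param path File path.
#' @return `read_registry_json()` returns a `"qof_registry"`.
#' @export
write_registry_json <- function(registry, path) {
  stopifnot(inherits(registry, "qof_registry"))
  ind <- do.call(rbind, lapply(registry$indicators, function(i)
    data.frame(id = i$id, disease_domain = i$disease_domain,
               max_points = i$max_points,
               lower_threshold = i$lower_threshold,
               upper_threshold = i$upper_threshold)))
  jsonlite::write_json(
    list(year = registry$year, price_per_point = registry$price_per_point,
         indicators = ind),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_registry_json
#' @export
read_registry_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  inds <- lapply(seq_len(nrow(x$indicators)), function(i) {
    row <- as.list(x$indicators[i, ])
    row$max_points <- as.numeric(row$max_points)
    do.call(qof_indicator, row)
  })
  qof_registry(as.numeric(x$year), inds, as.numeric(x$price_per_point))
}
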