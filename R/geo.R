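## Geodesic distances between practices and the distance-to-best-practice
## covariate (proxy for relocation cost t).

METRES_PER_MILE <- 1609.344

#' Vincenty (ellipsoidal) distance in miles
#'
#' Inverse geodesic distance on the WGS-84 ellipsoid between two points,
#' in miles. Uses the iterative Vincenty solution (via geosphere); in the
#' rare near-antipodal case where the iteration fails to converge, a
#' great-circle fallback is used and a warning is raised. Symmetric, and
#' zero iff the points coincide.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorised).
#' @return Distance(s) in miles.
#' @examples
#' vincenty_distance(53.48, -2.24, 51.51, -0.13)  # Manchester -> London
#' @export
vincenty_distance <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(lat1) <= 90), all(abs(lat2) <= 90),
            all(abs(lon1) <= 360), all(abs(lon2) <= 360))
  p1 <- cbind(lon1, lat1)
  p2 <- cbind(lon2, lat2)
  d <- suppressWarnings(geosphere::distVincentyEllipsoid(p1, p2))
  bad <- !is.finite(d)
  if (any(bad)) {
    warning("Vincenty iteration did not converge for ", sum(bad),
            " near-antipodal pair(s); using great-circle fallback",
            call. = FALSE)
    d[bad] <- geosphere::distCosine(p1[bad, , drop = FALSE],
                                    p2[bad, , drop = FALSE])
  }
  d / METRES_PER_MILE
}

# full pairwise distance matrix in miles; neighbour candidates are ranked by
# fast spherical distance, exact Vincenty is computed on the candidate pairs
practice_distance_matrix <- function(lat, lon, k = 10L) {
  n <- length(lat)
  stopifnot(n >= 2L, length(lon) == n)
  pts <- cbind(lon, lat)
  sph <- geosphere::distm(pts, fun = geosphere::distCosine)
  k <- min(k, n - 1L)
  nbr <- t(apply(sph, 1L, function(r) order(r)[2:(k + 1L)]))
  dist_mi <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    j <- nbr[i, ]
    dist_mi[i, j] <- vincenty_distance(rep(lat[i], length(j)),
                                       rep(lon[i], length(j)),
                                       lat[j], lon[j])
  }
  list(neighbours = nbr, miles = dist_mi)
}

#' Distance to the best practice among the nearest neighbours
#'
#' For each practice, take its 10 nearest neighbouring practices (fewer when
#' the market is smaller) and return the distance to the one with the
#' highest QOF score; ties on the score go to the nearer practice. Under the
#' assumption that relocation costs increase with distance this proxies the
#' relocation-cost parameter of the market model. The alternative reading
#' "the furthest of the 10 nearest" is available via
#' `rule = "furthest_of_10"`.
#'
#' @param lat,lon Practice coordinates (decimal degrees), one per practice.
#' @param qof_scores QOF proportion of total points per practice (0--100).
#' @param k Neighbourhood size (default 10).
#' @param rule `"best_neighbour"` (default) or `"furthest_of_10"`.
#' @return Numeric vector of distances in miles, one per practice.
#' @export
distance_to_best_practice <- function(lat, lon, qof_scores, k = 10L,
                                      rule = c("best_neighbour",
                                               "furthest_of_10")) {
  rule <- match.arg(rule)
  n <- length(lat)
  if (n < 2L)
    stop("distance to the best practice is undefined in a singleton market",
         call. = FALSE)
  stopifnot(length(lon) == n, length(qof_scores) == n)
  dm <- practice_distance_matrix(lat, lon, k = k)
  dist_to_best_from_dm(dm, qof_scores, rule = rule)
}

# core of distance_to_best_practice on a precomputed neighbour structure
dist_to_best_from_dm <- function(dm, qof_scores,
                                 rule = c("best_neighbour",
                                          "furthest_of_10")) {
  rule <- match.arg(rule)
  vapply(seq_len(nrow(dm$neighbours)), function(i) {
    j <- dm$neighbours[i, ]
    d <- dm$miles[i, j]
    if (rule == "furthest_of_10") return(max(d))
    best <- max(qof_scores[j])
    cand <- which(qof_scores[j] == best)
    min(d[cand])  # nearer practice wins ties
  }, numeric(1))
}

#' Recode a reported income band to its interval midpoint
#'
#' Survey income is reported in eight intervals from under 25,000 GBP to
#' over 150,000 GBP; only the two endpoints are published, so the interior
#' band edges are a package decision. Band 1 is [0, 25,000) and band 7 is
#' [125,000, 150,000); bands 2--6 split the remaining [25,000, 125,000)
#' evenly. Each closed band maps to its midpoint; the open top band (over
#' 150,000) is assigned the midpoint obtained by extrapolating the last
#' closed band's 25,000 width, i.e. 162,500.
#'
#' @param band Integer vector with values in 1..8.
#' @return Income in GBP (interval midpoints).
#' @examples
#' income_recode(c(1, 8))  # 12500, 162500
#' @export
income_recode <- function(band) {
  if (!all(band %in% 1:8))
    stop("income band must be an integer in 1..8", call. = FALSE)
  mids <- c(12500, 35000, 55000, 75000, 95000, 115000, 137500, 162500)
  mids[band]
}
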