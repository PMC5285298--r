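#' Structural parameters of the two-practice contract-choice model
#'
#' Bundles the primitives of the market game: two practices located a
#' relocation cost `t` apart compete for doctors who are either efficient
#' (type `v`, effort-cost parameter `gamma_v`) or inefficient (type `nv`,
#' cost normalised to 1). Practices receive a capitation payment `m` and a
#' pay-for-performance price `p` per unit of measured quality; doctors value
#' local amenities `b1`, `b2` and have outside option `w_outside`.
#'
#' @param m Capitation payment (money units, >= 0).
#' @param p Price per quality point (money per quality unit, >= 0).
#' @param pi Probability that a newly hired doctor is efficient, in `[0, 1]`.
#' @param gamma_v Effort-cost parameter of the efficient type, in `(0, 1]`.
#' @param gamma_nv Effort-cost parameter of the inefficient type; fixed at 1
#'   by normalisation.
#' @param t Relocation cost (money, >= 0).
#' @param b1,b2 Amenity benefits of the two locations (money, >= 0).
#' @param w_outside Outside-option utility of a new doctor; the model fixes
#'   this at 0 and equilibrium salaried wages inherit it.
#'
#' @return An object of class `"model_params"` (a validated named list).
#' @examples
#' model_params(m = 0.5, p = 1.25, pi = 0.2, gamma_v = 0.3, t = 0.4)
#' @export
model_params <- function(m = 0.5, p = 1.25, pi = 0.2, gamma_v = 0.3,
                         gamma_nv = 1, t = 0.4, b1 = 1, b2 = 0.8,
                         w_outside = 0) {
  stopifnot(
    is.numeric(m), length(m) == 1L, is.finite(m),
    is.numeric(p), length(p) == 1L, is.finite(p),
    is.numeric(pi), length(pi) == 1L, is.finite(pi),
    is.numeric(gamma_v), length(gamma_v) == 1L, is.finite(gamma_v),
    is.numeric(t), length(t) == 1L, is.finite(t),
    is.numeric(b1), length(b1) == 1L, is.finite(b1),
    is.numeric(b2), length(b2) == 1L, is.finite(b2)
  )
  if (m < 0 || p < 0 || t < 0 || b1 < 0 || b2 < 0)
    stop("m, p, t, b1, b2 must all be >= 0", call. = FALSE)
  if (pi < 0 || pi > 1)
    stop("pi must lie in [0, 1]", call. = FALSE)
  if (gamma_nv != 1)
    stop("gamma_nv is fixed at 1 by normalisation", call. = FALSE)
  if (gamma_v <= 0 || gamma_v > gamma_nv)
    stop("gamma_v must satisfy 0 < gamma_v <= gamma_nv = 1", call. = FALSE)
  if (w_outside != 0)
    stop("w_outside is fixed at 0; wages are set to the outside option",
         call. = FALSE)
  structure(
    list(m = m, p = p, pi = pi, gamma_v = gamma_v, gamma_nv = gamma_nv,
         t = t, b1 = b1, b2 = b2, w_outside = w_outside),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Two-practice market primitives:\n")
  cat(sprintf("  capitation m = %g, P4P price p = %g, Pr(efficient) pi = %g\n",
              x$m, x$p, x$pi))
  cat(sprintf("  effort costs gamma_v = %g, gamma_nv = %g\n",
              x$gamma_v, x$gamma_nv))
  cat(sprintf("  relocation t = %g, amenities b1 = %g, b2 = %g\n",
              x$t, x$b1, x$b2))
  invisible(x)
}

# resolve a doctor-type tag to its effort-cost parameter
gamma_of <- function(params, doctor_type) {
  switch(doctor_type,
         v = params$gamma_v,
         nv = params$gamma_nv,
         stop("unknown doctor type: ", doctor_type, call. = FALSE))
}
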