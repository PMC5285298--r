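## Closed-form equilibrium of the two-practice contract-choice game.
##
## Timing: in stage 1 each practice (run by a profit-oriented manager) either
## hires a new salaried doctor of unknown type or offers a partnership to a
## local doctor of known type (possibly outbidding the rival for an efficient
## doctor); in stage 2 the practice chooses quality investment q and the
## doctor chooses medical effort e simultaneously; care is provided in
## stage 3. Quality perceived by patients is Q = q + e, doctors are altruistic
## (Q enters utility), and a partner receives half the practice surplus.

# --- closed-form primitives -------------------------------------------------

# expected profit from hiring a new salaried doctor (wage = outside option 0)
profit_new_salaried <- function(params) {
  with(params, m + p^2 / 2 + p * (gamma_v + pi - gamma_v * pi) / gamma_v)
}

# manager's residual profit with a partner of cost gamma paid wage w
profit_manager <- function(params, gamma, w = 0) {
  with(params, (gamma * (2 * m + p^2) + p * (p + 2)) / (4 * gamma)) - w / 2
}

# partner's equilibrium utility (half surplus + wage + quality - effort cost)
utility_partner <- function(params, gamma, b = 0, w = 0) {
  with(params, b + (p + 2)^2 / (8 * gamma) + (2 * m + p^2 + 2 * w + 4 * p) / 4)
}

# salaried doctor's equilibrium utility
utility_salaried <- function(params, gamma, b = 0, w = 0) {
  with(params, w + p + 1 / (2 * gamma) + b)
}

new_contract_outcome <- function(contract, doctor_type, effort, investment,
                                 wage, doctor_utility, practice_profit) {
  structure(
    list(contract = contract, doctor_type = doctor_type,
         effort = effort, investment = investment,
         quality = investment + effort, wage = wage,
         doctor_utility = doctor_utility, practice_profit = practice_profit),
    class = "contract_outcome"
  )
}

#' @export
print.contract_outcome <- function(x, ...) {
  cat(sprintf("Contract outcome [%s, type %s]:\n", x$contract, x$doctor_type))
  cat(sprintf("  effort e = %.4f, investment q = %.4f, quality Q = %.4f\n",
              x$effort, x$investment, x$quality))
  cat(sprintf("  wage w = %.4f, doctor utility U = %.4f, profit = %.4f\n",
              x$wage, x$doctor_utility, x$practice_profit))
  invisible(x)
}

# --- stage-2 equilibrium ----------------------------------------------------

#' Stage-2 equilibrium outcomes for one contract configuration
#'
#' Evaluates the closed-form second-stage equilibrium: a salaried doctor
#' exerts effort `e = 1/gamma` (the pay-for-performance price `p` does not
#' enter because a salaried wage is quality-independent) while a partner,
#' who shares half the practice surplus, exerts `e = (2 + p)/(2 gamma)`.
#' The practice invests `q = p` under either contract, so a positive price
#' is necessary for any quality investment.
#'
#' @param params A [model_params()] object.
#' @param contract One of `"new_salaried"`, `"local_partnership"`,
#'   `"contested_partnership"`. The two partnership kinds share the same
#'   stage-2 problem and differ only in the wage the manager concedes.
#' @param doctor_type `"v"`, `"nv"`, or `"unknown"` (new salaried hires only;
#'   effort and quality are then expectations over the type distribution).
#' @param b Amenity benefit of the practice location entering the doctor's
#'   utility (default 0).
#' @param w Wage paid to the doctor; defaults to the outside option 0.
#'
#' @return A `"contract_outcome"`: effort, investment, quality `Q = q + e`,
#'   wage, doctor utility and practice profit. For `new_salaried` the profit
#'   is the ex-ante expected profit over doctor types, the quantity that
#'   governs the stage-1 hiring choice.
#' @examples
#' pp <- model_params(p = 2, gamma_v = 0.5)
#' equilibrium_outcomes(pp, "new_salaried", "v")$effort        # 1/gamma = 2
#' equilibrium_outcomes(pp, "local_partnership", "v")$effort   # (2+p)/(2 gamma) = 4
#' @export
equilibrium_outcomes <- function(params,
                                 contract = c("new_salaried",
                                              "local_partnership",
                                              "contested_partnership"),
                                 doctor_type = c("v", "nv", "unknown"),
                                 b = 0, w = 0) {
  stopifnot(inherits(params, "model_params"))
  contract <- match.arg(contract)
  doctor_type <- match.arg(doctor_type)
  p <- params$p

  if (contract == "new_salaried") {
    if (doctor_type == "unknown") {
      e <- params$pi / params$gamma_v + (1 - params$pi) / params$gamma_nv
      u <- params$pi * utility_salaried(params, params$gamma_v, b, w) +
        (1 - params$pi) * utility_salaried(params, params$gamma_nv, b, w)
    } else {
      g <- gamma_of(params, doctor_type)
      e <- 1 / g
      u <- utility_salaried(params, g, b, w)
    }
    return(new_contract_outcome(contract, doctor_type, effort = e,
                                investment = p, wage = w,
                                doctor_utility = u,
                                practice_profit = profit_new_salaried(params) - w))
  }

  if (doctor_type == "unknown")
    stop("a partnership requires a doctor of known type", call. = FALSE)
  g <- gamma_of(params, doctor_type)
  new_contract_outcome(contract, doctor_type,
                       effort = (2 + p) / (2 * g),
                       investment = p, wage = w,
                       doctor_utility = utility_partner(params, g, b, w),
                       practice_profit = profit_manager(params, g, w))
}

# --- parameter regions ------------------------------------------------------

#' Parameter regions where a partnership beats a new salaried hire
#'
#' A practice considers offering a partnership to a local doctor of cost
#' `gamma_z` only when the manager's residual profit exceeds
#' `max(0, Pi^N)`, the profit from hiring a new salaried doctor. That
#' condition defines the region `S = S1 U S2` in `(m, p, gamma_z, pi)` space,
#' with thresholds `m_bar` on the capitation payment and `p_bar` on the
#' price, split at the cutoff `pi = (1 - 2 gamma_z)/(2 (1 - gamma_z))`.
#' `S_hat` additionally requires relocation costs small enough
#' (`0 < t < Pi_v^M - Pi_nv^M`) for competition over the efficient doctor
#' to be feasible. Inefficient doctors (`gamma_z = 1`) are never in `S`.
#'
#' @param params A [model_params()] object.
#' @param gamma_z Effort-cost parameter of the candidate partner, in `(0, 1]`.
#' @return A `"region_report"` with logical flags `in_S1`, `in_S2`, `in_S`,
#'   `in_S_hat` and the thresholds `m_bar`, `p_bar`, `pi_cutoff`.
#' @export
region_membership <- function(params, gamma_z = params$gamma_v) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(gamma_z) || length(gamma_z) != 1L ||
      gamma_z <= 0 || gamma_z > 1)
    stop("gamma_z must lie in (0, 1]", call. = FALSE)
  m <- params$m; p <- params$p; pi <- params$pi; g <- gamma_z

  m_bar <- p * (p - g * p + 2 * (1 + 2 * g * (-1 + pi) - 2 * pi)) / (2 * g)
  p_bar <- if (g < 1) 2 * (2 * pi - 1 - 2 * g * (1 - pi)) / (1 - g) else Inf
  pi_cutoff <- if (g < 1) (1 - 2 * g) / (2 * (1 - g)) else -Inf

  in_S1 <- g < 1 && m >= 0 && m < m_bar && p > p_bar &&
    pi > pi_cutoff && pi < 1
  in_S2 <- g < 1 && m >= 0 && m < m_bar && p > 0 &&
    pi > 0 && pi < pi_cutoff
  in_S <- in_S1 || in_S2

  # feasibility of relocating the efficient doctor
  gap <- profit_manager(params, params$gamma_v) -
    profit_manager(params, params$gamma_nv)
  in_S_hat <- in_S && params$t > 0 && params$t < gap

  structure(
    list(in_S1 = in_S1, in_S2 = in_S2, in_S = in_S, in_S_hat = in_S_hat,
         m_bar = m_bar, p_bar = p_bar, pi_cutoff = pi_cutoff,
         profit_gap_v_nv = gap),
    class = "region_report"
  )
}

#' @export
print.region_report <- function(x, ...) {
  cat(sprintf("Region membership: S1 = %s, S2 = %s, S = %s, S_hat = %s\n",
              x$in_S1, x$in_S2, x$in_S, x$in_S_hat))
  cat(sprintf("  thresholds: m_bar = %.4f, p_bar = %.4f, pi_cutoff = %.4f\n",
              x$m_bar, x$p_bar, x$pi_cutoff))
  invisible(x)
}

# --- competition over the efficient doctor ----------------------------------

#' Wage competition for the efficient doctor (asymmetric allocation)
#'
#' With an efficient doctor local to practice 1 and an inefficient one local
#' to practice 2, and parameters in `S_hat`, practice 2 may pay the
#' relocation cost `t` and bid for the efficient doctor. The highest wage
#' practice 2 is willing to offer, `w_bar_2`, leaves it indifferent between
#' outbidding and hiring a new doctor; practice 1 retains its local doctor
#' with `w_bar_1 = w_bar_2 - 2 (b1 - b2)`, since the amenity differential is
#' worth `2 (b1 - b2)` to a partner on half shares. The resulting contested
#' profit exceeds the new-hire profit by exactly `b1 - b2 + t`: retention
#' hinges on relocation costs and area characteristics, not on the price `p`.
#'
#' @param params A [model_params()] object; must lie in `S_hat`.
#' @return A `"competition_outcome"` with `w_bar_2`, `w_bar_1`,
#'   `profit_contested` and `profit_advantage` (contested profit minus the
#'   new-salaried profit).
#' @export
competition_outcomes <- function(params) {
  stopifnot(inherits(params, "model_params"))
  reg <- region_membership(params, params$gamma_v)
  if (!reg$in_S_hat)
    stop("parameters are outside S_hat: competition over the efficient ",
         "doctor is not feasible", call. = FALSE)
  m <- params$m; p <- params$p; pi <- params$pi
  g <- params$gamma_v; t <- params$t; b1 <- params$b1; b2 <- params$b2

  w_bar_2 <- (p^2 - g * (2 * m + p^2 + 4 * t) +
                2 * p * (1 + 2 * g * (-1 + pi) - 2 * pi)) / (2 * g)
  w_bar_1 <- w_bar_2 - 2 * (b1 - b2)
  profit_contested <- profit_manager(params, g, w = w_bar_1)
  profit_advantage <- profit_contested - profit_new_salaried(params)

  structure(
    list(w_bar_2 = w_bar_2, w_bar_1 = w_bar_1,
         profit_contested = profit_contested,
         profit_advantage = profit_advantage),
    class = "competition_outcome"
  )
}

#' @export
print.competition_outcome <- function(x, ...) {
  cat(sprintf("Competition for the efficient doctor:\n"))
  cat(sprintf("  rival's max offer w_bar_2 = %.4f, retention wage w_bar_1 = %.4f\n",
              x$w_bar_2, x$w_bar_1))
  cat(sprintf("  contested profit = %.4f, advantage over new hire = %.4f\n",
              x$profit_contested, x$profit_advantage))
  invisible(x)
}

# --- stage-1 contract choice ------------------------------------------------

#' Stage-1 contract choice of the two practices
#'
#' Each practice chooses between hiring a new salaried doctor (profit
#' `Pi^N`) and offering a partnership to its local doctor of known type
#' (profit `Pi^M`), the latter only when `Pi^M > max(0, Pi^N)`. Partnerships
#' are never offered to inefficient doctors, and without a
#' pay-for-performance scheme (`p = 0`, where `Pi^M = m/2 < Pi^N = m`) both
#' practices hire new doctors. In the asymmetric configuration with
#' parameters in `S_hat` the rival bids for the efficient doctor and the
#' local practice retains them at the contested wage `w_bar_1` whenever the
#' contested profit still beats a new hire. Exact profit ties resolve to the
#' status quo (a new salaried hire).
#'
#' @param params A [model_params()] object.
#' @param local_types Character vector of length 2: the known types
#'   (`"v"`/`"nv"`) of the doctors local to practices 1 and 2.
#' @return A `"stage1_choice"`: a list with elements `practice1` and
#'   `practice2`, each a `"contract_outcome"`, plus the `region_report` used.
#' @export
stage1_contract_choice <- function(params, local_types = c("v", "nv")) {
  stopifnot(inherits(params, "model_params"))
  local_types <- as.character(local_types)
  if (length(local_types) != 2L || !all(local_types %in% c("v", "nv")))
    stop("local_types must be two of 'v'/'nv'", call. = FALSE)

  prof_new <- profit_new_salaried(params)
  bs <- c(params$b1, params$b2)

  local_choice <- function(i) {
    z <- local_types[i]
    if (profit_manager(params, gamma_of(params, z)) > max(0, prof_new)) {
      equilibrium_outcomes(params, "local_partnership", z, b = bs[i])
    } else {
      equilibrium_outcomes(params, "new_salaried", "unknown", b = bs[i])
    }
  }

  asymmetric <- local_types[1] != local_types[2]
  reg <- region_membership(params, params$gamma_v)

  if (asymmetric && reg$in_S_hat) {
    # the efficient doctor's practice faces a bid from the rival
    iv <- which(local_types == "v")
    inv <- which(local_types == "nv")
    # amenity differential from the retaining practice's viewpoint
    swapped <- iv == 2L
    pars <- if (swapped) {
      model_params(m = params$m, p = params$p, pi = params$pi,
                   gamma_v = params$gamma_v, t = params$t,
                   b1 = params$b2, b2 = params$b1)
    } else params
    comp <- competition_outcomes(pars)
    choice <- vector("list", 2L)
    if (comp$profit_advantage > 0 && comp$profit_contested > 0) {
      choice[[iv]] <- equilibrium_outcomes(params, "contested_partnership",
                                           "v", b = bs[iv], w = comp$w_bar_1)
    } else {
      choice[[iv]] <- equilibrium_outcomes(params, "new_salaried", "unknown",
                                           b = bs[iv])
    }
    choice[[inv]] <- local_choice(inv)  # never a partnership for type nv
    out <- list(practice1 = choice[[1L]], practice2 = choice[[2L]],
                region = reg, competition = comp)
  } else {
    out <- list(practice1 = local_choice(1L), practice2 = local_choice(2L),
                region = reg, competition = NULL)
  }
  structure(out, class = "stage1_choice")
}

#' @export
print.stage1_choice <- function(x, ...) {
  cat("Stage-1 choices:\n")
  cat(sprintf("  practice 1: %s (type %s)\n",
              x$practice1$contract, x$practice1$doctor_type))
  cat(sprintf("  practice 2: %s (type %s)\n",
              x$practice2$contract, x$practice2$doctor_type))
  invisible(x)
}

# --- comparative statics ----------------------------------------------------

# targets evaluable as smooth functions of the primitives
cs_target_value <- function(params, target) {
  switch(target,
         w_bar_1 = competition_outcomes(params)$w_bar_1,
         w_bar_2 = competition_outcomes(params)$w_bar_2,
         profit_contested = competition_outcomes(params)$profit_contested,
         profit_advantage = competition_outcomes(params)$profit_advantage,
         partnership_premium = profit_manager(params, params$gamma_v) -
           profit_new_salaried(params),
         effort_partner_v = (2 + params$p) / (2 * params$gamma_v),
         stop("unknown comparative-statics target: ", target, call. = FALSE))
}

cs_shift_param <- function(params, wrt, delta) {
  val <- params[[wrt]] + delta
  args <- params[c("m", "p", "pi", "gamma_v", "t", "b1", "b2")]
  args[[wrt]] <- val
  do.call(model_params, args)
}

#' Sign of a comparative-static derivative
#'
#' Central finite-difference derivative of a model quantity with respect to
#' one primitive, evaluated at `params`, returning its sign. The step is
#' `h = 1e-5 * max(1, |value|)`. If the parameter point (or either
#' perturbation) leaves the region on which the target is defined, a
#' boundary warning is raised and `NA` is returned.
#'
#' @param params A [model_params()] object.
#' @param target One of `"w_bar_1"`, `"w_bar_2"`, `"profit_contested"`,
#'   `"profit_advantage"`, `"partnership_premium"` (`Pi_v^M - Pi^N`),
#'   `"effort_partner_v"`.
#' @param wrt One of `"m"`, `"p"`, `"pi"`, `"gamma_v"`, `"t"`, `"b1"`, `"b2"`.
#' @return `-1L`, `0L` or `1L` with attribute `"derivative"`; `NA` on a
#'   region boundary.
#' @export
comparative_static_sign <- function(params, target, wrt) {
  stopifnot(inherits(params, "model_params"))
  if (!wrt %in% c("m", "p", "pi", "gamma_v", "t", "b1", "b2"))
    stop("cannot differentiate with respect to '", wrt, "'", call. = FALSE)
  h <- 1e-5 * max(1, abs(params[[wrt]]))
  lo <- try(cs_shift_param(params, wrt, -h), silent = TRUE)
  hi <- try(cs_shift_param(params, wrt, +h), silent = TRUE)
  if (inherits(lo, "try-error") || inherits(hi, "try-error")) {
    warning("parameter '", wrt, "' is on its domain boundary; no sign returned",
            call. = FALSE)
    return(NA_integer_)
  }
  flo <- try(cs_target_value(lo, target), silent = TRUE)
  fhi <- try(cs_target_value(hi, target), silent = TRUE)
  if (inherits(flo, "try-error") || inherits(fhi, "try-error")) {
    warning("parameters lie on a region boundary for target '", target,
            "'; no sign returned", call. = FALSE)
    return(NA_integer_)
  }
  d <- (fhi - flo) / (2 * h)
  s <- if (abs(d) < 1e-8) 0L else if (d > 0) 1L else -1L
  attr(s, "derivative") <- d
  s
}

# --- numeric oracle ---------------------------------------------------------

#' Numeric best-response oracle for the stage-2 equilibrium
#'
#' Independently verifies the closed forms by solving the simultaneous
#' stage-2 choices numerically: given the current investment `q`, the doctor
#' maximises utility over effort `e` by golden-section search on `[0, 50]`;
#' given current efforts, the practice maximises profit over `q` on the same
#' box; iteration continues to a fixed point. Equilibria are interior for
#' the parameter ranges of interest (`p <= 10`, `gamma >= 0.1`), except the
#' `p = 0` investment which sits on the lower bound `q = 0`.
#'
#' @inheritParams equilibrium_outcomes
#' @param tol Fixed-point tolerance on the maximum change per sweep; the
#'   inner univariate searches are solved to 1e-10, so equilibrium accuracy
#'   is governed by those, not by `tol`.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return A `"contract_outcome"` mirroring [equilibrium_outcomes()].
#' @export
equilibrium_oracle <- function(params,
                               contract = c("new_salaried",
                                            "local_partnership",
                                            "contested_partnership"),
                               doctor_type = c("v", "nv", "unknown"),
                               b = 0, w = 0, tol = 2e-6, max_iter = 500L) {
  stopifnot(inherits(params, "model_params"))
  contract <- match.arg(contract)
  doctor_type <- match.arg(doctor_type)
  m <- params$m; p <- params$p; pi <- params$pi
  box <- c(0, 50)

  if (contract == "new_salaried") {
    # salaried doctor of type z: U = w + (q + e) - gamma e^2/2 + b
    u_sal <- function(e, g, q) w + (q + e) - g * e^2 / 2 + b
    # practice: expected profit over types
    prof <- function(q, e_v, e_nv)
      m + p * (pi * (q + e_v) + (1 - pi) * (q + e_nv)) - w - q^2 / 2
    e_v <- 1; e_nv <- 1; q <- 0
    for (it in seq_len(max_iter)) {
      e_v_new <- stats::optimize(u_sal, box, g = params$gamma_v, q = q,
                                 maximum = TRUE, tol = 1e-10)$maximum
      e_nv_new <- stats::optimize(u_sal, box, g = params$gamma_nv, q = q,
                                  maximum = TRUE, tol = 1e-10)$maximum
      q_new <- stats::optimize(prof, box, e_v = e_v_new, e_nv = e_nv_new,
                               maximum = TRUE, tol = 1e-10)$maximum
      delta <- max(abs(c(e_v_new - e_v, e_nv_new - e_nv, q_new - q)))
      e_v <- e_v_new; e_nv <- e_nv_new; q <- q_new
      if (delta < tol) break
      if (it == max_iter)
        stop("best-response iteration did not converge", call. = FALSE)
    }
    q <- snap_to_box(q, box)
    e <- switch(doctor_type, v = e_v, nv = e_nv,
                unknown = pi * e_v + (1 - pi) * e_nv)
    u <- switch(doctor_type,
                v = u_sal(e_v, params$gamma_v, q),
                nv = u_sal(e_nv, params$gamma_nv, q),
                unknown = pi * u_sal(e_v, params$gamma_v, q) +
                  (1 - pi) * u_sal(e_nv, params$gamma_nv, q))
    return(new_contract_outcome(contract, doctor_type, effort = e,
                                investment = q, wage = w, doctor_utility = u,
                                practice_profit = prof(q, e_v, e_nv)))
  }

  if (doctor_type == "unknown")
    stop("a partnership requires a doctor of known type", call. = FALSE)
  g <- gamma_of(params, doctor_type)
  u_part <- function(e, q)
    0.5 * (m + p * (q + e) - w - q^2 / 2) + w + (q + e) - g * e^2 / 2 + b
  prof_mgr <- function(q, e) 0.5 * (m + p * (q + e) - w - q^2 / 2)
  e <- 1; q <- 0
  for (it in seq_len(max_iter)) {
    e_new <- stats::optimize(u_part, box, q = q, maximum = TRUE,
                             tol = 1e-10)$maximum
    q_new <- stats::optimize(prof_mgr, box, e = e_new, maximum = TRUE,
                             tol = 1e-10)$maximum
    delta <- max(abs(c(e_new - e, q_new - q)))
    e <- e_new; q <- q_new
    if (delta < tol) break
    if (it == max_iter)
      stop("best-response iteration did not converge", call. = FALSE)
  }
  q <- snap_to_box(q, box)
  new_contract_outcome(contract, doctor_type, effort = e, investment = q,
                       wage = w, doctor_utility = u_part(e, q),
                       practice_profit = prof_mgr(q, e))
}

# optimize() cannot land exactly on a bound; snap when the optimum is pinned
snap_to_box <- function(x, box, eps = 1e-6) {
  if (x - box[1] < eps) return(box[1])
  if (box[2] - x < eps) return(box[2])
  x
}
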