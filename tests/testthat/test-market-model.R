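# Closed-form equilibrium of the two-practice game.

test_that("parameter validation enforces the model's domain", {
  expect_error(model_params(gamma_v = 0), "gamma_v")
  expect_error(model_params(gamma_v = 1.2), "gamma_v")
  expect_error(model_params(pi = 1.5), "pi")
  expect_error(model_params(m = -1), ">= 0")
  expect_error(model_params(gamma_nv = 0.9), "normalisation")
})

test_that("stage-2 closed forms match the model's printed solutions", {
  # no P4P scheme: no investment, and expected profit collapses to m
  p0 <- model_params(p = 0, m = 3, gamma_v = 0.5)
  for (ct in c("new_salaried", "local_partnership")) {
    out <- equilibrium_outcomes(p0, ct, "v")
    expect_identical(out$investment, 0)
  }
  expect_identical(
    equilibrium_outcomes(p0, "new_salaried", "unknown")$practice_profit, 3)

  # gamma = 1: salaried effort 1; partner effort 1 at p = 0
  g1 <- model_params(p = 0, gamma_v = 1)
  expect_equal(equilibrium_outcomes(g1, "new_salaried", "nv")$effort, 1)
  expect_equal(equilibrium_outcomes(g1, "local_partnership", "nv")$effort, 1)

  # p = 2, gamma_v = 0.5: salaried 2, partner 4, and the P4P ordering
  pp <- model_params(p = 2, gamma_v = 0.5)
  eN <- equilibrium_outcomes(pp, "new_salaried", "v")$effort
  eP <- equilibrium_outcomes(pp, "local_partnership", "v")$effort
  expect_equal(eN, 2)
  expect_equal(eP, 4)
  expect_gte(eP, eN)

  expect_error(equilibrium_outcomes(pp, "local_partnership", "unknown"),
               "known type")
})

test_that("quality is investment plus effort and q equals p in all contracts", {
  set.seed(42)
  for (i in 1:20) {
    pars <- model_params(m = runif(1, 0, 3), p = runif(1, 0, 4),
                         pi = runif(1), gamma_v = runif(1, 0.1, 1))
    for (ct in c("new_salaried", "local_partnership",
                 "contested_partnership")) {
      type <- if (ct == "new_salaried") "unknown" else "v"
      out <- equilibrium_outcomes(pars, ct, type)
      expect_identical(out$quality, out$investment + out$effort)
      expect_identical(out$investment, pars$p)
      # partner effort always weakly exceeds salaried effort, equal iff p=0
      if (ct != "new_salaried") {
        eN <- equilibrium_outcomes(pars, "new_salaried", "v")$effort
        if (pars$p == 0) expect_equal(out$effort, eN)
        else expect_gt(out$effort, eN)
      }
    }
  }
})

test_that("partner utility definition agrees with its printed closed form", {
  set.seed(7)
  for (i in 1:50) {
    pars <- model_params(m = runif(1, 0, 3), p = runif(1, 0, 4),
                         pi = runif(1), gamma_v = runif(1, 0.1, 1))
    b <- runif(1, 0, 2); w <- runif(1, 0, 1)
    g <- pars$gamma_v
    out <- equilibrium_outcomes(pars, "local_partnership", "v", b = b, w = w)
    # definition: half surplus + wage + quality - effort cost + amenity
    surplus <- pars$m + pars$p * out$quality - w - out$investment^2 / 2
    u_def <- 0.5 * surplus + w + out$quality - g * out$effort^2 / 2 + b
    expect_lt(abs(u_def - out$doctor_utility), 1e-10)
    # and the manager keeps the other half of the surplus
    expect_lt(abs(out$practice_profit - 0.5 * surplus), 1e-10)
  }
})

test_that("region membership matches the defining profit comparison", {
  # the inefficient type is never offered a partnership
  set.seed(11)
  for (i in 1:50) {
    pars <- model_params(m = runif(1, 0, 3), p = runif(1, 0, 4),
                         pi = runif(1), gamma_v = runif(1, 0.1, 0.99))
    reg_nv <- region_membership(pars, gamma_z = 1)
    expect_false(reg_nv$in_S1)
    expect_false(reg_nv$in_S2)
    # brute force: S holds iff the manager profit beats max(0, Pi^N)
    reg_v <- region_membership(pars, pars$gamma_v)
    profM <- equilibrium_outcomes(pars, "local_partnership",
                                  "v")$practice_profit
    profN <- equilibrium_outcomes(pars, "new_salaried",
                                  "unknown")$practice_profit
    expect_identical(reg_v$in_S, profM > max(0, profN))
    expect_identical(reg_v$in_S, reg_v$in_S1 || reg_v$in_S2)
    if (reg_v$in_S_hat) expect_true(reg_v$in_S)
  }
  # p = 0: partnership profit m/2 < new-hire profit m, so never in S
  expect_false(region_membership(model_params(p = 0, m = 1),
                                 0.5)$in_S)
  expect_error(region_membership(model_params(), gamma_z = 0), "0, 1")
  expect_error(region_membership(model_params(), gamma_z = 1.1), "0, 1")
})

test_that("contested-profit identity and wage formulas hold on S_hat draws", {
  draws <- draw_params_in_region(200, seed = 3, shat = TRUE)
  for (pars in draws) {
    comp <- competition_outcomes(pars)
    adv <- pars$b1 - pars$b2 + pars$t
    expect_lt(abs(comp$profit_advantage - adv), 1e-10)
    expect_lt(abs(comp$w_bar_1 -
                    (comp$w_bar_2 - 2 * (pars$b1 - pars$b2))), 1e-12)
  }
  # zero amenity differential: both wages coincide
  pars <- draws[[1]]
  pars_eq <- model_params(m = pars$m, p = pars$p, pi = pars$pi,
                          gamma_v = pars$gamma_v, t = pars$t,
                          b1 = 1, b2 = 1)
  if (region_membership(pars_eq, pars_eq$gamma_v)$in_S_hat) {
    c2 <- competition_outcomes(pars_eq)
    expect_equal(c2$w_bar_1, c2$w_bar_2)
  }
  # outside S_hat the competition stage errors
  expect_error(competition_outcomes(model_params(p = 0)), "S_hat")
})

test_that("contested wage agrees with a constrained-maximisation oracle", {
  # practice 1 maximises its partner profit subject to matching the utility
  # the rival's best offer gives the doctor; grid search over the wage
  pars <- draw_params_in_region(5, seed = 9, shat = TRUE)[[3]]
  comp <- competition_outcomes(pars)
  # rival's best offer leaves it indifferent to a new hire after paying t
  profM0_rival <- equilibrium_outcomes(pars, "local_partnership",
                                       "v")$practice_profit
  profN <- equilibrium_outcomes(pars, "new_salaried",
                                "unknown")$practice_profit
  w2_grid <- seq(0, 20, by = 1e-5)
  feasible2 <- profM0_rival - w2_grid / 2 - pars$t >= profN
  w2_oracle <- max(w2_grid[feasible2])
  expect_lt(abs(w2_oracle - comp$w_bar_2), 1e-3)
  # doctor indifference pins the retention wage via the amenity wedge
  u1 <- function(w) equilibrium_outcomes(pars, "contested_partnership", "v",
                                         b = pars$b1, w = w)$doctor_utility
  u2_at_best <- equilibrium_outcomes(pars, "contested_partnership", "v",
                                     b = pars$b2,
                                     w = comp$w_bar_2)$doctor_utility
  expect_lt(abs(u1(comp$w_bar_1) - u2_at_best), 1e-10)
})

test_that("stage-1 choices follow the profit comparison", {
  # no P4P scheme: both practices hire new salaried doctors
  ch0 <- stage1_contract_choice(model_params(p = 0), c("v", "nv"))
  expect_identical(ch0$practice1$contract, "new_salaried")
  expect_identical(ch0$practice2$contract, "new_salaried")

  # inefficient doctors never receive partnership offers
  pars <- draw_params_in_region(1, seed = 5)[[1]]
  ch_nv <- stage1_contract_choice(pars, c("nv", "nv"))
  expect_identical(ch_nv$practice1$contract, "new_salaried")
  expect_identical(ch_nv$practice2$contract, "new_salaried")

  # asymmetric case in S_hat with positive advantage: practice 1 retains
  # the efficient doctor under competition
  ps <- draw_params_in_region(20, seed = 6, shat = TRUE)
  for (pars in ps) {
    if (pars$b1 - pars$b2 + pars$t <= 0) next
    ch <- stage1_contract_choice(pars, c("v", "nv"))
    expect_identical(ch$practice1$contract, "contested_partnership")
    expect_identical(ch$practice1$doctor_type, "v")
    expect_identical(ch$practice2$contract, "new_salaried")
  }
  expect_error(stage1_contract_choice(pars, c("v", "x")), "local_types")
})

test_that("comparative statics reproduce the model's stated signs", {
  ps <- draw_params_in_region(10, seed = 12, shat = TRUE)
  signs <- c(p = 1L, b2 = 1L, m = -1L, gamma_v = -1L, pi = -1L,
             t = -1L, b1 = -1L)
  for (pars in ps) {
    for (wrt in names(signs)) {
      s <- comparative_static_sign(pars, "w_bar_1", wrt)
      if (is.na(s)) next  # perturbation left S_hat: boundary case
      expect_identical(as.integer(s), signs[[wrt]],
                       label = sprintf("sign of d w_bar_1 / d %s", wrt))
    }
    # profitability of the local partnership falls with pi
    s_pi <- comparative_static_sign(pars, "partnership_premium", "pi")
    expect_identical(as.integer(s_pi), -1L)
  }
  # a parameter on its domain boundary yields a warning and NA
  edge <- model_params(p = 1.25, gamma_v = 0.3, pi = 0, t = 0.4)
  expect_warning(s <- comparative_static_sign(edge, "partnership_premium",
                                              "pi"), "boundary")
  expect_true(is.na(s))
})

test_that("numeric best-response oracle agrees with every closed form", {
  set.seed(21)
  for (i in 1:25) {
    pars <- model_params(m = runif(1, 0, 3), p = runif(1, 0, 4),
                         pi = runif(1), gamma_v = runif(1, 0.1, 1))
    sal <- equilibrium_oracle(pars, "new_salaried", "v")
    expect_lt(abs(sal$effort - 1 / pars$gamma_v), 1e-6)
    expect_lt(abs(sal$investment - pars$p), 1e-6)
    par_o <- equilibrium_oracle(pars, "local_partnership", "nv")
    expect_lt(abs(par_o$effort - (2 + pars$p) / 2), 1e-6)
    expect_lt(abs(par_o$investment - pars$p), 1e-6)
  }
  # p = 0 pins the investment on the lower search bound exactly
  o0 <- equilibrium_oracle(model_params(p = 0), "new_salaried", "nv")
  expect_identical(o0$investment, 0)
})
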