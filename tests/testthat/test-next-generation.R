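test_that("disease-free age profile matches the aging/mortality balance", {
  # n = 1: everything in the single stage
  pop1 <- scalar_pop()
  expect_equal(disease_free_equilibrium(pop1)$S_hat, 1)
  # n = 2 with alpha_2 = a_1 / (a_2 + delta_2) = 0.05 / 0.05 = 1
  pop2 <- population_structure(2, aging = c(0.05, 0),
                               mortality = c(0.0, 0.05),
                               immunity_loss = 0.02)
  expect_equal(disease_free_equilibrium(pop2)$S_hat, c(0.5, 0.5),
               tolerance = 1e-14)
  # oracle: the profile solves the linear stationarity system a_i-1 S_{i-1}
  # = (a_i + delta_i) S_i with unit total, independently of the recursion
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(2:6, 1)
    inst <- random_instance(n)
    A <- matrix(0, n, n)
    for (i in 2:n) {
      A[i, i - 1] <- inst$pop$aging[i - 1]
      A[i, i] <- -(inst$pop$aging[i] + inst$pop$mortality[i])
    }
    A[1, ] <- 1                       # replace redundant row by the total
    b <- c(inst$pop$total, rep(0, n - 1))
    expect_equal(disease_free_equilibrium(inst$pop)$S_hat,
                 solve(A, b), tolerance = 1e-12)
  }
})

test_that("terminal stage with no exit route is rejected", {
  expect_error(disease_free_equilibrium(
    population_structure(2, aging = c(0.05, 0), mortality = c(0.01, 0),
                         immunity_loss = 0)),
    "positive")
})

test_that("closed-form transition-matrix inverse is exact", {
  # n = 2 hand inversion: a1 = 1, mu = (2, 4)
  pop <- population_structure(2, aging = c(1, 0), mortality = c(0.5, 1),
                              immunity_loss = 0)
  strain <- strain_traits(c(0.5, 3), 0, tradeoff_power_law(1, 0.5))
  tm <- transition_matrix(pop, strain)
  expect_equal(tm$mu, c(2, 4))
  expect_equal(-tm$Sigma_inv, rbind(c(1 / 2, 0), c(1 / 8, 1 / 4)),
               tolerance = 1e-15)
  # random n = 5: Sigma %*% Sigma_inv = I
  set.seed(22)
  inst <- random_instance(5L)
  tm5 <- transition_matrix(inst$pop, inst$strain)
  expect_lt(max(abs(tm5$Sigma %*% tm5$Sigma_inv - diag(5))), 1e-12)
  expect_equal(tm5$Sigma_inv, solve(tm5$Sigma), tolerance = 1e-12)
})

test_that("R0 reduces to the scalar SIRS closed form at n = 1", {
  pop <- scalar_pop()
  strain <- scalar_strain()
  expect_equal(r0(pop, strain, unit_trans(), method = "trace"),
               0.4 / (0.1 + 0.01), tolerance = 1e-12)
  zero <- strain_traits(0.1, 0, tradeoff_power_law(1e-300, 0.5))
  expect_lt(r0(pop, zero, unit_trans()), 1e-100)
})

test_that("trace formula equals the dominant eigenvalue for rank-1 T", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    inst <- random_instance(n)
    rt <- r0(inst$pop, inst$strain, inst$trans, method = "trace")
    re <- r0(inst$pop, inst$strain, inst$trans, method = "eigen")
    expect_lt(abs(rt - re), 1e-10 * re)
    bundle <- next_generation(inst$pop, inst$strain, inst$trans,
                              disease_free_equilibrium(inst$pop)$S_hat,
                              method = "eigen")
    expect_true(all(bundle$K >= 0))
  }
})

test_that("the trace shortcut refuses non-separable transmission", {
  set.seed(24)
  pop <- population_structure(3, aging = c(0.02, 0.01, 0),
                              mortality = c(0.01, 0.02, 0.03),
                              immunity_loss = 0.02)
  strain <- strain_traits(rep(0.2, 3), 0, tradeoff_power_law(1, 0.5))
  trans <- transmission_general(matrix(stats::runif(9), 3, 3))
  expect_error(r0(pop, strain, trans, method = "trace"), "rank")
  # and for good reason: the trace genuinely differs from the spectral
  # radius for a generic full-rank matrix
  bundle <- next_generation(pop, strain, trans,
                            disease_free_equilibrium(pop)$S_hat,
                            method = "eigen")
  expect_gt(abs(sum(diag(bundle$K)) - bundle$value), 1e-6)
})

test_that("a mutant identical to the resident is neutral (Q0 = 1)", {
  for (build in list(function() list(sc = generate_scenario("single_stage")),
                     function() list(sc = generate_scenario("three_stage_human")))) {
    sc <- build()$sc
    eq <- endemic_equilibrium(sc$population, sc$strain, sc$transmission)
    q0 <- invasion_number(eq$state[seq_len(sc$population$n)],
                          sc$population, sc$strain, sc$transmission)
    expect_equal(q0, 1, tolerance = 1e-6)
  }
})

test_that("Q0 is linear in transmission", {
  sc <- generate_scenario("three_stage_human")
  eq <- endemic_equilibrium(sc$population, sc$strain, sc$transmission)
  S_star <- eq$state[1:3]
  trans2 <- transmission_outer(sc$transmission$susceptibility * 2,
                               sc$transmission$infectivity_weights)
  q1 <- invasion_number(S_star, sc$population, sc$strain, sc$transmission)
  q2 <- invasion_number(S_star, sc$population, sc$strain, trans2)
  expect_equal(q2, 2 * q1, tolerance = 1e-12)
})

test_that("Q0 predicts early mutant growth or decay in the full dynamics", {
  pop <- scalar_pop()
  trans <- unit_trans()
  resident <- scalar_strain()               # gamma = 0.1, tradeoff p = 0.5
  eq <- endemic_equilibrium(pop, resident, trans)
  tf <- resident$tradeoff
  for (gamma_mut in c(0.03, 0.4)) {
    mut <- strain_traits(gamma_mut, 0, tf)
    q0 <- invasion_number(eq$state[1], pop, mut, trans)
    st <- split_state <- eq$state
    seed <- 1e-6
    init <- system_state(st[["S1"]], st[["I1"]] - seed, st[["R1"]],
                         I_tilde = seed, R_tilde = 0)
    traj <- integrate_sirs(init, c(0, 400), pop, resident, trans,
                           mutant = mut)
    growth <- traj$Itilde1[2] / seed
    if (q0 > 1) expect_gt(growth, 1) else expect_lt(growth, 1)
  }
})

test_that("Q0 gradient vanishes at the trade-off optimum and not away from it", {
  pop <- scalar_pop()
  tf <- tradeoff_power_law(1, 0.5)
  gamma_star <- ess_power_law_closed_form(0.5, 0.01)
  trans <- unit_trans()
  at_ess <- strain_traits(gamma_star, 0, tf)
  g <- q0_gradient(at_ess, pop, trans)
  expect_lt(abs(g), 1e-6)
  below <- strain_traits(gamma_star / 2, 0, tf)
  expect_gt(q0_gradient(below, pop, trans), 0)   # acuter mutants invade
  above <- strain_traits(gamma_star * 2, 0, tf)
  expect_lt(q0_gradient(above, pop, trans), 0)
  # contact scale cancels: rescaled contacts leave the stationary point
  big <- transmission_outer(1000, 1)
  g_big <- q0_gradient(at_ess, pop, big)
  expect_lt(abs(g_big) / max(abs(q0_gradient(below, pop, big))), 1e-5)
})
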