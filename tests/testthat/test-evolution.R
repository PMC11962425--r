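test_that("mutation kernel statistics and degenerate cases", {
  kern0 <- mutation_kernel(0)
  expect_identical(propose_mutant(c(0.1, 0.2), kern0), c(0.1, 0.2))
  set.seed(31)
  kern <- mutation_kernel(0.1)
  props <- replicate(1e4, propose_mutant(0.05, kern))
  logratio <- log(props / 0.05)
  # log-normal kernel: mean log step 0 within 3 standard errors
  expect_lt(abs(mean(logratio)), 3 * 0.1 / sqrt(1e4))
  expect_equal(stats::sd(logratio), 0.1, tolerance = 0.05)
  expect_true(all(props > 0))
  # per-stage kernel touches exactly one stage per proposal
  kern1 <- mutation_kernel(0.2, per_stage = TRUE)
  set.seed(32)
  for (i in 1:20) {
    p <- propose_mutant(c(0.1, 0.2, 0.3), kern1)
    expect_equal(sum(p != c(0.1, 0.2, 0.3)), 1L)
  }
})

test_that("identical seeds reproduce trajectories bit for bit", {
  pop <- scalar_pop()
  strain <- strain_traits(0.04, 0, tradeoff_power_law(1, 0.5))
  t1 <- run_evolution(pop, strain, unit_trans(),
                      mutation_kernel(0.1, seed = 99), 40)
  t2 <- run_evolution(pop, strain, unit_trans(),
                      mutation_kernel(0.1, seed = 99), 40)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- run_evolution(pop, strain, unit_trans(),
                      mutation_kernel(0.1, seed = 100), 40)
  expect_false(identical(t1$q0, t3$q0))
})

test_that("a zero-step kernel freezes evolution", {
  pop <- scalar_pop()
  strain <- strain_traits(0.04, 0, tradeoff_power_law(1, 0.5))
  traj <- run_evolution(pop, strain, unit_trans(),
                        mutation_kernel(0, seed = 1), 10)
  expect_true(all(traj$outcome == "extinct"))   # Q0 = 1, never > 1
  expect_true(all(traj$resident_gamma1 == 0.04))
  expect_equal(traj$q0, rep(1, 10), tolerance = 1e-8)
})

test_that("competition outcome follows the invasion number", {
  pop <- scalar_pop()
  trans <- unit_trans()
  resident <- scalar_strain()                  # gamma = 0.1
  eq <- endemic_equilibrium(pop, resident, trans)
  tf <- resident$tradeoff
  q0_of <- function(g) invasion_number(eq$state[1], pop,
                                       strain_traits(g, 0, tf), trans)
  g_up <- stats::uniroot(function(g) q0_of(g) - 1.5, c(1e-3, 0.01))$root
  g_down <- stats::uniroot(function(g) q0_of(g) - 0.7, c(0.1, 10))$root
  expect_equal(compete(pop, resident, strain_traits(g_up, 0, tf), trans,
                       resident_eq = eq)$outcome, "fixed")
  expect_equal(compete(pop, resident, strain_traits(g_down, 0, tf), trans,
                       resident_eq = eq)$outcome, "extinct")
  # a neutral clone drifts nowhere in deterministic ODEs: timeout with the
  # mutant share pinned at its seeding ratio
  neut <- compete(pop, resident, resident, trans, resident_eq = eq,
                  max_time = 2000)
  expect_equal(neut$outcome, "timeout")
  expect_equal(neut$share, 1e-6 / sum(eq$state[["I1"]]), tolerance = 0.01)
})

test_that("dynamical competition agrees with the Q0 criterion away from
           neutrality", {
  # inside a narrow band around Q0 = 1 the mutant's growth time
  # ~ 1 / ((Q0 - 1)(gamma + delta)) exceeds any finite competition
  # horizon, so agreement is asserted outside it
  pop <- scalar_pop()
  trans <- unit_trans()
  resident <- strain_traits(0.03, 0, tradeoff_power_law(1, 0.5))
  eq <- endemic_equilibrium(pop, resident, trans)
  tf <- resident$tradeoff
  q0_of <- function(g) invasion_number(eq$state[1], pop,
                                       strain_traits(g, 0, tf), trans)
  for (q_target in c(0.9, 1.1)) {
    for (bracket in list(c(1e-3, 0.0095), c(0.0105, 5))) {
      root <- tryCatch(
        stats::uniroot(function(g) q0_of(g) - q_target, bracket)$root,
        error = function(e) NULL)
      if (is.null(root)) next      # no crossing on this side of the peak
      out <- compete(pop, resident, strain_traits(root, 0, tf), trans,
                     resident_eq = eq)
      expect_equal(out$outcome, if (q_target > 1) "fixed" else "extinct")
    }
  }
})

test_that("adaptive dynamics climbs toward the ESS from both sides", {
  pop <- scalar_pop()
  tf <- tradeoff_power_law(1, 0.5)
  gamma_star <- ess_power_law_closed_form(0.5, 0.01)
  for (start_factor in c(4, 0.25)) {
    strain <- strain_traits(gamma_star * start_factor, 0, tf)
    traj <- run_evolution(pop, strain, unit_trans(),
                          mutation_kernel(0.1, seed = 5), 150)
    fix <- traj[traj$outcome == "fixed", ]
    expect_gt(nrow(fix), 3)
    expect_true(all(fix$q0 > 1))
    expect_true(all(diff(fix$resident_r0) >= -1e-6))
    final <- traj$resident_gamma1[nrow(traj)]
    expect_lt(abs(final - gamma_star),
              abs(gamma_star * start_factor - gamma_star))
    expect_lt(abs(final - gamma_star) / gamma_star, 0.25)
  }
})

test_that("a displaced resident cannot re-invade (no invasion cycles)", {
  pop <- scalar_pop()
  tf <- tradeoff_power_law(1, 0.5)
  strain <- strain_traits(0.04, 0, tf)
  traj <- run_evolution(pop, strain, unit_trans(),
                        mutation_kernel(0.1, seed = 5), 60)
  fix_idx <- which(traj$outcome == "fixed")
  expect_gt(length(fix_idx), 0)
  k <- fix_idx[length(fix_idx)]
  old_gamma <- if (k == 1) 0.04 else traj$resident_gamma1[k - 1]
  new_resident <- strain_traits(traj$resident_gamma1[k], 0, tf)
  eq <- endemic_equilibrium(pop, new_resident, unit_trans())
  q0_back <- invasion_number(eq$state[1], pop,
                             strain_traits(old_gamma, 0, tf), unit_trans())
  expect_lt(q0_back, 1)
})

test_that("fixations rarify as the resident approaches the optimum", {
  pop <- scalar_pop()
  tf <- tradeoff_power_law(1, 0.5)
  strain <- strain_traits(0.08, 0, tf)       # 8x the ESS value 0.01
  traj <- run_evolution(pop, strain, unit_trans(),
                        mutation_kernel(0.1, seed = 11), 300)
  first <- mean(traj$outcome[1:100] == "fixed")
  last <- mean(traj$outcome[201:300] == "fixed")
  expect_gt(first, last)
})

test_that("random-contact sensitivity breaks rank 1 reproducibly", {
  base <- generate_scenario("three_stage_human")$transmission
  t1 <- sensitivity_random_contacts(base, seed = 3)
  t2 <- sensitivity_random_contacts(base, seed = 3)
  expect_identical(t1$contact_matrix, t2$contact_matrix)
  expect_true(all(t1$contact_matrix >= 0 & t1$contact_matrix <= 1))
  expect_equal(t1$mode, "general")
  expect_equal(qr(t1$contact_matrix)$rank, 3L)
  sc <- generate_scenario("three_stage_human")
  expect_error(r0(sc$population, sc$strain, t1, method = "trace"), "rank")
  expect_error(sensitivity_random_contacts(t1), "outer-product")
})

test_that("high-CFR mode raises the predicted ESS recovery rate", {
  sc <- generate_scenario("three_stage_human")
  hi <- sensitivity_high_cfr(sc$strain, sc$population, multiplier = 5)
  expect_equal(hi$disease_mortality, 50 * sc$population$mortality)
  g_low <- solve_ess(sc$population, sc$strain$disease_mortality,
                     sc$strain$tradeoff)$gamma_star
  g_high <- solve_ess(sc$population, hi$disease_mortality,
                      sc$strain$tradeoff)$gamma_star
  expect_true(all(g_high > g_low))
  expect_error(sensitivity_high_cfr(sc$strain, sc$population, 0.5), ">=")
})

test_that("evolution under high CFR tracks the shifted optimum", {
  # d >> delta: Eq.-5-style prediction gamma* ~ p (a+d+delta) / (1-p)
  pop <- scalar_pop()
  tf <- tradeoff_power_law(1, 0.5)
  strain0 <- strain_traits(0.05, 0.1, tf)     # CFR-dominated exit
  gamma_star <- solve_ess(pop, 0.1, tf)$gamma_star
  expect_equal(gamma_star, ess_power_law_closed_form(0.5, 0.11),
               tolerance = 1e-9)
  traj <- run_evolution(pop, strain0, unit_trans(),
                        mutation_kernel(0.1, seed = 13), 120)
  fix <- traj[traj$outcome == "fixed", ]
  # sign test: fixations move gamma toward the high-CFR optimum
  gam_path <- c(0.05, fix$resident_gamma1)
  toward <- sign(diff(gam_path)) == sign(gamma_star - gam_path[-length(gam_path)])
  expect_true(all(toward))
  expect_lt(abs(gam_path[length(gam_path)] - gamma_star),
            abs(0.05 - gamma_star))
})
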