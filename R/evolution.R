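#' Mutation kernel for evolutionary simulations
#'
#' Proposal distribution for invading variants: each proposal multiplies the
#' resident's per-stage recovery rates by independent log-normal factors
#' `exp(sigma * z)`, `z ~ N(0, 1)`, which keeps rates positive and is
#' scale-free. Either all stages are perturbed jointly or a single randomly
#' chosen stage per proposal.
#'
#' @param step_scale Relative perturbation magnitude `sigma > 0`.
#' @param per_stage If `TRUE`, perturb one randomly chosen stage per
#'   proposal; otherwise perturb all stages.
#' @param seed Integer seed recorded with the kernel; [run_evolution()]
#'   seeds its generator from it so identical configurations reproduce
#'   identical trajectories.
#' @return An object of class `"mutation_kernel"`.
#' @export
mutation_kernel <- function(step_scale = 0.1, per_stage = FALSE,
                            seed = NULL) {
  if (step_scale < 0)
    stop("'step_scale' must be nonnegative", call. = FALSE)
  structure(list(step_scale = step_scale, per_stage = isTRUE(per_stage),
                 seed = seed),
            class = "mutation_kernel")
}

#' Propose a mutant recovery-rate vector
#'
#' Draws one proposal from a [mutation_kernel()] using the current RNG
#' state. The mutant's infectivity follows from the shared trade-off, so the
#' recovery rates fully specify the proposed phenotype.
#'
#' @param gamma Resident per-stage recovery rates (> 0).
#' @param kernel A [mutation_kernel()].
#' @return Proposed rates `gamma_tilde`, same length as `gamma`.
#' @export
propose_mutant <- function(gamma, kernel) {
  stopifnot(inherits(kernel, "mutation_kernel"))
  n <- length(gamma)
  if (kernel$step_scale == 0) return(gamma)
  if (kernel$per_stage) {
    i <- sample.int(n, 1L)
    z <- rep(0, n)
    z[i] <- stats::rnorm(1)
  } else {
    z <- stats::rnorm(n)
  }
  gamma * exp(kernel$step_scale * z)
}

#' Head-to-head competition of resident and mutant
#'
#' Seeds a rare mutant at the resident's endemic equilibrium and integrates
#' the two-strain model until the mutant either fixes (its share of all
#' infections exceeds `fixation_threshold`), goes extinct (its pooled
#' density falls below `extinction_threshold` of the total population), or
#' time runs out (`"timeout"`, resident retained). The seed is taken out of
#' the resident infected pools proportionally, so the initial state stays on
#' the constant-population simplex.
#'
#' @param pop,resident,trans Model components; the resident must be
#'   supercritical.
#' @param mutant Invading [strain_traits()].
#' @param trans_mutant Transmission structure for the mutant.
#' @param resident_eq Optional precomputed [endemic_equilibrium()] of the
#'   resident.
#' @param seed_fraction Fraction of the total population moved into the
#'   mutant infected pool at the start (small, so the linearized invasion
#'   criterion governs early growth).
#' @param fixation_threshold Mutant share of infections declaring fixation.
#' @param extinction_threshold Pooled mutant density (relative to total
#'   population) declaring extinction.
#' @param max_time Maximum competition time.
#' @return A list: `outcome` (`"fixed"`, `"extinct"` or `"timeout"`),
#'   `share` (mutant share at the end), `time` elapsed, and `state`.
#' @export
compete <- function(pop, resident, mutant, trans, trans_mutant = trans,
                    resident_eq = NULL, seed_fraction = 1e-6,
                    fixation_threshold = 0.99, extinction_threshold = 1e-9,
                    max_time = 5e4) {
  n <- pop$n
  if (is.null(resident_eq))
    resident_eq <- endemic_equilibrium(pop, resident, trans)
  if (resident_eq$subcritical)
    stop("resident strain is subcritical: no endemic state to compete at",
         call. = FALSE)
  st <- split_state(resident_eq$state, n)
  seed_amt <- seed_fraction * pop$total
  if (sum(st$I) <= seed_amt)
    stop("resident infected pool smaller than the mutant seed", call. = FALSE)
  w <- st$I / sum(st$I)
  init <- system_state(st$S, st$I - seed_amt * w, st$R,
                       I_tilde = seed_amt * w, R_tilde = rep(0, n))
  t_el <- 0
  chunk <- 250
  y <- init
  repeat {
    traj <- integrate_sirs(y, c(0, chunk), pop, resident, trans,
                           mutant = mutant, trans_mutant = trans_mutant)
    y <- as.numeric(traj[nrow(traj), -1L])
    names(y) <- names(init)
    y[y < 0] <- 0
    t_el <- t_el + chunk
    chunk <- min(chunk * 2, 5000)
    tot_res <- sum(y[n + seq_len(n)])
    tot_mut <- sum(y[3L * n + seq_len(n)])
    share <- tot_mut / (tot_res + tot_mut)
    if (share > fixation_threshold)
      return(list(outcome = "fixed", share = share, time = t_el, state = y))
    if (tot_mut < extinction_threshold * pop$total)
      return(list(outcome = "extinct", share = share, time = t_el,
                  state = y))
    if (t_el >= max_time)
      return(list(outcome = "timeout", share = share, time = t_el,
                  state = y))
  }
}

#' Evolutionary invasion-replacement simulation
#'
#' Iterates the adaptive-dynamics loop: propose a random mutant from the
#' mutation kernel, score it against the resident at the resident's endemic
#' equilibrium, replace the resident when the mutant wins, and record the
#' trajectory of resident recovery rates and R0 over evolutionary time.
#'
#' Two modes decide fixation:
#' * `"adaptive_dynamics"` (fast surrogate): the mutant fixes if and only if
#'   its invasion number exceeds 1. Justified by the agreement of the
#'   dynamical and next-generation criteria away from `Q0 = 1`.
#' * `"ode_competition"`: each proposal is competed explicitly in the
#'   two-strain ODE system via [compete()].
#'
#' After each fixation the new resident's endemic equilibrium is recomputed
#' (warm-started from the previous one) before the next proposal.
#'
#' @param pop,strain,trans Initial resident configuration (supercritical).
#' @param kernel A [mutation_kernel()]; its `seed` (when non-NULL) seeds the
#'   simulation RNG.
#' @param n_attempts Number of invasion attempts.
#' @param mode `"adaptive_dynamics"` or `"ode_competition"`.
#' @param trans_mutant Transmission structure for mutants (defaults to the
#'   resident's; mutants differ only through their recovery rates).
#' @param ... Further arguments passed to [compete()] in
#'   `"ode_competition"` mode.
#' @return A data frame of class `"evolution_trajectory"`, one row per
#'   attempt, with columns `attempt`, `proposed_gamma<i>`, `q0`, `outcome`,
#'   `resident_gamma<i>`, `resident_r0`; attributes `mode` and `seed`.
#' @examples
#' \donttest{
#' pop <- population_structure(1, mortality = 0.01, immunity_loss = 0.02)
#' tf <- tradeoff_power_law(1, 0.5)
#' strain <- strain_traits(0.04, 0, tf)   # gamma* = 0.01
#' traj <- run_evolution(pop, strain, transmission_outer(1, 1),
#'                       mutation_kernel(0.1, seed = 1), n_attempts = 50)
#' tail(traj$resident_gamma1, 1)
#' }
#' @export
run_evolution <- function(pop, strain, trans, kernel, n_attempts,
                          mode = c("adaptive_dynamics", "ode_competition"),
                          trans_mutant = trans, ...) {
  mode <- match.arg(mode)
  n <- pop$n
  if (!is.null(kernel$seed)) set.seed(kernel$seed)
  resident <- strain
  eq <- endemic_equilibrium(pop, resident, trans)
  if (eq$subcritical)
    stop("initial strain is subcritical (R0 <= 1)", call. = FALSE)
  resident_r0 <- r0(pop, resident, trans, method = "auto")

  rec <- vector("list", n_attempts)
  for (k in seq_len(n_attempts)) {
    gamma_tilde <- propose_mutant(resident$recovery, kernel)
    mut <- strain_with_recovery(resident, gamma_tilde)
    q0 <- invasion_number(eq$state[seq_len(n)], pop, mut, trans_mutant,
                          method = "auto")
    outcome <- if (mode == "adaptive_dynamics") {
      if (q0 > 1) "fixed" else "extinct"
    } else {
      compete(pop, resident, mut, trans, trans_mutant,
              resident_eq = eq, ...)$outcome
    }
    if (outcome == "fixed") {
      resident <- mut
      eq <- endemic_equilibrium(pop, resident, trans, init = eq$state)
      if (!eq$converged)
        stop("endemic equilibrium failed to converge after fixation at ",
             "attempt ", k, call. = FALSE)
      resident_r0 <- r0(pop, resident, trans, method = "auto")
    }
    rec[[k]] <- c(attempt = k,
                  stats::setNames(gamma_tilde, paste0("proposed_gamma",
                                                      seq_len(n))),
                  q0 = q0,
                  outcome_fixed = as.numeric(outcome == "fixed"),
                  stats::setNames(resident$recovery,
                                  paste0("resident_gamma", seq_len(n))),
                  resident_r0 = resident_r0)
  }
  out <- as.data.frame(do.call(rbind, rec))
  out$outcome <- ifelse(out$outcome_fixed > 0, "fixed", "extinct")
  out$outcome_fixed <- NULL
  structure(out, class = c("evolution_trajectory", "data.frame"),
            mode = mode, seed = kernel$seed)
}

#' Sensitivity mode: non-separable random contact matrix
#'
#' Replaces an outer-product transmission structure by a general one whose
#' contact-modulation entries are independent Uniform(0, 1) draws. The
#' realized transmission matrix then generically has full rank, so
#' reproduction numbers must be computed by the eigenvalue method (the trace
#' shortcut refuses such matrices). Used to probe how much the
#' rank-1 assumption matters for the direction of evolution.
#'
#' @param trans Base transmission structure (outer-product mode).
#' @param seed RNG seed making the random matrix reproducible.
#' @return A general-mode transmission structure.
#' @export
sensitivity_random_contacts <- function(trans, seed = 1) {
  if (trans$mode != "outer_product")
    stop("base transmission structure must be in outer-product mode",
         call. = FALSE)
  n <- trans$n
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  cm <- matrix(stats::runif(n * n), n, n)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  transmission_general(cm)
}

#' Sensitivity mode: high case-fatality regime
#'
#' Scales the strain's disease mortality to dominate background mortality
#' (`d_i = 10 * delta_i * multiplier`), breaking the low-CFR assumption
#' behind the aggregate closed-form equilibrium. All equilibria must then be
#' obtained by integration; the ESS condition itself remains valid since
#' `d` simply enters `m = a + d + delta`.
#'
#' @param strain Base [strain_traits()].
#' @param pop The host population (supplies `delta`).
#' @param multiplier CFR multiplier `>= 1`.
#' @return A [strain_traits()] with inflated disease mortality.
#' @export
sensitivity_high_cfr <- function(strain, pop, multiplier = 1) {
  if (multiplier < 1)
    stop("'multiplier' must be >= 1", call. = FALSE)
  strain_traits(strain$recovery, 10 * pop$mortality * multiplier,
                strain$tradeoff)
}
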