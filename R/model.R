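#' System state of the age-structured SIRS model
#'
#' A state is a named numeric vector of compartment densities, in the fixed
#' order `S1..Sn, I1..In, R1..Rn` and, when a mutant strain is present,
#' `Itilde1..Itilden, Rtilde1..Rtilden`. Births balance deaths by
#' construction so the total density is constant along trajectories.
#'
#' @param S,I,R Per-stage densities of susceptible, infected and recovered
#'   hosts.
#' @param I_tilde,R_tilde Optional per-stage densities of the mutant-strain
#'   infected and recovered compartments.
#' @return A named numeric vector of length `3n` (single strain) or `5n`
#'   (two strains).
#' @export
system_state <- function(S, I, R, I_tilde = NULL, R_tilde = NULL) {
  n <- length(S)
  if (length(I) != n || length(R) != n)
    stop("S, I, R must have equal length", call. = FALSE)
  has_mutant <- !is.null(I_tilde) || !is.null(R_tilde)
  if (has_mutant) {
    if (is.null(I_tilde)) I_tilde <- rep(0, n)
    if (is.null(R_tilde)) R_tilde <- rep(0, n)
    if (length(I_tilde) != n || length(R_tilde) != n)
      stop("mutant compartments must have length n", call. = FALSE)
  }
  y <- c(S, I, R, I_tilde, R_tilde)
  names(y) <- state_names(n, has_mutant)
  y
}

state_names <- function(n, mutant = FALSE) {
  nm <- c(paste0("S", seq_len(n)), paste0("I", seq_len(n)),
          paste0("R", seq_len(n)))
  if (mutant)
    nm <- c(nm, paste0("Itilde", seq_len(n)), paste0("Rtilde", seq_len(n)))
  nm
}

# Split a state vector into its per-compartment blocks.
split_state <- function(y, n) {
  k <- length(y) / n
  if (k != 3 && k != 5)
    stop("state length must be 3n or 5n", call. = FALSE)
  out <- list(S = y[seq_len(n)], I = y[n + seq_len(n)],
              R = y[2L * n + seq_len(n)])
  if (k == 5) {
    out$I_tilde <- y[3L * n + seq_len(n)]
    out$R_tilde <- y[4L * n + seq_len(n)]
  }
  out
}

# Shift a per-stage vector to represent aging-in: (0, v_1, ..., v_{n-1}).
age_in <- function(a, v) {
  n <- length(v)
  if (n == 1L) return(0)
  c(0, a[-n] * v[-n])
}

#' Right-hand side of the single-strain SIRS model
#'
#' Time derivatives of the `3n` compartments. Stages `i >= 2` receive
#' aging-in from stage `i - 1`; the first susceptible compartment receives
#' the birth term, equal to the total death rate
#' `sum_i d_i I_i + delta_i (S_i + I_i + R_i)`, so that the population is
#' constant and everyone is born susceptible. Infection of stage `i` occurs
#' at rate `sum_j beta_ij S_i I_j`; recovered hosts lose immunity at rate
#' `omega`.
#'
#' @param state Named state vector (see [system_state()]), single-strain
#'   layout.
#' @param pop A [population_structure()].
#' @param strain A [strain_traits()] object.
#' @param trans A transmission structure.
#' @param B Optional precomputed `beta_ij` matrix (overrides `trans`); used
#'   internally by the integrator to avoid recomposition at every step.
#' @return Named vector of time derivatives, same layout as `state`.
#' @export
single_strain_rhs <- function(state, pop, strain, trans, B = NULL) {
  n <- pop$n
  if (length(state) != 3L * n)
    stop("state must have length 3n for the single-strain model",
         call. = FALSE)
  if (is.null(B)) B <- beta_matrix(trans, strain$tradeoff, strain$recovery)
  st <- split_state(state, n)
  a <- pop$aging; delta <- pop$mortality; omega <- pop$immunity_loss
  gamma <- strain$recovery; d <- strain$disease_mortality

  force_inf <- drop(B %*% st$I)            # sum_j beta_ij I_j, per stage i
  infection <- force_inf * st$S
  births <- sum(d * st$I + delta * (st$S + st$I + st$R))

  dS <- age_in(a, st$S) - a * st$S - delta * st$S + omega * st$R - infection
  dS[1L] <- dS[1L] + births
  dI <- age_in(a, st$I) + infection - (a + gamma + d + delta) * st$I
  dR <- age_in(a, st$R) + gamma * st$I - (a + delta + omega) * st$R

  out <- c(dS, dI, dR)
  names(out) <- names(state)
  out
}

#' Right-hand side of the two-strain (resident + mutant) SIRS model
#'
#' Extends the single-strain model with mutant infected and recovered
#' compartments under total cross-immunity: both strains compete for the same
#' susceptible pool, and immunity acquired against either blocks both.
#' Resident and mutant share demography, disease mortality and immunity-loss
#' rate; they differ in recovery rates and, through the trade-off, in
#' infectivity. The stage-1 birth term includes the mutant branch's deaths so
#' total population stays constant.
#'
#' @param state Named state vector with mutant compartments (`5n` entries).
#' @param pop A [population_structure()].
#' @param resident,mutant [strain_traits()] for the two strains (shared
#'   `disease_mortality`).
#' @param trans_resident,trans_mutant Transmission structures (usually
#'   identical; mutant infectivity differs through its recovery rates).
#' @param B,B_tilde Optional precomputed transmission-rate matrices.
#' @return Named vector of time derivatives, same layout as `state`.
#' @export
two_strain_rhs <- function(state, pop, resident, mutant,
                           trans_resident, trans_mutant = trans_resident,
                           B = NULL, B_tilde = NULL) {
  n <- pop$n
  if (length(state) != 5L * n)
    stop("state must have length 5n for the two-strain model", call. = FALSE)
  if (is.null(B))
    B <- beta_matrix(trans_resident, resident$tradeoff, resident$recovery)
  if (is.null(B_tilde))
    B_tilde <- beta_matrix(trans_mutant, mutant$tradeoff, mutant$recovery)
  st <- split_state(state, n)
  a <- pop$aging; delta <- pop$mortality; omega <- pop$immunity_loss
  gamma <- resident$recovery; gamma_t <- mutant$recovery
  d <- resident$disease_mortality

  inf_res <- drop(B %*% st$I) * st$S
  inf_mut <- drop(B_tilde %*% st$I_tilde) * st$S
  births <- sum(d * (st$I + st$I_tilde) +
                delta * (st$S + st$I + st$R + st$I_tilde + st$R_tilde))

  dS <- age_in(a, st$S) - a * st$S - delta * st$S +
    omega * (st$R + st$R_tilde) - inf_res - inf_mut
  dS[1L] <- dS[1L] + births
  dI <- age_in(a, st$I) + inf_res - (a + gamma + d + delta) * st$I
  dR <- age_in(a, st$R) + gamma * st$I - (a + delta + omega) * st$R
  dIt <- age_in(a, st$I_tilde) + inf_mut -
    (a + gamma_t + d + delta) * st$I_tilde
  dRt <- age_in(a, st$R_tilde) + gamma_t * st$I_tilde -
    (a + delta + omega) * st$R_tilde

  out <- c(dS, dI, dR, dIt, dRt)
  names(out) <- names(state)
  out
}

# deSolve-compatible wrappers ------------------------------------------------

rhs_single_desolve <- function(t, y, parms) {
  list(single_strain_rhs(y, parms$pop, parms$strain, trans = NULL,
                         B = parms$B))
}

rhs_two_desolve <- function(t, y, parms) {
  list(two_strain_rhs(y, parms$pop, parms$resident, parms$mutant,
                      trans_resident = NULL, B = parms$B,
                      B_tilde = parms$B_tilde))
}

#' Integrate the SIRS model
#'
#' Numerically integrates the single- or two-strain model with a
#' stiff-capable solver (`deSolve::lsoda`). The state layout selects the
#' model: `3n` entries integrate the single-strain system, `5n` entries the
#' two-strain system (then `mutant` must be supplied).
#'
#' @param init Initial state (named vector from [system_state()]).
#' @param times Output times (increasing, starting at the initial time).
#' @param pop,strain,trans As in [single_strain_rhs()].
#' @param mutant,trans_mutant Mutant strain and transmission structure
#'   (two-strain layout only).
#' @param rtol,atol Relative and absolute integrator tolerances.
#' @param equilibrium_tol Max-norm threshold on the right-hand side below
#'   which the terminal state is flagged as converged.
#' @return A data frame of class `"sirs_trajectory"`: one row per output
#'   time, one column per compartment, with attributes `converged` (logical)
#'   and `residual` (terminal RHS max-norm).
#' @examples
#' pop <- population_structure(1, mortality = 0.01, immunity_loss = 0.02)
#' tf <- tradeoff_power_law(1.2649, 0.5)
#' strain <- strain_traits(0.1, 0, tf)
#' trans <- transmission_outer(1, 1)
#' init <- system_state(S = 0.999, I = 0.001, R = 0)
#' traj <- integrate_sirs(init, seq(0, 100, 1), pop, strain, trans)
#' tail(traj, 2)
#' @export
integrate_sirs <- function(init, times, pop, strain, trans,
                           mutant = NULL, trans_mutant = trans,
                           rtol = 1e-9, atol = 1e-12,
                           equilibrium_tol = 1e-10) {
  n <- pop$n
  two <- length(init) == 5L * n
  if (!two && length(init) != 3L * n)
    stop("initial state length must be 3n or 5n", call. = FALSE)
  if (any(init < -atol))
    stop("initial state has negative entries", call. = FALSE)
  if (two && is.null(mutant))
    stop("two-strain layout requires 'mutant'", call. = FALSE)

  B <- beta_matrix(trans, strain$tradeoff, strain$recovery)
  if (two) {
    parms <- list(pop = pop, resident = strain, mutant = mutant, B = B,
                  B_tilde = beta_matrix(trans_mutant, mutant$tradeoff,
                                        mutant$recovery))
    fn <- rhs_two_desolve
  } else {
    parms <- list(pop = pop, strain = strain, B = B)
    fn <- rhs_single_desolve
  }
  sol <- deSolve::ode(y = init, times = times, func = fn, parms = parms,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("integrator failed before reaching the final time", call. = FALSE)
  traj <- as.data.frame(sol)
  terminal <- as.numeric(traj[nrow(traj), -1L])
  names(terminal) <- names(init)
  neg <- terminal < -1e-8 * pop$total
  if (any(neg))
    stop("negative compartment beyond tolerance at final time: ",
         paste(names(init)[neg], collapse = ", "), call. = FALSE)
  res <- if (two) {
    max(abs(two_strain_rhs(terminal, pop, strain, mutant,
                           trans_resident = NULL, B = parms$B,
                           B_tilde = parms$B_tilde)))
  } else {
    max(abs(single_strain_rhs(terminal, pop, strain, trans = NULL, B = B)))
  }
  structure(traj, class = c("sirs_trajectory", "data.frame"),
            converged = res < equilibrium_tol, residual = res)
}

# Newton polish of a single-strain equilibrium. The RHS conserves the total
# population, so its Jacobian is singular along the simplex direction; the
# first (birth) equation is replaced by the conservation constraint.
newton_polish <- function(y, pop, strain, B, tol = 1e-13, max_iter = 25L) {
  n3 <- length(y)
  f <- function(v) single_strain_rhs(v, pop, strain, trans = NULL, B = B)
  for (iter in seq_len(max_iter)) {
    Fv <- f(y)
    Fv[1L] <- sum(y) - pop$total
    if (max(abs(Fv)) < tol) break
    J <- matrix(0, n3, n3)
    h <- pmax(abs(y), 1e-6) * 1e-7
    for (k in seq_len(n3)) {
      yp <- y; ym <- y
      yp[k] <- yp[k] + h[k]; ym[k] <- ym[k] - h[k]
      J[, k] <- (f(yp) - f(ym)) / (2 * h[k])
    }
    J[1L, ] <- 1
    step <- tryCatch(solve(J, -Fv), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    y_new <- y + step
    if (any(!is.finite(y_new))) return(NULL)
    y <- y_new
  }
  if (any(y < -1e-10 * pop$total)) return(NULL)
  y
}

#' Endemic equilibrium of the single-strain model
#'
#' Integrates from a small infection seed at the disease-free age profile
#' until the dynamics settle, then polishes the state with a damped Newton
#' step (holding total population fixed) to drive the right-hand-side
#' residual to near machine precision. Per-stage equilibrium densities are
#' required by the invasion-number formula, which is why this routine always
#' works with the full `3n`-dimensional state rather than aggregates.
#'
#' @param pop,strain,trans Model components.
#' @param tol Convergence threshold on the RHS max-norm.
#' @param max_horizon Maximum integration time before giving up.
#' @param init Optional initial state (defaults to the disease-free profile
#'   with a 0.1% infection seed); a warm start from a nearby equilibrium
#'   speeds convergence considerably.
#' @return A list with elements `state` (named `3n` vector), `residual`,
#'   `converged`, `subcritical` (TRUE when R0 <= 1, in which case the
#'   disease-free equilibrium is returned) and `r0`.
#' @export
endemic_equilibrium <- function(pop, strain, trans, tol = 1e-10,
                                max_horizon = 1e6, init = NULL) {
  n <- pop$n
  B <- beta_matrix(trans, strain$tradeoff, strain$recovery)
  dfe <- disease_free_equilibrium(pop)
  r0_val <- r0(pop, strain, trans, method = "eigen")
  if (r0_val <= 1) {
    state <- system_state(dfe$S_hat, rep(0, n), rep(0, n))
    return(list(state = state, residual = 0, converged = TRUE,
                subcritical = TRUE, r0 = r0_val))
  }
  if (is.null(init)) {
    seed <- 1e-3
    init <- system_state(dfe$S_hat * (1 - seed), dfe$S_hat * seed, rep(0, n))
  }
  y <- init
  t_elapsed <- 0
  chunk <- 500
  residual <- max(abs(single_strain_rhs(y, pop, strain, NULL, B = B)))
  repeat {
    # try a Newton polish once the trajectory is in the equilibrium's basin
    if (residual < 1e-5 * pop$total) {
      polished <- newton_polish(y, pop, strain, B)
      if (!is.null(polished)) {
        res_p <- max(abs(single_strain_rhs(polished, pop, strain, NULL,
                                           B = B)))
        if (res_p < tol && sum(polished[n + seq_len(n)]) > 1e-8 * pop$total)
          return(list(state = polished, residual = res_p, converged = TRUE,
                      subcritical = FALSE, r0 = r0_val))
      }
    }
    if (residual < tol || t_elapsed >= max_horizon) break
    traj <- integrate_sirs(y, c(0, chunk), pop, strain, trans,
                           equilibrium_tol = tol)
    y <- as.numeric(traj[nrow(traj), -1L])
    names(y) <- state_names(n)
    y[y < 0] <- 0
    t_elapsed <- t_elapsed + chunk
    chunk <- min(2 * chunk, 5e4)
    residual <- max(abs(single_strain_rhs(y, pop, strain, NULL, B = B)))
  }
  if (residual >= tol)
    warning("endemic equilibrium not converged within horizon ",
            format(max_horizon), " (residual ", format(residual), ")",
            call. = FALSE)
  list(state = y, residual = residual, converged = residual < tol,
       subcritical = FALSE, r0 = r0_val)
}

#' Closed-form aggregate endemic equilibrium
#'
#' In the low case-fatality limit (`d << delta`) the totals
#' `S* = sum_i S_i` etc. at the endemic equilibrium obey the scalar SIRS
#' relations
#' \deqn{S^* = 1/R_0, \quad
#'       I^* = \frac{\delta (1 - 1/R_0)}{\gamma + \delta -
#'             \omega\gamma/(\omega+\delta)}, \quad
#'       R^* = \frac{\gamma I^*}{\omega + \delta},}
#' with `gamma` and `delta` the population-level rates averaged over the
#' stationary (disease-free) age profile. Exact for a single stage with
#' `d = 0`; an approximation otherwise.
#'
#' @param pop,strain,trans Model components.
#' @return A list of class `"aggregate_equilibrium"` with `S_star`,
#'   `I_star`, `R_star` (scaled to the population total), `gamma_bar`,
#'   `delta_bar`, `r0` and a `subcritical` flag (when `R0 <= 1` the
#'   disease-free aggregates are returned).
#' @export
aggregate_endemic <- function(pop, strain, trans) {
  dfe <- disease_free_equilibrium(pop)
  w <- dfe$S_hat / sum(dfe$S_hat)
  gamma_bar <- sum(w * strain$recovery)
  delta_bar <- sum(w * pop$mortality)
  omega <- pop$immunity_loss
  r0_val <- r0(pop, strain, trans, method = "eigen")
  if (r0_val <= 1) {
    out <- list(S_star = pop$total, I_star = 0, R_star = 0,
                gamma_bar = gamma_bar, delta_bar = delta_bar,
                r0 = r0_val, subcritical = TRUE)
  } else {
    S_star <- 1 / r0_val
    I_star <- delta_bar * (1 - 1 / r0_val) /
      (gamma_bar + delta_bar - omega * gamma_bar / (omega + delta_bar))
    R_star <- gamma_bar * I_star / (omega + delta_bar)
    out <- list(S_star = S_star * pop$total, I_star = I_star * pop$total,
                R_star = R_star * pop$total, gamma_bar = gamma_bar,
                delta_bar = delta_bar, r0 = r0_val, subcritical = FALSE)
  }
  class(out) <- "aggregate_equilibrium"
  out
}

#' @export
print.aggregate_equilibrium <- function(x, ...) {
  cat("Aggregate endemic equilibrium (low-CFR closed form)\n")
  cat(sprintf("  R0 = %.6g%s\n", x$r0,
              if (x$subcritical) "  [subcritical: disease-free]" else ""))
  cat(sprintf("  S* = %.6g   I* = %.6g   R* = %.6g\n",
              x$S_star, x$I_star, x$R_star))
  cat(sprintf("  averaged rates: gamma = %.6g, delta = %.6g\n",
              x$gamma_bar, x$delta_bar))
  invisible(x)
}
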