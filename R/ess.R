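#' Stationarity residual of the ESS condition
#'
#' Under a concave infectivity-recovery trade-off, the per-stage ESS
#' recovery rate solves
#' \deqn{\beta'(\gamma)\,(a + \gamma + d + \delta) = \beta(\gamma).}
#' This function returns the left minus the right side; its root is the ESS
#' candidate for the stage. The within-stage contact rate multiplies both
#' sides and therefore cancels: rescaling contacts scales the residual but
#' never moves the root.
#'
#' @param gamma Candidate recovery rate (> 0), vectorised.
#' @param a,d,delta Stage rates: aging, disease mortality, background
#'   mortality. Only their sum `m = a + d + delta` enters.
#' @param tf A [tradeoff()] object.
#' @param contact Optional within-stage contact scalar `c_ii` multiplying
#'   the infectivity (default 1); present to make the cancellation explicit.
#' @return `contact * (beta'(gamma) * (a + gamma + d + delta) - beta(gamma))`.
#' @export
ess_residual <- function(gamma, a = 0, d = 0, delta, tf, contact = 1) {
  m <- a + d + delta
  contact * (tradeoff_beta_prime(tf, gamma) * (m + gamma) -
             tradeoff_beta(tf, gamma))
}

#' Closed-form ESS recovery rate for a power-law trade-off
#'
#' For `beta(gamma) = c * gamma^p` with `0 < p < 1` the stationarity
#' condition has the explicit root
#' \deqn{\gamma^* = \frac{p\,m}{1 - p}, \qquad m = a + d + \delta.}
#' The coefficient `c` cancels. For `p >= 1` the optimum is unbounded (no
#' ESS: the trade-off no longer penalises acuteness) and an error is raised.
#'
#' @param p Power-law exponent, in (0, 1).
#' @param m Total non-recovery exit rate `a + d + delta` of the stage, > 0.
#' @return The ESS recovery rate `gamma*`.
#' @examples
#' ess_power_law_closed_form(0.5, 0.02)  # 0.02
#' @export
ess_power_law_closed_form <- function(p, m) {
  if (any(p <= 0) || any(p >= 1))
    stop("a power-law trade-off admits an ESS only for exponent p in ",
         "(0, 1); p >= 1 rewards unbounded acuteness (no ESS)",
         call. = FALSE)
  if (any(m <= 0))
    stop("'m' = a + d + delta must be positive", call. = FALSE)
  p * m / (1 - p)
}

#' Solve the per-stage ESS condition
#'
#' Finds, for every age stage, the recovery rate at which no rare mutant
#' perturbing that stage can invade, by bracketed root-finding on
#' [ess_residual()]. Stages decouple under the slow-aging approximation
#' (recovery and death much faster than aging), so each stage's
#' `gamma_i*` solves its own one-dimensional condition with
#' `m_i = a_i + d_i + delta_i`.
#'
#' @param pop A [population_structure()].
#' @param disease_mortality Per-stage disease mortality rates `d_i`
#'   (recycled; default 0).
#' @param tf A [tradeoff()] object. A power-law trade-off must have exponent
#'   in (0, 1).
#' @param trans Optional transmission structure; when supplied, `R0` at the
#'   ESS is computed and returned.
#' @param bracket Search interval for the root (default `c(1e-6, 1e3)` per
#'   time unit).
#' @param tol Root tolerance passed to [stats::uniroot()].
#' @return An object of class `"ess_result"`: `gamma_star`, `beta_star`,
#'   `residuals`, `r0_at_ess` (or `NA`), and per-stage tangency
#'   `diagnostics` (slope and intercept of the tangent line).
#' @examples
#' pop <- population_structure(1, mortality = 0.01, immunity_loss = 0.02)
#' solve_ess(pop, 0, tradeoff_power_law(1, 0.5))$gamma_star  # 0.01
#' @export
solve_ess <- function(pop, disease_mortality = 0, tf, trans = NULL,
                      bracket = c(1e-6, 1e3), tol = 1e-12) {
  n <- pop$n
  d <- rep_len(as.numeric(disease_mortality), n)
  if (tf$form == "power_law" && tf$exponent >= 1)
    stop("no ESS exists for a power-law trade-off with exponent >= 1: ",
         "the optimum is an unbounded 'Darwinian demon'", call. = FALSE)
  m <- pop$aging + d + pop$mortality

  gamma_star <- vapply(seq_len(n), function(i) {
    f <- function(g) ess_residual(g, a = pop$aging[i], d = d[i],
                                  delta = pop$mortality[i], tf = tf)
    # count sign changes on a log grid: the root should be unique under
    # concavity; report if the bracket holds more than one
    grid <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = 200))
    sgn <- sign(f(grid))
    changes <- sum(diff(sgn[sgn != 0]) != 0)
    if (changes == 0)
      stop("no sign change of the ESS residual in the bracket [",
           format(bracket[1]), ", ", format(bracket[2]), "] for stage ", i,
           call. = FALSE)
    if (changes > 1)
      warning("multiple sign changes of the ESS residual for stage ", i,
              "; returning the first root found -- the trade-off may not ",
              "be concave", call. = FALSE)
    stats::uniroot(f, interval = bracket, tol = tol)$root
  }, numeric(1))

  residuals <- vapply(seq_len(n), function(i)
    ess_residual(gamma_star[i], pop$aging[i], d[i], pop$mortality[i], tf),
    numeric(1))
  beta_star <- tradeoff_beta(tf, gamma_star)
  slope <- tradeoff_beta_prime(tf, gamma_star)
  diagnostics <- data.frame(stage = seq_len(n), m = m, slope = slope,
                            intercept = slope * m)
  r0_at_ess <- if (!is.null(trans)) {
    strain <- strain_traits(gamma_star, d, tf)
    r0(pop, strain, trans, method = "auto")
  } else NA_real_
  structure(
    list(gamma_star = gamma_star, beta_star = beta_star,
         residuals = residuals, r0_at_ess = r0_at_ess,
         diagnostics = diagnostics, disease_mortality = d,
         tradeoff = tf, pop = pop),
    class = "ess_result"
  )
}

#' @export
print.ess_result <- function(x, ...) {
  cat("ESS of the infectivity-recovery trade-off\n")
  for (i in seq_along(x$gamma_star))
    cat(sprintf("  stage %d: gamma* = %.8g, beta(gamma*) = %.8g, residual %.2e\n",
                i, x$gamma_star[i], x$beta_star[i], x$residuals[i]))
  if (!is.na(x$r0_at_ess))
    cat(sprintf("  R0 at the ESS: %.6g\n", x$r0_at_ess))
  invisible(x)
}

#' Tangency diagnostic for the ESS
#'
#' Geometrically, the stage ESS is the point where a straight line through
#' `(-m, 0)` with `m = a + d + delta` is tangent to the trade-off curve
#' `beta(gamma)`. For a concave trade-off the tangent line lies weakly above
#' the curve everywhere, so the tangency point is the global optimum. This
#' function evaluates the line-minus-curve gap on a grid; negative gaps flag
#' a concavity violation.
#'
#' @param gamma_star Stage ESS recovery rate (root of [ess_residual()]).
#' @param m Total non-recovery exit rate `a + d + delta` of the stage.
#' @param tf The trade-off.
#' @param grid Grid of recovery rates on which to check dominance (default:
#'   1000 log-spaced points spanning `gamma_star / 100` to
#'   `100 * gamma_star`).
#' @return A list: `slope` (`beta'(gamma*)`), `intercept` (line value at
#'   `gamma = 0`), `touch_gap` (line minus curve at `gamma*`, ~0),
#'   `min_gap` (most negative gap on the grid; `>= 0` up to round-off for a
#'   concave trade-off), `concave` (logical).
#' @export
tangency_check <- function(gamma_star, m, tf, grid = NULL) {
  if (is.null(grid))
    grid <- exp(seq(log(gamma_star / 100), log(gamma_star * 100),
                    length.out = 1000))
  slope <- tradeoff_beta_prime(tf, gamma_star)
  line <- function(g) slope * (g + m)
  gap <- line(grid) - tradeoff_beta(tf, grid)
  min_gap <- min(gap)
  scale <- max(abs(tradeoff_beta(tf, gamma_star)), 1e-300)
  concave <- min_gap >= -1e-9 * scale
  if (!concave)
    warning("tangent line falls below the trade-off curve (min gap ",
            format(min_gap), "): trade-off is not concave on the grid; ",
            "the tangency point is not a global optimum", call. = FALSE)
  list(slope = slope, intercept = slope * m,
       touch_gap = line(gamma_star) - tradeoff_beta(tf, gamma_star),
       min_gap = min_gap, concave = concave)
}

#' Verify an ESS by mutant invasion probes
#'
#' Confirms evolutionary stability directly from the invasion criterion:
#' places the resident at the candidate `gamma*`, integrates to its endemic
#' equilibrium, and scores a battery of probe mutants. Every probe's
#' invasion number must satisfy `Q0 <= 1 + tol`. Probes perturb each stage
#' separately by fixed multiplicative factors and, in addition, draw joint
#' random multiplicative perturbations of all stages.
#'
#' For several stages the per-stage ESS condition neglects cross-stage
#' aging terms, so the tolerance scales with `max_i a_i / (gamma_i + d_i)`
#' (zero aging recovers the exact single-stage case).
#'
#' @param ess An `"ess_result"` from [solve_ess()].
#' @param trans Transmission structure for resident and probes.
#' @param factors Multiplicative probe factors applied stage-wise.
#' @param n_random Number of joint random probes.
#' @param seed RNG seed for the random probes.
#' @param tol_base Base tolerance on `Q0 - 1` for a single stage.
#' @return A list: `max_q0`, `tol`, `pass`, `subcritical` (TRUE when the
#'   resident at `gamma*` has `R0 <= 1`, in which case the ESS is not
#'   epidemiologically attainable and no probing is done), and the probe
#'   table `probes` (one row per probe: factors applied and `Q0`).
#' @export
verify_ess_by_invasion <- function(ess, trans,
                                   factors = c(0.25, 0.5, 0.8, 0.9,
                                               1.1, 1.25, 2, 4),
                                   n_random = 50, seed = 1,
                                   tol_base = 1e-6) {
  pop <- ess$pop
  n <- pop$n
  resident <- strain_traits(ess$gamma_star, ess$disease_mortality,
                            ess$tradeoff)
  eq <- endemic_equilibrium(pop, resident, trans)
  if (eq$subcritical)
    return(list(max_q0 = NA_real_, tol = NA_real_, pass = FALSE,
                subcritical = TRUE, probes = NULL))
  S_star <- eq$state[seq_len(n)]

  # single-stage probes: one stage perturbed at a time
  probe_list <- list()
  for (i in seq_len(n)) {
    for (f in factors) {
      fac <- rep(1, n); fac[i] <- f
      probe_list[[length(probe_list) + 1L]] <- fac
    }
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  for (k in seq_len(n_random))
    probe_list[[length(probe_list) + 1L]] <- exp(stats::rnorm(n, 0, 0.3))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  q0 <- vapply(probe_list, function(fac) {
    mut <- strain_with_recovery(resident, resident$recovery * fac)
    invasion_number(S_star, pop, mut, trans, method = "auto")
  }, numeric(1))
  slow_aging <- max(pop$aging /
                    (resident$recovery + resident$disease_mortality))
  tol <- tol_base + if (n > 1L) slow_aging else 0
  probes <- data.frame(do.call(rbind, probe_list))
  names(probes) <- paste0("factor_stage", seq_len(n))
  probes$q0 <- q0
  list(max_q0 = max(q0), tol = tol, pass = all(q0 <= 1 + tol),
       subcritical = FALSE, probes = probes)
}
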