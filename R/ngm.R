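#' Disease-free equilibrium age profile
#'
#' With no infection, the susceptible stage densities settle at the balance
#' of aging and background mortality. Writing
#' `alpha_i = prod_{k=2..i} a_{k-1} / (a_k + delta_k)` the profile is
#' `S_hat_i = alpha_i * S_hat_1` with `S_hat_1 = total / (1 + sum_k alpha_k)`.
#'
#' @param pop A [population_structure()].
#' @return A list of class `"dfe_vector"`: `S_hat` (length `n`, summing to
#'   the population total) and `alpha` (length `n`, with `alpha[1] = 1`).
#' @export
disease_free_equilibrium <- function(pop) {
  n <- pop$n
  a <- pop$aging; delta <- pop$mortality
  alpha <- numeric(n)
  alpha[1L] <- 1
  if (n > 1L) {
    for (i in 2:n) {
      denom <- a[i] + delta[i]
      if (denom <= 0)
        stop("a_k + delta_k must be positive for every stage k >= 2 ",
             "(stage ", i, " has zero exit rate)", call. = FALSE)
      alpha[i] <- alpha[i - 1L] * a[i - 1L] / denom
    }
  }
  S1 <- pop$total / sum(alpha)
  structure(list(S_hat = alpha * S1, alpha = alpha), class = "dfe_vector")
}

#' Transition matrix of the infected subsystem and its closed-form inverse
#'
#' The linearization of the infected compartments about an equilibrium reads
#' `dI/dt = (T + Sigma) I`. `Sigma` is lower bidiagonal: diagonal `-mu_i`
#' with `mu_i = a_i + delta_i + gamma_i + d_i` (all routes out of the
#' infected class of stage `i`), subdiagonal `a_i` (aging while infected).
#' Its inverse has the closed form
#' `(-Sigma^{-1})_{ji} = (a_i ... a_{j-1}) / (mu_i ... mu_j)` for `j >= i`,
#' zero above the diagonal.
#'
#' @param pop A [population_structure()].
#' @param strain A [strain_traits()] (its recovery and disease-mortality
#'   rates enter `mu`).
#' @return A list with `Sigma`, `Sigma_inv` (closed form) and `mu`.
#' @export
transition_matrix <- function(pop, strain) {
  n <- pop$n
  a <- pop$aging
  mu <- a + pop$mortality + strain$recovery + strain$disease_mortality
  if (any(mu <= 0))
    stop("all mu_i = a_i + delta_i + gamma_i + d_i must be positive",
         call. = FALSE)
  Sigma <- diag(-mu, n, n)
  if (n > 1L)
    Sigma[cbind(2:n, 1:(n - 1L))] <- a[-n]
  Sigma_inv <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j)) {
      num <- if (j > i) prod(a[i:(j - 1L)]) else 1
      Sigma_inv[j, i] <- -num / prod(mu[i:j])
    }
  }
  list(Sigma = Sigma, Sigma_inv = Sigma_inv, mu = mu)
}

# Trace of -T Sigma^{-1} written out as a double sum over infection paths
# i <= j. S is the susceptible profile the transmission matrix is evaluated
# at (disease-free for R0, resident-endemic for Q0).
ngm_trace_formula <- function(B, S, a, mu) {
  n <- length(S)
  total <- 0
  for (j in seq_len(n)) {
    for (i in seq_len(j)) {
      num <- if (j > i) prod(a[i:(j - 1L)]) else 1
      total <- total + B[i, j] * S[i] * num / prod(mu[i:j])
    }
  }
  total
}

#' Next-generation matrix and its reproduction number
#'
#' Builds the transmission matrix `T_ij = beta_ij * S_i`, the transition
#' matrix `Sigma`, and the next-generation matrix `K = -T Sigma^{-1}` whose
#' spectral radius is the reproduction number. Two evaluation methods:
#'
#' * `"trace"`: the closed-form double sum over infection paths. Valid only
#'   for outer-product transmission, where `T` (hence `K`) has rank 1 and
#'   the trace equals the unique positive eigenvalue.
#' * `"eigen"`: dominant eigenvalue of the dense `K`; always valid.
#' * `"auto"`: trace when the transmission structure is outer-product,
#'   eigenvalue otherwise.
#'
#' @param pop,strain,trans Model components for the strain being scored.
#' @param S Susceptible age profile at which to linearize (disease-free for
#'   R0, resident endemic for the invasion number).
#' @param method One of `"auto"`, `"trace"`, `"eigen"`.
#' @return A list of class `"ngm_bundle"`: `T_mat`, `Sigma`, `Sigma_inv`,
#'   `K`, `value`, `method`.
#' @export
next_generation <- function(pop, strain, trans, S,
                            method = c("auto", "trace", "eigen")) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (trans$mode == "outer_product") "trace" else "eigen"
  if (method == "trace" && trans$mode != "outer_product")
    stop("the trace formula requires outer-product (rank-1) transmission; ",
         "for a general contact matrix the trace is not the spectral ",
         "radius -- use method = \"eigen\"", call. = FALSE)
  B <- beta_matrix(trans, strain$tradeoff, strain$recovery)
  tm <- transition_matrix(pop, strain)
  T_mat <- B * S                       # T_ij = beta_ij * S_i (recycle rows)
  K <- -T_mat %*% tm$Sigma_inv
  value <- if (method == "trace") {
    as.numeric(ngm_trace_formula(B, S, pop$aging, tm$mu))
  } else {
    max(Re(eigen(K, only.values = TRUE)$values))
  }
  structure(list(T_mat = T_mat, Sigma = tm$Sigma, Sigma_inv = tm$Sigma_inv,
                 K = K, value = value, method = method),
            class = "ngm_bundle")
}

#' @export
print.ngm_bundle <- function(x, ...) {
  cat("Next-generation matrix (", x$method, " method): value = ",
      format(x$value, digits = 10), "\n", sep = "")
  invisible(x)
}

#' Basic reproduction number R0
#'
#' Mean number of secondary infections caused by one infectious individual
#' in a fully susceptible population: the spectral radius of the
#' next-generation matrix evaluated at the disease-free age profile.
#'
#' @inheritParams next_generation
#' @return Scalar `R0 >= 0`.
#' @examples
#' pop <- population_structure(1, mortality = 0.01, immunity_loss = 0.02)
#' tf <- tradeoff_power_law(1.2649110640674, 0.5)   # beta(0.1) = 0.4
#' strain <- strain_traits(0.1, 0, tf)
#' r0(pop, strain, transmission_outer(1, 1))        # 0.4 / 0.11 = 3.6364
#' @export
r0 <- function(pop, strain, trans, method = c("auto", "trace", "eigen")) {
  S_hat <- disease_free_equilibrium(pop)$S_hat
  next_generation(pop, strain, trans, S_hat, method = method)$value
}

#' Invasion number Q0 of a mutant strain
#'
#' Mean number of secondary infections caused by a rare mutant carrier while
#' the host population sits at the resident strain's endemic equilibrium:
#' the spectral radius of the mutant's next-generation matrix evaluated at
#' the resident endemic susceptible profile `S*`. The mutant fails to invade
#' when `Q0 < 1`; a resident whose every competing mutant has `Q0 <= 1` is
#' an evolutionarily stable strategy.
#'
#' @param endemic_S Per-stage susceptible densities at the resident's
#'   endemic equilibrium (from [endemic_equilibrium()]).
#' @param pop The shared host population.
#' @param mutant The invading strain's traits (its `mu` uses the mutant
#'   recovery rates).
#' @param trans_mutant Transmission structure for the mutant.
#' @inheritParams next_generation
#' @return Scalar `Q0 >= 0`.
#' @export
invasion_number <- function(endemic_S, pop, mutant, trans_mutant,
                            method = c("auto", "trace", "eigen")) {
  if (length(endemic_S) != pop$n)
    stop("endemic_S must hold one susceptible density per stage",
         call. = FALSE)
  next_generation(pop, mutant, trans_mutant, endemic_S,
                  method = method)$value
}

#' Gradient of the invasion number at the resident phenotype
#'
#' Central-difference partials of `Q0` with respect to each stage's mutant
#' recovery rate, evaluated at mutant = resident. A necessary condition for
#' the resident to be an ESS is that this gradient vanishes; for a single
#' stage it vanishes exactly at the trade-off optimum, while for several
#' stages the per-stage ESS condition neglects cross-stage aging terms that
#' are small in the slow-aging regime.
#'
#' @param resident The resident [strain_traits()].
#' @param pop,trans Model components.
#' @param endemic_S Optional resident endemic susceptible profile; computed
#'   by integration when missing.
#' @param rel_step Relative step of the central difference (default `1e-5`
#'   of each stage's recovery rate).
#' @param method Passed to [invasion_number()].
#' @return Numeric vector of `n` partial derivatives `dQ0/dgamma_l`.
#' @export
q0_gradient <- function(resident, pop, trans, endemic_S = NULL,
                        rel_step = 1e-5,
                        method = c("auto", "trace", "eigen")) {
  if (is.null(endemic_S)) {
    eq <- endemic_equilibrium(pop, resident, trans)
    if (eq$subcritical)
      stop("resident is subcritical (R0 <= 1): no endemic equilibrium ",
           "to linearize at", call. = FALSE)
    endemic_S <- eq$state[seq_len(pop$n)]
  }
  gamma <- resident$recovery
  vapply(seq_len(pop$n), function(l) {
    h <- rel_step * gamma[l]
    if (h == 0) stop("differentiation step underflow", call. = FALSE)
    gp <- gamma; gp[l] <- gp[l] + h
    gm <- gamma; gm[l] <- gm[l] - h
    qp <- invasion_number(endemic_S, pop, strain_with_recovery(resident, gp),
                          trans, method = method)
    qm <- invasion_number(endemic_S, pop, strain_with_recovery(resident, gm),
                          trans, method = method)
    (qp - qm) / (2 * h)
  }, numeric(1))
}
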