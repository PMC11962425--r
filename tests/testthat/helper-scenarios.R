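# Shared fixture builders. Everything is generated in code; rates are per
# day unless a test says otherwise.

# Scalar SIRS building blocks with beta(0.1) = 0.4: R0 = 0.4 / 0.11.
scalar_pop <- function(delta = 0.01, omega = 0.02) {
  population_structure(1, aging = 0, mortality = delta,
                       immunity_loss = omega)
}

scalar_strain <- function(gamma = 0.1, d = 0, beta_at_gamma = 0.4,
                          p = 0.5) {
  tf <- tradeoff_power_law(beta_at_gamma / gamma^p, p)
  strain_traits(gamma, d, tf)
}

unit_trans <- function(n = 1) transmission_outer(rep(1, n), rep(1, n))

# Random model instance for next-generation-matrix properties.
random_instance <- function(n) {
  a <- stats::runif(n, 0.005, 0.1)
  a[n] <- 0
  pop <- population_structure(n, aging = a,
                              mortality = stats::runif(n, 0.001, 0.05),
                              immunity_loss = stats::runif(1, 0, 0.1))
  strain <- strain_traits(stats::runif(n, 0.05, 0.5),
                          stats::runif(n, 0, 0.02),
                          tradeoff_power_law(stats::runif(1, 0.5, 2), 0.5))
  trans <- transmission_outer(stats::runif(n, 0.2, 1.5),
                              stats::runif(n, 0.2, 1.5))
  list(pop = pop, strain = strain, trans = trans)
}

# Three-stage human population whose ESS is itself acute (slow aging at the
# ESS solution): substantial disease mortality so gamma* + d >> a.
acute_three_stage <- function(coefficient = 1) {
  generate_scenario("three_stage_human", overrides = list(
    strain = list(disease_mortality = c(0.02, 0.03, 0.05)),
    tradeoff = list(coefficient = coefficient)))
}

# Independent scalar oracle for the single-stage model (hand-transcribed
# equations, no matrix machinery).
scalar_rhs_oracle <- function(S, I, R, beta, gamma, d, delta, omega) {
  dS <- d * I + delta * (S + I + R) + omega * R - beta * S * I - delta * S
  dI <- beta * S * I - (gamma + d + delta) * I
  dR <- gamma * I - (delta + omega) * R
  c(dS, dI, dR)
}
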