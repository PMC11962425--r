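SCENARIO_SCHEMA <- "agesirs-scenario-v1"

#' Assemble a scenario
#'
#' A scenario bundles everything one run needs: host demography, resident
#' strain, trade-off, transmission structure and simulation settings. All
#' component invariants are validated on construction.
#'
#' @param population A [population_structure()].
#' @param strain A [strain_traits()] (carries the trade-off).
#' @param transmission A transmission structure.
#' @param simulation Named list of settings; unspecified entries take the
#'   defaults `rtol = 1e-9`, `atol = 1e-12`, `equilibrium_tol = 1e-10`,
#'   `max_horizon = 1e6`, `kernel_sigma = 0.1`, `n_attempts = 300`,
#'   `mode = "adaptive_dynamics"`, `seed = 1`.
#' @param name,description Metadata strings.
#' @return An object of class `"scenario"`.
#' @export
scenario <- function(population, strain, transmission,
                     simulation = list(), name = "scenario",
                     description = "") {
  stopifnot(inherits(population, "population_structure"),
            inherits(strain, "strain_traits"),
            inherits(transmission, "transmission_structure"))
  if (length(strain$recovery) != population$n)
    stop("strain defines ", length(strain$recovery),
         " stage(s) but the population has ", population$n, call. = FALSE)
  if (transmission$n != population$n)
    stop("transmission structure defines ", transmission$n,
         " stage(s) but the population has ", population$n, call. = FALSE)
  defaults <- list(rtol = 1e-9, atol = 1e-12, equilibrium_tol = 1e-10,
                   max_horizon = 1e6, kernel_sigma = 0.1, n_attempts = 300,
                   mode = "adaptive_dynamics", seed = 1)
  unknown <- setdiff(names(simulation), names(defaults))
  if (length(unknown))
    stop("unknown simulation setting(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  simulation <- utils::modifyList(defaults, simulation)
  structure(
    list(population = population, strain = strain,
         transmission = transmission, simulation = simulation,
         metadata = list(name = name, description = description)),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario '", x$metadata$name, "': ", x$population$n,
      " age stage(s)\n", sep = "")
  print(x$population)
  print(x$strain)
  print(x$transmission)
  invisible(x)
}

# recursively merge user overrides into a template definition
merge_overrides <- function(base, overrides) {
  if (is.null(overrides)) return(base)
  utils::modifyList(base, overrides)
}

#' Generate a built-in scenario
#'
#' Deterministic templates covering the regimes the package is designed to
#' explore. All use a power-law trade-off `beta = c * gamma^p` with
#' `p = 0.5` and a supercritical resident; rates are per day.
#'
#' * `single_stage`: one homogeneous stage, `a = 0`, `delta = 0.01`,
#'   `omega = 0.02`, `d = 0`, `gamma = 0.1` with the trade-off coefficient
#'   set so that `beta(0.1) = 0.4` (hence `R0 = 0.4 / 0.11`).
#' * `three_stage_human`: young / adult / old stages (20, 45 years, then
#'   open-ended), background mortality increasing with age, recovery about
#'   a week, slow aging (`gamma + d >= 50 a` in every stage).
#' * `slow_aging_n`: `n` equal 20-year stages with mortality increasing
#'   geometrically across stages; used for dimension-scaling checks.
#' * `high_cfr`: `three_stage_human` with disease mortality inflated to
#'   `10 * delta` (case fatality dominating background mortality).
#' * `random_contacts`: `three_stage_human` with the outer-product contact
#'   structure replaced by a seeded random Uniform(0,1) matrix.
#'
#' @param template Template name (see above).
#' @param overrides Nested named list merged over the template's definition
#'   before construction; e.g.
#'   `list(tradeoff = list(coefficient = 1), strain = list(recovery = 0.02))`.
#'   Recognised blocks: `population`, `strain`, `tradeoff`, `transmission`,
#'   `simulation`.
#' @param seed Seed stored in the simulation block and used by the
#'   `random_contacts` template for its contact matrix.
#' @param n Number of stages for `slow_aging_n`.
#' @return A [scenario()].
#' @examples
#' sc <- generate_scenario("single_stage")
#' r0(sc$population, sc$strain, sc$transmission)
#' @export
generate_scenario <- function(template = c("single_stage",
                                           "three_stage_human",
                                           "slow_aging_n", "high_cfr",
                                           "random_contacts"),
                              overrides = list(), seed = 1, n = 5) {
  template <- match.arg(template)
  day_year <- 365
  def <- switch(
    template,
    single_stage = list(
      population = list(n = 1, aging = 0, mortality = 0.01,
                        immunity_loss = 0.02, total = 1),
      strain = list(recovery = 0.1, disease_mortality = 0),
      tradeoff = list(coefficient = 0.4 / sqrt(0.1), exponent = 0.5),
      transmission = list(mode = "outer_product", susceptibility = 1,
                          infectivity_weights = 1)
    ),
    three_stage_human = ,
    high_cfr = ,
    random_contacts = list(
      population = list(n = 3,
                        aging = c(1 / (20 * day_year), 1 / (45 * day_year),
                                  0),
                        mortality = c(5e-6, 2e-5, 1.8e-4),
                        immunity_loss = 0.02, total = 1),
      strain = list(recovery = rep(1 / 7, 3),
                    disease_mortality = c(1e-6, 4e-6, 3.6e-5)),
      tradeoff = list(coefficient = 1, exponent = 0.5),
      transmission = list(mode = "outer_product",
                          susceptibility = c(1.2, 1, 0.8),
                          infectivity_weights = c(1.1, 1, 0.9))
    ),
    slow_aging_n = {
      a <- rep(1 / (20 * day_year), n); a[n] <- 0
      list(
        population = list(n = n, aging = a,
                          mortality = exp(seq(log(5e-6), log(2e-4),
                                              length.out = n)),
                          immunity_loss = 0.02, total = 1),
        strain = list(recovery = rep(1 / 7, n),
                      disease_mortality = rep(0, n)),
        tradeoff = list(coefficient = 1, exponent = 0.5),
        transmission = list(mode = "outer_product",
                            susceptibility = seq(1.2, 0.8, length.out = n),
                            infectivity_weights = seq(1.1, 0.9,
                                                      length.out = n))
      )
    }
  )
  def$simulation <- list(seed = seed)
  def <- merge_overrides(def, overrides)

  pop <- do.call(population_structure, def$population)
  tf <- tradeoff_power_law(def$tradeoff$coefficient, def$tradeoff$exponent)
  strain <- strain_traits(def$strain$recovery, def$strain$disease_mortality,
                          tf)
  if (template == "high_cfr")
    strain <- sensitivity_high_cfr(strain, pop, multiplier = 1)
  trans <- if (def$transmission$mode == "outer_product") {
    transmission_outer(def$transmission$susceptibility,
                       def$transmission$infectivity_weights)
  } else {
    transmission_general(def$transmission$contact_matrix)
  }
  if (template == "random_contacts")
    trans <- sensitivity_random_contacts(trans, seed = seed)
  scenario(pop, strain, trans, simulation = def$simulation,
           name = template,
           description = paste("built-in", template, "template"))
}

# plain-list (de)serialization -----------------------------------------------

scenario_to_list <- function(sc) {
  tf <- sc$strain$tradeoff
  if (tf$form != "power_law")
    stop("only power-law trade-offs can be serialized to a scenario file; ",
         "custom trade-off functions must be rebuilt in code",
         call. = FALSE)
  trans <- if (sc$transmission$mode == "outer_product") {
    list(mode = "outer_product",
         susceptibility = sc$transmission$susceptibility,
         infectivity_weights = sc$transmission$infectivity_weights)
  } else {
    list(mode = "general",
         contact_matrix = apply(sc$transmission$contact_matrix, 1L,
                                identity, simplify = FALSE))
  }
  list(schema = SCENARIO_SCHEMA,
       metadata = sc$metadata,
       population = list(n = sc$population$n,
                         aging = sc$population$aging,
                         mortality = sc$population$mortality,
                         immunity_loss = sc$population$immunity_loss,
                         total = sc$population$total),
       strain = list(recovery = sc$strain$recovery,
                     disease_mortality = sc$strain$disease_mortality),
       tradeoff = list(form = "power_law",
                       coefficient = tf$coefficient,
                       exponent = tf$exponent),
       transmission = trans,
       simulation = sc$simulation)
}

require_block <- function(lst, block, hint = NULL) {
  if (is.null(lst[[block]]))
    stop("scenario file is missing the '", block, "' block",
         if (!is.null(hint)) paste0("; ", hint) else "", call. = FALSE)
  lst[[block]]
}

scenario_from_list <- function(lst) {
  known <- c("schema", "metadata", "population", "strain", "tradeoff",
             "transmission", "simulation")
  unknown <- setdiff(names(lst), known)
  if (length(unknown))
    stop("unknown top-level key(s) in scenario file: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!identical(lst$schema, SCENARIO_SCHEMA))
    stop("scenario file schema tag is ",
         if (is.null(lst$schema)) "missing" else paste0("'", lst$schema, "'"),
         "; expected '", SCENARIO_SCHEMA, "'", call. = FALSE)
  p <- require_block(lst, "population")
  s <- require_block(lst, "strain")
  tfl <- require_block(
    lst, "tradeoff",
    hint = paste("add a power-law stanza such as: tradeoff: {form:",
                 "power_law, coefficient: 1.0, exponent: 0.5}"))
  tr <- require_block(lst, "transmission")
  if (any(unlist(p[c("aging", "mortality", "immunity_loss")]) < 0))
    stop("population block contains a negative rate", call. = FALSE)
  pop <- population_structure(p$n, unlist(p$aging), unlist(p$mortality),
                              p$immunity_loss,
                              total = if (is.null(p$total)) 1 else p$total)
  if (!identical(tfl$form, "power_law"))
    stop("tradeoff 'form' must be 'power_law' in scenario files ",
         "(got '", tfl$form, "')", call. = FALSE)
  tf <- tradeoff_power_law(tfl$coefficient, tfl$exponent)
  strain <- strain_traits(unlist(s$recovery), unlist(s$disease_mortality),
                          tf)
  trans <- switch(
    tr$mode,
    outer_product = transmission_outer(unlist(tr$susceptibility),
                                       unlist(tr$infectivity_weights)),
    general = transmission_general(do.call(rbind,
                                           lapply(tr$contact_matrix,
                                                  unlist))),
    stop("transmission 'mode' must be 'outer_product' or 'general'",
         call. = FALSE)
  )
  md <- if (is.null(lst$metadata)) list(name = "scenario", description = "")
        else lst$metadata
  scenario(pop, strain, trans,
           simulation = if (is.null(lst$simulation)) list()
                        else lst$simulation,
           name = md$name, description = md$description)
}

#' Read and write scenario files
#'
#' Scenarios are stored as YAML with blocks `population`, `strain`,
#' `tradeoff`, `transmission`, `simulation` under a versioned `schema` tag.
#' Loading validates the schema tag, rejects unknown keys and re-runs all
#' type invariants; saving followed by loading reproduces the scenario
#' exactly.
#'
#' @param path File path.
#' @return `load_scenario()` returns a [scenario()]; `save_scenario()`
#'   returns `path` invisibly.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path))
    stop("scenario file not found: ", path, call. = FALSE)
  lst <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("cannot parse scenario file ", path, ": ", conditionMessage(e),
         call. = FALSE))
  scenario_from_list(lst)
}

#' @rdname load_scenario
#' @param sc A [scenario()].
#' @export
save_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "scenario"))
  yaml::write_yaml(scenario_to_list(sc), path, precision = 17L)
  invisible(path)
}

#' Write a trajectory as a delimited table
#'
#' @param traj A trajectory data frame (from [integrate_sirs()] or
#'   [run_evolution()]).
#' @param path Output path; comma-separated with a header row.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
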