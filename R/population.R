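#' Age-structured host population
#'
#' Defines the host demography for the age-structured SIRS model: the number
#' of age stages, the per-stage aging rates, the per-stage background
#' (non-disease) mortality rates, and the age-invariant rate at which immunity
#' wanes. Total population size is constant by construction: every death is
#' balanced by a birth into the first susceptible compartment.
#'
#' The terminal stage does not age out (`aging[n]` must be 0); individuals
#' leave it only by death. With this convention the stationary age profile is
#' well defined provided the terminal background mortality is positive.
#'
#' @param n Number of age stages (positive integer).
#' @param aging Numeric vector of per-time aging rates `a_1..a_n`. The last
#'   entry must be 0. For `n = 1` the default `0` applies.
#' @param mortality Numeric vector of per-time background mortality rates
#'   `delta_1..delta_n`.
#' @param immunity_loss Scalar per-time rate `omega` at which recovered
#'   individuals return to the susceptible pool (age-invariant).
#' @param total Total population size; compartments are densities summing to
#'   this value (default 1).
#'
#' @return An object of class `"population_structure"`.
#' @examples
#' # One homogeneous stage, life expectancy 100 time units
#' population_structure(1, mortality = 0.01, immunity_loss = 0.02)
#'
#' # Three stages: young / adult / old, increasing mortality
#' population_structure(3, aging = c(1 / 7300, 1 / 16425, 0),
#'                      mortality = c(1e-05, 5e-05, 1.83e-04),
#'                      immunity_loss = 0.02)
#' @export
population_structure <- function(n, aging = rep(0, n), mortality,
                                 immunity_loss, total = 1) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("'n' must be a positive integer", call. = FALSE)
  aging <- rep_len(as.numeric(aging), n)
  mortality <- rep_len(as.numeric(mortality), n)
  if (any(aging < 0) || any(mortality < 0))
    stop("aging and mortality rates must be nonnegative", call. = FALSE)
  if (aging[n] != 0)
    stop("the terminal stage must not age out: aging[n] must be 0",
         call. = FALSE)
  if (length(immunity_loss) != 1L || immunity_loss < 0)
    stop("'immunity_loss' must be a single nonnegative rate", call. = FALSE)
  if (total <= 0)
    stop("'total' population must be positive", call. = FALSE)
  structure(
    list(n = n, aging = aging, mortality = mortality,
         immunity_loss = as.numeric(immunity_loss),
         total = as.numeric(total)),
    class = "population_structure"
  )
}

#' @export
print.population_structure <- function(x, ...) {
  cat("Age-structured host population:", x$n, "stage(s), total size",
      format(x$total), "\n")
  cat("  aging rates:     ", paste(signif(x$aging, 4), collapse = ", "), "\n")
  cat("  background mort.:", paste(signif(x$mortality, 4), collapse = ", "),
      "\n")
  cat("  immunity loss:   ", signif(x$immunity_loss, 4), "\n")
  invisible(x)
}

#' Strain phenotype: recovery, disease mortality and the trade-off
#'
#' Bundles a pathogen strain's per-stage recovery rates `gamma_i`, per-stage
#' disease-induced mortality rates `d_i`, and the infectivity-recovery
#' trade-off that maps each stage's recovery rate to its infectivity.
#' A mutant strain is represented by a second `strain_traits` object sharing
#' the host population and (by assumption) the disease mortality.
#'
#' @param recovery Numeric vector of per-stage recovery rates, all > 0.
#' @param disease_mortality Numeric vector of per-stage disease mortality
#'   rates, all >= 0 (default 0: the low case-fatality regime).
#' @param tradeoff A [tradeoff()] object giving infectivity beta(gamma).
#'
#' @return An object of class `"strain_traits"`.
#' @seealso [tradeoff_power_law()], [population_structure()]
#' @export
strain_traits <- function(recovery, disease_mortality = 0, tradeoff) {
  recovery <- as.numeric(recovery)
  n <- length(recovery)
  if (n < 1L)
    stop("'recovery' must contain at least one per-stage rate",
         call. = FALSE)
  disease_mortality <- rep_len(as.numeric(disease_mortality), n)
  if (any(recovery <= 0))
    stop("all recovery rates must be strictly positive", call. = FALSE)
  if (any(disease_mortality < 0))
    stop("disease mortality rates must be nonnegative", call. = FALSE)
  if (!inherits(tradeoff, "tradeoff"))
    stop("'tradeoff' must be a tradeoff object", call. = FALSE)
  structure(
    list(recovery = recovery, disease_mortality = disease_mortality,
         tradeoff = tradeoff),
    class = "strain_traits"
  )
}

#' @export
print.strain_traits <- function(x, ...) {
  cat("Pathogen strain over", length(x$recovery), "age stage(s)\n")
  cat("  recovery gamma:    ", paste(signif(x$recovery, 4), collapse = ", "),
      "\n")
  cat("  disease mortality: ",
      paste(signif(x$disease_mortality, 4), collapse = ", "), "\n")
  cat("  infectivity beta(gamma):",
      paste(signif(tradeoff_beta(x$tradeoff, x$recovery), 4),
            collapse = ", "), "\n")
  invisible(x)
}

# Replace a strain's recovery vector, keeping mortality and trade-off.
strain_with_recovery <- function(strain, recovery) {
  strain_traits(recovery, strain$disease_mortality, strain$tradeoff)
}
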