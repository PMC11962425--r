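#' Infectivity-recovery trade-off
#'
#' The model assumes that a strain's infectivity is an increasing function of
#' its recovery rate: acuter infections shed more pathogen but last shorter,
#' `beta = beta(gamma)`. For an evolutionarily stable strategy to exist the
#' trade-off must be concave; otherwise selection favours ever more acute (or
#' ever more chronic) strains without bound -- the "Darwinian demon" of
#' life-history theory.
#'
#' Two forms are supported:
#' * `power_law`: `beta(gamma) = c * gamma^p`. Concave, increasing for
#'   `0 < p < 1`; an interior ESS exists only in that range.
#' * `custom`: an arbitrary positive increasing function with its first
#'   derivative, both supplied by the user. Concavity is checked numerically
#'   on a grid and a warning is emitted if it fails.
#'
#' @param beta Function of one argument returning infectivity; vectorised.
#' @param beta_prime Its first derivative, also vectorised.
#' @param coefficient Multiplicative constant `c > 0` of the power law.
#' @param exponent Power-law exponent `p` (an interior ESS requires
#'   `0 < p < 1`; other positive values are representable so that convex
#'   counterexamples can be explored, but the ESS solver rejects them).
#'
#' @return An object of class `"tradeoff"`.
#' @examples
#' tf <- tradeoff_power_law(coefficient = 1, exponent = 0.5)
#' tradeoff_beta(tf, 0.04)        # 0.2
#' tradeoff_beta_prime(tf, 0.04)  # 2.5
#' @export
tradeoff_power_law <- function(coefficient = 1, exponent = 0.5) {
  if (coefficient <= 0)
    stop("power-law coefficient must be positive", call. = FALSE)
  if (exponent <= 0)
    stop("power-law exponent must be positive", call. = FALSE)
  structure(
    list(form = "power_law", coefficient = as.numeric(coefficient),
         exponent = as.numeric(exponent)),
    class = "tradeoff"
  )
}

#' @rdname tradeoff_power_law
#' @param check_interval Interval on which concavity of a custom trade-off is
#'   probed numerically (101-point grid on the log scale).
#' @export
tradeoff <- function(beta, beta_prime,
                     check_interval = c(1e-4, 10)) {
  if (!is.function(beta) || !is.function(beta_prime))
    stop("'beta' and 'beta_prime' must be functions", call. = FALSE)
  obj <- structure(
    list(form = "custom", beta = beta, beta_prime = beta_prime),
    class = "tradeoff"
  )
  grid <- exp(seq(log(check_interval[1]), log(check_interval[2]),
                  length.out = 101))
  b <- tradeoff_beta(obj, grid)
  bp <- tradeoff_beta_prime(obj, grid)
  if (any(b <= 0) || any(bp <= 0))
    stop("trade-off must satisfy beta(gamma) > 0 and beta'(gamma) > 0",
         call. = FALSE)
  if (any(diff(bp) > 1e-12 * max(abs(bp))))
    warning("trade-off derivative is not non-increasing on the check grid; ",
            "the trade-off is not concave there and an ESS may not exist",
            call. = FALSE)
  obj
}

#' Evaluate a trade-off or its derivative
#'
#' @param tf A [tradeoff()] object.
#' @param gamma Recovery rate(s), > 0.
#' @return Infectivity `beta(gamma)` (or its derivative), vectorised.
#' @export
tradeoff_beta <- function(tf, gamma) {
  stopifnot(inherits(tf, "tradeoff"))
  if (tf$form == "power_law") {
    tf$coefficient * gamma^tf$exponent
  } else {
    vapply(gamma, tf$beta, numeric(1))
  }
}

#' @rdname tradeoff_beta
#' @export
tradeoff_beta_prime <- function(tf, gamma) {
  stopifnot(inherits(tf, "tradeoff"))
  if (tf$form == "power_law") {
    tf$coefficient * tf$exponent * gamma^(tf$exponent - 1)
  } else {
    vapply(gamma, tf$beta_prime, numeric(1))
  }
}

#' @export
print.tradeoff <- function(x, ...) {
  if (x$form == "power_law") {
    cat("Infectivity-recovery trade-off: beta(gamma) =",
        format(x$coefficient), "* gamma ^", format(x$exponent), "\n")
  } else {
    cat("Infectivity-recovery trade-off: custom function\n")
  }
  invisible(x)
}
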