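#' Transmission structure between age stages
#'
#' Encodes how the `n^2` stage-to-stage infection rates `beta_ij` (from
#' infectious stage `j` to susceptible stage `i`) are composed. The contact
#' modulation `c_ij` multiplies the infectivity produced by the trade-off:
#' `beta_ij = c_ij * beta(gamma_j)` -- infectivity depends on the infected
#' individual's age stage `j` only.
#'
#' Two modes:
#' * `outer_product`: `c_ij = x_i * y_j`, where `x` holds the age-specific
#'   susceptibility weights and `y` the age-specific infectivity weights.
#'   The realized transmission matrix then has rank 1, which makes the basic
#'   reproduction number equal to the trace of the next-generation matrix.
#' * `general`: an arbitrary nonnegative `n x n` matrix `c_ij` (a WAIFW-style
#'   contact matrix). R0 and Q0 must then be computed by the eigenvalue
#'   method.
#'
#' @param susceptibility Vector `x_1..x_n` of susceptibility weights
#'   (outer-product mode).
#' @param infectivity_weights Vector `y_1..y_n` of infectivity weights
#'   (outer-product mode).
#' @param contact_matrix Nonnegative `n x n` matrix `c_ij` (general mode).
#'
#' @return An object of class `"transmission_structure"`.
#' @examples
#' transmission_outer(c(1.2, 1, 0.8), c(1.1, 1, 0.9))
#' transmission_general(matrix(runif(9), 3, 3))
#' @export
transmission_outer <- function(susceptibility, infectivity_weights) {
  x <- as.numeric(susceptibility)
  y <- as.numeric(infectivity_weights)
  if (length(x) != length(y))
    stop("susceptibility and infectivity weights must have equal length",
         call. = FALSE)
  if (any(x < 0) || any(y < 0))
    stop("transmission weights must be nonnegative", call. = FALSE)
  structure(
    list(mode = "outer_product", susceptibility = x,
         infectivity_weights = y, n = length(x)),
    class = "transmission_structure"
  )
}

#' @rdname transmission_outer
#' @export
transmission_general <- function(contact_matrix) {
  cm <- as.matrix(contact_matrix)
  if (nrow(cm) != ncol(cm))
    stop("contact matrix must be square", call. = FALSE)
  if (any(cm < 0))
    stop("contact matrix entries must be nonnegative", call. = FALSE)
  structure(
    list(mode = "general", contact_matrix = cm, n = nrow(cm)),
    class = "transmission_structure"
  )
}

#' Contact-modulation matrix of a transmission structure
#'
#' @param trans A transmission structure.
#' @return The `n x n` matrix `c_ij` (outer product `x y^T` in
#'   outer-product mode).
#' @export
contact_matrix <- function(trans) {
  stopifnot(inherits(trans, "transmission_structure"))
  if (trans$mode == "outer_product") {
    outer(trans$susceptibility, trans$infectivity_weights)
  } else {
    trans$contact_matrix
  }
}

#' Realized transmission-rate matrix beta_ij
#'
#' Composes the stage-to-stage infection rates
#' `beta_ij = c_ij * beta(gamma_j)` from a transmission structure, a
#' trade-off and a strain's per-stage recovery rates.
#'
#' @param trans A transmission structure.
#' @param tf A [tradeoff()] object.
#' @param gamma Per-stage recovery rates of the strain.
#' @return The `n x n` matrix of rates `beta_ij`.
#' @export
beta_matrix <- function(trans, tf, gamma) {
  cm <- contact_matrix(trans)
  if (length(gamma) != ncol(cm))
    stop("length of 'gamma' must match the number of age stages",
         call. = FALSE)
  sweep(cm, 2L, tradeoff_beta(tf, gamma), `*`)
}

# Rescale all contact rates by a positive constant (used to probe the
# contact-rate cancellation in the ESS condition).
scale_contacts <- function(trans, factor) {
  stopifnot(factor > 0)
  if (trans$mode == "outer_product") {
    transmission_outer(trans$susceptibility * factor,
                       trans$infectivity_weights)
  } else {
    transmission_general(trans$contact_matrix * factor)
  }
}

#' @export
print.transmission_structure <- function(x, ...) {
  cat("Transmission structure (", x$mode, " mode, ", x$n, " stage(s))\n",
      sep = "")
  invisible(x)
}
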