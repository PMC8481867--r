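#' Blood volume kinetics parameters
#'
#' Constructs the subject-specific parameter triple of the two-compartment
#' blood volume (BV) kinetics model: `alpha_u`, the ratio of volume gain
#' between the intravascular and interstitial compartments; `alpha_v`, the
#' ratio of volume loss between the compartments; and `k_p`, the rate of
#' fluid shift between them (1/min).
#'
#' The denominators `1 + alpha_u` and `1 + alpha_v` must be positive: of a
#' unit volume infused, a fraction `1/(1 + alpha_u)` is eventually retained
#' intravascularly; of a unit volume hemorrhaged, `1/(1 + alpha_v)` is the
#' eventual intravascular loss.
#'
#' @param alpha_u Dimensionless gain-distribution ratio, `> -1`.
#' @param alpha_v Dimensionless loss-distribution ratio, `> -1`.
#' @param k_p Fluid-shift rate constant in 1/min, `> 0`.
#' @return An object of class `"bv_params"`, a named list with the three
#'   components.
#' @examples
#' p <- bv_params(alpha_u = 3, alpha_v = 1.4, k_p = 0.14)
#' transfer_coeffs(p)
#' @export
bv_params <- function(alpha_u, alpha_v, k_p) {
  stopifnot(is.numeric(alpha_u), length(alpha_u) == 1L,
            is.numeric(alpha_v), length(alpha_v) == 1L,
            is.numeric(k_p), length(k_p) == 1L)
  if (!is.finite(k_p) || k_p <= 0)
    stop("k_p must be finite and > 0, got ", k_p)
  if (!is.finite(alpha_u) || 1 + alpha_u <= 0)
    stop("1 + alpha_u must be positive, got alpha_u = ", alpha_u)
  if (!is.finite(alpha_v) || 1 + alpha_v <= 0)
    stop("1 + alpha_v must be positive, got alpha_v = ", alpha_v)
  structure(list(alpha_u = alpha_u, alpha_v = alpha_v, k_p = k_p),
            class = "bv_params")
}

#' @export
print.bv_params <- function(x, digits = 4, ...) {
  cat("BV kinetics parameters:\n")
  cat(sprintf("  alpha_u = %.*g   alpha_v = %.*g   k_p = %.*g 1/min\n",
              digits, x$alpha_u, digits, x$alpha_v, digits, x$k_p))
  invisible(x)
}

#' @export
as.numeric.bv_params <- function(x, ...) {
  c(alpha_u = x$alpha_u, alpha_v = x$alpha_v, k_p = x$k_p)
}

#' Transfer-function coefficients of the BV kinetics model
#'
#' The model's input-output map has one pole at `k_p` and input-dependent
#' zeros `k_p/(1 + alpha_u)` (infusion channel) and `k_p/(1 + alpha_v)`
#' (hemorrhage channel). The map from parameters to these three coefficients
#' is a bijection whenever the pole is positive, which is the executable form
#' of the model's global structural identifiability: distinct parameter
#' triples produce distinct input-output behaviour, so noise-free data
#' determine the parameters uniquely.
#'
#' @param params A [bv_params()] object.
#' @return A named numeric vector `c(pole, zero_u, zero_v)` (all 1/min).
#' @seealso [params_from_transfer()] for the inverse map.
#' @export
transfer_coeffs <- function(params) {
  stopifnot(inherits(params, "bv_params"))
  c(pole = params$k_p,
    zero_u = params$k_p / (1 + params$alpha_u),
    zero_v = params$k_p / (1 + params$alpha_v))
}

#' Recover model parameters from transfer-function coefficients
#'
#' Inverse of [transfer_coeffs()]: `k_p = pole`,
#' `alpha_u = pole/zero_u - 1`, `alpha_v = pole/zero_v - 1`. Defined for
#' `pole > 0` and non-zero zeros; a zero equal to 0 corresponds to an
#' infinite distribution ratio and is rejected as non-finite.
#'
#' @param coeffs Named numeric vector with elements `pole`, `zero_u`,
#'   `zero_v`.
#' @return A [bv_params()] object.
#' @export
params_from_transfer <- function(coeffs) {
  stopifnot(all(c("pole", "zero_u", "zero_v") %in% names(coeffs)))
  pole <- unname(coeffs["pole"])
  zu <- unname(coeffs["zero_u"])
  zv <- unname(coeffs["zero_v"])
  if (!is.finite(pole) || pole <= 0)
    stop("pole must be finite and > 0; inverse map undefined")
  if (zu == 0 || zv == 0)
    stop("zero coefficient equal to 0 maps to an infinite alpha (non-finite)")
  bv_params(alpha_u = pole / zu - 1, alpha_v = pole / zv - 1, k_p = pole)
}
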