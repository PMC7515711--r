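## Closed-form accumulation kinetics of a constitutively transcribed miRNA:
## with synthesis rate beta (units/h) and first-order decay alpha = ln(2)/h,
## M(t) = (beta/alpha) (1 - exp(-alpha t)) rises to the steady state
## beta/alpha with half-life h.

#' Kinetic parameters from a half-life
#'
#' @param halflife miRNA half-life h in hours (> 0).
#' @param beta synthesis rate in units/h (default 1).
#' @return list of class `kinetic_params`: `beta`, `alpha` (= ln(2)/h),
#'   `halflife`.
#' @export
kinetic_params <- function(halflife, beta = 1) {
  stopifnot(halflife > 0, beta > 0)
  structure(list(beta = beta, alpha = log(2) / halflife, halflife = halflife),
            class = "kinetic_params")
}

#' miRNA level at time t
#'
#' `M(t) = (beta/alpha) (1 - exp(-alpha t))`: monotone increasing in t with
#' asymptote `beta/alpha`; at `t = h` exactly half the steady state.
#'
#' @param t time in hours (>= 0, vectorized).
#' @param params a [kinetic_params()].
#' @return miRNA level(s).
#' @export
mirna_level <- function(t, params) {
  if (any(t < 0)) stop("t must be >= 0")
  with(params, beta / alpha * (1 - exp(-t * alpha)))
}

#' Fraction of steady state reached by time t
#'
#' `1 - 2^(-t/h)`, independent of the synthesis rate.
#'
#' @param t time in hours (>= 0, vectorized).
#' @param h half-life in hours (> 0).
#' @return fraction in `[0, 1)`.
#' @examples
#' fraction_of_steady_state(168, 24)  # 7 days at a 24 h half-life
#' @export
fraction_of_steady_state <- function(t, h) {
  if (any(h <= 0)) stop("half-life must be positive")
  if (any(t < 0)) stop("t must be >= 0")
  1 - 2^(-t / h)
}
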