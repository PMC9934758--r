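# Smooth muscle active tone: shear-regulated magnitude, parabolic
# length-tension factor, and slow relaxation of the active reference
# radius.

#' Vasoactive tone magnitude
#'
#' Shear-regulated tone: decreases in flow (shear below homeostatic)
#' constrict, increases dilate, through a tanh sigmoid. Scaled by the
#' smooth muscle mass ratio.
#'
#' @param smc_mass_ratio current/homeostatic smooth muscle mass (> 0).
#' @param tau_ratio wall shear over its homeostatic value.
#' @param params a [tone_params()] object.
#' @return tone magnitude S, N/m, in `[0, 4 S_basal * mass_ratio]`.
#' @export
tone_magnitude <- function(smc_mass_ratio, tau_ratio, params) {
  if (any(smc_mass_ratio <= 0))
    stop("mass ratio must be positive", call. = FALSE)
  2 * params$S_basal * smc_mass_ratio *
    (1 + tanh(-params$k_ton * (tau_ratio - 1) - params$tone_offset))
}

#' Active length-tension factor
#'
#' Parabolic factor equal to 1 at the stretch of maximal contraction
#' `lambda_M` and 0 at `lambda_0`, clamped at zero outside the active
#' range (negative active stress is unphysical).
#'
#' @param lambda2_act active circumferential stretch (> 0).
#' @param params a [tone_params()] object.
#' @return factor in `[0, 1]`.
#' @export
length_tension <- function(lambda2_act, params) {
  if (any(lambda2_act <= 0))
    stop("active stretch must be positive", call. = FALSE)
  pmax(0, 1 - ((params$lambda_M - lambda2_act) /
                 (params$lambda_M - params$lambda_0))^2)
}

#' Relax the active reference radius toward the current radius
#'
#' Exact exponential update of `dr_act/dt = K_act (r - r_act)` over a
#' step, so `lambda2_act = r/r_act` relaxes toward 1 with time constant
#' `1/K_act`.
#'
#' @param r_act active reference radius.
#' @param r current mean radius (same units).
#' @param K_act relaxation rate, 1/day.
#' @param dt step, day (> 0).
#' @return updated active reference radius.
#' @export
update_active_radius <- function(r_act, r, K_act, dt) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  r + (r_act - r) * exp(-K_act * dt)
}

#' Active circumferential membrane stress
#'
#' @param S tone magnitude, N/m (>= 0).
#' @param lambda2_act active circumferential stretch.
#' @param params a [tone_params()] object.
#' @return `T_act = S * lambda2_act * f(lambda2_act)`, N/m (>= 0).
#' @export
active_membrane_stress <- function(S, lambda2_act, params) {
  if (any(S < 0)) stop("S must be non-negative", call. = FALSE)
  S * lambda2_act * length_tension(lambda2_act, params)
}

#' Scalar smooth muscle stress measure
#'
#' Circumferential membrane stress (passive part per the chosen
#' convention plus active tone) divided by the equivalent thickness of the
#' muscle compartment, `h_m = M_Rm / ((1 - phi_f) rho lambda1 lambda2)`.
#'
#' @param T22 circumferential passive membrane stress entering the
#'   measure, N/m.
#' @param T_act active membrane stress, N/m.
#' @param M_Rm smooth muscle mass per reference area, kg/m^2 (> 0).
#' @param lambda1,lambda2 current stretches.
#' @param phi_f fluid mass fraction.
#' @param rho wall density, kg/m^3.
#' @return muscle stress measure, kPa.
#' @export
smc_scalar_stress <- function(T22, T_act, M_Rm, lambda1, lambda2,
                              phi_f, rho) {
  if (any(M_Rm <= 0)) stop("mass must be positive", call. = FALSE)
  h_m <- M_Rm / ((1 - phi_f) * rho * lambda1 * lambda2)
  (T22 + T_act) / h_m / 1000
}
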