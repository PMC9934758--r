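# Two-compartment collagen turnover kinetics: mechano-regulated
# procollagen synthesis feeds an intermediate (soluble microfibril) pool
# carried in molar units per reference area; maturation converts it to
# cross-linked mass. All updates are exact exponential solutions of the
# linear ODEs with the production rate frozen over the step, so pools stay
# non-negative for any step size.

#' Procollagen mass production rate
#'
#' Baseline production scaled by the constituent mass ratio (cell number
#' grows with mass) and modulated by the intramural-stress and wall-shear
#' stimuli through dimensionless gains:
#' `m_p = mass_ratio * m_p0 * (1 + K_sigma*(sigma_ratio - 1)
#'  - K_tau*(tau_ratio - 1))`, clamped at zero because synthesis can be
#' attenuated but not reversed.
#'
#' @param mass_ratio current/homeostatic constituent mass.
#' @param sigma_ratio intramural stress over its homeostatic value.
#' @param tau_ratio wall shear stress over its homeostatic value.
#' @param K_sigma,K_tau dimensionless gains.
#' @param m_p0 baseline production rate, kg/m^2/day.
#' @return production rate, kg/m^2/day (>= 0).
#' @export
procollagen_rate <- function(mass_ratio, sigma_ratio, tau_ratio,
                             K_sigma, K_tau, m_p0) {
  if (any(mass_ratio <= 0))
    stop("mass ratio must be positive", call. = FALSE)
  raw <- mass_ratio * m_p0 *
    (1 + K_sigma * (sigma_ratio - 1) - K_tau * (tau_ratio - 1))
  if (any(raw < 0))
    warning("production stimulus is negative; clamping synthesis at zero")
  pmax(0, raw)
}

#' Advance the intermediate collagen pool over one step
#'
#' Exact exponential update of `dC/dt = beta1 m_p / MW - (beta2 + mu1) C`
#' with the production rate held constant over the step.
#'
#' @param C_IR intermediate pool, molecules/m^2 of reference area.
#' @param m_pR procollagen mass production rate, kg/m^2/day.
#' @param params a [kinetic_params()] object.
#' @param dt step, day (> 0).
#' @return updated pool (same units as `C_IR`).
#' @export
step_intermediate <- function(C_IR, m_pR, params, dt) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  a <- params$beta2 + params$mu1
  C_inf <- params$beta1 * m_pR / (params$MW * a)
  decay <- exp(-a * dt)
  C_IR * decay + C_inf * (1 - decay)
}

#' Maturation (cross-linking) rate of collagen
#'
#' Mass flux from the intermediate pool into mature cross-linked fibers.
#'
#' @param C_IR intermediate pool, molecules/m^2.
#' @param beta2 maturation rate, 1/day.
#' @param MW molecular weight, kg.
#' @return mass production rate of mature collagen, kg/m^2/day.
#' @export
maturation_rate <- function(C_IR, beta2, MW) {
  if (any(C_IR < 0)) stop("pool must be non-negative", call. = FALSE)
  MW * beta2 * C_IR
}

#' Homeostatic (steady-state) initialization of the turnover chain
#'
#' Given a homeostatic mature mass, returns the production, intermediate
#' pool, and synthesis levels at which the two-compartment chain is
#' exactly stationary: `m_R(0) = mu2 M_R(0)`,
#' `C_IR(0) = mu2 M_R(0) / (beta2 MW)`, and
#' `m_p(0) = (beta2 + mu1)/(beta1 beta2) * mu2 M_R(0)` (mass units).
#'
#' @param M_R0 homeostatic mature mass per reference area, kg/m^2.
#' @param params a [kinetic_params()] object.
#' @return list with `m_R0` (kg/m^2/day), `C_IR0` (molecules/m^2),
#'   `m_p0` (kg/m^2/day).
#' @examples
#' homeostatic_init(1, kinetic_params(beta1 = 0.7, beta2 = 0.2,
#'                                    mu1 = 0.1, mu2 = 0.01))$m_p0
#' @export
homeostatic_init <- function(M_R0, params) {
  if (any(M_R0 <= 0)) stop("mass must be positive", call. = FALSE)
  m_R0 <- params$mu2 * M_R0
  list(m_R0 = m_R0,
       C_IR0 = m_R0 / (params$beta2 * params$MW),
       m_p0 = (params$beta2 + params$mu1) /
         (params$beta1 * params$beta2) * m_R0)
}

#' Closed-form step response of the two-pool chain
#'
#' Explicit solution of the linear intermediate/mature system for a
#' constant synthesis rate switched on at `t = 0` from empty pools. Serves
#' as the independent oracle for the engine's stepped updates.
#'
#' @param m_p constant procollagen mass production rate, kg/m^2/day.
#' @param params a [kinetic_params()] object.
#' @param t time since the step, day (>= 0, vectorized).
#' @return list with molar pools `C_I` and `C_F` (molecules/m^2).
#' @export
two_pool_closed_form <- function(m_p, params, t) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  a <- params$beta2 + params$mu1
  mu2 <- params$mu2
  u <- params$beta1 * m_p / params$MW   # molar inflow
  C_I <- u / a * (1 - exp(-a * t))
  if (abs(a - mu2) > 1e-12 * max(a, mu2)) {
    # distinct decay rates
    C_F <- params$beta2 * u *
      ((1 - exp(-mu2 * t)) / (a * mu2) -
         (exp(-mu2 * t) - exp(-a * t)) / (a * (a - mu2)))
  } else {
    # repeated root a == mu2
    C_F <- params$beta2 * u *
      ((1 - exp(-a * t)) / a^2 - t * exp(-a * t) / a)
  }
  list(C_I = C_I, C_F = C_F)
}

#' Mean age of mature collagen
#'
#' With first-order removal at rate `mu2`, the age distribution of the
#' surviving mature pool is exponential with mean `1/mu2` (100 days at the
#' baseline rate; half-life `log(2)/mu2`, about 70 days).
#'
#' @param mu2 mature removal rate, 1/day (> 0).
#' @return mean age, day.
#' @export
mean_mature_age <- function(mu2) {
  if (any(mu2 <= 0)) stop("mu2 must be positive", call. = FALSE)
  1 / mu2
}
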