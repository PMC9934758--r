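# Parameter containers. Defaults are the mouse common carotid artery
# calibration: kinetic rates from the literature-derived table and wall /
# tone constants from the passive+active pressure-diameter fit.

#' Pressure unit conversion
#' @keywords internal
.MMHG_TO_PA <- 133.322

#' Collagen turnover kinetic parameters
#'
#' Two-compartment kinetics of extracellular collagen: a fraction `beta1`
#' of synthesized procollagen is secreted and assembles into an
#' intermediate (soluble, non-load-bearing) microfibril pool, which either
#' matures into cross-linked fibers at rate `beta2` or is removed at rate
#' `mu1`; mature fibers are removed at rate `mu2` (mean fiber age
#' `1/mu2`).
#'
#' @param beta1 secreted fraction of synthesized procollagen (0, 1].
#' @param beta2 maturation (cross-linking) rate, 1/day.
#' @param mu1 intermediate-pool removal rate, 1/day.
#' @param mu2 mature-fiber removal rate, 1/day.
#' @param MW collagen molecular weight, kg per molecule.
#' @param a_max maximum tracked cohort age, day.
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params()
#' mean_mature_age(kinetic_params()$mu2)
#' @export
kinetic_params <- function(beta1 = 0.7, beta2 = 0.2, mu1 = 0.1,
                           mu2 = 0.01, MW = 4.981617e-22, a_max = 350) {
  p <- list(beta1 = beta1, beta2 = beta2, mu1 = mu1, mu2 = mu2,
            MW = MW, a_max = a_max)
  class(p) <- "kinetic_params"
  validate_kinetic_params(p)
}

#' @keywords internal
validate_kinetic_params <- function(p) {
  stopifnot(is.numeric(p$beta1), is.numeric(p$beta2), is.numeric(p$mu1),
            is.numeric(p$mu2), is.numeric(p$MW), is.numeric(p$a_max))
  if (!(p$beta1 > 0 && p$beta1 <= 1))
    stop("beta1 must be in (0, 1]", call. = FALSE)
  if (p$beta2 <= 0 || p$mu2 <= 0)
    stop("beta2 and mu2 must be positive rates (1/day)", call. = FALSE)
  if (p$mu1 < 0) stop("mu1 must be non-negative", call. = FALSE)
  if (p$MW <= 0) stop("MW must be positive", call. = FALSE)
  if (p$a_max < 3 / p$mu2)
    warning("a_max is short relative to the mature-fiber lifetime 1/mu2; ",
            "truncation of the cohort window will be noticeable")
  p
}

#' Wall geometry, composition, and passive material parameters
#'
#' Homeostatic geometry, deposition (pre-)stretches, mass fractions and
#' constituent strain-energy constants of the arterial membrane model.
#' `phi0_k` are the four collagen family mass fractions in the order
#' axial (0 deg), circumferential (90 deg), +alpha_h, -alpha_h; the fiber
#' angle is measured from the axial direction in the fixed reference
#' configuration.
#'
#' @param r_oh_mm homeostatic outer radius, mm.
#' @param h_h_um homeostatic wall thickness, micrometers.
#' @param alpha_h_deg diagonal collagen fiber angle, degrees from axial.
#' @param G_hc,G_hm collagen and smooth-muscle deposition stretches.
#' @param G1e,G2e elastin axial and circumferential deposition stretches.
#' @param c1e elastin neo-Hookean constant, J/kg.
#' @param c2c,c3c collagen exponential fiber constants (J/kg, -).
#' @param c1m,c2m,c3m smooth-muscle passive constants (J/kg, J/kg, -).
#' @param sigma_h_kPa homeostatic intramural (fiber-level) stress, kPa.
#' @param tau_wh_Pa homeostatic wall shear stress, Pa.
#' @param P_h_mmHg homeostatic transmural pressure, mmHg.
#' @param phi0_e,phi0_m,phi_f elastin, muscle, and fluid mass fractions.
#' @param phi0_k numeric(4), collagen family mass fractions (see Details).
#' @param rho_wall wall tissue density, kg/m^3.
#' @param collagen_compression `"as_printed"` evaluates the exponential
#'   fiber energy for compressed fibers as written (it is symmetric in
#'   `(lambda^2-1)^2`); `"zero"` makes compressed fibers stress-free.
#' @return An object of class `wall_params`.
#' @export
wall_params <- function(r_oh_mm = 0.328, h_h_um = 21.2, alpha_h_deg = 47.6,
                        G_hc = 1.07, G_hm = 1.25, G1e = 2.19, G2e = 1.64,
                        c1e = 657.9, c2c = 3090, c3c = 18.9,
                        c1m = 103, c2m = 11.5, c3m = 0.794,
                        sigma_h_kPa = 120, tau_wh_Pa = 1.5, P_h_mmHg = 102,
                        phi0_e = 0.06, phi0_m = 0.09, phi_f = 0.70,
                        phi0_k = 0.15 * c(0.111, 0.0349, 0.427, 0.427),
                        rho_wall = 1050,
                        collagen_compression = c("as_printed", "zero")) {
  p <- list(r_oh_mm = r_oh_mm, h_h_um = h_h_um, alpha_h_deg = alpha_h_deg,
            G_hc = G_hc, G_hm = G_hm, G1e = G1e, G2e = G2e,
            c1e = c1e, c2c = c2c, c3c = c3c,
            c1m = c1m, c2m = c2m, c3m = c3m,
            sigma_h_kPa = sigma_h_kPa, tau_wh_Pa = tau_wh_Pa,
            P_h_mmHg = P_h_mmHg,
            phi0_e = phi0_e, phi0_m = phi0_m, phi_f = phi_f,
            phi0_k = phi0_k, rho_wall = rho_wall,
            collagen_compression = match.arg(collagen_compression))
  class(p) <- "wall_params"
  validate_wall_params(p)
}

#' @keywords internal
validate_wall_params <- function(p) {
  if (length(p$phi0_k) != 4)
    stop("phi0_k must have exactly 4 collagen family fractions",
         call. = FALSE)
  tot <- p$phi0_e + p$phi0_m + sum(p$phi0_k) + p$phi_f
  if (abs(tot - 1) > 1e-3)
    stop(sprintf("mass fractions must sum to 1 (got %.6f)", tot),
         call. = FALSE)
  stretches <- c(p$G_hc, p$G_hm, p$G1e, p$G2e)
  if (any(stretches <= 0)) stop("deposition stretches must be positive",
                                call. = FALSE)
  if (p$h_h_um * 1e-3 >= p$r_oh_mm)
    stop("wall thickness must be smaller than the outer radius",
         call. = FALSE)
  if (p$alpha_h_deg < 0 || p$alpha_h_deg > 90)
    stop("alpha_h_deg must lie in [0, 90]", call. = FALSE)
  if (any(c(p$c1e, p$c2c, p$c3c, p$c1m, p$c2m, p$c3m) < 0))
    stop("material constants must be non-negative", call. = FALSE)
  if (p$rho_wall <= 0 || p$phi_f < 0 || p$phi_f >= 1)
    stop("invalid density or fluid fraction", call. = FALSE)
  if (p$G_hc == 1)
    stop("G_hc = 1 makes the homeostatic fiber-tension denominator zero",
         call. = FALSE)
  p
}

#' Smooth muscle tone parameters
#'
#' The tone magnitude is `S = 2*S_basal*(M_m(t)/M_m(0)) *
#' (1 + tanh(-k_ton*(tau_w/tau_wh - 1) - tone_offset))`, bounded between 0
#' (full dilation at high shear) and `4*S_basal` times the muscle mass
#' ratio (maximal constriction at low shear). The active membrane stress
#' is `S * lambda2_act * f(lambda2_act)` with the parabolic length-tension
#' factor `f` vanishing at `lambda_0` and maximal at `lambda_M`, and
#' `lambda2_act = r/r_act` where the active reference radius `r_act`
#' relaxes toward the current radius at rate `K_act`.
#'
#' @param S_basal basal tone magnitude scale, N/m.
#' @param k_ton shear sensitivity of the tone sigmoid (dimensionless).
#' @param lambda_M,lambda_0 stretches of maximal and zero contraction.
#' @param K_act active-radius relaxation rate, 1/day.
#' @param tone_offset constant inside the tanh; `log(3/2)` places the
#'   basal operating point on the dilator side of the sigmoid.
#' @return An object of class `tone_params`.
#' @export
tone_params <- function(S_basal = 0.862, k_ton = 52 / 3,
                        lambda_M = 1.65, lambda_0 = 0.65,
                        K_act = 0.10, tone_offset = log(3 / 2)) {
  p <- list(S_basal = S_basal, k_ton = k_ton, lambda_M = lambda_M,
            lambda_0 = lambda_0, K_act = K_act, tone_offset = tone_offset)
  class(p) <- "tone_params"
  validate_tone_params(p)
}

#' @keywords internal
validate_tone_params <- function(p) {
  if (!(p$lambda_M > p$lambda_0 && p$lambda_0 > 0))
    stop("need lambda_M > lambda_0 > 0", call. = FALSE)
  if (p$K_act <= 0) stop("K_act must be positive", call. = FALSE)
  if (p$S_basal < 0) stop("S_basal must be non-negative", call. = FALSE)
  p
}

#' Growth-and-remodeling gain parameters
#'
#' Dimensionless gains coupling production to the intramural stress and
#' wall shear stimuli, and the constants of the tension-dependent removal
#' rate `mu2_k = K_mu1 + K_mu2*(zeta - zeta_c)^2` where `zeta` is the
#' cohort fiber-tension ratio (1 at the deposition stretch).
#'
#' @param K_sigma_c,K_sigma_m intramural-stress gains for collagen and
#'   smooth muscle production.
#' @param K_tau_c,K_tau_m wall-shear gains.
#' @param K_mu1 baseline removal rate, 1/day (also the constant smooth
#'   muscle apoptosis rate).
#' @param K_mu2 tension sensitivity of collagen removal, 1/day.
#' @param zeta_c homeostatic fiber-tension ratio (1 at the deposition
#'   stretch).
#' @return An object of class `gain_params`.
#' @export
gain_params <- function(K_sigma_c = 2, K_sigma_m = 2,
                        K_tau_c = 52, K_tau_m = 52,
                        K_mu1 = 0.01, K_mu2 = 0.01, zeta_c = 1) {
  p <- list(K_sigma_c = K_sigma_c, K_sigma_m = K_sigma_m,
            K_tau_c = K_tau_c, K_tau_m = K_tau_m,
            K_mu1 = K_mu1, K_mu2 = K_mu2, zeta_c = zeta_c)
  class(p) <- "gain_params"
  validate_gain_params(p)
}

#' @keywords internal
validate_gain_params <- function(p) {
  if (p$K_mu1 <= 0) stop("K_mu1 must be positive", call. = FALSE)
  gains <- c(p$K_sigma_c, p$K_sigma_m, p$K_tau_c, p$K_tau_m, p$K_mu2)
  if (any(gains < 0)) stop("gains must be non-negative", call. = FALSE)
  p
}

#' Numerical settings
#'
#' @param dt global time step, day.
#' @param duration default simulated duration, day.
#' @param output_interval interval between stored output rows, day.
#' @param newton_tol equilibrium residual tolerance relative to
#'   `P_h * r_h` (force per unit length scale).
#' @param newton_max_iter maximum Newton iterations for the radius solve.
#' @param fd_step finite-difference step for the Newton Jacobian, relative
#'   to `r_h`.
#' @param equilibrium_radius `"inner"` balances `P*r_i` against the
#'   membrane tension (consistent with the Laplace hoop-stress definition
#'   `sigma2 = P r_i / h`); `"mean"` balances `P*r` with the mean radius.
#' @param sigma_c_stimulus intramural-stress stimulus driving collagen
#'   production: `"fiber"` uses the per-family collagen fiber stress
#'   ratio (the constituent-level stress measure); `"total_hoop"` uses
#'   the total circumferential Cauchy stress ratio, so production is
#'   driven by how far the wall as a whole is from its stress set point.
#' @param sigma_m_stress circumferential membrane stress entering the
#'   smooth muscle stress measure: `"total"` (all constituents plus tone)
#'   or `"smc"` (the muscle-borne passive part plus tone).
#' @param balance how the model is brought to exact mechanical
#'   equilibrium at the homeostatic state (the printed constants are
#'   rounded and leave a small load residual): `"s_basal"` rescales the
#'   basal tone, `"c1e"` rescales the elastin stiffness and keeps the
#'   calibrated tone, `"none"` uses the constants as given (the first
#'   solve then settles slightly off the nominal geometry).
#' @return An object of class `numerics_params`.
#' @export
numerics_params <- function(dt = 0.1, duration = 300, output_interval = 1,
                            newton_tol = 1e-9, newton_max_iter = 100,
                            fd_step = 1e-7,
                            equilibrium_radius = c("inner", "mean"),
                            sigma_c_stimulus = c("fiber", "total_hoop"),
                            sigma_m_stress = c("total", "smc"),
                            balance = c("s_basal", "c1e", "none")) {
  p <- list(dt = dt, duration = duration,
            output_interval = output_interval,
            newton_tol = newton_tol, newton_max_iter = newton_max_iter,
            fd_step = fd_step,
            equilibrium_radius = match.arg(equilibrium_radius),
            sigma_c_stimulus = match.arg(sigma_c_stimulus),
            sigma_m_stress = match.arg(sigma_m_stress),
            balance = match.arg(balance))
  if (p$dt <= 0) stop("dt must be positive", call. = FALSE)
  if (p$output_interval < p$dt)
    stop("output_interval must be >= dt", call. = FALSE)
  class(p) <- "numerics_params"
  p
}

#' Assemble a full growth-and-remodeling parameter set
#'
#' Bundles the kinetic, wall, tone, gain, and numerical parameter groups.
#' All defaults together constitute the mouse carotid baseline.
#'
#' @param kinetics a [kinetic_params()] object.
#' @param wall a [wall_params()] object.
#' @param tone a [tone_params()] object.
#' @param gains a [gain_params()] object.
#' @param numerics a [numerics_params()] object.
#' @return An object of class `gr_params`.
#' @examples
#' p <- gr_params(gains = gain_params(K_sigma_c = 3, K_sigma_m = 3))
#' p$gains$K_sigma_c
#' @export
gr_params <- function(kinetics = kinetic_params(), wall = wall_params(),
                      tone = tone_params(), gains = gain_params(),
                      numerics = numerics_params()) {
  stopifnot(inherits(kinetics, "kinetic_params"),
            inherits(wall, "wall_params"),
            inherits(tone, "tone_params"),
            inherits(gains, "gain_params"),
            inherits(numerics, "numerics_params"))
  p <- list(kinetics = kinetics, wall = wall, tone = tone,
            gains = gains, numerics = numerics)
  class(p) <- "gr_params"
  p
}

#' @export
print.gr_params <- function(x, ...) {
  cat("Growth-and-remodeling parameter set\n")
  cat(sprintf("  wall: r_oh %.3f mm, h_h %.1f um, alpha %.1f deg\n",
              x$wall$r_oh_mm, x$wall$h_h_um, x$wall$alpha_h_deg))
  cat(sprintf("  kinetics: beta1 %.2f beta2 %.3g mu1 %.3g mu2 %.3g 1/day\n",
              x$kinetics$beta1, x$kinetics$beta2, x$kinetics$mu1,
              x$kinetics$mu2))
  cat(sprintf("  gains: K_sigma (c,m) = (%g, %g), K_tau = (%g, %g)\n",
              x$gains$K_sigma_c, x$gains$K_sigma_m,
              x$gains$K_tau_c, x$gains$K_tau_m))
  cat(sprintf("  tone: S_basal %.3f N/m, k_ton %.3f, K_act %.2f 1/day\n",
              x$tone$S_basal, x$tone$k_ton, x$tone$K_act))
  cat(sprintf("  numerics: dt %g day, equilibrium on %s radius\n",
              x$numerics$dt, x$numerics$equilibrium_radius))
  invisible(x)
}
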