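# Kinematics, constituent strain energies and membrane stress for the
# two-dimensional (membrane) constrained mixture. Energies are per unit
# constituent mass (J/kg); membrane stresses are forces per unit deformed
# length (N/m); Cauchy stresses are reported in kPa.

#' Fiber stretch of a family at angle alpha
#'
#' Stretch of a fiber oriented at `alpha` degrees from the axial direction
#' in the fixed reference configuration, under the planar deformation
#' `diag(lambda1, lambda2)`.
#'
#' @param lambda1,lambda2 axial and circumferential stretches (> 0).
#' @param alpha_deg fiber angle, degrees in `[0, 90]` (vectorized).
#' @return `sqrt(lambda1^2 cos^2(alpha) + lambda2^2 sin^2(alpha))`.
#' @examples
#' fiber_stretch(1, 1.2, 90)   # pure circumferential fiber
#' fiber_stretch(1, 1.2, 47.6) # diagonal family
#' @export
fiber_stretch <- function(lambda1, lambda2, alpha_deg) {
  if (any(lambda1 <= 0) || any(lambda2 <= 0))
    stop("stretches must be positive", call. = FALSE)
  a <- alpha_deg * pi / 180
  sqrt(lambda1^2 * cos(a)^2 + lambda2^2 * sin(a)^2)
}

#' Stretch of a cohort deposited at an earlier time
#'
#' Material laid down at time `tau` is incorporated at the deposition
#' stretch `G_h`, so its current stretch is `G_h` times the tissue-level
#' stretch accumulated since deposition.
#'
#' @param current current fiber (or principal) stretch of the tissue.
#' @param at_deposition the same stretch measure at the deposition time.
#' @param G_h deposition stretch of the constituent.
#' @return cohort stretch `G_h * current / at_deposition`.
#' @export
cohort_stretch <- function(current, at_deposition, G_h) {
  if (any(current <= 0) || any(at_deposition <= 0) || any(G_h <= 0))
    stop("stretches must be positive", call. = FALSE)
  G_h * current / at_deposition
}

# guard for the exponential fiber energy
.check_exp_arg <- function(x) {
  if (any(x > 700))
    stop("fiber stretch is unphysically large: exponential overflow",
         call. = FALSE)
  x
}

#' Collagen fiber strain energy per unit mass
#'
#' Exponential fiber model `c2c/(4 c3c) * (exp(c3c (lambda^2-1)^2) - 1)`.
#' Note the energy is symmetric in `(lambda^2-1)^2`; see
#' [wall_params()] `collagen_compression` for how the simulation engine
#' treats compressed fibers.
#'
#' @param lambda_n cohort fiber stretch (> 0), vectorized.
#' @param c2c stress-like constant, J/kg.
#' @param c3c dimensionless exponent.
#' @return energy, J/kg.
#' @examples
#' psi_collagen(1.07, 3090, 18.9) # energy at the deposition stretch
#' @export
psi_collagen <- function(lambda_n, c2c, c3c) {
  if (any(lambda_n <= 0)) stop("stretch must be positive", call. = FALSE)
  e <- .check_exp_arg(c3c * (lambda_n^2 - 1)^2)
  c2c / (4 * c3c) * (exp(e) - 1)
}

#' Derivative of the collagen fiber energy with respect to stretch
#' @inheritParams psi_collagen
#' @return `d psi / d lambda`, J/kg per unit stretch.
#' @export
dpsi_collagen <- function(lambda_n, c2c, c3c) {
  if (any(lambda_n <= 0)) stop("stretch must be positive", call. = FALSE)
  q <- lambda_n^2 - 1
  e <- .check_exp_arg(c3c * q^2)
  c2c * lambda_n * q * exp(e)
}

#' Smooth muscle passive strain energy per unit mass
#'
#' A 2D-incompressible neo-Hookean term plus an exponential
#' circumferential fiber term.
#'
#' @param lambda_n1,lambda_n2 cohort principal stretches (> 0).
#' @param c1m,c2m,c3m material constants (J/kg, J/kg, -).
#' @return energy, J/kg; zero at (1, 1).
#' @export
psi_smc <- function(lambda_n1, lambda_n2, c1m, c2m, c3m) {
  if (any(lambda_n1 <= 0) || any(lambda_n2 <= 0))
    stop("stretches must be positive", call. = FALSE)
  q <- lambda_n2^2 - 1
  e <- .check_exp_arg(c3m * q^2)
  c1m / 2 * (lambda_n1^2 + lambda_n2^2 +
               1 / (lambda_n1^2 * lambda_n2^2) - 3) +
    c2m / (4 * c3m) * (exp(e) - 1)
}

#' @rdname psi_smc
#' @return for the derivative forms, `d psi / d lambda_n1` and
#'   `d psi / d lambda_n2` respectively.
#' @export
dpsi_smc_d1 <- function(lambda_n1, lambda_n2, c1m, c2m, c3m) {
  c1m * (lambda_n1 - 1 / (lambda_n1^3 * lambda_n2^2))
}

#' @rdname psi_smc
#' @export
dpsi_smc_d2 <- function(lambda_n1, lambda_n2, c1m, c2m, c3m) {
  q <- lambda_n2^2 - 1
  e <- .check_exp_arg(c3m * q^2)
  c1m * (lambda_n2 - 1 / (lambda_n1^2 * lambda_n2^3)) +
    c2m * lambda_n2 * q * exp(e)
}

#' Elastin strain energy per unit mass
#'
#' Amorphous (neo-Hookean, 2D-incompressible) elastin energy.
#'
#' @param lambda_n1,lambda_n2 cohort principal stretches (> 0).
#' @param c1e material constant, J/kg.
#' @return energy, J/kg; zero at (1, 1).
#' @examples
#' psi_elastin(2.19, 1.64, 657.9) # energy at the elastin pre-stretches
#' @export
psi_elastin <- function(lambda_n1, lambda_n2, c1e) {
  if (any(lambda_n1 <= 0) || any(lambda_n2 <= 0))
    stop("stretches must be positive", call. = FALSE)
  c1e / 2 * (lambda_n1^2 + lambda_n2^2 +
               1 / (lambda_n1^2 * lambda_n2^2) - 3)
}

#' @rdname psi_elastin
#' @export
dpsi_elastin_d1 <- function(lambda_n1, lambda_n2, c1e) {
  c1e * (lambda_n1 - 1 / (lambda_n1^3 * lambda_n2^2))
}

#' @rdname psi_elastin
#' @export
dpsi_elastin_d2 <- function(lambda_n1, lambda_n2, c1e) {
  c1e * (lambda_n2 - 1 / (lambda_n1^2 * lambda_n2^3))
}

#' Cauchy membrane stress from a strain-energy function
#'
#' For a membrane with strain energy `w(lambda1, lambda2)` per unit
#' reference area, the in-plane Cauchy membrane stresses (force per unit
#' deformed length) are `T11 = (1/lambda2) dw/dlambda1` and
#' `T22 = (1/lambda1) dw/dlambda2`. If an analytic gradient is supplied it
#' is used; otherwise the derivatives are taken by central finite
#' difference (the simulation engine always uses analytic per-cohort
#' derivatives; the finite-difference path is for checking).
#'
#' @param w function of `(lambda1, lambda2)` returning energy per unit
#'   reference area, J/m^2.
#' @param lambda1,lambda2 evaluation point.
#' @param grad optional function returning
#'   `c(dw/dlambda1, dw/dlambda2)`.
#' @param step finite-difference step (absolute).
#' @return named numeric `c(T11, T22)`, N/m.
#' @export
membrane_stress <- function(w, lambda1, lambda2, grad = NULL,
                            step = 1e-6) {
  if (!is.null(grad)) {
    g <- grad(lambda1, lambda2)
  } else {
    g <- c((w(lambda1 + step, lambda2) - w(lambda1 - step, lambda2)) /
             (2 * step),
           (w(lambda1, lambda2 + step) - w(lambda1, lambda2 - step)) /
             (2 * step))
  }
  c(T11 = g[[1]] / lambda2, T22 = g[[2]] / lambda1)
}

#' Cauchy stresses of the thin wall
#'
#' @param T11,T22 passive membrane stresses, N/m.
#' @param T_act active circumferential membrane stress, N/m.
#' @param h current wall thickness, m.
#' @return named numeric `c(sigma1, sigma2)`, kPa.
#' @examples
#' # Laplace: P = 13.6 kPa, r_i = 306.8 um, h = 21.2 um
#' cauchy_stresses(0, 13.6e3 * 306.8e-6, 0, 21.2e-6)["sigma2"]
#' @export
cauchy_stresses <- function(T11, T22, T_act, h) {
  if (any(h <= 0)) stop("thickness must be positive", call. = FALSE)
  c(sigma1 = T11 / h / 1000, sigma2 = (T22 + T_act) / h / 1000)
}

#' Normalized wall shear stress
#'
#' With Poiseuille flow, `tau_w = 4 mu Q / (pi r_i^3)`, so the shear
#' normalized by its homeostatic value needs neither the viscosity nor the
#' absolute flow: `tau_w/tau_wh = eps / (r_i/r_ih)^3` where `eps = Q/Q_h`.
#'
#' @param eps normalized flow `Q/Q_h`.
#' @param r_i_ratio normalized inner radius `r_i/r_ih` (> 0).
#' @return shear ratio `tau_w / tau_wh`.
#' @examples
#' normalized_wall_shear(0.7, 0.7^(1/3)) # cube-root law closes the loop
#' @export
normalized_wall_shear <- function(eps, r_i_ratio) {
  if (any(r_i_ratio <= 0))
    stop("radius ratio must be positive", call. = FALSE)
  eps / r_i_ratio^3
}
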