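# Constrained-mixture time-marching core. State per constituent is a
# cohort table over deposition times tau (uniform spacing dt): production
# rate at deposition, survival fraction, and the fiber (or
# circumferential) stretch at deposition. The infinite homeostatic
# pre-history (tau < 0) is collapsed analytically into a single
# closed-form term: all pre-history cohorts share the reference deposition
# state, their pre-perturbation deaths integrate to
# B(t) = (m_h/mu2h)(1 - exp(-mu2h (a_max - t))), and their survival along
# the perturbed path is tracked as one multiplier Q0 per constituent.
# Axial stretch is held at 1 throughout growth and remodeling.

#' Tension-dependent removal rate of mature collagen
#'
#' @param zeta cohort fiber-tension ratio (1 at the deposition stretch).
#' @param K_mu1 baseline removal rate, 1/day.
#' @param K_mu2 tension sensitivity, 1/day.
#' @param zeta_c homeostatic tension ratio.
#' @return removal rate `K_mu1 + K_mu2 (zeta - zeta_c)^2`, 1/day.
#' @export
degradation_rate <- function(zeta, K_mu1, K_mu2, zeta_c = 1) {
  K_mu1 + K_mu2 * (zeta - zeta_c)^2
}

#' Fiber tension ratio of a cohort
#'
#' Ratio of the fiber-stress derivative of the energy at the cohort's
#' current stretch to its value at the deposition stretch; equals 1 for a
#' cohort sitting exactly at its deposition stretch.
#'
#' @param lambda_n current cohort stretch.
#' @param G_h deposition stretch.
#' @param dpsi derivative of the per-mass fiber energy, a function of
#'   stretch (e.g. a wrapper of [dpsi_collagen()]).
#' @return tension ratio (dimensionless).
#' @export
fiber_tension_ratio <- function(lambda_n, G_h, dpsi) {
  denom <- dpsi(G_h)
  if (abs(denom) < .Machine$double.eps)
    stop("fiber energy derivative vanishes at the deposition stretch; ",
         "G_h = 1 is not an admissible configuration", call. = FALSE)
  dpsi(lambda_n) / denom
}

#' Update a cohort survival fraction over one step
#'
#' Incremental form of the exponential survival function with the
#' cohort-specific current removal rate.
#'
#' @param q survival fraction in `[0, 1]`.
#' @param mu2_now current removal rate, 1/day.
#' @param dt step, day.
#' @return updated survival fraction.
#' @export
survival_update <- function(q, mu2_now, dt) {
  q * exp(-mu2_now * dt)
}

#' Heredity integrals over a cohort table
#'
#' Trapezoidal quadrature of `m_R(tau) q(t, tau) psi(tau) dtau` over a
#' uniform deposition-time grid. With `psi = 1` this is the surviving mass
#' (per reference area); with `psi` the per-mass strain energies of the
#' cohorts it is the constituent strain energy per reference area.
#'
#' @param tau deposition times, uniformly spaced, day.
#' @param m_R production rates at deposition, kg/m^2/day.
#' @param q survival fractions.
#' @param psi per-mass weights (default 1), J/kg for energies.
#' @return the integral (kg/m^2, or J/m^2 when `psi` is an energy).
#' @export
heredity_integral <- function(tau, m_R, q, psi = 1) {
  n <- length(tau)
  stopifnot(length(m_R) == n, length(q) == n)
  if (n < 2) return(0)
  v <- m_R * q * psi
  dt <- diff(tau)
  sum((v[-1] + v[-n]) / 2 * dt)
}

# ---------------------------------------------------------------------
# model assembly: SI conversion, homeostatic closed forms, anchors
# ---------------------------------------------------------------------

#' @keywords internal
assemble_model <- function(params) {
  w <- params$wall; k <- params$kinetics
  tn <- params$tone; g <- params$gains; nm <- params$numerics

  m <- list()
  m$rho <- w$rho_wall
  m$phi_f <- w$phi_f
  # effective solid mass fraction; the printed family fractions sum to
  # 0.299985 rather than 1 - phi_f = 0.30, so the thickness conversion
  # uses the actual solid fraction to keep h(0) = h_h exactly
  m$solid <- w$phi0_e + w$phi0_m + sum(w$phi0_k)
  m$h_h <- w$h_h_um * 1e-6
  m$r_oh <- w$r_oh_mm * 1e-3
  m$r_h <- m$r_oh - m$h_h / 2
  m$r_ih <- m$r_oh - m$h_h
  m$P_h <- w$P_h_mmHg * .MMHG_TO_PA

  ang <- c(0, 90, w$alpha_h_deg, -w$alpha_h_deg) * pi / 180
  m$cosA <- cos(ang); m$sinA <- sin(ang)
  m$cos2 <- m$cosA^2; m$sin2 <- m$sinA^2

  m$G_hc <- w$G_hc; m$G_hm <- w$G_hm
  m$G1e <- w$G1e; m$G2e <- w$G2e
  m$c1e <- w$c1e; m$c2c <- w$c2c; m$c3c <- w$c3c
  m$c1m <- w$c1m; m$c2m <- w$c2m; m$c3m <- w$c3m
  m$compression_zero <- identical(w$collagen_compression, "zero")

  m$M0k <- w$phi0_k * m$rho * m$h_h
  m$M0m <- w$phi0_m * m$rho * m$h_h
  m$M0e <- w$phi0_e * m$rho * m$h_h
  m$M0c <- sum(m$M0k)
  m$M0tot <- m$M0c + m$M0m + m$M0e

  # kinetics / turnover baselines. The removal rate of mature collagen at
  # homeostasis is K_mu1 (zeta = zeta_c); the finite cohort window a_max
  # truncates the homeostatic heredity integral by 1 - exp(-mu2 a_max),
  # so the baseline production is scaled up by the inverse factor to make
  # the discretized homeostatic state an exact fixed point.
  m$beta1 <- k$beta1; m$beta2 <- k$beta2
  m$mu1 <- k$mu1; m$MW <- k$MW; m$a_max <- k$a_max
  m$mu2c_h <- g$K_mu1
  m$mu2m <- g$K_mu1
  trunc_c <- 1 - exp(-m$mu2c_h * m$a_max)
  trunc_m <- 1 - exp(-m$mu2m * m$a_max)
  m$m_hk <- m$mu2c_h * m$M0k / trunc_c
  m$m_hm <- m$mu2m * m$M0m / trunc_m
  m$C0k <- m$m_hk / (m$beta2 * m$MW)
  m$mp0k <- (m$beta2 + m$mu1) / (m$beta1 * m$beta2) * m$m_hk

  m$gains <- g
  m$tone <- tn
  m$numerics <- nm

  # homeostatic passive membrane stress (all cohorts at their deposition
  # stretch, lambda1 = lambda2 = 1)
  dpsiG <- dpsi_collagen(m$G_hc, m$c2c, m$c3c)
  m$dpsiG <- dpsiG
  T22c0k <- m$M0k * dpsiG * m$G_hc * m$sin2
  T11c0k <- m$M0k * dpsiG * m$G_hc * m$cos2
  T22m0 <- m$M0m * dpsi_smc_d2(1, m$G_hm, m$c1m, m$c2m, m$c3m) * m$G_hm
  T11m0 <- m$M0m * dpsi_smc_d1(1, m$G_hm, m$c1m, m$c2m, m$c3m)
  T22e0 <- m$M0e * dpsi_elastin_d2(m$G1e, m$G2e, m$c1e) * m$G2e
  T11e0 <- m$M0e * dpsi_elastin_d1(m$G1e, m$G2e, m$c1e) * m$G1e
  m$T22p0 <- sum(T22c0k) + T22m0 + T22e0
  m$T11p0 <- sum(T11c0k) + T11m0 + T11e0
  m$T22m0 <- T22m0

  # collagen scalar stress anchors (kPa); these come out within ~0.3% of
  # the calibrated homeostatic intramural stress sigma_h
  hc0 <- m$M0c / (m$solid * m$rho)
  m$hc0 <- hc0
  Tc11 <- sum(T11c0k); Tc22 <- sum(T22c0k)
  m$sig_kh <- sqrt((Tc11 * m$cosA)^2 + (Tc22 * m$sinA)^2) / hc0 / 1000

  # close the homeostatic equilibrium: the printed constants are rounded,
  # so the basal tone is rescaled (balance = "s_basal") to carry exactly
  # the residual load at (P_h, lambda = 1)
  m$f1h <- length_tension(1, tn)
  r_eq0 <- if (nm$equilibrium_radius == "inner") m$r_ih else m$r_h
  m$r_eq0 <- r_eq0
  base <- 2 * (1 + tanh(-tn$tone_offset)) * m$f1h
  m$S_basal <- tn$S_basal
  m$balance_factor <- 1
  if (nm$balance == "c1e") {
    # rescale the elastin stiffness so the passive wall plus the printed
    # basal tone carry exactly the homeostatic load
    T_req_e <- m$P_h * r_eq0 - (sum(T22c0k) + T22m0) -
      tn$S_basal * base
    if (T_req_e <= 0)
      stop("collagen and muscle alone overcarry the homeostatic load; ",
           "cannot balance through the elastin stiffness", call. = FALSE)
    m$balance_factor <- T_req_e / T22e0
    m$c1e <- m$c1e * m$balance_factor
    T22e0 <- T22e0 * m$balance_factor
    T11e0 <- T11e0 * m$balance_factor
    m$T22p0 <- sum(T22c0k) + T22m0 + T22e0
    m$T11p0 <- sum(T11c0k) + T11m0 + T11e0
  } else if (nm$balance == "s_basal") {
    T_req <- m$P_h * r_eq0 - m$T22p0
    if (T_req <= 0)
      stop("passive wall overcarries the homeostatic load; cannot ",
           "balance with non-negative tone", call. = FALSE)
    m$S_basal <- T_req / base
    m$balance_factor <- m$S_basal / tn$S_basal
  }
  m$tone_eff <- tn
  m$tone_eff$S_basal <- m$S_basal
  m$S0 <- 2 * m$S_basal * (1 + tanh(-tn$tone_offset))
  m$Tact0 <- m$S0 * m$f1h

  # total circumferential Cauchy stress at homeostasis (stimulus anchor
  # for the "total_hoop" collagen production stimulus)
  m$sigma2_h <- (m$T22p0 + m$Tact0) / m$h_h / 1000

  # smooth muscle stress anchor, per the chosen convention
  hm0 <- m$M0m / (m$solid * m$rho)
  m$hm0 <- hm0
  T22_for_m <- if (nm$sigma_m_stress == "smc") T22m0 else m$T22p0
  m$sigma_mh <- (T22_for_m + m$Tact0) / hm0 / 1000

  m$params <- params
  m
}

# collagen fiber-stress derivative used in hot loops: exp argument is
# clamped (not an error) so that wild Newton trial radii produce a huge
# restoring stress instead of an overflow
.dpsi_col_fast <- function(ln, c2c, c3c, compression_zero) {
  q <- ln * ln - 1
  d <- c2c * ln * q * exp(pmin(c3c * q * q, 700))
  if (compression_zero) d[ln < 1] <- 0
  d
}

.dpsi_smc2_fast <- function(ln2, c1m, c2m, c3m) {
  q <- ln2 * ln2 - 1
  c1m * (ln2 - 1 / ln2^3) + c2m * ln2 * q * exp(pmin(c3m * q * q, 700))
}

# Passive membrane stresses at axial stretch 1 and circumferential
# stretch l2, from a state snapshot (per-family quadrature weights wq =
# trapezoid x m x q with the pre-history term appended, and the inverse
# deposition stretches). Returns T11, T22 totals and the collagen parts.
.passive_T <- function(mod, snap, l2) {
  T11c <- 0; T22c <- 0
  for (kf in 1:4) {
    lk <- sqrt(mod$cos2[kf] + l2 * l2 * mod$sin2[kf])
    ln <- (mod$G_hc * lk) * snap$invdep[[kf]]
    d <- .dpsi_col_fast(ln, mod$c2c, mod$c3c, mod$compression_zero)
    s <- sum(snap$wq[[kf]] * d * snap$invdep[[kf]])
    T22c <- T22c + mod$G_hc * l2 * mod$sin2[kf] / lk * s
    T11c <- T11c + mod$G_hc * mod$cos2[kf] / (lk * l2) * s
  }
  ln2 <- (mod$G_hm * l2) * snap$invdep_m
  d2 <- .dpsi_smc2_fast(ln2, mod$c1m, mod$c2m, mod$c3m)
  T22m <- sum(snap$wq_m * d2 * snap$invdep_m) * mod$G_hm
  d1 <- mod$c1m * (1 - 1 / ln2^2)        # lambda_n1 = 1 for all cohorts
  T11m <- sum(snap$wq_m * d1) / l2
  le2 <- mod$G2e * l2
  T22e <- mod$M0e * dpsi_elastin_d2(mod$G1e, le2, mod$c1e) * mod$G2e
  T11e <- mod$M0e * dpsi_elastin_d1(mod$G1e, le2, mod$c1e) * mod$G1e / l2
  list(T11 = T11c + T11m + T11e, T22 = T22c + T22m + T22e,
       T11c = T11c, T22c = T22c, T22m = T22m)
}

# equilibrium residual factory; S responds instantaneously to the shear
# implied by the trial radius, r_act and all histories are frozen
.residual_factory <- function(mod, snap) {
  tn <- mod$tone_eff
  inner <- mod$numerics$equilibrium_radius == "inner"
  force(snap)
  function(r) {
    l2 <- r / mod$r_h
    if (l2 <= 0) return(NaN)
    T22p <- .passive_T(mod, snap, l2)$T22
    h <- snap$Mtot / ((mod$solid * mod$rho) * l2)
    ri <- r - h / 2
    if (ri <= 0) return(NaN)
    taur <- snap$eps * (mod$r_ih / ri)^3
    S <- 2 * mod$S_basal * snap$mr_m *
      (1 + tanh(-tn$k_ton * (taur - 1) - tn$tone_offset))
    l2a <- r / snap$r_act
    fl <- max(0, 1 - ((tn$lambda_M - l2a) /
                        (tn$lambda_M - tn$lambda_0))^2)
    r_eq <- if (inner) ri else r
    T22p + S * l2a * fl - snap$P * r_eq
  }
}

# Newton with numerical Jacobian, bisection fallback on [0.5, 2] x r0
.solve_radius <- function(mod, snap, r0) {
  res <- .residual_factory(mod, snap)
  tol <- mod$numerics$newton_tol * mod$P_h * mod$r_h
  fd <- mod$numerics$fd_step * mod$r_h
  r <- r0
  for (it in seq_len(mod$numerics$newton_max_iter)) {
    f <- res(r)
    if (is.finite(f) && abs(f) < tol)
      return(list(r = r, resid = f, iter = it))
    fp <- (res(r + fd) - res(r - fd)) / (2 * fd)
    dr <- -f / fp
    if (!is.finite(dr) || abs(dr) > 0.25 * r) { r <- NA_real_; break }
    r <- r + dr
  }
  lo <- 0.5 * r0; hi <- 2 * r0
  flo <- res(lo); fhi <- res(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    return(NULL)
  u <- stats::uniroot(res, c(lo, hi), tol = 1e-15 * r0)
  f <- res(u$root)
  if (abs(f) >= tol) return(NULL)
  list(r = u$root, resid = f, iter = mod$numerics$newton_max_iter)
}

# pre-history age integral (deaths before t = 0 at the homeostatic rate,
# cohorts older than a_max excluded)
.prehistory_base <- function(m_h, mu2h, a_max, t) {
  if (t >= a_max) return(m_h * 0)
  m_h / mu2h * (1 - exp(-mu2h * (a_max - t)))
}

# ---------------------------------------------------------------------
# main time-marching loop
# ---------------------------------------------------------------------

#' Simulate arterial growth and remodeling
#'
#' Marches the coupled biochemomechanical model in time for a given
#' perturbation scenario of normalized pressure `gamma(t) = P/P_h` and
#' flow `eps(t) = Q/Q_h`. Each step solves circumferential equilibrium
#' for the mean radius (Newton iteration), relaxes the active reference
#' radius, evaluates the stress and shear stimuli, advances the
#' procollagen/intermediate/mature turnover chain and the smooth muscle
#' turnover, updates all cohort survival fractions with their
#' tension-dependent removal rates, and deposits a new cohort at the
#' current configuration.
#'
#' @param scenario a [build_scenario()] object (or a name understood by
#'   [build_scenario()], e.g. `"step_flow_0.7"`).
#' @param params a [gr_params()] parameter set.
#' @param dt time step, day (defaults from `params$numerics`).
#' @param duration simulated time, day.
#' @param output_interval spacing of stored output rows, day.
#' @param keep_state if `TRUE`, attach the final cohort tables (useful
#'   for diagnostics and cross-checking the heredity integrals).
#' @return An object of class `gr_sim` with elements `series` (data frame
#'   of the time courses), `model` (homeostatic anchors), `params`,
#'   `scenario`, and `diagnostics`.
#' @examples
#' \donttest{
#' sim <- simulate_gr("step_flow_0.7", gr_params(), duration = 60)
#' tail(sim$series[, c("t_day", "r_i_mm", "h_um", "tau_ratio")], 3)
#' }
#' @export
simulate_gr <- function(scenario, params = gr_params(),
                        dt = params$numerics$dt,
                        duration = params$numerics$duration,
                        output_interval = params$numerics$output_interval,
                        keep_state = FALSE) {
  if (is.character(scenario))
    scenario <- build_scenario(scenario, duration = duration)
  stopifnot(inherits(scenario, "gr_scenario"))
  if (dt <= 0 || duration <= 0) stop("dt and duration must be positive")

  mod <- assemble_model(params)
  g <- mod$gains; tn <- mod$tone_eff
  n_steps <- as.integer(round(duration / dt))
  n_amax <- as.integer(floor(mod$a_max / dt + 1e-9))
  cap <- min(n_steps, n_amax) + 1L

  # cohort tables; row 1 is the tau = 0 cohort carrying the homeostatic
  # production rate
  Mc <- matrix(0, cap, 4); Qc <- matrix(0, cap, 4); Lc <- matrix(1, cap, 4)
  Mc[1, ] <- mod$m_hk; Qc[1, ] <- 1
  mm <- numeric(cap); qm <- numeric(cap); lm <- numeric(cap)
  mm[1] <- mod$m_hm; qm[1] <- 1; lm[1] <- 1
  n <- 1L
  tau0 <- 0           # deposition time of row 1
  Q0c <- rep(1, 4)    # pre-history survival multipliers since t = 0
  Q0m <- 1
  C_IR <- mod$C0k

  r <- mod$r_h; r_act <- mod$r_h
  M_k <- mod$M0k; M_c <- mod$M0c; M_m <- mod$M0m
  Mtot <- mod$M0tot

  out_every <- max(1L, as.integer(round(output_interval / dt)))
  n_out <- n_steps %/% out_every + 1L
  cols <- c("t_day", "r_mm", "r_i_mm", "h_um", "lambda2", "lambda2_act",
            "r_act_mm", "tau_ratio", "sigma1_kPa", "sigma2_kPa",
            "sigma_m_kPa", "sigk1_ratio", "sigk2_ratio", "sigk3_ratio",
            "sigk4_ratio", "M_Rc_ratio", "M_Rm_ratio", "S_Npm",
            "T_act_Npm", "C_IR_total")
  out <- matrix(NA_real_, n_out, length(cols),
                dimnames = list(NULL, cols))
  out[1, ] <- c(0, mod$r_h * 1e3, mod$r_ih * 1e3, mod$h_h * 1e6, 1, 1,
                mod$r_h * 1e3, 1, mod$T11p0 / mod$h_h / 1000,
                (mod$T22p0 + mod$Tact0) / mod$h_h / 1000, mod$sigma_mh,
                1, 1, 1, 1, 1, 1, mod$S0, mod$Tact0, sum(C_IR))
  iout <- 1L

  max_resid <- 0; n_clamped <- 0L; tot_iter <- 0L
  trapw <- function(nn) {
    if (nn == 1L) return(0)
    w <- rep(dt, nn); w[c(1L, nn)] <- dt / 2; w
  }

  for (istep in seq_len(n_steps)) {
    t1 <- istep * dt
    P <- scenario$gamma(t1) * mod$P_h
    eps_t <- scenario$eps(t1)
    if (!is.finite(P) || P <= 0 || !is.finite(eps_t) || eps_t <= 0)
      stop(sprintf("scenario returned non-positive gamma/eps at t = %g",
                   t1))

    # --- snapshot of the heredity state for the equilibrium solve ---
    tw <- trapw(n)
    idx <- seq_len(n)
    Bc <- .prehistory_base(mod$m_hk, mod$mu2c_h, mod$a_max, t1 - dt)
    Bm <- .prehistory_base(mod$m_hm, mod$mu2m, mod$a_max, t1 - dt)
    wq <- vector("list", 4); invdep <- vector("list", 4)
    for (kf in 1:4) {
      wq[[kf]] <- c(tw * Mc[idx, kf] * Qc[idx, kf], Bc[kf] * Q0c[kf])
      invdep[[kf]] <- c(1 / Lc[idx, kf], 1)
    }
    snap <- list(wq = wq, invdep = invdep,
                 wq_m = c(tw * mm[idx] * qm[idx], Bm * Q0m),
                 invdep_m = c(1 / lm[idx], 1),
                 Mtot = Mtot, mr_m = M_m / mod$M0m, r_act = r_act,
                 P = P, eps = eps_t)

    sol <- .solve_radius(mod, snap, r)
    if (is.null(sol)) {
      dump <- file.path(tempdir(),
                        sprintf("gr_checkpoint_t%.3f.csv", t1))
      utils::write.csv(as.data.frame(out[seq_len(iout), , drop = FALSE]),
                       dump, row.names = FALSE)
      stop(sprintf(paste0("equilibrium solver failed at step %d ",
                          "(t = %.3f day); trajectory dumped to %s"),
                   istep, t1, dump), call. = FALSE)
    }
    r <- sol$r
    max_resid <- max(max_resid, abs(sol$resid))
    tot_iter <- tot_iter + sol$iter

    # --- active reference radius relaxes toward the solved radius ---
    r_act <- update_active_radius(r_act, r, tn$K_act, dt)

    # --- stimuli at the new configuration ---
    l2 <- r / mod$r_h
    Tp <- .passive_T(mod, snap, l2)
    h <- Mtot / ((mod$solid * mod$rho) * l2)
    ri <- r - h / 2
    taur <- eps_t * (mod$r_ih / ri)^3
    S <- tone_magnitude(M_m / mod$M0m, taur, tn)
    l2a <- r / r_act
    T_act <- active_membrane_stress(S, l2a, tn)

    lam_k <- sqrt(mod$cos2 + l2 * l2 * mod$sin2)
    h_c <- M_c / ((mod$solid * mod$rho) * l2)
    sig_k <- sqrt((Tp$T11c * mod$cosA)^2 +
                    (Tp$T22c * l2 * mod$sinA)^2) / lam_k / h_c / 1000
    sig_k_ratio <- sig_k / mod$sig_kh
    T22_for_m <- if (mod$numerics$sigma_m_stress == "smc")
      Tp$T22m else Tp$T22
    h_m <- M_m / ((mod$solid * mod$rho) * l2)
    sigma_m <- (T22_for_m + T_act) / h_m / 1000
    sigma_m_ratio <- sigma_m / mod$sigma_mh

    # --- production (clamped at zero) and turnover chain ---
    stim_c <- if (mod$numerics$sigma_c_stimulus == "fiber") sig_k_ratio
    else ((Tp$T22 + T_act) / h / 1000) / mod$sigma2_h
    raw_c <- (M_c / mod$M0c) * mod$mp0k *
      (1 + g$K_sigma_c * (stim_c - 1) - g$K_tau_c * (taur - 1))
    raw_m <- (M_m / mod$M0m) * mod$m_hm *
      (1 + g$K_sigma_m * (sigma_m_ratio - 1) - g$K_tau_m * (taur - 1))
    if (any(raw_c < 0) || raw_m < 0) n_clamped <- n_clamped + 1L
    m_p <- pmax(0, raw_c)
    m_Rm_new <- max(0, raw_m)
    C_IR <- step_intermediate(C_IR, m_p, mod$params$kinetics, dt)
    m_R_new <- maturation_rate(C_IR, mod$beta2, mod$MW)

    # --- survival updates with cohort-specific removal rates ---
    for (kf in 1:4) {
      ln <- mod$G_hc * lam_k[kf] / Lc[idx, kf]
      zeta <- .dpsi_col_fast(ln, mod$c2c, mod$c3c,
                             mod$compression_zero) / mod$dpsiG
      mu2 <- degradation_rate(zeta, g$K_mu1, g$K_mu2, g$zeta_c)
      Qc[idx, kf] <- Qc[idx, kf] * exp(-mu2 * dt)
      ln_pre <- mod$G_hc * lam_k[kf]
      zeta_pre <- .dpsi_col_fast(ln_pre, mod$c2c, mod$c3c,
                                 mod$compression_zero) / mod$dpsiG
      Q0c[kf] <- Q0c[kf] *
        exp(-degradation_rate(zeta_pre, g$K_mu1, g$K_mu2, g$zeta_c) * dt)
    }
    qm[idx] <- qm[idx] * exp(-mod$mu2m * dt)
    Q0m <- Q0m * exp(-mod$mu2m * dt)

    # --- deposit the new cohort; drop cohorts older than a_max ---
    if (n == cap) {
      keep <- 2:cap
      Mc[seq_len(cap - 1L), ] <- Mc[keep, ]
      Qc[seq_len(cap - 1L), ] <- Qc[keep, ]
      Lc[seq_len(cap - 1L), ] <- Lc[keep, ]
      mm[seq_len(cap - 1L)] <- mm[keep]
      qm[seq_len(cap - 1L)] <- qm[keep]
      lm[seq_len(cap - 1L)] <- lm[keep]
      n <- cap - 1L
      tau0 <- tau0 + dt
    }
    n <- n + 1L
    Mc[n, ] <- m_R_new; Qc[n, ] <- 1; Lc[n, ] <- lam_k
    mm[n] <- m_Rm_new; qm[n] <- 1; lm[n] <- l2

    # --- masses and geometry after turnover ---
    tw <- trapw(n)
    idx <- seq_len(n)
    Bc <- .prehistory_base(mod$m_hk, mod$mu2c_h, mod$a_max, t1)
    Bm <- .prehistory_base(mod$m_hm, mod$mu2m, mod$a_max, t1)
    M_k <- colSums(tw * Mc[idx, , drop = FALSE] *
                     Qc[idx, , drop = FALSE]) + Bc * Q0c
    M_c <- sum(M_k)
    M_m <- sum(tw * mm[idx] * qm[idx]) + Bm * Q0m
    Mtot <- M_c + M_m + mod$M0e
    h <- Mtot / ((mod$solid * mod$rho) * l2)
    ri <- r - h / 2

    if (istep %% out_every == 0L) {
      iout <- iout + 1L
      taur_out <- eps_t * (mod$r_ih / ri)^3
      out[iout, ] <- c(t1, r * 1e3, ri * 1e3, h * 1e6, l2, l2a,
                       r_act * 1e3, taur_out,
                       Tp$T11 / h / 1000, (Tp$T22 + T_act) / h / 1000,
                       sigma_m, sig_k_ratio,
                       M_c / mod$M0c, M_m / mod$M0m, S, T_act,
                       sum(C_IR))
    }
  }

  series <- as.data.frame(out[seq_len(iout), , drop = FALSE])
  res <- list(series = series,
              model = list(r_h_mm = mod$r_h * 1e3,
                           r_ih_mm = mod$r_ih * 1e3,
                           h_h_um = mod$h_h * 1e6,
                           P_h_Pa = mod$P_h,
                           sig_kh_kPa = mod$sig_kh,
                           sigma_mh_kPa = mod$sigma_mh,
                           S_basal_eff = mod$S_basal,
                           balance_factor = mod$balance_factor,
                           T22p0 = mod$T22p0, Tact0 = mod$Tact0,
                           M0k = mod$M0k, M0m = mod$M0m, M0e = mod$M0e,
                           solid_frac = mod$solid),
              params = params, scenario = scenario,
              dt = dt, duration = duration,
              diagnostics = list(max_resid_Npm = max_resid,
                                 resid_tol_Npm =
                                   params$numerics$newton_tol *
                                   mod$P_h * mod$r_h,
                                 n_clamped_steps = n_clamped,
                                 newton_iter_total = tot_iter))
  if (keep_state) {
    idx <- seq_len(n)
    res$state <- list(tau = tau0 + (idx - 1L) * dt,
                      Mc = Mc[idx, , drop = FALSE],
                      Qc = Qc[idx, , drop = FALSE],
                      Lc = Lc[idx, , drop = FALSE],
                      mm = mm[idx], qm = qm[idx], lm = lm[idx],
                      Q0c = Q0c, Q0m = Q0m, C_IR = C_IR,
                      r = r, r_act = r_act,
                      M_k = M_k, M_m = M_m, Mtot = Mtot)
  }
  class(res) <- "gr_sim"
  res
}

#' @export
print.gr_sim <- function(x, ...) {
  s <- x$series
  last <- s[nrow(s), ]
  cat(sprintf("Growth-and-remodeling simulation: '%s', %g days, dt = %g day\n",
              x$scenario$name, x$duration, x$dt))
  cat(sprintf("  final: r_i/r_ih = %.4f, h/h_h = %.4f, tau/tau_h = %.4f\n",
              last$r_i_mm / x$model$r_ih_mm,
              last$h_um / x$model$h_h_um, last$tau_ratio))
  cat(sprintf("  final masses: collagen x%.3f, muscle x%.3f\n",
              last$M_Rc_ratio, last$M_Rm_ratio))
  cat(sprintf("  basal tone rebalanced by factor %.3f; max |equilibrium residual| %.2e N/m\n",
              x$model$balance_factor, x$diagnostics$max_resid_Npm))
  if (x$diagnostics$n_clamped_steps > 0)
    cat(sprintf("  production clamped at zero in %d steps\n",
                x$diagnostics$n_clamped_steps))
  invisible(x)
}

# ---------------------------------------------------------------------
# active stress-stretch diagnostic
# ---------------------------------------------------------------------

#' Active stress-stretch diagnostic curve
#'
#' Sweeps the circumferential stretch at a chosen simulation day, with the
#' tone magnitude and the active reference radius frozen at their values
#' on that day, and evaluates the active Cauchy stress
#' `sigma_act = T_act / h_m`. This is a post-processing diagnostic (the
#' wall is not actually deformed), used to locate the peak of the active
#' response as remodeling progresses.
#'
#' @param sim a `gr_sim` object.
#' @param day simulation day at which to take the tone state.
#' @param lambda2 circumferential stretch grid.
#' @return data frame with `lambda2`, `lambda2_act`, `sigma_act_kPa`.
#' @export
active_stress_curve <- function(sim, day,
                                lambda2 = seq(0.65, 3, by = 0.01)) {
  stopifnot(inherits(sim, "gr_sim"))
  s <- sim$series
  i <- which.min(abs(s$t_day - day))
  tn <- sim$params$tone
  w <- sim$params$wall
  r_h <- sim$model$r_h_mm
  l2a <- lambda2 * r_h / s$r_act_mm[i]
  f <- length_tension(pmax(l2a, .Machine$double.eps), tn)
  M_m <- sim$model$M0m * s$M_Rm_ratio[i]
  sig <- s$S_Npm[i] * l2a * f *
    sim$model$solid_frac * w$rho_wall * lambda2 / M_m / 1000
  data.frame(lambda2 = lambda2, lambda2_act = l2a, sigma_act_kPa = sig,
             t_day = s$t_day[i])
}

#' Peak of the active stress-stretch diagnostic
#'
#' @inheritParams active_stress_curve
#' @return list with `lambda2_peak`, `sigma_peak_kPa`, and the actual
#'   `day` used.
#' @export
peak_active_stress <- function(sim, day,
                               lambda2 = seq(0.65, 3, by = 0.01)) {
  cur <- active_stress_curve(sim, day, lambda2)
  i <- which.max(cur$sigma_act_kPa)
  list(lambda2_peak = cur$lambda2[i],
       sigma_peak_kPa = cur$sigma_act_kPa[i],
       day = cur$t_day[1])
}
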