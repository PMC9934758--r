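# Constrained-mixture engine: survival/degradation, heredity integrals,
# equilibrium solve, fixed point, refinement, radius adaptation.

test_that("degradation rate: baseline at homeostatic tension, quadratic above", {
  expect_equal(degradation_rate(1, 0.01, 0.01, 1), 0.01)
  expect_equal(degradation_rate(2, 0.01, 0.01, 1), 0.02)
  z <- seq(-1, 3, by = 0.1)
  expect_true(all(degradation_rate(z, 0.01, 0.01, 1) >= 0.01))
})

test_that("fiber tension ratio: unity at deposition stretch, monotone, FD-consistent", {
  dpsi <- function(l) dpsi_collagen(l, 3090, 18.9)
  expect_equal(fiber_tension_ratio(1.07, 1.07, dpsi), 1)
  l <- seq(1.0, 1.25, by = 0.01)
  expect_true(all(diff(fiber_tension_ratio(l, 1.07, dpsi)) > 0))
  # derivative function cross-checked against FD of the energy
  expect_equal(dpsi(1.12),
               fd_deriv(function(x) psi_collagen(x, 3090, 18.9), 1.12),
               tolerance = 1e-6)
  expect_error(fiber_tension_ratio(1.1, 1, dpsi), "G_h = 1")
})

test_that("survival fractions decay exponentially at the removal rate", {
  expect_equal(survival_update(1, 0.01, log(2) / 0.01), 0.5)
  expect_equal(survival_update(1, 0.01, 350), exp(-3.5))
  expect_equal(exp(-3.5), 0.0302, tolerance = 1e-4)
  # incremental updates compose
  q <- 1
  for (i in 1:70) q <- survival_update(q, 0.01, 0.99)
  expect_equal(q, exp(-0.01 * 70 * 0.99))
})

test_that("heredity integral reproduces closed forms on exponential histories", {
  # constant production with constant removal: M = m_h (1 - e^(-mu t))/mu
  tau <- seq(0, 200, by = 0.1)
  m_h <- 3e-5; mu <- 0.01
  q <- exp(-mu * (200 - tau))
  expect_equal(heredity_integral(tau, rep(m_h, length(tau)), q),
               m_h * (1 - exp(-mu * 200)) / mu, tolerance = 1e-7)
  # energy weighting is linear: psi scales the integral
  expect_equal(heredity_integral(tau, rep(m_h, length(tau)), q, psi = 19.9),
               19.9 * heredity_integral(tau, rep(m_h, length(tau)), q))
  expect_equal(heredity_integral(0, m_h, 1), 0)  # single cohort: no width
})

test_that("unperturbed simulation is an exact homeostatic fixed point over 300 days", {
  sim <- sim_cache("homeo300", simulate_gr("constant", mouse_params(),
                                           duration = 300))
  s <- sim$series
  drift <- max(abs(s$r_i_mm / sim$model$r_ih_mm - 1),
               abs(s$h_um / sim$model$h_h_um - 1),
               abs(s$lambda2 - 1), abs(s$tau_ratio - 1),
               abs(s$M_Rc_ratio - 1), abs(s$M_Rm_ratio - 1),
               abs(s$sigma2_kPa / s$sigma2_kPa[1] - 1),
               abs(s$S_Npm / s$S_Npm[1] - 1),
               abs(s$C_IR_total / s$C_IR_total[1] - 1))
  expect_lt(drift, 1e-6)
})

test_that("equilibrium residual stays below tolerance at every step", {
  sim <- sim_cache("flow07_K2",
                   simulate_gr("step_flow_0.7", mouse_params(),
                               duration = 300, keep_state = TRUE))
  expect_lt(sim$diagnostics$max_resid_Npm, sim$diagnostics$resid_tol_Npm)
})

test_that("homeostatic strain energy equals mass times energy at deposition stretch", {
  sim <- sim_cache("homeo30",
                   simulate_gr("constant", mouse_params(), duration = 30,
                               keep_state = TRUE))
  st <- sim$state
  mod <- vasoadapt:::assemble_model(sim$params)
  psiG <- psi_collagen(mod$G_hc, mod$c2c, mod$c3c)
  for (k in 1:4) {
    w_k <- heredity_integral(st$tau, st$Mc[, k], st$Qc[, k], psiG) +
      vasoadapt:::.prehistory_base(mod$m_hk[k], mod$mu2c_h, mod$a_max, 30) *
        st$Q0c[k] * psiG
    expect_equal(w_k, psiG * st$M_k[k], tolerance = 1e-8)
    expect_equal(st$M_k[k], mod$M0k[k], tolerance = 1e-6)
  }
})

test_that("engine quadrature agrees with a 20x finer re-integration of mass and energy", {
  sim <- sim_cache("flow07_coarse",
                   simulate_gr("step_flow_0.7", mouse_params(), dt = 0.5,
                               duration = 30, keep_state = TRUE))
  st <- sim$state
  mod <- vasoadapt:::assemble_model(sim$params)
  l2 <- st$r / mod$r_h
  fine <- seq(0, 30, by = 0.5 / 20)
  for (k in c(2, 3)) {        # circumferential and diagonal families
    mfun <- stats::splinefun(st$tau, st$Mc[, k])
    qfun <- stats::splinefun(st$tau, log(st$Qc[, k]))
    lfun <- stats::splinefun(st$tau, st$Lc[, k])
    lam_now <- fiber_stretch(1, l2, c(0, 90, 47.6, -47.6)[k])
    # mass, Eq-20 style
    oracle_M <- heredity_integral(fine, mfun(fine), exp(qfun(fine))) +
      vasoadapt:::.prehistory_base(mod$m_hk[k], mod$mu2c_h, mod$a_max, 30) *
        st$Q0c[k]
    expect_equal(st$M_k[k], oracle_M, tolerance = 1e-3)
    # strain energy, Eq-5 style
    psi_now <- function(ldep)
      psi_collagen(mod$G_hc * lam_now / ldep, mod$c2c, mod$c3c)
    w_engine <- heredity_integral(st$tau, st$Mc[, k], st$Qc[, k],
                                  psi_now(st$Lc[, k])) +
      vasoadapt:::.prehistory_base(mod$m_hk[k], mod$mu2c_h, mod$a_max, 30) *
        st$Q0c[k] * psi_now(1)
    w_oracle <- heredity_integral(fine, mfun(fine), exp(qfun(fine)),
                                  psi_now(lfun(fine))) +
      vasoadapt:::.prehistory_base(mod$m_hk[k], mod$mu2c_h, mod$a_max, 30) *
        st$Q0c[k] * psi_now(1)
    expect_equal(w_engine, w_oracle, tolerance = 1e-3)
  }
})

test_that("Newton radius solve matches a dense grid scan on perturbed states", {
  mod <- vasoadapt:::assemble_model(mouse_params())
  base_snap <- function(P_fac, eps, r_act_fac, mass_fac) {
    list(wq = lapply(1:4, function(k) c(0, mass_fac * mod$M0k[k])),
         invdep = lapply(1:4, function(k) c(1, 1)),
         wq_m = c(0, mass_fac * mod$M0m), invdep_m = c(1, 1),
         Mtot = mass_fac * mod$M0tot, mr_m = mass_fac,
         r_act = r_act_fac * mod$r_h, P = P_fac * mod$P_h, eps = eps)
  }
  cases <- list(c(1.5, 1, 1, 1), c(1, 0.7, 0.98, 1.1), c(0.9, 1.2, 1.01, 0.95))
  for (cs in cases) {
    snap <- base_snap(cs[1], cs[2], cs[3], cs[4])
    res <- vasoadapt:::.residual_factory(mod, snap)
    sol <- vasoadapt:::.solve_radius(mod, snap, mod$r_h)
    # brute-force: bracket the sign change on a dense grid, then bisect
    grid <- seq(0.7, 1.4, by = 1e-4) * mod$r_h
    fg <- vapply(grid, res, numeric(1))
    i <- which(diff(sign(fg)) != 0)[1]
    root <- stats::uniroot(res, c(grid[i], grid[i + 1]),
                           tol = 1e-14 * mod$r_h)$root
    expect_equal(sol$r, root, tolerance = 1e-6)
  }
  # homeostatic state returns the homeostatic radius
  snap0 <- base_snap(1, 1, 1, 1)
  sol0 <- vasoadapt:::.solve_radius(mod, snap0, 0.97 * mod$r_h)
  expect_equal(sol0$r, mod$r_h, tolerance = 1e-8)
})

test_that("halving the time step changes the 300-day endpoint by < 0.1%", {
  sim1 <- sim_cache("flow07_K2",
                    simulate_gr("step_flow_0.7", mouse_params(),
                                duration = 300, keep_state = TRUE))
  sim2 <- simulate_gr("step_flow_0.7", mouse_params(), dt = 0.05,
                      duration = 300)
  n1 <- nrow(sim1$series); n2 <- nrow(sim2$series)
  expect_equal(sim1$series$r_i_mm[n1], sim2$series$r_i_mm[n2],
               tolerance = 1e-3)
  expect_equal(sim1$series$h_um[n1], sim2$series$h_um[n2],
               tolerance = 1e-3)
})

test_that("radius adapts to the cube-root law and shear closes for flow steps", {
  for (eps in c(0.8, 1.2)) {
    p <- mouse_params(K_sigma = 3)
    sim <- simulate_gr(build_scenario("step", magnitude = eps,
                                      what = "flow", duration = 300),
                       p, dt = 0.2, duration = 300)
    s <- sim$series; n <- nrow(s)
    expect_equal(s$r_i_mm[n] / sim$model$r_ih_mm, eps^(1 / 3),
                 tolerance = 0.01)
    expect_equal(s$tau_ratio[n], 1, tolerance = 0.01)
  }
})

test_that("production clamping is reported and the run survives extreme shear steps", {
  sim <- simulate_gr("step_flow_1.3", mouse_params(K_sigma = 3),
                     duration = 5)
  expect_gt(sim$diagnostics$n_clamped_steps, 0)
  expect_true(all(is.finite(as.matrix(sim$series))))
})

test_that("active stress diagnostic returns a curve with an interior peak", {
  sim <- sim_cache("homeo30",
                   simulate_gr("constant", mouse_params(), duration = 30,
                               keep_state = TRUE))
  cur <- active_stress_curve(sim, 0)
  expect_true(all(cur$sigma_act_kPa >= 0))
  pk <- peak_active_stress(sim, 0)
  expect_equal(pk$lambda2_peak, 2.06, tolerance = 0.015)
  # the peak stretch of lambda^2 f(lambda): grid-search oracle
  l <- seq(0.65, 3, by = 0.01)
  f <- length_tension(l, sim$params$tone)
  expect_equal(pk$lambda2_peak, l[which.max(l^2 * f)], tolerance = 1e-9)
})

test_that("homeostatic balancing factors under the equilibrium conventions", {
  m_in <- vasoadapt:::assemble_model(mouse_params())
  expect_equal(m_in$balance_factor, 0.631, tolerance = 1e-3)
  m_mean <- vasoadapt:::assemble_model(mouse_params(
    numerics = numerics_params(equilibrium_radius = "mean")))
  expect_equal(m_mean$balance_factor, 0.866, tolerance = 1e-3)
  # c1e mode keeps the printed tone and rescales elastin
  m_e <- vasoadapt:::assemble_model(mouse_params(
    numerics = numerics_params(balance = "c1e")))
  expect_equal(m_e$S_basal, 0.862)
  expect_equal(m_e$balance_factor, 0.901, tolerance = 1e-3)
  # all three start at exact equilibrium except "none"
  for (m in list(m_in, m_mean, m_e))
    expect_lt(abs(m$T22p0 + m$Tact0 - m$P_h * m$r_eq0), 1e-12)
})
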