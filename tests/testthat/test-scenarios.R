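# Scenario construction, ideal-adaptation analytics, I/O round trips,
# configuration, and the command-line driver.

test_that("ideal adaptation follows the cube-root law", {
  ia <- ideal_adaptation(1, 0.7)
  expect_equal(ia$r_ratio, 0.8879, tolerance = 1e-4)
  expect_equal(ia$h_ratio, 0.8879, tolerance = 1e-4)
  ia <- ideal_adaptation(1, 1.3)
  expect_equal(ia$r_ratio, 1.0914, tolerance = 1e-4)
  ia <- ideal_adaptation(1.5, 1)
  expect_equal(ia$r_ratio, 1)
  expect_equal(ia$h_ratio, 1.5)
  expect_error(ideal_adaptation(-1, 1), "positive")
})

test_that("step and ramp scenarios sample correctly, 1 before onset", {
  sc <- build_scenario("step", magnitude = 0.7, what = "flow")
  expect_equal(sc$eps(c(-5, 0)), c(1, 1))
  expect_equal(sc$eps(c(0.01, 100)), c(0.7, 0.7))
  expect_equal(sc$gamma(c(-1, 50)), c(1, 1))
  sc2 <- build_scenario("step", magnitude = 1.5, onset = 10,
                        what = "pressure")
  expect_equal(sc2$gamma(c(5, 9.99)), c(1, 1))
  expect_equal(sc2$gamma(c(10.01, 200)), c(1.5, 1.5))
  rp <- build_scenario("ramp", magnitude = 1.4, onset = 0, ramp_days = 10,
                       what = "pressure")
  expect_equal(rp$gamma(5), 1.2)   # linear interpolation between knots
  expect_equal(rp$gamma(10), 1.4)
  expect_equal(rp$gamma(250), 1.4) # constant extrapolation
  # shorthand names parse
  sc3 <- build_scenario("step_pressure_1.5")
  expect_equal(sc3$gamma(1), 1.5)
  expect_equal(sc3$eps(1), 1)
})

test_that("scenario CSV round trip reproduces samples exactly", {
  sc <- build_scenario("ramp", magnitude = 0.6, onset = 2, ramp_days = 15,
                       what = "flow", duration = 60)
  f <- tempfile(fileext = ".csv")
  write_scenario_csv(sc, f)
  back <- read_scenario_csv(f)
  tt <- seq(0.1, 60, by = 0.7)
  expect_identical(sc$eps(tt), back$eps(tt))
  expect_identical(sc$gamma(tt), back$gamma(tt))
  unlink(f)
})

test_that("malformed scenario CSVs fail with informative errors", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), f)
  expect_error(read_scenario_csv(f), "t_day")
  writeLines(c("t_day,eps", "0,1", "5,"), f)
  expect_error(read_scenario_csv(f), "line 2")
  writeLines(c("t_day,eps", "0,1", "5,-0.2"), f)
  expect_error(read_scenario_csv(f), "positive")
  unlink(f)
})

test_that("fixture scenarios are deterministic by seed and within bounds", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  p1 <- generate_fixture_scenarios(7, d1)
  p2 <- generate_fixture_scenarios(7, d2)
  expect_equal(basename(p1), basename(p2))
  for (i in seq_along(p1))
    expect_identical(readLines(p1[i]), readLines(p2[i]))
  for (f in p1) {
    df <- utils::read.csv(f)
    expect_true(all(df$gamma >= 1 & df$gamma <= 1.65))
    expect_true(all(df$eps >= 0.3 & df$eps <= 1.3))
  }
  # canonical steps are present
  expect_true(all(c("step_flow_0.7.csv", "step_flow_1.3.csv",
                    "step_pressure_1.5.csv") %in% basename(p1)))
  # a different seed changes the randomized traces
  p3 <- generate_fixture_scenarios(8, file.path(tempdir(), "fx3"))
  lig1 <- readLines(p1[grep("ligation_like_1", p1)])
  lig3 <- readLines(p3[grep("ligation_like_1", p3)])
  expect_false(identical(lig1, lig3))
  unlink(c(d1, d2, file.path(tempdir(), "fx3")), recursive = TRUE)
})

test_that("time-series round trip is exact and homeostatic ratios stay 1", {
  sim <- simulate_gr("constant", mouse_params(), dt = 0.5, duration = 5)
  f <- tempfile(fileext = ".csv")
  write_timeseries(sim, f)
  back <- read_timeseries(f)
  expect_identical(back$r_mm, sim$series$r_mm)
  expect_identical(back$sigma2_kPa, sim$series$sigma2_kPa)
  expect_equal(nrow(back), 5 / 1 + 1)   # duration/output_interval + 1
  expect_equal(back$M_Rc_ratio, rep(1, nrow(back)), tolerance = 1e-6)
  unlink(f)
})

test_that("config round trip: parse -> serialize -> parse is idempotent", {
  cfg <- system.file("extdata", "mouse_carotid.yaml", package = "vasoadapt")
  p1 <- read_gr_config(cfg)
  f <- tempfile(fileext = ".yaml")
  write_gr_config(p1, f)
  p2 <- read_gr_config(f)
  write_gr_config(p2, f)
  p3 <- read_gr_config(f)
  expect_equal(p2, p3)
  expect_equal(p1$wall$phi0_k, p2$wall$phi0_k)
  expect_equal(p1$kinetics$MW, p2$kinetics$MW)
  expect_equal(p1$numerics$equilibrium_radius, "inner")
  unlink(f)
})

test_that("unknown config keys are rejected", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("gains:", "  K_sigma_c: 2", "  bogus: 1"), f)
  expect_error(read_gr_config(f), "bogus")
  unlink(f)
})

test_that("cli: missing config is a usage error (exit 2)", {
  expect_equal(suppressMessages(gr_cli(character())), 2L)
  expect_equal(suppressMessages(gr_cli("--badflag=1")), 2L)
})

test_that("cli runs a short simulation, writes CSV and manifest, sweeps", {
  cfg <- system.file("extdata", "mouse_carotid.yaml", package = "vasoadapt")
  out <- file.path(tempdir(), "cli_run.csv")
  code <- suppressMessages(gr_cli(c("--config", cfg,
                                    "--scenario", "step_flow_0.7",
                                    "--dt", "0.5", "--duration", "3",
                                    "--out", out)))
  expect_equal(code, 0L)
  expect_true(file.exists(out))
  man <- jsonlite::read_json(file.path(tempdir(), "cli_run_manifest.json"))
  expect_equal(man$dt, 0.5)
  expect_equal(man$scenario, "step_flow_0.7")
  expect_true(!is.null(man$parameters$gains$K_sigma_c))
  # sweep writes one file per value
  out2 <- file.path(tempdir(), "cli_sweep.csv")
  code <- suppressMessages(gr_cli(c("--config", cfg,
                                    "--scenario", "step_flow_0.7",
                                    "--dt", "0.5", "--duration", "2",
                                    "--sweep", "Ksigma=0,2",
                                    "--out", out2)))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(tempdir(), "cli_sweep_Ksigma0.csv")))
  expect_true(file.exists(file.path(tempdir(), "cli_sweep_Ksigma2.csv")))
  # fixtures mode
  code <- suppressMessages(gr_cli(c("--fixtures", "3",
                                    "--out", file.path(tempdir(), "fx", "x.csv"))))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(tempdir(), "fx", "step_flow_0.7.csv")))
})

test_that("parameter validation catches inconsistent inputs", {
  expect_error(kinetic_params(beta1 = 0), "beta1")
  expect_error(wall_params(phi0_e = 0.3), "sum to 1")
  expect_error(wall_params(G_hc = 1), "G_hc")
  expect_error(tone_params(lambda_M = 0.5), "lambda_M")
  expect_error(gain_params(K_mu1 = 0), "K_mu1")
  expect_error(numerics_params(dt = -1), "dt")
})
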