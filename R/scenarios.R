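# Perturbation scenarios: piecewise time courses of normalized pressure
# gamma(t) = P/P_h and normalized flow eps(t) = Q/Q_h. Both are 1 for
# t <= 0 (the tissue is homeostatic before the perturbation).

#' Analytic ideal-adaptation targets (cube-root law)
#'
#' Complete adaptation restores both wall shear stress and hoop stress.
#' From the Poiseuille and Laplace relations, a sustained flow ratio `eps`
#' and pressure ratio `gamma` then require
#' `r_i/r_ih = eps^(1/3)` and `h/h_h = gamma * eps^(1/3)`.
#'
#' @param gamma normalized pressure `P/P_h` (> 0).
#' @param eps normalized flow `Q/Q_h` (> 0).
#' @return list with `r_ratio` and `h_ratio`.
#' @examples
#' ideal_adaptation(1, 0.7)   # 30% flow decrease
#' ideal_adaptation(1.5, 1)   # 50% pressure rise
#' @export
ideal_adaptation <- function(gamma, eps) {
  if (any(gamma <= 0) || any(eps <= 0))
    stop("gamma and eps must be positive", call. = FALSE)
  list(r_ratio = eps^(1 / 3), h_ratio = gamma * eps^(1 / 3))
}

.new_scenario <- function(name, gamma, eps, knots, duration) {
  s <- list(name = name, gamma = gamma, eps = eps, knots = knots,
            duration = duration)
  class(s) <- "gr_scenario"
  s
}

.knots_fun <- function(t_knots, v_knots) {
  af <- stats::approxfun(t_knots, v_knots, rule = 2)
  function(t) ifelse(t <= 0, 1, af(t))
}

#' Build a pressure/flow perturbation scenario
#'
#' Constructs piecewise-linear time courses of normalized pressure and
#' flow. `kind` may also be a shorthand name such as `"step_flow_0.7"`,
#' `"step_pressure_1.5"`, or `"constant"`.
#'
#' @param kind `"step"`, `"ramp"`, `"csv"`, `"constant"`, or a shorthand
#'   name.
#' @param magnitude the sustained level of the perturbed quantity
#'   (relative to homeostatic).
#' @param onset day at which the perturbation starts.
#' @param duration scenario duration, day.
#' @param what which quantity is perturbed, `"flow"` (eps) or
#'   `"pressure"` (gamma).
#' @param ramp_days rise time for `kind = "ramp"`.
#' @param path CSV file for `kind = "csv"` (see [read_scenario_csv()]).
#' @param name optional label.
#' @return An object of class `gr_scenario` with samplable functions
#'   `gamma(t)` and `eps(t)`.
#' @examples
#' sc <- build_scenario("step", magnitude = 0.7, what = "flow")
#' sc$eps(c(-1, 0, 1))
#' @export
build_scenario <- function(kind, magnitude = 1, onset = 0, duration = 300,
                           what = c("flow", "pressure"), ramp_days = 10,
                           path = NULL, name = NULL) {
  # shorthand names
  if (grepl("^step_(flow|pressure)_", kind)) {
    parts <- strsplit(kind, "_")[[1]]
    what <- parts[2]
    magnitude <- as.numeric(parts[3])
    if (!is.finite(magnitude))
      stop("cannot parse magnitude from scenario name: ", kind,
           call. = FALSE)
    name <- kind
    kind <- "step"
  } else if (identical(kind, "constant")) {
    one <- function(t) rep(1, length(t))
    return(.new_scenario("constant", one, one, NULL, duration))
  }
  what <- match.arg(what)
  kind <- match.arg(kind, c("step", "ramp", "csv"))

  if (kind == "csv") {
    if (is.null(path) || !file.exists(path))
      stop("scenario CSV path does not exist: ", path, call. = FALSE)
    return(read_scenario_csv(path, duration = duration, name = name))
  }

  if (magnitude <= 0) stop("magnitude must be positive", call. = FALSE)
  if (kind == "step") {
    tk <- if (onset > 0) c(0, onset, onset + 1e-9, duration)
          else c(0, duration)
    vk <- if (onset > 0) c(1, 1, magnitude, magnitude)
          else c(magnitude, magnitude)
  } else {                                    # ramp
    tk <- unique(c(0, onset, onset + ramp_days, duration))
    vk <- stats::approx(c(onset, onset + ramp_days),
                        c(1, magnitude), xout = tk, rule = 2)$y
    if (onset > 0) vk[tk <= onset] <- 1
  }
  fun <- .knots_fun(tk, vk)
  one <- function(t) rep(1, length(t))
  knots <- data.frame(t_day = tk,
                      gamma = if (what == "pressure") vk else 1,
                      eps = if (what == "flow") vk else 1)
  if (is.null(name))
    name <- sprintf("%s_%s_%g", kind, what, magnitude)
  if (what == "flow") .new_scenario(name, one, fun, knots, duration)
  else .new_scenario(name, fun, one, knots, duration)
}

#' Read a scenario from a CSV file
#'
#' Expected dialect: a header row and columns `t_day` plus one or both of
#' `gamma`, `eps`. Values are interpolated linearly between rows and held
#' constant after the last row; a missing column means no perturbation of
#' that quantity.
#'
#' @param path CSV file.
#' @param duration scenario duration, day (default: last knot).
#' @param name optional label (default: file name).
#' @return A `gr_scenario` object.
#' @export
read_scenario_csv <- function(path, duration = NULL, name = NULL) {
  df <- tryCatch(utils::read.csv(path, strip.white = TRUE),
                 error = function(e)
                   stop("cannot parse scenario CSV '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  if (!"t_day" %in% names(df))
    stop("scenario CSV must have a 't_day' column (", path, ")",
         call. = FALSE)
  if (!any(c("gamma", "eps") %in% names(df)))
    stop("scenario CSV must have a 'gamma' and/or 'eps' column (",
         path, ")", call. = FALSE)
  bad <- which(!stats::complete.cases(df))
  if (length(bad))
    stop(sprintf("scenario CSV '%s': missing value on data line %d",
                 path, bad[1]), call. = FALSE)
  if (is.unsorted(df$t_day))
    stop("scenario CSV times must be non-decreasing (", path, ")",
         call. = FALSE)
  for (v in c("gamma", "eps"))
    if (v %in% names(df) && any(df[[v]] <= 0))
      stop(sprintf("scenario CSV '%s': %s must be positive", path, v),
           call. = FALSE)
  one <- function(t) rep(1, length(t))
  gam <- if ("gamma" %in% names(df) && nrow(df) > 1)
    .knots_fun(df$t_day, df$gamma)
  else if ("gamma" %in% names(df))
    (function(v) function(t) ifelse(t <= 0, 1, rep(v, length(t))))(df$gamma[1])
  else one
  ep <- if ("eps" %in% names(df) && nrow(df) > 1)
    .knots_fun(df$t_day, df$eps)
  else if ("eps" %in% names(df))
    (function(v) function(t) ifelse(t <= 0, 1, rep(v, length(t))))(df$eps[1])
  else one
  if (is.null(duration)) duration <- max(df$t_day)
  knots <- data.frame(t_day = df$t_day,
                      gamma = if ("gamma" %in% names(df)) df$gamma else 1,
                      eps = if ("eps" %in% names(df)) df$eps else 1)
  .new_scenario(name %||% basename(path), gam, ep, knots, duration)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario's knots to CSV
#'
#' @param scenario a `gr_scenario` with knots (built-in step/ramp or CSV
#'   scenarios).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_scenario_csv <- function(scenario, path) {
  stopifnot(inherits(scenario, "gr_scenario"))
  if (is.null(scenario$knots))
    stop("scenario has no knot representation to write", call. = FALSE)
  .write_exact_csv(scenario$knots, path)
  invisible(path)
}

# full-precision CSV writer (doubles survive a round trip exactly)
.write_exact_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Generate synthetic scenario fixtures
#'
#' Writes a deterministic-by-seed family of scenario CSVs: the canonical
#' sustained steps (30% flow decrease, 30% flow increase, 50% pressure
#' rise) plus randomized piecewise-linear traces emulating the shapes of
#' ligation-like flow decays and hypertension-like pressure rises.
#' Pressure ratios stay within [1, 1.65] and flow ratios within
#' [0.3, 1.3]. These are synthetic stand-ins for experimental flow and
#' pressure time courses, which are not part of the package.
#'
#' @param seed integer seed; the same seed reproduces the files
#'   byte-for-byte.
#' @param dir output directory (created if needed).
#' @param n_random number of randomized traces of each family.
#' @return character vector of written file paths, invisibly.
#' @export
generate_fixture_scenarios <- function(seed, dir, n_random = 3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  paths <- character(0)
  wr <- function(fname, df) {
    p <- file.path(dir, fname)
    .write_exact_csv(df, p)
    paths <<- c(paths, p)
  }
  # canonical steps
  wr("step_flow_0.7.csv",
     data.frame(t_day = c(0, 300), gamma = c(1, 1), eps = c(0.7, 0.7)))
  wr("step_flow_1.3.csv",
     data.frame(t_day = c(0, 300), gamma = c(1, 1), eps = c(1.3, 1.3)))
  wr("step_pressure_1.5.csv",
     data.frame(t_day = c(0, 300), gamma = c(1.5, 1.5), eps = c(1, 1)))
  # ligation-like randomized flow decays
  for (i in seq_len(n_random)) {
    target <- stats::runif(1, 0.3, 0.8)
    ramp <- stats::runif(1, 5, 30)
    tt <- sort(c(0, stats::runif(3, 0, ramp), ramp, 56))
    vv <- stats::approx(c(0, ramp), c(1, target), xout = tt,
                        rule = 2)$y
    vv <- pmin(1.3, pmax(0.3, vv + stats::rnorm(length(vv), 0, 0.02)))
    vv[1] <- 1
    wr(sprintf("ligation_like_%d.csv", i),
       data.frame(t_day = tt, gamma = 1, eps = vv))
  }
  # hypertension-like randomized pressure rises
  for (i in seq_len(n_random)) {
    target <- stats::runif(1, 1.2, 1.65)
    ramp <- stats::runif(1, 10, 56)
    tt <- sort(c(0, stats::runif(3, 0, ramp), ramp, 56))
    vv <- stats::approx(c(0, ramp), c(1, target), xout = tt,
                        rule = 2)$y
    vv <- pmin(1.65, pmax(1, vv + stats::rnorm(length(vv), 0, 0.01)))
    vv[1] <- 1
    wr(sprintf("hypertension_like_%d.csv", i),
       data.frame(t_day = tt, gamma = vv, eps = 1))
  }
  invisible(paths)
}

#' @export
print.gr_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' over %g days\n", x$name, x$duration))
  probe <- c(0, x$duration / 2, x$duration)
  cat(sprintf("  gamma(t): %s\n",
              paste(sprintf("%g->%.3f", probe, x$gamma(probe)),
                    collapse = ", ")))
  cat(sprintf("  eps(t):   %s\n",
              paste(sprintf("%g->%.3f", probe, x$eps(probe)),
                    collapse = ", ")))
  invisible(x)
}
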