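# Time-series output and structured-text configuration.

# canonical output columns, in order
.TS_COLUMNS <- c("t_day", "r_mm", "r_i_mm", "h_um", "lambda2",
                 "tau_ratio", "sigma1_kPa", "sigma2_kPa", "M_Rc_ratio",
                 "M_Rm_ratio", "S_Npm", "T_act_Npm", "C_IR_total")

#' Write a simulation time series to CSV
#'
#' Writes the canonical output columns at full precision (doubles survive
#' a read round trip exactly): time (day), mean and inner radius (mm),
#' thickness (um), circumferential stretch, normalized wall shear, axial
#' and circumferential Cauchy stress (kPa), collagen and muscle mass
#' ratios, tone magnitude and active membrane stress (N/m), and the total
#' intermediate collagen pool.
#'
#' @param result a `gr_sim` object from [simulate_gr()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_timeseries <- function(result, path) {
  stopifnot(inherits(result, "gr_sim"))
  if (nrow(result$series) == 0) stop("empty simulation result",
                                     call. = FALSE)
  ok <- tryCatch({
    .write_exact_csv(result$series[, .TS_COLUMNS], path)
    TRUE
  }, error = function(e)
    stop("cannot write time series to '", path, "': ",
         conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a simulation time series written by [write_timeseries()]
#'
#' @param path CSV path.
#' @return data frame with the canonical columns.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path)
  missing <- setdiff(.TS_COLUMNS, names(df))
  if (length(missing))
    stop("not a simulation time series (missing columns: ",
         paste(missing, collapse = ", "), ")", call. = FALSE)
  df
}

#' Read a model configuration file
#'
#' YAML with sections `kinetics`, `wall`, `tone`, `gains`, `numerics`;
#' each section holds the arguments of the corresponding constructor
#' ([kinetic_params()], [wall_params()], [tone_params()],
#' [gain_params()], [numerics_params()]). Missing sections or keys fall
#' back to the mouse carotid defaults. A ready-made configuration ships
#' at `system.file("extdata", "mouse_carotid.yaml", package =
#' "vasoadapt")`.
#'
#' @param path YAML file.
#' @return a [gr_params()] object.
#' @export
read_gr_config <- function(path) {
  if (!file.exists(path))
    stop("config file does not exist: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("kinetics", "wall", "tone", "gains", "numerics")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    warning("ignoring unknown config sections: ",
            paste(extra, collapse = ", "))
  build <- function(ctor, section) {
    args <- raw[[section]]
    if (is.null(args)) return(ctor())
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad))
      stop(sprintf("unknown key(s) in [%s]: %s", section,
                   paste(bad, collapse = ", ")), call. = FALSE)
    if (section == "wall" && !is.null(args$phi0_k))
      args$phi0_k <- as.numeric(unlist(args$phi0_k))
    do.call(ctor, args)
  }
  gr_params(kinetics = build(kinetic_params, "kinetics"),
            wall = build(wall_params, "wall"),
            tone = build(tone_params, "tone"),
            gains = build(gain_params, "gains"),
            numerics = build(numerics_params, "numerics"))
}

#' Write a parameter set to a configuration file
#'
#' @param params a [gr_params()] object.
#' @param path output YAML path.
#' @return the path, invisibly.
#' @export
write_gr_config <- function(params, path) {
  stopifnot(inherits(params, "gr_params"))
  out <- lapply(unclass(params), unclass)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
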