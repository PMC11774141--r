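#' Observation-table dialect
#'
#' Declares the column and unit conventions of a delimited
#' gas-exchange observation file.  Required columns: `treatment`,
#' `gw_obs`, `psi_L`, `T_leaf`, `D_L`, `ca`, `PPFD`, `Patm`; optional:
#' `Vcmax25`, `Jmax25`, `An_obs`.
#'
#' @param gas_units `"mol"` or `"umol"`: units of `gw_obs`, `PPFD`,
#'   `An_obs`, `Vcmax25`, `Jmax25` in the file (converted to mol
#'   internally).
#' @param temp_units `"K"` or `"C"` for `T_leaf`.
#' @param sep Field delimiter.
#' @return List of class `obs_dialect`.
#' @export
observation_dialect <- function(gas_units = c("mol", "umol"),
                                temp_units = c("K", "C"), sep = ",") {
  structure(list(gas_units = match.arg(gas_units),
                 temp_units = match.arg(temp_units), sep = sep),
            class = "obs_dialect")
}

OBS_REQUIRED <- c("treatment", "gw_obs", "psi_L", "T_leaf", "D_L", "ca",
                  "PPFD", "Patm")

#' Read and validate a gas-exchange observation table
#'
#' Applies the declared unit conversions, rejects rows with
#' non-physical values (`gw_obs < 0`, `D_L <= 0`, `psi_L > 0`), and
#' attaches a row-level validation report.
#'
#' @param path File path.
#' @param dialect An [observation_dialect()].
#' @return Validated data frame (mol-based units, Kelvin) with
#'   attribute `validation` listing rejected row numbers and reasons.
#' @export
read_observations <- function(path, dialect = observation_dialect()) {
  if (!file.exists(path)) stop("observation file not found: ", path)
  d <- utils::read.csv(path, sep = dialect$sep, comment.char = "#",
                       stringsAsFactors = FALSE)
  missing_cols <- setdiff(OBS_REQUIRED, names(d))
  if (length(missing_cols)) {
    stop("observation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (dialect$gas_units == "umol") {
    for (cl in intersect(c("gw_obs", "PPFD", "An_obs", "Vcmax25", "Jmax25"),
                         names(d))) {
      d[[cl]] <- d[[cl]] * 1e-6
    }
  }
  if (dialect$temp_units == "C") d$T_leaf <- d$T_leaf + 273.15
  bad <- list()
  flag <- function(idx, why) {
    if (length(idx)) bad[[length(bad) + 1]] <<- data.frame(row = idx,
                                                           reason = why)
  }
  flag(which(d$gw_obs < 0), "gw_obs < 0")
  flag(which(d$D_L <= 0), "D_L <= 0")
  flag(which(d$psi_L > 0), "psi_L > 0")
  report <- if (length(bad)) do.call(rbind, bad) else
    data.frame(row = integer(), reason = character())
  keep <- setdiff(seq_len(nrow(d)), report$row)
  if (nrow(report)) {
    message(sprintf("read_observations: rejected %d row(s): %s",
                    nrow(report),
                    paste(unique(report$reason), collapse = "; ")))
  }
  out <- d[keep, , drop = FALSE]
  attr(out, "validation") <- report
  out
}

#' Read a meteorological forcing table
#'
#' @param path File path; requires columns `time` (ISO-8601), `precip`,
#'   `T_air`, `RH`, `PPFD`, `ca`, `Patm`, `LAI`.
#' @return Forcing data frame with parsed `time`.
#' @export
read_forcing <- function(path) {
  if (!file.exists(path)) stop("forcing file not found: ", path)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time", "precip", "T_air", "RH", "PPFD", "ca", "Patm", "LAI")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("forcing table is missing column(s): ",
                         paste(miss, collapse = ", "))
  d$time <- as.POSIXct(d$time, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                      "%Y-%m-%d %H:%M:%S", "%Y-%m-%d"))
  if (anyNA(d$time)) stop("unparseable time stamps in forcing table")
  if (any(d$precip < 0) || any(d$PPFD < 0) || any(d$LAI < 0)) {
    stop("forcing contains negative precip/PPFD/LAI")
  }
  d
}

# Flatten a nested list to dotted key=value strings (for provenance
# headers).
flatten_config <- function(cfg, prefix = "") {
  out <- character()
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(v)) out <- c(out, flatten_config(v, key))
    else out <- c(out, paste0(key, "=", paste(format(v), collapse = ",")))
  }
  out
}

#' Write a results table with a provenance header
#'
#' Prepends `#`-prefixed header lines carrying the package version, the
#' seed, the effective configuration and (on one isolated line) a
#' timestamp, then the CSV body.  [read_results()] inverts it.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param seed Seed used by the producing computation.
#' @param config Effective configuration (nested list), echoed in full.
#' @export
write_results <- function(df, path, seed = NA, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("stomopt"))
  writeLines(c(sprintf("# stomopt %s", ver),
               sprintf("# seed: %s", seed),
               sprintf("# written: %s", format(Sys.time(), tz = "UTC")),
               paste0("# cfg: ", flatten_config(config))), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path File path.
#' @return Data frame; header lines are exposed in attribute `header`.
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  d <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                       stringsAsFactors = FALSE)
  attr(d, "header") <- hdr
  d
}

#' Write posterior samples as labelled delimited text
#'
#' @param fit An `mcmc_fit` from [run_mcmc()].
#' @param path Output path.
#' @export
write_posterior <- function(fit, path) {
  write_results(fit$samples, path, seed = fit$config$seed,
                config = list(mcmc = list(n_iter = fit$config$n_iter,
                                          burn_frac = fit$config$burn_frac,
                                          thin = fit$config$thin,
                                          acceptance = fit$acceptance,
                                          psrf = round(fit$psrf, 4))))
}

#' Default run configuration
#'
#' The full nested configuration with every tunable the CLI exposes,
#' initialized to the fixture parameter values.
#'
#' @return Nested list.
#' @export
default_config <- function() {
  fx <- fixture_params()
  list(
    pv = fx$pv[c("af_max", "pi_L_star", "beta", "eps_L0", "SWC_L",
                 "alpha", "pi_L0_25", "c_DM")],
    photo = list(Vcmax25 = fx$photo$Vcmax25, Jmax25 = fx$photo$Jmax25,
                 Rd25 = fx$photo$Rd25, sf = fx$photo$sf,
                 psi_f = fx$photo$psi_f),
    hyd = fx$hyd[c("k_max", "d_k", "Q10", "T_ref")],
    hyd_ground = fx$hyd_ground[c("k_max", "d_k", "Q10", "T_ref")],
    eb = fx$eb[c("Q_abs", "emissivity", "g_bH", "n_sides")],
    soil = fx$soil[c("theta_sat", "psi_e", "b_ret", "Z_r", "evap_coef",
                     "theta_res")],
    solver = list(g0_min = 0.005, gw_cap = 5, lambda_floor = 1e-7),
    mcmc = list(n_iter = 3000, burn_frac = 0.5, thin = 5,
                closure_threshold = 0.05)
  )
}

merge_config <- function(defaults, override, path = "") {
  for (nm in names(override)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults)) {
      stop("unknown configuration key: ", key)
    }
    if (is.list(defaults[[nm]])) {
      if (!is.list(override[[nm]])) {
        stop("configuration key ", key, " must be a section")
      }
      defaults[[nm]] <- merge_config(defaults[[nm]], override[[nm]], key)
    } else {
      v <- override[[nm]]
      if (is.numeric(defaults[[nm]]) && !is.numeric(v)) {
        stop("type mismatch for configuration key ", key)
      }
      defaults[[nm]] <- v
    }
  }
  defaults
}

#' Read a YAML run configuration
#'
#' Unknown keys and type mismatches are rejected; missing keys fall
#' back to [default_config()].
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Fully resolved configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    over <- yaml::read_yaml(path)
    if (!is.null(over)) cfg <- merge_config(cfg, over)
  }
  cfg
}

# Instantiate parameter objects from a resolved configuration.
params_from_config <- function(cfg) {
  list(
    pv = do.call(leaf_pv_params, cfg$pv),
    photo = do.call(photo_params, cfg$photo),
    hyd = do.call(hydraulic_params, cfg$hyd),
    hyd_ground = do.call(hydraulic_params, cfg$hyd_ground),
    eb = do.call(energy_balance_params, cfg$eb),
    soil = do.call(soil_params, cfg$soil)
  )
}

#' Write a machine-readable event report
#'
#' Serializes an ecosystem run's event report (mortality dates,
#' supercritical days, budget diagnostics) as JSON.
#'
#' @param events Event list from an `ecosystem_run`.
#' @param path Output path.
#' @param seed Seed of the producing run.
#' @export
write_event_report <- function(events, path, seed = NA) {
  ev <- events
  ev$supercritical_days <- as.character(ev$supercritical_days)
  for (nm in grep("^mortality_plc", names(ev), value = TRUE)) {
    ev[[nm]] <- as.character(ev[[nm]])
  }
  ev$seed <- seed
  ev$version <- as.character(utils::packageVersion("stomopt"))
  jsonlite::write_json(ev, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}
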