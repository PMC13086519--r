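# Physical description of the sealed, stirred incubation vial: gas-liquid
# partitioning, unit conversions and redox stoichiometry shared by the
# simulator and the analysis. Amounts are umol per vial throughout;
# concentrations are derived on demand (uM in the liquid, umol/mL in the
# headspace). Pressure is treated as constant (the slight He overpressure
# left by sample replacement is not tracked).

.GAS_R <- 0.0820574  # L atm mol^-1 K^-1

.GAS_SPECIES <- c("O2", "NO", "N2O", "N2")

#' Gas properties for one species
#'
#' @param henry_cc Dimensionless Henry solubility, the ratio of liquid to gas
#'   concentration at equilibrium at the vial temperature. Must be >= 0.
#' @param kla Gas-liquid transfer coefficient in 1/h, or the sentinel string
#'   `"equilibrium"` (the default) meaning the phases are kept at equilibrium
#'   by vigorous stirring.
#' @return A `gas_props` list.
#' @export
gas_props <- function(henry_cc, kla = "equilibrium") {
  if (!.is_number(henry_cc) || henry_cc < 0) {
    stop("henry_cc must be a single non-negative number", call. = FALSE)
  }
  if (!(identical(kla, "equilibrium") || (.is_number(kla) && kla > 0))) {
    stop("kla must be > 0 or the sentinel \"equilibrium\"", call. = FALSE)
  }
  structure(list(henry_cc = henry_cc, kla = kla), class = "gas_props")
}

#' Default gas table at 20 C
#'
#' Reads the dimensionless Henry constants shipped with the package
#' (`inst/extdata/gas_table.yaml`); see that file for sources.
#'
#' @return Named list of [gas_props()] keyed by species symbol
#'   (O2, NO, N2O, N2, He).
#' @export
default_gas_table <- function() {
  path <- system.file("extdata", "gas_table.yaml", package = "denitkin",
                      mustWork = TRUE)
  raw <- .read_yaml(path)
  lapply(raw, function(g) gas_props(g$henry_cc, g$kla))
}

#' Configuration of the incubation vial
#'
#' Defaults describe the 120 mL serum vial used throughout: 50 mL mineral
#' medium, 70 mL headspace, 20 C, stirred to gas-liquid equilibrium, with
#' 1 mL headspace samples taken by the autosampler and replaced with He.
#'
#' @param liquid_volume,headspace_volume,sample_volume Volumes in mL.
#' @param temperature Temperature in C.
#' @param pressure Headspace pressure in atm (treated as constant).
#' @param gas_table Named list of [gas_props()], one entry per gas species
#'   used in a run.
#' @return A `vial_config` object.
#' @export
vial_config <- function(liquid_volume = 50, headspace_volume = 70,
                        temperature = 20, pressure = 1, sample_volume = 1,
                        gas_table = default_gas_table()) {
  for (v in c(liquid_volume, headspace_volume, temperature + 273.15,
              pressure)) {
    if (!.is_number(v) || v <= 0) {
      stop("vial volumes, absolute temperature and pressure must be positive",
           call. = FALSE)
    }
  }
  if (!.is_number(sample_volume) || sample_volume < 0 ||
      sample_volume >= headspace_volume) {
    stop("sample_volume must be in [0, headspace_volume)", call. = FALSE)
  }
  if (!is.list(gas_table) || is.null(names(gas_table))) {
    stop("gas_table must be a named list of gas_props", call. = FALSE)
  }
  structure(
    list(liquid_volume = liquid_volume, headspace_volume = headspace_volume,
         temperature = temperature, pressure = pressure,
         sample_volume = sample_volume, gas_table = gas_table),
    class = "vial_config")
}

.gas_entry <- function(cfg, species) {
  g <- cfg$gas_table[[species]]
  if (is.null(g)) {
    stop("species \"", species, "\" has no entry in the vial gas_table",
         call. = FALSE)
  }
  g
}

.gas_k <- function(cfg, species) .gas_entry(cfg, species)$henry_cc

#' Total gas capacity of the headspace
#'
#' Ideal-gas amount (umol) filling the headspace at the configured pressure
#' and temperature.
#' @param cfg A [vial_config()].
#' @export
headspace_capacity <- function(cfg) {
  cfg$pressure * (cfg$headspace_volume / 1000) /
    (.GAS_R * (cfg$temperature + 273.15)) * 1e6
}

#' Convert an initial O2 headspace percentage to total vial O2
#'
#' @param percent Volume percent O2 in the headspace.
#' @param cfg A [vial_config()].
#' @return Total O2 in the vial (umol), headspace plus equilibrium-dissolved.
#' @export
o2_percent_to_umol <- function(percent, cfg) {
  hs <- percent / 100 * headspace_capacity(cfg)
  k <- .gas_k(cfg, "O2")
  hs * (cfg$headspace_volume + k * cfg$liquid_volume) / cfg$headspace_volume
}

#' Amount of solute supplied at a medium concentration
#'
#' @param mM Concentration in the liquid (mM).
#' @param cfg A [vial_config()].
#' @return Amount in umol per vial (e.g. 2 mM in 50 mL -> 100 umol).
#' @export
amount_from_mM <- function(mM, cfg) mM * cfg$liquid_volume

#' Equilibrium gas-liquid partitioning
#'
#' Splits a total vial amount of a gas between headspace and liquid assuming
#' the two phases are at equilibrium (vigorously stirred vial).
#'
#' @param total_umol Total amount of the gas in the vial (umol).
#' @param species Gas species symbol, must be present in `cfg$gas_table`.
#' @param cfg A [vial_config()].
#' @return List with `headspace_umol`, `dissolved_umol` and `liquid_conc_uM`.
#'   Mass is conserved: `headspace_umol + dissolved_umol == total_umol`.
#' @export
equilibrium_partition <- function(total_umol, species, cfg) {
  if (!.is_number(total_umol) || total_umol < 0) {
    stop("total_umol must be a single non-negative number", call. = FALSE)
  }
  k <- .gas_k(cfg, species)
  denom <- cfg$headspace_volume + k * cfg$liquid_volume
  hs <- total_umol * cfg$headspace_volume / denom
  list(headspace_umol = hs,
       dissolved_umol = total_umol - hs,
       liquid_conc_uM = 1000 * k * total_umol / denom)
}

#' Transfer-limited steady-state liquid concentration
#'
#' For a gas consumed in the liquid at a given rate, with finite gas-liquid
#' transfer, the steady-state liquid concentration sits below the equilibrium
#' value by rate / (kla * V_liquid). Used only to reproduce sub-equilibrium
#' liquid O2 estimates; the default vial is at equilibrium, for which
#' [equilibrium_partition()] is the right tool.
#'
#' @param consumption_rate Consumption in the liquid (umol/h), >= 0.
#' @param species Gas species symbol.
#' @param cfg A [vial_config()] whose entry for `species` has a numeric kla.
#' @param headspace_umol Current headspace amount of the gas (umol).
#' @return Steady-state liquid concentration (uM), floored at 0.
#' @export
estimate_liquid_conc <- function(consumption_rate, species, cfg,
                                 headspace_umol) {
  g <- .gas_entry(cfg, species)
  if (identical(g$kla, "equilibrium")) {
    stop("gas \"", species, "\" is configured with the equilibrium sentinel; ",
         "use equilibrium_partition() instead", call. = FALSE)
  }
  if (!.is_number(consumption_rate) || consumption_rate < 0) {
    stop("consumption_rate must be a single non-negative number",
         call. = FALSE)
  }
  c_eq <- 1000 * g$henry_cc * headspace_umol / cfg$headspace_volume  # uM
  max(0, c_eq - consumption_rate / (g$kla * cfg$liquid_volume / 1000))
}

#' Electron stoichiometry of the reduction steps
#'
#' Electrons transferred per mole of N (per mole of O2 for the O2 step):
#' O2 -> H2O takes 4 per O2; NO3- -> NO2- takes 2; NO2- -> NO, NO -> 1/2 N2O
#' and N2O -> N2 take 1 each per N. The four N steps sum to 5 electrons per N
#' for complete denitrification.
#'
#' @return Named integer vector.
#' @export
stoichiometry_table <- function() {
  c("O2" = 4L, "NO3->NO2" = 2L, "NO2->NO" = 1L,
    "NO->N2O" = 1L, "N2O->N2" = 1L)
}

#' Electrons per mole for one reduction step
#'
#' @param step Step id, a name of [stoichiometry_table()].
#' @param table Stoichiometry table.
#' @export
electrons_for_step <- function(step, table = stoichiometry_table()) {
  if (!step %in% names(table)) {
    stop("unknown reduction step \"", step, "\"", call. = FALSE)
  }
  unname(table[[step]])
}

#' @export
print.vial_config <- function(x, ...) {
  cat(sprintf(
    "<vial_config> %g mL liquid / %g mL headspace, %g C, %g atm, %g mL samples\n",
    x$liquid_volume, x$headspace_volume, x$temperature, x$pressure,
    x$sample_volume))
  cat("gases:", paste(names(x$gas_table), collapse = ", "), "\n")
  invisible(x)
}
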