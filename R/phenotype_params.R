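# Regulatory and kinetic parameters that encode a strain's nitrite
# accumulation phenotype. Biomass is in abstract units (1 unit = 1 OD600 in
# the 50 mL culture); electron rates are umol electrons per biomass unit per
# hour; Km and Ki are liquid-phase concentrations in uM.

.RED <- c("nap", "nar", "nir", "nor", "nos")

#' Phenotype parameters for the batch-vial simulator
#'
#' The defaults are the full-nitrite-accumulator (FNA) reference
#' parameterisation; [preset()] derives the other phenotypes from it.
#'
#' @param has_nap,has_nar Presence of the periplasmic (Nap) and membrane-bound
#'   (Nar) dissimilatory nitrate reductases.
#' @param induction_o2_threshold Total vial O2 (umol) below which the
#'   denitrification genes are induced. Default 14: O2 keeps falling during
#'   the synthesis delay and the hourly instrument grid, so induction near
#'   the top of the observed 10-15 umol onset window places the *measured*
#'   onset of NO3- reduction mid-window.
#' @param delay_h Hours from induction to the start of synthesis, per
#'   reductase (named: nap, nar, nir, nor, nos). The 5 h nar delay of
#'   late-NarG strains goes here.
#' @param synthesis_rate First-order rate (1/h) at which each reductase
#'   activity rises from 0 towards 1 once synthesis starts. The FNA default
#'   makes first-pulse Nir synthesis minimal (the initial transcription
#'   pulse yields hardly any NO2- reduction); prompt-onset phenotypes set
#'   `c(nir = 2)`.
#' @param second_synthesis_rate Synthesis rate applied to Nir/Nor when the
#'   second transcription pulse fires (see `second_induction`).
#' @param vmax_e Maximal electron-flow capacity per reductase
#'   (umol e- / biomass / h), named o2, nap, nar, nir, nor, nos.
#' @param km Half-saturation liquid concentrations (uM), named
#'   o2, no3, no2, no, n2o.
#' @param nir_no3_inhibition_ki Half-inhibition constant (uM) of Nir activity
#'   by NO3- (the metabolic gating seen in FNA strains); `Inf` disables.
#' @param competition_weight Dimensionless electron-allocation priorities
#'   when the supply is insufficient for all demands.
#' @param nir_subpop_fraction Fraction of the biomass expressing Nir
#'   (only part of an FNA population respires NO2-, producing the
#'   electron-flow dip at the NO3- to NO2- transition).
#' @param second_induction If `TRUE`, a second Nir/Nor synthesis pulse fires
#'   when NO3- is depleted (the second transcription pulse of FNA strains).
#' @param v_supply Electron supply capacity (umol e- / biomass / h) from
#'   catabolism to the quinone pool.
#' @param yield Biomass formed per umol of electrons delivered.
#' @return A `phenotype_params` object.
#' @export
phenotype_params <- function(
    has_nap = TRUE, has_nar = TRUE,
    induction_o2_threshold = 14,
    delay_h = NULL,
    synthesis_rate = NULL,
    second_synthesis_rate = 0.25,
    vmax_e = NULL,
    km = NULL,
    nir_no3_inhibition_ki = 20,
    competition_weight = NULL,
    nir_subpop_fraction = 0.3,
    second_induction = TRUE,
    v_supply = 80,
    yield = 0.0015) {
  delay_h <- .merge_named(
    c(nap = 0.1, nar = 1, nir = 1, nor = 0.5, nos = 0), delay_h, "delay_h")
  synthesis_rate <- .merge_named(
    c(nap = 3, nar = 2, nir = 0.01, nor = 2, nos = 2), synthesis_rate,
    "synthesis_rate")
  vmax_e <- .merge_named(
    c(o2 = 250, nap = 25, nar = 100, nir = 30, nor = 800, nos = 800),
    vmax_e, "vmax_e")
  km <- .merge_named(
    c(o2 = 30, no3 = 1000, no2 = 5, no = 0.3, n2o = 3), km, "km")
  competition_weight <- .merge_named(
    c(o2 = 5, nap = 1, nar = 1, nir = 1, nor = 5, nos = 5),
    competition_weight, "competition_weight")

  stopifnot(is.logical(has_nap), is.logical(has_nar),
            is.logical(second_induction))
  vals <- c(induction_o2_threshold, delay_h, synthesis_rate,
            second_synthesis_rate, vmax_e, km[is.finite(km)],
            competition_weight, v_supply, yield)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all rates, delays, Km, weights and yields must be finite and >= 0",
         call. = FALSE)
  }
  if (!.is_number(nir_subpop_fraction) &&
      !identical(nir_subpop_fraction, 1)) {
    stop("nir_subpop_fraction must be a single number", call. = FALSE)
  }
  if (nir_subpop_fraction <= 0 || nir_subpop_fraction > 1) {
    stop("nir_subpop_fraction must be in (0, 1]", call. = FALSE)
  }
  if (!(is.infinite(nir_no3_inhibition_ki) || nir_no3_inhibition_ki > 0)) {
    stop("nir_no3_inhibition_ki must be > 0 (Inf disables the gating)",
         call. = FALSE)
  }
  structure(
    list(has_nap = has_nap, has_nar = has_nar,
         induction_o2_threshold = induction_o2_threshold,
         delay_h = delay_h, synthesis_rate = synthesis_rate,
         second_synthesis_rate = second_synthesis_rate,
         vmax_e = vmax_e, km = km,
         nir_no3_inhibition_ki = nir_no3_inhibition_ki,
         competition_weight = competition_weight,
         nir_subpop_fraction = nir_subpop_fraction,
         second_induction = second_induction,
         v_supply = v_supply, yield = yield),
    class = "phenotype_params")
}

#' @export
print.phenotype_params <- function(x, ...) {
  cat("<phenotype_params>",
      if (x$has_nap) "Nap" else NULL, if (x$has_nar) "Nar" else NULL,
      sprintf("Ki(NO3|Nir)=%g uM", x$nir_no3_inhibition_ki),
      sprintf("Nir subpop=%g", x$nir_subpop_fraction),
      if (x$second_induction) "second-pulse" else NULL, "\n")
  invisible(x)
}
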