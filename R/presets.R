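# Shipped scenario parameterisations. The three reference presets reproduce
# the printed phenotype bounds through the full simulate -> sample -> analyze
# pipeline: FNA accumulates >= 89% of the supplied NO3--N as NO2- before any
# NO2- reduction (strong NO3- gating of Nir, Nir expressed by a
# subpopulation, second synthesis pulse at NO3- depletion); PNA accumulates
# about half (no gating, Nir capacity about a quarter of Nar's); LNA at most
# 20% (high Nir capacity with Nar absent or synthesised ~5 h late). The
# competition presets restart pre-induced, anoxic cultures on 100 umol NO2-
# and spike 100 umol NO3- once a third of the NO2- is gone.

.PRESETS <- c("FNA_ref", "PNA_ref", "LNA_ref", "LNA_nap_only", "dNarG",
              "competition_FNA", "competition_PNA", "competition_LNA")

.pheno_for <- function(group) {
  switch(group,
    FNA = phenotype_params(),  # defaults are the FNA reference
    PNA = phenotype_params(nir_no3_inhibition_ki = Inf,
                           vmax_e = c(nar = 60, nir = 8),
                           synthesis_rate = c(nir = 2),
                           competition_weight = c(nir = 10),
                           nir_subpop_fraction = 1,
                           second_induction = FALSE),
    LNA = phenotype_params(nir_no3_inhibition_ki = Inf,
                           vmax_e = c(nir = 300),
                           synthesis_rate = c(nir = 2),
                           nir_subpop_fraction = 1,
                           delay_h = c(nar = 5),
                           second_induction = FALSE))
}

.competition_protocol <- function(duration = 40) {
  protocol(duration = duration, initial_o2_percent = 0, initial_no3 = 0,
           initial_no2 = 100, inoculum_biomass = 0.3, preinduced = TRUE,
           spike_events = list(
             spike_event("NO3", 100, when_no2_below = 100 * 2 / 3)),
           sampling_gas = seq(1, duration, by = 1),
           sampling_no2 = seq(0, duration, by = 2))
}

#' Shipped scenario presets
#'
#' @param name One of `FNA_ref`, `PNA_ref`, `LNA_ref` (reference phenotypes
#'   under the standard 100 umol NO3-, 1% O2 protocol), `LNA_nap_only`
#'   (Nar-less LNA strain), `dNarG` (the PNA reference without Nar — the
#'   narG deletion), and `competition_FNA` / `competition_PNA` /
#'   `competition_LNA` (pre-induced anoxic cultures on 100 umol NO2- with a
#'   state-triggered 100 umol NO3- spike).
#' @return List with `name`, `config`, `phenotype`, `protocol`.
#' @export
preset <- function(name = .PRESETS) {
  name <- match.arg(name)
  cfg <- vial_config()
  sc <- switch(name,
    FNA_ref = list(.pheno_for("FNA"), protocol(duration = 60)),
    PNA_ref = list(.pheno_for("PNA"), protocol(duration = 40)),
    LNA_ref = list(.pheno_for("LNA"), protocol(duration = 40)),
    LNA_nap_only = {
      p <- phenotype_params(nir_no3_inhibition_ki = Inf,
                            vmax_e = c(nir = 300),
                            synthesis_rate = c(nir = 2),
                            nir_subpop_fraction = 1,
                            has_nar = FALSE,
                            second_induction = FALSE)
      list(p, protocol(duration = 72))
    },
    dNarG = {
      p <- phenotype_params(nir_no3_inhibition_ki = Inf,
                            vmax_e = c(nar = 60, nir = 8),
                            synthesis_rate = c(nir = 2),
                            competition_weight = c(nir = 10),
                            nir_subpop_fraction = 1,
                            has_nar = FALSE,
                            second_induction = FALSE)
      list(p, protocol(duration = 96, sampling_no2 = seq(0, 96, by = 4)))
    },
    competition_FNA = list(.pheno_for("FNA"), .competition_protocol()),
    competition_PNA = list(.pheno_for("PNA"), .competition_protocol()),
    competition_LNA = list(.pheno_for("LNA"), .competition_protocol()))
  list(name = name, config = cfg, phenotype = sc[[1]], protocol = sc[[2]])
}
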