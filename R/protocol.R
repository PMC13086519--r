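# Incubation protocols: initial conditions, substrate spikes and the
# autosampler schedules. Times are hours post inoculation (hpi).

#' A substrate spike event
#'
#' Spikes are triggered either at a fixed time or when a state condition is
#' met. The state condition used in the electron-competition experiments is
#' "NO2- drawn down below a given amount" (e.g. one third of the initial
#' 100 umol reduced -> `when_no2_below = 100 * 2/3`).
#'
#' @param species `"NO3"` or `"NO2"`.
#' @param amount Amount added (umol), > 0.
#' @param at_time Fixed trigger time (hpi), or `NULL`.
#' @param when_no2_below State trigger: fires at the first trajectory grid
#'   time where the NO2- pool is at or below this amount (umol), or `NULL`.
#' @return A `spike_event` object.
#' @export
spike_event <- function(species = c("NO3", "NO2"), amount, at_time = NULL,
                        when_no2_below = NULL) {
  species <- match.arg(species)
  if (!.is_number(amount) || amount <= 0) {
    stop("spike amount must be > 0", call. = FALSE)
  }
  if (is.null(at_time) == is.null(when_no2_below)) {
    stop("give exactly one of at_time or when_no2_below", call. = FALSE)
  }
  structure(list(species = species, amount = amount, at_time = at_time,
                 when_no2_below = when_no2_below), class = "spike_event")
}

#' Incubation protocol
#'
#' @param duration Run length (h).
#' @param initial_o2_percent Initial O2 volume percent in the He headspace.
#' @param initial_no3,initial_no2 Initial substrate amounts (umol per vial).
#' @param inoculum_biomass Inoculum in biomass units (1 unit = OD600 of 1 in
#'   the 50 mL culture; the standard inoculum of OD600 0.05-0.10 maps to
#'   0.05-0.10 units).
#' @param preinduced If `TRUE` the culture enters the vial with a fully
#'   expressed denitrification proteome (all activities 1), as after anoxic
#'   pre-cultivation on NO3-.
#' @param spike_events List of [spike_event()]s.
#' @param sampling_gas Strictly increasing gas autosampling times (hpi).
#' @param sampling_no2 Strictly increasing NO2- sampling times (hpi); these
#'   samples are drawn from a parallel vial and do not disturb the headspace.
#' @return A `protocol` object.
#' @export
protocol <- function(duration = 48, initial_o2_percent = 1,
                     initial_no3 = 100, initial_no2 = 0,
                     inoculum_biomass = 0.075, preinduced = FALSE,
                     spike_events = list(),
                     sampling_gas = seq(1, duration, by = 1),
                     sampling_no2 = seq(0, duration, by = 2)) {
  stopifnot(.is_number(duration), duration > 0,
            initial_o2_percent >= 0, initial_no3 >= 0, initial_no2 >= 0,
            inoculum_biomass >= 0, is.logical(preinduced))
  for (s in list(sampling_gas, sampling_no2)) {
    if (length(s) && (any(diff(s) <= 0) || any(s < 0) ||
                      any(s > duration + 1e-9))) {
      stop("sampling schedules must be strictly increasing and within ",
           "[0, duration]", call. = FALSE)
    }
  }
  for (sp in spike_events) {
    if (!inherits(sp, "spike_event")) {
      stop("spike_events must be a list of spike_event objects", call. = FALSE)
    }
    if (!is.null(sp$at_time) && (sp$at_time <= 0 || sp$at_time > duration)) {
      stop("fixed spike times must lie within (0, duration]", call. = FALSE)
    }
  }
  structure(
    list(duration = duration, initial_o2_percent = initial_o2_percent,
         initial_no3 = initial_no3, initial_no2 = initial_no2,
         inoculum_biomass = inoculum_biomass, preinduced = preinduced,
         spike_events = spike_events, sampling_gas = sampling_gas,
         sampling_no2 = sampling_no2),
    class = "protocol")
}
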