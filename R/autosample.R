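# Observation model of the robotized incubation system: at each gas
# sampling time the autosampler draws sample_volume mL of headspace (the
# vial state loses the corresponding amount of every gas; the volume is
# replaced with He at constant pressure) and the gas concentrations are
# reported with multiplicative detector noise. NO2- is measured in liquid
# samples from parallel replicate vials that undergo the same gas-sampling
# program (liquid draws would change the headspace-to-liquid ratio), so the
# NO2- series reads the same trajectory without an extra perturbation.

#' Measurement noise model
#'
#' Multiplicative Gaussian noise per detector, truncated at zero. Defaults
#' reflect typical relative precisions: thermal-conductivity O2/N2 1%,
#' electron-capture N2O 2%, chemiluminescence NO 5%, NO2- assay 3%.
#'
#' @param cv_o2,cv_n2,cv_n2o,cv_no,cv_no2 Coefficients of variation.
#' @return A `noise_model` object. Pass `noise = NULL` to [autosample()] for
#'   noise-free sampling.
#' @export
noise_model <- function(cv_o2 = 0.01, cv_n2 = 0.01, cv_n2o = 0.02,
                        cv_no = 0.05, cv_no2 = 0.03) {
  cv <- c(O2 = cv_o2, N2 = cv_n2, N2O = cv_n2o, NO = cv_no, NO2 = cv_no2)
  stopifnot(all(cv >= 0))
  structure(list(cv = cv), class = "noise_model")
}

# deterministic part of a sampled run: segment-wise re-simulation between
# sampling events with physical gas removal, plus the NO2- truth series
# read from the same perturbed trajectory (the parallel NO2- vials undergo
# the same gas-sampling program; only the liquid draw is taken elsewhere);
# cacheable because measurement noise does not feed back
.sample_physical <- function(cfg, pheno, protocol, dt = 0.05) {
  cc <- .sim_consts(cfg, pheno)
  st <- .init_state(cfg, pheno, protocol)
  y <- st$y
  flags <- st$flags
  vh <- cfg$headspace_volume
  vl <- cfg$liquid_volume
  denom <- vapply(.GAS_SPECIES, function(s) {
    vh + .gas_k(cfg, s) * vl
  }, numeric(1))
  gs <- protocol$sampling_gas
  if (length(gs) && max(gs) > protocol$duration + 1e-9) {
    stop("gas sampling time beyond run duration", call. = FALSE)
  }
  conc <- matrix(0, nrow = length(gs), ncol = length(.GAS_SPECIES),
                 dimnames = list(NULL, .GAS_SPECIES))
  removed <- c(O2 = 0, NO = 0, N2O = 0, N2 = 0)
  prev <- 0
  segs <- list()
  for (i in seq_along(gs)) {
    res <- .simulate_core(y, flags, prev, gs[i], dt, cc, pheno, protocol)
    segs[[i]] <- if (i == 1) res$mat else res$mat[-1, , drop = FALSE]
    y <- res$y
    flags <- res$flags
    prev <- gs[i]
    for (s in .GAS_SPECIES) {
      cg <- max(y[[s]], 0) / denom[[s]]  # umol/mL in the headspace
      conc[i, s] <- cg
      rem <- cg * cfg$sample_volume
      y[[s]] <- y[[s]] - rem
      removed[[s]] <- removed[[s]] + rem
    }
  }
  if (prev < protocol$duration - 1e-9) {
    res <- .simulate_core(y, flags, prev, protocol$duration, dt, cc, pheno,
                          protocol)
    segs[[length(segs) + 1L]] <- if (length(segs)) {
      res$mat[-1, , drop = FALSE]
    } else res$mat
    y <- res$y
    flags <- res$flags
  }
  traj <- do.call(rbind, segs)
  ns <- protocol$sampling_no2
  if (length(ns) && max(ns) > protocol$duration + 1e-9) {
    stop("NO2- sampling time beyond run duration", call. = FALSE)
  }
  no2_true <- stats::approx(traj[, "time_h"], traj[, "NO2"], xout = ns,
                            rule = 1, ties = "ordered")$y
  fired <- which(flags$spike_fired)
  spike_log <- if (length(fired)) {
    data.frame(
      species = vapply(protocol$spike_events[fired],
                       function(s) s$species, ""),
      amount = vapply(protocol$spike_events[fired],
                      function(s) s$amount, 0),
      time_h = flags$spike_time[fired])
  } else {
    data.frame(species = character(), amount = numeric(), time_h = numeric())
  }
  list(gas_time = gs, conc = conc, no2_time = ns, no2_true_umol = no2_true,
       removed_cum = removed, final_state = y, traj = traj,
       spike_log = spike_log,
       o2_initial = if (protocol$initial_o2_percent > 0) {
         o2_percent_to_umol(protocol$initial_o2_percent, cfg)
       } else 0)
}

#' Sample a simulated incubation like the instrument would
#'
#' Re-simulates the vial segment-wise between gas sampling events; at each
#' event the headspace concentrations are recorded with detector noise and
#' the sampled gas is physically removed from the ongoing state
#' (sample_volume / (headspace + dissolved-equivalent) of each gas). The
#' NO2- series is read at its own (sparser) times from the same perturbed
#' trajectory without an extra headspace perturbation — the parallel NO2-
#' vials experience the same gas-sampling program, and their liquid draws
#' do not touch the headspace. Deterministic given `seed`.
#'
#' @param cfg,pheno,protocol As for [simulate_vial()].
#' @param noise A [noise_model()], or `NULL` for noise-free sampling.
#' @param seed Integer seed for the measurement noise.
#' @param dt Simulation grid step (h).
#' @param physical Optional precomputed deterministic record (an internal
#'   object returned by a previous call via `attr(run, "physical")`); the
#'   physical trajectory does not depend on the noise, so replicate noisy
#'   runs of the same scenario can reuse it.
#' @return A `sampled_run`: `$gas` (time_h plus headspace concentrations of
#'   O2, NO, N2O, N2 in umol/mL), `$no2` (time_h, no2_mM), and the metadata
#'   the analysis needs (vial config, provided NO3-, initial NO2- and O2,
#'   fired spikes, sample volume, seed).
#' @export
autosample <- function(cfg, pheno, protocol, noise = noise_model(),
                       seed = NULL, dt = 0.05, physical = NULL) {
  if (is.null(physical)) {
    physical <- .sample_physical(cfg, pheno, protocol, dt)
  }
  if (!is.null(seed)) set.seed(seed)
  cv <- if (is.null(noise)) {
    c(O2 = 0, N2 = 0, N2O = 0, NO = 0, NO2 = 0)
  } else {
    noise$cv
  }
  gas <- data.frame(time_h = physical$gas_time)
  for (s in .GAS_SPECIES) {
    x <- physical$conc[, s]
    gas[[s]] <- pmax(0, x * (1 + cv[[s]] * stats::rnorm(length(x))))
  }
  no2_true_mM <- physical$no2_true_umol / cfg$liquid_volume
  no2 <- data.frame(
    time_h = physical$no2_time,
    no2_mM = pmax(0, no2_true_mM *
                    (1 + cv[["NO2"]] * stats::rnorm(length(no2_true_mM)))))
  run <- structure(
    list(gas = gas, no2 = no2, config = cfg,
         no3_provided = protocol$initial_no3,
         no2_initial = protocol$initial_no2,
         o2_initial = physical$o2_initial,
         spikes = physical$spike_log,
         sample_volume = cfg$sample_volume,
         seed = seed),
    class = "sampled_run")
  attr(run, "physical") <- physical
  run
}

#' @export
print.sampled_run <- function(x, ...) {
  cat(sprintf(
    "<sampled_run> %d gas samplings, %d NO2- samplings, NO3- provided %g umol\n",
    nrow(x$gas), nrow(x$no2), x$no3_provided))
  if (nrow(x$spikes)) {
    cat("spikes:", paste(sprintf("%g umol %s @ %.2f h", x$spikes$amount,
                                 x$spikes$species, x$spikes$time_h),
                         collapse = "; "), "\n")
  }
  invisible(x)
}
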