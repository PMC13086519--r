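# The analysis proper: reconstruct loss-corrected cumulative pools from
# instrument-style data, infer NO3- by nitrogen mass balance (NO3- itself is
# never measured), estimate reduction rates, and partition the electron flow
# among the terminal reductases.

#' Correct headspace time series for autosampler losses
#'
#' Each gas sampling removed `sample_volume` mL of headspace (replaced with
#' He); the amount lost at sampling k is the measured concentration times the
#' sample volume, mirroring instrument practice. The corrected total at
#' sampling k is the current vial amount (headspace + equilibrium-dissolved,
#' from the measured concentration) plus everything removed before k.
#'
#' @param run A `sampled_run` (or any list with `$gas` in its schema).
#' @param cfg The [vial_config()]; defaults to the one stored in the run.
#' @return A `corrected_series` data frame with, per gas, the raw measured
#'   concentration (`*_conc`, umol/mL), the instantaneous vial total
#'   (`*_total`), the cumulative amount removed before each sampling
#'   (`*_removed_cum`) and the loss-corrected total (`*_corrected`), all in
#'   umol.
#' @export
correct_sampling_losses <- function(run, cfg = run$config) {
  gas <- run$gas
  if (is.null(gas$time_h) || is.unsorted(gas$time_h, strictly = TRUE)) {
    stop("gas sampling events must be in strictly increasing time order",
         call. = FALSE)
  }
  vs <- run$sample_volume %||% cfg$sample_volume
  out <- data.frame(time_h = gas$time_h)
  for (s in .GAS_SPECIES) {
    conc <- gas[[s]]
    if (is.null(conc)) {
      stop("missing species column \"", s, "\" in gas series", call. = FALSE)
    }
    if (any(conc < 0)) {
      warning("negative measured ", s, " concentration clipped to 0")
      conc <- pmax(conc, 0)
    }
    k <- .gas_k(cfg, s)
    total_now <- conc * (cfg$headspace_volume + k * cfg$liquid_volume)
    removed <- conc * vs
    removed_before <- cumsum(c(0, removed))[seq_along(removed)]
    out[[paste0(s, "_conc")]] <- conc
    out[[paste0(s, "_total")]] <- total_now
    out[[paste0(s, "_removed_cum")]] <- removed_before
    out[[paste0(s, "_corrected")]] <- total_now + removed_before
  }
  attr(out, "config") <- cfg
  attr(out, "o2_initial") <- run$o2_initial
  class(out) <- c("corrected_series", "data.frame")
  out
}

#' Interpolate sparse NO2- measurements onto a dense grid
#'
#' Cubic spline through the measured points (classic Forsythe-Malcolm-Moler
#' end conditions, which reproduce cubic polynomials exactly), evaluated on
#' the requested grid (no extrapolation), converted from medium
#' concentration to vial amount. Negative interpolants are clipped to zero.
#'
#' @param no2 Data frame with `time_h` and `no2_mM`.
#' @param grid Evaluation times (h) within the measurement span.
#' @param cfg A [vial_config()] (for the liquid volume).
#' @return Data frame `time_h`, `no2_umol`.
#' @export
interpolate_no2 <- function(no2, grid, cfg) {
  if (nrow(no2) < 2) {
    stop("need at least two NO2- measurements to interpolate", call. = FALSE)
  }
  if (min(grid) < min(no2$time_h) - 1e-9 ||
      max(grid) > max(no2$time_h) + 1e-9) {
    stop("grid extends beyond the NO2- measurement span (no extrapolation)",
         call. = FALSE)
  }
  f <- stats::splinefun(no2$time_h, no2$no2_mM * cfg$liquid_volume,
                        method = "fmm")
  data.frame(time_h = grid, no2_umol = pmax(0, f(grid)))
}

#' Infer NO3- and cumulative reduction pools by nitrogen mass balance
#'
#' NO3- is not measured; it is inferred from the provided (+ spiked) NO3--N
#' minus everything accounted for downstream. Cumulative amounts reduced at
#' each step (umol N): R3 (NO3- reduced) = change in the NO2- pool + R2;
#' R2 (NO2- reduced) = NO-N + N2O-N + N2-N produced; R1 = N2O-N + N2-N;
#' R0 = N2-N. Gas pools start at zero, so corrected totals are cumulative
#' productions.
#'
#' @param corrected A [correct_sampling_losses()] result.
#' @param no2_dense An [interpolate_no2()] result defining the common grid.
#' @param no3_provided Initially provided NO3- (umol).
#' @param spikes Data frame of fired spikes (`species`, `amount`, `time_h`),
#'   or `NULL`.
#' @param no2_initial Initially provided NO2- (umol); nonzero only in the
#'   electron-competition protocols.
#' @param tol Relative tolerance on R3 exceeding the supplied N before a
#'   data-inconsistency error is raised.
#' @return An `n_pools` data frame: grid, pool amounts in N units, R3..R0
#'   and inferred NO3-(t).
#' @export
infer_no3_pools <- function(corrected, no2_dense, no3_provided,
                            spikes = NULL, no2_initial = 0, tol = 0.05) {
  grid <- no2_dense$time_h
  ct <- corrected$time_h
  res <- function(col) stats::approx(ct, corrected[[col]], xout = grid,
                                     rule = 2)$y
  no2n <- no2_dense$no2_umol
  non <- res("NO_corrected")
  n2on <- 2 * res("N2O_corrected")
  n2n <- 2 * res("N2_corrected")
  spiked <- function(species) {
    if (is.null(spikes) || !nrow(spikes)) return(numeric(length(grid)))
    vapply(grid, function(t) {
      sum(spikes$amount[spikes$species == species & spikes$time_h <= t + 1e-9])
    }, numeric(1))
  }
  r2 <- pmax(non + n2on + n2n, 0)
  r1 <- pmax(n2on + n2n, 0)
  r0 <- pmax(n2n, 0)
  r3 <- pmax(no2n - no2_initial - spiked("NO2") + r2, 0)
  supplied <- no3_provided + spiked("NO3")
  total_n <- no3_provided + no2_initial +
    if (is.null(spikes) || !nrow(spikes)) 0 else sum(spikes$amount)
  # a persistent or terminal excess of R3 over the supplied N flags corrupt
  # inputs (wrong units, wrong metadata); isolated excursions at single
  # sampling points are ordinary measurement noise and pass through
  excess <- r3 - supplied
  allowed <- tol * max(total_n, 1) + 1e-6
  if (excess[length(excess)] > allowed ||
      mean(pmax(excess, 0)) > allowed) {
    stop("data inconsistency: inferred NO3- reduction exceeds supplied N ",
         "by more than ", 100 * tol, "%", call. = FALSE)
  }
  no3 <- pmax(supplied - r3, 0)
  out <- data.frame(time_h = grid, no2_n = no2n, no_n = non, n2o_n = n2on,
                    n2_n = n2n, r3 = r3, r2 = r2, r1 = r1, r0 = r0,
                    no3 = no3)
  attr(out, "no3_provided") <- no3_provided
  attr(out, "no2_initial") <- no2_initial
  attr(out, "spikes") <- spikes
  class(out) <- c("n_pools", "data.frame")
  out
}

# derivative of a series on a (near-)uniform grid
.series_deriv <- function(t, x, method = c("central", "spline"),
                          spar = NULL) {
  method <- match.arg(method)
  n <- length(t)
  if (n < 3) stop("need at least 3 grid points for rates", call. = FALSE)
  if (method == "central") {
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
    d[1] <- (x[2] - x[1]) / (t[2] - t[1])
    d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
    d
  } else {
    ss <- stats::smooth.spline(t, x, spar = spar %||% 0.5)
    stats::predict(ss, t, deriv = 1)$y
  }
}

#' Per-step reduction rates from cumulative pools
#'
#' Differentiates R3..R0 by smoothed central differences (default) or a
#' smoothing-spline derivative. Negative rates are clipped to zero for the
#' electron-flow computation; the raw signed rates are retained for
#' diagnostics (`raw_*` columns).
#'
#' @param pools An [infer_no3_pools()] result.
#' @param method `"central"` or `"spline"`.
#' @param spar Smoothing parameter for the spline method.
#' @return A `reduction_rates` data frame (umol N / h).
#' @export
reduction_rates <- function(pools, method = c("central", "spline"),
                            spar = NULL) {
  method <- match.arg(method)
  t <- pools$time_h
  out <- data.frame(time_h = t)
  for (nm in c("r3", "r2", "r1", "r0")) {
    d <- .series_deriv(t, pools[[nm]], method, spar)
    out[[paste0("d", nm)]] <- pmax(d, 0)
    out[[paste0("raw_d", nm)]] <- d
  }
  attr(out, "pools") <- pools
  class(out) <- c("reduction_rates", "data.frame")
  out
}

#' O2 consumption rate from the corrected O2 series
#'
#' @param corrected A [correct_sampling_losses()] result.
#' @param grid Common analysis grid (h).
#' @param o2_initial Initial total vial O2 (umol); defaults to the value
#'   recorded in the corrected series.
#' @inheritParams reduction_rates
#' @return Consumption rate (umol O2 / h) on the grid, clipped at 0.
#' @export
o2_consumption_rate <- function(corrected, grid,
                                o2_initial = attr(corrected, "o2_initial"),
                                method = c("central", "spline"),
                                spar = NULL) {
  method <- match.arg(method)
  o2 <- stats::approx(corrected$time_h, corrected$O2_corrected, xout = grid,
                      rule = 2)$y
  consumed <- (o2_initial %||% o2[1]) - o2
  pmax(.series_deriv(grid, consumed, method, spar), 0)
}

#' Electron flows to the terminal reductases
#'
#' Multiplies each reduction rate by its electrons-per-N (per O2 for the O2
#' step): V_eNar/Nap = 2 dR3/dt, V_eNir = dR2/dt, V_eNor = dR1/dt,
#' V_eNos = dR0/dt, V_eO2 = 4 x O2 consumption rate.
#'
#' @param rates A [reduction_rates()] result.
#' @param o2_rate O2 consumption rate (umol O2/h) on the same grid (0 if
#'   omitted).
#' @param table A [stoichiometry_table()].
#' @return An `electron_flows` data frame (umol e- / h) with `ve_total`.
#' @export
electron_flows <- function(rates, o2_rate = NULL,
                           table = stoichiometry_table()) {
  n <- nrow(rates)
  if (is.null(o2_rate)) o2_rate <- numeric(n)
  if (length(o2_rate) != n) {
    stop("o2_rate is not on the same grid as the rates", call. = FALSE)
  }
  out <- data.frame(
    time_h = rates$time_h,
    ve_o2 = electrons_for_step("O2", table) * o2_rate,
    ve_narnap = electrons_for_step("NO3->NO2", table) * rates$dr3,
    ve_nir = electrons_for_step("NO2->NO", table) * rates$dr2,
    ve_nor = electrons_for_step("NO->N2O", table) * rates$dr1,
    ve_nos = electrons_for_step("N2O->N2", table) * rates$dr0)
  out$ve_total <- out$ve_o2 + out$ve_narnap + out$ve_nir + out$ve_nor +
    out$ve_nos
  attr(out, "pools") <- attr(rates, "pools")
  class(out) <- c("electron_flows", "data.frame")
  out
}

#' Detect the onset of NO3- reduction
#'
#' Onset is the first grid time at which cumulative NO3- reduction (R3)
#' exceeds a threshold fraction of the provided NO3--N; the vial O2 at that
#' time (and its equilibrium liquid concentration) is reported.
#'
#' @param pools An [infer_no3_pools()] result.
#' @param corrected Optional [correct_sampling_losses()] result supplying
#'   the O2 series.
#' @param threshold_frac Fraction of provided NO3--N (default 1%).
#' @return An `onset_result` list: `onset_h`, `o2_umol`, `o2_liquid_uM`,
#'   `no_onset` flag.
#' @export
detect_onset <- function(pools, corrected = NULL, threshold_frac = 0.01) {
  prov <- attr(pools, "no3_provided")
  idx <- which(pools$r3 > threshold_frac * prov)
  if (!length(idx)) {
    return(structure(list(onset_h = NA_real_, o2_umol = NA_real_,
                          o2_liquid_uM = NA_real_, no_onset = TRUE),
                     class = "onset_result"))
  }
  onset <- pools$time_h[idx[1]]
  o2 <- o2l <- NA_real_
  if (!is.null(corrected)) {
    o2 <- stats::approx(corrected$time_h, corrected$O2_total, xout = onset,
                        rule = 2)$y
    cfg <- attr(corrected, "config")
    if (!is.null(cfg)) {
      o2l <- equilibrium_partition(max(o2, 0), "O2", cfg)$liquid_conc_uM
    }
  }
  structure(list(onset_h = onset, o2_umol = o2, o2_liquid_uM = o2l,
                 no_onset = FALSE), class = "onset_result")
}

#' Detect the electron-flow dip at the NO3- to NO2- transition
#'
#' Full nitrite accumulators show a prominent dip in total electron flow
#' when NO3- runs out and only a subpopulation carries on with NO2-. Depth
#' is 1 - V_e,total at the dip over the median V_e,total of the hours
#' preceding NO3- depletion. The dip is the deepest *local* minimum inside
#' a window centred on the depletion time whose flow rebounds afterwards
#' (by at least `recovery_frac` of the plateau at any later point of the
#' run — the post-dip recovery can be slower than the window); the terminal
#' decline of a finished run rebounds nowhere and therefore does not count
#' as a dip (smooth-transition phenotypes score 0).
#'
#' @param flows An [electron_flows()] result.
#' @param pools The matching [infer_no3_pools()] result.
#' @param window Half-width (h) of the window centred on NO3- depletion.
#' @param baseline Length (h) of the pre-transition window whose median is
#'   the reference plateau.
#' @param depletion_frac NO3- fraction of supplied N below which the pool
#'   counts as depleted.
#' @param recovery_frac Minimum rebound after the minimum, as a fraction of
#'   the plateau, for a minimum to count as a transient dip.
#' @return A `dip_result` list: `dip_time_h`, `depth` in [0, 1],
#'   `depletion_h`, `plateau`, `window_h`; or `no_depletion = TRUE`.
#' @export
detect_dip <- function(flows, pools = attr(flows, "pools"), window = 3,
                       baseline = 5, depletion_frac = 0.05,
                       recovery_frac = 0.1) {
  supplied <- attr(pools, "no3_provided") +
    sum((attr(pools, "spikes") %||% data.frame(amount = numeric()))$amount)
  idx <- which(pools$no3 <= depletion_frac * supplied &
                 pools$r3 > depletion_frac * supplied)
  if (!length(idx)) {
    return(structure(list(no_depletion = TRUE, depth = NA_real_,
                          dip_time_h = NA_real_), class = "dip_result"))
  }
  tdep <- pools$time_h[idx[1]]
  t <- flows$time_h
  if (tdep - baseline < min(t) - 1e-9 || tdep + window > max(t) + 1e-9) {
    stop("dip window extends outside the analyzed run", call. = FALSE)
  }
  pre <- t >= tdep - baseline & t <= tdep
  plateau <- stats::median(flows$ve_total[pre])
  win <- which(abs(t - tdep) <= window)
  depth <- 0
  tmin <- tdep
  if (is.finite(plateau) && plateau > 0 && length(win) >= 3) {
    vall <- flows$ve_total
    len <- length(vall)
    for (j in win) {
      if (j <= 1 || j >= len) next
      if (vall[j] <= vall[j - 1] && vall[j] <= vall[j + 1] &&
          max(vall[j:len]) - vall[j] >= recovery_frac * plateau) {
        d <- min(1, max(0, 1 - vall[j] / plateau))
        if (d > depth) {
          depth <- d
          tmin <- t[j]
        }
      }
    }
  }
  structure(list(no_depletion = FALSE, depth = depth, dip_time_h = tmin,
                 depletion_h = tdep, plateau = plateau,
                 window_h = c(tdep - window, tdep + window)),
            class = "dip_result")
}

#' Overlap between two electron-flow curves
#'
#' Area of min(a, b) over time, relative to the smaller of the two areas;
#' sequential reduction gives near-zero overlap, simultaneous reduction a
#' large one.
#'
#' @param flows An [electron_flows()] result.
#' @param a,b Column names.
#' @return Dimensionless fraction in [0, 1].
#' @export
flow_overlap <- function(flows, a = "ve_narnap", b = "ve_nir") {
  t <- flows$time_h
  aa <- .trapz(t, flows[[a]])
  ab <- .trapz(t, flows[[b]])
  if (min(aa, ab) <= 0) return(0)
  .trapz(t, pmin(flows[[a]], flows[[b]])) / min(aa, ab)
}

#' Run the full kinetics analysis on a sampled run
#'
#' Pipeline: loss correction, NO2- spline interpolation onto the gas grid,
#' N mass balance, reduction rates, O2 consumption, electron flows, onset
#' and dip detection.
#'
#' @param run A `sampled_run` (from [autosample()] or [read_sampled_run()]).
#' @param cfg Vial configuration; defaults to the one stored in the run.
#' @param rate_method Differentiation method, see [reduction_rates()].
#' @param spar Smoothing parameter when `rate_method = "spline"`.
#' @return A `kinetics_analysis` list with elements `corrected`, `no2_dense`,
#'   `pools`, `rates`, `o2_rate`, `flows`, `onset`, `dip`.
#' @export
analyze_run <- function(run, cfg = run$config,
                        rate_method = c("central", "spline"), spar = NULL) {
  rate_method <- match.arg(rate_method)
  corr <- correct_sampling_losses(run, cfg)
  span <- range(run$no2$time_h)
  grid <- corr$time_h[corr$time_h >= span[1] - 1e-9 &
                        corr$time_h <= span[2] + 1e-9]
  no2d <- interpolate_no2(run$no2, grid, cfg)
  pools <- infer_no3_pools(corr, no2d, run$no3_provided,
                           spikes = run$spikes,
                           no2_initial = run$no2_initial %||% 0)
  rr <- reduction_rates(pools, method = rate_method, spar = spar)
  o2r <- o2_consumption_rate(corr, grid, run$o2_initial,
                             method = rate_method, spar = spar)
  fl <- electron_flows(rr, o2r)
  onset <- detect_onset(pools, corr)
  dip <- tryCatch(detect_dip(fl, pools), error = function(e) NULL)
  structure(list(corrected = corr, no2_dense = no2d, pools = pools,
                 rates = rr, o2_rate = o2r, flows = fl, onset = onset,
                 dip = dip),
            class = "kinetics_analysis")
}
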