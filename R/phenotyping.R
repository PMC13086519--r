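# Phenotype classification: the fraction of supplied NO3--N transiently held
# as NO2- places a strain in one of three classes — full (FNA), partial
# (PNA) or low (LNA) nitrite accumulators — and the transient maxima of the
# gaseous intermediates are summarized alongside.

#' Maxima of the transient intermediate pools
#'
#' @param pools An [infer_no3_pools()] result.
#' @return List with the maximum NO2- pool (umol; NO2--N equals NO2-), the
#'   maximum NO pool (nmol), the maximum N2O pool (nmol per molecule of N2O,
#'   i.e. half the N2O-N), and the times of the maxima.
#' @export
max_transients <- function(pools) {
  if (!nrow(pools)) stop("empty pools grid", call. = FALSE)
  i2 <- which.max(pools$no2_n)
  ino <- which.max(pools$no_n)
  in2o <- which.max(pools$n2o_n)
  list(max_no2_umol = pools$no2_n[i2], t_max_no2 = pools$time_h[i2],
       max_no_nmol = 1000 * pools$no_n[ino], t_max_no = pools$time_h[ino],
       max_n2o_nmol = 1000 * pools$n2o_n[in2o] / 2,
       t_max_n2o = pools$time_h[in2o])
}

#' Classify a run by its transient NO2- fraction
#'
#' The fraction is max transient NO2--N over provided (+ spiked) NO3--N.
#' Low accumulators held at most 20% of the supplied N as NO2-, full
#' accumulators at least 89%; the observed gap between partial (<= 62.2%)
#' and full (>= 89%) accumulators is split at 0.80.
#'
#' @param fraction Dimensionless NO2- fraction(s), >= 0.
#' @param lna_max Upper fraction bound of the LNA class (inclusive).
#' @param fna_min Lower fraction bound of the FNA class (inclusive).
#' @return Character vector of labels in `{FNA, PNA, LNA}`.
#' @export
classify_no2_fraction <- function(fraction, lna_max = 0.20, fna_min = 0.80) {
  if (any(fraction < 0)) stop("fraction must be >= 0", call. = FALSE)
  stopifnot(lna_max < fna_min)
  ifelse(fraction <= lna_max, "LNA",
         ifelse(fraction >= fna_min, "FNA", "PNA"))
}

#' Full pipeline: analyze a sampled run and call its phenotype
#'
#' Composition of [analyze_run()], [max_transients()] and
#' [classify_no2_fraction()].
#'
#' @param run A `sampled_run` or a path readable by [read_sampled_run()].
#' @param cfg Vial configuration (default: stored in the run).
#' @param lna_max,fna_min Classification thresholds.
#' @param ... Passed to [analyze_run()].
#' @return A `phenotype_call` list: `label`, `no2_fraction`, the transient
#'   maxima with times, onset time and O2, and the dip depth.
#' @export
summarize_run <- function(run, cfg = NULL, lna_max = 0.20, fna_min = 0.80,
                          ...) {
  if (is.character(run)) run <- read_sampled_run(run)
  cfg <- cfg %||% run$config
  an <- analyze_run(run, cfg, ...)
  mt <- max_transients(an$pools)
  spiked_no3 <- if (nrow(run$spikes)) {
    sum(run$spikes$amount[run$spikes$species == "NO3"])
  } else 0
  denom <- run$no3_provided + spiked_no3
  frac <- if (denom > 0) mt$max_no2_umol / denom else NA_real_
  structure(
    c(list(label = if (is.na(frac)) NA_character_ else
             classify_no2_fraction(frac, lna_max, fna_min),
           no2_fraction = frac),
      mt,
      list(onset_h = an$onset$onset_h, onset_o2_umol = an$onset$o2_umol,
           dip_depth = if (is.null(an$dip) || isTRUE(an$dip$no_depletion)) {
             NA_real_
           } else an$dip$depth,
           dip_time_h = if (is.null(an$dip) ||
                            isTRUE(an$dip$no_depletion)) {
             NA_real_
           } else an$dip$dip_time_h,
           no3_supplied = denom)),
    class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat(sprintf("<phenotype_call> %s: max NO2- %.1f umol (%.1f%% of %g umol N)\n",
              x$label, x$max_no2_umol, 100 * x$no2_fraction, x$no3_supplied))
  cat(sprintf("  peaks: NO %.1f nmol @ %.1f h, N2O %.1f nmol @ %.1f h\n",
              x$max_no_nmol, x$t_max_no, x$max_n2o_nmol, x$t_max_n2o))
  cat(sprintf("  onset %.2f h at O2 %.1f umol; dip depth %s\n",
              x$onset_h, x$onset_o2_umol,
              if (is.na(x$dip_depth)) "-" else sprintf("%.2f", x$dip_depth)))
  invisible(x)
}
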