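# helper: a hand-built sampled run with constant headspace concentrations
flat_run <- function(conc = 0.2, s = 6, cfg = vial_config()) {
  gas <- data.frame(time_h = seq_len(s))
  for (g in c("O2", "NO", "N2O", "N2")) gas[[g]] <- rep(conc, s)
  structure(list(gas = gas,
                 no2 = data.frame(time_h = c(0, s), no2_mM = c(0, 0)),
                 config = cfg, no3_provided = 100, no2_initial = 0,
                 o2_initial = 30,
                 spikes = data.frame(species = character(),
                                     amount = numeric(),
                                     time_h = numeric()),
                 sample_volume = cfg$sample_volume, seed = NULL),
            class = "sampled_run")
}

test_that("sampling-loss correction has the closed-form cumulative term", {
  cfg <- vial_config()
  s <- 6
  conc <- 0.2
  run <- flat_run(conc, s, cfg)
  corr <- correct_sampling_losses(run, cfg)
  k <- denitkin:::.gas_k(cfg, "N2")
  # constant concentration: corrected_k = c (V_h + k V_l) + (k-1) c V_s
  expect_equal(corr$N2_corrected,
               conc * (70 + k * 50) + (seq_len(s) - 1) * conc * 1,
               tolerance = 1e-12)
  expect_equal(corr$N2_removed_cum[s], (s - 1) * conc * 1)
  # zero sample volume: corrected equals the instantaneous total
  cfg0 <- vial_config(sample_volume = 0)
  run0 <- flat_run(conc, s, cfg0)
  run0$sample_volume <- 0
  corr0 <- correct_sampling_losses(run0, cfg0)
  expect_equal(corr0$N2_corrected, corr0$N2_total)
  # schema errors
  bad <- flat_run()
  bad$gas$N2O <- NULL
  expect_error(correct_sampling_losses(bad, cfg), "N2O")
  neg <- flat_run()
  neg$gas$NO[2] <- -0.1
  expect_warning(correct_sampling_losses(neg, cfg), "clipped")
})

test_that("corrected series reconstruct the sampled vial's cumulative production", {
  for (nm in c("FNA_ref", "LNA_ref")) {
    run <- noise_free_run(nm)
    phys <- attr(run, "physical")
    corr <- correct_sampling_losses(run)
    # final corrected total = vial content at the end + all removed gas
    y <- phys$final_state
    for (g in c("N2", "N2O", "NO")) {
      produced <- y[[g]] + phys$removed_cum[[g]]
      n <- nrow(corr)
      expect_equal(corr[[paste0(g, "_corrected")]][n], produced,
                   tolerance = max(1e-3 * produced, 1e-9))
    }
    # mid-run: measured concentration times (V_h + k V_l) recovers the
    # pre-removal vial amount from the dense trajectory
    tr <- phys$traj
    i <- round(nrow(corr) / 2)
    t_i <- corr$time_h[i]
    truth_n2 <- approx(tr[, "time_h"], tr[, "N2"], t_i, ties = "ordered")$y
    expect_equal(corr$N2_total[i], truth_n2,
                 tolerance = max(1e-3 * truth_n2, 1e-6))
  }
})

test_that("NO2- spline interpolation is exact where it should be", {
  cfg <- vial_config()
  # knots reproduced exactly
  no2 <- data.frame(time_h = c(0, 2, 4, 6), no2_mM = c(0, 1, 0.5, 0.2))
  d <- interpolate_no2(no2, c(0, 2, 4, 6), cfg)
  expect_equal(d$no2_umol, no2$no2_mM * 50)
  # collinear points give back the line
  lin <- data.frame(time_h = 0:5, no2_mM = 0.1 * (0:5))
  g <- seq(0.25, 4.75, 0.5)
  dl <- interpolate_no2(lin, g, cfg)
  expect_equal(dl$no2_umol, 0.1 * g * 50, tolerance = 1e-10)
  # a sampled cubic is reproduced to numerical precision in the interior
  f <- function(t) 2 + 0.5 * t - 0.1 * t^2 + 0.01 * t^3
  cub <- data.frame(time_h = 0:10, no2_mM = f(0:10))
  gi <- seq(2, 8, 0.25)  # natural spline: away from the free ends
  dc <- interpolate_no2(cub, gi, cfg)
  expect_equal(dc$no2_umol, f(gi) * 50, tolerance = 1e-9)
  # error paths
  expect_error(interpolate_no2(no2[1, ], 0, cfg), "at least two")
  expect_error(interpolate_no2(no2, c(-1, 2), cfg), "extrapolation")
  expect_error(interpolate_no2(no2, c(2, 7), cfg), "extrapolation")
})

test_that("N mass balance infers NO3- without measuring it", {
  cfg <- vial_config()
  # nothing happened: all pools zero, NO3- stays at the provided amount
  run <- flat_run(0, 6, cfg)
  corr <- correct_sampling_losses(run, cfg)
  no2d <- data.frame(time_h = 1:6, no2_umol = numeric(6))
  pools <- infer_no3_pools(corr, no2d, 100)
  expect_equal(pools$no3, rep(100, 6))
  expect_equal(pools$r3 + pools$r2 + pools$r1 + pools$r0, numeric(6))

  # terminal balance of a complete run: everything ends as N2-N
  an <- noise_free_analysis("FNA_ref")
  n <- nrow(an$pools)
  for (r in c("r3", "r2", "r1", "r0")) {
    expect_equal(an$pools[[r]][n], 100, tolerance = 0.01)
  }
  expect_lt(an$pools$no3[n], 0.5)

  # inferred NO3-(t) tracks the sampled vial's truth within 1% of provided
  for (nm in c("FNA_ref", "PNA_ref", "LNA_ref")) {
    an <- noise_free_analysis(nm)
    tr <- attr(noise_free_run(nm), "physical")$traj
    no3_t <- approx(tr[, "time_h"], tr[, "NO3"], an$pools$time_h,
                    ties = "ordered")$y
    expect_lt(max(abs(an$pools$no3 - no3_t)), 0.01 * 100)
  }

  # gross inconsistency triggers the data error (NO2- in wrong units)
  bad_no2 <- data.frame(time_h = 1:6, no2_umol = rep(500, 6))
  expect_error(infer_no3_pools(corr, bad_no2, 100), "inconsistency")
})

test_that("R pools are ordered and monotone on NO3--fed presets", {
  for (nm in c("FNA_ref", "PNA_ref", "LNA_ref")) {
    p <- noise_free_analysis(nm)$pools
    expect_true(all(p$r3 >= p$r2 - 1e-9))
    expect_true(all(p$r2 >= p$r1 - 1e-9))
    expect_true(all(p$r1 >= p$r0 - 1e-9))
    expect_true(all(p$r0 >= -1e-9))
    for (r in c("r3", "r2", "r1", "r0")) {
      # non-decreasing within the spline-interpolation tolerance (2% of
      # the supplied N; ringing at the NO2- peak corner)
      expect_true(all(diff(p[[r]]) > -2))
    }
    expect_true(all(p$no3 >= 0))
  }
})

test_that("rate estimation recovers linear and constant pools", {
  grid <- 0:10
  pools <- structure(
    data.frame(time_h = grid, no2_n = 0, no_n = 0, n2o_n = 0, n2_n = 0,
               r3 = 3 * grid, r2 = rep(5, 11), r1 = 0, r0 = 0,
               no3 = 100 - 3 * grid),
    class = c("n_pools", "data.frame"))
  attr(pools, "no3_provided") <- 100
  rr <- reduction_rates(pools)
  expect_equal(rr$dr3, rep(3, 11))
  expect_equal(rr$dr2, rep(0, 11))
  rs <- reduction_rates(pools, method = "spline")
  expect_equal(rs$dr3, rep(3, 11), tolerance = 1e-6)
  expect_error(reduction_rates(pools[1:2, ]), "3 grid points")
})

test_that("the FNA phenotype halts NO2- reduction while NO3- remains", {
  tr <- preset_truth("FNA_ref")
  sel <- tr$NO3 > 10
  peak_rate3 <- max(tr$ve_narnap) / 2  # umol N/h
  expect_lt(max(tr$ve_nir[sel]), 0.02 * peak_rate3)
})

test_that("electron flows integrate to the stoichiometric total", {
  # 100 umol NO3--N fully denitrified carries 500 umol of electrons
  for (nm in c("FNA_ref", "PNA_ref", "LNA_ref")) {
    p <- noise_free_analysis(nm)$pools
    n <- nrow(p)
    e_total <- 2 * p$r3[n] + p$r2[n] + p$r1[n] + p$r0[n]
    expect_equal(e_total, 500, tolerance = 0.01 * 500)
  }
  # zero rates give zero flows
  rr <- structure(data.frame(time_h = 0:4, dr3 = 0, dr2 = 0, dr1 = 0,
                             dr0 = 0), class = c("reduction_rates",
                                                 "data.frame"))
  fl <- electron_flows(rr, numeric(5))
  expect_equal(fl$ve_total, numeric(5))
  expect_error(electron_flows(rr, numeric(3)), "grid")
})

test_that("flow overlap separates sequential from simultaneous reduction", {
  expect_lt(flow_overlap(noise_free_analysis("FNA_ref")$flows), 0.05)
  expect_gt(flow_overlap(noise_free_analysis("LNA_ref")$flows), 0.30)
})

test_that("onset detection reports the O2 window and behaves monotonically", {
  an <- noise_free_analysis("FNA_ref")
  on <- detect_onset(an$pools, an$corrected)
  expect_false(on$no_onset)
  expect_gte(on$o2_umol, 10)
  expect_lte(on$o2_umol, 15)
  # onset within one sampling interval of the sampled vial's truth
  tr <- attr(noise_free_run("FNA_ref"), "physical")$traj
  t_true <- tr[which(100 - tr[, "NO3"] > 1)[1], "time_h"]
  expect_lte(abs(on$onset_h - t_true), 1)
  # raising the threshold never makes the onset earlier
  o2 <- detect_onset(an$pools, an$corrected, threshold_frac = 0.05)
  expect_gte(o2$onset_h, on$onset_h)
  # a run with no denitrification is flagged
  cfg <- vial_config()
  run <- flat_run(0, 6, cfg)
  corr <- correct_sampling_losses(run, cfg)
  pools <- infer_no3_pools(corr, data.frame(time_h = 1:6,
                                            no2_umol = numeric(6)), 100)
  expect_true(detect_onset(pools, corr)$no_onset)
})

test_that("dip detection scores transition dips, not terminal shutdown", {
  # constant flow: no dip
  grid <- 0:30
  pools <- structure(
    data.frame(time_h = grid, no2_n = 0, no_n = 0, n2o_n = 0, n2_n = 0,
               r3 = pmin(10 * grid, 100), r2 = 0, r1 = 0, r0 = 0,
               no3 = pmax(100 - 10 * grid, 0)),
    class = c("n_pools", "data.frame"))
  attr(pools, "no3_provided") <- 100
  flows <- structure(
    data.frame(time_h = grid, ve_o2 = 0, ve_narnap = 20, ve_nir = 0,
               ve_nor = 0, ve_nos = 0, ve_total = 20),
    class = c("electron_flows", "data.frame"))
  expect_equal(detect_dip(flows, pools)$depth, 0)

  # the FNA transition dip is deep; the smooth LNA transition scores ~0
  fna <- noise_free_analysis("FNA_ref")
  lna <- noise_free_analysis("LNA_ref")
  d_fna <- detect_dip(fna$flows, fna$pools)
  d_lna <- detect_dip(lna$flows, lna$pools)
  expect_gt(d_fna$depth, d_lna$depth)
  expect_gt(d_fna$depth, 0.3)
  expect_lt(d_lna$depth, 0.1)

  # depth stays in [0, 1] for arbitrary flow shapes
  set.seed(11)
  for (i in 1:20) {
    v <- abs(rnorm(31, 20, 10))
    fl <- flows
    fl$ve_total <- v
    d <- detect_dip(fl, pools)
    expect_gte(d$depth, 0)
    expect_lte(d$depth, 1)
  }
})

test_that("noise-free round trip recovers the sampled vial's kinetics", {
  for (nm in c("FNA_ref", "PNA_ref", "LNA_ref")) {
    an <- noise_free_analysis(nm)
    tr <- attr(noise_free_run(nm), "physical")$traj
    # transient NO2- maximum within 1% of the provided NO3--N
    expect_lt(abs(max(an$pools$no2_n) - max(tr[, "NO2"])), 1)
    # cumulative electron turnover within 1%
    n <- nrow(an$pools)
    e_an <- 2 * an$pools$r3[n] + an$pools$r2[n] + an$pools$r1[n] +
      an$pools$r0[n]
    expect_equal(e_an, 500, tolerance = 0.01 * 500)
  }
})
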