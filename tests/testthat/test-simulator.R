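test_that("a sterile vial stays inert", {
  ps <- preset("FNA_ref")
  pr <- ps$protocol
  pr$inoculum_biomass <- 0
  pr$duration <- 10
  pr$sampling_gas <- seq(1, 10, 1)
  pr$sampling_no2 <- seq(0, 10, 2)
  tr <- simulate_vial(ps$config, ps$phenotype, pr)
  expect_equal(max(abs(tr$NO3 - 100)), 0)
  expect_equal(diff(range(tr$O2)), 0)
  expect_equal(max(tr$N2), 0)
})

test_that("nitrogen is conserved on every preset, including sampled-out N", {
  for (nm in c("FNA_ref", "PNA_ref", "LNA_ref", "competition_FNA")) {
    tr <- preset_truth(nm)
    ev <- attr(tr, "events")
    spiked <- vapply(tr$time_h, function(t) {
      if (!nrow(ev$spikes)) return(0)
      sum(ev$spikes$amount[ev$spikes$time_h < t - 1e-9])
    }, numeric(1))
    n0 <- total_n(tr)[1]
    drift <- abs(total_n(tr) - spiked - n0) / n0
    expect_lt(max(drift), 1e-6)

    # sampled vial: final state + everything removed must balance too
    phys <- preset_physical(nm)$physical
    y <- phys$final_state
    n_end <- y[["NO3"]] + y[["NO2"]] + y[["NO"]] + 2 * y[["N2O"]] +
      2 * y[["N2"]]
    removed_n <- phys$removed_cum[["NO"]] + 2 * phys$removed_cum[["N2O"]] +
      2 * phys$removed_cum[["N2"]]
    n_in <- n0 +
      if (nrow(phys$spike_log)) sum(phys$spike_log$amount) else 0
    expect_lt(abs(n_end + removed_n - n_in) / n_in, 1e-6)
  }
})

test_that("electron bookkeeping closes: integrated flow equals stoichiometric demand", {
  for (nm in c("FNA_ref", "LNA_ref")) {
    tr <- preset_truth(nm)
    t <- tr$time_h
    e_delivered <- denitkin:::.trapz(t, tr$ve_total)
    n <- nrow(tr)
    r3 <- 100 - tr$NO3[n]
    r2 <- r3 - tr$NO2[n]
    r1 <- r2 - tr$NO[n]
    r0 <- 2 * tr$N2[n]
    o2_consumed <- tr$O2[1] - tr$O2[n]
    e_required <- 2 * r3 + r2 + r1 + r0 + 4 * o2_consumed
    expect_equal(e_delivered, e_required, tolerance = 1e-3)
  }
})

test_that("NO3- gating shuts Nir down when NO3- is far above Ki", {
  ps <- preset("FNA_ref")
  cc <- denitkin:::.sim_consts(ps$config, ps$phenotype)
  state <- c(biomass = 0.5, NO3 = 50, NO2 = 50, O2 = 0, NO = 0, N2O = 0,
             N2 = 0, a_nap = 1, a_nar = 1, a_nir = 1, a_nor = 1, a_nos = 1)
  for (ki in c(1e-3, 1e-2, 1e-1)) {
    ph_g <- ps$phenotype
    ph_g$nir_no3_inhibition_ki <- ki
    ph_u <- ps$phenotype
    ph_u$nir_no3_inhibition_ki <- Inf
    # [NO3-] = 1000 uM here, far above 100 x Ki in every case
    v_g <- denitkin:::.fluxes_at(state, cc, ph_g)[["nir"]]
    v_u <- denitkin:::.fluxes_at(state, cc, ph_u)[["nir"]]
    expect_lt(v_g, 0.01 * v_u)
  }
})

test_that("pools move the right way: N2 accumulates, NO3- only falls between spikes", {
  for (nm in c("PNA_ref", "competition_FNA")) {
    tr <- preset_truth(nm)
    expect_true(all(diff(tr$N2) > -1e-9))
    ev <- attr(tr, "events")
    dn <- diff(tr$NO3)
    rising <- which(dn > 1e-9)
    # NO3- may only rise across a spike row
    if (length(rising)) {
      expect_true(all(vapply(rising, function(i) {
        any(abs(ev$spikes$time_h - tr$time_h[i]) < 1e-6)
      }, logical(1))))
    }
    expect_true(all(tr[c("NO3", "NO2", "O2", "NO", "N2O", "N2")] > -1e-9))
    acts <- as.matrix(tr[grep("^a_", names(tr))])
    expect_true(all(acts >= -1e-9 & acts <= 1 + 1e-9))
  }
})

test_that("halving the integration grid leaves the kinetics unchanged", {
  m1 <- max(preset_truth("FNA_ref", dt = 0.05)$NO2)
  m2 <- max(preset_truth("FNA_ref", dt = 0.025)$NO2)
  expect_lt(abs(m1 - m2) / m1, 0.005)
})

test_that("state-triggered spikes fire at the set point and impossible triggers warn", {
  tr <- preset_truth("competition_FNA")
  ev <- attr(tr, "events")
  expect_equal(nrow(ev$spikes), 1L)
  # fired at the first grid time with NO2- at or below 2/3 of the initial
  i <- which(abs(tr$time_h - ev$spikes$time_h) < 1e-9)
  expect_lte(tr$NO2[i], 100 * 2 / 3 + 1e-6)
  expect_gt(tr$NO2[i], 100 * 2 / 3 - 0.5)  # within one grid step of the mark

  ps <- preset("FNA_ref")
  pr <- ps$protocol
  pr$duration <- 5
  pr$sampling_gas <- 1:5
  pr$sampling_no2 <- c(0, 5)
  pr$spike_events <- list(spike_event("NO3", 10, when_no2_below = -5))
  expect_warning(simulate_vial(ps$config, ps$phenotype, pr),
                 "never satisfied")
})

test_that("autosampling dilutes the headspace by the sampled fraction", {
  # inert tracer in a sterile vial: only the sampler touches the gas
  gt <- list(O2 = gas_props(0), NO = gas_props(0), N2O = gas_props(0),
             N2 = gas_props(0), He = gas_props(0))
  cfg <- vial_config(gas_table = gt)
  pr <- protocol(duration = 3, initial_o2_percent = 1, initial_no3 = 0,
                 initial_no2 = 0, inoculum_biomass = 0,
                 sampling_gas = c(1, 2, 3), sampling_no2 = c(0, 3))
  ph <- preset("LNA_nap_only")$phenotype
  run <- autosample(cfg, ph, pr, noise = NULL)
  expect_equal(run$gas$O2[2] / run$gas$O2[1], 69 / 70, tolerance = 1e-10)
  expect_equal(run$gas$O2[3] / run$gas$O2[1], (69 / 70)^2,
               tolerance = 1e-10)
})

test_that("a zero-volume sampler observes the dense trajectory exactly", {
  ps <- preset("LNA_ref")
  cfg <- vial_config(sample_volume = 0)
  run <- autosample(cfg, ps$phenotype, ps$protocol, noise = NULL)
  tr <- simulate_vial(cfg, ps$phenotype, ps$protocol)
  k <- denitkin:::.gas_k(cfg, "N2")
  expect_equal(run$gas$N2,
               approx(tr$time_h, tr$N2, run$gas$time_h)$y / (70 + k * 50),
               tolerance = 1e-6)
})

test_that("sampling is reproducible under a fixed seed", {
  cp <- preset_physical("LNA_ref")
  r1 <- autosample(cp$ps$config, cp$ps$phenotype, cp$ps$protocol, seed = 7,
                   physical = cp$physical)
  r2 <- autosample(cp$ps$config, cp$ps$phenotype, cp$ps$protocol, seed = 7,
                   physical = cp$physical)
  expect_identical(r1$gas, r2$gas)
  expect_identical(r1$no2, r2$no2)
  r3 <- autosample(cp$ps$config, cp$ps$phenotype, cp$ps$protocol, seed = 8,
                   physical = cp$physical)
  expect_false(identical(r1$gas$NO, r3$gas$NO))
})

test_that("unknown presets and impossible phenotypes are rejected", {
  expect_error(preset("RPO_ref"))
  ps <- preset("FNA_ref")
  ph <- ps$phenotype
  ph$has_nap <- FALSE
  ph$has_nar <- FALSE
  expect_error(simulate_vial(ps$config, ph, ps$protocol),
               "nitrate reductase")
})
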