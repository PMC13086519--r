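# Mechanistic batch-vial simulator. The culture delivers electrons from
# catabolism at a supply capacity proportional to biomass; the terminal
# reductases (O2, Nap/Nar, Nir, Nor, Nos) place demands on that supply
# according to their synthesised activity, Michaelis-Menten substrate
# saturation in the liquid phase, and (for Nir) inhibition by NO3-. When the
# summed demand exceeds the supply, flows are allocated proportionally to
# competition_weight x demand, with no reductase receiving more than its
# demand. Pools advance by standard denitrification stoichiometry; biomass
# grows in proportion to total electron flow. Gases partition between
# headspace and liquid at equilibrium (stirred vial). Regulation is a
# delayed first-order rise of each activity after the O2 induction
# threshold is crossed, with an optional second Nir/Nor synthesis pulse at
# NO3- depletion. Deterministic for fixed inputs.

.STATE <- c("biomass", "NO3", "NO2", "O2", "NO", "N2O", "N2",
            "a_nap", "a_nar", "a_nir", "a_nor", "a_nos")
.POOL_IDX <- 2:7
.NO3_DEPLETION_EPS <- 0.5  # umol: "all NO3- reduced" trigger

# precomputed unit conversions: total vial amount (umol) -> liquid uM
.sim_consts <- function(cfg, pheno) {
  vh <- cfg$headspace_volume
  vl <- cfg$liquid_volume
  gconv <- vapply(c("O2", "NO", "N2O"), function(s) {
    k <- .gas_k(cfg, s)
    1000 * k / (vh + k * vl)
  }, numeric(1))
  .gas_k(cfg, "N2")  # every species used in a run must have an entry
  list(gconv = gconv, lconv = 1000 / vl,
       w = pheno$competition_weight[c("o2", "nap", "nar", "nir", "nor",
                                      "nos")])
}

# share a finite electron supply among competing demands: proportional to
# weight x demand, capped at each demand, freed supply re-shared
.allocate_supply <- function(demand, weight, supply) {
  tot <- sum(demand)
  if (tot <= supply || tot <= 0) return(demand)
  v <- numeric(length(demand))
  names(v) <- names(demand)
  act <- which(demand > 0)
  rem <- supply
  while (length(act) > 0 && rem > 0) {
    wd <- weight[act] * demand[act]
    prop <- rem * wd / sum(wd)
    over <- prop >= demand[act] - 1e-15
    if (!any(over)) {
      v[act] <- prop
      break
    }
    v[act[over]] <- demand[act[over]]
    rem <- rem - sum(demand[act[over]])
    act <- act[!over]
  }
  v
}

.monod <- function(s, k) if (s <= 0) 0 else s / (k + s)

# realized electron flows (umol e-/h) at one state
.fluxes_at <- function(y, cc, pheno) {
  B <- max(y[[1]], 0)
  zero <- c(o2 = 0, nap = 0, nar = 0, nir = 0, nor = 0, nos = 0)
  if (B <= 0) return(zero)
  no3 <- max(y[[2]], 0) * cc$lconv
  no2 <- max(y[[3]], 0) * cc$lconv
  o2c <- max(y[[4]], 0) * cc$gconv[["O2"]]
  noc <- max(y[[5]], 0) * cc$gconv[["NO"]]
  n2oc <- max(y[[6]], 0) * cc$gconv[["N2O"]]
  a <- pmin(pmax(y[8:12], 0), 1)
  vm <- pheno$vmax_e
  km <- pheno$km
  ki <- pheno$nir_no3_inhibition_ki
  gate <- if (is.infinite(ki)) 1 else ki / (ki + no3)
  D <- c(
    o2  = vm[["o2"]] * B * .monod(o2c, km[["o2"]]),
    nap = if (pheno$has_nap) a[[1]] * vm[["nap"]] * B *
            .monod(no3, km[["no3"]]) else 0,
    nar = if (pheno$has_nar) a[[2]] * vm[["nar"]] * B *
            .monod(no3, km[["no3"]]) else 0,
    nir = a[[3]] * vm[["nir"]] * B * .monod(no2, km[["no2"]]) * gate *
          pheno$nir_subpop_fraction,
    nor = a[[4]] * vm[["nor"]] * B * .monod(noc, km[["no"]]),
    nos = a[[5]] * vm[["nos"]] * B * .monod(n2oc, km[["n2o"]]))
  .allocate_supply(D, cc$w, pheno$v_supply * B)
}

.make_derivs <- function(cc, pheno, flags) {
  dl <- pheno$delay_h
  syn <- pheno$synthesis_rate
  function(t, y, parms) {
    V <- .fluxes_at(y, cc, pheno)
    a <- pmin(pmax(y[8:12], 0), 1)
    if (flags$induced) {
      r <- syn
      on <- t >= flags$t_ind + dl - 1e-12
      if (flags$second) {
        r[c("nir", "nor")] <- pmax(r[c("nir", "nor")],
                                   pheno$second_synthesis_rate)
        on[c("nir", "nor")] <- TRUE
      }
      da <- ifelse(on, r * (1 - a), 0)
    } else {
      da <- numeric(5)
    }
    vnar <- V[["nap"]] + V[["nar"]]
    list(c(pheno$yield * sum(V),        # biomass
           -vnar / 2,                   # NO3
           vnar / 2 - V[["nir"]],       # NO2
           -V[["o2"]] / 4,              # O2
           V[["nir"]] - V[["nor"]],     # NO
           (V[["nor"]] - V[["nos"]]) / 2,  # N2O (per molecule)
           V[["nos"]] / 2,              # N2 (per molecule)
           da))
  }
}

.init_state <- function(cfg, pheno, protocol) {
  o2 <- if (protocol$initial_o2_percent > 0) {
    o2_percent_to_umol(protocol$initial_o2_percent, cfg)
  } else 0
  a0 <- if (protocol$preinduced) 1 else 0
  y <- c(biomass = protocol$inoculum_biomass, NO3 = protocol$initial_no3,
         NO2 = protocol$initial_no2, O2 = o2, NO = 0, N2O = 0, N2 = 0,
         a_nap = a0, a_nar = a0, a_nir = a0, a_nor = a0, a_nos = a0)
  nspike <- length(protocol$spike_events)
  flags <- list(induced = protocol$preinduced,
                t_ind = if (protocol$preinduced) 0 else NA_real_,
                second = FALSE, t_second = NA_real_,
                spike_fired = rep(FALSE, nspike),
                spike_time = rep(NA_real_, nspike))
  list(y = y, flags = flags)
}

.pending_event <- function(t, y, flags, pheno, protocol) {
  if (!flags$induced &&
      y[["O2"]] <= pheno$induction_o2_threshold + 1e-9) return(TRUE)
  if (flags$induced && isTRUE(pheno$second_induction) && !flags$second &&
      y[["NO3"]] <= .NO3_DEPLETION_EPS) return(TRUE)
  sps <- protocol$spike_events
  for (i in seq_along(sps)) {
    if (flags$spike_fired[i]) next
    sp <- sps[[i]]
    if (!is.null(sp$when_no2_below)) {
      if (y[["NO2"]] <= sp$when_no2_below + 1e-9) return(TRUE)
    } else if (t >= sp$at_time - 1e-9) return(TRUE)
  }
  FALSE
}

.apply_events <- function(t, y, flags, pheno, protocol) {
  repeat {
    changed <- FALSE
    if (!flags$induced &&
        y[["O2"]] <= pheno$induction_o2_threshold + 1e-9) {
      flags$induced <- TRUE
      flags$t_ind <- t
      changed <- TRUE
    }
    if (flags$induced && isTRUE(pheno$second_induction) && !flags$second &&
        y[["NO3"]] <= .NO3_DEPLETION_EPS) {
      flags$second <- TRUE
      flags$t_second <- t
      changed <- TRUE
    }
    sps <- protocol$spike_events
    for (i in seq_along(sps)) {
      if (flags$spike_fired[i]) next
      sp <- sps[[i]]
      hit <- if (!is.null(sp$when_no2_below)) {
        y[["NO2"]] <= sp$when_no2_below + 1e-9
      } else {
        t >= sp$at_time - 1e-9
      }
      if (hit) {
        y[[sp$species]] <- y[[sp$species]] + sp$amount
        flags$spike_fired[i] <- TRUE
        flags$spike_time[i] <- t
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(y = y, flags = flags)
}

# integrate from t_from to t_to over a dt grid, firing discrete events at
# the first grid time whose state satisfies them; returns all grid rows
# (pre-event states at event times) plus the final state and flags
.simulate_core <- function(y, flags, t_from, t_to, dt, cc, pheno, protocol) {
  grid <- seq(t_from, t_to, by = dt)
  if (t_to - grid[length(grid)] > 1e-9) grid <- c(grid, t_to)
  fixed <- unlist(lapply(seq_along(protocol$spike_events), function(i) {
    sp <- protocol$spike_events[[i]]
    if (!flags$spike_fired[i] && !is.null(sp$at_time) &&
        sp$at_time > t_from + 1e-9 && sp$at_time <= t_to + 1e-9) {
      sp$at_time
    } else NULL
  }))
  grid <- sort(unique(c(grid, fixed)))

  ev <- .apply_events(grid[1], y, flags, pheno, protocol)
  y <- ev$y
  flags <- ev$flags
  rows <- vector("list", length(grid) + 8L)
  rows[[1L]] <- c(grid[1], unname(y))
  nrows <- 1L
  cur <- grid[1]
  while (cur < t_to - 1e-9) {
    times <- c(cur, grid[grid > cur + 1e-9])
    sol <- deSolve::ode(y, times, .make_derivs(cc, pheno, flags),
                        parms = NULL, method = "bdf", rtol = 1e-8,
                        atol = 1e-10, hmax = dt)
    if (nrow(sol) < length(times) || any(!is.finite(sol[, 1 + .POOL_IDX]))) {
      stop("integration failure near t = ", signif(cur, 6), " h",
           call. = FALSE)
    }
    if (min(sol[, 1 + .POOL_IDX]) < -1e-6) {
      stop("negative pool during integration near t = ", signif(cur, 6),
           " h; reduce the grid step", call. = FALSE)
    }
    hit <- 0L
    for (r in 2:nrow(sol)) {
      yr <- sol[r, -1]
      names(yr) <- .STATE
      if (.pending_event(sol[r, 1], yr, flags, pheno, protocol)) {
        hit <- r
        break
      }
    }
    last <- if (hit) hit else nrow(sol)
    for (r in 2:last) {
      nrows <- nrows + 1L
      rows[[nrows]] <- sol[r, ]
    }
    y <- sol[last, -1]
    names(y) <- .STATE
    y[.POOL_IDX] <- pmax(y[.POOL_IDX], 0)
    cur <- sol[last, 1]
    if (hit) {
      ev <- .apply_events(cur, y, flags, pheno, protocol)
      y <- ev$y
      flags <- ev$flags
    }
  }
  mat <- do.call(rbind, rows[seq_len(nrows)])
  colnames(mat) <- c("time_h", .STATE)
  list(mat = mat, y = y, flags = flags)
}

#' Simulate a denitrifying batch-vial incubation
#'
#' Integrates the electron-allocation model on a dense time grid. The
#' returned trajectory is the "truth" state of an undisturbed vial: total
#' vial amounts (umol, headspace + dissolved for gases), reductase
#' activities, and the instantaneous realized electron flow to each
#' reductase (`ve_*`, umol e-/h). Discrete events (induction, the second
#' Nir/Nor synthesis pulse, substrate spikes) fire at the first grid time
#' whose state satisfies their condition.
#'
#' @param cfg A [vial_config()].
#' @param pheno A [phenotype_params()].
#' @param protocol A [protocol()].
#' @param dt Output grid step (h).
#' @return A `vial_trajectory` data frame with attributes `events`
#'   (induction and spike times) and the input objects.
#' @export
simulate_vial <- function(cfg, pheno, protocol, dt = 0.05) {
  stopifnot(inherits(cfg, "vial_config"), inherits(pheno, "phenotype_params"),
            inherits(protocol, "protocol"), .is_number(dt), dt > 0)
  has_no3 <- protocol$initial_no3 > 0 ||
    any(vapply(protocol$spike_events, function(s) s$species == "NO3",
               logical(1)))
  if (has_no3 && !(pheno$has_nap || pheno$has_nar)) {
    stop("a NO3--containing protocol needs at least one nitrate reductase",
         call. = FALSE)
  }
  cc <- .sim_consts(cfg, pheno)
  st <- .init_state(cfg, pheno, protocol)
  res <- .simulate_core(st$y, st$flags, 0, protocol$duration, dt, cc, pheno,
                        protocol)
  for (i in seq_along(protocol$spike_events)) {
    if (!res$flags$spike_fired[i]) {
      warning("spike event ", i, " trigger never satisfied; event skipped",
              call. = FALSE)
    }
  }
  .assemble_trajectory(res, cc, cfg, pheno, protocol)
}

.assemble_trajectory <- function(res, cc, cfg, pheno, protocol) {
  mat <- res$mat
  mat[, 1 + .POOL_IDX] <- pmax(mat[, 1 + .POOL_IDX], 0)
  fl <- t(apply(mat[, -1, drop = FALSE], 1, .fluxes_at, cc = cc,
                pheno = pheno))
  traj <- data.frame(mat)
  names(traj) <- c("time_h", .STATE)
  traj$ve_o2 <- fl[, "o2"]
  traj$ve_nap <- fl[, "nap"]
  traj$ve_nar <- fl[, "nar"]
  traj$ve_narnap <- fl[, "nap"] + fl[, "nar"]
  traj$ve_nir <- fl[, "nir"]
  traj$ve_nor <- fl[, "nor"]
  traj$ve_nos <- fl[, "nos"]
  traj$ve_total <- rowSums(fl)
  fired <- which(res$flags$spike_fired)
  attr(traj, "events") <- list(
    t_induction = res$flags$t_ind,
    t_second_pulse = res$flags$t_second,
    spikes = if (length(fired)) {
      data.frame(
        species = vapply(protocol$spike_events[fired],
                         function(s) s$species, ""),
        amount = vapply(protocol$spike_events[fired],
                        function(s) s$amount, 0),
        time_h = res$flags$spike_time[fired])
    } else {
      data.frame(species = character(), amount = numeric(),
                 time_h = numeric())
    })
  attr(traj, "config") <- cfg
  attr(traj, "phenotype") <- pheno
  attr(traj, "protocol") <- protocol
  class(traj) <- c("vial_trajectory", "data.frame")
  traj
}
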