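# File formats: sampled runs as a CSV pair (gas + NO2-) with a JSON
# metadata sidecar, scenarios as YAML, summaries as JSON. All numeric
# payloads round-trip losslessly (full double precision in the CSVs).

.SCHEMA_VERSION <- "1.0"

.fmt_num <- function(x) {
  formatC(x, digits = 17, format = "g")
}

.write_num_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- .fmt_num(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

.read_num_csv <- function(path, required) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("file ", basename(path), " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (nm in names(df)) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(v) & !(df[[nm]] %in% c("NA", "")))
    if (length(bad)) {
      stop("file ", basename(path), ", column \"", nm, "\": ",
           "non-numeric value in row ", bad[1], call. = FALSE)
    }
    df[[nm]] <- v
  }
  if (is.unsorted(df$time_h, strictly = TRUE)) {
    i <- which(diff(df$time_h) <= 0)[1] + 1L
    stop("file ", basename(path), ": time_h not strictly increasing at row ",
         i, call. = FALSE)
  }
  df
}

#' Write a sampled run to disk
#'
#' Produces `<prefix>_gas.csv` (time_h, O2, NO, N2O, N2 headspace
#' concentrations in umol/mL, sample_event flag), `<prefix>_no2.csv`
#' (time_h, no2_mM) and `<prefix>_meta.json` (vial configuration, initial
#' amounts, spikes, seed, schema and package version).
#'
#' @param run A `sampled_run`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the three paths.
#' @export
write_sampled_run <- function(run, dir, prefix = "run") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gas_path <- file.path(dir, paste0(prefix, "_gas.csv"))
  no2_path <- file.path(dir, paste0(prefix, "_no2.csv"))
  meta_path <- file.path(dir, paste0(prefix, "_meta.json"))
  gas <- run$gas
  gas$sample_event <- 1L
  .write_num_csv(gas, gas_path)
  .write_num_csv(run$no2, no2_path)
  cfg <- run$config
  meta <- list(
    schema_version = .SCHEMA_VERSION,
    package = as.character(utils::packageVersion("denitkin")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    vial = list(
      liquid_volume = cfg$liquid_volume,
      headspace_volume = cfg$headspace_volume,
      temperature = cfg$temperature, pressure = cfg$pressure,
      sample_volume = cfg$sample_volume,
      gas_table = lapply(cfg$gas_table, function(g) {
        list(henry_cc = g$henry_cc, kla = g$kla)
      })),
    no3_provided = run$no3_provided,
    no2_initial = run$no2_initial,
    o2_initial = run$o2_initial,
    sample_volume = run$sample_volume,
    seed = run$seed,
    spikes = run$spikes)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(gas = gas_path, no2 = no2_path, meta = meta_path))
}

#' Read a sampled run written by [write_sampled_run()]
#'
#' Column order in the CSVs is irrelevant (header-keyed); schema violations
#' (missing columns, non-numeric cells, non-monotone or duplicate times)
#' raise descriptive errors naming the file, column and row.
#'
#' @param dir Directory holding the file triple (or the path of the
#'   `*_gas.csv` file itself).
#' @param prefix File name prefix used when writing.
#' @return A `sampled_run`.
#' @export
read_sampled_run <- function(dir, prefix = "run") {
  if (grepl("_gas\\.csv$", dir)) {
    prefix <- sub("_gas\\.csv$", "", basename(dir))
    dir <- dirname(dir)
  }
  gas_path <- file.path(dir, paste0(prefix, "_gas.csv"))
  no2_path <- file.path(dir, paste0(prefix, "_no2.csv"))
  meta_path <- file.path(dir, paste0(prefix, "_meta.json"))
  for (p in c(gas_path, no2_path, meta_path)) {
    if (!file.exists(p)) stop("missing run file: ", p, call. = FALSE)
  }
  gas <- .read_num_csv(gas_path, c("time_h", .GAS_SPECIES))
  gas <- gas[c("time_h", .GAS_SPECIES)]
  no2 <- .read_num_csv(no2_path, c("time_h", "no2_mM"))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  gt <- lapply(meta$vial$gas_table, function(g) {
    gas_props(g$henry_cc,
              if (identical(g$kla, "equilibrium")) "equilibrium"
              else as.numeric(g$kla))
  })
  cfg <- vial_config(meta$vial$liquid_volume, meta$vial$headspace_volume,
                     meta$vial$temperature, meta$vial$pressure,
                     meta$vial$sample_volume, gt)
  spikes <- meta$spikes
  if (is.null(spikes) || !length(spikes)) {
    spikes <- data.frame(species = character(), amount = numeric(),
                         time_h = numeric())
  } else {
    spikes <- as.data.frame(spikes)
  }
  structure(
    list(gas = gas, no2 = no2[c("time_h", "no2_mM")], config = cfg,
         no3_provided = meta$no3_provided,
         no2_initial = meta$no2_initial %||% 0,
         o2_initial = meta$o2_initial,
         spikes = spikes, sample_volume = meta$sample_volume,
         seed = meta$seed),
    class = "sampled_run")
}

#' Write a simulation scenario as YAML
#'
#' @param cfg,pheno,protocol The scenario triple.
#' @param path Output path.
#' @export
write_scenario <- function(cfg, pheno, protocol, path) {
  sc <- list(
    vial = list(
      liquid_volume = cfg$liquid_volume,
      headspace_volume = cfg$headspace_volume,
      temperature = cfg$temperature, pressure = cfg$pressure,
      sample_volume = cfg$sample_volume,
      gas_table = lapply(cfg$gas_table, function(g) {
        list(henry_cc = g$henry_cc, kla = g$kla)
      })),
    phenotype = unclass(pheno),
    protocol = lapply(unclass(protocol), function(x) x))
  sc$phenotype$delay_h <- as.list(pheno$delay_h)
  sc$phenotype$synthesis_rate <- as.list(pheno$synthesis_rate)
  sc$phenotype$vmax_e <- as.list(pheno$vmax_e)
  sc$phenotype$km <- as.list(pheno$km)
  sc$phenotype$competition_weight <- as.list(pheno$competition_weight)
  sc$protocol$spike_events <- lapply(protocol$spike_events, unclass)
  yaml::write_yaml(sc, path)
  invisible(path)
}

#' Read a YAML scenario into the configuration triple
#'
#' @param path Scenario file.
#' @return List with `config`, `phenotype`, `protocol`.
#' @export
read_scenario <- function(path) {
  sc <- .read_yaml(path)
  for (sec in c("vial", "phenotype", "protocol")) {
    if (is.null(sc[[sec]])) {
      stop("scenario file lacks the \"", sec, "\" section", call. = FALSE)
    }
  }
  v <- sc$vial
  gt <- if (is.null(v$gas_table)) default_gas_table() else {
    lapply(v$gas_table, function(g) gas_props(g$henry_cc, g$kla))
  }
  cfg <- vial_config(v$liquid_volume %||% 50, v$headspace_volume %||% 70,
                     v$temperature %||% 20, v$pressure %||% 1,
                     v$sample_volume %||% 1, gt)
  ph <- sc$phenotype
  num <- function(x) if (is.null(x)) NULL else unlist(x)
  pheno <- phenotype_params(
    has_nap = ph$has_nap %||% TRUE, has_nar = ph$has_nar %||% TRUE,
    induction_o2_threshold = ph$induction_o2_threshold %||% 12,
    delay_h = num(ph$delay_h), synthesis_rate = num(ph$synthesis_rate),
    second_synthesis_rate = ph$second_synthesis_rate %||% 4,
    vmax_e = num(ph$vmax_e), km = num(ph$km),
    nir_no3_inhibition_ki = ph$nir_no3_inhibition_ki %||% 1,
    competition_weight = num(ph$competition_weight),
    nir_subpop_fraction = ph$nir_subpop_fraction %||% 0.3,
    second_induction = ph$second_induction %||% TRUE,
    v_supply = ph$v_supply %||% 80, yield = ph$yield %||% 0.0025)
  pr <- sc$protocol
  spikes <- lapply(pr$spike_events %||% list(), function(s) {
    spike_event(s$species, s$amount, at_time = s$at_time,
                when_no2_below = s$when_no2_below)
  })
  dur <- pr$duration %||% 48
  proto <- protocol(
    duration = dur,
    initial_o2_percent = pr$initial_o2_percent %||% 1,
    initial_no3 = pr$initial_no3 %||% 0,
    initial_no2 = pr$initial_no2 %||% 0,
    inoculum_biomass = pr$inoculum_biomass %||% 0.075,
    preinduced = pr$preinduced %||% FALSE,
    spike_events = spikes,
    sampling_gas = unlist(pr$sampling_gas) %||% seq(1, dur, by = 1),
    sampling_no2 = unlist(pr$sampling_no2) %||% seq(0, dur, by = 3))
  list(config = cfg, phenotype = pheno, protocol = proto)
}

#' Write a trajectory to a wide CSV
#'
#' One row per grid time with pools, activities and truth electron-flow
#' columns.
#'
#' @param traj A `vial_trajectory`.
#' @param path Output path.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  names(df)[match(c("NO3", "NO2", "O2", "NO", "N2O", "N2"), names(df))] <-
    c("NO3_umol", "NO2_umol", "O2_umol", "NO_umol", "N2O_umol", "N2_umol")
  .write_num_csv(df, path)
  invisible(path)
}

#' Write a phenotype call (or any summary list) as JSON
#'
#' @param x A `phenotype_call` or plain list.
#' @param path Output path.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
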