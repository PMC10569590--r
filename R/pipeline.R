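# The four standard environment configurations (porosity %, frustule)
.CONFIGURATIONS <- list(
  water_column = list(porosity = 100, frustule = FALSE,
                      label = "Water column"),
  dry_sediment = list(porosity = 0, frustule = FALSE,
                      label = "Dry sediments"),
  benthic_mixture = list(porosity = 90, frustule = FALSE,
                         label = "Benthic mixture"),
  benthic_mixture_frustule = list(porosity = 90, frustule = TRUE,
                                  label = "Benthic mixture (frustule)")
)

#' Default pipeline configuration
#'
#' A nested list holding every tunable of the pipeline with its reference
#' value: geometry radii, material densities and stopping ratios, reference
#' activity concentrations (1000 Bq/L Rn-222, 30 Bq/g Ra-226), primary
#' counts, track-structure and damage parameters, and the configurations to
#' run. The same structure can be read from a YAML file with
#' [read_scenario_config()]; a commented reference file ships in
#' `system.file("extdata", "config_reference.yaml", package = "diatomdose")`.
#'
#' @return nested configuration list
#' @export
default_config <- function() {
  list(
    seed = 1,
    primaries = 1e6,
    nano_primaries = 8e3,
    n_nucleosomes = 30000,
    genome_mbp = 27,
    erica_threshold = 10,
    activities = list(c_rn = 1000, c_ra = 30),
    geometry = list(r_nucleus = 0.5, r_microorganism = 10,
                    frustule_thickness = 2),
    materials = list(sediment_density = 1.20,
                     sediment_mass_stopping_ratio = 0.77,
                     silicate_mass_stopping_ratio = 0.90),
    ts = list(mean_site_energy = 100, max_site_energy = 5000,
              electron_fraction = 0.40, displacement_mean = 2,
              step_nm = 50),
    damage = list(eps = 3.3, min_ssb_for_dsb = 2, s_point_prob = 0.08,
                  ramp_min = 5, ramp_max = 37.5),
    configurations = names(.CONFIGURATIONS)
  )
}

#' Read and validate a pipeline configuration from YAML
#'
#' Keys missing from the file keep their [default_config()] values.
#'
#' @param path YAML file path
#' @return validated configuration list
#' @export
read_scenario_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
}

#' @rdname read_scenario_config
#' @param config configuration list to validate
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  with(config, {
    stopifnot(primaries >= 1, nano_primaries >= 1, n_nucleosomes >= 1,
              genome_mbp > 0, activities$c_rn >= 0, activities$c_ra >= 0,
              geometry$r_nucleus > 0,
              geometry$r_nucleus < geometry$r_microorganism,
              geometry$frustule_thickness >= 0,
              materials$sediment_density > 0,
              materials$sediment_mass_stopping_ratio > 0,
              materials$silicate_mass_stopping_ratio > 0)
  })
  unknown <- setdiff(config$configurations, names(.CONFIGURATIONS))
  if (length(unknown)) {
    stop("unknown configuration(s): ", paste(unknown, collapse = ", "))
  }
  # constructing the parameter objects runs their own validation
  ts_from_config(config)
  damage_from_config(config)
  invisible(config)
}

#' Build parameter objects from a configuration list
#'
#' @param config a configuration list (see [default_config()])
#' @param name configuration name (one of `water_column`, `dry_sediment`,
#'   `benthic_mixture`, `benthic_mixture_frustule`)
#' @return the corresponding parameter object
#' @export
geometry_from_config <- function(config, name) {
  spec <- .CONFIGURATIONS[[name]]
  if (is.null(spec)) stop("unknown configuration: ", name)
  sed <- sediment_material(config$materials$sediment_density,
                           config$materials$sediment_mass_stopping_ratio)
  env <- mixture_material(spec$porosity, sediment = sed)
  cell_geometry(
    r_nucleus = config$geometry$r_nucleus,
    r_microorganism = config$geometry$r_microorganism,
    frustule_thickness = if (spec$frustule)
      config$geometry$frustule_thickness else 0,
    environment_material = env,
    frustule_material = silicate_material(
      config$materials$silicate_mass_stopping_ratio)
  )
}

#' @rdname geometry_from_config
#' @export
scenario_from_config <- function(config, name) {
  spec <- .CONFIGURATIONS[[name]]
  if (is.null(spec)) stop("unknown configuration: ", name)
  sed <- sediment_material(config$materials$sediment_density,
                           config$materials$sediment_mass_stopping_ratio)
  activity_scenario(
    c_rn = if (spec$porosity > 0) config$activities$c_rn else 0,
    c_ra = if (spec$porosity < 100) config$activities$c_ra else 0,
    porosity = spec$porosity,
    geometry = geometry_from_config(config, name),
    sediment = sed
  )
}

#' @rdname geometry_from_config
#' @export
ts_from_config <- function(config) {
  do.call(ts_params, config$ts)
}

#' @rdname geometry_from_config
#' @export
damage_from_config <- function(config) {
  do.call(dbscan_params, config$damage)
}

#' Measured spring activities
#'
#' Activity concentrations of Rn-222 in water (Bq/L) and Ra-226 in dry
#' sediment (Bq/g) measured by gamma spectrometry in the five studied
#' mineral springs.
#'
#' @return data.frame with columns `spring`, `site`, `c_rn`, `c_ra`
#' @export
spring_activities <- function() {
  data.frame(
    spring = paste("spring", 1:5),
    site = c("Joze", "Joze", "Joze", "Mariol", "Chateldon"),
    c_rn = c(13.7, 25.3, 421.6, 147.5, 4594.0),
    c_ra = c(30.8, 42.5, 21.4, 31.9, 31.4)
  )
}

#' Generate synthetic spring activity scenarios
#'
#' Returns the five measured springs as fixed named fixtures followed by
#' `n` synthetic scenarios sampled from the measured ranges: Rn-222
#' log-uniform (the measured concentrations span 13.7-4594 Bq/L, almost
#' three decades) and Ra-226 uniform over 21.4-42.5 Bq/g.
#'
#' @param n number of synthetic scenarios
#' @param seed optional integer seed
#' @param rn_range,ra_range sampling ranges (Bq/L, Bq/g)
#' @return data.frame with columns `spring`, `c_rn`, `c_ra`, `source`
#' @export
generate_scenarios <- function(n = 0, seed = NULL,
                               rn_range = c(13.7, 4594),
                               ra_range = c(21.4, 42.5)) {
  if (rn_range[1] > rn_range[2] || ra_range[1] > ra_range[2]) {
    stop("sampling ranges must be increasing")
  }
  if (any(rn_range <= 0)) stop("Rn range must be positive (log-uniform law)")
  if (!is.null(seed)) set.seed(seed)
  measured <- spring_activities()[, c("spring", "c_rn", "c_ra")]
  measured$source <- "measured"
  if (n < 1) return(measured)
  synth <- data.frame(
    spring = paste("synthetic", seq_len(n)),
    c_rn = exp(stats::runif(n, log(rn_range[1]), log(rn_range[2]))),
    c_ra = stats::runif(n, ra_range[1], ra_range[2]),
    source = "sampled"
  )
  rbind(measured, synth)
}

#' Run the full micro-to-nano pipeline
#'
#' For every requested configuration: (1) analog transport of `primaries`
#' decays per nuclide and activity normalisation to dose rates with the
#' ERICA 10 uGy/h screen; (2) nucleus-aimed transport of `nano_primaries`
#' weighted emissions feeding the nanodosimetric stage (specific-energy
#' rates per nucleosome) and the DBSCAN damage scorer (SSB/DSB per Gy per
#' Mbp and per day). Per-nuclide yields are combined by summing, and per-day
#' rates combine per-nuclide yields with per-nuclide dose rates.
#'
#' All randomness derives from `config$seed`; rerunning with the same
#' configuration gives identical output tables.
#'
#' @param config configuration list ([default_config()] /
#'   [read_scenario_config()])
#' @param out_dir if not NULL, write `dose_rates.csv`, `damage_yields.csv`,
#'   `se_spectra.csv` and `manifest.json` there
#' @param quiet suppress per-stage progress messages
#' @return `pipeline_result` with elements `dose_table`, `damage_table`,
#'   `dose_rate_results` (per configuration), `nano` (per configuration,
#'   per nuclide), and `config`
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         quiet = FALSE) {
  config <- validate_config(config)
  ts <- ts_from_config(config)
  dmg <- damage_from_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  dose_rows <- list(); damage_rows <- list()
  rate_results <- list(); nano_all <- list(); spectra_rows <- list()
  for (k in seq_along(config$configurations)) {
    name <- config$configurations[[k]]
    spec <- .CONFIGURATIONS[[name]]
    scn <- scenario_from_config(config, name)
    act <- total_activity(scn)
    zero <- scn$c_rn == 0 && scn$c_ra == 0
    seed_k <- config$seed + 1000L * k
    if (zero) {
      say("[%s] zero activity: all-zero report", name)
      dose_rows[[name]] <- data.frame(
        configuration = name, nuclide = NA_character_, absolute_dose_gy = 0,
        n_primaries = 0, activity_bq = 0, dose_rate = 0)
      damage_rows[[name]] <- data.frame(
        configuration = name, se_rate_ugy_h = 0, ssb_per_gy_mbp = 0,
        dsb_per_gy_mbp = 0, ssb_per_day = 0, dsb_per_day = 0)
      rate_results[[name]] <- combine_dose_rates(
        data.frame(nuclide = character(0), dose_rate = numeric(0)),
        configuration = name, threshold = config$erica_threshold)
      next
    }
    say("[%s] transport: %g primaries per nuclide (seed %d)",
        name, config$primaries, seed_k)
    micro <- run_microdose(scn, config$primaries, seed = seed_k,
                           keep_microorganism_phase_space = FALSE)
    rt <- dose_rate_table(micro)
    rt$configuration <- name
    for (nuc in names(micro$per_nuclide)) {
      r <- micro$per_nuclide[[nuc]]
      say("  %s: dose %.3e Gy/primary (rel SD %.2g), %d entrants",
          r$nuclide, r$dose_gy[["microorganism"]] / r$n_primaries,
          r$dose_rel_sd, r$entered_microorganism)
    }
    rate_results[[name]] <- combine_dose_rates(
      rt, configuration = name, threshold = config$erica_threshold)
    dose_rows[[name]] <- rt[, c("configuration", "nuclide",
                                "absolute_dose_gy", "n_primaries",
                                "activity_bq", "dose_rate")]
    say("[%s] nucleus-aimed transport: %g weighted emissions per nuclide",
        name, config$nano_primaries)
    forced <- run_microdose(scn, config$nano_primaries, seed = seed_k + 1L,
                            toward_nucleus = TRUE)
    set.seed(seed_k + 2L)
    targets <- place_nucleosomes(config$n_nucleosomes,
                                 nucleus_radius = scn$geometry$r_nucleus * 1000)
    se_total <- 0
    yields_ssb <- c(); yields_dsb <- c(); rates_nuc <- c()
    nano_cfg <- list()
    for (nuc in names(forced$per_nuclide)) {
      phsp <- forced$per_nuclide[[nuc]]$phase_space_nucleus
      nano <- run_nanodose(phsp, scn$geometry,
                           n_primaries = config$nano_primaries, ts = ts,
                           targets = targets, damage = dmg,
                           genome_mbp = config$genome_mbp,
                           seed = seed_k + 3L + match(nuc, names(forced$per_nuclide)))
      nano_cfg[[nuc]] <- nano
      se_total <- se_total + se_rate(nano, act[[nuc]])
      yields_ssb[nuc] <- nano$damage$ssb_per_gy_mbp
      yields_dsb[nuc] <- nano$damage$dsb_per_gy_mbp
      rates_nuc[nuc] <- rt$dose_rate[rt$nuclide == nuc]
      sp <- se_spectrum(nano)
      if (nrow(sp)) {
        sp$configuration <- name; sp$nuclide <- nuc
        spectra_rows[[paste(name, nuc)]] <- sp
      }
      say("  %s: %d nucleus tracks, mean z/primary %.3e Gy, DSB/Gy/Mbp %.3g",
          nuc, nano$n_tracks, nano$mean_z_per_primary,
          nano$damage$dsb_per_gy_mbp)
    }
    nano_all[[name]] <- nano_cfg
    damage_rows[[name]] <- data.frame(
      configuration = name,
      se_rate_ugy_h = se_total,
      ssb_per_gy_mbp = sum(yields_ssb),
      dsb_per_gy_mbp = sum(yields_dsb),
      ssb_per_day = per_day(yields_ssb, rates_nuc, config$genome_mbp),
      dsb_per_day = per_day(yields_dsb, rates_nuc, config$genome_mbp))
  }
  res <- structure(list(
    dose_table = do.call(rbind, c(dose_rows, list(make.row.names = FALSE))),
    damage_table = do.call(rbind, c(damage_rows, list(make.row.names = FALSE))),
    spectra = if (length(spectra_rows))
      do.call(rbind, c(spectra_rows, list(make.row.names = FALSE))) else NULL,
    dose_rate_results = rate_results,
    nano = nano_all,
    config = config
  ), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Write the pipeline output tables and run manifest
#'
#' @param result a `pipeline_result`
#' @param out_dir output directory (created if needed)
#' @return `out_dir`, invisibly
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$dose_table, file.path(out_dir, "dose_rates.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$damage_table,
                   file.path(out_dir, "damage_yields.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(result$spectra)) {
    utils::write.csv(result$spectra, file.path(out_dir, "se_spectra.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    package = "diatomdose",
    version = as.character(utils::packageVersion("diatomdose")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = result$config,
    erica = lapply(result$dose_rate_results, function(r) list(
      total_ugy_h = r$total, exceeds_threshold = r$exceeds_erica_threshold))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result\n\ndose rates (uGy/h):\n")
  print(x$dose_table, digits = 3)
  cat("\ndamage yields:\n")
  print(x$damage_table, digits = 3)
  invisible(x)
}

#' Screen measured or synthetic scenarios against the ERICA threshold
#'
#' Linearly rescales reference per-nuclide dose rates to each scenario's
#' activities ([scale_to_measured()]) and flags totals reaching the
#' screening threshold.
#'
#' @param scenarios data.frame with `c_rn`, `c_ra` columns (e.g. from
#'   [generate_scenarios()])
#' @param reference_rates named per-nuclide rates at the reference
#'   activities (uGy/h)
#' @param reference_activities reference concentrations
#' @param threshold screening threshold (uGy/h)
#' @return input data.frame with added `dose_rate` and
#'   `exceeds_erica_threshold` columns
#' @export
screen_scenarios <- function(scenarios, reference_rates,
                             reference_activities = c(c_rn = 1000, c_ra = 30),
                             threshold = 10) {
  stopifnot(all(c("c_rn", "c_ra") %in% names(scenarios)))
  scenarios$dose_rate <- vapply(seq_len(nrow(scenarios)), function(i) {
    scale_to_measured(reference_rates,
                      c(c_rn = scenarios$c_rn[i], c_ra = scenarios$c_ra[i]),
                      reference_activities)
  }, numeric(1))
  scenarios$exceeds_erica_threshold <- scenarios$dose_rate >= threshold
  scenarios
}
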