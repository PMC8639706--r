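#' Configure an end-to-end analysis run
#'
#' Collects every tunable of the pipeline: the station template for the
#' synthetic scenario, the incubation design, analysis thresholds,
#' stoichiometric constants and output handling. Accepts either arguments or
#' a YAML file with the same field names (`template:` fields are passed to
#' [profile_template()]).
#'
#' @param template a [profile_template()] describing the station.
#' @param seed master seed for every random draw in the run.
#' @param incubation_depths depths (m) at which bottles are incubated;
#'   `NULL` picks 8 depths spanning the template grid.
#' @param replicate_design label treatments making up one depth's bottle
#'   set; the shipboard design is one 15NO2-, one 15NH4- and three
#'   unlabeled bottles.
#' @param spike_fraction tracer addition as a fraction of the ambient pool.
#' @param do_floor minimum starting DO (nM) for incubation bottles: samples
#'   from depths with in situ DO below this receive a small oxygen addition
#'   (sealed-bottle sampling at anoxic depths unavoidably introduces some
#'   DO, and the resulting rates are potential rates), so their drawdown is
#'   measurable above the sensor detection limit.
#' @param manipulation_depth depth (m, on the template grid) of the oxygen
#'   manipulation experiment used for the kinetics stage; default the grid
#'   depth nearest the template's secondary chlorophyll maximum.
#' @param manipulation_DO_levels target initial DO levels (nM) of the
#'   manipulation experiment, spanning tens of nM to thousands of nM.
#' @param r2_min,mic_gap linearity-screen thresholds
#'   ([linearity_classification()]).
#' @param detect_mult tracer detectability multiplier
#'   ([nitrite_oxidation_rate()]).
#' @param do_ceiling partition-stage DO ceiling, nM ([partition_table()]).
#' @param low_do_cutoff mean-DO cutoff (nM) for low-level affinity fits.
#' @param target_pct target percentage for [threshold_do()].
#' @param eps15,eps18 nitrate-reduction isotope effects (permil) for the
#'   isotope stage.
#' @param reox_max,f_min maximum reoxidation overprint fraction and minimum
#'   nitrate fraction remaining across the profile's low-DO core.
#' @param out_dir optional output directory for CSV tables and the run
#'   manifest.
#' @param force overwrite an `out_dir` whose manifest records a different
#'   config hash.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(template = profile_template(),
                            seed = 1L,
                            incubation_depths = NULL,
                            replicate_design = c("15NO2", "15NH4", "unlabeled",
                                                 "unlabeled", "unlabeled"),
                            spike_fraction = 0.1,
                            do_floor = 300,
                            manipulation_depth = NULL,
                            manipulation_DO_levels = c(50, 100, 250, 500,
                                                       1000, 2500, 6000,
                                                       15000),
                            r2_min = 0.6,
                            mic_gap = 0.2,
                            detect_mult = 3,
                            do_ceiling = 18000,
                            low_do_cutoff = 235,
                            target_pct = 100,
                            eps15 = 25,
                            eps18 = 25,
                            reox_max = 0.4,
                            f_min = 0.8,
                            out_dir = NULL,
                            force = FALSE) {
  if (is.character(template) && length(template) == 1) {
    template <- do.call(profile_template, yaml::read_yaml(template))
  }
  if (!inherits(template, "profile_template")) {
    abort("`template` must be a profile_template() or a YAML path")
  }
  if (is.null(incubation_depths)) {
    z <- template$depths
    incubation_depths <- z[unique(round(seq(1, length(z), length.out = 8)))]
  }
  if (!all(incubation_depths %in% template$depths)) {
    abort("incubation_depths must be on the template depth grid")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys are [pipeline_config()] arguments;
#' a nested `template:` mapping is passed to [profile_template()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$template)) {
    raw$template <- do.call(profile_template, raw$template)
  }
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  keep <- setdiff(names(config), c("out_dir", "force"))
  rlang::hash(config[keep])
}

#' Run the full analysis pipeline on a synthetic station
#'
#' Executes the stages in the order the measurements dictate: simulate the
#' station profile and its bottle incubations; invert the 15NH4+ and then
#' the 15NO2- tracer endpoints into oxidation rates (ammonia oxidation rates
#' feed the isotope-dilution term of the nitrite rates); estimate oxygen
#' consumption rates and screen the monitored bottles for linearity; fit the
#' overall Michaelis-Menten oxygen affinities of OCR and nitrite oxidation
#' across depths, and low-level affinities from any nonlinear low-DO
#' bottles; partition OCR into its nitrite-oxidation share, fit the
#' percentage-versus-DO power law and solve for the DO threshold at which
#' nitrite oxidation accounts for all consumption; and compute the
#' Delta(15,18) deviation profile from the station's dual nitrate-isotope
#' trajectory. One structured log line reports record counts per stage.
#'
#' All randomness derives from the config seed, so a rerun with the same
#' config is byte-identical. If `out_dir` is set, every table is written as
#' CSV with the config hash in its header, together with a JSON run
#' manifest; an existing output directory with a different recorded hash is
#' refused unless `force = TRUE`.
#'
#' @param config a [pipeline_config()].
#' @return a list of class `pipeline_result`: `profile`, `bottles`, `rates`,
#'   `ocr`, `experiment` (the oxygen manipulation bottles and their rates),
#'   `kinetics` (list: `ocr_fit`, `no2ox_fit`, `low_level`),
#'   `partition` (list: `records`, `fit`, `threshold_nM`), `isotopes`
#'   (a [deviation_profile()]), and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be created by pipeline_config()")
  }
  hash <- config_hash(config)
  tp <- config$template
  tp$seed <- config$seed

  profile <- simulate_profile(tp)
  inform(sprintf("simulate: %d depths, station %s", nrow(profile), tp$station))

  prof_inc <- profile[profile$depth_m %in% config$incubation_depths, ]
  bottles <- purrr::map2(prof_inc$config, prof_inc$depth_m, function(cfg, z) {
    ex <- simulate_experiment(cfg, DO_levels = max(cfg$initial_O2,
                                                   config$do_floor),
                              treatments = config$replicate_design,
                              spike_fraction = config$spike_fraction,
                              seed = mix_seed(config$seed, round(z)))
    ex$station <- tp$station
    ex$depth_m <- z
    ex
  }) |> dplyr::bind_rows()
  bottles$bottle_id <- sprintf("%s_%03.0fm_%s", tp$station, bottles$depth_m,
                               bottles$bottle_id)
  bottles <- apply_substitutions(bottles)
  inform(sprintf("simulate: %d bottles at %d depths", nrow(bottles),
                 length(config$incubation_depths)))

  # rates: ammonia oxidation first; its per-depth rate feeds the
  # isotope-dilution term of the nitrite-oxidation inversion
  nh4_bottles <- bottles[bottles$treatment == "15NH4", , drop = FALSE]
  nh3ox <- ammonia_oxidation_rate(nh4_bottles, detect_mult = config$detect_mult)
  r_ao_by_depth <- nh3ox |>
    dplyr::group_by(.data$depth_m) |>
    dplyr::summarise(R_AO = mean(.data$nh3ox_rate), .groups = "drop")
  no2_bottles <- bottles[bottles$treatment == "15NO2", , drop = FALSE] |>
    dplyr::left_join(r_ao_by_depth, by = "depth_m")
  no2ox <- nitrite_oxidation_rate(no2_bottles, detect_mult = config$detect_mult)
  rates <- dplyr::bind_rows(
    no2ox |> dplyr::transmute(.data$bottle_id, .data$station, .data$depth_m,
                              process = "nitrite_oxidation",
                              rate = .data$no2ox_rate, se = .data$no2ox_se,
                              detectable = .data$no2ox_detectable),
    nh3ox |> dplyr::transmute(.data$bottle_id, .data$station, .data$depth_m,
                              process = "ammonia_oxidation",
                              rate = .data$nh3ox_rate, se = .data$nh3ox_se,
                              detectable = .data$nh3ox_detectable))
  inform(sprintf("rates: %d bottles in, %d rate estimates out (%d detectable)",
                 nrow(nh4_bottles) + nrow(no2_bottles), nrow(rates),
                 sum(rates$detectable)))

  # OCR: per-bottle regression on the monitored series, then replicate
  # aggregation per depth
  ocr_bottle <- purrr::map2(bottles$do_series, bottles$bottle_id,
                            function(s, id) {
    est <- ocr_regression(s, r2_min = config$r2_min, mic_gap = config$mic_gap)
    est$bottle_id <- id
    est
  }) |> dplyr::bind_rows() |>
    dplyr::left_join(bottles[, c("bottle_id", "station", "depth_m",
                                 "do_target_nM", "DO_nM_initial",
                                 "DO_nM_final")],
                     by = "bottle_id") |>
    dplyr::mutate(mean_DO_nM = (.data$DO_nM_initial + .data$DO_nM_final) / 2)
  ocr_depth <- ocr_bottle |>
    dplyr::group_by(.data$station, .data$depth_m) |>
    dplyr::group_modify(function(x, key) {
      agg <- if (sum(is.finite(x$rate)) >= 2) {
        replicate_ocr(x, rate_col = "rate")
      } else {
        tibble(mean_rate = NA_real_, sd_rate = NA_real_,
               n = sum(is.finite(x$rate)), n_lt_5 = TRUE)
      }
      dplyr::bind_cols(agg, mean_DO_nM = mean(x$mean_DO_nM, na.rm = TRUE))
    }) |>
    dplyr::ungroup()
  inform(sprintf("ocr: %d bottles -> %d depth means (%d nonlinear bottles)",
                 nrow(ocr_bottle), nrow(ocr_depth),
                 sum(ocr_bottle$classification == "nonlinear", na.rm = TRUE)))

  # kinetics: overall affinities from an oxygen manipulation experiment at
  # one depth (8 DO levels x {15NO2, 15NH4, unlabeled} = 24 bottles), since
  # a rate-vs-DO saturation curve is only meaningful within one assemblage
  man_depth <- config$manipulation_depth %||%
    profile$depth_m[which.min(abs(profile$depth_m - tp$scm_depth))]
  man_cfg <- profile$config[[match(man_depth, profile$depth_m)]]
  man <- simulate_experiment(man_cfg,
                             DO_levels = config$manipulation_DO_levels,
                             treatments = c("15NO2", "15NH4", "unlabeled"),
                             spike_fraction = config$spike_fraction,
                             seed = mix_seed(config$seed, 999983L))
  man$station <- tp$station
  man$depth_m <- man_depth
  man$mean_DO_nM <- (man$DO_nM_initial + man$DO_nM_final) / 2
  man$OCR <- ocr_endpoint(man$DO_nM_initial, man$DO_nM_final, man$t_hours)
  man_nh3 <- ammonia_oxidation_rate(man[man$treatment == "15NH4", ],
                                    detect_mult = config$detect_mult)
  man_no2 <- man[man$treatment == "15NO2", ] |>
    dplyr::left_join(man_nh3 |>
                       dplyr::select("do_target_nM", R_AO = "nh3ox_rate"),
                     by = "do_target_nM") |>
    nitrite_oxidation_rate(detect_mult = config$detect_mult)
  ocr_fit <- fit_michaelis_menten(man, do_col = "mean_DO_nM",
                                  rate_col = "OCR")
  no2ox_fit <- fit_michaelis_menten(man_no2, do_col = "mean_DO_nM",
                                    rate_col = "no2ox_rate")
  # low-level affinity: any nonlinear continuously monitored bottle whose
  # mean DO sits below the cutoff
  man_class <- purrr::map(man$do_series, linearity_classification) |>
    dplyr::bind_rows() |>
    dplyr::mutate(bottle_id = man$bottle_id,
                  mean_DO_nM = man$mean_DO_nM)
  low_cand <- dplyr::bind_rows(
    ocr_bottle[, c("bottle_id", "classification", "mean_DO_nM")],
    man_class[, c("bottle_id", "classification", "mean_DO_nM")])
  all_series <- c(stats::setNames(bottles$do_series, bottles$bottle_id),
                  stats::setNames(man$do_series, man$bottle_id))
  low_idx <- which(low_cand$classification == "nonlinear" &
                     low_cand$mean_DO_nM < config$low_do_cutoff)
  low_level <- purrr::map(low_idx, function(i) {
    id <- low_cand$bottle_id[i]
    fit <- tryCatch(
      suppressWarnings(fit_low_level_km(all_series[[id]],
                                        low_do_cutoff = config$low_do_cutoff)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(NULL)
    dplyr::mutate(glance(fit), bottle_id = id, Km = fit$Km, Km_se = fit$Km_se)
  }) |> purrr::compact() |> dplyr::bind_rows()
  inform(sprintf(
    "kinetics: manipulation at %.0f m, %d bottles; %d low-level fit(s)",
    man_depth, nrow(man), nrow(low_level)))

  # partition: profile depth means and same-bottle experiment pairs
  no2ox_depth <- no2ox |>
    dplyr::group_by(.data$depth_m) |>
    dplyr::summarise(no2ox_rate = mean(.data$no2ox_rate), .groups = "drop")
  kin_tbl <- ocr_depth |>
    dplyr::left_join(no2ox_depth, by = "depth_m")
  rec_profile <- partition_table(kin_tbl, do_col = "mean_DO_nM",
                                 ocr_col = "mean_rate",
                                 no2ox_col = "no2ox_rate",
                                 do_ceiling = config$do_ceiling)
  rec_exp <- partition_table(man_no2, do_col = "mean_DO_nM",
                             ocr_col = "OCR", no2ox_col = "no2ox_rate",
                             do_ceiling = config$do_ceiling)
  records <- dplyr::bind_rows(
    dplyr::mutate(rec_profile, source = "profile"),
    dplyr::mutate(rec_exp, source = "experiment"))
  pw_fit <- tryCatch(fit_power_law(records), error = function(e) {
    inform(paste("partition: power-law fit skipped:", conditionMessage(e)))
    NULL
  })
  threshold <- if (!is.null(pw_fit) && pw_fit$b < 0) {
    threshold_do(pw_fit, target_pct = config$target_pct)
  } else {
    NA_real_
  }
  inform(sprintf("partition: %d records, threshold %.0f nM", nrow(records),
                 threshold))

  # isotopes: Rayleigh + reoxidation overprint along the profile; the
  # overprint is confined to the SCM-SNM band where nitrite oxidizers sit
  z <- profile$depth_m
  gauss <- function(z, mu, sd) exp(-(z - mu)^2 / (2 * sd^2))
  denit <- gauss(z, tp$snm_depth, tp$snm_sd) *
    plogis((z - tp$oxycline_depth) / 5)
  f_rem <- 1 - (1 - config$f_min) * denit
  reox <- config$reox_max * gauss(z, tp$nob_depth, tp$nob_sd) *
    plogis((z - tp$oxycline_depth) / 5)
  iso <- purrr::map2(f_rem, reox, function(f, r) {
    simulate_dual_isotopes(f, eps15 = config$eps15, eps18 = config$eps18,
                           reox_fraction = r)
  }) |> dplyr::bind_rows()
  iso_tbl <- tibble(station = tp$station, depth_m = z,
                    delta15N = iso$delta15N, delta18O = iso$delta18O,
                    NO3_nM = tp$no3_deep * iso$f_remaining)
  deviations <- deviation_profile(iso_tbl)
  inform(sprintf("isotopes: %d depths, peak deviation at %.0f m", nrow(iso_tbl),
                 attr(deviations, "peak_depth_m")))

  manifest <- list(package = "nitroxr",
                   version = as.character(utils::packageVersion("nitroxr")),
                   seed = config$seed,
                   config_hash = hash,
                   created = "run_pipeline")
  result <- structure(list(profile = profile,
                           bottles = bottles,
                           rates = rates,
                           ocr = list(bottles = ocr_bottle, depths = ocr_depth),
                           experiment = list(bottles = man, no2ox = man_no2,
                                             nh3ox = man_nh3),
                           kinetics = list(ocr_fit = ocr_fit,
                                           no2ox_fit = no2ox_fit,
                                           low_level = low_level),
                           partition = list(records = records, fit = pw_fit,
                                            threshold_nM = threshold),
                           isotopes = deviations,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    write_pipeline_result(result, config$out_dir, force = config$force)
  }
  result
}

write_pipeline_result <- function(result, out_dir, force = FALSE) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    if (!identical(old$config_hash, result$manifest$config_hash) && !force) {
      abort(sprintf(
        "output directory %s holds results for a different config hash (%s); use force = TRUE to overwrite",
        out_dir, old$config_hash))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- result$manifest$config_hash
  write_profiles(result$profile, file.path(out_dir, "profile.csv"), hash)
  write_bottles(result$bottles, file.path(out_dir, "bottles.csv"), hash)
  wr <- function(tbl, name) {
    readr::write_lines(paste0("# config_hash: ", hash),
                       file.path(out_dir, name))
    readr::write_csv(tbl, file.path(out_dir, name), append = TRUE,
                     col_names = TRUE)
  }
  wr(result$rates, "rates.csv")
  wr(result$ocr$depths, "ocr_depths.csv")
  kin <- dplyr::bind_rows(
    dplyr::mutate(glance(result$kinetics$ocr_fit), response = "OCR",
                  Km = result$kinetics$ocr_fit$Km,
                  vmax = result$kinetics$ocr_fit$vmax),
    dplyr::mutate(glance(result$kinetics$no2ox_fit),
                  response = "nitrite_oxidation",
                  Km = result$kinetics$no2ox_fit$Km,
                  vmax = result$kinetics$no2ox_fit$vmax))
  wr(kin, "kinetics.csv")
  wr(result$partition$records, "partition_records.csv")
  wr(as_tibble(result$isotopes), "deviation_profile.csv")
  jsonlite::write_json(result$manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("nitroxr pipeline result\n")
  cat(sprintf("  %d profile depths, %d bottles, %d rate estimates\n",
              nrow(x$profile), nrow(x$bottles), nrow(x$rates)))
  cat(sprintf("  partition: %d records, threshold %.0f nM\n",
              nrow(x$partition$records), x$partition$threshold_nM))
  cat(sprintf("  peak Delta(15,18) deviation at %.0f m\n",
              attr(x$isotopes, "peak_depth_m")))
  invisible(x)
}
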