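# End-to-end orchestration: simulate -> geolocate -> classify -> build-panel
# -> fit-choice -> fit-distance -> daily, with seeded substreams, stage
# logging, and machine-readable outputs.

#' Pipeline run configuration
#'
#' @param out_dir artifact directory.
#' @param seed global seed; each stage derives its own deterministic
#'   substream so stages can be rerun independently.
#' @param world named list of [world_config()] arguments.
#' @param truth_args named list of [world_truth()] overrides.
#' @param noise named list of [log_noise()] arguments.
#' @param aqi_pattern AQI pattern for [gen_aqi()].
#' @param home_radius,facility_min,overlap labelling thresholds (metres,
#'   seconds, fraction).
#' @param measure,interactions model specification shared by the choice and
#'   distance fits.
#' @param zero_policy zero-count handling for the log-odds stage ("error",
#'   "continuity", "drop"); small demo panels need the continuity
#'   correction.
#' @param bootstrap_B bootstrap samples for the effect CIs (0 disables).
#' @param bootstrap_unit resampling unit.
#' @param tobit_max_rows cap on phone-hours entering the Tobit fit (a
#'   seeded subsample keeps the likelihood evaluation tractable at desk
#'   scale; 0 means no cap).
#' @param stages stages to run, in order.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("mobiaq_run_"), seed = 1L,
                       world = list(), truth_args = list(), noise = list(),
                       aqi_pattern = "wave",
                       home_radius = 500, facility_min = 2400, overlap = 0.05,
                       measure = "levels", interactions = "none",
                       zero_policy = "error",
                       bootstrap_B = 0, bootstrap_unit = "city-day",
                       tobit_max_rows = 200000,
                       stages = c("simulate", "geolocate", "classify",
                                  "build-panel", "fit-choice", "fit-distance",
                                  "daily")) {
  stopifnot(home_radius > 0, facility_min > 0, overlap > 0)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), world = world,
              truth_args = truth_args, noise = noise,
              aqi_pattern = aqi_pattern, home_radius = home_radius,
              facility_min = facility_min, overlap = overlap,
              measure = measure, interactions = interactions,
              zero_policy = zero_policy,
              bootstrap_B = bootstrap_B, bootstrap_unit = bootstrap_unit,
              tobit_max_rows = tobit_max_rows, stages = stages)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

stage_seed <- function(config, stage) {
  config$seed + 1009L * match(stage, c("simulate", "geolocate", "classify",
                                       "build-panel", "fit-choice",
                                       "fit-distance", "daily"))
}

# Atomic-ish writer: materialise under a .partial suffix, rename on success.
write_stage_csv <- function(df, path) {
  tmp <- paste0(path, ".partial")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
}

write_stage_json <- function(x, path) {
  tmp <- paste0(path, ".partial")
  jsonlite::write_json(strip_classes(x), tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
}

# jsonlite only knows base classes; flatten ours recursively
strip_classes <- function(x) {
  if (inherits(x, "data.frame")) {
    class(x) <- "data.frame"
    x
  } else if (is.list(x)) {
    lapply(unclass(x), strip_classes)
  } else x
}

#' Run the full pipeline
#'
#' Executes the configured stages in order, writing every intermediate
#' artifact (towers.csv, records.csv, facilities.geojson, aqi.csv,
#' truth.json, placements.csv, tower_tags.csv, panel.csv, effects.json,
#' distance_effects.json, daily_effects.json) plus a manifest with the
#' configuration, seed, versions, and per-stage row counts. Reruns with the
#' same seed are deterministic. A failing stage aborts with the stage named;
#' its partial outputs keep a ".partial" suffix.
#'
#' @param config a [run_config()].
#' @return the artifact directory, invisibly; the manifest is also returned
#'   as `attr(, "manifest")`.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("mobiaq")),
    r_version = R.version.string,
    config = config[setdiff(names(config), "stages")],
    stages = list()
  )
  cfg_file <- file.path(config$out_dir, "run_config.json")
  write_stage_json(config, cfg_file)
  manifest$config_md5 <- unname(tools::md5sum(cfg_file))
  env <- new.env()
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    set.seed(stage_seed(config, name))
    info <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- info
  }

  run_stage("simulate", function() {
    wc <- do.call(world_config, c(config$world, list(seed = stage_seed(config, "simulate"))))
    env$world <- gen_world(wc, config$truth_args)
    env$aqi <- gen_aqi(wc, config$aqi_pattern)
    env$choices <- gen_choices(env$world, env$aqi, measure = config$measure)
    env$records <- gen_logs(env$choices, env$world,
                            do.call(log_noise, config$noise))
    write_world(env$world, env$aqi, config$out_dir)
    write_stage_csv(env$records, file.path(config$out_dir, "records.csv"))
    list(n_records = nrow(env$records), n_users = nrow(env$world$homes),
         n_towers = nrow(env$world$towers))
  })

  run_stage("geolocate", function() {
    if (is.null(env$records)) {
      env$records <- utils::read.csv(file.path(config$out_dir, "records.csv"))
      env$world <- NULL
    }
    towers <- if (!is.null(env$world)) env$world$towers else
      utils::read.csv(file.path(config$out_dir, "towers.csv"))
    env$towers <- towers
    eligible <- filter_users(env$records)
    recs <- env$records[env$records$phone_id %in% eligible, ]
    env$placements <- hourly_placements(recs, towers)
    write_stage_csv(env$placements, file.path(config$out_dir, "placements.csv"))
    list(n_eligible = length(eligible),
         n_dropped_no_home = attr(env$placements, "dropped_no_home"),
         n_placements = nrow(env$placements))
  })

  run_stage("classify", function() {
    facs <- if (!is.null(env$world)) c(env$world$parks, env$world$malls) else
      read_facilities_geojson(file.path(config$out_dir, "facilities.geojson"))
    sa <- voronoi_service_areas(env$towers)
    env$tags <- tag_towers(sa, facs, config$overlap)
    env$labeled <- label_hours(env$placements, env$tags,
                               home_radius = config$home_radius,
                               facility_min = config$facility_min)
    write_stage_csv(env$tags, file.path(config$out_dir, "tower_tags.csv"))
    write_stage_csv(env$labeled, file.path(config$out_dir, "labeled_placements.csv"))
    list(n_park_towers = sum(env$tags$is_park_tower),
         n_mall_towers = sum(env$tags$is_mall_tower),
         label_conflicts = attr(env$labeled, "label_conflicts"),
         labels = as.list(table(env$labeled$label)))
  })

  run_stage("build-panel", function() {
    if (is.null(env$aqi)) {
      env$aqi <- utils::read.csv(file.path(config$out_dir, "aqi.csv"))
    }
    env$panel <- build_panel(env$labeled, env$aqi)
    write_stage_csv(env$panel, file.path(config$out_dir, "panel.csv"))
    list(n_rows = nrow(env$panel), n_total = sum(env$panel$n_total))
  })

  run_stage("fit-choice", function() {
    spec <- choice_spec(config$measure, config$interactions)
    env$choice_fit <- suppressMessages(
      fit_share_logit(env$panel, spec, zero_policy = config$zero_policy))
    out <- list(measure = config$measure)
    if (config$measure == "levels") {
      eff <- effect_level_switch(env$choice_fit)
      out$level_switch <- list(from = "Good", to = "Heavily_Polluted",
                               effects = eff)
      if (config$bootstrap_B > 0) {
        bs <- suppressMessages(bootstrap_ci(
          env$panel, spec, stat_level_switch(),
          B = config$bootstrap_B, unit = config$bootstrap_unit,
          seed = stage_seed(config, "fit-choice"),
          zero_policy = config$zero_policy))
        out$level_switch$ci_share <- bs$ci
      }
    } else {
      out$aqi10 <- list(delta = 10, effects = effect_continuous(env$choice_fit))
    }
    write_stage_json(out, file.path(config$out_dir, "effects.json"))
    env$effects <- out
    list(n_rows = nrow(env$panel))
  })

  run_stage("fit-distance", function() {
    pl <- env$labeled
    if (config$tobit_max_rows > 0 && nrow(pl) > config$tobit_max_rows) {
      pl <- pl[sample.int(nrow(pl), config$tobit_max_rows), ]
    }
    spec <- tobit_spec(config$measure, config$interactions)
    env$tobit_fit <- fit_tobit(pl, spec, aqi = env$aqi)
    eff <- if (config$measure == "levels") {
      tobit_effect(env$tobit_fit)
    } else {
      tobit_effect(env$tobit_fit, delta_aqi = 10)
    }
    out <- list(measure = config$measure, n = env$tobit_fit$n,
                sigma = env$tobit_fit$sigma,
                latent_m = eff$latent, observed_m = eff$observed)
    write_stage_json(out, file.path(config$out_dir, "distance_effects.json"))
    out
  })

  run_stage("daily", function() {
    env$daily <- build_daily(env$panel)
    fits <- lapply(c("max", "mean", "median", "official"), function(ms) {
      f <- fit_daily(env$daily, ms)
      list(measure = ms, coefficient = f$coefficient, se = f$se, p = f$p,
           ci = f$ci)
    })
    out <- list(outcome = "share1000_h", fits = fits)
    if (config$measure == "aqi") {
      cmp <- compare_scales(effect_continuous(env$choice_fit),
                            fit_daily(env$daily, "mean"))
      out$comparison <- cmp[c("hourly", "daily", "ratio", "verdict")]
    }
    write_stage_csv(env$daily, file.path(config$out_dir, "daily.csv"))
    write_stage_json(out, file.path(config$out_dir, "daily_effects.json"))
    list(n_rows = nrow(env$daily))
  })

  write_stage_json(manifest, file.path(config$out_dir, "manifest.json"))
  out <- invisible(config$out_dir)
  attr(out, "manifest") <- manifest
  out
}
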