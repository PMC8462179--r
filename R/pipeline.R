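## Pipeline orchestration: one config drives the stage order of the whole
## analysis - season filter, haulout/trip segmentation, dive prefilter/
## scoring/classification, location interpolation, covariate extraction,
## MCP/availability/pseudo-absences, VIF, model fit (or AIC selection),
## importance, prediction map, overlap, and trip statistics - and a run
## manifest records every parameter, seed and per-stage row count.

#' Default pipeline configuration
#'
#' Returns the complete configuration list for a synthetic run; any element
#' can be overridden. `species` switches the season window and the
#' return-trip-only restriction (active for gray seals).
#'
#' @param seed master seed; stage seeds derive from it.
#' @param species `"gray"` or `"harbor"`.
#' @return nested named list.
#' @export
default_config <- function(seed = 1L, species = "gray") {
  list(
    species = species,
    mode = "colony",
    coord_mode = "planar_km",
    seed = as.integer(seed),
    synthetic = list(
      extent_km = 100, cell_km = 2, coast_complexity = 1, max_depth = 150,
      n_sediment = 4, tidal_smoothness = 5, n_haulouts = 2,
      shelf_cutoff = 120,
      pref = list(b_bathy = -0.02, b_tidal = 0, b_shore = 0,
                  b_haulout = -0.08, sediment_logodds = 0, phi = 0.5),
      n_seals = 4, n_trips_per_seal = 6, dives_per_trip = 18,
      fix_interval_min = 20, dropout = 0.2),
    dive = list(v_max = 2, min_depth = 3, min_duration = 30,
                tad_quantile = 0.25, speed_exclusion = 0.10, max_gap_h = 6),
    trips = list(dry_start_min = 10, wet_end_s = 40, min_duration_h = 3,
                 radius_km = 50, step_min = 20),
    model = list(terms = c("bathy", "tidal", "dist_shore", "dist_haulout",
                           "sediment"),
                 k = 5, select = FALSE, subsample = "none"),
    availability = list(scale_factor = 3, pa_ratio = 2),
    overlap = list(n_grid = 80, level = 0.95),
    output_dir = NULL)
}

stage_rec <- function(manifest, name, ...) {
  manifest$stages[[name]] <- list(...)
  manifest
}

#' Run the full habitat-selection pipeline
#'
#' Executes the analysis end to end on synthetic data generated from the
#' config's `synthetic` block (or on tables supplied via `data`), in the
#' fixed stage order, and returns a manifest of parameters, seeds and
#' per-stage record counts. Any stage error aborts with the stage name;
#' completed stage outputs are preserved in the returned object.
#'
#' @param config a [default_config()]-style list (or path to a YAML file).
#' @return list of class `pipeline_run`: `manifest`, and the stage outputs
#'   (`seascape`, `sim`, `trips`, `dives`, `ua_table`, `model`,
#'   `importance`, `map`, `overlap`, `trip_comparison`).
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  manifest <- list(config = cfg, stages = list(),
                   package_version = as.character(utils::packageVersion("sealselect")))
  run <- list()
  stage <- "init"
  res <- try({
    ## ---- synthetic world + tracks ----
    stage <- "simulate"
    syn <- cfg$synthetic
    params <- seascape_params(
      extent_km = syn$extent_km, cell_km = syn$cell_km,
      coast_complexity = syn$coast_complexity, max_depth = syn$max_depth,
      n_sediment = syn$n_sediment, tidal_smoothness = syn$tidal_smoothness,
      n_haulouts = syn$n_haulouts, shelf_cutoff = syn$shelf_cutoff)
    seascape <- make_seascape(params, seed = cfg$seed)
    pref <- do.call(true_preference, syn$pref)
    sim <- simulate_seals(seascape, pref, n_seals = syn$n_seals,
                          n_trips_per_seal = syn$n_trips_per_seal,
                          seed = cfg$seed + 1L,
                          dives_per_trip = syn$dives_per_trip,
                          fix_interval_min = syn$fix_interval_min,
                          dropout = syn$dropout)
    seagraph <- build_sea_graph(seascape)
    run$seascape <- seascape; run$sim <- sim
    manifest <- stage_rec(manifest, "simulate", seed = cfg$seed + 1L,
                          n_fixes = nrow(sim$fixes), n_dives = nrow(sim$dives),
                          n_wetdry = nrow(sim$wetdry))

    ## ---- haulouts and trips ----
    stage <- "haulouts"
    events <- detect_haulouts(sim$wetdry,
                              dry_start_min = cfg$trips$dry_start_min,
                              wet_end_s = cfg$trips$wet_end_s)
    events <- assign_colony(events, sim$fixes, seascape$haulouts,
                            radius_km = cfg$trips$radius_km)
    manifest <- stage_rec(manifest, "haulouts", n_events = nrow(events))

    stage <- "trips"
    trips <- segment_trips(sim$fixes, events)
    windows <- season_windows(cfg$species)
    trips_f <- filter_trips(trips, windows,
                            min_duration_h = cfg$trips$min_duration_h,
                            return_only = cfg$species == "gray")
    trips_f <- trip_metrics(trips_f, seascape, seagraph,
                            step_min = cfg$trips$step_min)
    run$trips <- trips_f
    manifest <- stage_rec(manifest, "trips", n_trips = nrow(trips),
                          n_retained = nrow(trips_f),
                          return_only = cfg$species == "gray",
                          excluded_months = windows$excluded_months)

    ## ---- dives: prefilter -> score -> classify -> locate ----
    stage <- "dive_classification"
    rule <- classification_rule(cfg$dive$min_depth, cfg$dive$min_duration,
                                cfg$dive$tad_quantile,
                                cfg$dive$speed_exclusion)
    dv <- prefilter(sim$dives, rule)
    dv <- score_dives(dv, tad_params(v_max = cfg$dive$v_max))
    dv <- classify_foraging(dv, rule)
    dv <- interpolate_dive_locations(dv, sim$fixes,
                                     max_gap_h = cfg$dive$max_gap_h)
    run$dives <- dv
    manifest <- stage_rec(manifest, "dive_classification",
                          n_dives = nrow(sim$dives), n_prefiltered = nrow(dv),
                          n_foraging = sum(dv$foraging, na.rm = TRUE))

    ## ---- use-availability design ----
    stage <- "availability"
    fg <- dv[!is.na(dv$foraging) & dv$foraging, , drop = FALSE]
    fg$individual <- fg$seal
    hull <- mcp(fg[, c("x", "y")])
    region <- availability_region(hull, seascape,
                                  scale_factor = cfg$availability$scale_factor)
    pa <- sample_pseudo_absences(region, fg,
                                 ratio = cfg$availability$pa_ratio,
                                 seed = cfg$seed + 2L)
    manifest <- stage_rec(manifest, "availability",
                          area_mcp = region$area_mcp,
                          area_scaled = region$area_scaled,
                          area_clipped = region$area_clipped,
                          n_foraging = nrow(fg), n_pseudo = nrow(pa),
                          seed = cfg$seed + 2L)

    stage <- "covariates"
    fg_cov <- extract_covariates(fg[, c("x", "y", "individual")],
                                 seascape, seagraph)
    pa_cov <- extract_covariates(pa[, c("x", "y", "individual")],
                                 seascape, seagraph)
    ua <- build_ua_table(fg_cov, pa_cov)
    run$ua_table <- ua
    manifest <- stage_rec(manifest, "covariates", n_rows = nrow(ua),
                          n_dropped = (attr(fg_cov, "n_dropped") %||% 0) +
                            (attr(pa_cov, "n_dropped") %||% 0))

    ## ---- model ----
    stage <- "vif"
    vif_warn <- character()
    vif <- withCallingHandlers(vif_screen(ua), warning = function(w) {
      vif_warn <<- c(vif_warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    manifest <- stage_rec(manifest, "vif", vif = as.list(vif),
                          warnings = vif_warn)

    stage <- "model"
    if (isTRUE(cfg$model$select)) {
      sel <- select_model(ua, terms = cfg$model$terms, k = cfg$model$k,
                          mode = cfg$mode)
      model <- sel$best
      manifest <- stage_rec(manifest, "model_selection",
                            ledger = sel$ledger)
    } else {
      model <- fit_selection_model(ua, terms = cfg$model$terms,
                                   k = cfg$model$k, mode = cfg$mode,
                                   subsample = cfg$model$subsample)
    }
    imp <- term_importance(model, ua)
    run$model <- model; run$importance <- imp
    manifest <- stage_rec(manifest, "model", aic = model$aic,
                          explained_deviance = model$explained_deviance,
                          importance = as.list(imp),
                          reference_sediment = model$reference_sediment,
                          k = cfg$model$k, mode = cfg$mode)

    stage <- "map"
    run$map <- predict_map(model, seascape, seagraph)
    manifest <- stage_rec(manifest, "map",
                          n_cells = sum(is.finite(run$map$prob$values)))

    ## ---- overlap ----
    stage <- "overlap"
    n_per <- table(fg$individual)
    if (sum(n_per >= 10) >= 2) {
      ov <- pairwise_overlap(fg, id = "individual",
                             n_grid = cfg$overlap$n_grid,
                             level = cfg$overlap$level)
      run$overlap <- ov
      manifest <- stage_rec(manifest, "overlap", n_pairs = nrow(ov$pairs),
                            ba_mean = ov$mean, ba_sd = ov$sd)
    } else {
      manifest <- stage_rec(manifest, "overlap", skipped = "too few individuals")
    }

    ## ---- trip statistics ----
    stage <- "trip_stats"
    ok_tr <- !is.na(trips_f$max_extent_km) & trips_f$max_extent_km > 0 &
      trips_f$duration_h > 0
    tt <- trip_metrics_table(trips_f[ok_tr, , drop = FALSE],
                             site = trips_f$dep_site[ok_tr],
                             species = cfg$species)
    run$trip_table <- tt
    if (length(unique(tt$site)) >= 2 && min(table(tt$site)) >= 3) {
      cmp <- compare_sites(tt, "log_duration")
      run$trip_comparison <- cmp
      manifest <- stage_rec(manifest, "trip_stats", branch = cmp$branch,
                            p = cmp$p, n_trips = nrow(tt))
    } else {
      manifest <- stage_rec(manifest, "trip_stats",
                            skipped = "fewer than 2 usable sites")
    }
    "ok"
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 attr(res, "condition")$message), call. = FALSE)
  run$manifest <- manifest
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest_json(manifest),
                         file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(run, class = "pipeline_run")
}

## manifest without non-serializable payloads
manifest_json <- function(manifest) {
  manifest$stages <- lapply(manifest$stages, function(s)
    lapply(s, function(v) if (is.data.frame(v)) as.list(v) else v))
  manifest
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> stages:", paste(names(x$manifest$stages), collapse = " -> "),
      "\n")
  invisible(x)
}

#' Human-readable run report
#'
#' Formats the manifest of a [run_pipeline()] result as text: explained
#' deviance and per-covariate importance shares, the AIC ledger (when
#' model selection ran), trip statistics and overlap summaries. Sections
#' without data are omitted with a note.
#'
#' @param run a `pipeline_run` (or its manifest).
#' @return character vector of report lines (invisibly printed).
#' @export
make_report <- function(run) {
  m <- if (inherits(run, "pipeline_run")) run$manifest else run
  s <- m$stages
  ln <- c("=== sealselect run report ===",
          sprintf("species: %s   mode: %s   seed: %d",
                  m$config$species, m$config$mode, m$config$seed))
  if (!is.null(s$simulate))
    ln <- c(ln, sprintf("data: %d fixes, %d dives", s$simulate$n_fixes,
                        s$simulate$n_dives))
  if (!is.null(s$dive_classification))
    ln <- c(ln, sprintf("dives: %d -> %d prefiltered -> %d foraging (%.1f%%)",
                        s$dive_classification$n_dives,
                        s$dive_classification$n_prefiltered,
                        s$dive_classification$n_foraging,
                        100 * s$dive_classification$n_foraging /
                          max(1, s$dive_classification$n_prefiltered)))
  if (!is.null(s$availability))
    ln <- c(ln, sprintf("availability: MCP %.0f km2, buffer %.0f km2, clipped %.0f km2; %d pseudo-absences",
                        s$availability$area_mcp, s$availability$area_scaled,
                        s$availability$area_clipped, s$availability$n_pseudo))
  if (!is.null(s$model)) {
    imp <- unlist(s$model$importance)
    ln <- c(ln, sprintf("model: ED %.1f%% (AIC %.1f); importance: %s",
                        s$model$explained_deviance, s$model$aic,
                        paste(sprintf("%s %.1f%%", names(imp), imp),
                              collapse = ", ")))
  }
  if (!is.null(s$model_selection))
    ln <- c(ln, "model selection ledger (top rows):",
            utils::capture.output(print(utils::head(s$model_selection$ledger, 5),
                                        row.names = FALSE)))
  ln <- c(ln, if (!is.null(s$trip_stats$skipped))
    sprintf("trip stats: omitted (%s)", s$trip_stats$skipped)
    else sprintf("trip stats: %s branch, omnibus p = %.4g over %d trips",
                 s$trip_stats$branch, s$trip_stats$p, s$trip_stats$n_trips))
  ln <- c(ln, if (!is.null(s$overlap$skipped))
    sprintf("overlap: omitted (%s)", s$overlap$skipped)
    else sprintf("overlap: %d pairs, BA %.2f +/- %.2f", s$overlap$n_pairs,
                 s$overlap$ba_mean, ifelse(is.na(s$overlap$ba_sd), 0,
                                           s$overlap$ba_sd)))
  cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}
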