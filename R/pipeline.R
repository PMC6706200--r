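#' Reference pipeline configuration
#'
#' Houses the analysis constants of the reference fjord design: 24 hr
#' post-release removal, 4 min minimum transit, seasonal windows fixed at
#' the observed SST shifts, weekly metric series starting 25 August 2015
#' (the last release date), VIF threshold 3, and the node-strength /
#' degree model formulas.
#'
#' @param qc_window False-detection screening half-window, seconds.
#' @param qc_min_neighbors Minimum same-tag same-receiver neighbours.
#' @param postrelease_hours Discarded post-release window, hours.
#' @param min_transit_s Minimum plausible transit, seconds.
#' @param season A [season_windows()] object.
#' @param weekly_start First weekly-metric window start (date).
#' @param n_weeks Number of 7-day windows (default spans the study).
#' @param vif_threshold Collinearity screening threshold.
#' @param strength_predictors,degree_predictors Fixed-effect terms for the
#'   two connectivity models.
#' @param tz Day-boundary timezone.
#' @param seed Seed used for any randomised test (permutations).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(qc_window = 3600,
                            qc_min_neighbors = 1L,
                            postrelease_hours = 24,
                            min_transit_s = 240,
                            season = default_season_windows(),
                            weekly_start = as.Date("2015-08-25"),
                            n_weeks = 21L,
                            vif_threshold = 3,
                            strength_predictors = c("sst", "log_wind_speed",
                                                    "wind_direction"),
                            degree_predictors = c("sst", "wind_direction"),
                            tz = "Europe/Stockholm",
                            seed = 1L) {
  structure(list(qc_window = qc_window,
                 qc_min_neighbors = qc_min_neighbors,
                 postrelease_hours = postrelease_hours,
                 min_transit_s = min_transit_s, season = season,
                 weekly_start = as.Date(weekly_start),
                 n_weeks = as.integer(n_weeks),
                 vif_threshold = vif_threshold,
                 strength_predictors = strength_predictors,
                 degree_predictors = degree_predictors,
                 tz = tz, seed = seed),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Collects every problem found (window overlap or gaps, non-positive
#' thresholds, missing seed) rather than stopping at the first.
#'
#' @param config A [pipeline_config()].
#' @return The config, invisibly, when valid; otherwise stops with the
#'   collected error messages.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(config$qc_window > 0, "qc_window must be positive")
  chk(config$qc_min_neighbors >= 1, "qc_min_neighbors must be >= 1")
  chk(config$postrelease_hours >= 0, "postrelease_hours must be >= 0")
  chk(config$min_transit_s >= 0, "min_transit_s must be >= 0")
  chk(config$n_weeks > 0, "n_weeks must be positive")
  chk(config$vif_threshold > 0, "vif_threshold must be positive")
  chk(!is.null(config$seed) && is.finite(config$seed),
      "a seed must be provided")
  s <- config$season
  chk(inherits(s, "season_windows"), "season must be a season_windows object")
  if (inherits(s, "season_windows") && nrow(s) > 1) {
    chk(all(s$start[-1] == s$end[-nrow(s)] + 1L),
        "season windows must be contiguous and non-overlapping")
  }
  if (length(errs) > 0) {
    stop("invalid pipeline configuration:\n  - ",
         paste(errs, collapse = "\n  - "))
  }
  invisible(config)
}

#' Run the full movement-network analysis
#'
#' Orchestrates every stage on one input bundle: false-detection QC,
#' post-release removal, movement extraction, cohort exclusions, the
#' per-fish summary (days detected/monitored, RI, MI), aggregated seasonal
#' networks, weekly node-strength/degree series joined to environmental
#' covariates, VIF screening, the NB (strength) and ZINB (degree) mixed
#' models, monthly triad-census series with per-class temperature models,
#' and the seasonal/site/size comparison tests. When `outdir` is given,
#' stage outputs are written as CSV/GraphML/JSON with a manifest recording
#' the configuration and record counts in and out of every filter.
#'
#' @param bundle A `sim_bundle` from [simulate_telemetry()], or a list
#'   with elements `detections`, `fish`, `receivers`, `environment`,
#'   `sst_daily` in the same shapes the readers produce.
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory.
#' @return A list of stage results: `qc`, `detections`, `movements`,
#'   `exclusions`, `summary`, `seasonal_networks`, `weekly`, `vif`,
#'   `models`, `motifs`, `motif_models`, `comparisons`, `manifest`.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(), outdir = NULL) {
  validate_config(config)
  stage <- "qc"
  res <- tryCatch({
    counts <- list(raw = nrow(bundle$detections))
    det <- flag_false_detections(bundle$detections,
                                 window = config$qc_window,
                                 min_neighbors = config$qc_min_neighbors)
    counts$qc_valid <- sum(det$valid)
    det <- det[det$valid, , drop = FALSE]

    stage <- "postrelease"
    det <- remove_postrelease(det, bundle$fish,
                              window_hours = config$postrelease_hours)
    counts$post_release <- nrow(det)

    stage <- "movements"
    movements <- extract_movements(det, min_transit_s = config$min_transit_s)
    counts$movements <- nrow(movements)

    stage <- "exclusions"
    excl <- exclude_fish(bundle$fish, det, movements)
    keep <- excl$retained$transmitter_id
    det <- det[det$transmitter_id %in% keep, , drop = FALSE]
    movements <- movements[movements$transmitter_id %in% keep, , drop = FALSE]
    counts$fish_tagged <- nrow(bundle$fish)
    counts$fish_retained <- length(keep)

    stage <- "summary"
    study_end <- max(config$season$end)
    summ <- fish_summary(det, movements, excl$retained, study_end,
                         tz = config$tz)

    stage <- "networks"
    nodes <- sort(bundle$receivers$receiver_id)
    seasonal <- aggregate_seasonal(movements, config$season, nodes = nodes,
                                   tz = config$tz)
    weekly <- weekly_metrics(movements, config$weekly_start, config$n_weeks,
                             subjects = keep, nodes = nodes, tz = config$tz)
    env <- transform_predictors(bundle$environment)
    weekly <- merge(weekly, env, by = "week_start", all.x = TRUE,
                    sort = FALSE)
    weekly <- weekly[order(weekly$transmitter_id, weekly$week), , drop = FALSE]

    stage <- "vif"
    cand <- c("sst", "log_wind_speed", "sqrt_par", "sea_level",
              "wind_direction")
    vif <- vif_screen(env[cand], threshold = config$vif_threshold,
                      protect = "sst")

    stage <- "models"
    wk <- weekly[stats::complete.cases(weekly), , drop = FALSE]
    models <- list(
      strength = fit_nb_glmm(
        stats::reformulate(config$strength_predictors, "strength"),
        data = wk, subject = "transmitter_id"),
      degree = fit_zinb_glmm(
        stats::reformulate(config$degree_predictors, "degree"),
        data = wk, subject = "transmitter_id"))

    stage <- "motifs"
    months <- sort(unique(format(seq(min(config$season$start),
                                     max(config$season$end), by = "day"),
                                 "%Y-%m")))
    sst_mo <- monthly_mean_sst(bundle$sst_daily)
    motifs <- monthly_motif_series(movements, months, sst_mo,
                                   subjects = keep, nodes = nodes,
                                   tz = config$tz)
    motif_models <- lapply(stats::setNames(1:16, triad_classes()),
                           function(k) motif_temperature_model(motifs, k))

    stage <- "comparisons"
    rel <- relative_movements_per_day(movements, det, tz = config$tz)
    rel$season <- assign_season(rel$date, config$season)
    rel_ok <- rel[!is.na(rel$relative_movements), , drop = FALSE]
    set.seed(config$seed)
    # a season without variance in daily movement rates (e.g. a still
    # winter in a small cohort) leaves the seasonal tests undefined;
    # report the reason instead of aborting the run
    try_cmp <- function(expr) tryCatch(expr, error = function(e)
      list(error = conditionMessage(e)))
    comparisons <- list(
      season_welch = try_cmp(welch_anova(rel_ok$relative_movements,
                                         rel_ok$season)),
      season_posthoc = try_cmp(games_howell(rel_ok$relative_movements,
                                            rel_ok$season)),
      ri_site = site_comparison(summ$residency_index, summ$site, "t"),
      movements_site = site_comparison(summ$n_movements, summ$site,
                                       "wilcoxon"),
      size_vs_index = list(
        weight_ri = spearman_test(summ$weight, summ$residency_index),
        weight_mi = spearman_test(summ$weight, summ$movement_index),
        length_ri = spearman_test(summ$total_length, summ$residency_index),
        length_mi = spearman_test(summ$total_length, summ$movement_index)))

    manifest <- list(package = "fishconn",
                     version = as.character(utils::packageVersion("fishconn")),
                     seed = config$seed, counts = counts,
                     exclusions = excl$report,
                     config = config[setdiff(names(config), "season")])
    list(qc = counts, detections = det, movements = movements,
         exclusions = excl, summary = summ, seasonal_networks = seasonal,
         weekly = weekly, vif = vif, models = models, motifs = motifs,
         motif_models = motif_models, comparisons = comparisons,
         relative_daily = rel, manifest = manifest)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(outdir)) .write_pipeline_outputs(res, outdir)
  res
}

.write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$movements, file.path(outdir, "movements.csv"),
                   row.names = FALSE)
  utils::write.csv(res$summary, file.path(outdir, "fish_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(res$weekly, file.path(outdir, "weekly_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(res$motifs, file.path(outdir, "monthly_motifs.csv"),
                   row.names = FALSE)
  for (s in names(res$seasonal_networks)) {
    igraph::write_graph(res$seasonal_networks[[s]],
                        file.path(outdir, paste0("network_", s, ".graphml")),
                        format = "graphml")
  }
  coef_rows <- function(name, fit) {
    if (is.null(fit$coefficients)) return(NULL)
    cbind(response = name, fit$coefficients)
  }
  mod_tab <- rbind(coef_rows("strength", res$models$strength),
                   coef_rows("degree", res$models$degree))
  utils::write.csv(mod_tab, file.path(outdir, "model_estimates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  invisible(outdir)
}

#' Published per-fish summary of the reference fjord cohort
#'
#' The printed summary table of the 39 juvenile/subadult Atlantic cod
#' retained in the Gullmar Fjord tracking study: transmitter, release
#' site, weight (g), total length (cm), release date, days detected, days
#' monitored, and the published residency (RI) and movement (MI) indices
#' rounded to two decimals. Shipped as plain CSV and used as a worked
#' reference for the index arithmetic.
#'
#' @return A `data.frame` with 39 rows.
#' @export
reference_cohort_summary <- function() {
  path <- system.file("extdata", "reference_cohort_summary.csv",
                      package = "fishconn")
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(transmitter_id = "character"))
  out$release_date <- as.Date(out$release_date, format = "%d/%m/%Y")
  out
}
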