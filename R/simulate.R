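#' Configuration for the synthetic fjord telemetry generator
#'
#' Defaults emulate a two-site coastal fjord tracking design: 48 tagged
#' juvenile cod monitored by 11 moored receivers from mid-August 2015 to
#' 18 January 2016, transmitters pinging at uniform random 30--90 s
#' intervals, a seasonal SST decline whose seasonal-window means sit near
#' 16.3, 9.4 and 3.7 deg C, and a per-fish movement rate that declines
#' log-linearly with SST (`lambda_i(t) = exp(beta0 + b_i + beta_sst *
#' SST(t))` per day, `b_i ~ N(0, ranef_sd^2)`). Fish occupy discrete
#' receiver zones; between-site traffic is restricted to two corridor
#' pairs; a constant daily hazard governs permanent departure from the
#' array (emigration and mortality being indistinguishable to the array).
#'
#' @param n_fish Number of tagged fish.
#' @param study_start,study_end Study period dates.
#' @param interval_bounds Transmitter interval bounds, seconds.
#' @param sst List of SST curve parameters: `summer_level`, `winter_level`
#'   (deg C), `midpoint_day`, `scale_days` (logistic decline), `noise_sd`.
#' @param beta0 Log movement rate (per day) at SST 0 for an average fish.
#' @param beta_sst Log-linear SST effect on the movement rate (per deg C).
#' @param ranef_sd SD of the per-fish log-rate intercept.
#' @param emigration_hazard Daily hazard of permanently leaving the array.
#' @param detection_prob Probability a transmission inside a zone is
#'   logged (0.6 matches ranges defined by 60% detection efficiency).
#' @param dead_time_s Undetectable transit time between zones, seconds.
#' @param tz Local timezone of the array.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_fish = 48,
                       study_start = as.Date("2015-08-15"),
                       study_end = as.Date("2016-01-18"),
                       interval_bounds = c(30, 90),
                       sst = list(summer_level = 17.1, winter_level = 3.0,
                                  midpoint_day = 81, scale_days = 18,
                                  noise_sd = 1.2),
                       beta0 = -4.5,
                       beta_sst = 0.262,
                       ranef_sd = 1.0,
                       emigration_hazard = 0.015,
                       detection_prob = 0.6,
                       dead_time_s = 60,
                       tz = "Europe/Stockholm") {
  stopifnot(n_fish >= 1, interval_bounds[1] > 0,
            interval_bounds[1] <= interval_bounds[2],
            detection_prob >= 0, detection_prob <= 1,
            emigration_hazard >= 0)
  receivers <- data.frame(
    receiver_id = LETTERS[1:11],
    site = c(rep("I", 6), rep("II", 5)),
    longitude = 11.45 + seq(0, 0.10, length.out = 11),
    latitude = 58.30 + c(seq(0, 0.02, length.out = 6),
                         seq(0.035, 0.055, length.out = 5)),
    depth = c(5, 8, 12, 4, 20, 30, 6, 3, 10, 15, 25),
    detection_range = c(216, 216, 114, 94, 216, 216, 216, 104, 94, 216, 216),
    stringsAsFactors = FALSE)
  # dense links within each site, two corridor pairs between the sites
  within <- function(ids) t(utils::combn(ids, 2))
  adjacency <- rbind(within(LETTERS[1:6]), within(LETTERS[7:11]),
                     cbind(c("E", "F"), c("G", "G")))
  structure(list(n_fish = n_fish, receivers = receivers,
                 adjacency = adjacency,
                 study_start = as.Date(study_start),
                 study_end = as.Date(study_end),
                 interval_bounds = interval_bounds, sst = sst,
                 beta0 = beta0, beta_sst = beta_sst, ranef_sd = ranef_sd,
                 emigration_hazard = emigration_hazard,
                 detection_prob = detection_prob,
                 dead_time_s = dead_time_s, tz = tz),
            class = "sim_config")
}

#' Simulate a daily sea surface temperature series
#'
#' A smooth logistic seasonal decline from the summer to the winter level
#' plus Gaussian noise. With the default configuration the seasonal-window
#' means fall near 16.3 (summer), 9.4 (autumn) and 3.7 deg C (winter).
#'
#' @param dates `Date` vector.
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A `data.frame` with `date` and `sst`.
#' @export
simulate_sst <- function(dates, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- config$sst
  d <- as.numeric(as.Date(dates) - config$study_start)
  trend <- p$winter_level + (p$summer_level - p$winter_level) *
    stats::plogis((p$midpoint_day - d) / p$scale_days)
  data.frame(date = as.Date(dates),
             sst = trend + stats::rnorm(length(d), 0, p$noise_sd))
}

#' Simulate a tagged cohort
#'
#' Total lengths are drawn from a normal distribution (mean 29.8 cm, SD
#' 5.2) truncated to 16--47 cm; weights follow a cubic length--weight
#' relation with lognormal scatter (condition factor ~0.88). Releases are
#' staggered over 15--24 August 2015 and split between the two sites.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A fish metadata `data.frame` (see [read_fish_metadata()]).
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_fish
  tl <- stats::rnorm(n, 29.8, 5.2)
  while (any(bad <- tl < 16 | tl > 47)) {
    tl[bad] <- stats::rnorm(sum(bad), 29.8, 5.2)
  }
  tl <- round(tl)
  weight <- round(0.0088 * tl^3 * exp(stats::rnorm(n, 0, 0.15)))
  rel_day <- config$study_start + sample(0:9, n, replace = TRUE)
  rel <- as.POSIXct(paste(rel_day, "10:00:00"), tz = config$tz)
  data.frame(transmitter_id = sprintf("10%02d", seq_len(n)),
             release_site = sample(c("I", "II"), n, replace = TRUE),
             weight = weight, total_length = tl,
             release_datetime = rel, stringsAsFactors = FALSE)
}

# neighbours of a receiver in the (undirected) corridor-constrained graph
.neighbours <- function(adjacency, r) {
  c(adjacency[adjacency[, 1] == r, 2], adjacency[adjacency[, 2] == r, 1])
}

#' Simulate true fish movements over the receiver array
#'
#' Each fish is a continuous-time jump process on receiver zones: its
#' departure rate on a given day is `exp(beta0 + b_i + beta_sst * SST)`
#' per day, destinations are uniform over the zone's graph neighbours
#' (dense within a site, two corridor pairs between sites), and a constant
#' daily hazard ends its time in the array permanently.
#'
#' @param cohort Fish metadata from [simulate_cohort()].
#' @param sst_daily Daily SST series from [simulate_sst()].
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A list of class `sim_truth`: `movements` (transmitter_id, from,
#'   to, time), `occupancy` (transmitter_id, receiver_id, start, end),
#'   `fish` (per-fish `b`, `emigration_time`, `home`), `params`.
#' @export
simulate_movement <- function(cohort, sst_daily, config = sim_config(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(config$adjacency) == 0) stop("receiver adjacency is empty")
  sst_by_date <- stats::setNames(sst_daily$sst, as.character(sst_daily$date))
  end_instant <- as.POSIXct(paste(config$study_end, "23:59:59"),
                            tz = config$tz)
  mov_list <- list(); occ_list <- list(); fish_list <- list()
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$transmitter_id[i]
    b <- stats::rnorm(1, 0, config$ranef_sd)
    t0 <- as.numeric(cohort$release_datetime[i])
    emig <- if (config$emigration_hazard > 0) {
      t0 + stats::rexp(1, config$emigration_hazard) * 86400
    } else Inf
    t_end <- min(as.numeric(end_instant), emig)
    site_recs <- config$receivers$receiver_id[
      config$receivers$site == cohort$release_site[i]]
    cur <- sample(site_recs, 1)
    home <- cur
    # movement event times: piecewise-constant daily intensity
    events <- numeric(0)
    day0 <- as.Date(cohort$release_datetime[i], tz = config$tz)
    for (d in seq(day0, config$study_end, by = "day")) {
      d <- as.Date(d, origin = "1970-01-01")
      day_start <- max(t0, as.numeric(as.POSIXct(paste(d, "00:00:00"),
                                                 tz = config$tz)))
      day_end <- min(t_end, as.numeric(as.POSIXct(paste(d, "23:59:59"),
                                                  tz = config$tz)) + 1)
      if (day_end <= day_start) next
      s <- sst_by_date[as.character(d)]
      if (is.na(s)) next
      lam <- exp(config$beta0 + b + config$beta_sst * s)
      k <- stats::rpois(1, lam * (day_end - day_start) / 86400)
      if (k > 0) events <- c(events, sort(stats::runif(k, day_start, day_end)))
    }
    events <- sort(events)
    n_ev <- length(events)
    from <- character(n_ev); to <- character(n_ev)
    occ_rec <- character(n_ev + 1L)
    occ_t0 <- numeric(n_ev + 1L); occ_t1 <- numeric(n_ev + 1L)
    occ_start <- t0
    for (e in seq_len(n_ev)) {
      nb <- .neighbours(config$adjacency, cur)
      nxt <- if (length(nb) == 1) nb else sample(nb, 1)
      from[e] <- cur; to[e] <- nxt
      occ_rec[e] <- cur; occ_t0[e] <- occ_start; occ_t1[e] <- events[e]
      occ_start <- events[e] + config$dead_time_s
      cur <- nxt
    }
    occ_rec[n_ev + 1L] <- cur
    occ_t0[n_ev + 1L] <- occ_start; occ_t1[n_ev + 1L] <- t_end
    occ_list[[i]] <- data.frame(transmitter_id = id,
                                receiver_id = occ_rec,
                                start = occ_t0, end = occ_t1,
                                stringsAsFactors = FALSE)
    if (length(events) > 0) {
      mov_list[[i]] <- data.frame(transmitter_id = id, from = from, to = to,
                                  time = events, stringsAsFactors = FALSE)
    }
    fish_list[[i]] <- data.frame(transmitter_id = id, b = b,
                                 emigration_time = emig, home = home,
                                 stringsAsFactors = FALSE)
  }
  as_ct <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = "UTC")
  movements <- do.call(rbind, mov_list)
  if (is.null(movements)) {
    movements <- data.frame(transmitter_id = character(0), from = character(0),
                            to = character(0), time = numeric(0))
  }
  movements$time <- as_ct(movements$time)
  occupancy <- do.call(rbind, occ_list)
  occupancy <- occupancy[occupancy$end > occupancy$start, , drop = FALSE]
  occupancy$start <- as_ct(occupancy$start)
  occupancy$end <- as_ct(occupancy$end)
  fish <- do.call(rbind, fish_list)
  fish$emigration_time <- as_ct(fish$emigration_time)
  structure(list(movements = movements, occupancy = occupancy, fish = fish,
                 params = config[c("beta0", "beta_sst", "ranef_sd",
                                   "emigration_hazard")]),
            class = "sim_truth")
}

#' Simulate detection logs from true occupancy
#'
#' While a fish occupies a receiver zone its transmitter fires at uniform
#' random intervals within the configured bounds; each transmission is
#' logged with the configured detection probability and carries the
#' occupied receiver's id. No detection is ever emitted outside an
#' occupancy interval.
#'
#' @param truth A `sim_truth` from [simulate_movement()].
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A detection `data.frame` (as from [read_detections()]).
#' @export
simulate_detections <- function(truth, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lo <- config$interval_bounds[1]; hi <- config$interval_bounds[2]
  mean_int <- (lo + hi) / 2
  occ <- truth$occupancy
  res <- vector("list", nrow(occ))
  for (i in seq_len(nrow(occ))) {
    dur <- as.numeric(occ$end[i]) - as.numeric(occ$start[i])
    if (dur <= 0) next
    n_draw <- ceiling(dur / mean_int + 4 * sqrt(dur / mean_int) + 5)
    tx <- c(0, cumsum(stats::runif(n_draw, lo, hi)))
    while (tx[length(tx)] < dur) {          # rare: extend the ping train
      tx <- c(tx, tx[length(tx)] +
                cumsum(stats::runif(n_draw, lo, hi)))
    }
    tx <- tx[tx < dur]
    if (length(tx) == 0) next
    keep <- stats::runif(length(tx)) < config$detection_prob
    if (!any(keep)) next
    res[[i]] <- data.frame(
      timestamp = as.numeric(occ$start[i]) + tx[keep],
      transmitter_id = occ$transmitter_id[i],
      receiver_id = occ$receiver_id[i], stringsAsFactors = FALSE)
  }
  det <- do.call(rbind, res)
  if (is.null(det)) {
    det <- data.frame(timestamp = numeric(0), transmitter_id = character(0),
                      receiver_id = character(0))
  }
  det$timestamp <- as.POSIXct(det$timestamp, origin = "1970-01-01", tz = "UTC")
  det$valid <- rep(TRUE, nrow(det))
  det <- det[order(det$transmitter_id, det$timestamp), , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Simulate a weekly environmental covariate series
#'
#' Weekly means of SST (from the daily series), PAR (seasonally declining,
#' hence strongly collinear with SST), sea level, wind speed and wind
#' direction, on 7-day windows from `week_start`.
#'
#' @param sst_daily Daily SST series.
#' @param config A [sim_config()].
#' @param week_start First week start date (default 2015-08-25).
#' @param seed Optional integer seed.
#' @return An environmental `data.frame` (see [read_environment()]).
#' @export
simulate_environment <- function(sst_daily, config = sim_config(),
                                 week_start = as.Date("2015-08-25"),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  starts <- seq(as.Date(week_start), config$study_end - 6, by = "7 days")
  sst_by_date <- stats::setNames(sst_daily$sst, as.character(sst_daily$date))
  wk <- function(s) {
    days <- as.character(seq(s, s + 6, by = "day"))
    mean(sst_by_date[days], na.rm = TRUE)
  }
  sst <- vapply(starts, wk, numeric(1))
  n <- length(starts)
  data.frame(week_start = starts,
             sst = sst,
             par = pmax(1, 40 * sst + stats::rnorm(n, 0, 40)),
             sea_level = 120 - 9 * sst + stats::rnorm(n, 0, 20),
             wind_speed = exp(stats::rnorm(n, 1.5, 0.4)),
             wind_direction = stats::runif(n, 0, 360))
}

#' Generate a complete synthetic telemetry bundle
#'
#' Runs the full generator — cohort, daily SST, true movements, detection
#' logs and weekly environmental series — under one seed, returning both
#' the observable inputs the pipeline consumes and the ground truth for
#' recovery tests. Identical config and seed give identical bundles.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (required: the generator is only meaningful
#'   reproducibly).
#' @return A list of class `sim_bundle`: `detections`, `fish`,
#'   `receivers`, `environment`, `sst_daily`, `truth`, `config`, `seed`.
#' @export
simulate_telemetry <- function(config = sim_config(), seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)
  cohort <- simulate_cohort(config)
  dates <- seq(config$study_start, config$study_end, by = "day")
  sst_daily <- simulate_sst(dates, config)
  truth <- simulate_movement(cohort, sst_daily, config)
  detections <- simulate_detections(truth, config)
  environment <- simulate_environment(sst_daily, config)
  receivers <- config$receivers
  receivers$deployment_start <- as.POSIXct(paste(config$study_start,
                                                 "00:00:00"), tz = config$tz)
  receivers$deployment_end <- as.POSIXct(paste(config$study_end,
                                               "23:59:59"), tz = config$tz)
  receivers$clock_offset <- 0
  structure(list(detections = detections, fish = cohort,
                 receivers = receivers, environment = environment,
                 sst_daily = sst_daily, truth = truth, config = config,
                 seed = seed),
            class = "sim_bundle")
}

#' Write a synthetic bundle as the file set the readers consume
#'
#' Emits `detections.csv` (VR2 dialect), `receivers.csv`, `fish.csv`,
#' `environment.csv`, `sst_daily.csv` and `truth.json` into `dir`.
#'
#' @param bundle A `sim_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written.
#' @export
write_telemetry_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(detections = file.path(dir, "detections.csv"),
             receivers = file.path(dir, "receivers.csv"),
             fish = file.path(dir, "fish.csv"),
             environment = file.path(dir, "environment.csv"),
             sst_daily = file.path(dir, "sst_daily.csv"),
             truth = file.path(dir, "truth.json"))
  write_detections(bundle$detections, paths["detections"])
  rec <- bundle$receivers
  rec$deployment_start <- format(rec$deployment_start, tz = "UTC")
  rec$deployment_end <- format(rec$deployment_end, tz = "UTC")
  utils::write.csv(rec, paths["receivers"], row.names = FALSE)
  fish <- bundle$fish
  fish$release_datetime <- format(fish$release_datetime, tz = "UTC")
  utils::write.csv(fish, paths["fish"], row.names = FALSE)
  utils::write.csv(bundle$environment, paths["environment"],
                   row.names = FALSE)
  utils::write.csv(bundle$sst_daily, paths["sst_daily"], row.names = FALSE)
  truth <- bundle$truth
  truth$movements$time <- format(truth$movements$time, tz = "UTC")
  truth$occupancy$start <- format(truth$occupancy$start, tz = "UTC")
  truth$occupancy$end <- format(truth$occupancy$end, tz = "UTC")
  truth$fish$emigration_time <- format(truth$fish$emigration_time,
                                       tz = "UTC")
  jsonlite::write_json(unclass(truth), paths["truth"], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  paths
}

#' Monthly mean SST from a daily series
#'
#' @param sst_daily Daily SST series.
#' @return Named numeric vector keyed by `"YYYY-MM"`.
#' @export
monthly_mean_sst <- function(sst_daily) {
  mo <- format(sst_daily$date, "%Y-%m")
  vapply(split(sst_daily$sst, mo), mean, numeric(1))
}
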