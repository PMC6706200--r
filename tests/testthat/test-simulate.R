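# small, fast configurations for unit checks; the reference defaults are
# exercised in the acceptance suite
small_cfg <- function(n_fish = 6, ...) {
  sim_config(n_fish = n_fish, interval_bounds = c(300, 900), ...)
}

test_that("SST curve is deterministic without noise and seasonally ordered", {
  cfg <- sim_config()
  cfg$sst$noise_sd <- 0
  dates <- seq(cfg$study_start, cfg$study_end, by = "day")
  s <- simulate_sst(dates, cfg)
  expect_true(all(diff(s$sst) < 0))  # monotone decline
  season <- assign_season(s$date)
  m <- tapply(s$sst, season, mean)
  expect_true(m[["winter"]] < m[["autumn"]] && m[["autumn"]] < m[["summer"]])

  # with noise, the summer-window mean stays near 16.3
  s1 <- simulate_sst(dates, sim_config(), seed = 1)
  expect_lt(abs(mean(s1$sst[assign_season(s1$date) == "summer"]) - 16.3), 1)
})

test_that("simulated cohorts respect the printed size ranges and are reproducible", {
  cfg <- sim_config(n_fish = 48)
  co <- simulate_cohort(cfg, seed = 2)
  expect_equal(nrow(co), 48)
  expect_true(all(co$total_length >= 16 & co$total_length <= 47))
  expect_true(all(co$weight > 0))
  expect_true(cor(co$total_length, co$weight) > 0.5)
  expect_true(all(co$release_site %in% c("I", "II")))
  co2 <- simulate_cohort(cfg, seed = 2)
  expect_identical(co, co2)
})

test_that("movement rates respond to temperature as exp(beta_sst * dSST)", {
  # flat SST at 16 vs 4 deg C, no noise, no emigration: the closed-form
  # weekly rate ratio is exp(beta_sst * 12)
  cfg <- sim_config(n_fish = 60, study_end = as.Date("2015-08-28"),
                    beta_sst = 0.25, beta0 = -3.5, ranef_sd = 0,
                    emigration_hazard = 0)
  dates <- seq(cfg$study_start, cfg$study_end, by = "day")
  co <- simulate_cohort(cfg, seed = 3)
  co$release_datetime <- as.POSIXct("2015-08-15 00:00:00", tz = cfg$tz)
  warm <- simulate_movement(co, data.frame(date = dates, sst = 16), cfg,
                            seed = 4)
  cold <- simulate_movement(co, data.frame(date = dates, sst = 4), cfg,
                            seed = 5)
  ratio <- nrow(warm$movements) / nrow(cold$movements)
  expect_gt(ratio, exp(0.25 * 12) / 2.2)
  expect_lt(ratio, exp(0.25 * 12) * 2.2)

  # beta_sst = 0: warm and cold weeks are statistically flat
  cfg0 <- sim_config(n_fish = 60, study_end = as.Date("2015-08-28"),
                     beta_sst = 0, beta0 = -0.5, ranef_sd = 0,
                     emigration_hazard = 0)
  w0 <- simulate_movement(co, data.frame(date = dates, sst = 16), cfg0,
                          seed = 6)
  c0 <- simulate_movement(co, data.frame(date = dates, sst = 4), cfg0,
                          seed = 7)
  expect_lt(abs(log(nrow(w0$movements) / nrow(c0$movements))), 0.35)
})

test_that("default synthetic seasons move more in summer than winter", {
  cfg <- sim_config()
  set.seed(8)
  dates <- seq(cfg$study_start, cfg$study_end, by = "day")
  co <- simulate_cohort(cfg)
  sst <- simulate_sst(dates, cfg)
  tr <- simulate_movement(co, sst, cfg)
  season <- assign_season(tr$movements$time)
  expect_gt(sum(season == "summer"), sum(season == "winter"))
})

test_that("detections are emitted only inside occupancy at the stated rate", {
  # deterministic count: fixed 60 s interval, certain detection, 600 s zone
  cfg <- sim_config(interval_bounds = c(60, 60), detection_prob = 1)
  occ <- data.frame(transmitter_id = "f1", receiver_id = "A",
                    start = utc("2015-09-01 00:00:00"),
                    end = utc("2015-09-01 00:10:00"),
                    stringsAsFactors = FALSE)
  truth <- structure(list(occupancy = occ), class = "sim_truth")
  det <- simulate_detections(truth, cfg, seed = 9)
  expect_equal(nrow(det), 10)
  expect_true(all(det$timestamp >= occ$start & det$timestamp < occ$end))

  # zero detection probability: empty log
  cfg0 <- sim_config(interval_bounds = c(60, 60), detection_prob = 0)
  expect_equal(nrow(simulate_detections(truth, cfg0, seed = 9)), 0)

  # detection efficiency: observed fraction of a known ping train near 0.6
  cfg6 <- sim_config(interval_bounds = c(60, 60), detection_prob = 0.6)
  long <- occ; long$end <- utc("2015-09-03 00:00:00")
  truth_long <- structure(list(occupancy = long), class = "sim_truth")
  d6 <- simulate_detections(truth_long, cfg6, seed = 10)
  n_tx <- ceiling(as.numeric(long$end - long$start, units = "secs") / 60)
  phat <- nrow(d6) / n_tx
  expect_lt(abs(phat - 0.6), 3 * sqrt(0.6 * 0.4 / n_tx))
})

test_that("bundles are reproducible and detections never leave occupancy", {
  cfg <- small_cfg(study_end = as.Date("2015-09-30"))
  b1 <- simulate_telemetry(cfg, seed = 11)
  b2 <- simulate_telemetry(cfg, seed = 11)
  expect_identical(b1$detections, b2$detections)
  expect_identical(b1$environment, b2$environment)

  # cross-check detections against the truth's occupancy intervals
  occ <- b1$truth$occupancy
  for (tag in unique(b1$detections$transmitter_id)) {
    d <- b1$detections[b1$detections$transmitter_id == tag, ]
    o <- occ[occ$transmitter_id == tag, ]
    hit <- vapply(seq_len(nrow(d)), function(i) {
      any(o$receiver_id == d$receiver_id[i] &
            as.numeric(o$start) <= as.numeric(d$timestamp[i]) &
            as.numeric(o$end) > as.numeric(d$timestamp[i]))
    }, logical(1))
    expect_true(all(hit))
  }
})

test_that("the pipeline recovers the simulated movement structure", {
  cfg <- small_cfg(n_fish = 10, study_end = as.Date("2015-10-31"))
  b <- simulate_telemetry(cfg, seed = 12)
  det <- flag_false_detections(b$detections)
  det <- remove_postrelease(det[det$valid, ], b$fish)
  mov <- extract_movements(det)
  # extracted movements cannot exceed the truth
  expect_lte(nrow(mov), nrow(b$truth$movements))
  # per-fish extracted counts track the true counts
  true_n <- table(factor(b$truth$movements$transmitter_id,
                         levels = b$fish$transmitter_id))
  obs_n <- table(factor(mov$transmitter_id,
                        levels = b$fish$transmitter_id))
  expect_gt(cor(as.numeric(true_n), as.numeric(obs_n),
                method = "spearman"), 0.9)
})

test_that("bundle files round-trip through the readers", {
  cfg <- small_cfg(n_fish = 3, study_end = as.Date("2015-09-10"))
  b <- simulate_telemetry(cfg, seed = 13)
  dir <- withr::local_tempdir()
  paths <- write_telemetry_bundle(b, dir)
  expect_true(all(file.exists(paths)))
  det <- read_detections(paths[["detections"]])
  expect_equal(nrow(det), nrow(b$detections))
  expect_equal(attr(det, "n_rejected"), 0)
  fish <- read_fish_metadata(paths[["fish"]])
  expect_equal(sort(fish$transmitter_id), sort(b$fish$transmitter_id))
  env <- read_environment(paths[["environment"]])
  expect_equal(nrow(env), nrow(b$environment))
  rec <- read_receivers(paths[["receivers"]])
  expect_equal(nrow(rec), 11)
})
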