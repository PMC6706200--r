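#' Drop the post-release acclimation window
#'
#' Detections made within `window_hours` of a fish's release are removed to
#' avoid irregular movements caused by handling and anaesthesia.
#'
#' @param det Detection data frame.
#' @param fish Fish metadata (needs `transmitter_id`, `release_datetime`).
#' @param window_hours Length of the discarded window, hours (default 24).
#' @return The filtered detection data frame.
#' @export
remove_postrelease <- function(det, fish, window_hours = 24) {
  tags <- unique(det$transmitter_id)
  unknown <- setdiff(tags, fish$transmitter_id)
  if (length(unknown) > 0) {
    stop("no release metadata for transmitter(s): ",
         paste(unknown, collapse = ", "))
  }
  rel <- fish$release_datetime[match(det$transmitter_id, fish$transmitter_id)]
  keep <- as.numeric(det$timestamp) >= as.numeric(rel) + window_hours * 3600
  out <- det[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract between-receiver movements from a detection sequence
#'
#' A movement is a detection of a fish at one receiver followed by its next
#' detection at a different receiver. Runs of consecutive detections at the
#' same receiver are collapsed, the departure being the last detection of
#' the origin run and the arrival the first detection of the destination
#' run. Movements faster than `min_transit_s` are discarded as artefacts of
#' overlapping detection ranges; discarding a movement never splices its
#' endpoints into a new, longer movement (adjacency is fixed before the
#' filter), and non-positive transits are always dropped.
#'
#' @param det Detection data frame; only rows with `valid = TRUE` are used.
#' @param min_transit_s Minimum plausible transit time in seconds
#'   (default 240, i.e. 4 minutes).
#' @return A `data.frame` with columns `transmitter_id`, `from_receiver`,
#'   `to_receiver`, `departure`, `arrival` (POSIXct, UTC) and `transit_s`.
#' @export
extract_movements <- function(det, min_transit_s = 240) {
  det <- det[det$valid, , drop = FALSE]
  empty <- data.frame(transmitter_id = character(0),
                      from_receiver = character(0),
                      to_receiver = character(0),
                      departure = as.POSIXct(character(0), tz = "UTC"),
                      arrival = as.POSIXct(character(0), tz = "UTC"),
                      transit_s = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(det) == 0) return(empty)
  res <- lapply(split(det, det$transmitter_id), function(d) {
    if (is.unsorted(as.numeric(d$timestamp))) {
      stop("detections must be sorted by timestamp within each transmitter")
    }
    r <- rle(d$receiver_id)
    if (length(r$lengths) < 2) return(NULL)
    last_idx <- cumsum(r$lengths)            # last detection of each run
    first_idx <- c(1L, utils::head(last_idx, -1) + 1L)
    k <- length(r$lengths)
    data.frame(transmitter_id = d$transmitter_id[1],
               from_receiver = r$values[-k],
               to_receiver = r$values[-1],
               departure = d$timestamp[last_idx[-k]],
               arrival = d$timestamp[first_idx[-1]],
               stringsAsFactors = FALSE)
  })
  mov <- do.call(rbind, res)
  if (is.null(mov) || nrow(mov) == 0) return(empty)
  mov$transit_s <- as.numeric(mov$arrival) - as.numeric(mov$departure)
  mov <- mov[mov$transit_s > 0 & mov$transit_s >= min_transit_s, , drop = FALSE]
  mov <- mov[order(mov$transmitter_id, mov$departure), , drop = FALSE]
  rownames(mov) <- NULL
  mov
}

#' Residency index
#'
#' Days with at least one detection divided by days monitored (time at
#' liberty, release to study end). 0 means never present, 1 detected daily.
#'
#' @param days_detected,days_monitored Non-negative integer counts
#'   (vectorised).
#' @return The exact quotient in `[0, 1]`; round to 2 decimals for
#'   reporting.
#' @export
residency_index <- function(days_detected, days_monitored) {
  if (any(days_monitored <= 0)) stop("days_monitored must be positive")
  if (any(days_detected < 0 | days_detected > days_monitored)) {
    stop("days_detected must lie in [0, days_monitored]")
  }
  days_detected / days_monitored
}

#' Movement index
#'
#' Number of movements divided by days detected: a relative mobility score,
#' higher meaning more mobile.
#'
#' @param n_movements Non-negative movement counts (vectorised).
#' @param days_detected Positive day counts.
#' @return The exact quotient (>= 0).
#' @export
movement_index <- function(n_movements, days_detected) {
  if (any(days_detected <= 0)) stop("days_detected must be positive")
  if (any(n_movements < 0)) stop("n_movements must be non-negative")
  n_movements / days_detected
}

#' Count distinct calendar days with a detection
#'
#' @param det Detection data frame (valid rows only are counted).
#' @param tz Timezone defining the day boundary (default Europe/Stockholm,
#'   the local time of the array).
#' @return Named integer vector, one entry per transmitter present in
#'   `det`.
#' @export
count_days_detected <- function(det, tz = "Europe/Stockholm") {
  det <- det[det$valid, , drop = FALSE]
  if (nrow(det) == 0) return(stats::setNames(integer(0), character(0)))
  d <- as.Date(det$timestamp, tz = tz)
  vapply(split(d, det$transmitter_id), function(x) length(unique(x)),
         integer(1))
}

#' Days monitored per fish
#'
#' Whole days from the release date to the study end date; e.g. a release
#' on 2015-08-15 monitored until 2016-01-18 gives 156 days.
#'
#' @param fish Fish metadata.
#' @param study_end Study end `Date`.
#' @param tz Timezone used to turn `release_datetime` into a calendar date.
#' @return Named integer vector keyed by transmitter.
#' @export
days_monitored <- function(fish, study_end, tz = "Europe/Stockholm") {
  rel <- as.Date(fish$release_datetime, tz = tz)
  stats::setNames(as.integer(as.Date(study_end) - rel), fish$transmitter_id)
}

#' Per-fish summary: residency and movement indices
#'
#' Builds the standard cohort summary table: days detected, days monitored,
#' residency index (RI) and movement index (MI) per fish, alongside its
#' size and release information.
#'
#' @param det Post-QC, post-release-filtered detections.
#' @param movements Movement table from [extract_movements()].
#' @param fish Fish metadata.
#' @param study_end Study end `Date`.
#' @param tz Day-boundary timezone.
#' @return A `data.frame` with one row per fish in `fish`, columns
#'   `transmitter_id`, `site`, `weight`, `total_length`, `release_date`,
#'   `days_detected`, `days_monitored`, `residency_index`, `n_movements`,
#'   `movement_index` (NA when never detected).
#' @export
fish_summary <- function(det, movements, fish, study_end,
                         tz = "Europe/Stockholm") {
  dd <- count_days_detected(det, tz = tz)
  dm <- days_monitored(fish, study_end, tz = tz)
  nm <- table(movements$transmitter_id)
  out <- data.frame(
    transmitter_id = fish$transmitter_id,
    site = fish$release_site,
    weight = fish$weight,
    total_length = fish$total_length,
    release_date = as.Date(fish$release_datetime, tz = tz),
    days_detected = as.integer(ifelse(is.na(dd[fish$transmitter_id]), 0L,
                                      dd[fish$transmitter_id])),
    days_monitored = as.integer(dm[fish$transmitter_id]),
    stringsAsFactors = FALSE)
  out$n_movements <- as.integer(nm[out$transmitter_id])
  out$n_movements[is.na(out$n_movements)] <- 0L
  out$residency_index <- residency_index(out$days_detected,
                                         out$days_monitored)
  out$movement_index <- ifelse(out$days_detected > 0,
                               out$n_movements / out$days_detected, NA_real_)
  rownames(out) <- NULL
  out
}

#' Exclude fish with no usable movement data
#'
#' Applies the cohort exclusion rules: (a) fish with no detections left
#' after the post-release filter (they left the array immediately) and
#' (b) fish with detections but no extracted movements. Idempotent.
#'
#' @param fish Fish metadata (the full tagged cohort).
#' @param det Post-release-filtered detections.
#' @param movements Movement table.
#' @return A list with `retained` (fish rows kept) and `report` (a
#'   `data.frame` of `transmitter_id`, `reason` for every excluded fish;
#'   reasons are `"no_detections"` and `"no_movements"`).
#' @export
exclude_fish <- function(fish, det, movements) {
  detected <- unique(det$transmitter_id[det$valid])
  moving <- unique(movements$transmitter_id)
  reason <- rep(NA_character_, nrow(fish))
  reason[!(fish$transmitter_id %in% detected)] <- "no_detections"
  reason[is.na(reason) &
           !(fish$transmitter_id %in% moving)] <- "no_movements"
  list(retained = fish[is.na(reason), , drop = FALSE],
       report = data.frame(transmitter_id = fish$transmitter_id[!is.na(reason)],
                           reason = reason[!is.na(reason)],
                           stringsAsFactors = FALSE))
}

#' Define seasonal windows
#'
#' @param labels Character season labels.
#' @param starts,ends `Date` vectors of window starts and ends (both
#'   inclusive). Windows must be contiguous: each start is the day after
#'   the previous end.
#' @return A `data.frame` of class `season_windows`.
#' @export
season_windows <- function(labels, starts, ends) {
  starts <- as.Date(starts); ends <- as.Date(ends)
  if (length(labels) != length(starts) || length(starts) != length(ends)) {
    stop("labels, starts and ends must have equal length")
  }
  if (any(starts > ends)) stop("window start after window end")
  if (length(starts) > 1 &&
      any(starts[-1] != ends[-length(ends)] + 1L)) {
    stop("season windows must be contiguous and non-overlapping")
  }
  out <- data.frame(label = labels, start = starts, end = ends,
                    stringsAsFactors = FALSE)
  class(out) <- c("season_windows", "data.frame")
  out
}

#' Reference seasonal windows for the 2015/2016 fjord study design
#'
#' Summer 15 Aug - 5 Oct 2015, autumn 6 Oct - 11 Dec 2015, winter
#' 12 Dec 2015 - 18 Jan 2016; the boundaries track distinct shifts in sea
#' surface temperature.
#'
#' @return A `season_windows` object.
#' @export
default_season_windows <- function() {
  season_windows(c("summer", "autumn", "winter"),
                 as.Date(c("2015-08-15", "2015-10-06", "2015-12-12")),
                 as.Date(c("2015-10-05", "2015-12-11", "2016-01-18")))
}

#' Assign timestamps to seasons
#'
#' @param x `Date` or `POSIXct` vector.
#' @param windows A [season_windows()] object.
#' @param tz Timezone used to convert timestamps to dates.
#' @return Character vector of season labels. Errors if any value falls
#'   outside all windows.
#' @export
assign_season <- function(x, windows = default_season_windows(),
                          tz = "Europe/Stockholm") {
  d <- if (inherits(x, "POSIXct")) as.Date(x, tz = tz) else as.Date(x)
  idx <- rep(NA_integer_, length(d))
  for (i in seq_len(nrow(windows))) {
    idx[d >= windows$start[i] & d <= windows$end[i]] <- i
  }
  if (anyNA(idx)) {
    stop("timestamp(s) outside all season windows: ",
         paste(utils::head(format(d[is.na(idx)]), 3), collapse = ", "))
  }
  windows$label[idx]
}

#' Relative number of movements per day
#'
#' For each calendar day, the total number of movements divided by the
#' number of distinct fish detected that day. Days in which fish were
#' detected but none moved give 0; days with no detected fish give `NA`
#' (and a day with movements but no detections is flagged as inconsistent).
#'
#' @param movements Movement table (a movement is assigned to the calendar
#'   day of its departure).
#' @param det Valid detection data frame covering the same period.
#' @param tz Day-boundary timezone.
#' @return A `data.frame` with `date`, `n_movements`, `n_fish_detected`,
#'   `relative_movements` and logical `inconsistent`.
#' @export
relative_movements_per_day <- function(movements, det,
                                       tz = "Europe/Stockholm") {
  det <- det[det$valid, , drop = FALSE]
  days <- sort(unique(c(as.Date(det$timestamp, tz = tz),
                        as.Date(movements$departure, tz = tz))))
  if (length(days) == 0) {
    return(data.frame(date = as.Date(character(0)), n_movements = integer(0),
                      n_fish_detected = integer(0),
                      relative_movements = numeric(0),
                      inconsistent = logical(0)))
  }
  days <- seq(min(days), max(days), by = "day")
  dd <- as.Date(det$timestamp, tz = tz)
  md <- as.Date(movements$departure, tz = tz)
  nf <- vapply(days, function(x)
    length(unique(det$transmitter_id[dd == x])), integer(1))
  nm <- vapply(days, function(x) sum(md == x), integer(1))
  rel <- ifelse(nf > 0, nm / nf, NA_real_)
  data.frame(date = days, n_movements = nm, n_fish_detected = nf,
             relative_movements = rel,
             inconsistent = nm > 0 & nf == 0)
}
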