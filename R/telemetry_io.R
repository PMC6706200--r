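#' Read a receiver detection log
#'
#' Parses a detection export (VEMCO VR2/VR2W dialect by default) into a
#' detection data frame: one row per time-stamped detection of a transmitter
#' at a receiver. Rows whose timestamp cannot be parsed, or whose transmitter
#' or receiver field is empty, are dropped and reported via the
#' `"rejected"` attribute (a data frame with the offending line numbers).
#'
#' @param path Path to a delimited text file; gzip-compressed files are read
#'   transparently.
#' @param col_map Named character vector mapping the roles `timestamp`,
#'   `transmitter` and `receiver` to column names in the file.
#' @param tz Timezone the timestamps are recorded in. Detections are stored
#'   internally in UTC.
#' @param delim Field delimiter.
#' @param format `strptime` format for the timestamp column.
#'
#' @return A `data.frame` with columns `timestamp` (POSIXct, UTC),
#'   `transmitter_id`, `receiver_id` (character) and `valid` (logical, all
#'   `TRUE` on read), sorted by transmitter then timestamp. Attribute
#'   `"rejected"` holds malformed rows; attribute `"n_rejected"` their count.
#' @export
read_detections <- function(path,
                            col_map = c(timestamp = "Date and Time (UTC)",
                                        transmitter = "Transmitter",
                                        receiver = "Receiver"),
                            tz = "UTC",
                            delim = ",",
                            format = "%Y-%m-%d %H:%M:%S") {
  if (!file.exists(path)) stop("detection file not found: ", path)
  need <- c("timestamp", "transmitter", "receiver")
  if (!all(need %in% names(col_map))) {
    stop("col_map must name columns for: ", paste(need, collapse = ", "))
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  missing_cols <- setdiff(unname(col_map[need]), names(raw))
  if (length(missing_cols) > 0) {
    stop("detection file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ts_chr <- as.character(raw[[col_map[["timestamp"]]]])
  ts <- as.POSIXct(ts_chr, tz = tz, format = format)
  tag <- trimws(as.character(raw[[col_map[["transmitter"]]]]))
  rec <- trimws(as.character(raw[[col_map[["receiver"]]]]))
  bad <- is.na(ts) | tag == "" | rec == "" | is.na(tag) | is.na(rec)
  rejected <- data.frame(line = which(bad) + 1L,  # +1 for the header line
                         timestamp = ts_chr[bad],
                         transmitter_id = tag[bad],
                         receiver_id = rec[bad],
                         stringsAsFactors = FALSE)
  det <- data.frame(timestamp = as.POSIXct(as.numeric(ts[!bad]),
                                           origin = "1970-01-01", tz = "UTC"),
                    transmitter_id = tag[!bad],
                    receiver_id = rec[!bad],
                    valid = TRUE,
                    stringsAsFactors = FALSE)
  det <- det[order(det$transmitter_id, det$timestamp), , drop = FALSE]
  rownames(det) <- NULL
  attr(det, "rejected") <- rejected
  attr(det, "n_rejected") <- nrow(rejected)
  det
}

#' Write a detection data frame in the same dialect `read_detections` reads
#'
#' @param det Detection data frame.
#' @param path Output path (`.gz` suffix writes gzip).
#' @param col_map As in [read_detections()].
#' @return `path`, invisibly.
#' @export
write_detections <- function(det, path,
                             col_map = c(timestamp = "Date and Time (UTC)",
                                         transmitter = "Transmitter",
                                         receiver = "Receiver")) {
  out <- data.frame(format(det$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                    det$receiver_id, det$transmitter_id,
                    stringsAsFactors = FALSE)
  names(out) <- unname(col_map[c("timestamp", "receiver", "transmitter")])
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Read receiver station metadata
#'
#' @param path CSV with columns `receiver_id`, `site`, `longitude`,
#'   `latitude`, `depth`, `detection_range`, `deployment_start`,
#'   `deployment_end` and optionally `clock_offset` (seconds, clock error
#'   measured at retrieval).
#' @param tz Timezone of the deployment timestamps.
#' @return A validated `data.frame` of stations.
#' @export
read_receivers <- function(path, tz = "UTC") {
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("receiver_id", "site", "longitude", "latitude", "depth",
            "detection_range", "deployment_start", "deployment_end")
  miss <- setdiff(need, names(st))
  if (length(miss) > 0) stop("receiver file lacks column(s): ",
                             paste(miss, collapse = ", "))
  st$deployment_start <- as.POSIXct(st$deployment_start, tz = tz)
  st$deployment_end <- as.POSIXct(st$deployment_end, tz = tz)
  if (is.null(st$clock_offset)) st$clock_offset <- 0
  if (any(st$detection_range <= 0)) stop("detection_range must be positive")
  if (any(st$deployment_start >= st$deployment_end)) {
    stop("deployment_start must precede deployment_end")
  }
  if (!all(st$site %in% c("I", "II"))) stop("site must be 'I' or 'II'")
  st
}

#' Read fish tagging metadata
#'
#' @param path CSV with columns `transmitter_id`, `release_site`, `weight`
#'   (g), `total_length` (cm), `release_datetime`.
#' @param tz Timezone of `release_datetime`.
#' @return A validated `data.frame`.
#' @export
read_fish_metadata <- function(path, tz = "UTC") {
  fish <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("transmitter_id", "release_site", "weight", "total_length",
            "release_datetime")
  miss <- setdiff(need, names(fish))
  if (length(miss) > 0) stop("fish metadata lacks column(s): ",
                             paste(miss, collapse = ", "))
  fish$transmitter_id <- as.character(fish$transmitter_id)
  fish$release_datetime <- as.POSIXct(fish$release_datetime, tz = tz)
  if (any(fish$weight <= 0) || any(fish$total_length <= 0)) {
    stop("weight and total_length must be positive")
  }
  fish
}

#' Read a weekly environmental series
#'
#' @param path CSV with columns `week_start` (date), `sst` (deg C), `par`
#'   (umol/m2/s), `sea_level` (mm), `wind_speed` (m/s), `wind_direction`
#'   (degrees, in `[0, 360)`).
#' @return A validated `data.frame` ordered by `week_start`.
#' @export
read_environment <- function(path) {
  env <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("week_start", "sst", "par", "sea_level", "wind_speed",
            "wind_direction")
  miss <- setdiff(need, names(env))
  if (length(miss) > 0) stop("environmental file lacks column(s): ",
                             paste(miss, collapse = ", "))
  env$week_start <- as.Date(env$week_start)
  env <- env[order(env$week_start), , drop = FALSE]
  if (nrow(env) > 1) {
    gaps <- as.integer(diff(env$week_start))
    if (any(gaps != 7L)) stop("weeks must be contiguous, 7 days apart")
  }
  if (any(env$wind_direction < 0 | env$wind_direction >= 360)) {
    stop("wind_direction must lie in [0, 360)")
  }
  rownames(env) <- NULL
  env
}

#' Correct linear receiver clock drift
#'
#' Receiver clocks drift roughly linearly between deployment and retrieval.
#' Given the clock error measured at retrieval, each detection timestamp at
#' that receiver is shifted by the error scaled by the fraction of the
#' deployment elapsed: a record at the deployment midpoint of a receiver
#' whose clock gained 60 s is corrected by 30 s. Records falling outside the
#' deployment interval are left untouched and flagged.
#'
#' @param det Detection data frame.
#' @param stations Receiver metadata from [read_receivers()] with a
#'   `clock_offset` column (seconds; positive = receiver clock fast at
#'   retrieval, so recorded times are pulled back).
#' @return `det` with corrected timestamps and a logical column
#'   `outside_deployment` marking uncorrectable records.
#' @export
correct_time_drift <- function(det, stations) {
  det$outside_deployment <- FALSE
  for (i in seq_len(nrow(stations))) {
    sel <- det$receiver_id == stations$receiver_id[i]
    if (!any(sel)) next
    t0 <- as.numeric(stations$deployment_start[i])
    t1 <- as.numeric(stations$deployment_end[i])
    tt <- as.numeric(det$timestamp[sel])
    out <- tt < t0 | tt > t1
    frac <- (tt - t0) / (t1 - t0)
    shift <- ifelse(out, 0, stations$clock_offset[i] * frac)
    det$timestamp[sel] <- det$timestamp[sel] - shift
    det$outside_deployment[sel] <- out
  }
  det <- det[order(det$transmitter_id, det$timestamp), , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Screen isolated detections as likely false
#'
#' A detection is treated as plausible only if enough other detections of
#' the same transmitter occur at the same receiver nearby in time; spurious
#' code collisions typically produce isolated single hits. With the default
#' settings a detection with no same-tag, same-receiver companion within
#' one hour is flagged invalid. The function only annotates the `valid`
#' column; it never removes rows, and the flags are recomputed from the full
#' record set on every call, so it is idempotent.
#'
#' @param det Detection data frame.
#' @param window Half-width of the neighbourhood window, in seconds
#'   (default 3600).
#' @param min_neighbors Minimum number of other detections required inside
#'   `+/- window` (default 1).
#' @return `det` with the `valid` flag set.
#' @export
flag_false_detections <- function(det, window = 3600, min_neighbors = 1L) {
  if (nrow(det) == 0) {
    det$valid <- logical(0)
    return(det)
  }
  key <- paste(det$transmitter_id, det$receiver_id, sep = "\r")
  valid <- logical(nrow(det))
  for (g in split(seq_len(nrow(det)), key)) {
    tt <- as.numeric(det$timestamp[g])
    o <- order(tt)
    ts <- tt[o]
    # neighbours within +/- window, excluding the record itself
    n_le <- findInterval(ts + window, ts)
    n_lt <- findInterval(ts - window, ts, left.open = TRUE)
    cnt <- n_le - n_lt - 1L
    valid[g[o]] <- cnt >= min_neighbors
  }
  det$valid <- valid
  det
}
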