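# On-disk formats: per-channel sensor CSVs and the feature-table CSV.
# Everything is plain text; timestamps are ISO-8601 in local time with an
# explicit UTC offset (fatigue is diurnal in local time).

.TZ <- "Etc/GMT-1"  # fixed UTC+01 local clock, no DST surprises
.CHANNELS <- c("hr", "eda", "temp", "acc", "ibi", "steps")

# Fast ISO-8601 formatting/parsing. `start` is a local midnight, so dates can
# be resolved through a small per-day lookup and times through integer
# millisecond arithmetic (format()/strptime() per element would dominate IO
# for million-event IBI channels).
fmt_time <- function(start, seconds) {
  ms <- round(seconds * 1000)
  day <- ms %/% 86400000
  rem <- ms %% 86400000
  ud <- sort(unique(day))
  dstr <- format(start + ud * .DAY, "%Y-%m-%d", tz = .TZ)
  d <- dstr[match(day, ud)]
  hh <- rem %/% 3600000
  mi <- (rem %/% 60000) %% 60
  se <- (rem %/% 1000) %% 60
  mss <- rem %% 1000
  sprintf("%sT%02d:%02d:%02d.%03d+0100", d, hh, mi, se, mss)
}

parse_time <- function(x, start) {
  off <- unique(substr(x, 24, 28))
  slow <- length(off) != 1L || off != "+0100"
  if (!slow) {
    date <- substr(x, 1, 10)
    ud <- unique(date)
    base <- as.POSIXct(strptime(paste0(ud, "T00:00:00+0100"),
                                "%Y-%m-%dT%H:%M:%S%z", tz = .TZ))
    slow <- anyNA(base)
    if (!slow) {
      day_s <- as.numeric(difftime(base, start, units = "secs"))[match(date, ud)]
      hh <- as.numeric(substr(x, 12, 13))
      mi <- as.numeric(substr(x, 15, 16))
      se <- as.numeric(substr(x, 18, 23))
      t <- day_s + hh * 3600 + mi * 60 + se
      slow <- anyNA(t)
      if (!slow) return(round(t, 3))
    }
  }
  t <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%OS%z", tz = .TZ))
  if (anyNA(t)) {
    stopf("unparseable ISO-8601 timestamp (first: '%s')", x[which(is.na(t))[1]])
  }
  round(as.numeric(difftime(t, start, units = "secs")), 3)
}

#' Construct a sensor bundle
#'
#' One participant's raw recording: uniformly sampled heart rate (bpm),
#' electrodermal activity, skin temperature and total acceleration magnitude,
#' plus event-stamped inter-beat intervals (ms) and interval step counts.
#' All channel times are seconds since `start` (the participant's local
#' midnight before the first study night).
#'
#' @param id participant id.
#' @param age age in years (needed for the rest heart-rate threshold).
#' @param hr,eda,temp,acc data.frames with columns `time`, `value`.
#' @param ibi data.frame with `time` (event time, s) and `value` (ms).
#' @param steps data.frame with `time` (interval start, s) and `value`
#'   (count); interval width is carried in `step_interval`.
#' @param start POSIXct local start of the recording window.
#' @param step_interval width of each step-count interval in seconds.
#' @return object of class `sensor_bundle`.
#' @export
sensor_bundle <- function(id, age, hr, eda, temp, acc, ibi, steps,
                          start = as.POSIXct("2021-03-01 00:00:00", tz = .TZ),
                          step_interval = 60) {
  chk <- function(df, nm) {
    if (!is.data.frame(df) || !all(c("time", "value") %in% names(df))) {
      stopf("channel %s must be a data.frame with columns time, value", nm)
    }
    if (is.unsorted(df$time, strictly = FALSE)) {
      k <- which(diff(df$time) < 0)[1] + 1L
      stopf("channel %s: timestamp regression at row %d", nm, k)
    }
    df[, c("time", "value")]
  }
  b <- list(id = as.character(id), age = age, start = start,
            step_interval = step_interval,
            hr = chk(hr, "hr"), eda = chk(eda, "eda"), temp = chk(temp, "temp"),
            acc = chk(acc, "acc"), ibi = chk(ibi, "ibi"),
            steps = chk(steps, "steps"))
  class(b) <- "sensor_bundle"
  b
}

#' @export
print.sensor_bundle <- function(x, ...) {
  cat(sprintf("sensor_bundle %s (age %.0f): %d HR samples, %d IBIs, %.1f days\n",
              x$id, x$age, nrow(x$hr), nrow(x$ibi),
              (max(x$hr$time) - min(x$hr$time)) / .DAY))
  invisible(x)
}

#' Write a sensor bundle as per-channel CSV files
#'
#' Writes `hr.csv`, `eda.csv`, `temp.csv`, `acc.csv`, `ibi.csv`, `steps.csv`
#' (header `timestamp,value`, ISO-8601 local timestamps) plus `meta.json`
#' (id, age, start, step interval).
#'
#' @param bundle a [sensor_bundle()].
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_sensor_bundle <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (ch in .CHANNELS) {
    df <- bundle[[ch]]
    out <- data.frame(timestamp = fmt_time(bundle$start, df$time),
                      value = df$value)
    data.table::fwrite(out, file.path(path, paste0(ch, ".csv")), quote = FALSE)
  }
  meta <- list(id = bundle$id, age = bundle$age,
               start = fmt_time(bundle$start, 0),
               step_interval = bundle$step_interval)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a sensor bundle from a directory of per-channel CSV files
#'
#' @param path directory written by [write_sensor_bundle()].
#' @return a [sensor_bundle()].
#' @export
load_sensor_bundle <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stopf("meta.json missing in %s", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  start <- as.POSIXct(strptime(meta$start, "%Y-%m-%dT%H:%M:%OS%z", tz = .TZ))
  chans <- list()
  for (ch in .CHANNELS) {
    f <- file.path(path, paste0(ch, ".csv"))
    if (!file.exists(f)) stopf("channel %s missing", ch)
    df <- as.data.frame(data.table::fread(f, colClasses = c("character", "numeric"),
                                          showProgress = FALSE))
    tm <- if (nrow(df)) parse_time(df$timestamp, start) else numeric(0)
    if (is.unsorted(tm, strictly = FALSE)) {
      k <- which(diff(tm) < 0)[1] + 1L
      stopf("channel %s: timestamp regression at row %d", ch, k)
    }
    chans[[ch]] <- data.frame(time = tm, value = df$value)
  }
  sensor_bundle(meta$id, meta$age, chans$hr, chans$eda, chans$temp,
                chans$acc, chans$ibi, chans$steps,
                start = start, step_interval = meta$step_interval)
}

# ---- feature tables ---------------------------------------------------------

#' Construct a feature table
#'
#' The modeling table: one row per fatigue rating with identifying columns
#' (`rating_id`, `participant_id`, `rating_time`, `vas`), one numeric column
#' per feature, and one logical mask column `miss_<feature>` that is TRUE
#' where the feature could not be computed (missing raw data).
#'
#' @param df data.frame in the layout above.
#' @param feature_names character vector of feature column names; defaults to
#'   every non-id, non-mask column.
#' @return object of class `feature_table` (a data.frame).
#' @export
feature_table <- function(df, feature_names = NULL) {
  idc <- c("rating_id", "participant_id", "rating_time", "vas")
  if (!all(idc %in% names(df))) {
    stopf("feature table must contain columns %s", paste(idc, collapse = ", "))
  }
  if (is.null(feature_names)) {
    feature_names <- setdiff(names(df), c(idc, grep("^miss_", names(df), value = TRUE)))
  }
  for (f in feature_names) {
    m <- paste0("miss_", f)
    if (!m %in% names(df)) df[[m]] <- is.na(df[[f]])
    df[[m]] <- as.logical(df[[m]])
  }
  masks <- grep("^miss_", names(df), value = TRUE)
  orphan <- setdiff(sub("^miss_", "", masks), feature_names)
  if (length(orphan)) {
    stopf("mask column without matching feature column: %s", orphan[1])
  }
  df <- df[, c(idc, feature_names, paste0("miss_", feature_names))]
  attr(df, "feature_names") <- feature_names
  class(df) <- c("feature_table", "data.frame")
  df
}

#' @export
#' @rdname feature_table
#' @param x a `feature_table`.
feature_names <- function(x) attr(x, "feature_names")

#' Write / read the feature-table CSV
#'
#' Missing cells are written as empty strings; `write` then `read` is the
#' identity up to float round-trip.
#'
#' @param table a [feature_table()].
#' @param path CSV path.
#' @return `read_feature_table` returns a [feature_table()].
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  masks <- grep("^miss_", names(df), value = TRUE)
  feats <- sub("^miss_", "", masks)
  missing_feat <- setdiff(feats, names(df))
  if (length(missing_feat)) {
    stopf("mask column without matching feature column: %s", missing_feat[1])
  }
  for (f in feats) {
    m <- paste0("miss_", f)
    df[[m]] <- as.logical(df[[m]])
    bad <- which(is.na(df[[f]]) & !df[[m]])
    if (length(bad)) {
      stopf("schema error: %s missing at row %d but mask says present", f, bad[1])
    }
  }
  feature_table(df, feature_names = feats)
}
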