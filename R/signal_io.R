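#' Construct a labeled multivariate sensor recording
#'
#' A recording holds one subject's multi-axis signal for one activity:
#' an ordered set of equal-length named channels (e.g. \code{acc_x},
#' \code{acc_y}, \code{acc_z}) sampled at a fixed rate.
#'
#' @param subject opaque subject identifier (coerced to character).
#' @param activity non-empty class label.
#' @param sampling_rate samples per second, positive.
#' @param channels named list of equal-length numeric vectors. Channel order
#'   is preserved as given.
#' @return An object of class \code{"har_recording"}.
#' @export
har_recording <- function(subject, activity, sampling_rate, channels) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("'channels' must be a non-empty named list of numeric vectors")
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("all channels must have identical length")
  if (lens[[1L]] < 1L) stop("channels must contain at least one sample")
  for (nm in names(channels)) {
    if (!is.numeric(channels[[nm]]))
      stop("channel '", nm, "' is not numeric")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("'sampling_rate' must be a single positive number")
  activity <- as.character(activity)
  if (length(activity) != 1L || !nzchar(activity))
    stop("'activity' must be a non-empty label")
  structure(
    list(subject = as.character(subject), activity = activity,
         sampling_rate = as.numeric(sampling_rate),
         channels = lapply(channels, as.numeric)),
    class = "har_recording")
}

#' @export
print.har_recording <- function(x, ...) {
  cat(sprintf("<har_recording> subject=%s activity=%s  %d channel(s) x %d samples @ %g Hz\n",
              x$subject, x$activity, length(x$channels),
              length(x$channels[[1L]]), x$sampling_rate))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples per channel of a recording
#' @param x a \code{har_recording}.
#' @export
n_samples <- function(x) length(x$channels[[1L]])

# Deterministic channel order: sorted sensor name, then x, y, z within a
# sensor. Channel names are "<sensor>_<axis>"; names without an axis suffix
# sort alphabetically after decomposition.
order_channel_names <- function(nms) {
  sensor <- sub("_[xyz]$", "", nms)
  axis <- ifelse(grepl("_[xyz]$", nms), sub("^.*_", "", nms), "")
  axis_rank <- match(axis, c("x", "y", "z"), nomatch = 4L)
  nms[order(sensor, axis_rank, nms)]
}

#' Read labeled recordings from a long-form CSV sensor log
#'
#' Expects one row per sample with columns for subject, activity, timestamp,
#' sensor name and the x/y/z values (long form). Rows are grouped by
#' (subject, activity, contiguous timestamp run) into recordings; a run is
#' split whenever consecutive timestamps differ by more than twice the
#' nominal sampling interval.
#'
#' @param path CSV file path.
#' @param sampling_rate nominal sampling rate in Hz used both as recording
#'   metadata and to detect gaps.
#' @param schema named character vector mapping the canonical column roles
#'   \code{subject}, \code{activity}, \code{timestamp}, \code{sensor},
#'   \code{x}, \code{y}, \code{z} to the file's column names.
#' @return A list of \code{har_recording} objects, channels ordered by
#'   sorted sensor name then x, y, z.
#' @export
read_recordings <- function(path, sampling_rate,
                            schema = c(subject = "subject",
                                       activity = "activity",
                                       timestamp = "timestamp",
                                       sensor = "sensor",
                                       x = "x", y = "y", z = "z")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty dataset: ", path)
  roles <- c("subject", "activity", "timestamp", "sensor", "x", "y", "z")
  missing_roles <- setdiff(roles, names(schema))
  if (length(missing_roles))
    stop("schema error: no column mapped for role(s) ",
         paste(missing_roles, collapse = ", "))
  absent <- setdiff(unname(schema[roles]), names(df))
  if (length(absent))
    stop("schema error: column(s) not in file: ",
         paste(absent, collapse = ", "))
  for (role in c("timestamp", "x", "y", "z")) {
    col <- df[[schema[[role]]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad))
      stop("parse error: non-numeric value in column '", schema[[role]],
           "' at data row ", bad[[1L]])
    df[[schema[[role]]]] <- num
  }
  subj <- as.character(df[[schema[["subject"]]]])
  act <- as.character(df[[schema[["activity"]]]])
  ts <- df[[schema[["timestamp"]]]]
  sens <- as.character(df[[schema[["sensor"]]]])
  gap <- 2 / sampling_rate

  out <- list()
  for (s in unique(subj)) {
    for (a in unique(act[subj == s])) {
      sel <- which(subj == s & act == a)
      sel <- sel[order(ts[sel], sens[sel])]
      tvals <- sort(unique(ts[sel]))
      if (any(diff(tvals) <= 0)) stop("timestamps not strictly increasing")
      # split into contiguous runs at gaps > 2x nominal interval
      run_id <- cumsum(c(1, as.integer(diff(tvals) > gap)))
      for (r in unique(run_id)) {
        trun <- tvals[run_id == r]
        rows <- sel[ts[sel] %in% trun]
        sensors <- sort(unique(sens[rows]))
        channels <- list()
        for (sn in sensors) {
          srows <- rows[sens[rows] == sn]
          srows <- srows[order(ts[srows])]
          if (length(srows) != length(trun))
            stop("sensor '", sn, "' missing samples for subject ", s,
                 ", activity ", a)
          for (ax in c("x", "y", "z"))
            channels[[paste0(sn, "_", ax)]] <- df[[schema[[ax]]]][srows]
        }
        channels <- channels[order_channel_names(names(channels))]
        out[[length(out) + 1L]] <-
          har_recording(s, a, sampling_rate, channels)
      }
    }
  }
  out
}

#' Write recordings to the long-form CSV dialect read by
#' \code{\link{read_recordings}}
#'
#' @param recordings list of \code{har_recording} objects.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_recordings <- function(recordings, path) {
  rows <- lapply(recordings, function(rec) {
    n <- n_samples(rec)
    sensors <- unique(sub("_[xyz]$", "", names(rec$channels)))
    do.call(rbind, lapply(sensors, function(sn) {
      data.frame(subject = rec$subject, activity = rec$activity,
                 timestamp = (seq_len(n) - 1) / rec$sampling_rate,
                 sensor = sn,
                 x = rec$channels[[paste0(sn, "_x")]],
                 y = rec$channels[[paste0(sn, "_y")]],
                 z = rec$channels[[paste0(sn, "_z")]],
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  # full round-trip precision: 17 significant digits survive re-parsing
  for (col in c("timestamp", "x", "y", "z"))
    df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract sliding-window segments from a recording
#'
#' With step 1 a series of length n yields n - w + 1 windows of length w;
#' in general floor((n - w) / step) + 1. Trailing partial windows are
#' discarded, never padded. Start offsets are reported 0-based.
#'
#' @param recording a \code{har_recording}.
#' @param window_length window size w in samples, 1 <= w <= n.
#' @param step hop between consecutive window starts, >= 1.
#' @return An object of class \code{"har_segments"}: list with
#'   \code{starts} (0-based offsets), \code{window_length}, \code{step} and
#'   \code{segments}, a list (one per window) of named per-channel value
#'   blocks.
#' @export
segment_recording <- function(recording, window_length, step = window_length) {
  n <- n_samples(recording)
  if (step < 1) stop("parameter error: step must be >= 1")
  if (window_length < 1 || window_length > n)
    stop("window-too-long error: need 1 <= window_length <= ", n)
  starts <- seq.int(0L, n - window_length, by = step)
  segments <- lapply(starts, function(a) {
    lapply(recording$channels, function(ch) ch[(a + 1):(a + window_length)])
  })
  structure(list(subject = recording$subject, activity = recording$activity,
                 window_length = as.integer(window_length),
                 step = as.integer(step), starts = as.integer(starts),
                 segments = segments),
            class = "har_segments")
}

#' @export
print.har_segments <- function(x, ...) {
  cat(sprintf("<har_segments> %d window(s) of %d samples, step %d\n",
              length(x$starts), x$window_length, x$step))
  invisible(x)
}
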