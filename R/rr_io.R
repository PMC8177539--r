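#' Construct an R-R interval series
#'
#' Container for one session's beat-to-beat (R-R) intervals as recorded by
#' a heart-rate monitor. Beat times are derived from the cumulative sum of
#' the intervals: beat `i` occurs at `t0 + sum(rr[1:i]) / 1000` seconds.
#'
#' @param rr numeric vector of R-R intervals in milliseconds, all > 0.
#' @param session_id identifier of the recording session.
#' @param horse_id horse the session belongs to (optional).
#' @param condition condition label (optional).
#' @param t0 session-time origin in seconds of the first interval's start.
#' @return object of class `rr_series`.
#' @export
rr_series <- function(rr, session_id = "session", horse_id = NA_character_,
                      condition = NA_character_, t0 = 0) {
  rr <- as.numeric(rr)
  if (length(rr) && any(!is.finite(rr) | rr <= 0)) {
    stop("all R-R intervals must be finite and > 0 ms")
  }
  structure(
    list(session_id = as.character(session_id),
         horse_id = as.character(horse_id),
         condition = as.character(condition),
         t0 = as.numeric(t0), rr = rr),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("R-R series '%s': %d beats, %.1f s, mean HR %.1f bpm\n",
              x$session_id, length(x$rr), sum(x$rr) / 1000,
              if (length(x$rr)) 60000 / mean(x$rr) else NA_real_))
  invisible(x)
}

#' Beat times of an R-R series
#'
#' @param series an [rr_series()].
#' @return numeric vector of beat times (seconds), strictly increasing.
#' @export
beat_times <- function(series) {
  series$t0 + cumsum(series$rr) / 1000
}

#' Read an R-R interval file
#'
#' Supports two dialects: the Polar HRM sectioned text format (INI-style
#' `[Params]` / `[HRData]` sections, R-R values as integer milliseconds one
#' per line under `[HRData]`), and a plain two-column CSV fallback with
#' header `beat_time_s,rr_ms`. The dialect is auto-detected from the first
#' non-empty line.
#'
#' For HRM files `t0` is taken from a `StartTime=` key in `[Params]`
#' (seconds since midnight) when present, else 0. For the CSV fallback
#' `t0` is `beat_time_s[1] - rr_ms[1]/1000`.
#'
#' @param path file path.
#' @param session_id,horse_id,condition metadata attached to the series;
#'   default `session_id` is the file name without extension.
#' @return an [rr_series()].
#' @export
read_rr <- function(path, session_id = NULL, horse_id = NA_character_,
                    condition = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(session_id)) {
    session_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  first <- lines[nzchar(trimws(lines))][1]
  if (is.na(first)) stop(path, ": empty file")
  if (startsWith(trimws(first), "[")) {
    read_rr_hrm(lines, path, session_id, horse_id, condition)
  } else {
    read_rr_csv(path, session_id, horse_id, condition)
  }
}

read_rr_hrm <- function(lines, path, session_id, horse_id, condition) {
  lines <- trimws(lines)
  section <- cumsum(grepl("^\\[", lines))
  headers <- grepl("^\\[", lines)
  section_name <- rep(NA_character_, length(lines))
  sec_of <- function(name) {
    hdr <- which(lines == paste0("[", name, "]"))
    if (!length(hdr)) return(character(0))
    body <- lines[section == section[hdr[1]] & !headers]
    body[nzchar(body)]
  }
  data <- sec_of("HRData")
  if (!length(data)) stop(path, ": missing [HRData] section")
  rr <- suppressWarnings(as.numeric(data))
  if (any(is.na(rr))) {
    stop(path, ": non-numeric value in [HRData]: ", data[which(is.na(rr))[1]])
  }
  if (any(rr <= 0)) stop(path, ": non-positive R-R interval in [HRData]")
  t0 <- 0
  params <- sec_of("Params")
  st <- grep("^StartTime=", params, value = TRUE)
  if (length(st)) {
    tm <- sub("^StartTime=", "", st[1])
    parts <- suppressWarnings(as.numeric(strsplit(tm, ":")[[1]]))
    if (length(parts) == 3 && !any(is.na(parts))) {
      t0 <- parts[1] * 3600 + parts[2] * 60 + parts[3]
    }
  }
  rr_series(rr, session_id, horse_id, condition, t0 = t0)
}

read_rr_csv <- function(path, session_id, horse_id, condition) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("beat_time_s", "rr_ms") %in% names(df))) {
    stop(path, ": CSV fallback needs header 'beat_time_s,rr_ms'")
  }
  if (nrow(df) && any(!is.finite(df$rr_ms) | df$rr_ms <= 0)) {
    stop(path, ": non-positive R-R interval")
  }
  t0 <- if (nrow(df)) df$beat_time_s[1] - df$rr_ms[1] / 1000 else 0
  rr_series(df$rr_ms, session_id, horse_id, condition, t0 = t0)
}

#' Write an R-R series to file
#'
#' @param series an [rr_series()].
#' @param path output path.
#' @param format `"hrm"` for the Polar-style sectioned text format, `"csv"`
#'   for the `beat_time_s,rr_ms` fallback.
#' @return `path`, invisibly.
#' @export
write_rr <- function(series, path, format = c("hrm", "csv")) {
  format <- match.arg(format)
  if (format == "hrm") {
    t0 <- series$t0
    hh <- floor(t0 / 3600); mm <- floor((t0 - hh * 3600) / 60)
    ss <- t0 - hh * 3600 - mm * 60
    lines <- c("[Params]",
               "Version=106",
               "Mode=3 0 0",
               sprintf("StartTime=%02d:%02d:%04.1f", hh, mm, ss),
               "Interval=238",
               "",
               "[HRData]",
               format(series$rr, scientific = FALSE, trim = TRUE,
                      digits = 15))
    writeLines(lines, path)
  } else {
    df <- data.frame(beat_time_s = beat_times(series), rr_ms = series$rr)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
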