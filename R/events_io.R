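#' Read an annotation event table
#'
#' Reads a CSV of time-coded facial action occurrences, one row per coded
#' action, with required header `video_id,code,onset,offset` (times in
#' seconds, dot decimal). Events are validated against the EquiFACS
#' vocabulary and returned sorted by `(video_id, onset)`.
#'
#' Intervals are treated as closed-open `[onset, offset)`; zero-duration
#' events (`offset == onset`) are allowed and count for frequency while
#' contributing nothing to duration.
#'
#' @param path path to the CSV file.
#' @param vocabulary character vector of admissible codes; defaults to
#'   [equifacs_vocabulary()].
#' @param lax logical; if `TRUE`, rows with codes outside `vocabulary` are
#'   kept with a warning instead of raising an error.
#' @return data.frame with columns `video_id` (character), `code`
#'   (character), `onset`, `offset` (numeric seconds), sorted by
#'   `(video_id, onset)`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("video_id,code,onset,offset", "v1,AD38,1.50,3.25"), f)
#' read_events(f)
read_events <- function(path, vocabulary = equifacs_vocabulary(), lax = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character",
                                       "numeric", "numeric"))
  required <- c("video_id", "code", "onset", "offset")
  if (!identical(names(df), required)) {
    stop("events file must have header 'video_id,code,onset,offset', got: ",
         paste(names(df), collapse = ","))
  }
  validate_events(df, vocabulary = vocabulary, lax = lax,
                  what = basename(path))
}

#' Validate an in-memory event table
#'
#' Applies the same checks as [read_events()] to a data.frame that is
#' already in memory, and returns it sorted by `(video_id, onset)`.
#'
#' @inheritParams read_events
#' @param events data.frame with columns `video_id,code,onset,offset`.
#' @param what label used in error messages.
#' @return the validated, sorted data.frame.
#' @export
validate_events <- function(events, vocabulary = equifacs_vocabulary(),
                            lax = FALSE, what = "events") {
  stopifnot(is.data.frame(events))
  required <- c("video_id", "code", "onset", "offset")
  if (!all(required %in% names(events))) {
    stop(what, ": missing columns ",
         paste(setdiff(required, names(events)), collapse = ", "))
  }
  events <- events[required]
  events$video_id <- as.character(events$video_id)
  events$code <- as.character(events$code)
  bad <- which(!is.finite(events$onset) | !is.finite(events$offset))
  if (length(bad)) {
    stop(what, ": non-numeric or missing time in row ", bad[1],
         " (data line ", bad[1] + 1L, ")")
  }
  bad <- which(events$onset < 0)
  if (length(bad)) {
    stop(what, ": negative onset in row ", bad[1],
         " (data line ", bad[1] + 1L, ")")
  }
  bad <- which(events$offset < events$onset)
  if (length(bad)) {
    stop(what, ": offset earlier than onset in row ", bad[1],
         " (data line ", bad[1] + 1L, ")")
  }
  if (!is.null(vocabulary)) {
    unknown <- setdiff(unique(events$code), vocabulary)
    if (length(unknown)) {
      msg <- paste0(what, ": unknown code(s): ",
                    paste(unknown, collapse = ", "))
      if (lax) warning(msg, call. = FALSE) else stop(msg)
    }
  }
  events <- events[order(events$video_id, events$onset), , drop = FALSE]
  rownames(events) <- NULL
  events
}

#' Write an annotation event table
#'
#' @param events event data.frame as returned by [read_events()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events[c("video_id", "code", "onset", "offset")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read clip metadata
#'
#' Reads the per-clip metadata CSV with header
#' `video_id,horse_id,group,condition,clip_start,clip_length`:
#' one row per 30-second scored clip, with the horse it shows, its study
#' group (`PRI`/`UNI`), the condition (`baseline`/`transportation`/
#' `isolation`) and the clip's start within its recording session.
#'
#' @param path path to the CSV file.
#' @return validated data.frame of clips.
#' @export
read_clips <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clips(df, what = basename(path))
}

#' Validate in-memory clip metadata
#'
#' @param clips data.frame of clip metadata.
#' @param what label used in error messages.
#' @return the validated data.frame.
#' @export
validate_clips <- function(clips, what = "clips") {
  required <- c("video_id", "horse_id", "group", "condition",
                "clip_start", "clip_length")
  if (!all(required %in% names(clips))) {
    stop(what, ": missing columns ",
         paste(setdiff(required, names(clips)), collapse = ", "))
  }
  clips <- clips[required]
  for (col in c("video_id", "horse_id", "group", "condition")) {
    clips[[col]] <- as.character(clips[[col]])
  }
  if (anyDuplicated(clips$video_id)) {
    stop(what, ": duplicated video_id: ",
         clips$video_id[anyDuplicated(clips$video_id)])
  }
  bad <- setdiff(unique(clips$group), study_groups())
  if (length(bad)) stop(what, ": unknown group(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(clips$condition), study_conditions())
  if (length(bad)) {
    stop(what, ": unknown condition(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(clips$clip_length) | clips$clip_length <= 0)) {
    stop(what, ": clip_length must be > 0")
  }
  if (any(!is.finite(clips$clip_start) | clips$clip_start < 0)) {
    stop(what, ": clip_start must be >= 0")
  }
  rownames(clips) <- NULL
  clips
}

#' @rdname read_clips
#' @param clips validated clip data.frame.
#' @export
write_clips <- function(clips, path) {
  utils::write.csv(clips, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check that every event belongs to a known clip
#'
#' @param events event table.
#' @param clips clip metadata.
#' @return invisibly `TRUE`; errors if an event references an unknown clip.
#' @export
check_events_clips <- function(events, clips) {
  orphan <- setdiff(unique(events$video_id), clips$video_id)
  if (length(orphan)) {
    stop("events reference unknown video_id(s): ",
         paste(orphan, collapse = ", "))
  }
  invisible(TRUE)
}

#' Remove unscorable footage
#'
#' Drops `VC74` (unscorable) marker events, and any other event whose
#' interval lies entirely inside a `VC74` interval of the same video.
#' Events that only partially overlap unscorable footage are kept
#' untrimmed, preserving their coded durations.
#'
#' @param events event data.frame.
#' @return event data.frame without VC74 rows and without fully-covered
#'   events, in the original sort order.
#' @export
#' @examples
#' ev <- data.frame(video_id = "v1", code = c("VC74", "AU145", "AD38"),
#'                  onset = c(0, 1, 4), offset = c(5, 2, 7))
#' drop_unscorable(ev)  # AU145 fully covered -> removed; AD38 kept
drop_unscorable <- function(events) {
  is_vc <- events$code == vc_code()
  if (!any(is_vc)) return(events)
  keep <- !is_vc
  vc <- events[is_vc, , drop = FALSE]
  for (v in unique(vc$video_id)) {
    vvc <- vc[vc$video_id == v, , drop = FALSE]
    idx <- which(keep & events$video_id == v)
    if (!length(idx)) next
    covered <- vapply(idx, function(i) {
      any(events$onset[i] >= vvc$onset & events$offset[i] <= vvc$offset)
    }, logical(1))
    keep[idx[covered]] <- FALSE
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
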