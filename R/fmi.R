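#' Build "ear flicker" facial movement index events
#'
#' An "ear flicker" is an *ears forward* (EAD101) and an *ear rotator*
#' (EAD104) occurring together within a short interval (1 s by default).
#' Because a flicker is one composite facial movement, its two constituent
#' ear events must not additionally be counted as separate EAD101/EAD104
#' occurrences. This function pairs ear events greedily and returns the
#' composite flickers together with all unconsumed events.
#'
#' Pairing rule: ear events are scanned in onset order (ties broken by
#' input order); each unconsumed EAD101/EAD104 is paired with the earliest
#' subsequent unconsumed event of the *opposite* ear code whose onset lies
#' within `window` seconds (onset-to-onset), in either order. Both
#' constituents are consumed. The rule is deterministic and guarantees
#' that no residual EAD101 onset lies within `window` of a residual EAD104
#' onset.
#'
#' @param events event data.frame (any mix of videos; pairing never crosses
#'   video boundaries).
#' @param window maximum onset-to-onset separation in seconds (default 1).
#' @return list with elements
#'   \describe{
#'     \item{flickers}{data.frame of composite events: `video_id`, `code`
#'       (= [fmi_code()]), `onset` (earlier constituent onset), `offset`
#'       (later constituent offset), `onset_ead101`, `onset_ead104`.}
#'     \item{residual}{data.frame of all unconsumed events, including any
#'       unpaired ear events, sorted like the input.}
#'   }
#' @export
#' @examples
#' ev <- data.frame(video_id = "v1", code = c("EAD101", "EAD104"),
#'                  onset = c(1.0, 1.5), offset = c(1.2, 1.9))
#' build_ear_flicker(ev)
build_ear_flicker <- function(events, window = 1.0) {
  stopifnot(is.data.frame(events), window >= 0)
  is_ear <- events$code %in% ear_codes()
  flick_list <- list()
  consumed <- logical(nrow(events))
  for (v in unique(events$video_id[is_ear])) {
    idx <- which(is_ear & events$video_id == v)
    idx <- idx[order(events$onset[idx])]  # stable: ties keep input order
    taken <- logical(length(idx))
    for (a in seq_along(idx)) {
      if (taken[a]) next
      ia <- idx[a]
      for (b in seq_along(idx)[-seq_len(a)]) {
        if (taken[b]) next
        ib <- idx[b]
        if (events$onset[ib] - events$onset[ia] > window) break
        if (events$code[ib] == events$code[ia]) next
        taken[a] <- taken[b] <- TRUE
        consumed[ia] <- consumed[ib] <- TRUE
        i101 <- if (events$code[ia] == "EAD101") ia else ib
        i104 <- if (events$code[ia] == "EAD101") ib else ia
        flick_list[[length(flick_list) + 1L]] <- data.frame(
          video_id = v,
          code = fmi_code(),
          onset = min(events$onset[c(ia, ib)]),
          offset = max(events$offset[c(ia, ib)]),
          onset_ead101 = events$onset[i101],
          onset_ead104 = events$onset[i104],
          stringsAsFactors = FALSE
        )
        break
      }
    }
  }
  flickers <- if (length(flick_list)) {
    do.call(rbind, flick_list)
  } else {
    data.frame(video_id = character(0), code = character(0),
               onset = numeric(0), offset = numeric(0),
               onset_ead101 = numeric(0), onset_ead104 = numeric(0),
               stringsAsFactors = FALSE)
  }
  residual <- events[!consumed, , drop = FALSE]
  rownames(residual) <- NULL
  list(flickers = flickers, residual = residual)
}

#' Apply the ear-flicker adjustment to an event table
#'
#' Convenience wrapper around [build_ear_flicker()]: returns a single event
#' table in which each matched EAD101/EAD104 pair is replaced by one
#' composite row with code [fmi_code()], and all other events pass through
#' untouched. This is the "post-FMI" representation expected by
#' [occurrence_table()], [cooccur_contrast()] and [summarize_clips()].
#'
#' @inheritParams build_ear_flicker
#' @return event data.frame sorted by `(video_id, onset)`.
#' @export
apply_ear_flicker <- function(events, window = 1.0) {
  res <- build_ear_flicker(events, window = window)
  fl <- res$flickers[c("video_id", "code", "onset", "offset")]
  out <- rbind(res$residual[c("video_id", "code", "onset", "offset")], fl)
  out <- out[order(out$video_id, out$onset), , drop = FALSE]
  rownames(out) <- NULL
  out
}
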