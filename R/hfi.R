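#' Pool clips into intervention and control sets
#'
#' @keywords internal
pool_of <- function(clips, intervention, control) {
  pool <- rep(NA_character_, nrow(clips))
  pool[clips$condition %in% intervention] <- "intervention"
  pool[clips$condition %in% control] <- "control"
  pool
}

#' Occurrence table by condition pool
#'
#' Pools facial-action occurrences over all clips of the intervention
#' conditions and of the control conditions, and reports, per code: raw
#' occurrence counts, the percentage share of each pool's total
#' occurrences, and the per-clip mean frequency (occurrences per clip).
#' `VC74` events are excluded from the counts and from the denominators.
#'
#' Events should already carry the ear-flicker adjustment
#' ([apply_ear_flicker()]) so the composite index competes with ordinary
#' codes in the shares.
#'
#' @param events event data.frame (post-FMI).
#' @param clips clip metadata; every event's `video_id` must resolve.
#' @param intervention character vector of condition labels pooled as
#'   intervention (default both interventions).
#' @param control character vector of condition labels pooled as control.
#' @return data.frame with one row per code observed in either pool:
#'   `code`, `n_intervention`, `n_control`, `share_intervention`,
#'   `share_control` (percent), `freq_intervention`, `freq_control`
#'   (occurrences per clip), ordered by decreasing `share_intervention`.
#'   Attributes `n_clips_intervention` / `n_clips_control` carry the pool
#'   sizes.
#' @export
occurrence_table <- function(events, clips,
                             intervention = c("transportation", "isolation"),
                             control = "baseline") {
  check_events_clips(events, clips)
  pool <- pool_of(clips, intervention, control)
  n_clips <- c(intervention = sum(pool == "intervention", na.rm = TRUE),
               control = sum(pool == "control", na.rm = TRUE))
  if (any(n_clips == 0)) {
    stop("pool with zero clips: ",
         paste(names(n_clips)[n_clips == 0], collapse = ", "))
  }
  events <- events[events$code != vc_code(), , drop = FALSE]
  ev_pool <- pool[match(events$video_id, clips$video_id)]
  events <- events[!is.na(ev_pool), , drop = FALSE]
  ev_pool <- ev_pool[!is.na(ev_pool)]
  codes <- sort(unique(events$code))
  cnt <- function(p) {
    tab <- table(factor(events$code[ev_pool == p], levels = codes))
    as.integer(tab)
  }
  n_int <- cnt("intervention")
  n_ctl <- cnt("control")
  out <- data.frame(
    code = codes,
    n_intervention = n_int,
    n_control = n_ctl,
    share_intervention = 100 * n_int / max(1L, sum(n_int)),
    share_control = 100 * n_ctl / max(1L, sum(n_ctl)),
    freq_intervention = n_int / n_clips[["intervention"]],
    freq_control = n_ctl / n_clips[["control"]],
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$share_intervention, out$code), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_clips_intervention") <- n_clips[["intervention"]]
  attr(out, "n_clips_control") <- n_clips[["control"]]
  out
}

#' Frequency-threshold (HFI) code selection
#'
#' Selects the codes that (a) account for at least `threshold` percent of
#' all occurrences in the intervention pool and (b) occur at a higher
#' per-clip mean frequency during intervention than during control. The
#' reported `freq_difference` is the relative increase of the per-clip
#' mean frequency, in percent; it is `Inf` when the code never occurs in
#' control.
#'
#' Per-clip mean frequencies (not pooled counts) are compared so that
#' unbalanced pool sizes do not bias the contrast.
#'
#' @param table an [occurrence_table()].
#' @param threshold minimum intervention share in percent (default 5).
#' @return data.frame of selected codes with columns `code`,
#'   `share_intervention`, `share_control`, `freq_difference`, ordered by
#'   decreasing share.
#' @export
hfi_select <- function(table, threshold = 5.0) {
  stopifnot(is.data.frame(table),
            all(c("share_intervention", "freq_intervention",
                  "freq_control") %in% names(table)))
  sel <- table$share_intervention >= threshold &
    table$freq_intervention > table$freq_control
  out <- table[sel, , drop = FALSE]
  out$freq_difference <- ifelse(
    out$freq_control > 0,
    100 * (out$freq_intervention - out$freq_control) / out$freq_control,
    Inf
  )
  out <- out[order(-out$share_intervention, out$code),
             c("code", "share_intervention", "share_control",
               "freq_difference"), drop = FALSE]
  rownames(out) <- NULL
  out
}
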