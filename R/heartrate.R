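#' Filter artifact beats from an R-R series
#'
#' Median-based protection-zone artifact rejection, in the spirit of the
#' "medium" correction filters of commercial heart-rate software: beat
#' `i` (instantaneous rate `HR_i = 60000 / rr_i` bpm) is rejected when it
#' deviates from the median instantaneous rate of the `window_beats`-beat
#' window centred on it by more than
#' `max(protection_bpm, rel_threshold * median)`. Medians are computed on
#' the unfiltered series in a single pass; rejected intervals are removed
#' and beat times re-derived from the survivors.
#'
#' The protection zone (`protection_bpm`, default 6 bpm) is the deviation
#' below which a beat is never flagged, so filtering is conservative at
#' low heart rates; the relative component governs behaviour at high
#' rates.
#'
#' @param series an [rr_series()] with at least 5 beats.
#' @param protection_bpm minimum absolute deviation (bpm) for rejection.
#' @param rel_threshold relative deviation threshold (fraction of the
#'   local median rate).
#' @param window_beats centred window width in beats (odd; truncated at
#'   the series edges).
#' @return filtered [rr_series()]; attribute `rejected_fraction` reports
#'   the fraction of beats removed. A warning is raised when more than
#'   25\% of beats are rejected (poor signal quality).
#' @export
filter_rr <- function(series, protection_bpm = 6.0, rel_threshold = 0.15,
                      window_beats = 5) {
  stopifnot(inherits(series, "rr_series"))
  n <- length(series$rr)
  if (n < 5) stop("filter_rr needs at least 5 beats")
  half <- floor(window_beats / 2)
  hr <- 60000 / series$rr
  med <- vapply(seq_len(n), function(i) {
    stats::median(hr[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  reject <- abs(hr - med) > pmax(protection_bpm, rel_threshold * med)
  frac <- mean(reject)
  if (frac > 0.25) {
    warning(sprintf("%s: %.1f%% of beats rejected - poor signal quality",
                    series$session_id, 100 * frac), call. = FALSE)
  }
  out <- rr_series(series$rr[!reject], series$session_id, series$horse_id,
                   series$condition, t0 = series$t0)
  attr(out, "rejected_fraction") <- frac
  out
}

#' Clip-anchored five-minute mean heart rate
#'
#' Computes the mean heart rate over a window centred on an annotation
#' clip: the window opens `margin` seconds before the clip start and
#' closes `margin` seconds after the clip end (defaults: 135 s margin
#' around a 30 s clip, i.e. a 300 s window). The mean is time-weighted --
#' beats whose times fall inside the window divided by the elapsed time
#' they span -- not a mean of instantaneous rates.
#'
#' @param series a filtered [rr_series()].
#' @param clip_start clip onset in session time (seconds).
#' @param clip_length clip length in seconds (default 30).
#' @param margin seconds added before the clip start and after the clip
#'   end (default 135).
#' @param min_coverage minimum fraction of the window that must be covered
#'   by beats (default 0.5); below it an error is raised.
#' @return one-row data.frame: `session_id`, `window_start`, `window_end`,
#'   `mean_hr` (bpm), `n_beats`, `coverage`.
#' @export
window_mean <- function(series, clip_start, clip_length = 30, margin = 135,
                        min_coverage = 0.5) {
  stopifnot(inherits(series, "rr_series"))
  ws <- clip_start - margin
  we <- clip_start + clip_length + margin
  t <- beat_times(series)
  inside <- t >= ws & t <= we
  sec <- sum(series$rr[inside]) / 1000
  coverage <- sec / (we - ws)
  if (coverage < min_coverage) {
    stop(sprintf("%s: window [%g, %g] covered only %.0f%% (< %.0f%%)",
                 series$session_id, ws, we, 100 * coverage,
                 100 * min_coverage))
  }
  data.frame(session_id = series$session_id, window_start = ws,
             window_end = we, mean_hr = 60 * sum(inside) / sec,
             n_beats = sum(inside), coverage = coverage,
             stringsAsFactors = FALSE)
}

#' Heart-rate windows for all clips
#'
#' Filters each session's R-R series and extracts the clip-anchored
#' five-minute mean heart rate for every clip, matching sessions to clips
#' by horse and condition.
#'
#' @param rr_list list of [rr_series()] objects with `horse_id` and
#'   `condition` metadata set.
#' @param clips clip metadata.
#' @param filter logical; apply [filter_rr()] first (default `TRUE`).
#' @param ... passed to [filter_rr()] and [window_mean()] (e.g.
#'   `protection_bpm`, `margin`).
#' @return data.frame with one row per clip: clip metadata columns plus
#'   `mean_hr`, `n_beats`, `coverage`.
#' @export
hr_windows <- function(rr_list, clips, filter = TRUE, ...) {
  dots <- list(...)
  take <- function(f) dots[intersect(names(dots), names(formals(f)))]
  if (filter) {
    rr_list <- lapply(rr_list, function(s) {
      do.call(filter_rr, c(list(s), take(filter_rr)))
    })
  }
  keys <- vapply(rr_list, function(s) paste(s$horse_id, s$condition),
                 character(1))
  rows <- lapply(seq_len(nrow(clips)), function(i) {
    k <- paste(clips$horse_id[i], clips$condition[i])
    hit <- which(keys == k)
    if (!length(hit)) {
      stop("no R-R session for horse ", clips$horse_id[i], " condition ",
           clips$condition[i])
    }
    wm <- do.call(window_mean,
                  c(list(rr_list[[hit[1]]], clip_start = clips$clip_start[i],
                         clip_length = clips$clip_length[i]),
                    take(window_mean)))
    cbind(clips[i, c("video_id", "horse_id", "group", "condition")],
          wm[c("mean_hr", "n_beats", "coverage")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired heart-rate tests per study group
#'
#' Tests the rise in clip-window mean heart rate from baseline to each
#' intervention with paired Wilcoxon signed-rank tests at the horse level:
#' the PRI group has a single contrast (transportation vs baseline,
#' reported raw), while the UNI group's two contrasts (isolation vs
#' baseline, transportation vs baseline) form a family and are
#' Holm-adjusted.
#'
#' @param windows output of [hr_windows()].
#' @param clips clip metadata (used for the group labels if `windows`
#'   lacks them).
#' @return data.frame with columns `group`, `contrast`, `n_horses`,
#'   `mean_baseline`, `mean_intervention`, `p_raw`, `p_adj`.
#' @export
hr_tests <- function(windows, clips = NULL) {
  if (!("group" %in% names(windows)) && !is.null(clips)) {
    windows$group <- clips$group[match(windows$video_id, clips$video_id)]
  }
  agg <- stats::aggregate(mean_hr ~ horse_id + condition + group,
                          data = windows, FUN = mean)
  one <- function(group, interv) {
    sub <- agg[agg$group == group, , drop = FALSE]
    base <- sub[sub$condition == "baseline", , drop = FALSE]
    int <- sub[sub$condition == interv, , drop = FALSE]
    horses <- intersect(base$horse_id, int$horse_id)
    if (length(horses) < 2) {
      stop("contrast ", group, " ", interv, ": needs >= 2 paired horses")
    }
    b <- base$mean_hr[match(horses, base$horse_id)]
    x <- int$mean_hr[match(horses, int$horse_id)]
    data.frame(group = group,
               contrast = paste(interv, "vs baseline"),
               n_horses = length(horses),
               mean_baseline = mean(b), mean_intervention = mean(x),
               p_raw = wilcoxon_paired_p(x - b), stringsAsFactors = FALSE)
  }
  rows <- list()
  if ("PRI" %in% agg$group) rows$pri <- one("PRI", "transportation")
  if ("UNI" %in% agg$group) {
    uni <- rbind(one("UNI", "isolation"), one("UNI", "transportation"))
    uni$p_adj <- holm_adjust(uni$p_raw)
    rows$uni <- uni
  }
  if (!is.null(rows$pri)) rows$pri$p_adj <- rows$pri$p_raw
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
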