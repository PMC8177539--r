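#' Per-clip frequency and maximum-duration summary
#'
#' For every clip and every code in the vocabulary grid, reports how often
#' the code occurred in the clip (`frequency`) and the longest single
#' activation (`max_duration`, seconds; 0 when the code is absent).
#'
#' @param events event data.frame (post-FMI for analysis of the composite
#'   index, or raw for classifier features).
#' @param clips clip metadata; all clips appear in the output, including
#'   clips without any events.
#' @param vocabulary codes forming the column grid; default: all codes
#'   observed in `events` except `VC74`.
#' @return data.frame with one row per clip x code: `video_id`, `code`,
#'   `frequency`, `max_duration`.
#' @export
#' @examples
#' ev <- data.frame(video_id = "c1", code = "AD19",
#'                  onset = c(1, 5), offset = c(2, 8))
#' cl <- data.frame(video_id = "c1", horse_id = "h1", group = "UNI",
#'                  condition = "baseline", clip_start = 0, clip_length = 30)
#' summarize_clips(ev, cl)
summarize_clips <- function(events, clips, vocabulary = NULL) {
  check_events_clips(events, clips)
  events <- events[events$code != vc_code(), , drop = FALSE]
  if (is.null(vocabulary)) vocabulary <- sort(unique(events$code))
  grid <- expand.grid(video_id = clips$video_id, code = vocabulary,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(v, c) paste(v, c, sep = "\r")
  events <- events[events$code %in% vocabulary, , drop = FALSE]
  ev_key <- key(events$video_id, events$code)
  freq <- table(ev_key)
  dur <- tapply(events$offset - events$onset, ev_key, max)
  gkey <- key(grid$video_id, grid$code)
  grid$frequency <- as.integer(ifelse(is.na(freq[gkey]), 0L, freq[gkey]))
  grid$max_duration <- as.numeric(ifelse(is.na(dur[gkey]), 0, dur[gkey]))
  grid <- grid[order(grid$video_id, grid$code), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Paired signed-rank helper
#'
#' Two-sided Wilcoxon signed-rank p-value on paired differences, with
#' zero differences dropped, the exact null distribution when fewer than
#' 25 non-zero differences and no ties in absolute rank, and the normal
#' approximation otherwise. All-zero differences give p = 1.
#'
#' @param d numeric vector of paired differences.
#' @return two-sided p-value.
#' @keywords internal
wilcoxon_paired_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1.0)
  exact <- n < 25 && !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = !exact)$p.value
  )
}

paired_t_p <- function(d) {
  if (stats::sd(d) == 0) return(if (all(d == 0)) 1.0 else 0.0)
  stats::t.test(d)$p.value
}

#' Significance stars
#' @keywords internal
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Paired per-code tests of frequency and maximum duration
#'
#' For each code and measure, averages the per-clip values per horse within
#' each condition pool and tests the paired per-horse differences
#' (intervention minus control). The default test is the Wilcoxon
#' signed-rank (exact for small samples, zero differences dropped); a
#' paired t-test is available for sensitivity analyses.
#'
#' @param summary output of [summarize_clips()].
#' @param clips clip metadata.
#' @param intervention,control condition labels defining the pools.
#' @param measures which per-clip measures to test.
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return data.frame with columns `code`, `measure`, `n_horses`,
#'   `mean_intervention`, `mean_control`, `p`, `stars` (bands at
#'   0.05 / 0.01 / 0.001).
#' @export
paired_tests <- function(summary, clips,
                         intervention = c("transportation", "isolation"),
                         control = "baseline",
                         measures = c("frequency", "max_duration"),
                         method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  measures <- match.arg(measures, several.ok = TRUE)
  pool <- pool_of(clips, intervention, control)
  df <- merge(summary, data.frame(video_id = clips$video_id,
                                  horse_id = clips$horse_id, pool = pool,
                                  stringsAsFactors = FALSE),
              by = "video_id")
  df <- df[!is.na(df$pool), , drop = FALSE]
  has_both <- tapply(df$pool, df$horse_id,
                     function(p) all(c("intervention", "control") %in% p))
  horses <- names(has_both)[has_both]
  if (length(horses) < 2) {
    stop("paired tests need >= 2 horses with clips in both pools")
  }
  df <- df[df$horse_id %in% horses, , drop = FALSE]
  pfun <- if (method == "wilcoxon") wilcoxon_paired_p else paired_t_p
  rows <- list()
  for (code in sort(unique(df$code))) {
    for (ms in measures) {
      sub <- df[df$code == code, , drop = FALSE]
      agg <- tapply(sub[[ms]], list(sub$horse_id, sub$pool), mean)
      d <- agg[horses, "intervention"] - agg[horses, "control"]
      rows[[length(rows) + 1L]] <- data.frame(
        code = code, measure = ms, n_horses = length(horses),
        mean_intervention = mean(agg[horses, "intervention"]),
        mean_control = mean(agg[horses, "control"]),
        p = pfun(d), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$stars <- p_stars(out$p)
  rownames(out) <- NULL
  out
}

#' Wexler inter-rater agreement ratio
#'
#' Agreement between two coders' annotations of the same footage:
#' `2 * N_agree / (N1 + N2)`, where `N1`, `N2` are the two coders' event
#' counts and `N_agree` the number of matched pairs. Two events match when
#' they are in the same video, carry the same code and overlap in time;
#' each event is matched at most once (greedy sweep in onset order, which
#' attains the maximum matching for interval overlap).
#'
#' Intervals are closed-open, so abutting intervals (`offset_1 ==
#' onset_2`) with positive durations do not overlap; a zero-duration event
#' matches when its time point lies inside the other event's closed
#' interval.
#'
#' @param events_a,events_b the two coders' event data.frames.
#' @param min_overlap minimum overlap in seconds required for a match
#'   (default 0 = any positive overlap, with the zero-duration rule above).
#' @return agreement ratio in `[0, 1]`; defined as 1 when both coders
#'   coded nothing (vacuous agreement).
#' @export
#' @examples
#' a <- data.frame(video_id = "v", code = c("AU101", "AU145"),
#'                 onset = c(0, 2), offset = c(1, 3))
#' b <- data.frame(video_id = "v", code = c("AU101", "AD38"),
#'                 onset = c(0.5, 2), offset = c(1.5, 3))
#' wexler_agreement(a, b)  # 2 * 1 / 4 = 0.5
wexler_agreement <- function(events_a, events_b, min_overlap = 0) {
  n1 <- nrow(events_a)
  n2 <- nrow(events_b)
  if (n1 + n2 == 0) return(1.0)
  matches <- 0L
  keys <- intersect(paste(events_a$video_id, events_a$code),
                    paste(events_b$video_id, events_b$code))
  for (k in keys) {
    a <- events_a[paste(events_a$video_id, events_a$code) == k, , drop = FALSE]
    b <- events_b[paste(events_b$video_id, events_b$code) == k, , drop = FALSE]
    a <- a[order(a$onset, a$offset), , drop = FALSE]
    b <- b[order(b$onset, b$offset), , drop = FALSE]
    i <- j <- 1L
    while (i <= nrow(a) && j <= nrow(b)) {
      ov <- min(a$offset[i], b$offset[j]) - max(a$onset[i], b$onset[j])
      zero_dur <- (a$offset[i] == a$onset[i]) || (b$offset[j] == b$onset[j])
      hit <- if (min_overlap > 0) ov >= min_overlap
             else ov > 0 || (ov == 0 && zero_dur)
      if (hit) {
        matches <- matches + 1L
        i <- i + 1L
        j <- j + 1L
      } else if (a$offset[i] <= b$offset[j]) {
        i <- i + 1L
      } else {
        j <- j + 1L
      }
    }
  }
  2 * matches / (n1 + n2)
}

#' Holm step-down adjustment of a p-value family
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "holm"`, kept as a
#' named operation because the heart-rate analysis adjusts its
#' within-group family of contrasts this way.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, same order as the input.
#' @export
#' @examples
#' holm_adjust(c(0.004, 0.008))  # 0.008, 0.008
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")
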