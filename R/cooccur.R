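#' Build a directed co-occurrence graph for one clip
#'
#' Every onset opens an observation window of `ows` seconds. For each
#' ordered pair of occurrences (`a` of code A, `b` of code B, A != B) with
#' `onset(b) - onset(a)` in `(0, ows]`, the edge weight `w(A -> B)` is
#' incremented by one; pairs with exactly simultaneous onsets increment
#' both directions. Repetitions of a single code never count as
#' co-occurrence (no self-edges).
#'
#' @param events event data.frame for a single clip (post-FMI).
#' @param ows observation window size in seconds; must be > 0.
#' @param clip_length clip length in seconds, used by [code_profile()] to
#'   express degrees as per-minute rates (default 30).
#' @return object of class `cooccurrence_graph`: list with the integer
#'   adjacency matrix `w` (rows = source code, cols = target code), `ows`
#'   and `clip_length`.
#' @export
#' @examples
#' ev <- data.frame(video_id = "c1", code = c("AU25", "AD19"),
#'                  onset = c(0, 1), offset = c(0.5, 1.5))
#' build_graph(ev, ows = 2)$w
build_graph <- function(events, ows, clip_length = 30) {
  if (!is.numeric(ows) || length(ows) != 1 || ows <= 0) {
    stop("ows must be a single positive number of seconds")
  }
  codes <- sort(unique(events$code))
  w <- matrix(0L, length(codes), length(codes),
              dimnames = list(codes, codes))
  n <- nrow(events)
  if (n > 1) {
    on <- events$onset
    ci <- match(events$code, codes)
    dt <- outer(on, on, FUN = function(a, b) b - a)  # dt[i,j] = on[j]-on[i]
    hit <- which(dt >= 0 & dt <= ows, arr.ind = TRUE)
    hit <- hit[hit[, 1] != hit[, 2], , drop = FALSE]
    hit <- hit[ci[hit[, 1]] != ci[hit[, 2]], , drop = FALSE]
    if (nrow(hit)) {
      pair <- cbind(ci[hit[, 1]], ci[hit[, 2]])
      tab <- table(factor(pair[, 1], levels = seq_along(codes)),
                   factor(pair[, 2], levels = seq_along(codes)))
      w <- w + matrix(as.integer(tab), length(codes), length(codes),
                      dimnames = list(codes, codes))
    }
  }
  structure(list(w = w, ows = ows, clip_length = clip_length),
            class = "cooccurrence_graph")
}

#' @export
print.cooccurrence_graph <- function(x, ...) {
  cat(sprintf("co-occurrence graph: %d codes, %d edge counts, ows = %g s\n",
              nrow(x$w), sum(x$w), x$ows))
  invisible(x)
}

#' Per-code co-occurrence degree rate
#'
#' The co-occurrence activity of a code in one clip: the sum of its
#' outgoing and incoming edge weights, divided by the clip length in
#' minutes.
#'
#' @param graph a [build_graph()] result.
#' @return named numeric vector, degree counts per minute.
#' @export
code_profile <- function(graph) {
  stopifnot(inherits(graph, "cooccurrence_graph"))
  (rowSums(graph$w) + colSums(graph$w)) / (graph$clip_length / 60)
}

#' Condition contrast of co-occurrence profiles
#'
#' For one observation window size, builds a co-occurrence graph per clip,
#' takes each code's degree rate ([code_profile()]), averages it per horse
#' within each condition pool, and tests the per-horse paired differences
#' (intervention minus control) with a paired t-test. A code is `selected`
#' when its mean paired difference (the `score`) is positive, and
#' `significant` when additionally `p < alpha`.
#'
#' Horses lacking clips in either pool are dropped with a warning. At
#' least two horses with clips in both pools are required.
#'
#' @param events event data.frame (post-FMI).
#' @param clips clip metadata.
#' @param ows observation window size in seconds (scalar).
#' @param intervention,control condition labels defining the two pools.
#' @param alpha significance level for the `significant` flag.
#' @param p_adjust `"none"` (default, per-code raw p-values) or `"holm"`
#'   to Holm-adjust across codes within this window size.
#' @return data.frame with columns `ows`, `code`, `score` (mean per-horse
#'   difference of degree rate, per minute), `p`, `selected`,
#'   `significant`, ordered by decreasing score.
#' @export
cooccur_contrast <- function(events, clips, ows,
                             intervention = c("transportation", "isolation"),
                             control = "baseline", alpha = 0.05,
                             p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  check_events_clips(events, clips)
  pool <- pool_of(clips, intervention, control)
  keep <- !is.na(pool)
  clips_p <- clips[keep, , drop = FALSE]
  pool <- pool[keep]

  has_both <- tapply(pool, clips_p$horse_id,
                     function(p) all(c("intervention", "control") %in% p))
  horses <- names(has_both)[has_both]
  dropped <- names(has_both)[!has_both]
  if (length(dropped)) {
    warning("dropping horse(s) without both conditions: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (length(horses) < 2) {
    stop("paired t-test needs >= 2 horses with clips in both pools")
  }
  in_design <- clips_p$horse_id %in% horses
  clips_p <- clips_p[in_design, , drop = FALSE]
  pool <- pool[in_design]

  codes <- sort(unique(events$code[events$video_id %in% clips_p$video_id]))
  prof <- matrix(0, nrow(clips_p), length(codes),
                 dimnames = list(clips_p$video_id, codes))
  for (i in seq_len(nrow(clips_p))) {
    ev <- events[events$video_id == clips_p$video_id[i], , drop = FALSE]
    if (!nrow(ev)) next
    g <- build_graph(ev, ows = ows, clip_length = clips_p$clip_length[i])
    v <- code_profile(g)
    prof[i, names(v)] <- v
  }

  diff_mat <- matrix(0, length(horses), length(codes),
                     dimnames = list(horses, codes))
  for (h in horses) {
    hi <- clips_p$horse_id == h
    m_int <- colMeans(prof[hi & pool == "intervention", , drop = FALSE])
    m_ctl <- colMeans(prof[hi & pool == "control", , drop = FALSE])
    diff_mat[h, ] <- m_int - m_ctl
  }

  score <- colMeans(diff_mat)
  p <- vapply(seq_along(codes), function(j) {
    d <- diff_mat[, j]
    # constant differences: t undefined; all-zero is a perfect null (p = 1),
    # constant non-zero is treated as maximal evidence against it
    if (stats::sd(d) == 0) return(if (all(d == 0)) 1.0 else 0.0)
    stats::t.test(d)$p.value
  }, numeric(1))
  if (p_adjust == "holm") p <- stats::p.adjust(p, method = "holm")

  out <- data.frame(ows = ows, code = codes, score = score, p = p,
                    selected = score > 0,
                    significant = score > 0 & p < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Co-occurrence contrast over several window sizes
#'
#' Runs [cooccur_contrast()] at each observation window size and stacks
#' the results, mirroring a per-window selection table.
#'
#' @inheritParams cooccur_contrast
#' @param ows numeric vector of window sizes (default
#'   `c(2, 5, 10, 15, 20, 30)`).
#' @return data.frame as for [cooccur_contrast()], all windows stacked.
#' @export
cooccur_scan <- function(events, clips, ows = c(2, 5, 10, 15, 20, 30),
                         intervention = c("transportation", "isolation"),
                         control = "baseline", alpha = 0.05,
                         p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  do.call(rbind, lapply(ows, function(o) {
    cooccur_contrast(events, clips, ows = o, intervention = intervention,
                     control = control, alpha = alpha, p_adjust = p_adjust)
  }))
}
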