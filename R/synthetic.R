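#' Build a synthetic study configuration
#'
#' Describes a simulated annotation + heart-rate study: which horses and
#' conditions exist, how many clips are scored per horse and condition,
#' per-code occurrence rates and duration laws, condition-dependent rate
#' multipliers, triggered onset couplings, the ear-flicker structure, and
#' the heart-rate model. The generator ([generate_study()]) draws each
#' code's occurrences from a Poisson process at its condition-adjusted
#' rate, with log-normal durations, and injects coupled responses and
#' spawned ear events on top of that null model.
#'
#' @param horses data.frame with columns `horse_id`, `group` (`PRI`/`UNI`).
#' @param conditions named list: conditions recorded per group.
#' @param clips_per_condition clips scored per horse and condition.
#' @param clip_length clip length in seconds.
#' @param first_clip_start,clip_spacing session-time placement of the
#'   clips (seconds); defaults leave a full five-minute heart-rate window
#'   around every clip.
#' @param codes data.frame with columns `code`, `base_rate` (expected
#'   occurrences per clip at baseline), `meanlog`, `sdlog` (log-normal
#'   duration law, seconds).
#' @param multipliers named list (by condition) of named numeric vectors:
#'   per-code rate multipliers; codes not listed keep multiplier 1.
#' @param ear_flicker list with `prob`: named per-condition probability
#'   that an EAD101 occurrence spawns an EAD104 within U(0, 1) s of its
#'   onset (the generative "ear flicker" structure).
#' @param couplings list of couplings, each a list with `trigger`,
#'   `response`, `prob`, `lag_mean`, `lag_sd` (seconds) and `conditions`
#'   (labels in which the coupling is active). Each trigger occurrence
#'   spawns, with probability `prob`, a response onset at
#'   `trigger onset + max(0.05, N(lag_mean, lag_sd))`.
#' @param hr heart-rate model: named vectors `baseline_mean` and
#'   `baseline_sd` (bpm, per group; each horse's resting rate is drawn
#'   once from this normal law), `shift` (named list by condition of named
#'   per-group bpm shifts), `rr_cv` (multiplicative R-R jitter,
#'   coefficient of variation) and `artifact_prob` (probability that a
#'   beat is recorded as a spurious short interval, 0.4 x the true one).
#' @return list of class `synth_config`.
#' @seealso [default_study_config()], [generate_study()]
#' @export
synth_config <- function(horses, conditions, clips_per_condition = 1,
                         clip_length = 30, first_clip_start = 300,
                         clip_spacing = 600, codes,
                         multipliers = list(),
                         ear_flicker = list(prob = c(baseline = 0,
                                                     transportation = 0,
                                                     isolation = 0)),
                         couplings = list(),
                         hr = list(baseline_mean = c(PRI = 54, UNI = 35),
                                   baseline_sd = c(PRI = 20, UNI = 4.4),
                                   shift = list(
                                     transportation = c(PRI = 23, UNI = 53),
                                     isolation = c(UNI = 30)),
                                   rr_cv = 0.05, artifact_prob = 0.02)) {
  cfg <- structure(list(
    horses = horses, conditions = conditions,
    clips_per_condition = clips_per_condition, clip_length = clip_length,
    first_clip_start = first_clip_start, clip_spacing = clip_spacing,
    codes = codes, multipliers = multipliers, ear_flicker = ear_flicker,
    couplings = couplings, hr = hr
  ), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

#' Validate a synthetic configuration
#'
#' @param config a [synth_config()] (or plain list with the same fields).
#' @return the config, invisibly; errors list every offending key.
#' @export
validate_synth_config <- function(config) {
  bad <- character(0)
  chk <- function(ok, key) if (!isTRUE(ok)) bad <<- c(bad, key)
  chk(is.data.frame(config$horses) &&
        all(c("horse_id", "group") %in% names(config$horses)) &&
        all(config$horses$group %in% study_groups()), "horses")
  chk(is.list(config$conditions) &&
        all(unlist(config$conditions) %in% study_conditions()), "conditions")
  chk(is.numeric(config$clips_per_condition) &&
        config$clips_per_condition >= 1, "clips_per_condition")
  chk(is.numeric(config$clip_length) && config$clip_length > 0, "clip_length")
  chk(is.data.frame(config$codes) &&
        all(c("code", "base_rate", "meanlog", "sdlog") %in%
              names(config$codes)) &&
        all(config$codes$base_rate >= 0) &&
        all(config$codes$sdlog >= 0), "codes")
  chk(all(unlist(config$multipliers) >= 0), "multipliers")
  pf <- config$ear_flicker$prob
  chk(is.numeric(pf) && all(pf >= 0 & pf <= 1), "ear_flicker.prob")
  for (cp in config$couplings) {
    chk(all(c("trigger", "response", "prob", "lag_mean", "lag_sd",
              "conditions") %in% names(cp)) &&
          cp$prob >= 0 && cp$prob <= 1 && cp$lag_sd >= 0, "couplings")
  }
  chk(is.numeric(config$hr$rr_cv) && config$hr$rr_cv >= 0, "hr.rr_cv")
  chk(is.numeric(config$hr$artifact_prob) &&
        config$hr$artifact_prob >= 0 && config$hr$artifact_prob <= 1,
      "hr.artifact_prob")
  if (length(bad)) {
    stop("invalid synthetic config key(s): ",
         paste(unique(bad), collapse = ", "))
  }
  invisible(config)
}

mult_for <- function(config, condition, code) {
  m <- config$multipliers[[condition]]
  if (is.null(m)) return(rep(1, length(code)))
  out <- unname(m[code])
  out[is.na(out)] <- 1
  out
}

#' Expected annotations per clip under a configuration
#'
#' Closed-form expectation of the number of coded events per clip for one
#' condition, accounting for the Poisson base processes, spawned
#' ear-flicker partners and coupling injections (both thinned by the
#' probability that the injected onset still falls inside the clip).
#'
#' @param config a [synth_config()].
#' @param condition condition label.
#' @return expected event count per clip.
#' @export
expected_annotations <- function(config, condition) {
  L <- config$clip_length
  rate <- config$codes$base_rate *
    mult_for(config, condition, config$codes$code)
  total <- sum(rate)
  pf <- config$ear_flicker$prob[[condition]]
  if (!is.null(pf) && pf > 0) {
    i101 <- match("EAD101", config$codes$code)
    if (!is.na(i101)) total <- total + pf * rate[i101] * (1 - 0.5 / L)
  }
  for (cp in config$couplings) {
    if (!(condition %in% cp$conditions)) next
    itr <- match(cp$trigger, config$codes$code)
    if (is.na(itr)) next
    total <- total + cp$prob * rate[itr] * max(0, 1 - cp$lag_mean / L)
  }
  total
}

#' Default study configuration
#'
#' The study design the package's simulations emulate: 28 horses -- 18
#' privately-owned (PRI, baseline + transportation) and 10 university
#' horses (UNI, baseline + transportation + isolation) -- one 30-s clip
#' per horse and condition, a facial-action vocabulary with blink- and
#' ear-dominated baseline activity, condition-dependent rate increases
#' concentrated on eye-white, nostril and mouth codes, an intervention
#' AU25 -> AD19 onset coupling, ear-flicker structure, and a heart-rate
#' model with group-specific resting rates and intervention shifts.
#'
#' Rates are calibrated (exactly, via [expected_annotations()]) so the
#' expected number of annotations per clip is 26 at baseline, 57 during
#' transportation and 38 during isolation.
#'
#' @param clips_per_condition clips per horse and condition (default 1).
#' @return a [synth_config()].
#' @export
default_study_config <- function(clips_per_condition = 1) {
  horses <- data.frame(
    horse_id = sprintf("H%02d", 1:28),
    group = rep(c("PRI", "UNI"), c(18, 10)),
    stringsAsFactors = FALSE
  )
  conditions <- list(PRI = c("baseline", "transportation"),
                     UNI = c("baseline", "transportation", "isolation"))
  codes <- data.frame(
    code      = c("AU145", "AU47", "AU143", "EAD101", "EAD104", "EAD103",
                  "AU101", "AD1", "AD38", "AU5", "AD19", "AU25", "AUH13",
                  "AU17", "AD133", "AD160", "AD81"),
    base_rate = c(5.0, 2.9, 0.6, 3.4, 3.2, 0.8,
                  2.1, 1.2, 2.2, 1.5, 0.5, 0.6, 0.5,
                  0.5, 0.3, 0.3, 0.4),
    meanlog   = log(c(0.4, 0.5, 0.8, 1.0, 1.0, 1.2,
                      1.5, 1.2, 1.0, 0.8, 0.6, 0.8, 0.8,
                      1.0, 0.8, 1.5, 1.0)),
    sdlog     = c(0.4, 0.4, 0.5, 0.6, 0.6, 0.6,
                  0.6, 0.6, 0.6, 0.6, 0.5, 0.5, 0.5,
                  0.6, 0.5, 0.6, 0.6),
    stringsAsFactors = FALSE
  )
  m_tr <- c(AU145 = 1.30, AU47 = 1.30, AU143 = 1.30, EAD101 = 1.70,
            EAD104 = 1.70, EAD103 = 1.40, AU101 = 1.50, AD1 = 2.10,
            AD38 = 2.00, AU5 = 1.90, AD19 = 2.50, AU25 = 2.50,
            AUH13 = 1.60, AU17 = 1.40, AD133 = 1.40, AD160 = 1.40,
            AD81 = 1.40)
  m_iso <- c(AU145 = 1.10, AU47 = 0.90, AU143 = 1.00, EAD101 = 1.20,
             EAD104 = 1.20, EAD103 = 1.20, AU101 = 1.80, AD1 = 1.90,
             AD38 = 1.90, AU5 = 1.00, AD19 = 2.20, AU25 = 2.20,
             AUH13 = 1.50, AU17 = 1.30, AD133 = 1.20, AD160 = 1.20,
             AD81 = 1.30)
  cfg <- synth_config(
    horses = horses, conditions = conditions,
    clips_per_condition = clips_per_condition,
    codes = codes,
    multipliers = list(transportation = m_tr, isolation = m_iso),
    ear_flicker = list(prob = c(baseline = 0.45, transportation = 0.55,
                                isolation = 0.50)),
    couplings = list(list(trigger = "AU25", response = "AD19", prob = 0.85,
                          lag_mean = 0.5, lag_sd = 0.15,
                          conditions = c("transportation", "isolation")))
  )
  # exact calibration to the target per-clip annotation means
  targets <- c(baseline = 26, transportation = 57, isolation = 38)
  cfg$codes$base_rate <- cfg$codes$base_rate *
    targets[["baseline"]] / expected_annotations(cfg, "baseline")
  for (cond in c("transportation", "isolation")) {
    beta <- targets[[cond]] / expected_annotations(cfg, cond)
    cfg$multipliers[[cond]] <- cfg$multipliers[[cond]] * beta
  }
  cfg
}

sim_clip_events <- function(config, condition, clip_start) {
  L <- config$clip_length
  codes <- config$codes
  rate <- codes$base_rate * mult_for(config, condition, codes$code)
  onsets <- numeric(0); durs <- numeric(0); labs <- character(0)
  for (i in seq_len(nrow(codes))) {
    n <- stats::rpois(1, rate[i])
    if (n == 0) next
    on <- stats::runif(n, 0, L)
    du <- stats::rlnorm(n, codes$meanlog[i], codes$sdlog[i])
    onsets <- c(onsets, on); durs <- c(durs, du)
    labs <- c(labs, rep(codes$code[i], n))
  }
  # ear-flicker structure: EAD101 spawns a nearby EAD104
  pf <- config$ear_flicker$prob[[condition]]
  if (!is.null(pf) && pf > 0) {
    i104 <- match("EAD104", codes$code)
    for (on in onsets[labs == "EAD101"]) {
      if (stats::runif(1) < pf) {
        on2 <- on + stats::runif(1, 0, 1)
        if (on2 <= L && !is.na(i104)) {
          onsets <- c(onsets, on2)
          durs <- c(durs, stats::rlnorm(1, codes$meanlog[i104],
                                        codes$sdlog[i104]))
          labs <- c(labs, "EAD104")
        }
      }
    }
  }
  # triggered couplings
  for (cp in config$couplings) {
    if (!(condition %in% cp$conditions)) next
    ir <- match(cp$response, codes$code)
    if (is.na(ir)) next
    for (on in onsets[labs == cp$trigger]) {
      if (stats::runif(1) < cp$prob) {
        on2 <- on + max(0.05, stats::rnorm(1, cp$lag_mean, cp$lag_sd))
        if (on2 <= L) {
          onsets <- c(onsets, on2)
          durs <- c(durs, stats::rlnorm(1, codes$meanlog[ir],
                                        codes$sdlog[ir]))
          labs <- c(labs, cp$response)
        }
      }
    }
  }
  if (!length(onsets)) {
    return(data.frame(code = character(0), onset = numeric(0),
                      offset = numeric(0), stringsAsFactors = FALSE))
  }
  data.frame(code = labs,
             onset = clip_start + onsets,
             offset = clip_start + pmin(onsets + durs, L),
             stringsAsFactors = FALSE)
}

sim_rr_session <- function(config, bpm, session_len) {
  rr <- numeric(0)
  total <- 0
  while (total < session_len) {
    n <- max(16L, ceiling((session_len - total) * bpm / 60 * 1.3))
    chunk <- 60000 / bpm * exp(stats::rnorm(n, 0, config$hr$rr_cv))
    art <- stats::runif(n) < config$hr$artifact_prob
    chunk[art] <- chunk[art] * 0.4
    rr <- c(rr, chunk)
    total <- sum(rr) / 1000
  }
  keep <- cumsum(rr) / 1000 <= session_len
  rr[keep]
}

#' Generate a synthetic study
#'
#' Draws a complete synthetic dataset -- annotation events, clip metadata
#' and per-session R-R interval series -- from a [synth_config()]. Output
#' is fully determined by `seed`.
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @param include_rr logical; set `FALSE` to skip the heart-rate series
#'   (faster for purely facial analyses).
#' @return object of class `synthetic_study`: list with `events`
#'   (data.frame `video_id,code,onset,offset`), `clips` (clip metadata
#'   data.frame), `rr` (named list of [rr_series()], one per horse and
#'   condition; empty when `include_rr = FALSE`), `config` and `seed`.
#' @export
generate_study <- function(config, seed = 1, include_rr = TRUE) {
  validate_synth_config(config)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  horses <- config$horses
  resting <- stats::setNames(
    stats::rnorm(nrow(horses),
                 unlist(config$hr$baseline_mean)[horses$group],
                 unlist(config$hr$baseline_sd)[horses$group]),
    horses$horse_id
  )
  resting <- pmax(resting, 24)  # physiological floor of equine resting HR
  clip_rows <- list(); event_rows <- list(); rr_list <- list()
  n_clips <- config$clips_per_condition
  session_len <- config$first_clip_start + (n_clips - 1) * config$clip_spacing +
    config$clip_length + 135 + 30
  for (h in seq_len(nrow(horses))) {
    hid <- horses$horse_id[h]
    grp <- horses$group[h]
    for (cond in config$conditions[[grp]]) {
      for (j in seq_len(n_clips)) {
        vid <- sprintf("%s_%s_%02d", hid, cond, j)
        cs <- config$first_clip_start + (j - 1) * config$clip_spacing
        clip_rows[[vid]] <- data.frame(
          video_id = vid, horse_id = hid, group = grp, condition = cond,
          clip_start = cs, clip_length = config$clip_length,
          stringsAsFactors = FALSE
        )
        ev <- sim_clip_events(config, cond, cs)
        if (nrow(ev)) {
          ev <- cbind(video_id = vid, ev, stringsAsFactors = FALSE)
          event_rows[[vid]] <- ev
        }
      }
      if (include_rr) {
        shift <- config$hr$shift[[cond]]
        bpm <- resting[[hid]] +
          if (!is.null(shift) && grp %in% names(shift)) shift[[grp]] else 0
        sid <- paste(hid, cond, sep = "_")
        rr_list[[sid]] <- rr_series(
          sim_rr_session(config, bpm, session_len),
          session_id = sid, horse_id = hid, condition = cond
        )
      }
    }
  }
  events <- if (length(event_rows)) {
    do.call(rbind, event_rows)
  } else {
    data.frame(video_id = character(0), code = character(0),
               onset = numeric(0), offset = numeric(0),
               stringsAsFactors = FALSE)
  }
  events <- events[order(events$video_id, events$onset), , drop = FALSE]
  rownames(events) <- NULL
  clips <- do.call(rbind, clip_rows)
  rownames(clips) <- NULL
  structure(list(events = events, clips = clips, rr = rr_list,
                 config = config, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic study: %d horses, %d clips, %d events, %d R-R sessions (seed %d)\n",
              nrow(x$config$horses), nrow(x$clips), nrow(x$events),
              length(x$rr), x$seed))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes `events.csv`, `clips.csv` and one Polar-style `.hrm` file per
#' session under `dir/rr/`.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "rr"), recursive = TRUE, showWarnings = FALSE)
  write_events(study$events, file.path(dir, "events.csv"))
  write_clips(study$clips, file.path(dir, "clips.csv"))
  for (s in study$rr) {
    write_rr(s, file.path(dir, "rr", paste0(s$session_id, ".hrm")))
  }
  invisible(dir)
}

#' Simulate a second coder's annotations
#'
#' Produces a plausibly disagreeing re-annotation of an event table for
#' inter-rater agreement studies: each event is independently missed with
#' probability `drop_prob`, kept events get Gaussian onset/offset jitter,
#' and spurious extra events (codes and durations resampled from the
#' clip's own annotations, onsets uniform in the clip) are added at
#' `add_rate` times the clip's event count.
#'
#' @param events event data.frame (one coder's annotations).
#' @param clips clip metadata.
#' @param drop_prob probability a true event is missed.
#' @param add_rate expected spurious events per true event.
#' @param jitter_sd standard deviation of boundary jitter (seconds).
#' @return event data.frame in the same format.
#' @export
simulate_second_coder <- function(events, clips, drop_prob = 0.3,
                                  add_rate = 0.2, jitter_sd = 0.15) {
  keep <- stats::runif(nrow(events)) >= drop_prob
  out <- events[keep, , drop = FALSE]
  out$onset <- pmax(0, out$onset + stats::rnorm(nrow(out), 0, jitter_sd))
  out$offset <- pmax(out$onset,
                     out$offset + stats::rnorm(nrow(out), 0, jitter_sd))
  extra <- list()
  for (i in seq_len(nrow(clips))) {
    vid <- clips$video_id[i]
    ev <- events[events$video_id == vid, , drop = FALSE]
    if (!nrow(ev)) next
    n_add <- stats::rpois(1, add_rate * nrow(ev))
    if (n_add == 0) next
    pick <- sample.int(nrow(ev), n_add, replace = TRUE)
    on <- stats::runif(n_add, clips$clip_start[i],
                       clips$clip_start[i] + clips$clip_length[i])
    extra[[vid]] <- data.frame(
      video_id = vid, code = ev$code[pick], onset = on,
      offset = on + (ev$offset[pick] - ev$onset[pick]),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(out, do.call(rbind, extra))
  out <- out[order(out$video_id, out$onset), , drop = FALSE]
  rownames(out) <- NULL
  out
}
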