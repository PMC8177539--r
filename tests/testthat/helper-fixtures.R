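# small constructors used throughout the suite

ev_tab <- function(video_id, code, onset, offset) {
  data.frame(video_id = video_id, code = code, onset = onset,
             offset = offset, stringsAsFactors = FALSE)
}

clip_tab <- function(video_id, horse_id, condition, group = "PRI",
                     clip_start = 0, clip_length = 30) {
  data.frame(video_id = video_id, horse_id = horse_id, group = group,
             condition = condition, clip_start = clip_start,
             clip_length = clip_length, stringsAsFactors = FALSE)
}

rand_clip_events <- function(n, codes, clip_length = 30, video_id = "v") {
  on <- sort(round(runif(n, 0, clip_length), 3))
  du <- round(rexp(n, 1), 3)
  ev_tab(video_id, sample(codes, n, replace = TRUE), on,
         pmin(on + du, clip_length))
}

pri_horses <- function(n) {
  data.frame(horse_id = sprintf("P%02d", seq_len(n)), group = "PRI",
             stringsAsFactors = FALSE)
}

uni_horses <- function(n) {
  data.frame(horse_id = sprintf("U%02d", seq_len(n)), group = "UNI",
             stringsAsFactors = FALSE)
}

flat_flicker <- function(p = 0.45) {
  list(prob = c(baseline = p, transportation = p, isolation = p))
}

# two-condition null design: identical generative law in both pools
null_study_config <- function(n_horses = 10, clips_per_condition = 2) {
  synth_config(
    horses = pri_horses(n_horses),
    conditions = list(PRI = c("baseline", "transportation")),
    clips_per_condition = clips_per_condition,
    codes = default_study_config()$codes,
    ear_flicker = flat_flicker()
  )
}

# positive control for frequency-based selection: one code's rate doubled
doubled_rate_config <- function(code = "AD38", n_horses = 10,
                                clips_per_condition = 2) {
  m <- stats::setNames(2, code)
  synth_config(
    horses = pri_horses(n_horses),
    conditions = list(PRI = c("baseline", "transportation")),
    clips_per_condition = clips_per_condition,
    codes = default_study_config()$codes,
    multipliers = list(transportation = m),
    ear_flicker = flat_flicker()
  )
}

# positive control for the co-occurrence contrast: an AU25 -> AD19 onset
# coupling planted in the intervention condition only
coupling_config <- function(n_horses = 20, clips_per_condition = 6,
                            prob = 0.95) {
  codes <- default_study_config()$codes
  codes$base_rate[codes$code == "AU25"] <- 3.0
  synth_config(
    horses = pri_horses(n_horses),
    conditions = list(PRI = c("baseline", "transportation")),
    clips_per_condition = clips_per_condition,
    codes = codes,
    ear_flicker = flat_flicker(),
    couplings = list(list(trigger = "AU25", response = "AD19", prob = prob,
                          lag_mean = 0.5, lag_sd = 0.15,
                          conditions = "transportation"))
  )
}
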