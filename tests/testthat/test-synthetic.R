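test_that("generation is deterministic under a fixed seed", {
  cfg <- null_study_config(n_horses = 3, clips_per_condition = 1)
  a <- generate_study(cfg, seed = 7)
  b <- generate_study(cfg, seed = 7)
  expect_identical(a$events, b$events)
  expect_identical(a$clips, b$clips)
  expect_identical(lapply(a$rr, `[[`, "rr"), lapply(b$rr, `[[`, "rr"))
  c <- generate_study(cfg, seed = 8)
  expect_false(identical(a$events, c$events))

  # byte-for-byte determinism on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(a, d1); write_study(b, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("zero rates produce an empty but valid event table", {
  cfg <- null_study_config(n_horses = 2, clips_per_condition = 1)
  cfg$codes$base_rate[] <- 0
  cfg$ear_flicker$prob[] <- 0
  st <- generate_study(cfg, seed = 1, include_rr = FALSE)
  expect_equal(nrow(st$events), 0L)
  d <- withr::local_tempdir()
  write_study(st, d)
  expect_equal(readLines(file.path(d, "events.csv")),
               "video_id,code,onset,offset")
  expect_equal(nrow(read_events(file.path(d, "events.csv"))), 0L)
})

test_that("generated events validate against the vocabulary and clips", {
  st <- generate_study(default_study_config(), seed = 3, include_rr = FALSE)
  expect_silent(validate_events(st$events))
  expect_silent(validate_clips(st$clips))
  expect_true(check_events_clips(st$events, st$clips))
  expect_true(all(st$events$offset >= st$events$onset))
  # events stay within their clip
  cs <- st$clips$clip_start[match(st$events$video_id, st$clips$video_id)]
  cl <- st$clips$clip_length[match(st$events$video_id, st$clips$video_id)]
  expect_true(all(st$events$onset >= cs & st$events$offset <= cs + cl))
})

test_that("a doubled rate shows up as an empirical rate ratio near 2", {
  cfg <- doubled_rate_config(n_horses = 5, clips_per_condition = 100)
  st <- generate_study(cfg, seed = 5, include_rr = FALSE)
  cond <- st$clips$condition[match(st$events$video_id, st$clips$video_id)]
  n_int <- sum(st$events$code == "AD38" & cond == "transportation")
  n_ctl <- sum(st$events$code == "AD38" & cond == "baseline")
  ratio <- n_int / n_ctl  # equal numbers of clips per pool
  se <- ratio * sqrt(1 / n_int + 1 / n_ctl)  # Poisson, delta method
  expect_lt(abs(ratio - 2), 3 * se)
})

test_that("expected annotation counts are calibrated exactly", {
  cfg <- default_study_config()
  expect_equal(expected_annotations(cfg, "baseline"), 26)
  expect_equal(expected_annotations(cfg, "transportation"), 57)
  expect_equal(expected_annotations(cfg, "isolation"), 38)
})

test_that("invalid configurations name the offending keys", {
  cfg <- null_study_config(n_horses = 2)
  bad <- cfg
  bad$codes$base_rate[1] <- -1
  expect_error(validate_synth_config(bad), "codes")
  bad <- cfg
  bad$ear_flicker$prob[1] <- 1.5
  expect_error(validate_synth_config(bad), "ear_flicker.prob")
  bad <- cfg
  bad$hr$artifact_prob <- -0.1
  expect_error(validate_synth_config(bad), "artifact_prob")
  bad <- cfg
  bad$horses$group[1] <- "ZOO"
  expect_error(validate_synth_config(bad), "horses")
})

test_that("configurations round-trip through YAML", {
  cfg <- default_study_config()
  f1 <- withr::local_tempfile(fileext = ".yaml")
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_synth_config(cfg, f1)
  back <- read_synth_config(f1)
  write_synth_config(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  # the reconstructed config generates the same data (YAML stores numbers
  # at 15 significant digits, so equality is up to that precision)
  ev1 <- generate_study(cfg, seed = 4, include_rr = FALSE)$events
  ev2 <- generate_study(back, seed = 4, include_rr = FALSE)$events
  expect_identical(ev1[c("video_id", "code")], ev2[c("video_id", "code")])
  expect_equal(ev1$onset, ev2$onset, tolerance = 1e-9)
  expect_equal(ev1$offset, ev2$offset, tolerance = 1e-9)
})

test_that("the synthetic pipeline closes end-to-end at defaults", {
  st <- generate_study(default_study_config(), seed = 2)
  ev <- apply_ear_flicker(drop_unscorable(st$events))
  sel <- hfi_select(occurrence_table(ev, st$clips))
  expect_gt(nrow(sel), 0)
  cc <- cooccur_contrast(ev, st$clips, ows = 2)
  expect_true(any(cc$significant))
  summ <- summarize_clips(st$events, st$clips)
  ft <- build_features(summ, st$clips, setdiff(sel$code, fmi_code()))
  rep <- suppressWarnings(loo_evaluate(ft, seed = 1))
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 100)
  w <- hr_windows(st$rr, st$clips)
  expect_true(all(w$mean_hr > 20 & w$mean_hr < 250))
  ht <- hr_tests(w)
  expect_equal(nrow(ht), 3)
})

test_that("a simulated second coder yields intermediate agreement", {
  st <- generate_study(default_study_config(), seed = 6, include_rr = FALSE)
  set.seed(60)
  coder2 <- simulate_second_coder(st$events, st$clips)
  r <- wexler_agreement(st$events, coder2)
  expect_gt(r, 0.5)
  expect_lt(r, 0.95)
})
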