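test_that("per-clip summaries count and take maxima over the grid", {
  cl <- clip_tab("c1", "h1", "baseline")
  ev <- ev_tab("c1", "AD19", c(1, 5), c(2, 8))
  s <- summarize_clips(ev, cl)
  expect_equal(s$frequency, 2L)
  expect_equal(s$max_duration, 3.0)

  # empty clip: all-zero rows over the requested vocabulary
  s0 <- summarize_clips(ev[0, ], cl, vocabulary = c("AD19", "AD38"))
  expect_equal(nrow(s0), 2L)
  expect_equal(s0$frequency, c(0L, 0L))
  expect_equal(s0$max_duration, c(0, 0))
})

test_that("summaries match a brute-force groupby oracle", {
  set.seed(61)
  cl <- clip_tab(c("a", "b", "c"), "h1", "baseline")
  ev <- do.call(rbind, lapply(cl$video_id, function(v) {
    rand_clip_events(rpois(1, 12), c("AD1", "AD38", "AU145"), video_id = v)
  }))
  s <- summarize_clips(ev, cl)
  for (i in seq_len(nrow(s))) {
    sub <- ev[ev$video_id == s$video_id[i] & ev$code == s$code[i], ]
    expect_equal(s$frequency[i], nrow(sub))
    expect_equal(s$max_duration[i],
                 if (nrow(sub)) max(sub$offset - sub$onset) else 0)
  }
  # invariant: positive duration implies at least one occurrence
  expect_true(all(s$frequency[s$max_duration > 0] >= 1))
})

paired_design <- function(values_int, values_ctl, code = "AD38") {
  n <- length(values_int)
  horses <- sprintf("h%d", seq_len(n))
  cl <- rbind(clip_tab(paste0(horses, "_t"), horses, "transportation"),
              clip_tab(paste0(horses, "_b"), horses, "baseline"))
  summ <- rbind(
    data.frame(video_id = paste0(horses, "_t"), code = code,
               frequency = values_int, max_duration = values_int,
               stringsAsFactors = FALSE),
    data.frame(video_id = paste0(horses, "_b"), code = code,
               frequency = values_ctl, max_duration = values_ctl,
               stringsAsFactors = FALSE)
  )
  list(summ = summ, cl = cl)
}

test_that("identical per-horse values give p = 1", {
  fx <- paired_design(c(2, 3, 4), c(2, 3, 4))
  res <- paired_tests(fx$summ, fx$cl, intervention = "transportation")
  expect_equal(res$p, rep(1, nrow(res)))
  expect_equal(res$stars, rep("", nrow(res)))
})

test_that("six uniform-sign pairs give the exact signed-rank p of 2/64", {
  fx <- paired_design(c(2, 3, 4, 5, 6, 7), rep(1, 6))
  res <- paired_tests(fx$summ, fx$cl, intervention = "transportation",
                      measures = "frequency")
  expect_equal(res$p, 2 * (1 / 64))
  expect_equal(res$stars, "*")
})

test_that("significance bands fall at 0.05, 0.01 and 0.001", {
  p <- c(0.2, 0.049, 0.009, 0.0009)
  expect_equal(equifacs:::p_stars(p), c("", "*", "**", "***"))
})

test_that("paired_tests are invariant to horse relabeling", {
  set.seed(62)
  fx <- paired_design(rpois(8, 6) + 0.5, rpois(8, 3) + 0.2)
  res1 <- paired_tests(fx$summ, fx$cl, intervention = "transportation")
  # permute horse identities consistently
  perm <- sample(8)
  map <- setNames(sprintf("h%d", perm), sprintf("h%d", 1:8))
  cl2 <- fx$cl; cl2$horse_id <- unname(map[cl2$horse_id])
  res2 <- paired_tests(fx$summ, cl2, intervention = "transportation")
  expect_equal(res1$p, res2$p)
})

test_that("a doubled-rate code is flagged at p < 0.01 in most seeds", {
  hits <- vapply(1:20, function(s) {
    st <- generate_study(doubled_rate_config(n_horses = 20,
                                             clips_per_condition = 2),
                         seed = s, include_rr = FALSE)
    summ <- summarize_clips(st$events, st$clips)
    res <- paired_tests(summ, st$clips, intervention = "transportation",
                        measures = "frequency")
    res$p[res$code == "AD38"] < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Wexler agreement matches hand-computed ratios", {
  a <- ev_tab("v", c("AU101", "AU145"), c(0, 2), c(1, 3))
  expect_equal(wexler_agreement(a, a), 1.0)

  b <- ev_tab("v", c("AD38", "AD19"), c(0, 2), c(1, 3))
  expect_equal(wexler_agreement(a, b), 0.0)

  b2 <- ev_tab("v", c("AU101", "AD38"), c(0.5, 2), c(1.5, 3))
  expect_equal(wexler_agreement(a, b2), 0.5)  # one match out of four events

  expect_equal(wexler_agreement(a[0, ], b[0, ]), 1.0)  # vacuous agreement
})

test_that("agreement is symmetric and penalises unmatched extras", {
  set.seed(63)
  for (rep in 1:20) {
    a <- rand_clip_events(rpois(1, 10) + 1, c("AD38", "AU145", "AU101"))
    b <- rand_clip_events(rpois(1, 10) + 1, c("AD38", "AU145", "AU101"))
    expect_equal(wexler_agreement(a, b), wexler_agreement(b, a))
  }
  a <- ev_tab("v", "AD38", c(0, 10), c(1, 11))
  with_extra <- rbind(a, ev_tab("v", "AU145", 20, 21))
  expect_lt(wexler_agreement(a, with_extra), wexler_agreement(a, a))
})

test_that("Holm adjustment follows the max-step rule and is monotone", {
  expect_equal(holm_adjust(c(0.004, 0.008)), c(0.008, 0.008))
  set.seed(64)
  p <- runif(6, 0, 0.2)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))  # ordering preserved
})
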