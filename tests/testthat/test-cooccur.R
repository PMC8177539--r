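# literal O(n^2) pair-scan oracle for the adjacency counts
adjacency_oracle <- function(events, ows) {
  codes <- sort(unique(events$code))
  w <- matrix(0L, length(codes), length(codes),
              dimnames = list(codes, codes))
  n <- nrow(events)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dt <- events$onset[j] - events$onset[i]
      if (dt >= 0 && dt <= ows && events$code[i] != events$code[j]) {
        w[events$code[i], events$code[j]] <-
          w[events$code[i], events$code[j]] + 1L
      }
    }
  }
  w
}

test_that("edge counting follows the windowed ordered-pair definition", {
  expect_equal(sum(build_graph(ev_tab("c", "AD38", 1, 2), ows = 2)$w), 0)

  ev <- ev_tab("c", c("AU25", "AD19"), c(0, 1), c(0.5, 1.5))
  g <- build_graph(ev, ows = 2)
  expect_equal(g$w["AU25", "AD19"], 1L)
  expect_equal(g$w["AD19", "AU25"], 0L)

  # simultaneous onsets count in both directions; no self-edges
  ev <- ev_tab("c", c("A", "B", "A"), c(1, 1, 1.5), c(2, 2, 2))
  g <- build_graph(ev, ows = 2)
  # A@1 <-> B@1 simultaneous (1 each way); B@1 -> A@1.5 ordered
  expect_equal(g$w["A", "B"], 1L)
  expect_equal(g$w["B", "A"], 2L)
  expect_equal(g$w["A", "A"], 0L)

  expect_error(build_graph(ev, ows = 0), "positive")
})

test_that("adjacency equals the exhaustive pair-scan oracle", {
  set.seed(51)
  for (rep in 1:25) {
    ev <- rand_clip_events(20, c("AD1", "AD19", "AD38", "AU25", "AU145"))
    ows <- sample(c(2, 5, 10), 1)
    expect_identical(build_graph(ev, ows)$w, adjacency_oracle(ev, ows))
  }
})

test_that("code_profile is the degree sum per minute", {
  ev <- ev_tab("c", c("AU25", "AD19"), c(0, 1), c(0.5, 1.5))
  g <- build_graph(ev, ows = 2, clip_length = 30)
  expect_equal(code_profile(g), c(AD19 = 2, AU25 = 2))

  g0 <- build_graph(ev_tab("c", "AD38", 1, 2), ows = 2)
  expect_equal(unname(code_profile(g0)), 0)

  set.seed(52)
  ev <- rand_clip_events(25, c("A", "B", "C"))
  g <- suppressWarnings(build_graph(ev, ows = 5, clip_length = 30))
  expect_equal(code_profile(g),
               (rowSums(g$w) + colSums(g$w)) / 0.5)
})

test_that("edge weights and profiles are monotone in the window size", {
  set.seed(53)
  ev <- rand_clip_events(30, c("AD1", "AD19", "AD38", "AU25"))
  prev <- build_graph(ev, 2)
  for (ows in c(5, 10, 15, 20, 30)) {
    cur <- build_graph(ev, ows)
    expect_true(all(cur$w >= prev$w))
    expect_true(all(code_profile(cur) >= code_profile(prev)))
    prev <- cur
  }
})

test_that("graph building is invariant to event input order", {
  set.seed(54)
  ev <- rand_clip_events(25, c("AD1", "AD38", "AU145"))
  shuf <- ev[sample(nrow(ev)), ]
  expect_identical(build_graph(ev, 5)$w, build_graph(shuf, 5)$w)
})

contrast_fixture <- function() {
  # two horses, one clip per condition each, hand-sized event streams
  cl <- rbind(clip_tab(c("h1b", "h1t"), "h1", c("baseline", "transportation")),
              clip_tab(c("h2b", "h2t"), "h2", c("baseline", "transportation")))
  ev <- rbind(
    ev_tab("h1t", c("AU25", "AD19", "AU25", "AD19"), c(0, 0.5, 5, 5.6),
           c(1, 1, 6, 6)),
    ev_tab("h1b", c("AU25", "AD19"), c(0, 20), c(1, 21)),
    ev_tab("h2t", c("AU25", "AD19", "AD19"), c(2, 2.4, 9), c(3, 3, 10)),
    ev_tab("h2b", c("AU25", "AD19"), c(4, 25), c(5, 26))
  )
  list(ev = ev, cl = cl)
}

test_that("identical condition streams give zero scores and no selection", {
  cl <- rbind(clip_tab(c("h1b", "h1t"), "h1", c("baseline", "transportation")),
              clip_tab(c("h2b", "h2t"), "h2", c("baseline", "transportation")))
  base <- ev_tab("x", c("AU25", "AD19", "AD38"), c(0, 1, 5), c(1, 2, 6))
  ev <- do.call(rbind, lapply(cl$video_id, function(v) {
    e <- base; e$video_id <- v; e
  }))
  res <- cooccur_contrast(ev, cl, ows = 2, intervention = "transportation")
  expect_equal(res$score, rep(0, nrow(res)))
  expect_false(any(res$selected))
  expect_equal(res$p, rep(1, nrow(res)))
})

test_that("two-horse contrast matches the closed-form paired t-test", {
  fx <- contrast_fixture()
  res <- cooccur_contrast(fx$ev, fx$cl, ows = 2,
                          intervention = "transportation")
  # per-horse profile differences computed from first principles
  d <- vapply(c("h1", "h2"), function(h) {
    pt <- code_profile(build_graph(fx$ev[fx$ev$video_id == paste0(h, "t"), ], 2))
    pb <- code_profile(build_graph(fx$ev[fx$ev$video_id == paste0(h, "b"), ], 2))
    get0 <- function(v, nm) if (nm %in% names(v)) v[[nm]] else 0
    get0(pt, "AD19") - get0(pb, "AD19")
  }, numeric(1))
  tstat <- mean(d) / (sd(d) / sqrt(2))
  p_closed <- 2 * pt(-abs(tstat), df = 1)
  expect_equal(res$score[res$code == "AD19"], mean(d))
  expect_equal(res$p[res$code == "AD19"], p_closed, tolerance = 1e-12)
})

test_that("swapping condition labels negates scores, keeps p-values", {
  fx <- contrast_fixture()
  a <- cooccur_contrast(fx$ev, fx$cl, ows = 2,
                        intervention = "transportation",
                        control = "baseline")
  b <- cooccur_contrast(fx$ev, fx$cl, ows = 2, intervention = "baseline",
                        control = "transportation")
  b <- b[match(a$code, b$code), ]
  expect_equal(b$score, -a$score)
  expect_equal(b$p, a$p)
})

test_that("degenerate designs are rejected or trimmed with a warning", {
  fx <- contrast_fixture()
  one_horse <- fx$cl[fx$cl$horse_id == "h1", ]
  expect_error(
    cooccur_contrast(fx$ev[fx$ev$video_id %in% one_horse$video_id, ],
                     one_horse, ows = 2, intervention = "transportation"),
    ">= 2 horses")
  # a horse lacking the control condition is dropped with a warning
  cl3 <- rbind(fx$cl, clip_tab("h3t", "h3", "transportation"))
  ev3 <- rbind(fx$ev, ev_tab("h3t", c("AU25", "AD19"), c(0, 1), c(1, 2)))
  expect_warning(res <- cooccur_contrast(ev3, cl3, ows = 2,
                                         intervention = "transportation"),
                 "h3")
  expect_equal(res, cooccur_contrast(fx$ev, fx$cl, ows = 2,
                                     intervention = "transportation"))
})

test_that("cooccur_scan stacks one contrast per window size", {
  fx <- contrast_fixture()
  res <- cooccur_scan(fx$ev, fx$cl, ows = c(2, 5),
                      intervention = "transportation")
  expect_equal(sort(unique(res$ows)), c(2, 5))
  expect_equal(res[res$ows == 2, ],
               cooccur_contrast(fx$ev, fx$cl, 2,
                                intervention = "transportation"),
               ignore_attr = TRUE)
})
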