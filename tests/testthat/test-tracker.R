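test_that("simple frame pairs link as expected", {
  a <- data.frame(spot_id = 1:2, x_um = c(0, 50), y_um = c(0, 0))
  b <- data.frame(spot_id = 1:2, x_um = c(1, 51), y_um = c(0, 0))
  l <- link_frame_pair(a, b, d_max = 15)
  expect_equal(l$from, 1:2)
  expect_equal(l$to, 1:2)
  # a 20 um jump exceeds the zoospore linking distance
  a1 <- data.frame(spot_id = 1, x_um = 0, y_um = 0)
  b1 <- data.frame(spot_id = 1, x_um = 20, y_um = 0)
  expect_equal(nrow(link_frame_pair(a1, b1, d_max = 15)), 0)
  expect_error(link_frame_pair(a, b, d_max = 0), "positive")
})

test_that("greedy matching is near-optimal and exact when spots are sparse", {
  set.seed(19)
  for (case in 1:50) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    d_max <- 15
    a <- data.frame(spot_id = seq_len(n1),
                    x_um = runif(n1, 0, 100), y_um = runif(n1, 0, 100))
    b <- data.frame(spot_id = seq_len(n2),
                    x_um = runif(n2, 0, 100), y_um = runif(n2, 0, 100))
    greedy <- link_frame_pair(a, b, d_max)
    oracle <- exhaustive_links(a, b, d_max)
    # a maximal matching is at least half the maximum matching
    expect_gte(nrow(greedy), ceiling(nrow(oracle) / 2))
    if (nrow(oracle) > 0 && nrow(greedy) == nrow(oracle))
      expect_lte(sum(greedy$dist), 1.10 *
                   sum(sqrt((a$x_um[oracle$from] - b$x_um[oracle$to])^2 +
                              (a$y_um[oracle$from] - b$y_um[oracle$to])^2)))
  }
  # well-separated spots: greedy and exhaustive links are identical
  for (case in 1:20) {
    ctr <- expand.grid(x = c(0, 80, 160), y = c(0, 80, 160)) # > 2*d_max
    n <- sample(2:6, 1)
    pick <- sample(nrow(ctr), n)
    a <- data.frame(spot_id = seq_len(n), x_um = ctr$x[pick],
                    y_um = ctr$y[pick])
    b <- data.frame(spot_id = seq_len(n),
                    x_um = ctr$x[pick] + runif(n, -5, 5),
                    y_um = ctr$y[pick] + runif(n, -5, 5))
    g <- link_frame_pair(a, b, 15)
    o <- exhaustive_links(a, b, 15)
    expect_equal(g[order(g$from), c("from", "to")],
                 o[order(o$from), c("from", "to")], ignore_attr = TRUE)
  }
})

test_that("tracks chain across consecutive frames only", {
  stationary <- data.frame(frame = 1:10, spot_id = 1, x_um = 5, y_um = 5,
                           species = "zoospore")
  tr <- build_tracks(stationary, d_max = 15)
  expect_equal(length(unique(tr$track_id)), 1)
  m <- track_metrics(tr, dt = 0.0735)
  expect_equal(m$n_links, 9)
  expect_equal(m$net_um, 0)
  # a missing frame breaks the chain (no gap closing)
  gap <- stationary[stationary$frame != 5, ]
  tg <- build_tracks(gap, d_max = 15)
  expect_equal(length(unique(tg$track_id)), 2)
})

test_that("no spot is ever assigned to two tracks", {
  set.seed(8)
  for (case in 1:5) {
    n <- 15
    spots <- do.call(rbind, lapply(1:12, function(f)
      data.frame(frame = f, spot_id = seq_len(n),
                 x_um = runif(n, 0, 60), y_um = runif(n, 0, 60),
                 species = "zoospore")))
    tr <- build_tracks(spots, d_max = 10)
    expect_equal(anyDuplicated(tr[c("frame", "spot_id")]), 0)
    expect_equal(nrow(tr), nrow(spots)) # every spot lands in one track
    # within a track: strictly consecutive frames, steps <= d_max
    for (id in unique(tr$track_id)) {
      t1 <- tr[tr$track_id == id, ]
      if (nrow(t1) > 1) {
        expect_true(all(diff(t1$frame) == 1))
        expect_true(all(sqrt(diff(t1$x_um)^2 + diff(t1$y_um)^2) <= 10))
      }
    }
  }
})

test_that("tracking is deterministic and validates its input", {
  set.seed(4)
  spots <- do.call(rbind, lapply(1:5, function(f)
    data.frame(frame = f, spot_id = 1:8, x_um = runif(8, 0, 30),
               y_um = runif(8, 0, 30), species = "bacterium")))
  t1 <- build_tracks(spots, d_max = 5)
  t2 <- build_tracks(spots[sample(nrow(spots)), ], d_max = 5)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  dup <- rbind(spots, spots[1, ])
  expect_error(build_tracks(dup, d_max = 5), "duplicate")
  empty <- spots[0, ]
  expect_equal(nrow(build_tracks(empty, d_max = 5, species = "bacterium")),
               0)
})

test_that("the tracker recovers nearly all detectable ground-truth links", {
  ss <- scene_small()
  lr <- evaluate_link_recovery(ss$scene, ss$tracks)
  expect_gt(lr$zoospore$recovery, 0.95)
  expect_gt(lr$bacterium$recovery, 0.95)
})
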