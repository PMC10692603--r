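track_df <- function(x, y, species = "zoospore", id = 1) {
  data.frame(track_id = id, frame = seq_along(x), x_um = x, y_um = y,
             species = species)
}

test_that("closed forms: straight runs, loops, and the L-shaped path", {
  # constant velocity along y: 7.35 um per 0.0735 s frame = 100 um/s
  m <- track_metrics(track_df(c(0, 0, 0), c(0, 7.35, 14.7)), dt = 0.0735)
  expect_equal(m$mean_speed_ums, 100)
  expect_equal(m$confinement_ratio, 1)
  # square loop returns to the start
  sq <- track_metrics(track_df(c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0)),
                      dt = 0.0735)
  expect_equal(sq$net_um, 0)
  expect_equal(sq$confinement_ratio, 0)
  # L-shaped path
  L <- track_metrics(track_df(c(0, 10, 10), c(0, 0, 10)), dt = 0.0735)
  expect_equal(L$total_um, 20)
  expect_equal(L$net_um, 10 * sqrt(2))
  expect_equal(L$confinement_ratio, sqrt(2) / 2, tolerance = 1e-12)
})

test_that("confinement ratio is bounded by 1, reaching it only when straight", {
  set.seed(12)
  for (i in 1:30) {
    n <- sample(3:20, 1)
    m <- track_metrics(track_df(cumsum(rnorm(n)), cumsum(rnorm(n))),
                       dt = 0.0735)
    expect_gte(m$confinement_ratio, 0)
    expect_lte(m$confinement_ratio, 1)
  }
  # collinear monotone path attains exactly 1
  col <- track_metrics(track_df(c(1, 3, 7, 9), c(2, 6, 14, 18)),
                       dt = 0.0735)
  expect_equal(col$confinement_ratio, 1)
})

test_that("mean speed is invariant under rigid motions of the track", {
  set.seed(5)
  x <- cumsum(runif(10, -3, 3)); y <- cumsum(runif(10, -3, 3))
  base <- track_metrics(track_df(x, y), dt = 0.0735)
  th <- 1.1
  rx <- 40 + x * cos(th) - y * sin(th)
  ry <- -7 + x * sin(th) + y * cos(th)
  rot <- track_metrics(track_df(rx, ry), dt = 0.0735)
  expect_equal(rot$mean_speed_ums, base$mean_speed_ums)
  expect_equal(rot$confinement_ratio, base$confinement_ratio)
})

test_that("singleton tracks are excluded but counted", {
  df <- rbind(track_df(c(0, 1, 2), c(0, 0, 0), id = 1),
              data.frame(track_id = 2, frame = 4, x_um = 9, y_um = 9,
                         species = "zoospore"))
  m <- track_metrics(df, dt = 0.0735)
  expect_equal(nrow(m), 1)
  expect_equal(attr(m, "n_singletons"), 1L)
  # degenerate zero-path track gets ratio 0, not NaN
  still <- track_metrics(track_df(c(5, 5, 5), c(5, 5, 5)), dt = 0.0735)
  expect_equal(still$confinement_ratio, 0)
  expect_equal(still$mean_speed_ums, 0)
})

test_that("motility classes follow the species speed dichotomies", {
  mk <- function(species, speed)
    data.frame(species = species, mean_speed_ums = speed)
  expect_equal(classify_motility(mk("zoospore", 5)), "non_motile")
  expect_equal(classify_motility(mk("zoospore", 50)), "motile")
  expect_equal(classify_motility(mk("vorticella", 500)), "telotroch")
  expect_equal(classify_motility(mk("vorticella", 5)), "sessile")
  # boundary: strict < on the slow side
  expect_equal(classify_motility(mk("vorticella", 20)), "telotroch")
  expect_equal(classify_motility(mk("zoospore", 10)), "motile")
  expect_equal(classify_motility(mk("bacterium", 3)), "bacterium")
  expect_error(classify_motility(mk("amoeba", 1)), "unknown species")
})

test_that("an encysting subpopulation makes zoospore speeds bimodal", {
  ss <- scene_default()
  m <- track_metrics(ss$tracks$zoospore, dt = ss$cfg$frame_interval)
  m <- m[m$n_links >= 5, ]
  slow <- mean(m$mean_speed_ums < 10)
  fast <- mean(m$mean_speed_ums > 100)
  mid <- mean(m$mean_speed_ums >= 10 & m$mean_speed_ums <= 100)
  expect_gt(slow, 0.05) # encysted / non-motile mode
  expect_gt(fast, 0.3) # swimming mode at the configured speeds
  expect_lt(mid, min(slow, fast)) # trough between the modes
})
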