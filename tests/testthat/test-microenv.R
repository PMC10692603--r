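test_that("grid labels follow the letter-row / number-column convention", {
  g <- grid_spec(170, 1000, 800)
  expect_equal(grid_cell_of(g, 100, 50), "A1")
  expect_equal(grid_cell_of(g, 180, 50), "A2")
  expect_equal(grid_cell_of(g, 100, 200), "B1")
  expect_equal(grid_cell_of(g, c(0, 999), c(0, 799)), c("A1", "E6"))
})

test_that("mean-position assignment partitions tracks across cells", {
  ss <- scene_small()
  m <- track_metrics(ss$tracks$bacterium, dt = ss$cfg$frame_interval)
  g <- grid_spec(170, ss$cfg$field_width, ss$cfg$field_height)
  cells <- paste0(rep(LETTERS[1:g$n_rows], each = g$n_cols),
                  rep(1:g$n_cols, g$n_rows))
  envs <- lapply(cells, function(cl)
    microenvironment(cl, cl, c(1, 30), "bacterium"))
  n <- vapply(envs, function(e)
    nrow(suppressWarnings(assign_tracks(m, g, e))), 0L)
  expect_equal(sum(n), nrow(m)) # each track in exactly one cell
})

test_that("assignment validates labels, frames and species", {
  ss <- scene_small()
  m <- track_metrics(ss$tracks$bacterium, dt = ss$cfg$frame_interval)
  g <- grid_spec(170, ss$cfg$field_width, ss$cfg$field_height)
  expect_error(assign_tracks(m, g, microenvironment("x", "Z9", c(1, 10),
                                                    "bacterium")),
               "unknown grid label")
  out <- suppressWarnings(
    assign_tracks(m, g, microenvironment("x", "A1", c(1, 10), "zoospore")))
  expect_equal(nrow(out), 0)
  expect_warning(
    assign_tracks(m, g, microenvironment("x", "A1", c(1, 10), "zoospore")),
    "no tracks")
})

test_that("Sidak adjustment matches its closed form", {
  expect_equal(sidak_adjust(0.01, 3), 1 - 0.99^3, tolerance = 1e-14)
  expect_equal(sidak_adjust(0.01, 3), 0.029701, tolerance = 1e-9)
  p <- runif(20)
  expect_true(all(sidak_adjust(p, 5) >= p))
  # monotone in the family size
  for (m in 1:10)
    expect_true(all(sidak_adjust(p, m + 1) >= sidak_adjust(p, m)))
  expect_true(all(sidak_adjust(p, 3) <= 1))
})

test_that("ANOVA F agrees with a sum-of-squares oracle", {
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:40, 1),
                                                   mean = runif(1, 0, 3)))
    res <- one_way_anova(groups)
    expect_equal(res$F_statistic, anova_F_oracle(groups),
                 tolerance = 1e-10)
  }
})

test_that("ANOVA degenerate cases are handled explicitly", {
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$F_statistic, 0)
  # zero within-group variance, distinct means
  res <- one_way_anova(list(c(1, 1, 1), c(2, 2, 2)))
  expect_equal(res$F_statistic, Inf)
  expect_equal(res$anova_p, 0)
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "identical")
  expect_error(one_way_anova(list(1, c(1, 2))), "minimum size")
})

test_that("comparing a microenvironment with itself finds no difference", {
  ss <- scene_small()
  m <- track_metrics(ss$tracks$bacterium, dt = ss$cfg$frame_interval)
  g <- grid_spec(170, ss$cfg$field_width, ss$cfg$field_height)
  env <- microenvironment("self", c("A1", "A2", "B1", "B2"), c(1, 30),
                          "bacterium")
  res <- compare_microenvironments(m, g, list(list(env, env)),
                                   "mean_speed_ums")
  expect_lt(res$F, 1e-10)
  expect_gt(res$p, 0.999)
})

test_that("null groups are rejected at close to the nominal rate", {
  set.seed(77)
  rej <- mean(replicate(300, {
    one_way_anova(list(rnorm(50), rnorm(50)))$anova_p < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})
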