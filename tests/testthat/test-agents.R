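make_agent <- function(species, mode = "swimming", x = 500, y = 400,
                       heading = 0, speed = 0, radius = 5) {
  data.frame(agent_id = 1L, species = species, mode = mode, x = x, y = y,
             heading = heading, speed = speed, radius = radius, phase = 0)
}

test_that("motionless agents stay put", {
  cfg <- chamber_config()
  models <- default_motion_models()
  models$zoospore$encystment_threshold <- Inf
  fl <- flow_field()
  for (sp in c("zoospore", "bacterium")) {
    a <- make_agent(sp, speed = 0)
    b <- step_agents(a, conc_field(cfg), fl, dt = 0.0735, models = models)
    expect_equal(c(b$x, b$y), c(a$x, a$y))
  }
  s <- make_agent("vorticella", mode = "sessile")
  expect_equal(step_agents(s, conc_field(cfg), fl, dt = 0.0735,
                           models = models)[c("x", "y")],
               s[c("x", "y")])
})

test_that("a passive tracer at a vortex orbits at constant radius", {
  cfg <- chamber_config()
  fl <- flow_field(matrix(c(500, 400), ncol = 2))
  models <- default_motion_models()
  a <- make_agent("bacterium", x = 500 + 20, y = 400, speed = 0)
  models$bacterium$rotational_diffusion <- 0
  r0 <- 20
  for (k in 1:100)
    a <- step_agents(a, conc_field(cfg), fl, dt = 0.0735,
                     t = (k - 1) * 0.0735, models = models)
  r <- sqrt((a$x - 500)^2 + (a$y - 400)^2)
  expect_equal(r, r0, tolerance = 0.005)
})

test_that("zoospores drift away from the source; no drift without chemotaxis", {
  biased <- zoospore_drift(strength = 2, seed = 1)
  expect_lt(biased["mean"], 0)
  expect_lt(biased["mean"] + 3 * biased["sem"], 0)
  null <- zoospore_drift(strength = 0, seed = 1)
  expect_lt(abs(null["mean"]), 3 * null["sem"])
})

test_that("encystment is permanent and freezes the agent", {
  cfg <- chamber_config()
  models <- default_motion_models()
  models$zoospore$encystment_threshold <-
    encystment_threshold(cfg, fraction = 0.5)
  fl <- flow_field()
  a <- make_agent("zoospore", x = 500, y = 30, speed = 150) # near source
  set.seed(1)
  b <- step_agents(a, conc_field(cfg), fl, dt = 0.0735, models = models)
  expect_equal(b$mode, "encysted")
  expect_equal(b$speed, 0)
  pos <- c(b$x, b$y)
  for (k in 1:20)
    b <- step_agents(b, conc_field(cfg), fl, dt = 0.0735, models = models)
  expect_equal(b$mode, "encysted")
  expect_equal(c(b$x, b$y), pos)
})

test_that("reflecting boundaries keep all agents inside the field", {
  cfg <- chamber_config(field_width = 300, field_height = 200, rng_seed = 2)
  models <- default_motion_models()
  models$zoospore$encystment_threshold <- Inf
  set.seed(2)
  ag <- init_agents(cfg, models)
  fl <- flow_field()
  for (k in 1:50) {
    ag <- step_agents(ag, conc_field(cfg), fl, dt = 0.0735,
                      t = (k - 1) * 0.0735, models = models,
                      bounds = c(300, 200))
    expect_true(all(ag$x >= 0 & ag$x <= 300 & ag$y >= 0 & ag$y <= 200))
  }
})

test_that("non-finite concentration fields are rejected", {
  bad <- matrix(c(1, NaN, 1, 1), 2, 2)
  expect_error(conc_field(values = bad, pixel_size = 1), "non-finite")
})

test_that("identical seeds reproduce the scene bit for bit", {
  cfg <- chamber_config(field_width = 200, field_height = 150,
                        n_frames = 6, rng_seed = 33)
  s1 <- simulate_scene(cfg)
  s2 <- simulate_scene(cfg)
  expect_identical(s1$stack, s2$stack)
  expect_identical(s1$truth, s2$truth)
})

test_that("agent counts scale with density and chamber volume", {
  cfg <- chamber_config(rng_seed = 1) # 0.32 ul of suspension
  set.seed(1)
  ag <- init_agents(cfg)
  n <- table(ag$species)
  expect_equal(unname(n["zoospore"]), 64, ignore_attr = TRUE)
  expect_equal(unname(n["vorticella"]), 3, ignore_attr = TRUE)
  expect_equal(unname(n["bacterium"]), 640, ignore_attr = TRUE)
  expect_true(all(ag$speed[ag$mode != "swimming"] == 0))
})
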