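# Shared simulated scenes, built once per test run and cached.

.scene_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .scene_cache))
    assign(name, force(expr), envir = .scene_cache)
  get(name, envir = .scene_cache)
}

# community scene at the study densities, quarter-scale field
scene_small <- function() cached("small", {
  cfg <- chamber_config(field_width = 510, field_height = 340,
                        n_frames = 30, rng_seed = 11)
  sc <- simulate_scene(cfg)
  spots <- segment_stack(sc$stack, 110, cfg$pixel_size)
  part <- partition_spots(spots)
  tracks <- build_all_tracks(part)
  list(cfg = cfg, scene = sc, spots = spots, part = part,
       tracks = tracks)
})

# full-field scene at the study densities (partition / tracking checks)
scene_default <- function() cached("default", {
  cfg <- chamber_config(n_frames = 80, rng_seed = 5)
  sc <- simulate_scene(cfg)
  spots <- segment_stack(sc$stack, 110, cfg$pixel_size)
  part <- partition_spots(spots)
  tracks <- build_all_tracks(part)
  list(cfg = cfg, scene = sc, spots = spots, part = part,
       tracks = tracks)
})

# locomotion-only scene: no chemotaxis, no encystment, no sessile forms,
# so track speeds reflect the configured swimming speeds alone
scene_locomotion <- function() cached("locomotion", {
  cfg <- chamber_config(n_frames = 150, rng_seed = 3)
  models <- default_motion_models()
  models$zoospore$chemotaxis_strength <- 0
  models$zoospore$encystment_threshold <- Inf
  models$vorticella$sessile_fraction <- 0
  sc <- simulate_scene(cfg, models = models)
  spots <- segment_stack(sc$stack, 110, cfg$pixel_size)
  part <- partition_spots(spots)
  tracks <- build_all_tracks(part)
  metrics <- do.call(rbind, lapply(names(tracks), function(s)
    as.data.frame(track_metrics(tracks[[s]], dt = cfg$frame_interval))))
  class(metrics) <- c("microswarm_metrics", "data.frame")
  list(cfg = cfg, scene = sc, models = models, part = part,
       tracks = tracks, metrics = metrics)
})

# bacteria around a single sessile Vorticella (feeding-vortex scene)
scene_vortex <- function() cached("vortex", {
  cfg <- chamber_config(field_width = 680, field_height = 510,
                        n_frames = 143, rng_seed = 21)
  models <- default_motion_models()
  models$zoospore$density <- 0
  models$vorticella$density <- 0
  set.seed(cfg$rng_seed)
  agents <- init_agents(cfg, models)
  vort <- data.frame(agent_id = max(agents$agent_id, 0) + 1,
                     species = "vorticella", mode = "sessile",
                     x = 340, y = 255, heading = 0, speed = 0,
                     radius = 14, phase = 0)
  agents <- rbind(agents, vort)
  sc <- simulate_scene(cfg, models = models, agents = agents)
  spots <- segment_stack(sc$stack, 110, cfg$pixel_size)
  part <- partition_spots(spots)
  tracks <- build_all_tracks(part)
  metrics <- track_metrics(tracks$bacterium, dt = cfg$frame_interval)
  list(cfg = cfg, scene = sc, tracks = tracks, metrics = metrics)
})

# zoospore ensemble drift along the gradient axis (no rendering);
# returns mean and SEM of the toward-source displacement component
zoospore_drift <- function(strength, seed, n = 200, steps = 100) {
  cfg <- chamber_config()
  models <- default_motion_models()
  models$zoospore$chemotaxis_strength <- strength
  models$zoospore$encystment_threshold <- Inf
  fl <- flow_field()
  dt <- cfg$frame_interval
  set.seed(seed)
  ag <- data.frame(agent_id = seq_len(n), species = "zoospore",
                   mode = "swimming",
                   x = stats::runif(n, 0, cfg$field_width),
                   y = stats::runif(n, 0, cfg$field_height),
                   heading = stats::runif(n, 0, 2 * pi),
                   speed = stats::runif(n, 100, 200),
                   radius = 7, phase = 0)
  y0 <- ag$y
  for (k in seq_len(steps))
    ag <- step_agents(ag, conc_field(cfg, (k - 1) * dt), fl, dt,
                      (k - 1) * dt, models)
  toward <- -(ag$y - y0) # source sits on the top edge
  c(mean = mean(toward), sem = stats::sd(toward) / sqrt(n))
}
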