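#' Concentration field handle for agent stepping
#'
#' Wraps either the closed-form point-source kernel of a
#' [chamber_config()] (exact concentrations and gradients) or a
#' precomputed concentration matrix (nearest-pixel lookup, central
#' finite-difference gradients).
#'
#' @param config a [chamber_config()] (ignored if `values` is given as a
#'   standalone matrix together with `pixel_size`).
#' @param t seconds since sequence start.
#' @param values optional numeric matrix of concentrations on the pixel
#'   grid; must be finite everywhere.
#' @param pixel_size um/px, required with `values`.
#' @return object of class `conc_field`.
#' @export
conc_field <- function(config = NULL, t = 0, values = NULL,
                       pixel_size = NULL) {
  if (!is.null(values)) {
    if (any(!is.finite(values)))
      stop("concentration field contains non-finite values")
    stopifnot(is.numeric(pixel_size), pixel_size > 0)
    return(structure(list(kind = "grid", values = values,
                          pixel_size = pixel_size),
                     class = "conc_field"))
  }
  stopifnot(inherits(config, "chamber_config"))
  structure(list(kind = "closed_form", config = config, t = t),
            class = "conc_field")
}

field_concentration <- function(field, x, y) {
  if (field$kind == "closed_form")
    return(concentration_at(field$config, x, y, field$t))
  i <- pmin(nrow(field$values), pmax(1, round(y / field$pixel_size + 0.5)))
  j <- pmin(ncol(field$values), pmax(1, round(x / field$pixel_size + 0.5)))
  field$values[cbind(i, j)]
}

field_gradient <- function(field, x, y) {
  if (field$kind == "closed_form")
    return(concentration_gradient_at(field$config, x, y, field$t))
  ps <- field$pixel_size
  v <- field$values
  i <- pmin(nrow(v), pmax(1, round(y / ps + 0.5)))
  j <- pmin(ncol(v), pmax(1, round(x / ps + 0.5)))
  jp <- pmin(ncol(v), j + 1); jm <- pmax(1, j - 1)
  ip <- pmin(nrow(v), i + 1); im <- pmax(1, i - 1)
  list(gx = (v[cbind(i, jp)] - v[cbind(i, jm)]) / ((jp - jm) * ps),
       gy = (v[cbind(ip, j)] - v[cbind(im, j)]) / ((ip - im) * ps))
}

#' Initialize the agent population of a scene
#'
#' Draws per-species agent counts from the configured densities (cells/ul
#' times the field volume, width x height x chamber depth), positions
#' uniformly over the field, speeds and body radii uniformly from each
#' species' configured ranges, and headings uniformly on the circle.
#' A `sessile_fraction` of Vorticella agents start (and stay) sessile
#' with speed zero; their positions later define the vortex flow field.
#'
#' @param config a [chamber_config()].
#' @param models named list of [species_model()]s.
#' @return data.frame with columns agent_id, species, mode, x, y,
#'   heading, speed, radius, phase.
#' @export
init_agents <- function(config, models = default_motion_models()) {
  vol_ul <- config$field_width * config$field_height *
    config$chamber_depth / 1e9
  rows <- lapply(models, function(m) {
    n <- as.integer(round(m$density * vol_ul))
    if (n == 0) return(NULL)
    mode <- rep("swimming", n)
    speed <- stats::runif(n, m$speed_range[1], m$speed_range[2])
    if (m$species == "vorticella" && m$sessile_fraction > 0) {
      ns <- as.integer(round(m$sessile_fraction * n))
      if (ns > 0) {
        mode[seq_len(ns)] <- "sessile"
        speed[seq_len(ns)] <- 0
      }
    }
    data.frame(
      species = m$species, mode = mode,
      x = stats::runif(n, 0, config$field_width),
      y = stats::runif(n, 0, config$field_height),
      heading = stats::runif(n, 0, 2 * pi), speed = speed,
      radius = stats::runif(n, m$radius_range[1], m$radius_range[2]),
      phase = stats::runif(n, 0, 2 * pi),
      stringsAsFactors = FALSE)
  })
  agents <- do.call(rbind, rows)
  if (is.null(agents))
    agents <- data.frame(species = character(), mode = character(),
                         x = numeric(), y = numeric(), heading = numeric(),
                         speed = numeric(), radius = numeric(),
                         phase = numeric(), stringsAsFactors = FALSE)
  agents <- cbind(agent_id = seq_len(nrow(agents)), agents)
  rownames(agents) <- NULL
  agents
}

#' Advance agents by one time step
#'
#' Applies each species' motion model for a step of length `dt`:
#' zoospores tumble (unbiased, at the baseline rate) and reorient away
#' from the concentration gradient (at a rate proportional to
#' `chemotaxis_strength` times the positive part of their up-gradient
#' alignment), and encyst permanently where the concentration exceeds the
#' model's encystment threshold; free Vorticella swim ballistically with
#' a sinusoidal heading perturbation; bacteria rotate diffusively and are
#' advected by the vortex flow. Sessile and encysted agents do not move.
#' Chamber walls reflect.
#'
#' @param agents data.frame as from [init_agents()].
#' @param field a [conc_field()].
#' @param flow a [flow_field()].
#' @param dt time step, s, > 0.
#' @param t time at the start of the step, s (drives the sinusoid).
#' @param models named list of [species_model()]s; zoospore
#'   `encystment_threshold` must be resolved to a number (see
#'   [encystment_threshold()]).
#' @param bounds length-2 field size (um); reflections keep agents inside.
#' @return updated agents data.frame.
#' @export
step_agents <- function(agents, field, flow, dt, t = 0,
                        models = default_motion_models(),
                        bounds = NULL) {
  stopifnot(dt > 0)
  if (nrow(agents) == 0) return(agents)
  if (is.null(bounds) && field$kind == "closed_form")
    bounds <- c(field$config$field_width, field$config$field_height)
  stopifnot(length(bounds) == 2, all(bounds > 0))

  for (sp in unique(agents$species)) {
    m <- models[[sp]]
    if (is.null(m)) stop("no motion model for species ", sp)
    idx <- which(agents$species == sp & agents$mode == "swimming")
    if (length(idx) == 0) next
    x <- agents$x[idx]; y <- agents$y[idx]
    h <- agents$heading[idx]

    if (m$direction_model == "chemotactic_biased") {
      thr <- m$encystment_threshold
      if (is.null(thr)) stop("encystment_threshold unresolved for ", sp)
      conc <- field_concentration(field, x, y)
      if (any(!is.finite(conc)))
        stop("concentration field contains non-finite values")
      enc <- conc > thr
      if (any(enc)) {
        agents$mode[idx[enc]] <- "encysted"
        agents$speed[idx[enc]] <- 0
      }
      live <- !enc
      if (any(live)) {
        il <- idx[live]
        g <- field_gradient(field, x[live], y[live])
        toward <- atan2(g$gy, g$gx)       # up-gradient = towards source
        align <- cos(h[live] - toward)    # +1 when swimming up-gradient
        # baseline unbiased tumbles
        p_tumble <- -expm1(-m$tumble_rate * dt)
        tum <- stats::runif(length(il)) < p_tumble
        hl <- h[live]
        hl[tum] <- stats::runif(sum(tum), 0, 2 * pi)
        # chemotactic reorientation away from the gradient
        p_chem <- -expm1(-m$chemotaxis_strength * pmax(0, align) * dt)
        chem <- stats::runif(length(il)) < p_chem
        if (any(chem))
          hl[chem] <- toward[chem] + pi + stats::rnorm(sum(chem), 0, 0.4)
        hl <- hl + stats::rnorm(length(il),
                                sd = sqrt(2 * m$rotational_diffusion * dt))
        agents$heading[il] <- hl
        agents$x[il] <- x[live] + agents$speed[il] * dt * cos(hl)
        agents$y[il] <- y[live] + agents$speed[il] * dt * sin(hl)
      }
    } else if (m$direction_model == "ballistic_sinusoidal") {
      hl <- h + m$sine_amplitude * sin(2 * pi * t / m$sine_period +
                                         agents$phase[idx]) * dt +
        stats::rnorm(length(idx),
                     sd = sqrt(2 * m$rotational_diffusion * dt))
      agents$heading[idx] <- hl
      agents$x[idx] <- x + agents$speed[idx] * dt * cos(hl)
      agents$y[idx] <- y + agents$speed[idx] * dt * sin(hl)
    } else { # brownian_advected
      hl <- h + stats::rnorm(length(idx),
                             sd = sqrt(2 * m$rotational_diffusion * dt))
      # midpoint rule for the advection term keeps circular streamlines
      # closed (forward Euler makes vortex orbits spiral outwards)
      sx <- agents$speed[idx] * cos(hl)
      sy <- agents$speed[idx] * sin(hl)
      v1 <- flow_velocity(flow, x, y)
      vm <- flow_velocity(flow, x + (sx + v1$vx) * dt / 2,
                          y + (sy + v1$vy) * dt / 2)
      agents$heading[idx] <- hl
      agents$x[idx] <- x + (sx + vm$vx) * dt
      agents$y[idx] <- y + (sy + vm$vy) * dt
    }
  }
  reflect_agents(agents, bounds)
}

reflect_agents <- function(agents, bounds) {
  hx <- cos(agents$heading); hy <- sin(agents$heading)
  for (k in 1:2) { # at most two passes are ever needed for our step sizes
    lo_x <- agents$x < 0; hi_x <- agents$x > bounds[1]
    lo_y <- agents$y < 0; hi_y <- agents$y > bounds[2]
    if (!any(lo_x | hi_x | lo_y | hi_y)) break
    agents$x[lo_x] <- -agents$x[lo_x]
    agents$x[hi_x] <- 2 * bounds[1] - agents$x[hi_x]
    agents$y[lo_y] <- -agents$y[lo_y]
    agents$y[hi_y] <- 2 * bounds[2] - agents$y[hi_y]
    hx[lo_x | hi_x] <- -hx[lo_x | hi_x]
    hy[lo_y | hi_y] <- -hy[lo_y | hi_y]
  }
  agents$heading <- atan2(hy, hx)
  agents
}

#' Simulate a full scene
#'
#' Runs the agent-based model over `config$n_frames` frames, recording
#' the ground-truth state of every living agent at every frame, and
#' (optionally) renders the 8-bit grayscale stack. All randomness flows
#' from `config$rng_seed`: identical configurations give bit-identical
#' stacks and ground truth.
#'
#' @param config a [chamber_config()].
#' @param models named list of [species_model()]s.
#' @param flow a [flow_field()], or `NULL` to build one from the sessile
#'   Vorticella positions.
#' @param agents optional initial agent table (overrides random
#'   initialization; useful for controlled experiments).
#' @param noise_sd Gaussian intensity noise added by the renderer.
#' @param render logical; render the stack.
#' @return object of class `microswarm_scene`: list with `config`,
#'   `models`, `flow`, `truth` (data.frame: frame, agent_id, species,
#'   mode, x_um, y_um, heading, radius_um and pixel-coordinate mirrors),
#'   and `stack` (8-bit integer array y * x * frame, or `NULL`).
#' @examples
#' cfg <- chamber_config(field_width = 260, field_height = 260,
#'                       n_frames = 5, rng_seed = 7)
#' sc <- simulate_scene(cfg)
#' table(sc$truth$species[sc$truth$frame == 1])
#' @export
simulate_scene <- function(config, models = default_motion_models(),
                           flow = NULL, agents = NULL, noise_sd = 8,
                           render = TRUE) {
  stopifnot(inherits(config, "chamber_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  if (is.null(agents)) agents <- init_agents(config, models)
  if (is.null(flow)) {
    sess <- agents$species == "vorticella" & agents$mode == "sessile"
    flow <- flow_field(cbind(agents$x[sess], agents$y[sess]))
  }
  # resolve encystment thresholds needed by chemotactic species
  for (sp in names(models)) {
    m <- models[[sp]]
    if (m$direction_model == "chemotactic_biased" &&
        is.null(m$encystment_threshold))
      models[[sp]]$encystment_threshold <- encystment_threshold(config)
  }
  dt <- config$frame_interval
  frames <- vector("list", config$n_frames)
  for (k in seq_len(config$n_frames)) {
    frames[[k]] <- data.frame(
      frame = k, agent_id = agents$agent_id, species = agents$species,
      mode = agents$mode, x_um = agents$x, y_um = agents$y,
      heading = agents$heading, radius_um = agents$radius,
      stringsAsFactors = FALSE)
    if (k < config$n_frames)
      agents <- step_agents(agents, conc_field(config, t = (k - 1) * dt),
                            flow, dt, t = (k - 1) * dt, models = models)
  }
  truth <- do.call(rbind, frames)
  rownames(truth) <- NULL
  scene <- structure(list(config = config, models = models, flow = flow,
                          truth = truth, stack = NULL),
                     class = "microswarm_scene")
  if (render) {
    r <- render_frames(truth, config, noise_sd = noise_sd)
    scene$stack <- r$stack
    scene$truth <- r$truth
  }
  scene
}

#' @export
print.microswarm_scene <- function(x, ...) {
  n1 <- table(x$truth$species[x$truth$frame == 1])
  cat(sprintf("<microswarm_scene> %d frames, %d agents (%s)%s\n",
              x$config$n_frames, sum(n1),
              paste(names(n1), n1, sep = ": ", collapse = ", "),
              if (is.null(x$stack)) ", not rendered" else
                sprintf(", stack %d x %d px", dim(x$stack)[1],
                        dim(x$stack)[2])))
  invisible(x)
}
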