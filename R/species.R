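#' Species motion model
#'
#' Parameters governing one species' locomotion in the simulator. Three
#' direction models are available:
#' \describe{
#'   \item{chemotactic_biased}{run-and-tumble with baseline (unbiased)
#'     tumbles plus chemotactic reorientations away from the local
#'     concentration gradient; the chemotactic reorientation rate is
#'     `chemotaxis_strength` times the positive part of the up-gradient
#'     heading alignment. Used for zoospores, which also encyst
#'     (permanently stop) where the concentration exceeds
#'     `encystment_threshold`.}
#'   \item{ballistic_sinusoidal}{ballistic swimming with a sinusoidal
#'     heading perturbation, ignoring the gradient. Used for free
#'     (telotroch) Vorticella.}
#'   \item{brownian_advected}{rotational-diffusion random walk with the
#'     local vortex flow velocity added. Used for bacteria.}
#' }
#'
#' @param species one of "zoospore", "vorticella", "bacterium".
#' @param speed_range um/s, length-2; per-agent speeds are drawn
#'   uniformly from it. Must lie within the species' plausibility band
#'   (zoospore 0-213, vorticella 80-800 free-swimming, bacterium 0-28).
#' @param direction_model see Description.
#' @param chemotaxis_strength reorientation rate scale, 1/s, >= 0.
#' @param encystment_threshold concentration units; `NULL` means derive
#'   from the chamber via [encystment_threshold()] (zoospores only).
#' @param rotational_diffusion rad^2/s.
#' @param tumble_rate 1/s baseline unbiased tumble rate
#'   (chemotactic_biased only).
#' @param sine_amplitude,sine_period heading perturbation, rad/s and s
#'   (ballistic_sinusoidal only).
#' @param density cells per ul of suspension.
#' @param radius_range um, length-2 band of body equivalent radii.
#' @param sessile_fraction fraction of agents initialized sessile
#'   (vorticella only).
#' @return object of class `species_model`.
#' @export
species_model <- function(species,
                          speed_range,
                          direction_model = c("chemotactic_biased",
                                              "ballistic_sinusoidal",
                                              "brownian_advected"),
                          chemotaxis_strength = 0,
                          encystment_threshold = NULL,
                          rotational_diffusion = 0.5,
                          tumble_rate = 0.5,
                          sine_amplitude = 1.5,
                          sine_period = 1.2,
                          density = 0,
                          radius_range = c(1, 2),
                          sessile_fraction = 0) {
  species <- match.arg(species, c("zoospore", "vorticella", "bacterium"))
  direction_model <- match.arg(direction_model)
  stopifnot(length(speed_range) == 2, speed_range[1] <= speed_range[2],
            speed_range[1] >= 0, chemotaxis_strength >= 0,
            rotational_diffusion >= 0, density >= 0,
            length(radius_range) == 2, radius_range[1] > 0,
            sessile_fraction >= 0, sessile_fraction <= 1)
  band <- switch(species, zoospore = c(0, 213), vorticella = c(0, 800),
                 bacterium = c(0, 28))
  if (speed_range[1] < band[1] || speed_range[2] > band[2])
    stop(sprintf("%s speed_range outside plausibility band [%g, %g] um/s",
                 species, band[1], band[2]))
  structure(list(
    species = species, speed_range = as.numeric(speed_range),
    direction_model = direction_model,
    chemotaxis_strength = chemotaxis_strength,
    encystment_threshold = encystment_threshold,
    rotational_diffusion = rotational_diffusion,
    tumble_rate = tumble_rate,
    sine_amplitude = sine_amplitude, sine_period = sine_period,
    density = density, radius_range = as.numeric(radius_range),
    sessile_fraction = sessile_fraction
  ), class = "species_model")
}

#' Default motion models for the three community members
#'
#' Zoospores swim at 100-200 um/s (the dominant mode of the observed
#' mean-speed distribution) with negative chemotaxis to potassium and
#' encystment near the source; free Vorticella telotrochs swim
#' ballistically at 400-600 um/s; bacteria perform a slow
#' rotational-diffusion walk at 2-18 um/s and are advected by feeding
#' vortices. Densities default to the 200:10:2000 cells/ul calibration.
#'
#' @return named list of [species_model()] objects.
#' @export
default_motion_models <- function() {
  list(
    zoospore = species_model(
      "zoospore", speed_range = c(100, 200),
      direction_model = "chemotactic_biased",
      chemotaxis_strength = 2, encystment_threshold = NULL,
      rotational_diffusion = 0.5, tumble_rate = 0.5,
      density = 200, radius_range = c(5, 9)),
    vorticella = species_model(
      "vorticella", speed_range = c(400, 600),
      direction_model = "ballistic_sinusoidal",
      rotational_diffusion = 0.05,
      sine_amplitude = 1.5, sine_period = 1.2,
      density = 10, radius_range = c(11, 18), sessile_fraction = 0.5),
    bacterium = species_model(
      "bacterium", speed_range = c(2, 18),
      direction_model = "brownian_advected",
      rotational_diffusion = 2,
      density = 2000, radius_range = c(1, 2))
  )
}

#' Vortex flow field generated by sessile Vorticella
#'
#' Each sessile trophont generates a feeding vortex modeled as solid-body
#' rotation inside a core radius with 1/r decay outside it, truncated at
#' the influence radius (a single Vorticella influences particles up to
#' 450 um away). The tangential speed is `vortex_strength * r / core^2`
#' inside the core and `vortex_strength / r` outside, so the induced
#' speed decays monotonically with distance beyond the core and is zero
#' beyond `influence_radius`.
#'
#' @param vortex_centers 2-column matrix (x, y um) of sessile trophont
#'   positions; may have zero rows.
#' @param vortex_strength circulation scale in um^2/s; the peak
#'   tangential speed is `vortex_strength / core_radius`.
#' @param influence_radius um; flow is zero beyond it (default 450).
#' @param core_radius um of the solid-body core.
#' @return object of class `flow_field`.
#' @export
flow_field <- function(vortex_centers = matrix(numeric(0), ncol = 2),
                       vortex_strength = 540, influence_radius = 450,
                       core_radius = 30) {
  vortex_centers <- matrix(as.numeric(vortex_centers), ncol = 2)
  stopifnot(vortex_strength >= 0, influence_radius > 0, core_radius > 0,
            core_radius <= influence_radius)
  structure(list(vortex_centers = vortex_centers,
                 vortex_strength = vortex_strength,
                 influence_radius = influence_radius,
                 core_radius = core_radius),
            class = "flow_field")
}

#' Flow velocity at points
#'
#' Sum of the tangential (counter-clockwise in image coordinates) vortex
#' velocities from all centers of a [flow_field()].
#'
#' @param flow a [flow_field()].
#' @param x,y coordinates in um.
#' @return list of numeric vectors `vx`, `vy` in um/s.
#' @export
flow_velocity <- function(flow, x, y) {
  vx <- numeric(length(x))
  vy <- numeric(length(y))
  if (nrow(flow$vortex_centers) == 0 || flow$vortex_strength == 0)
    return(list(vx = vx, vy = vy))
  for (i in seq_len(nrow(flow$vortex_centers))) {
    dx <- x - flow$vortex_centers[i, 1]
    dy <- y - flow$vortex_centers[i, 2]
    r <- sqrt(dx^2 + dy^2)
    speed <- ifelse(r <= flow$core_radius,
                    flow$vortex_strength * r / flow$core_radius^2,
                    flow$vortex_strength / pmax(r, .Machine$double.eps))
    speed[r > flow$influence_radius] <- 0
    ok <- r > .Machine$double.eps & speed > 0
    # tangential unit vector: rotate radial by +90 degrees
    vx[ok] <- vx[ok] - speed[ok] * dy[ok] / r[ok]
    vy[ok] <- vy[ok] + speed[ok] * dx[ok] / r[ok]
  }
  list(vx = vx, vy = vy)
}
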