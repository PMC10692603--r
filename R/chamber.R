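#' Chamber and acquisition configuration
#'
#' Describes the imaged region of the microchamber, the acquisition
#' timing, and the lateral potassium point source. Defaults follow the
#' acquisition geometry of the study system: a 1000 x 800 um field imaged
#' at 0.0735 s per frame, with the KCl source at the mid-point of the top
#' edge and a pre-diffusion time of 300 s (imaging starts 5 min after the
#' KCl bolus is added).
#'
#' The image coordinate convention is origin at the top-left corner, x
#' increasing rightwards and y increasing downwards, both in micrometres.
#'
#' @param field_width,field_height field size in um.
#' @param pixel_size um per pixel. The default 1.3 um/px makes a 2 um
#'   bacterium span 1-2 pixels at 10x magnification.
#' @param frame_interval seconds between frames.
#' @param n_frames number of frames in a sequence.
#' @param source_position length-2 numeric, um, on or inside the field.
#' @param source_amount released amount in arbitrary mass units (scaled
#'   from a 0.5 ul bolus of 500 mM KCl).
#' @param diffusion_coefficient um^2/s of the solute.
#' @param time_offset seconds of diffusion elapsed before frame 1.
#' @param chamber_depth um, used to convert cells/ul densities into
#'   per-field agent counts.
#' @param rng_seed integer seed used by [simulate_scene()], or `NULL`.
#' @return object of class `chamber_config`.
#' @examples
#' cfg <- chamber_config(rng_seed = 1)
#' dim(diffuse_concentration(cfg, t = 0))
#' @export
chamber_config <- function(field_width = 1000, field_height = 800,
                           pixel_size = 1.3, frame_interval = 0.0735,
                           n_frames = 143,
                           source_position = c(field_width / 2, 0),
                           source_amount = 0.25,
                           diffusion_coefficient = 1000,
                           time_offset = 300,
                           chamber_depth = 400,
                           rng_seed = NULL) {
  stopifnot(
    field_width > 0, field_height > 0, pixel_size > 0,
    frame_interval > 0, n_frames >= 1, source_amount > 0,
    diffusion_coefficient > 0, time_offset >= 0, chamber_depth > 0,
    length(source_position) == 2
  )
  if (source_position[1] < 0 || source_position[1] > field_width ||
      source_position[2] < 0 || source_position[2] > field_height)
    stop("source_position must lie on or inside the field boundary")
  structure(list(
    field_width = field_width, field_height = field_height,
    pixel_size = pixel_size, frame_interval = frame_interval,
    n_frames = n_frames, source_position = as.numeric(source_position),
    source_amount = source_amount,
    diffusion_coefficient = diffusion_coefficient,
    time_offset = time_offset, chamber_depth = chamber_depth,
    rng_seed = rng_seed
  ), class = "chamber_config")
}

#' @export
print.chamber_config <- function(x, ...) {
  cat(sprintf(
    "<chamber_config> %g x %g um, %g um/px, dt = %g s, %d frames\n",
    x$field_width, x$field_height, x$pixel_size, x$frame_interval,
    x$n_frames))
  cat(sprintf("  source at (%g, %g) um, M = %g, D = %g um^2/s, t0 = %g s\n",
              x$source_position[1], x$source_position[2], x$source_amount,
              x$diffusion_coefficient, x$time_offset))
  invisible(x)
}

#' Closed-form point-source concentration field
#'
#' Planar concentration of a solute released instantaneously from a point
#' source, C(x, t) = M / (4 pi D t_eff) * exp(-|x - x0|^2 / (4 D t_eff)),
#' where t_eff = t + time_offset. Evaluated either at arbitrary points
#' (`concentration_at`) or at every pixel centre of the image grid
#' (`diffuse_concentration`).
#'
#' @param config a [chamber_config()].
#' @param t seconds since the start of the sequence (t >= 0). The
#'   effective diffusion time is `t + config$time_offset`; a zero
#'   effective time makes the kernel singular and is rejected.
#' @return `diffuse_concentration`: numeric matrix (rows = y pixels,
#'   columns = x pixels), non-negative. `concentration_at`: numeric
#'   vector.
#' @examples
#' cfg <- chamber_config()
#' C <- diffuse_concentration(cfg, t = 0)
#' max(C) == C[1, which.max(C[1, ])]  # maximum at the source (top edge)
#' @export
diffuse_concentration <- function(config, t) {
  stopifnot(inherits(config, "chamber_config"), t >= 0)
  nx <- pixel_dims(config)["nx"]
  ny <- pixel_dims(config)["ny"]
  xs <- (seq_len(nx) - 0.5) * config$pixel_size
  ys <- (seq_len(ny) - 0.5) * config$pixel_size
  pts <- expand_grid_xy(xs, ys)
  matrix(concentration_at(config, pts$x, pts$y, t), nrow = ny, ncol = nx)
}

#' @rdname diffuse_concentration
#' @param x,y coordinates in um (vectors of equal length).
#' @export
concentration_at <- function(config, x, y, t) {
  teff <- t + config$time_offset
  if (any(teff <= 0))
    stop("effective diffusion time must be positive (singular kernel at 0)")
  D <- config$diffusion_coefficient
  r2 <- (x - config$source_position[1])^2 + (y - config$source_position[2])^2
  config$source_amount / (4 * pi * D * teff) * exp(-r2 / (4 * D * teff))
}

#' Concentration gradient at points
#'
#' Analytic gradient of the point-source kernel. The gradient points
#' towards the source (concentration increases towards it).
#'
#' @inheritParams concentration_at
#' @return list with numeric vectors `gx`, `gy` (concentration units / um).
#' @export
concentration_gradient_at <- function(config, x, y, t) {
  teff <- t + config$time_offset
  if (any(teff <= 0))
    stop("effective diffusion time must be positive (singular kernel at 0)")
  D <- config$diffusion_coefficient
  C <- concentration_at(config, x, y, t)
  fac <- -1 / (2 * D * teff)
  list(gx = C * fac * (x - config$source_position[1]),
       gy = C * fac * (y - config$source_position[2]))
}

#' Default encystment threshold for a configuration
#'
#' Concentration value such that, at the start of the sequence, the
#' highest-concentration fraction `fraction` of the field area lies above
#' it. Zoospores entering that region encyst.
#'
#' @param config a [chamber_config()].
#' @param fraction area fraction of the field that encysts (default 0.2).
#' @return scalar concentration.
#' @export
encystment_threshold <- function(config, fraction = 0.2) {
  stopifnot(fraction > 0, fraction < 1)
  C <- diffuse_concentration(config, t = 0)
  stats::quantile(C, probs = 1 - fraction, names = FALSE)
}

pixel_dims <- function(config) {
  c(nx = max(1L, as.integer(round(config$field_width / config$pixel_size))),
    ny = max(1L, as.integer(round(config$field_height / config$pixel_size))))
}

expand_grid_xy <- function(xs, ys) {
  list(x = rep(xs, each = length(ys)), y = rep(ys, times = length(xs)))
}
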