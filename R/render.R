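#' Render ground truth into an 8-bit grayscale stack
#'
#' Draws every agent of every frame onto a bright background (intensity
#' 200) as a dark body (intensity 40): zoospores, sessile Vorticella and
#' bacteria as disks of their body radius, free (telotroch) Vorticella as
#' 2:1 ellipses of the same equivalent radius oriented along the heading.
#' Bodies smaller than one pixel are clamped to one pixel so every agent
#' leaves a mark. Gaussian noise of standard deviation `noise_sd` is then
#' added and the result clipped to [0, 255]. Overlapping agents merge
#' into single blobs; that is a property of the imaging being emulated,
#' not an error.
#'
#' @param truth ground-truth data.frame (frame, agent_id, species, mode,
#'   x_um, y_um, heading, radius_um).
#' @param config a [chamber_config()].
#' @param noise_sd intensity units; 0 disables noise.
#' @param background,foreground intensities of the empty field and of
#'   cell bodies.
#' @return list with `stack` (integer array y-pixels x x-pixels x frames)
#'   and `truth` (the input with pixel-coordinate columns `x_px`, `y_px`
#'   appended; continuous 0-based pixel units).
#' @export
render_frames <- function(truth, config, noise_sd = 8, background = 200,
                          foreground = 40) {
  stopifnot(inherits(config, "chamber_config"), noise_sd >= 0,
            foreground <= 60, background >= 180)
  ps <- config$pixel_size
  nd <- pixel_dims(config)
  nx <- nd["nx"]; ny <- nd["ny"]
  n_frames <- config$n_frames
  stack <- array(0L, dim = c(ny, nx, n_frames))
  fidx <- split(seq_len(nrow(truth)), truth$frame)
  for (k in seq_len(n_frames)) {
    img <- matrix(as.integer(background), ny, nx)
    rows <- fidx[[as.character(k)]]
    for (i in rows) {
      img <- draw_body(img, truth$x_um[i], truth$y_um[i],
                       truth$radius_um[i], truth$heading[i],
                       ellipse = truth$species[i] == "vorticella" &&
                         truth$mode[i] == "swimming",
                       ps = ps, value = as.integer(foreground))
    }
    if (noise_sd > 0) {
      img <- img + as.integer(round(stats::rnorm(length(img),
                                                 sd = noise_sd)))
      img[img < 0L] <- 0L
      img[img > 255L] <- 255L
    }
    stack[, , k] <- img
  }
  truth$x_px <- truth$x_um / ps
  truth$y_px <- truth$y_um / ps
  list(stack = stack, truth = truth)
}

# draw one body onto an integer image matrix (in place semantics via return)
draw_body <- function(img, cx, cy, r, heading, ellipse, ps, value) {
  ny <- nrow(img); nx <- ncol(img)
  r <- max(r, ps) # clamp bodies to >= 1 pixel
  half <- if (ellipse) r * sqrt(2) else r
  jmin <- max(1L, as.integer(floor((cx - half) / ps)))
  jmax <- min(nx, as.integer(ceiling((cx + half) / ps) + 1L))
  imin <- max(1L, as.integer(floor((cy - half) / ps)))
  imax <- min(ny, as.integer(ceiling((cy + half) / ps) + 1L))
  if (jmin <= jmax && imin <= imax) {
    xs <- (jmin:jmax - 0.5) * ps - cx
    ys <- (imin:imax - 0.5) * ps - cy
    X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    Y <- matrix(ys, length(ys), length(xs))
    if (ellipse) {
      a <- r * sqrt(2); b <- r / sqrt(2) # 2:1 aspect, same area as disk r
      u <- X * cos(heading) + Y * sin(heading)
      v <- -X * sin(heading) + Y * cos(heading)
      inside <- (u / a)^2 + (v / b)^2 <= 1
    } else {
      inside <- X^2 + Y^2 <= r^2
    }
    sub <- img[imin:imax, jmin:jmax, drop = FALSE]
    sub[inside] <- value
    img[imin:imax, jmin:jmax] <- sub
  }
  # guarantee at least the nearest pixel is set
  jn <- min(nx, max(1L, as.integer(ceiling(cx / ps))))
  in_ <- min(ny, max(1L, as.integer(ceiling(cy / ps))))
  img[in_, jn] <- value
  img
}
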