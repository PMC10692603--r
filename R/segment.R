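#' Binarize an 8-bit frame
#'
#' Thresholds a grayscale frame into a foreground mask of biological
#' objects. With `polarity = "dark_objects"` (bright-field convention:
#' dark bodies on a bright background) pixels with intensity `<=
#' threshold` become foreground; with `"bright_objects"` pixels `>=
#' threshold` do. The working threshold band for these scenes is 100-118:
#' lower values lose the smallest (bacterial) objects, higher values pick
#' up overexposed background. Values outside that band are allowed with a
#' warning; values outside [0, 255] are rejected.
#'
#' @param frame integer matrix with values in [0, 255].
#' @param threshold intensity threshold.
#' @param polarity "dark_objects" or "bright_objects".
#' @return object of class `binary_mask`: list with `mask` (logical
#'   matrix, TRUE = object), `threshold_used`, `polarity`.
#' @examples
#' f <- matrix(200L, 20, 20); f[5:8, 5:8] <- 50L
#' sum(binarize(f, 110)$mask)
#' @export
binarize <- function(frame, threshold,
                     polarity = c("dark_objects", "bright_objects")) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(frame))
  if (threshold < 0 || threshold > 255)
    stop("threshold must lie in [0, 255]")
  if (threshold < 100 || threshold > 118)
    warning("threshold ", threshold,
            " is outside the advisory band [100, 118]")
  if (any(frame < 0 | frame > 255, na.rm = TRUE))
    stop("frame is not 8-bit (values outside [0, 255])")
  mask <- if (polarity == "dark_objects") frame <= threshold
          else frame >= threshold
  frac <- mean(mask)
  if (frac >= 0.5)
    warning(sprintf("foreground fraction %.2f >= 0.5; check polarity/threshold",
                    frac))
  structure(list(mask = mask, threshold_used = threshold,
                 polarity = polarity),
            class = "binary_mask")
}

#' Label connected components of a mask
#'
#' @param mask a `binary_mask` or a logical matrix.
#' @param connectivity 4 or 8 (default 8: diagonally touching pixels
#'   belong to the same object, as in mask-based spot detection).
#' @return integer matrix of labels, 0 = background, components numbered
#'   1..n in column-major scan order.
#' @export
label_mask <- function(mask, connectivity = 8) {
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  stopifnot(is.logical(m), is.matrix(m))
  cc_label(m, as.integer(connectivity))
}

#' Detect spots in a binary mask
#'
#' One spot per connected component, with TrackMate-style morphometrics:
#' centroid (unweighted mean of member pixel centres, um), area
#' (pixel count x pixel_size^2), perimeter (Crofton 4-direction
#' estimator), circularity (4 pi area / perimeter^2, clipped to <= 1),
#' equivalent radius (sqrt(area / pi)), and a quality score defined as
#' the pixel count (so the permissive default quality threshold of 1
#' keeps every component, down to single-pixel bacteria). Components
#' touching the image border are retained and flagged. No contour
#' simplification is applied.
#'
#' @param mask a `binary_mask` or logical matrix.
#' @param pixel_size um per pixel.
#' @param connectivity 4 or 8.
#' @param quality_threshold minimum quality (pixel count); spots below it
#'   are discarded (default 1).
#' @param frame frame index stored in the output (default 1).
#' @return data.frame with columns frame, spot_id, x_um, y_um, area_um2,
#'   perimeter_um, circularity, radius_um, pixel_count, quality,
#'   on_border. `spot_id` equals the component label within the frame.
#' @examples
#' f <- matrix(200L, 32, 32); f[4:9, 4:9] <- 50L; f[20:22, 15:17] <- 50L
#' detect_spots(binarize(f, 110), pixel_size = 1)
#' @export
detect_spots <- function(mask, pixel_size, connectivity = 8,
                         quality_threshold = 1, frame = 1L) {
  stopifnot(pixel_size > 0, quality_threshold >= 0)
  lab <- label_mask(mask, connectivity)
  n <- max(lab)
  empty <- data.frame(frame = integer(), spot_id = integer(),
                      x_um = numeric(), y_um = numeric(),
                      area_um2 = numeric(), perimeter_um = numeric(),
                      circularity = numeric(), radius_um = numeric(),
                      pixel_count = integer(), quality = numeric(),
                      on_border = logical())
  if (n == 0) return(empty)
  ny <- nrow(lab); nx <- ncol(lab)
  idx <- which(lab > 0L)
  l <- lab[idx]
  rows <- ((idx - 1L) %% ny) + 1L
  cols <- ((idx - 1L) %/% ny) + 1L
  count <- tabulate(l, n)
  sum_c <- as.vector(rowsum(as.numeric(cols), l))
  sum_r <- as.vector(rowsum(as.numeric(rows), l))
  border <- as.vector(rowsum(
    as.numeric(rows == 1L | rows == ny | cols == 1L | cols == nx), l)) > 0
  per_px <- crofton_perimeter(lab, n)
  area <- count * pixel_size^2
  perim <- per_px * pixel_size
  circ <- pmin(1, 4 * pi * area / perim^2)
  out <- data.frame(
    frame = as.integer(frame), spot_id = seq_len(n),
    x_um = (sum_c / count - 0.5) * pixel_size,
    y_um = (sum_r / count - 0.5) * pixel_size,
    area_um2 = area, perimeter_um = perim, circularity = circ,
    radius_um = sqrt(area / pi), pixel_count = count,
    quality = as.numeric(count), on_border = border)
  out[out$quality >= quality_threshold, , drop = FALSE]
}

# Crofton 4-direction perimeter per label, in pixel units.
# P = (pi/8) * (h + v + (d1 + d2)/sqrt(2)), counting label/background (or
# label/other-label) transitions along rows, columns, and both diagonals.
crofton_perimeter <- function(lab, n = max(lab)) {
  p <- matrix(0L, nrow(lab) + 2L, ncol(lab) + 2L)
  p[2:(nrow(lab) + 1L), 2:(ncol(lab) + 1L)] <- lab
  nr <- nrow(p); nc <- ncol(p)
  count_dir <- function(a, b) {
    diff <- which(a != b)
    tabulate(c(a[diff], b[diff]), n) # zeros (background) fall out
  }
  h <- count_dir(p[, -1], p[, -nc])
  v <- count_dir(p[-1, ], p[-nr, ])
  d1 <- count_dir(p[-1, -1], p[-nr, -nc])
  d2 <- count_dir(p[-1, -nc], p[-nr, -1])
  (pi / 8) * (h + v + (d1 + d2) / sqrt(2))
}

#' Detect spots across a whole stack
#'
#' Binarizes and detects spots frame by frame.
#'
#' @param stack integer array (y, x, frame) with values in [0, 255].
#' @param threshold intensity threshold (see [binarize()]).
#' @param pixel_size um per pixel.
#' @param polarity,connectivity,quality_threshold passed through.
#' @return data.frame of spots over all frames (see [detect_spots()]).
#' @export
segment_stack <- function(stack, threshold, pixel_size,
                          polarity = "dark_objects", connectivity = 8,
                          quality_threshold = 1) {
  stopifnot(length(dim(stack)) == 3)
  out <- vector("list", dim(stack)[3])
  for (k in seq_len(dim(stack)[3])) {
    m <- suppressWarnings(binarize(stack[, , k], threshold, polarity))
    out[[k]] <- detect_spots(m, pixel_size, connectivity,
                             quality_threshold, frame = k)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
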