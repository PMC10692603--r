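#' Per-track motion metrics
#'
#' For every track with at least `min_length` spots: total path length
#' (sum of step lengths, um), net displacement (first to last position,
#' um), confinement ratio (net / total, defined as 0 for a zero-length
#' path; always in [0, 1] by the triangle inequality), mean speed (total
#' path / elapsed time, the per-track convention used throughout), and
#' duration. Singleton tracks are excluded and counted in the
#' `n_singletons` attribute.
#'
#' @param tracks a `microswarm_tracks` object (or data.frame with
#'   track_id, frame, x_um, y_um and optionally species).
#' @param dt frame interval, s, > 0.
#' @param min_length minimum number of spots per track (default 2).
#' @return data.frame of class `microswarm_metrics` with columns
#'   track_id, species, n_spots, n_links, total_um, net_um,
#'   confinement_ratio, mean_speed_ums, duration_s, mean_x_um, mean_y_um,
#'   first_frame, last_frame.
#' @examples
#' tr <- data.frame(track_id = 1, frame = 1:3, x_um = 0,
#'                  y_um = c(0, 7.35, 14.7), species = "zoospore")
#' track_metrics(tr, dt = 0.0735)  # mean speed 100 um/s, ratio 1
#' @export
track_metrics <- function(tracks, dt, min_length = 2) {
  stopifnot(dt > 0, min_length >= 2)
  df <- as.data.frame(tracks)
  if (is.null(df$species))
    df$species <- attr(tracks, "species") %||% NA_character_
  if (nrow(df) == 0) {
    out <- data.frame(track_id = integer(), species = character(),
                      n_spots = integer(), n_links = integer(),
                      total_um = numeric(), net_um = numeric(),
                      confinement_ratio = numeric(),
                      mean_speed_ums = numeric(), duration_s = numeric(),
                      mean_x_um = numeric(), mean_y_um = numeric(),
                      first_frame = integer(), last_frame = integer())
    return(structure(out, class = c("microswarm_metrics", "data.frame"),
                     n_singletons = 0L))
  }
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  n_spots <- as.vector(table(df$track_id)[as.character(unique(df$track_id))])
  ids <- unique(df$track_id)
  same <- c(FALSE, df$track_id[-1] == df$track_id[-nrow(df)])
  step <- sqrt(c(NA, diff(df$x_um))^2 + c(NA, diff(df$y_um))^2)
  step[!same] <- 0
  total <- as.vector(rowsum(step, df$track_id)[as.character(ids), ])
  first <- !duplicated(df$track_id)
  last <- !duplicated(df$track_id, fromLast = TRUE)
  net <- sqrt((df$x_um[last] - df$x_um[first])^2 +
                (df$y_um[last] - df$y_um[first])^2)
  conf <- ifelse(total > 0, pmin(1, net / total), 0)
  n_links <- n_spots - 1L
  out <- data.frame(
    track_id = ids, species = df$species[first], n_spots = n_spots,
    n_links = n_links, total_um = total, net_um = net,
    confinement_ratio = conf,
    mean_speed_ums = ifelse(n_links > 0, total / (n_links * dt), NA_real_),
    duration_s = n_links * dt,
    mean_x_um = as.vector(rowsum(df$x_um, df$track_id)[as.character(ids), ]) /
      n_spots,
    mean_y_um = as.vector(rowsum(df$y_um, df$track_id)[as.character(ids), ]) /
      n_spots,
    first_frame = df$frame[first], last_frame = df$frame[last])
  keep <- out$n_spots >= min_length
  n_singletons <- sum(out$n_spots == 1L)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("microswarm_metrics", "data.frame"),
            n_singletons = n_singletons)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Motility classification of tracks
#'
#' Species-specific speed rules: zoospores with mean speed below 10 um/s
#' are effectively non-motile (encysted or deflagellated forms);
#' Vorticella with mean speed below 20 um/s are sessile trophonts,
#' otherwise free-swimming telotrochs; bacteria have no established
#' speed dichotomy and are labeled "bacterium". Thresholds use strict
#' `<` on the slow side, so a Vorticella at exactly 20 um/s is a
#' telotroch.
#'
#' @param metrics a `microswarm_metrics` data.frame (or any data.frame
#'   with `species` and `mean_speed_ums`).
#' @param zoospore_still um/s threshold for non-motile zoospores.
#' @param vorticella_sessile um/s threshold for sessile Vorticella.
#' @return character vector of motility labels.
#' @export
classify_motility <- function(metrics, zoospore_still = 10,
                              vorticella_sessile = 20) {
  sp <- metrics$species
  v <- metrics$mean_speed_ums
  known <- c("zoospore", "vorticella", "bacterium")
  if (any(!sp %in% known))
    stop("unknown species: ", paste(setdiff(unique(sp), known),
                                    collapse = ", "))
  out <- character(length(sp))
  out[sp == "zoospore"] <-
    ifelse(v[sp == "zoospore"] < zoospore_still, "non_motile", "motile")
  out[sp == "vorticella"] <-
    ifelse(v[sp == "vorticella"] < vorticella_sessile,
           "sessile", "telotroch")
  out[sp == "bacterium"] <- "bacterium"
  out
}
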