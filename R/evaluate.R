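#' Match ground-truth agents to detected spots
#'
#' For every ground-truth agent record, finds the spot whose connected
#' component covers the agent's position (0 when the agent left no
#' detected spot of its own, e.g. because two bodies merged into one
#' blob). The frame is re-binarized and re-labeled with the same
#' settings the segmentation used, so the mapping is exact.
#'
#' @param scene a `microswarm_scene` with a rendered stack.
#' @param threshold,connectivity segmentation settings (must match those
#'   used to produce the spot table being evaluated).
#' @return the scene's truth data.frame with a `spot_id` column (0 = no
#'   covering component).
#' @export
match_truth_to_spots <- function(scene, threshold = 110,
                                 connectivity = 8) {
  stopifnot(inherits(scene, "microswarm_scene"), !is.null(scene$stack))
  ps <- scene$config$pixel_size
  truth <- scene$truth
  truth$spot_id <- 0L
  ny <- dim(scene$stack)[1]; nx <- dim(scene$stack)[2]
  for (k in seq_len(dim(scene$stack)[3])) {
    rows <- which(truth$frame == k)
    if (!length(rows)) next
    lab <- label_mask(suppressWarnings(
      binarize(scene$stack[, , k], threshold)), connectivity)
    j <- pmin(nx, pmax(1L, as.integer(ceiling(truth$x_um[rows] / ps))))
    i <- pmin(ny, pmax(1L, as.integer(ceiling(truth$y_um[rows] / ps))))
    truth$spot_id[rows] <- lab[cbind(i, j)]
  }
  truth
}

#' Species-partition agreement with ground truth
#'
#' Per-spot label agreement: each detected spot is attributed to the
#' ground-truth agent nearest to its centroid (every spot arises from at
#' least one agent), and agreement is the fraction of spots whose
#' assigned species matches that agent's species. Agents occluded inside
#' a merged blob are missed detections, not label errors; they are
#' counted separately as `n_occluded` so merging losses stay visible.
#'
#' @param scene a rendered `microswarm_scene`.
#' @param labeled_spots spot table with a `species` column (from
#'   [partition_spots()]).
#' @param threshold,connectivity segmentation settings used to produce
#'   the spots.
#' @return list with `agreement` (fraction of spots correctly labeled),
#'   `n_spots`, `n_occluded` (agent records sharing a component with
#'   another agent of any species) and a `confusion` table (true x
#'   assigned species, per spot).
#' @export
evaluate_partition <- function(scene, labeled_spots, threshold = 110,
                               connectivity = 8) {
  truth <- match_truth_to_spots(scene, threshold, connectivity)
  sp <- labeled_spots
  true_sp <- character(nrow(sp))
  for (k in unique(sp$frame)) {
    si <- which(sp$frame == k)
    t <- truth[truth$frame == k, , drop = FALSE]
    d2 <- outer(t$x_um, sp$x_um[si], "-")^2 +
      outer(t$y_um, sp$y_um[si], "-")^2
    true_sp[si] <- t$species[max.col(-t(d2))]
  }
  key <- paste(truth$frame, truth$spot_id)
  occluded <- truth$spot_id > 0 &
    key %in% names(which(table(key[truth$spot_id > 0]) > 1))
  list(agreement = mean(sp$species == true_sp), n_spots = nrow(sp),
       n_occluded = sum(occluded),
       confusion = table(true = true_sp, assigned = sp$species))
}

#' Ground-truth link recovery of the tracker
#'
#' A ground-truth link is an agent present in two consecutive frames. A
#' link is *detectable* when both of the agent's positions are covered
#' by detected spots of the agent's species table, neither spot being
#' shared with another agent of the same species (merged same-species
#' bodies yield one spot that cannot stand for two tracks). A link is
#' *recovered* when its two spots are consecutive members of the same
#' reconstructed track. `recovery` is measured over detectable links
#' (the tracker's own performance); `recovery_strict` divides by all
#' ground-truth links, so it additionally charges the tracker for
#' detection losses upstream.
#'
#' @param scene a rendered `microswarm_scene`.
#' @param tracks named list of `microswarm_tracks` (one per species), as
#'   from [build_all_tracks()].
#' @param threshold,connectivity segmentation settings used upstream.
#' @return named list per species: `recovery`, `recovery_strict`,
#'   `n_links` (ground truth), `n_detectable`.
#' @export
evaluate_link_recovery <- function(scene, tracks, threshold = 110,
                                   connectivity = 8) {
  truth <- match_truth_to_spots(scene, threshold, connectivity)
  out <- list()
  for (sp in names(tracks)) {
    long <- as.data.frame(tracks[[sp]])
    tkey <- paste(long$frame, long$spot_id)
    z <- truth[truth$species == sp, , drop = FALSE]
    z <- z[order(z$agent_id, z$frame), , drop = FALSE]
    n <- nrow(z)
    if (n < 2) next
    zk <- paste(z$frame, z$spot_id)
    shared <- z$spot_id > 0 &
      zk %in% names(which(table(zk[z$spot_id > 0]) > 1))
    consec <- z$agent_id[-n] == z$agent_id[-1] &
      z$frame[-1] == z$frame[-n] + 1
    t1 <- long$track_id[match(paste(z$frame[-n], z$spot_id[-n]), tkey)]
    t2 <- long$track_id[match(paste(z$frame[-1], z$spot_id[-1]), tkey)]
    covered <- z$spot_id[-n] > 0 & z$spot_id[-1] > 0 &
      !is.na(t1) & !is.na(t2)
    detectable <- consec & covered & !shared[-n] & !shared[-1]
    linked <- !is.na(t1) & !is.na(t2) & t1 == t2
    out[[sp]] <- list(
      recovery = sum(detectable & linked) / sum(detectable),
      recovery_strict = sum(consec & covered & linked) / sum(consec),
      n_links = sum(consec), n_detectable = sum(detectable))
  }
  out
}

#' Recovered versus configured species speeds
#'
#' Compares the mean of the per-track mean speeds reconstructed by the
#' full pipeline against the mean of each species' configured speed
#' range. Only tracks of motile forms are compared (zoospore tracks
#' below the non-motile threshold and sessile Vorticella are excluded,
#' since those forms are stationary by design).
#'
#' @param metrics a `microswarm_metrics` data.frame.
#' @param models named list of [species_model()]s the scene was run with.
#' @param truth optional ground-truth data.frame of the scene; when
#'   given, the per-species *realized* mean chord speed of the
#'   swimming agents is reported alongside. With few agents of a
#'   species the realized mean can sit well away from the configured
#'   mean by sampling alone, so the realized comparison isolates the
#'   pipeline's measurement error from that sampling noise.
#' @param dt frame interval (s), used for the realized speeds.
#' @param min_links minimum links per track for a stable speed estimate.
#' @return data.frame: species, configured_ums, recovered_ums,
#'   rel_error, n_tracks, and (with `truth`) realized_ums,
#'   rel_error_realized.
#' @export
evaluate_speed_recovery <- function(metrics, models, truth = NULL,
                                    dt = 0.0735, min_links = 5) {
  metrics <- metrics[metrics$n_links >= min_links, , drop = FALSE]
  motility <- classify_motility(metrics)
  keep <- !(motility %in% c("non_motile", "sessile"))
  metrics <- metrics[keep, , drop = FALSE]
  rows <- lapply(names(models), function(sp) {
    v <- metrics$mean_speed_ums[metrics$species == sp]
    conf <- mean(models[[sp]]$speed_range)
    out <- data.frame(species = sp, configured_ums = conf,
                      recovered_ums = mean(v),
                      rel_error = abs(mean(v) - conf) / conf,
                      n_tracks = length(v))
    if (!is.null(truth)) {
      t <- truth[truth$species == sp, , drop = FALSE]
      t <- t[order(t$agent_id, t$frame), , drop = FALSE]
      chord <- vapply(split(t, t$agent_id), function(a) {
        if (nrow(a) < 2 || any(a$mode != "swimming")) return(NA_real_)
        mean(sqrt(diff(a$x_um)^2 + diff(a$y_um)^2)) / dt
      }, 0)
      out$realized_ums <- mean(chord, na.rm = TRUE)
      out$rel_error_realized <-
        abs(out$recovered_ums - out$realized_ums) / out$realized_ums
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
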