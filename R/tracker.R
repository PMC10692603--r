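#' Link spots between two consecutive frames
#'
#' Greedy nearest-neighbor assignment: candidate pairs closer than
#' `d_max` are sorted by ascending distance (ties broken by the lower
#' spot id in frame t, then in frame t+1) and accepted one by one,
#' skipping pairs whose endpoint is already linked. The result is a
#' deterministic one-to-one matching with no link longer than `d_max`.
#'
#' @param spots_t,spots_t1 spot data.frames of the same species for
#'   frames t and t+1 (need columns spot_id, x_um, y_um).
#' @param d_max maximal linking distance, um, > 0.
#' @return data.frame with columns from (spot_id in t), to (spot_id in
#'   t+1) and dist (um); zero rows if nothing links.
#' @examples
#' a <- data.frame(spot_id = 1:2, x_um = c(0, 50), y_um = 0)
#' b <- data.frame(spot_id = 1:2, x_um = c(1, 51), y_um = 0)
#' link_frame_pair(a, b, d_max = 15)
#' @export
link_frame_pair <- function(spots_t, spots_t1, d_max) {
  if (d_max <= 0) stop("d_max must be positive")
  n1 <- nrow(spots_t); n2 <- nrow(spots_t1)
  empty <- data.frame(from = integer(), to = integer(), dist = numeric())
  if (n1 == 0 || n2 == 0) return(empty)
  dx <- outer(spots_t$x_um, spots_t1$x_um, "-")
  dy <- outer(spots_t$y_um, spots_t1$y_um, "-")
  d <- sqrt(dx^2 + dy^2)
  cand <- which(d <= d_max, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  dd <- d[cand]
  o <- order(dd, spots_t$spot_id[cand[, 1]], spots_t1$spot_id[cand[, 2]])
  cand <- cand[o, , drop = FALSE]
  dd <- dd[o]
  used1 <- logical(n1); used2 <- logical(n2)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used1[i] && !used2[j]) {
      used1[i] <- TRUE; used2[j] <- TRUE; keep[k] <- TRUE
    }
  }
  data.frame(from = spots_t$spot_id[cand[keep, 1]],
             to = spots_t1$spot_id[cand[keep, 2]],
             dist = dd[keep])
}

#' Build tracks from a per-species spot table
#'
#' Chains frame-pair links (see [link_frame_pair()]) across the stack
#' into tracks. Links connect strictly consecutive frame indices only;
#' there is no gap closing, splitting or merging. Spots that link to
#' nothing become singleton tracks (non-motile candidates); these are
#' retained in the output with `n_links = 0` and excluded from metric
#' analysis downstream.
#'
#' @param spots spot data.frame of a single species, with columns frame,
#'   spot_id, x_um, y_um (extra columns are carried along). (frame,
#'   spot_id) pairs must be unique.
#' @param d_max maximal linking distance, um. If `NULL`, taken from
#'   `rules` and the table's species.
#' @param rules optional [species_rules()] used to resolve `d_max`.
#' @param species species label stored on the result (defaults to the
#'   table's `species` column if present).
#' @return object of class `microswarm_tracks`: the spot table with a
#'   `track_id` column, ordered by track and frame. Attributes `species`
#'   and `d_max` record the linking parameters.
#' @export
build_tracks <- function(spots, d_max = NULL, rules = NULL,
                         species = NULL) {
  if (is.null(species))
    species <- if (!is.null(spots$species) && nrow(spots) > 0)
      spots$species[1] else NA_character_
  if (is.null(d_max)) {
    if (is.null(rules)) stop("supply d_max or rules")
    d_max <- rules$max_linking_distance[rules$species == species]
    if (length(d_max) != 1) stop("no linking rule for species ", species)
  }
  if (d_max <= 0) stop("d_max must be positive")
  if (nrow(spots) == 0) {
    out <- cbind(spots, track_id = integer(0))
    return(structure(out, class = c("microswarm_tracks", "data.frame"),
                     species = species, d_max = d_max))
  }
  if (anyDuplicated(spots[c("frame", "spot_id")]))
    stop("duplicate (frame, spot_id) in input")
  spots <- spots[order(spots$frame, spots$spot_id), , drop = FALSE]
  frames <- sort(unique(spots$frame))
  by_frame <- split(spots, spots$frame)
  track_of <- vector("list", length(frames)) # per frame: spot_id -> track
  next_id <- 0L
  assign_new <- function(ids) {
    tid <- next_id + seq_along(ids)
    next_id <<- next_id + length(ids)
    stats::setNames(tid, ids)
  }
  f1 <- as.character(frames[1])
  track_of[[1]] <- assign_new(by_frame[[f1]]$spot_id)
  if (length(frames) > 1) {
    for (k in 2:length(frames)) {
      prev <- by_frame[[as.character(frames[k - 1])]]
      cur <- by_frame[[as.character(frames[k])]]
      cur_map <- assign_new(cur$spot_id)
      if (frames[k] == frames[k - 1] + 1) { # consecutive frames only
        links <- link_frame_pair(prev, cur, d_max)
        if (nrow(links) > 0) {
          inherited <- track_of[[k - 1]][as.character(links$from)]
          cur_map[as.character(links$to)] <- inherited
        }
      }
      track_of[[k]] <- cur_map
    }
  }
  tid <- unlist(lapply(seq_along(frames), function(k)
    track_of[[k]][as.character(by_frame[[as.character(frames[k])]]$spot_id)]))
  spots$track_id <- as.integer(tid)
  # renumber tracks 1..n in order of first appearance, drop gaps from
  # provisional ids of spots that later inherited an earlier track
  spots$track_id <- match(spots$track_id, unique(spots$track_id))
  spots <- spots[order(spots$track_id, spots$frame), , drop = FALSE]
  rownames(spots) <- NULL
  structure(spots, class = c("microswarm_tracks", "data.frame"),
            species = species, d_max = d_max)
}

#' @export
print.microswarm_tracks <- function(x, ...) {
  cat(sprintf("<microswarm_tracks> %s: %d spots in %d tracks (d_max %g um)\n",
              attr(x, "species"), nrow(x),
              length(unique(x$track_id)), attr(x, "d_max")))
  invisible(x)
}

#' Build tracks for every species of a partition
#'
#' @param partition result of [partition_spots()].
#' @param rules a [species_rules()] providing per-species maximal
#'   linking distances.
#' @return named list of `microswarm_tracks` (unassigned spots are not
#'   tracked).
#' @export
build_all_tracks <- function(partition, rules = default_species_rules()) {
  out <- lapply(rules$species, function(s)
    build_tracks(partition$tables[[s]], rules = rules, species = s))
  names(out) <- rules$species
  out
}
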