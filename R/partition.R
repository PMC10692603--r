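#' Species classification rules
#'
#' Radius-band rules assigning each detected spot to a species, plus the
#' per-species maximal linking distance used downstream by the tracker.
#' The defaults resolve the double-filter scheme used for these three
#' species: bacteria are spots with equivalent radius <= 4.5 um,
#' zoospores have radius in (4.5, 10] um, Vorticella have radius > 10
#' um; maximal linking distances are 2, 15 and 60 um respectively.
#' Boundary values belong to the smaller-radius class (upper bounds are
#' inclusive, lower bounds strict).
#'
#' @param rules data.frame with columns species, radius_min, radius_max
#'   (um; NA = unbounded) and max_linking_distance (um). Bands must not
#'   overlap.
#' @return object of class `species_rules`.
#' @examples
#' r <- default_species_rules()
#' classify_spot(c(3, 7, 15), r)
#' @export
species_rules <- function(rules) {
  stopifnot(is.data.frame(rules),
            all(c("species", "radius_min", "radius_max",
                  "max_linking_distance") %in% names(rules)))
  if (anyDuplicated(rules$species))
    stop("duplicated species in rules")
  if (any(rules$max_linking_distance <= 0))
    stop("max_linking_distance must be positive")
  lo <- ifelse(is.na(rules$radius_min), -Inf, rules$radius_min)
  hi <- ifelse(is.na(rules$radius_max), Inf, rules$radius_max)
  if (any(lo >= hi)) stop("empty radius band in rules")
  o <- order(lo)
  if (any(hi[o][-length(o)] > lo[o][-1]))
    stop("species radius bands overlap")
  rules <- rules[o, , drop = FALSE]
  rownames(rules) <- NULL
  structure(rules, class = c("species_rules", "data.frame"))
}

#' @rdname species_rules
#' @export
default_species_rules <- function() {
  species_rules(data.frame(
    species = c("bacterium", "zoospore", "vorticella"),
    radius_min = c(NA, 4.5, 10),
    radius_max = c(4.5, 10, NA),
    max_linking_distance = c(2, 15, 60),
    stringsAsFactors = FALSE))
}

#' Classify spots by equivalent radius
#'
#' A spot with radius r belongs to the rule with
#' `radius_min < r <= radius_max` (missing bounds are unbounded). Radii
#' falling in a gap between bands are "unassigned".
#'
#' @param radius numeric vector of equivalent radii (um), or a spot
#'   data.frame with a `radius_um` column.
#' @param rules a [species_rules()] object.
#' @return character vector of species labels ("unassigned" for gaps).
#' @export
classify_spot <- function(radius, rules = default_species_rules()) {
  if (is.data.frame(radius)) radius <- radius$radius_um
  stopifnot(is.numeric(radius), inherits(rules, "species_rules"))
  if (any(radius < 0, na.rm = TRUE)) stop("negative radius")
  out <- rep("unassigned", length(radius))
  for (i in seq_len(nrow(rules))) {
    lo <- rules$radius_min[i]; hi <- rules$radius_max[i]
    ok <- (is.na(lo) | radius > lo) & (is.na(hi) | radius <= hi)
    out[ok] <- rules$species[i]
  }
  out
}

#' Partition a spot table by species
#'
#' Adds a `species` column and splits the table into one sub-table per
#' species plus an `unassigned` table. Every input spot appears in
#' exactly one table.
#'
#' @param spots spot data.frame (from [detect_spots()] or
#'   [segment_stack()]).
#' @param rules a [species_rules()] object.
#' @return list with `spots` (input plus `species` column), `tables`
#'   (named list of per-species data.frames, incl. `unassigned`), and
#'   `counts` (named integer vector).
#' @export
partition_spots <- function(spots, rules = default_species_rules()) {
  species <- classify_spot(spots$radius_um, rules)
  spots$species <- species
  lv <- c(rules$species, "unassigned")
  tables <- lapply(lv, function(s) {
    t <- spots[species == s, , drop = FALSE]
    rownames(t) <- NULL
    t
  })
  names(tables) <- lv
  counts <- vapply(tables, nrow, integer(1))
  stopifnot(sum(counts) == nrow(spots)) # partition is exhaustive
  list(spots = spots, tables = tables, counts = counts)
}
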