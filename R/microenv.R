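#' Square analysis grid over the field
#'
#' Cells are labeled letter-row (top-down) + number-column
#' (left-right): the cell containing the top-left corner is A1, the one
#' to its right A2, the one below B1. Default cell side 170 um.
#'
#' @param cell_side um, > 0.
#' @param field_width,field_height um; used to validate labels.
#' @return object of class `grid_spec`.
#' @examples
#' g <- grid_spec(170, 1000, 800)
#' grid_cell_of(g, c(100, 180), c(50, 50))  # "A1" "A2"
#' @export
grid_spec <- function(cell_side = 170, field_width = 1000,
                      field_height = 800) {
  stopifnot(cell_side > 0, field_width > 0, field_height > 0)
  structure(list(cell_side = cell_side, field_width = field_width,
                 field_height = field_height,
                 n_cols = ceiling(field_width / cell_side),
                 n_rows = ceiling(field_height / cell_side)),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param grid a `grid_spec`.
#' @param x,y coordinates in um.
#' @return `grid_cell_of`: character vector of cell labels.
#' @export
grid_cell_of <- function(grid, x, y) {
  col <- pmin(grid$n_cols, floor(x / grid$cell_side) + 1)
  row <- pmin(grid$n_rows, floor(y / grid$cell_side) + 1)
  paste0(LETTERS[row], col)
}

validate_cells <- function(grid, cells) {
  ok <- grepl("^[A-Z][0-9]+$", cells)
  rows <- match(substr(cells, 1, 1), LETTERS)
  cols <- suppressWarnings(as.integer(substring(cells, 2)))
  bad <- !ok | is.na(rows) | rows > grid$n_rows |
    is.na(cols) | cols < 1 | cols > grid$n_cols
  if (any(bad))
    stop("unknown grid label(s): ", paste(cells[bad], collapse = ", "))
  invisible(cells)
}

#' Define a microenvironment
#'
#' A named set of grid cells, an inclusive 1-based frame range and a
#' species, within which track metrics are aggregated (e.g. "Proximal to
#' KCl", cells A1-A2-A3, frames 1-143, zoospores).
#'
#' @param name label for reporting.
#' @param cells character vector of grid cell labels (non-empty).
#' @param frame_range length-2 inclusive frame interval.
#' @param species species analyzed in this microenvironment.
#' @return object of class `microenvironment`.
#' @export
microenvironment <- function(name, cells, frame_range, species) {
  stopifnot(length(cells) >= 1, length(frame_range) == 2,
            frame_range[1] >= 1, frame_range[1] <= frame_range[2])
  structure(list(name = name, cells = as.character(cells),
                 frame_range = as.integer(frame_range),
                 species = species),
            class = "microenvironment")
}

#' Restrict track metrics to a microenvironment
#'
#' A track belongs to the microenvironment if its species matches, its
#' frame span intersects the frame range, and (under the default
#' `rule = "mean"`) its mean position falls in one of the
#' microenvironment's cells. With `rule = "any"` a track qualifies if
#' any of its spots falls in one of the cells (requires `tracks`).
#'
#' @param metrics a `microswarm_metrics` data.frame.
#' @param grid a [grid_spec()].
#' @param env a [microenvironment()].
#' @param rule "mean" (mean track position) or "any" (any spot).
#' @param tracks long track table, needed for `rule = "any"`.
#' @return the rows of `metrics` belonging to `env` (warns if empty).
#' @export
assign_tracks <- function(metrics, grid, env, rule = c("mean", "any"),
                          tracks = NULL) {
  rule <- match.arg(rule)
  validate_cells(grid, env$cells)
  in_frames <- metrics$first_frame <= env$frame_range[2] &
    metrics$last_frame >= env$frame_range[1]
  sp_ok <- metrics$species == env$species
  if (rule == "mean") {
    cell <- grid_cell_of(grid, metrics$mean_x_um, metrics$mean_y_um)
    in_cells <- cell %in% env$cells
  } else {
    if (is.null(tracks)) stop("rule = 'any' needs the track table")
    tcell <- grid_cell_of(grid, tracks$x_um, tracks$y_um)
    hit <- unique(tracks$track_id[tcell %in% env$cells])
    in_cells <- metrics$track_id %in% hit
  }
  out <- metrics[in_frames & sp_ok & in_cells, , drop = FALSE]
  if (nrow(out) == 0)
    warning("no tracks fall in microenvironment '", env$name, "'")
  rownames(out) <- NULL
  out
}

#' Sidak adjustment for multiple comparisons
#'
#' `p_adj = 1 - (1 - p)^m`, computed with `expm1`/`log1p` for numerical
#' accuracy and clipped to [0, 1]. Non-decreasing in `m` and never
#' smaller than the raw p-value.
#'
#' @param p raw p-values.
#' @param m family size (number of comparisons).
#' @return adjusted p-values.
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1))
  pmin(1, pmax(p, -expm1(m * log1p(-p))))
}

#' One-way ANOVA with Sidak post hoc comparisons
#'
#' Classic fixed-effects one-way ANOVA (F = between-group mean square /
#' within-group mean square) followed by all pairwise t-tests with Sidak
#' adjustment over the family of pairs. Groups smaller than
#' `min_group_size` are refused: ANOVA is unreliable for very small
#' samples, and so comparisons involving them should not be reported.
#'
#' @param groups named (or unnamed) list of >= 2 numeric vectors.
#' @param var_equal logical; pooled-variance (TRUE, default) or Welch
#'   pairwise t-tests.
#' @param alpha significance level recorded on the result.
#' @param min_group_size minimum per-group n (default 2).
#' @return object of class `microswarm_anova`: list with group_names,
#'   group_sizes, F_statistic, anova_p, pairwise (data.frame: pair,
#'   raw_p, sidak_p), alpha.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3, 4), b = c(3, 4, 5, 6)))
#' @export
one_way_anova <- function(groups, var_equal = TRUE, alpha = 0.05,
                          min_group_size = 2) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  names(groups) <- make.unique(names(groups))
  sizes <- lengths(groups)
  if (any(sizes < min_group_size))
    stop("group(s) below the minimum size of ", min_group_size,
         "; one-way ANOVA is not reliable for such small samples")
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), sizes), levels = names(groups))
  if (stats::var(values) == 0)
    stop("all values identical; ANOVA undefined")
  gm <- tapply(values, fac, mean)
  ss_within <- sum((values - gm[fac])^2)
  if (ss_within == 0) { # distinct group means, no within-group spread
    F_stat <- Inf; p <- 0
  } else {
    ow <- stats::oneway.test(values ~ fac, var.equal = TRUE)
    F_stat <- unname(ow$statistic)
    p <- ow$p.value
  }
  pairs <- utils::combn(names(groups), 2)
  raw_p <- apply(pairs, 2, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    if (stats::var(a) == 0 && stats::var(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    stats::t.test(a, b, var.equal = var_equal)$p.value
  })
  m <- ncol(pairs)
  pw <- data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = " vs "),
                   raw_p = raw_p, sidak_p = sidak_adjust(raw_p, m))
  structure(list(group_names = names(groups),
                 group_sizes = as.integer(sizes),
                 F_statistic = F_stat, anova_p = p, pairwise = pw,
                 alpha = alpha),
            class = "microswarm_anova")
}

#' @export
print.microswarm_anova <- function(x, ...) {
  cat(sprintf("<one-way ANOVA> %s (n = %s)\n",
              paste(x$group_names, collapse = " / "),
              paste(x$group_sizes, collapse = " / ")))
  cat(sprintf("  F = %.4g, p = %.4g (alpha %.3g)\n", x$F_statistic,
              x$anova_p, x$alpha))
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare microenvironments pairwise
#'
#' Runs [one_way_anova()] on each requested microenvironment pair for
#' each requested metric, treating each pair as its own comparison
#' family (as the replicate-wise condition pairs are analyzed).
#'
#' @param metrics a `microswarm_metrics` data.frame.
#' @param grid a [grid_spec()].
#' @param env_pairs list of length-2 lists of [microenvironment()]s.
#' @param metric_names metric columns to compare (mean speed and/or
#'   confinement ratio).
#' @param ... passed to [assign_tracks()] and [one_way_anova()].
#' @return data.frame with one row per pair per metric: env_a, env_b,
#'   metric, n_a, n_b, mean_a, mean_b, F, p, sidak_p.
#' @export
compare_microenvironments <- function(metrics, grid, env_pairs,
                                      metric_names = c("mean_speed_ums",
                                                       "confinement_ratio"),
                                      ...) {
  rows <- list()
  for (pr in env_pairs) {
    stopifnot(length(pr) == 2)
    a <- assign_tracks(metrics, grid, pr[[1]])
    b <- assign_tracks(metrics, grid, pr[[2]])
    if (nrow(a) == 0 || nrow(b) == 0)
      stop("empty microenvironment in pair ", pr[[1]]$name, " vs ",
           pr[[2]]$name)
    for (mn in metric_names) {
      g <- list(a[[mn]], b[[mn]])
      names(g) <- c(pr[[1]]$name, pr[[2]]$name)
      res <- one_way_anova(g, ...)
      rows[[length(rows) + 1]] <- data.frame(
        env_a = pr[[1]]$name, env_b = pr[[2]]$name, metric = mn,
        n_a = nrow(a), n_b = nrow(b),
        mean_a = mean(a[[mn]]), mean_b = mean(b[[mn]]),
        F = res$F_statistic, p = res$anova_p,
        sidak_p = res$pairwise$sidak_p[1])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Log-scale frequency histogram of a track metric
#'
#' Relative-frequency histogram (percent) of a per-track metric on a
#' log10 axis, one overlaid outline per species, as used to display
#' area, perimeter and mean-speed distributions.
#'
#' @param metrics a `microswarm_metrics` data.frame.
#' @param metric column to plot (default mean speed).
#' @param breaks number of histogram bins.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the list of per-species histograms.
#' @export
plot_metric_hist <- function(metrics, metric = "mean_speed_ums",
                             breaks = 30, ...) {
  v <- metrics[[metric]]
  keep <- is.finite(v) & v > 0
  lv <- log10(v[keep])
  sp <- metrics$species[keep]
  brk <- seq(min(lv), max(lv), length.out = breaks + 1)
  hs <- lapply(split(lv, sp), function(z)
    graphics::hist(z, breaks = brk, plot = FALSE))
  ymax <- max(vapply(hs, function(h) max(h$counts / sum(h$counts)), 0)) * 100
  graphics::plot(NA, xlim = range(brk), ylim = c(0, ymax),
                 xlab = paste0("log10 ", metric),
                 ylab = "relative frequency (%)", ...)
  cols <- grDevices::hcl.colors(max(2, length(hs)), "Dark 3")
  for (i in seq_along(hs)) {
    h <- hs[[i]]
    graphics::lines(h$mids, 100 * h$counts / sum(h$counts), col = cols[i],
                    lwd = 2)
  }
  graphics::legend("topright", legend = names(hs),
                   col = cols[seq_along(hs)], lwd = 2, bty = "n")
  invisible(hs)
}
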