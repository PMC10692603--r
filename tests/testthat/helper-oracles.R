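# Independent oracles used to check the implementation.

# Brute-force flood-fill connected-component labeling (BFS), independent
# of the package's union-find labeler.
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8)
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
          c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  cur <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    cur <- cur + 1L
    queue <- matrix(c(r0, c0), ncol = 2)
    lab[r0, c0] <- cur
    while (nrow(queue) > 0) {
      p <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        r <- p[1] + offs[k, 1]; c <- p[2] + offs[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue <- rbind(queue, c(r, c))
        }
      }
    }
  }
  lab
}

# same partition of pixels, possibly different numbering
same_labeling <- function(a, b) {
  if (max(a) != max(b)) return(FALSE)
  fg <- a > 0
  if (!identical(fg, b > 0)) return(FALSE)
  length(unique(paste(a[fg], b[fg]))) == max(a)
}

# Exhaustive frame-pair assignment: maximize the number of links under
# d_max, then minimize the summed link distance (full enumeration).
exhaustive_links <- function(spots_t, spots_t1, d_max) {
  n1 <- nrow(spots_t); n2 <- nrow(spots_t1)
  d <- sqrt(outer(spots_t$x_um, spots_t1$x_um, "-")^2 +
              outer(spots_t$y_um, spots_t1$y_um, "-")^2)
  best <- list(n = -1L, cost = Inf, links = NULL)
  recurse <- function(i, used2, links, cost) {
    if (i > n1) {
      n <- nrow(links)
      if (n > best$n || (n == best$n && cost < best$cost))
        best <<- list(n = n, cost = cost, links = links)
      return(invisible())
    }
    recurse(i + 1L, used2, links, cost) # leave spot i unlinked
    for (j in seq_len(n2)) {
      if (!used2[j] && d[i, j] <= d_max) {
        used2[j] <- TRUE
        recurse(i + 1L, used2, rbind(links, c(i, j)), cost + d[i, j])
        used2[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(n2), matrix(integer(0), ncol = 2), 0)
  if (best$n <= 0) return(data.frame(from = integer(), to = integer()))
  data.frame(from = spots_t$spot_id[best$links[, 1]],
             to = spots_t1$spot_id[best$links[, 2]])
}

# one-way ANOVA F from first-principles sums of squares
anova_F_oracle <- function(groups) {
  values <- unlist(groups)
  k <- length(groups)
  n <- length(values)
  grand <- mean(values)
  ss_between <- sum(lengths(groups) *
                      (vapply(groups, mean, 0) - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

# rasterize shapes into an 8-bit frame (independent of the renderer)
frame_with_disk <- function(n, cx, cy, R, bg = 200L, fg = 50L) {
  i <- row(matrix(0, n, n)); j <- col(matrix(0, n, n))
  f <- matrix(bg, n, n)
  f[(i - cy)^2 + (j - cx)^2 <= R^2] <- fg
  f
}

frame_with_ellipse <- function(n, cx, cy, a, b, bg = 200L, fg = 50L) {
  i <- row(matrix(0, n, n)); j <- col(matrix(0, n, n))
  f <- matrix(bg, n, n)
  f[((j - cx) / a)^2 + ((i - cy) / b)^2 <= 1] <- fg
  f
}
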