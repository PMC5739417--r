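# Planar geometry helpers shared by all modules.
#
# Conventions: the chip plane is x-y in SI meters, y increases northward.
# Intersection arms are named by the compass direction (N, E, S, W) of the
# channel leaving the intersection center.

ARMS <- c("N", "E", "S", "W")

# outward unit vector of each compass arm
arm_dir <- function(arm) {
  switch(arm,
    N = c(0, 1), E = c(1, 0), S = c(0, -1), W = c(-1, 0),
    abort(paste0("unknown arm '", arm, "'"))
  )
}

# compass name of a unit direction vector (must be axis-aligned)
dir_arm <- function(d) {
  if (abs(d[1]) > abs(d[2])) {
    if (d[1] > 0) "E" else "W"
  } else {
    if (d[2] > 0) "N" else "S"
  }
}

# rotate a vector 90 degrees counterclockwise: the "left" of a flow direction
rot90ccw <- function(d) c(-d[2], d[1])

# Polyline of a segment in chip coordinates: from-node, waypoints, to-node.
# Returns an n x 2 matrix.
seg_polyline <- function(netlist, seg_row) {
  nodes <- netlist$nodes
  p1 <- unlist(nodes[nodes$id == seg_row$from, c("x", "y")])
  p2 <- unlist(nodes[nodes$id == seg_row$to, c("x", "y")])
  wp <- seg_row$waypoints[[1]]
  if (is.null(wp) || length(wp) == 0) wp <- matrix(numeric(0), ncol = 2)
  rbind(matrix(p1, 1), wp, matrix(p2, 1), deparse.level = 0)
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

# Leg direction vectors of a polyline (unit vectors), one per leg.
polyline_dirs <- function(pts) {
  d <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  d / len
}

# Offset a rectilinear polyline a signed distance `delta` to the left of the
# direction of travel. 90-degree corners are mitered; for perpendicular legs
# the miter point is corner + delta * (l1 + l2), where l1, l2 are the left
# normals of the adjoining legs.
offset_polyline <- function(pts, delta) {
  n <- nrow(pts)
  if (n < 2) return(pts)
  dirs <- polyline_dirs(pts)
  lefts <- t(apply(dirs, 1, rot90ccw))
  out <- matrix(0, n, 2)
  out[1, ] <- pts[1, ] + delta * lefts[1, ]
  out[n, ] <- pts[n, ] + delta * lefts[nrow(lefts), ]
  if (n > 2) {
    for (k in 2:(n - 1)) {
      out[k, ] <- pts[k, ] + delta * (lefts[k - 1, ] + lefts[k, ])
    }
  }
  out
}

# Axis-aligned rectangle covering a polyline leg of a channel of width w,
# with optional extensions beyond each end (used to fill junction cores).
leg_rect <- function(a, b, w, extend_a = 0, extend_b = 0) {
  d <- b - a
  len <- sqrt(sum(d^2))
  u <- d / len
  a <- a - extend_a * u
  b <- b + extend_b * u
  lo <- pmin(a, b) - abs(rot90ccw(u)) * w / 2
  hi <- pmax(a, b) + abs(rot90ccw(u)) * w / 2
  c(lo[1], lo[2], hi[1], hi[2]) # xmin, ymin, xmax, ymax
}

point_in_rects <- function(p, rects) {
  any(p[1] >= rects[, 1] & p[1] <= rects[, 3] &
      p[2] >= rects[, 2] & p[2] <= rects[, 4])
}

# Seed-scoped RNG: run expr under a fixed seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
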