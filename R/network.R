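# Channel-network hydraulics via the electrical-circuit analogy:
# pressure <-> voltage, volumetric flow <-> current, hydraulic resistance
# <-> resistance. Nodal (potential) analysis makes the loop law hold
# identically; the junction law is checked a posteriori.

#' Rectangular-duct geometric form factor
#'
#' Dimensionless correction `F` in the rectangular-channel hydraulic
#' resistance, from the standard infinite-series solution for pressure-driven
#' flow in a rectangular duct:
#' `F = 1 - (192/pi^5) (a/b) sum_{n odd} n^-5 tanh(n pi b / (2a))`
#' where `a` is the shorter and `b` the longer side of the cross section
#' (arguments are swapped internally if needed so the series is evaluated in
#' its convergent regime). The series is truncated at `n = 999`, leaving a
#' tail below 1e-12.
#'
#' @param h Channel height, m.
#' @param w Channel width, m.
#' @param n_max Largest odd series index retained.
#' @return `F` in (0, 1]; approaches 1 in the parallel-plate limit
#'   `h/w -> 0` and is about 0.4217 for a square duct.
#' @export
#' @examples
#' form_factor(100e-6, 200e-6)
form_factor <- function(h, w, n_max = 999) {
  stopifnot(h > 0, w > 0)
  a <- min(h, w)
  b <- max(h, w)
  n <- seq(1, n_max, by = 2)
  1 - (192 / pi^5) * (a / b) * sum(tanh(n * pi * b / (2 * a)) / n^5)
}

#' Hydraulic resistance of a rectangular channel
#'
#' `Rh = 12 eta L / (w h^3 F)` with `F` the rectangular form factor; the
#' pressure drop per unit volumetric flow (Pa s / m^3). The cube applies to
#' the shorter cross-sectional side.
#'
#' @param seg One-row segment tibble (or list) with `length`, `width`,
#'   `height` in m.
#' @param fluid A [fluid_props()] object.
#' @return Resistance in Pa s / m^3.
#' @export
hydraulic_resistance <- function(seg, fluid = fluid_props()) {
  L <- seg$length
  a <- pmin(seg$width, seg$height) # shorter side, cubed in the formula
  b <- pmax(seg$width, seg$height)
  stopifnot(L > 0, a > 0)
  FF <- vapply(seq_along(L), function(i) form_factor(a[i], b[i]), numeric(1))
  12 * fluid$viscosity * L / (b * a^3 * FF)
}

#' Equivalent resistance of channels in series
#' @param values Positive resistances.
#' @return Their sum.
#' @export
series_resistance <- function(values) {
  if (length(values) == 0) abort("series_resistance of an empty list")
  stopifnot(all(values > 0))
  sum(values)
}

#' Equivalent resistance of channels in parallel
#' @param values Positive resistances.
#' @return Reciprocal of the summed reciprocals; never exceeds the minimum.
#' @export
parallel_resistance <- function(values) {
  if (length(values) == 0) abort("parallel_resistance of an empty list")
  stopifnot(all(values > 0))
  1 / sum(1 / values)
}

#' Solve the channel network of a chip
#'
#' Sparse nodal analysis on the resistor-network analog of the chip:
#' per-node pressures, per-segment volumetric flows and mean velocities,
#' and per-intersection signed arm velocities (positive into the
#' intersection). Pressure-type terminals fix node potentials;
#' velocity-type terminals enter as flow sources. If no pressure terminal
#' exists, inflows must balance and the pressure level is pinned at the
#' first node.
#'
#' @param netlist A validated [chip_netlist()].
#' @return A `flow_solution` object with components `pressures` (tibble:
#'   `node`, `pressure` in Pa), `flows` (tibble: `segment`, `from`, `to`,
#'   `Rh`, `Q` in m^3/s signed from -> to, `mean_velocity` in m/s),
#'   `intersections` (tibble: `intersection`, `arm`, `segment`, `velocity`
#'   signed + into the intersection) and `kcl_residual` (max junction-law
#'   residual relative to max |Q|).
#' @export
solve_network <- function(netlist) {
  validate_netlist(netlist)
  nodes <- netlist$nodes
  segs <- netlist$segments
  bc <- netlist$bc
  n <- nrow(nodes)
  idx <- setNames(seq_len(n), nodes$id)
  Rh <- hydraulic_resistance(segs, netlist$fluid)
  g <- 1 / Rh
  ia <- idx[segs$from]
  ib <- idx[segs$to]
  # full Laplacian
  G <- Matrix::sparseMatrix(
    i = c(ia, ib, ia, ib), j = c(ib, ia, ia, ib),
    x = c(-g, -g, g, g), dims = c(n, n)
  )
  pres_bc <- bc[bc$type == "pressure", ]
  vel_bc <- bc[bc$type == "velocity", ]
  src <- numeric(n)
  for (i in seq_len(nrow(vel_bc))) {
    s <- which(segs$from == vel_bc$terminal[i] | segs$to == vel_bc$terminal[i])
    src[idx[vel_bc$terminal[i]]] <- src[idx[vel_bc$terminal[i]]] +
      vel_bc$value[i] * segs$width[s] * segs$height[s]
  }
  p <- numeric(n)
  if (nrow(pres_bc) > 0) {
    fixed <- idx[pres_bc$terminal]
    p[fixed] <- pres_bc$value
  } else {
    fixed <- 1L
    p[fixed] <- 0
  }
  free <- setdiff(seq_len(n), fixed)
  if (length(free)) {
    rhs <- src[free] - as.numeric(G[free, fixed, drop = FALSE] %*% p[fixed])
    sol <- tryCatch(
      Matrix::solve(G[free, free, drop = FALSE], rhs),
      error = function(e) {
        abort(paste0("network system is singular (no pressure reference ",
                     "reachable); ", conditionMessage(e)))
      }
    )
    p[free] <- as.numeric(sol)
  }
  Q <- (p[ia] - p[ib]) * g # signed from -> to
  mean_velocity <- Q / (segs$width * segs$height)
  flows <- tibble::tibble(segment = segs$id, from = segs$from, to = segs$to,
                          Rh = Rh, Q = Q, mean_velocity = mean_velocity)
  # junction-law residual at every node (terminals include their sources)
  resid <- src
  for (s in seq_len(nrow(segs))) {
    resid[ia[s]] <- resid[ia[s]] - Q[s]
    resid[ib[s]] <- resid[ib[s]] + Q[s]
  }
  term_p <- nodes$id %in% pres_bc$terminal
  qmax <- max(abs(Q), 1e-300)
  vals <- abs(resid[!term_p])
  kcl_residual <- if (length(vals)) max(vals) / qmax else 0
  # per-intersection signed arm velocities
  inter <- nodes$id[nodes$kind == "intersection"]
  empty <- tibble::tibble(intersection = character(0), arm = character(0),
                          segment = character(0), velocity = numeric(0))
  intersections <- if (length(inter) == 0) empty else
    purrr::map_dfr(inter, function(nid) {
    amap <- node_arm_map(netlist, nid) # segment id -> arm
    tibble::tibble(
      intersection = nid,
      arm = ARMS,
      segment = vapply(ARMS, function(a) {
        s <- names(amap)[amap == a]
        if (length(s)) s else NA_character_
      }, character(1)),
      velocity = vapply(ARMS, function(a) {
        s <- names(amap)[amap == a]
        if (!length(s)) return(0)
        k <- which(segs$id == s)
        # + into the intersection: flow toward nid
        if (segs$to[k] == nid) mean_velocity[k] else -mean_velocity[k]
      }, numeric(1))
    )
  })
  structure(list(pressures = tibble::tibble(node = nodes$id, pressure = p),
                 flows = flows, intersections = intersections,
                 kcl_residual = kcl_residual, netlist = netlist),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("<flow_solution>\n")
  cat("  segments:", nrow(x$flows), " max |Q| =",
      format(max(abs(x$flows$Q)), digits = 4), "m^3/s\n")
  cat("  junction-law residual (rel.):",
      format(x$kcl_residual, digits = 3), "\n")
  invisible(x)
}

#' Signed arm velocities of one intersection
#'
#' Mean velocities on the four compass arms of an intersection, positive
#' into the intersection; unused arms report exactly 0. These are the
#' boundary conditions handed to the intersection flow solver and the
#' library query.
#'
#' @param sol A `flow_solution`.
#' @param intersection_id Intersection node id.
#' @return Named numeric vector over `c("N","E","S","W")`, m/s.
#' @export
arm_boundary_conditions <- function(sol, intersection_id) {
  tab <- sol$intersections[sol$intersections$intersection == intersection_id, ]
  if (nrow(tab) == 0) {
    abort(paste0("unknown intersection '", intersection_id, "'"))
  }
  setNames(tab$velocity, tab$arm)[ARMS]
}

#' @rdname solve_network
#' @param x A `flow_solution`.
#' @param ... Unused.
#' @export
tidy.flow_solution <- function(x, ...) x$flows

#' @rdname solve_network
#' @export
glance.flow_solution <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$pressures),
    n_segments = nrow(x$flows),
    n_intersections = length(unique(x$intersections$intersection)),
    max_abs_Q = max(abs(x$flows$Q)),
    kcl_residual = x$kcl_residual
  )
}

#' Plot a flow solution
#'
#' Netlist geometry colored by mean flow speed per segment.
#'
#' @param object A `flow_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flow_solution <- function(object, ...) {
  nl <- object$netlist
  lines <- purrr::map_dfr(seq_len(nrow(nl$segments)), function(i) {
    pts <- seg_polyline(nl, nl$segments[i, ])
    tibble::tibble(segment = nl$segments$id[i],
                   speed = abs(object$flows$mean_velocity[i]) * 1e3,
                   x = pts[, 1] * 1e3, y = pts[, 2] * 1e3)
  })
  ggplot2::ggplot(lines, ggplot2::aes(.data$x, .data$y,
                                      group = .data$segment,
                                      colour = .data$speed)) +
    ggplot2::geom_path(linewidth = 2) +
    ggplot2::scale_colour_viridis_c(name = "|v| (mm/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
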