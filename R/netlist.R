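# Chip netlists: the user-supplied decomposition of a chip into terminals,
# 90-degree turns, T/+ intersections, and rectangular channel segments.

#' Fluid properties
#'
#' Dynamic viscosity and density of the working fluid. Defaults describe
#' water at room temperature, the fluid assumed throughout.
#'
#' @param viscosity Dynamic viscosity in Pa s.
#' @param density Density in kg/m^3.
#' @return A `fluid_props` list with elements `viscosity` and `density`.
#' @export
#' @examples
#' fluid_props()
fluid_props <- function(viscosity = 1.0e-3, density = 998) {
  stopifnot(is.numeric(viscosity), viscosity > 0,
            is.numeric(density), density > 0)
  structure(list(viscosity = viscosity, density = density),
            class = "fluid_props")
}

#' Construct a chip netlist
#'
#' A netlist is the graph description of a microfluidic chip: nodes
#' (terminals, 90-degree turns, intersections) at planar positions joined
#' by rectangular channel segments, plus per-terminal boundary conditions.
#' All lengths are SI meters. Positions are node centers; a segment's
#' centerline runs from its `from` node through its waypoints to its `to`
#' node, with every leg axis-aligned and consecutive legs perpendicular.
#'
#' @param nodes Tibble with columns `id`, `kind` (`"terminal"`, `"turn"` or
#'   `"intersection"`), `x`, `y` (m).
#' @param segments Tibble with columns `id`, `from`, `to`, `width`, `height`
#'   (m) and a list-column `waypoints` of k x 2 matrices (possibly empty).
#' @param bc Tibble of boundary conditions with columns `terminal`, `type`
#'   (`"pressure"` in Pa or `"velocity"` in m/s, positive into the chip),
#'   `value`.
#' @param fluid A [fluid_props()] object.
#' @param validate Run [validate_netlist()] on the result (default `TRUE`).
#' @return A `chip_netlist` object.
#' @export
chip_netlist <- function(nodes, segments, bc, fluid = fluid_props(),
                         validate = TRUE) {
  nodes <- tibble::as_tibble(nodes)
  segments <- tibble::as_tibble(segments)
  bc <- tibble::as_tibble(bc)
  if (!"waypoints" %in% names(segments)) {
    segments$waypoints <- rep(list(matrix(numeric(0), ncol = 2)),
                              nrow(segments))
  }
  segments$waypoints <- lapply(segments$waypoints, function(wp) {
    if (is.null(wp) || length(wp) == 0) matrix(numeric(0), ncol = 2)
    else matrix(as.numeric(wp), ncol = 2)
  })
  nl <- structure(list(nodes = nodes, segments = segments, bc = bc,
                       fluid = fluid),
                  class = "chip_netlist")
  nl$segments$length <- vapply(seq_len(nrow(segments)), function(i) {
    polyline_length(seg_polyline(nl, nl$segments[i, ]))
  }, numeric(1))
  if (validate) validate_netlist(nl)
  nl
}

#' @export
print.chip_netlist <- function(x, ...) {
  kinds <- table(x$nodes$kind)
  cat("<chip_netlist>\n")
  cat("  nodes:   ", nrow(x$nodes),
      sprintf(" (%s)", paste(names(kinds), kinds, sep = ": ",
                             collapse = ", ")), "\n", sep = "")
  cat("  segments:", nrow(x$segments),
      sprintf(" total length %.3g mm", sum(x$segments$length) * 1e3), "\n")
  cat("  fluid:    viscosity", x$fluid$viscosity, "Pa s, density",
      x$fluid$density, "kg/m^3\n")
  invisible(x)
}

node_degree <- function(netlist) {
  ids <- netlist$nodes$id
  deg <- setNames(integer(length(ids)), ids)
  for (s in seq_len(nrow(netlist$segments))) {
    deg[netlist$segments$from[s]] <- deg[netlist$segments$from[s]] + 1L
    deg[netlist$segments$to[s]] <- deg[netlist$segments$to[s]] + 1L
  }
  deg
}

# Compass arm of each segment attached to a node: direction of the first
# centerline leg leaving the node. Returns named character vector
# segment id -> arm.
node_arm_map <- function(netlist, node_id) {
  segs <- netlist$segments
  att <- which(segs$from == node_id | segs$to == node_id)
  arms <- character(0)
  for (s in att) {
    pts <- seg_polyline(netlist, segs[s, ])
    if (segs$to[s] == node_id) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
    d <- pts[2, ] - pts[1, ]
    arms[segs$id[s]] <- dir_arm(d / sqrt(sum(d^2)))
  }
  arms
}

#' Validate a chip netlist
#'
#' Checks structural invariants: unique ids, segment endpoints exist,
#' positive dimensions, axis-aligned centerline legs meeting at 90 degrees,
#' node degrees consistent with node kinds (terminals 1, turns 2,
#' intersections 3 or 4 with distinct compass arms), graph connectivity,
#' every terminal carrying a boundary condition, and solvability (at least
#' one pressure terminal, or velocity inflows that balance).
#'
#' @param netlist A `chip_netlist`.
#' @return The netlist, invisibly; errors on the first violation found.
#' @export
validate_netlist <- function(netlist) {
  nodes <- netlist$nodes
  segs <- netlist$segments
  bc <- netlist$bc
  if (anyDuplicated(nodes$id)) abort("duplicate node ids")
  if (anyDuplicated(segs$id)) abort("duplicate segment ids")
  if (!all(nodes$kind %in% c("terminal", "turn", "intersection"))) {
    abort("node kind must be terminal, turn or intersection")
  }
  missing_ep <- setdiff(c(segs$from, segs$to), nodes$id)
  if (length(missing_ep)) {
    abort(paste("segment endpoint references unknown node:",
                paste(missing_ep, collapse = ", ")))
  }
  if (any(segs$width <= 0) || any(segs$height <= 0)) {
    abort("segment width and height must be positive")
  }
  # centerline geometry: axis-aligned legs, consecutive legs perpendicular
  for (i in seq_len(nrow(segs))) {
    pts <- seg_polyline(netlist, segs[i, ])
    d <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    if (any(len <= 0)) abort(paste0("segment '", segs$id[i], "' has a zero-length leg"))
    ax <- abs(d) / len
    if (any(pmin(ax[, 1], ax[, 2]) > 1e-9)) {
      abort(paste0("segment '", segs$id[i], "' has a non-axis-aligned leg"))
    }
    if (nrow(d) > 1) {
      dots <- abs(rowSums(d[-1, , drop = FALSE] * d[-nrow(d), , drop = FALSE]))
      if (any(dots > 1e-18)) {
        abort(paste0("segment '", segs$id[i],
                     "' has consecutive legs that do not meet at 90 degrees"))
      }
    }
  }
  deg <- node_degree(netlist)
  for (i in seq_len(nrow(nodes))) {
    k <- nodes$kind[i]; d <- deg[[nodes$id[i]]]
    ok <- switch(k, terminal = d == 1, turn = d == 2,
                 intersection = d %in% c(3L, 4L))
    if (!ok) {
      abort(paste0(k, " '", nodes$id[i], "' has ", d,
                   " attached segments (terminals need 1, turns 2, ",
                   "intersections 3 or 4)"))
    }
    if (k == "intersection") {
      arms <- node_arm_map(netlist, nodes$id[i])
      if (anyDuplicated(arms)) {
        abort(paste0("intersection '", nodes$id[i],
                     "' has two segments on the same compass arm"))
      }
    }
  }
  # connectivity (undirected BFS)
  adj <- split(c(segs$to, segs$from), c(segs$from, segs$to))
  seen <- nodes$id[1]
  frontier <- seen
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (length(seen) < nrow(nodes)) {
    abort(paste("netlist graph is disconnected; unreachable nodes:",
                paste(setdiff(nodes$id, seen), collapse = ", ")))
  }
  terminals <- nodes$id[nodes$kind == "terminal"]
  if (!all(terminals %in% bc$terminal)) {
    abort(paste("terminal without boundary condition:",
                paste(setdiff(terminals, bc$terminal), collapse = ", ")))
  }
  if (!all(bc$terminal %in% terminals)) {
    abort("boundary condition references a non-terminal node")
  }
  if (!all(bc$type %in% c("pressure", "velocity"))) {
    abort("boundary condition type must be 'pressure' or 'velocity'")
  }
  if (!any(bc$type == "pressure")) {
    # all velocity sources: net volumetric flow must balance
    q <- vapply(seq_len(nrow(bc)), function(i) {
      sid <- which(segs$from == bc$terminal[i] | segs$to == bc$terminal[i])
      bc$value[i] * segs$width[sid] * segs$height[sid]
    }, numeric(1))
    if (abs(sum(q)) > 1e-9 * max(abs(q), 1e-300)) {
      abort("no pressure reference and terminal inflows do not sum to zero")
    }
  }
  invisible(netlist)
}

# ---- JSON serialization ----------------------------------------------------

#' Read a chip netlist from a JSON file
#'
#' The file format is documented in
#' `system.file("extdata", "netlist-schema.md", package = "chipflow")`; an
#' in-file `"units"` key (`"m"`, `"mm"` or `"um"`) declares the unit of all
#' geometric lengths, which are converted to meters on load. Pressures are
#' always Pa and velocities m/s.
#'
#' @param path Path to a netlist JSON file.
#' @return A validated [chip_netlist()].
#' @export
load_netlist <- function(path) {
  if (!file.exists(path)) abort(paste("netlist file not found:", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  for (key in c("nodes", "segments", "boundary_conditions")) {
    if (is.null(raw[[key]])) abort(paste0("netlist file missing key '", key, "'"))
  }
  scale <- switch(as.character(raw$units %||% "m"),
                  m = 1, mm = 1e-3, um = 1e-6,
                  abort(paste0("unknown units '", raw$units, "'")))
  fl <- if (is.null(raw$fluid)) fluid_props() else {
    fluid_props(viscosity = raw$fluid$viscosity, density = raw$fluid$density)
  }
  nodes <- tibble::as_tibble(raw$nodes)
  for (key in c("id", "kind", "x", "y")) {
    if (is.null(nodes[[key]])) abort(paste0("nodes missing key '", key, "'"))
  }
  nodes$x <- nodes$x * scale
  nodes$y <- nodes$y * scale
  segs <- tibble::as_tibble(raw$segments)
  for (key in c("id", "from", "to", "width", "height")) {
    if (is.null(segs[[key]])) abort(paste0("segments missing key '", key, "'"))
  }
  segs$width <- segs$width * scale
  segs$height <- segs$height * scale
  # waypoints may come back as NULL, a ragged list, or (when every segment
  # has the same number of waypoints) a simplified 3-d array
  nseg <- nrow(segs)
  wp_raw <- raw$segments$waypoints
  wp <- vector("list", nseg)
  if (is.null(wp_raw)) {
    wp <- rep(list(matrix(numeric(0), ncol = 2)), nseg)
  } else if (is.array(wp_raw) && length(dim(wp_raw)) == 3) {
    for (i in seq_len(nseg)) wp[[i]] <- matrix(wp_raw[i, , ], ncol = 2)
  } else {
    for (i in seq_len(nseg)) {
      m <- wp_raw[[i]]
      wp[[i]] <- if (is.null(m) || length(m) == 0) {
        matrix(numeric(0), ncol = 2)
      } else matrix(as.numeric(m), ncol = 2)
    }
  }
  segs$waypoints <- lapply(wp, function(m) m * scale)
  segs$length <- NULL
  bc <- tibble::as_tibble(raw$boundary_conditions)
  for (key in c("terminal", "type", "value")) {
    if (is.null(bc[[key]])) {
      abort(paste0("boundary_conditions missing key '", key, "'"))
    }
  }
  chip_netlist(nodes, segs[, c("id", "from", "to", "width", "height",
                               "waypoints")], bc, fl)
}

#' Write a chip netlist to a JSON file
#'
#' @param netlist A `chip_netlist`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_netlist <- function(netlist, path) {
  obj <- list(
    units = "m",
    fluid = list(viscosity = netlist$fluid$viscosity,
                 density = netlist$fluid$density),
    nodes = netlist$nodes[, c("id", "kind", "x", "y")],
    segments = list(
      id = netlist$segments$id,
      from = netlist$segments$from,
      to = netlist$segments$to,
      width = netlist$segments$width,
      height = netlist$segments$height,
      waypoints = netlist$segments$waypoints
    ),
    boundary_conditions = netlist$bc
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

# ---- fixture generators ----------------------------------------------------

default_bc <- function(terminal, type, value) {
  tibble::tibble(terminal = terminal, type = type, value = value)
}

#' Single straight-channel chip
#'
#' Two terminals joined by one straight channel; the minimal fixture, whose
#' flow field is plane Poiseuille flow throughout.
#'
#' @param length Channel length, m.
#' @param w,h Channel width and height, m.
#' @param mean_velocity Inflow mean velocity at the West terminal, m/s.
#' @return A `chip_netlist`.
#' @export
make_straight_chip <- function(length = 1.6e-3, w = 200e-6, h = 100e-6,
                               mean_velocity = 0.01) {
  nodes <- tibble::tibble(id = c("IN", "OUT"), kind = "terminal",
                          x = c(0, length), y = 0)
  segs <- tibble::tibble(id = "s1", from = "IN", to = "OUT",
                         width = w, height = h)
  bc <- default_bc(c("IN", "OUT"), c("velocity", "pressure"),
                   c(mean_velocity, 0))
  chip_netlist(nodes, segs, bc)
}

#' Single-channel chip with one 90-degree turn
#'
#' One channel running east then turning north, used to exercise
#' flow-fraction conservation through turns.
#'
#' @param leg Length of each leg, m.
#' @param w,h Channel width and height, m.
#' @param mean_velocity Inflow mean velocity, m/s.
#' @return A `chip_netlist`.
#' @export
make_elbow_chip <- function(leg = 0.8e-3, w = 200e-6, h = 100e-6,
                            mean_velocity = 0.01) {
  nodes <- tibble::tibble(id = c("IN", "OUT"), kind = "terminal",
                          x = c(0, leg), y = c(0, leg))
  segs <- tibble::tibble(id = "s1", from = "IN", to = "OUT",
                         width = w, height = h,
                         waypoints = list(matrix(c(leg, 0), 1)))
  bc <- default_bc(c("IN", "OUT"), c("velocity", "pressure"),
                   c(mean_velocity, 0))
  chip_netlist(nodes, segs, bc)
}

#' "H" channel chip
#'
#' The classic H layout: two vertical channels joined by a horizontal
#' crossbar, decomposing into seven channel segments, two three-arm
#' intersections (each with an unused fourth arm) and two collinear joint
#' nodes splitting the crossbar into thirds. The geometry is
#' mirror-symmetric about the perpendicular bisector of the crossbar.
#' Default boundary conditions drive 1 cm/s into the top-left terminal and
#' 2 cm/s into the bottom-left terminal, with both right terminals at 0 Pa,
#' so all crossbar flow leaves the left intersection through its East arm
#' at 3 cm/s.
#'
#' @param arm_length Length of each vertical arm, m.
#' @param w,h Channel width and height, m.
#' @param crossbar_length Total crossbar length (split into three equal
#'   segments), m.
#' @param v_top,v_bottom Inlet mean velocities at the left terminals, m/s.
#' @return A `chip_netlist`.
#' @export
make_h_chip <- function(arm_length = 0.8e-3, w = 200e-6, h = 100e-6,
                        crossbar_length = 2.4e-3,
                        v_top = 0.01, v_bottom = 0.02) {
  stopifnot(arm_length > 0, w > 0, h > 0, crossbar_length > 0)
  d <- crossbar_length
  nodes <- tibble::tibble(
    id = c("TL", "BL", "TR", "BR", "b", "j1", "j2", "hh"),
    kind = c(rep("terminal", 4), "intersection", "turn", "turn",
             "intersection"),
    x = c(0, 0, d, d, 0, d / 3, 2 * d / 3, d),
    y = c(arm_length, -arm_length, arm_length, -arm_length, 0, 0, 0, 0)
  )
  segs <- tibble::tibble(
    id = c("a", "c", "d", "e", "f", "g", "i"),
    from = c("TL", "BL", "b", "j1", "j2", "hh", "hh"),
    to = c("b", "b", "j1", "j2", "hh", "TR", "BR"),
    width = w, height = h
  )
  bc <- default_bc(c("TL", "BL", "TR", "BR"),
                   c("velocity", "velocity", "pressure", "pressure"),
                   c(v_top, v_bottom, 0, 0))
  chip_netlist(nodes, segs, bc)
}

#' Cascade chip: a chain of T-intersections along a vertical spine
#'
#' Reference layout with `n_inlets` inlet terminals and `n_outlets` outlet
#' terminals joined by `n_inlets + n_outlets - 2` T-intersections stacked
#' top to bottom. With the default (3, 2) this is a chip with three inlets,
#' two outlets and three intersections (labeled `a`, `b`, `c` from top to
#' bottom): `a` takes East and West inlets, `b` takes an East inlet, `c`
#' feeds an East outlet, and the spine drains through the bottom South
#' outlet. Default boundary conditions set every inlet to 3.5 mm/s and
#' draw 3 mm/s through each East outlet, with the South outlet as the 0 Pa
#' reference.
#'
#' @param n_inlets Number of inlet terminals (>= 2).
#' @param n_outlets Number of outlet terminals (>= 1).
#' @param seg_length Center-to-center length of every segment, m.
#' @param w,h Channel width and height, m.
#' @param inlet_velocity Mean inflow velocity at each inlet terminal, m/s.
#' @param east_outlet_velocity Mean outflow velocity drawn at each East
#'   outlet terminal, m/s.
#' @return A `chip_netlist`.
#' @export
make_cascade_chip <- function(n_inlets = 3, n_outlets = 2,
                              seg_length = 0.8e-3, w = 200e-6, h = 100e-6,
                              inlet_velocity = 3.5e-3,
                              east_outlet_velocity = 3e-3) {
  stopifnot(n_inlets >= 2, n_outlets >= 1, seg_length > 0)
  K <- n_inlets + n_outlets - 2
  int_id <- letters[seq_len(K)]
  nodes <- tibble::tibble(
    id = int_id, kind = "intersection", x = 0,
    y = -(seq_len(K) - 1) * seg_length
  )
  segs <- tibble::tibble(id = character(0), from = character(0),
                         to = character(0), width = numeric(0),
                         height = numeric(0))
  bc <- tibble::tibble(terminal = character(0), type = character(0),
                       value = numeric(0))
  add_node <- function(id, kind, x, y) {
    nodes <<- dplyr::bind_rows(nodes, tibble::tibble(
      id = id, kind = kind, x = x, y = y))
  }
  add_seg <- function(id, from, to) {
    segs <<- dplyr::bind_rows(segs, tibble::tibble(
      id = id, from = from, to = to, width = w, height = h))
  }
  # West inlet of the first intersection
  add_node("W1", "terminal", -seg_length, 0)
  add_seg("w1", "W1", int_id[1])
  bc <- dplyr::bind_rows(bc, default_bc("W1", "velocity", inlet_velocity))
  # East terminals: inlets for intersections 1..(n_inlets - 1), outlets after
  for (k in seq_len(K)) {
    tid <- paste0("E", k)
    add_node(tid, "terminal", seg_length, -(k - 1) * seg_length)
    add_seg(paste0("e", k), tid, int_id[k])
    if (k <= n_inlets - 1) {
      bc <- dplyr::bind_rows(bc, default_bc(tid, "velocity", inlet_velocity))
    } else {
      bc <- dplyr::bind_rows(bc, default_bc(tid, "velocity",
                                            -east_outlet_velocity))
    }
  }
  # spine
  if (K > 1) {
    for (k in seq_len(K - 1)) {
      add_seg(paste0("m", k), int_id[k], int_id[k + 1])
    }
  }
  add_node("SOUT", "terminal", 0, -K * seg_length)
  add_seg("sout", int_id[K], "SOUT")
  bc <- dplyr::bind_rows(bc, default_bc("SOUT", "pressure", 0))
  chip_netlist(nodes, segs, bc)
}

#' Random rectilinear grid chip
#'
#' Generates a connected random chip on a `rows` x `cols` grid of nodes:
#' a uniform random spanning tree plus extra grid edges retained with
#' probability `keep_prob`. Degree-1 nodes become terminals, degree-2 nodes
#' turns (90-degree corners or collinear joints), higher degrees T/+
#' intersections. The terminal with the lexicographically smallest id is
#' driven at 10 Pa and all other terminals are held at 0 Pa.
#'
#' @param seed Integer seed; the same seed always yields the same chip.
#' @param rows,cols Grid dimensions (>= 2).
#' @param pitch Grid pitch (segment length), m.
#' @param w,h Channel width and height, m.
#' @param keep_prob Probability of retaining each non-tree grid edge.
#' @return A `chip_netlist`.
#' @export
make_random_grid_chip <- function(seed, rows = 3, cols = 3, pitch = 0.8e-3,
                                  w = 200e-6, h = 100e-6, keep_prob = 0.3) {
  stopifnot(rows >= 2, cols >= 2)
  with_seed(seed, {
    node_id <- function(r, c) sprintf("n%02d_%02d", r, c)
    # all grid edges
    edges <- list()
    for (r in seq_len(rows)) for (c in seq_len(cols)) {
      if (c < cols) edges[[length(edges) + 1]] <- c(node_id(r, c), node_id(r, c + 1))
      if (r < rows) edges[[length(edges) + 1]] <- c(node_id(r, c), node_id(r + 1, c))
    }
    edges <- edges[sample.int(length(edges))]
    # randomized Kruskal spanning tree
    parent <- setNames(seq_len(rows * cols),
                       as.vector(outer(seq_len(rows), seq_len(cols), node_id)))
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    keep <- logical(length(edges))
    for (k in seq_along(edges)) {
      a <- find(which(names(parent) == edges[[k]][1]))
      b <- find(which(names(parent) == edges[[k]][2]))
      if (a != b) {
        parent[a] <- b
        keep[k] <- TRUE
      } else {
        keep[k] <- runif(1) < keep_prob
      }
    }
    edges <- edges[keep]
    # stub terminals at opposite corners guarantee an inlet and an outlet
    # even when every grid node keeps degree >= 2
    edges[[length(edges) + 1]] <- c("tin", node_id(1, 1))
    edges[[length(edges) + 1]] <- c(node_id(rows, cols), "tout")
    used <- sort(unique(unlist(edges)))
    coords <- do.call(rbind, lapply(used, function(id) {
      if (id == "tin") return(c(x = -pitch, y = 0))
      if (id == "tout") return(c(x = cols * pitch, y = -(rows - 1) * pitch))
      rc <- as.integer(strsplit(sub("^n", "", id), "_")[[1]])
      c(x = (rc[2] - 1) * pitch, y = -(rc[1] - 1) * pitch)
    }))
    deg <- setNames(integer(length(used)), used)
    for (e in edges) { deg[e[1]] <- deg[e[1]] + 1L; deg[e[2]] <- deg[e[2]] + 1L }
    kind <- ifelse(deg == 1L, "terminal", ifelse(deg == 2L, "turn",
                                                 "intersection"))
    nodes <- tibble::tibble(id = used, kind = unname(kind[used]),
                            x = coords[, 1], y = coords[, 2])
    segs <- tibble::tibble(
      id = sprintf("s%03d", seq_along(edges)),
      from = vapply(edges, `[`, character(1), 1),
      to = vapply(edges, `[`, character(1), 2),
      width = w, height = h
    )
    terminals <- sort(nodes$id[nodes$kind == "terminal"])
    bc <- default_bc(terminals, "pressure",
                     c(10, rep(0, length(terminals) - 1)))
    chip_netlist(nodes, segs, bc)
  })
}

#' Plot a chip netlist
#'
#' Draws segment centerlines scaled by channel width, with nodes marked by
#' kind. Coordinates are shown in millimeters.
#'
#' @param object A `chip_netlist`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chip_netlist <- function(object, ...) {
  lines <- purrr::map_dfr(seq_len(nrow(object$segments)), function(i) {
    pts <- seg_polyline(object, object$segments[i, ])
    tibble::tibble(segment = object$segments$id[i],
                   x = pts[, 1] * 1e3, y = pts[, 2] * 1e3)
  })
  nodes <- object$nodes
  ggplot2::ggplot() +
    ggplot2::geom_path(data = lines,
                       ggplot2::aes(.data$x, .data$y, group = .data$segment),
                       linewidth = 2, colour = "steelblue", alpha = 0.7) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x * 1e3, .data$y * 1e3,
                                     shape = .data$kind), size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", shape = NULL) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
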