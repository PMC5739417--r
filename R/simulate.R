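# Whole-chip particle simulation: network solve -> entry flow fraction ->
# alternating channel propagation (q conserved along streamlines through
# straight segments and 90-degree turns) and library-backed intersection
# traversal, until each particle reaches a chip outlet or freezes.

UNIT_FOOTPRINT <- 1.6e-3
UNIT_WIDTH <- 200e-6
UNIT_CENTER <- c(UNIT_FOOTPRINT / 2, UNIT_FOOTPRINT / 2)
# Polyline hand-off radius around an intersection center: the junction core
# (width/2) plus one channel width of flow-development length, where the
# traced streamline has relaxed onto its asymptotic transverse offset.
HANDOFF_HALF <- UNIT_WIDTH / 2 + UNIT_WIDTH

# q measured from the left bank flips under reflections (det -1)
map_q <- function(q, transform) if (transform$mirror) 1 - q else q

#' Propagate a flow fraction through one channel segment
#'
#' At low Reynolds number the cumulative flow fraction `q` (measured from
#' the left bank of the flow) is conserved along streamlines through
#' straight channels and 90-degree turns, so `q_out = q_in`; the particle
#' path is the centerline polyline offset to the transverse position
#' implied by `q`.
#'
#' @param netlist A [chip_netlist()].
#' @param segment_id Segment to traverse.
#' @param q_in Flow fraction in `[0, 1]`.
#' @param reverse Traverse from `to` to `from` instead.
#' @return List with `q_out` (= `q_in`) and `polyline` (n x 2 matrix, m).
#' @export
propagate_channel <- function(netlist, segment_id, q_in, reverse = FALSE) {
  if (q_in < 0 || q_in > 1) abort("q_in must lie in [0, 1]")
  s <- which(netlist$segments$id == segment_id)
  if (length(s) == 0) abort(paste0("unknown segment '", segment_id, "'"))
  seg <- netlist$segments[s, ]
  pts <- seg_polyline(netlist, seg)
  if (reverse) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  t <- flow_fraction_inverse(q_in, seg$width)
  list(q_out = q_in, polyline = offset_polyline(pts, seg$width / 2 - t))
}

# move the first/last point of a rectilinear polyline inward along its leg
trim_polyline <- function(pts, start_trim = 0, end_trim = 0) {
  n <- nrow(pts)
  if (start_trim > 0) {
    d <- pts[2, ] - pts[1, ]
    len <- sqrt(sum(d^2))
    pts[1, ] <- pts[1, ] + d / len * min(start_trim, 0.9 * len)
  }
  if (end_trim > 0) {
    d <- pts[n - 1, ] - pts[n, ]
    len <- sqrt(sum(d^2))
    pts[n, ] <- pts[n, ] + d / len * min(end_trim, 0.9 * len)
  }
  pts
}

# Follow segments from `node` through any chain of turn nodes, returning
# the centerline polyline (starting at node's center), the far node, the
# list of segment ids traversed, and the channel width.
channel_run <- function(netlist, node, via_segment, flows) {
  segs <- netlist$segments
  pts <- NULL
  ids <- character(0)
  cur <- node
  seg_id <- via_segment
  repeat {
    s <- which(segs$id == seg_id)
    seg <- segs[s, ]
    p <- seg_polyline(netlist, seg)
    forward <- seg$from == cur
    if (!forward) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    q_along <- flows$Q[flows$segment == seg_id]
    if ((forward && q_along < 0) || (!forward && q_along > 0)) {
      abort(paste0("flow in segment '", seg_id,
                   "' opposes the particle's direction of travel"))
    }
    pts <- if (is.null(pts)) p else rbind(pts, p[-1, , drop = FALSE])
    ids <- c(ids, seg_id)
    nxt <- if (forward) seg$to else seg$from
    kind <- netlist$nodes$kind[netlist$nodes$id == nxt]
    if (kind != "turn") {
      return(list(end_node = nxt, polyline = pts, segments = ids,
                  width = seg$width))
    }
    att <- segs$id[segs$from == nxt | segs$to == nxt]
    seg_id <- setdiff(att, seg_id)
    cur <- nxt
  }
}

# drop successive duplicated/collinear points so offsetting is stable
simplify_polyline <- function(pts) {
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 1e-15)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) <= 2) return(pts)
  d <- polyline_dirs(pts)
  col <- c(FALSE, abs(d[-1, 1] * d[-nrow(d), 2] -
                        d[-1, 2] * d[-nrow(d), 1]) < 1e-12, FALSE)
  pts[!col, , drop = FALSE]
}

#' Traverse an intersection using the pre-simulated library
#'
#' Retrieves the best-matching library record for the intersection's
#' boundary spec and predicts the particle's passage. Mode `"A"`
#' (default) re-traces the particle on the retrieved velocity field from
#' the entry position implied by `q_in` — the field is precomputed, so
#' this costs only the trace. Mode `"B"` interpolates the exit flow
#' fraction between the two stored release trajectories bracketing the
#' entry (requiring both to exit through the same arm; otherwise the
#' outcome snaps to the nearer release, recorded in the provenance).
#'
#' @param q_in Entry flow fraction.
#' @param entry_arm Compass arm through which the particle enters.
#' @param spec [unit_intersection_spec()] of the intersection.
#' @param library An `intersection_library`.
#' @param diameter Particle diameter, m.
#' @param mode `"A"` (re-trace) or `"B"` (bank interpolation).
#' @return List with `fate` (`"exited"`/`"frozen"`), `exit_arm`, `q_out`,
#'   `polyline` (local coordinates relative to the intersection center),
#'   and `provenance` (record id, match distance, mode, snap flag).
#' @export
traverse_intersection <- function(q_in, entry_arm, spec, library, diameter,
                                  mode = c("A", "B")) {
  mode <- match.arg(mode)
  match <- query_library(spec, library)
  rec <- library$records[[match$record_id]]
  tr_inv <- invert_spec_transform(match$transform)
  arm_can <- transform_arm(entry_arm, tr_inv)
  q_can <- map_q(q_in, match$transform)
  if (rec$spec$roles[arm_can] != "inlet") {
    abort(paste0("entry arm ", entry_arm,
                 " is not an inlet of the matched record"))
  }
  prov <- list(record_id = match$record_id, distance = match$distance,
               mode = mode, snap = FALSE)

  if (mode == "A") {
    start <- mouth_position(rec$field$domain, arm_can, q_can, "in")
    tr <- trace_particle(rec$field, start, diameter = diameter)
    pts_can <- tr$points
    fate <- tr$fate
    exit_arm_can <- tr$exit_arm
    q_out_can <- tr$q_exit
  } else {
    bank <- rec$bank[rec$bank$arm == arm_can, ]
    if (nrow(bank) == 0) abort("matched record has no bank for this inlet")
    dd <- abs(bank$diameter - diameter)
    bank <- bank[dd == min(dd), ]
    bank <- bank[order(bank$q_entry), ]
    lo <- max(which(bank$q_entry <= q_can), 0L)
    hi <- min(which(bank$q_entry >= q_can), nrow(bank) + 1L)
    if (lo == 0L) lo <- hi
    if (hi > nrow(bank)) hi <- lo
    nearer <- if (abs(bank$q_entry[lo] - q_can) <=
                    abs(bank$q_entry[hi] - q_can)) lo else hi
    can_interp <- lo != hi &&
      bank$fate[lo] == "exited" && bank$fate[hi] == "exited" &&
      identical(bank$exit_arm[lo], bank$exit_arm[hi])
    if (can_interp) {
      w1 <- (bank$q_entry[hi] - q_can) /
        (bank$q_entry[hi] - bank$q_entry[lo])
      q_out_can <- w1 * bank$q_exit[lo] + (1 - w1) * bank$q_exit[hi]
      fate <- "exited"
      exit_arm_can <- bank$exit_arm[lo]
    } else {
      prov$snap <- TRUE
      fate <- bank$fate[nearer]
      exit_arm_can <- bank$exit_arm[nearer]
      q_out_can <- bank$q_exit[nearer]
    }
    pts_can <- bank$trajectory[[nearer]]$points
  }

  pts <- transform_points(pts_can, match$transform, UNIT_CENTER)
  rel <- sweep(pts, 2, UNIT_CENTER)
  if (fate == "exited") {
    half <- HANDOFF_HALF + 1e-9
    inside <- abs(rel[, 1]) <= half & abs(rel[, 2]) <= half
    if (any(inside)) rel <- rel[inside, , drop = FALSE]
    list(fate = "exited",
         exit_arm = transform_arm(exit_arm_can, match$transform),
         q_out = map_q(q_out_can, match$transform),
         polyline = rel, provenance = prov)
  } else {
    list(fate = "frozen", exit_arm = NA_character_, q_out = NA_real_,
         polyline = rel, provenance = prov)
  }
}

#' Uniform particle releases at a chip terminal
#'
#' `n` release flow fractions for particles entering at a terminal,
#' evenly spaced in transverse position across the terminal mouth and
#' inset one particle radius from each wall (a single release sits at the
#' center).
#'
#' @param netlist A [chip_netlist()].
#' @param terminal Terminal id (repeatable, vectorized).
#' @param n Releases per terminal.
#' @param diameter Particle diameter, m.
#' @return Tibble with columns `terminal`, `diameter`, `q`.
#' @export
particle_releases <- function(netlist, terminal, n = 1, diameter = 1e-6) {
  purrr::map_dfr(terminal, function(term) {
    s <- which(netlist$segments$from == term | netlist$segments$to == term)
    if (length(s) != 1) abort(paste0("'", term, "' is not a terminal"))
    w <- netlist$segments$width[s]
    r <- diameter / 2
    if (diameter >= w) abort("particle diameter exceeds the channel width")
    t <- if (n == 1) w / 2 else seq(r, w - r, length.out = n)
    tibble::tibble(terminal = term, diameter = diameter,
                   q = flow_fraction(t, w))
  })
}

terminal_mouth_left <- function(netlist, term) {
  # inflow direction and its left normal at a terminal mouth
  s <- which(netlist$segments$from == term | netlist$segments$to == term)
  seg <- netlist$segments[s, ]
  pts <- seg_polyline(netlist, seg)
  if (seg$to == term) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  d <- pts[2, ] - pts[1, ]
  d <- d / sqrt(sum(d^2))
  list(dir_in = d, left = rot90ccw(d), width = seg$width,
       center = pts[1, ], segment = seg$id)
}

#' Simulate particle paths through a whole chip
#'
#' The complete decomposed simulation: solves the channel network by the
#' circuit analogy, converts each particle release to a flow fraction at
#' its inlet terminal, then alternates channel propagation (q conserved)
#' and library-backed intersection traversal until every particle reaches
#' an outlet terminal or freezes at a wall.
#'
#' @param netlist A library-compatible [chip_netlist()] (200 um channel
#'   widths, T/+ intersections, 90-degree turns).
#' @param particles Tibble of releases as from [particle_releases()]:
#'   columns `terminal`, `diameter`, `q`.
#' @param library An `intersection_library`.
#' @param mode Intersection traversal mode, `"A"` or `"B"` (see
#'   [traverse_intersection()]).
#' @param strict_envelope Abort if any intersection inlet exceeds the
#'   library envelope of 2 cm/s (the validity region of the pre-simulated
#'   database) rather than relying on Stokes scale invariance.
#' @return A `simulation_report`: tibble of per-particle outcomes plus
#'   the network solution, per-intersection match provenance, and library
#'   coverage statistics.
#' @export
simulate_chip <- function(netlist, particles, library, mode = c("A", "B"),
                          strict_envelope = TRUE) {
  mode <- match.arg(mode)
  t0 <- proc.time()[["elapsed"]]
  if (any(abs(netlist$segments$width - UNIT_WIDTH) > 1e-12)) {
    abort("library-backed simulation requires 200 um channel widths")
  }
  sol <- solve_network(netlist)
  inter_ids <- unique(sol$intersections$intersection)
  specs <- list()
  for (nid in inter_ids) {
    av <- arm_boundary_conditions(sol, nid)
    av[abs(av) < 1e-15 * max(abs(av))] <- 0
    if (strict_envelope && any(av > ENVELOPE_VMAX * (1 + 1e-9))) {
      abort(paste0("intersection '", nid, "' has an inlet at ",
                   format(max(av) * 100), " cm/s, outside the library ",
                   "envelope of 0-2 cm/s"))
    }
    specs[[nid]] <- unit_intersection_spec(av)
  }
  nodes <- netlist$nodes
  rows <- list()
  for (pi in seq_len(nrow(particles))) {
    term <- particles$terminal[pi]
    diam <- particles$diameter[pi]
    q <- particles$q[pi]
    tm <- terminal_mouth_left(netlist, term)
    q_flow <- sol$flows[sol$flows$segment == tm$segment, ]
    into <- if (q_flow$from == term) q_flow$Q > 0 else q_flow$Q < 0
    if (!into) {
      abort(paste0("terminal '", term, "' is not an inflow terminal"))
    }
    poly <- NULL
    prov <- NULL
    max_gap <- 0
    append_piece <- function(piece) {
      if (!is.null(poly) && nrow(piece) > 0) {
        gap <- sqrt(sum((piece[1, ] - poly[nrow(poly), ])^2))
        max_gap <<- max(max_gap, gap)
      }
      poly <<- if (is.null(poly)) piece else rbind(poly, piece)
    }
    q_log <- tibble::tibble(stage = character(0), q = numeric(0))
    fate <- NA_character_
    exit_terminal <- NA_character_
    node <- term
    via <- tm$segment
    guard <- 0L
    while (is.na(fate)) {
      guard <- guard + 1L
      if (guard > 10L * nrow(netlist$segments)) {
        abort("particle traversal did not terminate")
      }
      run <- channel_run(netlist, node, via, sol$flows)
      kind_end <- nodes$kind[nodes$id == run$end_node]
      ctr <- simplify_polyline(run$polyline)
      start_trim <- if (nodes$kind[nodes$id == node] == "intersection") {
        HANDOFF_HALF
      } else 0
      end_trim <- if (kind_end == "intersection") HANDOFF_HALF else 0
      ctr <- trim_polyline(ctr, start_trim, end_trim)
      t <- flow_fraction_inverse(q, run$width)
      off <- offset_polyline(ctr, run$width / 2 - t)
      append_piece(off)
      q_log <- dplyr::bind_rows(q_log, tibble::tibble(
        stage = paste0("channel:", paste(run$segments, collapse = "+")),
        q = q))
      if (kind_end == "terminal") {
        fate <- "exited"
        exit_terminal <- run$end_node
        break
      }
      # intersection traversal
      nid <- run$end_node
      amap <- node_arm_map(netlist, nid)
      entry_arm <- unname(amap[tail(run$segments, 1)])
      res <- traverse_intersection(q, entry_arm, specs[[nid]], library,
                                   diam, mode)
      npos <- unlist(nodes[nodes$id == nid, c("x", "y")])
      loc <- sweep(res$polyline, 2, -npos)
      if (res$fate == "exited") append_piece(loc) else poly <- rbind(poly, loc)
      prov <- dplyr::bind_rows(prov, tibble::tibble(
        intersection = nid, record_id = res$provenance$record_id,
        distance = res$provenance$distance, mode = mode,
        snap = res$provenance$snap, entry_arm = entry_arm,
        exit_arm = res$exit_arm, q_in = q, q_out = res$q_out))
      if (res$fate == "frozen") {
        fate <- "frozen"
        break
      }
      q <- res$q_out
      q_log <- dplyr::bind_rows(q_log, tibble::tibble(
        stage = paste0("intersection:", nid), q = q))
      via <- unname(names(amap)[amap == res$exit_arm])
      node <- nid
    }
    traj <- structure(list(points = poly, fate = fate,
                           exit_terminal = exit_terminal, q_exit = q,
                           max_stitch_gap = max_gap,
                           provenance = prov, q_log = q_log),
                      class = "chip_trajectory")
    rows[[pi]] <- tibble::tibble(
      particle = pi, terminal = term, diameter = diam,
      q_entry = particles$q[pi], fate = fate,
      exit_terminal = exit_terminal,
      q_exit = ifelse(fate == "exited", q, NA_real_),
      max_match_distance = if (is.null(prov)) 0 else max(prov$distance),
      trajectory = list(traj))
  }
  out <- dplyr::bind_rows(rows)
  structure(list(particles = out, network = sol, mode = mode,
                 wall_clock = proc.time()[["elapsed"]] - t0,
                 coverage = list(
                   max_match_distance = max(out$max_match_distance),
                   n_records = length(library$records))),
            class = "simulation_report")
}

#' @export
print.simulation_report <- function(x, ...) {
  cat("<simulation_report> ", nrow(x$particles), " particle(s), mode ",
      x$mode, ", ", sum(x$particles$fate == "exited"), " exited, ",
      sum(x$particles$fate == "frozen"), " frozen; max match distance ",
      format(x$coverage$max_match_distance, digits = 3),
      "; ", format(x$wall_clock, digits = 3), " s\n", sep = "")
  invisible(x)
}

#' @rdname simulate_chip
#' @param x A `simulation_report`.
#' @param ... Unused.
#' @export
tidy.simulation_report <- function(x, ...) {
  dplyr::select(x$particles, -"trajectory")
}

#' @rdname simulate_chip
#' @export
glance.simulation_report <- function(x, ...) {
  tibble::tibble(
    n_particles = nrow(x$particles),
    n_exited = sum(x$particles$fate == "exited"),
    n_frozen = sum(x$particles$fate == "frozen"),
    max_match_distance = x$coverage$max_match_distance,
    library_records = x$coverage$n_records,
    wall_clock = x$wall_clock
  )
}

#' Plot a simulation report
#'
#' Chip layout with the simulated particle paths overlaid.
#'
#' @param object A `simulation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.simulation_report <- function(object, ...) {
  nl <- object$network$netlist
  base <- autoplot(nl)
  paths <- purrr::map_dfr(seq_len(nrow(object$particles)), function(i) {
    tr <- object$particles$trajectory[[i]]
    tibble::tibble(particle = factor(i), x = tr$points[, 1] * 1e3,
                   y = tr$points[, 2] * 1e3)
  })
  base +
    ggplot2::geom_path(data = paths,
                       ggplot2::aes(.data$x, .data$y,
                                    colour = .data$particle),
                       linewidth = 0.6)
}

#' Compare the decomposed simulation against the direct solver
#'
#' Runs [simulate_chip()] and, independently, [trace_particle()] on the
#' whole-chip Stokes field from [solve_full_chip()], then reports the
#' absolute lateral (transverse) exit-position difference per particle.
#' This is the package's internal accuracy oracle for the decomposition.
#'
#' @param netlist,particles,library As in [simulate_chip()].
#' @param spacing Grid spacing of the direct solve, m.
#' @param mode Intersection traversal mode for the decomposed route.
#' @param strict_envelope Passed to [simulate_chip()].
#' @return Tibble with one row per particle: exit terminals from both
#'   routes, lateral exit positions `t_decomposed` / `t_direct` (m,
#'   measured from the left bank of the outflow), and `discrepancy` (m).
#' @export
compare_with_direct <- function(netlist, particles, library,
                                spacing = 4e-6, mode = "A",
                                strict_envelope = TRUE) {
  rep <- simulate_chip(netlist, particles, library, mode = mode,
                       strict_envelope = strict_envelope)
  field <- solve_full_chip(netlist, spacing)
  purrr::map_dfr(seq_len(nrow(particles)), function(i) {
    term <- particles$terminal[i]
    start <- mouth_position(field$domain, term, particles$q[i], "in")
    tr <- trace_particle(field, start, diameter = particles$diameter[i])
    dec <- rep$particles[i, ]
    w <- UNIT_WIDTH
    t_dec <- if (dec$fate == "exited") {
      flow_fraction_inverse(dec$q_exit, w)
    } else NA_real_
    t_dir <- if (tr$fate == "exited") {
      flow_fraction_inverse(tr$q_exit, w)
    } else NA_real_
    same <- identical(dec$exit_terminal, tr$exit_arm)
    tibble::tibble(
      particle = i, terminal = term,
      exit_decomposed = dec$exit_terminal, exit_direct = tr$exit_arm,
      same_exit = same,
      q_decomposed = dec$q_exit, q_direct = tr$q_exit,
      t_decomposed = t_dec, t_direct = t_dir,
      discrepancy = if (same) abs(t_dec - t_dir) else Inf)
  })
}
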