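# Massless particle advection along streamlines of a solved velocity
# field, with finite-size wall-freeze semantics: a particle whose
# center-to-wall distance falls to its radius sticks permanently.

#' Cumulative flow fraction across a channel
#'
#' The streamline coordinate used to propagate particles between
#' intersections: `q(y)` is the fraction of the channel's volumetric flow
#' passing between the wall at `y = 0` and the transverse position `y`,
#' under the fully developed parabolic profile. `q = 3 s^2 - 2 s^3` with
#' `s = y / width`; strictly increasing from 0 to 1.
#'
#' @param y Transverse position in `[0, width]`, m.
#' @param width Channel width, m.
#' @return Flow fraction in `[0, 1]`.
#' @seealso [flow_fraction_inverse()]
#' @export
flow_fraction <- function(y, width) {
  if (any(y < -1e-12 * width | y > width * (1 + 1e-12))) {
    abort("transverse position outside the channel")
  }
  s <- pmin(pmax(y / width, 0), 1)
  3 * s^2 - 2 * s^3
}

#' Inverse of the cumulative flow fraction
#'
#' Closed-form inverse of [flow_fraction()] (the real root of
#' `2 s^3 - 3 s^2 + q = 0` in `[0, 1]`).
#'
#' @param q Flow fraction in `[0, 1]`.
#' @param width Channel width, m.
#' @return Transverse position `y` in `[0, width]`, m.
#' @export
flow_fraction_inverse <- function(q, width) {
  if (any(q < -1e-12 | q > 1 + 1e-12)) abort("flow fraction outside [0, 1]")
  q <- pmin(pmax(q, 0), 1)
  s <- 0.5 - sin(asin(1 - 2 * q) / 3)
  s * width
}

#' Stokes relaxation time of a particle
#'
#' `tau = d^2 rho_p / (18 eta)`: the time scale over which a particle's
#' velocity relaxes onto the local fluid velocity. For micron-scale
#' particles in water this is well under a microsecond, which justifies
#' treating trajectories as fluid streamlines.
#'
#' @param diameter Particle diameter, m.
#' @param particle_density Particle density, kg/m^3.
#' @param viscosity Fluid dynamic viscosity, Pa s.
#' @return Relaxation time, s.
#' @export
particle_relaxation_time <- function(diameter, particle_density = 1050,
                                     viscosity = 1e-3) {
  diameter^2 * particle_density / (18 * viscosity)
}

# ---- mouth geometry / q mapping -------------------------------------------

mouth_row <- function(domain, id) {
  m <- domain$mouths[domain$mouths$id == id, ]
  if (nrow(m) == 0) abort(paste0("unknown mouth '", id, "'"))
  m
}

mouth_outward <- function(m) arm_dir(m$arm)

# Transverse position of flow fraction q on a mouth, measured so that q
# grows from the left bank of the flow (left = 90 degrees counterclockwise
# from the flow direction). `sense` is "in" for flow entering the domain
# through the mouth, "out" for flow leaving.
mouth_position <- function(domain, id, q, sense = c("in", "out")) {
  sense <- match.arg(sense)
  m <- mouth_row(domain, id)
  d <- mouth_outward(m)
  f <- if (sense == "in") -d else d
  l <- rot90ccw(f)
  t <- flow_fraction_inverse(q, m$width)
  c(m$cx, m$cy) + (m$width / 2 - t) * l
}

mouth_q <- function(domain, id, pos, sense = c("in", "out")) {
  sense <- match.arg(sense)
  m <- mouth_row(domain, id)
  d <- mouth_outward(m)
  f <- if (sense == "in") -d else d
  l <- rot90ccw(f)
  t <- m$width / 2 - sum((pos - c(m$cx, m$cy)) * l)
  flow_fraction(min(max(t, 0), m$width), m$width)
}

# ---- velocity interpolation ------------------------------------------------

# Bilinear interpolation of one staggered component. `gx`, `gy`: physical
# coordinates of the [1,1] sample.
interp_component <- function(arr, gx, gy, d, x, y) {
  nx <- nrow(arr); ny <- ncol(arr)
  fx <- (x - gx) / d; fy <- (y - gy) / d
  i0 <- floor(fx); j0 <- floor(fy)
  ax <- fx - i0; ay <- fy - j0
  i0 <- min(max(i0, 0), nx - 2); j0 <- min(max(j0, 0), ny - 2)
  a00 <- arr[i0 + 1, j0 + 1]; a10 <- arr[i0 + 2, j0 + 1]
  a01 <- arr[i0 + 1, j0 + 2]; a11 <- arr[i0 + 2, j0 + 2]
  (1 - ax) * (1 - ay) * a00 + ax * (1 - ay) * a10 +
    (1 - ax) * ay * a01 + ax * ay * a11
}

# Velocity vector at a point (bilinear per staggered component).
interp_velocity <- function(field, x, y) {
  d <- field$spacing; o <- field$origin
  c(interp_component(field$u, o[1], o[2] + d / 2, d, x, y),
    interp_component(field$v, o[1] + d / 2, o[2], d, x, y))
}

# ---- tracing ---------------------------------------------------------------

#' Trace a particle through a velocity field
#'
#' Integrates the streamline equation `dX/dt = u(X)` with classical
#' fourth-order Runge-Kutta and bilinear velocity interpolation, with the
#' time step bounded so each step moves at most `step_factor` grid
#' spacings. The trace ends when the particle crosses an open mouth
#' (fate `"exited"`, with the exit flow fraction evaluated from the
#' parabolic profile at the mouth) or when its center comes within one
#' radius of a wall (fate `"frozen"`). A particle that stalls at a
#' stagnation point raises an error carrying the last position.
#'
#' @param field A `velocity_field`.
#' @param start Numeric length-2 start position, m; must lie in the fluid
#'   with wall clearance at least the particle radius. A start exactly on
#'   a mouth plane is nudged half a grid cell into the domain.
#' @param diameter Particle diameter, m (0 traces the pure streamline).
#' @param step_factor Maximum per-step displacement in grid spacings.
#' @param max_steps Hard step cap.
#' @param direction `+1` for forward tracing, `-1` to integrate backward
#'   along the flow (kinematic reversibility).
#' @return A `trajectory`: list with `points` (n x 2 matrix, m), `fate`,
#'   `exit_arm`, `q_entry`, `q_exit`, `arc_length`, `diameter`.
#' @export
trace_particle <- function(field, start, diameter = 1e-6, step_factor = 0.5,
                           max_steps = 1e7, direction = 1) {
  domain <- field$domain
  d <- field$spacing
  r <- diameter / 2
  tau <- particle_relaxation_time(diameter)
  if (tau >= 1e-4) {
    abort(paste0("particle relaxation time ", format(tau),
                 " s is too large for massless streamline tracing"))
  }
  mouths <- domain$mouths
  mo_axis <- ifelse(mouths$axis == "x", 1L, 2L)
  mo_plane <- ifelse(mouths$axis == "x",
                     domain$origin[1] + mouths$line * d,
                     domain$origin[2] + mouths$line * d)
  mo_out <- mouths$outward
  mo_t0 <- ifelse(mouths$axis == "x", mouths$cy, mouths$cx) - mouths$width / 2
  mo_t1 <- mo_t0 + mouths$width

  pos <- as.numeric(start)
  # nudge starts sitting exactly on a mouth plane into the domain
  for (m in seq_len(nrow(mouths))) {
    s <- (pos[mo_axis[m]] - mo_plane[m]) * mo_out[m]
    tr <- pos[3L - mo_axis[m]]
    if (abs(s) < 1e-12 && tr >= mo_t0[m] && tr <= mo_t1[m]) {
      pos[mo_axis[m]] <- pos[mo_axis[m]] - mo_out[m] * d / 2
    }
  }
  if (wall_distance(pos, domain$walls) < r - 1e-12) {
    abort("start position lacks wall clearance of one particle radius")
  }
  q_entry <- NA_real_
  for (m in seq_len(nrow(mouths))) {
    s <- (pos[mo_axis[m]] - mo_plane[m]) * mo_out[m]
    tr <- pos[3L - mo_axis[m]]
    if (abs(s) <= d && tr >= mo_t0[m] && tr <= mo_t1[m]) {
      q_entry <- mouth_q(domain, mouths$id[m], pos, "in")
      break
    }
  }

  vmax <- max(abs(field$u), abs(field$v))
  u_stag <- 1e-9 * vmax
  cap <- 4096L
  pts <- matrix(NA_real_, cap, 2)
  pts[1, ] <- pos
  npts <- 1L
  fate <- NA_character_; exit_arm <- NA_character_; q_exit <- NA_real_
  vel <- function(p) direction * interp_velocity(field, p[1], p[2])

  step <- 0L
  anchor <- pos # progress check: guards against orbiting a stagnation point
  while (step < max_steps) {
    step <- step + 1L
    if (step %% 512L == 0L) {
      if (sqrt(sum((pos - anchor)^2)) < d) {
        cnd <- structure(
          class = c("chipflow_stagnation_error", "error", "condition"),
          list(message = paste0("particle made no progress near (",
                                paste(format(pos), collapse = ", "), ")"),
               call = NULL, position = pos))
        stop(cnd)
      }
      anchor <- pos
    }
    k1 <- vel(pos)
    sp <- sqrt(sum(k1^2))
    if (sp < u_stag) {
      cnd <- structure(
        class = c("chipflow_stagnation_error", "error", "condition"),
        list(message = paste0("particle stalled near a stagnation point at (",
                              paste(format(pos), collapse = ", "), ")"),
             call = NULL, position = pos))
      stop(cnd)
    }
    dt <- step_factor * d / sp
    k2 <- vel(pos + dt / 2 * k1)
    k3 <- vel(pos + dt / 2 * k2)
    k4 <- vel(pos + dt * k3)
    new <- pos + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)

    # mouth crossing?
    crossed <- FALSE
    for (m in seq_len(nrow(mouths))) {
      ax <- mo_axis[m]
      s_new <- (new[ax] - mo_plane[m]) * mo_out[m]
      if (s_new >= 0) {
        s_old <- (pos[ax] - mo_plane[m]) * mo_out[m]
        if (s_old < 0) {
          frac <- s_old / (s_old - s_new)
          hit <- pos + frac * (new - pos)
        } else {
          hit <- new
        }
        tr <- hit[3L - ax]
        if (tr >= mo_t0[m] - 1e-12 && tr <= mo_t1[m] + 1e-12) {
          pos <- hit
          fate <- "exited"
          exit_arm <- mouths$id[m]
          q_exit <- mouth_q(domain, exit_arm, pos,
                            if (direction > 0) "out" else "in")
          crossed <- TRUE
          break
        }
      }
    }
    if (!crossed) {
      wd <- wall_distance(new, domain$walls)
      if (wd <= r) {
        pos <- new
        fate <- "frozen"
      } else if (!point_in_rects(new, domain$rects)) {
        fate <- "frozen" # stepped through a wall seam: stick at last point
      } else {
        pos <- new
      }
    }
    npts <- npts + 1L
    if (npts > cap) {
      cap <- cap * 2L
      pts <- rbind(pts, matrix(NA_real_, cap / 2, 2))
    }
    pts[npts, ] <- pos
    if (!is.na(fate)) break
  }
  if (is.na(fate)) {
    abort(paste("step cap exceeded after", max_steps, "steps"))
  }
  pts <- pts[seq_len(npts), , drop = FALSE]
  structure(list(points = pts, fate = fate, exit_arm = exit_arm,
                 q_entry = q_entry, q_exit = q_exit,
                 arc_length = polyline_length(pts), diameter = diameter,
                 provenance = list(freeze_rule = "center_within_radius",
                                   step_factor = step_factor,
                                   direction = direction)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", nrow(x$points), " points, fate ", x$fate, sep = "")
  if (!is.na(x$exit_arm)) cat(" via ", x$exit_arm, sep = "")
  if (!is.na(x$q_exit)) cat(sprintf(" (q = %.4f)", x$q_exit))
  cat("\n")
  invisible(x)
}

#' Uniformly spaced particle releases across an inlet
#'
#' `n` start positions evenly spaced across a mouth of the flow domain,
#' inset one particle radius from each wall (a single release sits at the
#' center). Mirrors the uniform-release inlet condition used to build the
#' trajectory bank (default 10 particles per release).
#'
#' @param domain A `flow_domain`.
#' @param arm Mouth id (compass arm for unit intersections, terminal id
#'   for chips).
#' @param n Number of releases.
#' @param diameter Particle diameter, m; must be smaller than the arm
#'   width.
#' @return Tibble with columns `release`, `diameter`, `t` (transverse
#'   offset from the left bank of the inflow), `q_entry`, `x`, `y`.
#' @export
release_uniform <- function(domain, arm, n = 10, diameter = 1e-6) {
  m <- mouth_row(domain, arm)
  r <- diameter / 2
  if (diameter >= m$width) abort("particle diameter exceeds the arm width")
  stopifnot(n >= 1)
  t <- if (n == 1) m$width / 2 else seq(r, m$width - r, length.out = n)
  d <- mouth_outward(m)
  l <- rot90ccw(-d) # left of the inflow direction
  px <- m$cx + (m$width / 2 - t) * l[1]
  py <- m$cy + (m$width / 2 - t) * l[2]
  tibble::tibble(release = seq_len(n), diameter = diameter, t = t,
                 q_entry = flow_fraction(t, m$width), x = px, y = py)
}

#' Plot a trajectory over its domain
#'
#' @param object A `trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory <- function(object, ...) {
  df <- tibble::tibble(x = object$points[, 1] * 1e3,
                       y = object$points[, 2] * 1e3)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(colour = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
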