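# 2D incompressible Stokes flow on masked rectilinear domains.
#
# Discretization: uniform staggered (MAC) grid. Cell (i, j) covers
# [x0+(i-1)d, x0+i d] x [y0+(j-1)d, y0+j d]. x-velocity u lives on vertical
# faces (i = 1..nx+1, j = 1..ny), y-velocity v on horizontal faces
# (i = 1..nx, j = 1..ny+1), pressure at cell centers. Momentum and
# continuity are centered second-order; walls are enforced by face values
# (normal) and reflected ghosts (tangential); the saddle-point system is
# solved by a sparse direct method. Equations are assembled in grid units
# (lengths in d, pressure as p*d/viscosity) so all coefficients are O(1).

# ---- domains ---------------------------------------------------------------

# A flow_domain holds the raster mask, the exact rectangle union it was
# built from (for wall distances), and the open "mouths" where fluid enters
# or leaves. Mouth table columns:
#   id, axis ("x": normal along x, "y"), line (grid-line index 0..nx|ny),
#   lo, hi (transverse cell index range), outward (+1 if outside lies at
#   higher coordinate), cx, cy (mouth center), width.
new_flow_domain <- function(spacing, origin, nx, ny, mask, rects, mouths,
                            meta = list()) {
  walls <- extract_wall_segments(mask, spacing, origin, mouths)
  structure(list(spacing = spacing, origin = origin, nx = nx, ny = ny,
                 mask = mask, rects = rects, walls = walls,
                 mouths = mouths, meta = meta),
            class = "flow_domain")
}

# Exact wall geometry: every face between a fluid and a non-fluid cell is a
# wall, except across open mouths; contiguous collinear faces are merged
# into maximal segments. Returns a matrix with columns x1, y1, x2, y2
# (x1 <= x2, y1 <= y2).
extract_wall_segments <- function(mask, spacing, origin, mouths) {
  nx <- nrow(mask); ny <- ncol(mask)
  pad <- matrix(FALSE, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- mask
  segs <- NULL
  runs_to_segs <- function(cells, fixed, horizontal) {
    if (!length(cells)) return(NULL)
    grp <- cumsum(c(1, diff(cells) != 1))
    do.call(rbind, lapply(split(cells, grp), function(run) {
      lo <- origin[if (horizontal) 1 else 2] + (min(run) - 1) * spacing
      hi <- origin[if (horizontal) 1 else 2] + max(run) * spacing
      if (horizontal) c(lo, fixed, hi, fixed) else c(fixed, lo, fixed, hi)
    }))
  }
  for (l in 0:ny) { # horizontal grid lines
    wall <- which(xor(pad[2:(nx + 1), l + 1], pad[2:(nx + 1), l + 2]))
    mo <- mouths[mouths$axis == "y" & mouths$line == l, ]
    for (m in seq_len(nrow(mo))) {
      wall <- setdiff(wall, mo$lo[m]:mo$hi[m])
    }
    segs <- rbind(segs, runs_to_segs(wall, origin[2] + l * spacing, TRUE))
  }
  for (l in 0:nx) { # vertical grid lines
    wall <- which(xor(pad[l + 1, 2:(ny + 1)], pad[l + 2, 2:(ny + 1)]))
    mo <- mouths[mouths$axis == "x" & mouths$line == l, ]
    for (m in seq_len(nrow(mo))) {
      wall <- setdiff(wall, mo$lo[m]:mo$hi[m])
    }
    segs <- rbind(segs, runs_to_segs(wall, origin[1] + l * spacing, FALSE))
  }
  segs
}

# minimum distance from a point to any wall segment
wall_distance <- function(p, walls) {
  dx <- pmax(walls[, 1] - p[1], p[1] - walls[, 3], 0)
  dy <- pmax(walls[, 2] - p[2], p[2] - walls[, 4], 0)
  min(sqrt(dx * dx + dy * dy))
}

#' @export
print.flow_domain <- function(x, ...) {
  cat("<flow_domain> ", x$nx, "x", x$ny, " cells at ",
      format(x$spacing * 1e6), " um, ", sum(x$mask), " fluid cells, ",
      nrow(x$mouths), " mouths\n", sep = "")
  invisible(x)
}

snap_index <- function(x, origin, spacing) {
  i <- (x - origin) / spacing
  ir <- round(i)
  if (max(abs(i - ir)) > 1e-6) {
    abort("geometry is not aligned to the grid spacing")
  }
  as.integer(ir)
}

rects_to_mask <- function(rects, origin, spacing, nx, ny) {
  xc <- origin[1] + (seq_len(nx) - 0.5) * spacing
  yc <- origin[2] + (seq_len(ny) - 0.5) * spacing
  mask <- matrix(FALSE, nx, ny)
  for (k in seq_len(nrow(rects))) {
    r <- rects[k, ]
    ii <- which(xc > r[1] & xc < r[3])
    jj <- which(yc > r[2] & yc < r[4])
    if (length(ii) && length(jj)) mask[ii, jj] <- TRUE
  }
  mask
}

# Mouth row from center position, outward compass direction, and width.
make_mouth <- function(id, center, outward_arm, width, origin, spacing) {
  d <- arm_dir(outward_arm)
  if (abs(d[1]) > 0.5) { # x-normal
    axis <- "x"
    line <- snap_index(center[1], origin[1], spacing)
    lo <- snap_index(center[2] - width / 2, origin[2], spacing) + 1L
    out <- if (d[1] > 0) 1L else -1L
  } else {
    axis <- "y"
    line <- snap_index(center[2], origin[2], spacing)
    lo <- snap_index(center[1] - width / 2, origin[1], spacing) + 1L
    out <- if (d[2] > 0) 1L else -1L
  }
  tibble::tibble(id = id, axis = axis, line = line, lo = lo,
                 hi = lo + as.integer(round(width / spacing)) - 1L,
                 outward = out, cx = center[1], cy = center[2],
                 width = width, arm = outward_arm)
}

#' Unit-intersection flow domain
#'
#' The four-arm prototype junction: 200 um wide channels crossing in a
#' 1.6 x 1.6 mm square footprint, with the arms named by compass direction.
#' Arms absent from `active_arms` are omitted from the fluid mask (flush
#' wall), so the mask is cross- or T-shaped.
#'
#' @param active_arms Character subset of `c("N","E","S","W")` (>= 2 arms).
#' @param spacing Grid spacing, m; must divide the channel width and the
#'   arm length, and be at most width/10.
#' @param footprint Footprint side, m.
#' @param width Channel width, m.
#' @return A `flow_domain`.
#' @export
unit_intersection_domain <- function(active_arms = ARMS, spacing = 20e-6,
                                     footprint = 1.6e-3, width = 200e-6) {
  stopifnot(length(active_arms) >= 2, all(active_arms %in% ARMS))
  if (spacing > width / 10 + 1e-12) {
    abort("grid spacing must be at most width/10")
  }
  for (dim in c(width, (footprint - width) / 2)) {
    if (abs(dim / spacing - round(dim / spacing)) > 1e-6) {
      abort("spacing must divide the channel width and the arm length")
    }
  }
  cx <- footprint / 2
  half <- width / 2
  rects <- rbind(c(cx - half, cx - half, cx + half, cx + half))
  mouths <- NULL
  for (a in active_arms) {
    r <- switch(a,
      N = c(cx - half, cx + half, cx + half, footprint),
      S = c(cx - half, 0, cx + half, cx - half),
      E = c(cx + half, cx - half, footprint, cx + half),
      W = c(0, cx - half, cx - half, cx + half)
    )
    rects <- rbind(rects, r)
    center <- switch(a,
      N = c(cx, footprint), S = c(cx, 0),
      E = c(footprint, cx), W = c(0, cx)
    )
    mouths <- dplyr::bind_rows(
      mouths, make_mouth(a, center, a, width, c(0, 0), spacing))
  }
  nx <- as.integer(round(footprint / spacing))
  mask <- rects_to_mask(rects, c(0, 0), spacing, nx, nx)
  new_flow_domain(spacing, c(0, 0), nx, nx, mask, rects, mouths,
                  meta = list(kind = "unit_intersection",
                              footprint = footprint, width = width,
                              active_arms = active_arms))
}

# Rasterized whole-chip domain: union of channel rectangles, with a mouth at
# every terminal.
chip_domain <- function(netlist, spacing) {
  segs <- netlist$segments
  nodes <- netlist$nodes
  rects <- NULL
  for (s in seq_len(nrow(segs))) {
    pts <- seg_polyline(netlist, segs[s, ])
    w <- segs$width[s]
    nleg <- nrow(pts) - 1
    for (k in seq_len(nleg)) {
      a <- pts[k, ]; b <- pts[k + 1, ]
      # extend past interior junctions/turn corners to fill the cores
      ext_a <- if (k > 1) w / 2 else {
        if (nodes$kind[nodes$id == segs$from[s]] == "terminal") 0 else w / 2
      }
      ext_b <- if (k < nleg) w / 2 else {
        if (nodes$kind[nodes$id == segs$to[s]] == "terminal") 0 else w / 2
      }
      rects <- rbind(rects, leg_rect(a, b, w, ext_a, ext_b))
    }
  }
  origin <- c(min(rects[, 1]), min(rects[, 2]))
  nx <- snap_index(max(rects[, 3]), origin[1], spacing)
  ny <- snap_index(max(rects[, 4]), origin[2], spacing)
  mouths <- NULL
  for (t in which(nodes$kind == "terminal")) {
    nid <- nodes$id[t]
    s <- which(segs$from == nid | segs$to == nid)
    pts <- seg_polyline(netlist, segs[s, ])
    if (segs$to[s] == nid) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
    d_in <- pts[2, ] - pts[1, ]
    outward <- dir_arm(-d_in / sqrt(sum(d_in^2)))
    mouths <- dplyr::bind_rows(
      mouths,
      make_mouth(nid, c(nodes$x[t], nodes$y[t]), outward, segs$width[s],
                 origin, spacing))
  }
  mask <- rects_to_mask(rects, origin, spacing, nx, ny)
  new_flow_domain(spacing, origin, nx, ny, mask, rects, mouths,
                  meta = list(kind = "chip"))
}

# ---- boundary profiles -----------------------------------------------------

#' Fully developed plane-Poiseuille profile
#'
#' Parabolic transverse velocity profile of pressure-driven laminar flow
#' between parallel walls: zero at the walls, 1.5 x mean at the center,
#' averaging exactly to `mean_u`.
#'
#' @param width Channel width, m.
#' @param mean_u Mean velocity, m/s.
#' @return A vectorized function of the transverse position `y` in
#'   `[0, width]`.
#' @export
#' @examples
#' f <- poiseuille_profile(200e-6, 0.01)
#' f(100e-6) # 1.5 cm/s at the centerline
poiseuille_profile <- function(width, mean_u) {
  stopifnot(width > 0)
  function(y) 6 * mean_u * (y / width) * (1 - y / width)
}

# Exact cell averages of the parabolic profile on `n` equal cells across a
# mouth; their sum times the cell width is exactly mean_u * width.
profile_cell_averages <- function(n, width, mean_u) {
  t <- seq(0, width, length.out = n + 1)
  anti <- mean_u * (3 * t^2 / width - 2 * t^3 / width^2) # integral of profile
  diff(anti) / (width / n)
}

# ---- solver ----------------------------------------------------------------

# mouth_bc: tibble(id, type "velocity"|"natural", value) where velocity
# values are mean velocities signed positive INTO the domain, and natural
# values are gauge pressures (Pa) imposed just outside the mouth.
stokes_solve <- function(domain, mouth_bc, viscosity = 1e-3,
                         provenance = list()) {
  d <- domain$spacing
  nx <- domain$nx; ny <- domain$ny
  mask <- domain$mask
  mouths <- dplyr::left_join(domain$mouths, mouth_bc, by = "id")
  if (anyNA(mouths$type)) {
    abort("every domain mouth needs a boundary condition")
  }

  fluid <- function(ii, jj) {
    ok <- ii >= 1 & ii <= nx & jj >= 1 & jj <= ny
    out <- logical(length(ok))
    out[ok] <- mask[cbind(ii[ok], jj[ok])]
    out
  }

  # exact discrete flux balance when no natural mouth absorbs the mismatch
  vel <- mouths$type == "velocity"
  if (!any(mouths$type == "natural")) {
    qin <- mouths$value * mouths$width
    pos <- vel & qin > 0; neg <- vel & qin < 0
    tot_in <- sum(qin[pos]); tot_out <- -sum(qin[neg])
    if (tot_out > 0) {
      mouths$value[neg] <- mouths$value[neg] * tot_in / tot_out
    }
  }

  # ---- face classification
  # adjacency of u faces: cells (i-1, j) and (i, j)
  iu <- rep(seq_len(nx + 1), ny); ju <- rep(seq_len(ny), each = nx + 1)
  uL <- fluid(iu - 1, ju); uR <- fluid(iu, ju)
  uActive <- matrix(uL | uR, nx + 1, ny)
  uInterior <- matrix(uL & uR, nx + 1, ny)
  iv <- rep(seq_len(nx), ny + 1); jv <- rep(seq_len(ny + 1), each = nx)
  vB <- fluid(iv, jv - 1); vT <- fluid(iv, jv)
  vActive <- matrix(vB | vT, nx, ny + 1)
  vInterior <- matrix(vB & vT, nx, ny + 1)

  uNatural <- matrix(FALSE, nx + 1, ny); uGhostP <- matrix(0, nx + 1, ny)
  vNatural <- matrix(FALSE, nx, ny + 1); vGhostP <- matrix(0, nx, ny + 1)
  uVal <- matrix(0, nx + 1, ny) # Dirichlet values (walls 0, mouths profile)
  vVal <- matrix(0, nx, ny + 1)
  # natural-plane lookups for tangential ghosts
  natH <- matrix(FALSE, nx, ny + 1) # horizontal grid lines, per cell column
  natV <- matrix(FALSE, nx + 1, ny) # vertical grid lines, per cell row

  for (m in seq_len(nrow(mouths))) {
    mo <- mouths[m, ]
    idxs <- mo$lo:mo$hi
    ncell <- length(idxs)
    if (mo$type == "velocity") {
      avg <- profile_cell_averages(ncell, mo$width, mo$value)
      comp <- -mo$outward * avg # velocity component along the axis
      if (mo$axis == "x") uVal[cbind(mo$line + 1L, idxs)] <- comp
      else vVal[cbind(idxs, mo$line + 1L)] <- comp
    } else {
      pgh <- mo$value * d / viscosity # grid-unit ghost pressure
      if (mo$axis == "x") {
        uNatural[cbind(mo$line + 1L, idxs)] <- TRUE
        uGhostP[cbind(mo$line + 1L, idxs)] <- pgh
        natV[cbind(mo$line + 1L, idxs)] <- TRUE
      } else {
        vNatural[cbind(idxs, mo$line + 1L)] <- TRUE
        vGhostP[cbind(idxs, mo$line + 1L)] <- pgh
        natH[cbind(idxs, mo$line + 1L)] <- TRUE
      }
    }
  }

  uDir <- uActive & !uInterior & !uNatural
  vDir <- vActive & !vInterior & !vNatural
  uUnknown <- uInterior | uNatural
  vUnknown <- vInterior | vNatural

  uUnk <- matrix(0L, nx + 1, ny); uUnk[uUnknown] <- seq_len(sum(uUnknown))
  Nu <- sum(uUnknown)
  vUnk <- matrix(0L, nx, ny + 1); vUnk[vUnknown] <- seq_len(sum(vUnknown))
  Nv <- sum(vUnknown)
  pUnk <- matrix(0L, nx, ny); pUnk[mask] <- seq_len(sum(mask))
  Np <- sum(mask)
  ntot <- Nu + Nv + Np
  rhs <- numeric(ntot)

  # bulk triplet push (vectors)
  TI <- vector("list", 64); TJ <- vector("list", 64); TX <- vector("list", 64)
  nT <- 0L
  push <- function(i, j, x) {
    if (!length(i)) return(invisible())
    nT <<- nT + 1L
    TI[[nT]] <<- i; TJ[[nT]] <<- j
    TX[[nT]] <<- rep_len(x, length(i))
  }

  # ---- u momentum
  uf <- which(uUnknown, arr.ind = TRUE)
  if (nrow(uf)) {
    fi <- uf[, 1]; fj <- uf[, 2]
    rows <- uUnk[uf]
    diag <- rep(-4, length(rows))
    nb <- function(ni, nj) {
      n <- length(ni)
      ok <- ni >= 1 & ni <= nx + 1 & nj >= 1 & nj <= ny
      unk <- integer(n); dirv <- rep(NA_real_, n)
      w <- which(ok)
      if (length(w)) {
        idx <- cbind(ni[w], nj[w])
        unk[w] <- uUnk[idx]
        isdir <- unk[w] == 0 & uDir[idx]
        dirv[w[isdir]] <- uVal[idx[isdir, , drop = FALSE]]
      }
      list(unk = unk, dirv = dirv,
           missing = !ok | (unk == 0 & is.na(dirv)))
    }
    for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      r <- nb(fi + off[1], fj + off[2])
      has_unk <- r$unk > 0
      push(rows[has_unk], r$unk[has_unk], 1)
      isd <- !is.na(r$dirv)
      rhs[rows[isd]] <- rhs[rows[isd]] - r$dirv[isd]
      if (off[1] != 0) {
        # missing x-neighbor: outward side of a natural mouth -> du/dn = 0
        diag[r$missing] <- diag[r$missing] + 1
      } else {
        # missing y-neighbor: reflected ghost across a wall or Dirichlet
        # mouth plane (-u), zero-gradient across a natural mouth plane (+u)
        l <- if (off[2] < 0) fj - 1L else fj
        c1 <- fi - 1L; c2 <- fi
        okc <- c1 >= 1 & c2 <= nx
        nat <- logical(length(fi))
        nat[okc] <- natH[cbind(c1[okc], l[okc] + 1L)] &
          natH[cbind(c2[okc], l[okc] + 1L)]
        diag[r$missing & nat] <- diag[r$missing & nat] + 1
        diag[r$missing & !nat] <- diag[r$missing & !nat] - 1
      }
    }
    push(rows, rows, 0) # placeholder, replaced below by diag values
    TX[[nT]] <- diag
    # pressure gradient: -(pR - pL)
    pLf <- fluid(fi - 1L, fj); pRf <- fluid(fi, fj)
    idxL <- cbind(pmax(fi - 1L, 1L), fj); idxR <- cbind(pmin(fi, nx), fj)
    push(rows[pLf], Nu + Nv + pUnk[idxL[pLf, , drop = FALSE]], 1)
    push(rows[pRf], Nu + Nv + pUnk[idxR[pRf, , drop = FALSE]], -1)
    gh <- uGhostP[uf]
    rhs[rows[!pRf]] <- rhs[rows[!pRf]] + gh[!pRf]
    rhs[rows[!pLf]] <- rhs[rows[!pLf]] - gh[!pLf]
  }

  # ---- v momentum
  vf <- which(vUnknown, arr.ind = TRUE)
  if (nrow(vf)) {
    fi <- vf[, 1]; fj <- vf[, 2]
    rows <- Nu + vUnk[vf]
    diag <- rep(-4, length(rows))
    nb <- function(ni, nj) {
      n <- length(ni)
      ok <- ni >= 1 & ni <= nx & nj >= 1 & nj <= ny + 1
      unk <- integer(n); dirv <- rep(NA_real_, n)
      w <- which(ok)
      if (length(w)) {
        idx <- cbind(ni[w], nj[w])
        unk[w] <- vUnk[idx]
        isdir <- unk[w] == 0 & vDir[idx]
        dirv[w[isdir]] <- vVal[idx[isdir, , drop = FALSE]]
      }
      list(unk = unk, dirv = dirv,
           missing = !ok | (unk == 0 & is.na(dirv)))
    }
    for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      r <- nb(fi + off[1], fj + off[2])
      has_unk <- r$unk > 0
      push(rows[has_unk], Nu + r$unk[has_unk], 1)
      isd <- !is.na(r$dirv)
      rhs[rows[isd]] <- rhs[rows[isd]] - r$dirv[isd]
      if (off[2] != 0) {
        diag[r$missing] <- diag[r$missing] + 1
      } else {
        l <- if (off[1] < 0) fi - 1L else fi
        c1 <- fj - 1L; c2 <- fj
        okc <- c1 >= 1 & c2 <= ny
        nat <- logical(length(fi))
        nat[okc] <- natV[cbind(l[okc] + 1L, c1[okc])] &
          natV[cbind(l[okc] + 1L, c2[okc])]
        diag[r$missing & nat] <- diag[r$missing & nat] + 1
        diag[r$missing & !nat] <- diag[r$missing & !nat] - 1
      }
    }
    push(rows, rows, 0)
    TX[[nT]] <- diag
    pBf <- fluid(fi, fj - 1L); pTf <- fluid(fi, fj)
    idxB <- cbind(fi, pmax(fj - 1L, 1L)); idxT <- cbind(fi, pmin(fj, ny))
    push(rows[pBf], Nu + Nv + pUnk[idxB[pBf, , drop = FALSE]], 1)
    push(rows[pTf], Nu + Nv + pUnk[idxT[pTf, , drop = FALSE]], -1)
    gh <- vGhostP[vf]
    rhs[rows[!pTf]] <- rhs[rows[!pTf]] + gh[!pTf]
    rhs[rows[!pBf]] <- rhs[rows[!pBf]] - gh[!pBf]
  }

  # ---- continuity
  cells <- which(mask, arr.ind = TRUE)
  ci <- cells[, 1]; cj <- cells[, 2]
  crow <- Nu + Nv + pUnk[cells]
  pin <- !any(mouths$type == "natural")
  keep <- if (pin) crow != Nu + Nv + 1L else rep(TRUE, length(crow))
  cface <- function(fidx, unkmat, dirmat, valmat, sgn, block) {
    unk <- unkmat[fidx]
    has <- unk > 0 & keep
    push(crow[has], block + unk[has], sgn)
    isd <- dirmat[fidx] & keep
    rhs[crow[isd]] <<- rhs[crow[isd]] - sgn * valmat[fidx[isd, , drop = FALSE]]
  }
  cface(cbind(ci + 1L, cj), uUnk, uDir, uVal, 1, 0L)   # east u
  cface(cbind(ci, cj), uUnk, uDir, uVal, -1, 0L)       # west u
  cface(cbind(ci, cj + 1L), vUnk, vDir, vVal, 1, Nu)   # north v
  cface(cbind(ci, cj), vUnk, vDir, vVal, -1, Nu)       # south v
  if (pin) {
    push(Nu + Nv + 1L, Nu + Nv + 1L, 1)
    rhs[Nu + Nv + 1L] <- 0
  }

  A <- Matrix::sparseMatrix(i = unlist(TI[seq_len(nT)]),
                            j = unlist(TJ[seq_len(nT)]),
                            x = unlist(TX[seq_len(nT)]),
                            dims = c(ntot, ntot))
  sol <- as.numeric(Matrix::solve(A, rhs))

  u <- uVal; u[uUnknown] <- sol[uUnk[uUnknown]]
  v <- vVal; v[vUnknown] <- sol[Nu + vUnk[vUnknown]]
  p <- matrix(NA_real_, nx, ny)
  p[mask] <- sol[Nu + Nv + pUnk[mask]] * viscosity / d

  structure(list(u = u, v = v, p = p, domain = domain,
                 spacing = d, origin = domain$origin, mask = mask,
                 mouth_bc = mouths[, c("id", "type", "value")],
                 viscosity = viscosity,
                 provenance = c(provenance, list(spacing = d))),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat("<velocity_field> ", x$domain$nx, "x", x$domain$ny, " cells at ",
      format(x$spacing * 1e6), " um; max speed ",
      format(max(abs(x$u), abs(x$v)), digits = 4), " m/s\n", sep = "")
  invisible(x)
}

#' Solve Stokes flow in a unit intersection
#'
#' Steady incompressible viscous flow on the unit-intersection domain with
#' prescribed mean arm velocities. Fully developed parabolic profiles are
#' imposed on every active arm except one reference outlet (the arm with
#' the largest outflow, ties broken N < E < S < W), which carries a
#' traction-free outflow condition that also sets the pressure gauge.
#' Inertia is neglected (zero-Reynolds-number limit), which keeps the
#' problem linear: scaling all arm velocities scales the field exactly.
#'
#' @param domain A [unit_intersection_domain()] (or any `flow_domain` whose
#'   mouth ids are compass arms).
#' @param arm_velocities Named numeric over `c("N","E","S","W")`: mean arm
#'   velocities, m/s, positive into the intersection; arms absent from the
#'   domain must be 0.
#' @param viscosity Dynamic viscosity, Pa s.
#' @return A `velocity_field` with staggered `u`, `v` arrays (m/s),
#'   pressure `p` (Pa, `NA` outside the fluid), the domain, and provenance.
#' @export
solve_stokes <- function(domain, arm_velocities, viscosity = 1e-3) {
  if (is.null(names(arm_velocities))) {
    stopifnot(length(arm_velocities) == 4)
    names(arm_velocities) <- ARMS
  }
  av <- arm_velocities[ARMS]
  names(av) <- ARMS
  av[is.na(av)] <- 0
  act <- domain$mouths$id
  if (any(abs(av[setdiff(ARMS, act)]) > 0)) {
    abort("nonzero velocity on an arm that is not part of the domain")
  }
  tot <- sum(abs(av))
  if (tot == 0) abort("all arm velocities are zero")
  if (abs(sum(av)) > 1e-6 * tot) {
    abort(paste0("arm velocities do not conserve mass: net ",
                 format(sum(av)), " m/s"))
  }
  # choose reference outlet: largest outflow, ties N < E < S < W
  outl <- act[av[act] < 0]
  if (length(outl) == 0) abort("intersection has no outlet arm")
  ref <- outl[order(av[outl], match(outl, ARMS))][1]
  bc <- tibble::tibble(
    id = act,
    type = ifelse(act == ref, "natural", "velocity"),
    value = ifelse(act == ref, 0, av[act])
  )
  stokes_solve(domain, bc, viscosity,
               provenance = list(arm_velocities = av, reference_outlet = ref))
}

#' Solve Stokes flow over a whole chip
#'
#' Direct counterpart of [solve_stokes()] on the full rasterized chip
#' polygon; used as the internal oracle against which the decomposed
#' simulation is compared. Velocity-type terminals receive parabolic
#' profiles; pressure-type terminals receive traction-free outflow at the
#' given gauge pressure.
#'
#' @param netlist A [chip_netlist()]; all geometry must align to `spacing`.
#' @param spacing Grid spacing, m.
#' @return A `velocity_field`.
#' @export
solve_full_chip <- function(netlist, spacing) {
  validate_netlist(netlist)
  dom <- chip_domain(netlist, spacing)
  bc <- tibble::tibble(
    id = netlist$bc$terminal,
    type = ifelse(netlist$bc$type == "pressure", "natural", "velocity"),
    value = netlist$bc$value
  )
  stokes_solve(dom, bc, netlist$fluid$viscosity,
               provenance = list(kind = "full_chip"))
}

#' Maximum discrete divergence of a velocity field
#'
#' The largest absolute discrete divergence
#' `(u_e - u_w + v_n - v_s) / spacing` over fluid cells, in 1/s. Accepted
#' solves keep this far below `1e-8 * max|u| / spacing`.
#'
#' @param field A `velocity_field`.
#' @return Scalar, 1/s.
#' @export
check_divergence <- function(field) {
  nx <- field$domain$nx; ny <- field$domain$ny
  div <- (field$u[2:(nx + 1), , drop = FALSE] -
            field$u[1:nx, , drop = FALSE] +
            field$v[, 2:(ny + 1), drop = FALSE] -
            field$v[, 1:ny, drop = FALSE]) / field$spacing
  max(abs(div[field$mask]))
}

#' Plot a velocity field
#'
#' Speed magnitude at cell centers on the masked domain.
#'
#' @param object A `velocity_field`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.velocity_field <- function(object, ...) {
  nx <- object$domain$nx; ny <- object$domain$ny
  uc <- (object$u[1:nx, , drop = FALSE] +
           object$u[2:(nx + 1), , drop = FALSE]) / 2
  vc <- (object$v[, 1:ny, drop = FALSE] +
           object$v[, 2:(ny + 1), drop = FALSE]) / 2
  sp <- sqrt(uc^2 + vc^2)
  sp[!object$mask] <- NA
  df <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  df$x <- (object$origin[1] + (df$i - 0.5) * object$spacing) * 1e3
  df$y <- (object$origin[2] + (df$j - 0.5) * object$spacing) * 1e3
  df$speed <- sp[cbind(df$i, df$j)] * 1e3
  df <- df[!is.na(df$speed), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$speed)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "|u| (mm/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
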