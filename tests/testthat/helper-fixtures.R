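# Shared fixtures, memoized so expensive solves run once per test session.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# straight N->S channel through the unit footprint, solved at `sp`
straight_field <- function(sp = 20e-6, v = 0.01) {
  cached(paste0("straight_", sp), {
    dom <- chipflow:::unit_intersection_domain(c("N", "S"), spacing = sp)
    solve_stokes(dom, c(N = v, E = 0, S = -v, W = 0))
  })
}

# fully symmetric cross: N, S inflows, E, W outflows
cross_field <- function(sp = 20e-6) {
  cached(paste0("cross_", sp), {
    dom <- chipflow:::unit_intersection_domain(spacing = sp)
    solve_stokes(dom, c(N = 0.01, E = -0.01, S = 0.01, W = -0.01))
  })
}

# single-intersection chip: one T or cross junction at the origin with a
# terminal 0.8 mm out along each active arm; bc = named list arm ->
# list(type=, value=) boundary conditions at those terminals
make_single_intersection_chip <- function(bc, w = 200e-6, h = 100e-6,
                                          arm_len = 0.8e-3) {
  arms <- names(bc)
  dirs <- list(N = c(0, 1), E = c(1, 0), S = c(0, -1), W = c(-1, 0))
  nodes <- tibble::tibble(id = "X", kind = "intersection", x = 0, y = 0)
  segs <- NULL
  bct <- NULL
  for (a in arms) {
    tid <- paste0("T", a)
    nodes <- rbind(nodes, tibble::tibble(id = tid, kind = "terminal",
                                         x = dirs[[a]][1] * arm_len,
                                         y = dirs[[a]][2] * arm_len))
    segs <- rbind(segs, tibble::tibble(id = paste0("s", a), from = tid,
                                       to = "X", width = w, height = h))
    bct <- rbind(bct, tibble::tibble(terminal = tid, type = bc[[a]]$type,
                                     value = bc[[a]]$value))
  }
  chip_netlist(nodes, segs, bct)
}

# exact-match library for the default cascade chip at the given spacing
cascade_library <- function(sp = 20e-6) {
  cached(paste0("cascade_lib_", sp), {
    nl <- make_cascade_chip()
    sol <- solve_network(nl)
    specs <- lapply(c("a", "b", "c"), function(id) {
      unit_intersection_spec(arm_boundary_conditions(sol, id))
    })
    build_library(0, extra_specs = specs, spacing = sp, diameters = 1e-6)
  })
}

empty_library <- function() {
  cached("empty_lib", build_library(0, spacing = 20e-6))
}

expect_netlist_equal <- function(a, b) {
  expect_equal(a$nodes, b$nodes, tolerance = 1e-12)
  expect_equal(a$segments$id, b$segments$id)
  expect_equal(a$segments$width, b$segments$width, tolerance = 1e-12)
  expect_equal(a$segments$height, b$segments$height, tolerance = 1e-12)
  expect_equal(a$segments$length, b$segments$length, tolerance = 1e-12)
  for (i in seq_len(nrow(a$segments))) {
    expect_equal(a$segments$waypoints[[i]], b$segments$waypoints[[i]],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(a$bc, b$bc, tolerance = 1e-12)
  expect_equal(a$fluid$viscosity, b$fluid$viscosity)
  expect_equal(a$fluid$density, b$fluid$density)
}
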