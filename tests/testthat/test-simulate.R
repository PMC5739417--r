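test_that("a straight chip carries a center release straight across", {
  nl <- make_straight_chip()
  parts <- particle_releases(nl, "IN", n = 1)
  rep <- simulate_chip(nl, parts, empty_library())
  out <- tidy(rep)
  expect_equal(out$fate, "exited")
  expect_equal(out$exit_terminal, "OUT")
  expect_equal(out$q_exit, 0.5)
  tr <- rep$particles$trajectory[[1]]
  expect_lt(max(abs(tr$points[, 2] - 0)), 1e-12) # stays on the centerline
})

test_that("channel propagation conserves q and offsets the path", {
  nl <- make_elbow_chip()
  res <- propagate_channel(nl, "s1", 0.25)
  expect_equal(res$q_out, 0.25)
  # q < 0.5 lies nearer the left bank of the flow; traveling east, the
  # left bank is north, so the path is offset by +(w/2 - t) in y
  t <- flow_fraction_inverse(0.25, 200e-6)
  expect_equal(res$polyline[1, 2], 100e-6 - t, tolerance = 1e-12)
  expect_equal(nrow(res$polyline), 3) # corner is mitered, not rounded
  # q = 0.5 through a turn follows the centerline exactly
  mid <- propagate_channel(nl, "s1", 0.5)
  expect_equal(mid$polyline,
               rbind(c(0, 0), c(0.8e-3, 0), c(0.8e-3, 0.8e-3)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # composition over a multi-leg zigzag leaves q untouched
  q <- 0.37
  for (k in 1:5) q <- propagate_channel(nl, "s1", q)$q_out
  expect_equal(q, 0.37)
})

test_that("degenerate through-flow traversal is the identity on q", {
  spec <- unit_intersection_spec(c(N = 0.01, E = 0, S = -0.01, W = 0))
  lib <- build_library(0, extra_specs = list(spec), spacing = 10e-6)
  res <- traverse_intersection(0.3, "N", spec, lib, diameter = 1e-6)
  expect_equal(res$fate, "exited")
  expect_equal(res$exit_arm, "S")
  expect_lt(abs(res$q_out - 0.3), 1e-3)
  # the local polyline runs straight down the junction core
  expect_lt(diff(range(res$polyline[, 1])), 1e-6)
})

test_that("the H chip routes its left-intersection flow east", {
  nl <- make_h_chip() # 1 and 2 cm/s in at the left, 3 cm/s east through b
  sol <- solve_network(nl)
  spec_b <- unit_intersection_spec(arm_boundary_conditions(sol, "b"))
  spec_h <- unit_intersection_spec(arm_boundary_conditions(sol, "hh"))
  lib <- build_library(0, extra_specs = list(spec_b, spec_h),
                       spacing = 20e-6)
  parts <- particle_releases(nl, "TL", n = 1)
  # the crossbar runs at 3 cm/s, past the library's sampling envelope, so
  # the scale-invariant retrieval must be allowed explicitly
  expect_error(simulate_chip(nl, parts, lib), "envelope")
  rep <- simulate_chip(nl, parts, lib, strict_envelope = FALSE)
  out <- tidy(rep)
  expect_equal(out$fate, "exited")
  prov <- rep$particles$trajectory[[1]]$provenance
  expect_equal(prov$entry_arm[1], "N")
  expect_equal(prov$exit_arm[1], "E") # all flow through b leaves east
  expect_equal(prov$intersection, c("b", "hh"))
  expect_true(out$exit_terminal %in% c("TR", "BR"))
})

test_that("cascade center releases produce three complete trajectories", {
  nl <- make_cascade_chip()
  lib <- cascade_library(20e-6)
  parts <- particle_releases(nl, c("W1", "E1", "E2"), n = 1)
  rep <- simulate_chip(nl, parts, lib, mode = "A")
  out <- tidy(rep)
  expect_equal(out$fate, rep("exited", 3))
  expect_equal(out$max_match_distance, rep(0, 3))
  expect_true(all(out$exit_terminal %in% c("E3", "SOUT")))
  # deterministic end to end
  rep2 <- simulate_chip(nl, parts, lib, mode = "A")
  expect_equal(tidy(rep2), out)
  for (i in 1:3) {
    expect_identical(rep2$particles$trajectory[[i]]$points,
                     rep$particles$trajectory[[i]]$points)
  }
  # stitched polylines are continuous across hand-off points
  gaps <- vapply(rep$particles$trajectory, function(t) t$max_stitch_gap,
                 numeric(1))
  expect_lt(max(gaps), lib$meta$spacing)
})

test_that("mode B bank interpolation approximates mode A", {
  nl <- make_cascade_chip()
  lib <- cascade_library(20e-6)
  parts <- particle_releases(nl, "W1", n = 1)
  a <- tidy(simulate_chip(nl, parts, lib, mode = "A"))
  b <- tidy(simulate_chip(nl, parts, lib, mode = "B"))
  expect_equal(b$exit_terminal, a$exit_terminal)
  expect_equal(b$q_exit, a$q_exit, tolerance = 0.05)
})

test_that("library envelope violations abort with clear messages", {
  nl <- make_cascade_chip(w = 150e-6)
  parts <- particle_releases(nl, "W1", n = 1)
  expect_error(simulate_chip(nl, parts, empty_library()), "200 um")
  nl2 <- make_cascade_chip(inlet_velocity = 0.03)
  parts2 <- particle_releases(nl2, "W1", n = 1)
  expect_error(simulate_chip(nl2, parts2, empty_library()), "envelope")
})

test_that("releases into outflow terminals are rejected", {
  nl <- make_cascade_chip()
  parts <- particle_releases(nl, "SOUT", n = 1)
  expect_error(simulate_chip(nl, parts, cascade_library(20e-6)),
               "not an inflow")
})
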