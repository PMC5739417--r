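test_that("rectangular-duct form factor matches the series solution", {
  # independent oracle: the same series summed far past machine convergence
  oracle <- function(h, w) {
    a <- min(h, w); b <- max(h, w)
    n <- seq(1, 9999, by = 2)
    1 - (192 / pi^5) * (a / b) * sum(tanh(n * pi * b / (2 * a)) / n^5)
  }
  expect_equal(form_factor(1e-4, 1e-4), oracle(1e-4, 1e-4), tolerance = 1e-12)
  expect_equal(form_factor(1e-4, 1e-4), 0.4217, tolerance = 1e-4)
  expect_equal(form_factor(5e-5, 2e-4), oracle(5e-5, 2e-4), tolerance = 1e-12)
  # parallel-plate limit
  expect_gt(form_factor(1e-8, 1e-2), 1 - 1e-5)
  expect_lte(form_factor(1, 1), 1)
  # monotone decreasing in aspect ratio on (0, 1]
  aspects <- seq(0.01, 1, length.out = 50)
  Fs <- vapply(aspects, function(a) form_factor(a, 1), numeric(1))
  expect_true(all(diff(Fs) < 0))
})

test_that("hydraulic resistance follows Rh = 12 eta L / (w h^3 F)", {
  fl <- fluid_props()
  seg <- tibble::tibble(length = 1e-3, width = 200e-6, height = 100e-6)
  expected <- 12 * 1e-3 * 1e-3 /
    (2e-4 * (1e-4)^3 * form_factor(1e-4, 2e-4))
  expect_equal(hydraulic_resistance(seg, fl), expected, tolerance = 1e-12)
  seg2 <- seg; seg2$length <- 2e-3
  expect_equal(hydraulic_resistance(seg2, fl),
               2 * hydraulic_resistance(seg, fl), tolerance = 1e-12)
  # resistance decreases monotonically as the channel deepens
  hs <- seq(50e-6, 1e-3, length.out = 30)
  Rs <- vapply(hs, function(h) {
    hydraulic_resistance(tibble::tibble(length = 1e-3, width = 200e-6,
                                        height = h), fl)
  }, numeric(1))
  expect_true(all(diff(Rs) < 0))
})

test_that("series and parallel compositions behave like resistors", {
  expect_equal(series_resistance(c(1, 2, 3)), 6)
  expect_equal(series_resistance(5), 5)
  expect_equal(series_resistance(c(3, 1, 2)), series_resistance(c(1, 2, 3)))
  expect_equal(parallel_resistance(c(2, 2)), 1)
  expect_equal(parallel_resistance(7), 7)
  expect_equal(parallel_resistance(c(1, 1e12)), 1, tolerance = 1e-10)
  expect_lte(parallel_resistance(c(2, 3, 4)), 2)
  expect_error(series_resistance(numeric(0)), "empty")
  expect_error(parallel_resistance(numeric(0)), "empty")
})

test_that("nodal analysis solves elementary networks exactly", {
  # two identical segments in series: midpoint at half the drop
  nodes <- tibble::tibble(id = c("A", "M", "B"),
                          kind = c("terminal", "turn", "terminal"),
                          x = c(0, 1e-3, 2e-3), y = 0)
  segs <- tibble::tibble(id = c("s1", "s2"), from = c("A", "M"),
                         to = c("M", "B"), width = 200e-6, height = 100e-6)
  bc <- tibble::tibble(terminal = c("A", "B"), type = "pressure",
                       value = c(10, 0))
  nl <- chip_netlist(nodes, segs, bc)
  sol <- solve_network(nl)
  expect_equal(sol$pressures$pressure[sol$pressures$node == "M"], 5,
               tolerance = 1e-12)
  # single segment obeys Q = dP / Rh
  nl1 <- make_straight_chip()
  nl1$bc <- tibble::tibble(terminal = c("IN", "OUT"), type = "pressure",
                           value = c(10, 0))
  s1 <- solve_network(nl1)
  Rh <- hydraulic_resistance(nl1$segments, nl1$fluid)
  expect_equal(s1$flows$Q, 10 / Rh, tolerance = 1e-12)
})

test_that("mirror-symmetric boundary conditions give mirror-equal flows", {
  nl <- make_h_chip(v_top = 0.01, v_bottom = 0.01)
  sol <- solve_network(nl)
  fl <- sol$flows
  q <- setNames(fl$Q, fl$segment)
  expect_equal(abs(q[["a"]]), abs(q[["c"]]), tolerance = 1e-12)
  expect_equal(abs(q[["g"]]), abs(q[["i"]]), tolerance = 1e-12)
  expect_equal(abs(q[["d"]]), abs(q[["f"]]), tolerance = 1e-12)
})

test_that("solutions are linear in the applied pressures", {
  nl <- make_random_grid_chip(3)
  s1 <- solve_network(nl)
  nl2 <- nl
  nl2$bc$value <- nl2$bc$value * 3.5
  s2 <- solve_network(nl2)
  expect_equal(s2$flows$Q, 3.5 * s1$flows$Q, tolerance = 1e-10)
})

test_that("series/parallel ladder reduction agrees with the full solve", {
  # A -- s1 -- M -- {s2 | s3+s4} -- B, mixed series/parallel ladder
  nodes <- tibble::tibble(
    id = c("A", "M", "J", "B"),
    kind = c("terminal", "intersection", "intersection", "terminal"),
    x = c(0, 1e-3, 2e-3, 3e-3), y = 0)
  # parallel branch realized as two segments with different heights
  nodes <- rbind(nodes, tibble::tibble(id = "P", kind = "turn",
                                       x = 1.5e-3, y = 1e-3))
  segs <- tibble::tibble(
    id = c("s1", "s2", "s3", "s4"),
    from = c("A", "M", "M", "P"),
    to = c("M", "J", "P", "J"),
    width = 200e-6,
    height = c(100e-6, 80e-6, 120e-6, 120e-6),
    waypoints = list(matrix(numeric(0), ncol = 2),
                     matrix(numeric(0), ncol = 2),
                     matrix(c(1e-3, 1e-3), 1),
                     matrix(c(2e-3, 1e-3), 1)))
  segs <- rbind(segs, tibble::tibble(id = "s5", from = "J", to = "B",
                                     width = 200e-6, height = 100e-6,
                                     waypoints = list(matrix(numeric(0),
                                                             ncol = 2))))
  bc <- tibble::tibble(terminal = c("A", "B"), type = "pressure",
                       value = c(25, 0))
  nl <- chip_netlist(nodes, segs, bc)
  sol <- solve_network(nl)
  Rh <- setNames(sol$flows$Rh, sol$flows$segment)
  Req <- series_resistance(c(
    Rh[["s1"]],
    parallel_resistance(c(Rh[["s2"]],
                          series_resistance(c(Rh[["s3"]], Rh[["s4"]])))),
    Rh[["s5"]]))
  expect_equal(sol$flows$Q[sol$flows$segment == "s1"], 25 / Req,
               tolerance = 1e-10)
  expect_lt(sol$kcl_residual, 1e-12)
})

test_that("arm boundary conditions complete the printed worked examples", {
  # two inlets at 1 and 2 cm/s force a 3 cm/s outlet
  nl <- make_single_intersection_chip(list(
    N = list(type = "velocity", value = 0.01),
    S = list(type = "velocity", value = 0.02),
    E = list(type = "pressure", value = 0)))
  av <- arm_boundary_conditions(solve_network(nl), "X")
  expect_equal(av[["E"]], -0.03, tolerance = 1e-12)
  expect_identical(av[["W"]], 0) # unused arm reports exactly zero
  expect_equal(sum(av), 0, tolerance = 1e-15)
  expect_error(arm_boundary_conditions(solve_network(nl), "nope"), "unknown")
})

test_that("a turn in a segment does not change its hydraulic behavior", {
  straight <- make_straight_chip(length = 1.6e-3)
  elbow <- make_elbow_chip(leg = 0.8e-3) # same total length, one turn
  qs <- solve_network(straight)$flows$Q
  qe <- solve_network(elbow)$flows$Q
  expect_equal(qs, qe, tolerance = 1e-12)
})
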