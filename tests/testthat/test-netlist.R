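test_that("netlist JSON serialization round-trips losslessly", {
  for (nl in list(make_h_chip(), make_cascade_chip(), make_elbow_chip(),
                  make_random_grid_chip(7))) {
    path <- withr::local_tempfile(fileext = ".json")
    save_netlist(nl, path)
    expect_netlist_equal(load_netlist(path), nl)
  }
})

test_that("unit declarations in netlist files are converted on load", {
  nl <- make_straight_chip()
  path <- withr::local_tempfile(fileext = ".json")
  save_netlist(nl, path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$units <- "um"
  raw$nodes$x <- raw$nodes$x * 1e6
  raw$nodes$y <- raw$nodes$y * 1e6
  raw$segments$width <- raw$segments$width * 1e6
  raw$segments$height <- raw$segments$height * 1e6
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, path2, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  expect_netlist_equal(load_netlist(path2), nl)
})

test_that("H chip decomposes into 7 channels and 2 three-arm intersections", {
  nl <- make_h_chip()
  expect_equal(nrow(nl$segments), 7)
  expect_equal(sum(nl$nodes$kind == "intersection"), 2)
  expect_equal(sum(nl$nodes$kind == "terminal"), 4)
  # each intersection leaves one compass arm unused
  for (id in nl$nodes$id[nl$nodes$kind == "intersection"]) {
    arms <- chipflow:::node_arm_map(nl, id)
    expect_length(arms, 3)
    expect_length(setdiff(c("N", "E", "S", "W"), arms), 1)
  }
  # geometry is mirror-symmetric about the crossbar's perpendicular bisector
  axis_x <- mean(range(nl$nodes$x))
  reflected <- data.frame(x = round(2 * axis_x - nl$nodes$x, 12),
                          y = round(nl$nodes$y, 12))
  original <- data.frame(x = round(nl$nodes$x, 12), y = round(nl$nodes$y, 12))
  expect_setequal(do.call(paste, reflected), do.call(paste, original))
})

test_that("cascade chip counts follow the inlet/outlet arithmetic", {
  nl <- make_cascade_chip(3, 2)
  expect_equal(sum(nl$nodes$kind == "intersection"), 3)
  expect_equal(sum(nl$nodes$kind == "terminal"), 5)
  expect_equal(sort(nl$nodes$id[nl$nodes$kind == "intersection"]),
               c("a", "b", "c"))
  expect_true(all(abs(nl$segments$width - 200e-6) < 1e-15))
  nl2 <- make_cascade_chip(2, 1)
  expect_equal(sum(nl2$nodes$kind == "intersection"), 1)
})

test_that("validation rejects malformed netlists", {
  nl <- make_h_chip()
  # five segments on one intersection
  bad <- nl
  bad$nodes <- rbind(bad$nodes,
                     tibble::tibble(id = c("T5", "T6"), kind = "terminal",
                                    x = c(-0.8e-3, -0.4e-3), y = 0))
  bad$segments <- rbind(bad$segments,
                        tibble::tibble(id = c("x5", "x6"),
                                       from = c("T5", "T6"), to = "b",
                                       width = 200e-6, height = 100e-6,
                                       waypoints = list(
                                         matrix(numeric(0), ncol = 2),
                                         matrix(numeric(0), ncol = 2)),
                                       length = c(0.8e-3, 0.4e-3)))
  bad$bc <- rbind(bad$bc,
                  tibble::tibble(terminal = c("T5", "T6"),
                                 type = "pressure", value = 0))
  expect_error(validate_netlist(bad), "attached segments")
  # two arms on the same compass direction
  bad2 <- nl
  bad2$nodes$x[bad2$nodes$id == "TL"] <- 0.2e-3 # now east of b, like the crossbar
  bad2$nodes$y[bad2$nodes$id == "TL"] <- 0
  expect_error(validate_netlist(bad2), "compass")
  # disconnected graph
  bad3 <- nl
  bad3$nodes <- rbind(bad3$nodes,
                      tibble::tibble(id = c("I1", "I2"), kind = "terminal",
                                     x = c(10e-3, 11e-3), y = 0))
  bad3$segments <- rbind(bad3$segments,
                         tibble::tibble(id = "iso", from = "I1", to = "I2",
                                        width = 200e-6, height = 100e-6,
                                        waypoints = list(matrix(numeric(0),
                                                                ncol = 2)),
                                        length = 1e-3))
  bad3$bc <- rbind(bad3$bc,
                   tibble::tibble(terminal = c("I1", "I2"), type = "pressure",
                                  value = c(1, 0)))
  expect_error(validate_netlist(bad3), "disconnected")
  # schema violations on load
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(nodes = list()), path, auto_unbox = TRUE)
  expect_error(load_netlist(path), "segments")
})

test_that("random grid chips are deterministic, valid and solvable", {
  a <- make_random_grid_chip(11)
  b <- make_random_grid_chip(11)
  expect_netlist_equal(a, b)
  for (seed in 1:20) {
    nl <- make_random_grid_chip(seed, rows = 3, cols = 4)
    expect_silent(validate_netlist(nl))
    for (id in nl$nodes$id[nl$nodes$kind == "intersection"]) {
      expect_true(length(chipflow:::node_arm_map(nl, id)) %in% c(3, 4))
    }
    sol <- solve_network(nl)
    expect_lt(sol$kcl_residual, 1e-12)
  }
})
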