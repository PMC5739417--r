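test_that("exactly 14 role configurations survive mass conservation", {
  cfg <- enumerate_configurations()
  expect_equal(nrow(cfg), 14)
  expect_false("iiii" %in% cfg$pattern)
  expect_false("oooo" %in% cfg$pattern)
  expect_equal(anyDuplicated(cfg$pattern), 0L)
  # closed under the 8 symmetries of the square (brute-force group action)
  pats <- sort(cfg$pattern)
  for (el in chipflow:::symmetry_elements()) {
    perm <- chipflow:::element_perm(el)
    mapped <- apply(cfg[, c("N", "E", "S", "W")], 1, function(r) {
      out <- character(4)
      names(out) <- c("N", "E", "S", "W")
      out[perm[c("N", "E", "S", "W")]] <- substr(r, 1, 1)
      paste(out, collapse = "")
    })
    expect_setequal(sort(mapped), pats)
  }
})

test_that("sampled instances conserve mass within the velocity envelope", {
  set.seed(100)
  for (k in 1:300) {
    spec <- sample_instance()
    v <- spec$v
    expect_lt(abs(sum(v)), 1e-9 * sum(abs(v)))
    inl <- v[v > 0]
    expect_true(all(inl > 0 & inl <= 0.02))
    expect_true(any(v > 0) && any(v < 0))
  }
  s1 <- chipflow:::with_seed(5, sample_instance())
  s2 <- chipflow:::with_seed(5, sample_instance())
  expect_identical(s1, s2)
})

test_that("canonicalization collapses the symmetry and scale orbits", {
  v <- c(N = 0.01, E = 0.004, S = -0.02, W = 0.006)
  spec <- unit_intersection_spec(v)
  can <- canonicalize(spec)
  # every one of the 8 symmetric images maps to the same canonical spec
  for (el in chipflow:::symmetry_elements()) {
    img <- chipflow:::apply_element_to_spec(spec, el)
    expect_equal(canonicalize(img)$spec$v, can$spec$v, tolerance = 1e-14)
  }
  # uniform rescaling changes only the recorded scale
  can2 <- canonicalize(unit_intersection_spec(2 * v))
  expect_equal(can2$spec$v, can$spec$v, tolerance = 1e-14)
  expect_equal(can2$transform$scale, 2 * can$transform$scale,
               tolerance = 1e-14)
  # the transform inverts exactly
  back <- apply_spec_transform(can$spec, can$transform)
  expect_equal(back$v, spec$v, tolerance = 1e-14)
  rt <- apply_spec_transform(
    apply_spec_transform(can$spec, can$transform),
    invert_spec_transform(can$transform))
  expect_equal(rt$v, can$spec$v, tolerance = 1e-14)
})

test_that("library builds are reproducible and physically consistent", {
  lib <- build_library(3, seed = 42, spacing = 20e-6, diameters = 1e-6)
  expect_length(lib$records, 3)
  for (rec in lib$records) {
    f <- rec$field
    expect_lt(check_divergence(f),
              1e-8 * max(abs(f$u), abs(f$v)) / f$spacing)
    inlets <- sum(rec$spec$roles == "inlet")
    expect_equal(nrow(rec$bank), inlets * 10)
    expect_true(all(rec$bank$fate %in% c("exited", "frozen")))
  }
  lib2 <- build_library(3, seed = 42, spacing = 20e-6, diameters = 1e-6)
  for (id in names(lib$records)) {
    expect_identical(lib$records[[id]]$spec, lib2$records[[id]]$spec)
  }
  # round-trips through its single-file on-disk form
  path <- withr::local_tempfile(fileext = ".rds")
  write_library(lib, path)
  lib3 <- read_library(path)
  expect_identical(names(lib3$records), names(lib$records))
})

test_that("queries retrieve exact, rotated and rescaled matches", {
  spec <- unit_intersection_spec(c(N = 0.01, E = 0.005, S = -0.015, W = 0))
  lib <- build_library(0, extra_specs = list(spec), spacing = 20e-6)
  rec_spec <- lib$records[[1]]$spec
  m <- query_library(spec, lib)
  expect_equal(m$distance, 0, tolerance = 1e-12)
  # a rotated, x3-rescaled copy still matches at distance zero
  rot <- chipflow:::apply_element_to_spec(spec, list(k = 1, mirror = FALSE),
                                          scale = 3)
  m2 <- query_library(rot, lib)
  expect_equal(m2$distance, 0, tolerance = 1e-12)
  expect_equal(m2$transform$scale, 3 * m$transform$scale, tolerance = 1e-12)
  # transform maps the stored record onto the query
  back <- apply_spec_transform(rec_spec, m2$transform)
  expect_equal(back$v, rot$v, tolerance = 1e-12)
  # normalization makes queries scale-invariant
  m3 <- query_library(unit_intersection_spec(spec$v * 1.7), lib)
  expect_equal(m3$record_id, m$record_id)
  expect_equal(m3$distance, 0, tolerance = 1e-12)
})

test_that("the H-chip example intersection queries to an exact match", {
  b_spec <- unit_intersection_spec(c(N = 0.01, E = -0.03, S = 0.02, W = 0))
  lib <- build_library(0, extra_specs = list(b_spec), spacing = 20e-6)
  m <- query_library(b_spec, lib)
  expect_equal(m$distance, 0, tolerance = 1e-12)
})

test_that("coverage gaps error and extra records never hurt", {
  spec_t <- unit_intersection_spec(c(N = 0.01, E = -0.01, S = 0, W = 0))
  spec_x <- unit_intersection_spec(c(N = 0.01, E = -0.005, S = -0.0025,
                                     W = -0.0025))
  lib_t <- build_library(0, extra_specs = list(spec_t), spacing = 20e-6)
  expect_error(query_library(spec_x, lib_t),
               class = "chipflow_coverage_error")
  # adding records can only shrink the best distance
  near <- unit_intersection_spec(c(N = 0.012, E = -0.006, S = -0.003,
                                   W = -0.003))
  lib_1 <- build_library(0, extra_specs = list(spec_x), spacing = 20e-6)
  d1 <- query_library(near, lib_1)$distance
  lib_2 <- build_library(0, extra_specs = list(spec_x, near),
                         spacing = 20e-6)
  d2 <- query_library(near, lib_2)$distance
  expect_lte(d2, d1)
  expect_equal(d2, 0, tolerance = 1e-12)
})

test_that("distance-zero retrieval reproduces re-simulation", {
  # store one record; query a rotated + mirrored + rescaled copy and check
  # that mode-A traversal equals direct re-simulation of the query spec
  base <- unit_intersection_spec(c(N = 0.012, E = 0.006, S = -0.018, W = 0))
  lib <- build_library(0, extra_specs = list(base), spacing = 20e-6)
  el <- list(k = 3, mirror = TRUE)
  qspec <- chipflow:::apply_element_to_spec(base, el, scale = 2)
  entry_arm <- names(qspec$v)[qspec$v > 0][1]
  for (q_in in c(0.25, 0.5, 0.8)) {
    got <- traverse_intersection(q_in, entry_arm, qspec, lib,
                                 diameter = 1e-6, mode = "A")
    expect_equal(got$provenance$distance, 0, tolerance = 1e-12)
    # independent route: solve the query spec directly and trace
    dom <- chipflow:::unit_intersection_domain(
      chipflow:::active_arms_of(qspec), spacing = 20e-6)
    fq <- solve_stokes(dom, qspec$v)
    st <- chipflow:::mouth_position(dom, entry_arm, q_in, "in")
    tr <- trace_particle(fq, st, diameter = 1e-6)
    expect_equal(got$exit_arm, tr$exit_arm)
    expect_equal(got$q_out, tr$q_exit, tolerance = 1e-4)
  }
})
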