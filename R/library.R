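# The pre-simulated intersection library: random unit-intersection
# instances are solved once, their velocity fields and trajectory banks
# stored, and later retrieved by closest-match queries on arm roles and
# flow rates. Symmetries of the square and Stokes-flow linearity collapse
# rotated/reflected/rescaled instances onto one canonical representative.

ENVELOPE_VMAX <- 0.02 # library validity: arm speeds in (0, 2] cm/s

#' Feasible inlet/outlet configurations of the four-arm intersection
#'
#' All 2^4 assignments of inlet/outlet roles to the four compass arms,
#' minus the two forbidden by conservation of mass (all four inlets, all
#' four outlets): 14 feasible configurations. Unused arms are a property
#' of individual instances, not of the role patterns enumerated here.
#'
#' @return A 14-row tibble with character columns `N`, `E`, `S`, `W`
#'   (`"inlet"` or `"outlet"`) and a `pattern` key.
#' @export
enumerate_configurations <- function() {
  grid <- expand.grid(N = c("inlet", "outlet"), E = c("inlet", "outlet"),
                      S = c("inlet", "outlet"), W = c("inlet", "outlet"),
                      stringsAsFactors = FALSE)
  keep <- !(rowSums(grid == "inlet") == 4 | rowSums(grid == "outlet") == 4)
  out <- tibble::as_tibble(grid[keep, ])
  out$pattern <- apply(out[, ARMS], 1, function(r) {
    paste(substr(r, 1, 1), collapse = "")
  })
  out[order(out$pattern), ]
}

#' Unit-intersection boundary specification
#'
#' Arm roles and signed mean velocities (m/s, positive into the
#' intersection) of one instance of the four-arm prototype junction.
#' Velocities must conserve mass; role signs must be consistent (inlets
#' positive, outlets negative, unused exactly zero); at least one inlet
#' and one outlet are required.
#'
#' @param velocities Named numeric over `c("N","E","S","W")`: signed mean
#'   arm velocities, m/s. Roles are inferred from the signs: positive =
#'   inlet, negative = outlet, zero = unused.
#' @param check_envelope Error if an inlet exceeds the library envelope
#'   of 2 cm/s.
#' @return A `unit_intersection_spec` with fields `roles` and `v`.
#' @export
unit_intersection_spec <- function(velocities, check_envelope = FALSE) {
  if (is.null(names(velocities))) {
    stopifnot(length(velocities) == 4)
    names(velocities) <- ARMS
  }
  v <- setNames(as.numeric(velocities[ARMS]), ARMS)
  if (anyNA(v)) abort("velocities must be named over N, E, S, W")
  roles <- ifelse(v > 0, "inlet", ifelse(v < 0, "outlet", "unused"))
  if (!any(roles == "inlet") || !any(roles == "outlet")) {
    abort("spec needs at least one inlet and one outlet")
  }
  tot <- sum(abs(v))
  if (abs(sum(v)) > 1e-9 * tot) {
    abort("arm velocities do not conserve mass")
  }
  if (check_envelope && any(v > ENVELOPE_VMAX * (1 + 1e-9))) {
    abort(paste0("inlet velocity ", format(max(v)),
                 " m/s exceeds the library envelope of ", ENVELOPE_VMAX,
                 " m/s"))
  }
  structure(list(roles = setNames(roles, ARMS), v = v),
            class = "unit_intersection_spec")
}

#' @export
print.unit_intersection_spec <- function(x, ...) {
  cat("<unit_intersection_spec>\n")
  for (a in ARMS) {
    cat(sprintf("  %s: %-6s %10.4g mm/s\n", a, x$roles[a], x$v[a] * 1e3))
  }
  invisible(x)
}

spec_pattern <- function(spec) {
  paste(substr(spec$roles, 1, 1), collapse = "")
}

active_arms_of <- function(spec) ARMS[spec$roles != "unused"]

#' Sample a random unit-intersection instance
#'
#' Draws a role configuration uniformly from the 14 feasible patterns,
#' optionally degrades arms to unused with probability `unused_prob`
#' (rejecting draws that leave no inlet or no outlet), then draws inflow
#' rates uniformly on (0, 2] cm/s. For `N` outlets, `N - 1` outflow rates
#' are drawn uniformly on (0, 2] cm/s and the last outlet (in N, E, S, W
#' order) balances the total; draws whose balance is non-positive are
#' rejected and resampled.
#'
#' @param unused_prob Per-arm probability of degrading an arm to unused.
#' @param v_max Upper end of the sampled velocity range, m/s.
#' @param max_attempts Resampling bound before erroring.
#' @return A [unit_intersection_spec()]. Uses the current RNG stream;
#'   seed with `set.seed()` for reproducibility.
#' @export
sample_instance <- function(unused_prob = 0.25, v_max = ENVELOPE_VMAX,
                            max_attempts = 1000) {
  configs <- enumerate_configurations()
  for (attempt in seq_len(max_attempts)) {
    roles <- unlist(configs[sample.int(nrow(configs), 1), ARMS])
    drop <- runif(4) < unused_prob
    roles[drop] <- "unused"
    if (!any(roles == "inlet") || !any(roles == "outlet")) next
    v <- setNames(numeric(4), ARMS)
    inl <- ARMS[roles == "inlet"]
    out <- ARMS[roles == "outlet"]
    v[inl] <- runif(length(inl), 0, v_max)
    if (length(out) > 1) {
      v[head(out, -1)] <- -runif(length(out) - 1, 0, v_max)
    }
    bal <- -(sum(v[inl]) + sum(v[head(out, -1)]))
    if (bal >= 0) next # balancing outlet must carry positive outflow
    v[tail(out, 1)] <- bal
    return(unit_intersection_spec(v))
  }
  abort("failed to sample a mass-balanced instance")
}

# ---- square symmetries -----------------------------------------------------

# The 8 symmetries of the square: rotation by k * 90 degrees CCW, applied
# after an optional mirror about the horizontal axis (N <-> S).
symmetry_elements <- function() {
  els <- list()
  for (m in c(FALSE, TRUE)) for (k in 0:3) {
    els[[length(els) + 1]] <- list(k = k, mirror = m)
  }
  els
}

element_matrix <- function(el) {
  M <- if (el$mirror) matrix(c(1, 0, 0, -1), 2) else diag(2)
  R <- matrix(c(cos(pi / 2 * el$k), sin(pi / 2 * el$k),
                -sin(pi / 2 * el$k), cos(pi / 2 * el$k)), 2)
  round(R %*% M)
}

# permutation of arms: image arm of each original arm under the element
element_perm <- function(el) {
  Tm <- element_matrix(el)
  setNames(vapply(ARMS, function(a) {
    dir_arm(as.numeric(Tm %*% arm_dir(a)))
  }, character(1)), ARMS)
}

apply_element_to_spec <- function(spec, el, scale = 1) {
  perm <- element_perm(el)
  v <- setNames(numeric(4), ARMS)
  v[perm[ARMS]] <- spec$v[ARMS] * scale
  unit_intersection_spec(v)
}

invert_element <- function(el) {
  # (R^k M)^-1 = M R^-k = M rotation by -k then mirror; normalize to R^k' M^m
  if (!el$mirror) list(k = (4 - el$k) %% 4, mirror = FALSE)
  else el # mirror-then-rotate elements are involutions composed as R^k M
}

#' Canonical form of a unit-intersection spec
#'
#' Reduces a spec modulo the 8 symmetries of the square and (optionally)
#' velocity magnitude: velocities are divided by the total inflow (valid
#' because Stokes flow is linear in its boundary velocities) and the
#' lexicographically smallest image over the symmetry group is selected.
#' The returned transform maps the canonical spec back onto the original:
#' `apply_spec_transform(canonical, transform)` reproduces the input.
#'
#' @param spec A [unit_intersection_spec()].
#' @param normalize Divide velocities by total inflow.
#' @return List with `spec` (canonical), `transform` (list `k`, `mirror`,
#'   `scale`: rotate the canonical frame by `k` quarter-turns CCW after an
#'   optional N/S mirror, then multiply velocities by `scale`).
#' @export
canonicalize <- function(spec, normalize = TRUE) {
  scale <- if (normalize) sum(spec$v[spec$v > 0]) else 1
  base <- unit_intersection_spec(spec$v / scale)
  best <- NULL; best_el <- NULL
  for (el in symmetry_elements()) {
    img <- apply_element_to_spec(base, el)
    key_roles <- spec_pattern(img)
    if (is.null(best)) {
      take <- TRUE
    } else {
      br <- spec_pattern(best)
      take <- if (key_roles != br) key_roles < br else {
        dv <- img$v - best$v
        first <- which(abs(dv) > 1e-15)[1]
        !is.na(first) && dv[first] < 0
      }
    }
    if (take) { best <- img; best_el <- el }
  }
  list(spec = best,
       transform = list(k = invert_element(best_el)$k,
                        mirror = invert_element(best_el)$mirror,
                        scale = scale))
}

#' Apply a symmetry/scale transform to a spec
#'
#' @param spec A [unit_intersection_spec()].
#' @param transform A transform list (`k`, `mirror`, `scale`) as returned
#'   by [canonicalize()] or [query_library()].
#' @return The transformed `unit_intersection_spec`.
#' @export
apply_spec_transform <- function(spec, transform) {
  apply_element_to_spec(spec, list(k = transform$k, mirror = transform$mirror),
                        scale = transform$scale)
}

#' Invert a symmetry/scale transform
#' @param transform A transform list (`k`, `mirror`, `scale`).
#' @return The inverse transform.
#' @export
invert_spec_transform <- function(transform) {
  inv <- invert_element(list(k = transform$k, mirror = transform$mirror))
  list(k = inv$k, mirror = inv$mirror, scale = 1 / transform$scale)
}

# map points from the canonical unit-intersection frame into the frame of
# apply_spec_transform(spec, transform), rotating about the footprint center
transform_points <- function(pts, transform, center) {
  Tm <- element_matrix(list(k = transform$k, mirror = transform$mirror))
  sweep((pts - matrix(center, nrow(pts), 2, byrow = TRUE)) %*% t(Tm), 2,
        -center)
}

# arm in the transformed frame corresponding to a canonical-frame arm
transform_arm <- function(arm, transform) {
  perm <- element_perm(list(k = transform$k, mirror = transform$mirror))
  unname(perm[arm])
}

# ---- library build / query -------------------------------------------------

simulate_record <- function(spec, id, diameters, spacing, n_release = 10,
                            footprint = 1.6e-3, width = 200e-6) {
  active <- active_arms_of(spec)
  dom <- unit_intersection_domain(active, spacing = spacing,
                                  footprint = footprint, width = width)
  field <- solve_stokes(dom, spec$v)
  bank <- NULL
  for (diam in diameters) {
    for (arm in ARMS[spec$roles == "inlet"]) {
      rel <- release_uniform(dom, arm, n = n_release, diameter = diam)
      for (i in seq_len(nrow(rel))) {
        tr <- trace_particle(field, c(rel$x[i], rel$y[i]), diameter = diam)
        bank <- dplyr::bind_rows(bank, tibble::tibble(
          diameter = diam, arm = arm, release = i,
          q_entry = rel$q_entry[i], fate = tr$fate,
          exit_arm = tr$exit_arm, q_exit = tr$q_exit,
          trajectory = list(tr)))
      }
    }
  }
  structure(list(id = id, spec = spec, field = field, bank = bank,
                 provenance = list(spacing = spacing,
                                   diameters = diameters,
                                   n_release = n_release)),
            class = "intersection_record")
}

#' Build a library of pre-simulated unit intersections
#'
#' Samples `n` random instances (see [sample_instance()]), canonicalizes
#' each, solves its Stokes field, traces the trajectory bank (every inlet
#' arm x every diameter x `n_release` uniform releases), and stores the
#' records. Additional specs can be forced into the library via
#' `extra_specs` (canonicalized likewise), e.g. to guarantee exact
#' matches for a known chip.
#'
#' @param n Number of random instances.
#' @param seed Integer seed making the build reproducible.
#' @param diameters Particle diameters in the bank, m.
#' @param spacing Grid spacing of the stored fields, m.
#' @param extra_specs List of [unit_intersection_spec()] to include.
#' @param unused_prob Passed to [sample_instance()].
#' @param n_release Releases per inlet arm per diameter.
#' @param path Optional path; if given the library is also written there
#'   (serialized single-file database, see [write_library()]).
#' @param quiet Suppress per-record progress messages.
#' @return An `intersection_library` object.
#' @export
build_library <- function(n, seed = 1, diameters = 1e-6, spacing = 20e-6,
                          extra_specs = list(), unused_prob = 0.25,
                          n_release = 10, path = NULL, quiet = TRUE) {
  specs <- with_seed(seed, {
    lapply(seq_len(n), function(i) sample_instance(unused_prob = unused_prob))
  })
  specs <- c(specs, extra_specs)
  records <- list()
  failures <- character(0)
  for (i in seq_along(specs)) {
    can <- canonicalize(specs[[i]])
    id <- sprintf("rec%04d", i)
    rec <- tryCatch(
      simulate_record(can$spec, id, diameters, spacing,
                      n_release = n_release),
      error = function(e) {
        failures <<- c(failures, paste0(id, ": ", conditionMessage(e)))
        NULL
      })
    if (!is.null(rec)) {
      rec$source_scale <- can$transform$scale
      records[[id]] <- rec
      if (!quiet) message("built ", id, " (", spec_pattern(can$spec), ")")
    }
  }
  if (length(failures) && !quiet) {
    message(length(failures), " record(s) failed:\n  ",
            paste(failures, collapse = "\n  "))
  }
  lib <- structure(list(records = records,
                        meta = list(seed = seed, spacing = spacing,
                                    diameters = diameters,
                                    n_release = n_release,
                                    failures = failures,
                                    schema_version = 1L)),
                   class = "intersection_library")
  if (!is.null(path)) write_library(lib, path)
  lib
}

#' @export
print.intersection_library <- function(x, ...) {
  pats <- vapply(x$records, function(r) spec_pattern(r$spec), character(1))
  cat("<intersection_library> ", length(x$records), " records (",
      length(unique(pats)), " patterns), spacing ",
      format(x$meta$spacing * 1e6), " um\n", sep = "")
  invisible(x)
}

#' Write / read an intersection library
#'
#' The library is stored as one serialized file (an embedded single-file
#' database with a versioned schema).
#'
#' @param library An `intersection_library`.
#' @param path File path.
#' @return `path` (write) or the library (read).
#' @export
write_library <- function(library, path) {
  saveRDS(library, path)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  lib <- readRDS(path)
  if (!inherits(lib, "intersection_library")) {
    abort("file does not contain an intersection library")
  }
  lib
}

#' Find the closest pre-simulated intersection
#'
#' Searches the library for the record that best matches a query spec:
#' candidates must have an identical arm-role pattern after one of the 8
#' square symmetries (configuration mismatches change the topology of the
#' streamline split and are never interpolated); among those, the record
#' minimizing the Euclidean distance between inflow-normalized signed
#' velocity 4-vectors wins, with deterministic tie-breaking by record id
#' and symmetry order.
#'
#' @param spec A [unit_intersection_spec()].
#' @param library An `intersection_library`.
#' @param normalize Compare inflow-normalized velocities (default), making
#'   the query invariant to uniform velocity scaling; `FALSE` compares raw
#'   magnitudes as well.
#' @return A `match_result`: list with `record_id`, `distance`, and
#'   `transform` (`k`, `mirror`, `scale`) mapping the stored record's
#'   canonical frame onto the query frame.
#' @export
query_library <- function(spec, library, normalize = TRUE) {
  if (length(library$records) == 0) abort("library is empty")
  scale <- if (normalize) sum(spec$v[spec$v > 0]) else 1
  base <- unit_intersection_spec(spec$v / scale)
  best <- NULL
  for (el in symmetry_elements()) {
    img <- apply_element_to_spec(base, el) # query mapped into candidate frame
    pat <- spec_pattern(img)
    for (rid in names(library$records)) {
      rec <- library$records[[rid]]
      if (spec_pattern(rec$spec) != pat) next
      dist <- sqrt(sum((img$v - rec$spec$v)^2))
      if (is.null(best) || dist < best$distance - 1e-15) {
        inv <- invert_element(el)
        best <- list(record_id = rid, distance = dist,
                     transform = list(k = inv$k, mirror = inv$mirror,
                                      scale = scale))
      }
    }
  }
  if (is.null(best)) {
    cnd <- structure(
      class = c("chipflow_coverage_error", "error", "condition"),
      list(message = paste0(
        "no library record matches configuration ", spec_pattern(spec),
        " (any symmetry); augment the library with this configuration"),
        call = NULL, pattern = spec_pattern(spec)))
    stop(cnd)
  }
  structure(best, class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> record ", x$record_id, ", distance ",
      format(x$distance, digits = 4), ", transform k=", x$transform$k,
      " mirror=", x$transform$mirror, " scale=",
      format(x$transform$scale, digits = 4), "\n", sep = "")
  invisible(x)
}
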