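test_that("interfacial membership follows the dual-proximity rule", {
  sys <- toy_sys()
  frame1 <- sys$base_xyz
  ids <- water_ids(sys$atoms)
  mem <- interfacial_waters(frame1, sys$atoms, d_int = 4)
  truthw <- sys$water
  ## every permanent and transient bead starts on the interface plane;
  ## bulk beads 20+ Angstrom away never qualify
  expect_setequal(mem, ids[c(truthw$permanent, truthw$transient)])
  expect_length(intersect(mem, ids[truthw$bulk]), 0L)
  ## shrinking d_int below the gap half-width empties the set
  expect_length(interfacial_waters(frame1, sys$atoms, d_int = 0.5), 0L)
})

test_that("topologies without waters warn and return empty results", {
  spec <- toy_protein_spec(n_permanent = 0L, n_transient = 0L, n_bulk = 0L)
  dry <- build_toy_system(spec, seed = 1L)
  expect_warning(mem <- interfacial_waters(dry$base_xyz, dry$atoms), "no waters")
  expect_length(mem, 0L)
})

test_that("hydrogen bonds apply distance and angle criteria", {
  ## two waters, donor O-H pointing straight at the acceptor: edge at 2.8 A
  mk <- function(sep) {
    df <- data.frame(serial = 1:6,
                     name = rep(c("OH2", "H1", "H2"), 2L),
                     element = rep(c("O", "H", "H"), 2L),
                     resname = "TIP3", resid = rep(1:2, each = 3L),
                     chain = "W", role = "water", copy = NA_integer_,
                     stringsAsFactors = FALSE)
    xyz <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0),
                 c(sep, 0, 0), c(sep + 0.96, 0, 0), c(sep - 0.24, 0.93, 0))
    list(atoms = atom_table(df), xyz = xyz)
  }
  w <- mk(2.8)
  hb <- hydrogen_bonds(w$xyz, w$atoms)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$dist, 2.8)
  expect_false(attr(hb, "distance_only"))
  ## same pair at 5.0 A: no edge
  w <- mk(5.0)
  expect_equal(nrow(hydrogen_bonds(w$xyz, w$atoms)), 0L)
  ## within distance but hopeless angle: no edge
  w <- mk(2.8)
  w$xyz[2L, ] <- c(0, 0, 0.96)   # donor H perpendicular to the O...O axis
  w$xyz[5L, ] <- c(2.8, 0, 0.96)
  expect_equal(nrow(hydrogen_bonds(w$xyz, w$atoms, angle_min = 150)), 0L)
})

test_that("hydrogen-bond graphs equal the brute-force evaluation on random frames", {
  set.seed(41)
  for (rep in 1:8) {
    nw <- 20L
    df <- data.frame(serial = seq_len(3L * nw),
                     name = rep(c("OH2", "H1", "H2"), nw),
                     element = rep(c("O", "H", "H"), nw),
                     resname = "TIP3", resid = rep(seq_len(nw), each = 3L),
                     chain = "W", role = "water", copy = NA_integer_,
                     stringsAsFactors = FALSE)
    o <- matrix(runif(nw * 3, 0, 12), nw, 3L)
    xyz <- matrix(NA_real_, 3L * nw, 3L)
    for (i in seq_len(nw)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      v <- rnorm(3); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
      xyz[3L * i - 2L, ] <- o[i, ]
      xyz[3L * i - 1L, ] <- o[i, ] + 0.96 * u
      xyz[3L * i, ] <- o[i, ] + 0.96 * (cos(1.82) * u + sin(1.82) * v)
    }
    atoms <- atom_table(df)
    got <- hydrogen_bonds(xyz, atoms, d_hb = 3.5, angle_min = 140)
    ## independent exhaustive triple loop
    oracle <- list()
    for (i in seq_len(nw - 1L)) for (j in (i + 1L):nw) {
      d <- sqrt(sum((o[i, ] - o[j, ])^2))
      if (d > 3.5) next
      hit <- FALSE
      for (hd in list(c(i, j), c(j, i))) {
        for (h in c(3L * hd[1L] - 1L, 3L * hd[1L])) {
          v1 <- o[hd[1L], ] - xyz[h, ]; v2 <- o[hd[2L], ] - xyz[h, ]
          ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                    sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
          if (ang >= 140) hit <- TRUE
        }
      }
      if (hit) oracle[[length(oracle) + 1L]] <- c(3L * i - 2L, 3L * j - 2L, d)
    }
    om <- if (length(oracle)) do.call(rbind, oracle) else matrix(numeric(), 0L, 3L)
    expect_equal(nrow(got), nrow(om))
    if (nrow(om)) {
      key <- function(a, b) paste(pmin(a, b), pmax(a, b))
      expect_setequal(key(got$a, got$b), key(om[, 1L], om[, 2L]))
      expect_equal(sort(got$dist), sort(om[, 3L]), tolerance = 1e-9)
    }
  }
})

test_that("water persistence recovers the scripted permanence classes", {
  sys <- toy_sys()
  cs <- lapply(seq_len(14L), function(i)
    copy_script(i, if (i <= 7L) "A" else "B", "Xe4", list(type = "none")))
  st <- script_trajectory(sys, event_script(cs, n_frames = 80L, seed = 2L))
  ## 12 scripted permanent + 5 transient (resident 60% of frames)
  res <- persistent_water_count(st$trajectory, sys$atoms, residence_min = 1.0)
  expect_equal(res$count, 12L)
  expect_setequal(res$records$water[res$records$residence == 1],
                  st$truth$water$permanent)
  res50 <- persistent_water_count(st$trajectory, sys$atoms, residence_min = 0.5)
  expect_equal(res50$count, 17L)
  ## monotonicity: non-increasing in residence_min, non-decreasing in d_int
  counts_rm <- vapply(c(0.2, 0.5, 0.8, 1.0), function(rm)
    persistent_water_count(st$trajectory, sys$atoms, residence_min = rm)$count,
    numeric(1))
  expect_true(all(diff(counts_rm) <= 0))
  counts_di <- vapply(c(2.5, 4, 6), function(di)
    persistent_water_count(st$trajectory, sys$atoms, d_int = di,
                           residence_min = 0.5)$count, numeric(1))
  expect_true(all(diff(counts_di) >= 0))
  expect_error(persistent_water_count(st$trajectory, sys$atoms, residence_min = 0),
               "residence_min")
  expect_error(persistent_water_count(st$trajectory, sys$atoms, residence_min = 1.2),
               "residence_min")
  ## the per-frame network series sees the interfacial cluster
  ser <- water_network_series(st$trajectory, sys$atoms)
  expect_equal(nrow(ser), 80L)
  expect_true(all(ser$n_interfacial >= 12L))
})
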