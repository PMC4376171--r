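test_that("min_surface_distance matches hand values and a brute-force oracle", {
  expect_equal(min_surface_distance(c(0, 0, 6), rbind(c(0, 0, 0))), 6)
  expect_equal(min_surface_distance(rbind(c(0, 0, 0), c(0, 0, 0)),
                                    rbind(c(0, 0, 0), c(9, 9, 9))), 0)
  ## geometric center of a diatomic is used
  expect_equal(min_surface_distance(rbind(c(0, 0, 5), c(0, 0, 7)),
                                    rbind(c(0, 0, 0))), 6)
  expect_error(min_surface_distance(c(0, 0, 0), matrix(numeric(), 0, 3)),
               "at least one")
  set.seed(21)
  for (i in 1:25) {
    cloud <- matrix(rnorm(50 * 3, sd = 8), 50, 3)
    lig <- matrix(rnorm(6, sd = 8), 2, 3)
    ctr <- colMeans(lig)
    oracle <- min(vapply(seq_len(50), function(j)
      sqrt(sum((cloud[j, ] - ctr)^2)), numeric(1)))
    expect_equal(min_surface_distance(lig, cloud), oracle, tolerance = 1e-12)
  }
})

test_that("detect_escape applies the threshold + persistence contract", {
  ## distance series [1,2,6,7,8], threshold 5, persistence 2 -> third frame
  ev <- detect_escape(fake_track(c(1, 2, 6, 7, 8)), threshold = 5, persistence = 2)
  expect_equal(ev$frame, 3L)
  ## never above threshold: non-escaper
  expect_null(detect_escape(fake_track(c(1, 2, 3, 4.9, 2))))
  ## flicker [1,6,1,6,6,6] with persistence 3: the durable run wins
  ev <- detect_escape(fake_track(c(1, 6, 1, 6, 6, 6)), threshold = 5, persistence = 3)
  expect_equal(ev$frame, 4L)
  ## a run reaching the trajectory end counts even if shorter than persistence
  ev <- detect_escape(fake_track(c(1, 1, 6, 6)), threshold = 5, persistence = 10)
  expect_equal(ev$frame, 3L)
  expect_error(detect_escape(fake_track(c(1, 6)), persistence = 0), "persistence")
})

test_that("raising the threshold never yields an earlier escape frame", {
  set.seed(31)
  for (i in 1:40) {
    d <- abs(cumsum(rnorm(80, mean = 0.1, sd = 1.2)))
    f_lo <- detect_escape(fake_track(d), threshold = 4, persistence = 5)
    f_hi <- detect_escape(fake_track(d), threshold = 6, persistence = 5)
    if (!is.null(f_hi)) {
      expect_false(is.null(f_lo))
      expect_lte(f_lo$frame, f_hi$frame)
    }
  }
})

test_that("portal classification breaks exact ties deterministically", {
  ## three single-atom 'helices' equidistant from the exit point: the two
  ## alphabetically smallest labels win
  fix <- micro_atoms(rbind(c(10, 0, 2), c(-10, 0, 2), c(0, 10, 2), c(0, 0, -2)))
  atoms <- atom_table(fix$atoms)
  regions <- data.frame(chain = "A", label = c("D", "C", "B"),
                        start = 1:3, end = 1:3, type = "helix",
                        stringsAsFactors = FALSE)
  ann <- md_annotation(regions)
  coords <- array(rep(fix$xyz, 3), dim = c(4L, 3L, 3L))
  traj <- md_trajectory(coords)
  tr <- fake_track(c(1, 4, 9), chains = "A")
  tr$z <- c(0, 2, 30)
  ev <- list(copy = 1L, frame = 3L)
  expect_equal(classify_portal(tr, ev, window = 2L, annotation = ann,
                               atoms = atoms, trajectory = traj,
                               classify_bound = 15), "B-C")
  ## far beyond the classifiability bound -> unclassified
  expect_equal(classify_portal(tr, ev, window = 2L, annotation = ann,
                               atoms = atoms, trajectory = traj,
                               classify_bound = 5), "unclassified")
  expect_error(classify_portal(tr, NULL, window = 2L, annotation = ann,
                               atoms = atoms, trajectory = traj), "NULL event")
})

test_that("cavity occupancy uses nearest-within-cutoff with alphabetical ties", {
  ## two overlapping cavities; ligand exactly between -> alphabetical winner
  lining <- rbind(c(-4, -1, 0), c(-4, 1, 0), c(-4, 0, 1),   # cavity M, centroid (-4,0,1/3)
                  c(4, -1, 0), c(4, 1, 0), c(4, 0, 1))      # cavity K, centroid (4,0,1/3)
  fix <- micro_atoms(lining)
  atoms <- atom_table(rbind(fix$atoms,
    data.frame(serial = 7:8, name = c("O1", "O2"), element = "O",
               resname = "O2", resid = 9001L, chain = "A", role = "ligand",
               copy = 1L, stringsAsFactors = FALSE)))
  ann <- md_annotation(
    data.frame(chain = "A", label = "A", start = 1L, end = 6L, type = "helix"),
    list(cavity_definition("M", "A", 1:3, cutoff = 6),
         cavity_definition("K", "A", 4:6, cutoff = 6)))
  mk_traj <- function(lig) {
    xyz <- rbind(lining, lig + c(0, 0, 0.5), lig - c(0, 0, 0.5))
    md_trajectory(array(xyz, dim = c(8L, 3L, 1L)))
  }
  tracks <- build_ligand_tracks(mk_traj(c(0, 0, 1 / 3)), atoms, ann)
  expect_equal(tracks[[1L]]$cavity, "K")           # exact tie -> alphabetical
  tracks <- build_ligand_tracks(mk_traj(c(-1, 0, 1 / 3)), atoms, ann)
  expect_equal(tracks[[1L]]$cavity, "M")           # nearer centroid wins
  tracks <- build_ligand_tracks(mk_traj(c(0, 30, 0)), atoms, ann)
  expect_true(is.na(tracks[[1L]]$cavity))          # outside every cutoff
})

test_that("crossing detection honors the dwell contract", {
  mk <- function(s) fake_track(rep(1, length(s)), subunit = s)
  ## A -> B with a confirmed dwell: one event, not returned
  s <- c(rep("A", 40), rep("interface", 3), rep("B", 50))
  ev <- detect_crossings(mk(s), dwell = 10)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$origin, "A"); expect_equal(ev$destination, "B")
  expect_false(ev$returned)
  expect_equal(ev$departure_frame, 40L)
  expect_equal(ev$arrival_frame, 44L)
  ## flicker shorter than the dwell: no event
  s <- c(rep("A", 40), rep("B", 5), rep("A", 40))
  expect_equal(nrow(detect_crossings(mk(s), dwell = 10)), 0L)
  ## A -> B -> A with both dwells: one event, returned
  s <- c(rep("A", 40), rep("B", 30), rep("A", 30))
  ev <- detect_crossings(mk(s), dwell = 10)
  expect_equal(nrow(ev), 1L)
  expect_true(ev$returned)
  ## single-chain topology: crossing undefined
  tr <- fake_track(rep(1, 10), subunit = rep("A", 10), chains = "A")
  expect_error(detect_crossings(tr), "single-chain")
})

test_that("interface residency requires a terminal interface run and no escape", {
  s <- c(rep("A", 50), rep("interface", 50))
  expect_true(is_interface_resident(fake_track(rep(1, 100), subunit = s), FALSE, dwell = 25))
  expect_false(is_interface_resident(fake_track(rep(1, 100), subunit = s), TRUE, dwell = 25))
  s2 <- c(rep("A", 90), rep("interface", 10))
  expect_false(is_interface_resident(fake_track(rep(1, 100), subunit = s2), FALSE, dwell = 25))
})

test_that("pathway summaries enforce the accounting identity and reject duplicates", {
  s <- summarize_pathways(NULL, n_copies = 14L)
  expect_equal(s$n_non_escaped, 14L)
  expect_length(s$portal_counts, 0L)
  esc <- data.frame(copy = c(1L, 2L, 3L), frame = c(10L, 20L, 30L),
                    portal = c("B-G", "B-G", "E-F"),
                    last_cavity = "Xe4", stringsAsFactors = FALSE)
  s <- summarize_pathways(esc, n_copies = 14L, interface_resident = 4L)
  expect_equal(s$portal_counts, list(`B-G` = 2L, `E-F` = 1L))
  expect_equal(s$n_non_escaped, 10L)
  expect_equal(sum(unlist(s$portal_counts)) + s$n_interface_resident +
                 s$n_non_escaped, 14L)
  expect_error(summarize_pathways(esc[c(1, 1, 2), ], n_copies = 14L), "duplicate")
  expect_error(summarize_pathways(esc, n_copies = 14L, interface_resident = 1L),
               "both escaped and interface-resident")
})

test_that("identical inputs give byte-identical event tables", {
  sys <- toy_sys()
  sc <- random_event_script(sys, seed = 9L, n_frames = 150L)
  st <- script_trajectory(sys, sc)
  dir <- withr::local_tempdir()
  out <- character(2L)
  for (i in 1:2) {
    ana <- analyze_trajectory(st$trajectory, sys$atoms, sys$annotation)
    f <- write_event_table(event_table(ana$escapes, ana$crossings), ana$summary,
                           file.path(dir, paste0("run", i)))
    out[i] <- paste(readLines(f[["events"]]), collapse = "\n")
  }
  expect_identical(out[1L], out[2L])
})
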