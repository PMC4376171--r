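test_that("the default toy system carries 14 ligand copies, 7 per chain", {
  sys <- toy_sys()
  expect_equal(n_ligand_copies(sys$atoms), 14L)
  cc <- table(ligand_copy_chains(sys$atoms))
  expect_equal(unname(cc[c("A", "B")]), c(7L, 7L), ignore_attr = TRUE)
  expect_equal(sum(sys$atoms$role == "water") / 3L,
               length(sys$water$permanent) + length(sys$water$transient) +
                 length(sys$water$bulk))
  validate_annotation(sys$annotation, sys$atoms)
})

test_that("regeneration with the same seed gives an identical topology", {
  a <- build_toy_system(toy_protein_spec(), seed = 7L)
  b <- build_toy_system(toy_protein_spec(), seed = 7L)
  expect_identical(as.data.frame(a$atoms), as.data.frame(b$atoms))
  expect_identical(a$base_xyz, b$base_xyz)
})

test_that("a waterless spec builds a valid topology with an empty water set", {
  dry <- build_toy_system(toy_protein_spec(n_permanent = 0L, n_transient = 0L,
                                           n_bulk = 0L), seed = 1L)
  expect_equal(sum(dry$atoms$role == "water"), 0L)
  expect_equal(n_ligand_copies(dry$atoms), 14L)
})

test_that("the feasible portal set covers the wild-type pathway mix", {
  sys <- toy_sys()
  fp <- feasible_portals(sys, "A")
  expect_true(all(c("B-G", "E-F", "B-E", "C-G", "corner:FG") %in% fp))
  ## mirror symmetry of the layout
  expect_identical(fp, feasible_portals(sys, "B"))
})

test_that("a single scripted escape is recovered exactly end to end", {
  sys <- toy_sys()
  cs <- c(list(copy_script(1L, "A", c("Xe4", "Xe2"),
                           list(type = "escape", portal = "B-G", frame = 200L))),
          lapply(2:14, function(i)
            copy_script(i, if (i <= 7L) "A" else "B", "B", list(type = "none"))))
  st <- script_trajectory(sys, event_script(cs, n_frames = 300L, seed = 3L))
  ana <- analyze_trajectory(st$trajectory, sys$atoms, sys$annotation)
  expect_equal(nrow(ana$escapes), 1L)
  expect_equal(ana$escapes$copy, 1L)
  expect_equal(ana$escapes$portal, "B-G")
  expect_equal(ana$escapes$frame, 200L)
  expect_equal(ana$escapes$last_cavity, "Xe2")
  expect_equal(ana$summary$n_non_escaped, 13L)
})

test_that("an all-non-escape script yields 14 non-escapers", {
  sys <- toy_sys()
  cs <- lapply(1:14, function(i)
    copy_script(i, if (i <= 7L) "A" else "B",
                sample(c("B", "Xe1", "Xe2", "Xe4"), 2L), list(type = "none")))
  st <- script_trajectory(sys, event_script(cs, n_frames = 150L, seed = 6L))
  ana <- analyze_trajectory(st$trajectory, sys$atoms, sys$annotation)
  expect_length(ana$summary$portal_counts, 0L)
  expect_equal(ana$summary$n_non_escaped, 14L)
  expect_equal(nrow(ana$crossings), 0L)
})

test_that("the wild-type-like mix is recovered exactly at zero noise", {
  sys <- toy_sys()
  st <- script_trajectory(sys, wt_like_script(sys, n_frames = 300L, seed = 1L))
  ana <- analyze_trajectory(st$trajectory, sys$atoms, sys$annotation)
  expect_equal(ana$summary$portal_counts,
               list(`B-E` = 2L, `B-G` = 5L, `C-G` = 1L, `E-F` = 4L))
  expect_equal(ana$summary$n_interface_resident, 1L)
  expect_equal(ana$summary$n_non_escaped, 1L)   # the inter-subunit crosser
  expect_equal(nrow(ana$crossings), 1L)
  ## last-cavity dwell pattern among the escapers: 7 Xe4, 2 Xe2, 2 Xe1, 1 B
  tab <- table(ana$escapes$last_cavity)
  expect_equal(tab[["Xe4"]], 7L)
  expect_equal(tab[["Xe2"]], 2L)
  expect_equal(tab[["Xe1"]], 2L)
  expect_equal(tab[["B"]], 1L)
})

test_that("scripted crossings reproduce departure, arrival and return", {
  sys <- toy_sys()
  cs <- c(list(copy_script(1L, "A", "Xe4",
                           list(type = "crossing", depart_frame = 90L,
                                arrive_frame = 120L, return_frame = 190L))),
          lapply(2:14, function(i)
            copy_script(i, if (i <= 7L) "A" else "B", "B", list(type = "none"))))
  st <- script_trajectory(sys, event_script(cs, n_frames = 300L, seed = 4L))
  ana <- analyze_trajectory(st$trajectory, sys$atoms, sys$annotation)
  expect_equal(nrow(ana$crossings), 1L)
  expect_equal(ana$crossings$origin, "A")
  expect_equal(ana$crossings$destination, "B")
  expect_true(ana$crossings$returned)
  ## the detector places departure/arrival at the subunit-assignment flips,
  ## which bracket the scripted cavity-to-cavity frames
  expect_lte(abs(ana$crossings$departure_frame - 90L), 20L)
  expect_lte(abs(ana$crossings$arrival_frame - 120L), 20L)
  expect_lt(ana$crossings$departure_frame, ana$crossings$arrival_frame)
})

test_that("shell jitter exercises per-frame centroids without breaking recovery", {
  sys <- toy_sys()
  cs <- c(list(copy_script(1L, "A", c("B", "Xe4"),
                           list(type = "escape", portal = "E-F", frame = 150L))),
          lapply(2:14, function(i)
            copy_script(i, if (i <= 7L) "A" else "B", "Xe2", list(type = "none"))))
  st <- script_trajectory(sys, event_script(cs, n_frames = 220L, seed = 5L,
                                            jitter_shell = 0.1))
  ana <- analyze_trajectory(st$trajectory, sys$atoms, sys$annotation)
  expect_equal(ana$escapes$portal, "E-F")
  expect_equal(ana$escapes$last_cavity, "Xe4")
  ## centroids genuinely move frame to frame under jitter
  cv <- sys$annotation$cavities[[1L]]
  c1 <- cavity_centroid(st$trajectory$coords[, , 1L], cv, sys$atoms)
  c2 <- cavity_centroid(st$trajectory$coords[, , 2L], cv, sys$atoms)
  expect_gt(sqrt(sum((c1 - c2)^2)), 0)
})

test_that("script validation rejects inconsistent inputs", {
  sys <- toy_sys()
  cs <- lapply(1:14, function(i)
    copy_script(i, if (i <= 7L) "A" else "B", "B", list(type = "none")))
  bad <- cs; bad[[1L]] <- copy_script(1L, "A", "NotACavity", list(type = "none"))
  expect_error(script_trajectory(sys, event_script(bad, n_frames = 150L)),
               "undeclared cavity")
  expect_error(script_trajectory(sys, event_script(cs[-1L], n_frames = 150L)),
               "every ligand copy")
  bad2 <- cs; bad2[[1L]] <- copy_script(1L, "A", "B",
                                        list(type = "escape", portal = "B-G",
                                             frame = 10L))
  expect_error(script_trajectory(sys, event_script(bad2, n_frames = 150L)),
               "out of range")
  expect_error(copy_script(1L, "A", "B", list(type = "teleport")), "outcome")
})

test_that("infeasible portals are reported, not silently misplaced", {
  sys <- toy_sys()
  expect_error(find_exit_direction(sys, "A", "A-H"), "no feasible exit direction")
  expect_error(find_exit_direction(sys, "A", "Q-Z"), "does not name two declared helices")
})
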