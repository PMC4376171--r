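# Shared fixtures, built in code. The toy system is deterministic, so one
# instance (with its exit-direction cache) is shared across test files.

.fixture_env <- new.env(parent = emptyenv())

toy_sys <- function() {
  if (is.null(.fixture_env$sys))
    .fixture_env$sys <- build_toy_system(toy_protein_spec(), seed = 1L)
  .fixture_env$sys
}

## a minimal hand-built atom table: n single-atom protein residues at given
## coordinates, plus optional extras rbind-ed on
micro_atoms <- function(xyz, chain = "A", role = "protein", resname = "ALA",
                        name = "CA") {
  n <- nrow(xyz)
  df <- data.frame(serial = seq_len(n), name = name, element = "C",
                   resname = resname, resid = seq_len(n), chain = chain,
                   role = role, copy = NA_integer_, stringsAsFactors = FALSE)
  list(atoms = df, xyz = xyz)
}

## a bare ligand track (for detector unit tests)
fake_track <- function(surf_dist, subunit = NULL, cavity = NA_character_,
                       copy = 1L, chains = c("A", "B")) {
  n <- length(surf_dist)
  df <- data.frame(frame = seq_len(n), x = 0, y = 0, z = 0,
                   surf_dist = surf_dist,
                   subunit = if (is.null(subunit)) rep("A", n) else subunit,
                   cavity = rep(cavity, length.out = n),
                   stringsAsFactors = FALSE)
  attr(df, "copy") <- copy
  attr(df, "chain") <- "A"
  attr(df, "chains") <- chains
  class(df) <- c("ligand_track", "data.frame")
  df
}

## hand-written PSF text, independent of write_psf()
write_fixture_psf <- function(path, n_protein = 100L, copies_per_chain = 7L) {
  lines <- c("PSF", "", "       1 !NTITLE", " REMARKS hand-built fixture", "")
  natom <- n_protein + 2L * 2L * copies_per_chain
  lines <- c(lines, sprintf("%8d !NATOM", natom))
  serial <- 0L
  for (i in seq_len(n_protein)) {
    serial <- serial + 1L
    ch <- if (i <= n_protein / 2) "A" else "B"
    lines <- c(lines, sprintf("%8d %-4s %-4d %-4s %-4s %-4s %10.6f %13.4f %11d",
                              serial, ch, i, "GLY", "CA", "CA", 0, 12.011, 0))
  }
  for (ch in c("A", "B")) {
    for (k in seq_len(copies_per_chain)) {
      for (nm in c("O1", "O2")) {
        serial <- serial + 1L
        lines <- c(lines, sprintf("%8d %-4s %-4d %-4s %-4s %-4s %10.6f %13.4f %11d",
                                  serial, ch, 9000L + k, "O2", nm, "O", 0, 15.999, 0))
      }
    }
  }
  lines <- c(lines, "", "       0 !NBOND: bonds", "")
  writeLines(lines, path)
  path
}

## recovery scorecard for one scripted run against its analysis
recovery_score <- function(st, ana) {
  tr <- st$truth$events
  esc <- tr[tr$outcome == "escape", , drop = FALSE]
  ok_port <- ok_cav <- ok_frame <- 0L
  for (i in seq_len(nrow(esc))) {
    g <- ana$escapes[ana$escapes$copy == esc$copy[i], , drop = FALSE]
    if (nrow(g) == 1L) {
      ok_port <- ok_port + (g$portal == esc$portal[i])
      ok_cav <- ok_cav + identical(g$last_cavity, esc$last_cavity[i])
      ok_frame <- ok_frame + (abs(g$frame - esc$escape_frame[i]) <= 10L)
    }
  }
  cross <- tr[tr$outcome == "crossing", , drop = FALSE]
  ok_cross <- 0L
  for (i in seq_len(nrow(cross))) {
    g <- ana$crossings[ana$crossings$copy == cross$copy[i], , drop = FALSE]
    if (nrow(g) == 1L && g$origin == cross$origin[i] &&
        g$destination == cross$destination[i] && g$returned == cross$returned[i])
      ok_cross <- ok_cross + 1L
  }
  list(n_escape = nrow(esc), ok_portal = ok_port, ok_cavity = ok_cav,
       ok_frame = ok_frame, n_cross = nrow(cross), ok_cross = ok_cross,
       ## crossers are scripted non-escapers too (they never leave the protein)
       non_ok = setequal(c(tr$copy[tr$outcome == "none"],
                           tr$copy[tr$outcome == "crossing"]),
                         ana$summary$non_escaped_copies),
       if_ok = setequal(tr$copy[tr$outcome == "interface"],
                        ana$summary$interface_resident_copies))
}
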