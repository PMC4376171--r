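#' Minimum distance from a ligand copy to the protein surface
#'
#' The "protein surface" is operationalized as the minimum Euclidean
#' distance from the ligand geometric center to any protein heavy atom (not
#' a SASA construction); the 5 Angstrom escape criterion is applied to this
#' quantity.
#'
#' @param ligand_xyz `k x 3` matrix of the copy's atom coordinates (its
#'   geometric center is used), or a length-3 position.
#' @param protein_xyz `n x 3` matrix of protein heavy-atom coordinates.
#' @return Minimum distance in Angstrom.
#' @export
min_surface_distance <- function(ligand_xyz, protein_xyz) {
  if (is.null(dim(ligand_xyz))) ligand_xyz <- matrix(ligand_xyz, nrow = 1L)
  center <- colMeans(as_xyz(ligand_xyz))
  protein_xyz <- as_xyz(protein_xyz)
  assert_that(nrow(protein_xyz) >= 1L, "need at least one protein heavy atom")
  min_dist_to_set(center, protein_xyz)
}

#' Build per-copy ligand tracks from a trajectory
#'
#' For every ligand copy and frame computes the copy center, the minimum
#' distance to the protein surface, the per-chain minimum distances, the
#' subunit assignment (chain of the nearest protein atom, `"interface"` when
#' the two chains' nearest-atom distances differ by less than
#' `interface_margin`), and, when cavities are annotated, the occupied
#' cavity label (nearest centroid within its cutoff; exact ties broken
#' alphabetically).
#'
#' @param trajectory an [md_trajectory()].
#' @param atoms an [atom_table()].
#' @param annotation optional [md_annotation()] supplying cavities.
#' @param interface_margin subunit-ambiguity margin, Angstrom (default 1.5).
#' @return A `ligand_tracks` list of per-copy data.frames with columns
#'   `frame`, `x`, `y`, `z`, `surf_dist`, `subunit`, `cavity` plus one
#'   `d_<chain>` column per protein chain; attributes `copy` and `chain`
#'   (the copy's starting chain).
#' @export
build_ligand_tracks <- function(trajectory, atoms, annotation = NULL,
                                interface_margin = 1.5) {
  copies <- ligand_copy_atoms(atoms)
  assert_that(length(copies) > 0L, "no ligand copies in topology")
  chains <- sort(unique(atoms$chain[atoms$role == "protein"]))
  pidx <- lapply(chains, function(ch)
    which(atoms$role == "protein" & atoms$element != "H" & atoms$chain == ch))
  names(pidx) <- chains
  nf <- trajectory$nframes; nc <- length(copies)

  centers <- array(NA_real_, dim = c(nf, nc, 3L))
  dmin <- array(NA_real_, dim = c(nf, nc, length(chains)))
  for (f in seq_len(nf)) {
    fr <- frame_xyz(trajectory, f)
    C <- t(vapply(copies, function(i) colMeans(fr[i, , drop = FALSE]), numeric(3L)))
    centers[f, , ] <- C
    for (j in seq_along(chains)) dmin[f, , j] <- cross_min_dist(C, fr[pidx[[j]], , drop = FALSE])
  }
  surf <- apply(dmin, c(1L, 2L), min)

  if (length(chains) >= 2L) {
    ## subunit of the two nearest chains; ambiguity margin defines interface
    ord <- apply(dmin, c(1L, 2L), function(v) order(v)[1:2])
    d1 <- apply(dmin, c(1L, 2L), function(v) sort(v)[1L])
    d2 <- apply(dmin, c(1L, 2L), function(v) sort(v)[2L])
    sub_lab <- matrix(chains[ord[1L, , ]], nf, nc)
    sub_lab[abs(d1 - d2) < interface_margin] <- "interface"
  } else {
    sub_lab <- matrix(chains[1L], nf, nc)
  }

  cav_lab <- matrix(NA_character_, nf, nc)
  cavities <- if (!is.null(annotation)) annotation$cavities else list()
  if (length(cavities) > 0L) {
    ## label-sorted so that which.min resolves exact ties alphabetically
    o <- order(vapply(cavities, `[[`, character(1L), "name"),
               vapply(cavities, `[[`, character(1L), "chain"))
    cavities <- cavities[o]
    cuts <- vapply(cavities, `[[`, numeric(1L), "cutoff")
    labs <- vapply(cavities, `[[`, character(1L), "name")
    cen <- cavity_centroid_series(trajectory, cavities, atoms)
    for (j in seq_len(nc)) {
      cj <- matrix(centers[, j, ], nrow = nf)
      d2c <- vapply(seq_along(cavities), function(k)
        rowSums((cj - matrix(cen[, k, ], nrow = nf))^2), numeric(nf))
      d2c <- matrix(d2c, nf)
      d2c[sweep(d2c, 2L, cuts^2, ">")] <- Inf
      hit <- apply(d2c, 1L, function(v) if (all(is.infinite(v))) NA_integer_ else which.min(v))
      cav_lab[, j] <- ifelse(is.na(hit), NA_character_, labs[hit])
    }
  }

  tracks <- lapply(seq_len(nc), function(j) {
    df <- data.frame(frame = seq_len(nf),
                     x = centers[, j, 1L], y = centers[, j, 2L], z = centers[, j, 3L],
                     surf_dist = surf[, j], subunit = sub_lab[, j],
                     cavity = cav_lab[, j], stringsAsFactors = FALSE)
    for (k in seq_along(chains)) df[[paste0("d_", chains[k])]] <- dmin[, j, k]
    attr(df, "copy") <- as.integer(names(copies)[j])
    idx0 <- which(sub_lab[, j] != "interface")
    attr(df, "chain") <- sub_lab[if (length(idx0)) idx0[1L] else 1L, j]
    class(df) <- c("ligand_track", "data.frame")
    df
  })
  names(tracks) <- names(copies)
  structure(tracks, class = "ligand_tracks", chains = chains)
}

#' Detect a durable surface escape in a ligand track
#'
#' The escape event is placed at the first frame where the surface distance
#' exceeds `threshold` and remains above it for at least `persistence`
#' consecutive stored frames (or through the end of the trajectory,
#' whichever is shorter). Copies that never meet the criterion return `NULL`
#' and are counted as non-escapers.
#'
#' @param track a `ligand_track` data.frame (needs `surf_dist`).
#' @param threshold escape distance, Angstrom (default 5).
#' @param persistence minimum run of above-threshold frames (default 10).
#' @return list(copy, frame) or `NULL`.
#' @export
detect_escape <- function(track, threshold = 5, persistence = 10) {
  assert_that(persistence >= 1L, "persistence must be >= 1, got %s", persistence)
  d <- track$surf_dist
  runs <- rle_runs(d > threshold)
  n <- length(d)
  hit <- runs[runs$value == "TRUE" &
                (runs$length >= persistence | runs$end == n), , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  list(copy = attr(track, "copy"), frame = hit$start[1L])
}

#' Classify the escape portal of an event
#'
#' At the last interior frame (surface distance <= `threshold`) preceding
#' the escape, the minimum atom distance from the ligand center to each
#' annotated helix of the copy's current chain is computed. The portal is
#' the alphabetized pair of the two nearest distinct helices ("B-G", never
#' "G-B"); if a declared corner pseudo-region is the single nearest feature
#' the label is `"corner:<XY>"`; if the nearest protein atoms belong to the
#' opposite chain the label is `"interface"`; if the nearest helix is
#' farther than `classify_bound` the label is `"unclassified"`. Ties are
#' broken by (distance, label) lexicographic order.
#'
#' @param track the copy's `ligand_track`.
#' @param event escape event from [detect_escape()] (must not be `NULL`).
#' @param window how many frames before the event to search for the last
#'   interior frame (default 20).
#' @param annotation [md_annotation()] with the helix table.
#' @param atoms the [atom_table()].
#' @param trajectory the [md_trajectory()].
#' @param threshold escape threshold used for "interior", Angstrom.
#' @param classify_bound distance beyond which no helix is considered
#'   classifiable, Angstrom (default 10).
#' @return Portal label, character scalar.
#' @export
classify_portal <- function(track, event, window = 20, annotation, atoms,
                            trajectory, threshold = 5, classify_bound = 10) {
  assert_that(!is.null(event), "classify_portal called with a NULL event")
  assert_that(window >= 1L, "window must be >= 1")
  lo <- max(1L, event$frame - window)
  cand <- seq(lo, max(lo, event$frame - 1L))
  interior <- cand[track$surf_dist[cand] <= threshold]
  f0 <- if (length(interior)) max(interior) else max(1L, event$frame - 1L)
  p <- c(track$x[f0], track$y[f0], track$z[f0])
  fr <- frame_xyz(trajectory, f0)

  chains <- attr(track, "chains") %||% sort(unique(atoms$chain[atoms$role == "protein"]))
  ## nearest protein atoms of the opposite chain win -> interface
  own <- track$subunit[f0]
  if (own == "interface") return("interface")
  if (length(chains) >= 2L) {
    dcols <- paste0("d_", chains)
    dvals <- vapply(dcols, function(cn) track[[cn]][f0], numeric(1L))
    if (chains[which.min(dvals)] != own) return("interface")
    own_chain <- own
  } else own_chain <- chains[1L]

  reg <- annotation$regions[annotation$regions$chain == own_chain, , drop = FALSE]
  assert_that(nrow(reg) > 0L, "no annotated regions for chain %s", own_chain)
  pidx <- which(atoms$role == "protein" & atoms$element != "H" & atoms$chain == own_chain)
  resid <- atoms$resid[pidx]
  dist_to_region <- function(i) {
    sel <- pidx[resid >= reg$start[i] & resid <= reg$end[i]]
    if (length(sel) == 0L) return(Inf)
    min_dist_to_set(p, fr[sel, , drop = FALSE])
  }
  dists <- vapply(seq_len(nrow(reg)), dist_to_region, numeric(1L))
  ord <- order(dists, reg$label)
  nearest <- ord[1L]
  if (reg$type[nearest] == "corner") return(paste0("corner:", reg$label[nearest]))
  helix_ord <- ord[reg$type[ord] == "helix"]
  if (length(helix_ord) < 2L || dists[helix_ord[1L]] > classify_bound) return("unclassified")
  portal_label(reg$label[helix_ord[1L]], reg$label[helix_ord[2L]])
}

#' Cavity occupancy of a ligand track
#'
#' Per-frame cavity labels are computed by [build_ligand_tracks()]; this
#' helper extracts the itinerary (compressed visit runs) and the last cavity
#' occupied before a given frame.
#'
#' @param track a `ligand_track` with a `cavity` column.
#' @param before frame before which to look for the last occupied cavity
#'   (default: end of track).
#' @return list(`labels`: per-frame character vector, `visits`: data.frame
#'   of (cavity, start, end), `last_cavity`: label or `NA`).
#' @export
cavity_occupancy <- function(track, before = nrow(track) + 1L) {
  lab <- track$cavity
  occ <- which(!is.na(lab) & track$frame < before)
  last <- if (length(occ)) lab[max(occ)] else NA_character_
  runs <- rle_runs(ifelse(is.na(lab), "<none>", lab))
  runs <- runs[runs$value != "<none>", c("value", "start", "end"), drop = FALSE]
  names(runs)[1L] <- "cavity"
  rownames(runs) <- NULL
  list(labels = lab, visits = runs, last_cavity = last)
}

#' Detect inter-subunit crossings in a ligand track
#'
#' The per-frame subunit assignment (chain of the nearest protein atom,
#' `"interface"` inside the ambiguity margin) is compressed into runs; a
#' crossing is recorded when the assignment changes chain and the new chain
#' persists for at least `dwell` stored frames. A subsequent confirmed
#' return to the origin chain sets `returned = TRUE` on the event rather
#' than emitting a second event.
#'
#' @param track a `ligand_track`.
#' @param dwell minimum confirmed residence, stored frames (default 25).
#' @return data.frame of crossing events (possibly 0 rows) with columns
#'   `copy`, `departure_frame`, `arrival_frame`, `origin`, `destination`,
#'   `returned`, `last_cavity`.
#' @export
detect_crossings <- function(track, dwell = 25) {
  chains <- setdiff(unique(track$subunit), "interface")
  all_chains <- attr(track, "chains")
  if (!is.null(all_chains) && length(all_chains) < 2L)
    stopf("crossing detection undefined for a single-chain topology")
  runs <- rle_runs(track$subunit)
  cr <- runs[runs$value != "interface", , drop = FALSE]
  if (nrow(cr) == 0L) return(empty_crossings())
  confirmed <- cr[cr$length >= dwell | seq_len(nrow(cr)) == 1L, , drop = FALSE]
  ev <- list()
  prev <- 1L
  for (i in seq_len(nrow(confirmed))[-1L]) {
    if (confirmed$value[i] != confirmed$value[prev]) {
      co <- cavity_occupancy(track, before = confirmed$end[prev] + 1L)
      open <- length(ev) && !ev[[length(ev)]]$returned &&
        ev[[length(ev)]]$destination == confirmed$value[prev] &&
        ev[[length(ev)]]$origin == confirmed$value[i]
      if (open) {
        ev[[length(ev)]]$returned <- TRUE
      } else {
        ev[[length(ev) + 1L]] <- list(copy = attr(track, "copy"),
                                      departure_frame = confirmed$end[prev],
                                      arrival_frame = confirmed$start[i],
                                      origin = confirmed$value[prev],
                                      destination = confirmed$value[i],
                                      returned = FALSE,
                                      last_cavity = co$last_cavity)
      }
      prev <- i
    } else prev <- i
  }
  if (length(ev) == 0L) return(empty_crossings())
  do.call(rbind, lapply(ev, function(e)
    data.frame(e, stringsAsFactors = FALSE)))
}

empty_crossings <- function() {
  data.frame(copy = integer(), departure_frame = integer(), arrival_frame = integer(),
             origin = character(), destination = character(), returned = logical(),
             last_cavity = character(), stringsAsFactors = FALSE)
}

#' Is a copy interface-resident?
#'
#' A copy that never escaped and whose final assignment run is `"interface"`
#' extending to the end of the trajectory for at least `dwell` frames is
#' flagged as interface-resident (it parked between the subunits).
#'
#' @param track a `ligand_track`.
#' @param escaped logical: did the copy produce an escape event?
#' @param dwell minimum terminal interface residence, stored frames.
#' @return logical scalar.
#' @export
is_interface_resident <- function(track, escaped, dwell = 25) {
  if (escaped) return(FALSE)
  runs <- rle_runs(track$subunit)
  last <- runs[nrow(runs), ]
  last$value == "interface" && last$length >= dwell
}

#' Summarize escapes, crossings and residents into a pathway summary
#'
#' @param escapes data.frame of escape events (`copy`, `frame`, `portal`,
#'   `last_cavity`), 0 rows allowed.
#' @param crossings data.frame from [detect_crossings()].
#' @param n_copies number of ligand copies in the simulation.
#' @param interface_resident integer vector of interface-resident copy ids.
#' @param label simulation label.
#' @return A `pathway_summary`: list with `label`, `portal_counts` (named,
#'   alphabetical), `n_escaped`, `n_non_escaped`, `n_interface_resident`,
#'   `non_escaped_copies`, `interface_resident_copies`, `crossings`. The
#'   accounting identity sum(portal counts) + interface-resident +
#'   non-escaped = `n_copies` holds by construction and is asserted.
#' @export
summarize_pathways <- function(escapes, crossings = empty_crossings(),
                               n_copies, interface_resident = integer(),
                               label = "simulation") {
  if (is.null(escapes) || nrow(escapes) == 0L)
    escapes <- data.frame(copy = integer(), frame = integer(),
                          portal = character(), last_cavity = character(),
                          stringsAsFactors = FALSE)
  assert_that(!anyDuplicated(escapes$copy), "duplicate copy %d in escape events",
              escapes$copy[duplicated(escapes$copy)][1L])
  assert_that(length(intersect(escapes$copy, interface_resident)) == 0L,
              "copy cannot be both escaped and interface-resident")
  portal_counts <- if (nrow(escapes) == 0L) setNames(list(), character(0L)) else {
    counts <- table(escapes$portal)
    lapply(as.list(counts[order(names(counts))]), as.integer)
  }
  all_copies <- seq_len(n_copies)
  non_escaped <- setdiff(all_copies, c(escapes$copy, interface_resident))
  out <- structure(list(label = label,
                        n_copies = as.integer(n_copies),
                        portal_counts = portal_counts,
                        n_escaped = nrow(escapes),
                        n_interface_resident = length(interface_resident),
                        n_non_escaped = length(non_escaped),
                        interface_resident_copies = as.integer(interface_resident),
                        non_escaped_copies = as.integer(non_escaped),
                        crossings = crossings),
                   class = "pathway_summary")
  total <- sum(unlist(out$portal_counts)) + out$n_interface_resident + out$n_non_escaped
  assert_that(total == n_copies,
              "pathway accounting broken: %d portal + %d interface + %d non-escaped != %d copies",
              sum(unlist(out$portal_counts)), out$n_interface_resident,
              out$n_non_escaped, n_copies)
  out
}

#' @export
print.pathway_summary <- function(x, ...) {
  cat(sprintf("<pathway_summary> %s: %d copies\n", x$label, x$n_copies))
  if (length(x$portal_counts))
    for (p in names(x$portal_counts))
      cat(sprintf("  %-12s %d\n", p, x$portal_counts[[p]]))
  cat(sprintf("  %-12s %d\n  %-12s %d\n", "interface", x$n_interface_resident,
              "non-escaped", x$n_non_escaped))
  if (nrow(x$crossings))
    cat(sprintf("  crossings: %d (%s)\n", nrow(x$crossings),
                paste(sprintf("copy %d %s->%s%s", x$crossings$copy, x$crossings$origin,
                              x$crossings$destination,
                              ifelse(x$crossings$returned, " (returned)", "")),
                      collapse = "; ")))
  invisible(x)
}

#' Full event analysis of a trajectory
#'
#' Convenience driver: builds tracks, detects escapes, classifies portals,
#' extracts last cavities, detects crossings and interface residents, and
#' assembles the [summarize_pathways()] record.
#'
#' @param trajectory an [md_trajectory()].
#' @param atoms an [atom_table()].
#' @param annotation an [md_annotation()].
#' @param threshold escape threshold, Angstrom.
#' @param persistence escape persistence, stored frames.
#' @param window portal-classification lookback, frames.
#' @param dwell crossing/residency dwell, stored frames.
#' @param interface_margin subunit ambiguity margin, Angstrom.
#' @param classify_bound portal classifiability bound, Angstrom.
#' @param label simulation label.
#' @return list(`tracks`, `escapes`, `crossings`, `interface_resident`,
#'   `summary`, `params`).
#' @export
analyze_trajectory <- function(trajectory, atoms, annotation,
                               threshold = 5, persistence = 10, window = 20,
                               dwell = 25, interface_margin = 1.5,
                               classify_bound = 10, label = "simulation") {
  params <- list(threshold = threshold, persistence = persistence,
                 window = window, dwell = dwell,
                 interface_margin = interface_margin,
                 classify_bound = classify_bound)
  tracks <- build_ligand_tracks(trajectory, atoms, annotation,
                                interface_margin = interface_margin)
  chains <- attr(tracks, "chains")
  esc <- list(); crossings <- list(); residents <- integer()
  for (tr in tracks) {
    attr(tr, "chains") <- chains
    ev <- detect_escape(tr, threshold = threshold, persistence = persistence)
    if (!is.null(ev)) {
      portal <- classify_portal(tr, ev, window = window, annotation = annotation,
                                atoms = atoms, trajectory = trajectory,
                                threshold = threshold, classify_bound = classify_bound)
      occ <- cavity_occupancy(tr, before = ev$frame)
      esc[[length(esc) + 1L]] <- data.frame(copy = ev$copy, frame = ev$frame,
                                            portal = portal,
                                            last_cavity = occ$last_cavity,
                                            stringsAsFactors = FALSE)
    }
    if (length(chains) >= 2L) {
      cr <- detect_crossings(tr, dwell = dwell)
      if (nrow(cr)) crossings[[length(crossings) + 1L]] <- cr
      if (is_interface_resident(tr, escaped = !is.null(ev), dwell = dwell))
        residents <- c(residents, attr(tr, "copy"))
    }
  }
  escapes <- if (length(esc)) do.call(rbind, esc) else NULL
  crossings <- if (length(crossings)) do.call(rbind, crossings) else empty_crossings()
  summary <- summarize_pathways(escapes, crossings, n_copies = length(tracks),
                                interface_resident = residents, label = label)
  list(tracks = tracks, escapes = escapes, crossings = crossings,
       interface_resident = residents, summary = summary, params = params)
}
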