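#' Specification of the two-chain toy pseudo-protein
#'
#' The toy system emulates the geometry the analysis stack needs — not the
#' physics: two spherical pseudo-atom shells (chains A and B) facing each
#' other across a narrow interface gap, eight helix arcs per chain laid out
#' as compact caps on the shell, an FG "corner" pseudo-region, four internal
#' cavities with explicit lining pseudo-residues, an interior scaffold of
#' core atoms (so the minimum-distance "surface" is well defined inside),
#' 14 two-atom ligand copies (7 per chain) and scripted water beads
#' (permanent interfacial cluster, transient visitors, bulk).
#'
#' The helix cap layout puts B at the outward pole surrounded by G, C, E, F
#' at mid-latitude (so the portal pairs reported for the wild-type protein —
#' B-G, E-F, B-E, C-G — are all realizable), with A, D, H on the lower
#' hemisphere. Use [feasible_portals()] to enumerate which helix pairs admit
#' a clean exit direction in a built system.
#'
#' @param shell_radius shell radius, Angstrom.
#' @param chain_gap surface-to-surface gap between the two shells, Angstrom.
#' @param atoms_per_helix pseudo-atoms per helix cap.
#' @param cap_deg angular radius of a helix cap, degrees.
#' @param n_loop loop-atom candidate count (Fibonacci sphere).
#' @param core_spacing,core_radius interior scaffold grid, Angstrom.
#' @param cavity_radius distance of cavity centers from the chain center.
#' @param cavity_cutoff centroid-membership cutoff, Angstrom.
#' @param n_copies_per_chain ligand copies per chain (default 7).
#' @param n_permanent,n_transient,n_bulk water bead counts.
#' @param transient_fraction fraction of frames transient waters spend at
#'   the interface (default 0.6).
#' @return A `toy_protein_spec`.
#' @export
toy_protein_spec <- function(shell_radius = 15, chain_gap = 4,
                             atoms_per_helix = 16L, cap_deg = 12,
                             n_loop = 180L, core_spacing = 5, core_radius = 12,
                             cavity_radius = 4.5, cavity_cutoff = 4.5,
                             n_copies_per_chain = 7L,
                             n_permanent = 12L, n_transient = 5L, n_bulk = 6L,
                             transient_fraction = 0.6) {
  lat <- function(deg) sin(deg * pi / 180)
  ll <- function(latd, lond) {
    c(cos(latd * pi / 180) * cos(lond * pi / 180),
      cos(latd * pi / 180) * sin(lond * pi / 180),
      sin(latd * pi / 180))
  }
  helix_dirs <- rbind(A = ll(-30, 30), B = ll(90, 0), C = ll(45, 90),
                      D = ll(-30, 150), E = ll(45, 180), F = ll(45, 270),
                      G = ll(45, 0), H = ll(-30, 270))
  corner_dir <- unit(helix_dirs["F", ] + helix_dirs["G", ])
  cavity_dirs <- rbind(B = c(0, 0, 1),
                       Xe4 = c(0.943, 0, -0.333),
                       Xe2 = c(-0.471, 0.816, -0.333),
                       Xe1 = c(-0.471, -0.816, -0.333))
  structure(list(shell_radius = shell_radius, chain_gap = chain_gap,
                 atoms_per_helix = as.integer(atoms_per_helix),
                 cap_deg = cap_deg, n_loop = as.integer(n_loop),
                 core_spacing = core_spacing, core_radius = core_radius,
                 helix_dirs = helix_dirs, corner_dir = corner_dir,
                 corner_label = "FG", corner_deg = 8, corner_atoms = 6L,
                 cavity_dirs = cavity_dirs, cavity_radius = cavity_radius,
                 cavity_cutoff = cavity_cutoff,
                 n_copies_per_chain = as.integer(n_copies_per_chain),
                 n_permanent = as.integer(n_permanent),
                 n_transient = as.integer(n_transient),
                 n_bulk = as.integer(n_bulk),
                 transient_fraction = transient_fraction),
            class = "toy_protein_spec")
}

## chain frames: local +z maps to the outward direction of each shell
toy_chain_frames <- function(spec) {
  half <- spec$shell_radius + spec$chain_gap / 2
  Ry <- function(th) matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3L, 3L)
  list(A = list(center = c(-half, 0, 0), rot = Ry(-pi / 2)),
       B = list(center = c(half, 0, 0), rot = Ry(pi / 2)))
}

#' Build the toy two-chain system
#'
#' Deterministic given `(spec, seed)`. Produces the topology (an
#' [atom_table()]), the matching annotation, static base coordinates, and a
#' serializable ground-truth record of the generated geometry.
#'
#' @param spec a [toy_protein_spec()].
#' @param seed RNG seed (reserved for jittered variants; the default build
#'   is fully deterministic).
#' @return A `toy_system` list: `atoms`, `annotation`, `base_xyz`, `frames`
#'   (chain centers/rotations), `helix_atoms` (global coordinates per chain
#'   and region), `cavity_centers` (global, per chain), `water` (ids and
#'   scripted classes), `spec`, `seed`, `truth`.
#' @export
build_toy_system <- function(spec = toy_protein_spec(), seed = 1L) {
  frames <- toy_chain_frames(spec)
  R <- spec$shell_radius
  cap <- spec$cap_deg * pi / 180
  helix_labels <- rownames(spec$helix_dirs)

  rows <- list(); xyz <- list(); regions <- list(); cavities <- list()
  add_atoms <- function(chain, local_xyz, resname, name, role, resid0) {
    n <- nrow(local_xyz)
    fr <- frames[[chain]]
    g <- local_xyz %*% t(fr$rot) + matrix(fr$center, n, 3L, byrow = TRUE)
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = NA_integer_, name = name, element = NA_character_,
      resname = resname, resid = resid0 + seq_len(n) - 1L, chain = chain,
      role = NA_character_, copy = NA_integer_, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <<- g
    resid0 + n
  }

  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  for (chain in c("A", "B")) {
    resid <- 1L
    for (h in helix_labels) {
      pts <- cap_points(spec$helix_dirs[h, ], spec$atoms_per_helix, cap, R)
      start <- resid
      resid <- add_atoms(chain, pts, "ALA", "CA", "protein", resid)
      regions[[length(regions) + 1L]] <- data.frame(
        chain = chain, label = h, start = start, end = resid - 1L,
        type = "helix", stringsAsFactors = FALSE)
    }
    pts <- cap_points(spec$corner_dir, spec$corner_atoms,
                      spec$corner_deg * pi / 180, R)
    start <- resid
    resid <- add_atoms(chain, pts, "ALA", "CA", "protein", resid)
    regions[[length(regions) + 1L]] <- data.frame(
      chain = chain, label = spec$corner_label, start = start, end = resid - 1L,
      type = "corner", stringsAsFactors = FALSE)
    ## loop atoms: shell points clear of every cap
    cand <- fibonacci_sphere(spec$n_loop)
    clear <- rep(TRUE, nrow(cand))
    for (h in helix_labels)
      clear <- clear & apply(cand, 1L, angular_dist, v = spec$helix_dirs[h, ]) > cap + 3 * pi / 180
    clear <- clear & apply(cand, 1L, angular_dist, v = spec$corner_dir) >
      (spec$corner_deg + 3) * pi / 180
    resid <- add_atoms(chain, R * cand[clear, , drop = FALSE], "GLY", "CA", "protein", resid)
    ## interior scaffold grid
    ax <- seq(-spec$core_radius, spec$core_radius, by = spec$core_spacing)
    grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
    grid <- grid[sqrt(rowSums(grid^2)) <= spec$core_radius, , drop = FALSE]
    resid <- add_atoms(chain, grid, "GLY", "CB", "protein", resid)
    ## cavity lining residues
    for (cv in rownames(spec$cavity_dirs)) {
      cen <- spec$cavity_radius * spec$cavity_dirs[cv, ]
      pts <- matrix(cen, 4L, 3L, byrow = TRUE) + 2.2 * tet
      start <- resid
      resid <- add_atoms(chain, pts, "ALA", "CB", "protein", start)
      cavities[[paste(cv, chain, sep = "|")]] <-
        cavity_definition(cv, chain, seq(start, resid - 1L), spec$cavity_cutoff)
    }
  }
  ## ligand copies: 7 per chain, two atoms each, start at the chain center
  for (chain in c("A", "B")) {
    for (k in seq_len(spec$n_copies_per_chain)) {
      fr <- frames[[chain]]
      pos <- rbind(fr$center + c(0, 0, 0.6), fr$center - c(0, 0, 0.6))
      rows[[length(rows) + 1L]] <- data.frame(
        serial = NA_integer_, name = c("O1", "O2"), element = NA_character_,
        resname = "O2", resid = 9000L + k, chain = chain,
        role = NA_character_, copy = NA_integer_, stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1L]] <- pos
    }
  }
  ## waters: permanent interfacial lattice, transient ring, bulk
  wbase <- toy_water_layout(spec)
  if (nrow(wbase$pos_o) > 0L) {
    for (i in seq_len(nrow(wbase$pos_o))) {
      o <- wbase$pos_o[i, ]
      rows[[length(rows) + 1L]] <- data.frame(
        serial = NA_integer_, name = c("OH2", "H1", "H2"), element = NA_character_,
        resname = "TIP3", resid = i, chain = "W",
        role = NA_character_, copy = NA_integer_, stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1L]] <- water_atoms_at(o)
    }
  }

  df <- do.call(rbind, rows)
  base_xyz <- do.call(rbind, xyz)
  df$element <- element_from_name(df$name)
  df$role <- classify_roles(df$resname)
  df <- assign_copy_indices(df)
  df$serial <- seq_len(nrow(df))
  atoms <- atom_table(df)
  annotation <- md_annotation(do.call(rbind, regions), unname(cavities))
  validate_annotation(annotation, atoms)

  cavity_centers <- lapply(frames, function(fr) {
    cc <- spec$cavity_radius * spec$cavity_dirs %*% t(fr$rot) +
      matrix(fr$center, nrow(spec$cavity_dirs), 3L, byrow = TRUE)
    rownames(cc) <- rownames(spec$cavity_dirs)
    cc
  })
  truth <- list(seed = seed,
                n_atoms = nrow(atoms), n_copies = n_ligand_copies(atoms),
                copies_per_chain = as.list(table(ligand_copy_chains(atoms))),
                shell_radius = R, chain_gap = spec$chain_gap,
                cavity_centers = cavity_centers,
                water = wbase[c("permanent", "transient", "bulk")])
  structure(list(atoms = atoms, annotation = annotation, base_xyz = base_xyz,
                 frames = frames, cavity_centers = cavity_centers,
                 water = wbase, spec = spec, seed = as.integer(seed),
                 truth = truth, cache = new.env(parent = emptyenv())),
            class = "toy_system")
}

## water oxygens + ids by scripted class; positions for the interfacial state
toy_water_layout <- function(spec) {
  grid <- as.matrix(expand.grid(y = seq(-4.4, 4.4, by = 2.2),
                                z = seq(-4.4, 4.4, by = 2.2)))
  grid <- grid[order(rowSums(grid^2)), , drop = FALSE]
  perm <- if (spec$n_permanent > 0L)
    cbind(0, grid[seq_len(min(spec$n_permanent, nrow(grid))), , drop = FALSE])
  else matrix(numeric(), 0L, 3L)
  ang <- 2 * pi * seq_len(spec$n_transient) / max(1L, spec$n_transient)
  trans <- cbind(0, 5.2 * cos(ang), 5.2 * sin(ang))
  bulk <- cbind(0, 42 + 4 * seq_len(spec$n_bulk), 25)
  pos <- rbind(perm, if (spec$n_transient > 0L) trans, if (spec$n_bulk > 0L) bulk)
  if (is.null(pos)) pos <- matrix(numeric(), 0L, 3L)
  np <- nrow(perm)
  list(pos_o = pos,
       permanent = seq_len(np),
       transient = if (spec$n_transient > 0L) np + seq_len(spec$n_transient) else integer(),
       bulk = if (spec$n_bulk > 0L) np + spec$n_transient + seq_len(spec$n_bulk) else integer(),
       bulk_park = cbind(55, 8 * seq_len(max(spec$n_transient, 1L)), -20))
}

water_atoms_at <- function(o) {
  rbind(o, o + c(0, 0.96, 0), o + c(0, -0.24, 0.93))
}

## -- exit-direction search --------------------------------------------------

toy_exit_candidates <- function(system, chain) {
  key <- paste0("cand_", chain)
  if (!is.null(system$cache[[key]])) return(system$cache[[key]])
  spec <- system$spec
  fr <- system$frames[[chain]]
  u <- fibonacci_sphere(2400L)
  toward_other <- if (chain == "A") c(1, 0, 0) else c(-1, 0, 0)
  u <- u[u %*% toward_other <= 0.1, , drop = FALSE]
  probe <- u * (spec$shell_radius + 3) +
    matrix(fr$center, nrow(u), 3L, byrow = TRUE)
  atoms <- system$atoms
  reg <- system$annotation$regions
  reg <- reg[reg$chain == chain, , drop = FALSE]
  pidx <- which(atoms$role == "protein" & atoms$chain == chain)
  resid <- atoms$resid[pidx]
  dists <- matrix(NA_real_, nrow(u), nrow(reg))
  for (i in seq_len(nrow(reg))) {
    sel <- pidx[resid >= reg$start[i] & resid <= reg$end[i]]
    dists[, i] <- cross_min_dist(probe, system$base_xyz[sel, , drop = FALSE])
  }
  own <- cross_min_dist(probe, system$base_xyz[pidx, , drop = FALSE])
  oidx <- which(atoms$role == "protein" & atoms$chain != chain)
  other <- cross_min_dist(probe, system$base_xyz[oidx, , drop = FALSE])
  keep <- other > own + 2
  out <- list(u = u[keep, , drop = FALSE], dists = dists[keep, , drop = FALSE],
              labels = reg$label, types = reg$type)
  system$cache[[key]] <- out
  out
}

## region distances from an arbitrary point; mirrors the classifier geometry
toy_region_dists <- function(system, chain, p) {
  reg <- system$annotation$regions
  reg <- reg[reg$chain == chain, , drop = FALSE]
  atoms <- system$atoms
  pidx <- which(atoms$role == "protein" & atoms$chain == chain)
  resid <- atoms$resid[pidx]
  d <- vapply(seq_len(nrow(reg)), function(i) {
    sel <- pidx[resid >= reg$start[i] & resid <= reg$end[i]]
    min_dist_to_set(p, system$base_xyz[sel, , drop = FALSE])
  }, numeric(1L))
  list(labels = reg$label, types = reg$type, d = d)
}

#' Find a clean exit direction for a portal (or corner) in the toy system
#'
#' Scans candidate directions on the shell for one whose two nearest helix
#' arcs are exactly the requested pair (or whose single nearest feature is
#' the requested corner), preferring directions that hug the portal mouth.
#' Each candidate is verified at its solved last-interior radius: the
#' portal-classification geometry there must name exactly the requested
#' label with safety margins (`1.2` Angstrom against the next feature,
#' `1.5` Angstrom inside `classify_bound`), so scripted events are
#' recoverable by construction and robust to sub-Angstrom noise. Errors
#' when the layout admits no such direction.
#'
#' @param system a `toy_system`.
#' @param chain `"A"` or `"B"`.
#' @param portal `"X-Y"` helix pair (alphabetized) or `"corner:FG"`.
#' @param threshold escape criterion the exit is solved against, Angstrom.
#' @param classify_bound classifiability bound the analysis will use.
#' @return list(`u` unit direction (global), `margin`).
#' @export
find_exit_direction <- function(system, chain, portal, threshold = 5,
                                classify_bound = 10) {
  key <- paste("exit", chain, portal, threshold, classify_bound, sep = "|")
  if (!is.null(system$cache[[key]])) {
    out <- system$cache[[key]]
    if (is.character(out)) stopf("%s", out)
    return(out)
  }
  cand <- toy_exit_candidates(system, chain)
  helix <- cand$types == "helix"
  is_corner <- grepl("^corner:", portal)
  if (is_corner) {
    lab <- sub("^corner:", "", portal)
    ci <- which(cand$labels == lab & cand$types == "corner")
    assert_that(length(ci) == 1L, "no corner region '%s' declared", lab)
    d_c <- cand$dists[, ci]
    d_rest <- apply(cand$dists[, -ci, drop = FALSE], 1L, min)
    ok <- d_rest - d_c > 1.2
    cost <- ifelse(ok, d_c, Inf)
  } else {
    pair <- strsplit(portal, "-", fixed = TRUE)[[1L]]
    assert_that(length(pair) == 2L && all(pair %in% cand$labels[helix]),
                "portal '%s' does not name two declared helices", portal)
    hi <- vapply(pair, function(p) which(cand$labels == p & helix), integer(1L))
    d_pair <- cand$dists[, hi, drop = FALSE]
    d_near <- pmax(d_pair[, 1L], d_pair[, 2L])
    d_rest <- apply(cand$dists[, -hi, drop = FALSE], 1L, min)
    ok <- d_rest - d_near > 1.2
    cost <- ifelse(ok, d_near + 0.5 * abs(d_pair[, 1L] - d_pair[, 2L]), Inf)
  }
  ctr <- system$frames[[chain]]$center
  for (j in order(cost)[seq_len(min(50L, sum(is.finite(cost))))]) {
    u <- cand$u[j, ]
    rad <- tryCatch(solve_escape_radii(system, chain, u, threshold),
                    error = function(e) NULL)
    if (is.null(rad)) next
    rd <- toy_region_dists(system, chain, ctr + rad$r_in * u)
    o <- order(rd$d, rd$labels)
    if (is_corner) {
      good <- rd$types[o[1L]] == "corner" && rd$labels[o[1L]] == lab &&
        rd$d[o[2L]] - rd$d[o[1L]] >= 1.2 && rd$d[o[1L]] <= classify_bound - 1.5
    } else {
      ho <- o[rd$types[o] == "helix"]
      good <- rd$types[o[1L]] == "helix" &&
        setequal(rd$labels[ho[1:2]], pair) &&
        min(rd$d[setdiff(o, ho[1:2])]) - rd$d[ho[2L]] >= 1.2 &&
        rd$d[ho[1L]] <= classify_bound - 1.5 && rd$d[ho[2L]] <= classify_bound - 1.5
    }
    if (isTRUE(good)) {
      out <- list(u = u, margin = if (is_corner) (d_rest - d_c)[j] else (d_rest - d_near)[j])
      system$cache[[key]] <- out
      return(out)
    }
  }
  msg <- sprintf("no feasible exit direction for %s on chain %s", portal, chain)
  system$cache[[key]] <- msg
  stopf("%s", msg)
}

#' Enumerate feasible escape portals of the toy layout
#'
#' @param system a `toy_system`.
#' @param chain chain to probe (the layout is mirror-symmetric).
#' @return Character vector of feasible portal labels (helix pairs and
#'   corners) for scripted escapes.
#' @export
feasible_portals <- function(system, chain = "A") {
  labs <- rownames(system$spec$helix_dirs)
  pairs <- utils::combn(labs, 2L)
  out <- character()
  for (j in seq_len(ncol(pairs))) {
    p <- portal_label(pairs[1L, j], pairs[2L, j])
    ok <- tryCatch({ find_exit_direction(system, chain, p); TRUE },
                   error = function(e) FALSE)
    if (ok) out <- c(out, p)
  }
  cp <- paste0("corner:", system$spec$corner_label)
  if (tryCatch({ find_exit_direction(system, chain, cp); TRUE },
               error = function(e) FALSE))
    out <- c(out, cp)
  out
}

## surface-distance profile along a ray from the chain center
solve_escape_radii <- function(system, chain, u, threshold = 5, margin = 0.4) {
  fr <- system$frames[[chain]]
  prot <- system$base_xyz[system$atoms$role == "protein", , drop = FALSE]
  rs <- seq(system$spec$shell_radius - 1, system$spec$shell_radius + 14, by = 0.05)
  P <- matrix(fr$center, length(rs), 3L, byrow = TRUE) + rs %o% u
  g <- cross_min_dist(P, prot)
  i_out <- which(g >= threshold + margin)
  assert_that(length(i_out) > 0L, "no exit radius reaches threshold + margin")
  i_out <- i_out[1L]
  i_in <- which(g[seq_len(i_out)] <= threshold - margin)
  assert_that(length(i_in) > 0L, "no interior radius below threshold - margin")
  list(r_in = rs[max(i_in)], r_out = rs[i_out],
       r_far = rs[i_out] + 15)
}

## -- event scripts ----------------------------------------------------------

#' Script for a single ligand copy
#'
#' @param copy global copy index.
#' @param chain origin chain.
#' @param itinerary ordered cavity names to visit (may be empty).
#' @param outcome one of
#'   `list(type = "escape", portal =, frame =)`,
#'   `list(type = "crossing", depart_frame =, arrive_frame =, return_frame = NULL)`,
#'   `list(type = "interface", frame =)`,
#'   `list(type = "none")`.
#' @return A `copy_script` list.
#' @export
copy_script <- function(copy, chain, itinerary = character(), outcome = list(type = "none")) {
  assert_that(outcome$type %in% c("escape", "crossing", "interface", "none"),
              "unknown outcome type '%s'", outcome$type)
  structure(list(copy = as.integer(copy), chain = chain,
                 itinerary = as.character(itinerary), outcome = outcome),
            class = "copy_script")
}

#' Assemble an event script
#'
#' @param copies list of [copy_script()]s, one per ligand copy.
#' @param n_frames trajectory length in stored frames.
#' @param noise_sd i.i.d. Gaussian positional noise on ligand and water
#'   beads, Angstrom (0 = exact ground truth).
#' @param seed RNG seed for the noise stream.
#' @param jitter_shell also jitter protein shell atoms (exercises per-frame
#'   cavity centroids); sd in Angstrom, 0 disables.
#' @return An `event_script`.
#' @export
event_script <- function(copies, n_frames = 300L, noise_sd = 0, seed = 1L,
                         jitter_shell = 0) {
  structure(list(copies = copies, n_frames = as.integer(n_frames),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 jitter_shell = jitter_shell),
            class = "event_script")
}

## schedule keyframes through an itinerary ending (at the last cavity) at
## frame f_end; falls back to dwelling in the last cavity when f_end is tight
itinerary_keyframes <- function(centers, f_end, transit = 8L) {
  k <- nrow(centers)
  f_end <- max(2L, f_end)
  if (k > 1L) {
    dwell <- (f_end - 1L - transit * (k - 1L)) %/% k
    if (dwell < 2L) k <- 1L
  }
  if (k == 1L) {
    last <- centers[nrow(centers), , drop = FALSE]
    return(list(frames = c(1L, f_end), pos = last[c(1L, 1L), , drop = FALSE]))
  }
  fkey <- integer(2L * k)
  t <- 1L
  for (i in seq_len(k)) {
    fkey[2L * i - 1L] <- t
    fkey[2L * i] <- t + dwell
    t <- t + dwell + transit
  }
  fkey[2L * k] <- f_end
  list(frames = fkey, pos = centers[rep(seq_len(k), each = 2L), , drop = FALSE])
}

## great-circle waypoints from direction a to direction b at fixed radius,
## including both endpoints (>= 2 rows)
slerp_dirs <- function(a, b, radius, step = pi / 5) {
  a <- unit(a); b <- unit(b)
  ang <- angular_dist(a, b)
  if (ang < 1e-6) return(radius * rbind(a, b))
  if (ang > pi - 1e-6) {
    mid <- basis_from_z(a)[, 1L]     # arbitrary perpendicular for antipodes
    return(rbind(slerp_dirs(a, mid, radius, step),
                 slerp_dirs(mid, b, radius, step)[-1L, , drop = FALSE]))
  }
  k <- max(1L, ceiling(ang / step))
  t <- seq(0, 1, length.out = k + 1L)
  pts <- (sin((1 - t) * ang) %o% a + sin(t * ang) %o% b) / sin(ang)
  radius * pts
}

## clearance of a sampled path against non-target cavity centers
path_clear_of_cavities <- function(path, centers, cutoff) {
  if (is.null(centers) || nrow(centers) == 0L) return(TRUE)
  all(cross_min_dist(centers, path) > cutoff)
}

#' Generate a scripted trajectory with exact ground truth
#'
#' Every ligand copy follows smooth interpolated keyframe paths through its
#' cavity itinerary and outcome; escaping copies cross the surface-distance
#' threshold exactly at their scripted frame (at zero noise), crossings park
#' in the destination subunit past the dwell, interface-resident copies hold
#' the midplane, and waters follow their permanence class. All randomness
#' flows through the script seed.
#'
#' @param system a `toy_system` from [build_toy_system()].
#' @param script an [event_script()].
#' @param threshold escape criterion the scripted exits are solved against,
#'   Angstrom (default 5).
#' @return A `scripted_trajectory`: list(`trajectory`, `truth`, `system`,
#'   `script`). `truth$events` is a per-copy data.frame of the scripted
#'   outcomes; `truth$water` records permanent/transient/bulk classes.
#' @export
script_trajectory <- function(system, script, threshold = 5) {
  spec <- system$spec
  atoms <- system$atoms
  n <- script$n_frames
  set.seed(script$seed)
  copies <- ligand_copy_atoms(atoms)
  got <- vapply(script$copies, `[[`, integer(1L), "copy")
  assert_that(setequal(got, as.integer(names(copies))) && !anyDuplicated(got),
              "script must cover every ligand copy exactly once")

  coords <- array(NA_real_, dim = c(nrow(atoms), 3L, n))
  for (f in seq_len(n)) coords[, , f] <- system$base_xyz
  if (script$jitter_shell > 0) {
    pidx <- which(atoms$role == "protein")
    for (f in seq_len(n))
      coords[pidx, , f] <- coords[pidx, , f] +
        matrix(stats::rnorm(3L * length(pidx), sd = script$jitter_shell),
               length(pidx), 3L)
  }

  ev <- list()
  for (cs in script$copies) {
    chain <- cs$chain
    cav <- system$cavity_centers[[chain]]
    bad <- setdiff(cs$itinerary, rownames(cav))
    assert_that(length(bad) == 0L,
                "script error: itinerary references undeclared cavity '%s'", bad[1L])
    centers <- if (length(cs$itinerary)) cav[cs$itinerary, , drop = FALSE]
    else cav[1L, , drop = FALSE]
    out <- cs$outcome
    rec <- list(copy = cs$copy, chain = chain, outcome = out$type,
                portal = NA_character_,
                escape_frame = NA_integer_,
                last_cavity = if (length(cs$itinerary)) cs$itinerary[length(cs$itinerary)]
                else rownames(cav)[1L],
                origin = NA_character_, destination = NA_character_,
                departure_frame = NA_integer_, arrival_frame = NA_integer_,
                returned = NA)
    if (out$type == "escape") {
      f_esc <- as.integer(out$frame)
      assert_that(f_esc > 30L && f_esc <= n - 25L,
                  "escape frame %d out of range for copy %d", f_esc, cs$copy)
      exit <- find_exit_direction(system, chain, out$portal)
      rad <- solve_escape_radii(system, chain, exit$u, threshold)
      ctr <- system$frames[[chain]]$center
      fs <- f_esc - 13L
      it <- itinerary_keyframes(centers, fs)
      c_last <- centers[nrow(centers), ]
      others <- cav[setdiff(rownames(cav), rec$last_cavity), , drop = FALSE]
      ## leave the last cavity radially, then swing at constant radius (well
      ## outside every cavity cutoff) to the exit direction, then head out
      c_dir <- unit(c_last - ctr)
      arc <- slerp_dirs(c_dir, exit$u, radius = 10)
      kf_arc <- fs + 2L + round(seq_len(nrow(arc)) * (9 / (nrow(arc) + 1L)))
      kf <- c(it$frames, kf_arc, f_esc - 1L, f_esc, min(n, f_esc + 25L))
      kp <- rbind(it$pos, arc + matrix(ctr, nrow(arc), 3L, byrow = TRUE),
                  ctr + rad$r_in * exit$u, ctr + rad$r_out * exit$u,
                  ctr + rad$r_far * exit$u)
      keep <- !duplicated(kf)
      path <- interpolate_path(kf[keep], kp[keep, , drop = FALSE], n)
      pre <- path[seq(it$frames[length(it$frames)], f_esc - 1L), , drop = FALSE]
      assert_that(path_clear_of_cavities(pre, others, spec$cavity_cutoff + 0.4),
                  "exit path of copy %d strays into another cavity", cs$copy)
      rec$portal <- out$portal
      rec$escape_frame <- f_esc
    } else if (out$type == "crossing") {
      dest <- setdiff(c("A", "B"), chain)
      f_dep <- as.integer(out$depart_frame); f_arr <- as.integer(out$arrive_frame)
      assert_that(f_dep > 20L && f_arr > f_dep && f_arr <= n - 30L,
                  "bad crossing frames for copy %d", cs$copy)
      lane_ang <- 2 * pi * (cs$copy %% 7L) / 7
      lane <- c(0, 4.5 * cos(lane_ang), 4.5 * sin(lane_ang))
      sgn <- if (chain == "A") -1 else 1
      inner_o <- c(sgn * 3.5, lane[2L], lane[3L])
      inner_d <- c(-sgn * 3.5, lane[2L], lane[3L])
      dest_cav <- system$cavity_centers[[dest]][rec$last_cavity, ]
      it <- itinerary_keyframes(centers, f_dep)
      kf <- c(it$frames, f_dep + 4L, f_dep + 8L, f_arr, min(n, f_arr + 10L))
      kp <- rbind(it$pos, inner_o, lane, inner_d, dest_cav)
      ret <- !is.null(out$return_frame)
      if (ret) {
        f_ret <- as.integer(out$return_frame)
        assert_that(f_ret > f_arr + 25L && f_ret <= n - 30L,
                    "bad return frame for copy %d", cs$copy)
        kf <- c(kf, f_ret, f_ret + 4L, f_ret + 8L, min(n, f_ret + 14L))
        kp <- rbind(kp, dest_cav, inner_d, lane, centers[nrow(centers), ])
      }
      path <- interpolate_path(kf, kp, n)
      rec$origin <- chain; rec$destination <- dest
      rec$departure_frame <- f_dep; rec$arrival_frame <- f_arr
      rec$returned <- ret
    } else if (out$type == "interface") {
      f_if <- as.integer(out$frame)
      assert_that(f_if > 20L && f_if <= n - 40L,
                  "interface frame %d out of range for copy %d", f_if, cs$copy)
      lane_ang <- 2 * pi * ((cs$copy + 3L) %% 7L) / 7
      lane <- c(0, 4.5 * cos(lane_ang), 4.5 * sin(lane_ang))
      sgn <- if (chain == "A") -1 else 1
      inner_o <- c(sgn * 3.5, lane[2L], lane[3L])
      it <- itinerary_keyframes(centers, f_if - 8L)
      kf <- c(it$frames, f_if - 4L, f_if)
      kp <- rbind(it$pos, inner_o, lane)
      path <- interpolate_path(kf, kp, n)
      rec$outcome <- "interface"
    } else {
      it <- itinerary_keyframes(centers, n)
      path <- interpolate_path(it$frames, it$pos, n)
    }
    if (script$noise_sd > 0)
      path <- path + matrix(stats::rnorm(3L * n, sd = script$noise_sd), n, 3L)
    rows <- copies[[as.character(cs$copy)]]
    off <- rbind(c(0, 0, 0.6), c(0, 0, -0.6))
    for (a in 1:2) coords[rows[a], , ] <- t(path) + off[a, ]
    ev[[length(ev) + 1L]] <- rec
  }

  ## waters
  w <- system$water
  wox <- which(atoms$role == "water" & atoms$element == "O")
  if (length(wox)) {
    n_if <- max(2L, floor(spec$transient_fraction * n))
    for (i in seq_along(wox)) {
      o0 <- w$pos_o[i, ]
      if (i %in% w$transient) {
        park <- w$bulk_park[match(i, w$transient), ]
        pathw <- interpolate_path(c(1L, n_if, n_if + 5L),
                                  rbind(o0, o0, park), n)
      } else {
        pathw <- matrix(o0, n, 3L, byrow = TRUE)
      }
      if (script$noise_sd > 0)
        pathw <- pathw + matrix(stats::rnorm(3L * n, sd = script$noise_sd), n, 3L)
      at <- which(atoms$chain == atoms$chain[wox[i]] & atoms$resid == atoms$resid[wox[i]] &
                    atoms$role == "water")
      for (f in seq_len(n)) coords[at, , f] <- water_atoms_at(pathw[f, ])
    }
  }

  events <- do.call(rbind, lapply(ev, function(e)
    data.frame(e, stringsAsFactors = FALSE)))
  truth <- list(n_frames = n, noise_sd = script$noise_sd, seed = script$seed,
                threshold = threshold, events = events,
                water = list(permanent = water_ids(atoms)[w$permanent],
                             transient = water_ids(atoms)[w$transient],
                             bulk = water_ids(atoms)[w$bulk],
                             transient_fraction = spec$transient_fraction))
  structure(list(trajectory = md_trajectory(coords, timestep_ps = 10000 / n),
                 truth = truth, system = system, script = script),
            class = "scripted_trajectory")
}

#' Wild-type-like scripted mix
#'
#' 12 portal escapes (5 B-G, 4 E-F, 2 B-E, 1 C-G), one inter-subunit
#' crossing and one interface-resident copy, with last-cavity dwell pattern
#' 7 Xe4 / 2 Xe2 / 2 Xe1 / 1 B among the escapers.
#'
#' @param system a `toy_system`.
#' @param n_frames,noise_sd,seed passed to [event_script()].
#' @return An [event_script()].
#' @export
wt_like_script <- function(system, n_frames = 300L, noise_sd = 0, seed = 1L) {
  portals <- c("B-G", "B-G", "B-G", "B-G", "B-G", "E-F", "E-F", "E-F", "E-F",
               "B-E", "B-E", "C-G")
  lastc <- c(rep("Xe4", 7L), "Xe2", "Xe2", "Xe1", "Xe1", "B")
  chains <- rep(c("A", "B"), each = 7L)
  fr <- round(seq(0.4, 0.85, length.out = 12L) * n_frames)
  cs <- vector("list", 14L)
  for (i in 1:12) {
    itin <- if (lastc[i] == "Xe4") c("B", "Xe4") else lastc[i]
    cs[[i]] <- copy_script(i, chains[i], itin,
                           list(type = "escape", portal = portals[i], frame = fr[i]))
  }
  cs[[13L]] <- copy_script(13L, chains[13L], c("B", "Xe4"),
                           list(type = "crossing",
                                depart_frame = round(0.35 * n_frames),
                                arrive_frame = round(0.45 * n_frames)))
  cs[[14L]] <- copy_script(14L, chains[14L], "Xe2",
                           list(type = "interface", frame = round(0.5 * n_frames)))
  event_script(cs, n_frames = n_frames, noise_sd = noise_sd, seed = seed)
}

#' Randomized scripted mix with exact ground truth
#'
#' Samples portals from the layout's feasible set, itineraries from the
#' declared cavities, and a configurable mix of outcome classes.
#'
#' @param system a `toy_system`.
#' @param seed RNG seed (drives both the sampling and the noise stream).
#' @param n_frames trajectory length.
#' @param noise_sd positional noise, Angstrom.
#' @param n_escape,n_crossing,n_interface number of copies per outcome
#'   class; the remainder are non-escapers. Must not exceed the copy count.
#' @return An [event_script()].
#' @export
random_event_script <- function(system, seed = 1L, n_frames = 300L, noise_sd = 0,
                                n_escape = 10L, n_crossing = 1L, n_interface = 1L) {
  set.seed(seed)
  n_copies <- n_ligand_copies(system$atoms)
  assert_that(n_escape + n_crossing + n_interface <= n_copies,
              "outcome mix exceeds %d copies", n_copies)
  assert_that(n_frames >= 120L, "random scripts need >= 120 frames, got %d", n_frames)
  chains <- ligand_copy_chains(system$atoms)
  portals <- feasible_portals(system, "A")
  cavs <- rownames(system$spec$cavity_dirs)
  kinds <- sample(c(rep("escape", n_escape), rep("crossing", n_crossing),
                    rep("interface", n_interface),
                    rep("none", n_copies - n_escape - n_crossing - n_interface)))
  fr_esc <- round(seq(0.45, 0.78, length.out = max(1L, sum(kinds == "escape"))) * n_frames)
  ei <- 0L
  cs <- vector("list", n_copies)
  for (i in seq_len(n_copies)) {
    itin <- sample(cavs, sample(1:3, 1L))
    outcome <- switch(kinds[i],
      escape = {
        ei <- ei + 1L
        list(type = "escape", portal = sample(portals, 1L), frame = fr_esc[ei])
      },
      crossing = list(type = "crossing",
                      depart_frame = round(0.3 * n_frames),
                      arrive_frame = round(0.42 * n_frames),
                      return_frame = if (stats::runif(1) < 0.5) round(0.62 * n_frames)),
      interface = list(type = "interface", frame = round(0.5 * n_frames)),
      none = list(type = "none"))
    cs[[i]] <- copy_script(i, chains[[as.character(i)]], itin, outcome)
  }
  event_script(cs, n_frames = n_frames, noise_sd = noise_sd, seed = seed)
}

#' Write a toy bundle to disk (PSF + DCD + annotation + ground truth)
#'
#' The generator emits the very formats the readers consume, closing the
#' format loop for end-to-end tests and the command-line interface.
#'
#' @param scripted a `scripted_trajectory` from [script_trajectory()].
#' @param dir output directory (created).
#' @param prefix file name prefix.
#' @return Named character vector of the files written, invisibly.
#' @export
write_toy_bundle <- function(scripted, dir, prefix = "toy") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  psf <- file.path(dir, paste0(prefix, ".psf"))
  dcd <- file.path(dir, paste0(prefix, ".dcd"))
  ann <- file.path(dir, paste0(prefix, "_annotation.txt"))
  tj <- file.path(dir, paste0(prefix, "_truth.json"))
  write_psf(scripted$system$atoms, psf)
  write_trajectory(scripted$trajectory, dcd)
  write_annotation(scripted$system$annotation, ann)
  tr <- scripted$truth
  tr$events <- as.list(tr$events)
  jsonlite::write_json(tr, tj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(c(psf = psf, dcd = dcd, annotation = ann, truth = tj))
}
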