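#' Interfacial water molecules in one frame
#'
#' A water is interfacial when its oxygen lies within `d_int` of protein
#' heavy atoms of *both* chains (dual-proximity rule): the waters sandwiched
#' between the two subunits.
#'
#' @param frame `n_atoms x 3` coordinates for one frame.
#' @param atoms an [atom_table()]; needs two protein chains.
#' @param d_int proximity cutoff, Angstrom (default 4.0).
#' @return Character vector of water identifiers (`"<chain>:<resid>"`);
#'   empty with a warning when the topology has no waters.
#' @export
interfacial_waters <- function(frame, atoms, d_int = 4.0) {
  chains <- sort(unique(atoms$chain[atoms$role == "protein"]))
  assert_that(length(chains) >= 2L, "interfacial waters need two protein chains")
  wox <- which(atoms$role == "water" & atoms$element == "O")
  if (length(wox) == 0L) {
    warning("no waters in topology; interfacial set is empty")
    return(character())
  }
  W <- frame[wox, , drop = FALSE]
  near_both <- rep(TRUE, length(wox))
  for (ch in chains[1:2]) {
    P <- frame[which(atoms$role == "protein" & atoms$element != "H" &
                       atoms$chain == ch), , drop = FALSE]
    near_both <- near_both & (cross_min_dist(W, P) <= d_int)
  }
  paste(atoms$chain[wox[near_both]], atoms$resid[wox[near_both]], sep = ":")
}

water_ids <- function(atoms) {
  wox <- which(atoms$role == "water" & atoms$element == "O")
  paste(atoms$chain[wox], atoms$resid[wox], sep = ":")
}

#' Hydrogen bonds in one frame
#'
#' Geometric criterion: an edge between two candidate heavy atoms (donor,
#' acceptor) exists iff their distance is at most `d_hb` and some hydrogen
#' covalently associated with the donor (same residue, within 1.25 Angstrom)
#' makes a donor-H...acceptor angle of at least `angle_min` degrees. Either
#' atom of a pair may act as donor. When the topology carries no hydrogens
#' the distance criterion alone is applied and the result is flagged
#' (`attr(, "distance_only")`).
#'
#' @param frame `n_atoms x 3` coordinates for one frame.
#' @param atoms an [atom_table()].
#' @param candidates atom row indices of the candidate heavy atoms (e.g.
#'   water oxygens plus interface-facing protein O/N). Default: all water
#'   oxygens.
#' @param d_hb heavy-atom distance cutoff, Angstrom (default 3.5).
#' @param angle_min minimum donor-H...acceptor angle, degrees (default 150).
#' @return data.frame of unordered edges (`a`, `b` atom serials, `dist`),
#'   with the criteria recorded as attributes; class `hbond_frame`.
#' @export
hydrogen_bonds <- function(frame, atoms, candidates = NULL,
                           d_hb = 3.5, angle_min = 150) {
  if (is.null(candidates))
    candidates <- which(atoms$role == "water" & atoms$element == "O")
  candidates <- sort(unique(candidates))
  n <- length(candidates)
  hyd <- which(atoms$element == "H")
  have_h <- length(hyd) > 0L
  ## hydrogens attached to each candidate: same chain+resid, within 1.25 A
  h_of <- vector("list", n)
  if (have_h) {
    for (i in seq_len(n)) {
      ai <- candidates[i]
      same <- hyd[atoms$chain[hyd] == atoms$chain[ai] & atoms$resid[hyd] == atoms$resid[ai]]
      if (length(same)) {
        d <- sqrt(dist2_to_point(frame[same, , drop = FALSE], frame[ai, ]))
        h_of[[i]] <- same[d <= 1.25]
      }
    }
  }
  edges <- list()
  if (n >= 2L) {
    X <- frame[candidates, , drop = FALSE]
    for (i in seq_len(n - 1L)) {
      d <- sqrt(dist2_to_point(X[(i + 1L):n, , drop = FALSE], X[i, ]))
      for (jj in which(d <= d_hb)) {
        j <- i + jj
        ok <- if (!have_h) TRUE else {
          hs <- c(h_of[[i]], h_of[[j]])
          donors <- c(rep(i, length(h_of[[i]])), rep(j, length(h_of[[j]])))
          acceptors <- ifelse(donors == i, j, i)
          any(vapply(seq_along(hs), function(k) {
            hb_angle(frame[candidates[donors[k]], ], frame[hs[k], ],
                     frame[candidates[acceptors[k]], ]) >= angle_min
          }, logical(1L)))
        }
        if (ok) edges[[length(edges) + 1L]] <-
            data.frame(a = atoms$serial[candidates[i]], b = atoms$serial[candidates[j]],
                       dist = d[jj])
      }
    }
  }
  out <- if (length(edges)) do.call(rbind, edges)
  else data.frame(a = integer(), b = integer(), dist = numeric())
  attr(out, "d_hb") <- d_hb
  attr(out, "angle_min") <- angle_min
  attr(out, "distance_only") <- !have_h
  class(out) <- c("hbond_frame", "data.frame")
  out
}

## Donor-H...acceptor angle in degrees.
hb_angle <- function(d, h, a) {
  v1 <- d - h; v2 <- a - h
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Persistent interfacial waters across a trajectory
#'
#' For every water, the fraction of frames in which it is interfacial (dual
#' proximity, see [interfacial_waters()]) is computed; waters with residence
#' fraction at least `residence_min` are counted as persistent. Water
#' identity is tracked by residue identifier, not position, so exchange
#' events count against persistence. The default `residence_min = 1`
#' realizes "stayed in the interface throughout the simulation".
#'
#' @param trajectory an [md_trajectory()] (>= 2 frames).
#' @param atoms an [atom_table()].
#' @param d_int dual-proximity cutoff, Angstrom.
#' @param residence_min required residence fraction in (0, 1].
#' @return list(`count`, `records`) where `records` is a data.frame with
#'   `water`, `frames_interfacial`, `residence` sorted by decreasing
#'   residence.
#' @export
persistent_water_count <- function(trajectory, atoms, d_int = 4.0,
                                   residence_min = 1.0) {
  assert_that(residence_min > 0 && residence_min <= 1,
              "residence_min must lie in (0, 1], got %s", residence_min)
  assert_that(trajectory$nframes >= 2L, "need at least 2 frames")
  ids <- water_ids(atoms)
  if (length(ids) == 0L) {
    warning("no waters in topology")
    return(list(count = 0L, records = data.frame(water = character(),
                                                 frames_interfacial = integer(),
                                                 residence = numeric())))
  }
  hits <- setNames(integer(length(ids)), ids)
  for (f in seq_len(trajectory$nframes)) {
    mem <- interfacial_waters(frame_xyz(trajectory, f), atoms, d_int = d_int)
    hits[mem] <- hits[mem] + 1L
  }
  res <- hits / trajectory$nframes
  records <- data.frame(water = ids, frames_interfacial = as.integer(hits),
                        residence = as.numeric(res), stringsAsFactors = FALSE)
  records <- records[order(-records$residence, records$water), , drop = FALSE]
  rownames(records) <- NULL
  list(count = sum(res >= residence_min), records = records)
}

#' Per-frame hydrogen-bond edge counts for the interfacial network
#'
#' @param trajectory an [md_trajectory()].
#' @param atoms an [atom_table()].
#' @param d_int interfacial membership cutoff, Angstrom.
#' @param d_hb,angle_min hydrogen-bond criteria (see [hydrogen_bonds()]).
#' @return data.frame with `frame`, `n_interfacial`, `n_edges`.
#' @export
water_network_series <- function(trajectory, atoms, d_int = 4.0,
                                 d_hb = 3.5, angle_min = 150) {
  wox <- which(atoms$role == "water" & atoms$element == "O")
  ids <- water_ids(atoms)
  out <- data.frame(frame = seq_len(trajectory$nframes),
                    n_interfacial = 0L, n_edges = 0L)
  for (f in seq_len(trajectory$nframes)) {
    fr <- frame_xyz(trajectory, f)
    mem <- interfacial_waters(fr, atoms, d_int = d_int)
    sel <- wox[ids %in% mem]
    out$n_interfacial[f] <- length(sel)
    if (length(sel) >= 2L)
      out$n_edges[f] <- nrow(hydrogen_bonds(fr, atoms, candidates = sel,
                                            d_hb = d_hb, angle_min = angle_min))
  }
  out
}
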