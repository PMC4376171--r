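#' Read a topology file (PSF or PDB) into an atom table
#'
#' Parses X-PLOR/CHARMM PSF (the `!NATOM` section) or falls back to PDB
#' `ATOM`/`HETATM` records. Every atom is classified into a role flag
#' (protein / water / ligand / heme / ion); ligand copies are identified by
#' residue name against `ligand_spec` and numbered by file order within the
#' file, which within each chain gives a deterministic contiguous numbering.
#'
#' @param path topology file.
#' @param ligand_spec regular expression matched (case-insensitively) against
#'   residue names to tag ligand copies. Default matches O2/OXY-type names.
#' @param format `"auto"` (by extension/signature), `"psf"` or `"pdb"`.
#' @return An [atom_table()].
#' @export
read_topology <- function(path, ligand_spec = default_ligand_pattern(),
                          format = c("auto", "psf", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("topology file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "psf") "psf"
    else if (ext %in% c("pdb", "ent")) "pdb"
    else if (grepl("^PSF", readLines(path, n = 1L, warn = FALSE)[1L] %||% "")) "psf"
    else "pdb"
  }
  df <- if (format == "psf") parse_psf(path) else parse_pdb(path)
  assert_that(nrow(df) > 0L, "no atoms parsed from %s", path)
  df$element <- element_from_name(df$name)
  df$role <- classify_roles(df$resname, ligand_spec)
  ## heme iron atoms keep role heme via resname; mark FE element
  df$element[df$role == "heme" & toupper(df$name) == "FE"] <- "FE"
  assert_that(any(df$role == "protein"), "topology %s contains zero protein atoms", path)
  df <- assign_copy_indices(df)
  df$serial <- seq_len(nrow(df))
  atom_table(df)
}

parse_psf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  assert_that(length(lines) > 0L && grepl("^PSF", lines[1L]),
              "not a PSF file (missing PSF signature): %s", path)
  natom_line <- grep("!NATOM", lines, fixed = TRUE)
  assert_that(length(natom_line) == 1L, "PSF parse error in %s: expected one !NATOM section", path)
  natom <- suppressWarnings(as.integer(strsplit(trimws(lines[natom_line]), "[[:space:]]+")[[1L]][1L]))
  assert_that(!is.na(natom) && natom > 0L, "PSF parse error at line %d: bad atom count", natom_line)
  body <- lines[seq(natom_line + 1L, length.out = natom)]
  if (length(body) < natom || anyNA(body))
    stopf("PSF file %s truncated: expected %d atom lines after line %d", path, natom, natom_line)
  toks <- strsplit(trimws(body), "[[:space:]]+")
  nt <- lengths(toks)
  bad <- which(nt < 8L)
  if (length(bad))
    stopf("PSF parse error in %s at line %d: expected >=8 fields, got %d",
          path, natom_line + bad[1L], nt[bad[1L]])
  m <- t(vapply(toks, function(x) x[1:8], character(8L)))
  resid <- suppressWarnings(as.integer(m[, 3L]))
  if (anyNA(resid))
    stopf("PSF parse error in %s: non-numeric residue id at atom line %d",
          path, which(is.na(resid))[1L])
  data.frame(serial = as.integer(m[, 1L]), name = m[, 5L], element = NA_character_,
             resname = m[, 4L], resid = resid, chain = m[, 2L],
             role = NA_character_, copy = NA_integer_, stringsAsFactors = FALSE)
}

parse_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  keep <- lines[rec %in% c("ATOM  ", "HETATM")]
  assert_that(length(keep) > 0L, "no ATOM/HETATM records in %s", path)
  name <- trimws(substr(keep, 13L, 16L))
  resname <- trimws(substr(keep, 18L, 21L))
  chainid <- trimws(substr(keep, 22L, 22L))
  resid <- suppressWarnings(as.integer(trimws(substr(keep, 23L, 26L))))
  segid <- trimws(substr(keep, 73L, 76L))
  if (anyNA(resid)) stopf("PDB parse error in %s: bad residue number", path)
  ## segment identifier first, chain identifier second
  chain <- ifelse(nzchar(segid), segid, ifelse(nzchar(chainid), chainid, "A"))
  data.frame(serial = seq_along(keep), name = name, element = NA_character_,
             resname = resname, resid = resid, chain = chain,
             role = NA_character_, copy = NA_integer_, stringsAsFactors = FALSE)
}

#' Write an atom table as a CHARMM-style PSF file
#'
#' Emits the `!NTITLE` and `!NATOM` sections (and an empty `!NBOND`), enough
#' for [read_topology()] round-trips and external viewers.
#'
#' @param atoms an [atom_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_psf <- function(atoms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("PSF", "", sprintf("%8d !NTITLE", 1L),
               " REMARKS synthetic topology written by mdescape", ""), con)
  writeLines(sprintf("%8d !NATOM", nrow(atoms)), con)
  writeLines(sprintf("%8d %-4s %-4d %-4s %-4s %-4s %10.6f %13.4f %11d",
                     atoms$serial, atoms$chain, atoms$resid, atoms$resname,
                     atoms$name, atoms$name, 0, 1, 0), con)
  writeLines(c("", sprintf("%8d !NBOND: bonds", 0L), ""), con)
  invisible(path)
}

## -- DCD --------------------------------------------------------------------

.AKMA_PS <- 0.0488882129  # 1 AKMA time unit in picoseconds

#' Write a CHARMM-format DCD trajectory
#'
#' Little-endian, 32-bit record markers, single-precision coordinates,
#' CHARMM version tag 24, no unit cell. The header `DELTA` is stored in AKMA
#' units as NAMD/CHARMM do, derived from `timestep_ps` and `nsavc`.
#'
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @param path output file.
#' @param timestep_ps time between stored frames, picoseconds.
#' @param istart,nsavc bookkeeping fields mirrored into the header.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(coords, path, timestep_ps = 1, istart = 0L, nsavc = 1L) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2L] == 3L)
  natom <- dim(coords)[1L]; nframes <- dim(coords)[3L]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  delta <- timestep_ps / (.AKMA_PS * nsavc)
  wi(84L); writeChar("CORD", con, nchars = 4L, eos = NULL)
  wi(c(nframes, istart, nsavc, nframes * nsavc, 0L, 0L, 0L, 0L, 0L))
  wf(delta)
  wi(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 24L))
  wi(84L)
  title <- formatC("Synthetic trajectory written by mdescape", width = -80L)
  wi(4L + 80L); wi(1L); writeChar(title, con, nchars = 80L, eos = NULL); wi(4L + 80L)
  wi(4L); wi(natom); wi(4L)
  for (f in seq_len(nframes)) {
    for (ax in 1:3) {
      wi(4L * natom); wf(coords[, ax, f]); wi(4L * natom)
    }
  }
  invisible(path)
}

#' Read a CHARMM/NAMD DCD trajectory
#'
#' Supports little-endian 32-bit-marker DCDs with or without per-frame unit
#' cell records. Frames are returned strictly in file order.
#'
#' @param path DCD file.
#' @return list with `coords` (`n_atoms x 3 x n_frames`), `natoms`,
#'   `nframes`, `timestep_ps`, `box` (`n_frames x 6` or `NULL`).
#' @export
read_dcd <- function(path) {
  if (!file.exists(path)) stopf("trajectory file not found: %s", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n = 1L) readBin(con, "integer", n = n, size = 4L, endian = "little")
  rf <- function(n = 1L) readBin(con, "numeric", n = n, size = 4L, endian = "little")
  rd <- function(n = 1L) readBin(con, "numeric", n = n, size = 8L, endian = "little")
  m0 <- ri()
  if (length(m0) == 0L || m0 != 84L)
    stopf("DCD parse error in %s at byte 0: bad header record length (%s)", path,
          if (length(m0)) m0 else "EOF")
  sig <- readChar(con, nchars = 4L, useBytes = TRUE)
  if (sig != "CORD") stopf("DCD parse error in %s: signature %s != CORD", path, sig)
  icntrl_raw <- readBin(con, "raw", n = 80L)
  ints <- readBin(icntrl_raw, "integer", n = 20L, size = 4L, endian = "little")
  nframes_hdr <- ints[1L]; nsavc <- max(1L, ints[3L])
  has_cell <- ints[11L] == 1L
  charmm <- ints[20L] > 0L
  delta <- if (charmm) readBin(icntrl_raw[37:40], "numeric", size = 4L, endian = "little")
  else readBin(icntrl_raw[37:44], "numeric", size = 8L, endian = "little")
  if (ri() != 84L) stopf("DCD parse error in %s: unterminated header record", path)
  tlen <- ri()
  ntitle <- ri()
  if (ntitle > 0L) readChar(con, nchars = 80L * ntitle, useBytes = TRUE)
  if (ri() != tlen) stopf("DCD parse error in %s: unterminated title record", path)
  if (ri() != 4L) stopf("DCD parse error in %s: bad NATOM record", path)
  natom <- ri()
  if (ri() != 4L) stopf("DCD parse error in %s: unterminated NATOM record", path)
  assert_that(natom > 0L, "DCD %s declares %d atoms", path, natom)

  frames <- list(); boxes <- list(); f <- 0L
  repeat {
    m <- ri()
    if (length(m) == 0L) break
    f <- f + 1L
    xyz <- matrix(NA_real_, natom, 3L)
    if (has_cell) {
      if (m != 48L) stopf("DCD parse error in %s, frame %d: bad cell record", path, f)
      boxes[[f]] <- rd(6L)
      if (ri() != 48L) stopf("DCD parse error in %s, frame %d: unterminated cell record", path, f)
      m <- ri()
      if (length(m) == 0L) stopf("DCD %s truncated inside frame %d", path, f)
    }
    for (ax in 1:3) {
      if (ax > 1L) m <- ri()
      if (length(m) == 0L || m != 4L * natom)
        stopf("DCD parse error in %s: corrupt frame %d (coordinate record)", path, f)
      v <- rf(natom)
      if (length(v) < natom) stopf("DCD %s truncated inside frame %d", path, f)
      xyz[, ax] <- v
      trailer <- ri()
      if (length(trailer) == 0L || trailer != 4L * natom)
        stopf("DCD parse error in %s: corrupt frame %d (record trailer)", path, f)
    }
    frames[[f]] <- xyz
  }
  assert_that(f > 0L, "DCD %s contains no frames (file size %d)", path, sz)
  coords <- array(unlist(frames, use.names = FALSE), dim = c(natom, 3L, f))
  timestep_ps <- if (charmm) delta * .AKMA_PS * nsavc else delta * nsavc
  list(coords = coords, natoms = natom, nframes = f,
       timestep_ps = timestep_ps,
       box = if (has_cell) do.call(rbind, boxes) else NULL,
       nframes_header = nframes_hdr)
}

## -- trajectory container ---------------------------------------------------

#' Construct a trajectory object
#'
#' @param coords array `n_atoms x 3 x n_frames`, Angstrom.
#' @param timestep_ps time between stored frames (ps).
#' @param box optional `n_frames x 6` unit cell rows, or `NULL`.
#' @return An `md_trajectory`: list with `coords`, `natoms`, `nframes`,
#'   `timestep_ps`, `times_ps` (strictly increasing), `box`.
#' @export
md_trajectory <- function(coords, timestep_ps = 1, box = NULL) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2L] == 3L)
  assert_that(all(is.finite(coords)), "trajectory contains non-finite coordinates")
  assert_that(timestep_ps > 0, "timestep must be positive")
  n <- dim(coords)[3L]
  structure(list(coords = coords, natoms = dim(coords)[1L], nframes = n,
                 timestep_ps = timestep_ps,
                 times_ps = timestep_ps * seq_len(n), box = box),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d atoms x %d frames, dt = %.4g ps (%.4g ns total)%s\n",
              x$natoms, x$nframes, x$timestep_ps,
              x$timestep_ps * x$nframes / 1000,
              if (is.null(x$box)) "" else ", periodic cell"))
  invisible(x)
}

frame_xyz <- function(trajectory, f) trajectory$coords[, , f, drop = TRUE]

#' Read a DCD trajectory against an atom table
#'
#' @param path DCD file.
#' @param atoms [atom_table()] the file must match in atom count.
#' @return An [md_trajectory()].
#' @export
read_trajectory <- function(path, atoms) {
  raw <- read_dcd(path)
  if (raw$natoms != nrow(atoms))
    stopf("atom-count mismatch: trajectory %s has %d atoms, topology has %d",
          path, raw$natoms, nrow(atoms))
  if (!all(is.finite(raw$coords)))
    stopf("trajectory %s contains non-finite coordinates", path)
  md_trajectory(raw$coords, timestep_ps = raw$timestep_ps, box = raw$box)
}

#' Write a trajectory to DCD
#' @param trajectory an [md_trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  write_dcd(trajectory$coords, path, timestep_ps = trajectory$timestep_ps)
}

## -- event tables -----------------------------------------------------------

#' Write escape/crossing events and a pathway summary to disk
#'
#' Produces `<prefix>_events.tsv` (one row per event: copy, frame, event
#' type, portal, last cavity, detail) and `<prefix>_summary.json` (portal
#' counts, non-escaped and interface-resident tallies, crossings, and the
#' full resolved parameter set for provenance). Counts in the summary are
#' revalidated against the event table before writing.
#'
#' @param events data.frame as produced by [event_table()].
#' @param summary a [pathway_summary()].
#' @param prefix output path prefix (directories are created).
#' @return Named character vector of the two files written, invisibly.
#' @export
write_event_table <- function(events, summary, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  tsv <- paste0(prefix, "_events.tsv")
  js <- paste0(prefix, "_summary.json")
  ## consistency: portal counts derivable from the table must equal summary
  esc <- events[events$event == "escape", , drop = FALSE]
  tab <- table(esc$portal)
  for (p in names(summary$portal_counts)) {
    derived <- if (p %in% names(tab)) as.integer(tab[[p]]) else 0L
    assert_that(derived == summary$portal_counts[[p]],
                "summary/table mismatch for portal %s: %d vs %d",
                p, summary$portal_counts[[p]], derived)
  }
  ok <- tryCatch({
    con <- file(tsv, "w"); on.exit(close(con), add = TRUE)
    writeLines("copy\tframe\tevent\tportal\tlast_cavity\tdetail", con)
    if (nrow(events) > 0L)
      writeLines(sprintf("%d\t%d\t%s\t%s\t%s\t%s", events$copy, events$frame,
                         events$event, events$portal, events$last_cavity,
                         events$detail), con)
    TRUE
  }, error = function(e) stopf("cannot write event table %s: %s", tsv, conditionMessage(e)))
  jsonlite::write_json(unclass(summary), js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(events = tsv, summary = js))
}

#' Flatten escapes and crossings into one event table
#'
#' @param escapes data.frame of escape events (possibly 0 rows) with columns
#'   `copy`, `frame`, `portal`, `last_cavity`.
#' @param crossings data.frame of crossing events with columns `copy`,
#'   `departure_frame`, `arrival_frame`, `origin`, `destination`, `returned`.
#' @return data.frame with columns copy, frame, event, portal, last_cavity,
#'   detail, ordered by frame then copy.
#' @export
event_table <- function(escapes = NULL, crossings = NULL) {
  rows <- list()
  if (!is.null(escapes) && nrow(escapes) > 0L) {
    rows[[1L]] <- data.frame(copy = escapes$copy, frame = escapes$frame,
                             event = "escape", portal = escapes$portal,
                             last_cavity = ifelse(is.na(escapes$last_cavity), "none",
                                                  escapes$last_cavity),
                             detail = "", stringsAsFactors = FALSE)
  }
  if (!is.null(crossings) && nrow(crossings) > 0L) {
    rows[[length(rows) + 1L]] <-
      data.frame(copy = crossings$copy, frame = crossings$departure_frame,
                 event = "crossing", portal = "interface",
                 last_cavity = if ("last_cavity" %in% names(crossings))
                   ifelse(is.na(crossings$last_cavity), "none", crossings$last_cavity)
                 else "none",
                 detail = sprintf("%s->%s arrival=%d returned=%s",
                                  crossings$origin, crossings$destination,
                                  crossings$arrival_frame,
                                  ifelse(crossings$returned, "yes", "no")),
                 stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(copy = integer(), frame = integer(), event = character(),
                      portal = character(), last_cavity = character(),
                      detail = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$frame, out$copy), , drop = FALSE]
}
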