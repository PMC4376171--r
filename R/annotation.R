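#' Structure annotation: globin-fold helices and internal cavities
#'
#' An `md_annotation` holds a region table (helices A..H and optional
#' "corner" pseudo-regions, as inclusive residue ranges per chain) plus a
#' list of cavity definitions (name, chain, centroid-membership cutoff in
#' Angstrom, and the lining residues whose per-frame heavy-atom centroid
#' defines the cavity center).
#'
#' The flat key-value config dialect, one directive per line:
#' \preformatted{
#' helix  <chain> <label> <start> <end>
#' corner <chain> <label> <start> <end>
#' cavity <name> <chain> <cutoff>
#' cavity_residue <name> <chain> <resid>
#' }
#'
#' @param regions data.frame with columns `chain`, `label`, `start`, `end`,
#'   `type` (`"helix"` or `"corner"`).
#' @param cavities list of cavity definitions as returned by
#'   [cavity_definition()].
#' @return An `md_annotation`.
#' @export
md_annotation <- function(regions, cavities = list()) {
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  need <- c("chain", "label", "start", "end", "type")
  assert_that(all(need %in% names(regions)), "region table needs columns %s",
              paste(need, collapse = ", "))
  regions$start <- as.integer(regions$start); regions$end <- as.integer(regions$end)
  assert_that(all(regions$start <= regions$end), "region start must be <= end")
  ## per-chain: no duplicate labels, no overlapping ranges
  for (ch in unique(regions$chain)) {
    sub <- regions[regions$chain == ch, , drop = FALSE]
    dup <- sub$label[duplicated(sub$label)]
    assert_that(length(dup) == 0L, "duplicate region label %s in chain %s", dup[1L], ch)
    o <- order(sub$start)
    s <- sub$start[o]; e <- sub$end[o]
    if (nrow(sub) > 1L && any(s[-1L] <= e[-nrow(sub)]))
      stopf("overlapping residue ranges in chain %s (near residue %d)",
            ch, s[-1L][which(s[-1L] <= e[-nrow(sub)])[1L]])
  }
  for (cv in cavities) validate_cavity(cv)
  structure(list(regions = regions, cavities = cavities), class = "md_annotation")
}

#' Define an internal cavity by its lining residues
#'
#' @param name cavity name (e.g. `"Xe4"`, `"B"`, or a custom name).
#' @param chain chain/segment the cavity belongs to.
#' @param residues integer vector of lining residue numbers (>= 3).
#' @param cutoff centroid-membership cutoff, Angstrom (> 0; default 4.5).
#' @return A `cavity_definition` list.
#' @export
cavity_definition <- function(name, chain, residues, cutoff = 4.5) {
  cv <- structure(list(name = as.character(name), chain = as.character(chain),
                       residues = as.integer(residues), cutoff = as.numeric(cutoff)),
                  class = "cavity_definition")
  validate_cavity(cv)
  cv
}

validate_cavity <- function(cv) {
  assert_that(length(cv$residues) >= 3L,
              "cavity %s needs >= 3 lining residues, got %d", cv$name, length(cv$residues))
  assert_that(is.numeric(cv$cutoff) && cv$cutoff > 0, "cavity %s cutoff must be > 0", cv$name)
  invisible(TRUE)
}

#' @export
print.md_annotation <- function(x, ...) {
  cat(sprintf("<md_annotation> %d regions (%d helices, %d corners), %d cavities\n",
              nrow(x$regions), sum(x$regions$type == "helix"),
              sum(x$regions$type == "corner"), length(x$cavities)))
  invisible(x)
}

#' Load an annotation config file
#'
#' @param path config file in the flat key-value dialect (see
#'   [md_annotation()]).
#' @param atoms optional [atom_table()]; when supplied every referenced
#'   residue is validated against the topology.
#' @return An [md_annotation()].
#' @export
load_annotation <- function(path, atoms = NULL) {
  toks <- read_config_lines(path)
  regions <- list(); cav <- list()
  for (tk in toks) {
    kind <- tolower(tk[1L])
    if (kind %in% c("helix", "corner")) {
      assert_that(length(tk) == 5L, "bad %s line in %s: need <chain> <label> <start> <end>", kind, path)
      regions[[length(regions) + 1L]] <-
        data.frame(chain = tk[2L], label = tk[3L],
                   start = as.integer(tk[4L]), end = as.integer(tk[5L]),
                   type = kind, stringsAsFactors = FALSE)
    } else if (kind == "cavity") {
      assert_that(length(tk) == 4L, "bad cavity line in %s: need <name> <chain> <cutoff>", path)
      key <- paste(tk[2L], tk[3L], sep = "|")
      cav[[key]] <- list(name = tk[2L], chain = tk[3L],
                         cutoff = as.numeric(tk[4L]), residues = integer())
    } else if (kind == "cavity_residue") {
      assert_that(length(tk) == 4L, "bad cavity_residue line in %s", path)
      key <- paste(tk[2L], tk[3L], sep = "|")
      assert_that(!is.null(cav[[key]]), "cavity_residue before cavity declaration for %s", tk[2L])
      cav[[key]]$residues <- c(cav[[key]]$residues, as.integer(tk[4L]))
    } else {
      stopf("unknown annotation directive '%s' in %s", tk[1L], path)
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions)
  else data.frame(chain = character(), label = character(), start = integer(),
                  end = integer(), type = character(), stringsAsFactors = FALSE)
  cavities <- lapply(unname(cav), function(cv)
    cavity_definition(cv$name, cv$chain, cv$residues, cv$cutoff))
  ann <- md_annotation(regions, cavities)
  if (!is.null(atoms)) validate_annotation(ann, atoms)
  ann
}

#' Validate an annotation against a topology
#'
#' Every cavity lining residue (and every region chain) must exist in the
#' atom table.
#' @param annotation an [md_annotation()].
#' @param atoms an [atom_table()].
#' @return `TRUE`, invisibly; errors name the offending residue.
#' @export
validate_annotation <- function(annotation, atoms) {
  prot <- atoms[atoms$role == "protein", , drop = FALSE]
  chains <- unique(prot$chain)
  bad <- setdiff(unique(annotation$regions$chain), chains)
  assert_that(length(bad) == 0L, "annotation references unknown chain %s", bad[1L])
  for (cv in annotation$cavities) {
    present <- unique(prot$resid[prot$chain == cv$chain])
    miss <- setdiff(cv$residues, present)
    assert_that(length(miss) == 0L,
                "cavity %s: residue %s/%d absent from topology", cv$name, cv$chain, miss[1L])
  }
  invisible(TRUE)
}

#' Write an annotation config file
#' @param annotation an [md_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  r <- annotation$regions
  writeLines("# mdescape annotation config", con)
  if (nrow(r))
    writeLines(sprintf("%s %s %s %d %d", r$type, r$chain, r$label, r$start, r$end), con)
  for (cv in annotation$cavities) {
    writeLines(sprintf("cavity %s %s %g", cv$name, cv$chain, cv$cutoff), con)
    writeLines(sprintf("cavity_residue %s %s %d", cv$name, cv$chain, cv$residues), con)
  }
  invisible(path)
}

#' Assign a residue to a helix (or corner region)
#'
#' Pure lookup in the region table; residues falling outside every declared
#' range (loops, termini) return `NA`.
#'
#' @param chain chain/segment identifier.
#' @param resid residue number (file numbering).
#' @param table an [md_annotation()] or its `regions` data.frame.
#' @return The region label, or `NA_character_` if unassigned. Helices take
#'   precedence over corner pseudo-regions if config ranges overlap-free
#'   rules were relaxed upstream.
#' @export
assign_helix <- function(chain, resid, table) {
  r <- if (inherits(table, "md_annotation")) table$regions else table
  assert_that(chain %in% r$chain, "unknown chain '%s' in helix table", chain)
  hit <- r[r$chain == chain & r$start <= resid & r$end >= resid, , drop = FALSE]
  if (nrow(hit) == 0L) return(NA_character_)
  if (nrow(hit) > 1L) hit <- hit[order(hit$type != "helix"), , drop = FALSE]
  hit$label[1L]
}

#' Per-frame centroid of a cavity's lining residues
#'
#' Unweighted mean of the lining residues' heavy-atom coordinates in one
#' frame; cavities move with the protein, so centers are per-frame.
#'
#' @param frame `n_atoms x 3` coordinate matrix for one frame (atom order of
#'   `atoms`).
#' @param cavity a [cavity_definition()].
#' @param atoms the [atom_table()].
#' @return Length-3 numeric position (Angstrom).
#' @export
cavity_centroid <- function(frame, cavity, atoms) {
  idx <- which(atoms$role == "protein" & atoms$element != "H" &
                 atoms$chain == cavity$chain & atoms$resid %in% cavity$residues)
  found <- unique(atoms$resid[idx])
  miss <- setdiff(cavity$residues, found)
  assert_that(length(miss) == 0L, "cavity %s: residue %s/%d missing from frame",
              cavity$name, cavity$chain, miss[1L])
  colMeans(frame[idx, , drop = FALSE])
}

## Centroids of all cavities for all frames: array n_frames x n_cav x 3.
cavity_centroid_series <- function(trajectory, cavities, atoms) {
  ncav <- length(cavities)
  out <- array(NA_real_, dim = c(trajectory$nframes, ncav, 3L))
  idx_list <- lapply(cavities, function(cv)
    which(atoms$role == "protein" & atoms$element != "H" &
            atoms$chain == cv$chain & atoms$resid %in% cv$residues))
  for (f in seq_len(trajectory$nframes)) {
    fr <- frame_xyz(trajectory, f)
    for (k in seq_len(ncav))
      out[f, k, ] <- colMeans(fr[idx_list[[k]], , drop = FALSE])
  }
  out
}

#' Path to the shipped default HbI annotation
#'
#' Helix ranges and Xe-cavity linings for the Scapharca dimeric hemoglobin
#' are a reconstructed default (see the methods vignette); they are data, not
#' code, and meant to be overridden via `--annotation`.
#' @return File path.
#' @export
hbi_annotation_path <- function() {
  system.file("extdata", "hbi_annotation.txt", package = "mdescape", mustWork = TRUE)
}
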