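#' Atom tables
#'
#' An `atom_table` is a `data.frame` with one row per atom and columns
#' `serial` (1-based, contiguous), `name`, `element`, `resname`, `resid`
#' (file numbering, never renumbered), `chain` (segment identifier first,
#' chain identifier second), `role` (one of `"protein"`, `"water"`,
#' `"ligand"`, `"heme"`, `"ion"`) and `copy` (ligand copy index, `NA` for
#' non-ligand atoms). Ligand copies are numbered deterministically by file
#' order; for dimeric hemoglobin inputs this yields seven copies per chain.
#'
#' @param df data.frame with the columns described above.
#' @return A validated `atom_table`.
#' @export
atom_table <- function(df) {
  need <- c("serial", "name", "element", "resname", "resid", "chain", "role", "copy")
  miss <- setdiff(need, names(df))
  assert_that(length(miss) == 0L, "atom_table missing columns: %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df[, need], stringsAsFactors = FALSE)
  df$serial <- as.integer(df$serial)
  df$resid <- as.integer(df$resid)
  df$copy <- as.integer(df$copy)
  validate_atom_table(df)
  class(df) <- c("atom_table", "data.frame")
  df
}

validate_atom_table <- function(df) {
  n <- nrow(df)
  assert_that(n > 0L, "atom_table is empty")
  assert_that(!anyDuplicated(df$serial) && all(df$serial == seq_len(n)),
              "atom serials must be unique and contiguous 1..%d", n)
  bad <- setdiff(unique(df$role), c("protein", "water", "ligand", "heme", "ion"))
  assert_that(length(bad) == 0L, "unknown role flag(s): %s", paste(bad, collapse = ", "))
  lig <- df$role == "ligand"
  assert_that(!anyNA(df$copy[lig]), "every ligand atom must carry a copy index")
  assert_that(all(is.na(df$copy[!lig])), "copy index only allowed on ligand atoms")
  invisible(TRUE)
}

#' @export
print.atom_table <- function(x, ...) {
  cat(sprintf("<atom_table> %d atoms | %d protein, %d water, %d ligand (%d copies), %d heme, %d ion\n",
              nrow(x), sum(x$role == "protein"), sum(x$role == "water"),
              sum(x$role == "ligand"), n_ligand_copies(x),
              sum(x$role == "heme"), sum(x$role == "ion")))
  cat(sprintf("  chains: %s\n", paste(unique(x$chain), collapse = ", ")))
  invisible(x)
}

#' Number of ligand copies in an atom table
#' @param atoms an `atom_table`.
#' @return Integer count of distinct ligand copy indices.
#' @export
n_ligand_copies <- function(atoms) {
  length(unique(atoms$copy[atoms$role == "ligand"]))
}

#' Ligand copy membership
#'
#' @param atoms an `atom_table`.
#' @return Named list: for each copy index (as character), the atom row
#'   indices of that copy.
#' @export
ligand_copy_atoms <- function(atoms) {
  lig <- which(atoms$role == "ligand")
  split(lig, atoms$copy[lig])
}

#' Chain of each ligand copy (chain of its first atom).
#' @param atoms an `atom_table`.
#' @return Named character vector keyed by copy index.
#' @export
ligand_copy_chains <- function(atoms) {
  vapply(ligand_copy_atoms(atoms), function(i) atoms$chain[i[1L]], character(1L))
}

## -- role classification ----------------------------------------------------

.water_resnames <- c("HOH", "TIP3", "TIP4", "TIP5", "TP3", "WAT", "SPC", "SPCE", "SOL", "H2O")
.ion_resnames <- c("SOD", "CLA", "POT", "CES", "LIT", "RUB", "MG", "CAL", "ZN",
                   "ZN2", "NA", "CL", "K", "CA", "BAR", "CD2")
.heme_resnames <- c("HEM", "HEME", "HEMO", "HEC")

#' Default ligand residue-name pattern (O2/OXY-type diatomic oxygen).
#' @export
default_ligand_pattern <- function() "^(O2|OXY|DIO|OX2)$"

classify_roles <- function(resname, ligand_spec = default_ligand_pattern()) {
  rn <- toupper(resname)
  role <- rep("protein", length(rn))
  role[rn %in% .water_resnames] <- "water"
  role[rn %in% .ion_resnames] <- "ion"
  role[rn %in% .heme_resnames] <- "heme"
  role[grepl(ligand_spec, rn, ignore.case = TRUE)] <- "ligand"
  role
}

## Element from an atom name: strip leading digits, take leading letters,
## normalize two-letter elements we actually meet; hydrogens by leading H.
element_from_name <- function(name) {
  s <- toupper(sub("^[0-9]+", "", name))
  first <- substr(s, 1L, 1L)
  two <- substr(s, 1L, 2L)
  el <- first
  ## two-letter symbols that cannot collide with protein atom names
  ## ("CA" stays carbon: alpha carbons outnumber calcium ions here)
  sel <- two %in% c("CL", "ZN", "FE", "MG")
  el[sel] <- two[sel]
  el
}

## Assign ligand copy indices by file order of (chain, resid) groups.
assign_copy_indices <- function(df) {
  df$copy <- NA_integer_
  lig <- which(df$role == "ligand")
  if (length(lig) == 0L) return(df)
  key <- paste(df$chain[lig], df$resid[lig], df$resname[lig], sep = "|")
  new_grp <- c(TRUE, key[-1L] != key[-length(key)])
  df$copy[lig] <- cumsum(new_grp)
  df
}

heavy_atoms <- function(atoms) atoms$element != "H"

protein_heavy_idx <- function(atoms) {
  which(atoms$role == "protein" & heavy_atoms(atoms))
}
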