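#' Build a structure model from an atom table
#'
#' Low-level constructor used by [read_structure()] and by the synthetic
#' fixture generators. The atom table is a data frame with one row per atom.
#'
#' @param atoms data frame with columns `chain`, `resno` (author residue
#'   number), `insert` (insertion code, "" if none), `resid` (residue name),
#'   `elety` (atom name), `element` (element symbol), `x`, `y`, `z`
#'   (angstrom), `occupancy`, `altloc`.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "resno", "insert", "resid", "elety", "element",
            "x", "y", "z", "occupancy", "altloc")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ",
                         paste(miss, collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite atomic coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety,
               atoms$altloc)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, insert, atom, altloc) keys in atom table")
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model: %d atoms, chains %s\n", nrow(x$atoms),
              paste(sort(unique(x$atoms$chain)), collapse = ", ")))
  invisible(x)
}

#' Read a PDB-format coordinate file
#'
#' Parses the first model of a PDB file. Alternate locations are resolved to
#' the highest-occupancy conformer (ties broken in favour of altloc "A");
#' waters (HOH/WAT/DOD) are always skipped; other heteroatoms are skipped by
#' default since they have no standard surface-area radii.
#'
#' @param path path to a PDB file.
#' @param keep_hetero keep non-water HETATM records (default FALSE).
#' @return A [structure_model()].
#' @export
read_structure <- function(path, keep_hetero = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("PDB parse error in ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no ATOM records in ", path)
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (!keep_hetero) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no usable ATOM records in ", path)
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  ## altloc resolution: per (chain, resno, insert, atom name) keep the
  ## highest occupancy; ties go to altloc "A". File order of the surviving
  ## atoms is preserved.
  at$.file_order <- seq_len(nrow(at))
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -at$o, at$alt != "A", at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "\r")), , drop = FALSE]
  at <- at[order(at$.file_order), , drop = FALSE]
  element <- at$elesy
  if (is.null(element)) element <- rep(NA_character_, nrow(at))
  blank <- is.na(element) | element == ""
  element[blank] <- substr(trimws(at$elety[blank]), 1L, 1L)
  atoms <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                      resid = at$resid, elety = at$elety,
                      element = toupper(trimws(element)),
                      x = at$x, y = at$y, z = at$z,
                      occupancy = at$o, altloc = at$alt,
                      stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  structure_model(atoms)
}

#' Write a structure model as a PDB file
#'
#' Minimal fixed-width PDB writer used by the synthetic fixture generators;
#' round-trips through [read_structure()].
#'
#' @param model a [structure_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)),
    ifelse(nchar(at$elety) < 4L, paste0(" ", at$elety), at$elety),
    ifelse(at$altloc == "", " ", at$altloc),
    at$resid, at$chain, at$resno,
    ifelse(at$insert == "", " ", at$insert),
    at$x, at$y, at$z, at$occupancy, 0,
    at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

## Subset a model to given chains (or drop them with negate).
subset_chains <- function(model, chains, negate = FALSE) {
  keep <- model$atoms$chain %in% chains
  if (negate) keep <- !keep
  structure_model(model$atoms[keep, , drop = FALSE])
}

## Heavy atoms only (surface-area and contact computations ignore hydrogens).
heavy_atoms <- function(atoms) {
  atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
}

residue_key <- function(atoms) paste0(atoms$chain, ":", atoms$resno,
                                      ifelse(atoms$insert == "", "",
                                             atoms$insert))

## Parse "A:176" / "A:176B" residue references.
parse_resref <- function(ref) {
  m <- regmatches(ref, regexec("^([A-Za-z0-9]):(-?[0-9]+)([A-Za-z]?)$", ref))[[1]]
  if (length(m) == 0L) stop("malformed residue reference: ", ref,
                            " (expected chain:resnum, e.g. A:176)")
  list(chain = m[2L], resno = as.integer(m[3L]), insert = m[4L])
}
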