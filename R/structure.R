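#' Parse a macromolecular structure file
#'
#' Reads PDB or mmCIF coordinates through `bio3d` and returns a lightweight
#' atom table.  Hydrogens are dropped; for alternate locations only the
#' first conformer (altloc `''` or `'A'`) is retained.  Coordinates and
#' residue numbering are used exactly as in the file (author numbering,
#' insertion codes preserved); nothing is renumbered.
#'
#' @param path Path to the file, or a `pdb_text` object from one of the
#'   structure generators.
#' @param format `"pdb"` or `"mmcif"`; default guessed from the extension.
#' @return A `structure3d` object: list with `atoms` (data frame `chain`,
#'   `resno`, `insert`, `resid`, `elety`, `x`, `y`, `z`, `key`), `chains`,
#'   and `source`.  `key` is `"chain:resno"` (plus the insertion code when
#'   present) and is unique per residue.
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (inherits(path, "pdb_text")) {
    tmp <- tempfile(fileext = ".pdb")
    writeLines(unclass(path), tmp)
    on.exit(unlink(tmp), add = TRUE)
    path <- tmp
    format <- "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("could not parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0) stop("no atoms in '", path, "'", call. = FALSE)
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  at <- at[is.na(at$elesy) | at$elesy != "H", , drop = FALSE]
  at <- at[!grepl("^H", trimws(at$elety)) | at$resid == "HIS", , drop = FALSE]
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    stop("non-finite atom coordinates in '", path, "'", call. = FALSE)
  ins <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  atoms <- data.frame(
    chain = at$chain, resno = at$resno, insert = ins,
    resid = at$resid, elety = trimws(at$elety),
    x = at$x, y = at$y, z = at$z,
    key = paste0(at$chain, ":", at$resno, ins),
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, chains = unique(atoms$chain), source = path),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms, %d residues, chains %s\n",
              nrow(x$atoms), length(unique(x$atoms$key)),
              paste(x$chains, collapse = ",")))
  invisible(x)
}

# Charged side-chain atom table.  The salt-bridge convention: carboxylate
# oxygens (and terminal OXT) versus Lys NZ / Arg guanidinium nitrogens.
negative_atoms <- function(atoms, include_oxt = TRUE) {
  sel <- (atoms$resid == "GLU" & atoms$elety %in% c("OE1", "OE2")) |
    (atoms$resid == "ASP" & atoms$elety %in% c("OD1", "OD2"))
  if (include_oxt) sel <- sel | atoms$elety == "OXT"
  atoms[sel, , drop = FALSE]
}

positive_atoms <- function(atoms, include_his = FALSE,
                           include_n_terminus = FALSE) {
  sel <- (atoms$resid == "LYS" & atoms$elety == "NZ") |
    (atoms$resid == "ARG" & atoms$elety %in% c("NE", "NH1", "NH2"))
  if (include_his)
    sel <- sel | (atoms$resid == "HIS" & atoms$elety %in% c("ND1", "NE2"))
  if (include_n_terminus) {
    first <- !duplicated(atoms$chain)
    first_keys <- atoms$key[first]
    sel <- sel | (atoms$elety == "N" & atoms$key %in% first_keys)
  }
  atoms[sel, , drop = FALSE]
}

#' One-letter sequence of a chain
#'
#' @param struct A `structure3d`.
#' @param chain Chain identifier.
#' @return List with `seq` (one-letter string) and `resno` (author residue
#'   numbers in the same order), taken from the CA trace.
#' @export
chain_sequence <- function(struct, chain) {
  stopifnot(inherits(struct, "structure3d"))
  at <- struct$atoms
  ca <- at[at$chain == chain & at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop("no CA atoms in chain ", chain, call. = FALSE)
  aa1 <- bio3d::aa321(ca$resid)
  list(seq = paste(aa1, collapse = ""), resno = ca$resno, key = ca$key)
}
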