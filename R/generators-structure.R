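# PDB text construction for the synthetic structural fixtures.  Atom
# records are written through bio3d::write.pdb so the output is standard
# fixed-width v3.3 ATOM text that round-trips through parse_structure().

pdb_text_from_atoms <- function(atoms) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(file = tmp,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   resno = atoms$resno, resid = atoms$resid,
                   eleno = seq_len(nrow(atoms)), elety = atoms$elety,
                   chain = atoms$chain)
  structure(readLines(tmp), class = "pdb_text")
}

#' @export
print.pdb_text <- function(x, ...) {
  cat(sprintf("PDB text, %d lines (%d ATOM records)\n", length(x),
              sum(grepl("^ATOM", x))))
  invisible(x)
}

atom_row <- function(chain, resno, resid, elety, xyz) {
  data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
             x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
}

# Minimal charged residues: enough atoms for contact detection and
# carboxylate centroids, one charged atom placed exactly where asked.
glu_at <- function(chain, resno, o1, o2 = o1 + c(-1.1, 0.6, 0)) {
  cd <- (o1 + o2) / 2 + c(0, 0, 0.6)
  rbind(atom_row(chain, resno, "GLU", "CA", cd + c(-1.5, -1.5, 1.5)),
        atom_row(chain, resno, "GLU", "CD", cd),
        atom_row(chain, resno, "GLU", "OE1", o1),
        atom_row(chain, resno, "GLU", "OE2", o2))
}

asp_at <- function(chain, resno, o1, o2 = o1 + c(-1.1, 0.6, 0)) {
  cg <- (o1 + o2) / 2 + c(0, 0, 0.6)
  rbind(atom_row(chain, resno, "ASP", "CA", cg + c(-1.5, -1.5, 1.5)),
        atom_row(chain, resno, "ASP", "CG", cg),
        atom_row(chain, resno, "ASP", "OD1", o1),
        atom_row(chain, resno, "ASP", "OD2", o2))
}

lys_at <- function(chain, resno, nz) {
  rbind(atom_row(chain, resno, "LYS", "CA", nz + c(3, 1.5, 1.5)),
        atom_row(chain, resno, "LYS", "NZ", nz))
}

arg_at <- function(chain, resno, nh1) {
  rbind(atom_row(chain, resno, "ARG", "CA", nh1 + c(3, 1.5, 1.5)),
        atom_row(chain, resno, "ARG", "NE", nh1 + c(1.1, 0.8, 0)),
        atom_row(chain, resno, "ARG", "NH1", nh1),
        atom_row(chain, resno, "ARG", "NH2", nh1 + c(1.1, -0.8, 0)))
}

#' Generate a toy two-chain complex with planted ionic contacts
#'
#' Builds PDB text for a two-chain complex in which chain A (the "core")
#' carries acidic residues and chain B (the "regulator") basic residues.
#' Each requested pair places one carboxylate oxygen of chain A at exactly
#' the stated distance from the nearest charged nitrogen of chain B; all
#' other charged-atom cross distances of that pair are strictly larger, so
#' the minimum-atom-pair distance reported by [find_ionic_contacts()]
#' equals the planted value.  Decoy charged residues are placed farther
#' than 8 A from any opposite charge.
#'
#' @param pairs Data frame with columns `negative` (`"GLU"`/`"ASP"`),
#'   `positive` (`"LYS"`/`"ARG"`), `distance` (A, > 0).  May have 0 rows.
#' @param decoys Number of decoy charged residues (alternating chains).
#' @param seed Integer seed (jitters decoy placement).
#' @return A `pdb_text` object with attributes `planted` (the pairs table
#'   with residue keys) and `n_atoms`.
#' @export
gen_toy_complex <- function(pairs, decoys = 0L, seed = 1L) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) > 0) {
    stopifnot(all(pairs$negative %in% c("GLU", "ASP")),
              all(pairs$positive %in% c("LYS", "ARG")))
    if (any(pairs$distance <= 0)) stop("distances must be > 0", call. = FALSE)
  }
  rows <- list()
  planted <- NULL
  for (i in seq_len(nrow(pairs))) {
    base <- c(0, 30 * (i - 1), 0)
    o1 <- base
    npos <- base + c(pairs$distance[i], 0, 0)
    rows[[length(rows) + 1L]] <-
      if (pairs$negative[i] == "GLU") glu_at("A", i, o1) else asp_at("A", i, o1)
    rows[[length(rows) + 1L]] <-
      if (pairs$positive[i] == "LYS") lys_at("B", i, npos) else arg_at("B", i, npos)
    planted <- rbind(planted, data.frame(
      neg_key = paste0("A:", i), pos_key = paste0("B:", i),
      distance = pairs$distance[i]))
  }
  decoys <- as.integer(decoys)
  if (decoys > 0) {
    jit <- with_seed(seed, matrix(stats::runif(decoys * 3, -2, 2), ncol = 3))
    for (j in seq_len(decoys)) {
      if (j %% 2 == 1) {          # acidic decoy on chain A, far from chain B
        pos <- c(0, -25 - 15 * j, 0) + jit[j, ]
        rows[[length(rows) + 1L]] <- glu_at("A", nrow(pairs) + j, pos)
      } else {                    # basic decoy on chain B, far from chain A
        pos <- c(100, -25 - 15 * j, 0) + jit[j, ]
        rows[[length(rows) + 1L]] <- lys_at("B", nrow(pairs) + j, pos)
      }
    }
  }
  if (!length(rows))
    stop("nothing to write: no pairs and no decoys", call. = FALSE)
  atoms <- do.call(rbind, rows)
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  txt <- pdb_text_from_atoms(atoms)
  attr(txt, "planted") <- planted
  attr(txt, "n_atoms") <- nrow(atoms)
  txt
}

#' Generate a pseudo alpha-ring with a planted square charge cluster
#'
#' Builds PDB text emulating a heptameric (or `n_subunits`-meric) ring of
#' pseudo-subunits, one chain per subunit, each carrying acidic residues
#' whose carboxylate centroids are scattered over the ring surface.  One
#' inter-subunit groove additionally carries a planted quadruplet of
#' centroids forming an exact square of side `square_side`, emulating a
#' charge cluster matched by a square-planar tetra-cationic ligand.
#'
#' @param n_subunits Number of subunits (>= 4).
#' @param square_side Side of the planted square (A, > 0).
#' @param seed Integer seed for the scattered centroids.
#' @param scatter_per_subunit Scattered acidic residues per subunit
#'   (default 2).
#' @return A `pdb_text` with attributes `planted_keys` (residue keys of the
#'   square corners), `centroid_keys` (all acidic residue keys) and
#'   `n_atoms`.
#' @export
gen_pseudo_ring <- function(n_subunits, square_side, seed = 1L,
                            scatter_per_subunit = 2L) {
  n_subunits <- as.integer(n_subunits)
  if (n_subunits < 4) stop("'n_subunits' must be >= 4", call. = FALSE)
  if (square_side <= 0) stop("'square_side' must be > 0", call. = FALSE)
  R <- 35                                  # ring radius, ~20S alpha-ring scale
  chains <- LETTERS[seq_len(n_subunits)]
  rows <- list()
  keys <- character()

  centroid_res <- function(chain, resno, centroid, tilt) {
    w <- c(cos(tilt), sin(tilt), 0) * 0.55 # OE1/OE2 straddle the centroid
    glu_at(chain, resno, centroid + w, centroid - w)
  }

  scatter <- with_seed(seed, {
    ang <- stats::runif(n_subunits * scatter_per_subunit, 0, 2 * pi)
    rad <- stats::runif(n_subunits * scatter_per_subunit, 0.6 * R, 1.2 * R)
    zz <- stats::runif(n_subunits * scatter_per_subunit, -3, 3)
    tl <- stats::runif(n_subunits * scatter_per_subunit, 0, pi)
    data.frame(ang = ang, rad = rad, z = zz, tilt = tl)
  })
  idx <- 0L
  for (s in seq_len(n_subunits)) {
    theta0 <- 2 * pi * (s - 1) / n_subunits
    for (j in seq_len(scatter_per_subunit)) {
      idx <- idx + 1L
      th <- theta0 + (scatter$ang[idx] %% (2 * pi / n_subunits))
      c0 <- c(scatter$rad[idx] * cos(th), scatter$rad[idx] * sin(th),
              scatter$z[idx])
      rows[[length(rows) + 1L]] <- centroid_res(chains[s], j, c0,
                                                scatter$tilt[idx])
      keys <- c(keys, paste0(chains[s], ":", j))
    }
  }

  # planted square in the groove between subunits 1 and 2, tangent plane
  groove <- 2 * pi * 0.5 / n_subunits
  centre <- c(R * cos(groove), R * sin(groove), 0)
  u <- c(-sin(groove), cos(groove), 0)     # tangential
  v <- c(0, 0, 1)                          # axial
  half <- square_side / 2
  corners <- list(centre + half * (u + v), centre + half * (u - v),
                  centre + half * (-u + v), centre + half * (-u - v))
  planted_keys <- character()
  for (q in seq_along(corners)) {
    rows[[length(rows) + 1L]] <- centroid_res(chains[1], 100 + q,
                                              corners[[q]], q * pi / 5)
    planted_keys <- c(planted_keys, paste0(chains[1], ":", 100 + q))
  }
  atoms <- do.call(rbind, rows)
  txt <- pdb_text_from_atoms(atoms)
  attr(txt, "planted_keys") <- planted_keys
  attr(txt, "centroid_keys") <- c(keys, planted_keys)
  attr(txt, "n_atoms") <- nrow(atoms)
  txt
}
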