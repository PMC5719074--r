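#' Find ionic contacts across a two-group interface
#'
#' Detects salt bridges between two disjoint chain groups: every pair of a
#' side-chain carboxylate oxygen (Glu OE1/OE2, Asp OD1/OD2, terminal OXT)
#' and a basic side-chain nitrogen (Lys NZ, Arg NE/NH1/NH2) that crosses
#' the groups with an inter-atomic distance at or below `cutoff`.  Both
#' orientations are considered, so swapping the groups returns the same
#' contacts; the negative partner is always listed first.  Pairs are
#' deduplicated at the residue-pair level, keeping the minimum-distance
#' atom pair (residues, not atoms, are the objects of interest), and sorted
#' by distance.
#'
#' Candidate pairs are generated with a uniform cell grid of cell size
#' `cutoff` (only neighbouring cells are scanned), which is equivalent to
#' the all-pairs scan but linear in atom count for biological densities.
#'
#' @param struct A `structure3d` from [parse_structure()].
#' @param group_a,group_b Disjoint, non-empty chain identifier sets;
#'   `group_a` is the core-particle side.
#' @param cutoff Distance cutoff in Angstrom (default 4.0, the standard
#'   salt-bridge convention).
#' @param include_his Also treat His ND1/NE2 as positive (default off).
#' @param include_termini Also treat each chain's first backbone N as
#'   positive (default off; terminal OXT is always acidic).
#' @return Data frame of class `ionic_contacts`: `neg_key`, `neg_resid`,
#'   `neg_atom`, `pos_key`, `pos_resid`, `pos_atom`, `distance`, ordered by
#'   distance.
#' @export
find_ionic_contacts <- function(struct, group_a, group_b, cutoff = 4.0,
                                include_his = FALSE, include_termini = FALSE) {
  stopifnot(inherits(struct, "structure3d"))
  if (length(intersect(group_a, group_b)) > 0)
    stop("chain groups overlap", call. = FALSE)
  if (!length(group_a) || !length(group_b))
    stop("both chain groups must be non-empty", call. = FALSE)
  at <- struct$atoms
  a <- at[at$chain %in% group_a, , drop = FALSE]
  b <- at[at$chain %in% group_b, , drop = FALSE]

  hits <- rbind(
    contact_pairs(negative_atoms(a), positive_atoms(b, include_his,
                                                    include_termini), cutoff),
    contact_pairs(negative_atoms(b), positive_atoms(a, include_his,
                                                    include_termini), cutoff))
  if (is.null(hits) || nrow(hits) == 0) {
    return(structure(data.frame(
      neg_key = character(), neg_resid = character(), neg_atom = character(),
      pos_key = character(), pos_resid = character(), pos_atom = character(),
      distance = numeric()), class = c("ionic_contacts", "data.frame")))
  }
  # residue-pair dedup: keep the closest atom pair
  hits <- hits[order(hits$distance), , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$neg_key, hits$pos_key)), , drop = FALSE]
  rownames(hits) <- NULL
  structure(hits, class = c("ionic_contacts", "data.frame"))
}

# Cell-grid candidate generation followed by exact distance evaluation.
contact_pairs <- function(neg, pos, cutoff) {
  if (nrow(neg) == 0 || nrow(pos) == 0 || cutoff <= 0) return(NULL)
  cs <- max(cutoff, 1e-6)
  cell_id <- function(df) {
    paste(floor(df$x / cs), floor(df$y / cs), floor(df$z / cs), sep = ",")
  }
  neg_cell <- cell_id(neg)
  pos_ix <- floor(pos$x / cs); pos_iy <- floor(pos$y / cs)
  pos_iz <- floor(pos$z / cs)
  pos_by_cell <- split(seq_len(nrow(pos)),
                       paste(pos_ix, pos_iy, pos_iz, sep = ","))
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  out <- list()
  for (i in seq_len(nrow(neg))) {
    ix <- floor(neg$x[i] / cs); iy <- floor(neg$y[i] / cs)
    iz <- floor(neg$z[i] / cs)
    keys <- paste(ix + offsets$dx, iy + offsets$dy, iz + offsets$dz, sep = ",")
    cand <- unlist(pos_by_cell[keys], use.names = FALSE)
    if (!length(cand)) next
    d <- sqrt((pos$x[cand] - neg$x[i])^2 + (pos$y[cand] - neg$y[i])^2 +
                (pos$z[cand] - neg$z[i])^2)
    keep <- which(d <= cutoff)
    if (!length(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      neg_key = neg$key[i], neg_resid = neg$resid[i], neg_atom = neg$elety[i],
      pos_key = pos$key[cand[keep]], pos_resid = pos$resid[cand[keep]],
      pos_atom = pos$elety[cand[keep]], distance = d[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Group interface contacts by inter-subunit groove
#'
#' Assigns each contact to exactly one group labelled from user-supplied
#' chain-to-subunit annotations (no proteasome topology is hard-coded): the
#' label is `"<subunit of negative chain>-<subunit of positive chain>"`.
#' Reports the unique negative residues and counts per group.
#'
#' @param contacts An `ionic_contacts` data frame.
#' @param annotations Named character vector mapping chain identifiers to
#'   subunit labels (e.g. `c(A = "alpha4", B = "Rpt6")`).
#' @return An `interface_map`: list with `contacts` (with a `group`
#'   column), `groups` (list of unique negative residue keys per label) and
#'   `counts`.
#' @export
interface_map <- function(contacts, annotations) {
  stopifnot(inherits(contacts, "ionic_contacts"))
  chain_of <- function(key) sub(":.*$", "", key)
  need <- unique(c(chain_of(contacts$neg_key), chain_of(contacts$pos_key)))
  missing <- setdiff(need, names(annotations))
  if (length(missing))
    stop("no subunit annotation for chain(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  group <- paste(annotations[chain_of(contacts$neg_key)],
                 annotations[chain_of(contacts$pos_key)], sep = "-")
  contacts$group <- if (nrow(contacts)) group else character()
  groups <- lapply(split(contacts$neg_key, contacts$group), unique)
  structure(list(contacts = contacts, groups = groups,
                 counts = vapply(groups, length, integer(1))),
            class = "interface_map")
}

#' @export
print.interface_map <- function(x, ...) {
  cat(sprintf("Interface map: %d contacts in %d groove group(s)\n",
              nrow(x$contacts), length(x$groups)))
  for (g in names(x$groups))
    cat(sprintf("  %s: %d unique negative residue(s)\n", g, x$counts[[g]]))
  invisible(x)
}

#' Align two sequences and map residue numbering
#'
#' Global (Needleman-Wunsch) alignment with affine gap penalties (BLOSUM62,
#' gap open 10, extend 0.5 — suited to homolog transfer between orthologous
#' subunits of high similarity) and extraction of the induced position
#' mapping.  Positions aligned to gaps are unmapped.  The mapping records,
#' per aligned pair, whether the residues are identical and whether the
#' charge class (acidic/basic/neutral) is conserved.
#'
#' @param template_seq,target_seq Amino-acid strings (standard 20-letter
#'   alphabet).
#' @param template_resno,target_resno Optional author residue numbers for
#'   each sequence position (default `1..nchar`).
#' @return A `residue_mapping` data frame: `template_pos`, `target_pos`
#'   (author numbers; `NA` where aligned to a gap), `template_aa`,
#'   `target_aa`, `identical`, `charge_conserved`.
#' @export
align_and_map <- function(template_seq, target_seq,
                          template_resno = NULL, target_resno = NULL) {
  check_seq <- function(s, nm) {
    if (!nzchar(s)) stop(nm, " is empty", call. = FALSE)
    if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", s))
      stop("illegal characters in ", nm, call. = FALSE)
  }
  check_seq(template_seq, "template_seq"); check_seq(target_seq, "target_seq")
  template_resno <- template_resno %||% seq_len(nchar(template_seq))
  target_resno <- target_resno %||% seq_len(nchar(target_seq))
  aln <- Biostrings::pairwiseAlignment(
    pattern = template_seq, subject = target_seq, type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ip <- 0L; is <- 0L
  rows <- vector("list", length(pat))
  for (k in seq_along(pat)) {
    if (pat[k] != "-") ip <- ip + 1L
    if (sub[k] != "-") is <- is + 1L
    if (pat[k] == "-" && sub[k] == "-") next
    rows[[k]] <- data.frame(
      template_pos = if (pat[k] == "-") NA_integer_ else template_resno[ip],
      target_pos = if (sub[k] == "-") NA_integer_ else target_resno[is],
      template_aa = if (pat[k] == "-") NA_character_ else pat[k],
      target_aa = if (sub[k] == "-") NA_character_ else sub[k],
      stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, rows)
  charge_class <- function(aa) {
    ifelse(aa %in% c("D", "E"), "acidic",
           ifelse(aa %in% c("K", "R"), "basic", "neutral"))
  }
  map$identical <- !is.na(map$template_aa) & !is.na(map$target_aa) &
    map$template_aa == map$target_aa
  map$charge_conserved <- !is.na(map$template_aa) & !is.na(map$target_aa) &
    charge_class(map$template_aa) == charge_class(map$target_aa)
  structure(map, class = c("residue_mapping", "data.frame"))
}

#' Transfer interface contacts onto homolog numbering
#'
#' Re-indexes every contact of an interface map through per-chain residue
#' mappings from [align_and_map()].  Contacts whose negative residue is
#' aligned to a gap or to a non-acidic target residue are dropped and
#' counted; contacts whose positive residue is aligned to a gap or to a
#' non-basic target are likewise dropped and counted separately.
#'
#' @param map An `interface_map` or `ionic_contacts` object.
#' @param mappings Named list of `residue_mapping`s, one per chain
#'   identifier occurring in the contacts.
#' @return A list of class `transferred_map`: `contacts` (re-indexed),
#'   `dropped_negative`, `dropped_positive` (counts), `drop_detail`.
#' @export
transfer_contacts <- function(map, mappings) {
  contacts <- if (inherits(map, "interface_map")) map$contacts else map
  stopifnot(is.data.frame(contacts))
  split_key <- function(key) {
    list(chain = sub(":.*$", "", key),
         resno = as.integer(sub("^[^:]*:", "", key)))
  }
  lookup <- function(chain, resno) {
    m <- mappings[[chain]]
    if (is.null(m))
      stop("no residue mapping for chain ", chain, call. = FALSE)
    row <- m[!is.na(m$template_pos) & m$template_pos == resno, , drop = FALSE]
    if (nrow(row) == 0) {
      data.frame(target_pos = NA_integer_, target_aa = NA_character_)
    } else row[1, c("target_pos", "target_aa")]
  }
  keep <- logical(nrow(contacts))
  dropped_neg <- 0L; dropped_pos <- 0L
  detail <- list()
  out <- contacts
  for (i in seq_len(nrow(contacts))) {
    nk <- split_key(contacts$neg_key[i]); pk <- split_key(contacts$pos_key[i])
    tn <- lookup(nk$chain, nk$resno); tp <- lookup(pk$chain, pk$resno)
    if (is.na(tn$target_pos) || !tn$target_aa %in% c("D", "E")) {
      dropped_neg <- dropped_neg + 1L
      detail[[length(detail) + 1L]] <- data.frame(
        key = contacts$neg_key[i], side = "negative",
        reason = if (is.na(tn$target_pos)) "gap" else "not acidic")
      next
    }
    if (is.na(tp$target_pos) || !tp$target_aa %in% c("K", "R")) {
      dropped_pos <- dropped_pos + 1L
      detail[[length(detail) + 1L]] <- data.frame(
        key = contacts$pos_key[i], side = "positive",
        reason = if (is.na(tp$target_pos)) "gap" else "not basic")
      next
    }
    keep[i] <- TRUE
    out$neg_key[i] <- paste0(nk$chain, ":", tn$target_pos)
    out$pos_key[i] <- paste0(pk$chain, ":", tp$target_pos)
  }
  structure(list(contacts = out[keep, , drop = FALSE],
                 dropped_negative = dropped_neg,
                 dropped_positive = dropped_pos,
                 drop_detail = if (length(detail)) do.call(rbind, detail) else NULL),
            class = "transferred_map")
}

#' @export
print.transferred_map <- function(x, ...) {
  cat(sprintf(
    "Transferred map: %d contact(s) kept, %d dropped (negative), %d dropped (positive)\n",
    nrow(x$contacts), x$dropped_negative, x$dropped_positive))
  invisible(x)
}
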