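#' Carboxylate centroid geometry of a set of acidic residues
#'
#' For each requested Asp/Glu residue computes the centroid of its
#' side-chain carboxylate oxygens (OD1/OD2 or OE1/OE2) and the full
#' symmetric pairwise Euclidean distance matrix of the centroids.
#'
#' @param struct A `structure3d`.
#' @param residues Character vector of residue keys (`"chain:resno"`).
#' @return A `site_geometry`: list with `centroids` (data frame `key`,
#'   `resid`, `x`, `y`, `z`) and `distances` (symmetric matrix, A,
#'   zero diagonal, dimnames = keys).
#' @export
site_geometry <- function(struct, residues) {
  stopifnot(inherits(struct, "structure3d"))
  at <- struct$atoms
  cents <- do.call(rbind, lapply(residues, function(key) {
    ra <- at[at$key == key, , drop = FALSE]
    if (nrow(ra) == 0) stop("residue not found: ", key, call. = FALSE)
    resid <- ra$resid[1]
    ox <- switch(resid,
                 GLU = ra[ra$elety %in% c("OE1", "OE2"), , drop = FALSE],
                 ASP = ra[ra$elety %in% c("OD1", "OD2"), , drop = FALSE],
                 stop("residue ", key, " is ", resid, ", not Asp/Glu",
                      call. = FALSE))
    if (nrow(ox) == 0)
      stop("residue ", key, " is missing carboxylate oxygens", call. = FALSE)
    data.frame(key = key, resid = resid, x = mean(ox$x), y = mean(ox$y),
               z = mean(ox$z), stringsAsFactors = FALSE)
  }))
  m <- as.matrix(stats::dist(cents[, c("x", "y", "z")]))
  dimnames(m) <- list(cents$key, cents$key)
  structure(list(centroids = cents, distances = m), class = "site_geometry")
}

#' @export
print.site_geometry <- function(x, ...) {
  cat(sprintf("Site geometry: %d carboxylate centroid(s)\n",
              nrow(x$centroids)))
  invisible(x)
}

square_score <- function(d6, side) {
  ideal <- sort(c(rep(side, 4), rep(side * sqrt(2), 2)))
  sqrt(mean((sort(d6) - ideal)^2))
}

#' Match a square charge arrangement against site geometry
#'
#' Scores every 4-subset of the centroids against an ideal square of the
#' given side: the score is the RMS deviation of the subset's six sorted
#' pairwise distances from the ideal multiset
#' `(side x4, side*sqrt(2) x2)`.  Subsets containing any pairwise distance
#' outside `[side - 3*tolerance, side*sqrt(2) + 3*tolerance]` are pruned
#' before scoring (exhaustive semantics at tractable cost).  Scoring uses
#' only pairwise distances, so it is invariant under rigid motion of the
#' coordinates.
#'
#' @param geom A [site_geometry()] with >= 4 centroids.
#' @param side Square side in Angstrom, > 0 (e.g. a ligand's adjacent
#'   charge spacing from [adjacent_charge_spacing()]).
#' @param tolerance Score threshold in Angstrom (default 1.0); subsets with
#'   score <= tolerance are returned.
#' @return Data frame of class `square_matches` with columns `key1..key4`
#'   and `score`, ascending by score.  Attribute `n_scored` records how
#'   many subsets survived pruning.
#' @export
match_ligand_geometry <- function(geom, side, tolerance = 1.0) {
  stopifnot(inherits(geom, "site_geometry"))
  keys <- geom$centroids$key
  n <- length(keys)
  if (n < 4) stop("need at least 4 centroids", call. = FALSE)
  if (side <= 0) stop("'side' must be > 0", call. = FALSE)
  D <- geom$distances
  lo <- side - 3 * tolerance
  hi <- side * sqrt(2) + 3 * tolerance
  ok_pair <- D >= lo & D <= hi
  combs <- utils::combn(n, 4)
  rows <- list()
  n_scored <- 0L
  for (j in seq_len(ncol(combs))) {
    id <- combs[, j]
    sub <- D[id, id]
    d6 <- sub[upper.tri(sub)]
    if (!all(ok_pair[id, id][upper.tri(sub)])) next
    n_scored <- n_scored + 1L
    sc <- square_score(d6, side)
    if (sc <= tolerance) {
      rows[[length(rows) + 1L]] <- data.frame(
        key1 = keys[id[1]], key2 = keys[id[2]], key3 = keys[id[3]],
        key4 = keys[id[4]], score = sc, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(key1 = character(), key2 = character(), key3 = character(),
               key4 = character(), score = numeric())
  out <- out[order(out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_scored") <- n_scored
  class(out) <- c("square_matches", "data.frame")
  out
}
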