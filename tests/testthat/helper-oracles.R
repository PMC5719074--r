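# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: plain arithmetic, all-pairs scans and exhaustive
# enumeration.

logspace <- function(from, to, length.out) {
  exp(seq(log(from), log(to), length.out = length.out))
}

# Two-state open fraction by direct arithmetic (no log-space tricks).
oracle_f_open <- function(x, K_o, K_c, L, n) {
  num <- L * (1 + K_o * x)^n
  num / ((1 + K_c * x)^n + num)
}

# Cooperative k_obs by direct arithmetic.
oracle_kobs <- function(x, K_o, K_c, k_o, k_c, k_off, L, n) {
  fo <- oracle_f_open(x, K_o, K_c, L, n)
  (k_c * (1 - fo) + k_o * fo) * x + k_off
}

# All-pairs salt-bridge scan on a parsed structure (no spatial index, no
# shared helpers): every acidic oxygen vs every basic nitrogen across the
# two chain groups, residue-pair dedup by minimum distance.
oracle_contacts <- function(struct, chains_a, chains_b, cutoff) {
  at <- struct$atoms
  is_neg <- (at$resid == "GLU" & at$elety %in% c("OE1", "OE2")) |
    (at$resid == "ASP" & at$elety %in% c("OD1", "OD2")) |
    at$elety == "OXT"
  is_pos <- (at$resid == "LYS" & at$elety == "NZ") |
    (at$resid == "ARG" & at$elety %in% c("NE", "NH1", "NH2"))
  res <- NULL
  for (orient in 1:2) {
    ga <- if (orient == 1) chains_a else chains_b
    gb <- if (orient == 1) chains_b else chains_a
    neg <- at[is_neg & at$chain %in% ga, ]
    pos <- at[is_pos & at$chain %in% gb, ]
    for (i in seq_len(nrow(neg))) for (j in seq_len(nrow(pos))) {
      d <- sqrt(sum((c(neg$x[i], neg$y[i], neg$z[i]) -
                       c(pos$x[j], pos$y[j], pos$z[j]))^2))
      if (d <= cutoff)
        res <- rbind(res, data.frame(neg_key = neg$key[i],
                                     pos_key = pos$key[j], distance = d))
    }
  }
  if (is.null(res)) return(res)
  res <- res[order(res$distance), ]
  res <- res[!duplicated(paste(res$neg_key, res$pos_key)), ]
  rownames(res) <- NULL
  res
}

# Exhaustive square matching over every 4-subset, no pruning.
oracle_square_matches <- function(distmat, side, tol) {
  keys <- rownames(distmat)
  ideal <- sort(c(rep(side, 4), rep(side * sqrt(2), 2)))
  combs <- utils::combn(length(keys), 4)
  out <- NULL
  for (j in seq_len(ncol(combs))) {
    id <- combs[, j]
    d6 <- sort(distmat[id, id][upper.tri(diag(4))])
    sc <- sqrt(mean((d6 - ideal)^2))
    if (sc <= tol)
      out <- rbind(out, data.frame(subset = paste(sort(keys[id]),
                                                  collapse = "|"),
                                   score = sc))
  }
  if (!is.null(out)) out <- out[order(out$score), ]
  out
}

random_rigid_motion <- function(xyz, seed) {
  set.seed(seed)
  ang <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Rz <- rbind(c(cos(ang[2]), -sin(ang[2]), 0),
              c(sin(ang[2]), cos(ang[2]), 0), c(0, 0, 1))
  t(Rz %*% Rx %*% t(as.matrix(xyz))) +
    matrix(runif(3, -20, 20), nrow(xyz), 3, byrow = TRUE)
}
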