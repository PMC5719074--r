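#' Idealized porphyrin arm specification
#'
#' Describes one meso arm of a tetra-substituted cationic porphyrin as a
#' count of para-phenylene spacer rings between the macrocycle and the
#' terminal N-methylpyridinium cation: 0 spacers for the parent
#' tetrakis(N-methylpyridyl) scaffold, 1 for the phenyl-extended analogue.
#'
#' @param spacer_rings Integer >= 0, number of para-phenylene spacers.
#' @return An `arm_spec` object.
#' @export
arm_spec <- function(spacer_rings = 0L) {
  spacer_rings <- as.integer(spacer_rings)
  if (is.na(spacer_rings) || spacer_rings < 0)
    stop("'spacer_rings' must be an integer >= 0", call. = FALSE)
  structure(list(spacer_rings = spacer_rings, terminal = "pyridinium-N"),
            class = "arm_spec")
}

# Idealized planar (D4h) geometry constants, all in Angstrom:
#   r_meso : porphyrin centre -> meso carbon                 3.45
#   b_link : biaryl single bond, macrocycle -> first ring    1.49
#   d_para : para-phenylene ring span (C1 -> C4)             2.78
#   b_link2: ring -> ring single bond within the spacer      1.48
#   d_pyr  : pyridine ipso carbon -> para nitrogen span      2.79
.arm_constants <- c(r_meso = 3.45, b_link = 1.49, d_para = 2.78,
                    b_link2 = 1.48, d_pyr = 2.79)

#' Radial centre-to-cation distance of an idealized porphyrin arm
#'
#' Distance from the porphyrin centre to the terminal pyridinium nitrogen
#' along one meso arm, summed from standard bond-length constants for an
#' idealized planar geometry:
#' `r = r_meso + b_link + spacer_rings * (d_para + b_link2) + d_pyr`.
#' The constants (documented in the source) give r = 7.73 A with no spacer
#' and 11.99 A with one para-phenylene spacer.
#'
#' @param arm An [arm_spec()].
#' @return Radial distance in Angstrom.
#' @export
radial_charge_distance <- function(arm) {
  stopifnot(inherits(arm, "arm_spec"))
  k <- .arm_constants
  unname(k["r_meso"] + k["b_link"] +
           arm$spacer_rings * (k["d_para"] + k["b_link2"]) + k["d_pyr"])
}

#' Adjacent and diagonal cation spacing of the tetra-substituted scaffold
#'
#' For four identical arms in the square-planar (D4h-idealized) arrangement
#' the adjacent cation-cation distance is `r * sqrt(2)` and the diagonal is
#' `2 r`, with `r` from [radial_charge_distance()].  This reproduces the
#' design spacings of the two scaffolds: about 11 A with no spacer and about
#' 17 A with one para-phenylene spacer per arm.
#'
#' @param arm An [arm_spec()].
#' @return Named numeric vector `c(radial, adjacent, diagonal)` in Angstrom.
#' @export
adjacent_charge_spacing <- function(arm) {
  r <- radial_charge_distance(arm)
  c(radial = r, adjacent = r * sqrt(2), diagonal = 2 * r)
}
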