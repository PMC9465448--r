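# Solvent-accessible surface area by the Shrake-Rupley method: each heavy
# atom's solvent-expanded sphere is sampled with a deterministic golden-spiral
# lattice and the exposed fraction of points is converted to area.

#' Per-residue solvent-accessible surface area
#'
#' Shrake-Rupley SASA over heavy atoms with element-based van der Waals
#' radii (C 1.70, N 1.55, O 1.52, S 1.80 A). Per-atom areas are summed into
#' their parent residues, so the residue areas add up to the molecular SASA
#' exactly.
#'
#' @param s a `protein_structure`
#' @param probe_radius solvent probe radius in Angstrom
#' @param n_points sphere sample points per atom
#' @return named numeric vector of areas (A^2), names are `chain:resno` keys
#' @export
residue_sasa <- function(s, probe_radius = 1.4, n_points = 960) {
  at <- s$atom[s$atom$element != "H", , drop = FALSE]
  if (nrow(at) == 0) stop("structure has no heavy atoms")
  xyz <- coords_matrix(at)
  rad <- VDW_RADII[at$element]
  if (any(is.na(rad)))
    stop("no van der Waals radius for element(s): ",
         paste(unique(at$element[is.na(rad)]), collapse = ", "))
  rad <- unname(rad) + probe_radius
  pts <- sphere_points(n_points)
  n <- nrow(at)
  area <- numeric(n)
  # neighbour lists via squared-distance cutoff
  maxr <- max(rad)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
          (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad[i] + rad)^2 & d2 > 1e-12)
    surf <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    if (length(nb) > 0) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
               (surf[, 3] - xyz[j, 3])^2
        free <- free & dj2 > rad[j]^2
        if (!any(free)) break
      }
      frac <- sum(free) / n_points
    } else frac <- 1
    area[i] <- frac * 4 * pi * rad[i]^2
  }
  keys <- residue_keys(at)
  out <- tapply(area, factor(keys, levels = unique(keys)), sum)
  res <- as.numeric(out)
  names(res) <- names(out)
  res
}
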