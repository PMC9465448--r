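# Rotamer handling: loading the bundled (or a user-supplied) chi-angle
# table, building side chains onto a fixed backbone at given chi angles,
# measuring chi from coordinates, and picking structurally diverse subsets.

#' Load a side-chain rotamer library
#'
#' Reads a plain-text chi-angle table (`AA chi1 ... chiN weight`, `#`
#' comments). The bundled backbone-independent table is used by default;
#' tables derived from the Dunbrack library in the same format are accepted.
#' Rows are ordered by decreasing weight; the first row of each amino acid
#' is the seed rotamer for diversity selection.
#'
#' @param source path to a rotamer table, or `NULL` for the bundled table
#' @return named list mapping 3-letter codes to data.frames with columns
#'   `chi1`..`chi4` (NA beyond the residue's chi count) and `weight`
#' @export
load_rotamer_library <- function(source = NULL) {
  if (is.null(source))
    source <- system.file("extdata", "rotamer_chi.txt", package = "scafdock")
  if (!file.exists(source)) stop("rotamer table not found: ", source)
  lines <- readLines(source)
  rows <- list()
  for (ln in seq_along(lines)) {
    txt <- trimws(sub("#.*$", "", lines[ln]))
    if (!nzchar(txt)) next
    tok <- strsplit(txt, "[[:space:]]+")[[1]]
    aa <- toupper(tok[1])
    if (!aa %in% AA3)
      stop(sprintf("line %d: unknown amino acid '%s'", ln, tok[1]))
    vals <- suppressWarnings(as.numeric(tok[-1]))
    if (any(is.na(vals)) || length(vals) != n_chi(aa) + 1)
      stop(sprintf("line %d: expected %d chi angles and a weight for %s",
                   ln, n_chi(aa), aa))
    chi <- rep(NA_real_, 4)
    if (n_chi(aa) > 0) chi[seq_len(n_chi(aa))] <- vals[seq_len(n_chi(aa))]
    if (any(chi <= -180 | chi > 180, na.rm = TRUE))
      stop(sprintf("line %d: chi angles must lie in (-180, 180]", ln))
    rows[[length(rows) + 1]] <- data.frame(
      aa = aa, chi1 = chi[1], chi2 = chi[2], chi3 = chi[3], chi4 = chi[4],
      weight = vals[length(vals)], stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  lib <- split(tab[, -1], tab$aa)
  lib <- lapply(lib, function(d) {
    d <- d[order(-d$weight), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  needed <- unique(c("ALA", "GLY", POLAR_ALPHABET, CASCADE_POLAR,
                     CASCADE_NONPOLAR))
  miss <- setdiff(needed, names(lib))
  if (length(miss) > 0)
    stop("rotamer table is missing amino acid(s): ",
         paste(miss, collapse = ", "))
  lib
}

rotamer_chi <- function(lib, aa, idx) {
  d <- lib[[aa]]
  if (is.null(d) || idx > nrow(d)) stop("no rotamer ", idx, " for ", aa)
  chi <- as.numeric(d[idx, c("chi1", "chi2", "chi3", "chi4")])
  chi[seq_len(n_chi(aa))]
}

#' Build a side chain onto a fixed backbone
#'
#' Constructs the side chain of `aa` (heavy atoms plus polar hydrogens) at
#' residue `chain:resno` from the site's N/CA/C frame, using ideal internal
#' coordinates and the supplied chi angles. Backbone atoms are carried over
#' unchanged; at GLY sites the CB is first constructed at the ideal
#' tetrahedral position. Existing side-chain atoms are discarded.
#'
#' @param s a `protein_structure`
#' @param chain,resno the site
#' @param aa target 3-letter code (may differ from the native type)
#' @param chi numeric vector of chi angles, degrees (length `n_chi(aa)`)
#' @return data.frame of the rebuilt residue's atoms (a `placed_rotamer`)
#' @export
place_rotamer <- function(s, chain, resno, aa, chi = numeric(0)) {
  at <- residue_atoms(s, chain, resno)
  if (nrow(at) == 0) stop("no such residue: ", chain, ":", resno)
  if (!"CA" %in% at$elety) stop("site ", chain, ":", resno, " lacks CA")
  if (!aa %in% names(SIDECHAIN_ZMAT)) stop("unknown amino acid: ", aa)
  if (length(chi) < n_chi(aa))
    stop(aa, " needs ", n_chi(aa), " chi angles, got ", length(chi))
  bb <- at[is_backbone_name(at$elety), , drop = FALSE]
  bb$resid <- aa
  zm <- SIDECHAIN_ZMAT[[aa]]
  placed <- bb
  for (j in seq_len(nrow(zm))) {
    row <- zm[j, ]
    refs <- lapply(c(row$a, row$b, row$c), atom_coord, res_atoms = placed)
    if (any(vapply(refs, is.null, logical(1))))
      stop("cannot place ", row$name, " at ", chain, ":", resno,
           ": reference atom missing")
    tors <- if (row$chi > 0) chi[row$chi] + row$off else row$tors
    xyz <- place_atom(refs[[1]], refs[[2]], refs[[3]], row$bond, row$angle,
                      tors)
    placed <- rbind(placed, atom_row(bb, row$name, element_of(row$name), xyz))
  }
  rownames(placed) <- NULL
  class(placed) <- c("placed_rotamer", class(placed))
  placed
}

#' Measure chi dihedrals of a residue from its coordinates
#' @param res_atoms residue atom data.frame
#' @param aa 3-letter code (defaults to the residue's own type)
#' @return numeric vector of chi angles, degrees
#' @export
measure_chi <- function(res_atoms, aa = res_atoms$resid[1]) {
  defs <- CHI_ATOMS[[aa]]
  vapply(defs, function(q) {
    pts <- lapply(q, atom_coord, res_atoms = res_atoms)
    if (any(vapply(pts, is.null, logical(1)))) return(NA_real_)
    vdihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  }, numeric(1))
}

#' Select structurally diverse rotamers for a site
#'
#' Greedy farthest-point selection on side-chain heavy-atom RMSD after
#' placement at the site, seeded with the library's first (most probable)
#' rotamer. Deterministic; ties go to the lower library index.
#'
#' @param lib rotamer library (from [load_rotamer_library()])
#' @param s a `protein_structure`
#' @param chain,resno the site
#' @param aa amino acid whose rotamers are ranked
#' @param k maximum number to return
#' @return integer vector of selected library row indices, seed first
#' @export
select_diverse <- function(lib, s, chain, resno, aa, k = 5) {
  stopifnot(k >= 1)
  d <- lib[[aa]]
  if (is.null(d) || nrow(d) == 0) stop("no rotamers for ", aa)
  m <- nrow(d)
  if (m <= k) return(seq_len(m))
  coords <- lapply(seq_len(m), function(i) {
    p <- place_rotamer(s, chain, resno, aa, rotamer_chi(lib, aa, i))
    sc <- p[!is_backbone_name(p$elety) & p$element != "H", , drop = FALSE]
    coords_matrix(sc[order(sc$elety), , drop = FALSE])
  })
  rmsd <- matrix(0, m, m)
  for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
    v <- sqrt(mean(rowSums((coords[[i]] - coords[[j]])^2)))
    rmsd[i, j] <- v
    rmsd[j, i] <- v
  }
  sel <- 1L
  while (length(sel) < k) {
    rest <- setdiff(seq_len(m), sel)
    mind <- vapply(rest, function(i) min(rmsd[i, sel]), numeric(1))
    sel <- c(sel, rest[which.max(mind)])
  }
  sel
}
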