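# Hydrogen-bond half-sites. A scaffold half-site (paratope binding region,
# PBR) is a polar atom plus two constructed points on the atom-antecedent
# axis: the primary point 1.25 A beyond the atom (the ideal partner
# position) and the secondary point 1 A further, used to orient the bond.
# An epitope half-site (epitope binding atom, EBA) is the polar atom itself
# (primary) plus its antecedent position (secondary).

PRIMARY_OFFSET <- 1.25
SECONDARY_OFFSET <- 1.0

half_site_rows_for <- function(res_atoms, aa) {
  tab <- HALF_SITE_TABLE
  rows <- tab[tab$aa == "BB" | tab$aa == aa, , drop = FALSE]
  rows[rows$atom %in% res_atoms$elety, , drop = FALSE]
}

antecedent_point <- function(res_atoms, row) {
  a1 <- atom_coord(res_atoms, row$ant1)
  if (is.null(a1)) return(NULL)
  if (!is.na(row$ant2)) {
    a2 <- atom_coord(res_atoms, row$ant2)
    if (is.null(a2)) return(NULL)
    (a1 + a2) / 2
  } else a1
}

charged_class_of <- function(aa, is_bb) {
  ifelse(is_bb, "neu",
         ifelse(aa %in% c("ARG", "LYS"), "pos",
                ifelse(aa %in% c("ASP", "GLU"), "neg", "neu")))
}

half_site_record <- function(res_atoms, aa, row, kind, rotamer = 0L) {
  atom <- atom_coord(res_atoms, row$atom)
  ant <- antecedent_point(res_atoms, row)
  if (is.null(ant)) {
    warning("skipping half-site ", row$atom, " of ", aa, " ",
            res_atoms$chain[1], ":", res_atoms$resno[1],
            ": antecedent atom missing")
    return(NULL)
  }
  is_bb <- row$atom %in% c("O", "OT1", "OT2", "HN", "HN1", "HN2", "HN3")
  if (kind == "pbr") {
    u <- vunit(atom - ant)
    p <- atom + PRIMARY_OFFSET * u
    s <- p + SECONDARY_OFFSET * u
  } else {
    p <- atom
    s <- ant
  }
  data.frame(chain = res_atoms$chain[1], resno = res_atoms$resno[1],
             key = paste0(res_atoms$chain[1], ":", res_atoms$resno[1]),
             aa = aa, atom = row$atom,
             polarity = if (element_of(row$atom) == "H") "donor" else "acceptor",
             charged = charged_class_of(aa, is_bb), bb = is_bb,
             rotamer = rotamer,
             ax = atom[1], ay = atom[2], az = atom[3],
             antx = ant[1], anty = ant[2], antz = ant[3],
             px = p[1], py = p[2], pz = p[3],
             sx = s[1], sy = s[2], sz = s[3],
             stringsAsFactors = FALSE)
}

#' Construct scaffold hydrogen-bond half-sites (PBRs) for one residue
#'
#' One half-site per applicable polar-atom/antecedent row for the residue
#' type, plus the backbone rows (every residue; terminal rows only when the
#' atoms exist). The primary point lies exactly 1.25 A from the polar atom
#' along the antecedent-to-atom direction, the secondary point exactly 1 A
#' further.
#'
#' @param res_atoms residue atom data.frame (e.g. from [place_rotamer()] or
#'   `residue_atoms`); polar hydrogens must be present
#' @param aa amino acid providing the side-chain atoms (defaults to the
#'   residue's type); record it when the atoms come from a mutated rotamer
#' @param rotamer rotamer index tag (0 = native coordinates)
#' @param backbone include the backbone rows
#' @param sidechain include the side-chain rows
#' @return data.frame of half-site records (possibly empty)
#' @export
make_pbrs <- function(res_atoms, aa = res_atoms$resid[1], rotamer = 0L,
                      backbone = TRUE, sidechain = TRUE) {
  rows <- half_site_rows_for(res_atoms, aa)
  out <- list()
  for (i in seq_len(nrow(rows))) {
    is_bb_row <- rows$aa[i] == "BB"
    if (is_bb_row && !backbone) next
    if (!is_bb_row && !sidechain) next
    rec <- half_site_record(res_atoms, aa, rows[i, ], "pbr",
                            rotamer = rotamer)
    if (!is.null(rec)) out[[length(out) + 1]] <- rec
  }
  if (length(out) == 0) return(empty_half_sites())
  do.call(rbind, out)
}

#' Construct epitope hydrogen-bond half-sites (EBAs)
#'
#' Enumerates the polar-atom table over the epitope residues, keeping only
#' residues whose solvent accessibility exceeds `sasa_threshold` so that
#' buried atoms cannot be targeted.
#'
#' @param s the antigen `protein_structure` (with polar hydrogens)
#' @param epitope a `residue_selection`
#' @param sasa named per-residue SASA vector (from [residue_sasa()]); if
#'   `NULL` it is computed from `s`
#' @param sasa_threshold minimum exposed area (A^2)
#' @return data.frame of half-site records
#' @export
make_ebas <- function(s, epitope, sasa = NULL, sasa_threshold = 0.1) {
  if (is.null(sasa)) sasa <- residue_sasa(s)
  out <- list()
  for (i in seq_len(nrow(epitope))) {
    key <- epitope$key[i]
    if (is.na(sasa[key]) || sasa[key] <= sasa_threshold) next
    at <- residue_atoms(s, epitope$chain[i], epitope$resno[i])
    aa <- at$resid[1]
    rows <- half_site_rows_for(at, aa)
    for (j in seq_len(nrow(rows))) {
      rec <- half_site_record(at, aa, rows[j, ], "eba", rotamer = NA_integer_)
      if (!is.null(rec)) out[[length(out) + 1]] <- rec
    }
  }
  if (length(out) == 0) return(empty_half_sites())
  hs <- do.call(rbind, out)
  hs$id <- seq_len(nrow(hs))
  hs
}

empty_half_sites <- function() {
  data.frame(chain = character(0), resno = integer(0), key = character(0),
             aa = character(0), atom = character(0), polarity = character(0),
             charged = character(0), bb = logical(0), rotamer = integer(0),
             ax = numeric(0), ay = numeric(0), az = numeric(0),
             antx = numeric(0), anty = numeric(0), antz = numeric(0),
             px = numeric(0), py = numeric(0), pz = numeric(0),
             sx = numeric(0), sy = numeric(0), sz = numeric(0),
             stringsAsFactors = FALSE)
}

#' Hydrogen-bond validity on realized coordinates
#'
#' A designed bond is accepted when the acceptor-hydrogen distance is below
#' `dist_limit` and the acceptor-hydrogen-donor angle exceeds `angle_limit`
#' (both strict).
#'
#' @param hydrogen,donor_heavy,acceptor length-3 coordinates; `hydrogen`
#'   must be covalently bound to `donor_heavy`
#' @param dist_limit,angle_limit thresholds (2.5 A, 120 degrees)
#' @return logical
#' @export
is_valid_hbond <- function(hydrogen, donor_heavy, acceptor,
                           dist_limit = 2.5, angle_limit = 120) {
  d <- vnorm(acceptor - hydrogen)
  if (d >= dist_limit) return(FALSE)
  vangle(acceptor, hydrogen, donor_heavy) > angle_limit
}

#' Salt-bridge test between a carboxylate and a basic side chain
#'
#' True when any side-chain carboxylate oxygen (OD1/OD2/OE1/OE2) lies within
#' `cutoff` of any charged side-chain nitrogen (NH1/NH2/NE/NZ).
#'
#' @param res_acidic atoms of an ASP or GLU residue
#' @param res_basic atoms of an ARG or LYS residue
#' @param cutoff O...N distance cutoff, 4.0 A
#' @return logical
#' @export
is_salt_bridge <- function(res_acidic, res_basic, cutoff = 4.0) {
  if (!res_acidic$resid[1] %in% c("ASP", "GLU"))
    stop("first residue must be ASP or GLU, got ", res_acidic$resid[1])
  if (!res_basic$resid[1] %in% c("ARG", "LYS"))
    stop("second residue must be ARG or LYS, got ", res_basic$resid[1])
  ox <- res_acidic[res_acidic$elety %in% c("OD1", "OD2", "OE1", "OE2"), ,
                   drop = FALSE]
  nz <- res_basic[res_basic$elety %in% c("NH1", "NH2", "NE", "NZ"), ,
                  drop = FALSE]
  if (nrow(ox) == 0 || nrow(nz) == 0) return(FALSE)
  d2 <- outer(seq_len(nrow(ox)), seq_len(nrow(nz)), Vectorize(function(i, j)
    sum((as.numeric(ox[i, c("x", "y", "z")]) -
         as.numeric(nz[j, c("x", "y", "z")]))^2)))
  any(d2 <= cutoff^2)
}

#' Nonpolar-contact test for a candidate side chain
#'
#' True when at least one candidate C or S atom lies strictly within
#' `cutoff` of an antigen C or S atom.
#'
#' @param candidate_atoms side-chain atom data.frame
#' @param antigen_atoms antigen atom data.frame
#' @param cutoff distance cutoff, 4.5 A
#' @return logical
#' @export
is_nonpolar_contact <- function(candidate_atoms, antigen_atoms, cutoff = 4.5) {
  a <- candidate_atoms[candidate_atoms$element %in% c("C", "S"), ,
                       drop = FALSE]
  b <- antigen_atoms[antigen_atoms$element %in% c("C", "S"), , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) return(FALSE)
  xa <- coords_matrix(a)
  xb <- coords_matrix(b)
  for (i in seq_len(nrow(xa))) {
    d2 <- (xb[, 1] - xa[i, 1])^2 + (xb[, 2] - xa[i, 2])^2 +
          (xb[, 3] - xa[i, 3])^2
    if (any(d2 < cutoff^2)) return(TRUE)
  }
  FALSE
}
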