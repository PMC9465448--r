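# Synthetic test systems with analytically known hydrogen-bond geometry.
# An ideal secondary-structure scaffold carries donor (or acceptor) side
# chains; short capped antigen fragments are placed so that their epitope
# polar atoms sit exactly at the scaffold half-site primary points, giving a
# planted solution group with known ground truth. The whole antigen is then
# displaced by a seeded rigid motion that the docking search must undo.

AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

parse_sequence <- function(sequence) {
  if (length(sequence) == 1 && !sequence %in% AA3) {
    aa <- AA1TO3[strsplit(toupper(sequence), "")[[1]]]
    if (anyNA(aa)) stop("unknown one-letter code in sequence")
    unname(aa)
  } else {
    stopifnot(all(sequence %in% AA3))
    sequence
  }
}

#' Build an idealized polypeptide chain
#'
#' Constructs a chain with ideal backbone geometry at fixed (phi, psi),
#' omega = 180, ideal side chains at the given (or the library's first)
#' rotamer, and polar hydrogens. Purely deterministic.
#'
#' @param sequence one-letter string or vector of 3-letter codes
#' @param phi,psi backbone dihedrals, degrees
#' @param chain chain identifier
#' @param first_resno number of the first residue
#' @param start coordinate of the first N atom
#' @param chi optional list of chi vectors per residue (NULL = library seed
#'   rotamer)
#' @param lib rotamer library (loaded on demand)
#' @return a `protein_structure`
#' @export
make_ideal_chain <- function(sequence, phi = -57, psi = -47, chain = "A",
                             first_resno = 1, start = c(0, 0, 0),
                             chi = NULL, lib = NULL) {
  aa <- parse_sequence(sequence)
  n <- length(aa)
  if (is.null(lib)) lib <- load_rotamer_library()
  # backbone trace
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- start
  CA[1, ] <- start + c(1.458, 0, 0)
  dir1 <- cos(111.2 * pi / 180) * c(-1, 0, 0) +
          sin(111.2 * pi / 180) * c(0, 1, 0)
  C[1, ] <- CA[1, ] + 1.525 * dir1
  for (i in seq_len(n)) {
    if (i < n) {
      N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, psi)
      CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], 1.458, 121.7,
                                180)
      C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], 1.525,
                               111.2, phi)
      O[i, ] <- place_atom(N[i + 1, ], CA[i, ], C[i, ], 1.231, 120.8, 180)
    } else {
      nv <- place_atom(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, psi)
      O[i, ] <- place_atom(nv, CA[i, ], C[i, ], 1.231, 120.8, 180)
    }
  }
  rows <- list()
  for (i in seq_len(n)) {
    for (nm in c("N", "CA", "C", "O")) {
      xyz <- switch(nm, N = N[i, ], CA = CA[i, ], C = C[i, ], O = O[i, ])
      rows[[length(rows) + 1]] <- data.frame(
        chain = chain, resno = first_resno + i - 1, resid = aa[i],
        elety = nm, element = substr(nm, 1, 1),
        x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    }
  }
  s <- new_structure(do.call(rbind, rows), source = "ideal-chain")
  for (i in seq_len(n)) {
    if (aa[i] == "GLY") next
    ch <- if (!is.null(chi) && !is.null(chi[[i]])) chi[[i]]
          else if (n_chi(aa[i]) > 0) rotamer_chi(lib, aa[i], 1)
          else numeric(0)
    placed <- place_rotamer(s, chain, first_resno + i - 1, aa[i], ch)
    s <- replace_residue_atoms(s, chain, first_resno + i - 1,
                               as.data.frame(placed))
  }
  add_hydrogens(s)
}

#' Build an ideal alpha-helix
#'
#' [make_ideal_chain()] at helical dihedrals (phi = -57, psi = -47).
#'
#' @inheritParams make_ideal_chain
#' @export
make_ideal_helix <- function(sequence, chain = "A", first_resno = 1,
                             start = c(0, 0, 0), chi = NULL, lib = NULL) {
  make_ideal_chain(sequence, phi = -57, psi = -47, chain = chain,
                   first_resno = first_resno, start = start, chi = chi,
                   lib = lib)
}

# Rigidly map a fragment so that anchor point `o` lands on `p`, direction
# v1 lands on `u`, and the component of v2 orthogonal to the axis lands on
# `w`.
.frame_place <- function(frag, o, v1, v2, p, u, w) {
  e1 <- vunit(v1)
  e2 <- vunit(v2 - sum(v2 * e1) * e1)
  e3 <- vcross(e1, e2)
  f1 <- vunit(u)
  f2 <- vunit(w - sum(w * f1) * f1)
  f3 <- vcross(f1, f2)
  rot <- cbind(f1, f2, f3) %*% t(cbind(e1, e2, e3))
  transform_structure(frag, list(rotation = rot,
                                 translation = p - as.numeric(rot %*% o)))
}

#' Generate a scaffold/antigen pair with planted hydrogen bonds
#'
#' Builds an ideal-helix scaffold whose hydroxyl side chains (SER by
#' default) provide donor half-sites, and places one short antigen fragment
#' per planted bond so that the fragment's epitope atom sits exactly at the
#' half-site primary point with its antecedent on the half-site axis. At
#' zero noise the planted interactions therefore form a solution group with
#' zero geometric deviations. The assembled antigen is displaced by a
#' seeded random rigid motion; fixture generation is a pure function of its
#' arguments.
#'
#' `n_design` of the planted bonds are provided not by native side chains
#' but by the seed rotamer of `donor_aa` at ALA sites, so that recovering
#' those bonds requires the corresponding design mutations.
#'
#' @param n_bonds number of planted bonds (>= 0)
#' @param donor_aa scaffold residue type providing the planted half-sites
#' @param mode `"scaffold_donor"` plants scaffold hydroxyl donors against
#'   antigen backbone O acceptors; `"scaffold_acceptor"` plants scaffold
#'   hydroxyl-oxygen acceptors against antigen SER hydroxyl donors
#' @param noise per-bond displacement of the fragment placement (A)
#' @param seed integer seed for the noise and the rigid displacement
#' @param n_design how many planted bonds run through design mutations
#' @param fragment_len antigen fragment length (odd; planted residue is the
#'   middle one)
#' @param lib rotamer library
#' @return list with `scaffold`, `antigen` (both protonated), selection
#'   strings `paratope`, `variable`, `epitope`, the ground-truth
#'   `expected` interaction table, and `displacement` (the rigid motion
#'   applied to the antigen)
#' @export
make_planted_complex <- function(n_bonds = 3, donor_aa = "SER",
                                 mode = c("scaffold_donor",
                                          "scaffold_acceptor"),
                                 noise = 0, seed = 1, n_design = 0,
                                 fragment_len = 5, lib = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_bonds >= 0, n_bonds <= 6, noise >= 0, n_design <= n_bonds)
  stopifnot(donor_aa %in% c("SER", "THR", "TYR"))
  if (is.null(lib)) lib <- load_rotamer_library()
  positions <- c(2, 5, 9, 12, 16, 19)[seq_len(max(n_bonds, 1))]
  helix_len <- 20
  aa <- rep("ALA", helix_len)
  design_pos <- if (n_design > 0) positions[seq_len(n_design)] else integer(0)
  native_pos <- setdiff(positions[seq_len(n_bonds)], design_pos)
  aa[native_pos] <- donor_aa
  if (mode == "scaffold_acceptor" && n_design > 0)
    stop("design mutations are only supported in scaffold_donor mode")
  scaffold <- make_ideal_helix(aa, chain = "A", lib = lib)
  if (mode == "scaffold_acceptor") {
    # turn the planted hydroxyls inward (dihedral 0) so the acceptor
    # lone-pair axis of the oxygen faces the solvent
    for (p_site in native_pos) {
      at <- residue_atoms(scaffold, "A", p_site)
      hname <- c(SER = "HG1", THR = "HG1", TYR = "HH")[[donor_aa]]
      oname <- c(SER = "OG", THR = "OG1", TYR = "OH")[[donor_aa]]
      h <- place_atom(atom_coord(at, "CA"), atom_coord(at, "CB"),
                      atom_coord(at, oname), 0.96, 109.5, 0)
      i <- which(scaffold$atom$chain == "A" &
                 scaffold$atom$resno == p_site &
                 scaffold$atom$elety == hname)
      scaffold$atom[i, c("x", "y", "z")] <- as.list(h)
    }
  }
  ctr <- colMeans(coords_matrix(
    scaffold$atom[scaffold$atom$elety == "CA", ]))
  hydroxyl <- c(SER = "HG1", THR = "HG1", TYR = "HH")[[donor_aa]]
  oxy <- c(SER = "OG", THR = "OG1", TYR = "OH")[[donor_aa]]
  rs <- NULL
  if (exists(".Random.seed", envir = globalenv()))
    rs <- get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()))
  set.seed(seed)
  mid <- (fragment_len + 1) %/% 2
  frag_seq_donor <- rep("ALA", fragment_len)
  frag_seq_acc <- replace(rep("ALA", fragment_len), mid, "SER")
  frags <- list()
  expected <- list()
  for (j in seq_len(n_bonds)) {
    p_site <- positions[j]
    res <- if (p_site %in% design_pos)
      place_rotamer(scaffold, "A", p_site, donor_aa,
                    rotamer_chi(lib, donor_aa, 1))
    else residue_atoms(scaffold, "A", p_site)
    if (mode == "scaffold_donor") {
      atom <- atom_coord(res, hydroxyl)
      ant <- atom_coord(res, oxy)
    } else {
      atom <- atom_coord(res, oxy)
      ant <- (atom_coord(res, hydroxyl) + atom_coord(res, "CB")) / 2
    }
    u <- vunit(atom - ant)
    p <- atom + PRIMARY_OFFSET * u
    if (noise > 0) {
      dv <- stats::rnorm(3)
      p <- p + noise * dv / vnorm(dv)
    }
    # run the fragment diagonally across the helix surface: mostly along
    # the axis (so flanking residues lie over the scaffold, giving a
    # protein-sized interface) with a tangential tilt that steers it off
    # the i/i+4 ridge of planted side chains
    ca <- coords_matrix(scaffold$atom[scaffold$atom$elety == "CA", ])
    axis <- vunit(ca[nrow(ca), ] - ca[1, ])
    w0 <- (axis - sum(axis * u) * u) + 0.7 * vcross(u, axis)
    w <- w0 - sum(w0 * u) * u
    if (vnorm(w) < 1e-6) w <- vcross(u, c(0, 0, 1))
    base_resno <- 100 + 20 * j
    if (mode == "scaffold_donor") {
      frag <- make_ideal_chain(frag_seq_donor, phi = -139, psi = 135,
                               chain = "B", first_resno = base_resno,
                               lib = lib)
      mid_at <- residue_atoms(frag, "B", base_resno + mid - 1)
      o <- atom_coord(mid_at, "O")
      frag_ca <- coords_matrix(frag$atom[frag$atom$elety == "CA", ])
      frag_axis <- frag_ca[nrow(frag_ca), ] - frag_ca[1, ]
      frag <- .frame_place(frag, o, atom_coord(mid_at, "C") - o,
                           frag_axis, p, u, vunit(w))
      e_atom <- "O"
    } else {
      frag <- make_ideal_chain(frag_seq_acc, phi = -139, psi = 135,
                               chain = "B", first_resno = base_resno,
                               lib = lib)
      mid_at <- residue_atoms(frag, "B", base_resno + mid - 1)
      o <- atom_coord(mid_at, "HG1")
      frag_ca <- coords_matrix(frag$atom[frag$atom$elety == "CA", ])
      frag_axis <- frag_ca[nrow(frag_ca), ] - frag_ca[1, ]
      frag <- .frame_place(frag, o, atom_coord(mid_at, "OG") - o,
                           frag_axis, p, u, vunit(w))
      e_atom <- "HG1"
    }
    frags[[j]] <- frag
    expected[[j]] <- data.frame(
      scaffold_site = paste0("A:", p_site),
      scaffold_atom = if (mode == "scaffold_donor") hydroxyl else oxy,
      scaffold_aa = donor_aa,
      design = p_site %in% design_pos,
      epitope_site = paste0("B:", base_resno + mid - 1),
      epitope_atom = e_atom, stringsAsFactors = FALSE)
  }
  expected <- if (n_bonds > 0) do.call(rbind, expected) else
    data.frame(scaffold_site = character(0), scaffold_atom = character(0),
               scaffold_aa = character(0), design = logical(0),
               epitope_site = character(0), epitope_atom = character(0))
  antigen <- if (n_bonds > 0) {
    ag <- frags[[1]]
    for (j in seq_len(n_bonds)[-1]) ag <- combine_structures(ag, frags[[j]])
    ag
  } else make_ideal_chain(frag_seq_donor, phi = -139, psi = 135,
                          chain = "B", first_resno = 100, lib = lib)
  # seeded rigid displacement the docking search must undo
  rot <- random_rotation()
  trans <- stats::rnorm(3, sd = 10)
  displacement <- list(rotation = rot, translation = trans)
  antigen <- transform_structure(antigen, displacement)
  antigen$source <- "planted-antigen"
  epitope_keys <- if (n_bonds > 0) expected$epitope_site else
    paste0("B:", 100 + mid - 1)
  list(scaffold = scaffold, antigen = antigen,
       paratope = paste(paste0("A:", positions[seq_len(max(n_bonds, 1))]),
                        collapse = ","),
       variable = if (length(design_pos) > 0)
         paste(paste0("A:", design_pos), collapse = ",") else "",
       epitope = paste(epitope_keys, collapse = ","),
       expected = expected, displacement = displacement,
       mode = mode, seed = seed, noise = noise)
}
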