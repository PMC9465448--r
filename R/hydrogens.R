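# Polar-hydrogen placement at ideal covalent geometry. Only hydrogens that
# define hydrogen-bond half-sites are built (backbone HN plus the side-chain
# donors of the half-site table); apolar hydrogens are left to the user.

#' Add missing polar hydrogens with CHARMM-style names
#'
#' Builds backbone amide `HN` (in the peptide plane, on the reverse bisector
#' of the C(prev)-N-CA angle, N-H 1.0 A) and the side-chain polar hydrogens
#' of each residue type (`HG1`, `HH`, `HD21`, `HH11`, ...) at ideal internal
#' geometry (O-H 0.96 A, N-H 1.0 A; rotatable hydroxyls anti). Existing
#' hydrogens and all heavy atoms are left untouched, so the operation is
#' idempotent. Chain-start residues (including residues after a numbering
#' gap) receive no `HN` because the preceding carbonyl that orients it is
#' absent.
#'
#' @param s a `protein_structure`
#' @return the structure with hydrogens added
#' @export
add_hydrogens <- function(s) {
  rt <- residue_table(s)
  out <- list()
  for (i in seq_len(nrow(rt))) {
    at <- residue_atoms(s, rt$chain[i], rt$resno[i])
    aa <- rt$resid[i]
    new <- at
    # backbone amide hydrogen (not for PRO, not at chain starts)
    prev <- s$atom[s$atom$chain == rt$chain[i] &
                   s$atom$resno == rt$resno[i] - 1 &
                   s$atom$elety == "C", , drop = FALSE]
    if (aa != "PRO" && !any(at$elety %in% c("HN", "H")) && nrow(prev) == 1) {
      n <- atom_coord(at, "N"); ca <- atom_coord(at, "CA")
      cprev <- as.numeric(prev[1, c("x", "y", "z")])
      h <- n + 1.0 * vunit(-(vunit(cprev - n) + vunit(ca - n)))
      new <- rbind(new, atom_row(at, "HN", "H", h))
    }
    if (!aa %in% names(SIDECHAIN_ZMAT)) {
      warning("unknown residue type ", aa, " at ", rt$key[i],
              "; no hydrogens added")
      out[[i]] <- new
      next
    }
    zm <- SIDECHAIN_ZMAT[[aa]]
    if (nrow(zm) > 0) {
      hz <- zm[element_of(zm$name) == "H", , drop = FALSE]
      for (j in seq_len(nrow(hz))) {
        row <- hz[j, ]
        if (row$name %in% new$elety) next
        refs <- lapply(c(row$a, row$b, row$c), atom_coord, res_atoms = new)
        if (any(vapply(refs, is.null, logical(1)))) next
        h <- place_atom(refs[[1]], refs[[2]], refs[[3]],
                        row$bond, row$angle, row$tors)
        new <- rbind(new, atom_row(at, row$name, "H", h))
      }
    }
    out[[i]] <- new
  }
  s$atom <- do.call(rbind, out)
  rownames(s$atom) <- NULL
  s
}

atom_row <- function(res_atoms, name, element, coord) {
  data.frame(chain = res_atoms$chain[1], resno = res_atoms$resno[1],
             resid = res_atoms$resid[1], elety = name, element = element,
             x = coord[1], y = coord[2], z = coord[3],
             stringsAsFactors = FALSE)
}
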