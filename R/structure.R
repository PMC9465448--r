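# Protein structures are stored as a light hierarchy mirroring bio3d: a flat
# atom table plus provenance. One row per atom; residues are identified by
# (chain, resno) and kept in file order.

new_structure <- function(atom, source = "in-memory") {
  needed <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  stopifnot(all(needed %in% names(atom)))
  atom <- as.data.frame(atom)[, needed]
  rownames(atom) <- NULL
  structure(list(atom = atom, source = source), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  keys <- unique(residue_keys(x))
  cat(sprintf("protein_structure: %d atoms, %d residues, chains %s [%s]\n",
              nrow(x$atom), length(keys),
              paste(unique(x$atom$chain), collapse = ","), x$source))
  invisible(x)
}

residue_keys <- function(s) {
  at <- if (inherits(s, "protein_structure")) s$atom else s
  paste0(at$chain, ":", at$resno)
}

# Ordered unique residue table: chain, resno, resid, key.
residue_table <- function(s) {
  at <- s$atom
  keys <- residue_keys(s)
  idx <- !duplicated(keys)
  data.frame(chain = at$chain[idx], resno = at$resno[idx],
             resid = at$resid[idx], key = keys[idx], stringsAsFactors = FALSE)
}

# Atom rows of one residue (data.frame subset, original order).
residue_atoms <- function(s, chain, resno) {
  s$atom[s$atom$chain == chain & s$atom$resno == resno, , drop = FALSE]
}

atom_coord <- function(res_atoms, name) {
  i <- match(name, res_atoms$elety)
  if (is.na(i)) return(NULL)
  as.numeric(res_atoms[i, c("x", "y", "z")])
}

coords_matrix <- function(at) {
  m <- as.matrix(at[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

is_backbone_name <- function(name) name %in% BACKBONE_ATOMS

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (waters and other het groups are excluded), collapses
#' alternate locations to the highest-occupancy copy, and checks that every
#' residue carries a complete N/CA/C backbone.
#'
#' @param path path to a PDB v3.3 file
#' @return a `protein_structure`
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  p <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- p$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  # collapse altLocs: keep the highest-occupancy copy (first wins ties)
  if (any(!is.na(at$alt) & at$alt != "")) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    key <- paste(at$chain, at$resno, at$elety)
    keep <- logical(nrow(at))
    for (k in unique(key)) {
      i <- which(key == k)
      keep[i[which.max(occ[i])]] <- TRUE
    }
    at <- at[keep, , drop = FALSE]
  }
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- element_of(at$elety[bad])
  atom <- data.frame(chain = ifelse(is.na(at$chain), "A", at$chain),
                     resno = at$resno, resid = at$resid, elety = at$elety,
                     element = elem, x = at$x, y = at$y, z = at$z,
                     stringsAsFactors = FALSE)
  dup <- duplicated(paste(atom$chain, atom$resno, atom$elety))
  if (any(dup)) atom <- atom[!dup, , drop = FALSE]
  s <- new_structure(atom, source = path)
  check_backbone(s)
  s
}

check_backbone <- function(s) {
  rt <- residue_table(s)
  for (i in seq_len(nrow(rt))) {
    at <- residue_atoms(s, rt$chain[i], rt$resno[i])
    miss <- setdiff(c("N", "CA", "C"), at$elety)
    if (length(miss) > 0)
      stop(sprintf("residue %s %s is missing backbone atom(s): %s",
                   rt$resid[i], rt$key[i], paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Write a protein structure to a PDB file
#'
#' @param s a `protein_structure`
#' @param path output path
#' @param remarks optional character vector written as REMARK records ahead
#'   of the coordinates
#' @export
write_pdb <- function(s, path, remarks = NULL) {
  at <- s$atom
  xyz <- as.numeric(t(coords_matrix(at)))
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resno,
                   resid = at$resid, chain = at$chain, elety = at$elety,
                   elesy = at$element, o = rep(1, nrow(at)),
                   b = rep(0, nrow(at)))
  if (!is.null(remarks) && length(remarks) > 0) {
    body <- readLines(path)
    writeLines(c(sprintf("REMARK %s", remarks), body), path)
  }
  invisible(path)
}

#' Resolve a residue-selection string against a structure
#'
#' Selection strings list `CHAIN:NUM` tokens or `CHAIN:NUM-NUM` ranges,
#' comma-separated, e.g. `"A:10-12,A:20"`. Duplicates are collapsed.
#'
#' @param s a `protein_structure`
#' @param spec_text selection string (or a character vector of tokens)
#' @param role one of `"paratope"`, `"variable"`, `"epitope"`
#' @return a `residue_selection`: data.frame with `chain`, `resno`, `key`
#'   plus attribute `role`
#' @export
resolve_selection <- function(s, spec_text, role = c("paratope", "variable",
                                                     "epitope")) {
  role <- match.arg(role)
  toks <- unlist(strsplit(paste(spec_text, collapse = ","), ",", fixed = TRUE))
  toks <- trimws(toks[nzchar(trimws(toks))])
  if (length(toks) == 0) {
    sel <- data.frame(chain = character(0), resno = integer(0),
                      key = character(0), stringsAsFactors = FALSE)
    attr(sel, "role") <- role
    class(sel) <- c("residue_selection", "data.frame")
    return(sel)
  }
  parse_tok <- function(tk) {
    m <- regmatches(tk, regexec("^([A-Za-z0-9]):(-?[0-9]+)(?:-([0-9]+))?$", tk))[[1]]
    if (length(m) == 0) stop("malformed selection token: '", tk, "'")
    from <- as.integer(m[3])
    to <- if (m[4] == "") from else as.integer(m[4])
    data.frame(chain = m[2], resno = seq(from, to), stringsAsFactors = FALSE)
  }
  sel <- do.call(rbind, lapply(toks, parse_tok))
  sel$key <- paste0(sel$chain, ":", sel$resno)
  sel <- sel[!duplicated(sel$key), , drop = FALSE]
  missing <- setdiff(sel$key, residue_keys(s))
  if (length(missing) > 0)
    stop("selection names absent residue(s): ", paste(missing, collapse = ", "))
  rownames(sel) <- NULL
  attr(sel, "role") <- role
  class(sel) <- c("residue_selection", "data.frame")
  sel
}

# Check the variable-within-paratope invariant; returns invisibly or errors.
check_selections <- function(paratope, variable) {
  extra <- setdiff(variable$key, paratope$key)
  if (length(extra) > 0)
    stop("variable residues not contained in the paratope: ",
         paste(extra, collapse = ", "))
  invisible(TRUE)
}

# Replace the atoms of one residue (side-chain swap); backbone rows keep
# their original positions in the table, new side-chain atoms follow them.
replace_residue_atoms <- function(s, chain, resno, new_atoms) {
  at <- s$atom
  in_res <- at$chain == chain & at$resno == resno
  if (!any(in_res)) stop("no such residue: ", chain, ":", resno)
  first <- which(in_res)[1]
  before <- at[seq_len(first - 1), , drop = FALSE]
  before <- before[!(before$chain == chain & before$resno == resno), , drop = FALSE]
  after <- if (first < nrow(at))
    at[seq(first, nrow(at)), , drop = FALSE] else at[0, ]
  after <- after[!(after$chain == chain & after$resno == resno), , drop = FALSE]
  s$atom <- rbind(before, new_atoms, after)
  rownames(s$atom) <- NULL
  s
}

# Apply a rigid transform to every atom of a structure.
transform_structure <- function(s, transform) {
  xyz <- apply_transform(coords_matrix(s$atom), transform)
  s$atom$x <- xyz[, 1]
  s$atom$y <- xyz[, 2]
  s$atom$z <- xyz[, 3]
  s
}

# Concatenate two structures (e.g. scaffold + posed antigen).
combine_structures <- function(a, b, source = "complex") {
  new_structure(rbind(a$atom, b$atom), source = source)
}
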