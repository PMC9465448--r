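# Constructed clash scenes for the mutation cascade. The mutable site A:6
# carries PHE; a "blocker" antigen residue holds one carbon exactly at the
# CZ position of every PHE rotamer, so repacking the native type always
# clashes while short candidate side chains stay clear. Additional antigen
# residues then open exactly one rescue route.

scene_lib <- load_rotamer_library()

.blob_row <- function(name, coord, chain = "B", resno = 900,
                      resid = "GLY", element = NULL) {
  if (is.null(element)) element <- scafdock:::element_of(name)
  data.frame(chain = chain, resno = resno, resid = resid, elety = name,
             element = element, x = coord[1], y = coord[2], z = coord[3],
             stringsAsFactors = FALSE)
}

make_cascade_scene <- function(type = c("repack", "salt_asp", "salt_glu",
                                        "polar", "nonpolar",
                                        "irreconcilable", "clean")) {
  type <- match.arg(type)
  aa <- rep("ALA", 11)
  aa[6] <- if (type == "repack") "LEU" else "PHE"
  h <- make_ideal_helix(aa, lib = scene_lib)
  site <- residue_atoms(h, "A", 6)
  ca <- scafdock:::atom_coord(site, "CA")
  cb <- scafdock:::atom_coord(site, "CB")
  out_dir <- scafdock:::vunit(cb - ca)
  rows <- list()
  if (type == "repack") {
    # block only the native rotamer's distal atom; rotamer 2 stays free
    p1 <- place_rotamer(h, "A", 6, "LEU",
                        scafdock:::rotamer_chi(scene_lib, "LEU", 1))
    rows[[1]] <- .blob_row("C1", scafdock:::atom_coord(p1, "CD1"))
  } else if (type != "clean") {
    for (i in seq_len(nrow(scene_lib$PHE))) {
      p <- place_rotamer(h, "A", 6, "PHE",
                         scafdock:::rotamer_chi(scene_lib, "PHE", i))
      rows[[length(rows) + 1]] <-
        .blob_row(paste0("C", i), scafdock:::atom_coord(p, "CZ"))
    }
  }
  if (type == "salt_asp") {
    # first ASP rotamer whose amine placement clears the scaffold
    heavy <- as.matrix(h$atom[h$atom$element != "H", c("x", "y", "z")])
    nz <- NULL
    for (i in seq_len(nrow(scene_lib$ASP))) {
      asp <- place_rotamer(h, "A", 6, "ASP",
                           scafdock:::rotamer_chi(scene_lib, "ASP", i))
      od1 <- scafdock:::atom_coord(asp, "OD1")
      cand <- od1 + 3.0 * scafdock:::vunit(od1 - ca)
      if (min(sqrt(rowSums(sweep(heavy, 2, cand)^2))) > 3.0) {
        nz <- cand
        break
      }
    }
    stopifnot(!is.null(nz))
    ctr <- colMeans(as.matrix(h$atom[h$atom$elety == "CA",
                                     c("x", "y", "z")]))
    tail_dir <- scafdock:::vunit(nz - ctr)
    rows[[length(rows) + 1]] <- .blob_row("NZ", nz, resno = 910,
                                          resid = "LYS")
    for (k in seq_along(c("CE", "CD", "CG", "CB", "CA", "N", "C")))
      rows[[length(rows) + 1]] <-
        .blob_row(c("CE", "CD", "CG", "CB", "CA", "N", "C")[k],
                  nz + (1.4 * k) * tail_dir, resno = 910, resid = "LYS")
  }
  if (type == "salt_glu") {
    # a LYS amine reachable by GLU but at least 4 A from every ASP oxygen
    asp_o <- list()
    for (i in seq_len(nrow(scene_lib$ASP))) {
      p <- place_rotamer(h, "A", 6, "ASP",
                         scafdock:::rotamer_chi(scene_lib, "ASP", i))
      asp_o[[length(asp_o) + 1]] <- scafdock:::atom_coord(p, "OD1")
      asp_o[[length(asp_o) + 1]] <- scafdock:::atom_coord(p, "OD2")
    }
    nz <- NULL
    for (i in seq_len(nrow(scene_lib$GLU))) {
      p <- place_rotamer(h, "A", 6, "GLU",
                         scafdock:::rotamer_chi(scene_lib, "GLU", i))
      oe1 <- scafdock:::atom_coord(p, "OE1")
      cand <- oe1 + 3.0 * scafdock:::vunit(oe1 - ca)
      if (min(vapply(asp_o, function(o) sqrt(sum((o - cand)^2)),
                     numeric(1))) > 4.2) {
        nz <- cand
        break
      }
    }
    stopifnot(!is.null(nz))
    ctr <- colMeans(as.matrix(h$atom[h$atom$elety == "CA",
                                     c("x", "y", "z")]))
    tail_dir <- scafdock:::vunit(nz - ctr)
    rows[[length(rows) + 1]] <- .blob_row("NZ", nz, resno = 910,
                                          resid = "LYS")
    for (k in seq_along(c("CE", "CD", "CG", "CB", "CA", "N", "C")))
      rows[[length(rows) + 1]] <-
        .blob_row(c("CE", "CD", "CG", "CB", "CA", "N", "C")[k],
                  nz + (1.4 * k) * tail_dir, resno = 910, resid = "LYS")
  }
  if (type == "polar") {
    ser <- place_rotamer(h, "A", 6, "SER",
                         scafdock:::rotamer_chi(scene_lib, "SER", 1))
    hg1 <- scafdock:::atom_coord(ser, "HG1")
    og <- scafdock:::atom_coord(ser, "OG")
    u <- scafdock:::vunit(hg1 - og)
    acc <- hg1 + 1.25 * u
    rows[[length(rows) + 1]] <- .blob_row("O", acc, resno = 920)
    rows[[length(rows) + 1]] <- .blob_row("C", acc + 1.4 * u, resno = 920)
    rows[[length(rows) + 1]] <- .blob_row("CA", acc + 2.9 * u, resno = 920)
    rows[[length(rows) + 1]] <- .blob_row("N", acc + 4.3 * u, resno = 920)
  }
  if (type == "nonpolar") {
    rows[[length(rows) + 1]] <- .blob_row("C9", cb + 4.0 * out_dir,
                                          resno = 930)
  }
  if (type == "irreconcilable") {
    rows[[length(rows) + 1]] <- .blob_row("C9", cb + 1.2 * out_dir,
                                          resno = 930)
  }
  antigen <- scafdock:::new_structure(
    if (length(rows) > 0) do.call(rbind, rows) else
      .blob_row("C1", c(50, 50, 50)), source = "scene-antigen")
  pose <- list(
    group = NULL, transform = list(rotation = diag(3),
                                   translation = c(0, 0, 0)),
    superposition_rmsd = 0, scaffold_state = h, antigen_state = antigen,
    pbrs = NULL, ebas = NULL, variable_keys = "A:6",
    group_sites = character(0), hbonds = NULL,
    clash_records = if (type == "clean")
      data.frame(key_a = character(0), key_b = character(0),
                 backbone_a = logical(0))
    else data.frame(key_a = "A:6", key_b = "B:900", backbone_a = FALSE),
    mutations = scafdock:::bind_records(list()),
    status = "accepted", reason = NA_character_)
  class(pose) <- "dock_pose"
  pose
}
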