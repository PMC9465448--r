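# Clash-rescue mutation cascade. Variable paratope residues that still
# clash after posing are rescued, in ascending residue order, by the first
# of: (1) an alternate rotamer of the current amino acid, (2) an ASP or
# (3) a GLU rotamer forming a salt bridge with an unclaimed antigen ARG/LYS,
# (4) a polar rotamer (SER, THR, ASN, ASP, HIS, in that order) forming the
# required number of hydrogen bonds, (5) a nonpolar rotamer (ALA, VAL, LEU,
# ILE, PHE) making a nonpolar contact. If all fail the pose is rejected as
# an irreconcilable steric clash. ARG, LYS, MET, TRP, TYR, GLN and GLU
# (outside the salt-bridge step) are never introduced.

# Residues of `s` (excluding `skip_key`) with any heavy atom within
# `radius` of point `ctr`.
.nearby_residues <- function(s, ctr, radius, skip_key = NULL) {
  at <- .heavy(s$atom)
  d2 <- (at$x - ctr[1])^2 + (at$y - ctr[2])^2 + (at$z - ctr[3])^2
  keys <- unique(residue_keys(at)[d2 <= radius^2])
  setdiff(keys, skip_key)
}

.site_center <- function(state, chain, resno) {
  at <- residue_atoms(state, chain, resno)
  cb <- atom_coord(at, "CB")
  if (is.null(cb)) cb <- atom_coord(at, "CA")
  cb
}

# Clash test of a candidate residue against surrounding scaffold and
# antigen residues (peptide-bond pairs of sequence neighbours excluded).
.candidate_clash_free <- function(placed, state, antigen, nb_scaffold,
                                  nb_antigen, config) {
  for (k in nb_scaffold) {
    part <- strsplit(k, ":", fixed = TRUE)[[1]]
    other <- residue_atoms(state, part[1], as.integer(part[2]))
    excl <- NULL
    if (part[1] == placed$chain[1]) {
      dr <- as.integer(part[2]) - placed$resno[1]
      if (dr == 1) excl <- cbind("C", "N")
      if (dr == -1) excl <- cbind("N", "C")
    }
    if (detect_clash(placed, other, config, exclude = excl)) return(FALSE)
  }
  for (k in nb_antigen) {
    part <- strsplit(k, ":", fixed = TRUE)[[1]]
    other <- residue_atoms(antigen, part[1], as.integer(part[2]))
    if (detect_clash(placed, other, config)) return(FALSE)
  }
  TRUE
}

#' Cascade step 1: repack the current amino acid
#'
#' First library rotamer of the residue's current type that is free of
#' steric clash against all surrounding antigen and scaffold residues.
#'
#' @param site `chain:resno` key
#' @param pose a `dock_pose`
#' @param lib rotamer library
#' @param config a [match_config()]
#' @return list(aa, rotamer, placed, evidence) or `NULL`
#' @export
step1_repack <- function(site, pose, lib, config = match_config()) {
  ctx <- .site_context(site, pose, config)
  aa <- ctx$current_aa
  if (n_chi(aa) == 0) return(NULL)  # nothing to repack
  for (idx in seq_len(nrow(lib[[aa]]))) {
    placed <- place_rotamer(pose$scaffold_state, ctx$chain, ctx$resno, aa,
                            rotamer_chi(lib, aa, idx))
    if (.candidate_clash_free(placed, pose$scaffold_state,
                              pose$antigen_state, ctx$nb_scaffold,
                              ctx$nb_antigen, config))
      return(list(aa = aa, rotamer = idx, placed = placed,
                  evidence = "clash-free rotamer"))
  }
  NULL
}

#' Cascade steps 2-3: salt-bridge mutation
#'
#' First clash-free ASP rotamer forming a salt bridge with an antigen
#' ARG/LYS not already claimed in this pose; failing that, the first such
#' GLU rotamer. ASP is preferred for its smaller, lower-entropy side chain.
#'
#' @inheritParams step1_repack
#' @param claimed character vector of antigen residue keys already engaged
#'   in a rescue salt bridge
#' @return list(aa, rotamer, placed, partner, evidence) or `NULL`
#' @export
step2_3_salt_bridge <- function(site, pose, lib, claimed = character(0),
                                config = match_config()) {
  ctx <- .site_context(site, pose, config)
  basic <- ctx$nb_antigen_atoms
  basic_keys <- unique(residue_keys(basic)[basic$resid %in% c("ARG", "LYS")])
  basic_keys <- setdiff(basic_keys, claimed)
  if (length(basic_keys) == 0) return(NULL)
  for (aa in c("ASP", "GLU")) {
    for (idx in seq_len(nrow(lib[[aa]]))) {
      placed <- place_rotamer(pose$scaffold_state, ctx$chain, ctx$resno, aa,
                              rotamer_chi(lib, aa, idx))
      if (!.candidate_clash_free(placed, pose$scaffold_state,
                                 pose$antigen_state, ctx$nb_scaffold,
                                 ctx$nb_antigen, config)) next
      for (k in basic_keys) {
        part <- strsplit(k, ":", fixed = TRUE)[[1]]
        other <- residue_atoms(pose$antigen_state, part[1],
                               as.integer(part[2]))
        if (is_salt_bridge(placed, other, config$salt_bridge_dist))
          return(list(aa = aa, rotamer = idx, placed = placed, partner = k,
                      evidence = paste0("salt bridge with ", k)))
      }
    }
  }
  NULL
}

#' Cascade step 4: polar hydrogen-bonding mutation
#'
#' Searches SER, THR, ASN, ASP, HIS in order for the first clash-free
#' rotamer whose side chain forms the required number of valid hydrogen
#' bonds with the antigen: one for SER/THR, two for ASN/ASP/HIS. An ASN
#' rotamer with a single bond is accepted when its partner is an antigen
#' backbone atom. GLN and GLU are never considered here.
#'
#' @inheritParams step1_repack
#' @return list(aa, rotamer, placed, n_hbonds, evidence) or `NULL`
#' @export
step4_polar <- function(site, pose, lib, config = match_config()) {
  ctx <- .site_context(site, pose, config)
  for (aa in CASCADE_POLAR) {
    need <- CASCADE_POLAR_MIN_HBONDS[[aa]]
    for (idx in seq_len(nrow(lib[[aa]]))) {
      placed <- place_rotamer(pose$scaffold_state, ctx$chain, ctx$resno, aa,
                              rotamer_chi(lib, aa, idx))
      if (!.candidate_clash_free(placed, pose$scaffold_state,
                                 pose$antigen_state, ctx$nb_scaffold,
                                 ctx$nb_antigen, config)) next
      hb <- .count_sidechain_hbonds(placed, aa, pose$antigen_state,
                                    ctx$nb_antigen, config)
      ok <- nrow(hb) >= need ||
        (aa == "ASN" && nrow(hb) == 1 && all(hb$partner_bb))
      if (ok)
        return(list(aa = aa, rotamer = idx, placed = placed,
                    n_hbonds = nrow(hb),
                    evidence = paste0(nrow(hb), " H-bond(s) with ",
                                      paste(unique(hb$partner),
                                            collapse = ","))))
    }
  }
  NULL
}

#' Cascade step 5: nonpolar packing mutation
#'
#' First clash-free rotamer of ALA, VAL, LEU, ILE or PHE (in that order)
#' whose side chain makes at least one nonpolar contact (C/S atom within
#' 4.5 A of an antigen C/S atom). MET, TRP and TYR are excluded.
#'
#' @inheritParams step1_repack
#' @return list(aa, rotamer, placed, evidence) or `NULL`
#' @export
step5_nonpolar <- function(site, pose, lib, config = match_config()) {
  ctx <- .site_context(site, pose, config)
  if (nrow(ctx$nb_antigen_atoms) == 0) return(NULL)
  for (aa in CASCADE_NONPOLAR) {
    n_rot <- max(1L, nrow(lib[[aa]]))
    for (idx in seq_len(n_rot)) {
      chi <- if (n_chi(aa) > 0) rotamer_chi(lib, aa, idx) else numeric(0)
      placed <- place_rotamer(pose$scaffold_state, ctx$chain, ctx$resno, aa,
                              chi)
      if (!.candidate_clash_free(placed, pose$scaffold_state,
                                 pose$antigen_state, ctx$nb_scaffold,
                                 ctx$nb_antigen, config)) next
      sc <- placed[!is_backbone_name(placed$elety), , drop = FALSE]
      if (is_nonpolar_contact(sc, ctx$nb_antigen_atoms,
                              config$nonpolar_dist))
        return(list(aa = aa, rotamer = idx, placed = placed,
                    evidence = "nonpolar contact"))
    }
  }
  NULL
}

#' Rescue clashing variable residues of a pose
#'
#' Applies the six-step cascade to every clashing variable residue in
#' ascending residue order; earlier rescues are visible to later sites. On
#' success the pose carries the applied clash mutations; if any site
#' exhausts steps 1-5 the pose is rejected with an irreconcilable clash.
#'
#' @param pose an accepted `dock_pose` with possibly non-empty
#'   `clash_records`
#' @param lib rotamer library
#' @param config a [match_config()]
#' @return the finalized pose
#' @export
resolve_clashes <- function(pose, lib, config = match_config()) {
  if (nrow(pose$clash_records) == 0) return(pose)
  sites <- unique(pose$clash_records$key_a)
  parts <- do.call(rbind, strsplit(sites, ":", fixed = TRUE))
  sites <- sites[order(parts[, 1], as.integer(parts[, 2]))]
  claimed <- character(0)
  for (site in sites) {
    ctx <- .site_context(site, pose, config)
    cur <- residue_atoms(pose$scaffold_state, ctx$chain, ctx$resno)
    if (.candidate_clash_free(cur, pose$scaffold_state, pose$antigen_state,
                              ctx$nb_scaffold, ctx$nb_antigen, config))
      next  # resolved as a side effect of an earlier rescue
    from <- cur$resid[1]
    res <- step1_repack(site, pose, lib, config)
    step <- 1L
    if (is.null(res)) {
      res <- step2_3_salt_bridge(site, pose, lib, claimed, config)
      step <- if (!is.null(res) && res$aa == "GLU") 3L else 2L
      if (!is.null(res)) claimed <- c(claimed, res$partner)
    }
    if (is.null(res)) {
      res <- step4_polar(site, pose, lib, config)
      step <- 4L
    }
    if (is.null(res)) {
      res <- step5_nonpolar(site, pose, lib, config)
      step <- 5L
    }
    if (is.null(res)) {
      pose$status <- "rejected"
      pose$reason <- "irreconcilable_clash"
      return(pose)
    }
    pose$scaffold_state <- replace_residue_atoms(
      pose$scaffold_state, ctx$chain, ctx$resno, as.data.frame(res$placed))
    pose$mutations <- rbind(pose$mutations, data.frame(
      site = site, from_aa = from, to_aa = res$aa, kind = "clash",
      cascade_step = step, evidence = res$evidence, stringsAsFactors = FALSE))
  }
  pose$clash_records <- pose$clash_records[0, ]
  pose
}

# Site context: coordinates, neighbourhood keys and atoms.
.site_context <- function(site, pose, config) {
  part <- strsplit(site, ":", fixed = TRUE)[[1]]
  chain <- part[1]
  resno <- as.integer(part[2])
  ctr <- .site_center(pose$scaffold_state, chain, resno)
  nb_s <- .nearby_residues(pose$scaffold_state, ctr, config$neighbor_radius,
                           skip_key = site)
  nb_a <- .nearby_residues(pose$antigen_state, ctr, config$neighbor_radius)
  at_a <- pose$antigen_state$atom
  nb_atoms <- at_a[residue_keys(at_a) %in% nb_a, , drop = FALSE]
  cur <- residue_atoms(pose$scaffold_state, chain, resno)
  list(chain = chain, resno = resno, center = ctr, nb_scaffold = nb_s,
       nb_antigen = nb_a, nb_antigen_atoms = nb_atoms,
       current_aa = cur$resid[1])
}

# Valid hydrogen bonds between a placed side chain and nearby antigen
# residues (geometric criterion only). One row per valid donor/acceptor
# pair; `partner_bb` marks antigen backbone partners.
.count_sidechain_hbonds <- function(placed, aa, antigen, nb_antigen,
                                    config) {
  tab <- HALF_SITE_TABLE
  own <- tab[tab$aa == aa & tab$atom %in% placed$elety, , drop = FALSE]
  rows <- list()
  for (k in nb_antigen) {
    part <- strsplit(k, ":", fixed = TRUE)[[1]]
    other <- residue_atoms(antigen, part[1], as.integer(part[2]))
    orows <- half_site_rows_for(other, other$resid[1])
    for (i in seq_len(nrow(own))) for (j in seq_len(nrow(orows))) {
      mine_h <- element_of(own$atom[i]) == "H"
      theirs_h <- element_of(orows$atom[j]) == "H"
      if (mine_h == theirs_h) next
      a1 <- atom_coord(placed, own$atom[i])
      ant1 <- antecedent_point(placed, own[i, ])
      a2 <- atom_coord(other, orows$atom[j])
      ant2 <- antecedent_point(other, orows[j, ])
      if (is.null(a1) || is.null(ant1) || is.null(a2) || is.null(ant2)) next
      ok <- if (mine_h)
        is_valid_hbond(a1, ant1, a2, config$hbond_dist, config$hbond_angle)
      else
        is_valid_hbond(a2, ant2, a1, config$hbond_dist, config$hbond_angle)
      if (ok)
        rows[[length(rows) + 1]] <- data.frame(
          own_atom = own$atom[i], partner = k, partner_atom = orows$atom[j],
          partner_bb = orows$atom[j] %in% c("O", "OT1", "OT2", "HN", "HN1",
                                            "HN2", "HN3"),
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(own_atom = character(0), partner = character(0),
                      partner_atom = character(0), partner_bb = logical(0)))
  do.call(rbind, rows)
}
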