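# Pose realization and filtering: rigid superposition of the antigen onto a
# solution group's primary points, installation of design rotamers on the
# fixed scaffold backbone, heavy-atom steric-clash tests, the coarse-grained
# sphere filter, and all-atom validation of the designed hydrogen bonds.

#' Superpose the antigen onto a solution group
#'
#' Least-squares rigid transform (Kabsch) mapping the epitope half-site
#' primary atoms onto their matched scaffold primary points.
#'
#' @param group a `solution_group`
#' @param pbrs,ebas half-site tables
#' @return list with `transform` (rotation + translation) and `rmsd` (A)
#' @export
superpose <- function(group, pbrs, ebas) {
  pbrs <- ensure_ids(pbrs)
  ebas <- ensure_ids(ebas)
  pi_ <- match(group$interactions$pbr, pbrs$id)
  ei_ <- match(group$interactions$eba, ebas$id)
  if (anyNA(pi_) || anyNA(ei_)) stop("group refers to unknown half-sites")
  x <- as.matrix(ebas[ei_, c("px", "py", "pz")])
  y <- as.matrix(pbrs[pi_, c("px", "py", "pz")])
  fit <- kabsch(x, y)
  list(transform = list(rotation = fit$rotation,
                        translation = fit$translation),
       rmsd = fit$rmsd)
}

# Heavy-atom coordinates and backbone flags of a residue.
.heavy <- function(res_atoms) {
  res_atoms[res_atoms$element != "H", , drop = FALSE]
}

#' Steric clash between two residues
#'
#' Hydrogens are ignored. A clash exists when (1) any heavy-atom pair is
#' closer than `clash_hard` (1.3 A), (2) more than one pair is closer than
#' `clash_soft` (1.8 A), or (3) exactly one pair is closer than `clash_soft`
#' and it involves a backbone atom. `exclude` names atom pairs (A-side,
#' B-side) to skip, used for the peptide bond between sequence neighbours.
#'
#' @param res_a,res_b residue atom data.frames
#' @param config a [match_config()]
#' @param exclude optional 2-column character matrix of atom-name pairs
#' @return logical
#' @export
detect_clash <- function(res_a, res_b, config = match_config(),
                         exclude = NULL) {
  a <- .heavy(res_a)
  b <- .heavy(res_b)
  if (nrow(a) == 0 || nrow(b) == 0) return(FALSE)
  xa <- coords_matrix(a)
  xb <- coords_matrix(b)
  d2 <- outer(rowSums(xa^2), rep(1, nrow(xb))) +
        outer(rep(1, nrow(xa)), rowSums(xb^2)) - 2 * xa %*% t(xb)
  if (!is.null(exclude)) {
    for (r in seq_len(nrow(exclude))) {
      ii <- which(a$elety == exclude[r, 1])
      jj <- which(b$elety == exclude[r, 2])
      if (length(ii) && length(jj)) d2[ii, jj] <- Inf
    }
  }
  if (any(d2 < config$clash_hard^2)) return(TRUE)
  close <- d2 < config$clash_soft^2
  n_close <- sum(close)
  if (n_close > 1) return(TRUE)
  if (n_close == 1) {
    ij <- which(close, arr.ind = TRUE)
    return(is_backbone_name(a$elety[ij[1, 1]]) ||
           is_backbone_name(b$elety[ij[1, 2]]))
  }
  FALSE
}

# Residue-pair clash scan between two structures. Returns a data.frame of
# clashing pairs with a flag for whether the A-side backbone alone already
# clashes (i.e. the clash cannot be removed by mutating A's side chain).
# With `adjacency = TRUE` (intra-scaffold scans) the peptide-bond atom pair
# of sequence neighbours is excluded.
scan_clashes <- function(str_a, str_b, config = match_config(),
                         adjacency = FALSE, keys_a = NULL) {
  rta <- residue_table(str_a)
  rtb <- residue_table(str_b)
  if (!is.null(keys_a)) rta <- rta[rta$key %in% keys_a, , drop = FALSE]
  prof <- function(s, rt) {
    lapply(seq_len(nrow(rt)), function(i) {
      at <- .heavy(residue_atoms(s, rt$chain[i], rt$resno[i]))
      xyz <- coords_matrix(at)
      ctr <- colMeans(xyz)
      list(at = at, ctr = ctr, rad = sqrt(max(rowSums(sweep(xyz, 2, ctr)^2))))
    })
  }
  pa <- prof(str_a, rta)
  pb <- prof(str_b, rtb)
  hits <- list()
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    if (rta$key[i] == rtb$key[j]) next
    lim <- pa[[i]]$rad + pb[[j]]$rad + config$clash_soft
    if (sum((pa[[i]]$ctr - pb[[j]]$ctr)^2) > lim^2) next
    excl <- NULL
    if (adjacency && rta$chain[i] == rtb$chain[j]) {
      if (rtb$resno[j] - rta$resno[i] == 1) excl <- cbind("C", "N")
      if (rta$resno[i] - rtb$resno[j] == 1) excl <- cbind("N", "C")
    }
    if (detect_clash(pa[[i]]$at, pb[[j]]$at, config, exclude = excl)) {
      bb <- pa[[i]]$at[is_backbone_name(pa[[i]]$at$elety), , drop = FALSE]
      hits[[length(hits) + 1]] <- data.frame(
        key_a = rta$key[i], key_b = rtb$key[j],
        backbone_a = detect_clash(bb, pb[[j]]$at, config, exclude = excl),
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(key_a = character(0), key_b = character(0),
                      backbone_a = logical(0)))
  do.call(rbind, hits)
}

#' Coarse-grained bounding spheres of a structure
#'
#' Each residue is split into a backbone and a side-chain unit; every unit
#' is a sphere at the heavy-atom center of mass with radius equal to the
#' distance of the farthest atom from that center.
#'
#' @param s a `protein_structure`
#' @return data.frame with `key`, `unit`, center coordinates and `r`
#' @export
coarse_spheres <- function(s) {
  rt <- residue_table(s)
  out <- list()
  for (i in seq_len(nrow(rt))) {
    at <- .heavy(residue_atoms(s, rt$chain[i], rt$resno[i]))
    for (unit in c("backbone", "sidechain")) {
      sub <- at[is_backbone_name(at$elety) == (unit == "backbone"), ,
                drop = FALSE]
      if (nrow(sub) == 0) next
      xyz <- coords_matrix(sub)
      ctr <- colMeans(xyz)
      out[[length(out) + 1]] <- data.frame(
        key = rt$key[i], unit = unit, cx = ctr[1], cy = ctr[2], cz = ctr[3],
        r = sqrt(max(rowSums(sweep(xyz, 2, ctr)^2))),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Coarse-grained interface filter
#'
#' Rejects a pose as a major clash when any scaffold-antigen sphere pair
#' violates the minimum-separation rule (default: center distance below
#' r1 + r2 - 3.39 A), and as a small interface when fewer than
#' `min_sphere_contacts` sphere pairs are in contact (center distance within
#' r1 + r2 + `contact_pad`).
#'
#' @param scaffold_state,antigen_state the two posed structures
#' @param config a [match_config()]
#' @return list with `status` ("pass" or "reject"), `reason` and
#'   `n_contacts`
#' @export
coarse_filter <- function(scaffold_state, antigen_state,
                          config = match_config()) {
  sa <- coarse_spheres(scaffold_state)
  sb <- coarse_spheres(antigen_state)
  ca <- as.matrix(sa[, c("cx", "cy", "cz")])
  cb <- as.matrix(sb[, c("cx", "cy", "cz")])
  d <- sqrt(outer(rowSums(ca^2), rep(1, nrow(cb))) +
            outer(rep(1, nrow(ca)), rowSums(cb^2)) - 2 * ca %*% t(cb))
  rsum <- outer(sa$r, sb$r, "+")
  min_allowed <- if (config$sphere_rule == "overlap")
    rsum - config$sphere_gap else config$sphere_gap
  if (any(d < min_allowed))
    return(list(status = "reject", reason = "coarse_clash",
                n_contacts = NA_integer_))
  n_contacts <- sum(d <= rsum + config$contact_pad)
  if (n_contacts < config$min_sphere_contacts)
    return(list(status = "reject", reason = "small_interface",
                n_contacts = n_contacts))
  list(status = "pass", reason = NA_character_, n_contacts = n_contacts)
}

#' Install a solution group's design rotamers on the scaffold
#'
#' Places every non-native rotamer used by the group (mutations and
#' repacked native side chains) on the fixed backbone, then checks the
#' placed rotamers for steric clashes against each other and against all
#' scaffold residues that cannot change (non-variable residues and the
#' group's own sites). Clashes against other variable residues are recorded
#' for the mutation stage instead of causing rejection.
#'
#' @param scaffold a `protein_structure`
#' @param group a `solution_group`
#' @param lib rotamer library
#' @param variable a `residue_selection` of mutable paratope residues
#' @param config a [match_config()]
#' @return list with `state` (mutated scaffold), `rejected`, `reason`,
#'   `clash_records` (variable residues left for rescue) and
#'   `design_records` (mutations applied)
#' @export
install_design_rotamers <- function(scaffold, group, lib, variable,
                                    config = match_config()) {
  sites <- names(group$rotamers)
  state <- scaffold
  design_records <- list()
  rt <- residue_table(scaffold)
  for (site in sites) {
    i <- match(site, rt$key)
    aa <- group$rotamer_aa[[site]]
    chi <- rotamer_chi(lib, aa, group$rotamers[[site]])
    placed <- place_rotamer(state, rt$chain[i], rt$resno[i], aa, chi)
    state <- replace_residue_atoms(state, rt$chain[i], rt$resno[i],
                                   as.data.frame(placed))
    from <- rt$resid[i]
    if (from != aa)
      design_records[[length(design_records) + 1]] <- data.frame(
        site = site, from_aa = from, to_aa = aa, kind = "design",
        cascade_step = NA_integer_, evidence = "designed H-bond",
        stringsAsFactors = FALSE)
  }
  clash_records <- data.frame(key_a = character(0), key_b = character(0),
                              backbone_a = logical(0))
  if (length(sites) > 0) {
    hits <- scan_clashes(state, state, config, adjacency = TRUE,
                         keys_a = sites)
    if (nrow(hits) > 0) {
      group_sites <- unique(pose_group_sites(group))
      partner_variable <- hits$key_b %in% variable$key &
        !(hits$key_b %in% group_sites)
      if (any(!partner_variable))
        return(list(state = state, rejected = TRUE,
                    reason = "rotamer_clash",
                    clash_records = clash_records,
                    design_records = bind_records(design_records)))
      clash_records <- data.frame(key_a = hits$key_b[partner_variable],
                                  key_b = hits$key_a[partner_variable],
                                  backbone_a = FALSE)
    }
  }
  list(state = state, rejected = FALSE, reason = NA_character_,
       clash_records = clash_records,
       design_records = bind_records(design_records))
}

bind_records <- function(lst) {
  if (length(lst) == 0)
    return(data.frame(site = character(0), from_aa = character(0),
                      to_aa = character(0), kind = character(0),
                      cascade_step = integer(0), evidence = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lst)
}

# Scaffold sites participating in a group (designed H-bond residues).
pose_group_sites <- function(group) {
  group$sites
}

#' Validate a posed complex
#'
#' Re-checks every designed hydrogen bond on realized coordinates and scans
#' all scaffold-antigen residue pairs for steric clashes. Clashes involving
#' the scaffold backbone, a non-variable side chain, or a residue forming a
#' designed bond reject the pose; clashes confined to the side chains of
#' other variable residues are recorded for the mutation stage.
#'
#' @param pose a `dock_pose` (from `realize_group`) that passed the coarse
#'   filter
#' @param config a [match_config()]
#' @return the pose with `hbonds`, `clash_records` and `status` updated
#' @export
validate_pose <- function(pose, config = match_config()) {
  hb <- realized_hbonds(pose, config)
  pose$hbonds <- hb
  if (any(!hb$valid)) {
    pose$status <- "rejected"
    pose$reason <- "hbond_fail"
    return(pose)
  }
  hits <- scan_clashes(pose$scaffold_state, pose$antigen_state, config)
  if (nrow(hits) > 0) {
    protected <- !(hits$key_a %in% pose$variable_keys) |
      hits$key_a %in% pose$group_sites | hits$backbone_a
    if (any(protected)) {
      pose$status <- "rejected"
      pose$reason <- "clash_fixed"
      return(pose)
    }
    pose$clash_records <- unique(rbind(pose$clash_records, hits))
  }
  pose$status <- "accepted"
  pose
}

# Realized geometry of each designed bond (scaffold frame).
realized_hbonds <- function(pose, config = match_config()) {
  pbrs <- pose$pbrs
  ebas <- pose$ebas
  tr <- pose$transform
  rows <- list()
  for (r in seq_len(nrow(pose$group$interactions))) {
    p <- pbrs[match(pose$group$interactions$pbr[r], pbrs$id), ]
    e <- ebas[match(pose$group$interactions$eba[r], ebas$id), ]
    e_atom <- as.numeric(apply_transform(rbind(c(e$ax, e$ay, e$az)), tr))
    e_ant <- as.numeric(apply_transform(rbind(c(e$antx, e$anty, e$antz)), tr))
    if (p$polarity == "donor") {
      h <- c(p$ax, p$ay, p$az); donor <- c(p$antx, p$anty, p$antz)
      acceptor <- e_atom
    } else {
      h <- e_atom; donor <- e_ant
      acceptor <- c(p$ax, p$ay, p$az)
    }
    rows[[r]] <- data.frame(
      pbr = p$id, eba = e$id, scaffold_site = p$key, epitope_site = e$key,
      scaffold_atom = p$atom, epitope_atom = e$atom,
      dist = vnorm(acceptor - h),
      angle = vangle(acceptor, h, donor),
      valid = is_valid_hbond(h, donor, acceptor, config$hbond_dist,
                             config$hbond_angle))
  }
  do.call(rbind, rows)
}

#' Write a pose as a multi-chain PDB file
#'
#' Scaffold chains followed by the transformed antigen chains, preceded by
#' REMARK records listing the designed hydrogen bonds and all mutations.
#'
#' @param pose an accepted `dock_pose`
#' @param path output path
#' @export
write_pose_pdb <- function(pose, path) {
  remarks <- c(
    sprintf("scafdock pose: %d designed H-bonds, status %s",
            nrow(pose$hbonds), pose$status),
    sprintf("HBOND %s %s -- %s %s  dist %.2f A angle %.1f deg",
            pose$hbonds$scaffold_site, pose$hbonds$scaffold_atom,
            pose$hbonds$epitope_site, pose$hbonds$epitope_atom,
            pose$hbonds$dist, pose$hbonds$angle))
  if (nrow(pose$mutations) > 0)
    remarks <- c(remarks,
      sprintf("MUTATION %s %s->%s (%s%s)", pose$mutations$site,
              pose$mutations$from_aa, pose$mutations$to_aa,
              pose$mutations$kind,
              ifelse(is.na(pose$mutations$cascade_step), "",
                     paste0(" step ", pose$mutations$cascade_step))))
  cplx <- combine_structures(pose$scaffold_state, pose$antigen_state,
                             source = "pose")
  write_pdb(cplx, path, remarks = remarks)
}
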