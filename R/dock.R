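# End-to-end docking driver: build scaffold half-sites (native residues
# plus diverse rotamers of polar mutations at variable sites), epitope
# half-sites of exposed residues, enumerate compatible couples, expand them
# into solution groups, and realize each group as a filtered, mutated pose.

#' Build the scaffold half-site table
#'
#' Native backbone and side-chain half-sites for every paratope residue,
#' plus side-chain half-sites for up to `config$max_rotamers` structurally
#' diverse rotamers of every polar mutation at each variable residue.
#'
#' @param scaffold protonated `protein_structure`
#' @param paratope,variable `residue_selection`s (variable within paratope)
#' @param lib rotamer library
#' @param config a [match_config()]
#' @return half-site table with `id` and `native_aa` columns
#' @export
build_pbr_set <- function(scaffold, paratope, variable, lib,
                          config = match_config()) {
  check_selections(paratope, variable)
  out <- list()
  for (i in seq_len(nrow(paratope))) {
    at <- residue_atoms(scaffold, paratope$chain[i], paratope$resno[i])
    native <- at$resid[1]
    rec <- make_pbrs(at, rotamer = 0L)
    if (nrow(rec) > 0) {
      rec$native_aa <- native
      out[[length(out) + 1]] <- rec
    }
    if (paratope$key[i] %in% variable$key) {
      for (aa in POLAR_ALPHABET) {
        idxs <- select_diverse(lib, scaffold, paratope$chain[i],
                               paratope$resno[i], aa, k = config$max_rotamers)
        for (idx in idxs) {
          placed <- place_rotamer(scaffold, paratope$chain[i],
                                  paratope$resno[i], aa,
                                  rotamer_chi(lib, aa, idx))
          rec <- make_pbrs(placed, aa = aa, rotamer = as.integer(idx),
                           backbone = FALSE)
          if (nrow(rec) > 0) {
            rec$native_aa <- native
            out[[length(out) + 1]] <- rec
          }
        }
      }
    }
  }
  if (length(out) == 0) {
    hs <- empty_half_sites()
    hs$native_aa <- character(0)
    hs$id <- integer(0)
    return(hs)
  }
  pbrs <- do.call(rbind, out)
  pbrs$id <- seq_len(nrow(pbrs))
  rownames(pbrs) <- NULL
  pbrs
}

# Assemble and filter one pose from a solution group.
realize_group <- function(group, scaffold, antigen, pbrs, ebas, lib,
                          variable, config = match_config()) {
  sp <- superpose(group, pbrs, ebas)
  pose <- list(group = group, transform = sp$transform,
               superposition_rmsd = sp$rmsd,
               scaffold_state = scaffold,
               antigen_state = transform_structure(antigen, sp$transform),
               pbrs = pbrs, ebas = ebas,
               variable_keys = variable$key,
               group_sites = group$sites,
               hbonds = NULL,
               clash_records = data.frame(key_a = character(0),
                                          key_b = character(0),
                                          backbone_a = logical(0)),
               mutations = bind_records(list()),
               status = "pending", reason = NA_character_)
  class(pose) <- "dock_pose"
  inst <- install_design_rotamers(scaffold, group, lib, variable, config)
  pose$scaffold_state <- inst$state
  pose$mutations <- inst$design_records
  if (inst$rejected) {
    pose$status <- "rejected"
    pose$reason <- inst$reason
    return(pose)
  }
  pose$clash_records <- inst$clash_records
  cf <- coarse_filter(pose$scaffold_state, pose$antigen_state, config)
  pose$n_sphere_contacts <- cf$n_contacts
  if (cf$status == "reject") {
    pose$status <- "rejected"
    pose$reason <- cf$reason
    return(pose)
  }
  pose <- validate_pose(pose, config)
  if (pose$status != "accepted") return(pose)
  resolve_clashes(pose, lib, config)
}

#' @export
print.dock_pose <- function(x, ...) {
  cat(sprintf("dock_pose [%s%s]: %d designed H-bonds, %d mutation(s), superposition RMSD %.3f A\n",
              x$status, ifelse(is.na(x$reason), "", paste0(": ", x$reason)),
              x$group$size, nrow(x$mutations), x$superposition_rmsd))
  invisible(x)
}

as_structure_arg <- function(x) {
  if (inherits(x, "protein_structure")) x else read_pdb(x)
}

as_selection_arg <- function(s, x, role) {
  if (inherits(x, "residue_selection")) x else resolve_selection(s, x, role)
}

#' Dock a scaffold onto a target epitope
#'
#' Runs the full pipeline: protonation, epitope solvent-accessibility
#' screening, half-site construction (native plus mutated rotamers at
#' variable sites), geometric couple matching, solution-group expansion,
#' pose realization with steric/coarse-grained/H-bond filters, and the
#' clash-rescue mutation cascade. The pipeline is deterministic: identical
#' inputs give identical outputs.
#'
#' @param scaffold,antigen `protein_structure`s or PDB paths
#' @param paratope,variable,epitope selection strings or
#'   `residue_selection`s (`variable` must lie within `paratope`; may be
#'   empty)
#' @param lib rotamer library (default: bundled table)
#' @param config a [match_config()]
#' @param outdir if non-NULL, accepted pose PDBs, a mutation TSV and a JSON
#'   summary are written there
#' @param verbose print per-stage counts
#' @return list with `summary` (named counts), `poses` (all realized
#'   poses), `accepted` (indices of accepted poses), plus the intermediate
#'   `pbrs`, `ebas`, `couples` and `groups`
#' @export
dock <- function(scaffold, antigen, paratope, variable = "", epitope,
                 lib = NULL, config = match_config(), outdir = NULL,
                 verbose = FALSE) {
  if (is.null(lib)) lib <- load_rotamer_library()
  scaffold <- add_hydrogens(as_structure_arg(scaffold))
  antigen <- add_hydrogens(as_structure_arg(antigen))
  paratope <- as_selection_arg(scaffold, paratope, "paratope")
  variable <- as_selection_arg(scaffold, variable, "variable")
  epitope <- as_selection_arg(antigen, epitope, "epitope")
  check_selections(paratope, variable)
  sasa <- residue_sasa(antigen)
  ebas <- make_ebas(antigen, epitope, sasa,
                    sasa_threshold = config$sasa_threshold)
  pbrs <- build_pbr_set(scaffold, paratope, variable, lib, config)
  if (verbose)
    message(sprintf("half-sites: %d scaffold (PBR), %d epitope (EBA)",
                    nrow(pbrs), nrow(ebas)))
  couples <- enumerate_couples(pbrs, ebas, config)
  groups <- expand_groups(couples, pbrs, ebas, config)
  if (verbose)
    message(sprintf("%d couples -> %d solution groups", nrow(couples),
                    length(groups)))
  poses <- lapply(groups, realize_group, scaffold = scaffold,
                  antigen = antigen, pbrs = pbrs, ebas = ebas, lib = lib,
                  variable = variable, config = config)
  accepted <- which(vapply(poses, function(p) p$status == "accepted",
                           logical(1)))
  reasons <- vapply(poses, function(p)
    if (p$status == "accepted") "accepted" else p$reason, character(1))
  n_design <- vapply(poses[accepted], function(p)
    sum(p$mutations$kind == "design"), integer(1))
  n_clashmut <- vapply(poses[accepted], function(p)
    sum(p$mutations$kind == "clash"), integer(1))
  pct <- function(x) if (length(n_design) == 0) 0 else
    round(100 * mean(x), 2)
  summary <- list(
    n_pbrs = nrow(pbrs), n_ebas = nrow(ebas), n_couples = nrow(couples),
    n_groups = length(groups),
    poses_accepted = length(accepted),
    poses_rejected = list(
      rotamer_clash = sum(reasons == "rotamer_clash"),
      coarse_clash = sum(reasons == "coarse_clash"),
      small_interface = sum(reasons == "small_interface"),
      hbond_fail = sum(reasons == "hbond_fail"),
      clash_fixed = sum(reasons == "clash_fixed"),
      irreconcilable_clash = sum(reasons == "irreconcilable_clash")),
    design_mutation_pct = list(
      "0" = pct(n_design == 0), "1" = pct(n_design == 1),
      "2" = pct(n_design == 2), "3" = pct(n_design >= 3)),
    any_clash_mutation_pct = pct(n_clashmut > 0))
  if (verbose)
    message(sprintf("%d poses accepted / %d groups", length(accepted),
                    length(groups)))
  result <- list(summary = summary, poses = poses, accepted = accepted,
                 pbrs = pbrs, ebas = ebas, couples = couples,
                 groups = groups)
  if (!is.null(outdir)) write_run_outputs(result, outdir)
  result
}

write_run_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(result$accepted)) {
    pose <- result$poses[[result$accepted[k]]]
    write_pose_pdb(pose, file.path(outdir, sprintf("pose_%03d.pdb", k)))
  }
  muts <- list()
  for (k in seq_along(result$accepted)) {
    pose <- result$poses[[result$accepted[k]]]
    if (nrow(pose$mutations) > 0) {
      m <- pose$mutations
      m$pose_id <- sprintf("pose_%03d", k)
      muts[[length(muts) + 1]] <- m[, c("pose_id", "site", "from_aa",
                                        "to_aa", "kind", "cascade_step",
                                        "evidence")]
    }
  }
  mut_tab <- if (length(muts) > 0) do.call(rbind, muts) else
    data.frame(pose_id = character(0), site = character(0),
               from_aa = character(0), to_aa = character(0),
               kind = character(0), cascade_step = integer(0),
               evidence = character(0))
  utils::write.table(mut_tab, file.path(outdir, "mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
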