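# Geometric matching of scaffold and epitope half-site pairs. For each pair
# of half-sites a distance and the four interior angles of the quadrilateral
# S1-P1-P2-S2 are computed; a scaffold pair and an epitope pair are
# compatible when the distance and the four positionally-corresponding
# angles agree within the configured limits. Compatible couples are expanded
# into solution groups (maximal mutually-compatible interaction sets).

#' Matching and filter configuration
#'
#' Bundles the geometric thresholds of the whole pipeline. The defaults are
#' the calibrated values: distance window 1.8 A and angle window 70 degrees
#' (chosen to admit 85% of antibody-antigen H-bonds), group size >= 3,
#' at most 2000 poses, H-bond validity 2.5 A / 120 degrees, clash distances
#' 1.3 / 1.8 A, coarse-sphere separation budget 3.39 A with a minimum of 12
#' sphere contacts.
#'
#' @param d_limit primary-point distance window (A)
#' @param a_limit angle window (degrees)
#' @param min_group_size minimum designed H-bonds per solution
#' @param max_poses cap on emitted solution groups
#' @param hbond_dist,hbond_angle H-bond validation thresholds
#' @param clash_hard,clash_soft steric clash distances (A)
#' @param sphere_gap coarse-sphere minimum separation constant (A)
#' @param min_sphere_contacts minimum contacting sphere pairs
#' @param contact_pad surface gap below which two spheres count as in
#'   contact (A)
#' @param sphere_rule `"overlap"`: reject when center distance <
#'   r1 + r2 - sphere_gap; `"center"`: reject when center distance <
#'   sphere_gap
#' @param salt_bridge_dist O...N cutoff for salt bridges (A)
#' @param nonpolar_dist C/S...C/S cutoff for nonpolar contacts (A)
#' @param sasa_threshold minimum residue SASA for epitope half-sites (A^2)
#' @param max_rotamers diverse rotamers per mutation per site
#' @param neighbor_radius radius defining "surrounding" residues for clash
#'   rescue (A)
#' @return a `match_config` list
#' @export
match_config <- function(d_limit = 1.8, a_limit = 70, min_group_size = 3,
                         max_poses = 2000, hbond_dist = 2.5,
                         hbond_angle = 120, clash_hard = 1.3,
                         clash_soft = 1.8, sphere_gap = 3.39,
                         min_sphere_contacts = 12, contact_pad = 2.0,
                         sphere_rule = c("overlap", "center"),
                         salt_bridge_dist = 4.0, nonpolar_dist = 4.5,
                         sasa_threshold = 0.1, max_rotamers = 5,
                         neighbor_radius = 10) {
  sphere_rule <- match.arg(sphere_rule)
  cfg <- list(d_limit = d_limit, a_limit = a_limit,
              min_group_size = min_group_size, max_poses = max_poses,
              hbond_dist = hbond_dist, hbond_angle = hbond_angle,
              clash_hard = clash_hard, clash_soft = clash_soft,
              sphere_gap = sphere_gap,
              min_sphere_contacts = min_sphere_contacts,
              contact_pad = contact_pad, sphere_rule = sphere_rule,
              salt_bridge_dist = salt_bridge_dist,
              nonpolar_dist = nonpolar_dist,
              sasa_threshold = sasa_threshold, max_rotamers = max_rotamers,
              neighbor_radius = neighbor_radius)
  num <- unlist(cfg[vapply(cfg, is.numeric, logical(1))])
  if (any(num <= 0)) stop("all match_config values must be positive")
  class(cfg) <- "match_config"
  cfg
}

#' Pairwise geometry of two half-sites
#'
#' Distance between the primary points and the four interior angles of the
#' quadrilateral S1-P1-P2-S2: at each primary point between its secondary
#' point and the other primary point, and at each secondary point between
#' its own primary point and the other secondary point.
#'
#' @param h1,h2 one-row half-site records (from [make_pbrs()]/[make_ebas()])
#' @return list with `D`, `ang_1p`, `ang_2p`, `ang_1s`, `ang_2s`
#' @export
pair_geometry <- function(h1, h2) {
  p1 <- c(h1$px, h1$py, h1$pz); s1 <- c(h1$sx, h1$sy, h1$sz)
  p2 <- c(h2$px, h2$py, h2$pz); s2 <- c(h2$sx, h2$sy, h2$sz)
  if (vnorm(p1 - p2) < 1e-9 || vnorm(p1 - s1) < 1e-9 || vnorm(p2 - s2) < 1e-9)
    stop("degenerate half-site pair: coincident points")
  list(D = vnorm(p1 - p2),
       ang_1p = vangle(s1, p1, p2),
       ang_2p = vangle(s2, p2, p1),
       ang_1s = vangle(p1, s1, s2),
       ang_2s = vangle(p2, s2, s1))
}

# Vectorized angle at vertex rows: angle between (a - v) and (b - v).
.row_angle <- function(a, v, b) {
  u1 <- a - v
  u2 <- b - v
  num <- rowSums(u1 * u2)
  den <- sqrt(rowSums(u1^2) * rowSums(u2^2))
  acos(pmin(1, pmax(-1, num / den))) * 180 / pi
}

# All unordered half-site pairs from distinct residues, with geometry.
# `exclude_double_positive` drops pairs with two positively charged
# side-chain half-sites (scaffold side).
half_site_pairs <- function(hs, exclude_double_positive = FALSE) {
  n <- nrow(hs)
  if (n < 2)
    return(data.frame(i = integer(0), j = integer(0), D = numeric(0),
                      a1p = numeric(0), a2p = numeric(0), a1s = numeric(0),
                      a2s = numeric(0)))
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  keep <- hs$key[i] != hs$key[j]
  if (exclude_double_positive)
    keep <- keep & !(hs$charged[i] == "pos" & hs$charged[j] == "pos")
  i <- i[keep]; j <- j[keep]
  P <- as.matrix(hs[, c("px", "py", "pz")])
  S <- as.matrix(hs[, c("sx", "sy", "sz")])
  p1 <- P[i, , drop = FALSE]; p2 <- P[j, , drop = FALSE]
  s1 <- S[i, , drop = FALSE]; s2 <- S[j, , drop = FALSE]
  data.frame(i = i, j = j,
             D = sqrt(rowSums((p1 - p2)^2)),
             a1p = .row_angle(s1, p1, p2),
             a2p = .row_angle(s2, p2, p1),
             a1s = .row_angle(p1, s1, s2),
             a2s = .row_angle(p2, s2, s1))
}

#' Is a single scaffold-epitope half-site pairing allowed?
#'
#' Donor/acceptor polarities must be complementary and the amino-acid class
#' pair must be one of the allowed combinations: scaffold backbone with any
#' epitope atom; any scaffold side chain except ARG/LYS/GLN with epitope
#' backbone; ARG/LYS with ASP/GLU (either direction); and side chains among
#' HIS, ASN, ASP, TYR, SER, THR, TRP with each other, except ASN with ASP.
#'
#' @param pbr,eba one-row half-site records
#' @return logical
#' @export
pairing_allowed <- function(pbr, eba) {
  pairing_allowed_matrix(pbr, eba)[1, 1]
}

# Logical matrix over all (pbr, eba) combinations.
pairing_allowed_matrix <- function(pbrs, ebas) {
  np <- nrow(pbrs); ne <- nrow(ebas)
  pol <- outer(pbrs$polarity, ebas$polarity,
               function(a, b) (a == "donor" & b == "acceptor") |
                              (a == "acceptor" & b == "donor"))
  low_entropy <- c("HIS", "ASN", "ASP", "TYR", "SER", "THR", "TRP")
  pbb <- matrix(pbrs$bb, np, ne)
  ebb <- matrix(ebas$bb, np, ne, byrow = TRUE)
  paa <- matrix(pbrs$aa, np, ne)
  eaa <- matrix(ebas$aa, np, ne, byrow = TRUE)
  cls <- pbb |                                      # scaffold backbone - all
    (!pbb & ebb & !(paa %in% c("ARG", "LYS", "GLN"))) |
    (!pbb & !ebb & paa %in% c("ARG", "LYS") & eaa %in% c("ASP", "GLU")) |
    (!pbb & !ebb & paa %in% c("ASP", "GLU") & eaa %in% c("ARG", "LYS")) |
    (!pbb & !ebb & paa %in% low_entropy & eaa %in% low_entropy &
       !((paa == "ASN" & eaa == "ASP") | (paa == "ASP" & eaa == "ASN")))
  pol & cls
}

#' Geometric compatibility of a scaffold pair with an epitope pair
#'
#' True when the primary-point distances differ by less than `d_limit` and
#' the four positionally corresponding angle deviations are each below
#' `a_limit` (slot 1 with slot 1, slot 2 with slot 2).
#'
#' @param pbr_geom,eba_geom geometries from [pair_geometry()]
#' @param config a [match_config()]
#' @return logical
#' @export
couple_compatible <- function(pbr_geom, eba_geom, config = match_config()) {
  abs(pbr_geom$D - eba_geom$D) < config$d_limit &&
    abs(pbr_geom$ang_1p - eba_geom$ang_1p) < config$a_limit &&
    abs(pbr_geom$ang_2p - eba_geom$ang_2p) < config$a_limit &&
    abs(pbr_geom$ang_1s - eba_geom$ang_1s) < config$a_limit &&
    abs(pbr_geom$ang_2s - eba_geom$ang_2s) < config$a_limit
}

ensure_ids <- function(hs) {
  if (!"id" %in% names(hs)) hs$id <- seq_len(nrow(hs))
  hs
}

#' Enumerate all compatible couples
#'
#' A couple is a pair of scaffold half-sites from distinct residues matched
#' with a pair of epitope half-sites from distinct residues, such that each
#' slot pairing is allowed, at most one scaffold half-site is positively
#' charged, and the two pair geometries are compatible. Both assignments of
#' each pair combination are tested and emitted separately when valid.
#'
#' @param pbrs,ebas half-site tables
#' @param config a [match_config()]
#' @return data.frame with columns `pbr1`, `pbr2`, `eba1`, `eba2` (half-site
#'   ids; the interactions are pbr1-eba1 and pbr2-eba2), in deterministic
#'   order
#' @export
enumerate_couples <- function(pbrs, ebas, config = match_config()) {
  pbrs <- ensure_ids(pbrs)
  ebas <- ensure_ids(ebas)
  empty <- data.frame(pbr1 = integer(0), pbr2 = integer(0),
                      eba1 = integer(0), eba2 = integer(0))
  if (nrow(pbrs) < 2 || nrow(ebas) < 2) return(empty)
  pp <- half_site_pairs(pbrs, exclude_double_positive = TRUE)
  ee <- half_site_pairs(ebas)
  if (nrow(pp) == 0 || nrow(ee) == 0) return(empty)
  allowed <- pairing_allowed_matrix(pbrs, ebas)
  out <- vector("list", nrow(ee))
  for (r in seq_len(nrow(ee))) {
    e <- ee[r, ]
    near <- which(abs(pp$D - e$D) < config$d_limit)
    if (length(near) == 0) next
    sub <- pp[near, , drop = FALSE]
    direct <- allowed[cbind(sub$i, e$i)] & allowed[cbind(sub$j, e$j)] &
      abs(sub$a1p - e$a1p) < config$a_limit &
      abs(sub$a2p - e$a2p) < config$a_limit &
      abs(sub$a1s - e$a1s) < config$a_limit &
      abs(sub$a2s - e$a2s) < config$a_limit
    swapped <- allowed[cbind(sub$i, e$j)] & allowed[cbind(sub$j, e$i)] &
      abs(sub$a1p - e$a2p) < config$a_limit &
      abs(sub$a2p - e$a1p) < config$a_limit &
      abs(sub$a1s - e$a2s) < config$a_limit &
      abs(sub$a2s - e$a1s) < config$a_limit
    res <- list()
    if (any(direct))
      res[[1]] <- data.frame(pbr1 = pbrs$id[sub$i[direct]],
                             pbr2 = pbrs$id[sub$j[direct]],
                             eba1 = ebas$id[e$i], eba2 = ebas$id[e$j])
    if (any(swapped))
      res[[2]] <- data.frame(pbr1 = pbrs$id[sub$i[swapped]],
                             pbr2 = pbrs$id[sub$j[swapped]],
                             eba1 = ebas$id[e$j], eba2 = ebas$id[e$i])
    if (length(res) > 0) out[[r]] <- do.call(rbind, res)
  }
  couples <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(couples)) return(empty)
  couples <- couples[order(couples$pbr1, couples$pbr2, couples$eba1,
                           couples$eba2), , drop = FALSE]
  rownames(couples) <- NULL
  couples
}

#' Expand couples into solution groups
#'
#' Builds the interaction-compatibility graph (vertices are the distinct
#' scaffold-epitope interactions, edges are the enumerated couples) and
#' reports each maximal clique of at least `min_group_size` interactions as
#' one solution group: a candidate pose with its design mutations.
#'
#' @param couples output of [enumerate_couples()]
#' @param pbrs,ebas the half-site tables the couples refer to; `pbrs` may
#'   carry a `native_aa` column identifying each site's native type
#' @param config a [match_config()]
#' @return list of `solution_group` objects, largest first, capped at
#'   `config$max_poses`
#' @export
expand_groups <- function(couples, pbrs, ebas, config = match_config()) {
  if (nrow(couples) == 0) return(list())
  pbrs <- ensure_ids(pbrs)
  ebas <- ensure_ids(ebas)
  v1 <- paste0(couples$pbr1, ".", couples$eba1)
  v2 <- paste0(couples$pbr2, ".", couples$eba2)
  verts <- sort(unique(c(v1, v2)))
  g <- igraph::graph_from_edgelist(cbind(v1, v2), directed = FALSE)
  g <- igraph::simplify(g)
  cliques <- igraph::max_cliques(g, min = config$min_group_size)
  if (length(cliques) == 0) return(list())
  groups <- lapply(cliques, function(cl) {
    labs <- igraph::V(g)$name[as.integer(cl)]
    parts <- do.call(rbind, strsplit(labs, ".", fixed = TRUE))
    inter <- data.frame(pbr = as.integer(parts[, 1]),
                        eba = as.integer(parts[, 2]))
    inter <- inter[order(inter$pbr, inter$eba), , drop = FALSE]
    rownames(inter) <- NULL
    make_solution_group(inter, pbrs, ebas)
  })
  # at most one positively charged scaffold residue per solution
  groups <- Filter(function(gr) gr$n_positive <= 1, groups)
  ord <- order(-vapply(groups, function(gr) gr$size, numeric(1)),
               vapply(groups, function(gr) gr$label, character(1)))
  groups <- groups[ord]
  if (length(groups) > config$max_poses)
    groups <- groups[seq_len(config$max_poses)]
  groups
}

make_solution_group <- function(interactions, pbrs, ebas) {
  pi_ <- match(interactions$pbr, pbrs$id)
  ei_ <- match(interactions$eba, ebas$id)
  sites <- pbrs$key[pi_]
  if (anyDuplicated(sites) || anyDuplicated(ebas$key[ei_]))
    stop("inconsistent solution group: repeated residue slot")
  native <- if ("native_aa" %in% names(pbrs)) pbrs$native_aa[pi_]
            else pbrs$aa[pi_]
  sc <- !pbrs$bb[pi_]
  design_idx <- which(sc & pbrs$aa[pi_] != native)
  design <- stats::setNames(pbrs$aa[pi_][design_idx], sites[design_idx])
  rot_idx <- which(sc & pbrs$rotamer[pi_] > 0)
  rotamers <- stats::setNames(pbrs$rotamer[pi_][rot_idx], sites[rot_idx])
  aa_by_rot <- stats::setNames(pbrs$aa[pi_][rot_idx], sites[rot_idx])
  gr <- list(interactions = interactions,
             size = nrow(interactions),
             sites = sites,
             epitope_sites = ebas$key[ei_],
             design = design,
             rotamers = rotamers,
             rotamer_aa = aa_by_rot,
             n_positive = length(unique(sites[pbrs$charged[pi_] == "pos"])),
             label = paste(paste0(interactions$pbr, ".", interactions$eba),
                           collapse = "+"))
  class(gr) <- "solution_group"
  gr
}

#' @export
print.solution_group <- function(x, ...) {
  cat(sprintf("solution_group: %d designed H-bonds, %d design mutation(s)\n",
              x$size, length(x$design)))
  invisible(x)
}
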