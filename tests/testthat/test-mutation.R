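# The six-step clash-rescue cascade on constructed scenes (see
# helper-scenes.R) and its ordering/alphabet invariants.

cfg <- match_config()

test_that("a pose without clash records is returned unchanged", {
  pose <- make_cascade_scene("clean")
  out <- resolve_clashes(pose, scene_lib, cfg)
  expect_equal(out$status, "accepted")
  expect_equal(nrow(out$mutations), 0)
  expect_identical(out$scaffold_state$atom, pose$scaffold_state$atom)
})

test_that("step 1 repacks the native amino acid when an alternate rotamer
           fits", {
  pose <- make_cascade_scene("repack")
  out <- resolve_clashes(pose, scene_lib, cfg)
  expect_equal(out$status, "accepted")
  m <- out$mutations
  expect_equal(nrow(m), 1)
  expect_equal(m$cascade_step, 1L)
  expect_equal(m$from_aa, "LEU")
  expect_equal(m$to_aa, "LEU")  # rotamer change, no amino-acid change
  new_chi <- measure_chi(residue_atoms(out$scaffold_state, "A", 6), "LEU")
  old_chi <- scafdock:::rotamer_chi(scene_lib, "LEU", 1)
  expect_gt(max(abs(new_chi - old_chi)), 1)
})

test_that("step 2 introduces ASP when it can bridge an antigen LYS, and the
           native type verifiably had no clash-free rotamer", {
  pose <- make_cascade_scene("salt_asp")
  out <- resolve_clashes(pose, scene_lib, cfg)
  expect_equal(out$status, "accepted")
  m <- out$mutations
  expect_equal(m$to_aa, "ASP")
  expect_equal(m$cascade_step, 2L)
  expect_match(m$evidence, "salt bridge")
  # realized salt bridge on final coordinates
  asp <- residue_atoms(out$scaffold_state, "A", 6)
  lys <- residue_atoms(out$antigen_state, "B", 910)
  expect_true(is_salt_bridge(asp, lys, cfg$salt_bridge_dist))
  # independent check that step 1 was impossible: every native rotamer has
  # a blocked distal atom
  blob <- residue_atoms(pose$antigen_state, "B", 900)
  for (i in seq_len(nrow(scene_lib$PHE))) {
    p <- place_rotamer(pose$scaffold_state, "A", 6, "PHE",
                       scafdock:::rotamer_chi(scene_lib, "PHE", i))
    cz <- scafdock:::atom_coord(p, "CZ")
    d <- sqrt((blob$x - cz[1])^2 + (blob$y - cz[2])^2 + (blob$z - cz[3])^2)
    expect_lt(min(d), cfg$clash_hard)
  }
})

test_that("step 3 falls back to GLU only when no ASP rotamer can reach the
           antigen charge", {
  pose <- make_cascade_scene("salt_glu")
  out <- resolve_clashes(pose, scene_lib, cfg)
  expect_equal(out$status, "accepted")
  m <- out$mutations
  expect_equal(m$to_aa, "GLU")
  expect_equal(m$cascade_step, 3L)
  # independent check: no clash-free ASP rotamer reaches the LYS within
  # the salt-bridge cutoff
  lys <- residue_atoms(pose$antigen_state, "B", 910)
  for (i in seq_len(nrow(scene_lib$ASP))) {
    p <- place_rotamer(pose$scaffold_state, "A", 6, "ASP",
                       scafdock:::rotamer_chi(scene_lib, "ASP", i))
    expect_false(is_salt_bridge(p, lys, cfg$salt_bridge_dist))
  }
})

test_that("step 4 installs the first polar type meeting its hydrogen-bond
           quota", {
  pose <- make_cascade_scene("polar")
  out <- resolve_clashes(pose, scene_lib, cfg)
  expect_equal(out$status, "accepted")
  m <- out$mutations
  expect_equal(m$to_aa, "SER")
  expect_equal(m$cascade_step, 4L)
  expect_match(m$evidence, "H-bond")
  # the realized bond passes the geometric criterion
  ser <- residue_atoms(out$scaffold_state, "A", 6)
  acc <- residue_atoms(out$antigen_state, "B", 920)
  expect_true(is_valid_hbond(scafdock:::atom_coord(ser, "HG1"),
                             scafdock:::atom_coord(ser, "OG"),
                             scafdock:::atom_coord(acc, "O")))
})

test_that("step 5 installs a small nonpolar residue making a contact when
           no polar rescue exists", {
  pose <- make_cascade_scene("nonpolar")
  out <- resolve_clashes(pose, scene_lib, cfg)
  expect_equal(out$status, "accepted")
  m <- out$mutations
  expect_equal(m$to_aa, "ALA")  # first in the nonpolar search order
  expect_equal(m$cascade_step, 5L)
})

test_that("a site with no clash-free rotamer of any allowed type rejects
           the pose", {
  pose <- make_cascade_scene("irreconcilable")
  out <- resolve_clashes(pose, scene_lib, cfg)
  expect_equal(out$status, "rejected")
  expect_equal(out$reason, "irreconcilable_clash")
})

test_that("forbidden amino acids never appear among clash mutations and
           final poses are clash free", {
  forbidden <- c("MET", "TRP", "TYR", "GLN", "LYS", "ARG")
  for (type in c("repack", "salt_asp", "salt_glu", "polar", "nonpolar")) {
    pose <- make_cascade_scene(type)
    out <- resolve_clashes(pose, scene_lib, cfg)
    expect_false(any(out$mutations$to_aa %in% forbidden))
    hits <- scafdock:::scan_clashes(out$scaffold_state, out$antigen_state,
                                    cfg)
    expect_equal(nrow(hits), 0)
  }
})

test_that("the cascade is strictly ordered: a recorded step-k mutation
           implies every earlier step had no qualifying rotamer", {
  for (type in c("salt_asp", "salt_glu", "polar", "nonpolar")) {
    pose <- make_cascade_scene(type)
    out <- resolve_clashes(pose, scene_lib, cfg)
    step <- out$mutations$cascade_step[1]
    if (step >= 2) expect_null(step1_repack("A:6", pose, scene_lib, cfg))
    if (step >= 4)
      expect_null(step2_3_salt_bridge("A:6", pose, scene_lib,
                                      config = cfg))
    if (step >= 5) expect_null(step4_polar("A:6", pose, scene_lib, cfg))
  }
})

test_that("each antigen basic residue anchors at most one rescue salt
           bridge per pose", {
  # two clashing sites, one reachable LYS: the second site must not reuse it
  pose <- make_cascade_scene("salt_asp")
  claimed <- character(0)
  r1 <- step2_3_salt_bridge("A:6", pose, scene_lib, claimed, cfg)
  expect_equal(r1$aa, "ASP")
  r2 <- step2_3_salt_bridge("A:6", pose, scene_lib,
                            claimed = r1$partner, cfg)
  expect_null(r2)
})
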