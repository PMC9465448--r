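# Pairwise geometry, pairing rules, couple enumeration and group expansion,
# each against an independent oracle.

mk_hs <- function(p, s, key = "A:1", aa = "SER", atom = "HG1", bb = FALSE) {
  pol <- if (scafdock:::element_of(atom) == "H") "donor" else "acceptor"
  data.frame(chain = substr(key, 1, 1),
             resno = as.integer(sub(".*:", "", key)), key = key, aa = aa,
             atom = atom, polarity = pol,
             charged = scafdock:::charged_class_of(aa, bb), bb = bb,
             rotamer = 0L, ax = p[1], ay = p[2], az = p[3],
             antx = s[1], anty = s[2], antz = s[3],
             px = p[1], py = p[2], pz = p[3],
             sx = s[1], sy = s[2], sz = s[3], stringsAsFactors = FALSE)
}

test_that("a planar rectangle gives D = 2 and four right angles", {
  g <- pair_geometry(mk_hs(c(0, 0, 0), c(0, 1, 0)),
                     mk_hs(c(2, 0, 0), c(2, 1, 0), key = "A:2"))
  expect_equal(g$D, 2)
  expect_equal(c(g$ang_1p, g$ang_2p, g$ang_1s, g$ang_2s), rep(90, 4))
})

test_that("collinear secondary points give 180-degree angles", {
  g <- pair_geometry(mk_hs(c(0, 0, 0), c(-1, 0, 0)),
                     mk_hs(c(2, 0, 0), c(3, 0, 0), key = "A:2"))
  expect_equal(g$ang_1p, 180)
  expect_equal(g$ang_2p, 180)
})

test_that("coincident points are rejected", {
  expect_error(pair_geometry(mk_hs(c(0, 0, 0), c(0, 1, 0)),
                             mk_hs(c(0, 0, 0), c(0, 1, 0), key = "A:2")),
               "degenerate")
})

test_that("pair geometry matches a law-of-cosines oracle on 50 random
           configurations", {
  set.seed(101)
  for (i in 1:50) {
    p1 <- runif(3, -5, 5); s1 <- p1 + rnorm(3)
    p2 <- runif(3, -5, 5); s2 <- p2 + rnorm(3)
    g <- pair_geometry(mk_hs(p1, s1), mk_hs(p2, s2, key = "A:2"))
    o <- oracle_pair_geometry(p1, s1, p2, s2)
    expect_equal(g$D, o$D, tolerance = 1e-9)
    for (f in c("ang_1p", "ang_2p", "ang_1s", "ang_2s"))
      expect_equal(g[[f]], o[[f]], tolerance = 1e-6)
  }
})

test_that("the pairing table allows and forbids the documented classes", {
  p <- c(0, 0, 0); s <- c(1, 0, 0)
  arg <- mk_hs(p, s, aa = "ARG", atom = "HH11")
  glu_sc <- mk_hs(p, s, key = "B:1", aa = "GLU", atom = "OE1")
  expect_true(pairing_allowed(arg, glu_sc))
  asn <- mk_hs(p, s, aa = "ASN", atom = "HD21")
  asp_sc <- mk_hs(p, s, key = "B:1", aa = "ASP", atom = "OD1")
  expect_false(pairing_allowed(asn, asp_sc))
  ser_d <- mk_hs(p, s, aa = "SER", atom = "HG1")
  expect_true(pairing_allowed(ser_d, asp_sc))
  gln <- mk_hs(p, s, aa = "GLN", atom = "HE21")
  bb_o <- mk_hs(p, s, key = "B:1", aa = "GLY", atom = "O", bb = TRUE)
  expect_false(pairing_allowed(gln, bb_o))
  expect_true(pairing_allowed(ser_d, bb_o))
  # scaffold backbone pairs with anything of opposite polarity
  bb_hn <- mk_hs(p, s, aa = "LEU", atom = "HN", bb = TRUE)
  lys_like <- mk_hs(p, s, key = "B:1", aa = "GLN", atom = "OE1")
  expect_true(pairing_allowed(bb_hn, lys_like))
  # polarity must be complementary
  expect_false(pairing_allowed(ser_d, mk_hs(p, s, key = "B:1", aa = "SER",
                                            atom = "HG1")))
})

test_that("couple compatibility applies the distance and angle windows and
           is symmetric under swapping both interactions", {
  cfg <- match_config()
  g1 <- list(D = 10, ang_1p = 80, ang_2p = 100, ang_1s = 60, ang_2s = 120)
  expect_true(couple_compatible(g1, g1, cfg))
  g2 <- g1; g2$D <- 12
  expect_false(couple_compatible(g1, g2, cfg))
  g3 <- g1; g3$ang_1p <- 80 + 70
  expect_false(couple_compatible(g1, g3, cfg))
  swap <- function(g) list(D = g$D, ang_1p = g$ang_2p, ang_2p = g$ang_1p,
                           ang_1s = g$ang_2s, ang_2s = g$ang_1s)
  set.seed(7)
  for (i in 1:20) {
    a <- list(D = runif(1, 2, 12), ang_1p = runif(1, 0, 180),
              ang_2p = runif(1, 0, 180), ang_1s = runif(1, 0, 180),
              ang_2s = runif(1, 0, 180))
    b <- list(D = a$D + runif(1, -3, 3),
              ang_1p = a$ang_1p + runif(1, -90, 90),
              ang_2p = a$ang_2p + runif(1, -90, 90),
              ang_1s = a$ang_1s + runif(1, -90, 90),
              ang_2s = a$ang_2s + runif(1, -90, 90))
    b <- lapply(b, function(v) pmax(0, pmin(180, v)))
    b$D <- a$D + runif(1, -3, 3)
    expect_equal(couple_compatible(a, b, cfg),
                 couple_compatible(swap(a), swap(b), cfg))
  }
})

test_that("couple enumeration equals brute force on random instances", {
  set.seed(202)
  for (rep in 1:8) {
    pbrs <- random_half_sites(8, "pbr")
    ebas <- random_half_sites(8, "eba")
    mine <- enumerate_couples(pbrs, ebas)
    ref <- oracle_enumerate_couples(pbrs, ebas)
    expect_equal(mine, ref)
  }
})

test_that("pairs of positively charged scaffold half-sites are excluded
           regardless of geometry", {
  p1 <- c(0, 0, 0); p2 <- c(3, 0, 0)
  pbrs <- rbind(mk_hs(p1, p1 - c(1, 0, 0), key = "A:1", aa = "ARG",
                      atom = "HH11"),
                mk_hs(p2, p2 - c(1, 0, 0), key = "A:2", aa = "LYS",
                      atom = "HZ1"))
  e1 <- c(10, 0, 0); e2 <- c(13, 0, 0)
  ebas <- rbind(mk_hs(e1, e1 - c(1, 0, 0), key = "B:1", aa = "GLU",
                      atom = "OE1"),
                mk_hs(e2, e2 - c(1, 0, 0), key = "B:2", aa = "ASP",
                      atom = "OD1"))
  pbrs$id <- 1:2; ebas$id <- 1:2
  expect_equal(nrow(enumerate_couples(pbrs, ebas)), 0)
  # one positive + one neutral is fine with identical geometry
  pbrs2 <- pbrs
  pbrs2$aa[2] <- "SER"; pbrs2$atom[2] <- "HG1"; pbrs2$charged[2] <- "neu"
  expect_gt(nrow(enumerate_couples(pbrs2, ebas)), 0)
})

test_that("enlarging the windows never loses couples", {
  set.seed(303)
  pbrs <- random_half_sites(8, "pbr")
  ebas <- random_half_sites(8, "eba")
  base <- enumerate_couples(pbrs, ebas, match_config())
  wider <- enumerate_couples(pbrs, ebas,
                             match_config(d_limit = 3.6, a_limit = 140))
  key <- function(d) paste(d$pbr1, d$pbr2, d$eba1, d$eba2)
  expect_true(all(key(base) %in% key(wider)))
  expect_gte(nrow(wider), nrow(base))
})

test_that("group expansion reproduces the worked three-couple example", {
  # a congruent scaffold/epitope triangle: the identity couples AB, AC, BC
  # must be enumerated and expand to the triple ABC
  pbr_p <- list(c(0, 0, 0), c(5, 0, 0), c(0, 11, 0))
  eba_p <- list(c(20, 0, 0), c(25, 0, 0), c(20, 11, 0))
  pbrs <- do.call(rbind, lapply(1:3, function(i)
    mk_hs(pbr_p[[i]], pbr_p[[i]] - c(0, 0, 1), key = paste0("A:", i),
          aa = "SER", atom = "HG1")))
  ebas <- do.call(rbind, lapply(1:3, function(i)
    mk_hs(eba_p[[i]], eba_p[[i]] - c(0, 0, 1), key = paste0("B:", i),
          aa = "GLY", atom = "O", bb = TRUE)))
  pbrs$id <- 1:3; ebas$id <- 1:3
  couples <- enumerate_couples(pbrs, ebas)
  key <- paste(couples$pbr1, couples$pbr2, couples$eba1, couples$eba2)
  expect_true(all(c("1 2 1 2", "1 3 1 3", "2 3 2 3") %in% key))
  groups <- expand_groups(couples, pbrs, ebas)
  ids <- lapply(groups, function(g)
    paste(g$interactions$pbr, g$interactions$eba, sep = ".",
          collapse = "+"))
  expect_true("1.1+2.2+3.3" %in% ids)
  # the worked example in isolation: couples AB, AC, BC give exactly ABC,
  # and dropping BC leaves nothing of size >= 3
  abc <- data.frame(pbr1 = c(1, 1, 2), pbr2 = c(2, 3, 3),
                    eba1 = c(1, 1, 2), eba2 = c(2, 3, 3))
  groups1 <- expand_groups(abc, pbrs, ebas)
  expect_length(groups1, 1)
  expect_equal(groups1[[1]]$size, 3)
  expect_setequal(groups1[[1]]$sites, c("A:1", "A:2", "A:3"))
  expect_length(expand_groups(abc[1:2, ], pbrs, ebas), 0)
})

test_that("group expansion equals Bron-Kerbosch maximal cliques on random
           compatibility graphs", {
  set.seed(404)
  for (rep in 1:12) {
    n <- sample(6:12, 1)
    adj <- matrix(FALSE, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      adj[i, j] <- adj[j, i] <- runif(1) < 0.45
    # encode vertex v as interaction (pbr v, eba v); an edge (i, j) becomes
    # a couple
    edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
    if (nrow(edges) == 0) next
    couples <- data.frame(pbr1 = edges[, 1], pbr2 = edges[, 2],
                          eba1 = edges[, 1], eba2 = edges[, 2])
    pbrs <- random_half_sites(n, "pbr")
    ebas <- random_half_sites(n, "eba")
    groups <- expand_groups(couples, pbrs, ebas,
                            match_config(min_group_size = 3))
    mine <- lapply(groups, function(g) sort(g$interactions$pbr))
    ref <- oracle_max_cliques(adj, min_size = 3)
    # positive-charge cap can drop cliques; ignore those here
    ref <- Filter(function(cl)
      sum(pbrs$charged[cl] == "pos") <= 1, ref)
    expect_setequal(lapply(mine, paste, collapse = ","),
                    lapply(ref, paste, collapse = ","))
  }
})

test_that("every emitted group's interaction pairs satisfy the geometric
           constraints post hoc", {
  set.seed(505)
  pbrs <- random_half_sites(10, "pbr")
  ebas <- random_half_sites(10, "eba")
  cfg <- match_config(min_group_size = 2)
  couples <- enumerate_couples(pbrs, ebas, cfg)
  groups <- expand_groups(couples, pbrs, ebas, cfg)
  for (g in groups) {
    k <- nrow(g$interactions)
    for (a in seq_len(k - 1)) for (b in seq((a + 1), k)) {
      gp <- pair_geometry(pbrs[match(g$interactions$pbr[a], pbrs$id), ],
                          pbrs[match(g$interactions$pbr[b], pbrs$id), ])
      ge <- pair_geometry(ebas[match(g$interactions$eba[a], ebas$id), ],
                          ebas[match(g$interactions$eba[b], ebas$id), ])
      expect_true(couple_compatible(gp, ge, cfg))
    }
  }
})
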