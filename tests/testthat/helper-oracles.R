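# Independent oracle implementations used to cross-check the package: these
# deliberately avoid the code paths they verify.

# Law-of-cosines angle at vertex b of triangle a-b-c (degrees).
oracle_angle <- function(a, b, c) {
  ab <- sqrt(sum((a - b)^2))
  cb <- sqrt(sum((c - b)^2))
  ac <- sqrt(sum((a - c)^2))
  acos(pmin(1, pmax(-1, (ab^2 + cb^2 - ac^2) / (2 * ab * cb)))) * 180 / pi
}

# Quadrilateral geometry of two half-sites from raw points.
oracle_pair_geometry <- function(p1, s1, p2, s2) {
  list(D = sqrt(sum((p1 - p2)^2)),
       ang_1p = oracle_angle(s1, p1, p2),
       ang_2p = oracle_angle(s2, p2, p1),
       ang_1s = oracle_angle(p1, s1, s2),
       ang_2s = oracle_angle(p2, s2, s1))
}

# Brute-force couple enumeration: loop over every scaffold pair, epitope
# pair and both assignments, with explicit predicate checks.
oracle_enumerate_couples <- function(pbrs, ebas, config = match_config()) {
  pt <- function(h) list(p = c(h$px, h$py, h$pz), s = c(h$sx, h$sy, h$sz))
  res <- list()
  np <- nrow(pbrs); ne <- nrow(ebas)
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (i >= j) next
    if (pbrs$key[i] == pbrs$key[j]) next
    if (pbrs$charged[i] == "pos" && pbrs$charged[j] == "pos") next
    hi <- pt(pbrs[i, ]); hj <- pt(pbrs[j, ])
    gp <- oracle_pair_geometry(hi$p, hi$s, hj$p, hj$s)
    for (k in seq_len(ne)) for (l in seq_len(ne)) {
      if (k == l || ebas$key[k] == ebas$key[l]) next
      if (!pairing_allowed(pbrs[i, ], ebas[k, ])) next
      if (!pairing_allowed(pbrs[j, ], ebas[l, ])) next
      ek <- pt(ebas[k, ]); el <- pt(ebas[l, ])
      ge <- oracle_pair_geometry(ek$p, ek$s, el$p, el$s)
      ok <- abs(gp$D - ge$D) < config$d_limit &&
        abs(gp$ang_1p - ge$ang_1p) < config$a_limit &&
        abs(gp$ang_2p - ge$ang_2p) < config$a_limit &&
        abs(gp$ang_1s - ge$ang_1s) < config$a_limit &&
        abs(gp$ang_2s - ge$ang_2s) < config$a_limit
      if (ok)
        res[[length(res) + 1]] <- data.frame(pbr1 = pbrs$id[i],
                                             pbr2 = pbrs$id[j],
                                             eba1 = ebas$id[k],
                                             eba2 = ebas$id[l])
    }
  }
  if (length(res) == 0)
    return(data.frame(pbr1 = integer(0), pbr2 = integer(0),
                      eba1 = integer(0), eba2 = integer(0)))
  out <- unique(do.call(rbind, res))
  out <- out[order(out$pbr1, out$pbr2, out$eba1, out$eba2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Bron-Kerbosch maximal clique enumeration (no pivoting) on an adjacency
# matrix; returns a list of sorted integer vectors.
oracle_max_cliques <- function(adj, min_size = 1) {
  n <- nrow(adj)
  cliques <- list()
  bk <- function(r, p, x) {
    if (length(p) == 0 && length(x) == 0) {
      if (length(r) >= min_size)
        cliques[[length(cliques) + 1]] <<- sort(r)
      return()
    }
    for (v in p) {
      nv <- which(adj[v, ])
      bk(c(r, v), intersect(p, nv), intersect(x, nv))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  cliques
}

# Independent Shrake-Rupley SASA with seeded random sphere points.
oracle_sasa <- function(s, probe = 1.4, n_points = 6000, seed = 42) {
  set.seed(seed)
  v <- matrix(stats::rnorm(3 * n_points), ncol = 3)
  pts <- v / sqrt(rowSums(v^2))
  at <- s$atom[s$atom$element != "H", , drop = FALSE]
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- unname(radii[at$element]) + probe
  area <- numeric(nrow(at))
  for (i in seq_len(nrow(at))) {
    surf <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(nrow(at))) {
      if (j == i) next
      if (sum((xyz[j, ] - xyz[i, ])^2) > (rad[i] + rad[j])^2) next
      dj2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
             (surf[, 3] - xyz[j, 3])^2
      free <- free & dj2 > rad[j]^2
    }
    area[i] <- mean(free) * 4 * pi * rad[i]^2
  }
  keys <- paste0(at$chain, ":", at$resno)
  out <- tapply(area, factor(keys, levels = unique(keys)), sum)
  res <- as.numeric(out)
  names(res) <- names(out)
  res
}

# Random synthetic half-site table (geometry only; types drawn from the
# polar-atom table so pairing rules are exercised).
random_half_sites <- function(n, kind = c("pbr", "eba"), box = 12) {
  kind <- match.arg(kind)
  tab <- scafdock:::HALF_SITE_TABLE
  rows <- tab[sample(nrow(tab), n, replace = TRUE), ]
  aa_pool <- c("SER", "THR", "TYR", "ASN", "ASP", "GLU", "GLN", "HIS",
               "TRP", "ARG", "LYS", "ALA", "GLY", "LEU")
  out <- list()
  for (i in seq_len(n)) {
    row <- rows[i, ]
    bb <- row$aa == "BB"
    aa <- if (bb) sample(aa_pool, 1) else row$aa
    atom <- stats::runif(3, -box, box)
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    blen <- stats::runif(1, 0.96, 1.4)
    ant <- atom - blen * dir
    if (kind == "pbr") {
      p <- atom + 1.25 * dir
      s <- atom + 2.25 * dir
    } else {
      p <- atom
      s <- ant
    }
    out[[i]] <- data.frame(
      chain = if (kind == "pbr") "A" else "B", resno = i,
      key = paste0(if (kind == "pbr") "A:" else "B:", i),
      aa = aa, atom = row$atom,
      polarity = if (scafdock:::element_of(row$atom) == "H") "donor"
                 else "acceptor",
      charged = scafdock:::charged_class_of(aa, bb), bb = bb, rotamer = 0L,
      ax = atom[1], ay = atom[2], az = atom[3],
      antx = ant[1], anty = ant[2], antz = ant[3],
      px = p[1], py = p[2], pz = p[3], sx = s[1], sy = s[2], sz = s[3],
      stringsAsFactors = FALSE)
  }
  hs <- do.call(rbind, out)
  hs$id <- seq_len(n)
  hs
}

# Single-residue structure from explicit atoms: list of (name, x, y, z).
atoms_structure <- function(..., resid = "ALA", chain = "A", resno = 1) {
  rows <- list(...)
  at <- do.call(rbind, lapply(rows, function(r)
    data.frame(chain = chain, resno = resno, resid = resid, elety = r[[1]],
               element = scafdock:::element_of(r[[1]]),
               x = as.numeric(r[[2]]), y = as.numeric(r[[3]]),
               z = as.numeric(r[[4]]), stringsAsFactors = FALSE)))
  scafdock:::new_structure(at, source = "test")
}

coords_matrix_test <- function(s) {
  unname(as.matrix(s$atom[, c("x", "y", "z")]))
}

# Whether a docking result recovered the fixture's planted bonds in at
# least one accepted pose.
recovered_planted <- function(fx, res) {
  want <- paste(fx$expected$scaffold_site, fx$expected$scaffold_atom,
                fx$expected$epitope_site, fx$expected$epitope_atom)
  for (i in res$accepted) {
    hb <- res$poses[[i]]$hbonds
    got <- paste(hb$scaffold_site, hb$scaffold_atom, hb$epitope_site,
                 hb$epitope_atom)
    if (all(want %in% got)) return(TRUE)
  }
  FALSE
}
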