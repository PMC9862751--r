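# helper: minimal complex from an atom spec list
.mk <- function(rows) {
  at <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(serial = i, name = r$name, element = r$el,
               res_name = r$res, res_id = r$rid, chain = "A",
               x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               formal_charge = if (is.null(r$fc)) NA_real_ else r$fc,
               role = r$role, stringsAsFactors = FALSE)
  }))
  mol_structure(at)
}

test_that("hydrogen-bond detection honours all three geometric criteria", {
  # linear O-H...O, H...O = 2.0 A
  lin <- .mk(list(
    list(name = "O1", el = "O", res = "LIG", rid = 1, xyz = c(0, 0, 0), role = "ligand"),
    list(name = "H1", el = "H", res = "LIG", rid = 1, xyz = c(0.96, 0, 0), role = "ligand"),
    list(name = "OG", el = "O", res = "SER", rid = 5, xyz = c(2.96, 0, 0), role = "receptor"),
    list(name = "CB", el = "C", res = "SER", rid = 5, xyz = c(4.36, 0, 0), role = "receptor")))
  got <- detect_hbonds(lin)
  expect_equal(nrow(got), 1)
  expect_equal(got$direction, "donor")
  expect_equal(got$distance, 2.0, tolerance = 1e-9)
  expect_equal(got$res_id, 5)

  # same donor bent to a 100-degree D-H...A angle: rejected
  ang <- 100 * pi / 180
  bent <- .mk(list(
    list(name = "O1", el = "O", res = "LIG", rid = 1, xyz = c(0, 0, 0), role = "ligand"),
    list(name = "H1", el = "H", res = "LIG", rid = 1, xyz = c(0.96, 0, 0), role = "ligand"),
    list(name = "OG", el = "O", res = "SER", rid = 5,
         xyz = c(0.96 - 2 * cos(ang), 2 * sin(ang), 0), role = "receptor"),
    list(name = "CB", el = "C", res = "SER", rid = 5,
         xyz = c(0.96 - 2 * cos(ang), 2 * sin(ang) + 1.4, 0), role = "receptor")))
  expect_equal(nrow(detect_hbonds(bent)), 0)

  # acceptor-side angle violation: X sits on top of the H...A axis
  axv <- .mk(list(
    list(name = "O1", el = "O", res = "LIG", rid = 1, xyz = c(0, 0, 0), role = "ligand"),
    list(name = "H1", el = "H", res = "LIG", rid = 1, xyz = c(0.96, 0, 0), role = "ligand"),
    list(name = "OG", el = "O", res = "SER", rid = 5, xyz = c(2.96, 0, 0), role = "receptor"),
    list(name = "CB", el = "C", res = "SER", rid = 5, xyz = c(1.6, 0, 0), role = "receptor")))
  expect_equal(nrow(detect_hbonds(axv)), 0)
})

test_that("planted multi-HB fixtures match an exhaustive pairwise oracle", {
  cx <- make_toy_complex(n_hb = 3)
  got <- detect_hbonds(cx$structure)
  expect_equal(nrow(got), 3)
  # independent oracle: enumerate every (N/O + bonded H) x (N/O) pair
  # across the interface and test the three criteria directly
  at <- cx$structure$atoms
  xyz <- mol_xyz(cx$structure)
  d <- as.matrix(dist(xyz))
  n_expect <- 0
  for (di in which(at$element %in% c("N", "O"))) {
    hs <- which(at$element == "H" & d[di, ] < 1.8)
    for (h in hs) for (ai in which(at$element %in% c("N", "O"))) {
      if (ai == di || at$role[ai] == at$role[di]) next
      if (d[h, ai] > 2.8) next
      v1 <- xyz[di, ] - xyz[h, ]; v2 <- xyz[ai, ] - xyz[h, ]
      dha <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (dha < 120) next
      xs <- which(d[ai, ] < 1.8 & at$element != "H" & seq_len(nrow(at)) != ai)
      ok <- all(vapply(xs, function(x) {
        u <- xyz[h, ] - xyz[ai, ]; w <- xyz[x, ] - xyz[ai, ]
        acos(sum(u * w) / sqrt(sum(u^2) * sum(w^2))) * 180 / pi >= 90
      }, TRUE))
      if (ok) n_expect <- n_expect + 1
    }
  }
  expect_equal(nrow(got), n_expect)
})

.benzene <- function(center, normal_axis = "z") {
  ang <- (0:5) * pi / 3
  ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  if (normal_axis == "x") ring <- ring[, c(3, 1, 2)]
  sweep(ring, 2, center, `+`)
}

.ring_complex <- function(lig_center, rec_center, rec_axis = "z") {
  rows <- list()
  lr <- .benzene(lig_center)
  rr <- .benzene(rec_center, rec_axis)
  for (k in 1:6) rows[[k]] <- list(name = paste0("CL", k), el = "C",
                                   res = "LIG", rid = 1, xyz = lr[k, ],
                                   role = "ligand")
  for (k in 1:6) rows[[6 + k]] <- list(name = paste0("CR", k), el = "C",
                                       res = "PHE", rid = 9, xyz = rr[k, ],
                                       role = "receptor")
  m <- .mk(rows)
  list(mol = m, rings = list(1:6, 7:12))
}

test_that("pi-pi stacking distinguishes face-to-face and edge-to-face", {
  f2f <- .ring_complex(c(0, 0, 0), c(0, 0, 3.8))
  got <- detect_pipi(f2f$mol, f2f$rings)
  expect_equal(nrow(got), 1)
  expect_equal(got$direction, "f2f")

  e2f <- .ring_complex(c(0, 0, 0), c(0, 0, 5.0), rec_axis = "x")
  got <- detect_pipi(e2f$mol, e2f$rings)
  expect_equal(nrow(got), 1)
  expect_equal(got$direction, "e2f")

  far <- .ring_complex(c(0, 0, 0), c(0, 0, 6.0))
  expect_equal(nrow(detect_pipi(far$mol, far$rings)), 0)
  expect_error(detect_pipi(f2f$mol, list(1:2, 7:12)), "<3 atoms")
})

test_that("ionic bridges require opposite charges within the cutoff", {
  mk_pair <- function(d, lig_fc = 1, rec_res = "ASP") .mk(list(
    list(name = "N1", el = "N", res = "LIG", rid = 1, xyz = c(0, 0, 0),
         role = "ligand", fc = lig_fc),
    list(name = "OD1", el = "O", res = rec_res, rid = 3, xyz = c(d, 0, 0),
         role = "receptor")))
  expect_equal(nrow(detect_ionic(mk_pair(3.0))), 1)
  expect_equal(nrow(detect_ionic(mk_pair(5.0))), 0)
  # like charges never bridge
  like <- .mk(list(
    list(name = "N1", el = "N", res = "LIG", rid = 1, xyz = c(0, 0, 0),
         role = "ligand", fc = 1),
    list(name = "NZ", el = "N", res = "LYS", rid = 3, xyz = c(3, 0, 0),
         role = "receptor")))
  expect_equal(nrow(detect_ionic(like)), 0)
  # no charge information at all is an error
  none <- .mk(list(
    list(name = "C1", el = "C", res = "LIG", rid = 1, xyz = c(0, 0, 0),
         role = "ligand"),
    list(name = "CB", el = "C", res = "GLY", rid = 3, xyz = c(3, 0, 0),
         role = "receptor")))
  expect_error(detect_ionic(none), "no charge assignments")
})

test_that("hydrophobic contacts exclude polar carbons and group by residue", {
  two_c <- .mk(list(
    list(name = "C1", el = "C", res = "LIG", rid = 1, xyz = c(0, 0, 0), role = "ligand"),
    list(name = "CD1", el = "C", res = "LEU", rid = 7, xyz = c(4, 0, 0), role = "receptor")))
  expect_equal(nrow(detect_hydrophobic(two_c)), 1)

  # carbonyl carbon (bonded to O) is polar: excluded
  carbonyl <- .mk(list(
    list(name = "C1", el = "C", res = "LIG", rid = 1, xyz = c(0, 0, 0), role = "ligand"),
    list(name = "O1", el = "O", res = "LIG", rid = 1, xyz = c(0, 1.23, 0), role = "ligand"),
    list(name = "CD1", el = "C", res = "LEU", rid = 7, xyz = c(4, 0, 0), role = "receptor")))
  expect_equal(nrow(detect_hydrophobic(carbonyl)), 0)

  cx <- make_toy_complex(n_hydrophobic = 2)
  expect_equal(nrow(detect_hydrophobic(cx$structure)), 2)
})

test_that("all detectors are invariant under rigid transforms", {
  cx <- make_toy_complex(n_hb = 2, n_pipi = 1, n_ionic = 1,
                         n_hydrophobic = 1)
  before <- detect_interactions(cx$structure, cx$ring_defs)
  for (s in c(11, 12, 13)) {
    moved <- transform_mol(cx$structure, s)
    after <- detect_interactions(moved, cx$ring_defs)
    expect_equal(after$kind, before$kind)
    expect_equal(after$res_id, before$res_id)
    expect_equal(after$distance, before$distance, tolerance = 1e-8)
  }
})

test_that("larger distance cutoffs never remove detected records", {
  cx <- make_toy_complex(n_hb = 2, n_ionic = 1, n_hydrophobic = 2)
  n_hb <- sapply(c(2.0, 2.8, 4.0), function(d)
    nrow(detect_hbonds(cx$structure, d_ha_max = d)))
  n_io <- sapply(c(3.5, 4.0, 6.0), function(d)
    nrow(detect_ionic(cx$structure, d_max = d)))
  n_hy <- sapply(c(4.0, 4.5, 6.0), function(d)
    nrow(detect_hydrophobic(cx$structure, d_max = d)))
  expect_true(all(diff(n_hb) >= 0))
  expect_true(all(diff(n_io) >= 0))
  expect_true(all(diff(n_hy) >= 0))
})

test_that("SIFt bits encode residue contacts deterministically", {
  cx <- make_toy_complex(n_hb = 1)
  fp <- build_sift(cx$structure, cx$receptor_site)
  r <- which(cx$receptor_site$res_name == "SER")
  expect_equal(unname(fp$bits[r, "any_contact"]), 1L)
  expect_equal(unname(fp$bits[r, "polar"]), 1L)
  # ligand donates, so the residue is the acceptor
  expect_equal(unname(fp$bits[r, "hb_acceptor"]), 1L)
  expect_equal(unname(fp$bits[r, "hb_donor"]), 0L)
  # untouched residues are all-zero
  expect_true(all(fp$bits[-r, ] == 0))
  # any_contact is the OR of the remaining bits
  expect_equal(fp$bits[, "any_contact"],
               as.integer(rowSums(fp$bits[, -1]) > 0))

  # no contacts at all: zero matrix
  far <- cx$structure
  lig <- role_idx(far, "ligand")
  far$atoms$y[lig] <- far$atoms$y[lig] - 50
  expect_true(all(build_sift(far, cx$receptor_site)$bits == 0))

  # planted HB + ring stack matches the hand-built matrix
  cx2 <- make_toy_complex(n_hb = 1, n_pipi = 1)
  fp2 <- build_sift(cx2$structure, cx2$receptor_site,
                    ring_defs = cx2$ring_defs)
  hand <- matrix(0L, nrow(cx2$receptor_site), 9,
                 dimnames = list(NULL, colnames(fp2$bits)))
  ser <- which(cx2$receptor_site$res_name == "SER")
  phe <- which(cx2$receptor_site$res_name == "PHE")
  hand[ser, c("any_contact", "sidechain", "polar", "hb_acceptor")] <- 1L
  hand[phe, c("any_contact", "sidechain", "aromatic", "hydrophobic")] <- 1L
  expect_equal(fp2$bits, hand)
  expect_error(build_sift(cx$structure, cx$receptor_site[0, ]), "at least one")
})

test_that("tanimoto similarity has its closed-form values and bounds", {
  cx <- make_toy_complex(n_hb = 1, n_pipi = 1)
  fp <- build_sift(cx2 <- cx$structure, cx$receptor_site,
                   ring_defs = cx$ring_defs)
  expect_equal(tanimoto(fp, fp), 1.0)

  mk_fp <- function(bits_idx, n_res = 4) {
    res <- data.frame(chain = "A", res_id = 1:n_res, res_name = "GLY")
    bits <- matrix(0L, n_res, 9,
                   dimnames = list(NULL, colnames(fp$bits)))
    bits[bits_idx] <- 1L
    structure(list(residues = res, bits = bits), class = "sift")
  }
  a <- mk_fp(cbind(c(1, 1, 2), c(1, 4, 6)))
  b <- mk_fp(cbind(c(3, 4), c(2, 3)))
  expect_equal(tanimoto(a, b), 0.0)
  # 3 shared bits of 5 total set
  c1 <- mk_fp(cbind(c(1, 1, 2, 3), c(1, 4, 6, 2)))
  c2 <- mk_fp(cbind(c(1, 1, 2, 4), c(1, 4, 6, 3)))
  expect_equal(tanimoto(c1, c2), 0.6)
  # both all-zero: defined as 1
  z1 <- mk_fp(cbind(1, 1)); z1$bits[] <- 0L
  z2 <- mk_fp(cbind(2, 2)); z2$bits[] <- 0L
  expect_equal(tanimoto(z1, z2), 1)
  expect_error(tanimoto(a, mk_fp(cbind(1, 1), n_res = 5)),
               "different residue lists")

  # property: symmetric and within [0, 1] over random fingerprints
  set.seed(99)
  for (i in 1:1000) {
    u <- mk_fp(cbind(sample(4, 3, TRUE), sample(9, 3, TRUE)))
    v <- mk_fp(cbind(sample(4, 3, TRUE), sample(9, 3, TRUE)))
    tv <- tanimoto(u, v)
    expect_true(tv >= 0 && tv <= 1)
    expect_identical(tv, tanimoto(v, u))
  }
})

# fingerprint archetypes for clustering tests
.archetype_poses <- function(scores, groups) {
  res <- data.frame(chain = "A", res_id = 1:6, res_name = "GLY")
  base <- make_toy_complex(n_hb = 1)$structure
  lapply(seq_along(scores), function(i) {
    bits <- matrix(0L, 6, 9, dimnames = list(NULL, poseval:::.SIFT_BITS))
    bits[groups[i], c(1, 4)] <- 1L      # archetype g touches residue g
    fp <- structure(list(residues = res, bits = bits), class = "sift")
    pose_record(sprintf("pose-%02d", i), base, scores[i], fp)
  })
}

test_that("pose clustering partitions by archetype and keeps best scores", {
  # four identical fingerprints: one cluster, lowest score kept
  p4 <- .archetype_poses(c(-8, -9.5, -7, -9), rep(1, 4))
  cl <- cluster_poses(p4)
  expect_equal(cl$n_clusters, 1)
  expect_equal(cl$representatives[[1]]$pose_id, "pose-02")

  # disjoint fingerprints: separate clusters
  p2 <- .archetype_poses(c(-8, -9), c(1, 2))
  expect_equal(cluster_poses(p2)$n_clusters, 2)

  # 8 poses from 4 archetypes: 4 clusters matching a brute-force check
  set.seed(5)
  groups <- c(1, 2, 3, 4, 1, 2, 3, 4)
  scores <- round(runif(8, -10, -6), 2)
  p8 <- .archetype_poses(scores, groups)
  cl8 <- cluster_poses(p8)
  expect_equal(cl8$n_clusters, 4)
  got_parts <- lapply(cl8$clusters, sort)
  want_parts <- lapply(split(sprintf("pose-%02d", 1:8), groups), sort)
  expect_setequal(got_parts, unname(want_parts))
  # every pose in exactly one cluster
  expect_setequal(unlist(cl8$clusters), sprintf("pose-%02d", 1:8))
  # brute-force representative: per-group score minimum
  for (g in 1:4) {
    ids <- sprintf("pose-%02d", which(groups == g))
    best <- ids[which.min(scores[groups == g])]
    reps <- vapply(cl8$representatives, `[[`, "", "pose_id")
    expect_true(best %in% reps)
  }

  # permutation invariance of the partition
  perm <- c(5, 2, 8, 1, 6, 3, 7, 4)
  clp <- cluster_poses(p8[perm])
  expect_setequal(lapply(clp$clusters, sort), got_parts)
  expect_error(cluster_poses(list()), "empty")
})

test_that("top-k selection is score-ascending and tolerant of short lists", {
  set.seed(8)
  reps <- .archetype_poses(runif(15, -12, -6), rep(1:5, 3))
  top <- select_top_k(reps, 3)
  expect_length(top, 3)
  sc <- vapply(top, `[[`, 0, "score")
  expect_true(all(diff(sc) >= 0))
  expect_equal(sc[1], min(vapply(reps, `[[`, 0, "score")))
  expect_length(select_top_k(reps[1:2], 3), 2)
  one <- select_top_k(reps, 1)
  expect_equal(one[[1]]$score, min(vapply(reps, `[[`, 0, "score")))
})
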