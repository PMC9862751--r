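# Geometric detection of ligand-receptor interactions (hydrogen bonds,
# pi-pi stacking, ionic bridges, hydrophobic contacts), structural
# interaction fingerprints (SIFt) and contact-similarity pose clustering.

.SIFT_BITS <- c("any_contact", "backbone", "sidechain", "polar",
                "hydrophobic", "hb_donor", "hb_acceptor", "aromatic",
                "charged")
.BACKBONE_NAMES <- c("N", "CA", "C", "O")

.empty_records <- function() {
  data.frame(kind = character(0), ligand_atoms = character(0),
             chain = character(0), res_id = numeric(0),
             res_name = character(0), direction = character(0),
             distance = numeric(0), angle = numeric(0),
             receptor_atom = numeric(0), donor_serial = numeric(0),
             h_serial = numeric(0), acceptor_serial = numeric(0),
             stringsAsFactors = FALSE)
}

.record_row <- function(kind, lig_serials, rec_atom_row, direction,
                        distance, angle = NA_real_, donor = NA_real_,
                        h = NA_real_, acceptor = NA_real_) {
  data.frame(kind = kind,
             ligand_atoms = paste(lig_serials, collapse = "+"),
             chain = rec_atom_row$chain, res_id = rec_atom_row$res_id,
             res_name = rec_atom_row$res_name, direction = direction,
             distance = distance, angle = angle,
             receptor_atom = rec_atom_row$serial, donor_serial = donor,
             h_serial = h, acceptor_serial = acceptor,
             stringsAsFactors = FALSE)
}

.dist_mat <- function(a, b) {
  # pairwise Euclidean distances between rows of a and b
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * (a %*% t(b))
  sqrt(pmax(d2, 0))
}

#' Covalent bond list from a distance heuristic
#'
#' Atom pairs closer than `cutoff` Angstrom are taken as bonded.  Used
#' for donor/acceptor typing and hydrophobic-carbon polarity rules; the
#' package performs no bond-order perception.
#'
#' @param mol a `mol` object.
#' @param cutoff bond distance cutoff, Angstrom.
#' @return two-column matrix of atom indices (i < j).
#' @export
bond_list <- function(mol, cutoff = 1.8) {
  xyz <- mol_xyz(mol)
  d <- .dist_mat(xyz, xyz)
  diag(d) <- Inf
  which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
}

.angle_deg <- function(a, b, c) {
  # angle at vertex b, degrees
  u <- a - b; v <- c - b
  cosv <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
}

# geometry test shared by detect_hbonds and the persistence scorer
.hb_geometry_ok <- function(xyz, d_i, h_i, a_i, x_i, d_ha_max, dha_min,
                            hax_min) {
  dha <- sqrt(sum((xyz[h_i, ] - xyz[a_i, ])^2))
  if (dha > d_ha_max) return(FALSE)
  if (.angle_deg(xyz[d_i, ], xyz[h_i, ], xyz[a_i, ]) < dha_min) return(FALSE)
  if (length(x_i)) {
    for (x in x_i) {
      if (.angle_deg(xyz[h_i, ], xyz[a_i, ], xyz[x, ]) < hax_min)
        return(FALSE)
    }
  }
  TRUE
}

#' Detect ligand-receptor hydrogen bonds
#'
#' Donors are N/O atoms with a covalently bonded hydrogen; acceptors are
#' N/O atoms.  A bond is recorded when all three Maestro-style criteria
#' hold: H...A distance <= `d_ha_max`, D-H...A angle >= `dha_min`, and
#' every H...A-X angle (X = heavy atoms bonded to the acceptor)
#' >= `hax_min`.  Only pairs spanning the ligand/receptor interface are
#' reported; `direction` is the ligand's role in the bond.
#'
#' @param complex `mol` with roles assigned and hydrogens present.
#' @param d_ha_max H...A distance cutoff, Angstrom.
#' @param dha_min donor angle cutoff, degrees.
#' @param hax_min acceptor angle cutoff, degrees.
#' @return data frame of interaction records (one per donor-H/acceptor
#'   pair), including `donor_serial`, `h_serial`, `acceptor_serial` so
#'   the persistence scorer can re-test the same bonds on later frames.
#' @export
detect_hbonds <- function(complex, d_ha_max = 2.8, dha_min = 120,
                          hax_min = 90) {
  at <- complex$atoms
  xyz <- mol_xyz(complex)
  bonds <- bond_list(complex)
  adj <- vector("list", nrow(at))
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  polar <- which(at$element %in% c("N", "O"))
  donors <- list()
  for (d in polar) {
    hs <- adj[[d]][at$element[adj[[d]]] == "H"]
    for (h in hs) donors[[length(donors) + 1]] <- c(d, h)
  }
  recs <- .empty_records()
  for (dh in donors) {
    d_i <- dh[1]; h_i <- dh[2]
    for (a_i in polar) {
      if (a_i == d_i) next
      # interface only: donor and acceptor on opposite roles
      rd <- at$role[d_i]; ra <- at$role[a_i]
      if (!((rd == "ligand" && ra == "receptor") ||
            (rd == "receptor" && ra == "ligand"))) next
      x_i <- adj[[a_i]][at$element[adj[[a_i]]] != "H"]
      if (!.hb_geometry_ok(xyz, d_i, h_i, a_i, x_i, d_ha_max, dha_min,
                           hax_min)) next
      lig_side <- if (rd == "ligand") c(d_i, h_i) else a_i
      rec_side <- if (rd == "ligand") a_i else d_i
      recs <- rbind(recs, .record_row(
        "hb", at$serial[lig_side], at[rec_side, , drop = FALSE],
        direction = if (rd == "ligand") "donor" else "acceptor",
        distance = sqrt(sum((xyz[h_i, ] - xyz[a_i, ])^2)),
        angle = .angle_deg(xyz[d_i, ], xyz[h_i, ], xyz[a_i, ]),
        donor = at$serial[d_i], h = at$serial[h_i],
        acceptor = at$serial[a_i]))
    }
  }
  recs
}

.ring_geometry <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(center = ctr, normal = sv$v[, 3],
       planarity = max(abs(sweep(xyz, 2, ctr) %*% sv$v[, 3])))
}

#' Detect pi-pi stacking between declared aromatic rings
#'
#' Ring membership must be supplied (`ring_defs`, a list of atom-serial
#' vectors); the package performs no aromatic perception.  Face-to-face
#' stacking: centroid distance <= `d_f2f` and interplanar angle <= 30
#' degrees.  Edge-to-face: distance <= `d_e2f` and angle in 60-120
#' degrees.
#'
#' @param complex `mol` with roles assigned.
#' @param ring_defs list of integer vectors of atom serials (>= 3 atoms
#'   each, planar within ~0.2 Angstrom).
#' @param d_f2f face-to-face centroid distance cutoff, Angstrom.
#' @param d_e2f edge-to-face centroid distance cutoff, Angstrom.
#' @return data frame of interaction records (kind `"pipi"`; `direction`
#'   records `"f2f"`/`"e2f"`).
#' @export
detect_pipi <- function(complex, ring_defs, d_f2f = 4.4, d_e2f = 5.5) {
  at <- complex$atoms
  xyz <- mol_xyz(complex)
  if (!length(ring_defs)) return(.empty_records())
  rings <- lapply(ring_defs, function(serials) {
    idx <- match(serials, at$serial)
    if (anyNA(idx)) stop("ring definition names unknown atom serial(s)")
    if (length(idx) < 3) stop("ring with <3 atoms")
    g <- .ring_geometry(xyz[idx, , drop = FALSE])
    g$idx <- idx
    g$role <- if (any(at$role[idx] == "ligand")) "ligand" else "receptor"
    g
  })
  lig <- rings[vapply(rings, function(r) r$role == "ligand", TRUE)]
  rec <- rings[vapply(rings, function(r) r$role == "receptor", TRUE)]
  recs <- .empty_records()
  for (L in lig) for (R in rec) {
    d <- sqrt(sum((L$center - R$center)^2))
    ang <- acos(pmin(abs(sum(L$normal * R$normal)), 1)) * 180 / pi
    mode <- NULL
    if (d <= d_f2f && ang <= 30) mode <- "f2f"
    else if (d <= d_e2f && ang >= 60) mode <- "e2f"  # folded angle <= 90
    if (is.null(mode)) next
    recs <- rbind(recs, .record_row(
      "pipi", at$serial[L$idx], at[R$idx[1], , drop = FALSE],
      direction = mode, distance = d, angle = ang))
  }
  recs
}

#' Assign formal charges from residue templates
#'
#' pH-7 templates: Asp/Glu side-chain carboxylate oxygens -1, Lys NZ and
#' Arg NH1/NH2/NE +1.  Atoms with an explicit `formal_charge` value keep
#' it.
#'
#' @param mol a `mol` object.
#' @return `mol` with `formal_charge` filled where a template matches.
#' @export
assign_formal_charges <- function(mol) {
  at <- mol$atoms
  fc <- at$formal_charge
  neg <- at$res_name %in% c("ASP", "GLU") &
    at$name %in% c("OD1", "OD2", "OE1", "OE2")
  pos <- (at$res_name == "LYS" & at$name == "NZ") |
    (at$res_name == "ARG" & at$name %in% c("NH1", "NH2", "NE"))
  fc[is.na(fc) & neg] <- -1
  fc[is.na(fc) & pos] <- 1
  mol$atoms$formal_charge <- fc
  mol
}

#' Detect ionic bridges (salt bridges)
#'
#' Records one interaction per opposite-formal-charge atom pair across
#' the ligand/receptor interface within `d_max` Angstrom.  Charges come
#' from the `formal_charge` column, topped up by the pH-7 residue
#' templates of [assign_formal_charges()].
#'
#' @param complex `mol` with roles assigned.
#' @param d_max distance cutoff, Angstrom.
#' @return data frame of interaction records (kind `"ionic"`).
#' @export
detect_ionic <- function(complex, d_max = 4.0) {
  complex <- assign_formal_charges(complex)
  at <- complex$atoms
  if (all(is.na(at$formal_charge)))
    stop("no charge assignments available (no formal_charge values and no template residues)")
  xyz <- mol_xyz(complex)
  lig <- which(at$role == "ligand" & !is.na(at$formal_charge) &
                 at$formal_charge != 0)
  rec <- which(at$role == "receptor" & !is.na(at$formal_charge) &
                 at$formal_charge != 0)
  recs <- .empty_records()
  for (i in lig) for (j in rec) {
    if (sign(at$formal_charge[i]) == sign(at$formal_charge[j])) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d > d_max) next
    recs <- rbind(recs, .record_row("ionic", at$serial[i],
                                    at[j, , drop = FALSE],
                                    direction = "n/a", distance = d))
  }
  recs
}

#' Detect hydrophobic contacts
#'
#' Nonpolar heavy atoms are carbons/sulfurs not covalently bonded to N or
#' O.  One record is emitted per receptor residue having at least one
#' nonpolar-nonpolar pair with the ligand within `d_max` Angstrom; its
#' distance is the closest such pair.
#'
#' @param complex `mol` with roles assigned.
#' @param d_max contact distance cutoff, Angstrom.
#' @return data frame of interaction records (kind `"hydrophobic"`).
#' @export
detect_hydrophobic <- function(complex, d_max = 4.5) {
  at <- complex$atoms
  xyz <- mol_xyz(complex)
  bonds <- bond_list(complex)
  polar_nbr <- rep(FALSE, nrow(at))
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    if (at$element[j] %in% c("N", "O")) polar_nbr[i] <- TRUE
    if (at$element[i] %in% c("N", "O")) polar_nbr[j] <- TRUE
  }
  nonpolar <- at$element %in% c("C", "S") & !polar_nbr
  lig <- which(at$role == "ligand" & nonpolar)
  rec <- which(at$role == "receptor" & nonpolar)
  recs <- .empty_records()
  if (!length(lig) || !length(rec)) return(recs)
  d <- .dist_mat(xyz[lig, , drop = FALSE], xyz[rec, , drop = FALSE])
  for (res in split(seq_along(rec),
                    paste(at$chain[rec], at$res_id[rec]))) {
    sub <- d[, res, drop = FALSE]
    if (min(sub) > d_max) next
    hit <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    j <- rec[res[hit[2]]]
    recs <- rbind(recs, .record_row(
      "hydrophobic", at$serial[lig[hit[1]]],
      at[j, , drop = FALSE], direction = "n/a", distance = min(sub)))
  }
  recs[order(recs$chain, recs$res_id), , drop = FALSE]
}

#' Run every interaction detector on a complex
#'
#' @param complex `mol` with roles assigned.
#' @param ring_defs optional ring definitions for [detect_pipi()].
#' @param hb,ionic,hydrophobic named lists of cutoff overrides.
#' @return combined record data frame.
#' @export
detect_interactions <- function(complex, ring_defs = list(), hb = list(),
                                ionic = list(), hydrophobic = list()) {
  out <- do.call(detect_hbonds, c(list(complex), hb))
  if (length(ring_defs))
    out <- rbind(out, detect_pipi(complex, ring_defs))
  ion <- tryCatch(do.call(detect_ionic, c(list(complex), ionic)),
                  error = function(e) .empty_records())
  out <- rbind(out, ion)
  rbind(out, do.call(detect_hydrophobic, c(list(complex), hydrophobic)))
}

# ---- pose records and fingerprints ---------------------------------------

#' Construct a pose record
#' @param pose_id identifier string.
#' @param structure `mol` of the receptor-ligand complex.
#' @param score docking/IFD-style score, kcal/mol (lower is better).
#' @param fingerprint optional precomputed [build_sift()] fingerprint.
#' @return object of class `pose_record`.
#' @export
pose_record <- function(pose_id, structure, score, fingerprint = NULL) {
  if (!is.finite(score)) stop("pose score must be finite")
  structure(list(pose_id = pose_id, structure = structure, score = score,
                 fingerprint = fingerprint), class = "pose_record")
}

#' Structural interaction fingerprint (SIFt) of a pose
#'
#' Per binding-site residue, nine bits: any_contact, backbone, sidechain,
#' polar, hydrophobic, hb_donor, hb_acceptor, aromatic, charged.  The
#' donor/acceptor bits describe the *residue's* role in the hydrogen
#' bond.  `any_contact` is the OR of the remaining bits.  Residues are
#' ordered by (chain, res_id).
#'
#' @param pose a `pose_record` (or a bare `mol`).
#' @param receptor_site data frame with columns `chain`, `res_id` naming
#'   the binding-site residues.
#' @param ring_defs optional ring definitions for the aromatic bit.
#' @param records optional precomputed [detect_interactions()] output.
#' @return object of class `sift`: list with `residues` and a
#'   `n_residues x 9` binary `bits` matrix.
#' @export
build_sift <- function(pose, receptor_site, ring_defs = list(),
                       records = NULL) {
  mol <- if (inherits(pose, "pose_record")) pose$structure else pose
  if (is.null(receptor_site) || !nrow(receptor_site))
    stop("receptor_site must name at least one residue")
  receptor_site <- receptor_site[order(receptor_site$chain,
                                       receptor_site$res_id), , drop = FALSE]
  if (is.null(records)) records <- detect_interactions(mol, ring_defs)
  bits <- matrix(0L, nrow(receptor_site), length(.SIFT_BITS),
                 dimnames = list(NULL, .SIFT_BITS))
  at <- mol$atoms
  for (r in seq_len(nrow(records))) {
    rec <- records[r, ]
    ridx <- which(receptor_site$chain == rec$chain &
                    receptor_site$res_id == rec$res_id)
    if (!length(ridx)) next
    atom_name <- at$name[match(rec$receptor_atom, at$serial)]
    if (!is.na(atom_name) && atom_name %in% .BACKBONE_NAMES)
      bits[ridx, "backbone"] <- 1L
    else bits[ridx, "sidechain"] <- 1L
    switch(rec$kind,
           hb = {
             bits[ridx, "polar"] <- 1L
             # record direction is the ligand's role; invert for residue
             if (rec$direction == "donor") bits[ridx, "hb_acceptor"] <- 1L
             else bits[ridx, "hb_donor"] <- 1L
           },
           ionic = {
             bits[ridx, "polar"] <- 1L
             bits[ridx, "charged"] <- 1L
           },
           pipi = bits[ridx, "aromatic"] <- 1L,
           hydrophobic = bits[ridx, "hydrophobic"] <- 1L)
  }
  bits[, "any_contact"] <- as.integer(rowSums(bits[, -1, drop = FALSE]) > 0)
  structure(list(residues = receptor_site, bits = bits), class = "sift")
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|` over the flattened bit matrices; defined as 1
#' when both fingerprints are all-zero.
#'
#' @param a,b `sift` objects over the identical residue list.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  if (!identical(dim(a$bits), dim(b$bits)) ||
      !identical(a$residues$chain, b$residues$chain) ||
      !identical(a$residues$res_id, b$residues$res_id))
    stop("fingerprints are defined over different residue lists")
  va <- as.logical(a$bits); vb <- as.logical(b$bits)
  un <- sum(va | vb)
  if (un == 0) return(1)
  sum(va & vb) / un
}

#' Cluster poses by fingerprint similarity
#'
#' Deterministic complete-linkage agglomeration: clusters are merged
#' while the *minimum* pairwise Tanimoto similarity between them is
#' >= `sim_threshold` (every member of a final cluster is within the
#' threshold of every other).  Ties in merge order are broken by the
#' lexicographically smallest pose-id pair, so the partition does not
#' depend on input order.  Each cluster keeps its best-scoring (lowest
#' score) pose as representative, ties broken by pose id.
#'
#' @param poses list of `pose_record`s with fingerprints computed.
#' @param sim_threshold Tanimoto threshold in [0, 1].
#' @return list with `n_poses`, `n_clusters`, `clusters` (list of
#'   pose-id vectors) and `representatives` (list of `pose_record`).
#' @export
cluster_poses <- function(poses, sim_threshold = 0.7) {
  if (!length(poses)) stop("empty pose list")
  ids <- vapply(poses, function(p) p$pose_id, "")
  if (anyDuplicated(ids)) stop("duplicate pose ids")
  fps <- lapply(poses, function(p) {
    if (is.null(p$fingerprint)) stop("pose ", p$pose_id,
                                     " has no fingerprint")
    p$fingerprint
  })
  n <- length(poses)
  S <- diag(1, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      S[i, j] <- S[j, i] <- tanimoto(fps[[i]], fps[[j]])
  }
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) < 2) break
    best <- NULL; best_sim <- -Inf; best_key <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      link <- min(S[clusters[[i]], clusters[[j]]])
      if (link < sim_threshold) next
      key <- paste(sort(c(sort(ids[clusters[[i]]])[1],
                          sort(ids[clusters[[j]]])[1])), collapse = "|")
      if (link > best_sim || (link == best_sim && key < best_key)) {
        best <- c(i, j); best_sim <- link; best_key <- key
      }
    }
    if (is.null(best)) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  # canonical order: by best pose id within each cluster
  lead <- vapply(clusters, function(cl) sort(ids[cl])[1], "")
  clusters <- clusters[order(lead)]
  reps <- lapply(clusters, function(cl) {
    sc <- vapply(cl, function(k) poses[[k]]$score, 0)
    cand <- cl[sc == min(sc)]
    poses[[cand[order(ids[cand])[1]]]]
  })
  list(n_poses = n, n_clusters = length(clusters),
       clusters = lapply(clusters, function(cl) sort(ids[cl])),
       representatives = reps)
}

#' Select the top-k cluster representatives by score
#'
#' @param representatives list of `pose_record`s.
#' @param k number to keep (fewer are returned when fewer exist).
#' @return list of `pose_record`s, score-ascending.
#' @export
select_top_k <- function(representatives, k = 3) {
  if (k < 1) stop("k must be >= 1")
  sc <- vapply(representatives, function(p) p$score, 0)
  ids <- vapply(representatives, function(p) p$pose_id, "")
  ord <- order(sc, ids)
  representatives[ord][seq_len(min(k, length(representatives)))]
}

#' Write interaction records to CSV
#' @param records data frame from the detectors.
#' @param path output CSV path.
#' @param pose_id identifier column value.
#' @return `path`, invisibly.
#' @export
write_interaction_report <- function(records, path, pose_id = "") {
  out <- cbind(pose_id = pose_id,
               records[, c("kind", "chain", "res_id", "res_name",
                           "direction", "distance", "angle")])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
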