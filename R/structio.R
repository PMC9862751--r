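# Core structural containers, PDB/PDBQT/XYZ readers and writers,
# rigid-body superposition, RMSD, and docking-box geometry.

# element symbols accepted by the parsers (H through Og)
.ELEMENTS <- c(
  "H", "HE", "LI", "BE", "B", "C", "N", "O", "F", "NE", "NA", "MG", "AL",
  "SI", "P", "S", "CL", "AR", "K", "CA", "SC", "TI", "V", "CR", "MN", "FE",
  "CO", "NI", "CU", "ZN", "GA", "GE", "AS", "SE", "BR", "KR", "RB", "SR",
  "Y", "ZR", "NB", "MO", "TC", "RU", "RH", "PD", "AG", "CD", "IN", "SN",
  "SB", "TE", "I", "XE", "CS", "BA", "LA", "CE", "PR", "ND", "PM", "SM",
  "EU", "GD", "TB", "DY", "HO", "ER", "TM", "YB", "LU", "HF", "TA", "W",
  "RE", "OS", "IR", "PT", "AU", "HG", "TL", "PB", "BI", "PO", "AT", "RN",
  "FR", "RA", "AC", "TH", "PA", "U"
)

.norm_element <- function(el) {
  el <- toupper(trimws(el))
  ok <- el %in% .ELEMENTS
  if (!all(ok)) {
    stop("unknown element symbol(s): ", paste(unique(el[!ok]), collapse = ", "))
  }
  # restore conventional capitalisation (Cl, Zn, ...)
  idx <- match(el, .ELEMENTS)
  canon <- c(.ELEMENTS)
  canon <- paste0(substr(canon, 1, 1), tolower(substr(canon, 2, 2)))
  canon[idx]
}

#' Construct a molecular structure
#'
#' A `mol` object is the package's central container: an ordered atom
#' table (one row per atom, coordinates in Angstrom) plus a title.
#' Optional per-atom energetics columns (`charge`, `lj_sigma`,
#' `lj_epsilon`, `gb_radius`, `gb_screen`, `formal_charge`) are carried
#' alongside so that the GB/SA module never needs an external force
#' field.
#'
#' @param atoms data frame with at least columns `serial`, `name`,
#'   `element`, `res_name`, `res_id`, `chain`, `x`, `y`, `z`.  A `role`
#'   column (`"receptor"`, `"ligand"` or `"other"`) marks which molecule
#'   each atom belongs to.
#' @param title free-text title.
#' @return object of class `mol`.
#' @export
mol_structure <- function(atoms, title = "") {
  req <- c("serial", "name", "element", "res_name", "res_id", "chain",
           "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!nrow(atoms)) stop("structure must contain at least one atom")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  if (any(atoms$res_id < 1)) stop("res_id must be >= 1 (PDB convention)")
  atoms$element <- .norm_element(atoms$element)
  if (is.null(atoms$role)) atoms$role <- "other"
  for (col in c("charge", "lj_sigma", "lj_epsilon", "gb_radius",
                "gb_screen", "formal_charge")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  }
  atoms$is_heavy <- atoms$element != "H"
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title), class = "mol")
}

#' @export
print.mol <- function(x, ...) {
  cat(sprintf("<mol> %d atoms (%d heavy), %d residue(s)%s\n",
              nrow(x$atoms), sum(x$atoms$is_heavy),
              nrow(unique(x$atoms[, c("chain", "res_id")])),
              if (nzchar(x$title)) paste0(" - ", x$title) else ""))
  invisible(x)
}

#' Number of atoms in a structure
#' @param mol a `mol` object.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Coordinate matrix of a structure
#' @param mol a `mol` object.
#' @param idx optional row indices.
#' @return N x 3 numeric matrix (Angstrom).
#' @export
mol_xyz <- function(mol, idx = NULL) {
  m <- as.matrix(mol$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

#' Replace the coordinates of a structure
#' @param mol a `mol` object.
#' @param xyz N x 3 matrix matching the atom count.
#' @return updated `mol`.
#' @export
set_xyz <- function(mol, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != n_atoms(mol) || ncol(xyz) != 3)
    stop("coordinate matrix must be n_atoms x 3")
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

#' Subset a structure by atom index
#' @param mol a `mol` object.
#' @param idx logical or integer atom selector.
#' @return `mol` containing the selected atoms, order preserved.
#' @export
mol_subset <- function(mol, idx) {
  at <- mol$atoms[idx, , drop = FALSE]
  if (!nrow(at)) stop("empty atom selection")
  mol_structure(at, title = mol$title)
}

#' Indices of atoms by role
#' @param mol a `mol` object.
#' @param role one of `"receptor"`, `"ligand"`, `"other"`.
#' @param heavy_only drop hydrogens.
#' @return integer indices.
#' @export
role_idx <- function(mol, role, heavy_only = FALSE) {
  i <- which(mol$atoms$role == role)
  if (heavy_only) i <- i[mol$atoms$is_heavy[i]]
  i
}

#' Assign receptor/ligand roles
#'
#' Roles can be assigned by residue name (e.g. the ligand's HET code) or
#' by chain.  Atoms not matched keep their current role.
#'
#' @param mol a `mol` object.
#' @param ligand_res_name residue name(s) to label as ligand.
#' @param ligand_chain chain id(s) to label as ligand.
#' @return updated `mol` with remaining atoms labelled `"receptor"`.
#' @export
assign_roles <- function(mol, ligand_res_name = NULL, ligand_chain = NULL) {
  lig <- rep(FALSE, n_atoms(mol))
  if (!is.null(ligand_res_name)) lig <- lig | mol$atoms$res_name %in% ligand_res_name
  if (!is.null(ligand_chain)) lig <- lig | mol$atoms$chain %in% ligand_chain
  mol$atoms$role <- ifelse(lig, "ligand", "receptor")
  mol
}

# ---- parsing -------------------------------------------------------------

.num_field <- function(txt, lineno, what) {
  v <- suppressWarnings(as.numeric(txt))
  if (any(is.na(v) | !nzchar(trimws(txt)))) {
    bad <- lineno[which(is.na(v) | !nzchar(trimws(txt)))[1]]
    stop(sprintf("parse error at line %d: malformed %s field", bad, what))
  }
  v
}

.parse_pdb_lines <- function(lines, lineno, pdbqt = FALSE) {
  rec <- substr(lines, 1, 6)
  keep <- trimws(rec) %in% c("ATOM", "HETATM")
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines)) stop("no ATOM/HETATM records found")
  short <- nchar(lines) < 54
  if (any(short))
    stop(sprintf("parse error at line %d: truncated coordinate field",
                 lineno[which(short)[1]]))
  serial <- .num_field(substr(lines, 7, 11), lineno, "serial")
  name <- trimws(substr(lines, 13, 16))
  res_name <- trimws(substr(lines, 18, 20))
  chain <- trimws(substr(lines, 22, 22))
  chain[!nzchar(chain)] <- "A"
  res_id <- .num_field(substr(lines, 23, 26), lineno, "residue number")
  x <- .num_field(substr(lines, 31, 38), lineno, "x coordinate")
  y <- .num_field(substr(lines, 39, 46), lineno, "y coordinate")
  z <- .num_field(substr(lines, 47, 54), lineno, "z coordinate")
  element <- trimws(substr(lines, 77, 78))
  # fall back to the atom-name convention when the element column is blank
  guess <- sub("^[0-9]*", "", name)
  guess2 <- toupper(substr(guess, 1, 2))
  guess1 <- toupper(substr(guess, 1, 1))
  element <- ifelse(nzchar(element), element,
                    ifelse(guess2 %in% c("CL", "BR", "ZN", "FE", "MG", "NA",
                                         "MN", "SE") & nchar(guess) > 1,
                           guess2, guess1))
  charge <- rep(NA_real_, length(lines))
  if (pdbqt) {
    ctxt <- trimws(substr(lines, 71, 76))
    charge <- suppressWarnings(as.numeric(ctxt))
    # PDBQT atom-type column is authoritative for the element when present
    atype <- trimws(substr(lines, 78, 79))
    el_from_type <- sub("[^A-Za-z].*$", "", atype)
    el_from_type[toupper(el_from_type) %in% c("A", "G")] <- "C"  # aromatic C
    el_from_type[toupper(el_from_type) == "HD"] <- "H"
    el_from_type[toupper(el_from_type) %in% c("OA", "NA.")] <- ""
    element <- ifelse(nzchar(el_from_type), el_from_type, element)
  }
  data.frame(serial = serial, name = name, element = element,
             res_name = res_name, res_id = res_id, chain = chain,
             x = x, y = y, z = z, charge = charge,
             stringsAsFactors = FALSE)
}

.split_models <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (!length(starts)) return(list(seq_along(lines)))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  lapply(seq_along(starts), function(i) seq(starts[i], ends[i]))
}

.parse_xyz_blocks <- function(lines) {
  blocks <- list(); i <- 1; ln <- 1
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(n) || n < 1)
      stop(sprintf("parse error at line %d: expected atom count", ln))
    if (ln + 1 + n > length(lines))
      stop(sprintf("parse error at line %d: truncated XYZ block", ln))
    body <- lines[(ln + 2):(ln + 1 + n)]
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(toks, length, 1L) < 4)
    if (length(bad))
      stop(sprintf("parse error at line %d: malformed XYZ atom line",
                   ln + 1 + bad[1]))
    el <- vapply(toks, `[[`, "", 1)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop(sprintf("parse error near line %d: non-numeric coordinate", ln + 2))
    blocks[[i]] <- list(element = el, xyz = xyz, comment = lines[ln + 1])
    i <- i + 1; ln <- ln + 2 + n
  }
  if (!length(blocks)) stop("no XYZ blocks found")
  blocks
}

#' Read a molecular structure from file
#'
#' Supports PDB v3.3 (`ATOM`/`HETATM`; the first `MODEL` of a multi-model
#' file), the AutoDock PDBQT dialect (partial charges, columns 71-76, are
#' loaded into the `charge` field) and plain XYZ.
#'
#' @param path file path.
#' @param format `"pdb"`, `"pdbqt"` or `"xyz"`; default guesses from the
#'   file extension.
#' @return a [mol_structure()] with atoms in file order.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "pdbqt", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "pdbqt", "xyz")) ext else "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "xyz") {
    b <- .parse_xyz_blocks(lines)[[1]]
    at <- data.frame(serial = seq_along(b$element), name = b$element,
                     element = b$element, res_name = "LIG", res_id = 1,
                     chain = "A", x = b$xyz[, 1], y = b$xyz[, 2],
                     z = b$xyz[, 3], stringsAsFactors = FALSE)
    return(mol_structure(at, title = trimws(b$comment)))
  }
  models <- .split_models(lines)
  idx <- models[[1]]
  at <- .parse_pdb_lines(lines[idx], idx, pdbqt = (format == "pdbqt"))
  title <- grep("^TITLE", lines, value = TRUE)
  mol_structure(at, title = if (length(title))
    trimws(substr(title[1], 11, nchar(title[1]))) else "")
}

#' Write a structure to PDB (or XYZ)
#'
#' @param mol a `mol` object.
#' @param path output path.
#' @param format `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(mol, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "xyz") {
    at <- mol$atoms
    writeLines(c(nrow(at), mol$title,
                 sprintf("%-2s %12.6f %12.6f %12.6f",
                         at$element, at$x, at$y, at$z)), path)
    return(invisible(path))
  }
  writeLines(c(.pdb_atom_lines(mol), "END"), path)
  invisible(path)
}

.pdb_atom_lines <- function(mol) {
  at <- mol$atoms
  rec <- ifelse(at$role == "ligand", "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name),
                  substr(at$name, 1, 4))
  sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, at$serial %% 100000, name4, substr(at$res_name, 1, 3),
          at$chain, at$res_id %% 10000, at$x, at$y, at$z, 1, 0,
          toupper(at$element))
}

# ---- trajectories --------------------------------------------------------

#' Construct a trajectory ensemble
#'
#' Container for `n_trials` trajectories of identical atom count and
#' frame count, sharing one set of timestamps (ps) and an atom template.
#'
#' @param trials list of N x 3 x T coordinate arrays (or a single array).
#' @param timestamps numeric vector of length T, strictly increasing (ps).
#' @param atom_template `mol` describing the atoms.
#' @return object of class `traj_ensemble`.
#' @export
traj_ensemble <- function(trials, timestamps, atom_template) {
  if (is.array(trials) && length(dim(trials)) == 3) trials <- list(trials)
  if (!length(trials)) stop("ensemble needs at least one trial")
  dims <- vapply(trials, function(a) dim(a), numeric(3))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[3, ] != dims[3, 1]))
    stop("all trials must have identical atom and frame counts")
  if (dims[1, 1] != n_atoms(atom_template))
    stop("trial atom count does not match atom template")
  if (length(timestamps) != dims[3, 1])
    stop("timestamps length must equal frame count")
  if (any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  structure(list(trials = trials, timestamps = as.numeric(timestamps),
                 atom_template = atom_template),
            class = "traj_ensemble")
}

#' @export
print.traj_ensemble <- function(x, ...) {
  d <- dim(x$trials[[1]])
  cat(sprintf("<traj_ensemble> %d trial(s) x %d frames x %d atoms, %g-%g ps\n",
              length(x$trials), d[3], d[1], min(x$timestamps),
              max(x$timestamps)))
  invisible(x)
}

#' Number of frames per trial
#' @param ens a `traj_ensemble`.
#' @return integer.
#' @export
n_frames <- function(ens) dim(ens$trials[[1]])[3]

#' Extract one frame as a structure
#' @param ens a `traj_ensemble`.
#' @param frame frame index (1-based).
#' @param trial trial index.
#' @return a `mol` with the frame's coordinates.
#' @export
frame_structure <- function(ens, frame, trial = 1) {
  set_xyz(ens$atom_template, ens$trials[[trial]][, , frame])
}

#' Read a single-trial trajectory
#'
#' Multi-model PDB (one `MODEL` per frame) and multi-block XYZ are the
#' interchange formats.  Timestamps are `(frame_index - 1) * timestep_ps`.
#'
#' @param path file path.
#' @param format `"pdb"` or `"xyz"` (default guesses from extension).
#' @param timestep_ps frame spacing in ps.
#' @return single-trial [traj_ensemble()].
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz"),
                            timestep_ps = 200) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "xyz") "xyz" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "xyz") {
    blocks <- .parse_xyz_blocks(lines)
    counts <- vapply(blocks, function(b) length(b$element), 1L)
    if (any(counts != counts[1]))
      stop(sprintf("atom-count mismatch at model %d (%d vs %d atoms)",
                   which(counts != counts[1])[1], counts[which(counts != counts[1])[1]],
                   counts[1]))
    b1 <- blocks[[1]]
    at <- data.frame(serial = seq_along(b1$element), name = b1$element,
                     element = b1$element, res_name = "LIG", res_id = 1,
                     chain = "A", x = b1$xyz[, 1], y = b1$xyz[, 2],
                     z = b1$xyz[, 3], stringsAsFactors = FALSE)
    template <- mol_structure(at)
    coords <- array(0, c(counts[1], 3, length(blocks)))
    for (k in seq_along(blocks)) coords[, , k] <- blocks[[k]]$xyz
  } else {
    models <- .split_models(lines)
    tabs <- lapply(seq_along(models), function(k) {
      idx <- models[[k]]
      .parse_pdb_lines(lines[idx], idx)
    })
    counts <- vapply(tabs, nrow, 1L)
    if (any(counts != counts[1])) {
      k <- which(counts != counts[1])[1]
      stop(sprintf("atom-count mismatch at model %d (%d vs %d atoms)",
                   k, counts[k], counts[1]))
    }
    template <- mol_structure(tabs[[1]])
    coords <- array(0, c(counts[1], 3, length(tabs)))
    for (k in seq_along(tabs))
      coords[, , k] <- as.matrix(tabs[[k]][, c("x", "y", "z")])
  }
  traj_ensemble(coords, (seq_len(dim(coords)[3]) - 1) * timestep_ps, template)
}

#' Write a trajectory as a multi-model PDB
#' @param ens a `traj_ensemble`.
#' @param path output path.
#' @param trial trial index to write.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(ens, path, trial = 1) {
  out <- character(0)
  for (k in seq_len(n_frames(ens))) {
    m <- frame_structure(ens, k, trial)
    out <- c(out, sprintf("MODEL %8d", k), .pdb_atom_lines(m), "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

# ---- parameter sidecar ---------------------------------------------------

#' Read a per-atom parameter sidecar CSV
#'
#' Columns: `serial, charge, lj_sigma, lj_epsilon, gb_radius, gb_screen`
#' (optionally `formal_charge`).  Units: e, Angstrom, kcal/mol, Angstrom,
#' unitless.
#'
#' @param path CSV path.
#' @return data frame of parameters.
#' @export
read_params <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(p$serial)) stop("parameter CSV must have a 'serial' column")
  p
}

#' Attach sidecar parameters to a structure by atom serial
#' @param mol a `mol` object.
#' @param params data frame from [read_params()].
#' @return updated `mol`.
#' @export
attach_params <- function(mol, params) {
  i <- match(mol$atoms$serial, params$serial)
  if (anyNA(i)) stop("parameters missing for serial(s): ",
                     paste(mol$atoms$serial[is.na(i)], collapse = ", "))
  for (col in intersect(c("charge", "lj_sigma", "lj_epsilon", "gb_radius",
                          "gb_screen", "formal_charge"), names(params))) {
    mol$atoms[[col]] <- params[[col]][i]
  }
  mol
}

# ---- superposition and RMSD ----------------------------------------------

#' Root-mean-square deviation at fixed correspondence
#'
#' No superposition and no symmetry permutation is applied: atom i of `a`
#' is compared with atom i of `b`.
#'
#' @param a,b N x 3 coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd_fixed <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in size")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD of `mobile` onto `reference`.
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3.
#' @param weights optional non-negative per-point weights.
#' @return object of class `superposition`: list with `rotation` (3 x 3,
#'   det +1), `translation` (length 3) and `rmsd` (unweighted, after
#'   transform).  Apply with [apply_superposition()].
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  P <- as.matrix(mobile); Q <- as.matrix(reference)
  if (!all(dim(P) == dim(Q))) stop("point sets differ in size")
  n <- nrow(P)
  if (n < 3) stop("at least 3 points required")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  w <- weights / sum(weights)
  pc <- colSums(P * w); qc <- colSums(Q * w)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  C <- t(Pc * w) %*% Qc
  s <- svd(C)
  if (s$d[2] < 1e-12) stop("degenerate (rank-deficient) point set")
  d <- sign(det(s$u %*% t(s$v)))
  A <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)   # row-vector rotation
  translation <- qc - drop(pc %*% A)
  moved <- sweep(P %*% A, 2, translation, `+`)
  structure(list(rotation = t(A), translation = translation,
                 rmsd = rmsd_fixed(moved, Q)),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param sp a `superposition` from [kabsch_superpose()].
#' @param coords N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
apply_superposition <- function(sp, coords) {
  sweep(as.matrix(coords) %*% t(sp$rotation), 2, sp$translation, `+`)
}

# ---- docking grid box ----------------------------------------------------

#' Docking grid box around a ligand
#'
#' The box spans the ligand's heavy atoms, padded by `pad` Angstrom on
#' each side of every axis.  The box centre defaults to the heavy-atom
#' bounding-box midpoint; `center = "centroid"` uses the mean position.
#'
#' @param ligand `mol` (only heavy atoms are used).
#' @param pad padding per side, Angstrom.
#' @param spacing grid spacing, Angstrom.
#' @param center `"midpoint"` or `"centroid"`.
#' @return object of class `grid_box`: list with `center`, `dims`,
#'   `spacing`.
#' @export
make_grid_box <- function(ligand, pad = 10, spacing = 1,
                          center = c("midpoint", "centroid")) {
  center <- match.arg(center)
  if (pad < 0 || spacing <= 0) stop("pad must be >= 0 and spacing > 0")
  xyz <- mol_xyz(ligand, which(ligand$atoms$is_heavy))
  if (!nrow(xyz)) stop("ligand has no heavy atoms")
  lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
  ctr <- if (center == "midpoint") (lo + hi) / 2 else colMeans(xyz)
  structure(list(center = ctr, dims = (hi - lo) + 2 * pad, spacing = spacing),
            class = "grid_box")
}

#' @export
print.grid_box <- function(x, ...) {
  cat(sprintf("<grid_box> center (%.2f, %.2f, %.2f) dims (%.1f, %.1f, %.1f) A, spacing %.2f A\n",
              x$center[1], x$center[2], x$center[3],
              x$dims[1], x$dims[2], x$dims[3], x$spacing))
  invisible(x)
}

# run expr with a private, seeded RNG stream; global state untouched
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}
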