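# Deterministic synthetic-data generators.  Every other module is
# testable against these without any download: toy receptor-ligand
# complexes with planted interactions, trajectory ensembles with
# programmed RMSD-drift plateaus and hydrogen-bond persistence
# fractions, two-basin trajectories, and synthetic assay tables and
# dose-response curves.  All generators are seed-deterministic.

.PARAM_TABLE <- data.frame(
  element = c("H", "C", "N", "O", "S"),
  lj_sigma = c(2.5, 3.4, 3.25, 3.0, 3.5),
  lj_epsilon = c(0.02, 0.08, 0.17, 0.21, 0.25),
  gb_radius = c(1.2, 1.7, 1.55, 1.5, 1.8),
  gb_screen = c(0.85, 0.72, 0.79, 0.85, 0.96),
  charge = c(0.30, 0.00, -0.30, -0.40, 0.00),
  stringsAsFactors = FALSE)

.fill_params <- function(at) {
  i <- match(at$element, .PARAM_TABLE$element)
  for (col in c("lj_sigma", "lj_epsilon", "gb_radius", "gb_screen")) {
    at[[col]] <- .PARAM_TABLE[[col]][i]
  }
  at$charge <- ifelse(is.na(at$charge), .PARAM_TABLE$charge[i], at$charge)
  at
}

.atom_row <- function(name, element, res_name, res_id, chain, x, y, z,
                      role, charge = NA_real_, formal = NA_real_) {
  data.frame(serial = NA_real_, name = name, element = element,
             res_name = res_name, res_id = res_id, chain = chain,
             x = x, y = y, z = z, charge = charge,
             formal_charge = formal, role = role,
             stringsAsFactors = FALSE)
}

#' Toy receptor-ligand complex with planted interactions
#'
#' Builds a small cage-like receptor plus a ligand laid out on a lattice
#' (units 8 Angstrom apart, so detectors cannot cross-talk) with exactly
#' the requested number of hydrogen bonds, face-to-face ring stacks,
#' ionic bridges and hydrophobic contacts.  Full per-atom charges,
#' Lennard-Jones and GB parameters are filled in, so the energetics
#' module needs no external force field.
#'
#' @param n_hb planted ligand-donor hydrogen bonds (H...O 2.0 A, linear).
#' @param n_pipi planted parallel ring stacks (centroids 3.8 A).
#' @param n_ionic planted ammonium/carboxylate bridges (3.0 A).
#' @param n_hydrophobic planted nonpolar carbon contacts (4.0 A).
#' @param n_cage glycine backbone residues forming the distant cage
#'   (provides alignment atoms; >= 1).
#' @param ligand_atom_budget optional cap on ligand atoms; an error is
#'   raised when the requested units do not fit.
#' @param seed kept for interface symmetry (construction is analytic).
#' @return list with `structure` (a `mol`), `ring_defs`,
#'   `receptor_site` (residue data frame) and `params` (sidecar table).
#' @export
make_toy_complex <- function(n_hb = 1, n_pipi = 0, n_ionic = 0,
                             n_hydrophobic = 0, n_cage = 3,
                             ligand_atom_budget = NULL, seed = 1) {
  need <- 3 * n_hb + 6 * n_pipi + n_ionic + n_hydrophobic
  if (!is.null(ligand_atom_budget) && need > ligand_atom_budget)
    stop(sprintf("infeasible request: %d ligand atoms needed but budget is %d",
                 need, ligand_atom_budget))
  if (n_cage < 1) stop("n_cage must be >= 1")
  # one planted unit per 8-Angstrom lattice slot: no cross-talk between
  # detectors (largest cutoff in play is 5.5 A)
  rows <- list(); rings <- list(); res_id <- 10; slot <- 0
  add <- function(...) rows[[length(rows) + 1]] <<- .atom_row(...)
  for (i in seq_len(n_hb)) {
    x0 <- 8 * slot; slot <- slot + 1
    add("C1", "C", "LIG", 1, "L", x0, -1.40, 0, "ligand")
    add("O1", "O", "LIG", 1, "L", x0, 0.00, 0, "ligand")
    add("H1", "H", "LIG", 1, "L", x0, 0.96, 0, "ligand")
    add("OG", "O", "SER", res_id, "A", x0, 2.96, 0, "receptor")
    add("CB", "C", "SER", res_id, "A", x0, 4.36, 0, "receptor")
    res_id <- res_id + 1
  }
  for (i in seq_len(n_pipi)) {
    x0 <- 8 * slot; slot <- slot + 1
    ang <- (0:5) * pi / 3
    lig_start <- length(rows) + 1
    for (k in 1:6)
      add(paste0("CL", k), "C", "LIG", 1, "L",
          x0 + 1.39 * cos(ang[k]), 1.39 * sin(ang[k]), 0, "ligand")
    rec_start <- length(rows) + 1
    for (k in 1:6)
      add(paste0("CR", k), "C", "PHE", res_id, "A",
          x0 + 1.39 * cos(ang[k]), 1.39 * sin(ang[k]), 3.8, "receptor")
    rings[[length(rings) + 1]] <- lig_start:(lig_start + 5)
    rings[[length(rings) + 1]] <- rec_start:(rec_start + 5)
    res_id <- res_id + 1
  }
  for (i in seq_len(n_ionic)) {
    x0 <- 8 * slot; slot <- slot + 1
    add("N1", "N", "LIG", 1, "L", x0, 0, 0, "ligand",
        charge = 1.0, formal = 1)
    add("OD1", "O", "ASP", res_id, "A", x0, 3.0, 0, "receptor",
        charge = -1.0)
    add("CG", "C", "ASP", res_id, "A", x0, 4.4, 0, "receptor")
    res_id <- res_id + 1
  }
  for (i in seq_len(n_hydrophobic)) {
    x0 <- 8 * slot; slot <- slot + 1
    add("C2", "C", "LIG", 1, "L", x0, 0, 0, "ligand")
    add("CD1", "C", "LEU", res_id, "A", x0, 4.0, 0, "receptor")
    res_id <- res_id + 1
  }
  if (!slot) {  # no units requested: bare one-carbon ligand
    add("C2", "C", "LIG", 1, "L", 0, 0, 0, "ligand")
    slot <- 1
  }
  # distant glycine cage: alignment backbone, inert to all detectors
  x_mid <- 8 * (slot - 1) / 2
  for (g in seq_len(n_cage)) {
    xg <- x_mid + 4 * (g - (n_cage + 1) / 2)
    add("N", "N", "GLY", 100 + g, "A", xg + 0.00, 0.00, -7, "receptor")
    add("CA", "C", "GLY", 100 + g, "A", xg + 1.46, 0.00, -7, "receptor")
    add("C", "C", "GLY", 100 + g, "A", xg + 2.06, 1.35, -7, "receptor")
    add("O", "O", "GLY", 100 + g, "A", xg + 2.06, 2.58, -7, "receptor")
  }
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  at <- .fill_params(at)
  mol <- mol_structure(at, title = sprintf(
    "toy complex: %d hb, %d pipi, %d ionic, %d hydrophobic",
    n_hb, n_pipi, n_ionic, n_hydrophobic))
  ring_defs <- lapply(rings, function(idx) mol$atoms$serial[idx])
  rec <- unique(mol$atoms[mol$atoms$role == "receptor",
                          c("chain", "res_id", "res_name")])
  rec <- rec[order(rec$chain, rec$res_id), ]
  rownames(rec) <- NULL
  params <- mol$atoms[, c("serial", "charge", "lj_sigma", "lj_epsilon",
                          "gb_radius", "gb_screen", "formal_charge")]
  list(structure = mol, ring_defs = ring_defs, receptor_site = rec,
       params = params)
}

# smooth 0->1 ramp reaching exactly 1 at ramp_end
.ramp <- function(frame_idx, n_frames, ramp_frac) {
  ramp_end <- max(1, ceiling(ramp_frac * (n_frames - 1)))
  pmin(1, (frame_idx - 1) / ramp_end)
}

#' Trajectory ensemble with a programmed RMSD-drift plateau
#'
#' The ligand is rigidly displaced along a fixed unit vector with a
#' smooth ramp up to the requested plateau; the receptor never moves.
#' Because the shift is rigid and uniform, the analytic ligand RMSD at
#' every frame equals the displacement magnitude, so the ensemble's
#' PoseScore equals `mean(plateau)` exactly.
#'
#' @param plateau target plateau(s), Angstrom; recycled to `n_trials`
#'   (mixed values give a trial-averaged plateau of their mean).
#' @param n_trials,n_frames ensemble dimensions.
#' @param ramp_frac fraction of the run spent ramping up.
#' @param timestep_ps frame spacing, ps.
#' @param direction drift direction (normalised internally).
#' @param complex optional base complex from [make_toy_complex()].
#' @return a [traj_ensemble()].
#' @export
make_drift_ensemble <- function(plateau, n_trials = 10, n_frames = 50,
                                ramp_frac = 0.4, timestep_ps = 200,
                                direction = c(1, 0, 0), complex = NULL) {
  if (any(plateau < 0)) stop("plateau must be >= 0")
  if (is.null(complex)) complex <- make_toy_complex(n_hb = 1)
  mol <- complex$structure
  plateau <- rep_len(plateau, n_trials)
  dirv <- direction / sqrt(sum(direction^2))
  base <- mol_xyz(mol)
  lig <- role_idx(mol, "ligand")
  ramp <- .ramp(seq_len(n_frames), n_frames, ramp_frac)
  trials <- lapply(seq_len(n_trials), function(k) {
    arr <- array(base, c(nrow(base), 3, n_frames))
    for (t in seq_len(n_frames)) {
      shift <- plateau[k] * ramp[t] * dirv
      arr[lig, 1, t] <- base[lig, 1] + shift[1]
      arr[lig, 2, t] <- base[lig, 2] + shift[2]
      arr[lig, 3, t] <- base[lig, 3] + shift[3]
    }
    arr
  })
  traj_ensemble(trials, (seq_len(n_frames) - 1) * timestep_ps, mol)
}

#' Trajectory ensemble with a programmed hydrogen-bond persistence
#'
#' Starts from a complex with `n_hb` planted hydrogen bonds.  Within the
#' scoring window (final `window_frac` of frames) the acceptor residues
#' are displaced 3 Angstrom in exactly `round((1 - persistence) *
#' n_window)` frames, breaking every reference bond there; all other
#' frames keep the bonds intact.  On windows where `(1 - persistence) *
#' n_window` is an integer the recovered PersScore is exact.
#'
#' @param persistence target persistence fraction in [0, 1].
#' @param n_trials,n_frames ensemble dimensions.
#' @param window_frac scoring window fraction (match [pers_score()]).
#' @param n_hb planted hydrogen bonds.
#' @param timestep_ps frame spacing, ps.
#' @return a [traj_ensemble()]; attribute `"persistence_planted"` holds
#'   the exactly realised fraction.
#' @export
make_hb_ensemble <- function(persistence, n_trials = 1, n_frames = 50,
                             window_frac = 0.2, n_hb = 2,
                             timestep_ps = 200) {
  if (persistence < 0 || persistence > 1)
    stop("persistence must be in [0, 1]")
  cx <- make_toy_complex(n_hb = n_hb)
  mol <- cx$structure
  base <- mol_xyz(mol)
  acceptor_atoms <- which(mol$atoms$res_name == "SER")
  n_win <- max(1, floor(window_frac * n_frames))
  n_broken <- round((1 - persistence) * n_win)
  broken_frames <- if (n_broken > 0)
    (n_frames - n_broken + 1):n_frames else integer(0)
  arr <- array(base, c(nrow(base), 3, n_frames))
  for (t in broken_frames) arr[acceptor_atoms, 2, t] <-
    base[acceptor_atoms, 2] + 3
  trials <- rep(list(arr), n_trials)
  ens <- traj_ensemble(trials, (seq_len(n_frames) - 1) * timestep_ps, mol)
  attr(ens, "persistence_planted") <- 1 - n_broken / n_win
  ens
}

#' Two-basin trajectory with a planted majority conformer
#'
#' A single-trial ensemble in which a `weights[1]` fraction of frames
#' jitters around the starting ligand pose (basin X) and the remainder
#' around a pose displaced by `displacement` Angstrom (basin Y), the
#' minority frames interleaved every few frames.  The receptor is
#' static.
#'
#' @param weights basin occupancies, length 2, summing to 1.
#' @param displacement basin separation, Angstrom.
#' @param n_frames frames.
#' @param jitter coordinate noise sd, Angstrom.
#' @param timestep_ps frame spacing, ps.
#' @param seed RNG seed.
#' @param complex optional base complex.
#' @return a [traj_ensemble()]; attribute `"basin"` is the per-frame
#'   basin label (1 = majority).
#' @export
make_basin_trajectory <- function(weights = c(0.8, 0.2),
                                  displacement = 3, n_frames = 50,
                                  jitter = 0.05, timestep_ps = 200,
                                  seed = 1, complex = NULL) {
  if (length(weights) != 2 || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be two fractions summing to 1")
  # ring-bearing ligand: enough non-collinear heavy atoms to superpose on
  if (is.null(complex)) complex <- make_toy_complex(n_hb = 1, n_pipi = 1)
  mol <- complex$structure
  base <- mol_xyz(mol)
  lig <- role_idx(mol, "ligand")
  n_minor <- round(weights[2] * n_frames)
  # spread the minority frames evenly through the run
  minor <- if (n_minor > 0)
    unique(round(seq(2, n_frames, length.out = n_minor))) else integer(0)
  basin <- rep(1L, n_frames); basin[minor] <- 2L
  arr <- .with_seed(seed, {
    a <- array(base, c(nrow(base), 3, n_frames))
    for (t in seq_len(n_frames)) {
      a[lig, , t] <- base[lig, , drop = FALSE] +
        matrix(stats::rnorm(3 * length(lig), sd = jitter), length(lig), 3)
      if (basin[t] == 2L) a[lig, 1, t] <- a[lig, 1, t] + displacement
    }
    a
  })
  ens <- traj_ensemble(arr, (seq_len(n_frames) - 1) * timestep_ps, mol)
  attr(ens, "basin") <- basin
  ens
}

#' Synthetic assay table with a controllable hit count
#'
#' @param n compounds.
#' @param n_above compounds with inhibition strictly above `threshold`.
#' @param threshold percent threshold.
#' @param seed RNG seed.
#' @return data frame shaped like [load_assay_reference()].
#' @export
make_assay_table <- function(n, n_above, threshold = 70, seed = 1) {
  if (n_above > n) stop("n_above cannot exceed n")
  if (n == 0)
    return(data.frame(compound_id = character(0), vina_score = numeric(0),
                      inhibition_pct = numeric(0), ic50 = numeric(0)))
  .with_seed(seed, {
    hi <- stats::runif(n_above, threshold + 1, 100)
    lo <- stats::runif(n - n_above, 0, max(0, threshold - 1))
    inh <- sample(c(hi, lo))
    data.frame(compound_id = sprintf("SYN-%04d", seq_len(n)),
               vina_score = round(stats::runif(n, -14, -8), 1),
               inhibition_pct = round(inh, 1),
               ic50 = NA_real_, stringsAsFactors = FALSE)
  })
}

#' Synthetic dose-response curve
#'
#' Noiseless (or Gaussian-noised) four-parameter logistic observations,
#' for closed-loop testing of [fit_4pl()].
#'
#' @param ic50 true IC50, uM.
#' @param hill Hill slope.
#' @param bottom,top response asymptotes, percent.
#' @param concentrations uM; default 8 half-log points around `ic50`.
#' @param noise_sd Gaussian response noise, percent.
#' @param seed RNG seed.
#' @return data frame with `conc_uM`, `response_pct`.
#' @export
make_dose_response <- function(ic50, hill = 1, bottom = 0, top = 100,
                               concentrations = ic50 * 10^seq(-2, 1.5,
                                                              by = 0.5),
                               noise_sd = 0, seed = 1) {
  y <- bottom + (top - bottom) /
    (1 + 10^((log10(ic50) - log10(concentrations)) * hill))
  if (noise_sd > 0)
    y <- .with_seed(seed, y + stats::rnorm(length(y), sd = noise_sd))
  data.frame(conc_uM = concentrations, response_pct = y)
}
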