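# Single-trajectory MM/GBSA binding free-energy estimator:
# dG_bind = G(complex) - G(receptor) - G(ligand), with
# G = E_coulomb + E_LJ + G_GB (Still pairwise generalized Born on
# HCT/OBC effective radii) + gamma * SASA (Shrake-Rupley).
# All parameters are per-atom and user-supplied (sidecar CSV); no
# proprietary force field is involved, so absolute values are model
# energies, not reproductions of any published force field.

.COULOMB_K <- 332.0636   # kcal A / (mol e^2)
.GB_K <- 166.03          # Still prefactor (half the Coulomb constant)

#' GB/SA model parameters
#'
#' @param eps_in solute dielectric (>= 1).
#' @param eps_out solvent dielectric (> eps_in).
#' @param surface_tension nonpolar term gamma, kcal/(mol A^2).
#' @param probe_radius solvent probe, Angstrom.
#' @param sasa_points quadrature points per atom sphere.
#' @return object of class `gb_params`.
#' @export
gb_params <- function(eps_in = 1.0, eps_out = 78.5,
                      surface_tension = 0.0072, probe_radius = 1.4,
                      sasa_points = 960) {
  if (!(eps_out > eps_in && eps_in >= 1))
    stop("require eps_out > eps_in >= 1")
  structure(list(eps_in = eps_in, eps_out = eps_out,
                 surface_tension = surface_tension,
                 probe_radius = probe_radius, sasa_points = sasa_points),
            class = "gb_params")
}

.require_col <- function(mol, col, what) {
  v <- mol$atoms[[col]]
  if (any(is.na(v)))
    stop("missing ", what, " for atom serial(s): ",
         paste(mol$atoms$serial[is.na(v)], collapse = ", "))
  v
}

#' Coulomb energy of a structure
#'
#' `sum_{i<j} 332.0636 q_i q_j / r_ij` over all atom pairs of the
#' structure (no exclusions; bonded terms cancel exactly in binding
#' deltas because the geometries are identical).
#'
#' @param mol `mol` with `charge` on every atom.
#' @return energy, kcal/mol.
#' @export
coulomb_energy <- function(mol) {
  q <- .require_col(mol, "charge", "partial charge")
  if (n_atoms(mol) < 2) return(0)
  xyz <- mol_xyz(mol)
  d <- .dist_mat(xyz, xyz)
  qq <- outer(q, q)
  up <- upper.tri(d)
  .COULOMB_K * sum(qq[up] / d[up])
}

#' Lennard-Jones energy of a structure
#'
#' `sum_{i<j} 4 eps_ij [(sigma_ij/r)^12 - (sigma_ij/r)^6]` with
#' Lorentz-Berthelot mixing (arithmetic sigma, geometric epsilon).
#'
#' @param mol `mol` with `lj_sigma` (Angstrom) and `lj_epsilon`
#'   (kcal/mol) on every atom.
#' @return energy, kcal/mol.
#' @export
lj_energy <- function(mol) {
  sig <- .require_col(mol, "lj_sigma", "LJ sigma")
  eps <- .require_col(mol, "lj_epsilon", "LJ epsilon")
  if (n_atoms(mol) < 2) return(0)
  xyz <- mol_xyz(mol)
  d <- .dist_mat(xyz, xyz)
  sij <- outer(sig, sig, `+`) / 2
  eij <- sqrt(outer(eps, eps))
  up <- upper.tri(d)
  sr6 <- (sij[up] / d[up])^6
  sum(4 * eij[up] * (sr6^2 - sr6))
}

#' Effective Born radii (pairwise descreening, OBC rescaling)
#'
#' Hawkins-Cramer-Truhlar pairwise descreening integrals with the
#' Onufriev-Bashford-Case tanh rescaling (alpha 1.0, beta 0.8, gamma
#' 4.85, zero radius offset).  An isolated atom's effective radius
#' equals its intrinsic `gb_radius`; burying an atom grows it.
#'
#' @param mol `mol` with `gb_radius` (Angstrom) and `gb_screen`
#'   (unitless) on every atom.
#' @return numeric vector of effective radii, Angstrom.
#' @export
born_radii <- function(mol) {
  rho <- .require_col(mol, "gb_radius", "GB radius")
  scr <- .require_col(mol, "gb_screen", "GB screening factor")
  if (any(rho <= 0)) stop("nonpositive GB radius")
  n <- n_atoms(mol)
  xyz <- mol_xyz(mol)
  d <- .dist_mat(xyz, xyz)
  I <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      r <- d[i, j]
      sr <- scr[j] * rho[j]
      if (rho[i] >= r + sr) next          # j's sphere fully inside i
      U <- r + sr
      L <- max(abs(r - sr), rho[i])
      term <- 0.5 * (1 / L - 1 / U + (r / 4) * (1 / U^2 - 1 / L^2) +
                       (1 / (2 * r)) * log(L / U) +
                       (sr^2 / (4 * r)) * (1 / L^2 - 1 / U^2))
      if (rho[i] < sr - r) term <- term + (1 / rho[i] - 1 / L)
      acc <- acc + term
    }
    I[i] <- acc
  }
  psi <- I * rho
  inv <- 1 / rho - tanh(psi - 0.8 * psi^2 + 4.85 * psi^3) / rho
  1 / inv
}

#' Generalized Born polar solvation energy (Still)
#'
#' `-166.03 (1/eps_in - 1/eps_out) sum_{i,j} q_i q_j / f_GB` over the
#' full double sum (diagonal = Born self terms), with
#' `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))`.
#'
#' @param mol `mol` with charges.
#' @param radii effective Born radii from [born_radii()].
#' @param params a [gb_params()].
#' @return polar solvation energy, kcal/mol.
#' @export
gb_polar_energy <- function(mol, radii = born_radii(mol),
                            params = gb_params()) {
  q <- .require_col(mol, "charge", "partial charge")
  xyz <- mol_xyz(mol)
  d <- .dist_mat(xyz, xyz)
  RR <- outer(radii, radii)
  f <- sqrt(d^2 + RR * exp(-d^2 / (4 * RR)))
  -.GB_K * (1 / params$eps_in - 1 / params$eps_out) *
    sum(outer(q, q) / f)
}

# deterministic Fibonacci-spiral point set on the unit sphere
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic spiral quadrature: for each atom, points on the sphere
#' of radius `gb_radius + probe` are tested for burial inside any other
#' atom's probe-expanded sphere.
#'
#' @param mol `mol` with `gb_radius` on every atom.
#' @param probe probe radius, Angstrom.
#' @param n_points quadrature points per atom.
#' @return list with `total` (A^2) and `per_atom`.
#' @export
sasa <- function(mol, probe = 1.4, n_points = 960) {
  rad <- .require_col(mol, "gb_radius", "atomic radius") + probe
  n <- n_atoms(mol)
  xyz <- mol_xyz(mol)
  pts <- .sphere_points(n_points)
  per_atom <- numeric(n)
  d <- .dist_mat(xyz, xyz)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < rad[i] + rad & seq_len(n) != i)
    # coincident spheres: keep the area on the first atom only
    dup <- nb[d[i, nb] < 1e-9 & rad[nb] >= rad[i]]
    nb <- setdiff(nb, dup[dup > i])
    if (any(d[i, nb] < 1e-9 & nb < i & rad[nb] >= rad[i])) next
    p <- sweep(pts * rad[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj <- sqrt(colSums((t(p) - xyz[j, ])^2))
      exposed <- exposed & dj >= rad[j]
    }
    per_atom[i] <- mean(exposed) * 4 * pi * rad[i]^2
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

.energy_breakdown <- function(mol, params) {
  ec <- coulomb_energy(mol)
  el <- lj_energy(mol)
  gb <- gb_polar_energy(mol, born_radii(mol), params)
  sa <- params$surface_tension *
    sasa(mol, params$probe_radius, params$sasa_points)$total
  structure(list(e_coulomb = ec, e_lj = el, g_gb = gb, g_sa = sa,
                 total = ec + el + gb + sa),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown> Coul %.2f  LJ %.2f  GB %.2f  SA %.2f  total %.2f kcal/mol\n",
              x$e_coulomb, x$e_lj, x$g_gb, x$g_sa, x$total))
  invisible(x)
}

#' Single-trajectory MM/GBSA binding free energy
#'
#' `dG_bind = G(complex) - G(receptor) - G(ligand)`, each term evaluated
#' on the geometry extracted from the same complex frame (no
#' re-minimisation of the separated species, no entropy term).  More
#' favourable binding gives a more negative value.
#'
#' @param complex `mol` carrying full per-atom parameters and roles.
#' @param receptor_idx,ligand_idx atom index selections; default from
#'   roles.  Must not overlap.
#' @param params a [gb_params()].
#' @return list with `dg_bind` (kcal/mol), per-species breakdowns
#'   (`complex`, `receptor`, `ligand`) and the component `delta`s.
#' @export
delta_g_bind <- function(complex, receptor_idx = NULL, ligand_idx = NULL,
                         params = gb_params()) {
  if (is.null(receptor_idx)) receptor_idx <- role_idx(complex, "receptor")
  if (is.null(ligand_idx)) ligand_idx <- role_idx(complex, "ligand")
  if (length(intersect(receptor_idx, ligand_idx)))
    stop("receptor and ligand selections overlap")
  if (!length(receptor_idx) || !length(ligand_idx))
    stop("receptor and ligand selections must be non-empty")
  both <- sort(c(receptor_idx, ligand_idx))
  g_c <- .energy_breakdown(mol_subset(complex, both), params)
  g_r <- .energy_breakdown(mol_subset(complex, receptor_idx), params)
  g_l <- .energy_breakdown(mol_subset(complex, ligand_idx), params)
  delta <- lapply(c(e_coulomb = "e_coulomb", e_lj = "e_lj", g_gb = "g_gb",
                    g_sa = "g_sa", total = "total"),
                  function(f) g_c[[f]] - g_r[[f]] - g_l[[f]])
  list(dg_bind = delta$total, complex = g_c, receptor = g_r, ligand = g_l,
       delta = delta)
}

#' Binding free-energy change across a simulation
#'
#' `before - after`: positive values mean the pose became *more*
#' favourable (stabilised) after the simulation.
#'
#' @param before,after dG_bind values, kcal/mol.
#' @return ddG, kcal/mol.
#' @export
delta_delta_g <- function(before, after) before - after

#' Write an energy report as JSON
#' @param dg result of [delta_g_bind()].
#' @param path output path (`NULL` returns the string).
#' @return JSON string, invisibly.
#' @export
write_energy_report <- function(dg, path = NULL) {
  flat <- list(dg_bind = dg$dg_bind,
               delta = dg$delta,
               complex = unclass(dg$complex),
               receptor = unclass(dg$receptor),
               ligand = unclass(dg$ligand))
  js <- jsonlite::toJSON(flat, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}
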