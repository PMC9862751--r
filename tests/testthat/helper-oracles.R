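# Independent oracles used across the suite.  These deliberately avoid
# the package's own linear-algebra paths.

# rotation matrix from z-y-x Euler angles (row-vector convention)
euler_rot <- function(a, b, c) {
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
               byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), -sin(c), 0, sin(c), cos(c)), 3, 3,
               byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# brute-force best-fit RMSD: coarse Euler-angle grid then local refine,
# translation handled by centroid matching (optimal for any rotation)
brute_force_fit_rmsd <- function(mobile, reference, step_deg = 15) {
  pc <- colMeans(mobile); qc <- colMeans(reference)
  P <- sweep(mobile, 2, pc); Q <- sweep(reference, 2, qc)
  obj <- function(ang) {
    R <- euler_rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  grid <- seq(0, 2 * pi - 1e-9, by = step_deg * pi / 180)
  gridb <- seq(-pi / 2, pi / 2, by = step_deg * pi / 180)
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a in grid) for (b in gridb) for (c in grid) {
    v <- obj(c(a, b, c))
    if (v < best) { best <- v; best_ang <- c(a, b, c) }
  }
  opt <- stats::optim(best_ang, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 5000))
  opt$value
}

# analytic solvent-accessible area of two overlapping spheres
# (radii already include the probe)
two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  cap <- function(ra, rb) {
    # height of the cap of sphere a buried inside sphere b
    h <- ra - (d^2 + ra^2 - rb^2) / (2 * d)
    2 * pi * ra * h
  }
  4 * pi * (r1^2 + r2^2) - cap(r1, r2) - cap(r2, r1)
}

# random rigid transform applied to a coordinate matrix
random_rigid <- function(xyz, seed) {
  set.seed(seed)
  R <- euler_rot(runif(1, 0, 2 * pi), runif(1, -pi / 2, pi / 2),
                 runif(1, 0, 2 * pi))
  t <- runif(3, -20, 20)
  sweep(xyz %*% t(R), 2, t, `+`)
}

# apply a rigid transform to every atom of a mol
transform_mol <- function(mol, seed) {
  set_xyz(mol, random_rigid(mol_xyz(mol), seed))
}
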