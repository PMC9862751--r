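# Minimal metadynamics engine: RMSD collective variable, Gaussian hill
# deposition, overdamped (Euler-Maruyama) Langevin dynamics on analytic
# toy energy surfaces.  Exists to generate desk-scale BPMD-style trial
# ensembles and to validate the biasing arithmetic; it is not a
# production MD engine (no solvent, no membranes, no PME).

.KB <- 0.0019872041  # kcal/(mol K)

#' RMSD collective variable
#'
#' CV value = fixed-correspondence RMSD of the selected atoms from their
#' reference (starting) positions.
#'
#' @param selection integer indices of the atoms entering the RMSD
#'   (ligand heavy atoms, typically).
#' @param reference full N x 3 reference coordinates (frame 0).
#' @return object of class `cv_rmsd`.
#' @export
cv_rmsd <- function(selection, reference) {
  if (!length(selection)) stop("CV atom selection must be non-empty")
  reference <- as.matrix(reference)
  if (max(selection) > nrow(reference))
    stop("selection indexes beyond the reference coordinates")
  structure(list(kind = "rmsd", selection = as.integer(selection),
                 reference = reference[selection, , drop = FALSE]),
            class = "cv_rmsd")
}

#' Evaluate a collective variable
#' @param cv a `cv_rmsd`.
#' @param coords full N x 3 coordinates.
#' @return CV value, Angstrom.
#' @export
cv_value <- function(cv, coords) {
  coords <- as.matrix(coords)
  if (max(cv$selection) > nrow(coords))
    stop("coordinates do not match the CV selection")
  rmsd_fixed(coords[cv$selection, , drop = FALSE], cv$reference)
}

#' Gaussian hill store
#'
#' Holds the metadynamics bias: hill centers (CV values, deposition
#' order), a common height (kcal/mol), width (Angstrom) and deposition
#' interval (steps).  Defaults follow published settings for the
#' binding-pose protocol this engine emulates.
#'
#' @param height hill height, kcal/mol.
#' @param width Gaussian width, Angstrom.
#' @param deposition_interval steps between hills.
#' @return object of class `hill_store`.
#' @export
hill_store <- function(height = 0.05, width = 0.02,
                       deposition_interval = 100) {
  if (height <= 0 || width <= 0) stop("hill height and width must be > 0")
  structure(list(centers = numeric(0), height = height, width = width,
                 deposition_interval = as.integer(deposition_interval)),
            class = "hill_store")
}

#' Metadynamics bias energy at a CV value
#'
#' Sum of deposited Gaussians: `sum_i h * exp(-(s - s_i)^2 / (2 w^2))`;
#' zero for an empty store.
#'
#' @param store a `hill_store`.
#' @param s CV value(s), Angstrom.
#' @return bias energy, kcal/mol (vectorised over `s`).
#' @export
bias_energy <- function(store, s) {
  if (!length(store$centers)) return(rep(0, length(s)))
  vapply(s, function(si)
    sum(store$height * exp(-(si - store$centers)^2 /
                             (2 * store$width^2))), 0)
}

# dE_bias/ds
.bias_denergy <- function(store, s) {
  if (!length(store$centers)) return(0)
  sum(store$height * exp(-(s - store$centers)^2 / (2 * store$width^2)) *
        (-(s - store$centers) / store$width^2))
}

#' Per-atom bias force
#'
#' Chain rule of the bias through the RMSD CV:
#' `F = -dE/ds * ds/dx`, with `ds/dx_i = (x_i - ref_i) / (N s)` on the
#' selected atoms and zero elsewhere.  At `s = 0` the RMSD gradient is
#' undefined and the force is zero by convention.
#'
#' @param store a `hill_store`.
#' @param cv a `cv_rmsd`.
#' @param coords full N x 3 coordinates.
#' @return N x 3 force matrix, kcal/(mol Angstrom).
#' @export
bias_force <- function(store, cv, coords) {
  coords <- as.matrix(coords)
  F <- matrix(0, nrow(coords), 3)
  if (!length(store$centers)) return(F)
  s <- cv_value(cv, coords)
  if (s == 0) return(F)
  dEds <- .bias_denergy(store, s)
  nsel <- length(cv$selection)
  dsdx <- (coords[cv$selection, , drop = FALSE] - cv$reference) / (nsel * s)
  F[cv$selection, ] <- -dEds * dsdx
  F
}

#' Toy particle system on an analytic potential
#'
#' @param potential function of an N x 3 coordinate matrix returning the
#'   energy in kcal/mol.
#' @param coords starting N x 3 coordinates, Angstrom.
#' @param temperature Kelvin.
#' @param friction 1/ps (overdamped mobility is `1/friction`).
#' @param gradient optional analytic gradient function (same signature,
#'   returns N x 3); a central finite difference is used when `NULL`.
#' @param template optional `mol` matching the coordinates, so emitted
#'   trajectories can feed the pose-scoring module.
#' @return object of class `toy_system`.
#' @export
toy_system <- function(potential, coords, temperature = 300, friction = 1,
                       gradient = NULL, template = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be N x 3")
  if (is.null(gradient)) {
    h <- 1e-5
    gradient <- function(x) {
      g <- matrix(0, nrow(x), 3)
      for (i in seq_len(nrow(x))) for (j in 1:3) {
        xp <- x; xm <- x
        xp[i, j] <- xp[i, j] + h; xm[i, j] <- xm[i, j] - h
        g[i, j] <- (potential(xp) - potential(xm)) / (2 * h)
      }
      g
    }
  }
  structure(list(potential = potential, gradient = gradient,
                 coords = coords, temperature = temperature,
                 friction = friction, template = template),
            class = "toy_system")
}

#' Run one (biased) Langevin trial
#'
#' Euler-Maruyama overdamped Langevin dynamics with metadynamics hills
#' deposited on the CV every `deposition_interval` steps.  With
#' `hill_height = 0` the run is plain unbiased dynamics.  Fully
#' deterministic for a given seed.
#'
#' @param system a `toy_system`.
#' @param cv a `cv_rmsd` (reference taken at the starting coordinates if
#'   `NULL`).
#' @param n_steps number of integration steps.
#' @param dt timestep, ps.
#' @param hill_height,hill_width,deposition_interval hill parameters
#'   (see [hill_store()]); `hill_height = 0` disables biasing.
#' @param frame_interval steps between recorded frames (default
#'   `n_steps / 50`, mirroring the 10 ns / 200 ps recording ratio of the
#'   full-scale protocol).
#' @param seed RNG seed (required; the global RNG state is untouched).
#' @return list with `trajectory` (N x 3 x F array), `timestamps` (ps),
#'   `store` (the filled `hill_store`), `cv_trace` (per-step CV values).
#' @export
run_trial <- function(system, cv = NULL, n_steps = 5000, dt = 0.01,
                      hill_height = 0.05, hill_width = 0.02,
                      deposition_interval = 100,
                      frame_interval = max(1L, n_steps %/% 50L),
                      seed = 1) {
  if (n_steps < frame_interval) stop("n_steps must be >= frame_interval")
  x <- system$coords
  if (is.null(cv)) cv <- cv_rmsd(seq_len(nrow(x)), x)
  store <- if (hill_height > 0)
    hill_store(hill_height, hill_width, deposition_interval)
  else structure(list(centers = numeric(0), height = 0, width = 1,
                      deposition_interval = as.integer(deposition_interval)),
                 class = "hill_store")
  mob <- 1 / system$friction
  noise_sd <- sqrt(2 * .KB * system$temperature * mob * dt)
  n_rec <- n_steps %/% frame_interval
  traj <- array(0, c(nrow(x), 3, n_rec + 1))
  traj[, , 1] <- x
  cv_trace <- numeric(n_steps)
  .with_seed(seed, {
    for (step in seq_len(n_steps)) {
      e <- system$potential(x)
      if (!is.finite(e)) stop("non-finite energy at step ", step)
      f <- -system$gradient(x) + bias_force(store, cv, x)
      x <- x + mob * dt * f
      if (noise_sd > 0)
        x <- x + matrix(stats::rnorm(length(x), sd = noise_sd), nrow(x), 3)
      s <- cv_value(cv, x)
      cv_trace[step] <- s
      if (hill_height > 0 && step %% store$deposition_interval == 0)
        store$centers <- c(store$centers, s)
      if (step %% frame_interval == 0)
        traj[, , step %/% frame_interval + 1] <- x
    }
  })
  list(trajectory = traj,
       timestamps = (0:n_rec) * frame_interval * dt,
       store = store, cv_trace = cv_trace)
}

#' Run an ensemble of independent trials
#'
#' Repeats [run_trial()] with distinct seeds and packages the result for
#' the pose-scoring module.  Ten trials is the convention for
#' binding-pose metadynamics.
#'
#' @param system a `toy_system` (must carry a `template` `mol`).
#' @param cv a `cv_rmsd`, or `NULL` for whole-system RMSD.
#' @param n_trials number of trials.
#' @param seeds one seed per trial, all distinct.
#' @param ... passed to [run_trial()].
#' @return a [traj_ensemble()]; each trial's hill store is attached as
#'   attribute `"stores"`.
#' @export
run_ensemble <- function(system, cv = NULL, n_trials = 10,
                         seeds = seq_len(n_trials), ...) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (length(seeds) != n_trials) stop("need one seed per trial")
  if (anyDuplicated(seeds)) stop("duplicate seeds across trials")
  if (is.null(system$template))
    stop("system needs an atom template to build an ensemble")
  runs <- lapply(seeds, function(sd) run_trial(system, cv, seed = sd, ...))
  ens <- traj_ensemble(lapply(runs, `[[`, "trajectory"),
                       runs[[1]]$timestamps, system$template)
  attr(ens, "stores") <- lapply(runs, `[[`, "store")
  ens
}

#' Reconstruct the free-energy estimate from deposited hills
#'
#' Standard non-tempered estimator: `F(s) = -E_bias(s)`, shifted so the
#' minimum over the grid is exactly zero.
#'
#' @param store a filled `hill_store`.
#' @param grid CV values at which to evaluate, Angstrom.
#' @return data frame with columns `s`, `free_energy` (kcal/mol).
#' @export
reconstruct_fes <- function(store, grid) {
  if (!length(store$centers)) stop("empty hill store: no bias deposited")
  f <- -bias_energy(store, grid)
  data.frame(s = grid, free_energy = f - min(f))
}

#' Write a hill log as CSV
#' @param store a `hill_store`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hill_log <- function(store, path) {
  utils::write.csv(
    data.frame(step = seq_along(store$centers) * store$deposition_interval,
               center = store$centers, height = store$height,
               width = store$width),
    path, row.names = FALSE)
  invisible(path)
}

#' One-particle double-well toy system
#'
#' Quartic double well along x, harmonic in y/z:
#' `U = barrier * ((x/half_sep)^2 - 1)^2 + k (y^2 + z^2)`, with minima at
#' `x = +/- half_sep` and a barrier of `barrier` kcal/mol at `x = 0`.
#' The particle starts in the left well.  A matching RMSD CV with its
#' reference shifted to `x = x_ref` (default far left of the sampled
#' region) makes the CV a monotone function of x, so the reconstructed
#' free-energy profile can be compared with the analytic potential.
#'
#' @param barrier barrier height, kcal/mol.
#' @param half_sep half the well separation, Angstrom.
#' @param k transverse stiffness, kcal/(mol A^2).
#' @param temperature Kelvin.
#' @param x_ref CV reference x position, Angstrom.
#' @return list with `system` (a `toy_system`), `cv` (a `cv_rmsd`),
#'   `potential_1d` (function of x) and `cv_of_x` (function mapping x to
#'   the CV value).
#' @export
double_well_system <- function(barrier = 3, half_sep = 1, k = 5,
                               temperature = 300, x_ref = -4) {
  pot <- function(xm) {
    barrier * ((xm[1, 1] / half_sep)^2 - 1)^2 +
      k * (xm[1, 2]^2 + xm[1, 3]^2)
  }
  grad <- function(xm) {
    matrix(c(barrier * 4 * xm[1, 1] * ((xm[1, 1] / half_sep)^2 - 1) /
               half_sep^2,
             2 * k * xm[1, 2], 2 * k * xm[1, 3]), 1, 3)
  }
  start <- matrix(c(-half_sep, 0, 0), 1, 3)
  sys <- toy_system(pot, start, temperature = temperature,
                    gradient = grad)
  cv <- cv_rmsd(1L, matrix(c(x_ref, 0, 0), 1, 3))
  list(system = sys, cv = cv,
       potential_1d = function(x) barrier * ((x / half_sep)^2 - 1)^2,
       cv_of_x = function(x) x - x_ref)
}
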