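# bare structure with explicit energetics parameters
.emol <- function(xyz, q = 0, sigma = 3.4, eps = 0.1, rad = 1.7,
                  screen = 0.8, element = "C") {
  n <- nrow(xyz)
  mol_structure(data.frame(
    serial = 1:n, name = rep_len(element, n),
    element = rep_len(element, n), res_name = "LIG", res_id = 1,
    chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_len(q, n), lj_sigma = rep_len(sigma, n),
    lj_epsilon = rep_len(eps, n), gb_radius = rep_len(rad, n),
    gb_screen = rep_len(screen, n)))
}

test_that("Coulomb energy follows the 332.0636 pair formula", {
  pair <- .emol(rbind(c(0, 0, 0), c(3.32, 0, 0)), q = c(1, -1))
  expect_equal(coulomb_energy(pair), -332.0636 / 3.32)
  expect_equal(coulomb_energy(pair), -100.0192, tolerance = 1e-4)
  zero <- .emol(rbind(c(0, 0, 0), c(2, 0, 0)), q = 0)
  expect_equal(coulomb_energy(zero), 0)
  # 4-atom system vs explicit O(N^2) summation
  set.seed(2)
  xyz <- matrix(runif(12, 0, 6), 4, 3)
  q <- c(0.3, -0.5, 0.2, -0.1)
  m <- .emol(xyz, q = q)
  hand <- 0
  for (i in 1:3) for (j in (i + 1):4)
    hand <- hand + 332.0636 * q[i] * q[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  expect_equal(coulomb_energy(m), hand)
  bad <- m; bad$atoms$charge[2] <- NA
  expect_error(coulomb_energy(bad), "serial")
})

test_that("Lennard-Jones energy has its zero and minimum where it should", {
  sig <- 3.4; eps <- 0.2
  at_sigma <- .emol(rbind(c(0, 0, 0), c(sig, 0, 0)), sigma = sig, eps = eps)
  expect_equal(lj_energy(at_sigma), 0, tolerance = 1e-12)
  at_min <- .emol(rbind(c(0, 0, 0), c(2^(1 / 6) * sig, 0, 0)),
                  sigma = sig, eps = eps)
  expect_equal(lj_energy(at_min), -eps)
  # 3-atom system vs term-by-term sum with Lorentz-Berthelot mixing
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(0, 4.1, 0))
  sigs <- c(3.0, 3.4, 3.6); epss <- c(0.1, 0.2, 0.15)
  m <- .emol(xyz, sigma = sigs, eps = epss)
  hand <- 0
  for (i in 1:2) for (j in (i + 1):3) {
    s <- (sigs[i] + sigs[j]) / 2; e <- sqrt(epss[i] * epss[j])
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    hand <- hand + 4 * e * ((s / r)^12 - (s / r)^6)
  }
  expect_equal(lj_energy(m), hand)
})

test_that("Born radii: isolation limit, approach monotonicity, burial", {
  single <- .emol(matrix(c(0, 0, 0), 1, 3), rad = 1.5)
  expect_equal(born_radii(single), 1.5)
  # two atoms approaching: effective radii grow monotonically
  seps <- seq(8, 2.6, length.out = 10)
  eff <- sapply(seps, function(d)
    born_radii(.emol(rbind(c(0, 0, 0), c(d, 0, 0)), rad = 1.6))[1])
  expect_true(all(diff(eff) > 0))
  expect_true(all(eff > 1.6))
  # a caged atom is more buried than its shell
  shell_dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                      c(0, 0, 1), c(0, 0, -1),
                      cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), 0) / sqrt(2))
  cage <- .emol(rbind(c(0, 0, 0), 3 * shell_dirs), rad = 1.6)
  eff2 <- born_radii(cage)
  expect_gt(eff2[1], max(eff2[-1]))
  bad <- single; bad$atoms$gb_radius <- -1
  expect_error(born_radii(bad), "nonpositive")
})

test_that("GB polar energy reduces to the Born equation for one ion", {
  for (q in c(1, -1, 0.5)) for (a in c(1.2, 1.5, 2.0)) {
    ion <- .emol(matrix(0, 1, 3), q = q, rad = a)
    want <- -166.03 * (1 - 1 / 78.5) * q^2 / a
    expect_equal(gb_polar_energy(ion), want, tolerance = 1e-6 * abs(want))
  }
  neutral <- .emol(rbind(c(0, 0, 0), c(3, 0, 0)), q = 0)
  expect_equal(gb_polar_energy(neutral), 0)
  # two-ion system vs direct evaluation of the Still formula
  duo <- .emol(rbind(c(0, 0, 0), c(4, 0, 0)), q = c(1, -1), rad = 1.5)
  R <- born_radii(duo)
  f12 <- sqrt(16 + R[1] * R[2] * exp(-16 / (4 * R[1] * R[2])))
  hand <- -166.03 * (1 - 1 / 78.5) *
    (1 / R[1] + 1 / R[2] + 2 * (-1) / f12)
  expect_equal(gb_polar_energy(duo), hand)
})

test_that("SASA quadrature matches sphere closed forms", {
  iso <- .emol(matrix(0, 1, 3), rad = 1.6)
  got <- sasa(iso)$total
  want <- 4 * pi * 3.0^2
  expect_lt(abs(got - want) / want, 0.01)
  # coincident identical spheres expose a single sphere's area
  co <- .emol(rbind(c(0, 0, 0), c(0, 0, 0)), rad = 1.6)
  expect_equal(sasa(co)$total, got, tolerance = 1e-9)
  # partial overlap vs the analytic two-sphere formula
  for (d in c(2.0, 3.5, 5.0)) {
    duo <- .emol(rbind(c(0, 0, 0), c(d, 0, 0)), rad = 1.6)
    want2 <- two_sphere_area(3.0, 3.0, d)
    expect_lt(abs(sasa(duo)$total - want2) / want2, 0.02)
  }
  # never exceeds the sum of isolated spheres; equality iff no overlap
  apart <- .emol(rbind(c(0, 0, 0), c(50, 0, 0)), rad = 1.6)
  expect_equal(sasa(apart)$total, 2 * want, tolerance = 0.01 * want)
  near <- .emol(rbind(c(0, 0, 0), c(3, 0, 0)), rad = 1.6)
  expect_lt(sasa(near)$total, 2 * want)
})

# a parameterised receptor/ligand dimer at controllable separation
.dimer <- function(sep, q_rec = 0, q_lig = 0, sigma = 3.4, eps = 0.2) {
  at <- data.frame(
    serial = 1:2, name = c("C1", "C2"), element = "C",
    res_name = c("REC", "LIG"), res_id = c(1, 2), chain = "A",
    x = c(0, sep), y = 0, z = 0,
    charge = c(q_rec, q_lig), lj_sigma = sigma, lj_epsilon = eps,
    gb_radius = 1.7, gb_screen = 0.8,
    role = c("receptor", "ligand"))
  mol_structure(at)
}

# net-neutral charged species: each side is a +q/-q pair 3 A apart
.zwitter_dimer <- function(sep, q = 1) {
  at <- data.frame(
    serial = 1:4, name = c("N1", "O1", "N2", "O2"),
    element = c("N", "O", "N", "O"),
    res_name = c("REC", "REC", "LIG", "LIG"),
    res_id = c(1, 1, 2, 2), chain = "A",
    x = c(0, 3, sep, sep + 3), y = 0, z = 0,
    charge = c(q, -q, q, -q), lj_sigma = 3.2, lj_epsilon = 0.2,
    gb_radius = 1.55, gb_screen = 0.8,
    role = c("receptor", "receptor", "ligand", "ligand"))
  mol_structure(at)
}

test_that("binding free energy vanishes at full separation", {
  for (sep in c(50, 100)) {
    neutral <- delta_g_bind(.dimer(sep))
    expect_lt(abs(neutral$dg_bind), 0.01)
    # charged groups with counter-placed charges (net neutral per side)
    charged <- delta_g_bind(.zwitter_dimer(sep))
    expect_lt(abs(charged$dg_bind), 0.01)
  }
})

test_that("an LJ dimer at its minimum binds by exactly -epsilon in LJ", {
  eps <- 0.2
  d <- delta_g_bind(.dimer(2^(1 / 6) * 3.4, eps = eps))
  expect_equal(d$delta$e_lj, -eps, tolerance = 1e-9)
  expect_lt(d$dg_bind, 0)   # favourable: negative by sign convention
  expect_equal(d$dg_bind, d$delta$e_coulomb + d$delta$e_lj +
                 d$delta$g_gb + d$delta$g_sa)
  expect_equal(d$complex$total, d$complex$e_coulomb + d$complex$e_lj +
                 d$complex$g_gb + d$complex$g_sa)
})

test_that("doubling a non-interacting system doubles every component", {
  cx <- make_toy_complex(n_hb = 1, n_hydrophobic = 1)
  m <- cx$structure
  m$atoms$charge <- 0   # suppress long-range electrostatic cross terms
  far <- m$atoms
  far$x <- far$x + 500
  far$serial <- far$serial + 1000
  both <- mol_structure(rbind(m$atoms, far))
  d1 <- delta_g_bind(m)
  d2 <- delta_g_bind(both)
  for (comp in c("e_coulomb", "e_lj", "g_gb", "g_sa", "total")) {
    expect_equal(d2$delta[[comp]], 2 * d1$delta[[comp]],
                 tolerance = 1e-8)
  }
})

test_that("selection safety checks and ddG arithmetic hold", {
  m <- .dimer(4)
  expect_error(delta_g_bind(m, receptor_idx = 1:2, ligand_idx = 2),
               "overlap")
  expect_equal(delta_delta_g(-97.84, -118.15), 20.31)
  expect_equal(delta_delta_g(-81.32, -91.97), 10.65)
  expect_equal(delta_delta_g(-5, -5), 0)
  js <- write_energy_report(delta_g_bind(m))
  expect_match(as.character(js), "dg_bind")
})
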