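test_that("potential closed forms", {
  ff <- force_field()
  expect_equal(ff$kappa_s, 1000 / 3.4^2)
  expect_equal(ff$kappa_smc, 1 / 3.4^2)
  expect_equal(ff$kappa_b, 45 / 3.4)
  expect_equal(bond_energy(3.4, ff$kappa_s, 3.4), 0)
  expect_equal(bond_energy(4.4, ff$kappa_s, 3.4), ff$kappa_s)
  expect_equal(angle_energy(pi, ff$kappa_b), 0)           # straight chain
  expect_equal(angle_energy(0, ff$kappa_b), 2 * ff$kappa_b)
  expect_equal(angle_energy(pi / 2, ff$kappa_b), ff$kappa_b)
  expect_equal(soft_pair_energy(0, 5, 3.4), 10)           # bounded at 2A
  expect_equal(soft_pair_energy(3.4 / 2, 5, 3.4), 5)
  expect_equal(soft_pair_energy(3.4, 5, 3.4), 0)
  expect_equal(soft_pair_energy(10, 5, 3.4), 0)
  # mode tables
  expect_equal(ff$modes$minimize_crossing$A[1, 1], 0.2)
  expect_equal(ff$modes$swell$rc[1, 1], 3 * 3.4)
  expect_equal(ff$modes$normal$rc[1, 1], 3.4)
  expect_equal(ff$modes$normal$rc[1, 2], 11.7)            # DNA-ribosome
  expect_equal(ff$modes$normal$rc[2, 2], 20)              # ribo-ribo
  expect_equal(ff$modes$normal$A[3, 3], 0)                # bdry-bdry inert
})

test_that("engine energy matches a hand summation on a tiny system", {
  ff <- force_field()
  pos <- rbind(c(0, 0, 0), c(4, 0, 0), c(4, 3, 0))
  sys <- bead_system(
    pos, rep("dna_mother", 3),
    bonds = rbind(c(1L, 2L), c(2L, 3L)),
    angles = rbind(c(1L, 2L, 3L))
  )
  out <- total_energy_and_forces(sys, ff, "normal")
  # bonds: 4 and 3 nm; angle at bead 2 is 90 deg; pairs 1-2, 2-3, 1-3 are all
  # excluded (bonded or angle outer beads), so no soft term
  e_hand <- bond_energy(4, ff$kappa_s, 3.4) + bond_energy(3, ff$kappa_s, 3.4) +
    angle_energy(pi / 2, ff$kappa_b)
  expect_equal(out$energy, e_hand, tolerance = 1e-12)

  # unbonded close pair contributes the soft term
  sys2 <- bead_system(rbind(c(0, 0, 0), c(2, 0, 0)), rep("dna_mother", 2))
  out2 <- total_energy_and_forces(sys2, ff, "normal")
  expect_equal(out2$energy, soft_pair_energy(2, 5, 3.4), tolerance = 1e-12)
  # equal and opposite forces along the pair axis
  expect_equal(out2$forces[1, ], -out2$forces[2, ], tolerance = 1e-12)
  expect_lt(out2$forces[1, 1], 0)   # repulsion pushes bead 1 to -x
})

test_that("forces are the negative numerical gradient of the energy", {
  set.seed(11)
  ff <- force_field()
  n <- 30
  pos <- matrix(cumsum(rnorm(3 * n, sd = 2)), ncol = 3)
  species <- c(rep("dna_mother", 24), rep("ribosome", 4), rep("boundary", 2))
  bonds <- cbind(1:23, 2:24)
  angles <- cbind(1:22, 2:23, 3:24)
  sys <- bead_system(pos, species, bonds = bonds,
                     bond_kind = c(rep("backbone", 20), rep("smc", 3)),
                     angles = angles)
  for (mode in c("normal", "swell", "minimize_crossing")) {
    out <- total_energy_and_forces(sys, ff, mode)
    h <- 1e-6
    idx <- cbind(c(1, 5, 12, 25, 29), c(1, 2, 3, 1, 2))
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; dim <- idx[k, 2]
      sp <- sys; sm <- sys
      sp$positions[i, dim] <- sp$positions[i, dim] + h
      sm$positions[i, dim] <- sm$positions[i, dim] - h
      num <- -(total_energy_and_forces(sp, ff, mode)$energy -
               total_energy_and_forces(sm, ff, mode)$energy) / (2 * h)
      expect_equal(out$forces[i, dim], num, tolerance = 1e-5)
    }
  }
})

test_that("grid pair search is exact against the all-pairs sum", {
  set.seed(12)
  ff <- force_field()
  n <- 400
  pos <- matrix(runif(3 * n, -60, 60), ncol = 3)
  species <- sample(c("dna_mother", "dna_dL", "ribosome", "boundary"),
                    n, replace = TRUE, prob = c(0.5, 0.2, 0.2, 0.1))
  sys <- bead_system(pos, species, bonds = cbind(1:10, 11:20))
  for (mode in c("normal", "swell", "minimize_crossing")) {
    g <- total_energy_and_forces(sys, ff, mode, use_grid = TRUE)
    a <- total_energy_and_forces(sys, ff, mode, use_grid = FALSE)
    expect_equal(g$energy, a$energy, tolerance = 1e-12)
    expect_equal(g$forces, a$forces, tolerance = 1e-12)
  }
})

test_that("minimisation relaxes a stretched dimer to the bond length", {
  ff <- force_field()
  sys <- bead_system(rbind(c(0, 0, 0), c(8, 0, 0)), rep("dna_mother", 2),
                     bonds = rbind(c(1L, 2L)))
  out <- minimize(sys, ff, mode = "normal", tol = 1e-8, max_iter = 5000)
  expect_true(attr(out, "converged"))
  r <- sqrt(sum((out$positions[1, ] - out$positions[2, ])^2))
  expect_equal(r, 3.4, tolerance = 1e-4)
  expect_lt(attr(out, "energy"), 1e-6)

  # energy never increases across accepted iterations of a bigger problem
  set.seed(13)
  n <- 50
  ring <- bead_system(
    matrix(rnorm(3 * n, sd = 6), ncol = 3), rep("dna_mother", n),
    bonds = cbind(1:n, c(2:n, 1L)),
    angles = cbind(1:n, c(2:n, 1L), c(3:n, 1L, 2L))
  )
  e0 <- total_energy_and_forces(ring, ff, "normal")$energy
  rel <- minimize(ring, ff, mode = "normal", tol = 1e-4, max_iter = 3000)
  expect_lt(attr(rel, "energy"), e0)

  # ribosomes and boundary particles are pinned during minimisation
  mix <- bead_system(
    rbind(c(0, 0, 0), c(1, 0, 0), c(5, 5, 5), c(-9, 0, 2)),
    c("dna_mother", "dna_mother", "ribosome", "boundary"),
    bonds = rbind(c(1L, 2L))
  )
  relm <- minimize(mix, ff, max_iter = 200)
  expect_equal(relm$positions[3, ], c(5, 5, 5))
  expect_equal(relm$positions[4, ], c(-9, 0, 2))
})

test_that("Brownian dynamics parameters and free diffusion", {
  bd <- bd_params()
  expect_equal(bd$dt, 25e-9)
  # Stokes-Einstein for a 3.4 nm bead at 310 K in 1.2 Pa s, nm^2/s
  D_expect <- 1.380649e-23 * 310 / (3 * pi * 1.2 * 3.4e-9) * 1e18
  expect_equal(bd$mobility(3.4), D_expect, tolerance = 1e-12)

  # free beads diffuse with per-step displacement variance 2 D dt per axis
  set.seed(14)
  n <- 400
  sys <- bead_system(matrix(runif(3 * n, -1e5, 1e5), ncol = 3),
                     rep("dna_mother", n))
  p0 <- sys$positions
  out <- brownian_run(sys, force_field(), bd, n_steps = 25)
  disp2 <- rowSums((out$positions - p0)^2)
  expect_equal(mean(disp2), 6 * D_expect * bd$dt * 25, tolerance = 0.1)

  # boundary particles never move under BD
  sysb <- bead_system(rbind(c(0, 0, 0), c(50, 0, 0)),
                      c("dna_mother", "boundary"))
  outb <- brownian_run(sysb, force_field(), bd, n_steps = 100)
  expect_equal(outb$positions[2, ], c(50, 0, 0))
  expect_false(isTRUE(all.equal(outb$positions[1, ], c(0, 0, 0))))
})

test_that("equilibration schedule", {
  expect_equal(equilibration_schedule("long_minute"), 500000L)
  expect_equal(equilibration_schedule("swell_tick", 30), 20000L)
  expect_equal(equilibration_schedule("swell_tick", 65), 20000L)
  expect_equal(equilibration_schedule("swell_tick", 67), 20000L + 9000L)
  expect_equal(equilibration_schedule("swell_tick", 105),
               20000L + 4500L * 40L)
})
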