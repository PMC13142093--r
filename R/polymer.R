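# Bead-spring force field and dynamics.
#
# Potentials (units: nm, kBT):
#   backbone bond   U = kappa_s (r - r0)^2,  kappa_s = 1000 kBT/sigma^2, r0 = sigma
#   SMC loop bond   U = kappa   (r - r0)^2,  kappa   = 1 kBT/sigma^2,    r0 = sigma
#   bending         U = kappa_b (1 - cos(pi - theta)), kappa_b = lp kBT / sigma
#   excluded volume U = A (1 + cos(pi r / r_c)) for r < r_c (soft, bounded)
#
# Three excluded-volume modes drive the simulation cadence:
#   "minimize_crossing": DNA-DNA A = 0.2 kBT, r_c = sigma  -- the lowered
#       barrier lets strands pass, emulating type-II topoisomerase action
#   "swell":  DNA-DNA A = 5 kBT, r_c = 3 sigma = 10.2 nm   -- expanded
#       diameter relaxation that counteracts SMC-induced compaction
#   "normal": DNA-DNA A = 5 kBT, r_c = sigma               -- basal diameter

SPECIES_LEVELS <- c("dna_mother", "dna_dL", "dna_dR", "ribosome", "boundary")

# pair class per species: 1 = DNA, 2 = ribosome, 3 = boundary
species_pclass <- function(species) {
  cls <- c(
    dna_mother = 1L, dna_dL = 1L, dna_dR = 1L,
    ribosome = 2L, boundary = 3L
  )[species]
  if (any(is.na(cls))) stop("unknown species label")
  unname(cls)
}

#' Force-field parameter set
#'
#' @param sigma_dna DNA bead diameter, nm (default 3.4; 10 bp per bead).
#' @param lp DNA persistence length, nm (default 45).
#' @param r_ribo Ribosome radius, nm (default 10; 20 nm diameter spheres).
#' @param r_bdry Boundary-particle radius, nm (default 10).
#' @param temperature Kelvin (default 310); energies are expressed in kBT.
#' @return Object of class `force_field` with spring constants in kBT/nm^2
#'   and the per-mode soft-pair tables.
#' @export
force_field <- function(sigma_dna = 3.4, lp = 45, r_ribo = 10, r_bdry = 10,
                        temperature = 310) {
  r_dna <- sigma_dna / 2
  soft <- function(a_dd, rc_dd) {
    A <- matrix(0, 3, 3)
    Rc <- matrix(1, 3, 3)
    A[1, 1] <- a_dd; Rc[1, 1] <- rc_dd
    A[1, 2] <- A[2, 1] <- 1; Rc[1, 2] <- Rc[2, 1] <- r_ribo + r_dna
    A[1, 3] <- A[3, 1] <- 1; Rc[1, 3] <- Rc[3, 1] <- r_bdry + r_dna
    A[2, 3] <- A[3, 2] <- 1; Rc[2, 3] <- Rc[3, 2] <- r_bdry + r_ribo
    A[2, 2] <- 1; Rc[2, 2] <- 2 * r_ribo  # ribosome-ribosome excluded volume
    list(A = A, rc = Rc)
  }
  structure(
    list(
      sigma_dna = sigma_dna,
      lp = lp,
      r_ribo = r_ribo,
      r_bdry = r_bdry,
      temperature = temperature,
      kappa_s = 1000 / sigma_dna^2,
      kappa_smc = 1 / sigma_dna^2,
      r0 = sigma_dna,
      kappa_b = lp / sigma_dna,
      modes = list(
        minimize_crossing = soft(0.2, sigma_dna),
        swell = soft(5, 3 * sigma_dna),
        normal = soft(5, sigma_dna)
      )
    ),
    class = "force_field"
  )
}

#' Harmonic bond energy
#' @param r Separation, nm (vectorised). @param kappa_s Spring constant,
#'   kBT/nm^2. @param r0 Equilibrium length, nm.
#' @return Energy in kBT.
#' @export
bond_energy <- function(r, kappa_s, r0) {
  stopifnot(all(r >= 0))
  kappa_s * (r - r0)^2
}

#' Cosine bending energy
#'
#' `kappa_b (1 - cos(pi - theta))`: zero for a straight chain
#' (`theta = pi`), maximal (`2 kappa_b`) for a full fold.
#'
#' @param theta Bond angle in radians, `[0, pi]` (vectorised).
#' @param kappa_b Bending constant, kBT.
#' @export
angle_energy <- function(theta, kappa_b) {
  stopifnot(all(theta >= -1e-12 & theta <= pi + 1e-12))
  kappa_b * (1 - cos(pi - theta))
}

#' Soft excluded-volume pair energy
#'
#' `A (1 + cos(pi r / r_c))` for `r < r_c`, zero beyond the cutoff. Bounded
#' at `2A` for full overlap, which is what permits strand crossing when `A`
#' is small.
#'
#' @param r Separation, nm (vectorised). @param A Barrier scale, kBT.
#' @param r_c Cutoff, nm.
#' @export
soft_pair_energy <- function(r, A, r_c) {
  stopifnot(all(r >= 0))
  ifelse(r < r_c, A * (1 + cos(pi * r / r_c)), 0)
}

#' Brownian-dynamics parameters
#'
#' Overdamped dynamics with per-species drag `gamma = 3 pi eta sigma`; the
#' thermal noise obeys fluctuation-dissipation at `temperature`.
#'
#' @param dt Timestep, s (default 25e-9).
#' @param eta Dynamic viscosity, Pa s (default 1.2).
#' @param temperature Kelvin (default 310).
#' @return Object of class `bd_params`; `mobility(sigma_nm)` gives
#'   `kBT / (3 pi eta sigma)` in nm^2/s, i.e. the diffusion coefficient.
#' @export
bd_params <- function(dt = 25e-9, eta = 1.2, temperature = 310) {
  stopifnot(dt > 0, eta > 0, temperature > 0)
  kBT_J <- 1.380649e-23 * temperature
  structure(
    list(
      dt = dt, eta = eta, temperature = temperature, kBT_J = kBT_J,
      # mobility in nm^2 / (kBT s) for a sphere of diameter sigma (nm)
      mobility = function(sigma_nm) {
        kBT_J / (3 * pi * eta * sigma_nm * 1e-9) * 1e18 / 1
      }
    ),
    class = "bd_params"
  )
}

# per-bead mobility vector (nm^2/s per unit kBT force); boundary beads get a
# placeholder (they are never mobile)
bead_mobility <- function(species, ff, bd) {
  sig <- c(
    dna_mother = ff$sigma_dna, dna_dL = ff$sigma_dna, dna_dR = ff$sigma_dna,
    ribosome = 2 * ff$r_ribo, boundary = 2 * ff$r_bdry
  )[species]
  bd$mobility(unname(sig))
}

#' Assemble a bead system
#'
#' @param positions n x 3 matrix, nm.
#' @param species Character vector of `r toString(SPECIES_LEVELS)`.
#' @param bonds Integer matrix (m x 2) of 1-based bead indices.
#' @param bond_kind Character vector, `"backbone"` or `"smc"`, per bond.
#' @param angles Integer matrix (a x 3), centre bead in column 2.
#' @return Object of class `bead_system`.
#' @export
bead_system <- function(positions, species, bonds = NULL, bond_kind = NULL,
                        angles = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, length(species) == nrow(positions))
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  if (is.null(angles)) angles <- matrix(integer(0), 0, 3)
  if (is.null(bond_kind)) bond_kind <- rep("backbone", nrow(bonds))
  structure(
    list(
      positions = positions, species = species,
      bonds = bonds, bond_kind = bond_kind, angles = angles
    ),
    class = "bead_system"
  )
}

#' @export
print.bead_system <- function(x, ...) {
  cat(sprintf(
    "<bead_system> %d beads (%s), %d bonds, %d angles\n",
    nrow(x$positions),
    paste(sprintf("%s=%d", names(table(x$species)), table(x$species)),
          collapse = ", "),
    nrow(x$bonds), nrow(x$angles)
  ))
  invisible(x)
}

# Topological exclusions: pair terms skip directly bonded beads (1-2) and
# the outer beads of each bending triplet (backbone 1-3), the reference MD
# convention for bonded polymers.
bond_exclusions <- function(bonds, angles) {
  excl <- rbind(
    bonds,
    if (nrow(angles) > 0) angles[, c(1, 3), drop = FALSE]
  )
  if (is.null(excl) || nrow(excl) == 0) {
    return(matrix(integer(0), 0, 2))
  }
  excl <- cbind(pmin(excl[, 1], excl[, 2]), pmax(excl[, 1], excl[, 2]))
  unique(excl)
}

# Internal: pack arguments for the compiled kernels.
engine_args <- function(system, ff, mode) {
  mode <- match.arg(mode, names(ff$modes))
  soft <- ff$modes[[mode]]
  bond_k <- ifelse(system$bond_kind == "smc", ff$kappa_smc, ff$kappa_s)
  list(
    pclass = as.integer(species_pclass(system$species) - 1L),
    pairA = soft$A, pairRc = soft$rc,
    bonds = matrix(as.integer(system$bonds - 1L), ncol = 2),
    bond_k = as.numeric(bond_k),
    bond_r0 = rep(ff$r0, nrow(system$bonds)),
    angles = matrix(as.integer(system$angles - 1L), ncol = 3),
    kappa_b = ff$kappa_b,
    excl = matrix(as.integer(bond_exclusions(system$bonds,
                                             system$angles) - 1L),
                  ncol = 2)
  )
}

mobile_mask <- function(system, phase = c("bd", "minimize")) {
  phase <- match.arg(phase)
  if (phase == "minimize") {
    # ribosome and boundary positions held fixed during minimisations
    !(system$species %in% c("ribosome", "boundary"))
  } else {
    system$species != "boundary"
  }
}

#' Total potential energy and forces
#'
#' Forces are the analytic negative gradient of the bonded, bending and soft
#' pair terms; pair interactions are found on a uniform grid with cell edge
#' at least the largest cutoff (exact, verified against the all-pairs sum).
#'
#' @param system A [bead_system()].
#' @param forcefield A [force_field()].
#' @param mode `"normal"`, `"swell"` or `"minimize_crossing"`.
#' @param use_grid Set `FALSE` to force the all-pairs O(n^2) path.
#' @return List with `energy` (kBT) and `forces` (n x 3, kBT/nm).
#' @export
total_energy_and_forces <- function(system, forcefield, mode = "normal",
                                    use_grid = TRUE) {
  a <- engine_args(system, forcefield, mode)
  cpp_energy_forces(
    system$positions, a$pclass, a$pairA, a$pairRc, a$bonds, a$bond_k,
    a$bond_r0, a$angles, a$kappa_b, a$excl, use_grid
  )
}

#' Energy minimisation (FIRE descent)
#'
#' In `"minimize_crossing"` mode the DNA-DNA barrier is 0.2 kBT so strands
#' pass through one another, emulating topoisomerase strand passage while
#' SMC loop bonds are pulled to their new positions. Accepted iterations are
#' monotone non-increasing in energy; ribosomes and boundary particles are
#' held fixed.
#'
#' @inheritParams total_energy_and_forces
#' @param tol Convergence threshold on the largest per-bead force, kBT/nm.
#' @param max_iter Iteration cap.
#' @return The system with relaxed positions; attributes `energy`,
#'   `iterations`, `converged`, `max_force`.
#' @export
minimize <- function(system, forcefield, mode = "minimize_crossing",
                     tol = 1e-3, max_iter = 10000) {
  a <- engine_args(system, forcefield, mode)
  res <- cpp_minimize(
    system$positions, mobile_mask(system, "minimize"), a$pclass, a$pairA,
    a$pairRc, a$bonds, a$bond_k, a$bond_r0, a$angles, a$kappa_b, a$excl,
    tol, as.integer(max_iter)
  )
  system$positions <- res$pos
  attr(system, "energy") <- res$energy
  attr(system, "iterations") <- res$iterations
  attr(system, "converged") <- res$converged
  attr(system, "max_force") <- res$max_force
  system
}

#' Overdamped Brownian dynamics
#'
#' Euler-Maruyama integration of `gamma dr/dt = -grad U + R(t)` at 310 K
#' with a 25 ns timestep: `dr = (F/gamma) dt + sqrt(2 kBT dt / gamma) xi`.
#' Boundary particles are fixed; ribosomes move with their own drag.
#'
#' @inheritParams total_energy_and_forces
#' @param bd A [bd_params()].
#' @param n_steps Number of BD steps.
#' @param save_every If positive, keep a position snapshot every this many
#'   steps (attribute `"snapshots"`).
#' @return The system with updated positions. A warning is raised if any
#'   single-step displacement exceeded one DNA bead diameter.
#' @export
brownian_run <- function(system, forcefield, bd = bd_params(), mode = "normal",
                         n_steps = 1000, save_every = 0) {
  stopifnot(n_steps >= 0)
  if (n_steps == 0) {
    return(system)
  }
  a <- engine_args(system, forcefield, mode)
  res <- cpp_bd(
    system$positions, mobile_mask(system, "bd"),
    bead_mobility(system$species, forcefield, bd),
    a$pclass, a$pairA, a$pairRc, a$bonds, a$bond_k, a$bond_r0, a$angles,
    a$kappa_b, a$excl, bd$dt, 1.0, as.integer(n_steps), as.integer(save_every)
  )
  if (res$n_large_steps > 0) {
    warning(sprintf(
      "%d BD step displacement(s) exceeded one bead diameter; timestep may be too large for the current forces",
      res$n_large_steps
    ))
  }
  system$positions <- res$pos
  if (save_every > 0) attr(system, "snapshots") <- res$snapshots
  system
}

#' Number of BD steps per relaxation phase
#'
#' Swell-mode relaxations (every 2-s tick) use 20,000 steps during spherical
#' growth and grow by 4,500 steps per minute once division geometry begins
#' at 65 min, to accommodate the expanding dumbbell. The long basal-diameter
#' equilibration every minute uses 500,000 steps.
#'
#' @param mode `"swell_tick"` or `"long_minute"`.
#' @param t_biological_min Cell-cycle time in minutes.
#' @param ramp_start Minute at which the swell-step ramp begins (default 65).
#' @return Integer step count.
#' @export
equilibration_schedule <- function(mode = c("swell_tick", "long_minute"),
                                   t_biological_min = 0, ramp_start = 65) {
  mode <- match.arg(mode)
  if (mode == "long_minute") {
    return(500000L)
  }
  extra <- if (t_biological_min > ramp_start) {
    4500 * (t_biological_min - ramp_start)
  } else 0
  as.integer(20000 + extra)
}
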