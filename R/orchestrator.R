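# Cell-cycle orchestrator: drives the simulation on two cadences.
#
# Every 2-s tick: loop-extrusion iterations, fork advance (spawning daughter
# beads), SMC bond rebuild, energy minimization with strand crossing allowed
# (topoisomerase emulation), and a swollen-diameter BD relaxation.
# Every 1-min event: a long basal-diameter BD equilibration, conformation
# sampling, ribosome addition and membrane geometry update.

#' Simulation configuration
#'
#' Presets scale the full model down to tractable sizes; any field can be
#' overridden. `"paper"` is the full 543,379-bp cell; `"desk"` is a
#' 10x-reduced genome with 1/10 the relaxation steps; `"micro"` is a 6-kb
#' toy cell with a compressed 35-min cycle for fast end-to-end runs.
#'
#' @param preset `"paper"`, `"desk"` or `"micro"`.
#' @param ... Named overrides of top-level fields; list-valued fields
#'   (`smc`, `growth`, `ribosomes`, `equil`, `bd`, `ff`, `minimize`) are
#'   merged element-wise.
#' @param seed Master seed; subsystem streams (placement, loop extrusion,
#'   BD noise) are derived from it so toggling one subsystem does not
#'   perturb the others' draws.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(preset = c("paper", "desk", "micro"), ..., seed = 1L) {
  preset <- match.arg(preset)
  base <- list(
    paper = list(
      length_bp = 543379L, bp_per_bead = 10L,
      smc = list(N = 20, v = 500, tau = 100, blocking_enabled = TRUE,
                 stall_death_prob = NULL, fork_policy = "stall_and_trail",
                 bypass_time = 20, bypass_search_sites = 15),
      fork_beads_per_tick = 20L,
      growth = list(t_start = 5, t_vol_double = 65, t_div = 105, R0 = 200),
      init_radius = 206,
      ribosomes = list(initial = 500L, per_minute = 5L),
      equil = list(smc_1d = 360000L, swell_base = 20000L,
                   swell_ramp_per_min = 4500L, long_steps = 500000L),
      ticks_per_minute = 30L
    ),
    desk = list(
      length_bp = 54340L, bp_per_bead = 10L,
      smc = list(N = 5, v = 500, tau = 40, blocking_enabled = TRUE,
                 stall_death_prob = NULL, fork_policy = "stall_and_trail",
                 bypass_time = 20, bypass_search_sites = 15),
      fork_beads_per_tick = 2L,
      growth = list(t_start = 5, t_vol_double = 65, t_div = 105, R0 = 93),
      init_radius = 96,
      ribosomes = list(initial = 50L, per_minute = 1L),
      equil = list(smc_1d = 36000L, swell_base = 2000L,
                   swell_ramp_per_min = 450L, long_steps = 50000L),
      ticks_per_minute = 30L
    ),
    micro = list(
      length_bp = 3000L, bp_per_bead = 10L,
      smc = list(N = 3, v = 500, tau = 3.6, blocking_enabled = TRUE,
                 stall_death_prob = NULL, fork_policy = "stall_and_trail",
                 bypass_time = 20, bypass_search_sites = 15),
      fork_beads_per_tick = 1L,
      growth = list(t_start = 5, t_vol_double = 11, t_div = 17, R0 = 36),
      init_radius = 37,
      ribosomes = list(initial = 5L, per_minute = 1L),
      equil = list(smc_1d = 2000L, swell_base = 150L,
                   swell_ramp_per_min = 50L, long_steps = 2000L),
      ticks_per_minute = 30L
    )
  )[[preset]]
  base$preset <- preset
  base$bd <- list(dt = 25e-9, eta = 1.2, temperature = 310)
  base$ff <- list(sigma_dna = 3.4, lp = 45)
  base$minimize <- list(
    tol = 1.0,
    max_iter = c(paper = 500L, desk = 300L, micro = 60L)[[preset]]
  )
  base$topo_after <- "all"
  base$seed <- as.integer(seed)

  ov <- list(...)
  unknown <- setdiff(names(ov), names(base))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(ov)) {
    if (is.list(base[[nm]]) && is.list(ov[[nm]])) {
      bad <- setdiff(names(ov[[nm]]), names(base[[nm]]))
      if (length(bad) > 0) {
        stop(sprintf("unknown %s field(s): %s", nm, paste(bad, collapse = ", ")))
      }
      base[[nm]] <- utils::modifyList(base[[nm]], ov[[nm]])
    } else {
      base[[nm]] <- ov[[nm]]
    }
  }
  validate_config(base)
  class(base) <- "sim_config"
  base
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      length_bp > 0, bp_per_bead > 0,
      smc$N >= 0, smc$v > 0, smc$tau > 0,
      fork_beads_per_tick >= 1,
      growth$R0 > 0, init_radius > 0,
      ribosomes$initial >= 0, ribosomes$per_minute >= 0,
      equil$swell_base >= 0, equil$long_steps >= 0, equil$smc_1d >= 0,
      ticks_per_minute >= 1,
      topo_after %in% c("all", "smc_only")
    )
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> preset=%s L=%d bp N=%d v=%g tau=%g (coverage %.2f) seed=%d\n",
    x$preset, x$length_bp, x$smc$N, x$smc$v, x$smc$tau,
    loop_coverage(x$smc$N, x$smc$v, x$smc$tau, x$length_bp), x$seed
  ))
  invisible(x)
}

config_smc_params <- function(cfg) {
  do.call(smc_params, c(cfg$smc[c("N", "v", "tau", "blocking_enabled",
                                  "fork_policy", "bypass_time",
                                  "bypass_search_sites")],
                        list(stall_death_prob = cfg$smc$stall_death_prob)))
}

#' Initialise a cell state
#'
#' Builds the starting configuration: membrane at `init_radius`, uniform
#' ribosome field, self-avoiding chromosome ring threaded through it, and a
#' 1D-pre-equilibrated SMC ensemble at `N` bound complexes.
#'
#' @param config A [sim_config()].
#' @return Mutable environment of class `cell_state`.
#' @export
init_cell <- function(config) {
  cell <- new.env(parent = emptyenv())
  cell$config <- config
  cell$genome <- init_genome(config$length_bp, config$bp_per_bead)
  cell$state <- replication_state(cell$genome)
  cell$schedule <- do.call(growth_schedule, config$growth)
  cell$ff <- do.call(force_field, config$ff)
  cell$bd <- do.call(bd_params, config$bd)
  cell$streams <- make_rng_streams(config$seed)
  cell$t <- config$growth$t_start
  cell$axis <- c(0, 0, 1)
  cell$shape <- cell_shape(config$init_radius, 0, cell$axis)
  cell$boundary <- boundary_shell(cell$shape)
  with_stream(cell$streams, "placement", {
    cell$ribosomes <- generate_ribosomes(config$ribosomes$initial, cell$shape)
    cell$dna <- generate_ring(cell$genome, cell$shape, cell$ribosomes,
                              sigma = cell$ff$sigma_dna)
  })
  params <- config_smc_params(config)
  with_stream(cell$streams, "smc", {
    cell$ens <- smc_ensemble(cell$genome, params)
    for (k in seq_len(params$N)) load_smc(cell$ens)
    equilibrate_1d(cell$ens, config$equil$smc_1d)
  })
  cell$frames <- list()
  cell$metrics <- list()
  class(cell) <- "cell_state"
  cell
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf(
    "<cell_state> t=%.2f min, %d DNA beads (f=%.2f), %d ribosomes, %d SMCs\n",
    x$t, x$state$n_dna_beads, replicated_fraction(x$state),
    x$ribosomes$count, smc_count(x$ens)
  ))
  invisible(x)
}

# assemble the full bead system (DNA first, then ribosomes, then boundary)
# with current chromosome topology and SMC loop bonds
build_system <- function(cell) {
  smc_pairs <- loop_bond_pairs(cell$ens, cell$state)
  topo <- chromosome_topology(cell$state, smc_pairs)
  species <- c(dna_species(cell$state),
               rep("ribosome", cell$ribosomes$count),
               rep("boundary", nrow(cell$boundary)))
  bead_system(
    rbind(cell$dna, cell$ribosomes$positions, cell$boundary),
    species, topo$bonds, topo$bond_kind, topo$angles
  )
}

write_back <- function(cell, sys) {
  n_dna <- cell$state$n_dna_beads
  cell$dna <- sys$positions[seq_len(n_dna), , drop = FALSE]
  if (cell$ribosomes$count > 0) {
    cell$ribosomes$positions <-
      sys$positions[n_dna + seq_len(cell$ribosomes$count), , drop = FALSE]
  }
  invisible(cell)
}

tick_guard <- function(cell, what, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf(
      "tick at t=%.3f min failed in %s: %s [beads=%d, f=%.3f, SMCs=%d]",
      cell$t, what, conditionMessage(e), cell$state$n_dna_beads,
      replicated_fraction(cell$state), smc_count(cell$ens)
    ), call. = FALSE)
  })
}

smc_phase <- function(cell) {
  params <- cell$ens$params
  with_stream(cell$streams, "smc", {
    for (k in seq_len(params$iters_per_tick)) step_iteration(cell$ens)
  })
}

fork_phase <- function(cell) {
  if (cell$state$complete) {
    return(invisible(cell))
  }
  cell$state <- advance_forks(cell$state, cell$config$fork_beads_per_tick)
  nb <- attr(cell$state, "new_beads")
  with_stream(cell$streams, "placement", {
    cell$dna <- spawn_daughter_coordinates(cell$dna, cell$state, nb)
  })
  with_stream(cell$streams, "smc", {
    handle_fork_advance(cell$ens, nb)
    target <- target_bound_count(cell$config$smc$N,
                                 replicated_fraction(cell$state))
    while (smc_count(cell$ens) < target) {
      load_smc(cell$ens)
      if (!isTRUE(attr(cell$ens, "loaded"))) break  # defer to next tick
    }
  })
  invisible(cell)
}

relax_phase <- function(cell, n_swell_steps) {
  sys <- build_system(cell)
  sys <- minimize(sys, cell$ff, mode = "minimize_crossing",
                  tol = cell$config$minimize$tol,
                  max_iter = cell$config$minimize$max_iter)
  with_stream(cell$streams, "bd", {
    sys <- suppressWarnings(
      brownian_run(sys, cell$ff, cell$bd, mode = "swell",
                   n_steps = n_swell_steps)
    )
  })
  write_back(cell, sys)
}

#' Advance one 2-s communication tick
#'
#' In order: (1) `v/10` loop-extrusion iterations; (2) fork advance with
#' daughter-bead spawning, SMC/fork synchronisation and loading up to the
#' ramped target count; (3) SMC bond rebuild; (4) minimization with strand
#' crossing allowed; (5) swollen-diameter BD relaxation. With
#' `topo_after = "smc_only"` the rebuild/minimization runs directly after
#' the SMC update, before the fork advance.
#'
#' @param cell A [init_cell()] state; modified in place.
#' @return The cell, invisibly.
#' @export
tick_2s <- function(cell) {
  if (cell$t >= cell$config$growth$t_div) stop("cell cycle already complete")
  swell <- swell_steps(cell)
  if (cell$config$topo_after == "smc_only") {
    tick_guard(cell, "loop extrusion", smc_phase(cell))
    tick_guard(cell, "crossing minimization", {
      sys <- build_system(cell)
      sys <- minimize(sys, cell$ff, mode = "minimize_crossing",
                      tol = cell$config$minimize$tol,
                      max_iter = cell$config$minimize$max_iter)
      write_back(cell, sys)
    })
    tick_guard(cell, "replication", fork_phase(cell))
    tick_guard(cell, "relaxation", {
      sys <- build_system(cell)
      with_stream(cell$streams, "bd", {
        sys <- suppressWarnings(
          brownian_run(sys, cell$ff, cell$bd, mode = "swell", n_steps = swell)
        )
      })
      write_back(cell, sys)
    })
  } else {
    tick_guard(cell, "loop extrusion", smc_phase(cell))
    tick_guard(cell, "replication", fork_phase(cell))
    tick_guard(cell, "relaxation", relax_phase(cell, swell))
  }
  cell$t <- cell$t + 2 / 60
  invisible(cell)
}

swell_steps <- function(cell) {
  g <- cell$config$growth
  extra <- if (cell$t > g$t_vol_double) {
    cell$config$equil$swell_ramp_per_min * (cell$t - g$t_vol_double)
  } else 0
  as.integer(cell$config$equil$swell_base + extra)
}

daughter_slots <- function(state) {
  list(
    dL = which(state$replicated),
    dR = seq_len(state$n_dna_beads)[-seq_len(state$genome$n_beads)]
  )
}

make_frame <- function(cell) {
  ds <- daughter_slots(cell$state)
  structure(
    list(
      t = cell$t,
      positions = cell$dna,
      species = dna_species(cell$state),
      bead_bp = replicating_map_layout(cell$state)$bead_bp,
      ribosomes = cell$ribosomes$positions,
      smc_pairs = loop_bond_pairs(cell$ens, cell$state),
      shape = cell$shape,
      fork = list(
        left_fork_beads = cell$state$left_fork_beads,
        right_fork_beads = cell$state$right_fork_beads,
        complete = cell$state$complete,
        n_dna_beads = cell$state$n_dna_beads
      ),
      seed = cell$config$seed
    ),
    class = "trajectory_frame"
  )
}

#' @export
print.trajectory_frame <- function(x, ...) {
  cat(sprintf(
    "<trajectory_frame> t=%.2f min, %d DNA beads, %d ribosomes, %d SMC bonds\n",
    x$t, nrow(x$positions), nrow(x$ribosomes), nrow(x$smc_pairs)
  ))
  invisible(x)
}

metrics_row <- function(cell) {
  ds <- daughter_slots(cell$state)
  part <- if (length(ds$dL) > 0 && length(ds$dR) > 0) {
    partitioning(cell$dna[ds$dL, , drop = FALSE],
                 cell$dna[ds$dR, , drop = FALSE])
  } else NA_real_
  data.frame(
    t = cell$t,
    n_dna_beads = cell$state$n_dna_beads,
    replicated_fraction = replicated_fraction(cell$state),
    smc_bound = smc_count(cell$ens),
    rog = radius_of_gyration(cell$dna),
    partitioning = part,
    shape_R = cell$shape$R,
    shape_d = cell$shape$d,
    n_ribosomes = cell$ribosomes$count
  )
}

#' Run the 1-min event
#'
#' In order: long basal-diameter BD equilibration; conformation sampling
#' (frame + metrics); addition of new ribosomes at random valid positions;
#' membrane geometry update (with the division axis oriented along the
#' daughter centre-of-mass axis) and boundary-shell regeneration. Beads left
#' outside the updated membrane are projected just inside.
#'
#' @param cell A [init_cell()] state; modified in place.
#' @return The cell, invisibly.
#' @export
minute_event <- function(cell) {
  tick_guard(cell, "long equilibration", {
    sys <- build_system(cell)
    with_stream(cell$streams, "bd", {
      sys <- suppressWarnings(
        brownian_run(sys, cell$ff, cell$bd, mode = "normal",
                     n_steps = cell$config$equil$long_steps)
      )
    })
    write_back(cell, sys)
  })
  cell$frames[[length(cell$frames) + 1L]] <- make_frame(cell)
  cell$metrics[[length(cell$metrics) + 1L]] <- metrics_row(cell)
  tick_guard(cell, "ribosome addition", add_ribosomes(cell))
  tick_guard(cell, "geometry update", update_geometry(cell))
  invisible(cell)
}

add_ribosomes <- function(cell) {
  k <- cell$config$ribosomes$per_minute
  if (k == 0) {
    return(invisible(cell))
  }
  with_stream(cell$streams, "placement", {
    pos <- cell$ribosomes$positions
    for (i in seq_len(k)) {
      for (a in seq_len(5000)) {
        p <- sample_point_in_shape(cell$shape, margin = cell$ribosomes$radius)
        if (nrow(pos) == 0 ||
            min((pos[, 1] - p[1])^2 + (pos[, 2] - p[2])^2 +
                  (pos[, 3] - p[3])^2) >= 400) {
          pos <- rbind(pos, p)
          break
        }
        if (a == 5000) stop("ribosome addition failed: cell overpacked")
      }
    }
    cell$ribosomes$positions <- pos
    cell$ribosomes$count <- nrow(pos)
  })
  invisible(cell)
}

update_geometry <- function(cell) {
  ds <- daughter_slots(cell$state)
  if (length(ds$dL) > 0 && length(ds$dR) > 0) {
    cell$axis <- orient_axis(
      colMeans(cell$dna[ds$dL, , drop = FALSE]),
      colMeans(cell$dna[ds$dR, , drop = FALSE])
    )
  }
  cell$shape <- shape_at(min(cell$t, cell$schedule$t_div), cell$schedule,
                         axis = cell$axis)
  cell$boundary <- boundary_shell(cell$shape)
  cell$dna <- project_inside(cell$dna, cell$shape, cell$ff$sigma_dna / 2)
  if (cell$ribosomes$count > 0) {
    cell$ribosomes$positions <- project_inside(
      cell$ribosomes$positions, cell$shape, cell$ribosomes$radius
    )
  }
  invisible(cell)
}

#' Run a full cell cycle
#'
#' Simulates from replication initiation (`t_start`, 5 min) to division
#' (`t_div`): each minute runs `ticks_per_minute` 2-s ticks followed by the
#' minute event. A frame is sampled at the start and at every minute event,
#' giving `elapsed minutes + 1` frames.
#'
#' @param config A [sim_config()].
#' @param progress Print a line per simulated minute.
#' @return Object of class `trajectory`: `frames` (list of frames),
#'   `metrics` (per-frame data.frame) and the `config`.
#' @export
run_cell_cycle <- function(config, progress = FALSE) {
  cell <- init_cell(config)
  cell$frames[[1L]] <- make_frame(cell)
  cell$metrics[[1L]] <- metrics_row(cell)
  g <- config$growth
  for (minute in seq_len(round(g$t_div - g$t_start))) {
    t0 <- Sys.time()
    for (k in seq_len(config$ticks_per_minute)) tick_2s(cell)
    cell$t <- g$t_start + minute          # absorb 2-s rounding
    minute_event(cell)
    if (progress) {
      message(sprintf(
        "t=%5.1f min  beads=%6d  f=%.2f  SMCs=%3d  [%.1f s]",
        cell$t, cell$state$n_dna_beads, replicated_fraction(cell$state),
        smc_count(cell$ens), as.numeric(Sys.time() - t0, units = "secs")
      ))
    }
  }
  structure(
    list(
      frames = cell$frames,
      metrics = do.call(rbind, cell$metrics),
      config = config
    ),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d frames, t=%.1f..%.1f min (preset %s, seed %d)\n",
    length(x$frames), x$frames[[1]]$t, x$frames[[length(x$frames)]]$t,
    x$config$preset, x$config$seed
  ))
  invisible(x)
}

#' Stationary-phase looping simulation
#'
#' Looping only, without replication or cell growth: single chromosome,
#' fixed spherical membrane at `growth$R0`, fixed ribosome count. Runs
#' `n_replicates` independent replicates of `t_run_min` minutes and samples
#' one conformation per minute (`n_replicates * t_run_min` total).
#'
#' @param config A [sim_config()]; `smc` fields other than those set by the
#'   scenario are taken from it.
#' @param scenario `"blocking"` (tau = 2500 s, stalled SMCs unload at
#'   1/200 s), `"no_blocking"` (tau = 2500 s, SMCs pass freely) or
#'   `"short_dwell"` (tau = 4 s).
#' @param n_replicates Number of replicates (default 10).
#' @param t_run_min Minutes per replicate (default 10).
#' @param progress Print a line per replicate.
#' @return List of class `stationary_run`: `frames`, `scenario`, `config`.
#' @export
run_stationary <- function(config, scenario = c("blocking", "no_blocking",
                                                "short_dwell"),
                           n_replicates = 10, t_run_min = 10,
                           progress = FALSE) {
  scenario <- match.arg(scenario)
  iter_s <- 2 / (config$smc$v / 10)
  ov <- switch(scenario,
    blocking = list(tau = 2500, blocking_enabled = TRUE,
                    stall_death_prob = iter_s / 200),
    no_blocking = list(tau = 2500, blocking_enabled = FALSE,
                       stall_death_prob = NULL),
    short_dwell = list(tau = 4, blocking_enabled = TRUE,
                       stall_death_prob = NULL)
  )
  config$smc <- utils::modifyList(config$smc, ov,
                                  keep.null = TRUE)
  frames <- list()
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    class(cfg) <- "sim_config"
    cell <- new.env(parent = emptyenv())
    cell$config <- cfg
    cell$genome <- init_genome(cfg$length_bp, cfg$bp_per_bead)
    cell$state <- replication_state(cell$genome)
    cell$ff <- do.call(force_field, cfg$ff)
    cell$bd <- do.call(bd_params, cfg$bd)
    cell$streams <- make_rng_streams(cfg$seed)
    cell$t <- 0
    cell$axis <- c(0, 0, 1)
    cell$shape <- cell_shape(cfg$growth$R0, 0)
    cell$boundary <- boundary_shell(cell$shape)
    with_stream(cell$streams, "placement", {
      cell$ribosomes <- generate_ribosomes(cfg$ribosomes$initial, cell$shape)
      cell$dna <- generate_ring(cell$genome, cell$shape, cell$ribosomes,
                                sigma = cell$ff$sigma_dna)
    })
    params <- config_smc_params(cfg)
    with_stream(cell$streams, "smc", {
      cell$ens <- smc_ensemble(cell$genome, params)
      for (k in seq_len(params$N)) load_smc(cell$ens)
      equilibrate_1d(cell$ens, cfg$equil$smc_1d)
    })
    cell$frames <- list()
    cell$metrics <- list()
    class(cell) <- "cell_state"
    for (minute in seq_len(t_run_min)) {
      for (k in seq_len(cfg$ticks_per_minute)) {
        tick_guard(cell, "loop extrusion", smc_phase(cell))
        tick_guard(cell, "relaxation", relax_phase(cell, swell_steps(cell)))
        cell$t <- cell$t + 2 / 60
      }
      cell$t <- minute
      tick_guard(cell, "long equilibration", {
        sys <- build_system(cell)
        with_stream(cell$streams, "bd", {
          sys <- suppressWarnings(
            brownian_run(sys, cell$ff, cell$bd, mode = "normal",
                         n_steps = cfg$equil$long_steps)
          )
        })
        write_back(cell, sys)
      })
      cell$frames[[length(cell$frames) + 1L]] <- make_frame(cell)
    }
    frames <- c(frames, cell$frames)
    if (progress) {
      message(sprintf("replicate %d/%d done (%d frames)", r, n_replicates,
                      length(cell$frames)))
    }
  }
  structure(
    list(frames = frames, scenario = scenario, config = config),
    class = "stationary_run"
  )
}

#' @export
print.stationary_run <- function(x, ...) {
  cat(sprintf(
    "<stationary_run> scenario=%s, %d conformations\n",
    x$scenario, length(x$frames)
  ))
  invisible(x)
}

#' Aggregate contact map over a set of conformations
#'
#' @param frames List of trajectory frames (e.g. from [run_stationary()]).
#' @param resolution Segment size, bp. @param cutoff Contact distance, nm.
#' @return A `counts` [contact_matrix()].
#' @export
frames_contact_map <- function(frames, resolution = 1000L, cutoff = 6) {
  span <- max(vapply(frames, function(f) max(f$bead_bp) + 1, numeric(1)))
  span <- resolution * ceiling(span / resolution)
  mats <- lapply(frames, function(f) {
    detect_contacts(f$positions, f$bead_bp, span, resolution, cutoff)
  })
  aggregate_contacts(mats)
}
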