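# cheap override set for orchestration tests: dynamics are heavily trimmed
# (the physics-bearing settings are exercised in the acceptance tests)
tiny_cfg <- function(..., seed = 1) {
  sim_config("micro",
             equil = list(smc_1d = 500L, swell_base = 10L, long_steps = 50L),
             minimize = list(max_iter = 10L),
             ...,
             seed = seed)
}

test_that("configuration presets and validation", {
  cfg <- sim_config("paper")
  expect_equal(cfg$length_bp, 543379L)
  expect_equal(cfg$smc[c("N", "v", "tau")], list(N = 20, v = 500, tau = 100))
  expect_equal(cfg$growth, list(t_start = 5, t_vol_double = 65, t_div = 105,
                                R0 = 200))
  expect_equal(cfg$init_radius, 206)
  expect_equal(cfg$equil$long_steps, 500000L)
  expect_equal(cfg$ticks_per_minute, 30L)
  expect_equal(cfg$topo_after, "all")
  expect_equal(loop_coverage(cfg$smc$N, cfg$smc$v, cfg$smc$tau, cfg$length_bp),
               1.84, tolerance = 0.005)
  d <- sim_config("desk")
  expect_equal(d$length_bp, 54340L)
  expect_equal(d$growth$R0, 93)
  m <- sim_config("micro")
  expect_equal(m$length_bp, 3000L)
  # micro keeps the paper's high loop coverage at toy scale
  expect_equal(loop_coverage(m$smc$N, m$smc$v, m$smc$tau, m$length_bp), 1.8)

  # overrides merge element-wise; unknown keys are rejected loudly
  o <- sim_config("micro", smc = list(tau = 7), seed = 9)
  expect_equal(o$smc$tau, 7)
  expect_equal(o$smc$v, 500)
  expect_equal(o$seed, 9L)
  expect_error(sim_config("micro", wibble = 1), "unknown config field")
  expect_error(sim_config("micro", smc = list(speed = 1)), "unknown smc field")
  expect_error(sim_config("micro", smc = list(N = -1)))
  expect_error(sim_config("micro", growth = list(R0 = 0)))
})

test_that("init_cell builds a consistent starting state", {
  cfg <- tiny_cfg(seed = 61)
  cell <- init_cell(cfg)
  expect_s3_class(cell, "cell_state")
  expect_equal(cell$t, 5)
  expect_equal(nrow(cell$dna), 300)
  expect_true(all(inside_shape(cell$dna, cell$shape)))
  expect_equal(cell$ribosomes$count, 5L)
  expect_true(all(inside_shape(cell$ribosomes$positions, cell$shape,
                               margin = cell$ribosomes$radius)))
  expect_equal(smc_count(cell$ens), 3L)
  expect_equal(cell$shape$R, 37)
  sys <- chromocycle:::build_system(cell)
  # ring backbone + SMC loop bonds; one angle per DNA bead
  expect_equal(sum(sys$bond_kind == "backbone"), 300)
  expect_equal(sum(sys$bond_kind == "smc"), 3)
  expect_equal(nrow(sys$angles), 300)
  expect_equal(table(sys$species)[["boundary"]], nrow(cell$boundary))
})

test_that("2-s ticks advance replication and keep bookkeeping consistent", {
  cfg <- tiny_cfg(seed = 62)
  cell <- init_cell(cfg)
  for (k in 1:10) {
    n0 <- cell$state$n_dna_beads
    tick_2s(cell)
    grown <- cell$state$n_dna_beads - n0
    expect_true(grown >= 0 && grown <= 2 * cfg$fork_beads_per_tick)
    expect_equal(nrow(cell$dna), cell$state$n_dna_beads)
    target <- target_bound_count(cfg$smc$N, replicated_fraction(cell$state))
    expect_lte(smc_count(cell$ens), target)
  }
  expect_equal(cell$t, 5 + 20 / 60, tolerance = 1e-9)
  expect_equal(replicated_fraction(cell$state), 10 / 150)
  # the SMC occupancy invariant holds mid-replication
  expect_identical(smc_rebuild_occupancy(cell$ens), cell$ens$occ)
  # after completion the fork phase is a no-op
  while (!cell$state$complete) {
    cell$state <- advance_forks(cell$state, 1L)
    cell$dna <- spawn_daughter_coordinates(cell$dna, cell$state)
    handle_fork_advance(cell$ens, attr(cell$state, "new_beads"))
  }
  n_final <- cell$state$n_dna_beads
  expect_equal(n_final, 600L)
  tick_2s(cell)
  expect_equal(cell$state$n_dna_beads, n_final)
})

test_that("minute event samples, adds ribosomes and updates geometry", {
  cfg <- tiny_cfg(seed = 63)
  cell <- init_cell(cfg)
  for (k in 1:3) tick_2s(cell)
  cell$t <- 6
  n_frames0 <- length(cell$frames)
  n_ribo0 <- cell$ribosomes$count
  minute_event(cell)
  expect_equal(length(cell$frames), n_frames0 + 1)
  expect_equal(length(cell$metrics), n_frames0 + 1)
  fr <- cell$frames[[length(cell$frames)]]
  expect_equal(fr$t, 6)
  expect_equal(nrow(fr$positions), cell$state$n_dna_beads)
  expect_equal(cell$ribosomes$count, n_ribo0 + cfg$ribosomes$per_minute)
  # geometry advanced to t = 6 and everything is back inside
  expect_equal(cell$shape$R, shape_at(6, cell$schedule)$R)
  expect_true(all(inside_shape(cell$dna, cell$shape)))
  expect_true(all(inside_shape(cell$ribosomes$positions, cell$shape,
                               margin = cell$ribosomes$radius - 1e-9)))
})

test_that("a short cell cycle is deterministic under a fixed seed", {
  cfg <- tiny_cfg(growth = list(t_vol_double = 6, t_div = 7), seed = 64)
  t1 <- run_cell_cycle(cfg)
  t2 <- run_cell_cycle(cfg)
  expect_equal(length(t1$frames), 3)           # t = 5, 6, 7
  expect_identical(t1$metrics, t2$metrics)
  expect_identical(t1$frames[[3]]$positions, t2$frames[[3]]$positions)
  expect_identical(t1$frames[[3]]$smc_pairs, t2$frames[[3]]$smc_pairs)
  # different seed, different trajectory
  t3 <- run_cell_cycle(tiny_cfg(growth = list(t_vol_double = 6, t_div = 7),
                                seed = 65))
  expect_false(identical(t1$frames[[3]]$positions, t3$frames[[3]]$positions))
  # metrics carry the expected schema
  expect_equal(names(t1$metrics),
               c("t", "n_dna_beads", "replicated_fraction", "smc_bound",
                 "rog", "partitioning", "shape_R", "shape_d", "n_ribosomes"))
  expect_true(all(diff(t1$metrics$n_dna_beads) >= 0))
})

test_that("stationary runs loop without replication or growth", {
  cfg <- tiny_cfg(seed = 66)
  run <- run_stationary(cfg, "short_dwell", n_replicates = 2, t_run_min = 2)
  expect_s3_class(run, "stationary_run")
  expect_length(run$frames, 4)
  for (f in run$frames) {
    expect_equal(nrow(f$positions), 300)       # never replicates
    expect_false(f$fork$complete)
    expect_equal(f$shape$R, 36)                # fixed membrane at R0
    expect_equal(f$shape$d, 0)
    expect_equal(nrow(f$smc_pairs), 3)
  }
  # scenario parameter overrides
  expect_equal(run$config$smc$tau, 4)
  cfg_b <- tiny_cfg(seed = 66)
  run_b <- run_stationary(cfg_b, "blocking", n_replicates = 1, t_run_min = 1)
  expect_equal(run_b$config$smc$tau, 2500)
  expect_equal(run_b$config$smc$stall_death_prob, (2 / 50) / 200)
  run_n <- run_stationary(cfg_b, "no_blocking", n_replicates = 1, t_run_min = 1)
  expect_false(run_n$config$smc$blocking_enabled)

  # aggregate contact map over the sampled conformations
  cm <- frames_contact_map(run$frames)
  expect_s3_class(cm, "contact_matrix")
  expect_equal(cm$n_segments, 3)               # 3 kb genome at 1 kb
  expect_true(all(diag(cm$values) == length(run$frames)))
  expect_true(isSymmetric(cm$values))
  pc <- contact_probability_curve(cm)
  expect_equal(pc$s, c(0, 1000))
  expect_equal(pc$p[1], length(run$frames))
})
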