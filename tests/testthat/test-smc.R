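fresh_ens <- function(n_sites = 1000, ..., seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- smc_params(...)
  smc_ensemble(init_genome(n_sites * 10L, 10L), p)
}

test_that("parameter derivations", {
  p <- smc_params(N = 50, v = 500, tau = 100)
  expect_equal(p$iters_per_tick, 50L)           # v/10 iterations per 2 s
  expect_equal(p$iter_seconds, 0.04)
  expect_equal(p$basal_death_prob, 20 / (500 * 100))
  expect_equal(p$bypass_prob, 0.002)            # 40 ms / 20 s
  p2 <- smc_params(v = 500, tau = 2500)
  expect_equal(p2$basal_death_prob, 1.6e-5)
  p3 <- smc_params(v = 500, tau = 4)
  expect_equal(p3$basal_death_prob, 0.01)
  expect_error(smc_params(v = 505), "multiple of 10")
})

test_that("loading places heads three sites apart on free sites, uniformly", {
  ens <- fresh_ens(500, N = 1, seed = 1)
  load_smc(ens)
  expect_true(attr(ens, "loaded"))
  id <- which(ens$active)
  expect_length(id, 1)
  gap <- (ens$right[id] - ens$left[id]) %% ens$n
  expect_equal(gap, 3L)
  # occupancy is exactly the two 3-site footprints
  expect_equal(sum(ens$occ$mother == id), 6L)
  expect_identical(smc_rebuild_occupancy(ens), ens$occ)
  # daughter copies do not exist before replication
  expect_true(all(ens$occ$dL == -1L))

  # uniformity of the load position over the lattice (chi-square)
  set.seed(42)
  heads <- replicate(3000, {
    e <- fresh_ens(500, N = 1)
    load_smc(e)
    e$left[1]
  })
  obs <- tabulate(ceiling(heads / 50), nbins = 10)
  pval <- stats::chisq.test(obs)$p.value
  expect_gt(pval, 1e-3)
})

test_that("free SMC extrudes one site per head per iteration", {
  ens <- fresh_ens(1000, N = 1, basal_death_prob = 0, seed = 2)
  load_smc(ens)
  l0 <- ens$left[1]
  r0 <- ens$right[1]
  for (k in 1:10) step_iteration(ens)
  expect_equal((l0 - ens$left[1]) %% ens$n, 10L)
  expect_equal((ens$right[1] - r0) %% ens$n, 10L)
  expect_identical(smc_rebuild_occupancy(ens), ens$occ)
})

test_that("converging SMCs block each other and record blockers", {
  ens <- fresh_ens(1000, N = 2, basal_death_prob = 0, bypass_time = 1e12,
                   seed = 3)
  # hand-place two SMCs with facing heads separated by one free site
  place <- function(ens, id, left) {
    ens$copy <- c(ens$copy, 1L)
    ens$left <- c(ens$left, as.integer(left))
    ens$right <- c(ens$right, as.integer(left + 3L))
    ens$stall_l <- c(ens$stall_l, FALSE)
    ens$stall_r <- c(ens$stall_r, FALSE)
    ens$block_l <- c(ens$block_l, 0L)
    ens$block_r <- c(ens$block_r, 0L)
    ens$active <- c(ens$active, TRUE)
    ens$occ$mother[chromocycle:::smc_sites(ens, id)] <- id
    ens
  }
  place(ens, 1L, 100)    # right head at 103, footprint to 104
  place(ens, 2L, 109)    # left head at 109, footprint from 108
  for (k in 1:5) step_iteration(ens)
  # SMC 1 right head wants site 105/106 region occupied by SMC 2
  expect_true(ens$stall_r[1])
  expect_equal(ens$block_r[1], 2L)
  expect_true(ens$stall_l[2])
  expect_equal(ens$block_l[2], 1L)
  # outer heads kept extruding
  expect_lt(ens$left[1], 100)
  expect_gt(ens$right[2], 112)
  expect_identical(smc_rebuild_occupancy(ens), ens$occ)

  # certain bypass relocates the head past the obstruction
  ens$params$bypass_prob <- 1
  attempt_bypass(ens, 1L)
  expect_false(ens$stall_r[1])
  # new footprint clear of SMC 2 and beyond its old blocking point
  expect_identical(smc_rebuild_occupancy(ens), ens$occ)
  expect_gt(ens$counts[["bypasses"]], 0)
})

test_that("without blocking SMCs pass through each other", {
  ens <- fresh_ens(1000, N = 2, basal_death_prob = 0, blocking_enabled = FALSE,
                   seed = 4)
  # hand-place two SMCs with identical footprints: occupancy counts overlap
  for (id in 1:2) {
    ens$copy <- c(ens$copy, 1L)
    ens$left <- c(ens$left, 100L)
    ens$right <- c(ens$right, 103L)
    ens$stall_l <- c(ens$stall_l, FALSE)
    ens$stall_r <- c(ens$stall_r, FALSE)
    ens$block_l <- c(ens$block_l, 0L)
    ens$block_r <- c(ens$block_r, 0L)
    ens$active <- c(ens$active, TRUE)
    sites <- chromocycle:::smc_sites(ens, id)
    ens$occ$mother[sites] <- ens$occ$mother[sites] + 1L
  }
  expect_true(any(ens$occ$mother > 1L))  # coverage counts, not ids
  for (k in 1:50) step_iteration(ens)
  # extrusion proceeded right through the other complex: no stalls, no
  # SMC-SMC blockers, and the rebuilt coverage matches
  expect_true(all(!ens$stall_l & !ens$stall_r))
  expect_true(all(ens$block_l <= 0) && all(ens$block_r <= 0))
  expect_equal((ens$right[1] - 103L) %% ens$n, 50)
  expect_equal((ens$right[2] - 103L) %% ens$n, 50)
  expect_identical(smc_rebuild_occupancy(ens), ens$occ)
})

test_that("unbinding conserves the bound count and reloads elsewhere", {
  ens <- fresh_ens(2000, N = 10, basal_death_prob = 0.5, seed = 5)
  for (k in 1:10) load_smc(ens)
  for (k in 1:50) step_iteration(ens)
  expect_equal(smc_count(ens), 10L)
  expect_gt(ens$counts[["deaths"]], 50)           # churn happened
  expect_identical(smc_rebuild_occupancy(ens), ens$occ)
})

test_that("fork advance evicts mother-side SMCs and opens daughter sites", {
  g <- init_genome(10000, 10)
  st <- replication_state(g)
  ens <- smc_ensemble(g, smc_params(N = 5, basal_death_prob = 0), state = st)
  set.seed(6)
  for (k in 1:5) load_smc(ens)
  st <- advance_forks(st, 50L)
  handle_fork_advance(ens, attr(st, "new_beads"))
  expect_equal(smc_count(ens), 5L)                # evicted SMCs reloaded
  rep_sites <- which(st$replicated)
  expect_true(all(ens$occ$mother[rep_sites] == -1L))
  expect_true(all(ens$occ$dL[rep_sites] >= 0L))
  expect_true(all(ens$occ$dR[rep_sites] >= 0L))
  # no active SMC holds a vanished mother site
  for (id in which(ens$active)) {
    sites <- chromocycle:::smc_sites(ens, id)
    cp <- ens$copy[id]
    expect_true(all(ens$occ[[cp]][sites] == id))
  }
  expect_identical(smc_rebuild_occupancy(ens), ens$occ)

  # loop bonds map daughter heads onto the right bead slots
  pairs <- loop_bond_pairs(ens, st)
  expect_true(all(pairs >= 1 & pairs <= st$n_dna_beads))
  for (id in which(ens$active & ens$copy == 3L)) {
    expect_equal(pairs[match(id, which(ens$active)), 1],
                 st$dr_slot[ens$left[id]])
  }
})

test_that("SMCs stall at forks and trail them", {
  g <- init_genome(5000, 10)     # 500 sites, ori site 251 (bead 250)
  st <- replication_state(g)
  st <- advance_forks(st, 30L)   # daughters exist on beads 220..279
  p <- smc_params(N = 1, basal_death_prob = 0)
  ens <- smc_ensemble(g, p, state = st)
  # place an SMC on the left daughter next to the left fork (bead 279 is the
  # last replicated, so dL sites 221..280 exist)
  ens$copy <- 2L
  ens$left <- 270L
  ens$right <- 273L
  ens$stall_l <- FALSE; ens$stall_r <- FALSE
  ens$block_l <- 0L; ens$block_r <- 0L
  ens$active <- TRUE
  ens$occ$dL[chromocycle:::smc_sites(ens, 1L)] <- 1L
  set.seed(7)
  for (k in 1:20) step_iteration(ens)
  expect_true(ens$stall_r[1])
  expect_equal(ens$block_r[1], -1L)        # fork blocker, never bypassed
  expect_equal(ens$right[1], 279L)         # trailing right behind the fork
  # fork moves on; the stall is released and the SMC follows
  st <- advance_forks(st, 10L)
  handle_fork_advance(ens, attr(st, "new_beads"))
  for (k in 1:5) step_iteration(ens)
  expect_gt(ens$right[1], 279L)
})

test_that("fork unloading policies", {
  make_stalled <- function(policy) {
    g <- init_genome(5000, 10)
    st <- replication_state(g)
    st <- advance_forks(st, 30L)
    p <- smc_params(N = 1, basal_death_prob = 0, fork_policy = policy)
    ens <- smc_ensemble(g, p, state = st)
    ens$copy <- 2L; ens$left <- 275L; ens$right <- 278L
    ens$stall_l <- FALSE; ens$stall_r <- TRUE
    ens$block_l <- 0L; ens$block_r <- -1L
    ens$active <- TRUE
    ens$occ$dL[chromocycle:::smc_sites(ens, 1L)] <- 1L
    ens
  }
  set.seed(8)
  ens <- make_stalled("unload_immediate")
  apply_unbinding(ens)
  expect_equal(ens$counts[["deaths"]], 1L)   # certain unload...
  expect_equal(smc_count(ens), 1L)           # ...with immediate reload
  ens2 <- make_stalled("unload_enhanced")
  expect_equal(ens2$params$fork_unload_prob, 20 / (500 * 25))
  ens3 <- make_stalled("stall_and_trail")
  apply_unbinding(ens3)
  expect_equal(ens3$counts[["deaths"]], 0L)  # basal prob is 0 here
})

test_that("bound-count target ramps with replication", {
  expect_equal(target_bound_count(50, 0), 50L)
  expect_equal(target_bound_count(50, 0.5), 75L)
  expect_equal(target_bound_count(50, 1), 100L)
  expect_equal(target_bound_count(3, 1 / 3), 4L)
  expect_error(target_bound_count(50, 1.2))
})

test_that("loading defers when no valid position exists", {
  ens <- fresh_ens(10, N = 1, seed = 9)      # 10 sites: one SMC leaves only 4
  load_smc(ens)
  load_smc(ens, max_draws = 50)
  expect_false(attr(ens, "loaded"))
  expect_equal(smc_count(ens), 1L)
  expect_gt(ens$counts[["deferred"]], 0)
})
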