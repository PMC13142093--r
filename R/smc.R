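# Stochastic 1D SMC loop-extrusion engine on the replicating lattice.
#
# Lattice sites are the 10-bp chromosome beads. Each SMC has two motor heads
# loaded three sites apart; every algorithm iteration each head attempts to
# move one site outward (20 bp of loop growth per iteration for a free SMC).
# A head whose target is covered by another SMC footprint stalls and may
# bypass the obstruction; a head at a replication fork stalls and trails the
# fork. SMCs dissociate stochastically and are immediately reloaded at a new
# uniformly drawn valid position, so the bound count is conserved.
#
# Three chromosome copies share the genomic site indexing: copy 1 is the
# unreplicated mother arc, copies 2/3 are the left/right daughter arcs
# (sites exist where the mother has been replicated). Sites are stored in
# per-copy integer arrays: -1 nonexistent, 0 free, id > 0 an SMC footprint
# (with blocking disabled the arrays hold coverage counts instead of ids,
# since footprints may then overlap).
#
# The ensemble is a mutable environment: update operations modify it in
# place and return it, keeping the hot loop free of vector copies.

SMC_COPIES <- c("mother", "dL", "dR")

#' SMC loop-extrusion parameters
#'
#' The translocation speed is realised by running `v/10` algorithm
#' iterations per 2-s communication tick, each moving every free head one
#' 10-bp site; one iteration then spans `20/v` seconds of biological time
#' (40 ms at v = 500 bp/s). The basal unbinding probability per iteration is
#' `20 / (v tau)`, which gives a mean dwell time of `tau` seconds and a mean
#' extruded length of `v tau` bp. The bypass probability is scaled by the
#' iteration duration so the mean blocked-to-bypass waiting time is
#' `bypass_time` seconds regardless of `v`.
#'
#' @param N Number of bound SMC complexes per chromosome (20-50 in scans).
#' @param v Effective two-sided translocation speed, bp/s (multiple of 10).
#' @param tau Mean dwell time, s.
#' @param w Footprint half-width in sites (footprint `1 + 2w` sites).
#' @param step_prob Per-iteration head move probability.
#' @param bypass_time Mean waiting time for a blocked head to bypass, s
#'   (default 20 s, i.e. probability 0.002 per 40-ms iteration).
#' @param bypass_search_sites Forward search range for a vacant site beyond
#'   an obstruction (default 15 sites).
#' @param blocking_enabled If `FALSE`, converging SMCs pass through each
#'   other freely (only forks block).
#' @param basal_death_prob Per-iteration unbinding probability; defaults to
#'   `20 / (v tau)`.
#' @param stall_death_prob Optional per-iteration unbinding probability for
#'   stalled SMCs (used in the stationary-phase blocking scenario).
#' @param fork_policy What happens to a daughter-side SMC that reaches a
#'   fork: `"stall_and_trail"` (default), `"unload_immediate"` or
#'   `"unload_enhanced"` (unbinds at `20 / (v * fork_unload_tau)`).
#' @param fork_unload_tau Mean unloading time at the fork for the enhanced
#'   policy, s (default 25).
#' @return Object of class `smc_params`.
#' @export
smc_params <- function(N = 50, v = 500, tau = 100, w = 1, step_prob = 1.0,
                       bypass_time = 20, bypass_search_sites = 15,
                       blocking_enabled = TRUE, basal_death_prob = NULL,
                       stall_death_prob = NULL,
                       fork_policy = c("stall_and_trail", "unload_immediate",
                                       "unload_enhanced"),
                       fork_unload_tau = 25) {
  fork_policy <- match.arg(fork_policy)
  if (v <= 0 || v %% 10 != 0) stop("v must be a positive multiple of 10 bp/s")
  stopifnot(N >= 0, tau > 0, w >= 0, step_prob >= 0, step_prob <= 1)
  iters_per_tick <- as.integer(v / 10)
  iter_seconds <- 2 / iters_per_tick
  p <- list(
    N = as.integer(N), v = v, tau = tau, w = as.integer(w),
    step_prob = step_prob,
    bypass_time = bypass_time,
    bypass_prob = iter_seconds / bypass_time,
    bypass_search_sites = as.integer(bypass_search_sites),
    blocking_enabled = isTRUE(blocking_enabled),
    basal_death_prob = basal_death_prob %||% (20 / (v * tau)),
    stall_death_prob = stall_death_prob,
    fork_policy = fork_policy,
    fork_unload_prob = 20 / (v * fork_unload_tau),
    iters_per_tick = iters_per_tick,
    iter_seconds = iter_seconds
  )
  class(p) <- "smc_params"
  p
}

#' @export
print.smc_params <- function(x, ...) {
  cat(sprintf(
    "<smc_params> N=%d v=%g bp/s tau=%g s (coverage needs L); %d iters/tick, basal death %.3g/iter, bypass %.3g/iter%s\n",
    x$N, x$v, x$tau, x$iters_per_tick, x$basal_death_prob, x$bypass_prob,
    if (x$blocking_enabled) ", blocking on" else ", blocking off"
  ))
  invisible(x)
}

msite <- function(s, n) ((s - 1L) %% n) + 1L

#' Create an (empty) SMC ensemble on a chromosome lattice
#'
#' @param genome A [init_genome()].
#' @param params An [smc_params()].
#' @param state Optional [replication_state()] used to initialise site
#'   existence (default: fresh unreplicated chromosome).
#' @return Environment of class `smc_ensemble`.
#' @export
smc_ensemble <- function(genome, params, state = NULL) {
  n <- genome$n_beads
  ens <- new.env(parent = emptyenv())
  ens$genome <- genome
  ens$params <- params
  ens$n <- n
  ens$occ <- list(
    mother = integer(n),
    dL = rep(-1L, n),
    dR = rep(-1L, n)
  )
  if (!is.null(state)) {
    idx <- which(state$replicated)
    ens$occ$mother[idx] <- -1L
    ens$occ$dL[idx] <- 0L
    ens$occ$dR[idx] <- 0L
  }
  ens$copy <- integer(0)
  ens$left <- integer(0)
  ens$right <- integer(0)
  ens$stall_l <- logical(0)
  ens$stall_r <- logical(0)
  ens$block_l <- integer(0)   # 0 none, -1 fork, >0 blocking SMC id
  ens$block_r <- integer(0)
  ens$active <- logical(0)
  ens$counts <- c(loads = 0L, deaths = 0L, bypasses = 0L, deferred = 0L)
  class(ens) <- "smc_ensemble"
  ens
}

#' @export
print.smc_ensemble <- function(x, ...) {
  cat(sprintf(
    "<smc_ensemble> %d bound SMCs on %d-site lattice (loads %d, deaths %d, bypasses %d)\n",
    sum(x$active), x$n, x$counts["loads"], x$counts["deaths"],
    x$counts["bypasses"]
  ))
  invisible(x)
}

#' Number of bound SMCs
#' @param ens An [smc_ensemble()].
#' @export
smc_count <- function(ens) sum(ens$active)

# all sites covered by an SMC: both head footprints
smc_sites <- function(ens, id) {
  w <- ens$params$w
  c(
    msite((ens$left[id] - w):(ens$left[id] + w), ens$n),
    msite((ens$right[id] - w):(ens$right[id] + w), ens$n)
  )
}

occ_clear <- function(ens, id) {
  cp <- ens$copy[id]
  sites <- smc_sites(ens, id)
  if (ens$params$blocking_enabled) {
    ens$occ[[cp]][sites] <- 0L
  } else {
    ens$occ[[cp]][sites] <- ens$occ[[cp]][sites] - 1L
  }
}

occ_set <- function(ens, id) {
  cp <- ens$copy[id]
  sites <- smc_sites(ens, id)
  if (ens$params$blocking_enabled) {
    ens$occ[[cp]][sites] <- id
  } else {
    ens$occ[[cp]][sites] <- ens$occ[[cp]][sites] + 1L
  }
}

#' Load one SMC at a uniformly drawn valid position
#'
#' The head pair is placed three sites apart at a position drawn uniformly
#' over all existing lattice sites (any chromosome copy); a draw is valid if
#' the neighbourhoods of both heads (six consecutive sites) exist, are
#' unoccupied, and do not overlap a replication fork. After `max_draws`
#' failed draws the load is deferred to the next tick.
#'
#' @param ens An [smc_ensemble()]; modified in place.
#' @param id Optional SMC id to (re)use; default allocates a new one.
#' @param max_draws Bounded number of placement draws (default 200).
#' @return The ensemble, invisibly; attribute `"loaded"` is `TRUE`/`FALSE`.
#' @export
load_smc <- function(ens, id = NULL, max_draws = 200) {
  w <- ens$params$w
  span <- 2L * (2L * w + 1L)              # six sites for w = 1
  exist <- lapply(ens$occ, function(v) which(v >= 0L))
  n_exist <- vapply(exist, length, 1L)
  loaded <- FALSE
  if (sum(n_exist) > 0) {
    for (k in seq_len(max_draws)) {
      cp <- sample.int(3L, 1L, prob = n_exist)
      s <- exist[[cp]][sample.int(n_exist[cp], 1L)]
      sites <- msite((s - w):(s + span - w - 1L), ens$n)
      if (length(unique(sites)) < span) next    # lattice too small to wrap
      if (all(ens$occ[[cp]][sites] == 0L)) {
        if (is.null(id)) {
          id <- length(ens$active) + 1L
          ens$copy <- c(ens$copy, 0L)
          ens$left <- c(ens$left, 0L)
          ens$right <- c(ens$right, 0L)
          ens$stall_l <- c(ens$stall_l, FALSE)
          ens$stall_r <- c(ens$stall_r, FALSE)
          ens$block_l <- c(ens$block_l, 0L)
          ens$block_r <- c(ens$block_r, 0L)
          ens$active <- c(ens$active, FALSE)
        }
        ens$copy[id] <- cp
        ens$left[id] <- s
        ens$right[id] <- msite(s + 2L * w + 1L, ens$n)
        ens$stall_l[id] <- FALSE
        ens$stall_r[id] <- FALSE
        ens$block_l[id] <- 0L
        ens$block_r[id] <- 0L
        ens$active[id] <- TRUE
        occ_set(ens, id)
        ens$counts["loads"] <- ens$counts["loads"] + 1L
        loaded <- TRUE
        break
      }
    }
  }
  if (!loaded) ens$counts["deferred"] <- ens$counts["deferred"] + 1L
  attr(ens, "loaded") <- loaded
  invisible(ens)
}

# Attempt to relocate one blocked head past its obstruction to the nearest
# vacant valid footprint within the search range. Returns TRUE on success.
bypass_search <- function(ens, id, side) {
  w <- ens$params$w
  n <- ens$n
  cp <- ens$copy[id]
  occ <- ens$occ[[cp]]
  search <- ens$params$bypass_search_sites
  s <- if (side == "l") ens$left[id] else ens$right[id]
  dir <- if (side == "l") -1L else 1L
  for (k in (2L + w - 1L):(search + w)) {
    p <- msite(s + dir * k, n)
    fp <- msite((p - w):(p + w), n)
    if (all(occ[fp] == 0L)) {
      old <- msite((s - w):(s + w), n)
      ens$occ[[cp]][old] <- 0L
      ens$occ[[cp]][fp] <- id
      if (side == "l") {
        ens$left[id] <- p
        ens$stall_l[id] <- FALSE
        ens$block_l[id] <- 0L
      } else {
        ens$right[id] <- p
        ens$stall_r[id] <- FALSE
        ens$block_r[id] <- 0L
      }
      ens$counts["bypasses"] <- ens$counts["bypasses"] + 1L
      return(TRUE)
    }
  }
  FALSE
}

#' Attempt to bypass an SMC obstruction
#'
#' For each head of `id` stalled behind another SMC, with probability
#' `bypass_prob` the head jumps to the nearest vacant valid site within the
#' forward search range beyond the obstruction. Fork blockers are never
#' bypassed.
#'
#' @param ens An [smc_ensemble()]; modified in place.
#' @param id SMC id.
#' @return The ensemble, invisibly.
#' @export
attempt_bypass <- function(ens, id) {
  if (!ens$params$blocking_enabled) {
    return(invisible(ens))
  }
  if (ens$stall_l[id] && ens$block_l[id] > 0L &&
      stats::runif(1) < ens$params$bypass_prob) {
    bypass_search(ens, id, "l")
  }
  if (ens$stall_r[id] && ens$block_r[id] > 0L &&
      stats::runif(1) < ens$params$bypass_prob) {
    bypass_search(ens, id, "r")
  }
  invisible(ens)
}

# advance one head one site outward if the newly covered site is free
move_head <- function(ens, id, side) {
  w <- ens$params$w
  n <- ens$n
  cp <- ens$copy[id]
  dir <- if (side == "l") -1L else 1L
  s <- if (side == "l") ens$left[id] else ens$right[id]
  newcov <- msite(s + dir * (w + 1L), n)
  val <- ens$occ[[cp]][newcov]
  blocking <- ens$params$blocking_enabled
  free <- if (blocking) val == 0L else val >= 0L
  if (free) {
    if (blocking) {
      ens$occ[[cp]][msite(s - dir * w, n)] <- 0L
      ens$occ[[cp]][newcov] <- id
    } else {
      ens$occ[[cp]][msite(s - dir * w, n)] <- ens$occ[[cp]][msite(s - dir * w, n)] - 1L
      ens$occ[[cp]][newcov] <- val + 1L
    }
    if (side == "l") {
      ens$left[id] <- msite(s + dir, n)
      ens$stall_l[id] <- FALSE
      ens$block_l[id] <- 0L
    } else {
      ens$right[id] <- msite(s + dir, n)
      ens$stall_r[id] <- FALSE
      ens$block_r[id] <- 0L
    }
  } else {
    blk <- if (val == -1L) -1L else val
    if (side == "l") {
      ens$stall_l[id] <- TRUE
      ens$block_l[id] <- blk
    } else {
      ens$stall_r[id] <- TRUE
      ens$block_r[id] <- blk
    }
  }
  invisible(NULL)
}

#' One iteration of the loop-extrusion algorithm
#'
#' SMCs are visited in a fresh random permutation. Each head independently
#' attempts to move one site outward (with probability `step_prob`); blocked
#' heads record their blocker. Bypass attempts follow for SMC-blocked heads,
#' then unbinding/reloading draws.
#'
#' @param ens An [smc_ensemble()]; modified in place.
#' @return The ensemble, invisibly.
#' @export
step_iteration <- function(ens) {
  ids <- which(ens$active)
  if (length(ids) == 0) {
    return(invisible(ens))
  }
  ids <- if (length(ids) > 1) sample(ids) else ids
  sp <- ens$params$step_prob
  for (id in ids) {
    if (sp >= 1 || stats::runif(1) < sp) move_head(ens, id, "l")
    if (sp >= 1 || stats::runif(1) < sp) move_head(ens, id, "r")
  }
  if (ens$params$blocking_enabled &&
      any((ens$stall_l & ens$block_l > 0L) | (ens$stall_r & ens$block_r > 0L))) {
    for (id in ids) attempt_bypass(ens, id)
  }
  apply_unbinding(ens)
  invisible(ens)
}

#' Stochastic unbinding with immediate reloading
#'
#' Each bound SMC unbinds with its applicable per-iteration probability
#' (basal; `stall_death_prob` when stalled, if configured; the enhanced or
#' immediate fork rate when trailing a fork under those policies) and is
#' immediately reloaded at a new valid position, conserving the bound count.
#'
#' @param ens An [smc_ensemble()]; modified in place.
#' @return The ensemble, invisibly.
#' @export
apply_unbinding <- function(ens) {
  ids <- which(ens$active)
  if (length(ids) == 0) {
    return(invisible(ens))
  }
  p <- ens$params
  prob <- rep(p$basal_death_prob, length(ids))
  stalled <- ens$stall_l[ids] | ens$stall_r[ids]
  if (!is.null(p$stall_death_prob)) {
    prob[stalled] <- p$stall_death_prob
  }
  fork_stalled <- (ens$stall_l[ids] & ens$block_l[ids] == -1L) |
    (ens$stall_r[ids] & ens$block_r[ids] == -1L)
  if (p$fork_policy == "unload_immediate") {
    prob[fork_stalled] <- 1
  } else if (p$fork_policy == "unload_enhanced") {
    prob[fork_stalled] <- p$fork_unload_prob
  }
  dead <- ids[stats::runif(length(ids)) < prob]
  for (id in dead) {
    occ_clear(ens, id)
    ens$active[id] <- FALSE
    ens$counts["deaths"] <- ens$counts["deaths"] + 1L
    load_smc(ens, id = id)
  }
  invisible(ens)
}

#' Equilibrate SMC positions in 1D
#'
#' Runs `n_iterations` loop-extrusion iterations on the (unreplicated)
#' chromosome before the recorded simulation starts.
#'
#' @param ens An [smc_ensemble()]; modified in place.
#' @param n_iterations Number of iterations (default 360000).
#' @return The ensemble, invisibly.
#' @export
equilibrate_1d <- function(ens, n_iterations = 360000L) {
  for (k in seq_len(n_iterations)) step_iteration(ens)
  invisible(ens)
}

#' Synchronise the ensemble with advanced replication forks
#'
#' Mother-side SMCs overtaken by a fork are actively unloaded and reloaded
#' elsewhere (count conserved); the overtaken mother sites vanish and the
#' corresponding daughter sites appear; daughter-side SMCs stalled at a fork
#' have their stall re-evaluated so they can trail the moved fork.
#'
#' @param ens An [smc_ensemble()]; modified in place.
#' @param new_beads The `"new_beads"` attribute from [advance_forks()].
#' @return The ensemble, invisibly.
#' @export
handle_fork_advance <- function(ens, new_beads) {
  if (is.null(new_beads) || nrow(new_beads) == 0) {
    return(invisible(ens))
  }
  pos <- unique(new_beads$g) + 1L            # 1-based lattice sites
  hit <- logical(ens$n)
  hit[pos] <- TRUE
  # unload mother-side SMCs overtaken by the forks
  for (id in which(ens$active & ens$copy == 1L)) {
    if (any(hit[smc_sites(ens, id)])) {
      occ_clear(ens, id)
      ens$active[id] <- FALSE
      ens$counts["deaths"] <- ens$counts["deaths"] + 1L
    }
  }
  reload <- which(!ens$active & ens$copy > 0L)
  ens$occ$mother[pos] <- -1L
  ens$occ$dL[pos] <- 0L
  ens$occ$dR[pos] <- 0L
  for (id in reload) load_smc(ens, id = id)
  # daughter-side fork stalls are re-evaluated against the moved fork
  daughters <- ens$active & ens$copy > 1L
  relax_l <- daughters & ens$stall_l & ens$block_l == -1L
  relax_r <- daughters & ens$stall_r & ens$block_r == -1L
  ens$stall_l[relax_l] <- FALSE
  ens$block_l[relax_l] <- 0L
  ens$stall_r[relax_r] <- FALSE
  ens$block_r[relax_r] <- 0L
  invisible(ens)
}

#' Target number of bound SMCs during replication
#'
#' The bound pool ramps linearly with the replicated fraction from `N` to
#' `2N` (constant `2N` after completion).
#'
#' @param N Baseline SMC count per chromosome.
#' @param replicated_fraction Fraction of the genome replicated, `[0, 1]`.
#' @return Integer target count.
#' @export
target_bound_count <- function(N, replicated_fraction) {
  stopifnot(replicated_fraction >= 0, replicated_fraction <= 1)
  as.integer(round(N * (1 + replicated_fraction)))
}

#' SMC loop bonds as 3D bead slot pairs
#'
#' Maps each bound SMC's lattice heads to bead slots on the correct
#' chromosome copy (mother and left daughter share the original slots; right
#' daughter slots come from the replication state's slot map).
#'
#' @param ens An [smc_ensemble()].
#' @param state A [replication_state()] (needed once replication started).
#' @return Integer matrix (k x 2) of 1-based bead slots.
#' @export
loop_bond_pairs <- function(ens, state = NULL) {
  ids <- which(ens$active)
  out <- matrix(integer(0), 0, 2)
  if (length(ids) == 0) {
    return(out)
  }
  slot_of <- function(cp, site) {
    if (cp <= 2L) {
      return(site)
    }
    if (is.null(state)) stop("right-daughter SMC requires a replication state")
    s <- state$dr_slot[site]
    if (is.na(s)) stop("SMC head on a nonexistent right-daughter bead (replication sync bug)")
    s
  }
  out <- cbind(
    mapply(slot_of, ens$copy[ids], ens$left[ids]),
    mapply(slot_of, ens$copy[ids], ens$right[ids])
  )
  matrix(as.integer(out), ncol = 2)
}

#' Recompute occupancy arrays from SMC footprints
#'
#' Reference reconstruction used by the invariant checks: the stored
#' incremental occupancy must equal the union of all SMC footprints over the
#' existing sites.
#'
#' @param ens An [smc_ensemble()].
#' @return List of three integer vectors in the stored format.
#' @export
smc_rebuild_occupancy <- function(ens) {
  out <- lapply(ens$occ, function(v) {
    w <- v
    w[w > 0L] <- 0L
    w
  })
  for (id in which(ens$active)) {
    cp <- ens$copy[id]
    sites <- smc_sites(ens, id)
    if (ens$params$blocking_enabled) {
      out[[cp]][sites] <- id
    } else {
      out[[cp]][sites] <- out[[cp]][sites] + 1L
    }
  }
  out
}
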