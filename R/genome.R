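# Circular genome discretisation and train-track replication state.
#
# The chromosome is a circle of `length_bp` base pairs discretised at
# `bp_per_bead` (10 bp per bead by default, the elastic worm-like-chain
# resolution used throughout). The origin of replication sits at L/2 and the
# terminus at 0; two replication forks start at the origin and independently
# traverse the two arms toward the terminus. When a mother bead is replicated
# it is replaced by two daughter beads: the left daughter inherits the
# mother's bead slot (and genomic index), while right-daughter beads are
# appended past the mother indexing, so the total DNA bead count grows by one
# per replicated mother bead (54,338 -> 108,676 at completion for defaults).

#' Create a circular genome discretisation
#'
#' @param length_bp Genome length in base pairs (default 543379, the
#'   JCVI-Syn3A chromosome).
#' @param bp_per_bead Base pairs per polymer bead (default 10).
#' @return An object of class `circular_genome` with fields `length_bp`,
#'   `bp_per_bead`, `n_beads`, `ori_bp`, `ter_bp`, `ori_bead`.
#' @examples
#' g <- init_genome()
#' g$n_beads  # 54338
#' @export
init_genome <- function(length_bp = 543379L, bp_per_bead = 10L) {
  if (length_bp <= 0 || bp_per_bead <= 0) {
    stop("length_bp and bp_per_bead must be positive")
  }
  length_bp <- as.integer(length_bp)
  bp_per_bead <- as.integer(bp_per_bead)
  g <- list(
    length_bp = length_bp,
    bp_per_bead = bp_per_bead,
    n_beads = as.integer(ceiling(length_bp / bp_per_bead)),
    ori_bp = as.integer(length_bp %/% 2L),
    ter_bp = 0L
  )
  g$ori_bead <- as.integer(g$ori_bp %/% bp_per_bead)
  class(g) <- "circular_genome"
  g
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf(
    "<circular_genome> %d bp, %d bp/bead, %d beads; ori at %d bp, ter at %d bp\n",
    x$length_bp, x$bp_per_bead, x$n_beads, x$ori_bp, x$ter_bp
  ))
  invisible(x)
}

#' Circular genomic distance
#'
#' Shortest distance along the circle between two genomic coordinates,
#' `min(|i - j|, L - |i - j|)`. Maximum value is `floor(L / 2)`.
#'
#' @param i,j Genomic coordinates in bp, `0 <= i, j < L`. Vectorised.
#' @param genome A [init_genome()] object.
#' @return Distance(s) in bp.
#' @export
genomic_distance <- function(i, j, genome) {
  if (any(i < 0 | i >= genome$length_bp | j < 0 | j >= genome$length_bp)) {
    stop("genomic coordinates must lie in [0, L)")
  }
  d <- abs(i - j)
  pmin(d, genome$length_bp - d)
}

# Arm capacities (beads) for the two forks. The left fork replicates beads
# ori_bead, ori_bead+1, ..., n-1 (through the high-index arm to the terminus
# side); the right fork replicates ori_bead-1, ..., 1, 0 (terminus assigned
# to the right fork so the two arms tile the circle exactly).
arm_capacities <- function(genome) {
  c(left = genome$n_beads - genome$ori_bead, right = genome$ori_bead)
}

#' Initialise a train-track replication state
#'
#' @param genome A [init_genome()] object.
#' @return An object of class `replication_state`: fork progress per arm
#'   (`left_fork_beads`, `right_fork_beads`), a logical vector `replicated`
#'   over mother bead indices, the right-daughter slot map `dr_slot`
#'   (1-based slot in the DNA bead array, `NA` while unreplicated),
#'   `n_dna_beads` (current total DNA bead count) and `complete`.
#' @export
replication_state <- function(genome) {
  st <- list(
    genome = genome,
    left_fork_beads = 0L,
    right_fork_beads = 0L,
    replicated = rep(FALSE, genome$n_beads),
    dr_slot = rep(NA_integer_, genome$n_beads),
    n_dna_beads = genome$n_beads,
    complete = FALSE
  )
  class(st) <- "replication_state"
  st
}

#' @export
print.replication_state <- function(x, ...) {
  cat(sprintf(
    "<replication_state> forks L=%d R=%d of %s beads (f=%.3f)%s\n",
    x$left_fork_beads, x$right_fork_beads, x$genome$n_beads,
    replicated_fraction(x), if (x$complete) " [complete]" else ""
  ))
  invisible(x)
}

#' Fraction of the mother chromosome replicated
#' @param state A [replication_state()].
#' @export
replicated_fraction <- function(state) {
  (state$left_fork_beads + state$right_fork_beads) / state$genome$n_beads
}

#' Advance both replication forks
#'
#' Each incomplete fork advances by up to `beads_per_fork` beads along its
#' arm (20 beads per 2-s tick at the 100 bp/s replication rate). Newly
#' replicated mother beads are recorded: the left daughter reuses the mother
#' bead slot, the right daughter bead is appended after the current last DNA
#' bead. The ids of all daughter beads created this call (two per replicated
#' mother bead) are attached as attribute `"new_beads"`, a data.frame with
#' columns `g` (0-based genomic bead index), `daughter` (`"L"`/`"R"`) and
#' `slot` (1-based index in the DNA bead array).
#'
#' @param state A [replication_state()].
#' @param beads_per_fork Integer beads to advance per fork.
#' @return The updated state (warns and returns unchanged if complete).
#' @export
advance_forks <- function(state, beads_per_fork = 20L) {
  if (state$complete) {
    warning("replication already complete; advance_forks is a no-op")
    attr(state, "new_beads") <- empty_new_beads()
    return(state)
  }
  caps <- arm_capacities(state$genome)
  o <- state$genome$ori_bead
  n <- state$genome$n_beads
  adv_l <- min(beads_per_fork, caps["left"] - state$left_fork_beads)
  adv_r <- min(beads_per_fork, caps["right"] - state$right_fork_beads)
  new_l <- if (adv_l > 0) o + state$left_fork_beads + seq_len(adv_l) - 1L else integer(0)
  new_r <- if (adv_r > 0) o - state$right_fork_beads - seq_len(adv_r) else integer(0)
  new_g <- c(new_l, new_r)  # 0-based mother bead indices, no wrap by construction
  stopifnot(all(new_g >= 0 & new_g < n), !any(state$replicated[new_g + 1L]))

  state$left_fork_beads <- state$left_fork_beads + as.integer(adv_l)
  state$right_fork_beads <- state$right_fork_beads + as.integer(adv_r)
  state$replicated[new_g + 1L] <- TRUE
  slots_r <- state$n_dna_beads + seq_along(new_g)
  state$dr_slot[new_g + 1L] <- as.integer(slots_r)
  state$n_dna_beads <- state$n_dna_beads + length(new_g)
  state$complete <- state$left_fork_beads == caps["left"] &&
    state$right_fork_beads == caps["right"]

  attr(state, "new_beads") <- data.frame(
    g = rep(new_g, 2L),
    daughter = rep(c("L", "R"), each = length(new_g)),
    slot = c(new_g + 1L, slots_r)
  )
  state
}

empty_new_beads <- function() {
  data.frame(g = integer(0), daughter = character(0), slot = integer(0))
}

#' Place daughter beads created by the latest fork advance
#'
#' Each pair of daughter beads appears centred about the mother bead's
#' position: the left daughter is displaced by `+delta`, the right daughter
#' by `-delta`, where `delta` is a random unit vector (one per fork per
#' call) scaled to `offset` nm. The returned matrix has rows appended for
#' the new right-daughter slots.
#'
#' @param positions DNA bead position matrix (rows = slots present before the
#'   fork advance).
#' @param state The replication state returned by [advance_forks()].
#' @param new_beads The `"new_beads"` attribute from [advance_forks()]
#'   (defaults to reading it off `state`).
#' @param offset Displacement magnitude in nm (default 0.85, half a bead
#'   radius).
#' @return Position matrix with `state$n_dna_beads` rows.
#' @export
spawn_daughter_coordinates <- function(positions, state,
                                       new_beads = attr(state, "new_beads"),
                                       offset = 0.85) {
  if (is.null(new_beads) || nrow(new_beads) == 0) {
    return(positions)
  }
  n_new_r <- sum(new_beads$daughter == "R")
  out <- rbind(positions, matrix(0, nrow = n_new_r, ncol = 3))
  o <- state$genome$ori_bead
  # one random offset direction per fork (left arm: g >= ori_bead)
  for (arm in c("left", "right")) {
    sel <- if (arm == "left") new_beads$g >= o else new_beads$g < o
    nb <- new_beads[sel, , drop = FALSE]
    if (nrow(nb) == 0) next
    delta <- random_unit_vector() * offset
    mothers <- positions[nb$g[nb$daughter == "L"] + 1L, , drop = FALSE]
    gl <- nb[nb$daughter == "L", , drop = FALSE]
    gr <- nb[nb$daughter == "R", , drop = FALSE]
    out[gl$slot, ] <- sweep(mothers, 2, delta, `+`)
    out[gr$slot, ] <- sweep(mothers, 2, delta, `-`)
  }
  out
}

#' Population-average origin-to-terminus marker ratio
#'
#' For an unsynchronised population uniformly distributed in cell age, a
#' marker present in one copy before its replication time and two copies
#' after has mean copy number `(2 C - t_rep) / C` over a cycle of length
#' `C`. The ori:ter ratio follows from the initiation and termination times.
#'
#' @param t_init Replication initiation time, min (default 5).
#' @param t_term Replication termination time, min (default 50).
#' @param t_cycle Cell-cycle length, min (default 105).
#' @return The ori:ter copy-number ratio (1.28 for the defaults).
#' @export
ori_ter_ratio <- function(t_init = 5, t_term = 50, t_cycle = 105) {
  stopifnot(t_init >= 0, t_term >= t_init, t_cycle >= t_term)
  (2 * t_cycle - t_init) / (2 * t_cycle - t_term)
}
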