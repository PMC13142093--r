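# Bond/angle topology of the (partially) replicated chromosome.
#
# Bead slot layout: slots 1..n hold the original circle. A replicated mother
# bead's slot is inherited by the left daughter; right-daughter beads occupy
# slots n+1.. in creation order (state$dr_slot maps genomic index -> slot).
# The original ring bonds therefore always describe the mother arc, the left
# daughter arc and their fork junctions; the right daughter contributes its
# own internal bonds plus one junction bond per fork into the unreplicated
# mother. Bending triplets follow each continuous strand through the forks.

#' Chromosome bonds and bending triplets for a replication state
#'
#' @param state A [replication_state()] (or a [init_genome()] for the
#'   unreplicated circle).
#' @param smc_pairs Optional integer matrix (k x 2) of SMC loop-bond bead
#'   slots, appended with kind `"smc"`.
#' @return List with `bonds` (m x 2, 1-based slots), `bond_kind`, `angles`
#'   (a x 3, centre second).
#' @export
chromosome_topology <- function(state, smc_pairs = NULL) {
  if (inherits(state, "circular_genome")) {
    state <- replication_state(state)
  }
  n <- state$genome$n_beads
  slotR <- state$dr_slot                        # by genomic index (1-based pos)
  rep_mask <- state$replicated

  ring <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  gv <- seq_len(n)                              # genomic position i (bead i-1)
  nv <- c(seq_len(n)[-1], 1L)                   # successor position
  r1 <- rep_mask[gv]
  r2 <- rep_mask[nv]
  b_rr <- cbind(slotR[gv[r1 & r2]], slotR[nv[r1 & r2]])
  b_rm <- cbind(slotR[gv[r1 & !r2]], nv[r1 & !r2])
  b_mr <- cbind(gv[!r1 & r2], slotR[nv[!r1 & r2]])
  bonds <- rbind(ring, b_rr, b_rm, b_mr)
  bond_kind <- rep("backbone", nrow(bonds))

  angles <- matrix(integer(0), 0, 3)
  if (n >= 3) {
    pv <- c(n, seq_len(n - 1L))                 # predecessor position
    # mother / left-daughter strand: the original ring adjacency
    angles <- cbind(pv, gv, nv)
    # right-daughter strand: slots switch to dr_slot where replicated
    rp <- rep_mask[pv]
    rn <- rep_mask[nv]
    keep <- r1 | rp | rn
    if (any(keep)) {
      nbR <- function(pos, repl) ifelse(repl, slotR[pos], pos)
      angles <- rbind(angles, cbind(
        nbR(pv[keep], rp[keep]),
        nbR(gv[keep], r1[keep]),
        nbR(nv[keep], rn[keep])
      ))
    }
  }

  if (!is.null(smc_pairs) && nrow(smc_pairs) > 0) {
    bonds <- rbind(bonds, smc_pairs)
    bond_kind <- c(bond_kind, rep("smc", nrow(smc_pairs)))
  }
  list(
    bonds = matrix(as.integer(bonds), ncol = 2),
    bond_kind = bond_kind,
    angles = matrix(as.integer(angles), ncol = 3)
  )
}

#' DNA species labels implied by a replication state
#'
#' Slots of replicated mother beads are relabelled `dna_dL`; appended slots
#' are `dna_dR`; the rest remain `dna_mother`.
#'
#' @param state A [replication_state()].
#' @return Character vector of length `state$n_dna_beads`.
#' @export
dna_species <- function(state) {
  n <- state$genome$n_beads
  sp <- rep("dna_mother", state$n_dna_beads)
  sp[which(state$replicated)] <- "dna_dL"
  if (state$n_dna_beads > n) sp[(n + 1L):state$n_dna_beads] <- "dna_dR"
  sp
}
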