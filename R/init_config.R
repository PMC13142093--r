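# Initial configuration generators: uniform ribosome field, self-avoiding
# circular chromosome threaded through it, and deterministic test fixtures.
#
# The chromosome generator replaces the externally cited fractal-globule
# recipe with a hierarchical midpoint refinement of a coarse random closed
# loop: each round inserts perturbed edge midpoints (halving edge lengths by
# ~1/sqrt(2) per round) until the bead count is reached, then a minimization
# plus geometric fix-up passes enforce the containment, bond-length and
# clearance contracts exactly.

#' Generate a uniform non-overlapping ribosome field
#'
#' Ribosomes are 10-nm-radius spheres placed uniformly inside the membrane
#' by rejection sampling, with pairwise centre distances of at least one
#' diameter (20 nm) and full containment.
#'
#' @param n Number of ribosomes.
#' @param shape A [cell_shape()].
#' @param min_separation Minimum centre-centre distance, nm (default 20).
#' @param max_attempts Bounded placement attempts per ribosome.
#' @return Object of class `ribosome_field` (`positions`, `radius`, `count`).
#' @export
generate_ribosomes <- function(n, shape, min_separation = 20,
                               max_attempts = 5000) {
  radius <- 10
  pos <- matrix(numeric(0), 0, 3)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      p <- sample_point_in_shape(shape, margin = radius)
      if (nrow(pos) > 0) {
        d2 <- (pos[, 1] - p[1])^2 + (pos[, 2] - p[2])^2 + (pos[, 3] - p[3])^2
        if (min(d2) < min_separation^2) next
      }
      pos <- rbind(pos, p)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(sprintf(
        "ribosome packing failed at %d of %d (volume %.3g nm^3, packing fraction %.2f)",
        k, n, union_volume(shape$R, shape$d),
        n * (4 / 3) * pi * radius^3 / union_volume(shape$R, shape$d)
      ))
    }
  }
  structure(
    list(positions = pos, radius = radius, count = n),
    class = "ribosome_field"
  )
}

#' @export
print.ribosome_field <- function(x, ...) {
  cat(sprintf("<ribosome_field> %d ribosomes, radius %g nm\n", x$count, x$radius))
  invisible(x)
}

# uniform point inside the union of spheres (rejection over sphere picks,
# corrected for the overlap lens)
sample_point_in_shape <- function(shape, margin = 0) {
  ctr <- shape_centers(shape)
  repeat {
    k <- if (nrow(ctr) == 1) 1L else sample.int(2L, 1L)
    u <- stats::runif(1)^(1 / 3) * (shape$R - margin)
    p <- ctr[k, ] + random_unit_vector() * u
    n_in <- sum(inside_shape(matrix(p, 1, 3), shape, margin))
    # count membership in each sphere for uniformity over the union
    m <- sum(sqrt(rowSums((ctr - matrix(p, nrow(ctr), 3, byrow = TRUE))^2)) <=
               shape$R - margin)
    if (stats::runif(1) < 1 / m) {
      return(p)
    }
  }
}

#' Generate a self-avoiding circular chromosome conformation
#'
#' Builds a closed ring of `genome$n_beads` beads inside `shape`, threaded
#' around the ribosome field, by hierarchical midpoint refinement followed
#' by energy minimization and geometric fix-up. The result satisfies:
#' consecutive bead distance within `[0.5, 1.5] sigma`, all beads inside the
#' membrane, no DNA-DNA pair below `0.8 sigma`, and no bead within
#' `ribo_clearance` of a ribosome centre.
#'
#' @param genome A [init_genome()].
#' @param shape A [cell_shape()].
#' @param ribosomes Optional [generate_ribosomes()] field.
#' @param sigma DNA bead diameter, nm (default 3.4).
#' @param ribo_clearance Minimum DNA-ribosome centre distance, nm (11.7).
#' @param max_fix_passes Fix-up iterations before failing (default 400).
#' @return n x 3 matrix of bead positions (nm).
#' @export
generate_ring <- function(genome, shape, ribosomes = NULL, sigma = 3.4,
                          ribo_clearance = 11.7, max_fix_passes = 400) {
  n <- genome$n_beads
  rpos <- if (is.null(ribosomes)) matrix(numeric(0), 0, 3) else ribosomes$positions
  margin <- sigma / 2

  # coarse loop sized so ~sqrt(2) edge contraction per round lands at sigma
  m0 <- max(4L, ceiling(n / 2^floor(log2(n / 4))))
  pos <- t(vapply(seq_len(m0), function(i) sample_point_in_shape(shape, margin),
                  numeric(3)))
  while (2L * nrow(pos) <= n) pos <- refine_loop(pos, shape, rpos, ribo_clearance, margin)
  if (nrow(pos) < n) pos <- split_longest_edges(pos, n - nrow(pos), shape, margin)
  stopifnot(nrow(pos) == n)

  # relax with the full force field (ribosomes and boundary as fixed obstacles)
  bdry <- boundary_shell(shape)
  species <- c(rep("dna_mother", n), rep("ribosome", nrow(rpos)),
               rep("boundary", nrow(bdry)))
  topo <- chromosome_topology(init_genome(n * genome$bp_per_bead, genome$bp_per_bead))
  sys <- bead_system(rbind(pos, rpos, bdry), species, topo$bonds,
                     topo$bond_kind, topo$angles)
  ff <- force_field(sigma_dna = sigma)
  sys <- minimize(sys, ff, mode = "normal", tol = 0.5,
                  max_iter = max(2000L, 40L * ceiling(sqrt(n))))
  pos <- sys$positions[seq_len(n), , drop = FALSE]

  for (pass in seq_len(max_fix_passes)) {
    pos <- project_inside(pos, shape, margin)
    moved <- FALSE
    if (nrow(rpos) > 0) {
      clear <- cpp_unmixed_flags(pos, rpos, ribo_clearance)
      for (i in which(!clear)) {
        d <- sqrt(rowSums(sweep(rpos, 2, pos[i, ])^2))
        k <- which.min(d)
        dir <- pos[i, ] - rpos[k, ]
        nd <- sqrt(sum(dir^2))
        if (nd < 1e-9) dir <- random_unit_vector() else dir <- dir / nd
        pos[i, ] <- rpos[k, ] + dir * (ribo_clearance * 1.02)
        moved <- TRUE
      }
    }
    pairs <- cpp_pairs_within(pos, 0.8 * sigma)
    pairs <- pairs[abs(pairs[, 1] - pairs[, 2]) > 1 &
                     abs(pairs[, 1] - pairs[, 2]) < n - 1, , drop = FALSE]
    if (nrow(pairs) > 0) {
      moved <- TRUE
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        dir <- pos[i, ] - pos[j, ]
        nd <- sqrt(sum(dir^2))
        if (nd < 1e-9) dir <- random_unit_vector() else dir <- dir / nd
        push <- (0.85 * sigma - nd) / 2
        pos[i, ] <- pos[i, ] + dir * push
        pos[j, ] <- pos[j, ] - dir * push
      }
    }
    # bond-length projection toward sigma for out-of-range edges
    nxt <- c(seq_len(n)[-1], 1L)
    dvec <- pos[nxt, ] - pos
    dl <- sqrt(rowSums(dvec^2))
    bad <- dl < 0.6 * sigma | dl > 1.4 * sigma
    if (any(bad)) {
      moved <- TRUE
      for (i in which(bad)) {
        j <- nxt[i]
        mid <- (pos[i, ] + pos[j, ]) / 2
        dir <- pos[j, ] - pos[i, ]
        nd <- sqrt(sum(dir^2))
        if (nd < 1e-9) dir <- random_unit_vector() else dir <- dir / nd
        pos[i, ] <- mid - dir * sigma / 2
        pos[j, ] <- mid + dir * sigma / 2
      }
    }
    if (!moved && ring_contract_ok(pos, shape, rpos, sigma, ribo_clearance)) {
      return(pos)
    }
  }
  stop(sprintf(
    paste0("ring packing failed after %d passes: %d beads, R=%.0f nm, ",
           "DNA volume fraction %.3f, %d ribosomes"),
    max_fix_passes, n, shape$R,
    n * (4 / 3) * pi * (sigma / 2)^3 / union_volume(shape$R, shape$d), nrow(rpos)
  ))
}

refine_loop <- function(pos, shape, rpos, ribo_clearance, margin) {
  m <- nrow(pos)
  nxt <- c(seq_len(m)[-1], 1L)
  out <- matrix(0, 2L * m, 3L)
  out[seq(1L, 2L * m, by = 2L), ] <- pos
  for (i in seq_len(m)) {
    out[2L * i, ] <- insert_midpoint(pos[i, ], pos[nxt[i], ], shape, rpos,
                                     ribo_clearance, margin)
  }
  out
}

insert_midpoint <- function(a, b, shape, rpos, ribo_clearance, margin,
                            tries = 12L) {
  e <- sqrt(sum((b - a)^2))
  mid <- (a + b) / 2
  best <- mid
  for (k in seq_len(tries)) {
    cand <- mid + random_unit_vector() * (e / 2) * stats::runif(1, 0.6, 1)
    if (!inside_shape(matrix(cand, 1, 3), shape, margin)) next
    if (nrow(rpos) > 0) {
      d2 <- (rpos[, 1] - cand[1])^2 + (rpos[, 2] - cand[2])^2 +
        (rpos[, 3] - cand[3])^2
      if (min(d2) < ribo_clearance^2) next
    }
    return(cand)
  }
  project_inside(matrix(best, 1, 3), shape, margin)[1, ]
}

split_longest_edges <- function(pos, k, shape, margin) {
  m <- nrow(pos)
  nxt <- c(seq_len(m)[-1], 1L)
  dl <- sqrt(rowSums((pos[nxt, ] - pos)^2))
  idx <- sort(order(dl, decreasing = TRUE)[seq_len(k)])
  out <- vector("list", m)
  for (i in seq_len(m)) {
    p <- pos[i, , drop = FALSE]
    if (i %in% idx) {
      mid <- (pos[i, ] + pos[nxt[i], ]) / 2
      mid <- project_inside(matrix(mid, 1, 3), shape, margin)
      p <- rbind(p, mid)
    }
    out[[i]] <- p
  }
  do.call(rbind, out)
}

ring_contract_ok <- function(pos, shape, rpos, sigma, ribo_clearance) {
  n <- nrow(pos)
  nxt <- c(seq_len(n)[-1], 1L)
  dl <- sqrt(rowSums((pos[nxt, ] - pos)^2))
  if (any(dl < 0.5 * sigma | dl > 1.5 * sigma)) {
    return(FALSE)
  }
  if (!all(inside_shape(pos, shape))) {
    return(FALSE)
  }
  if (nrow(rpos) > 0 && !all(cpp_unmixed_flags(pos, rpos, ribo_clearance))) {
    return(FALSE)
  }
  pairs <- cpp_pairs_within(pos, 0.8 * sigma)
  pairs <- pairs[abs(pairs[, 1] - pairs[, 2]) > 1 &
                   abs(pairs[, 1] - pairs[, 2]) < n - 1, , drop = FALSE]
  nrow(pairs) == 0
}

#' Deterministic small-system fixtures
#'
#' @param kind One of `"two_blobs"`, `"straight_chain"`, `"ideal_ring"`,
#'   `"crafted_contacts"`.
#' @param params Named list of fixture parameters: `n` (beads per blob or
#'   chain), `sep` (blob centre separation, nm), `sd` (blob spread, nm),
#'   `spacing` (chain spacing, nm), `radius` (ring radius, nm).
#' @return A [bead_system()] (no angles; chain/ring bonds where sensible).
#' @export
fixture <- function(kind = c("two_blobs", "straight_chain", "ideal_ring",
                             "crafted_contacts"),
                    params = list()) {
  kind <- match.arg(kind)
  p <- utils::modifyList(
    list(n = 100L, sep = 100, sd = 5, spacing = 3.4, radius = 50),
    params
  )
  no_bonds <- matrix(integer(0), 0, 2)
  no_ang <- matrix(integer(0), 0, 3)
  if (kind == "two_blobs") {
    a <- matrix(stats::rnorm(3 * p$n, sd = p$sd), ncol = 3)
    b <- matrix(stats::rnorm(3 * p$n, sd = p$sd), ncol = 3)
    b[, 1] <- b[, 1] + p$sep
    pos <- rbind(a, b)
    species <- rep(c("dna_dL", "dna_dR"), each = p$n)
    return(bead_system(pos, species, no_bonds, character(0), no_ang))
  }
  if (kind == "straight_chain") {
    pos <- cbind((seq_len(p$n) - 1) * p$spacing, 0, 0)
    bonds <- cbind(seq_len(p$n - 1L), 2:p$n)
    return(bead_system(pos, rep("dna_mother", p$n), bonds,
                       rep("backbone", nrow(bonds)), no_ang))
  }
  if (kind == "ideal_ring") {
    th <- 2 * pi * (seq_len(p$n) - 1) / p$n
    pos <- cbind(p$radius * cos(th), p$radius * sin(th), 0)
    bonds <- cbind(seq_len(p$n), c(2:p$n, 1L))
    return(bead_system(pos, rep("dna_mother", p$n), bonds,
                       rep("backbone", nrow(bonds)), no_ang))
  }
  # crafted_contacts: 10-bp beads in 1-kb segments with hand-placed pairs:
  # segment 1 bead near a segment 2 bead at 5 nm (contact) and a segment 3
  # bead at 7 nm from both (no contact), plus isolated far beads.
  pos <- rbind(
    c(0, 0, 0),        # bead 0   -> segment 1
    c(5, 0, 0),        # bead 100 -> segment 2 (5 nm: contact with seg 1)
    c(0, 0, 500),      # bead 200 -> segment 3, far from everything
    c(7, 0, 500)       # bead 300 -> segment 4 (7 nm from seg 3: no contact)
  )
  sys <- bead_system(pos, rep("dna_mother", 4), no_bonds, character(0), no_ang)
  attr(sys, "genomic_bead") <- c(0L, 100L, 200L, 300L)
  sys
}
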