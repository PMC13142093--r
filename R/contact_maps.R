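# In-silico 3C contact maps: 1-kb segmentation, 6-nm voxelized contact
# detection, per-conformation binary matrices, aggregation over replicates,
# Knight-Ruiz balancing and contact-probability-vs-distance curves.

#' Contact matrix container
#'
#' @param values Square numeric matrix.
#' @param resolution Segment size, bp (default 1000).
#' @param kind `"binary"`, `"counts"` or `"balanced"`.
#' @param circular Whether the underlying genome is circular.
#' @return Object of class `contact_matrix`.
#' @export
contact_matrix <- function(values, resolution = 1000L, kind = "counts",
                           circular = TRUE) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values), all(values >= 0))
  structure(
    list(
      values = values, n_segments = nrow(values),
      resolution = as.integer(resolution), kind = kind, circular = circular
    ),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "<contact_matrix> %d x %d segments @ %d bp (%s)\n",
    x$n_segments, x$n_segments, x$resolution, x$kind
  ))
  invisible(x)
}

#' Genomic coordinate layout for (partially) replicated conformations
#'
#' Maps each DNA bead slot to a genomic coordinate for contact-map rows: the
#' left daughter keeps the mother's coordinates and right-daughter beads are
#' appended past the genome length (`bp >= L`), so a fully replicated cell
#' spans `2 L`.
#'
#' @param state A [replication_state()] (or [init_genome()]).
#' @return List with `bead_bp` (per bead slot) and `coord_span` (bp extent
#'   of the matrix).
#' @export
replicating_map_layout <- function(state) {
  if (inherits(state, "circular_genome")) state <- replication_state(state)
  g <- state$genome
  bead_bp <- (seq_len(g$n_beads) - 1L) * g$bp_per_bead
  if (state$n_dna_beads > g$n_beads) {
    rep_idx <- which(state$replicated)
    dr_bp <- integer(state$n_dna_beads - g$n_beads)
    dr_bp[state$dr_slot[rep_idx] - g$n_beads] <-
      g$length_bp + (rep_idx - 1L) * g$bp_per_bead
    bead_bp <- c(bead_bp, dr_bp)
  }
  span <- if (state$n_dna_beads > g$n_beads) 2L * g$length_bp else g$length_bp
  list(bead_bp = bead_bp, coord_span = span)
}

#' Detect contacts in one conformation
#'
#' A contact between 1-kb segments is registered when any bead of one lies
#' within the hard cutoff of any bead of the other; multiple bead pairs
#' count once and the diagonal is always 1. Detection is voxelized (grid
#' edge = cutoff, 27-cell neighbourhood) and exact.
#'
#' @param positions DNA bead positions, n x 3 (nm).
#' @param bead_bp Genomic coordinate (bp) of each bead, e.g. from
#'   [replicating_map_layout()].
#' @param coord_span Total coordinate extent in bp (sets the matrix size).
#' @param resolution Segment size, bp (default 1000).
#' @param cutoff Contact distance, nm (default 6).
#' @return Binary [contact_matrix()].
#' @export
detect_contacts <- function(positions, bead_bp,
                            coord_span = max(bead_bp) + 1, resolution = 1000L,
                            cutoff = 6) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == length(bead_bp), all(bead_bp >= 0),
            all(bead_bp < coord_span))
  nseg <- as.integer(ceiling(coord_span / resolution))
  seg0 <- as.integer(bead_bp %/% resolution)           # 0-based segments
  pairs <- cpp_contact_pairs(positions, seg0, cutoff)
  M <- matrix(0L, nseg, nseg)
  if (nrow(pairs) > 0) {
    M[pairs] <- 1L
    M[pairs[, c(2, 1), drop = FALSE]] <- 1L
  }
  diag(M) <- 1L
  contact_matrix(M, resolution, kind = "binary")
}

#' Sum contact matrices over conformations
#'
#' @param matrices List of [contact_matrix()] objects of identical shape.
#' @return A `counts` [contact_matrix()] with the elementwise sum.
#' @export
aggregate_contacts <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  n <- matrices[[1]]$n_segments
  res <- matrices[[1]]$resolution
  out <- matrix(0, n, n)
  for (m in matrices) {
    if (!inherits(m, "contact_matrix") || m$n_segments != n ||
        m$resolution != res) {
      stop("contact matrices have mismatched shapes or resolutions")
    }
    out <- out + m$values
  }
  contact_matrix(out, res, kind = "counts")
}

#' Knight-Ruiz matrix balancing
#'
#' Scales a symmetric nonnegative matrix to doubly stochastic form
#' `D M D` via the Knight-Ruiz inner-outer Newton iteration (conjugate
#' gradient inner solves). All-zero rows/columns are removed first and
#' reinserted as zeros.
#'
#' @param m A [contact_matrix()] or square symmetric matrix.
#' @param tol Row/column-sum tolerance (default 1e-6).
#' @param max_iter Outer iteration cap.
#' @return A `balanced` [contact_matrix()]; attribute `"scaling"` holds the
#'   diagonal of `D` (NA for removed rows).
#' @export
kr_balance <- function(m, tol = 1e-6, max_iter = 1000) {
  values <- if (inherits(m, "contact_matrix")) m$values else as.matrix(m)
  res <- if (inherits(m, "contact_matrix")) m$resolution else 1000L
  if (!isSymmetric(unname(values), tol = 1e-10)) {
    stop("kr_balance requires a symmetric matrix")
  }
  n <- nrow(values)
  keep <- rowSums(values) > 0
  A <- values[keep, keep, drop = FALSE]
  x <- kr_vector(A, tol = tol, max_iter = max_iter)
  scaling <- rep(NA_real_, n)
  scaling[keep] <- x
  out <- matrix(0, n, n)
  out[keep, keep] <- A * tcrossprod(x)
  resid <- max(abs(rowSums(out[keep, , drop = FALSE]) - 1))
  if (resid > tol) {
    stop(sprintf(
      "KR balancing did not converge in %d iterations (residual %.3g)",
      max_iter, resid
    ))
  }
  cm <- contact_matrix(out, res, kind = "balanced")
  attr(cm, "scaling") <- scaling
  cm
}

# Knight-Ruiz scaling vector for a fully supported symmetric matrix
# (inner-outer Newton with CG, bounded line steps).
kr_vector <- function(A, tol = 1e-6, max_iter = 1000, delta = 0.1, Delta = 3) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9
  etamax <- 0.1
  eta <- etamax
  stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1
  rold <- rout
  iter <- 0
  while (rout > rt) {
    iter <- iter + 1
    if (iter > max_iter) break
    k <- 0
    y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k > 200) break
    }
    x <- x * y
    v <- x * as.vector(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    rat <- rout / rold
    rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / res_norm)
  }
  x
}

#' Contact probability versus genomic distance
#'
#' Mean matrix value over all segment pairs at each circular genomic
#' distance `s` (segment units times resolution), for `s` up to half the
#' ring.
#'
#' @param m A [contact_matrix()] over an unreplicated circular genome.
#' @return `data.frame(s, p)` with `s` in bp.
#' @export
contact_probability_curve <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  V <- m$values
  n <- nrow(V)
  smax <- n %/% 2L
  i <- seq_len(n)
  p <- vapply(0:smax, function(k) {
    j <- ((i - 1L + k) %% n) + 1L
    mean(V[cbind(i, j)])
  }, numeric(1))
  data.frame(s = (0:smax) * m$resolution, p = p)
}

#' Reference all-pairs contact detection (O(n^2) oracle)
#'
#' Brute-force equivalent of [detect_contacts()], used to verify the
#' voxelized path.
#'
#' @inheritParams detect_contacts
#' @return Binary [contact_matrix()].
#' @export
detect_contacts_bruteforce <- function(positions, bead_bp,
                                       coord_span = max(bead_bp) + 1,
                                       resolution = 1000L, cutoff = 6) {
  positions <- as.matrix(positions)
  nseg <- as.integer(ceiling(coord_span / resolution))
  seg <- as.integer(bead_bp %/% resolution) + 1L
  M <- matrix(0L, nseg, nseg)
  d <- as.matrix(stats::dist(positions))
  hit <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  if (nrow(hit) > 0) {
    si <- seg[hit[, 1]]
    sj <- seg[hit[, 2]]
    M[cbind(si, sj)] <- 1L
    M[cbind(sj, si)] <- 1L
  }
  diag(M) <- 1L
  contact_matrix(M, resolution, kind = "binary")
}
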