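# Analysis metrics: daughter partitioning, loop coverage, radius of
# gyration, radial distributions, SMC clustering.

#' Daughter-chromosome partitioning
#'
#' A daughter bead is partitioned when no bead of the opposite daughter lies
#' within `radius`. The headline statistic pools both daughters: the
#' fraction of all daughter beads that are partitioned (1 = fully
#' segregated, 0 = fully mixed).
#'
#' @param coords_dL,coords_dR Daughter bead positions (n x 3, nm).
#' @param radius Mixing radius, nm (default 30).
#' @param per_daughter If `TRUE`, return the two per-daughter fractions
#'   instead of the pooled one.
#' @return Pooled fraction in `[0, 1]`, or named vector `c(dL=, dR=)`.
#' @export
partitioning <- function(coords_dL, coords_dR, radius = 30,
                         per_daughter = FALSE) {
  coords_dL <- matrix(coords_dL, ncol = 3)
  coords_dR <- matrix(coords_dR, ncol = 3)
  if (nrow(coords_dL) == 0 || nrow(coords_dR) == 0) {
    stop("both daughters must be non-empty")
  }
  stopifnot(radius > 0)
  fL <- cpp_unmixed_flags(coords_dL, coords_dR, radius)
  fR <- cpp_unmixed_flags(coords_dR, coords_dL, radius)
  if (per_daughter) {
    return(c(dL = mean(fL), dR = mean(fR)))
  }
  (sum(fL) + sum(fR)) / (length(fL) + length(fR))
}

# brute-force O(n^2) reference for the partitioning oracle tests
partitioning_bruteforce <- function(coords_dL, coords_dR, radius = 30) {
  coords_dL <- matrix(coords_dL, ncol = 3)
  coords_dR <- matrix(coords_dR, ncol = 3)
  mind <- function(a, b) {
    apply(a, 1, function(p) min(sqrt(colSums((t(b) - p)^2))))
  }
  part <- c(mind(coords_dL, coords_dR) >= radius,
            mind(coords_dR, coords_dL) >= radius)
  mean(part)
}

#' Loop coverage
#'
#' `N v tau / L`: the expected fraction of the genome held in SMC loops
#' (number of SMCs times processivity over genome length). The key scan
#' parameter for segregation.
#'
#' @param N Number of SMCs. @param v Extrusion speed, bp/s.
#' @param tau Dwell time, s. @param L Genome length, bp.
#' @return Dimensionless coverage.
#' @export
loop_coverage <- function(N, v, tau, L) {
  stopifnot(N >= 0, v >= 0, tau >= 0, L > 0)
  N * v * tau / L
}

#' Radius of gyration
#'
#' `sqrt(mean |r - COM|^2)`.
#'
#' @param coords n x 3 matrix (nm).
#' @return RoG in nm.
#' @export
radius_of_gyration <- function(coords) {
  coords <- matrix(coords, ncol = 3)
  stopifnot(nrow(coords) >= 1)
  com <- colMeans(coords)
  sqrt(mean((coords[, 1] - com[1])^2 + (coords[, 2] - com[2])^2 +
              (coords[, 3] - com[3])^2))
}

#' Radial probability-density profile in a spherical cell
#'
#' Probability per unit volume `p_r` of finding a bead in each radial shell,
#' as a function of normalized radius `r/R`, scaled by `R^3` (so a uniform
#' distribution gives the flat value `3 / (4 pi)`). The profile integrates
#' to 1 over the ball.
#'
#' @param coords n x 3 matrix (nm).
#' @param shape A sphere-mode [cell_shape()].
#' @param n_bins Number of radial shells (default 20).
#' @return `data.frame(r_norm, p_r, p_r_scaled)` with shell midpoints.
#' @export
radial_distribution <- function(coords, shape, n_bins = 20) {
  if (shape$mode != "sphere") {
    stop("radial_distribution supports sphere-mode shapes only")
  }
  coords <- matrix(coords, ncol = 3)
  r <- sqrt((coords[, 1] - shape$center[1])^2 +
              (coords[, 2] - shape$center[2])^2 +
              (coords[, 3] - shape$center[3])^2)
  edges <- seq(0, shape$R, length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(r, edges, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  shell_v <- (4 / 3) * pi * (edges[-1]^3 - edges[-(n_bins + 1)]^3)
  p_r <- counts / (sum(counts) * shell_v)
  data.frame(
    r_norm = (edges[-1] + edges[-(n_bins + 1)]) / (2 * shape$R),
    p_r = p_r,
    p_r_scaled = p_r * shape$R^3
  )
}

#' Single-linkage SMC cluster sizes
#'
#' Clusters are connected components of the graph linking head midpoints
#' closer than `link_distance`.
#'
#' @param points SMC positions (k x 3, nm), e.g. loop-bond midpoints.
#' @param link_distance Linkage distance, nm (default 30).
#' @return Integer vector of cluster sizes, decreasing.
#' @export
smc_cluster_stats <- function(points, link_distance = 30) {
  points <- matrix(points, ncol = 3)
  n <- nrow(points)
  stopifnot(n >= 1)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pairs <- cpp_pairs_within(points, link_distance)
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1])
    b <- find(pairs[r, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, 1L)
  sort(as.integer(table(roots)), decreasing = TRUE)
}
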