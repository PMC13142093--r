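# Time-dependent membrane geometry.
#
# The cell grows as a sphere until its volume doubles (radius 200 -> 252 nm),
# then divides at constant volume as two symmetric overlapping spheres
# ("dumbbell") whose separation grows until the surface area has doubled and
# the spheres are tangent (two 200 nm daughters). Closed forms for the union
# volume and area of two equal overlapping spheres parameterise the shape.

#' Cell shape (sphere or symmetric overlapping spheres)
#'
#' @param R Sphere radius, nm.
#' @param d Centre separation, nm (`0` for a single sphere); `0 <= d <= 2R`.
#' @param axis Unit vector along the sphere-centre axis.
#' @param center Midpoint of the two centres (the union centre of mass axis
#'   point), nm.
#' @return Object of class `cell_shape`.
#' @export
cell_shape <- function(R, d = 0, axis = c(0, 0, 1), center = c(0, 0, 0)) {
  if (d < 0 || d > 2 * R + 1e-9) stop("require 0 <= d <= 2R")
  axis <- axis / sqrt(sum(axis^2))
  structure(
    list(
      mode = if (d > 0) "dumbbell" else "sphere",
      R = R, d = d, axis = axis, center = center
    ),
    class = "cell_shape"
  )
}

#' @export
print.cell_shape <- function(x, ...) {
  cat(sprintf(
    "<cell_shape> %s R=%.1f nm d=%.1f nm (V=%.3g nm^3, A=%.3g nm^2)\n",
    x$mode, x$R, x$d, union_volume(x$R, x$d), union_area(x$R, x$d)
  ))
  invisible(x)
}

#' Union volume of two equal overlapping spheres
#'
#' `(8/3) pi R^3 - (pi/12) (4R + d) (2R - d)^2`; reduces to one sphere at
#' `d = 0` and two tangent spheres at `d = 2R`.
#'
#' @param R Radius, nm. @param d Centre separation, nm.
#' @return Volume in nm^3.
#' @export
union_volume <- function(R, d) {
  if (any(d < 0 | d > 2 * R + 1e-9)) stop("require 0 <= d <= 2R")
  (8 / 3) * pi * R^3 - (pi / 12) * (4 * R + d) * (2 * R - d)^2
}

#' Union surface area of two equal overlapping spheres
#'
#' `4 pi R^2 + 2 pi R d` (each cap of height `R - d/2` is excluded).
#'
#' @inheritParams union_volume
#' @return Area in nm^2.
#' @export
union_area <- function(R, d) {
  if (any(d < 0 | d > 2 * R + 1e-9)) stop("require 0 <= d <= 2R")
  4 * pi * R^2 + 2 * pi * R * d
}

#' Cell growth schedule
#'
#' @param t_start Simulation start, biological min (replication initiation).
#' @param t_vol_double Time at which the volume has doubled and division
#'   (dumbbell) geometry begins, min.
#' @param t_div End of the cycle (two tangent spheres), min.
#' @param R0 Initial = final daughter sphere radius, nm.
#' @return Object of class `growth_schedule`.
#' @export
growth_schedule <- function(t_start = 5, t_vol_double = 65, t_div = 105,
                            R0 = 200) {
  stopifnot(t_start >= 0, t_vol_double > t_start, t_div > t_vol_double, R0 > 0)
  structure(
    list(
      t_start = t_start, t_vol_double = t_vol_double, t_div = t_div,
      R0 = R0, V0 = (4 / 3) * pi * R0^3, A0 = 4 * pi * R0^2
    ),
    class = "growth_schedule"
  )
}

#' Membrane shape at a given cell-cycle time
#'
#' Up to `t_vol_double` the cell is a sphere whose volume grows linearly in
#' time from `V0` (at t = 0) to `2 V0`. Afterwards the volume is held at
#' `2 V0` while the union surface area grows linearly from `2^(2/3) A0` to
#' `2 A0`; the dumbbell parameters `(R, d)` are solved from the two closed
#' forms.
#'
#' @param t Biological time in minutes, `0 <= t <= t_div`.
#' @param schedule A [growth_schedule()].
#' @param axis Division axis (unit vector); see [orient_axis()].
#' @param center Shape centre.
#' @return A [cell_shape()].
#' @export
shape_at <- function(t, schedule = growth_schedule(), axis = c(0, 0, 1),
                     center = c(0, 0, 0)) {
  if (t < 0 || t > schedule$t_div + 1e-9) stop("t outside the cell cycle")
  if (t <= schedule$t_vol_double) {
    V <- schedule$V0 * (1 + t / schedule$t_vol_double)
    return(cell_shape(schedule$R0 * (V / schedule$V0)^(1 / 3), 0, axis, center))
  }
  frac <- (t - schedule$t_vol_double) / (schedule$t_div - schedule$t_vol_double)
  A_target <- schedule$A0 * (2^(2 / 3) + frac * (2 - 2^(2 / 3)))
  V_target <- 2 * schedule$V0
  # R(d) from the volume constraint, then root-find d on the area residual
  R_of_d <- function(d) {
    stats::uniroot(
      function(R) union_volume(R, d) - V_target,
      lower = max(schedule$R0 * 0.99, d / 2),
      upper = schedule$R0 * 2^(1 / 3) * 1.01,
      tol = 1e-10
    )$root
  }
  resid <- function(d) union_area(R_of_d(d), d) - A_target
  d_hi <- 2 * schedule$R0
  if (frac >= 1 - 1e-12) {
    d <- d_hi
  } else {
    d <- stats::uniroot(resid, lower = 0, upper = d_hi, tol = 1e-9)$root
  }
  R <- R_of_d(d)
  if (abs(union_volume(R, d) - V_target) > 1e-6 * V_target ||
      abs(union_area(R, d) - A_target) > 1e-6 * A_target) {
    stop(sprintf(
      "dumbbell solver failed: volume residual %.3g, area residual %.3g",
      union_volume(R, d) - V_target, union_area(R, d) - A_target
    ))
  }
  cell_shape(R, d, axis, center)
}

# Sphere centres of a shape (1 or 2 rows).
shape_centers <- function(shape) {
  if (shape$mode == "sphere") {
    matrix(shape$center, nrow = 1)
  } else {
    rbind(
      shape$center + shape$axis * shape$d / 2,
      shape$center - shape$axis * shape$d / 2
    )
  }
}

#' Test whether points are inside the membrane
#'
#' @param points n x 3 matrix (nm).
#' @param shape A [cell_shape()].
#' @param margin Required clearance from the surface, nm.
#' @return Logical vector.
#' @export
inside_shape <- function(points, shape, margin = 0) {
  points <- matrix(points, ncol = 3)
  ctr <- shape_centers(shape)
  ok <- rep(FALSE, nrow(points))
  for (k in seq_len(nrow(ctr))) {
    d2 <- (points[, 1] - ctr[k, 1])^2 + (points[, 2] - ctr[k, 2])^2 +
      (points[, 3] - ctr[k, 3])^2
    ok <- ok | d2 <= (shape$R - margin)^2
  }
  ok
}

# Radially project points to just inside the membrane (toward the nearest
# sphere centre); used after geometry updates leave beads outside.
project_inside <- function(points, shape, margin) {
  points <- matrix(points, ncol = 3)
  out <- points
  ctr <- shape_centers(shape)
  inside <- inside_shape(points, shape, margin)
  for (i in which(!inside)) {
    d <- sqrt(rowSums((ctr - matrix(points[i, ], nrow(ctr), 3, byrow = TRUE))^2))
    k <- which.min(d)
    if (d[k] < 1e-9) next
    out[i, ] <- ctr[k, ] + (points[i, ] - ctr[k, ]) * (shape$R - margin) / d[k]
  }
  out
}

# Fibonacci-lattice points on a unit sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Boundary-particle shell tiling the membrane
#'
#' Boundary particles (radius 10 nm) tile the union surface on a Fibonacci
#' lattice dense enough that nearest-neighbour spacing is well below one
#' particle diameter, leaving no gap a DNA bead can pass. For a dumbbell,
#' points falling inside the partner sphere (the interior lens) are dropped.
#'
#' @param shape A [cell_shape()].
#' @param particle_radius Boundary bead radius, nm (default 10).
#' @return n x 3 matrix of particle centres on the surface.
#' @export
boundary_shell <- function(shape, particle_radius = 10) {
  area_sphere <- 4 * pi * shape$R^2
  n_pts <- max(64L, ceiling(0.75 * area_sphere / particle_radius^2))
  pts <- fibonacci_sphere(n_pts) * shape$R
  ctr <- shape_centers(shape)
  out <- vector("list", nrow(ctr))
  for (k in seq_len(nrow(ctr))) {
    p <- sweep(pts, 2, ctr[k, ], `+`)
    if (nrow(ctr) == 2) {
      other <- ctr[3 - k, ]
      d2 <- (p[, 1] - other[1])^2 + (p[, 2] - other[2])^2 + (p[, 3] - other[3])^2
      p <- p[d2 >= shape$R^2 * (1 - 1e-12), , drop = FALSE]
    }
    out[[k]] <- p
  }
  do.call(rbind, out)
}

#' Division axis from daughter-chromosome centres of mass
#'
#' The vector between the two overlapping spheres points along the vector
#' between the daughter chromosome centres of mass; degenerate (coincident)
#' centres fall back to +z.
#'
#' @param com_dL,com_dR Centres of mass (length-3) of the two daughters.
#' @return Unit vector.
#' @export
orient_axis <- function(com_dL, com_dR) {
  v <- com_dL - com_dR
  n <- sqrt(sum(v^2))
  if (n < 1e-9) return(c(0, 0, 1))
  v / n
}
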