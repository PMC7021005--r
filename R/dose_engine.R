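#' Dose-kernel parameters for the planar dose engine
#'
#' The planar dose engine convolves fluence with a radially symmetric
#' two-component kernel: a narrow primary Gaussian modeling the effective
#' source/penumbra and a broad scatter Gaussian.  Depth dose along each ray
#' is a single exponential.  Inverse-square and beam divergence are not
#' modeled; doses are per-MU relative, and every study-facing output is a
#' percent difference or a gamma comparison, both of which are unit-free.
#'
#' @param sigma_primary_mm standard deviation of the primary Gaussian, mm.
#' @param sigma_scatter_mm standard deviation of the scatter Gaussian, mm.
#' @param scatter_weight fraction of the kernel in the scatter component,
#'   in `[0, 1)`.
#' @param mu_attenuation_per_cm effective linear attenuation of the beam in
#'   phantom material, 1/cm.
#' @param sad_mm source-axis distance, mm (geometry bookkeeping only).
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(sigma_primary_mm = 1, sigma_scatter_mm = 20,
                          scatter_weight = 0.1, mu_attenuation_per_cm = 0.05,
                          sad_mm = 1000) {
  stopifnot(sigma_primary_mm > 0, sigma_scatter_mm > 0,
            scatter_weight >= 0, scatter_weight < 1,
            mu_attenuation_per_cm > 0, sad_mm > 0)
  structure(list(sigma_primary_mm = sigma_primary_mm,
                 sigma_scatter_mm = sigma_scatter_mm,
                 scatter_weight = scatter_weight,
                 mu_attenuation_per_cm = mu_attenuation_per_cm,
                 sad_mm = sad_mm), class = "kernel_params")
}

# Discrete 1-D Gaussian row-convolution matrix between two coordinate
# vectors, normalized so that rows sum to 1 when the source axis fully
# covers the kernel support (flat-field preservation; boundary truncation
# lowers edge rows, as physical).
.gauss_matrix <- function(to, from, sigma, spacing) {
  m <- exp(-outer(to, from, "-")^2 / (2 * sigma^2))
  # normalization constant of the *infinite* discrete kernel at this pitch,
  # so truncation at the grid edge is visible rather than renormalized away
  k <- seq(-ceiling(8 * sigma / spacing), ceiling(8 * sigma / spacing))
  z <- sum(exp(-(k * spacing)^2 / (2 * sigma^2)))
  m / z
}

#' Fluence of one beam (sum of MU-weighted segment transmission maps)
#'
#' @param segments list of [mlc_segment()] sharing one gantry angle.
#' @param model a [beam_model()].
#' @param grid a [grid_spec()].
#' @return A [dose_map()] holding the MU-weighted fluence.
#' @export
beam_fluence <- function(segments, model, grid) {
  if (inherits(segments, "mlc_segment")) segments <- list(segments)
  stopifnot(length(segments) >= 1)
  g <- vapply(segments, function(s) s$gantry_deg, numeric(1))
  if (max(g) - min(g) > 1e-9)
    stop("all segments of a beam must share the gantry angle")
  vals <- 0
  for (s in segments)
    vals <- vals + s$mu * segment_transmission_map(s, model, grid)$values
  dose_map(grid, vals)
}

#' Planar dose from fluence by two-Gaussian convolution
#'
#' Separable convolution with the primary + scatter kernel of
#' [kernel_params()].  The total integral is preserved up to truncation at
#' the grid boundary.
#'
#' @param fluence a [dose_map()] of fluence.
#' @param kernel a [kernel_params()].
#' @return A [dose_map()] of planar dose on the same grid.
#' @export
planar_dose <- function(fluence, kernel) {
  stopifnot(inherits(fluence, "dose_map"), inherits(kernel, "kernel_params"))
  g <- fluence$grid
  ax <- grid_axes(g)
  v <- fluence$values
  out <- 0
  wts <- c(1 - kernel$scatter_weight, kernel$scatter_weight)
  sig <- c(kernel$sigma_primary_mm, kernel$sigma_scatter_mm)
  for (c_i in 1:2) {
    Kx <- .gauss_matrix(ax$x, ax$x, sig[c_i], g$spacing_mm)
    Ky <- .gauss_matrix(ax$y, ax$y, sig[c_i], g$spacing_mm)
    out <- out + wts[c_i] * (Kx %*% v %*% t(Ky))
  }
  out[out < 0] <- 0
  dose_map(g, out)
}

#' Planar dose evaluated directly at points
#'
#' Evaluates the kernel convolution of a fluence map at arbitrary
#' beam's-eye-view points without rasterizing the full dose map; exact
#' (same quadrature) for points on or off the grid.  If `tensor = TRUE`,
#' `u_mm` and `v_mm` are axis vectors and the full outer grid is returned
#' as a matrix; otherwise they are paired coordinates.
#'
#' @param fluence a [dose_map()] of fluence.
#' @param kernel a [kernel_params()].
#' @param u_mm,v_mm beam's-eye-view coordinates, mm.
#' @param tensor logical; see Description.
#' @return numeric vector (paired) or `length(u_mm) x length(v_mm)` matrix
#'   (tensor).
#' @export
planar_dose_at <- function(fluence, kernel, u_mm, v_mm, tensor = FALSE) {
  stopifnot(inherits(fluence, "dose_map"), inherits(kernel, "kernel_params"))
  g <- fluence$grid
  ax <- grid_axes(g)
  v <- fluence$values
  wts <- c(1 - kernel$scatter_weight, kernel$scatter_weight)
  sig <- c(kernel$sigma_primary_mm, kernel$sigma_scatter_mm)
  out <- 0
  for (c_i in 1:2) {
    Ku <- .gauss_matrix(u_mm, ax$x, sig[c_i], g$spacing_mm)  # nu x nx
    Kv <- .gauss_matrix(v_mm, ax$y, sig[c_i], g$spacing_mm)  # nv x ny
    if (tensor) {
      out <- out + wts[c_i] * (Ku %*% v %*% t(Kv))
    } else {
      stopifnot(length(u_mm) == length(v_mm))
      A <- Ku %*% v                       # npts x ny
      out <- out + wts[c_i] * rowSums(A * Kv)
    }
  }
  pmax(out, 0)
}

#' Virtual cylindrical phantom
#'
#' A water-equivalent cylinder whose axis lies along the leaf-pair (y)
#' axis, with a primary target (PTV1, sphere), a secondary target (PTV2,
#' sphere) and a spinal-cord avoidance cylinder posterior to PTV1 separated
#' by `cord_gap_mm`.  Coordinates: x lateral, z anterior(+)/posterior(-),
#' isocenter at the origin; all positions in mm in the axial plane `(x, z)`.
#'
#' @param radius_mm cylinder radius.
#' @param ptv1_center,ptv2_center,cord_center axial-plane centres `(x, z)`.
#' @param ptv_radii_mm radii of PTV1 and PTV2 (spheres).
#' @param cord_radius_mm cord cylinder radius.
#' @param cord_gap_mm required PTV1-surface to cord-surface margin (> 0);
#'   this gap is where the dose gradient the study probes lives.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(radius_mm = 80,
                         ptv1_center = c(0, 15), ptv2_center = c(40, 15),
                         cord_center = c(0, -25),
                         ptv_radii_mm = c(25, 15), cord_radius_mm = 5,
                         cord_gap_mm = 10) {
  stopifnot(radius_mm > 0, cord_gap_mm > 0, all(ptv_radii_mm > 0),
            cord_radius_mm > 0)
  inside <- function(c2, r) sqrt(sum(c2^2)) + r <= radius_mm
  if (!inside(ptv1_center, ptv_radii_mm[1]) ||
      !inside(ptv2_center, ptv_radii_mm[2]) ||
      !inside(cord_center, cord_radius_mm))
    stop("all structures must lie inside the phantom cylinder")
  gap <- sqrt(sum((ptv1_center - cord_center)^2)) -
    ptv_radii_mm[1] - cord_radius_mm
  if (gap < cord_gap_mm - 1e-9)
    stop("cord is closer to PTV1 than cord_gap_mm")
  structure(list(radius_mm = radius_mm, ptv1_center = ptv1_center,
                 ptv2_center = ptv2_center, cord_center = cord_center,
                 ptv_radii_mm = ptv_radii_mm, cord_radius_mm = cord_radius_mm,
                 cord_gap_mm = cord_gap_mm), class = "phantom_spec")
}

#' Default head-and-neck-like phantom
#'
#' Deterministic constructor of the study phantom: an 80 mm radius
#' cylinder, a 25 mm primary target anterior of isocenter, a 15 mm lateral
#' secondary target, and a 5 mm cord 10 mm posterior of the PTV1 surface.
#'
#' @return A [phantom_spec()].
#' @export
default_phantom <- function() phantom_spec()

#' Radiological depth of a point for a gantry angle
#'
#' Path length (mm) from the cylinder surface to the point along the beam
#' direction.  Gantry 0 deg enters anteriorly (from +z), angles increase
#' clockwise when viewed from the phantom's superior end.
#'
#' @param x_mm,z_mm axial-plane coordinates of the point(s), mm
#'   (vectorized).
#' @param gantry_deg gantry angle, degrees.
#' @param phantom a [phantom_spec()].
#' @return numeric vector of depths, mm.  Points outside the cylinder are
#'   an error.
#' @export
ray_depth <- function(x_mm, z_mm, gantry_deg, phantom) {
  stopifnot(inherits(phantom, "phantom_spec"))
  r2 <- x_mm^2 + z_mm^2
  if (any(r2 > phantom$radius_mm^2 + 1e-9))
    stop("point outside the phantom cylinder")
  th <- gantry_deg * pi / 180
  # beam direction (unit), from source toward isocenter
  dx <- -sin(th); dz <- -cos(th)
  pd <- x_mm * dx + z_mm * dz
  pd + sqrt(pmax(pd^2 - r2 + phantom$radius_mm^2, 0))
}

# Beam's-eye-view coordinates of axial-plane points: u is the crossplane
# (leaf-travel) coordinate, v the leaf-pair coordinate (= y, unchanged by
# gantry rotation about the y axis).
.bev_u <- function(x_mm, z_mm, gantry_deg) {
  th <- gantry_deg * pi / 180
  x_mm * cos(th) - z_mm * sin(th)
}

#' Composite point dose of a plan under a beam model
#'
#' Sums, over all beams (static segments grouped by gantry angle), the
#' exponentially attenuated planar dose at the beam's-eye projection of
#' each point: `D(p) = sum_b exp(-mu * depth_b(p)) * PD_b(u_b(p), v(p))`.
#'
#' @param plan a `treatment_plan` (see [generate_plan_suite()]).
#' @param model a [beam_model()].
#' @param points data frame with columns `x_mm`, `y_mm`, `z_mm` (phantom
#'   frame; `y_mm` is along the cylinder axis).
#' @param phantom a [phantom_spec()].
#' @param kernel a [kernel_params()].
#' @param grid a [grid_spec()] for fluence rasterization.
#' @return numeric vector of doses (arbitrary per-MU units), one per point.
#' @export
composite_point_dose <- function(plan, model, points,
                                 phantom = default_phantom(),
                                 kernel = kernel_params(),
                                 grid = grid_spec()) {
  stopifnot(inherits(plan, "treatment_plan"),
            all(c("x_mm", "y_mm", "z_mm") %in% names(points)))
  dose <- numeric(nrow(points))
  for (beam in plan$beams) {
    fl <- beam_fluence(beam$segments, model, grid)
    th <- beam$gantry_deg
    u <- .bev_u(points$x_mm, points$z_mm, th)
    att <- exp(-kernel$mu_attenuation_per_cm *
                 ray_depth(points$x_mm, points$z_mm, th, phantom) / 10)
    dose <- dose + att * planar_dose_at(fl, kernel, u, points$y_mm)
  }
  dose
}
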