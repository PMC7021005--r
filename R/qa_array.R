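#' Virtual diode-array specification
#'
#' A planar diode array in the coronal plane through isocenter (the plane
#' z = 0 containing the phantom axis), with diodes on a square grid.  This
#' planar stand-in for a cylindrical 3-D array preserves what the QA
#' comparison consumes — pointwise measured/calculated dose pairs at
#' roughly 1 cm pitch — without helical geometry.
#'
#' @param spacing_mm diode pitch (default 10 mm).
#' @param extent_mm half-width of the array; diodes span
#'   `[-extent_mm, extent_mm]` in both axes and must stay inside the
#'   phantom cylinder.
#' @param noise_sigma_pct Gaussian measurement noise as a percentage of
#'   the maximum sampled dose (default 0.5, typical diode-array
#'   reproducibility); set 0 for deterministic output.
#' @param seed integer seed for the noise stream.
#' @return An object of class `array_spec`.
#' @export
array_spec <- function(spacing_mm = 10, extent_mm = 70,
                       noise_sigma_pct = 0.5, seed = 1L) {
  stopifnot(spacing_mm > 0, extent_mm > 0, noise_sigma_pct >= 0)
  structure(list(spacing_mm = spacing_mm, extent_mm = extent_mm,
                 noise_sigma_pct = noise_sigma_pct, seed = as.integer(seed)),
            class = "array_spec")
}

#' Composite dose on the array plane
#'
#' Dose of a plan under a beam model evaluated on a rectangular grid of
#' points `(x, y, z = 0)` of the coronal isocenter plane, with the ray
#' attenuation of the cylindrical phantom applied per beam.
#'
#' @param plan a `treatment_plan`.
#' @param model a [beam_model()].
#' @param xs,ys plane coordinates, mm; `max(|xs|)` must not exceed the
#'   phantom radius.
#' @param phantom a [phantom_spec()].
#' @param kernel a [kernel_params()].
#' @param grid fluence rasterization grid.
#' @return `length(xs) x length(ys)` dose matrix.
#' @export
plane_dose <- function(plan, model, xs, ys, phantom = default_phantom(),
                       kernel = kernel_params(), grid = grid_spec()) {
  stopifnot(inherits(plan, "treatment_plan"))
  out <- matrix(0, length(xs), length(ys))
  for (beam in plan$beams) {
    fl <- beam_fluence(beam$segments, model, grid)
    th <- beam$gantry_deg
    att <- exp(-kernel$mu_attenuation_per_cm *
                 ray_depth(xs, rep(0, length(xs)), th, phantom) / 10)
    u <- .bev_u(xs, rep(0, length(xs)), th)
    out <- out + att * planar_dose_at(fl, kernel, u, ys, tensor = TRUE)
  }
  out
}

.array_positions <- function(array) {
  s <- seq(-array$extent_mm, array$extent_mm, by = array$spacing_mm)
  list(x = s, y = s)
}

#' Noiseless candidate-model prediction on the diode array
#'
#' Deterministic sampling of the candidate-model composite dose at the
#' diode positions.
#'
#' @param plan a `treatment_plan`.
#' @param candidate_model a [beam_model()].
#' @param array an [array_spec()].
#' @param phantom a [phantom_spec()].
#' @param kernel a [kernel_params()].
#' @param grid fluence grid.
#' @return data frame `x_mm`, `y_mm`, `dose` (one row per diode).
#' @export
predicted_on_array <- function(plan, candidate_model, array = array_spec(),
                               phantom = default_phantom(),
                               kernel = kernel_params(), grid = grid_spec()) {
  pos <- .array_positions(array)
  d <- plane_dose(plan, candidate_model, pos$x, pos$y, phantom, kernel, grid)
  data.frame(x_mm = rep(pos$x, times = length(pos$y)),
             y_mm = rep(pos$y, each = length(pos$x)),
             dose = as.vector(d))
}

#' Virtual diode-array measurement
#'
#' Samples the truth-model composite dose at the diode positions and adds
#' seeded zero-mean Gaussian noise scaled by `noise_sigma_pct` of the
#' noiseless maximum.  Negative noisy samples are clipped at zero.
#'
#' @inheritParams predicted_on_array
#' @param truth_model the [beam_model()] that "delivers" the plan.
#' @return data frame `x_mm`, `y_mm`, `dose`.
#' @export
virtual_measurement <- function(plan, truth_model, array = array_spec(),
                                phantom = default_phantom(),
                                kernel = kernel_params(),
                                grid = grid_spec()) {
  s <- predicted_on_array(plan, truth_model, array, phantom, kernel, grid)
  add_measurement_noise(s, array)
}

#' Add the array's measurement noise to noiseless samples
#'
#' Split out from [virtual_measurement()] so noise replicates can reuse
#' one dose computation.
#'
#' @param samples data frame `x_mm`, `y_mm`, `dose` (noiseless).
#' @param array an [array_spec()]; its `seed` and `noise_sigma_pct` drive
#'   the noise.
#' @return data frame of the same shape with noisy `dose`.
#' @export
add_measurement_noise <- function(samples, array) {
  if (array$noise_sigma_pct == 0) return(samples)
  sd_abs <- array$noise_sigma_pct / 100 * max(samples$dose)
  set.seed(array$seed)
  samples$dose <- pmax(0, samples$dose +
                         stats::rnorm(nrow(samples), 0, sd_abs))
  samples
}

#' Write / read sampled dose points as CSV
#'
#' @param samples data frame `x_mm`, `y_mm`, `dose`.
#' @param path file path.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(samples[, c("x_mm", "y_mm", "dose")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) utils::read.csv(path)
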