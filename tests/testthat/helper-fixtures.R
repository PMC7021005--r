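# Shared fixtures and independent oracles, all built in code.

# A simple rectangular aperture over the whole bank.
rect_aperture <- function(left = -30, right = 30, n_pairs = 8, pitch = 5) {
  y0 <- (seq_len(n_pairs) - 1 - n_pairs / 2) * pitch
  data.frame(pair_index = seq_len(n_pairs), y_low_mm = y0,
             y_high_mm = y0 + pitch,
             left_pos_mm = left, right_pos_mm = right)
}

random_aperture <- function(n_pairs = 8, pitch = 5) {
  y0 <- (seq_len(n_pairs) - 1 - n_pairs / 2) * pitch
  l <- runif(n_pairs, -40, 10)
  data.frame(pair_index = seq_len(n_pairs), y_low_mm = y0,
             y_high_mm = y0 + pitch,
             left_pos_mm = l, right_pos_mm = l + runif(n_pairs, 0, 50))
}

small_grid <- function(half = 40, spacing = 2) {
  n <- as.integer(2 * half / spacing) + 1L
  grid_spec(c(-half, -half), spacing, n, n)
}

# Scalar per-point oracle for a transmission map: evaluates
# leaf_pair_transmission point by point, picking the pair by y membership.
transmission_map_oracle <- function(segment, model, grid) {
  ax <- grid_axes(grid)
  ap <- segment$aperture
  vals <- matrix(NA_real_, grid$nx, grid$ny)
  for (j in seq_along(ax$y)) {
    y <- ax$y[j]
    # pair intervals are left-closed; the top edge belongs to the last pair
    k <- which(ap$y_low_mm <= y & (y < ap$y_high_mm |
                                     (y == max(ap$y_high_mm) &
                                        ap$y_high_mm == max(ap$y_high_mm))))[1]
    if (is.na(k)) { vals[, j] <- model$leaf_transmission; next }
    pr <- leaf_pair(ap$pair_index[k], ap$y_low_mm[k], ap$y_high_mm[k],
                    ap$left_pos_mm[k], ap$right_pos_mm[k])
    for (i in seq_along(ax$x))
      vals[i, j] <- leaf_pair_transmission(ax$x[i], pr, model)
  }
  vals
}

# Brute-force 2-D convolution oracle for the planar dose kernel: direct
# double sum with the discrete two-Gaussian kernel normalized by the
# infinite-lattice sum (independent of the separable implementation).
planar_dose_oracle <- function(fluence, kernel) {
  g <- fluence$grid
  ax <- grid_axes(g)
  comp <- function(sig) {
    ks <- seq(-ceiling(8 * sig / g$spacing_mm), ceiling(8 * sig / g$spacing_mm))
    z1 <- sum(exp(-(ks * g$spacing_mm)^2 / (2 * sig^2)))
    out <- matrix(0, g$nx, g$ny)
    for (i in seq_len(g$nx)) for (j in seq_len(g$ny)) {
      kx <- exp(-(ax$x[i] - ax$x)^2 / (2 * sig^2))
      ky <- exp(-(ax$y[j] - ax$y)^2 / (2 * sig^2))
      out[i, j] <- as.numeric(kx %*% fluence$values %*% ky) / z1^2
    }
    out
  }
  (1 - kernel$scatter_weight) * comp(kernel$sigma_primary_mm) +
    kernel$scatter_weight * comp(kernel$sigma_scatter_mm)
}

# Smooth positive random field on a grid: a base level plus a few broad
# Gaussian bumps.  Bump widths >= 12 mm keep dose gradients below ~2% of
# the maximum per mm, so that discrete gamma searches at the stated
# sampling resolutions are converged well within the comparison
# tolerances.
random_smooth_map <- function(grid, n_bumps = 4, base = 30) {
  ax <- grid_axes(grid)
  v <- matrix(base, grid$nx, grid$ny)
  for (b in seq_len(n_bumps)) {
    cx <- runif(1, min(ax$x), max(ax$x))
    cy <- runif(1, min(ax$y), max(ax$y))
    s <- runif(1, 12, 20); a <- runif(1, 10, 30)
    v <- v + a * outer(exp(-(ax$x - cx)^2 / (2 * s^2)),
                       exp(-(ax$y - cy)^2 / (2 * s^2)))
  }
  dose_map(grid, v)
}

# Interior point samples of a map, leaving `margin` mm so the gamma
# search disk stays inside the evaluated grid.
interior_samples <- function(map, every = 4, margin = 10) {
  s <- map_to_samples(map, every = every)
  ax <- grid_axes(map$grid)
  s[s$x_mm >= min(ax$x) + margin & s$x_mm <= max(ax$x) - margin &
      s$y_mm >= min(ax$y) + margin & s$y_mm <= max(ax$y) - margin, ]
}

# A QA-like perturbation of a dose map: global rescale, small rigid
# shift, and one extra low-amplitude bump.  Keeps gamma values in the
# clinically relevant range where the search minima are interior points.
perturbed_map <- function(map, scale = NULL, shift_mm = NULL) {
  g <- map$grid
  ax <- grid_axes(g)
  if (is.null(scale)) scale <- runif(1, 0.97, 1.03)
  if (is.null(shift_mm)) shift_mm <- runif(2, -1.5, 1.5)
  v <- matrix(interp_map(map, rep(ax$x - shift_mm[1], times = g$ny),
                         rep(ax$y - shift_mm[2], each = g$nx)),
              g$nx, g$ny)
  cx <- runif(1, min(ax$x), max(ax$x)); cy <- runif(1, min(ax$y), max(ax$y))
  s <- runif(1, 12, 20); a <- runif(1, 0, 0.06) * max(map$values)
  v <- scale * v + a * outer(exp(-(ax$x - cx)^2 / (2 * s^2)),
                             exp(-(ax$y - cy)^2 / (2 * s^2)))
  dose_map(g, v)
}

# Tie-corrected pairwise concordance (Mann-Whitney) oracle for the ROC
# AUC, with "lower score indicates positive" orientation.
auc_pairwise <- function(pos_scores, neg_scores) {
  cmp <- outer(pos_scores, neg_scores,
               function(p, q) (p < q) + 0.5 * (p == q))
  mean(cmp)
}

# A tiny two-beam plan used where a full synthetic plan would be
# needlessly slow.
tiny_plan <- function(mu = c(60, 40)) {
  ap1 <- rect_aperture(-20, 20)
  ap2 <- rect_aperture(-15, 25)
  structure(list(
    plan_id = "TINY", technique = "imrt",
    beams = list(
      list(gantry_deg = 0, segments = list(mlc_segment(ap1, mu[1], 0))),
      list(gantry_deg = 180, segments = list(mlc_segment(ap2, mu[2], 180)))),
    total_mu = sum(mu), spec = NULL), class = "treatment_plan")
}
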