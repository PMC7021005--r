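#' Deterministic seed fan-out
#'
#' Derives the seed of an independent random stream (a plan's modulation,
#' a noise replicate) from the master seed by affine hashing modulo
#' 2^31 - 2; results are always valid positive 32-bit seeds.
#'
#' @param master master integer seed.
#' @param stream integer stream identifier.
#' @return a positive integer seed.
#' @export
split_seed <- function(master, stream) {
  as.integer((as.numeric(master) * 7919 + as.numeric(stream) * 104729 + 1) %%
               2147483646 + 1)
}

# MLC bank geometry used throughout: 40 pairs at 5 mm pitch (Agility-like),
# leaf travel limited to +/- 100 mm, closed pairs parked at -80 mm.
.bank_geometry <- function() {
  n <- 40L; pitch <- 5
  y_low <- (seq_len(n) - 1 - n / 2) * pitch
  list(n_pairs = n, pitch = pitch, y_low = y_low, y_high = y_low + pitch,
       y_mid = y_low + pitch / 2, travel_mm = 100, park_mm = -80)
}

#' Plan-suite specification row
#'
#' @param plan_id label.
#' @param technique `"imrt"` (step-and-shoot) or `"vmat"` (full arcs).
#' @param n_beams_or_arcs beam count (7 or 9) for IMRT, arc count (2 or 3)
#'   for VMAT.
#' @param segments_per_beam static segments per IMRT beam (ignored for
#'   VMAT, where arcs are discretized at the control-point spacing).
#' @param total_mu total plan monitor units; must lie in `[1469, 2114]`.
#' @param modulation_strength fraction in `[0, 1]` controlling how far the
#'   random sub-aperture shrinkage may pull leaves into the conformal
#'   aperture.
#' @param seed integer seed for this plan's random modulation.
#' @return An object of class `plan_spec`.
#' @export
plan_spec <- function(plan_id, technique = c("imrt", "vmat"),
                      n_beams_or_arcs, segments_per_beam = 6,
                      total_mu, modulation_strength = 0.5, seed = 1L) {
  technique <- match.arg(technique)
  if (technique == "imrt" && !n_beams_or_arcs %in% c(7, 9))
    stop("IMRT plans have 7 or 9 beams")
  if (technique == "vmat" && !n_beams_or_arcs %in% c(2, 3))
    stop("VMAT plans have 2 or 3 arcs")
  if (total_mu < 1469 || total_mu > 2114)
    stop("total MU must lie in [1469, 2114]")
  stopifnot(modulation_strength >= 0, modulation_strength <= 1)
  structure(list(plan_id = plan_id, technique = technique,
                 n_beams_or_arcs = as.integer(n_beams_or_arcs),
                 segments_per_beam = as.integer(segments_per_beam),
                 total_mu = as.numeric(total_mu),
                 modulation_strength = as.numeric(modulation_strength),
                 seed = as.integer(seed)), class = "plan_spec")
}

#' @export
print.treatment_plan <- function(x, ...) {
  nseg <- sum(vapply(x$beams, function(b) length(b$segments), integer(1)))
  cat(sprintf("<treatment_plan> %s (%s): %d beams/control points, %d segments, %.0f MU\n",
              x$plan_id, x$technique, length(x$beams), nseg, x$total_mu))
  invisible(x)
}

# Conformal aperture for one gantry angle: cover the union of the PTV
# projections, block the cord shadow (with margin) by pulling one leaf to
# the cord edge.  `block_side` chooses which side of the cord stays open
# when the cord splits the target shadow; segments alternate sides so the
# cord sees penumbra from both banks over a delivery.
.conformal_aperture <- function(gantry_deg, phantom, bank,
                                block_side = c("wider", "left", "right"),
                                cord_margin_mm = 2,
                                structure_half_length_mm = 60) {
  block_side <- match.arg(block_side)
  ptvs <- list(list(c = phantom$ptv1_center, r = phantom$ptv_radii_mm[1]),
               list(c = phantom$ptv2_center, r = phantom$ptv_radii_mm[2]))
  cord_u <- .bev_u(phantom$cord_center[1], phantom$cord_center[2], gantry_deg)
  cord_lo <- cord_u - phantom$cord_radius_mm - cord_margin_mm
  cord_hi <- cord_u + phantom$cord_radius_mm + cord_margin_mm
  left <- right <- rep(bank$park_mm, bank$n_pairs)
  for (k in seq_len(bank$n_pairs)) {
    ym <- bank$y_mid[k]
    lo <- Inf; hi <- -Inf
    for (p in ptvs) {
      re2 <- p$r^2 - ym^2                  # spherical cross-section
      if (re2 <= 0) next
      uc <- .bev_u(p$c[1], p$c[2], gantry_deg)
      lo <- min(lo, uc - sqrt(re2)); hi <- max(hi, uc + sqrt(re2))
    }
    if (!is.finite(hi)) next               # pair off-target: parked closed
    if (abs(ym) <= structure_half_length_mm && cord_lo < hi && cord_hi > lo) {
      seg_l <- c(lo, min(cord_lo, hi))     # open interval left of the cord
      seg_r <- c(max(cord_hi, lo), hi)     # ... and right of it
      wl <- max(0, diff(seg_l)); wr <- max(0, diff(seg_r))
      side <- switch(block_side,
                     wider = if (wl >= wr) "left" else "right",
                     left = "left", right = "right")
      iv <- if (side == "left") seg_l else seg_r
      if (diff(iv) <= 0) iv <- if (wl >= wr) seg_l else seg_r
      if (diff(iv) <= 0) next              # fully shadowed: keep closed
      lo <- iv[1]; hi <- iv[2]
    }
    left[k] <- max(-bank$travel_mm, lo)
    right[k] <- min(bank$travel_mm, hi)
  }
  data.frame(pair_index = seq_len(bank$n_pairs),
             y_low_mm = bank$y_low, y_high_mm = bank$y_high,
             left_pos_mm = left, right_pos_mm = right)
}

# Random sub-aperture modulation: shrink each open pair by independent
# uniform fractions of its half-gap, and close a pair outright with small
# probability.  Uses the current RNG stream.
.modulate_aperture <- function(ap, bank, strength) {
  open <- ap$right_pos_mm > ap$left_pos_mm
  n <- sum(open)
  if (n == 0 || strength == 0) return(ap)
  half <- (ap$right_pos_mm[open] - ap$left_pos_mm[open]) / 2
  ap$left_pos_mm[open] <- ap$left_pos_mm[open] +
    stats::runif(n, 0, strength) * half
  ap$right_pos_mm[open] <- ap$right_pos_mm[open] -
    stats::runif(n, 0, strength) * half
  shut <- open & (stats::runif(nrow(ap)) < 0.1 * strength)
  ap$left_pos_mm[shut] <- bank$park_mm
  ap$right_pos_mm[shut] <- bank$park_mm
  ap
}

.make_imrt_plan <- function(spec, phantom, bank) {
  set.seed(spec$seed)
  n_b <- spec$n_beams_or_arcs
  angles <- (seq_len(n_b) - 1) * 360 / n_b + stats::runif(1, 0, 360 / n_b)
  nseg_tot <- n_b * spec$segments_per_beam
  w <- stats::runif(nseg_tot, 0.5, 1.5)
  mu <- spec$total_mu * w / sum(w)
  beams <- vector("list", n_b)
  s_idx <- 0L
  for (b in seq_len(n_b)) {
    segs <- vector("list", spec$segments_per_beam)
    for (s in seq_len(spec$segments_per_beam)) {
      s_idx <- s_idx + 1L
      side <- if (s %% 2 == 0) "left" else "right"
      ap <- .conformal_aperture(angles[b], phantom, bank, block_side = side)
      ap <- .modulate_aperture(ap, bank, spec$modulation_strength)
      segs[[s]] <- mlc_segment(ap, mu[s_idx], angles[b])
    }
    beams[[b]] <- list(gantry_deg = angles[b], segments = segs)
  }
  structure(list(plan_id = spec$plan_id, technique = "imrt", beams = beams,
                 total_mu = spec$total_mu, spec = spec),
            class = "treatment_plan")
}

.make_vmat_plan <- function(spec, phantom, bank, control_spacing_deg = 4) {
  set.seed(spec$seed)
  n_a <- spec$n_beams_or_arcs
  n_cp <- as.integer(360 / control_spacing_deg)
  w <- stats::runif(n_a * n_cp, 0.5, 1.5)
  mu <- spec$total_mu * w / sum(w)
  beams <- vector("list", n_a * n_cp)
  i <- 0L
  for (a in seq_len(n_a)) {
    start <- 2 * (a - 1)                   # stagger arcs slightly
    for (cp in seq_len(n_cp)) {
      i <- i + 1L
      ang <- (start + (cp - 1) * control_spacing_deg) %% 360
      side <- if ((cp + a) %% 2 == 0) "left" else "right"
      ap <- .conformal_aperture(ang, phantom, bank, block_side = side)
      ap <- .modulate_aperture(ap, bank, spec$modulation_strength)
      seg <- mlc_segment(ap, mu[i], ang)
      beams[[i]] <- list(gantry_deg = ang, segments = list(seg))
    }
  }
  structure(list(plan_id = spec$plan_id, technique = "vmat", beams = beams,
                 total_mu = spec$total_mu, spec = spec),
            class = "treatment_plan")
}

#' Generate the default nine-plan synthetic suite
#'
#' Produces five step-and-shoot IMRT plans (7, 7, 7, 9 and 9 equally
#' spaced beams) and four VMAT plans (2, 2, 2 and 3 full arcs discretized
#' at 4 degree control points), with total MU per plan fixed at typical
#' clinical values in the 1469-2114 MU range.  Apertures conformally cover
#' both targets while blocking the cord shadow, with seeded random
#' sub-aperture modulation emulating plan-to-plan optimizer variety.  The
#' same seed always reproduces the identical suite.
#'
#' @param seed master integer seed.
#' @param phantom a [phantom_spec()].
#' @return list of `treatment_plan` objects (length 9), each carrying its
#'   `plan_spec` in `$spec`.
#' @examples
#' suite <- generate_plan_suite(1)
#' vapply(suite, function(p) p$technique, character(1))
#' @export
generate_plan_suite <- function(seed = 1L, phantom = default_phantom()) {
  bank <- .bank_geometry()
  design <- data.frame(
    plan_id = c("IMRT0", "IMRT1", "IMRT2", "IMRT3", "IMRT4",
                "VMAT1", "VMAT2", "VMAT3", "VMAT4"),
    technique = c(rep("imrt", 5), rep("vmat", 4)),
    n = c(7, 7, 7, 9, 9, 2, 2, 2, 3),
    total_mu = c(1542, 1772, 1733, 1747, 1818, 1711, 1871, 2114, 1469))
  plans <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    pseed <- split_seed(seed, i)
    set.seed(pseed)
    mod <- stats::runif(1, 0.3, 0.7)
    sp <- plan_spec(design$plan_id[i], design$technique[i], design$n[i],
                    segments_per_beam = 6, total_mu = design$total_mu[i],
                    modulation_strength = mod, seed = pseed)
    plans[[i]] <- if (sp$technique == "imrt")
      .make_imrt_plan(sp, phantom, bank)
    else
      .make_vmat_plan(sp, phantom, bank)
  }
  names(plans) <- design$plan_id
  plans
}

#' TLD-like regions of interest of the phantom
#'
#' Four small disk ROIs at the dosimeter positions of the phantom:
#' PTV1_center and PTV2 (low-gradient, inside the targets), and
#' PTV1_periphery and SpinalCord (high-gradient: at the posterior PTV1
#' edge and inside the cord block shadow).
#'
#' @param phantom a [phantom_spec()].
#' @param roi_radius_mm dosimeter radius (default 3 mm).
#' @return data frame with columns `roi`, `x_mm`, `z_mm`, `radius_mm`,
#'   `gradient` (`"low"`/`"high"`).
#' @export
tld_rois <- function(phantom = default_phantom(), roi_radius_mm = 3) {
  p1 <- phantom$ptv1_center; p2 <- phantom$ptv2_center
  cc <- phantom$cord_center
  periph <- c(p1[1], p1[2] - phantom$ptv_radii_mm[1] + roi_radius_mm)
  out <- data.frame(
    roi = c("PTV1_center", "PTV1_periphery", "PTV2", "SpinalCord"),
    x_mm = c(p1[1], periph[1], p2[1], cc[1]),
    z_mm = c(p1[2], periph[2], p2[2], cc[2]),
    radius_mm = roi_radius_mm,
    gradient = c("low", "high", "low", "high"))
  if (anyDuplicated(out[, c("x_mm", "z_mm")]))
    stop("ROI centres must be pairwise distinct")
  r <- sqrt(out$x_mm^2 + out$z_mm^2) + roi_radius_mm
  if (any(r > phantom$radius_mm)) stop("ROI disks must lie inside phantom")
  out
}

# Sample points for a disk ROI: centre plus a hexagonal ring at 2/3 radius;
# the ROI dose is the mean over these points (small-volume mean dose).
.roi_sample_points <- function(x, z, radius_mm) {
  a <- seq(0, 2 * pi, length.out = 7)[-7]
  data.frame(x_mm = c(x, x + 2 / 3 * radius_mm * cos(a)),
             y_mm = 0,
             z_mm = c(z, z + 2 / 3 * radius_mm * sin(a)))
}

#' A single open (unmodulated) square field plan
#'
#' One anterior beam with a single fully open square aperture; used to
#' demonstrate that the leaf-tip model barely affects open fields while
#' strongly affecting modulated plans.
#'
#' @param size_mm side of the square field, mm.
#' @param mu monitor units.
#' @return A `treatment_plan` with one beam and one segment.
#' @export
open_field_plan <- function(size_mm = 100, mu = 100) {
  bank <- .bank_geometry()
  half <- size_mm / 2
  left <- right <- rep(bank$park_mm, bank$n_pairs)
  in_field <- bank$y_low >= -half - 1e-9 & bank$y_high <= half + 1e-9
  left[in_field] <- -half; right[in_field] <- half
  ap <- data.frame(pair_index = seq_len(bank$n_pairs),
                   y_low_mm = bank$y_low, y_high_mm = bank$y_high,
                   left_pos_mm = left, right_pos_mm = right)
  structure(list(plan_id = sprintf("OPEN%g", size_mm), technique = "open",
                 beams = list(list(gantry_deg = 0,
                                   segments = list(mlc_segment(ap, mu, 0)))),
                 total_mu = mu, spec = NULL),
            class = "treatment_plan")
}
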