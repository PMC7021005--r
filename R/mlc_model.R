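#' MLC beam-model parameters (double-step leaf-tip model)
#'
#' The leaf end is modeled as a double step in transmission: the open field
#' transmits 1, a tip region of width `leaf_tip_width_mm` starting at the
#' effective leaf edge transmits an intermediate fraction `tip_transmission`,
#' and the full leaf beyond the tip transmits the intraleaf leakage
#' `leaf_transmission`.  The effective edge is the nominal leaf position
#' shifted outward by `leaf_tip_offset_mm`: a positive offset retracts every
#' leaf and models an effectively larger field, a negative offset a smaller
#' field.
#'
#' The tip transmission is derived from the intraleaf transmission `T` by
#' `tip_rule`:
#' \describe{
#'   \item{`"sqrt"`}{`tau = sqrt(T)` (geometric mean of open and blocked,
#'     the default; keeps a genuine intermediate step `T < tau < 1`).}
#'   \item{`"literal"`}{`tau = T` (the tip region attenuates like the full
#'     leaf; the double step degenerates to a single step).}
#' }
#'
#' @param leaf_tip_offset_mm signed offset of the modeled tip from the
#'   nominal leaf position, mm; |offset| <= 5 mm.
#' @param leaf_tip_width_mm width of the partial-transmission tip region,
#'   mm, >= 0.
#' @param leaf_transmission intraleaf leakage fraction, in (0, 1).
#' @param tip_rule how the tip transmission is derived from
#'   `leaf_transmission`; see Details.
#' @param model_id label for the model; auto-generated from the parameters
#'   when omitted.
#' @return An object of class `beam_model` with fields
#'   `leaf_tip_offset_mm`, `leaf_tip_width_mm`, `leaf_transmission`,
#'   `tip_transmission`, `tip_rule`, `model_id`.
#' @examples
#' clinical <- beam_model(-0.5, 4.5)
#' clinical$tip_transmission   # sqrt(0.005)
#' @export
beam_model <- function(leaf_tip_offset_mm = 0, leaf_tip_width_mm = 4.5,
                       leaf_transmission = 0.005,
                       tip_rule = c("sqrt", "literal"),
                       model_id = NULL) {
  tip_rule <- match.arg(tip_rule)
  stopifnot(is.numeric(leaf_tip_offset_mm), length(leaf_tip_offset_mm) == 1,
            abs(leaf_tip_offset_mm) <= 5,
            is.numeric(leaf_tip_width_mm), leaf_tip_width_mm >= 0,
            leaf_transmission > 0, leaf_transmission < 1)
  tau <- switch(tip_rule, sqrt = sqrt(leaf_transmission),
                literal = leaf_transmission)
  stopifnot(tau >= leaf_transmission, tau <= 1)
  if (is.null(model_id))
    model_id <- sprintf("d%+.2f_w%.2f_%s", leaf_tip_offset_mm,
                        leaf_tip_width_mm, tip_rule)
  structure(list(leaf_tip_offset_mm = as.numeric(leaf_tip_offset_mm),
                 leaf_tip_width_mm = as.numeric(leaf_tip_width_mm),
                 leaf_transmission = as.numeric(leaf_transmission),
                 tip_transmission = tau,
                 tip_rule = tip_rule,
                 model_id = model_id),
            class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf(
    "<beam_model> %s: offset %+.2f mm, tip width %.2f mm, T %.4g, tau %.4g (%s)\n",
    x$model_id, x$leaf_tip_offset_mm, x$leaf_tip_width_mm,
    x$leaf_transmission, x$tip_transmission, x$tip_rule))
  invisible(x)
}

#' One leaf pair of an MLC aperture
#'
#' @param pair_index 1-based index of the pair within the bank.
#' @param y_low_mm,y_high_mm lateral extent of the pair (leaf-pair axis),
#'   `y_low_mm < y_high_mm`; the pitch is `y_high_mm - y_low_mm`.
#' @param left_pos_mm,right_pos_mm nominal tip positions along leaf travel
#'   (x); `left_pos_mm <= right_pos_mm`.
#' @return An object of class `leaf_pair`.
#' @export
leaf_pair <- function(pair_index, y_low_mm, y_high_mm,
                      left_pos_mm, right_pos_mm) {
  stopifnot(y_low_mm < y_high_mm, left_pos_mm <= right_pos_mm + 1e-12)
  structure(list(pair_index = as.integer(pair_index),
                 y_low_mm = as.numeric(y_low_mm),
                 y_high_mm = as.numeric(y_high_mm),
                 left_pos_mm = as.numeric(left_pos_mm),
                 right_pos_mm = as.numeric(right_pos_mm)),
            class = "leaf_pair")
}

#' A static MLC segment (control point)
#'
#' A segment is one static aperture delivered with a monitor-unit weight at
#' a fixed gantry angle.  Apertures are stored compactly as a data frame
#' with one row per leaf pair (`pair_index`, `y_low_mm`, `y_high_mm`,
#' `left_pos_mm`, `right_pos_mm`).
#'
#' @param aperture data frame of leaf-pair rows, or a list of [leaf_pair()]
#'   objects.
#' @param mu monitor units, >= 0.
#' @param gantry_deg gantry angle in degrees (0 = anterior, clockwise).
#' @param collimator_deg collimator angle (must be 0; rotations are not
#'   modeled).
#' @return An object of class `mlc_segment`.
#' @export
mlc_segment <- function(aperture, mu, gantry_deg, collimator_deg = 0) {
  if (is.list(aperture) && !is.data.frame(aperture))
    aperture <- do.call(rbind, lapply(aperture, function(p)
      data.frame(pair_index = p$pair_index, y_low_mm = p$y_low_mm,
                 y_high_mm = p$y_high_mm, left_pos_mm = p$left_pos_mm,
                 right_pos_mm = p$right_pos_mm)))
  stopifnot(is.data.frame(aperture),
            all(c("pair_index", "y_low_mm", "y_high_mm", "left_pos_mm",
                  "right_pos_mm") %in% names(aperture)),
            mu >= 0, collimator_deg == 0)
  if (anyDuplicated(aperture$pair_index))
    stop("each leaf pair must appear exactly once in a segment")
  if (any(aperture$left_pos_mm > aperture$right_pos_mm + 1e-9))
    stop("aperture has left_pos_mm > right_pos_mm")
  aperture <- aperture[order(aperture$pair_index), , drop = FALSE]
  rownames(aperture) <- NULL
  structure(list(aperture = aperture, mu = as.numeric(mu),
                 gantry_deg = as.numeric(gantry_deg),
                 collimator_deg = 0), class = "mlc_segment")
}

#' Effective leaf-tip edges under a beam model
#'
#' Applies the leaf-tip offset per bank: each tip retracts outward by the
#' offset, so the effective gap changes by twice the offset.  If the
#' effective gap would be negative the pair is clamped to a zero-width gap
#' centred at the nominal gap midpoint.
#'
#' @param pair a [leaf_pair()] (or any list with `left_pos_mm`,
#'   `right_pos_mm`).
#' @param model a [beam_model()].
#' @return numeric length-2 `c(left_eff_mm, right_eff_mm)`.
#' @examples
#' effective_edges(leaf_pair(1, -2.5, 2.5, -10, 10), beam_model(+1))
#' @export
effective_edges <- function(pair, model) {
  stopifnot(inherits(model, "beam_model"))
  d <- model$leaf_tip_offset_mm
  l <- pair$left_pos_mm - d
  r <- pair$right_pos_mm + d
  if (r < l) {
    mid <- (pair$left_pos_mm + pair$right_pos_mm) / 2
    l <- r <- mid
  }
  c(left_eff_mm = l, right_eff_mm = r)
}

# Single-leaf transmission profiles, vectorized over x.  The left leaf
# occupies x < left_eff: open (1) for x >= left_eff, tip (tau) within the
# tip width under the leaf, intraleaf leakage (T) beyond.
.left_leaf_profile <- function(x, left_eff, w, T, tau) {
  out <- rep(T, length(x))
  out[x >= left_eff - w] <- tau
  out[x >= left_eff] <- 1
  out
}

.right_leaf_profile <- function(x, right_eff, w, T, tau) {
  out <- rep(T, length(x))
  out[x <= right_eff + w] <- tau
  out[x <= right_eff] <- 1
  out
}

#' Transmission of one leaf pair at positions along leaf travel
#'
#' The pair transmission is the pointwise minimum of the two single-leaf
#' double-step profiles: a point attenuated by both tips cannot transmit
#' more than the more attenuating leaf.  Values lie in
#' `[leaf_transmission, 1]`.
#'
#' @param x_mm positions along leaf travel, mm (vectorized).
#' @param pair a [leaf_pair()].
#' @param model a [beam_model()].
#' @return numeric vector of transmissions, same length as `x_mm`.
#' @examples
#' p <- leaf_pair(1, -2.5, 2.5, -30, 30)
#' leaf_pair_transmission(c(-40, -32, 0, 40), p, beam_model(0, 4.5, 0.0049))
#' @export
leaf_pair_transmission <- function(x_mm, pair, model) {
  e <- effective_edges(pair, model)
  w <- model$leaf_tip_width_mm
  T <- model$leaf_transmission
  tau <- model$tip_transmission
  pmin(.left_leaf_profile(x_mm, e[1], w, T, tau),
       .right_leaf_profile(x_mm, e[2], w, T, tau))
}

#' Rasterize a segment aperture into a transmission map
#'
#' Each grid point takes the transmission of the leaf pair whose lateral
#' interval contains its y coordinate (intervals are left-closed: a point
#' on the boundary between two pairs belongs to the upper one).  Grid rows
#' lateral of the whole bank are treated as jaw-blocked and take the
#' full-leaf transmission.  The grid must cover the leaf bank (a bank
#' wider than the grid is a contract violation:
#' the MLC model does not define transmission there).
#'
#' @param segment an [mlc_segment()].
#' @param model a [beam_model()].
#' @param grid a [grid_spec()].
#' @return A [dose_map()] of transmissions in `[leaf_transmission, 1]`
#'   (MU is *not* applied; see [beam_fluence()]).
#' @export
segment_transmission_map <- function(segment, model, grid) {
  stopifnot(inherits(segment, "mlc_segment"), inherits(model, "beam_model"),
            inherits(grid, "grid_spec"))
  ap <- segment$aperture
  ax <- grid_axes(grid)
  # map each grid y to its pair row: pairs are contiguous intervals; grid
  # rows lateral of the whole bank sit under the backup jaws and take the
  # full-leaf transmission T
  lo <- ap$y_low_mm; hi <- ap$y_high_mm
  if (min(lo) < min(ax$y) - grid$spacing_mm ||
      max(hi) > max(ax$y) + grid$spacing_mm)
    stop("grid does not cover the leaf bank")
  idx <- findInterval(ax$y, c(lo[1], hi), rightmost.closed = TRUE)
  outside <- ax$y < min(lo) | ax$y > max(hi)
  idx[idx == 0L] <- 1L
  idx <- pmin(idx, nrow(ap))
  vals <- matrix(NA_real_, grid$nx, grid$ny)
  profs <- .pair_profiles(ap, model, ax$x)  # nx x npairs
  vals[] <- profs[, idx]
  vals[, outside] <- model$leaf_transmission
  dose_map(grid, vals)
}

# Transmission profiles for every pair of an aperture at the x samples:
# returns an nx x npairs matrix.  Vectorized over x per pair; the per-pair
# loop is over ~40 pairs and is not a bottleneck.
.pair_profiles <- function(aperture, model, x) {
  d <- model$leaf_tip_offset_mm
  w <- model$leaf_tip_width_mm
  T <- model$leaf_transmission
  tau <- model$tip_transmission
  l <- aperture$left_pos_mm - d
  r <- aperture$right_pos_mm + d
  closed <- r < l
  mid <- (aperture$left_pos_mm + aperture$right_pos_mm) / 2
  l[closed] <- mid[closed]; r[closed] <- mid[closed]
  n <- length(l)
  out <- matrix(T, length(x), n)
  for (k in seq_len(n)) {
    left <- .left_leaf_profile(x, l[k], w, T, tau)
    right <- .right_leaf_profile(x, r[k], w, T, tau)
    out[, k] <- pmin(left, right)
  }
  out
}
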