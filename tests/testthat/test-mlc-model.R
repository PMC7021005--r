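test_that("effective edges apply the offset per bank and clamp closed pairs", {
  p <- leaf_pair(1, -2.5, 2.5, -10, 10)
  expect_equal(unname(effective_edges(p, beam_model(0))), c(-10, 10))
  # +1 mm offset retracts each tip: 22 mm effective gap (larger field)
  expect_equal(unname(effective_edges(p, beam_model(1))), c(-11, 11))
  expect_equal(unname(effective_edges(p, beam_model(-1))), c(-9, 9))
  # a negative offset larger than the half-gap clamps to zero width at the
  # nominal midpoint
  q <- leaf_pair(1, -2.5, 2.5, -0.5, 0.5)
  expect_equal(unname(effective_edges(q, beam_model(-1))), c(0, 0))
  q2 <- leaf_pair(1, -2.5, 2.5, 4, 5)
  expect_equal(unname(effective_edges(q2, beam_model(-2))), c(4.5, 4.5))
})

test_that("tip transmission rules give a genuine double step", {
  m <- beam_model(0, 4.5, 0.0049, tip_rule = "sqrt")
  expect_equal(m$tip_transmission, 0.07)
  lit <- beam_model(0, 4.5, 0.0049, tip_rule = "literal")
  expect_equal(lit$tip_transmission, 0.0049)
  expect_error(beam_model(6), "5")
  expect_error(beam_model(0, leaf_transmission = 0))
})

test_that("pair transmission is open/tip/leakage with min combination", {
  m <- beam_model(0, 4.5, 0.005)
  p <- leaf_pair(1, -2.5, 2.5, -30, 30)
  expect_equal(leaf_pair_transmission(0, p, m), 1)
  # far under the right leaf: full-leaf leakage
  expect_equal(leaf_pair_transmission(30 + 4.5 + 0.1, p, m), 0.005)
  # inside the tip region
  m2 <- beam_model(0, 4.5, 0.0049)
  expect_equal(leaf_pair_transmission(-32, p, m2), 0.07)
  expect_equal(leaf_pair_transmission(32, p, m2), 0.07)
  # values always within [T, 1]
  x <- seq(-60, 60, by = 0.25)
  v <- leaf_pair_transmission(x, p, m2)
  expect_true(all(v >= 0.0049 & v <= 1))
})

test_that("closed pairs with overlapping tips match a two-leaf brute force", {
  m <- beam_model(-1, 6, 0.004)
  p <- leaf_pair(1, -2.5, 2.5, -0.5, 0.5)   # clamps fully closed
  x <- seq(-15, 15, by = 0.05)
  got <- leaf_pair_transmission(x, p, m)
  e <- effective_edges(p, m)
  # brute force: explicit min of the two single-leaf double steps
  left_prof <- ifelse(x >= e[1], 1, ifelse(x >= e[1] - 6, m$tip_transmission,
                                           m$leaf_transmission))
  right_prof <- ifelse(x <= e[2], 1, ifelse(x <= e[2] + 6, m$tip_transmission,
                                            m$leaf_transmission))
  expect_equal(got, pmin(left_prof, right_prof))
})

test_that("zero width and zero offset reduce to a binary aperture", {
  m0 <- beam_model(0, 0, 0.005)
  p <- leaf_pair(1, -2.5, 2.5, -10, 10)
  x <- seq(-30, 30, by = 0.5)
  v <- leaf_pair_transmission(x, p, m0)
  expect_true(all(v %in% c(0.005, 1)))
  expect_equal(v, ifelse(x >= -10 & x <= 10, 1, 0.005))
})

test_that("rasterized maps match the scalar per-point oracle", {
  set.seed(42)
  g <- small_grid(30, 3)
  for (i in 1:5) {
    ap <- random_aperture()
    m <- beam_model(runif(1, -2, 2), runif(1, 0, 6), 0.005)
    seg <- mlc_segment(ap, 1, 0)
    expect_equal(segment_transmission_map(seg, m, g)$values,
                 transmission_map_oracle(seg, m, g), tolerance = 1e-12)
  }
})

test_that("transmission maps are pointwise non-decreasing in the offset", {
  set.seed(7)
  g <- small_grid(40, 2)
  for (i in 1:5) {
    seg <- mlc_segment(random_aperture(), 1, 0)
    prev <- NULL
    for (d in seq(-1, 1, by = 0.25)) {
      v <- segment_transmission_map(seg, beam_model(d, 4.5), g)$values
      if (!is.null(prev)) expect_true(all(v >= prev - 1e-12))
      prev <- v
    }
  }
})

test_that("width changes act only inside tip regions", {
  g <- small_grid(40, 1)
  ap <- rect_aperture(-20, 10)
  m1 <- beam_model(-0.5, 2.5)
  m2 <- beam_model(-0.5, 6.0)
  v1 <- segment_transmission_map(mlc_segment(ap, 1, 0), m1, g)$values
  v2 <- segment_transmission_map(mlc_segment(ap, 1, 0), m2, g)$values
  ax <- grid_axes(g)
  # outside the widest tip region both maps agree exactly
  outside <- ax$x >= -19.5 + 0 & ax$x <= 9.5 |        # open interior
    ax$x < -19.5 - 6 | ax$x > 9.5 + 6                  # beyond both tips
  expect_equal(v1[outside, ], v2[outside, ])
  expect_false(isTRUE(all.equal(v1, v2)))
})

test_that("segment construction validates its aperture", {
  ap <- rect_aperture()
  bad <- ap; bad$left_pos_mm[2] <- bad$right_pos_mm[2] + 5
  expect_error(mlc_segment(bad, 10, 0), "left_pos_mm")
  dup <- rbind(ap, ap[1, ])
  expect_error(mlc_segment(dup, 10, 0), "exactly once")
  expect_error(mlc_segment(ap, -1, 0))
})
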