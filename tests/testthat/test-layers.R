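test_that("annulus partition matches analytic ring areas", {
  sl <- generate_annulus_slice(annulus_spec(c(220, 220), 100, 200,
                                            trabecular_depth = 20,
                                            epicardial_rim = 20))
  part <- assign_layers(sl$roi, 441, 441)
  expect_true(part$midline_feasible)
  lab <- part$labels
  analytic <- c(
    trabecular = pi * (120^2 - 100^2),
    epicardium = pi * (200^2 - 180^2),
    inner_compact = pi * (150^2 - 120^2),
    outer_compact = pi * (180^2 - 150^2)
  )
  for (ly in names(analytic)) {
    expect_lt(abs(sum(lab == ly) - analytic[[ly]]) / analytic[[ly]], 0.01)
  }
  # partition property: layer counts sum to the ROI pixel count
  roi_px <- sum(polygon_mask(sl$roi$outline$outer, 441, 441) &
                  !polygon_mask(sl$roi$outline$inner, 441, 441))
  expect_equal(sum(lab != "background"), roi_px)
})

test_that("the equidistant midline is equidistant and splits exactly", {
  sl <- generate_annulus_slice(annulus_spec(c(210, 210), 100, 200))
  part <- assign_layers(sl$roi, 421, 421)
  compact <- part$labels %in% c("inner_compact", "outer_compact")
  epi_b <- rasterize_polyline(sl$roi$epicardial_boundary, 421, 421)
  trab_b <- rasterize_polyline(sl$roi$trabecular_boundary, 421, 421)
  sp <- split_compact(matrix(compact, 421, 421), epi_b, trab_b)
  # midline pixels: |d_epi - d_trab| <= 1 px
  expect_true(all(abs((sp$d_epi - sp$d_trab)[part$midline]) <= 1))
  # mean midline radius within 0.5 px of the analytic value
  idx <- which(part$midline, arr.ind = TRUE)
  rad <- sqrt((idx[, 1] - 1 - 210)^2 + (idx[, 2] - 1 - 210)^2)
  expect_lt(abs(mean(rad) - 150), 0.5)
  # inner + outer partition the compact mask exactly
  expect_equal(sum(sp$inner) + sum(sp$outer), sum(compact))
  expect_false(any(sp$inner & sp$outer))
  # analytic half-ring areas within 2%
  expect_lt(abs(sum(sp$inner) - pi * (150^2 - 100^2)) / (pi * (150^2 - 100^2)), 0.02)
  expect_lt(abs(sum(sp$outer) - pi * (200^2 - 150^2)) / (pi * (200^2 - 150^2)), 0.02)
})

test_that("degenerate thin walls are handled without crashing", {
  # 2 px wall: every pixel near both boundaries, fallback triggered
  sl <- generate_annulus_slice(annulus_spec(c(110, 110), 98, 101))
  part <- assign_layers(sl$roi, 221, 221)
  expect_false(part$midline_feasible)
  expect_match(part$status, "thickness")
  expect_true(any(part$labels == "compact"))

  # trabecular boundary equal to epicardial boundary: empty compact, flagged
  ring <- circle_polygon(c(60, 60), 40)
  roi <- section_roi(list(outer = circle_polygon(c(60, 60), 55),
                          inner = circle_polygon(c(60, 60), 20)),
                     epicardial_boundary = ring, trabecular_boundary = ring)
  part2 <- assign_layers(roi, 121, 121)
  expect_false(part2$midline_feasible)
  expect_match(part2$status, "degenerate")

  # crossing boundaries raise a diagnostic error
  roi3 <- section_roi(list(outer = circle_polygon(c(60, 60), 55)),
                      epicardial_boundary = circle_polygon(c(60, 60), 30),
                      trabecular_boundary = circle_polygon(c(60, 60), 45))
  expect_error(assign_layers(roi3, 121, 121), "cross")
})

test_that("septal sections have no epicardium and trigger the fallback", {
  roi <- section_roi(
    outline = list(outer = circle_polygon(c(110, 110), 100),
                   inner = circle_polygon(c(110, 110), 40)),
    trabecular_boundary = circle_polygon(c(110, 110), 60),
    has_epicardium = FALSE, section_id = "septum")
  part <- assign_layers(roi, 221, 221)
  expect_false(part$midline_feasible)
  expect_equal(sum(part$labels == "epicardium"), 0)
  expect_setdiff <- setdiff(unique(as.character(part$labels)),
                            c("background", "compact", "trabecular"))
  expect_length(expect_setdiff, 0)
})

test_that("fallback copies the whole-myocardium value into both compact layers", {
  roi <- section_roi(
    outline = list(outer = circle_polygon(c(60, 60), 55),
                   inner = circle_polygon(c(60, 60), 15)),
    trabecular_boundary = circle_polygon(c(60, 60), 30),
    has_epicardium = FALSE, section_id = "septum")
  part <- assign_layers(roi, 121, 121)
  fr <- tibble::tibble(
    layer = c("trabecular", "compact"),
    connective_pct = c(12, 12),
    myocyte_pct = c(80, 80),
    adipose_pct = c(8, 8),
    analyzed_area_px = c(1000L, 3000L),
    denominator_mode = "tissue"
  )
  out <- apply_fallback(part, fr)
  inner <- out[out$layer == "inner_compact", ]
  outer <- out[out$layer == "outer_compact", ]
  expect_equal(inner$connective_pct, 12)
  expect_equal(outer$connective_pct, 12)
  expect_equal(inner$provenance, "fallback")
  expect_equal(outer$provenance, "fallback")

  # feasible partitions pass through unchanged
  sl <- generate_annulus_slice(annulus_spec(c(110, 110), 50, 100))
  pf <- assign_layers(sl$roi, 221, 221)
  fr2 <- tibble::tibble(layer = c("trabecular", "inner_compact", "outer_compact"),
                        connective_pct = c(10, 20, 30),
                        myocyte_pct = c(85, 75, 65),
                        adipose_pct = c(5, 5, 5),
                        analyzed_area_px = c(100L, 200L, 300L),
                        denominator_mode = "tissue")
  out2 <- apply_fallback(pf, fr2)
  expect_equal(out2$connective_pct, fr2$connective_pct)
  expect_true(all(out2$provenance == "measured"))
})

test_that("layer areas are invariant under rigid motion of the section", {
  base <- generate_annulus_slice(annulus_spec(c(130, 130), 60, 120,
                                              trabecular_depth = 10,
                                              epicardial_rim = 10))
  p1 <- assign_layers(base$roi, 261, 261)
  # translate by (15, -9)
  shift <- function(p) cbind(p[, 1] + 15, p[, 2] - 9)
  roi2 <- section_roi(
    outline = list(outer = shift(base$roi$outline$outer),
                   inner = shift(base$roi$outline$inner)),
    epicardial_boundary = shift(base$roi$epicardial_boundary),
    trabecular_boundary = shift(base$roi$trabecular_boundary))
  p2 <- assign_layers(roi2, 291, 261)
  for (ly in c("trabecular", "inner_compact", "outer_compact", "epicardium")) {
    a1 <- sum(p1$labels == ly); a2 <- sum(p2$labels == ly)
    expect_lt(abs(a1 - a2) / a1, 0.005)
  }
})

test_that("distance transform agrees with a brute-force nearest point search", {
  set.seed(8)
  target <- matrix(FALSE, 30, 30)
  target[cbind(sample(30, 6), sample(30, 6))] <- TRUE
  d <- distance_to(target)
  pts <- which(target, arr.ind = TRUE)
  for (i in seq(1, 30, by = 7)) for (j in seq(1, 30, by = 7)) {
    bf <- sqrt(min((i - pts[, 1])^2 + (j - pts[, 2])^2))
    expect_equal(d[i, j], bf, tolerance = 1e-9)
  }
})
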