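test_that("the region scheme partitions the circle into 8 contiguous spans", {
  sc <- region_scheme()
  expect_equal(sort(sc$region_id), 1:8)
  deg <- 0:359
  rid <- sapply(deg, function(d) {
    sc$region_id[sc$start_deg <= d & d < sc$end_deg]
  })
  expect_true(all(lengths(rid) == 1))
  expect_setequal(unique(unlist(rid)), 1:8)
  # spans contiguous: sorted by angle, each starts where the previous ends
  by_angle <- sc[order(sc$start_deg), ]
  expect_equal(by_angle$start_deg[-1], by_angle$end_deg[-8])
  expect_error(region_scheme(360), "rv_start_deg")
})

test_that("degenerate layouts assign degrees by symmetry", {
  center <- c(0, 0)
  full <- slice_layout(tibble::tibble(
    section_id = "A", ventricle = "LV",
    polygon = list(wedge_polygon(center, 40, 90, 0, 360, n = 256))), center)
  asg <- angular_assignment(full)
  expect_true(all(asg$section_id == "A"))

  halves <- slice_layout(tibble::tibble(
    section_id = c("A", "B"), ventricle = c("LV", "RV"),
    polygon = list(wedge_polygon(center, 40, 90, 0, 180),
                   wedge_polygon(center, 40, 90, 180, 360))), center)
  asg2 <- angular_assignment(halves)
  # degrees exactly on the cut (0, 180) may land on either shared edge
  expect_true(all(asg2$section_id[asg2$degree %in% 1:179] == "A"))
  expect_true(all(asg2$section_id[asg2$degree %in% 181:359] == "B"))
})

test_that("angular assignment agrees with a point-in-polygon oracle", {
  lay <- make_wedge_layout(seed = 31)
  asg <- angular_assignment(lay)
  expect_equal(sum(!is.na(asg$section_id)), 360)
  oracle <- vapply(0:359, function(d) {
    u <- ray_direction(d + 0.0, lay$angular_zero)
    pt <- matrix(lay$center + 75 * u, 1)
    hit <- which(vapply(lay$sections$polygon, function(p) {
      mgcv::in.out(rbind(p, p[1, ]), pt)
    }, logical(1)))
    if (length(hit)) lay$sections$section_id[hit[1]] else NA_character_
  }, character(1))
  ok <- !is.na(oracle)
  expect_gt(mean(ok), 0.98) # oracle points can sit exactly on a cut edge
  expect_equal(asg$section_id[ok], oracle[ok])
})

test_that("annotation validates section identity", {
  lay <- make_wedge_layout(seed = 3)
  fr <- make_fractions_table(lay)
  ann <- annotate_sections(fr, lay)
  expect_equal(nrow(ann), nrow(fr))
  expect_true(all(c("ventricle", "polygon") %in% names(ann)))

  # an 11-section layout carries 11 annotated placements
  center <- c(0, 0)
  cuts <- seq(0, 360, length.out = 12)
  lay11 <- slice_layout(tibble::tibble(
    section_id = paste0("sl", 1:11),
    ventricle = c(rep("LV", 8), rep("RV", 3)),
    polygon = lapply(1:11, function(i) {
      wedge_polygon(center, 40, 90, cuts[i], cuts[i + 1])
    })), center)
  fr11 <- tibble::tibble(section_id = paste0("sl", 1:11), layer = "trabecular",
                         connective_pct = 1:11, adipose_pct = 0,
                         myocyte_pct = 99 - 1:11, analyzed_area_px = 100L)
  expect_equal(nrow(annotate_sections(fr11, lay11)), 11)

  fr_bad <- dplyr::mutate(fr, section_id = sub("S1$", "S99", .data$section_id))
  expect_error(annotate_sections(fr_bad, lay), "S99")
  expect_error(slice_layout(tibble::tibble(
    section_id = c("A", "A"), ventricle = "LV",
    polygon = list(diag(2), diag(2))), c(0, 0)), "duplicate")
})

test_that("region summaries are area-weighted and self-consistent", {
  center <- c(0, 0)
  # constant field: every region reports the constant
  lay <- make_wedge_layout(seed = 7)
  fr <- make_fractions_table(lay)
  frc <- dplyr::mutate(fr, connective_pct = 10, adipose_pct = 10)
  sch <- slice_schematic(frc, lay)
  reg <- summarize_regions(sch)
  expect_true(all(abs(reg$value - 10) < 1e-9))

  # two sections, values 10 and 30, areas 1 and 3: weighted mean 25
  lay2 <- slice_layout(tibble::tibble(
    section_id = c("A", "B"), ventricle = c("LV", "LV"),
    polygon = list(wedge_polygon(center, 40, 90, 0, 180),
                   wedge_polygon(center, 40, 90, 180, 360))), center)
  fr2 <- tibble::tibble(section_id = c("A", "B"), layer = "trabecular",
                        connective_pct = c(10, 30), adipose_pct = c(0, 0),
                        myocyte_pct = c(90, 70),
                        analyzed_area_px = c(1L, 3L))
  sch2 <- slice_schematic(fr2, lay2, layers = "trabecular")
  reg2 <- summarize_regions(sch2)
  both <- reg2[reg2$measure == "connective_pct" & !is.na(reg2$value), ]
  # regions straddling the A/B cut see both sections: weighted mean 25
  expect_true(any(abs(both$value - 25) < 1e-12))

  # independent recomputation from the raw table
  sch3 <- slice_schematic(fr, lay)
  reg3 <- summarize_regions(sch3)
  deg <- angular_assignment(lay)
  deg$region_id <- NA_integer_
  sc <- sch3$scheme
  for (i in 1:8) {
    span <- deg$degree >= sc$start_deg[i] & deg$degree < sc$end_deg[i]
    deg$region_id[span] <- sc$region_id[i]
  }
  for (rid in 1:8) {
    secs <- unique(deg$section_id[deg$region_id == rid])
    sub <- fr[fr$section_id %in% secs, ]
    expected <- sum(sub$connective_pct * sub$analyzed_area_px) /
      sum(sub$analyzed_area_px)
    got <- reg3$value[reg3$region_id == rid & reg3$measure == "connective_pct"]
    expect_equal(got, expected, tolerance = 1e-12)
  }

  # aggregation consistency: region means weighted by region area equal the
  # global weighted mean over (region, section) incidence pairs
  r3 <- reg3[reg3$measure == "connective_pct", ]
  global <- sum(r3$value * r3$area) / sum(r3$area)
  incidence <- dplyr::distinct(deg[!is.na(deg$section_id), ],
                               .data$region_id, .data$section_id)
  pairs <- dplyr::inner_join(incidence, fr, by = "section_id",
                             relationship = "many-to-many")
  expect_equal(global,
               sum(pairs$connective_pct * pairs$analyzed_area_px) /
                 sum(pairs$analyzed_area_px),
               tolerance = 1e-12)
})

test_that("schematic rendering is deterministic and flags missing data", {
  lay <- make_wedge_layout(seed = 13)
  fr <- make_fractions_table(lay)
  sch <- slice_schematic(fr, lay)
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  write_schematic_svg(sch, "connective_pct", f1)
  write_schematic_svg(sch, "connective_pct", f2)
  expect_identical(readLines(f1), readLines(f2))

  # a layout hole renders in the designated missing colour
  center <- c(0, 0)
  partial <- slice_layout(tibble::tibble(
    section_id = "A", ventricle = "LV",
    polygon = list(wedge_polygon(center, 40, 90, 0, 300))), center)
  frp <- tibble::tibble(section_id = "A", layer = "trabecular",
                        connective_pct = 50, adipose_pct = 5,
                        myocyte_pct = 45, analyzed_area_px = 10L)
  expect_warning(schp <- slice_schematic(frp, partial, layers = "trabecular"),
                 "no section")
  f3 <- withr::local_tempfile(fileext = ".svg")
  write_schematic_svg(schp, "connective_pct", f3)
  expect_true(any(grepl("#BBBBBB", readLines(f3), fixed = TRUE)))

  expect_error(write_schematic_svg(sch, "nope", tempfile()), "unknown measure")
  expect_s3_class(autoplot(sch), "ggplot")
})
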