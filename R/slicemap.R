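# Angular convention: degrees are measured clockwise (as seen on screen, with
# y pointing down) from the layout's angular zero direction, which defaults to
# "up" (anterior). All of it is configurable on the layout.

#' Unit direction vector for a schematic degree
#'
#' @param deg Angle in degrees, clockwise from `zero`.
#' @param zero Length-2 zero-direction vector (default up = anterior).
#' @return Length-2 unit vector in pixel coordinates (y down).
#' @export
ray_direction <- function(deg, zero = c(0, -1)) {
  a <- deg * pi / 180
  z <- zero / sqrt(sum(zero^2))
  c(z[1] * cos(a) - z[2] * sin(a), z[1] * sin(a) + z[2] * cos(a))
}

#' Annular wedge polygon
#'
#' Convenience constructor for section placements: the area between two radii
#' over a degree span, in the schematic's angular convention.
#'
#' @param center (x, y) centre.
#' @param r_inner,r_outer Radii (px); `r_inner = 0` gives a circular sector.
#' @param deg_start,deg_end Degree span (clockwise from `zero`).
#' @param zero Zero direction.
#' @param n Vertices per arc.
#' @return `m x 2` polygon matrix.
#' @export
wedge_polygon <- function(center, r_inner, r_outer, deg_start, deg_end,
                          zero = c(0, -1), n = 64L) {
  degs <- seq(deg_start, deg_end, length.out = n)
  dirs <- t(vapply(degs, ray_direction, numeric(2), zero = zero))
  outer_arc <- cbind(center[1] + r_outer * dirs[, 1],
                     center[2] + r_outer * dirs[, 2])
  out <- if (r_inner > 0) {
    inner_arc <- cbind(center[1] + r_inner * dirs[, 1],
                       center[2] + r_inner * dirs[, 2])
    rbind(outer_arc, inner_arc[rev(seq_len(n)), ])
  } else {
    rbind(matrix(center, 1, 2), outer_arc)
  }
  colnames(out) <- c("x", "y")
  out
}

#' Slice layout: section placements on the transverse heart map
#'
#' @param sections Tibble/data frame with columns `section_id`, `ventricle`
#'   (`"LV"`, `"RV"` or `"septum"`), and `polygon` (list column of `n x 2`
#'   placement polygons in map coordinates).
#' @param center (x, y) of the "middle of the ventricles"; all angular
#'   properties are measured from here.
#' @param angular_zero Zero-direction vector (default up = anterior),
#'   clockwise-positive.
#' @return List of class `fq_slice_layout`.
#' @export
slice_layout <- function(sections, center, angular_zero = c(0, -1)) {
  sections <- tibble::as_tibble(sections)
  req <- c("section_id", "ventricle", "polygon")
  if (!all(req %in% names(sections))) {
    fq_validation_error("layout sections need columns: %s", paste(req, collapse = ", "))
  }
  if (anyDuplicated(sections$section_id)) {
    fq_validation_error("duplicate section_id in layout: %s",
                        paste(unique(sections$section_id[duplicated(sections$section_id)]),
                              collapse = ", "))
  }
  structure(list(sections = sections, center = as.numeric(center),
                 angular_zero = as.numeric(angular_zero)),
            class = "fq_slice_layout")
}

#' Anatomical region scheme (6 LV + 2 RV regions)
#'
#' Partitions the 360 schematic degrees into the eight anatomical regions:
#' six left-ventricular sectors (anterior, anterolateral, lateral,
#' posterolateral, posterior, septal) of equal width over the LV span and two
#' right-ventricular sectors (posterior, anterior) over the remainder. Region
#' ids follow the conventional legend ordering: 1 LV posterolateral, 2 LV
#' posterior, 3 septum, 4 LV anterior, 5 LV anterolateral, 6 LV lateral,
#' 7 RV posterior, 8 RV anterior. The degree boundaries are operator-defined
#' anatomy, so the RV span is configurable.
#'
#' @param rv_start_deg Degree at which the right ventricle span begins; the
#'   LV occupies `[0, rv_start_deg)`, the RV `[rv_start_deg, 360)`.
#' @return Tibble with `region_id`, `name`, `ventricle`, `start_deg`,
#'   `end_deg` (spans are half-open `[start, end)`).
#' @export
region_scheme <- function(rv_start_deg = 240) {
  if (rv_start_deg <= 0 || rv_start_deg >= 360) {
    fq_validation_error("rv_start_deg must be in (0, 360)")
  }
  lv_names <- c("LV anterior", "LV anterolateral", "LV lateral",
                "LV posterolateral", "LV posterior", "septum")
  lv_edges <- seq(0, rv_start_deg, length.out = 7L)
  rv_names <- c("RV posterior", "RV anterior")
  rv_edges <- seq(rv_start_deg, 360, length.out = 3L)
  tbl <- tibble::tibble(
    name = c(lv_names, rv_names),
    ventricle = c(rep("LV", 5), "septum", "RV", "RV"),
    start_deg = c(lv_edges[1:6], rv_edges[1:2]),
    end_deg = c(lv_edges[2:7], rv_edges[2:3])
  )
  id_of <- c("LV posterolateral" = 1L, "LV posterior" = 2L, "septum" = 3L,
             "LV anterior" = 4L, "LV anterolateral" = 5L, "LV lateral" = 6L,
             "RV posterior" = 7L, "RV anterior" = 8L)
  tbl$region_id <- unname(id_of[tbl$name])
  dplyr::arrange(tbl[, c("region_id", "name", "ventricle", "start_deg", "end_deg")],
                 .data$region_id)
}

region_of_degree <- function(scheme, degrees) {
  out <- rep(NA_integer_, length(degrees))
  for (i in seq_len(nrow(scheme))) {
    hit <- degrees >= scheme$start_deg[i] & degrees < scheme$end_deg[i]
    out[hit] <- scheme$region_id[i]
  }
  out
}

# minimum positive ray-polygon entry distance (Inf when the ray misses)
ray_entry <- function(center, u, poly) {
  p1 <- poly
  p2 <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  d <- p2 - p1
  b1 <- p1[, 1] - center[1]
  b2 <- p1[, 2] - center[2]
  det <- u[2] * d[, 1] - u[1] * d[, 2]
  ok <- abs(det) > 1e-12
  t <- (b2 * d[, 1] - b1 * d[, 2]) / det
  s <- (u[1] * b2 - u[2] * b1) / det
  # small tolerance on the segment parameter so rays through a vertex are not
  # lost between two adjacent edges; double hits are harmless (min t wins)
  hit <- ok & t >= 0 & s >= -1e-9 & s <= 1 + 1e-9
  if (any(hit)) min(t[hit]) else Inf
}

#' Assign every schematic degree to a section
#'
#' Casts a ray from the layout centre at each integer degree and assigns the
#' degree to the section whose placement the ray enters first (smallest entry
#' distance). For rays that cross both ventricular walls this nearest-wall
#' rule selects the wall belonging to the ray's own sector. Degrees hitting
#' no placement are marked missing with a warning.
#'
#' @param layout A [slice_layout()].
#' @return Tibble with `degree` (0-359) and `section_id` (`NA` = missing).
#' @export
angular_assignment <- function(layout) {
  stopifnot(inherits(layout, "fq_slice_layout"))
  secs <- layout$sections
  out <- character(360L)
  for (d in 0:359) {
    u <- ray_direction(d, layout$angular_zero)
    ts <- vapply(secs$polygon, function(p) ray_entry(layout$center, u, as.matrix(p)),
                 numeric(1))
    out[d + 1L] <- if (all(is.infinite(ts))) NA_character_ else
      secs$section_id[which.min(ts)]
  }
  if (anyNA(out)) {
    warning(sprintf("%d degree bins hit no section placement", sum(is.na(out))))
  }
  tibble::tibble(degree = 0:359, section_id = out)
}

#' Join per-section values onto the slice layout
#'
#' Validates that every quantified section has a placement and vice versa.
#'
#' @param fractions Per-section (per-layer) tibble with a `section_id` column.
#' @param layout A [slice_layout()].
#' @return The fractions joined with `ventricle` and the placement polygon.
#' @export
annotate_sections <- function(fractions, layout) {
  stopifnot(inherits(layout, "fq_slice_layout"))
  miss <- setdiff(unique(fractions$section_id), layout$sections$section_id)
  if (length(miss) > 0) {
    fq_validation_error("sections missing from layout: %s",
                        paste(miss, collapse = ", "))
  }
  dplyr::inner_join(fractions, layout$sections, by = "section_id")
}

#' Build the standardized circular slice schematic
#'
#' Transforms per-section per-layer percentages into the per-degree schematic:
#' every integer degree is assigned to a section by ray casting from the
#' ventricular centre, to an anatomical region by the region scheme, and
#' carries that section's layer values for each measure. The epicardium is
#' excluded by construction.
#'
#' @param fractions Per-section per-layer tibble (from [quantify_section()] /
#'   [fq_quantify()]).
#' @param layout A [slice_layout()].
#' @param scheme A [region_scheme()].
#' @param measures Value columns to carry (default fibrosis + adipose).
#' @param layers Layers shown as rings, innermost first. The epicardium is
#'   not allowed here.
#' @return Object of class `fq_slice_schematic` with tibbles `degrees`
#'   (degree, section_id, region_id) and `values` (degree, layer, measure,
#'   value), plus the inputs.
#' @export
slice_schematic <- function(fractions, layout, scheme = region_scheme(),
                            measures = c("connective_pct", "adipose_pct"),
                            layers = c("trabecular", "inner_compact",
                                       "outer_compact")) {
  if ("epicardium" %in% layers) {
    fq_validation_error("the epicardium is excluded from the schematic")
  }
  annotate_sections(dplyr::distinct(fractions, .data$section_id), layout)
  assign <- angular_assignment(layout)
  assign$region_id <- region_of_degree(scheme, assign$degree)
  vals <- fractions |>
    dplyr::filter(.data$layer %in% layers) |>
    dplyr::select(dplyr::all_of(c("section_id", "layer", measures))) |>
    tidyr::pivot_longer(dplyr::all_of(measures), names_to = "measure",
                        values_to = "value")
  values <- tidyr::expand_grid(degree = 0:359, layer = layers,
                               measure = measures) |>
    dplyr::left_join(assign[, c("degree", "section_id")], by = "degree") |>
    dplyr::left_join(vals, by = c("section_id", "layer", "measure")) |>
    dplyr::select(dplyr::all_of(c("degree", "layer", "measure",
                                  "section_id", "value")))
  structure(list(
    degrees = assign, values = values, fractions = fractions,
    layout = layout, scheme = scheme, layers = layers, measures = measures
  ), class = "fq_slice_schematic")
}

#' Area-weighted per-region summaries
#'
#' For each of the eight anatomical regions, computes the area-weighted mean
#' of each measure over the (section, layer) pairs whose section intersects
#' the region's degree span, weighting by the analyzed area of each pair.
#' This is the surface-area correction used before the repeated-measures
#' analysis.
#'
#' @param schematic A [slice_schematic()].
#' @param layers Layers to include (default: the schematic's layers; the
#'   epicardium is never included).
#' @return Tibble with `region_id`, `name`, `measure`, `value` (`NA` for
#'   regions containing no section), and `area` (total weight).
#' @export
summarize_regions <- function(schematic, layers = NULL) {
  stopifnot(inherits(schematic, "fq_slice_schematic"))
  if (is.null(layers)) layers <- schematic$layers
  if ("epicardium" %in% layers) {
    fq_validation_error("the epicardium is excluded from analysis")
  }
  incidence <- schematic$degrees |>
    dplyr::filter(!is.na(.data$section_id)) |>
    dplyr::distinct(.data$region_id, .data$section_id)
  fr <- schematic$fractions |>
    dplyr::filter(.data$layer %in% layers) |>
    dplyr::select(dplyr::all_of(c("section_id", "layer", "analyzed_area_px",
                                  schematic$measures))) |>
    tidyr::pivot_longer(dplyr::all_of(schematic$measures),
                        names_to = "measure", values_to = "value")
  out <- incidence |>
    dplyr::inner_join(fr, by = "section_id",
                      relationship = "many-to-many") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$region_id, .data$measure) |>
    dplyr::summarise(
      value = sum(.data$value * .data$analyzed_area_px) / sum(.data$analyzed_area_px),
      area = sum(.data$analyzed_area_px), .groups = "drop"
    )
  full <- tidyr::expand_grid(region_id = schematic$scheme$region_id,
                             measure = schematic$measures)
  full |>
    dplyr::left_join(schematic$scheme[, c("region_id", "name")], by = "region_id") |>
    dplyr::left_join(out, by = c("region_id", "measure")) |>
    dplyr::arrange(.data$region_id, .data$measure)
}

# 0-100% colour ramp (blue -> yellow -> red), plus grey for missing data
schematic_palette <- function() {
  grDevices::colorRampPalette(c("#313695", "#4575B4", "#74ADD1", "#FFFFBF",
                                "#F46D43", "#D73027", "#A50026"))(101)
}

#' Write the circular schematic as a deterministic SVG
#'
#' Concentric rings are the myocardial layers (innermost ring = trabecular,
#' outermost = outer compact; the epicardium is absent), 360 angular bins,
#' colour scale 0-100% with a printed legend. The output is assembled with
#' fixed-precision formatting, so identical inputs yield byte-identical
#' files.
#'
#' @param schematic A [slice_schematic()].
#' @param measure One of the schematic's measures.
#' @param path Output file.
#' @param palette Vector of 101 colours for 0-100%.
#' @param missing_color Fill for degree bins with no data.
#' @param comment Optional comment embedded in the SVG (e.g. config hash).
#' @return `path`, invisibly.
#' @export
write_schematic_svg <- function(schematic, measure, path,
                                palette = schematic_palette(),
                                missing_color = "#BBBBBB", comment = NULL) {
  stopifnot(inherits(schematic, "fq_slice_schematic"))
  if (!measure %in% schematic$measures) {
    fq_validation_error("unknown measure '%s'", measure)
  }
  layers <- schematic$layers
  nl <- length(layers)
  r0 <- 40; ring_w <- 25
  cx <- 150; cy <- 140
  vals <- schematic$values |>
    dplyr::filter(.data$measure == !!measure)
  fmt <- function(x) sprintf("%.3f", x)
  wedge_path <- function(ra, rb, d) {
    a0 <- (d - 90) * pi / 180; a1 <- (d + 1 - 90) * pi / 180
    p <- function(r, a) paste0(fmt(cx + r * cos(a)), ",", fmt(cy + r * sin(a)))
    paste0("M", p(ra, a0), " L", p(rb, a0),
           " A", fmt(rb), ",", fmt(rb), " 0 0 1 ", p(rb, a1),
           " L", p(ra, a1),
           " A", fmt(ra), ",", fmt(ra), " 0 0 0 ", p(ra, a0), " Z")
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"300\" height=\"320\" viewBox=\"0 0 300 320\">",
    if (!is.null(comment)) paste0("<!-- ", comment, " -->"),
    "<rect width=\"300\" height=\"320\" fill=\"white\"/>"
  )
  for (li in seq_len(nl)) {
    ra <- r0 + (li - 1) * ring_w
    rb <- ra + ring_w
    lv <- vals[vals$layer == layers[li], ]
    lv <- lv[order(lv$degree), ]
    fills <- ifelse(is.na(lv$value), missing_color,
                    palette[pmin(100, pmax(0, round(lv$value))) + 1L])
    for (d in 0:359) {
      lines <- c(lines, paste0(
        "<path d=\"", wedge_path(ra, rb, d), "\" fill=\"", fills[d + 1L],
        "\" stroke=\"none\"/>"))
    }
  }
  # legend: 0-100% gradient bar
  for (i in 0:100) {
    lines <- c(lines, paste0(
      "<rect x=\"", fmt(50 + i * 2), "\" y=\"290\" width=\"2\" height=\"12\" fill=\"",
      palette[i + 1L], "\"/>"))
  }
  lines <- c(lines,
    "<text x=\"50\" y=\"285\" font-size=\"10\" font-family=\"sans-serif\">0%</text>",
    "<text x=\"235\" y=\"285\" font-size=\"10\" font-family=\"sans-serif\">100%</text>",
    paste0("<text x=\"150\" y=\"18\" font-size=\"12\" text-anchor=\"middle\" ",
           "font-family=\"sans-serif\">", measure, "</text>"),
    "</svg>")
  writeLines(lines, path)
  invisible(path)
}

#' Plot a slice schematic with ggplot2
#'
#' @param object A [slice_schematic()].
#' @param measure Measure to display (default: the first).
#' @param ... Unused.
#' @return A ggplot object (polar heat rings; innermost = trabecular).
#' @export
autoplot.fq_slice_schematic <- function(object, measure = object$measures[1],
                                        ...) {
  df <- dplyr::filter(object$values, .data$measure == !!measure)
  df$ring <- match(df$layer, object$layers)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$degree, xmax = .data$degree + 1,
      ymin = .data$ring, ymax = .data$ring + 1, fill = .data$value)) +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::scale_fill_gradientn(colours = schematic_palette(),
                                  limits = c(0, 100), name = "%",
                                  na.value = "#BBBBBB") +
    ggplot2::ylim(0, length(object$layers) + 1) +
    ggplot2::labs(title = measure, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
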