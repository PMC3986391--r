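#' Region-of-interest annotation for one section
#'
#' Holds the manually drawn boundaries delimiting the myocardial layers of one
#' slide section. Boundaries are closed rings (simple polygons): the outline
#' has an outer ring and, for annular sections, an inner (luminal) ring; the
#' epicardial boundary separates epicardium from compact myocardium; the
#' trabecular boundary separates compact from trabeculated myocardium.
#' Coordinates are 0-based pixel centres, x right, y down.
#'
#' @param outline Either an `n x 2` matrix (single ring) or a list with
#'   elements `outer` and optionally `inner`.
#' @param epicardial_boundary,trabecular_boundary `n x 2` ring matrices
#'   (either may be `NULL`).
#' @param has_epicardium `FALSE` for septal sections that carry no epicardium.
#' @param section_id Section identifier.
#' @return List of class `fq_section_roi`.
#' @export
section_roi <- function(outline, epicardial_boundary = NULL,
                        trabecular_boundary = NULL, has_epicardium = TRUE,
                        section_id = "S1") {
  if (is.matrix(outline)) outline <- list(outer = outline, inner = NULL)
  if (is.null(outline$outer)) fq_validation_error("outline must have an outer ring")
  structure(list(
    outline = outline,
    epicardial_boundary = epicardial_boundary,
    trabecular_boundary = trabecular_boundary,
    has_epicardium = isTRUE(has_epicardium),
    section_id = section_id
  ), class = "fq_section_roi")
}

roi_mask <- function(roi, width, height) {
  m <- polygon_mask(roi$outline$outer, width, height)
  if (!is.null(roi$outline$inner)) {
    m <- m & !polygon_mask(roi$outline$inner, width, height)
  }
  m
}

#' Split the compact myocardium along the equidistant midline
#'
#' Computes Euclidean distance transforms to the rasterised epicardial and
#' trabecular boundaries. Pixels closer to the epicardial boundary form the
#' outer compact half, pixels closer to the trabecular boundary the inner
#' half; exact ties go to the half named by `tie_to`. The midline is the set
#' of compact pixels whose two distances differ by less than 1 px (the raster
#' analogue of the equidistance locus).
#'
#' @param compact_mask Logical matrix of compact-myocardium pixels (nonempty).
#' @param epi_boundary,trab_boundary Logical matrices with the rasterised
#'   boundaries.
#' @param tie_to `"inner"` (default) or `"outer"`.
#' @return List with logical matrices `outer`, `inner`, `midline`, and the
#'   distance matrices `d_epi`, `d_trab`.
#' @export
split_compact <- function(compact_mask, epi_boundary, trab_boundary,
                          tie_to = c("inner", "outer")) {
  tie_to <- match.arg(tie_to)
  if (!any(compact_mask)) fq_validation_error("compact mask is empty")
  if (!any(epi_boundary) || !any(trab_boundary)) {
    fq_validation_error("split_compact: a boundary raster is empty")
  }
  d_epi <- distance_to(epi_boundary)
  d_trab <- distance_to(trab_boundary)
  diff <- d_epi - d_trab
  outer <- compact_mask & (diff < 0)
  inner <- compact_mask & (diff > 0)
  ties <- compact_mask & (diff == 0)
  if (tie_to == "inner") inner <- inner | ties else outer <- outer | ties
  list(
    outer = outer, inner = inner,
    midline = compact_mask & (abs(diff) < 1),
    d_epi = d_epi, d_trab = d_trab
  )
}

#' Partition a section into myocardial layers
#'
#' Rasterises the annotated boundaries and labels every ROI pixel as
#' epicardium (between outline and epicardial boundary), trabecular (inside
#' the trabecular boundary, down to the luminal outline), or compact
#' (between the two boundaries). The compact layer is split into outer and
#' inner halves along the equidistant midline when feasible; a midline is
#' considered feasible when both boundaries exist, the compact layer is
#' nonempty, and its minimum thickness (min over compact pixels of
#' `d_epi + d_trab`) is at least `min_thickness`. Otherwise a single
#' `compact` label is kept and downstream results fall back to
#' whole-myocardium values (see [apply_fallback()]).
#'
#' @param roi A [section_roi()].
#' @param width,height Raster size in pixels.
#' @param min_thickness Feasibility threshold in px (default 4).
#' @param tie_to Tie rule passed to [split_compact()].
#' @return Object of class `fq_layer_partition`: list with `labels`
#'   (`H x W` character matrix: `"background"`, `"epicardium"`,
#'   `"outer_compact"`, `"inner_compact"`, `"compact"`, `"trabecular"`),
#'   `midline_feasible`, `midline` (logical matrix), `status`, and the ROI.
#' @examples
#' sl <- generate_annulus_slice(annulus_spec(c(110, 110), 50, 100,
#'                                           trabecular_depth = 10,
#'                                           epicardial_rim = 10))
#' part <- assign_layers(sl$roi, 221, 221)
#' table(part$labels)
#' @export
assign_layers <- function(roi, width, height, min_thickness = 4,
                          tie_to = c("inner", "outer")) {
  stopifnot(inherits(roi, "fq_section_roi"))
  tie_to <- match.arg(tie_to)
  O <- roi_mask(roi, width, height)
  labels <- matrix("background", height, width)
  status <- "ok"

  has_epi_b <- roi$has_epicardium && !is.null(roi$epicardial_boundary)
  E_in <- if (has_epi_b) {
    polygon_mask(roi$epicardial_boundary, width, height)
  } else {
    matrix(TRUE, height, width)
  }
  has_trab_b <- !is.null(roi$trabecular_boundary)
  T_in <- if (has_trab_b) {
    polygon_mask(roi$trabecular_boundary, width, height)
  } else {
    matrix(FALSE, height, width)
  }
  if (has_epi_b && has_trab_b && any(T_in & !E_in & O)) {
    fq_processing_error(
      "section %s: trabecular and epicardial boundaries cross", roi$section_id)
  }

  epicardium <- O & !E_in
  trabecular <- O & T_in
  compact <- O & E_in & !T_in
  labels[epicardium] <- "epicardium"
  labels[trabecular] <- "trabecular"

  midline <- matrix(FALSE, height, width)
  feasible <- FALSE
  if (!any(compact)) {
    status <- "degenerate: empty compact layer"
    labels[compact] <- "compact"
  } else if (has_epi_b && has_trab_b) {
    epi_b <- rasterize_polyline(roi$epicardial_boundary, width, height)
    trab_b <- rasterize_polyline(roi$trabecular_boundary, width, height)
    sp <- split_compact(compact, epi_b, trab_b, tie_to = tie_to)
    thickness <- min((sp$d_epi + sp$d_trab)[compact])
    if (thickness >= min_thickness) {
      feasible <- TRUE
      labels[sp$outer] <- "outer_compact"
      labels[sp$inner] <- "inner_compact"
      midline <- sp$midline
    } else {
      status <- sprintf("midline infeasible: wall thickness %.1f px < %g px",
                        thickness, min_thickness)
      labels[compact] <- "compact"
    }
  } else {
    status <- "midline infeasible: missing boundary"
    labels[compact] <- "compact"
  }

  structure(list(
    labels = labels,
    midline_feasible = feasible,
    midline = midline,
    status = status,
    roi = roi
  ), class = "fq_layer_partition")
}

#' Whole-myocardium fallback for infeasible midlines
#'
#' When the equidistant midline could not be constructed (thin wall, septal
#' section without epicardium), the inner- and outer-compact rows of a
#' per-layer fractions table are replaced by the area-weighted
#' whole-myocardium value (compact + trabecular), and flagged `"fallback"` in
#' the `provenance` column. Feasible partitions pass through unchanged (with
#' `provenance = "measured"`).
#'
#' @param partition A [assign_layers()] result.
#' @param fractions Tibble of per-layer fractions (columns `layer`,
#'   `connective_pct`, `myocyte_pct`, `adipose_pct`, `analyzed_area_px`).
#' @return The fractions tibble with inner/outer compact rows resolved and a
#'   `provenance` column.
#' @export
apply_fallback <- function(partition, fractions) {
  stopifnot(inherits(partition, "fq_layer_partition"))
  fractions <- dplyr::mutate(fractions, provenance = "measured")
  if (partition$midline_feasible) return(fractions)

  myo <- dplyr::filter(fractions, .data$layer %in% c("compact", "trabecular"),
                       !is.na(.data$connective_pct))
  if (nrow(myo) == 0L) return(fractions)
  wmean <- function(v) sum(v * myo$analyzed_area_px) / sum(myo$analyzed_area_px)
  repl <- tibble::tibble(
    layer = c("outer_compact", "inner_compact"),
    connective_pct = wmean(myo$connective_pct),
    myocyte_pct = wmean(myo$myocyte_pct),
    adipose_pct = wmean(myo$adipose_pct),
    analyzed_area_px = as.integer(round(sum(myo$analyzed_area_px) / 2)),
    denominator_mode = myo$denominator_mode[1],
    provenance = "fallback"
  )
  extra <- setdiff(names(fractions), names(repl))
  for (nm in extra) repl[[nm]] <- fractions[[nm]][1]
  fractions <- dplyr::filter(fractions,
                             !.data$layer %in% c("outer_compact", "inner_compact"))
  dplyr::bind_rows(fractions, repl[names(fractions)])
}

#' Quantify tissue fractions per layer for one section
#'
#' Runs the full single-section pipeline: colour deconvolution, stain-mask
#' classification, adipocyte detection, class resolution, layer partition,
#' and per-layer fraction computation with the whole-myocardium fallback.
#' The epicardium row is emitted but flagged excluded from analysis.
#'
#' @param image `H x W x 3` RGB intensity array.
#' @param roi A [section_roi()].
#' @param config A [fq_config()] (stain vectors, morphology, denominators).
#' @return Tibble: one row per layer with percentages, areas, `provenance`,
#'   `excluded_from_analysis` and `section_id`; plus attribute `masks`.
#' @export
quantify_section <- function(image, roi, config = fq_config()) {
  h <- dim(image)[1]; w <- dim(image)[2]
  M <- build_stain_matrix(config$stain$blue, config$stain$red)
  I0 <- if (identical(config$i0, "estimate")) estimate_background(image) else config$i0
  od <- rgb_to_od(image, I0)
  maps <- deconvolve(od, M)
  part <- assign_layers(roi, w, h, min_thickness = config$midline_min_thickness,
                        tie_to = config$tie_to)
  analysis_roi <- part$labels != "background"
  if (!any(analysis_roi)) {
    fq_processing_error("section %s: empty ROI", roi$section_id)
  }
  params <- config$morpho
  conn_raw <- classify_stain_mask(maps$blue, params, roi = analysis_roi)
  myo_raw <- classify_stain_mask(maps$red, params, roi = analysis_roi)
  adip_raw <- detect_adipocytes(image, params, roi = analysis_roi)
  masks <- resolve_classes(conn_raw, myo_raw, adip_raw, analysis_roi)

  layer_names <- unique(as.character(part$labels))
  layer_names <- setdiff(layer_names, "background")
  fr <- purrr::map_dfr(layer_names, function(ly) {
    dplyr::mutate(
      compute_fractions(masks, region = part$labels == ly,
                        denominator_mode = config$denominator_mode),
      layer = ly, .before = 1
    )
  })
  fr <- apply_fallback(part, fr)
  fr <- dplyr::mutate(
    fr,
    excluded_from_analysis = .data$layer %in% c("epicardium"),
    section_id = roi$section_id,
    midline_feasible = part$midline_feasible
  )
  ord <- c("trabecular", "inner_compact", "outer_compact", "compact", "epicardium")
  fr <- dplyr::arrange(fr, match(.data$layer, ord))
  attr(fr, "masks") <- masks
  attr(fr, "partition") <- part
  # record every implicitly applied default for the run log
  attr(fr, "log") <- c(
    sprintf("section %s: I0 = (%s)%s", roi$section_id,
            paste(sprintf("%.1f", I0), collapse = ", "),
            if (identical(config$i0, "estimate")) " [white-patch estimate]" else ""),
    sprintf("section %s: %s threshold blue = %.4f, red = %.4f", roi$section_id,
            params$threshold_method, attr(conn_raw, "threshold"),
            attr(myo_raw, "threshold")),
    sprintf("section %s: midline %s%s", roi$section_id,
            if (part$midline_feasible) "feasible" else "infeasible -> fallback",
            if (part$status == "ok") "" else paste0(" (", part$status, ")"))
  )
  fr
}

#' Pseudo-colour overlay of resolved tissue masks
#'
#' Reproduces the conventional overlay colouring: red cardiomyocytes, blue
#' connective tissue, green adipose tissue, white background.
#'
#' @param masks A [resolve_classes()] result.
#' @return `H x W x 3` array in \[0, 1\] suitable for `png::writePNG`.
#' @export
overlay_image <- function(masks) {
  stopifnot(inherits(masks, "fq_tissue_masks"))
  h <- nrow(masks$connective); w <- ncol(masks$connective)
  img <- array(1, dim = c(h, w, 3))
  paint <- function(img, mask, rgb) {
    for (c in 1:3) {
      ch <- img[, , c]; ch[mask] <- rgb[c]; img[, , c] <- ch
    }
    img
  }
  img <- paint(img, masks$myocyte, c(0.8, 0.1, 0.1))
  img <- paint(img, masks$connective, c(0.1, 0.2, 0.8))
  img <- paint(img, masks$adipose, c(0.1, 0.7, 0.2))
  img
}
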