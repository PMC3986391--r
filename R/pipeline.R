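#' Run configuration
#'
#' Collects every tunable of the pipeline: stain OD vectors, background
#' intensity policy, morphological parameters, denominator mode, midline
#' feasibility threshold and tie rule, angular convention and region scheme,
#' log offset, significance level and seed. All values are validated at
#' construction, and the configuration hash is embedded in every output file.
#'
#' @param stain List with `blue` and `red` OD vectors.
#' @param i0 Background intensity per channel, or `"estimate"` for the
#'   per-slide white-patch estimate (99th-percentile channel intensity).
#' @param morpho A [morpho_params()].
#' @param denominator_mode `"tissue"` (default) or `"roi"`.
#' @param midline_min_thickness Midline feasibility threshold (px).
#' @param tie_to Midline tie rule, `"inner"` or `"outer"`.
#' @param rv_start_deg Region scheme anchor (see [region_scheme()]).
#' @param angular_zero Schematic zero direction.
#' @param log_offset Offset for [log_transform()].
#' @param alpha Interaction gate level.
#' @param seed Integer seed for any stochastic step.
#' @return List of class `fq_config`.
#' @export
fq_config <- function(stain = list(blue = masson_stain_vectors()["blue", ],
                                   red = masson_stain_vectors()["red", ]),
                      i0 = c(255, 255, 255),
                      morpho = morpho_params(),
                      denominator_mode = c("tissue", "roi"),
                      midline_min_thickness = 4,
                      tie_to = c("inner", "outer"),
                      rv_start_deg = 240,
                      angular_zero = c(0, -1),
                      log_offset = 0.5,
                      alpha = 0.05,
                      seed = 1L) {
  denominator_mode <- match.arg(denominator_mode)
  tie_to <- match.arg(tie_to)
  build_stain_matrix(stain$blue, stain$red) # validates
  if (!inherits(morpho, "fq_morpho_params")) morpho <- do.call(morpho_params, morpho)
  if (!identical(i0, "estimate")) {
    i0 <- rep_len(as.numeric(i0), 3L)
    if (any(i0 <= 0)) fq_validation_error("i0 must be positive (or 'estimate')")
  }
  structure(list(
    stain = lapply(stain, as.numeric), i0 = i0, morpho = morpho,
    denominator_mode = denominator_mode,
    midline_min_thickness = midline_min_thickness, tie_to = tie_to,
    rv_start_deg = rv_start_deg, angular_zero = as.numeric(angular_zero),
    log_offset = log_offset, alpha = alpha, seed = as.integer(seed)
  ), class = "fq_config")
}

#' Read a run configuration from YAML
#'
#' Missing fields take their defaults from [fq_config()].
#'
#' @param path YAML file.
#' @return An [fq_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) fq_validation_error("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  args <- list()
  for (nm in intersect(names(raw), names(formals(fq_config)))) args[[nm]] <- raw[[nm]]
  do.call(fq_config, args)
}

#' Hash of a run configuration
#'
#' MD5 of the canonical YAML serialisation; embedded in every output file so
#' results can be traced to the configuration that produced them.
#'
#' @param config An [fq_config()].
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  canon <- rapply(unclass(config), function(x) {
    if (is.numeric(x)) round(x, 12) else x
  }, how = "replace")
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(canon), tmp)
  unname(tools::md5sum(tmp))
}

file_header <- function(config) {
  sprintf("# fibroquant %s config=%s",
          as.character(utils::packageVersion("fibroquant")),
          config_hash(config))
}

#' Write a table as deterministic CSV with an embedded config hash
#'
#' Doubles are printed with six decimals so that repeated runs are
#' byte-identical.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param config Configuration whose hash is embedded (first comment line).
#' @return `path`, invisibly.
#' @export
fq_write_csv <- function(df, path, config = fq_config()) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) {
      ifelse(is.na(col), "NA", sprintf("%.6f", col))
    } else {
      as.character(col)
    }
  })
  body <- do.call(paste, c(cols, sep = ","))
  writeLines(c(file_header(config), paste(names(df), collapse = ","), body),
             path)
  invisible(path)
}

#' Read a CSV written by [fq_write_csv()]
#' @param path CSV path.
#' @return Tibble.
#' @export
fq_read_csv <- function(path) {
  tibble::as_tibble(read.csv(path, comment.char = "#"))
}

#' Read an RGB image as an intensity array
#'
#' PNG via the png package, TIFF via the tiff package (if installed).
#'
#' @param path Image path.
#' @return `H x W x 3` array of intensities in \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) fq_validation_error("image not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      fq_processing_error("the 'tiff' package is required for TIFF input")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE] * 255
}

#' Write an intensity array as PNG
#' @param image `H x W x 3` array, 0-255.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

poly_to_list <- function(p) lapply(seq_len(nrow(p)), function(i) as.numeric(p[i, ]))
list_to_poly <- function(l) {
  if (is.null(l)) return(NULL)
  m <- do.call(rbind, lapply(l, as.numeric))
  colnames(m) <- c("x", "y")
  m
}

#' Write section ROIs to JSON
#'
#' @param rois List of [section_roi()] objects.
#' @param path Output path.
#' @param images Optional named character vector section_id -> image file.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(rois, path, images = NULL) {
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  sections <- lapply(rois, function(r) {
    drop_null(list(
      section_id = r$section_id,
      has_epicardium = r$has_epicardium,
      image = if (!is.null(images)) images[[r$section_id]] else NULL,
      outline = drop_null(list(outer = poly_to_list(r$outline$outer),
                               inner = if (!is.null(r$outline$inner))
                                 poly_to_list(r$outline$inner))),
      epicardial_boundary = if (!is.null(r$epicardial_boundary))
        poly_to_list(r$epicardial_boundary),
      trabecular_boundary = if (!is.null(r$trabecular_boundary))
        poly_to_list(r$trabecular_boundary)
    ))
  })
  jsonlite::write_json(list(sections = sections), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read section ROIs from JSON
#' @param path JSON path.
#' @return Named list of [section_roi()] objects; each carries an `image`
#'   attribute when the file names one.
#' @export
read_roi_json <- function(path) {
  if (!file.exists(path)) fq_validation_error("ROI file not found: %s", path)
  raw <- jsonlite::read_json(path)
  if (is.null(raw$sections)) fq_validation_error("malformed ROI file: %s", path)
  rois <- lapply(raw$sections, function(s) {
    r <- section_roi(
      outline = list(outer = list_to_poly(s$outline$outer),
                     inner = list_to_poly(s$outline$inner)),
      epicardial_boundary = list_to_poly(s$epicardial_boundary),
      trabecular_boundary = list_to_poly(s$trabecular_boundary),
      has_epicardium = isTRUE(s$has_epicardium),
      section_id = s$section_id
    )
    attr(r, "image") <- s$image
    r
  })
  names(rois) <- vapply(rois, `[[`, character(1), "section_id")
  rois
}

#' Write a slice layout to JSON
#' @param layout A [slice_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout_json <- function(layout, path) {
  sections <- lapply(seq_len(nrow(layout$sections)), function(i) {
    list(section_id = layout$sections$section_id[i],
         ventricle = layout$sections$ventricle[i],
         polygon = poly_to_list(as.matrix(layout$sections$polygon[[i]])))
  })
  jsonlite::write_json(list(center = layout$center,
                            angular_zero = layout$angular_zero,
                            sections = sections),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a slice layout from JSON
#' @param path JSON path.
#' @return A [slice_layout()].
#' @export
read_layout_json <- function(path) {
  if (!file.exists(path)) fq_validation_error("layout file not found: %s", path)
  raw <- jsonlite::read_json(path)
  if (is.null(raw$sections) || is.null(raw$center)) {
    fq_validation_error("malformed layout file: %s", path)
  }
  slice_layout(
    sections = tibble::tibble(
      section_id = vapply(raw$sections, `[[`, character(1), "section_id"),
      ventricle = vapply(raw$sections, `[[`, character(1), "ventricle"),
      polygon = lapply(raw$sections, function(s) list_to_poly(s$polygon))
    ),
    center = unlist(raw$center),
    angular_zero = if (!is.null(raw$angular_zero)) unlist(raw$angular_zero)
    else c(0, -1)
  )
}

#' Quantify all sections of a slice
#'
#' Runs stain separation, tissue classification and layer-resolved fraction
#' computation for every section listed in the ROI file.
#'
#' @param image_dir Directory holding the section images named in the ROI
#'   file (or `<section_id>.png`).
#' @param roi_file ROI JSON path (see [read_roi_json()]).
#' @param config An [fq_config()].
#' @param out_dir Optional output directory: writes `fractions.csv` and one
#'   pseudo-colour overlay PNG per section.
#' @return Per-section per-layer fractions tibble.
#' @export
fq_quantify <- function(image_dir, roi_file, config = fq_config(),
                        out_dir = NULL) {
  rois <- read_roi_json(roi_file)
  if (length(rois) == 0L) fq_validation_error("ROI file lists no sections")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- purrr::map(rois, function(roi) {
    img_name <- attr(roi, "image")
    if (is.null(img_name) || length(img_name) == 0L) {
      img_name <- paste0(roi$section_id, ".png")
    }
    img <- read_image(file.path(image_dir, img_name))
    fr <- quantify_section(img, roi, config)
    if (!is.null(out_dir)) {
      write_image(overlay_image(attr(fr, "masks")) * 255,
                  file.path(out_dir, paste0(roi$section_id, "_overlay.png")))
    }
    fr
  })
  out <- dplyr::bind_rows(lapply(res, function(x) { attributes(x)$masks <- NULL; x }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fq_write_csv(out, file.path(out_dir, "fractions.csv"), config)
    log_lines <- unlist(lapply(res, attr, "log"))
    writeLines(c(file_header(config), log_lines),
               file.path(out_dir, "log.txt"))
  }
  out
}

#' Map per-section fractions onto the standardized schematic
#'
#' @param fractions Tibble from [fq_quantify()] (or its CSV).
#' @param layout A [slice_layout()] or layout JSON path.
#' @param config An [fq_config()].
#' @param out_dir Optional output directory: writes `per_degree.csv`,
#'   `per_region.csv` and one schematic SVG per measure.
#' @return List with the `schematic` and the per-`regions` tibble.
#' @export
fq_map <- function(fractions, layout, config = fq_config(), out_dir = NULL) {
  if (is.character(layout)) layout <- read_layout_json(layout)
  if (is.character(fractions)) fractions <- fq_read_csv(fractions)
  scheme <- region_scheme(config$rv_start_deg)
  layout$angular_zero <- config$angular_zero
  sch <- slice_schematic(fractions, layout, scheme)
  regions <- summarize_regions(sch)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fq_write_csv(sch$values, file.path(out_dir, "per_degree.csv"), config)
    fq_write_csv(regions, file.path(out_dir, "per_region.csv"), config)
    for (m in sch$measures) {
      write_schematic_svg(sch, m, file.path(out_dir, paste0("schematic_", m, ".svg")),
                          comment = file_header(config))
    }
  }
  list(schematic = sch, regions = regions)
}

#' Statistical comparison of per-region values across conditions
#'
#' @param region_values Tibble with columns `subject`, `region`, `measure`,
#'   `value` (percent scale), or a CSV path.
#' @param conditions Tibble with `subject`, `condition`, or a CSV path.
#' @param config An [fq_config()].
#' @param out_dir Optional: writes `stats_<measure>.txt` and a JSON report.
#' @return Named list of [analyze_regions()] reports, one per measure.
#' @export
fq_stats <- function(region_values, conditions, config = fq_config(),
                     out_dir = NULL) {
  if (is.character(region_values)) region_values <- fq_read_csv(region_values)
  if (is.character(conditions)) conditions <- fq_read_csv(conditions)
  tbl <- dplyr::inner_join(region_values, conditions, by = "subject")
  reports <- lapply(split(tbl, tbl$measure), function(d) {
    analyze_regions(
      tibble::tibble(subject = factor(d$subject),
                     condition = factor(d$condition),
                     region = factor(d$region),
                     response = d$value),
      offset = config$log_offset, alpha = config$alpha)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (m in names(reports)) {
      txt <- file.path(out_dir, paste0("stats_", m, ".txt"))
      con <- file(txt, open = "wt")
      writeLines(file_header(config), con)
      sink(con); print(reports[[m]]); sink()
      close(con)
    }
    js <- lapply(reports, function(r) list(
      epsilon = r$anova$epsilon,
      interaction_significant = r$anova$interaction_significant,
      anova = r$anova$table,
      posthoc_performed = r$posthoc$performed,
      posthoc = r$posthoc$contrasts
    ))
    jsonlite::write_json(
      list(tool = file_header(config), reports = js),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = 10,
      dataframe = "rows", na = "null")
  }
  reports
}

#' Run the full workflow on a slice directory
#'
#' Expects `roi.json`, `layout.json` and the section images in `input_dir`
#' (plus optional `region_values.csv`/`conditions.csv` for the statistics
#' stage). Deterministic: re-running with the same configuration produces
#' byte-identical CSV/SVG outputs.
#'
#' @param input_dir Input directory.
#' @param out_dir Output directory (created).
#' @param config An [fq_config()].
#' @return List with `fractions`, `map`, and `stats` (`NULL` when no
#'   condition table is supplied).
#' @export
fq_run_all <- function(input_dir, out_dir, config = fq_config()) {
  roi_file <- file.path(input_dir, "roi.json")
  layout_file <- file.path(input_dir, "layout.json")
  if (!dir.exists(input_dir) || !file.exists(roi_file)) {
    fq_validation_error("input directory must contain roi.json: %s", input_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fractions <- fq_quantify(input_dir, roi_file, config, out_dir = out_dir)
  map <- NULL
  if (file.exists(layout_file)) {
    map <- fq_map(fractions, layout_file, config, out_dir = out_dir)
  }
  stats_rep <- NULL
  cond_file <- file.path(input_dir, "conditions.csv")
  rv_file <- file.path(input_dir, "region_values.csv")
  if (file.exists(cond_file) && file.exists(rv_file)) {
    stats_rep <- fq_stats(rv_file, cond_file, config, out_dir = out_dir)
  }
  list(fractions = fractions, map = map, stats = stats_rep)
}

#' Generate a packaged phantom slice input directory
#'
#' Writes a complete synthetic input set for [fq_run_all()]: one annular
#' trichrome phantom section image, its ROI rings, and a single-section
#' layout.
#'
#' @param dir Target directory (created).
#' @param size Image side length (px).
#' @param seed Integer seed.
#' @return Invisibly, a list with the phantom, ROI and layout objects.
#' @export
fq_phantom_slice <- function(dir, size = 320L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  c0 <- (size - 1) / 2
  asp <- annulus_spec(c(c0, c0), r_trab = 0.28 * size, r_epi = 0.46 * size,
                      trabecular_depth = 0.05 * size,
                      epicardial_rim = 0.04 * size, seed = seed)
  sl <- generate_annulus_slice(asp, section_id = "S1")
  ph <- generate_trichrome_phantom(phantom_spec(size, size, seed = seed))
  write_image(ph$image, file.path(dir, "S1.png"))
  write_roi_json(list(sl$roi), file.path(dir, "roi.json"),
                 images = c(S1 = "S1.png"))
  layout <- slice_layout(
    tibble::tibble(section_id = "S1", ventricle = "LV",
                   polygon = list(sl$roi$outline$outer)),
    center = c(c0, c0))
  write_layout_json(layout, file.path(dir, "layout.json"))
  invisible(list(phantom = ph, slice = sl, layout = layout))
}
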