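#' Morphological parameters for tissue classification
#'
#' Kernel radii, thresholds and adipocyte size bounds used by
#' [classify_stain_mask()] and [detect_adipocytes()]. Defaults are tuned for
#' imagery at 10% of a 20x scan (roughly 2 um/px class resolution), where
#' adipocytes of 40-120 um diameter appear as vacuoles of ~5-12 px radius
#' bounded by 1-2 px septa. Every value can be overridden via the run
#' configuration.
#'
#' @param median_radius Median-filter disk radius for stain maps (px).
#' @param dilation_radius Grayscale dilation radius for stain maps (px).
#' @param closing_radius Binary closing radius for stain masks (px).
#' @param threshold_method `"otsu"` (on nonzero map values within the ROI) or
#'   `"fixed"`.
#' @param fixed_threshold Threshold in concentration (OD) units when
#'   `threshold_method = "fixed"`.
#' @param adipo_median_radius Median-filter radius for the adipocyte detector.
#' @param adipo_threshold Grayscale intensity (0-255) below which a pixel
#'   counts as stained in the adipocyte detector.
#' @param adipo_opening_radius,adipo_closing_radius Opening/closing radii for
#'   the adipocyte detector (px).
#' @param min_adipocyte_area,max_adipocyte_area Area bounds in px^2 for a
#'   single adipocyte vacuole; applied to each enclosed unstained hole (the
#'   upper bound rejects enclosed lumens). The minimum also drops final
#'   components smaller than one adipocyte.
#' @param subtract_direction Operand order of the chain-link subtraction step:
#'   `"thresholded_minus_opened"` (default; isolates the thin stained septa)
#'   or `"opened_minus_thresholded"` (the literal reading; empty by set
#'   inclusion, kept for comparison).
#' @return List of class `fq_morpho_params`.
#' @export
morpho_params <- function(median_radius = 2L, dilation_radius = 1L,
                          closing_radius = 2L,
                          threshold_method = c("otsu", "fixed"),
                          fixed_threshold = 0.3,
                          adipo_median_radius = 3L, adipo_threshold = 220,
                          adipo_opening_radius = 3L, adipo_closing_radius = 3L,
                          min_adipocyte_area = 30, max_adipocyte_area = 5000,
                          subtract_direction = c("thresholded_minus_opened",
                                                 "opened_minus_thresholded")) {
  threshold_method <- match.arg(threshold_method)
  subtract_direction <- match.arg(subtract_direction)
  radii <- c(median_radius, dilation_radius, closing_radius,
             adipo_median_radius, adipo_opening_radius, adipo_closing_radius)
  if (any(radii < 0)) fq_validation_error("all radii must be >= 0")
  if (min_adipocyte_area >= max_adipocyte_area) {
    fq_validation_error("min_adipocyte_area must be < max_adipocyte_area")
  }
  structure(list(
    median_radius = as.integer(median_radius),
    dilation_radius = as.integer(dilation_radius),
    closing_radius = as.integer(closing_radius),
    threshold_method = threshold_method,
    fixed_threshold = fixed_threshold,
    adipo_median_radius = as.integer(adipo_median_radius),
    adipo_threshold = adipo_threshold,
    adipo_opening_radius = as.integer(adipo_opening_radius),
    adipo_closing_radius = as.integer(adipo_closing_radius),
    min_adipocyte_area = min_adipocyte_area,
    max_adipocyte_area = max_adipocyte_area,
    subtract_direction = subtract_direction
  ), class = "fq_morpho_params")
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# median filter wrapper: EBImage::medianFilter clamps values to [0,1], so
# rescale by the max first; radius 0 is the identity
median_disk <- function(x, radius) {
  if (radius <= 0) return(x)
  mx <- max(x)
  if (mx <= 0) return(x)
  as.matrix(EBImage::medianFilter(x / mx, size = as.integer(radius))) * mx
}

# Otsu threshold restricted to a value vector (EBImage::otsu works on whole
# images only); standard between-class variance maximisation on a 256-bin
# histogram
otsu_vector <- function(v, n_bins = 256L) {
  if (length(v) == 0L) return(NA_real_)
  rng <- range(v)
  if (!is.finite(diff(rng)) || diff(rng) == 0) return(NA_real_)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_bins)
  p <- counts / sum(counts)
  mids <- (br[-1] + br[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- w0 * (1 - w0)
  sb <- ifelse(denom > 0, (mu_t * w0 - mu)^2 / denom, 0)
  mids[which.max(sb)]
}

#' Classify a stain concentration map into a binary tissue mask
#'
#' Pipeline, in order: 2D median filter (disk), grayscale dilation (disk),
#' threshold (Otsu on the nonzero values within the ROI, or a fixed value),
#' binary closing (disk).
#'
#' @param conc_map `H x W` nonnegative concentration matrix (one stain).
#' @param params [morpho_params()].
#' @param roi Optional logical matrix restricting the analysis (and the Otsu
#'   histogram); the returned mask is false outside it.
#' @return Logical `H x W` mask.
#' @examples
#' m <- matrix(0, 60, 60); m[10:40, 10:40] <- 1
#' mask <- classify_stain_mask(m, morpho_params(threshold_method = "fixed",
#'                                              fixed_threshold = 0.5))
#' sum(mask)
#' @export
classify_stain_mask <- function(conc_map, params = morpho_params(), roi = NULL) {
  if (any(!is.finite(conc_map))) fq_validation_error("concentration map must be finite")
  x <- median_disk(conc_map, params$median_radius)
  if (params$dilation_radius > 0) {
    x <- as.matrix(EBImage::dilate(x, disc_brush(params$dilation_radius)))
  }
  vals <- if (is.null(roi)) x[x > 0] else x[roi & x > 0]
  if (params$threshold_method == "otsu") {
    thr <- otsu_vector(vals)
    if (is.na(thr)) {
      warning("Otsu threshold undefined (empty or constant map); returning empty mask")
      return(matrix(FALSE, nrow(conc_map), ncol(conc_map)))
    }
  } else {
    thr <- params$fixed_threshold
  }
  mask <- x >= thr
  if (params$closing_radius > 0) {
    mask <- as.matrix(EBImage::closing(mask + 0, disc_brush(params$closing_radius))) > 0.5
  }
  if (!is.null(roi)) mask <- mask & roi
  attr(mask, "threshold") <- thr
  mask
}

#' Detect adipose tissue via its chain-link structure
#'
#' Adipocytes appear on trichrome slides as unstained vacuoles bounded by thin
#' stained septa ("chain-link"). The detector converts the image to Rec. 601
#' luminance, median-filters it, thresholds stained (dark) pixels, and removes
#' bulk tissue with a binary opening; the set difference
#' thresholded-minus-opened then isolates the thin septa. Vacuole interiors
#' are recovered as the unstained holes fully enclosed by stained tissue,
#' with the per-adipocyte area bounds applied to each hole so enclosed
#' lumens are rejected. Consecutive closing and opening consolidate septa
#' and vacuoles into filled adipocyte regions; interstitial gaps enclosed
#' inside chain-link clusters are filled, and components smaller than one
#' adipocyte are dropped.
#'
#' @param image `H x W x 3` RGB intensity array (0-255).
#' @param params [morpho_params()].
#' @param roi Optional logical matrix; detection restricted to it.
#' @return Logical `H x W` adipose mask.
#' @export
detect_adipocytes <- function(image, params = morpho_params(), roi = NULL) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    fq_validation_error("image must be an H x W x 3 array")
  }
  gray <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  med <- median_disk(gray / 255, params$adipo_median_radius) * 255
  stained <- med < params$adipo_threshold
  if (!is.null(roi)) stained <- stained & roi
  opened <- stained
  if (params$adipo_opening_radius > 0) {
    opened <- as.matrix(EBImage::opening(
      stained + 0, disc_brush(params$adipo_opening_radius))) > 0.5
  }
  septa <- if (params$subtract_direction == "thresholded_minus_opened") {
    stained & !opened
  } else {
    opened & !stained
  }
  # vacuole interiors are the holes of the stained mask: unstained regions
  # fully enclosed by stained septa/tissue; keep only hole components within
  # the per-adipocyte area bounds (rejects enclosed lumens)
  filled_stained <- as.matrix(EBImage::fillHull(EBImage::bwlabel(stained + 0))) > 0
  holes <- filled_stained & !stained
  hlab <- EBImage::bwlabel(holes + 0)
  nh <- max(hlab)
  vacuoles <- matrix(FALSE, nrow(holes), ncol(holes))
  if (nh > 0) {
    hareas <- tabulate(hlab[hlab > 0], nh)
    hk <- which(hareas >= params$min_adipocyte_area &
                  hareas <= params$max_adipocyte_area)
    vacuoles <- matrix(hlab %in% hk, nrow(hlab), ncol(hlab))
  }
  x <- septa | vacuoles
  if (params$adipo_closing_radius > 0) {
    x <- as.matrix(EBImage::closing(x + 0, disc_brush(params$adipo_closing_radius))) > 0.5
  }
  if (params$adipo_opening_radius > 0) {
    x <- as.matrix(EBImage::opening(x + 0, disc_brush(params$adipo_opening_radius))) > 0.5
  }
  # fill interstitial gaps enclosed inside chain-link clusters, then drop
  # components below the single-adipocyte minimum area
  x <- as.matrix(EBImage::fillHull(EBImage::bwlabel(x + 0))) > 0
  lab <- EBImage::bwlabel(x + 0)
  nlab <- max(lab)
  if (nlab > 0) {
    areas <- tabulate(lab[lab > 0], nlab)
    keep <- which(areas >= params$min_adipocyte_area)
    x <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  }
  if (!is.null(roi)) x <- x & roi
  x
}

#' Resolve overlapping detections into exclusive tissue masks
#'
#' Precedence on overlapping pixels: adipose over connective over myocyte
#' (the adipocyte detector is the most specific, and septal pixels are stained
#' so they also trigger the stain classifiers). Pixels in the ROI claimed by
#' no detector become background. The four returned masks are mutually
#' exclusive and jointly exhaustive over the ROI.
#'
#' @param connective_raw,myocyte_raw,adipose_raw Logical masks, same shape.
#' @param roi Logical analysis mask (nonempty).
#' @return List of class `fq_tissue_masks` with logical matrices
#'   `connective`, `myocyte`, `adipose`, `background`.
#' @export
resolve_classes <- function(connective_raw, myocyte_raw, adipose_raw, roi) {
  dims <- dim(connective_raw)
  if (!identical(dims, dim(myocyte_raw)) || !identical(dims, dim(adipose_raw)) ||
      !identical(dims, dim(roi))) {
    fq_validation_error("masks must share shape")
  }
  if (!any(roi)) fq_validation_error("ROI is empty")
  adipose <- adipose_raw & roi
  connective <- connective_raw & roi & !adipose
  myocyte <- myocyte_raw & roi & !adipose & !connective
  background <- roi & !adipose & !connective & !myocyte
  structure(list(connective = connective, myocyte = myocyte,
                 adipose = adipose, background = background),
            class = "fq_tissue_masks")
}

#' Tissue-class area percentages within a region
#'
#' With `denominator_mode = "tissue"` the denominator is the count of
#' connective + myocyte + adipose pixels in the region (lumen/background
#' excluded, so the three percentages sum to 100); with `"roi"` it is every
#' region pixel including background. A zero denominator yields missing
#' percentages (not zeros).
#'
#' @param masks [resolve_classes()] output.
#' @param region Logical matrix selecting the region (default: whole ROI).
#' @param denominator_mode `"tissue"` or `"roi"`.
#' @return One-row tibble: `connective_pct`, `myocyte_pct`, `adipose_pct`,
#'   `analyzed_area_px`, `denominator_mode`.
#' @export
compute_fractions <- function(masks, region = NULL,
                              denominator_mode = c("tissue", "roi")) {
  denominator_mode <- match.arg(denominator_mode)
  stopifnot(inherits(masks, "fq_tissue_masks"))
  roi <- masks$connective | masks$myocyte | masks$adipose | masks$background
  if (is.null(region)) region <- roi
  counts <- c(
    connective = sum(masks$connective & region),
    myocyte = sum(masks$myocyte & region),
    adipose = sum(masks$adipose & region)
  )
  denom <- if (denominator_mode == "tissue") sum(counts) else sum(roi & region)
  if (denom == 0) {
    message("compute_fractions: zero denominator; reporting missing percentages")
    pct <- rep(NA_real_, 3)
  } else {
    pct <- unname(100 * counts / denom)
  }
  tibble::tibble(
    connective_pct = pct[1], myocyte_pct = pct[2], adipose_pct = pct[3],
    analyzed_area_px = as.integer(denom),
    denominator_mode = denominator_mode
  )
}
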