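#' Specification of a synthetic trichrome tile
#'
#' Describes a phantom image tile that emulates the three tissue classes seen
#' on a Masson's trichrome slide: connective tissue (methyl-blue stained),
#' cardiomyocytes (ponceau-fuchsin stained), and adipose tissue rendered as
#' unstained vacuoles separated by thin stained septa (the "chain-link"
#' appearance). Remaining area is blank glass background.
#'
#' @param width,height Tile size in pixels.
#' @param target_fractions Named or ordered triple (connective, myocyte,
#'   adipose), each in \[0, 1\], summing to at most 1; the remainder is
#'   background.
#' @param adipocyte_radius_range Length-2 range of adipocyte (vacuole) radii
#'   in pixels; minimum 2 px.
#' @param texture_noise_sd Additive Gaussian intensity noise (0-255 units).
#' @param connective_od Peak methyl-blue concentration of connective tissue;
#'   lower it (e.g. 0.35) to emulate pale collagen.
#' @param seed Integer seed; identical seeds reproduce identical phantoms.
#' @return A list of class `fq_phantom_spec`.
#' @export
phantom_spec <- function(width = 512L, height = 512L,
                         target_fractions = c(connective = 0.4, myocyte = 0.4,
                                              adipose = 0.2),
                         adipocyte_radius_range = c(5, 12),
                         texture_noise_sd = 4,
                         connective_od = 0.9,
                         seed = 1L) {
  f <- as.numeric(target_fractions)
  if (length(f) != 3L || any(f < 0) || any(f > 1) || sum(f) > 1 + 1e-9) {
    fq_validation_error(
      "target_fractions must be three values in [0,1] summing to <= 1")
  }
  if (width <= 0 || height <= 0) fq_validation_error("width and height must be > 0")
  if (length(adipocyte_radius_range) != 2L || min(adipocyte_radius_range) < 2) {
    fq_validation_error("adipocyte radii must be >= 2 px")
  }
  structure(list(
    width = as.integer(width), height = as.integer(height),
    target_fractions = setNames(f, c("connective", "myocyte", "adipose")),
    adipocyte_radius_range = sort(as.numeric(adipocyte_radius_range)),
    texture_noise_sd = texture_noise_sd,
    connective_od = connective_od,
    seed = as.integer(seed)
  ), class = "fq_phantom_spec")
}

# hex-lattice adipocyte centres for one placement zone component.
# spacing 2r + 3 leaves a ~3 px gap between vacuole interiors that the two
# 1.5 px septal rings fill, giving shared septa between neighbouring cells.
hex_centers <- function(allowed, r, offset) {
  h <- nrow(allowed); w <- ncol(allowed)
  s <- 2 * r + 3
  dy <- s * sqrt(3) / 2
  ys <- seq(r + 2, h - 1 - (r + 2), by = dy)
  if (length(ys) == 0L) return(NULL)
  out <- vector("list", length(ys))
  for (k in seq_along(ys)) {
    x0 <- r + 2 + ((k %% 2) * s / 2 + offset) %% s
    xs <- seq(x0, w - 1 - (r + 2), by = s)
    if (length(xs) == 0L) next
    yk <- rep(ys[k], length(xs))
    keep <- allowed[cbind(round(yk) + 1L, round(xs) + 1L)]
    if (any(keep)) out[[k]] <- cbind(x = xs[keep], y = yk[keep])
  }
  do.call(rbind, out)
}

# rasterise adipocytes: interior (vacuole) and septal ring masks
rasterize_adipocytes <- function(centers, radii, width, height, septum = 1.5) {
  interior <- matrix(FALSE, height, width)
  full <- matrix(FALSE, height, width)
  if (is.null(centers) || nrow(centers) == 0L) {
    return(list(interior = interior, full = full))
  }
  for (i in seq_len(nrow(centers))) {
    r <- radii[i]; R <- r + septum
    cx <- centers[i, 1]; cy <- centers[i, 2]
    jx <- max(0, floor(cx - R)):min(width - 1, ceiling(cx + R))
    jy <- max(0, floor(cy - R)):min(height - 1, ceiling(cy + R))
    d2 <- outer((jy - cy)^2, (jx - cx)^2, "+")
    sub_full <- d2 <= R^2
    sub_int <- d2 <= r^2
    rows <- jy + 1L; cols <- jx + 1L
    full[rows, cols] <- full[rows, cols] | sub_full
    interior[rows, cols] <- interior[rows, cols] | sub_int
  }
  list(interior = interior, full = full)
}

# place adipocytes to hit a target pixel count; bisection on the placement-zone
# area fraction. All randomness is pre-drawn so the search is deterministic.
place_adipocytes <- function(spec, field, target_px) {
  h <- spec$height; w <- spec$width
  rr <- spec$adipocyte_radius_range
  comp_radii <- runif(256, rr[1], rr[2])
  offset <- runif(1, 0, 1) * (2 * rr[1] + 3)

  attempt <- function(zone_frac) {
    thresh <- quantile(field, 1 - zone_frac, names = FALSE)
    zone <- field >= thresh
    comps <- EBImage::bwlabel(zone)
    ncomp <- max(comps)
    centers <- NULL; radii <- NULL
    for (ci in seq_len(min(ncomp, 256L))) {
      r <- comp_radii[ci]
      cmask <- comps == ci
      if (sum(cmask) < (2 * r + 4)^2) next
      allowed <- as.matrix(EBImage::erode(
        cmask + 0, EBImage::makeBrush(2 * ceiling(r + 2) + 1, "disc"))) > 0.5
      if (!any(allowed)) next
      cc <- hex_centers(allowed, r, offset)
      if (!is.null(cc)) {
        centers <- rbind(centers, cc)
        radii <- c(radii, rep(r, nrow(cc)))
      }
    }
    ras <- rasterize_adipocytes(centers, radii, w, h)
    list(zone = zone, ras = ras, count = sum(ras$full))
  }

  lo <- max(target_px / (w * h), 1e-4)
  hi <- min(0.999, 6 * target_px / (w * h) + 0.05)
  best <- NULL
  for (it in 1:12) {
    mid <- (lo + hi) / 2
    res <- attempt(mid)
    if (is.null(best) || abs(res$count - target_px) < abs(best$count - target_px)) {
      best <- res
    }
    if (abs(res$count - target_px) <= 0.004 * w * h) break
    if (res$count < target_px) lo <- mid else hi <- mid
  }
  if (best$count < target_px - 0.03 * w * h) {
    fq_validation_error(
      "infeasible adipocyte packing: reached %.1f%% of tile, target %.1f%%",
      100 * best$count / (w * h), 100 * target_px / (w * h))
  }
  best
}

#' Generate a synthetic trichrome phantom tile
#'
#' Builds a per-pixel ground-truth label image (0 background, 1 connective,
#' 2 myocyte, 3 adipose) and renders it to RGB through the same stain matrix
#' and Beer-Lambert forward model used for deconvolution. Adipocytes are laid
#' out as jittered hexagonally packed vacuoles with shared 1.5 px stained
#' septa; connective and myocyte areas are blob-shaped regions carved from a
#' smooth Gaussian random field so that their pixel counts match the targets
#' exactly. Interstitial pixels inside an adipose placement zone that are not
#' part of a cell are stained like the surrounding myocardium.
#'
#' @param spec A [phantom_spec()].
#' @param M Stain matrix used for forward rendering.
#' @return A list of class `fq_phantom` with elements `image` (`H x W x 3`
#'   8-bit intensities), `labels` (`H x W` integer matrix), and
#'   `true_fractions` (tibble with exact pixel recounts; fractions are
#'   relative to tissue pixels, matching the quantifier's default
#'   denominator).
#' @examples
#' ph <- generate_trichrome_phantom(phantom_spec(128, 128, seed = 7))
#' ph$true_fractions
#' @export
generate_trichrome_phantom <- function(spec, M = build_stain_matrix()) {
  stopifnot(inherits(spec, "fq_phantom_spec"))
  set.seed(spec$seed)
  w <- spec$width; h <- spec$height; N <- w * h
  f <- spec$target_fractions
  sigma <- max(8, min(w, h) / 16)

  labels <- matrix(0L, h, w)
  interior <- full <- matrix(FALSE, h, w)
  zone <- matrix(FALSE, h, w)
  if (f[["adipose"]] > 0) {
    field_a <- smooth_field(w, h, sigma)
    placed <- place_adipocytes(spec, field_a, round(f[["adipose"]] * N))
    interior <- placed$ras$interior
    full <- placed$ras$full
    zone <- placed$zone
    labels[full] <- 3L
  }

  # interstitial pixels inside the adipose zone: stained myocardium
  gap <- zone & !full
  gap_class <- if (f[["myocyte"]] > 0) 2L else if (f[["connective"]] > 0) 1L else 0L
  if (gap_class > 0L) labels[gap] <- gap_class

  # split the remainder into connective / background / myocyte bands of a
  # smooth field, with exact pixel counts
  remaining <- which(labels == 0L)
  n_conn <- max(0L, round(f[["connective"]] * N))
  n_myo <- max(0L, round(f[["myocyte"]] * N) - sum(labels == 2L))
  n_conn <- min(n_conn, length(remaining))
  n_myo <- min(n_myo, length(remaining) - n_conn)
  if (length(remaining) > 0L && (n_conn > 0L || n_myo > 0L)) {
    field_t <- smooth_field(w, h, sigma)
    ord <- remaining[order(field_t[remaining])]
    if (n_conn > 0L) labels[ord[seq_len(n_conn)]] <- 1L
    if (n_myo > 0L) labels[ord[seq.int(length(ord) - n_myo + 1L, length(ord))]] <- 2L
  }

  # render: concentration fields per class, mild spatial texture
  tex <- smooth_field(w, h, sigma / 2)
  cb <- matrix(0, h, w); cr <- matrix(0, h, w)
  conn <- labels == 1L; myo <- labels == 2L
  cb[conn] <- pmax(0, spec$connective_od + 0.1 * tex[conn])
  cr[conn] <- 0.03
  cr[myo] <- pmax(0, 0.85 + 0.1 * tex[myo])
  cb[myo] <- 0.03
  ring <- full & !interior
  cr[ring] <- 0.9; cb[ring] <- 0.05
  cb[interior] <- 0.02; cr[interior] <- 0.02

  image <- synthesize_trichrome(cb, cr, M = M, noise_sd = spec$texture_noise_sd,
                                quantize = TRUE)

  structure(list(
    image = image,
    labels = labels,
    true_fractions = recount_fractions(labels),
    spec = spec
  ), class = "fq_phantom")
}

#' Recount ground-truth fractions from a label image
#'
#' Exact pixel counts per class, with fractions relative to tissue pixels
#' (classes 1-3). Zero everywhere when the tile has no tissue.
#'
#' @param labels Integer matrix: 0 background, 1 connective, 2 myocyte,
#'   3 adipose.
#' @return Tibble with columns `class`, `pixels`, `fraction`.
#' @export
recount_fractions <- function(labels) {
  counts <- vapply(1:3, function(k) sum(labels == k), numeric(1))
  tissue <- sum(counts)
  tibble::tibble(
    class = c("connective", "myocyte", "adipose"),
    pixels = as.integer(counts),
    fraction = if (tissue > 0) counts / tissue else rep(0, 3)
  )
}

#' Specification of a synthetic annular slice geometry
#'
#' A concentric annular section with an outline (outer and luminal rings), an
#' epicardial boundary at `r_epi - epicardial_rim`, and a trabecular boundary
#' at `r_trab + trabecular_depth`. Optional smooth radial jitter is applied
#' with opposite sign to the two internal boundaries, which perturbs every
#' boundary point while keeping the analytic equidistant-midline radius at
#' `(r_trab + trabecular_depth + r_epi - epicardial_rim) / 2`.
#'
#' @param center (x, y) centre in pixels.
#' @param r_trab Inner (luminal) radius; the trabecular boundary sits at
#'   `r_trab + trabecular_depth`.
#' @param r_epi Outer radius; the epicardial boundary sits at
#'   `r_epi - epicardial_rim`.
#' @param trabecular_depth,epicardial_rim Layer thicknesses in pixels.
#' @param jitter Peak radial boundary perturbation in pixels (0 = perfect
#'   circles).
#' @param seed Integer seed for the jitter harmonics.
#' @return A list of class `fq_annulus_spec`.
#' @export
annulus_spec <- function(center, r_trab, r_epi, trabecular_depth = 0,
                         epicardial_rim = 0, jitter = 0, seed = 1L) {
  if (!(r_trab > 0 && r_trab < r_epi)) {
    fq_validation_error("need 0 < r_trab < r_epi")
  }
  if (trabecular_depth + epicardial_rim >= r_epi - r_trab) {
    fq_validation_error("trabecular_depth + epicardial_rim must be < r_epi - r_trab")
  }
  structure(list(
    center = as.numeric(center), r_trab = r_trab, r_epi = r_epi,
    trabecular_depth = trabecular_depth, epicardial_rim = epicardial_rim,
    jitter = jitter, seed = as.integer(seed)
  ), class = "fq_annulus_spec")
}

#' Generate ROI polygons for an annular slice phantom
#'
#' @param spec An [annulus_spec()].
#' @param n_vertices Vertices per ring polygon.
#' @param section_id Identifier stored on the emitted ROI.
#' @return List with `roi` (a [section_roi()]), `midline_radius` (analytic
#'   equidistant-midline radius), and `size` (suggested raster width/height).
#' @examples
#' sl <- generate_annulus_slice(annulus_spec(c(220, 220), 100, 200))
#' sl$midline_radius
#' @export
generate_annulus_slice <- function(spec, n_vertices = 720L, section_id = "S1") {
  stopifnot(inherits(spec, "fq_annulus_spec"))
  set.seed(spec$seed)
  theta <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  delta <- 0
  if (spec$jitter > 0) {
    amp <- runif(3); phase <- runif(3, 0, 2 * pi)
    raw <- amp[1] * sin(theta + phase[1]) + amp[2] * sin(2 * theta + phase[2]) +
      amp[3] * sin(3 * theta + phase[3])
    delta <- spec$jitter * raw / max(abs(raw))
  }
  ring <- function(radius, d) {
    cbind(x = spec$center[1] + (radius + d) * cos(theta),
          y = spec$center[2] + (radius + d) * sin(theta))
  }
  r_epi_b <- spec$r_epi - spec$epicardial_rim
  r_trab_b <- spec$r_trab + spec$trabecular_depth
  roi <- section_roi(
    outline = list(outer = ring(spec$r_epi, delta),
                   inner = ring(spec$r_trab, -delta)),
    epicardial_boundary = ring(r_epi_b, delta),
    trabecular_boundary = ring(r_trab_b, -delta),
    has_epicardium = TRUE,
    section_id = section_id
  )
  list(
    roi = roi,
    midline_radius = (r_trab_b + r_epi_b) / 2,
    # suggested raster size (width, height) containing the jittered outline
    size = ceiling(spec$center + spec$r_epi + spec$jitter + 3)
  )
}

#' Specification of a synthetic repeated-measures dataset
#'
#' Balanced complete design: `n_conditions` between-subject groups of
#' `n_per_condition` subjects, each measured once in every region. Responses
#' are built on the log scale as grand mean + condition effect + region effect
#' + interaction + subject random intercept + residual noise.
#'
#' @param n_per_condition Subjects per condition.
#' @param n_conditions,n_regions Factor level counts.
#' @param grand_mean Log-scale grand mean.
#' @param condition_effects,region_effects Effect vectors (recycled zeros by
#'   default); must match the declared level counts.
#' @param interaction_effects `n_conditions x n_regions` matrix (default all
#'   zero).
#' @param subject_sd,residual_sd Standard deviations of the subject intercept
#'   and the residual, log units; must be nonnegative.
#' @param seed Integer seed.
#' @return A list of class `fq_rm_spec`.
#' @export
rm_dataset_spec <- function(n_per_condition = 5L, n_conditions = 3L,
                            n_regions = 8L, grand_mean = 2,
                            condition_effects = NULL, region_effects = NULL,
                            interaction_effects = NULL,
                            subject_sd = 0.4, residual_sd = 0.3, seed = 1L) {
  if (is.null(condition_effects)) condition_effects <- rep(0, n_conditions)
  if (is.null(region_effects)) region_effects <- rep(0, n_regions)
  if (is.null(interaction_effects)) {
    interaction_effects <- matrix(0, n_conditions, n_regions)
  }
  if (length(condition_effects) != n_conditions ||
      length(region_effects) != n_regions ||
      !all(dim(interaction_effects) == c(n_conditions, n_regions))) {
    fq_validation_error("effect containers must match declared dimensions")
  }
  if (subject_sd < 0 || residual_sd < 0) {
    fq_validation_error("standard deviations must be >= 0")
  }
  structure(list(
    n_per_condition = as.integer(n_per_condition),
    n_conditions = as.integer(n_conditions),
    n_regions = as.integer(n_regions),
    grand_mean = grand_mean,
    condition_effects = condition_effects,
    region_effects = region_effects,
    interaction_effects = interaction_effects,
    subject_sd = subject_sd, residual_sd = residual_sd,
    seed = as.integer(seed)
  ), class = "fq_rm_spec")
}

#' Generate a balanced repeated-measures dataset
#'
#' @param spec An [rm_dataset_spec()].
#' @return Tibble with columns `subject`, `condition`, `region`, `response`
#'   (log scale), one row per subject x region.
#' @examples
#' head(generate_rm_dataset(rm_dataset_spec(seed = 3)))
#' @export
generate_rm_dataset <- function(spec) {
  stopifnot(inherits(spec, "fq_rm_spec"))
  set.seed(spec$seed)
  a <- spec$n_conditions; n <- spec$n_per_condition; k <- spec$n_regions
  cond_names <- if (a == 3L) c("control", "AC", "DCM") else paste0("C", seq_len(a))
  grid <- tidyr::expand_grid(
    condition = factor(cond_names, levels = cond_names),
    subj_in_cond = seq_len(n),
    region = factor(seq_len(k))
  )
  subj_id <- paste0(grid$condition, "_", grid$subj_in_cond)
  intercepts <- rnorm(a * n, 0, spec$subject_sd)
  names(intercepts) <- unique(subj_id)
  ci <- as.integer(grid$condition); ri <- as.integer(grid$region)
  response <- spec$grand_mean +
    spec$condition_effects[ci] +
    spec$region_effects[ri] +
    spec$interaction_effects[cbind(ci, ri)] +
    intercepts[subj_id] +
    rnorm(nrow(grid), 0, spec$residual_sd)
  tibble::tibble(
    subject = factor(subj_id, levels = unique(subj_id)),
    condition = grid$condition,
    region = grid$region,
    response = unname(response)
  )
}
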