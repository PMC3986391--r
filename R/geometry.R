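# Raster/vector geometry helpers shared by the layer and slice-map modules.
# Pixel coordinate convention throughout: 0-based, x to the right (columns),
# y down (rows); pixel (row i, col j) has centre (x, y) = (j - 1, i - 1).

#' Rasterise a polygon to a logical mask
#'
#' A pixel is inside when its centre falls inside the polygon
#' (even-odd rule, via `mgcv::in.out`).
#'
#' @param poly Two-column matrix of polygon vertices (x, y), 0-based pixel
#'   coordinates; closed implicitly.
#' @param width,height Raster size in pixels.
#' @return `height x width` logical matrix.
#' @export
polygon_mask <- function(poly, width, height) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || nrow(poly) < 3L) {
    fq_validation_error("polygon must be an n x 2 matrix with n >= 3")
  }
  # close the ring for in.out
  bnd <- rbind(poly, poly[1L, ])
  pts <- cbind(
    x = rep(0:(width - 1L), each = height),
    y = rep(0:(height - 1L), times = width)
  )
  inside <- mgcv::in.out(bnd, pts)
  matrix(inside, nrow = height, ncol = width)
}

#' Rasterise a polyline into a logical matrix (8-connected Bresenham)
#'
#' @param coords Two-column (x, y) matrix of vertices, 0-based.
#' @param width,height Raster size.
#' @param close Join the last vertex back to the first?
#' @return `height x width` logical matrix with `TRUE` on the drawn line.
#' @export
rasterize_polyline <- function(coords, width, height, close = TRUE) {
  coords <- as.matrix(coords)
  m <- matrix(FALSE, height, width)
  n <- nrow(coords)
  if (n == 0L) return(m)
  idx <- if (close) c(seq_len(n), 1L) else seq_len(n)
  xs <- round(coords[idx, 1]); ys <- round(coords[idx, 2])
  for (s in seq_len(length(idx) - 1L)) {
    x0 <- xs[s]; y0 <- ys[s]; x1 <- xs[s + 1L]; y1 <- ys[s + 1L]
    steps <- max(abs(x1 - x0), abs(y1 - y0))
    if (steps == 0) {
      px <- x0; py <- y0
    } else {
      t <- 0:steps
      px <- round(x0 + t * (x1 - x0) / steps)
      py <- round(y0 + t * (y1 - y0) / steps)
    }
    keep <- px >= 0 & px < width & py >= 0 & py < height
    m[cbind(py[keep] + 1L, px[keep] + 1L)] <- TRUE
  }
  m
}

#' Euclidean distance transform to a pixel set
#'
#' Distance from every pixel to the nearest `TRUE` pixel of `target`
#' (exact Euclidean metric, via `EBImage::distmap`).
#'
#' @param target Logical matrix marking the target pixel set.
#' @return Numeric matrix of distances (0 on the target itself).
#' @export
distance_to <- function(target) {
  if (!any(target)) {
    fq_validation_error("distance_to: target pixel set is empty")
  }
  # distmap measures distance to the nearest zero-valued pixel
  as.matrix(EBImage::distmap(ifelse(target, 0, 1), metric = "euclidean"))
}

#' Regular polygon approximation of a circle
#'
#' @param center Length-2 (x, y) centre.
#' @param radius Circle radius in pixels.
#' @param n Number of vertices.
#' @param radial_offset Optional per-vertex radial perturbation (length `n`).
#' @return `n x 2` matrix of (x, y) vertices.
#' @export
circle_polygon <- function(center, radius, n = 720L, radial_offset = 0) {
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  r <- radius + rep_len(radial_offset, n)
  cbind(x = center[1] + r * cos(theta), y = center[2] + r * sin(theta))
}

# smooth Gaussian random field (white noise blurred with sigma), used by the
# phantom generator for blob-shaped tissue regions
smooth_field <- function(width, height, sigma) {
  # gblur's kernel (2*ceiling(3*sigma)+1) must fit inside the image
  sigma <- min(sigma, (min(width, height) - 2) / 7)
  x <- matrix(rnorm(width * height), height, width)
  f <- as.matrix(EBImage::gblur(x, sigma = sigma))
  (f - mean(f)) / stats::sd(f)
}
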