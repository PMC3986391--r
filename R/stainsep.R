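#' Default Masson's trichrome stain vectors
#'
#' Unit optical-density vectors (R, G, B components) for the two constituent
#' stains of Masson's trichrome: methyl blue, which marks collagen/connective
#' tissue, and ponceau-fuchsin, which marks cardiomyocyte cytoplasm. The values
#' are the published colour-deconvolution vectors in the Ruifrok convention, as
#' distributed with the ImageJ/Fiji colour deconvolution plugin; both rows are
#' returned normalised to unit Euclidean length. They can be overridden in the
#' run configuration when a laboratory has calibrated its own vectors.
#'
#' @return A 2 x 3 numeric matrix with rows `blue` (methyl blue) and `red`
#'   (ponceau-fuchsin) and columns `R`, `G`, `B`.
#' @examples
#' masson_stain_vectors()
#' @export
masson_stain_vectors <- function() {
  v <- rbind(
    blue = c(0.7995107, 0.5913521, 0.10528667),
    red  = c(0.09997159, 0.73738605, 0.6680326)
  )
  colnames(v) <- c("R", "G", "B")
  sweep(v, 1, sqrt(rowSums(v^2)), "/")
}

#' Build a 3 x 3 stain matrix for colour deconvolution
#'
#' Rows are unit optical-density vectors: the two stains of interest plus a
#' residual channel. The residual row is the normalised cross product of the
#' two stain rows, with its sign chosen so that its largest-magnitude component
#' is positive (a deterministic orientation).
#'
#' @param blue_vec Numeric length-3 OD vector for methyl blue (nonnegative,
#'   nonzero).
#' @param red_vec Numeric length-3 OD vector for ponceau-fuchsin.
#' @return A 3 x 3 matrix of class `fq_stain_matrix`, rows
#'   `blue`, `red`, `residual`, each of unit length.
#' @examples
#' M <- build_stain_matrix(c(0, 0, 1), c(1, 0, 0))
#' M %*% t(M) # identity: rows orthonormal here
#' @export
build_stain_matrix <- function(blue_vec = masson_stain_vectors()["blue", ],
                               red_vec = masson_stain_vectors()["red", ]) {
  blue_vec <- as.numeric(blue_vec)
  red_vec <- as.numeric(red_vec)
  if (length(blue_vec) != 3L || length(red_vec) != 3L) {
    fq_validation_error("stain vectors must have length 3")
  }
  if (any(blue_vec < 0) || any(red_vec < 0) ||
      all(blue_vec == 0) || all(red_vec == 0)) {
    fq_validation_error("stain vectors must be nonzero with nonnegative components")
  }
  b <- blue_vec / sqrt(sum(blue_vec^2))
  r <- red_vec / sqrt(sum(red_vec^2))
  res <- c(
    b[2] * r[3] - b[3] * r[2],
    b[3] * r[1] - b[1] * r[3],
    b[1] * r[2] - b[2] * r[1]
  )
  nrm <- sqrt(sum(res^2))
  if (nrm < 1e-12) {
    fq_validation_error("stain vectors are parallel; stain matrix would be singular")
  }
  res <- res / nrm
  if (res[which.max(abs(res))] < 0) res <- -res
  M <- rbind(blue = b, red = r, residual = res)
  colnames(M) <- c("R", "G", "B")
  class(M) <- c("fq_stain_matrix", class(M))
  M
}

#' Convert an RGB image to optical density
#'
#' Applies the Beer-Lambert relation per channel:
#' `OD_c = -log10(max(I_c, 1) / I0_c)`, where `I0` is the background (blank
#' glass) intensity. Intensities of 0 are clamped to 1 so the OD stays finite.
#'
#' @param image An `H x W x 3` numeric array of intensities in \[0, 255\].
#' @param I0 Background intensity per channel, values in (0, 255\]. A scalar is
#'   recycled over channels.
#' @return An `H x W x 3` array of optical densities.
#' @examples
#' img <- array(255, dim = c(2, 2, 3))
#' rgb_to_od(img) # blank glass: all zero
#' @export
rgb_to_od <- function(image, I0 = c(255, 255, 255)) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    fq_validation_error("image must be an H x W x 3 array")
  }
  I0 <- rep_len(as.numeric(I0), 3L)
  if (any(!is.finite(I0)) || any(I0 <= 0)) {
    fq_validation_error("I0 must be positive in every channel")
  }
  od <- array(0, dim = dim(image))
  for (c in 1:3) {
    od[, , c] <- -log10(pmax(image[, , c], 1) / I0[c])
  }
  od
}

#' Estimate background (blank glass) intensity from a slide
#'
#' White-patch estimate: the given per-channel intensity quantile, capped at
#' 255. Useful when scanner white balance drifts from pure white.
#'
#' @param image `H x W x 3` intensity array.
#' @param probs Quantile used per channel (default 0.99).
#' @return Length-3 numeric vector of background intensities.
#' @export
estimate_background <- function(image, probs = 0.99) {
  vapply(1:3, function(c) {
    min(255, as.numeric(quantile(image[, , c], probs, names = FALSE)))
  }, numeric(1))
}

#' Separate an OD image into per-stain concentration maps
#'
#' Solves, per pixel, `od = c %*% M` for the concentration row vector `c`
#' (i.e. `c = od %*% solve(M)`). The methyl-blue and ponceau-fuchsin maps are
#' clipped at zero; the raw (signed) third-channel values are kept in the
#' residual map, and the fraction of pixels clipped in each stain map is
#' recorded as a diagnostic attribute.
#'
#' @param od `H x W x 3` optical-density array (from [rgb_to_od()]).
#' @param M Stain matrix from [build_stain_matrix()].
#' @return An object of class `fq_concentration_maps`: a list with `H x W`
#'   matrices `blue`, `red`, `residual`, plus attribute `clipped_fraction`.
#' @examples
#' M <- build_stain_matrix()
#' od <- array(0, dim = c(4, 4, 3))
#' maps <- deconvolve(od, M)
#' range(maps$blue)
#' @export
deconvolve <- function(od, M = build_stain_matrix()) {
  if (length(dim(od)) != 3L || dim(od)[3] != 3L) {
    fq_validation_error("od must be an H x W x 3 array")
  }
  Minv <- tryCatch(solve(unclass(M)), error = function(e) {
    fq_validation_error("stain matrix is singular")
  })
  h <- dim(od)[1]; w <- dim(od)[2]
  conc <- matrix(od, ncol = 3L) %*% Minv
  clipped <- c(
    blue = mean(conc[, 1] < -1e-12),
    red = mean(conc[, 2] < -1e-12)
  )
  out <- list(
    blue = matrix(pmax(conc[, 1], 0), h, w),
    red = matrix(pmax(conc[, 2], 0), h, w),
    residual = matrix(conc[, 3], h, w)
  )
  attr(out, "clipped_fraction") <- clipped
  class(out) <- "fq_concentration_maps"
  out
}

#' Forward Beer-Lambert synthesis of a trichrome image
#'
#' Renders an RGB image from methyl-blue and ponceau-fuchsin concentration
#' fields through the stain matrix: `I_c = I0_c * 10^-(OD_c)` with
#' `OD = c_blue * v_blue + c_red * v_red`. Optional additive Gaussian
#' intensity noise, then clipping to \[0, 255\] and (optionally) 8-bit
#' quantisation. With `noise_sd = 0` and `quantize = FALSE` this is the exact
#' inverse of [rgb_to_od()] + [deconvolve()], which makes the deconvolution
#' round-trip testable to numerical precision.
#'
#' @param c_blue,c_red `H x W` nonnegative concentration matrices.
#' @param M Stain matrix ([build_stain_matrix()]).
#' @param I0 Background intensity per channel.
#' @param noise_sd Gaussian intensity noise standard deviation (0-255 units).
#' @param quantize Round to whole 8-bit intensities?
#' @return `H x W x 3` intensity array.
#' @export
synthesize_trichrome <- function(c_blue, c_red, M = build_stain_matrix(),
                                 I0 = c(255, 255, 255), noise_sd = 0,
                                 quantize = TRUE) {
  if (!identical(dim(c_blue), dim(c_red))) {
    fq_validation_error("concentration fields must share dimensions")
  }
  I0 <- rep_len(as.numeric(I0), 3L)
  h <- nrow(c_blue); w <- ncol(c_blue)
  od <- cbind(as.numeric(c_blue), as.numeric(c_red)) %*% unclass(M)[1:2, ]
  img <- array(0, dim = c(h, w, 3))
  for (c in 1:3) {
    img[, , c] <- I0[c] * 10^(-matrix(od[, c], h, w))
  }
  if (noise_sd > 0) {
    img <- img + array(rnorm(length(img), 0, noise_sd), dim = dim(img))
  }
  img <- pmin(pmax(img, 0), 255)
  if (quantize) img <- round(img)
  img
}
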