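#' Parameters for the ab initio local-threshold picker
#'
#' The picker needs only three user-facing parameters: the particle
#' diameter in unbinned pixels, the binning factor used to speed detection,
#' and the detection threshold on the normalized deviation scale. Working
#' values on real micrographs are a bin size of 7-9 and thresholds of
#' 0.001-0.0015.
#'
#' @param particle_size particle diameter in unbinned pixels (>= 8); also
#'   the minimum allowed center-to-center distance between picks
#' @param bin_size integer binning factor (default 9)
#' @param threshold detection floor on the deviation-from-local-mean image
#'   after min-max normalization (default 0.0015)
#' @param invert pick dark particles by negating the image first
#' @param noise_k width, in robust standard deviations of the deviation
#'   image, of the automatic noise gate combined with `threshold` (see
#'   [local_threshold_mask()]); 0 disables the gate
#' @return an object of class `localpicker_params`
#' @export
localpicker_params <- function(particle_size, bin_size = 9L,
                               threshold = 0.0015, invert = FALSE,
                               noise_k = 4) {
  if (particle_size < 8) stop("particle_size must be >= 8 pixels")
  if (bin_size < 1 || bin_size != round(bin_size)) {
    stop("bin_size must be an integer >= 1")
  }
  if (threshold <= 0) stop("threshold must be > 0")
  structure(list(particle_size = particle_size,
                 bin_size = as.integer(bin_size),
                 threshold = threshold, invert = isTRUE(invert),
                 noise_k = noise_k),
            class = "localpicker_params")
}

#' Adaptive local-threshold mask
#'
#' Computes the deviation of every pixel from the mean of a square window
#' centered on it (reflective boundary handling) and switches a pixel on
#' when the deviation exceeds both the user threshold and an automatic
#' noise gate of `noise_k` pixel-noise standard deviations. The noise scale
#' is the median absolute horizontal first difference of the image divided
#' by 0.6745 sqrt(2) -- the classic difference-based estimator, blind to
#' smooth structure (particles, contaminant plateaus and their halos) and
#' robust to the thin edges they contribute. The gate adapts the fixed
#' threshold to the image's noise floor; with `noise_k = 0` the rule
#' reduces to a pure deviation-over-threshold test.
#'
#' @param image numeric matrix, already binned and min-max normalized to
#'   \[0, 1\]
#' @param window_px odd window side, >= 3 and no larger than the image
#' @param threshold detection floor on the deviation scale (> 0)
#' @param noise_k noise-gate width in robust SDs (default 4)
#' @return logical matrix of the same shape
#' @export
local_threshold_mask <- function(image, window_px, threshold,
                                 noise_k = 4) {
  image <- as_image_matrix(image)
  if (window_px %% 2 == 0 || window_px < 3) {
    stop("window_px must be odd and >= 3")
  }
  if (window_px > nrow(image) || window_px > ncol(image)) {
    stop("window_px (", window_px, ") larger than image (",
         nrow(image), "x", ncol(image), ")")
  }
  if (threshold <= 0) stop("threshold must be > 0")
  dev <- image - .cpp_box_mean_reflect(image, as.integer(window_px))
  dx <- image[, -1, drop = FALSE] - image[, -ncol(image), drop = FALSE]
  sigma <- stats::median(abs(dx)) / (0.6745 * sqrt(2))
  gate <- max(threshold, noise_k * sigma)
  dev > gate
}

#' Detect features as connected components of a threshold mask
#'
#' Labels the mask with 8-connectivity and reduces every component to its
#' deviation-weighted centroid. Components whose maximum deviation from the
#' local mean is below `threshold` are discarded.
#'
#' @param mask logical matrix from [local_threshold_mask()]
#' @param image the same normalized binned image the mask was computed from
#' @param threshold detection floor (same scale as the mask call)
#' @param window_px window used for the local mean (same as the mask call)
#' @return data.frame with 0-based centroid columns `x`, `y`, component
#'   `area` (pixels) and `peak` deviation, ordered by label
#' @export
detect_features <- function(mask, image, threshold, window_px) {
  image <- as_image_matrix(image)
  stopifnot(is.logical(mask), all(dim(mask) == dim(image)))
  if (!any(mask)) {
    return(data.frame(x = numeric(0), y = numeric(0), area = numeric(0),
                      peak = numeric(0)))
  }
  dev <- image - .cpp_box_mean_reflect(image, as.integer(window_px))
  lab <- .cpp_label8(mask)
  on <- which(mask)
  labs <- lab[on]
  yy <- (on - 1) %% nrow(mask)        # 0-based row
  xx <- (on - 1) %/% nrow(mask)       # 0-based col
  w <- pmax(dev[on], 0)
  area <- as.vector(rowsum(rep(1, length(on)), labs))
  wsum <- as.vector(rowsum(w, labs))
  # fall back to unweighted centroids for zero-weight components
  zero <- wsum <= 0
  if (any(zero)) {
    w <- ifelse(wsum[labs] <= 0, 1, w)
    wsum <- as.vector(rowsum(w, labs))
  }
  cx <- as.vector(rowsum(w * xx, labs)) / wsum
  cy <- as.vector(rowsum(w * yy, labs)) / wsum
  peak <- as.vector(tapply(dev[on], labs, max))
  keep <- peak >= threshold
  data.frame(x = cx, y = cy, area = area, peak = peak)[keep, , drop = FALSE]
}

#' Remove candidates that are too close together
#'
#' Greedy acceptance in order of descending score (ties broken by `x` then
#' `y`): a candidate is kept iff its Euclidean distance to every
#' already-accepted candidate is at least `min_dist`. Result rows are in
#' acceptance order.
#'
#' @param coords data.frame with columns `x`, `y`
#' @param min_dist minimum center-to-center distance, same pixel frame as
#'   the coordinates (>= 0)
#' @param scores ranking scores; defaults to a `score` column if present,
#'   else to input order (earlier rows win)
#' @return the surviving rows of `coords`
#' @export
enforce_min_distance <- function(coords, min_dist, scores = NULL) {
  if (min_dist < 0) stop("min_dist must be >= 0")
  if (nrow(coords) == 0) return(coords)
  if (is.null(scores)) {
    scores <- coords$score %||% rev(seq_len(nrow(coords)))
  }
  keep <- greedy_min_dist(coords$x, coords$y, scores, min_dist)
  coords[keep, , drop = FALSE]
}

#' Ab initio particle picking by adaptive local thresholding
#'
#' Pipeline: bin the micrograph, min-max normalize, threshold deviations
#' from the local mean ([local_threshold_mask()] with a window of twice the
#' binned particle diameter), label features and take their centroids
#' ([detect_features()]), map centroids back to the unbinned frame and
#' remove picks closer than one particle diameter, larger features winning
#' ([enforce_min_distance()]). Bright contaminants such as crystalline ice
#' are picked at this stage by design; the downstream class-selection and
#' CNN stages are responsible for rejecting them.
#'
#' @param mg a [micrograph()]
#' @param params a [localpicker_params()]
#' @return data.frame of picks with columns `micrograph_id`, `x`, `y`
#'   (0-based unbinned pixel centers) and `area` (feature area, binned px)
#' @export
localpick <- function(mg, params) {
  stopifnot(inherits(mg, "micrograph"),
            inherits(params, "localpicker_params"))
  img <- mg$image
  if (params$invert) img <- -img
  b <- params$bin_size
  binned <- bin_image(img, b)
  norm <- normalize01(binned)
  binned_size <- params$particle_size / b
  window <- 2L * as.integer(ceiling(binned_size)) + 1L
  window <- min(window, 2L * ((min(dim(norm)) - 1L) %/% 2L) + 1L)
  mask <- local_threshold_mask(norm, window, params$threshold,
                               params$noise_k)
  feats <- detect_features(mask, norm, params$threshold, window)
  # binned pixel j covers unbinned [j*b, (j+1)*b); centers map accordingly
  feats$x <- (feats$x + 0.5) * b - 0.5
  feats$y <- (feats$y + 0.5) * b - 0.5
  kept <- enforce_min_distance(feats, params$particle_size,
                               scores = feats$area)
  data.frame(micrograph_id = rep(mg$id, nrow(kept)),
             x = kept$x, y = kept$y, area = kept$area)
}
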