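#' Bin an image by block averaging
#'
#' Each output pixel is the mean of its `factor` x `factor` block; trailing
#' rows/columns that do not fill a block are dropped.
#'
#' @param image numeric matrix (or [micrograph()])
#' @param factor integer binning factor, at least 1
#' @return binned matrix of dimensions `floor(dim(image) / factor)`
#' @export
bin_image <- function(image, factor) {
  image <- as_image_matrix(image)
  if (length(factor) != 1 || factor < 1 || factor != round(factor)) {
    stop("factor must be a single integer >= 1")
  }
  if (factor > nrow(image) || factor > ncol(image)) {
    stop("bin factor (", factor, ") larger than image (",
         nrow(image), "x", ncol(image), ")")
  }
  .cpp_bin_image(image, as.integer(factor))
}

#' Extract, bin and standardize particle crops
#'
#' Windows of `box_px` unbinned pixels centered at each coordinate are cut
#' out, block-binned by `bin_factor`, resampled bilinearly to 64 x 64 and
#' standardized to zero mean / unit variance (a flat crop maps to zeros).
#' Coordinates whose window crosses the micrograph edge are dropped and the
#' drop count reported via the `n_dropped` attribute and a message.
#'
#' @param mg a [micrograph()]
#' @param coords data.frame with 0-based center columns `x`, `y`
#' @param box_px box side in unbinned pixels (must be divisible by
#'   `bin_factor`)
#' @param bin_factor integer binning applied inside the window
#' @return a `particle_stack`: list with `crops` (64 x 64 x N array),
#'   `source` (data.frame micrograph_id, x, y), `bin_factor` and
#'   `effective_pixel_size` (angstrom per crop pixel)
#' @export
extract_particles <- function(mg, coords, box_px, bin_factor = 1L) {
  stopifnot(inherits(mg, "micrograph"))
  box_px <- as.integer(box_px)
  bin_factor <- as.integer(bin_factor)
  if (box_px %% bin_factor != 0) {
    stop("box_px (", box_px, ") must be divisible by bin_factor (",
         bin_factor, ")")
  }
  h <- nrow(mg$image); w <- ncol(mg$image)
  if (nrow(coords) == 0) {
    return(new_particle_stack(array(0, c(64, 64, 0)),
                              data.frame(micrograph_id = character(0),
                                         x = numeric(0), y = numeric(0)),
                              bin_factor,
                              mg$pixel_size * box_px / 64, 0L))
  }
  x0 <- round(coords$x) - box_px %/% 2
  y0 <- round(coords$y) - box_px %/% 2
  ok <- x0 >= 0 & y0 >= 0 & x0 + box_px <= w & y0 + box_px <= h
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " coordinate(s) dropped: window of ", box_px,
            " px exceeds the micrograph edge")
  }
  kept <- coords[ok, , drop = FALSE]
  flat <- .cpp_extract_windows(mg$image, kept$x, kept$y, box_px, bin_factor,
                               64L)
  crops <- array(flat, c(64, 64, nrow(kept)))
  src <- data.frame(micrograph_id = rep(mg$id, nrow(kept)),
                    x = kept$x, y = kept$y)
  new_particle_stack(crops, src, bin_factor,
                     mg$pixel_size * box_px / 64, n_dropped)
}

new_particle_stack <- function(crops, source, bin_factor,
                               effective_pixel_size, n_dropped = 0L) {
  structure(list(crops = crops, source = source,
                 bin_factor = as.integer(bin_factor),
                 effective_pixel_size = effective_pixel_size),
            n_dropped = n_dropped, class = "particle_stack")
}

#' Combine particle stacks extracted with identical geometry
#' @param ... particle_stack objects
#' @return a single `particle_stack`
#' @export
combine_stacks <- function(...) {
  stacks <- list(...)
  if (length(stacks) == 1 && is.list(stacks[[1]]) &&
      !inherits(stacks[[1]], "particle_stack")) {
    stacks <- stacks[[1]]
  }
  stopifnot(length(stacks) >= 1)
  eps <- vapply(stacks, function(s) s$effective_pixel_size, numeric(1))
  if (max(eps) - min(eps) > 1e-9) {
    stop("stacks have differing effective pixel sizes")
  }
  crops <- array(unlist(lapply(stacks, function(s) s$crops)),
                 c(64, 64, sum(vapply(stacks, n_particles, integer(1)))))
  src <- do.call(rbind, lapply(stacks, function(s) s$source))
  new_particle_stack(crops, src, stacks[[1]]$bin_factor, eps[1])
}

#' Number of particles in a stack
#' @param stack a `particle_stack`
#' @return integer count
#' @export
n_particles <- function(stack) {
  if (length(dim(stack$crops)) < 3) return(0L)
  dim(stack$crops)[3]
}

subset_stack <- function(stack, idx) {
  new_particle_stack(stack$crops[, , idx, drop = FALSE],
                     stack$source[idx, , drop = FALSE],
                     stack$bin_factor, stack$effective_pixel_size)
}

#' @export
print.particle_stack <- function(x, ...) {
  cat(sprintf("<particle_stack: %d crops 64x64, bin %d, %.4g A/px>\n",
              n_particles(x), x$bin_factor, x$effective_pixel_size))
  invisible(x)
}
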