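# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# deterministic per-stage sub-seed, kept well inside 32-bit integer range
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) %% 65011 * 31 + k * 7919) %% 2147483647L)
}

# min-max normalization to [0, 1]; a constant image maps to all zeros
normalize01 <- function(image) {
  r <- range(image)
  if (r[2] - r[1] < .Machine$double.eps) {
    return(array(0, dim = dim(image)))
  }
  (image - r[1]) / (r[2] - r[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# greedy minimum-distance acceptance shared by enforce_min_distance() and
# nms(): rank by descending score (ties: x then y), accept a candidate iff
# it is >= min_dist from every already-accepted one
greedy_min_dist <- function(x, y, score, min_dist) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  ord <- order(-score, x, y)
  acc <- integer(0)
  ax <- numeric(0)
  ay <- numeric(0)
  for (i in ord) {
    if (length(acc) == 0L ||
        all((ax - x[i])^2 + (ay - y[i])^2 >= min_dist^2)) {
      acc <- c(acc, i)
      ax <- c(ax, x[i])
      ay <- c(ay, y[i])
    }
  }
  acc
}

# default crop geometry for a given particle diameter (unbinned px):
# a box ~1.2x the particle, binned so the binned box lands near 64 px
crop_geometry <- function(particle_size, box_px = NULL, bin_factor = NULL) {
  if (is.null(bin_factor)) {
    bin_factor <- max(1L, as.integer(floor(1.2 * particle_size / 64)))
  }
  if (is.null(box_px)) {
    box_px <- as.integer(bin_factor * ceiling(1.2 * particle_size / bin_factor))
  }
  if (box_px %% bin_factor != 0) {
    stop("box_px (", box_px, ") must be divisible by bin_factor (",
         bin_factor, ")")
  }
  list(box_px = as.integer(box_px), bin_factor = as.integer(bin_factor))
}

as_image_matrix <- function(image) {
  if (inherits(image, "micrograph")) image <- image$image
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("expected a numeric matrix or a micrograph")
  }
  image
}
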