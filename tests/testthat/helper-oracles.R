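# Independent reference implementations used as oracles. These are written
# naively (explicit loops, flood fill, O(n^2) scans) on purpose: they must
# not share code paths with the package internals they check.

# reflect-101 index for 1-based positions
reflect1 <- function(i, n) {
  if (n == 1) return(1)
  period <- 2 * (n - 1)
  j <- abs(i - 1) %% period
  if (j < n) j + 1 else period - j + 1
}

# brute-force windowed local mean with reflective boundaries
brute_local_mean <- function(img, window) {
  r <- window %/% 2
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (y in 1:h) {
    for (x in 1:w) {
      acc <- 0
      for (dy in -r:r) {
        for (dx in -r:r) {
          acc <- acc + img[reflect1(y + dy, h), reflect1(x + dx, w)]
        }
      }
      out[y, x] <- acc / window^2
    }
  }
  out
}

# flood-fill (8-connectivity) labelling with explicit stack
flood_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (x0 in 1:w) {
    for (y0 in 1:h) {
      if (!mask[y0, x0] || lab[y0, x0] > 0) next
      nxt <- nxt + 1L
      stack <- list(c(y0, x0))
      lab[y0, x0] <- nxt
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dy in -1:1) for (dx in -1:1) {
          y <- p[1] + dy; x <- p[2] + dx
          if (y >= 1 && y <= h && x >= 1 && x <= w &&
              mask[y, x] && lab[y, x] == 0) {
            lab[y, x] <- nxt
            stack[[length(stack) + 1]] <- c(y, x)
          }
        }
      }
    }
  }
  lab
}

# reference greedy minimum-distance filter, quadratic scan
reference_greedy <- function(x, y, score, min_dist) {
  ord <- order(-score, x, y)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if ((x[i] - x[j])^2 + (y[i] - y[j])^2 < min_dist^2) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

# tiny labelled crop set (particles vs background) built from generated
# scenes; returns list(crops, labels) with labels 1 = particle
make_crop_set <- function(n_scenes, n_particles, diameter = 48, snr = 1.0,
                          size = 640, n_contaminants = 0, master_seed = 1,
                          neg_per_pos = 1) {
  mgs <- list(); coords <- list()
  for (s in seq_len(n_scenes)) {
    p <- scene_params(size = size, n_particles = n_particles,
                      diameter = diameter, snr = snr,
                      n_contaminants = n_contaminants,
                      seed = 1000 * master_seed + s)
    sc <- generate_micrograph(p)
    mgs[[s]] <- sc$micrograph
    co <- sc$truth$centers
    co$micrograph_id <- sc$micrograph$id
    coords[[s]] <- co
  }
  ts <- make_training_set(mgs, do.call(rbind, coords), diameter,
                          neg_per_pos = neg_per_pos, seed = master_seed)
  list(crops = ts$crops, labels = ts$labels, micrographs = mgs,
       coords = do.call(rbind, coords))
}
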