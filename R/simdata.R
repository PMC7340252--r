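#' Parameters of a synthetic micrograph scene
#'
#' The generator emulates a motion-corrected cryo-EM micrograph: many
#' copies of one roughly round (disk), ring or rod particle template
#' stamped at random non-overlapping positions and orientations, optional
#' bright irregular contaminant blobs mimicking crystalline ice, and
#' additive white Gaussian noise of unit standard deviation. `snr` is the
#' particle peak amplitude over the noise standard deviation.
#'
#' @param size image side in pixels
#' @param pixel_size angstrom per pixel
#' @param n_particles particles per scene (Poisson-drawn when
#'   `jitter = TRUE`)
#' @param template `"disk"`, `"ring"`, `"rod"`, or a numeric matrix used
#'   as the template (peak expected near 1)
#' @param diameter particle diameter in pixels
#' @param snr particle peak contrast over noise sd
#' @param n_contaminants number of ice-like blobs
#' @param contaminant_scale blob intensity as a multiple of the particle
#'   amplitude (> 1; blobs are always bright)
#' @param polarity `"bright"` or `"dark"` particles
#' @param spacing_factor minimum center spacing as a multiple of the
#'   diameter (>= 1)
#' @param jitter draw the per-scene particle count from
#'   Poisson(n_particles)
#' @param seed scene seed
#' @return an object of class `scene_params`
#' @export
scene_params <- function(size = 1024L, pixel_size = 1.0, n_particles = 30L,
                         template = "disk", diameter = 60, snr = 1.0,
                         n_contaminants = 0L, contaminant_scale = 5,
                         polarity = c("bright", "dark"),
                         spacing_factor = 1.25, jitter = FALSE, seed = 0L) {
  polarity <- match.arg(polarity)
  if (snr <= 0) stop("snr must be > 0")
  if (spacing_factor < 1) stop("spacing_factor must be >= 1")
  if (contaminant_scale <= 1) stop("contaminant_scale must exceed 1")
  structure(list(size = as.integer(size), pixel_size = pixel_size,
                 n_particles = as.integer(n_particles), template = template,
                 diameter = diameter, snr = snr,
                 n_contaminants = as.integer(n_contaminants),
                 contaminant_scale = contaminant_scale, polarity = polarity,
                 spacing_factor = spacing_factor, jitter = isTRUE(jitter),
                 seed = as.integer(seed)),
            class = "scene_params")
}

#' Particle template image
#'
#' Soft-edged unit-peak templates: a disk, a ring (annulus) or a rod (bar
#' of one third the diameter in width). Edges are cosine-tapered so block
#' binning behaves smoothly.
#'
#' @param type `"disk"`, `"ring"` or `"rod"`
#' @param diameter template diameter in pixels
#' @return square numeric matrix with values in \[0, 1\]
#' @export
particle_template <- function(type = c("disk", "ring", "rod"), diameter) {
  type <- match.arg(type)
  d <- ceiling(diameter)
  c0 <- (d - 1) / 2
  xy <- seq_len(d) - 1 - c0
  r <- sqrt(outer(xy^2, xy^2, "+"))
  rmax <- diameter / 2
  taper <- max(2, 0.15 * diameter)
  soft <- function(dist) {
    v <- dist / taper
    v[v < 0] <- 0
    v[v > 1] <- 1
    v
  }
  tpl <- switch(type,
    disk = soft(rmax - r),
    ring = pmin(soft(rmax - r), soft(r - 0.45 * rmax)),
    rod = {
      ax <- abs(matrix(xy, d, d, byrow = TRUE))   # along x
      ay <- abs(matrix(xy, d, d))                 # across y
      pmin(soft(rmax - ax), soft(diameter / 6 - ay))
    })
  tpl
}

#' Generate one synthetic micrograph with ground truth
#'
#' Background is white Gaussian noise of sd 1; each particle is the
#' template rotated by a random angle and stamped with peak amplitude
#' `snr` (negated for dark polarity); contaminants are unions of random
#' ellipses at `contaminant_scale` times the particle amplitude, kept away
#' from particles. Deterministic given the scene seed.
#'
#' @param params a [scene_params()]
#' @return list with `micrograph` (a [micrograph()]) and `truth` (class
#'   `scene_truth`: `centers` data.frame, logical `contaminant_mask`,
#'   `params`)
#' @export
generate_micrograph <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, {
    sz <- params$size
    d <- params$diameter
    n_p <- if (params$jitter) rpois(1, params$n_particles) else
      params$n_particles
    margin <- d
    # ice first: contaminants occupy area, particles settle elsewhere
    cmask <- if (params$n_contaminants > 0) {
      make_contaminant_mask(params)
    } else {
      matrix(FALSE, sz, sz)
    }
    centers <- place_centers(n_p, sz, margin, params$spacing_factor * d,
                             forbidden = cmask, clearance = d)
    tpl <- if (is.matrix(params$template)) params$template else
      particle_template(params$template, d)
    # pad so rotation never clips the template
    pad_sz <- ceiling(nrow(tpl) * sqrt(2)) + 2
    pad <- matrix(0, pad_sz, pad_sz)
    off <- floor((pad_sz - nrow(tpl)) / 2)
    pad[off + seq_len(nrow(tpl)), off + seq_len(ncol(tpl))] <- tpl
    amp <- params$snr * if (params$polarity == "bright") 1 else -1

    img <- matrix(0, sz, sz)
    if (n_p > 0) {
      for (i in seq_len(n_p)) {
        stamp <- .cpp_rotate_reflect(pad, runif(1, 0, 360))
        x0 <- round(centers$x[i]) - pad_sz %/% 2
        y0 <- round(centers$y[i]) - pad_sz %/% 2
        xs <- x0 + seq_len(pad_sz); ys <- y0 + seq_len(pad_sz)
        okx <- xs >= 1 & xs <= sz; oky <- ys >= 1 & ys <= sz
        img[ys[oky], xs[okx]] <- img[ys[oky], xs[okx]] +
          amp * stamp[oky, okx]
      }
    }
    if (any(cmask)) {
      img[cmask] <- img[cmask] + params$contaminant_scale * params$snr
    }
    img <- img + matrix(rnorm(sz * sz), sz, sz)
    truth <- structure(list(centers = centers, contaminant_mask = cmask,
                            params = params),
                       class = "scene_truth")
    list(micrograph = micrograph(img, params$pixel_size,
                                 id = sprintf("sim_%06d", params$seed)),
         truth = truth)
  })
}

# rejection-sample n centers with margin from edges, a minimum spacing and
# a clearance around a forbidden (contaminant) mask
place_centers <- function(n, size, margin, min_spacing, forbidden = NULL,
                          clearance = 0) {
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  free <- if (is.null(forbidden) || !any(forbidden)) NULL else forbidden
  clear_of_mask <- function(cx, cy) {
    if (is.null(free)) return(TRUE)
    r <- ceiling(clearance)
    xs <- max(1, round(cx) + 1 - r):min(size, round(cx) + 1 + r)
    ys <- max(1, round(cy) + 1 - r):min(size, round(cy) + 1 + r)
    !any(free[ys, xs])
  }
  xs <- numeric(0); ys <- numeric(0)
  attempts <- 0L
  max_attempts <- 4000L * n
  while (length(xs) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    cx <- runif(1, margin, size - 1 - margin)
    cy <- runif(1, margin, size - 1 - margin)
    if ((length(xs) == 0 ||
         all((xs - cx)^2 + (ys - cy)^2 >= min_spacing^2)) &&
        clear_of_mask(cx, cy)) {
      xs <- c(xs, cx); ys <- c(ys, cy)
    }
  }
  if (length(xs) < n) {
    stop("could only place ", length(xs), " of ", n,
         " particles under the spacing constraints")
  }
  data.frame(x = xs, y = ys)
}

# irregular ice-like blobs: union of random ellipses per blob
make_contaminant_mask <- function(params) {
  sz <- params$size
  d <- params$diameter
  cmask <- matrix(FALSE, sz, sz)
  xg <- matrix(0:(sz - 1), sz, sz, byrow = TRUE)
  yg <- matrix(0:(sz - 1), sz, sz)
  for (blob in seq_len(params$n_contaminants)) {
    bx <- runif(1, 1.5 * d, sz - 1 - 1.5 * d)
    by <- runif(1, 1.5 * d, sz - 1 - 1.5 * d)
    # crystalline ice patches are large relative to the particle and
    # irregular: chains of anisotropic, size-diverse ellipses
    scale <- runif(1, 1.5, 3.0)
    for (e in seq_len(sample(2:6, 1))) {
      ex <- bx + runif(1, -0.35, 0.35) * d * scale
      ey <- by + runif(1, -0.35, 0.35) * d * scale
      a <- runif(1, 0.5, 1.1) * d / 2 * scale
      b <- runif(1, 0.5, 1.1) * d / 2 * scale
      th <- runif(1, 0, pi)
      u <- (xg - ex) * cos(th) + (yg - ey) * sin(th)
      v <- -(xg - ex) * sin(th) + (yg - ey) * cos(th)
      cmask <- cmask | ((u / a)^2 + (v / b)^2 <= 1)
    }
  }
  cmask
}

#' Generate a reproducible synthetic dataset
#'
#' Derives one seed per micrograph from the master seed; optionally writes
#' MRC images, ground-truth coordinate STAR files and a JSON manifest from
#' which the dataset can be regenerated exactly.
#'
#' @param n_micrographs number of micrographs (>= 1)
#' @param params a [scene_params()] shared by all micrographs
#' @param master_seed master seed (per-scene seeds are derived from it)
#' @param out_dir optional output directory
#' @return list with `micrographs`, `truths` and `manifest`
#' @export
generate_dataset <- function(n_micrographs, params, master_seed = 0L,
                             out_dir = NULL) {
  stopifnot(n_micrographs >= 1)
  seeds <- vapply(seq_len(n_micrographs), function(i) {
    derive_seed(master_seed, i)
  }, integer(1))
  scenes <- lapply(seeds, function(s) {
    p <- params
    p$seed <- s
    generate_micrograph(p)
  })
  micrographs <- lapply(scenes, `[[`, "micrograph")
  truths <- lapply(scenes, `[[`, "truth")
  manifest <- list(n_micrographs = n_micrographs, master_seed = master_seed,
                   seeds = seeds,
                   params = unclass(params)[setdiff(names(params), "seed")])
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (i in seq_len(n_micrographs)) {
      mg <- micrographs[[i]]
      write_mrc(mg, file.path(out_dir, paste0(mg$id, ".mrc")))
      write_star_coords(truths[[i]]$centers,
                        file.path(out_dir, paste0(mg$id, "_truth.star")))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(micrographs = micrographs, truths = truths, manifest = manifest)
}

#' Compare picked coordinates with ground truth
#'
#' Greedy one-to-one matching by ascending center distance: candidate
#' pairs within `tolerance_px` are accepted closest-first, each pick and
#' each truth center matching at most once.
#'
#' @param picked data.frame with `x`, `y`
#' @param truth data.frame with `x`, `y`, or a `scene_truth`
#' @param tolerance_px matching radius in pixels (> 0)
#' @return object of class `pick_metrics`: `precision`, `recall`, `f1`,
#'   `n_matched`, `mean_error_px`, `tolerance_px`
#' @export
evaluate_picks <- function(picked, truth, tolerance_px) {
  if (tolerance_px <= 0) stop("tolerance_px must be > 0")
  if (inherits(truth, "scene_truth")) truth <- truth$centers
  n_p <- nrow(picked); n_t <- nrow(truth)
  if (n_p == 0 || n_t == 0) {
    return(structure(list(precision = 0, recall = 0, f1 = 0, n_matched = 0L,
                          mean_error_px = 0, tolerance_px = tolerance_px),
                     class = "pick_metrics"))
  }
  dmat <- sqrt(outer(picked$x, truth$x, "-")^2 +
               outer(picked$y, truth$y, "-")^2)
  cand <- which(dmat <= tolerance_px, arr.ind = TRUE)
  matched_p <- logical(n_p); matched_t <- logical(n_t)
  errors <- numeric(0)
  if (nrow(cand) > 0) {
    cand <- cand[order(dmat[cand]), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!matched_p[i] && !matched_t[j]) {
        matched_p[i] <- matched_t[j] <- TRUE
        errors <- c(errors, dmat[i, j])
      }
    }
  }
  m <- sum(matched_p)
  precision <- m / n_p
  recall <- m / n_t
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(precision = precision, recall = recall, f1 = f1,
                 n_matched = m,
                 mean_error_px = if (m > 0) mean(errors) else 0,
                 tolerance_px = tolerance_px),
            class = "pick_metrics")
}

#' @export
print.pick_metrics <- function(x, ...) {
  cat(sprintf(
    "<pick_metrics: precision %.3f, recall %.3f, F1 %.3f, %d matched, mean error %.2f px (tol %g)>\n",
    x$precision, x$recall, x$f1, x$n_matched, x$mean_error_px,
    x$tolerance_px))
  invisible(x)
}

#' Fraction of picks falling inside contaminant regions
#'
#' @param picks data.frame with `x`, `y` (0-based)
#' @param mask logical contaminant mask (rows = y)
#' @return fraction in \[0, 1\] (0 for no picks)
#' @export
fraction_in_mask <- function(picks, mask) {
  if (nrow(picks) == 0) return(0)
  ix <- pmin(pmax(round(picks$x), 0), ncol(mask) - 1) + 1
  iy <- pmin(pmax(round(picks$y), 0), nrow(mask) - 1) + 1
  mean(mask[cbind(iy, ix)])
}
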