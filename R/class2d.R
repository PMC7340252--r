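#' Number of 2D classes for a given particle count
#'
#' One class per 200 particles, rounded half-up, never fewer than 2.
#'
#' @param n_particles particle count (>= 1)
#' @return integer number of classes
#' @export
num_classes <- function(n_particles) {
  if (n_particles < 1) stop("n_particles must be >= 1")
  max(2L, as.integer(floor(n_particles / 200 + 0.5)))
}

#' Reference-free 2D class averaging
#'
#' Correlation-based hard-assignment k-means over a rotation and
#' integer-shift grid: class references are seeded k-means++-style from
#' single crops (correlation distance), each round every particle is
#' assigned to the (class, rotation, shift) maximizing the normalized
#' cross-correlation, and class averages are recomputed from the aligned
#' members; several restarts are run and the one with the highest mean
#' alignment correlation kept. This is a fast,
#' deterministic stand-in for maximum-likelihood 2D classification; its
#' purpose is to rank classes for the %/Res selection rule, not to produce
#' publication-grade averages.
#'
#' @param stack a `particle_stack` (64 x 64 standardized crops)
#' @param K number of classes (>= 1; K = 1 is allowed for testing)
#' @param n_iter alternating assignment/averaging rounds
#' @param n_angles uniform in-plane rotations searched over 360 degrees
#' @param max_shift maximum integer shift searched per axis (binned px)
#' @param seed RNG seed for the initial partitions
#' @param n_start independent restarts; the run with the highest mean
#'   alignment correlation wins (alternating k-means is bistable in
#'   whether a low-correlation junk class separates)
#' @return an object of class `class2d_set`: list of per-class records
#'   (`class_id`, `average`, `member_indices`, `distribution_pct`,
#'   `resolution_A`, `ratio`) plus the assignment vector
#' @export
classify2d <- function(stack, K, n_iter = 6L, n_angles = 8L, max_shift = 2L,
                       seed = 0L, n_start = 3L) {
  N <- n_particles(stack)
  if (K > N) stop("K (", K, ") exceeds the number of particles (", N, ")")
  if (K < 1) stop("K must be >= 1")
  X <- matrix(stack$crops, nrow = 64 * 64, ncol = N)
  Xn <- normalize_columns(X)

  angles <- (seq_len(n_angles) - 1) * 360 / n_angles
  shifts <- expand.grid(dy = -max_shift:max_shift, dx = -max_shift:max_shift)
  n_tpl_per_class <- n_angles * nrow(shifts)

  # templates for a set of 64x64 reference images: all rotations x shifts
  build_templates <- function(averages) {
    Tm <- matrix(0, 64 * 64, length(averages) * n_tpl_per_class)
    col <- 0L
    for (k in seq_along(averages)) {
      for (a in angles) {
        rot <- .cpp_rotate_reflect(averages[[k]], a)
        for (s in seq_len(nrow(shifts))) {
          col <- col + 1L
          Tm[, col] <- .cpp_shift_circ(rot, shifts$dy[s], shifts$dx[s])
        }
      }
    }
    normalize_columns(Tm)
  }

  # k-means++-style seeding on single crops with alignment-correlation
  # distance: after a template-like seed is drawn, low-correlation (junk)
  # crops are far from it and likely to seed their own class, which a
  # random even partition essentially never achieves
  seed_averages <- function(run_seed) {
    with_seed(run_seed, {
      idx <- integer(K)
      idx[1] <- sample.int(N, 1)
      if (K > 1) {
        for (k in 2:K) {
          Tn <- build_templates(lapply(idx[1:(k - 1)], function(i) {
            matrix(X[, i], 64, 64)
          }))
          d <- 1 - apply(crossprod(Xn, Tn), 1, max)
          d[idx[1:(k - 1)]] <- 0
          d <- pmax(d, 0)
          idx[k] <- sample.int(N, 1, prob = d^2)
        }
      }
      lapply(idx, function(i) matrix(X[, i], 64, 64))
    })
  }

  # one alternating run; returns assignment, alignment and mean best NCC
  run_once <- function(run_seed) {
    averages <- seed_averages(run_seed)
    assign_vec <- integer(N)
    best_angle <- numeric(N)
    best_dy <- integer(N)
    best_dx <- integer(N)
    score <- 0
    for (it in seq_len(n_iter)) {
      Tn <- build_templates(averages)
      scores <- crossprod(Xn, Tn)                     # N x (K * templates)
      best <- max.col(scores, ties.method = "first")
      score <- mean(scores[cbind(seq_len(N), best)])
      assign_vec <- (best - 1L) %/% n_tpl_per_class + 1L
      within <- (best - 1L) %% n_tpl_per_class
      best_angle <- angles[within %/% nrow(shifts) + 1L]
      srow <- within %% nrow(shifts) + 1L
      best_dy <- shifts$dy[srow]
      best_dx <- shifts$dx[srow]
      for (k in seq_len(K)) {
        members <- which(assign_vec == k)
        if (length(members) == 0) next   # empty class keeps its average
        acc <- matrix(0, 64, 64)
        for (i in members) {
          tmp <- .cpp_shift_circ(matrix(X[, i], 64, 64),
                                 -best_dy[i], -best_dx[i])
          acc <- acc + .cpp_rotate_reflect(tmp, -best_angle[i])
        }
        averages[[k]] <- acc / length(members)
      }
    }
    list(assign = assign_vec, angle = best_angle, dy = best_dy,
         dx = best_dx, score = score)
  }

  # restart from several seedings, keep the highest mean alignment NCC
  runs <- lapply(seq_len(max(1L, n_start)), function(r) {
    run_once(derive_seed(seed, 7000L + r))
  })
  top <- runs[[which.max(vapply(runs, `[[`, numeric(1), "score"))]]
  assign_vec <- top$assign
  best_angle <- top$angle
  best_dy <- top$dy
  best_dx <- top$dx

  aligned_crop <- function(i) {
    crop <- matrix(X[, i], 64, 64)
    tmp <- .cpp_shift_circ(crop, -best_dy[i], -best_dx[i])
    .cpp_rotate_reflect(tmp, -best_angle[i])
  }

  classes <- vector("list", K)
  for (k in seq_len(K)) {
    members <- which(assign_vec == k)
    if (length(members) >= 2) {
      al <- array(0, c(64, 64, length(members)))
      for (j in seq_along(members)) al[, , j] <- aligned_crop(members[j])
      avg <- apply(al, c(1, 2), mean)
      # gold-standard resolution: even/odd halves refined independently so
      # that a shared alignment reference cannot correlate their noise
      h1 <- refine_half_average(X, members[seq(1, length(members), 2)],
                                angles, shifts)
      h2 <- refine_half_average(X, members[seq(2, length(members), 2)],
                                angles, shifts)
      res <- frc_resolution(array(c(h1, h2), c(64, 64, 2)),
                            stack$effective_pixel_size)
    } else {
      res <- Inf
      avg <- if (length(members) == 1) aligned_crop(members) else
        matrix(0, 64, 64)
    }
    pct <- 100 * length(members) / N
    classes[[k]] <- list(class_id = k, average = avg,
                         member_indices = members,
                         distribution_pct = pct,
                         resolution_A = res,
                         ratio = if (is.finite(res)) pct / res else 0)
  }
  structure(list(classes = classes, assignments = assign_vec, K = K,
                 n_particles = N, seed = seed),
            class = "class2d_set")
}

#' @export
print.class2d_set <- function(x, ...) {
  cat(sprintf("<class2d_set: %d classes over %d particles>\n",
              x$K, x$n_particles))
  for (cl in x$classes) {
    cat(sprintf("  class %d: %5.1f%%  res %s A  %%/Res %.3f\n",
                cl$class_id, cl$distribution_pct,
                ifelse(is.finite(cl$resolution_A),
                       sprintf("%.1f", cl$resolution_A), "unresolved"),
                cl$ratio))
  }
  invisible(x)
}

# Independently refine one half-set: align members to their own running
# average for a few rounds, starting from unaligned crops. Returns the
# refined half-average (64 x 64). X holds flattened crops column-wise.
# Two safeguards keep the resolution estimate honest: the average is a
# per-pixel 20% trimmed mean, so a small minority of unrelated members
# (e.g. a few centered particles inside a contaminant class) cannot anchor
# both half-averages; and alignment references are low-pass filtered
# (first 8 shells), so the refinement cannot manufacture correlation at
# frequencies it never saw -- only genuinely shared structure survives
# beyond the alignment cutoff.
refine_half_average <- function(X, members, angles, shifts, n_refine = 3L,
                                align_shell = 8) {
  Xm <- X[, members, drop = FALSE]
  Xn <- normalize_columns(Xm)
  trimmed_rowmean <- function(M) {
    if (ncol(M) < 5) return(rowMeans(M))
    apply(M, 1, mean, trim = 0.2)
  }
  fidx <- c(0:32, -31:-1)
  lp_mask <- sqrt(outer(fidx^2, fidx^2, "+")) <= align_shell
  lowpass <- function(img) Re(fft(fft(img) * lp_mask, inverse = TRUE)) / 4096
  al <- Xm
  for (it in seq_len(n_refine)) {
    ref <- lowpass(matrix(trimmed_rowmean(al), 64, 64))
    Tm <- matrix(0, 64 * 64, length(angles) * nrow(shifts))
    col <- 0L
    for (a in angles) {
      rot <- .cpp_rotate_reflect(ref, a)
      for (s in seq_len(nrow(shifts))) {
        col <- col + 1L
        Tm[, col] <- .cpp_shift_circ(rot, shifts$dy[s], shifts$dx[s])
      }
    }
    best <- max.col(crossprod(Xn, normalize_columns(Tm)),
                    ties.method = "first")
    ai <- (best - 1L) %/% nrow(shifts) + 1L
    si <- (best - 1L) %% nrow(shifts) + 1L
    for (j in seq_len(ncol(Xm))) {
      tmp <- .cpp_shift_circ(matrix(Xm[, j], 64, 64),
                             -shifts$dy[si[j]], -shifts$dx[si[j]])
      al[, j] <- as.vector(.cpp_rotate_reflect(tmp, -angles[ai[j]]))
    }
  }
  matrix(trimmed_rowmean(al), 64, 64)
}

# center and scale columns to unit norm (zero-norm columns stay zero)
normalize_columns <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  nrm <- sqrt(colSums(X^2))
  nrm[nrm < 1e-12] <- 1
  sweep(X, 2, nrm, "/")
}

#' Class resolution from the Fourier ring correlation of half-averages
#'
#' Members are split into even/odd halves, each averaged, and the FRC
#' computed per radial frequency shell. The resolution is the inverse
#' frequency at which the FRC first drops below 0.5 (linear interpolation
#' between shells). If the FRC never drops below 0.5 the Nyquist resolution
#' (2 x pixel size) is returned; if the first resolvable shell is already
#' below 0.5 the class carries no resolvable signal and the conventional
#' unresolved cap of 999 angstrom is returned. Fewer than 2 members give
#' `Inf` (unresolved sentinel).
#'
#' @param members 64 x 64 x m array of aligned member crops
#' @param effective_pixel_size angstrom per crop pixel
#' @return resolution in angstrom
#' @export
frc_resolution <- function(members, effective_pixel_size) {
  m <- dim(members)[3]
  if (is.na(m) || m < 2) return(Inf)
  h1 <- apply(members[, , seq(1, m, by = 2), drop = FALSE], c(1, 2), mean)
  h2 <- apply(members[, , seq(2, m, by = 2), drop = FALSE], c(1, 2), mean)
  n <- nrow(h1)
  F1 <- fft(h1)
  F2 <- fft(h2)
  fidx <- c(0:(n / 2), -(n / 2 - 1):-1)        # frequency index per axis
  r <- sqrt(outer(fidx^2, fidx^2, "+"))        # radius in shell units
  shell <- pmin(round(r), n / 2)
  num <- Re(F1 * Conj(F2))
  d1 <- Mod(F1)^2
  d2 <- Mod(F2)^2
  s_num <- as.vector(rowsum(as.vector(num), as.vector(shell)))
  s_d1 <- as.vector(rowsum(as.vector(d1), as.vector(shell)))
  s_d2 <- as.vector(rowsum(as.vector(d2), as.vector(shell)))
  denom <- sqrt(s_d1 * s_d2)
  frc <- ifelse(denom > 0, s_num / denom, 0)   # index s+1 holds shell s
  ns <- n / 2
  below <- which(frc[2:(ns + 1)] < 0.5)
  if (length(below) == 0) return(2 * effective_pixel_size)
  s <- below[1]                                 # first shell below 0.5
  if (s == 1) return(999)                       # nothing resolved
  f_hi <- frc[s + 1]
  f_lo <- frc[s]
  s_star <- (s - 1) + (f_lo - 0.5) / (f_lo - f_hi)
  min(999, n * effective_pixel_size / s_star)
}

#' Select 2D classes by the %/Res rule
#'
#' A class is selected iff its percent class distribution divided by its
#' estimated resolution in angstrom strictly exceeds `cutoff`. Works on a
#' [classify2d()] result or on external class metadata read with
#' [read_class_metadata()] (whose stored fractions are converted to percent
#' first).
#'
#' @param classes a `class2d_set` or a data.frame with columns
#'   `distribution` (fractions) and `resolution`
#' @param cutoff selection cutoff on the %/Res scale (default 0.1)
#' @return list with `selected_ids`, `particle_indices` (NULL for external
#'   metadata) and `state` (a selection record with `n_input`,
#'   `n_selected`, `selected_fraction`)
#' @export
select_classes <- function(classes, cutoff = 0.1) {
  if (inherits(classes, "class2d_set")) {
    ratios <- vapply(classes$classes, function(cl) cl$ratio, numeric(1))
    ids <- vapply(classes$classes, function(cl) cl$class_id, integer(1))
    if (length(ids) == 0) stop("empty class list")
    sel <- ratios > cutoff
    particle_indices <- sort(unlist(lapply(classes$classes[sel],
                                           function(cl) cl$member_indices)))
    n_input <- classes$n_particles
    n_selected <- length(particle_indices)
    frac <- if (n_input > 0) n_selected / n_input else 0
  } else {
    if (nrow(classes) == 0) stop("empty class list")
    pct <- classes$distribution * 100
    res <- classes$resolution
    ratios <- ifelse(is.finite(res) & res > 0, pct / res, 0)
    ids <- classes$class_id %||% seq_len(nrow(classes))
    sel <- ratios > cutoff
    particle_indices <- NULL
    n_input <- 100
    n_selected <- sum(pct[sel])
    frac <- n_selected / 100
  }
  list(selected_ids = ids[sel],
       particle_indices = particle_indices,
       ratios = ratios,
       state = selection_state(0L, n_input, n_selected, frac))
}

selection_state <- function(round, n_input, n_selected, selected_fraction) {
  structure(list(round = round, n_input = n_input, n_selected = n_selected,
                 selected_fraction = selected_fraction),
            class = "selection_state")
}

#' Iterative class-based particle selection
#'
#' Repeatedly classifies the current particle subset (with K = N / 200
#' classes) and keeps the particles of classes passing the %/Res rule,
#' stopping once at least `stop_fraction` of a round's input particles are
#' selected. A hard round cap guards against non-convergence.
#'
#' @param stack a `particle_stack`
#' @param cutoff %/Res selection cutoff (default 0.1)
#' @param stop_fraction stop once this fraction of the round's input is
#'   selected (default 0.90)
#' @param max_rounds hard cap with warning (default 10)
#' @param seed master seed; each round uses a derived sub-seed
#' @param ... further arguments passed to [classify2d()]
#' @return list with `indices` (surviving particle indices into the input
#'   stack) and `states` (one selection record per round)
#' @export
iterate_selection <- function(stack, cutoff = 0.1, stop_fraction = 0.90,
                              max_rounds = 10L, seed = 0L, ...) {
  current <- seq_len(n_particles(stack))
  states <- list()
  for (round in seq_len(max_rounds)) {
    sub <- subset_stack(stack, current)
    K <- num_classes(length(current))
    cls <- classify2d(sub, K, seed = derive_seed(seed, round), ...)
    sel <- select_classes(cls, cutoff)
    if (length(sel$particle_indices) == 0) {
      stop("selection removed every particle in round ", round,
           "; consider lowering the cutoff (currently ", cutoff, ")")
    }
    frac <- sel$state$selected_fraction
    states[[round]] <- selection_state(round, length(current),
                                       length(sel$particle_indices), frac)
    current <- current[sel$particle_indices]
    if (frac >= stop_fraction) break
    if (round == max_rounds) {
      warning("selection did not reach ", stop_fraction * 100,
              "% within ", max_rounds, " rounds; returning round-",
              max_rounds, " selection")
    }
  }
  list(indices = current, states = states)
}
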