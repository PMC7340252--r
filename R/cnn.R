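#' Configuration of the CNN particle classifier
#'
#' The network maps a standardized 64 x 64 crop to a two-way softmax
#' (background, particle): three 3 x 3 convolution blocks each followed by
#' 2 x 2 max pooling, one hidden dense layer, ReLU activations throughout,
#' cross-entropy loss, Adam optimizer. Filter counts and the hidden width
#' are configurable; the depth (exactly three conv + pool blocks) and the
#' two-output head are fixed architectural contracts.
#'
#' @param conv_filters integer vector of length 3: filters per conv block
#' @param dense_hidden hidden dense layer width
#' @param epochs training epochs (default 30)
#' @param lr Adam learning rate
#' @param batch_size minibatch size
#' @param val_fraction validation split fraction
#' @param max_angle augmentation rotation range in degrees (angles drawn
#'   uniformly in \[-max_angle, max_angle\])
#' @param seed seed for weight initialization and training shuffles
#' @return an object of class `cnn_config`
#' @export
cnn_config <- function(conv_filters = c(32L, 64L, 128L), dense_hidden = 128L,
                       epochs = 30L, lr = 1e-3, batch_size = 16L,
                       val_fraction = 0.2, max_angle = 20, seed = 0L) {
  if (length(conv_filters) != 3) stop("exactly 3 conv blocks are required")
  structure(list(conv_filters = as.integer(conv_filters),
                 dense_hidden = as.integer(dense_hidden),
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, max_angle = max_angle,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' Build an untrained CNN picker
#'
#' Weights are He-initialized deterministically from the config seed.
#'
#' @param config a [cnn_config()]
#' @return an object of class `cryo_cnn`
#' @export
build_cnn <- function(config = cnn_config()) {
  f <- config$conv_filters
  weights <- .cpp_cnn_init(f[1], f[2], f[3], config$dense_hidden,
                           config$seed)
  structure(list(weights = weights, config = config, history = NULL,
                 trained = FALSE),
            class = "cryo_cnn")
}

#' @export
print.cryo_cnn <- function(x, ...) {
  f <- x$config$conv_filters
  n_par <- sum(vapply(x$weights, length, numeric(1)))
  cat(sprintf(
    "<cryo_cnn: conv(%d,%d,%d) + dense(%d) -> 2-way softmax, %s, %d params>\n",
    f[1], f[2], f[3], x$config$dense_hidden,
    if (x$trained) "trained" else "untrained", n_par))
  invisible(x)
}

# accept a particle_stack, 64 x 64 x N array or 4096 x N matrix
crops_to_matrix <- function(crops) {
  if (inherits(crops, "particle_stack")) crops <- crops$crops
  if (is.array(crops) && length(dim(crops)) == 3) {
    stopifnot(dim(crops)[1] == 64, dim(crops)[2] == 64)
    return(matrix(crops, nrow = 64 * 64))
  }
  if (is.matrix(crops) && nrow(crops) == 64 * 64) return(crops)
  stop("crops must be a particle_stack, a 64x64xN array or a 4096xN matrix")
}

#' Predict class probabilities for particle crops
#'
#' @param object a `cryo_cnn`
#' @param crops a `particle_stack`, 64 x 64 x N array or 4096 x N matrix of
#'   standardized crops
#' @param ... unused
#' @return N x 2 matrix of probabilities with columns `background`,
#'   `particle`; rows sum to 1
#' @export
predict.cryo_cnn <- function(object, crops, ...) {
  X <- crops_to_matrix(crops)
  if (ncol(X) == 0) {
    return(matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("background", "particle"))))
  }
  P <- .cpp_cnn_predict(object$weights, X)
  colnames(P) <- c("background", "particle")
  P
}

#' Assemble a labelled training set from picked coordinates
#'
#' Positives are crops extracted at the supplied coordinates (label 1).
#' Negatives are crops at random centers rejection-sampled so that every
#' negative center lies at least one particle diameter from every positive
#' center on the same micrograph (label 0).
#'
#' @param micrographs a [micrograph()] or list of them
#' @param positive_coords data.frame with `micrograph_id`, `x`, `y`
#' @param particle_size particle diameter in unbinned pixels
#' @param neg_per_pos negatives sampled per positive (default 1)
#' @param box_px,bin_factor crop geometry; defaults derived from
#'   `particle_size` (see package docs)
#' @param seed RNG seed for negative placement
#' @return list with `crops` (64 x 64 x N), `labels` (0/1) and `source`
#' @export
make_training_set <- function(micrographs, positive_coords, particle_size,
                              neg_per_pos = 1, box_px = NULL,
                              bin_factor = NULL, seed = 0L) {
  if (inherits(micrographs, "micrograph")) micrographs <- list(micrographs)
  geom <- crop_geometry(particle_size, box_px, bin_factor)
  stacks <- list()
  labels <- list()
  for (mi in seq_along(micrographs)) {
    mg <- micrographs[[mi]]
    pos <- positive_coords[positive_coords$micrograph_id == mg$id, ,
                           drop = FALSE]
    if (nrow(pos) == 0) next
    pstack <- extract_particles(mg, pos, geom$box_px, geom$bin_factor)
    n_pos <- n_particles(pstack)
    n_neg <- round(neg_per_pos * n_pos)
    neg <- sample_negatives(mg, pos, particle_size, n_neg, geom$box_px,
                            derive_seed(seed, mi))
    nstack <- extract_particles(mg, neg, geom$box_px, geom$bin_factor)
    stacks <- c(stacks, list(pstack, nstack))
    labels <- c(labels, list(rep(1L, n_pos), rep(0L, n_particles(nstack))))
  }
  if (length(stacks) == 0) stop("no positive coordinates matched any micrograph")
  stack <- combine_stacks(stacks)
  list(crops = stack$crops, labels = unlist(labels), source = stack$source,
       stack = stack)
}

# rejection-sample n centers >= particle_size away from every positive
sample_negatives <- function(mg, pos, particle_size, n, box_px, seed) {
  h <- nrow(mg$image); w <- ncol(mg$image)
  half <- box_px %/% 2
  lo_x <- half; hi_x <- w - box_px + half - 1
  lo_y <- half; hi_y <- h - box_px + half - 1
  if (hi_x <= lo_x || hi_y <= lo_y) stop("micrograph smaller than the crop box")
  with_seed(seed, {
    out_x <- numeric(0); out_y <- numeric(0)
    attempts <- 0L
    max_attempts <- max(2000L, 500L * n)
    while (length(out_x) < n && attempts < max_attempts) {
      m <- min(4L * (n - length(out_x)), 4096L)
      attempts <- attempts + m
      cx <- runif(m, lo_x, hi_x)
      cy <- runif(m, lo_y, hi_y)
      ok <- rep(TRUE, m)
      if (nrow(pos) > 0) {
        for (j in seq_len(m)) {
          ok[j] <- all((pos$x - cx[j])^2 + (pos$y - cy[j])^2 >=
                         particle_size^2)
        }
      }
      out_x <- c(out_x, cx[ok]); out_y <- c(out_y, cy[ok])
    }
    if (length(out_x) < n) {
      stop("could only place ", length(out_x), " of ", n,
           " negatives at >= ", particle_size, " px from positives on '",
           mg$id, "'")
    }
    data.frame(micrograph_id = rep(mg$id, n),
               x = out_x[seq_len(n)], y = out_y[seq_len(n)])
  })
}

#' Augment a batch of crops
#'
#' Each crop independently receives a rotation with angle uniform in
#' \[-max_angle, +max_angle\] (reflect-padded, recropped to 64 x 64), then a
#' horizontal and a vertical flip each with probability 0.5. Deterministic
#' given the seed.
#'
#' @param crops 64 x 64 x N array or 4096 x N matrix
#' @param seed RNG seed
#' @param max_angle rotation range in degrees
#' @return augmented crops in the same layout as the input
#' @export
augment_batch <- function(crops, seed = 0L, max_angle = 20) {
  X <- crops_to_matrix(crops)
  A <- .cpp_augment(X, as.integer(seed), max_angle)
  if (is.array(crops) && length(dim(crops)) == 3) {
    array(A, dim(crops))
  } else {
    A
  }
}

#' Train the CNN picker
#'
#' Stratified validation split, augmentation applied to the training
#' portion only (re-drawn every epoch), minibatch Adam on the two-way
#' softmax cross-entropy. A warning is emitted when fewer than 100 positive
#' examples are supplied, below which training is known to be unreliable.
#'
#' @param model a `cryo_cnn` from [build_cnn()]
#' @param crops training crops (`particle_stack`, array or matrix)
#' @param labels 0 (background) / 1 (particle) per crop
#' @param epochs number of epochs; defaults to the model config
#' @param val_fraction validation fraction; defaults to the model config
#' @param seed seed for split/shuffles/augmentation; defaults to config
#' @param augment apply augmentation to the training portion
#' @return the trained `cryo_cnn` with a `history` data.frame (per-epoch
#'   train/validation loss and accuracy)
#' @export
train_cnn <- function(model, crops, labels, epochs = NULL,
                      val_fraction = NULL, seed = NULL, augment = TRUE) {
  stopifnot(inherits(model, "cryo_cnn"))
  X <- crops_to_matrix(crops)
  labels <- as.integer(labels)
  stopifnot(length(labels) == ncol(X))
  if (length(unique(labels)) < 2) {
    stop("training labels contain a single class; ",
         "need both particles (1) and background (0)")
  }
  n_pos <- sum(labels == 1)
  if (n_pos < 100) {
    warning("only ", n_pos, " positive examples; at least 100 particles ",
            "are recommended for reliable training")
  }
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  val_fraction <- val_fraction %||% cfg$val_fraction
  seed <- seed %||% cfg$seed
  idx_val <- with_seed(derive_seed(seed, 1L), {
    unlist(lapply(split(seq_along(labels), labels), function(ix) {
      sample(ix, round(val_fraction * length(ix)))
    }))
  })
  idx_tr <- setdiff(seq_along(labels), idx_val)
  fit <- .cpp_cnn_train(model$weights,
                        X[, idx_tr, drop = FALSE], labels[idx_tr],
                        X[, idx_val, drop = FALSE], labels[idx_val],
                        epochs, cfg$batch_size, cfg$lr,
                        derive_seed(seed, 2L), isTRUE(augment),
                        cfg$max_angle)
  model$weights <- fit$weights
  model$history <- data.frame(epoch = seq_len(epochs),
                              train_loss = fit$history[, 1],
                              train_accuracy = fit$history[, 2],
                              val_loss = fit$history[, 3],
                              val_accuracy = fit$history[, 4])
  model$trained <- TRUE
  model
}

#' Scan a micrograph with the CNN
#'
#' Slides a window of one crop box over the micrograph at the given stride,
#' extracts/bins/standardizes every window exactly as training crops, and
#' returns window centers whose particle probability reaches `p_min`.
#'
#' @param model a trained `cryo_cnn`
#' @param mg a [micrograph()]
#' @param particle_size particle diameter in unbinned pixels
#' @param stride scan stride in unbinned pixels (default particle_size / 4)
#' @param p_min minimum particle probability (default 0.9); 0 returns every
#'   window
#' @param box_px,bin_factor crop geometry; defaults from `particle_size`
#' @return data.frame of candidates: `x`, `y`, `prob`
#' @export
scan_micrograph <- function(model, mg, particle_size, stride = NULL,
                            p_min = 0.9, box_px = NULL, bin_factor = NULL) {
  stopifnot(inherits(model, "cryo_cnn"), inherits(mg, "micrograph"))
  geom <- crop_geometry(particle_size, box_px, bin_factor)
  box <- geom$box_px
  h <- nrow(mg$image); w <- ncol(mg$image)
  if (h < box || w < box) {
    stop("micrograph (", h, "x", w, ") smaller than the scan box (", box, ")")
  }
  stride <- stride %||% max(1L, round(particle_size / 4))
  half <- box %/% 2
  xs <- seq(half, w - box + half, by = stride)
  ys <- seq(half, h - box + half, by = stride)
  grid <- expand.grid(x = xs, y = ys)
  probs <- numeric(nrow(grid))
  chunk <- 2048L
  for (i0 in seq(1, nrow(grid), by = chunk)) {
    i1 <- min(nrow(grid), i0 + chunk - 1L)
    flat <- .cpp_extract_windows(mg$image, grid$x[i0:i1], grid$y[i0:i1],
                                 box, geom$bin_factor, 64L)
    probs[i0:i1] <- .cpp_cnn_predict(model$weights, flat)[, 2]
  }
  keep <- probs >= p_min
  data.frame(x = grid$x[keep], y = grid$y[keep], prob = probs[keep])
}

#' Non-maximum suppression of scored candidates
#'
#' Greedy by descending probability (ties broken by `x` then `y`): of two
#' candidates closer than `min_dist` the one with the higher probability is
#' kept.
#'
#' @param candidates data.frame with `x`, `y`, `prob`
#' @param min_dist minimum center-to-center distance
#' @return surviving candidates in acceptance order
#' @export
nms <- function(candidates, min_dist) {
  if (nrow(candidates) == 0) return(candidates)
  keep <- greedy_min_dist(candidates$x, candidates$y, candidates$prob,
                          min_dist)
  candidates[keep, , drop = FALSE]
}

#' Pick particles on a micrograph with a trained CNN
#'
#' [scan_micrograph()] followed by [nms()] with a minimum distance of one
#' particle diameter.
#'
#' @inheritParams scan_micrograph
#' @return data.frame of picks: `micrograph_id`, `x`, `y`, `score`
#' @export
cnn_pick <- function(model, mg, particle_size, p_min = 0.9, stride = NULL,
                     box_px = NULL, bin_factor = NULL) {
  cand <- scan_micrograph(model, mg, particle_size, stride = stride,
                          p_min = p_min, box_px = box_px,
                          bin_factor = bin_factor)
  kept <- nms(cand, particle_size)
  data.frame(micrograph_id = rep(mg$id, nrow(kept)),
             x = kept$x, y = kept$y, score = kept$prob)
}
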