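test_that("softmax output contract and deterministic initialization", {
  set.seed(2)
  X <- matrix(rnorm(4096 * 8), 4096, 8)
  m1 <- build_cnn(cnn_config(seed = 5))
  p1 <- predict(m1, X)
  expect_equal(dim(p1), c(8, 2))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_equal(rowSums(p1), rep(1, 8), tolerance = 1e-6)

  m2 <- build_cnn(cnn_config(seed = 5))
  expect_identical(predict(m2, X), p1)
  m3 <- build_cnn(cnn_config(seed = 6))
  expect_false(identical(predict(m3, X), p1))
})

test_that("make_training_set balances labels and respects the exclusion radius", {
  p <- scene_params(size = 512, n_particles = 15, diameter = 48, snr = 1,
                    seed = 19)
  sc <- generate_micrograph(p)
  co <- sc$truth$centers
  co$micrograph_id <- sc$micrograph$id
  ts <- make_training_set(sc$micrograph, co, 48, neg_per_pos = 1, seed = 2)
  expect_equal(sum(ts$labels == 1), 15)
  expect_equal(sum(ts$labels == 0), 15)
  neg <- ts$source[ts$labels == 0, ]
  for (i in seq_len(nrow(neg))) {
    expect_gte(min(sqrt((co$x - neg$x[i])^2 + (co$y - neg$y[i])^2)), 48)
  }
})

test_that("negative sampling fails informatively on a fully tiled micrograph", {
  img <- matrix(rnorm(128 * 128), 128, 128)
  mg <- micrograph(img, 1, id = "tiled")
  co <- expand.grid(x = seq(10, 118, by = 22), y = seq(10, 118, by = 22))
  co$micrograph_id <- "tiled"
  expect_error(
    make_training_set(mg, co, particle_size = 100, box_px = 24,
                      bin_factor = 1, seed = 1),
    "could only place")
})

test_that("augmentation is seeded and built from exact symmetries", {
  set.seed(3)
  crops <- array(rnorm(64 * 64 * 5), c(64, 64, 5))
  a1 <- augment_batch(crops, seed = 11)
  a2 <- augment_batch(crops, seed = 11)
  expect_identical(a1, a2)
  expect_false(identical(a1, augment_batch(crops, seed = 12)))

  img <- matrix(rnorm(64 * 64), 64, 64)
  expect_equal(cryopick:::.cpp_rotate_reflect(img, 0), img)
  # horizontal + vertical flip equals a 180-degree rotation
  flipped <- img[64:1, 64:1]
  expect_equal(cryopick:::.cpp_rotate_reflect(img, 180), flipped,
               tolerance = 1e-12)
})

test_that("training learns an easy task and guards its inputs", {
  cs <- make_crop_set(n_scenes = 4, n_particles = 25, size = 640,
                      master_seed = 7)
  m <- build_cnn(cnn_config(seed = 1))
  expect_error(train_cnn(m, cs$crops, rep(1, length(cs$labels))),
               "single class")
  m <- train_cnn(m, cs$crops, cs$labels, epochs = 6)
  expect_true(m$trained)
  expect_equal(nrow(m$history), 6)
  expect_true(all(m$history$train_accuracy >= 0 &
                  m$history$train_accuracy <= 1))
  expect_true(all(m$history$val_loss >= 0))
  expect_gt(tail(m$history$val_accuracy, 1), 0.9)

  # learned-signal property: held-out particles score far above background
  hold <- make_crop_set(n_scenes = 1, n_particles = 20, size = 640,
                        master_seed = 8)
  pr <- predict(m, hold$crops)[, "particle"]
  expect_gte(mean(pr[hold$labels == 1]) - mean(pr[hold$labels == 0]), 0.5)
})

test_that("too few positives trigger a warning but training proceeds", {
  cs <- make_crop_set(n_scenes = 1, n_particles = 12, size = 512,
                      master_seed = 5)
  m <- build_cnn(cnn_config(seed = 0))
  expect_warning(m <- train_cnn(m, cs$crops, cs$labels, epochs = 1),
                 "at least 100")
  expect_true(m$trained)
})

test_that("scan geometry: threshold off returns the full window grid", {
  img <- matrix(rnorm(300 * 260), 260, 300)
  mg <- micrograph(img, 1, id = "g")
  m <- build_cnn(cnn_config(seed = 2))
  cand <- scan_micrograph(m, mg, particle_size = 48, stride = 16,
                          p_min = 0, box_px = 64, bin_factor = 1)
  nx <- length(seq(32, 300 - 64 + 32, by = 16))
  ny <- length(seq(32, 260 - 64 + 32, by = 16))
  expect_equal(nrow(cand), nx * ny)
  # grid coverage: any point in the scanned area has a window center
  # within stride * sqrt(2) / 2
  expect_true(all(diff(sort(unique(cand$x))) == 16))
  expect_error(scan_micrograph(m, micrograph(matrix(0, 64, 64), 1),
                               particle_size = 48, box_px = 70),
               "smaller than the scan box")
})

test_that("scan windows and training crops produce identical inputs", {
  p <- scene_params(size = 384, n_particles = 8, diameter = 48, seed = 23)
  sc <- generate_micrograph(p)
  m <- build_cnn(cnn_config(seed = 3))
  geom <- cryopick:::crop_geometry(48)
  # a scan-grid center: stride 12, box 58 -> centers at 29 + 12 k
  center <- data.frame(micrograph_id = sc$micrograph$id, x = 29 + 12 * 8,
                       y = 29 + 12 * 5)
  stack <- extract_particles(sc$micrograph, center, geom$box_px,
                             geom$bin_factor)
  p_train <- predict(m, stack)[1, "particle"]
  cand <- scan_micrograph(m, sc$micrograph, 48, p_min = 0)
  row <- cand[cand$x == center$x & cand$y == center$y, ]
  expect_equal(nrow(row), 1)
  expect_identical(row$prob, unname(p_train))
})

test_that("nms keeps the higher-probability pick and matches the reference", {
  two <- data.frame(x = c(0, 5), y = c(0, 0), prob = c(0.95, 0.92))
  kept <- nms(two, 10)
  expect_equal(kept$x, 0)

  far <- data.frame(x = c(0, 100), y = c(0, 0), prob = c(0.5, 0.6))
  expect_equal(nrow(nms(far, 10)), 2)

  set.seed(29)
  cand <- data.frame(x = runif(200, 0, 500), y = runif(200, 0, 500),
                     prob = runif(200))
  got <- nms(cand, 40)
  ref <- reference_greedy(cand$x, cand$y, cand$prob, 40)
  expect_equal(as.integer(rownames(got)), ref)

  # invariant to input order
  perm <- sample(200)
  got2 <- nms(cand[perm, ], 40)
  expect_equal(sort(got2$x), sort(got$x))
  expect_equal(got2$x, got$x)   # same acceptance order too
})

test_that("cnn_pick output respects spacing and is deterministic", {
  p <- scene_params(size = 384, n_particles = 10, diameter = 48, seed = 31)
  sc <- generate_micrograph(p)
  m <- build_cnn(cnn_config(seed = 9))   # untrained: only contracts checked
  picks <- cnn_pick(m, sc$micrograph, 48, p_min = 0.5)
  if (nrow(picks) > 1) {
    d <- as.matrix(dist(picks[, c("x", "y")]))
    expect_true(all(d[upper.tri(d)] >= 48))
  }
  expect_identical(picks, cnn_pick(m, sc$micrograph, 48, p_min = 0.5))
})
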