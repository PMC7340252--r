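test_that("local_threshold_mask matches a brute-force windowed-mean oracle", {
  set.seed(11)
  img <- matrix(runif(64 * 64), 64, 64)
  for (window in c(5, 9)) {
    lm <- brute_local_mean(img, window)
    dev <- img - lm
    # pure deviation rule (gate disabled)
    expect_identical(local_threshold_mask(img, window, 0.01, noise_k = 0),
                     dev > 0.01)
    # default rule with the robust noise gate, reproduced independently
    diffs <- numeric(0)
    for (y in 1:64) for (x in 1:63) {
      diffs <- c(diffs, img[y, x + 1] - img[y, x])
    }
    gate <- max(0.01, 4 * median(abs(diffs)) / (0.6745 * sqrt(2)))
    expect_identical(local_threshold_mask(img, window, 0.01),
                     dev > gate)
  }
})

test_that("mask edge cases: constant image, single bright pixel, bad window", {
  flat <- matrix(0.5, 32, 32)
  expect_false(any(local_threshold_mask(flat, 5, 0.001)))

  img <- matrix(0, 32, 32)
  img[16, 16] <- 1
  m <- local_threshold_mask(img, 5, 0.001)
  expect_true(m[16, 16])          # deviation 24/25 over threshold

  expect_error(local_threshold_mask(img, 4, 0.01), "odd")
  expect_error(local_threshold_mask(img, 33, 0.01), "larger than image")
  expect_error(local_threshold_mask(img, 5, 0), "> 0")
})

test_that("detect_features labels components like a flood-fill reference", {
  set.seed(21)
  # scatter 20 non-touching 2x2..3x3 blobs on a 96x96 canvas
  img <- matrix(0, 96, 96)
  centers <- expand.grid(x = seq(8, 88, by = 20), y = seq(8, 88, by = 20))
  centers <- centers[sample(nrow(centers), 20), ]
  for (k in seq_len(20)) {
    s <- sample(2:3, 1)
    ys <- centers$y[k] + seq_len(s) - 1
    xs <- centers$x[k] + seq_len(s) - 1
    img[ys, xs] <- runif(s * s, 0.8, 1)
  }
  window <- 9
  mask <- local_threshold_mask(img, window, 0.05, noise_k = 0)
  feats <- detect_features(mask, img, 0.05, window)

  lab_ref <- flood_label(mask)
  expect_equal(nrow(feats), max(lab_ref))
  # reference centroids with the same deviation weights
  dev <- img - brute_local_mean(img, window)
  ref <- t(sapply(seq_len(max(lab_ref)), function(l) {
    px <- which(lab_ref == l, arr.ind = TRUE)
    w <- pmax(dev[px], 0)
    c(x = sum(w * (px[, 2] - 1)) / sum(w),
      y = sum(w * (px[, 1] - 1)) / sum(w))
  }))
  ord_f <- order(round(feats$x), round(feats$y))
  ord_r <- order(round(ref[, "x"]), round(ref[, "y"]))
  expect_equal(feats$x[ord_f], ref[ord_r, "x"], tolerance = 1e-10)
  expect_equal(feats$y[ord_f], ref[ord_r, "y"], tolerance = 1e-10)
})

test_that("detect_features handles empty masks and symmetric blobs", {
  img <- matrix(0, 64, 64)
  mask <- matrix(FALSE, 64, 64)
  expect_equal(nrow(detect_features(mask, img, 0.01, 5)), 0)

  img[10:12, 20:22] <- 1
  img[40:42, 50:52] <- 1
  mask <- local_threshold_mask(img, 9, 0.05, noise_k = 0)
  feats <- detect_features(mask, img, 0.05, 9)
  expect_equal(nrow(feats), 2)
  feats <- feats[order(feats$x), ]
  expect_equal(feats$x, c(20, 50), tolerance = 0.01)  # 0-based centers
  expect_equal(feats$y, c(10, 40), tolerance = 0.01)
})

test_that("enforce_min_distance equals the quadratic reference greedy", {
  set.seed(31)
  n <- 50
  coords <- data.frame(x = runif(n, 0, 200), y = runif(n, 0, 200))
  scores <- runif(n)
  got <- enforce_min_distance(coords, 20, scores = scores)
  ref <- reference_greedy(coords$x, coords$y, scores, 20)
  expect_equal(as.integer(rownames(got)), ref)   # acceptance order too
  d <- as.matrix(dist(got[, c("x", "y")]))
  expect_true(all(d[upper.tri(d)] >= 20))
})

test_that("enforce_min_distance dominance, identity and error cases", {
  two <- data.frame(x = c(0, 5), y = c(0, 0))
  kept <- enforce_min_distance(two, 10, scores = c(0.9, 0.8))
  expect_equal(nrow(kept), 1)
  expect_equal(kept$x, 0)

  all_kept <- enforce_min_distance(two, 0, scores = c(0.9, 0.8))
  expect_equal(nrow(all_kept), 2)
  expect_error(enforce_min_distance(two, -1), ">= 0")
})

test_that("localpick recovers separated disks and is deterministic", {
  p <- scene_params(size = 1024, n_particles = 30, diameter = 60, snr = 1.0,
                    seed = 12)
  sc <- generate_micrograph(p)
  lp <- localpicker_params(60)
  picks <- localpick(sc$micrograph, lp)
  m <- evaluate_picks(picks, sc$truth, 30)
  expect_gte(m$recall, 0.85)
  expect_gte(m$precision, 0.8)
  # deterministic
  expect_identical(picks, localpick(sc$micrograph, lp))
  # all pairwise distances respect the particle size
  d <- as.matrix(dist(picks[, c("x", "y")]))
  expect_true(all(d[upper.tri(d)] >= 60))
})

test_that("picking is invariant to affine intensity rescaling", {
  p <- scene_params(size = 512, n_particles = 12, diameter = 48, snr = 1.0,
                    seed = 4)
  sc <- generate_micrograph(p)
  lp <- localpicker_params(48)
  base <- localpick(sc$micrograph, lp)
  scaled <- micrograph(3.7 * sc$micrograph$image + 42, 1.0,
                       id = sc$micrograph$id)
  expect_equal(localpick(scaled, lp)[, c("x", "y")], base[, c("x", "y")],
               tolerance = 1e-9)
})

test_that("bright ice contaminants are picked by the ab initio stage", {
  p <- scene_params(size = 768, n_particles = 20, diameter = 60, snr = 1.0,
                    n_contaminants = 3, seed = 6)
  sc <- generate_micrograph(p)
  picks <- localpick(sc$micrograph, localpicker_params(60))
  n_in_ice <- sum(sc$truth$contaminant_mask[
    cbind(round(picks$y) + 1, round(picks$x) + 1)])
  expect_gte(n_in_ice, 2)   # expected pre-CNN behavior
})

test_that("a blank noise micrograph yields almost no picks", {
  counts <- vapply(1:3, function(s) {
    p <- scene_params(size = 1024, n_particles = 0, diameter = 60, seed = s)
    sc <- generate_micrograph(p)
    nrow(localpick(sc$micrograph,
                   localpicker_params(60, threshold = 0.05)))
  }, numeric(1))
  expect_lte(max(counts), 2)
})
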