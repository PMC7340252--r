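test_that("a null scene is unit-variance noise and scenes are reproducible", {
  p <- scene_params(size = 256, n_particles = 0, diameter = 20, seed = 8)
  sc <- generate_micrograph(p)
  expect_lt(abs(sd(sc$micrograph$image) - 1), 0.05)
  expect_equal(nrow(sc$truth$centers), 0)

  sc2 <- generate_micrograph(p)
  expect_identical(sc$micrograph$image, sc2$micrograph$image)
})

test_that("scene generation leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_micrograph(scene_params(size = 128, n_particles = 2,
                                             diameter = 16, seed = 1)))
  expect_identical(runif(1), before)
})

test_that("requested SNR matches the stamped contrast", {
  # mean image value at particle centers minus the background median,
  # averaged over scenes, estimates the peak amplitude = snr * noise sd
  for (snr in c(1, 3)) {
    vals <- numeric(0)
    for (s in 1:10) {
      p <- scene_params(size = 384, n_particles = 12, diameter = 32,
                        snr = snr, seed = 500 + s)
      sc <- generate_micrograph(p)
      img <- sc$micrograph$image
      ctr <- sc$truth$centers
      vals <- c(vals, img[cbind(round(ctr$y) + 1, round(ctr$x) + 1)] -
                  median(img))
    }
    expect_lt(abs(mean(vals) - snr) / snr, 0.1)
  }
})

test_that("high-SNR disks are detectable at their stated centers", {
  p <- scene_params(size = 512, n_particles = 20, diameter = 40, snr = 10,
                    seed = 77)
  sc <- generate_micrograph(p)
  sm <- bin_image(sc$micrograph$image, 4)
  for (i in seq_len(20)) {
    cx <- (sc$truth$centers$x[i] + 0.5) / 4 - 0.5
    cy <- (sc$truth$centers$y[i] + 0.5) / 4 - 0.5
    win_x <- round(cx) + 1 + (-2:2)
    win_y <- round(cy) + 1 + (-2:2)
    local <- sm[win_y, win_x]
    # the local maximum of the smoothed image sits within 2 binned px
    expect_gte(max(local), max(sm[round(cy) + 1 + (-8:-6), win_x]))
  }
})

test_that("particle spacing and edge margins hold in every scene", {
  for (s in 1:5) {
    p <- scene_params(size = 384, n_particles = 15, diameter = 30,
                      seed = 40 + s)
    sc <- generate_micrograph(p)
    ctr <- sc$truth$centers
    d <- as.matrix(dist(ctr))
    expect_true(all(d[upper.tri(d)] >= 1.25 * 30))
    expect_true(all(ctr$x >= 30 & ctr$x <= 384 - 1 - 30))
    expect_true(all(ctr$y >= 30 & ctr$y <= 384 - 1 - 30))
  }
})

test_that("impossible packing is refused with the achievable count", {
  p <- scene_params(size = 256, n_particles = 200, diameter = 60, seed = 1)
  expect_error(generate_micrograph(p), "could only place")
})

test_that("generate_dataset writes a regenerable set of files", {
  p <- scene_params(size = 128, n_particles = 3, diameter = 16, seed = 0)
  dir <- withr::local_tempdir()
  ds <- generate_dataset(4, p, master_seed = 9, out_dir = dir)
  expect_length(ds$micrographs, 4)
  expect_length(list.files(dir, pattern = "\\.mrc$"), 4)
  expect_length(list.files(dir, pattern = "_truth\\.star$"), 4)
  expect_true(file.exists(file.path(dir, "manifest.json")))

  # regeneration from the manifest parameters is exact
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  p2 <- do.call(scene_params, mf$params[setdiff(names(mf$params),
                                                c("template"))] |>
                  c(list(template = mf$params$template)))
  ds2 <- generate_dataset(mf$n_micrographs, p2, master_seed = mf$master_seed)
  expect_identical(ds$micrographs[[2]]$image, ds2$micrographs[[2]]$image)

  # per-scene seeds differ, so scenes differ
  expect_false(identical(ds$micrographs[[1]]$image,
                         ds$micrographs[[2]]$image))
})

test_that("Poisson jitter keeps the mean particle count on target", {
  p <- scene_params(size = 256, n_particles = 12, diameter = 20,
                    jitter = TRUE, seed = 0)
  ds <- generate_dataset(20, p, master_seed = 3)
  counts <- vapply(ds$truths, function(tr) nrow(tr$centers), numeric(1))
  expect_lt(abs(mean(counts) - 12) / 12, 0.15)
  expect_gt(var(counts), 0)
})

test_that("evaluate_picks counts matches, misses and spurious picks", {
  truth <- data.frame(x = c(10, 50, 90), y = c(10, 50, 90))
  m <- evaluate_picks(truth, truth, 5)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$mean_error_px, 0)

  spurious <- rbind(truth, data.frame(x = 200, y = 200))
  m2 <- evaluate_picks(spurious, truth, 5)
  expect_equal(m2$precision, 3 / 4)
  expect_equal(m2$recall, 1)

  none <- evaluate_picks(truth[0, ], truth, 5)
  expect_equal(none$precision, 0)
  expect_equal(none$recall, 0)
  expect_error(evaluate_picks(truth, truth, 0), "> 0")
})

test_that("greedy matching equals optimal assignment on separable cases", {
  set.seed(13)
  truth <- data.frame(x = runif(50, 0, 1000), y = runif(50, 0, 1000))
  picked <- truth + matrix(rnorm(100, sd = 1), 50, 2)   # jitter << tol
  decoys <- data.frame(x = runif(10, 2000, 3000), y = runif(10, 2000, 3000))
  picked <- rbind(setNames(picked, c("x", "y")), decoys)
  tol <- 20
  m <- evaluate_picks(picked, truth, tol)

  # independent maximum bipartite matching oracle (igraph)
  dmat <- sqrt(outer(picked$x, truth$x, "-")^2 +
               outer(picked$y, truth$y, "-")^2)
  edges <- which(dmat <= tol, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = nrow(picked) + nrow(truth),
                                directed = FALSE)
  g <- igraph::add_edges(g, rbind(edges[, 1], nrow(picked) + edges[, 2]))
  igraph::V(g)$type <- c(rep(FALSE, nrow(picked)), rep(TRUE, nrow(truth)))
  opt <- igraph::max_bipartite_match(g)$matching_size
  expect_equal(m$n_matched, opt)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 50 / 60)
})

test_that("recall is non-decreasing in the matching tolerance", {
  set.seed(17)
  truth <- data.frame(x = runif(30, 50, 450), y = runif(30, 50, 450))
  picked <- data.frame(x = truth$x + rnorm(30, sd = 8),
                       y = truth$y + rnorm(30, sd = 8))
  tols <- c(2, 5, 10, 20, 40)
  recalls <- vapply(tols, function(t) evaluate_picks(picked, truth, t)$recall,
                    numeric(1))
  expect_true(all(diff(recalls) >= 0))
})
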