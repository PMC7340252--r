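test_that("num_classes implements the one-per-200 rule with floor 2", {
  expect_equal(num_classes(1000), 5)
  expect_equal(num_classes(150), 2)     # floor guard
  expect_equal(num_classes(4656), 23)
  expect_equal(num_classes(1), 2)
  expect_equal(num_classes(500), 3)     # 2.5 rounds half-up
  expect_error(num_classes(0), ">= 1")
})

# build a stack of rotated template copies with light noise; splits each
# request over as many 45-particle scenes as needed to keep packing easy
template_stack <- function(types, n_each, seed = 1, snr = 20) {
  crops <- list()
  for (ti in seq_along(types)) {
    got <- 0L
    sub <- list()
    sc_i <- 0L
    while (got < n_each) {
      sc_i <- sc_i + 1L
      take <- min(45L, n_each - got)
      p <- scene_params(size = 768, n_particles = take, diameter = 48,
                        template = types[ti], snr = snr,
                        seed = seed * 1000 + ti * 100 + sc_i)
      sc <- generate_micrograph(p)
      sub[[sc_i]] <- extract_particles(sc$micrograph, sc$truth$centers,
                                       box_px = 64)
      got <- got + take
    }
    crops[[ti]] <- combine_stacks(sub)
  }
  list(stack = combine_stacks(crops),
       labels = rep(seq_along(types), each = n_each))
}

test_that("classify2d separates two distinct templates perfectly", {
  ts <- template_stack(c("disk", "ring"), 100)
  cls <- classify2d(ts$stack, K = 2, seed = 7)
  a <- cls$assignments
  # perfect co-assignment up to label swap
  tab <- table(a, ts$labels)
  expect_equal(sum(apply(tab, 1, max)), length(a))
  # distribution sums to 100
  pct <- vapply(cls$classes, `[[`, numeric(1), "distribution_pct")
  expect_equal(sum(pct), 100, tolerance = 1e-6)
})

test_that("classify2d is deterministic and supports K = 1", {
  ts <- template_stack("disk", 60)
  c1 <- classify2d(ts$stack, K = 3, seed = 42)
  c2 <- classify2d(ts$stack, K = 3, seed = 42)
  expect_identical(c1$assignments, c2$assignments)

  k1 <- classify2d(ts$stack, K = 1, seed = 0)
  expect_equal(k1$classes[[1]]$distribution_pct, 100, tolerance = 1e-9)
  expect_error(classify2d(ts$stack, K = 100), "exceeds")
})

test_that("frc_resolution: perfect halves give Nyquist, noise gives the unresolved cap", {
  tpl <- particle_template("disk", 40)
  img <- matrix(0, 64, 64)
  img[13:52, 13:52] <- tpl
  members <- array(rep(img, 4), c(64, 64, 4))
  expect_equal(frc_resolution(members, 1.5), 3.0)   # 2 x pixel size

  set.seed(5)
  noise <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
  expect_equal(frc_resolution(noise, 1.5), 999)

  expect_equal(frc_resolution(array(0, c(64, 64, 1)), 1), Inf)
})

test_that("frc_resolution finds a constructed crossover within one shell", {
  # two members sharing signal strictly below shell s0, independent above
  set.seed(9)
  n <- 64
  s0 <- 10
  fidx <- c(0:(n / 2), -(n / 2 - 1):-1)
  r <- sqrt(outer(fidx^2, fidx^2, "+"))
  lo <- r < s0
  hi <- !lo
  common <- fft(matrix(rnorm(n * n), n, n))
  mk <- function() {
    own <- fft(matrix(rnorm(n * n), n, n))
    Re(fft(common * lo + own * hi, inverse = TRUE)) / (n * n)
  }
  members <- array(c(mk(), mk()), c(n, n, 2))
  apix <- 1.2
  res <- frc_resolution(members, apix)
  # crossing between shells s0 - 1 and s0
  expect_gte(res, n * apix / s0)
  expect_lte(res, n * apix / (s0 - 1))
})

test_that("select_classes applies the strict %/Res rule on both input paths", {
  md <- data.frame(class_id = 1:3,
                   distribution = c(0.043, 0.009, 0.020),
                   resolution = c(14.0, 30.0, 20.0))
  sel <- select_classes(md, cutoff = 0.1)
  expect_equal(sel$ratios, c(4.3 / 14, 0.9 / 30, 2.0 / 20), tolerance = 1e-12)
  # 0.307 selected; 0.030 not; exactly 0.1 NOT selected (strict >)
  expect_equal(sel$selected_ids, 1)
  expect_error(select_classes(md[0, ]), "empty")

  # the STAR metadata path makes identical decisions
  path <- withr::local_tempfile(fileext = ".star")
  writeLines(c("data_model_classes", "", "loop_",
               "_rlnClassDistribution #1", "_rlnEstimatedResolution #2",
               "0.043 14.0", "0.009 30.0", "0.020 20.0"), path)
  sel2 <- select_classes(read_class_metadata(path), cutoff = 0.1)
  expect_equal(sel2$selected_ids, sel$selected_ids)
  expect_equal(sel2$ratios, sel$ratios, tolerance = 1e-9)
})

test_that("select_classes on classification output is idempotent", {
  ts <- template_stack("disk", 80)
  cls <- classify2d(ts$stack, K = 2, seed = 3)
  sel <- select_classes(cls, cutoff = 0.1)
  expect_gt(length(sel$particle_indices), 0)
  # restrict to selected classes and reapply: nothing changes
  kept <- cls
  kept$classes <- cls$classes[cls$classes |>
    vapply(function(cl) cl$class_id %in% sel$selected_ids, logical(1))]
  sel2 <- select_classes(kept, cutoff = 0.1)
  expect_equal(sel2$selected_ids, sel$selected_ids)
  expect_equal(sel2$particle_indices, sel$particle_indices)
})

test_that("iterate_selection terminates and never regrows the subset", {
  # homogeneous stack: terminates in round 1 with nearly everything kept
  ts <- template_stack("disk", 120, seed = 2, snr = 1.5)
  res0 <- iterate_selection(ts$stack, cutoff = 0.1, stop_fraction = 0.9,
                            seed = 3)
  expect_length(res0$states, 1)
  expect_gte(res0$states[[1]]$selected_fraction, 0.9)

  # template + noise mixture: structural loop properties (purity at the
  # full bench scale is asserted in the acceptance suite)
  noise <- array(rnorm(64 * 64 * 60), c(64, 64, 60))
  noise <- sweep(noise, 3, apply(noise, 3, mean))
  noise <- sweep(noise, 3, apply(noise, 3, sd), "/")
  all_crops <- array(c(ts$stack$crops[, , 1:120], noise), c(64, 64, 180))
  src <- data.frame(micrograph_id = rep("x", 180),
                    x = rep(0, 180), y = rep(0, 180))
  stack <- cryopick:::new_particle_stack(all_crops, src, 1L,
                                         ts$stack$effective_pixel_size)
  res <- iterate_selection(stack, cutoff = 0.1, stop_fraction = 0.9,
                           seed = 4)
  expect_true(all(res$indices %in% seq_len(180)))
  n_in <- vapply(res$states, `[[`, numeric(1), "n_input")
  n_sel <- vapply(res$states, `[[`, numeric(1), "n_selected")
  expect_true(all(n_sel <= n_in))
  if (length(n_in) > 1) {
    expect_true(all(diff(n_in) <= 0))
  }
})

test_that("iterate_selection honors the round cap with a warning", {
  ts <- template_stack("disk", 30, seed = 6, snr = 0.3)  # hard data
  noise <- array(rnorm(64 * 64 * 30), c(64, 64, 30))
  crops <- array(c(ts$stack$crops, noise), c(64, 64, 60))
  src <- data.frame(micrograph_id = rep("x", 60), x = 0, y = 0)
  stack <- cryopick:::new_particle_stack(crops, src, 1L, 1)
  out <- tryCatch(
    withCallingHandlers(
      iterate_selection(stack, cutoff = 0.1, stop_fraction = 0.999,
                        max_rounds = 1, seed = 1),
      warning = function(w) {
        expect_match(conditionMessage(w), "within 1 round")
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (!is.null(out)) {
    expect_length(out$states, 1)
  }
})
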