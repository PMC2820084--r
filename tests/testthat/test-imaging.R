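# Detector chain: binarize -> label -> classify -> count -> CCsurf.

test_that("binarize marks exactly the pixels at or below the threshold", {
  f <- make_field(32, 32, background = 200)
  expect_false(any(binarize(f, detection_config(binarization_threshold = 100))))
  expect_true(all(binarize(f, 255)))

  f2 <- make_field(64, 64, squares = list(list(r = 10, c = 10, side = 10,
                                               level = 10)))
  m <- binarize(f2, detection_config(binarization_threshold = 100))
  expect_identical(sum(m), 100L)
  expect_true(all(which(m) == which(f2$raster == 10)))
})

test_that("label_particles separates components and measures them", {
  f <- make_field(64, 64, squares = list(
    list(r = 5, c = 5, side = 10, level = 10),
    list(r = 40, c = 40, side = 5, level = 10)))
  det <- label_particles(binarize(f, detection_config()), detection_config(),
                         field = f)
  expect_equal(nrow(det), 2L)
  expect_setequal(det$pixel_count, c(100L, 25L))
  expect_equal(det$area, det$pixel_count * 0.25)
  expect_equal(det$mean_intensity, c(10, 10))

  empty <- label_particles(matrix(FALSE, 8, 8), detection_config())
  expect_equal(nrow(empty), 0L)
})

test_that("components below min_particle_pixels are dropped", {
  m <- matrix(FALSE, 16, 16)
  m[2, 2] <- TRUE            # 1 px
  m[8:9, 8:9] <- TRUE        # 4 px
  det <- label_particles(m, detection_config(min_particle_pixels = 4))
  expect_equal(nrow(det), 1L)
  expect_equal(det$pixel_count, 4L)
})

test_that("connectivity 4 splits what connectivity 8 joins", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE   # touch only diagonally
  det8 <- label_particles(m, detection_config(connectivity = 8,
                                              min_particle_pixels = 1))
  det4 <- label_particles(m, detection_config(connectivity = 4,
                                              min_particle_pixels = 1))
  expect_equal(nrow(det8), 1L)
  expect_equal(nrow(det4), 2L)
})

test_that("circularity follows the exposed-edge perimeter convention", {
  # a digitized square of side 10: perimeter 40 edges, circularity
  # 4*pi*100/1600
  f <- make_field(32, 32, squares = list(list(r = 5, c = 5, side = 10,
                                              level = 10)))
  det <- label_particles(binarize(f, detection_config()), detection_config(),
                         field = f)
  expect_equal(det$perimeter, 40)
  expect_equal(det$circularity, 4 * pi * 100 / 40^2, tolerance = 1e-12)
  expect_equal(det$solidity, 1)
})

test_that("solidity of an L-shaped component matches brute-force hull", {
  # 12-pixel L: vertical arm 4x2 plus a 2x2 foot
  m <- matrix(FALSE, 16, 16)
  m[3:6, 3:4] <- TRUE
  m[5:6, 5:6] <- TRUE
  expect_equal(sum(m), 12L)
  det <- label_particles(m, detection_config())
  expect_equal(det$pixel_count, 12L)
  coords <- which(m, arr.ind = TRUE)
  grid <- as.matrix(expand.grid(row = 3:6, col = 3:6))
  hull_n <- sum(apply(grid, 1, function(p) brute_in_hull(p, coords)))
  expect_lt(det$solidity, 1)
  expect_equal(det$solidity, 12 / hull_n, tolerance = 1e-12)
})

test_that("classification applies the opacity and angularity screens", {
  cfg <- detection_config(opacity_cutoff = 50, max_circularity = 0.9)
  # opaque square: accepted
  f <- make_field(32, 32, squares = list(list(r = 5, c = 5, side = 10,
                                              level = 10)))
  det <- classify_particles(
    label_particles(binarize(f, cfg), cfg, field = f), cfg)
  expect_true(all(det$accepted))
  # semi-opaque particle at level 120 with a permissive threshold: rejected
  cfg2 <- detection_config(binarization_threshold = 150, opacity_cutoff = 50)
  f2 <- make_field(32, 32, squares = list(list(r = 5, c = 5, side = 8,
                                               level = 120)))
  det2 <- classify_particles(
    label_particles(binarize(f2, cfg2), cfg2, field = f2), cfg2)
  expect_false(any(det2$accepted))
  expect_true(all(det2$angular))  # rejection was the opacity screen
  # near-circular dark detection: rejected by the angularity screen alone
  d <- list(mean_intensity = 10, circularity = 0.95)
  expect_false(classify_particle(d, cfg))
  expect_true(classify_particle(list(mean_intensity = 10,
                                     circularity = 0.5), cfg))
})

test_that("charcoal pixel count is additive over accepted detections", {
  det <- data.frame(pixel_count = c(100L, 250L, 40L),
                    accepted = c(TRUE, TRUE, FALSE))
  expect_identical(count_charcoal_pixels(det), 350L)
  expect_identical(count_charcoal_pixels(det[0, ]), 0L)
  det$accepted <- FALSE
  expect_identical(count_charcoal_pixels(det), 0L)
})

test_that("compute_ccsurf matches independent arithmetic and the worked case", {
  expect_equal(compute_ccsurf(0, 0.25, 1.735e9, 0.1, 0.2, 1e8), 0)
  # identity configuration: Sp = 1, Sr = Ss, D = W = 1
  expect_equal(compute_ccsurf(1234, 1, 5e7, 1, 1, 5e7), 1234)
  expect_equal(compute_ccsurf(1000, 0.25, 1.735e9, 0.1, 0.2, 1e8),
               2.16875e5, tolerance = 1e-12)
  # random draws against the log-domain oracle
  set.seed(421)
  for (i in 1:50) {
    P <- sample(0:5000, 1)
    Sp <- runif(1, 0.01, 2); Sr <- runif(1, 1e8, 2e9)
    D <- runif(1, 0.01, 1); W <- runif(1, 0.05, 1); Ss <- runif(1, 1e6, 1e8)
    expect_equal(compute_ccsurf(P, Sp, Sr, D, W, Ss),
                 ccsurf_oracle(P, Sp, Sr, D, W, Ss),
                 tolerance = 1e-12)
  }
  expect_error(compute_ccsurf(10, 0.25, 1.735e9, 0, 0.2, 1e8), "D")
  expect_error(compute_ccsurf(10, 0.25, 1.735e9, 0.1, -1, 1e8), "W")
  expect_error(compute_ccsurf(-5, 0.25, 1.735e9, 0.1, 0.2, 1e8), "P")
})

test_that("CCsurf is homogeneous of degree 1 in P and -1 in W", {
  set.seed(99)
  for (i in 1:20) {
    P <- sample(1:5000, 1); k <- runif(1, 0.1, 10)
    Sp <- runif(1, 0.01, 2); Sr <- runif(1, 1e8, 2e9)
    D <- runif(1, 0.01, 1); W <- runif(1, 0.05, 1); Ss <- runif(1, 1e6, 1e8)
    base <- compute_ccsurf(P, Sp, Sr, D, W, Ss)
    expect_equal(compute_ccsurf(k * P, Sp, Sr, D, W, Ss), k * base,
                 tolerance = 1e-12)
    expect_equal(compute_ccsurf(P, Sp, Sr, D, k * W, Ss), base / k,
                 tolerance = 1e-12)
  }
})

test_that("process_sample composes the chain and respects metadata", {
  meta <- sample_meta("blank", depth = 50)
  blank <- make_field(32, 32)
  r <- process_sample(blank, meta)
  expect_equal(r$record$ccsurf, 0)
  expect_equal(r$record$charcoal_pixels_P, 0L)

  sim <- generate_micrograph(imaging_sim_params(seed = 11,
                                                background_noise_sd = 0))
  gt_P <- sum(sim$particles$pixel_count[sim$particles$class_label ==
                                          "charcoal"])
  r1 <- process_sample(sim$field, meta)
  expect_identical(r1$record$charcoal_pixels_P, as.integer(gt_P))
  expect_equal(r1$record$ccsurf,
               compute_ccsurf(gt_P, sim$field$pixel_area,
                              meta$filter_area_Sr, meta$dilution_D,
                              meta$dry_weight_W, meta$scanned_area_Ss))
  # doubling W halves CCsurf on the same field
  meta2 <- sample_meta("blank", depth = 50, dry_weight_W = 0.4)
  r2 <- process_sample(sim$field, meta2)
  expect_equal(r2$record$ccsurf, r1$record$ccsurf / 2)
})

test_that("adding a charcoal particle never decreases CCsurf", {
  meta <- sample_meta("mono", depth = 1)
  base_squares <- list(list(r = 5, c = 5, side = 8, level = 10))
  f1 <- make_field(64, 64, squares = base_squares)
  f2 <- make_field(64, 64, squares = c(base_squares,
                                       list(list(r = 40, c = 40, side = 6,
                                                 level = 10))))
  expect_gte(process_sample(f2, meta)$record$ccsurf,
             process_sample(f1, meta)$record$ccsurf)
})

test_that("Otsu initializer separates the modes and matches EBImage's objective", {
  sim <- generate_micrograph(imaging_sim_params(seed = 5))
  th <- auto_threshold(sim$field)
  # the threshold must land in the gap between the dark particle modes
  # and the translucent/background modes
  expect_gt(th, 90)
  expect_lt(th, 170)
  # EBImage resolves argmax plateaus by averaging while we take the first
  # maximum, so compare the between-class variance the two achieve, not
  # the raw threshold
  eb <- round(255 * EBImage::otsu(EBImage::Image(sim$field$raster / 255),
                                  range = c(0, 1), levels = 256))
  between <- function(t) {
    p <- tabulate(as.integer(sim$field$raster) + 1L, 256L) / length(sim$field$raster)
    lev <- 0:255
    w0 <- sum(p[1:(t + 1)]); w1 <- 1 - w0
    m0 <- sum(p[1:(t + 1)] * lev[1:(t + 1)]) / w0
    m1 <- sum(p[(t + 2):256] * lev[(t + 2):256]) / w1
    w0 * w1 * (m0 - m1)^2
  }
  expect_gte(between(th) + 1e-9, between(eb))
  expect_equal(between(th), between(eb), tolerance = 1e-6)
})

test_that("threshold calibration sweep recovers an effective threshold", {
  sims <- lapply(1:3, function(k)
    generate_micrograph(imaging_sim_params(seed = 30 + k)))
  fields <- lapply(sims, `[[`, "field")
  truth <- vapply(sims, function(s)
    sum(s$particles$pixel_count[s$particles$class_label == "charcoal"]),
    numeric(1))
  sweep <- calibrate_threshold(fields, truth, thresholds = seq(20, 240, 20))
  best <- attr(sweep, "best")
  expect_true(best > 15 && best < 200)
  expect_equal(min(sweep$total_abs_error),
               sweep$total_abs_error[sweep$threshold == best])
  expect_equal(min(sweep$total_abs_error), 0)
})
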