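test_that("tracking parameters are validated", {
  expect_error(tracking_params(gfa_threshold = 1.5), "gfa_threshold")
  expect_error(tracking_params(turning_angle = 95), "turning_angle")
  expect_error(tracking_params(seed_count = 0), "seed_count")
  expect_error(tracking_params(step_size = -1), "step_size")
})

test_that("peak extraction handles flat and multi-modal ODFs", {
  dirs <- odf_directions()
  expect_equal(nrow(extract_peaks(rep(1, 642), dirs)), 0)
  # sharp single bump
  e1 <- c(0.3, -0.5, 0.81)
  e1 <- e1 / sqrt(sum(e1^2))
  psi <- exp(40 * ((dirs %*% e1)^2 - 1))
  pk <- extract_peaks(psi, dirs)
  expect_equal(nrow(pk), 1)
  expect_lte(axis_angle(pk[1, ], e1), 5)
  # two orthogonal bumps at equal weight
  e2 <- c(e1[2], -e1[1], 0)
  e2 <- e2 / sqrt(sum(e2^2))
  psi2 <- exp(40 * ((dirs %*% e1)^2 - 1)) + exp(40 * ((dirs %*% e2)^2 - 1))
  pk2 <- extract_peaks(psi2, dirs)
  expect_equal(nrow(pk2), 2)
})

straight_field <- function(dims = c(20L, 10L, 10L)) {
  make_direction_field(function(p) c(1, 0, 0), dims,
                       voxel_size = c(0.2, 0.2, 0.2), gfa_value = 0.5)
}

test_that("a homogeneous field tracks straight lines out of the volume", {
  field <- straight_field()
  seed_mask <- array(FALSE, field$dims)
  seed_mask[9:11, 4:6, 4:6] <- TRUE
  tr <- track(field, seed_mask, tracking_params(seed_count = 200, rng_seed = 4))
  expect_s3_class(tr, "tractogram")
  expect_true(all(tr$reason == "out_of_volume"))
  for (i in seq_len(tr$n)) {
    pts <- streamline_points(tr, i)
    # straight: lateral deviation below one voxel
    expect_lt(max(abs(pts[, 2] - pts[1, 2])), 0.2)
    expect_lt(max(abs(pts[, 3] - pts[1, 3])), 0.2)
    # constant step length
    steps <- sqrt(rowSums(diff(pts)^2))
    expect_lt(max(abs(steps - tr$params$step_size)), 1e-6)
    # spans the volume in x
    expect_gt(diff(range(pts[, 1])), 3)
  }
})

test_that("a sub-threshold gFA map stops every streamline at its seed", {
  field <- straight_field()
  field$gfa[] <- 0.1
  seed_mask <- array(TRUE, field$dims)
  tr <- track(field, seed_mask, tracking_params(seed_count = 100, rng_seed = 1))
  expect_true(all(tr$lengths == 1L))
  expect_true(all(tr$reason == "low_gfa"))
})

knee_field <- function(turn_deg, dims = c(40L, 20L, 8L)) {
  # direction turns by turn_deg at the plane x = 4 mm
  a <- turn_deg * pi / 180
  make_direction_field(function(p) {
    if (p[1] < 4) c(1, 0, 0) else c(cos(a), sin(a), 0)
  }, dims, voxel_size = c(0.2, 0.2, 0.2), gfa_value = 0.5)
}

test_that("the turning-angle criterion gates a bend by its sharpness", {
  params <- tracking_params(seed_count = 150, rng_seed = 9, max_steps = 500)
  seed_mask <- array(FALSE, c(40L, 20L, 8L))
  seed_mask[5:10, 8:12, 3:5] <- TRUE
  gentle <- track(knee_field(40), seed_mask, params)
  # streamlines traverse the 40-degree bend and leave the volume
  expect_true(all(gentle$reason == "out_of_volume"))
  passed <- vapply(seq_len(gentle$n), function(i)
    max(streamline_points(gentle, i)[, 1]) > 5, logical(1))
  expect_gte(mean(passed), 0.95)
  sharp <- track(knee_field(80), seed_mask, params)
  expect_true(all(sharp$reason == "sharp_turn"))
  stopped <- vapply(seq_len(sharp$n), function(i)
    max(streamline_points(sharp, i)[, 1]) < 4.4, logical(1))
  expect_true(all(stopped))
})

test_that("tracking is bit-reproducible given the rng seed", {
  field <- straight_field()
  seed_mask <- array(FALSE, field$dims)
  seed_mask[9:11, 4:6, 4:6] <- TRUE
  p <- tracking_params(seed_count = 100, rng_seed = 77)
  t1 <- track(field, seed_mask, p)
  t2 <- track(field, seed_mask, p)
  expect_identical(t1$points, t2$points)
  expect_identical(t1$reason, t2$reason)
  t3 <- track(field, seed_mask, tracking_params(seed_count = 100,
                                                rng_seed = 78))
  expect_false(identical(t1$points, t3$points))
})

test_that("tighter thresholds never lengthen the tractogram", {
  rec <- cached_recon("healthy")
  truth <- cached_truth("healthy")
  seed_mask <- seed_corpus_callosum(truth, rec$spec)
  pk <- field_peaks(rec$field)
  base <- tracking_params(seed_count = 500, rng_seed = 5)
  len <- function(p) tract_length(track(rec$field, seed_mask, p, peaks = pk))
  l_base <- len(base)
  l_high_gfa <- len(tracking_params(gfa_threshold = 0.3, seed_count = 500,
                                    rng_seed = 5))
  l_low_angle <- len(tracking_params(turning_angle = 20, seed_count = 500,
                                     rng_seed = 5))
  expect_lte(l_high_gfa, l_base)
  expect_lte(l_low_angle, l_base)
  expect_gt(l_base, 0)
})

test_that("interhemispheric counting needs both sides plus the target", {
  field <- straight_field()           # fibers along x, volume 4 mm wide
  dims <- field$dims
  seed_mask <- array(FALSE, dims)
  seed_mask[9:11, 4:6, 4:6] <- TRUE
  tr <- track(field, seed_mask, tracking_params(seed_count = 300, rng_seed = 2))
  target <- array(FALSE, dims)
  target[1:3, , ] <- TRUE             # far left band
  n <- count_interhemispheric(tr, midline_x = 2, target_mask = target)
  expect_equal(n, tr$n)               # every fiber spans the whole volume
  # a target the fibers never visit
  target2 <- array(FALSE, dims)
  target2[, , 10] <- TRUE
  target2[, 1:9, ] <- FALSE
  empty_target <- array(FALSE, dims)
  expect_equal(count_interhemispheric(tr, 2, empty_target), 0L)
  # seed-count scaling is about linear
  tr5 <- track(field, seed_mask, tracking_params(seed_count = 50, rng_seed = 2))
  n5 <- count_interhemispheric(tr5, 2, target)
  expect_lt(abs(n5 / n * (300 / 50) - 1), 0.2)
})

test_that("termination reasons are exhaustive and exclusive", {
  field <- straight_field()
  seed_mask <- array(FALSE, field$dims)
  seed_mask[9:11, 4:6, 4:6] <- TRUE
  tr <- track(field, seed_mask, tracking_params(seed_count = 50, rng_seed = 3))
  expect_false(anyNA(tr$reason))
  expect_equal(length(tr$reason), tr$n)
  expect_true(all(levels(tr$reason) %in% c("low_gfa", "sharp_turn",
                                           "out_of_volume", "no_signal",
                                           "max_steps")))
})

test_that("tractograms round-trip through .trk and the text dialect", {
  field <- straight_field()
  seed_mask <- array(FALSE, field$dims)
  seed_mask[9:11, 4:6, 4:6] <- TRUE
  tr <- track(field, seed_mask, tracking_params(seed_count = 20, rng_seed = 6))
  trk <- withr::local_tempfile(fileext = ".trk")
  write_trk(tr, trk)
  back <- read_trk(trk)
  expect_equal(back$n, tr$n)
  expect_equal(back$lengths, tr$lengths)
  expect_equal(back$points, tr$points, tolerance = 1e-6)  # float32 storage
  expect_equal(back$voxel_size, tr$voxel_size, tolerance = 1e-6)
  txt <- withr::local_tempfile(fileext = ".txt")
  write_streamlines_text(tr, txt)
  back2 <- read_streamlines_text(txt)
  expect_equal(back2$n, tr$n)
  expect_equal(back2$points, unname(tr$points), tolerance = 1e-6)
  expect_equal(as.character(back2$reason), as.character(tr$reason))
})

test_that("seed masks come from the stated anatomical analogs", {
  spec_h <- make_scenario("healthy", 1)
  cc <- seed_corpus_callosum(cached_truth("healthy"), spec_h)
  expect_gt(sum(cc), 0)
  ix <- which(cc, arr.ind = TRUE)
  x_mm <- (ix[, 1] - 0.5) * spec_h$voxel_size[1]
  expect_true(all(abs(x_mm - spec_h$midline_x) <= 0.9))
  # severed: the callosal slab excludes the gap columns entirely
  spec_s <- make_scenario("severed_bridge", 1)
  cc_s <- seed_corpus_callosum(cached_truth("severed_bridge"), spec_s)
  ix_s <- which(cc_s, arr.ind = TRUE)
  x_s <- (ix_s[, 1] - 0.5) * spec_s$voxel_size[1]
  expect_true(all(abs(x_s - spec_s$midline_x) > spec_s$voxel_size[1]))
  expect_error(seed_high_gfa_area(array(FALSE, c(2, 2, 2))), "empty")
})
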