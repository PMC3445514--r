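test_that("scenario construction is deterministic and validates its tag", {
  a <- make_scenario("healthy", 1)
  b <- make_scenario("healthy", 1)
  expect_identical(a, b)
  expect_error(make_scenario("sham", 1), "healthy.*remodeled.*severed_bridge")
})

test_that("the severed scenario removes a contiguous midline gap", {
  truth_sev <- cached_truth("severed_bridge")
  truth_rem <- cached_truth("remodeled")
  spec <- make_scenario("severed_bridge", 1)
  nb <- ncol(truth_sev$frac) - 1
  bundle_cols <- grepl("^cc_ic", colnames(truth_sev$frac)[seq_len(nb)])
  f_sev <- array(rowSums(truth_sev$frac[, which(bundle_cols), drop = FALSE]),
                 truth_sev$dims)
  f_rem <- array(truth_rem$frac[, "cc_ic"], truth_rem$dims)
  centers_x <- (seq_len(truth_sev$dims[1]) - 0.5) * truth_sev$voxel_size[1]
  col_has_core <- apply(f_sev >= 0.5, 1, any)
  # contiguous run of core-free columns straddling the midline
  gap_cols <- which(!col_has_core &
                      abs(centers_x - spec$midline_x) < 1)
  expect_gte(length(gap_cols), 3)
  expect_true(all(diff(gap_cols) == 1))
  expect_true(any(centers_x[gap_cols] < spec$midline_x) &&
                any(centers_x[gap_cols] > spec$midline_x))
  # the intact remodeled bridge does cross there
  expect_true(all(apply(f_rem[gap_cols, , ] >= 0.5, 1, any)))
})

test_that("the remodeled descending bundle is displaced rostrally", {
  spec_h <- make_scenario("healthy", 1)
  spec_r <- make_scenario("remodeled", 1)
  limb_centroid <- function(truth, col) {
    f <- rowSums(truth$frac[, col, drop = FALSE])
    centers <- as.matrix(expand.grid(
      (seq_len(truth$dims[1]) - 0.5) * truth$voxel_size[1],
      (seq_len(truth$dims[2]) - 0.5) * truth$voxel_size[2],
      (seq_len(truth$dims[3]) - 0.5) * truth$voxel_size[3]))
    # right descending limb: lateral right, below the arc
    sel <- f >= 0.5 & centers[, 1] > 5.5 & centers[, 3] < 6
    colSums(centers[sel, ]) / sum(sel)
  }
  c_h <- limb_centroid(cached_truth("healthy"), "cc_ic")
  c_r <- limb_centroid(cached_truth("remodeled"), "cc_ic")
  expect_equal(unname(c_r[2] - c_h[2]), spec_r$rostral_offset_mm,
               tolerance = 0.1)
  # displacement is purely rostral (y), not lateral or dorsal
  expect_lt(abs(c_r[1] - c_h[1]), 0.1)
  expect_lt(abs(c_r[3] - c_h[3]), 0.3)
})

test_that("voxelization yields proper partial-volume fractions and truth FA", {
  truth <- cached_truth("healthy")
  expect_true(all(truth$frac >= 0 & truth$frac <= 1))
  expect_equal(rowSums(truth$frac), rep(1, nrow(truth$frac)), tolerance = 1e-9)
  # interior single-compartment voxels: ground-truth FA equals fa(lambda)
  spec <- make_scenario("healthy", 1)
  pure <- which(truth$frac[, "cc_ic"] == 1)
  expect_gt(length(pure), 50)
  lam <- spec$bundles$cc_ic$lambda
  expect_equal(truth$fa[pure], rep(fa(lam[1], lam[2], lam[3]), length(pure)),
               tolerance = 1e-12)
})

test_that("the diffusion forward model matches the closed-form signal", {
  s <- cached_scheme()
  # isotropic-only phantom: direction-independent mono-exponential decay
  spec <- make_scenario("healthy", 1, grid_shape = c(4L, 4L, 2L), snr = 30)
  spec$bundles <- list()
  truth <- voxelize_phantom(spec)
  noiseless <- simulate_dwi(spec, s, truth, noiseless = TRUE)
  sig <- noiseless$dwi[1, 1, 1, ]
  expect_equal(sig, spec$S0 * exp(-s$points$b_value * spec$background_d),
               tolerance = 1e-12)
  b0 <- which(s$points$b_value == 0)
  expect_identical(unname(noiseless$dwi[2, 2, 1, b0]), spec$S0)
  # single-tensor voxel inside a straight bundle: closed-form Gaussian signal
  spec2 <- make_scenario("healthy", 1)
  data2 <- simulate_dwi(spec2, s, cached_truth("healthy"), noiseless = TRUE)
  truth2 <- cached_truth("healthy")
  pure <- which(truth2$frac[, "cc_ic"] == 1 &
                  abs(abs(truth2$tangent$cc_ic[, 3]) - 1) < 1e-9)[1]
  ijk <- arrayInd(pure, truth2$dims)
  sim <- data2$dwi[ijk[1], ijk[2], ijk[3], ]
  oracle <- tensor_signal(s, c(0, 0, 1), spec2$bundles$cc_ic$lambda,
                          S0 = spec2$S0)
  expect_equal(sim, oracle, tolerance = 1e-9)
  # parallel vs perpendicular attenuation ratio at fixed b ((0,0,3) shell)
  lam <- spec2$bundles$cc_ic$lambda
  b <- 1384
  par_sig <- oracle[s$points$b_value == b & s$points$gz == 1]
  perp_sig <- oracle[s$points$b_value == b & s$points$gz == 0][1]
  expect_length(par_sig, 1)
  expect_equal(par_sig / perp_sig, exp(-b * (lam[1] - lam[3])),
               tolerance = 1e-9)
})

test_that("Rician noise has the analytic magnitude-signal mean", {
  s <- cached_scheme()
  spec <- make_scenario("healthy", 7, grid_shape = c(30L, 30L, 10L), snr = 5)
  spec$bundles <- list()
  truth <- voxelize_phantom(spec)
  data <- simulate_dwi(spec, s, truth)
  b0 <- which(s$points$b_value == 0)
  observed <- mean(data$dwi[, , , b0])
  # analytic Rician mean via the Laguerre half polynomial (besselI oracle)
  nu <- spec$S0
  sg <- spec$noise_sigma
  x <- -nu^2 / (2 * sg^2)
  l_half <- exp(x / 2) * ((1 - x) * besselI(-x / 2, 0) - x * besselI(-x / 2, 1))
  rician_mean <- sg * sqrt(pi / 2) * l_half
  expect_equal(observed / rician_mean, 1, tolerance = 0.02)
})

test_that("the block paradigm yields 115 volumes with rest at both ends", {
  par <- block_paradigm()
  expect_equal(par$n_volumes, 115L)
  expect_equal(sum(par$stim), 25L)
  expect_equal(sum(!par$stim), 90L)
  expect_false(par$stim[1])
  expect_false(par$stim[115])
  expect_error(block_paradigm(volume_spacing = 2), "divide")
})

test_that("noiseless BOLD boxcar scales active voxels exactly", {
  par <- block_paradigm()
  mask <- array(FALSE, c(4, 4, 2))
  mask[1:2, 1, 1] <- TRUE
  ts <- simulate_bold(par, mask, effect = 2, noise_sigma = 0, seed = 1)
  y_act <- ts[1, 1, 1, ]
  y_in <- ts[4, 4, 2, ]
  expect_equal(mean(y_act[par$stim]) / mean(y_act[!par$stim]), 1.02,
               tolerance = 1e-12)
  expect_equal(unname(y_in), rep(100, 115))
  expect_error(simulate_bold(par, mask, effect = -1), "non-negative")
})
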