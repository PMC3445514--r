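test_that("the sphere tessellation is antipodally paired", {
  dirs <- odf_directions()
  K <- nrow(dirs)
  expect_equal(K, 642L)
  nh <- K / 2
  expect_identical(dirs[seq_len(nh), ], -dirs[nh + seq_len(nh), ])
  expect_equal(sqrt(rowSums(dirs^2)), rep(1, K), tolerance = 1e-12)
})

test_that("q-space regridding places each sample at its lattice site", {
  s <- cached_scheme()
  g <- regrid_qspace(rep(1, 203), s)
  expect_equal(dim(g), c(11, 11, 11))
  expect_equal(sum(g != 0), 203)
  expect_true(all(g %in% c(0, 1)))
  g2 <- regrid_qspace(c(42, rep(1, 202)), s)
  expect_equal(g2[6, 6, 6], 42)  # b = 0 at the grid origin
  expect_error(regrid_qspace(rep(1, 100), s), "100.*203|203.*100")
})

test_that("an all-ones q-grid transforms to a delta-like propagator", {
  pr <- reconstruct_propagator(array(1, c(11, 11, 11)), window = FALSE,
                               pad_factor = 1)
  v <- pr$values
  ctr <- v[6, 6, 6]
  expect_gt(ctr / mean(v[-(6 + 5 * 11 + 5 * 121)]), 100)
  expect_error(reconstruct_propagator(array(1, c(10, 10, 10))), "odd")
  expect_error(reconstruct_propagator(array(1, c(11, 11, 9))), "cube")
})

test_that("the propagator is centrosymmetric and non-negative", {
  s <- cached_scheme()
  set.seed(3)
  sig <- tensor_signal(s, random_unit(1)[1, ])
  pr <- reconstruct_propagator(regrid_qspace(sig, s))
  m <- dim(pr$raw)[1]
  flipped <- pr$raw[m:1, m:1, m:1]
  expect_lt(max(abs(pr$raw - flipped)), 1e-9 * max(abs(pr$raw)))
  expect_true(all(pr$values >= 0))
})

test_that("an isotropic Gaussian signal reconstructs its analytic propagator", {
  s <- cached_scheme()
  d <- 3e-3  # free water: well sampled by the b <= 2000 keyhole
  tau <- (s$delta_large - s$delta_small / 3) / 1000
  pr <- reconstruct_propagator(regrid_qspace(exp(-s$points$b_value * d), s),
                               window = FALSE)
  m <- dim(pr$values)[1]
  half <- (m - 1) / 2
  dq <- max(s$points$q_radius) / sqrt(13)
  cell <- (1 / dq) / m   # zero-padding refines sampling, the FOV is fixed
  ax <- seq(-half, half) * cell
  analytic <- exp(-outer(outer(ax^2, ax^2, "+"), ax^2, "+") / (4 * d * tau))
  expect_gt(stats::cor(as.vector(pr$values), as.vector(analytic)), 0.99)
  # spherical symmetry: relative spread over a fixed-radius shell
  set.seed(1)
  U <- random_unit(200)
  tw <- dsitract:::trilinear_weights(U * 2 * pr$upsampling, half)
  shell <- rowSums(matrix(pr$values[tw$idx], ncol = 8) * tw$wts)
  expect_lt(stats::sd(shell) / mean(shell), 0.05)
})

test_that("windowing suppresses truncation ringing", {
  s <- cached_scheme()
  sig <- exp(-s$points$b_value * 0.7e-3)
  g <- regrid_qspace(sig, s)
  pw <- reconstruct_propagator(g, window = TRUE)
  pu <- reconstruct_propagator(g, window = FALSE)
  expect_gte(min(pw$raw), min(pu$raw))
})

test_that("a constant propagator yields a constant ODF", {
  dirs <- odf_directions()
  psi <- compute_odf(array(1, c(11, 11, 11)), dirs)
  expect_lt((max(psi) - min(psi)) / mean(psi), 1e-6)
  nh <- nrow(dirs) / 2
  expect_identical(psi[seq_len(nh)], psi[nh + seq_len(nh)])
})

test_that("single-fiber and crossing ODF peaks land on the true axes", {
  s <- cached_scheme()
  dirs <- odf_directions()
  set.seed(11)
  for (i in 1:12) {
    e1 <- random_unit(1)[1, ]
    psi <- compute_odf(reconstruct_propagator(regrid_qspace(
      tensor_signal(s, e1), s)), dirs)
    pk <- extract_peaks(psi, dirs)
    expect_equal(nrow(pk), 1)
    expect_lte(axis_angle(pk[1, ], e1), 10)
  }
  for (i in 1:12) {
    e1 <- random_unit(1)[1, ]
    tmp <- random_unit(1)[1, ]
    e2 <- tmp - sum(tmp * e1) * e1
    e2 <- e2 / sqrt(sum(e2^2))
    sig <- 0.5 * tensor_signal(s, e1) + 0.5 * tensor_signal(s, e2)
    psi <- compute_odf(reconstruct_propagator(regrid_qspace(sig, s)), dirs)
    pk <- extract_peaks(psi, dirs)
    expect_equal(nrow(pk), 2)
    err1 <- min(axis_angle(pk[1, ], e1), axis_angle(pk[1, ], e2))
    err2 <- min(axis_angle(pk[2, ], e1), axis_angle(pk[2, ], e2))
    expect_lte(max(err1, err2), 10)
  }
})

test_that("gfa matches its closed forms and stays within [0, 1]", {
  expect_equal(gfa(rep(3.7, 50)), 0)
  for (K in c(60, 181, 321, 642))
    expect_equal(gfa(c(1, rep(0, K - 1))), sqrt(1 - 1 / K), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:200) {
    psi <- stats::runif(321)
    g <- gfa(psi)
    expect_true(g >= 0 && g <= 1)
    # scale invariance
    expect_equal(gfa(psi * 1e6), g, tolerance = 1e-12)
    expect_equal(gfa(psi * 1e-6), g, tolerance = 1e-12)
  }
  expect_error(gfa(rep(0, 10)), "degenerate")
  expect_error(gfa(c(-1, 1)), "non-negative")
})

test_that("fa matches its closed forms", {
  expect_equal(fa(1, 1, 1), 0)
  expect_equal(fa(1, 0, 0), 1)
  expect_equal(fa(2, 1, 1), 1 / sqrt(6), tolerance = 1e-12)
  expect_equal(fa(c(1, 2), c(1, 1), c(1, 1)), c(0, 1 / sqrt(6)),
               tolerance = 1e-12)
  expect_error(fa(0, 0, 0), "zero")
  expect_error(fa(-1, 1, 1), "non-negative")
})

test_that("fa and gfa rank single-tensor anisotropies consistently", {
  s <- cached_scheme()
  dirs <- odf_directions()
  e1 <- c(0, 0, 1)
  psi_sharp <- compute_odf(reconstruct_propagator(regrid_qspace(
    tensor_signal(s, e1, c(1.7e-3, 0.3e-3, 0.3e-3)), s)), dirs)
  psi_blunt <- compute_odf(reconstruct_propagator(regrid_qspace(
    tensor_signal(s, e1, c(1e-3, 0.8e-3, 0.8e-3)), s)), dirs)
  expect_gt(fa(1.7, 0.3, 0.3), fa(1, 0.8, 0.8))
  expect_gt(gfa(psi_sharp), gfa(psi_blunt))
})

test_that("the fused volume path agrees with the explicit per-voxel chain", {
  s <- cached_scheme()
  dirs <- odf_directions()
  set.seed(21)
  E <- random_unit(4)
  dwi <- array(0, c(4, 1, 1, 203))
  for (i in 1:4) dwi[i, 1, 1, ] <- tensor_signal(s, E[i, ], S0 = 100)
  field <- full_reconstruction(dwi, s)
  for (i in 1:4) {
    psi_f <- odf_at(field, i)
    psi_e <- compute_odf(reconstruct_propagator(regrid_qspace(
      dwi[i, 1, 1, ], s)), dirs)
    # the fused path omits the intermediate propagator clip; the windowed
    # ripple bounds the difference
    expect_lt(max(abs(psi_f - psi_e)) / max(psi_e), 0.05)
    expect_equal(which.max(psi_f), which.max(psi_e))
    expect_lt(abs(gfa(psi_f) - gfa(psi_e)), 0.03)
  }
  expect_error(odf_at(field, 4000), "outside")
})

test_that("full reconstruction is deterministic and gfa_map consistent", {
  s <- cached_scheme()
  set.seed(8)
  dwi <- array(stats::runif(2 * 2 * 2 * 203, 10, 100), c(2, 2, 2, 203))
  f1 <- full_reconstruction(dwi, s)
  f2 <- full_reconstruction(dwi, s)
  expect_identical(f1$psi_hemi, f2$psi_hemi)
  expect_identical(as.vector(f1$gfa), as.vector(f2$gfa))
  expect_equal(as.vector(gfa_map(f1)), as.vector(f1$gfa), tolerance = 1e-12)
  # per-voxel gfa agrees with the scalar definition
  expect_equal(f1$gfa[1, 1, 1], gfa(odf_at(f1, 1)), tolerance = 1e-12)
})

test_that("phantom gFA maps separate bundle, strip and background", {
  rec <- cached_recon("remodeled")
  masks <- scenario_masks(cached_truth("remodeled"), rec$spec)
  g <- rec$field$gfa
  m_bundle <- mean(g[masks$bundle])
  m_strip <- mean(g[masks$strip])
  m_bg <- mean(g[masks$background])
  expect_gt(m_bundle, m_strip)
  expect_gt(m_strip, m_bg)
  # all-background phantom stays near the noise floor
  s <- cached_scheme()
  spec <- make_scenario("healthy", 3, grid_shape = c(10L, 10L, 4L))
  spec$bundles <- list()
  f <- full_reconstruction(simulate_dwi(spec, s, voxelize_phantom(spec)))
  expect_lt(mean(f$gfa), 0.1)
})
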