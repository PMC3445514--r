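# Fiber phantoms: geometric bundle scenarios (healthy brain, post-stroke
# remodeling, severed callosal bridge), multi-tensor diffusion signal
# simulation with Rician noise, and synthetic block-design BOLD series.

# -- geometry helpers ---------------------------------------------------------

# resample a polyline to roughly uniform spacing (mm), keeping endpoints
resample_polyline <- function(pts, spacing = 0.1) {
  seg <- diff(pts)
  len <- sqrt(rowSums(seg^2))
  keep <- c(TRUE, len > 1e-12)   # drop duplicated consecutive points
  pts <- pts[keep, , drop = FALSE]
  len <- len[len > 1e-12]
  s <- c(0, cumsum(len))
  total <- s[length(s)]
  t_out <- seq(0, total, by = spacing)
  if (t_out[length(t_out)] < total) t_out <- c(t_out, total)
  out <- matrix(0, length(t_out), 3)
  for (j in 1:3) out[, j] <- stats::approx(s, pts[, j], xout = t_out)$y
  out
}

polyline_tangents <- function(pts) {
  n <- nrow(pts)
  tg <- rbind(pts[2, ] - pts[1, ],
              pts[seq(3, n), ] - pts[seq(1, n - 2), ],
              pts[n, ] - pts[n - 1, ])
  tg / sqrt(rowSums(tg^2))
}

quad_bezier <- function(p0, p1, p2, n = 40) {
  t <- seq(0, 1, length.out = n)
  out <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
  out
}

#' Construct a fiber bundle
#'
#' A bundle is a tube of given radius around a 3D centerline; its diffusion
#' compartment is an axially symmetric tensor whose principal axis follows
#' the local centerline tangent.
#'
#' @param name Bundle label.
#' @param centerline n x 3 matrix of points in mm (resampled internally).
#' @param radius Tube radius in mm.
#' @param lambda Tensor eigenvalues `(l1, l2, l3)` in mm^2/s, `l1 >= l2 >= l3`.
#' @return A list of class `fiber_bundle`.
#' @export
fiber_bundle <- function(name, centerline, radius,
                         lambda = c(1.7e-3, 0.3e-3, 0.3e-3)) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2) stop("centerline needs at least 2 points")
  if (radius <= 0) stop("radius must be positive")
  if (any(lambda < 0) || is.unsorted(rev(lambda)))
    stop("lambda must be non-negative with l1 >= l2 >= l3")
  cl <- resample_polyline(centerline, spacing = 0.05)
  structure(list(name = name, centerline = cl,
                 tangents = polyline_tangents(cl),
                 radius = radius, lambda = lambda),
            class = "fiber_bundle")
}

# squared distance from points (m x 3) to the bundle centerline, plus tangent
# at the nearest centerline point; vectorized over points, looped over segments
nearest_on_polyline <- function(pts, cl, tangents) {
  m <- nrow(pts)
  best_d2 <- rep(Inf, m)
  best_tan <- matrix(0, m, 3)
  nseg <- nrow(cl) - 1
  for (k in seq_len(nseg)) {
    a <- cl[k, ]; b <- cl[k + 1, ]
    d <- b - a
    dd <- sum(d^2)
    pa <- sweep(pts, 2, a)
    t <- pmin(pmax((pa %*% d) / dd, 0), 1)
    dx <- pa - outer(as.vector(t), d)
    d2 <- rowSums(dx^2)
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_tan[upd, ] <- rep(tangents[k, ], each = sum(upd))
    }
  }
  list(d2 = best_d2, tangent = best_tan)
}

# -- scenarios ----------------------------------------------------------------

scenario_tags <- c("healthy", "remodeled", "severed_bridge")

# geometry constants (mm) for the default 40 x 40 x 20 grid at (0.2,0.2,0.5)
.geom <- list(
  midline_x = 4.0,
  limb_x = c(left = 1.8, right = 6.2),
  limb_y = 4.0,
  limb_z = c(2.0, 6.5),
  arc_center_z = 6.5, arc_radius = 2.2,
  bundle_radius = 0.45,
  ec_center_z = 4.5, ec_radius = 1.2, ec_bundle_radius = 0.35,
  strip_x = 5.2, strip_z = c(2.5, 5.5), strip_radius = 0.4,
  gap_halfwidth = 0.8,   # centerline cut; with the 0.45 mm tube radius the
                         # material gap spans ~0.7 mm (>= 3 in-plane voxels)
  rostral_offset = 1.2,
  bundle_lambda = c(1.7e-3, 0.3e-3, 0.3e-3),
  strip_lambda = c(1.6e-3, 0.35e-3, 0.35e-3)
)

# the corpus-callosum bridge + two descending internal-capsule limbs as one
# continuous U-shaped centerline; y drifts from limb_y to y_right across the arc
u_bundle_centerline <- function(y_right) {
  g <- .geom
  zs <- seq(g$limb_z[1], g$limb_z[2], by = 0.1)
  left_limb <- cbind(g$limb_x["left"], g$limb_y, zs)
  theta <- seq(pi, 0, length.out = 80)
  arc <- cbind(g$midline_x + g$arc_radius * cos(theta),
               g$limb_y + (y_right - g$limb_y) * (1 + cos(theta)) / 2,
               g$arc_center_z + g$arc_radius * sin(theta))
  right_limb <- cbind(g$limb_x["right"], y_right, rev(zs))
  unname(rbind(left_limb, arc, right_limb))
}

external_capsule_centerline <- function(side) {
  g <- .geom
  cx <- g$limb_x[side]
  sgn <- if (side == "left") -1 else 1
  theta <- seq(-pi / 2, pi / 2, length.out = 50)
  cbind(cx + sgn * g$ec_radius * cos(theta), g$limb_y,
        g$ec_center_z + g$ec_radius * sin(theta))
}

# periventricular strip: a vertical bundle medial to the right limb that bends
# dorsally to merge tangentially into the callosal arc
strip_centerline <- function(y_right) {
  g <- .geom
  ys <- y_right
  zs <- seq(g$strip_z[1], g$strip_z[2], by = 0.1)
  vertical <- cbind(g$strip_x, ys, zs)
  theta_j <- 70 * pi / 180  # junction point on the arc
  pj <- c(g$midline_x + g$arc_radius * cos(theta_j),
          g$limb_y + (ys - g$limb_y) * (1 + cos(theta_j)) / 2,
          g$arc_center_z + g$arc_radius * sin(theta_j))
  blend <- quad_bezier(c(g$strip_x, ys, g$strip_z[2]),
                       c(g$strip_x, ys, 7.5), pj, n = 40)
  unname(rbind(vertical, blend[-1, ]))
}

#' Build a phantom scenario
#'
#' The three scenarios emulate (i) a healthy brain: two parasagittal
#' descending bundles joined by a midline callosal bridge, plus an external
#' capsule arc per hemisphere; (ii) `remodeled`: the right descending bundle
#' displaced rostrally by `rostral_offset_mm` and a periventricular strip of
#' intermediate anisotropy merging into the bridge; (iii) `severed_bridge`:
#' the remodeled geometry with a midline gap cut out of the bridge. Geometry
#' is deterministic; the seed controls only the simulated measurement noise.
#'
#' @param name One of `"healthy"`, `"remodeled"`, `"severed_bridge"`.
#' @param seed Integer RNG seed stored in the spec and used by
#'   [simulate_dwi()].
#' @param grid_shape Voxel grid dimensions (default `c(40, 40, 20)`).
#' @param voxel_size Voxel size in mm (default `c(0.2, 0.2, 0.5)`).
#' @param snr Signal-to-noise ratio on the unweighted signal; the Rician
#'   noise scale is `S0 / snr` (default 30).
#' @param S0 Unweighted signal level (default 100).
#' @param background_d Isotropic background diffusivity, mm^2/s.
#' @return An object of class `phantom_spec`.
#' @export
make_scenario <- function(name, seed = 1L,
                          grid_shape = c(40L, 40L, 20L),
                          voxel_size = c(0.2, 0.2, 0.5),
                          snr = 30, S0 = 100, background_d = 0.7e-3) {
  if (!name %in% scenario_tags)
    stop("unknown scenario ", sQuote(name), "; valid tags: ",
         paste(scenario_tags, collapse = ", "))
  if (any(grid_shape <= 0)) stop("grid_shape must be positive")
  if (snr <= 0) stop("snr must be positive")
  g <- .geom
  y_right <- if (name == "healthy") g$limb_y else g$limb_y + g$rostral_offset
  u_cl <- u_bundle_centerline(y_right)
  bundles <- list()
  if (name == "severed_bridge") {
    keep_left <- u_cl[, 1] < g$midline_x - g$gap_halfwidth
    keep_right <- u_cl[, 1] > g$midline_x + g$gap_halfwidth
    bundles$cc_ic_left <- fiber_bundle("cc_ic_left", u_cl[keep_left, ],
                                       g$bundle_radius, g$bundle_lambda)
    bundles$cc_ic_right <- fiber_bundle("cc_ic_right", u_cl[keep_right, ],
                                        g$bundle_radius, g$bundle_lambda)
  } else {
    bundles$cc_ic <- fiber_bundle("cc_ic", u_cl, g$bundle_radius,
                                  g$bundle_lambda)
  }
  bundles$ec_left <- fiber_bundle("ec_left", external_capsule_centerline("left"),
                                  g$ec_bundle_radius, g$bundle_lambda)
  bundles$ec_right <- fiber_bundle("ec_right", external_capsule_centerline("right"),
                                   g$ec_bundle_radius, g$bundle_lambda)
  if (name %in% c("remodeled", "severed_bridge"))
    bundles$strip <- fiber_bundle("strip", strip_centerline(y_right),
                                  g$strip_radius, g$strip_lambda)
  structure(list(
    scenario = name, seed = as.integer(seed),
    grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
    bundles = bundles, background_d = background_d,
    S0 = S0, snr = snr, noise_sigma = S0 / snr,
    midline_x = g$midline_x, rostral_offset_mm = g$rostral_offset,
    y_right = y_right), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Phantom scenario", sQuote(x$scenario), "on a",
      paste(x$grid_shape, collapse = "x"), "grid at (",
      paste(x$voxel_size, collapse = ", "), ") mm\n")
  cat("  bundles:", paste(names(x$bundles), collapse = ", "), "\n")
  cat("  S0 =", x$S0, ", SNR =", x$snr, ", seed =", x$seed, "\n")
  invisible(x)
}

# -- voxelization -------------------------------------------------------------

voxel_centers <- function(grid_shape, voxel_size) {
  cx <- (seq_len(grid_shape[1]) - 0.5) * voxel_size[1]
  cy <- (seq_len(grid_shape[2]) - 0.5) * voxel_size[2]
  cz <- (seq_len(grid_shape[3]) - 0.5) * voxel_size[3]
  as.matrix(expand.grid(x = cx, y = cy, z = cz))
}

#' Voxelize a phantom onto its grid with partial-volume fractions
#'
#' Each voxel is supersampled on a `supersample`^3 lattice of subvoxel
#' points; a subpoint belongs to the nearest bundle whose tube contains it,
#' and the per-voxel compartment fraction is the subpoint share. The
#' remainder is isotropic background. Ground truth includes per-bundle mean
#' tangent directions, the composite-tensor fractional anisotropy and the
#' dominant fiber direction per voxel.
#'
#' @param spec A `phantom_spec`.
#' @param supersample Subvoxel sampling per axis (default 3).
#' @return An object of class `phantom_truth` with elements `frac` (nvox x
#'   n_bundles+1 matrix, last column background), `tangent` (list of nvox x 3
#'   matrices), `fa`, `principal`, `dims`, `voxel_size`.
#' @export
voxelize_phantom <- function(spec, supersample = 3) {
  dims <- spec$grid_shape
  vs <- spec$voxel_size
  nvox <- prod(dims)
  nb <- length(spec$bundles)
  offs <- (seq_len(supersample) - 0.5) / supersample - 0.5
  sub <- as.matrix(expand.grid(offs * vs[1], offs * vs[2], offs * vs[3]))
  nsub <- nrow(sub)
  centers <- voxel_centers(dims, vs)
  # per-bundle: distance of subpoints to centerline within bundle bounding box
  d2 <- matrix(Inf, nvox * nsub, nb)
  pts_all <- centers[rep(seq_len(nvox), each = nsub), ] +
    sub[rep(seq_len(nsub), nvox), ]
  for (b in seq_len(nb)) {
    bd <- spec$bundles[[b]]
    lo <- apply(bd$centerline, 2, min) - bd$radius - 1e-9
    hi <- apply(bd$centerline, 2, max) + bd$radius + 1e-9
    inbox <- pts_all[, 1] >= lo[1] & pts_all[, 1] <= hi[1] &
             pts_all[, 2] >= lo[2] & pts_all[, 2] <= hi[2] &
             pts_all[, 3] >= lo[3] & pts_all[, 3] <= hi[3]
    if (!any(inbox)) next
    near <- nearest_on_polyline(pts_all[inbox, , drop = FALSE],
                                bd$centerline, bd$tangents)
    d2[inbox, b] <- near$d2
  }
  # assignment: each subpoint goes to the nearest bundle whose tube holds it
  radius2 <- vapply(spec$bundles, function(b) b$radius^2, numeric(1))
  inside_any <- sweep(d2, 2, radius2, "<=")
  d2_masked <- d2
  d2_masked[!inside_any] <- Inf
  owner <- max.col(-d2_masked, ties.method = "first")
  owner[!is.finite(d2_masked[cbind(seq_along(owner), owner)])] <- 0L
  vox_of_sub <- rep(seq_len(nvox), each = nsub)
  frac <- matrix(0, nvox, nb + 1)
  colnames(frac) <- c(names(spec$bundles), "background")
  for (b in seq_len(nb)) {
    sel <- owner == b
    if (any(sel)) {
      counts <- tabulate(vox_of_sub[sel], nbins = nvox)
      frac[, b] <- counts / nsub
    }
  }
  frac[, nb + 1] <- 1 - rowSums(frac[, seq_len(nb), drop = FALSE])
  # mean tangent per voxel per bundle (recomputed cleanly)
  tangent <- vector("list", nb)
  names(tangent) <- names(spec$bundles)
  for (b in seq_len(nb)) {
    tangent[[b]] <- matrix(0, nvox, 3)
    sel <- owner == b
    if (!any(sel)) next
    vi <- vox_of_sub[sel]
    near <- nearest_on_polyline(pts_all[sel, , drop = FALSE],
                                spec$bundles[[b]]$centerline,
                                spec$bundles[[b]]$tangents)
    # align signs before averaging (tangent is axial)
    ref <- near$tangent[!duplicated(vi), , drop = FALSE]
    ref_of <- ref[match(vi, unique(vi)), , drop = FALSE]
    flip <- sign(rowSums(near$tangent * ref_of))
    flip[flip == 0] <- 1
    tg <- near$tangent * flip
    ui <- sort(unique(vi))
    cnt <- tabulate(match(vi, ui))
    tangent[[b]][ui, ] <- rowsum(tg, vi) / cnt
    nrm <- sqrt(rowSums(tangent[[b]]^2))
    nz <- nrm > 0
    tangent[[b]][nz, ] <- tangent[[b]][nz, ] / nrm[nz]
  }
  # composite tensor FA and dominant direction
  fa_vals <- numeric(nvox)
  principal <- matrix(NA_real_, nvox, 3)
  has_fiber <- which(frac[, nb + 1] < 1 - 1e-12)
  for (v in has_fiber) {
    D <- diag(rep(spec$background_d, 3)) * frac[v, nb + 1]
    for (b in seq_len(nb)) {
      if (frac[v, b] <= 0) next
      e1 <- tangent[[b]][v, ]
      lam <- spec$bundles[[b]]$lambda
      Db <- lam[2] * diag(3) + (lam[1] - lam[2]) * tcrossprod(e1)
      D <- D + frac[v, b] * Db
    }
    ev <- eigen(D, symmetric = TRUE)
    fa_vals[v] <- fa(ev$values[1], ev$values[2], ev$values[3])
    principal[v, ] <- ev$vectors[, 1]
  }
  structure(list(frac = frac, tangent = tangent, fa = fa_vals,
                 principal = principal, dims = dims, voxel_size = vs,
                 scenario = spec$scenario),
            class = "phantom_truth")
}

#' Ground-truth region masks of a voxelized scenario
#'
#' Returns logical 3D arrays: the coherent-bundle core (`bundle`), the
#' midline callosal bridge slab (`bridge`), the periventricular strip
#' (`strip`, empty for the healthy scenario), the contralesional descending
#' limb used as white-matter reference (`internal_capsule_ref`), hemisphere
#' masks and pure background.
#'
#' @param truth A `phantom_truth`.
#' @param spec The `phantom_spec` it came from.
#' @return A named list of logical arrays of the grid shape.
#' @export
scenario_masks <- function(truth, spec) {
  dims <- truth$dims
  vs <- truth$voxel_size
  centers <- voxel_centers(dims, vs)
  nb <- ncol(truth$frac) - 1
  bnames <- colnames(truth$frac)[seq_len(nb)]
  core_of <- function(cols, thr = 0.5) {
    f <- rowSums(truth$frac[, cols, drop = FALSE])
    array(f >= thr, dims)
  }
  u_cols <- bnames[grepl("^cc_ic", bnames)]
  bundle <- core_of(u_cols)
  strip <- if ("strip" %in% bnames) core_of("strip") else array(FALSE, dims)
  x <- array(centers[, 1], dims)
  z <- array(centers[, 3], dims)
  bridge <- bundle & abs(x - spec$midline_x) <= 0.8 & z > .geom$arc_center_z
  ic_ref <- bundle & x < 3 & z < 6
  list(bundle = bundle, strip = strip, bridge = bridge,
       internal_capsule_ref = ic_ref,
       hemisphere_left = array(centers[, 1] < spec$midline_x, dims),
       hemisphere_right = array(centers[, 1] > spec$midline_x, dims),
       background = array(truth$frac[, nb + 1] >= 1 - 1e-12, dims))
}

# bilateral "S1 cortex" boxes used by the BOLD stage
#' Bilateral sensory-cortex analog masks for BOLD simulation
#'
#' @param spec A `phantom_spec`.
#' @return List with logical arrays `contra` (left) and `ipsi` (right).
#' @export
scenario_bold_masks <- function(spec) {
  dims <- spec$grid_shape
  centers <- voxel_centers(dims, spec$voxel_size)
  box <- function(xlim) array(
    centers[, 1] >= xlim[1] & centers[, 1] <= xlim[2] &
      centers[, 2] >= 3 & centers[, 2] <= 5 &
      centers[, 3] >= 8 & centers[, 3] <= 9.5, dims)
  list(contra = box(c(0.6, 1.8)), ipsi = box(c(6.2, 7.4)))
}

# -- diffusion signal ---------------------------------------------------------

#' Simulate diffusion-weighted volumes from a phantom
#'
#' Multi-tensor forward model: per voxel,
#' `S(b, g) = S0 * sum_i f_i * exp(-b g' D_i g)`, with axially symmetric
#' bundle tensors oriented along the local tangent and an isotropic
#' background compartment, followed by Rician noise of scale
#' `spec$noise_sigma` (magnitude of the complex signal plus i.i.d. Gaussian
#' channel noise).
#'
#' @param spec A `phantom_spec`.
#' @param scheme A `qspace_scheme`.
#' @param truth Optional precomputed [voxelize_phantom()] result (the
#'   geometry is deterministic, so it can be shared across noise seeds).
#' @param noiseless If `TRUE`, skip the noise stage.
#' @return A list of class `dsi_data`: `dwi` (4D array, last dimension the
#'   203 encoding points), `truth`, `scheme`, `spec`.
#' @export
simulate_dwi <- function(spec, scheme, truth = NULL, noiseless = FALSE) {
  validate_scheme(scheme, strict = FALSE)
  if (is.null(truth)) truth <- voxelize_phantom(spec)
  p <- scheme$points
  npts <- nrow(p)
  dims <- truth$dims
  nvox <- prod(dims)
  G <- as.matrix(p[, c("gx", "gy", "gz")])
  b <- p$b_value
  nb <- ncol(truth$frac) - 1
  # background attenuation, identical for all voxels per encoding point
  att_bg <- exp(-b * spec$background_d)
  signal <- outer(truth$frac[, nb + 1], att_bg)
  for (k in seq_len(nb)) {
    f <- truth$frac[, k]
    sel <- which(f > 0)
    if (!length(sel)) next
    lam <- spec$bundles[[k]]$lambda
    dot <- truth$tangent[[k]][sel, , drop = FALSE] %*% t(G)  # nsel x npts
    bterm <- matrix(b, length(sel), npts, byrow = TRUE)
    att <- exp(-bterm * (lam[2] + (lam[1] - lam[2]) * dot^2))
    signal[sel, ] <- signal[sel, ] + f[sel] * att
  }
  signal <- spec$S0 * signal
  if (!noiseless && spec$noise_sigma > 0) {
    set.seed(spec$seed)
    n1 <- matrix(stats::rnorm(nvox * npts), nvox, npts)
    n2 <- matrix(stats::rnorm(nvox * npts), nvox, npts)
    signal <- sqrt((signal + spec$noise_sigma * n1)^2 +
                     (spec$noise_sigma * n2)^2)
  }
  structure(list(dwi = array(signal, c(dims, npts)), truth = truth,
                 scheme = scheme, spec = spec),
            class = "dsi_data")
}

# -- BOLD ---------------------------------------------------------------------

#' Block-design stimulation paradigm
#'
#' Five blocks of 45 s rest followed by 15 s stimulation, closed by a
#' trailing 45 s rest; at the default 3 s volume spacing this yields 115
#' volumes (25 stimulation, 90 rest).
#'
#' @param n_blocks Number of rest+stimulation blocks (default 5).
#' @param rest_s,stim_s,trailing_rest_s Block timing in seconds.
#' @param volume_spacing Seconds per volume (default 3; must divide the
#'   total duration exactly).
#' @return An object of class `block_paradigm` with logical `stim` labels
#'   per volume.
#' @export
block_paradigm <- function(n_blocks = 5, rest_s = 45, stim_s = 15,
                           trailing_rest_s = 45, volume_spacing = 3) {
  total <- n_blocks * (rest_s + stim_s) + trailing_rest_s
  if (abs(total / volume_spacing - round(total / volume_spacing)) > 1e-9)
    stop("volume spacing must divide the total paradigm duration exactly")
  n_vol <- as.integer(round(total / volume_spacing))
  t0 <- (seq_len(n_vol) - 1) * volume_spacing
  phase <- t0 %% (rest_s + stim_s)
  stim <- phase >= rest_s & t0 < n_blocks * (rest_s + stim_s)
  par <- structure(list(n_blocks = n_blocks, rest_s = rest_s, stim_s = stim_s,
                        trailing_rest_s = trailing_rest_s,
                        volume_spacing = volume_spacing,
                        n_volumes = n_vol, stim = stim),
                   class = "block_paradigm")
  stopifnot(!par$stim[1], !par$stim[n_vol])
  par
}

#' Simulate a block-design BOLD time series
#'
#' Active voxels follow `baseline * (1 + effect/100 * boxcar(t))`, inactive
#' voxels stay at baseline; i.i.d. Gaussian noise is added everywhere.
#'
#' @param paradigm A [block_paradigm()].
#' @param active_mask Logical 3D array marking responsive voxels.
#' @param effect Percent signal change during stimulation (>= 0).
#' @param noise_sigma Gaussian noise standard deviation (signal units).
#' @param seed RNG seed.
#' @param baseline Baseline signal level (default 100).
#' @return A 4D array (grid x volumes) with the paradigm attached as
#'   attribute `paradigm`.
#' @export
simulate_bold <- function(paradigm, active_mask, effect = 2,
                          noise_sigma = 2, seed = 1L, baseline = 100) {
  if (effect < 0) stop("effect size must be non-negative")
  dims <- dim(active_mask)
  n_vol <- paradigm$n_volumes
  nvox <- prod(dims)
  boxcar <- as.numeric(paradigm$stim)
  base <- matrix(baseline, nvox, n_vol)
  act <- as.vector(active_mask)
  if (any(act))
    base[act, ] <- base[act, ] *
      matrix(1 + effect / 100 * boxcar, sum(act), n_vol, byrow = TRUE)
  if (noise_sigma > 0) {
    set.seed(seed)
    base <- base + matrix(stats::rnorm(nvox * n_vol, sd = noise_sigma),
                          nvox, n_vol)
  }
  out <- array(base, c(dims, n_vol))
  attr(out, "paradigm") <- paradigm
  out
}
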