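# Propagator / ODF reconstruction from Cartesian q-space samples, and the
# FA / gFA anisotropy metrics.

# -- single-voxel operations --------------------------------------------------

#' Place one voxel's q-space samples on the Cartesian reconstruction grid
#'
#' Each encoding point is mapped to its (near-)integer lattice site, scaled
#' so the maximum q-radius lands at the scheme's native lattice radius
#' (sqrt(13) for the 203-point scheme); the surrounding grid out to
#' `grid_radius` stays zero (keyhole zero-padding). If the scheme covers
#' only a half-ball, conjugate-symmetric completion `S(q) = S(-q)` fills the
#' mirror sites.
#'
#' @param signal Numeric vector, one sample per encoding point.
#' @param scheme A `qspace_scheme`.
#' @param grid_radius Grid half-width (default from the scheme).
#' @return A cubic array of side `2 * grid_radius + 1`.
#' @export
regrid_qspace <- function(signal, scheme, grid_radius = scheme$grid_radius) {
  p <- scheme$points
  if (length(signal) != nrow(p))
    stop("signal has ", length(signal), " samples but the scheme has ",
         nrow(p), " encoding points")
  n <- 2 * grid_radius + 1
  sites <- round(scheme_lattice_sites(scheme))
  if (max(abs(sites)) > grid_radius)
    stop("scheme lattice exceeds grid_radius ", grid_radius)
  grid <- array(0, c(n, n, n))
  idx <- sites + grid_radius + 1
  grid[idx] <- signal
  # conjugate-symmetric completion for half-ball schemes
  midx <- -sites + grid_radius + 1
  empty <- grid[midx] == 0
  if (any(empty)) grid[midx[empty, , drop = FALSE]] <- signal[empty]
  grid
}

# radial Hanning window over the cubic grid, tapering to zero at the radius
# of the outermost sampled q-space site (the classic DSI filter); falls back
# to the grid half-width when no support radius is given
hanning_window <- function(grid_radius, support_radius = grid_radius) {
  n <- 2 * grid_radius + 1
  ax <- seq(-grid_radius, grid_radius)
  r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  w <- 0.5 * (1 + cos(pi * pmin(r, support_radius) / support_radius))
  array(w, c(n, n, n))
}

# circular shifts mapping centered coordinates to FFT order and back (odd n)
ifftshift3 <- function(a) {
  n <- dim(a)[1]; h <- (n + 1) %/% 2
  ix <- c(h:n, seq_len(h - 1))
  a[ix, ix, ix]
}
fftshift3 <- function(a) {
  n <- dim(a)[1]; h <- (n + 1) %/% 2
  ix <- c((n - h + 2):n, seq_len(n - h + 1))
  a[ix, ix, ix]
}

#' Reconstruct the diffusion propagator from a q-space grid
#'
#' Applies an optional radial Hanning window, zero-pads the q-space grid by
#' `pad_factor` (finer sampling of the same band-limited propagator, which
#' sharpens the later radial interpolation without changing the physical
#' field of view), takes the centered 3D discrete Fourier transform of the
#' (conjugate-symmetric) signal, keeps the real part and clips negative
#' ripple at zero.
#'
#' @param qgrid Cubic array with odd side, as from [regrid_qspace()].
#' @param window Apply the Hanning window (default `TRUE`).
#' @param pad_factor Odd integer zero-padding factor (default 3: an 11^3
#'   q-grid yields a 33^3 propagator sampled at 1/3 native cell).
#' @return A list of class `propagator_grid`: `values` (non-negative cubic
#'   array, centrosymmetric), `raw` (unclipped real part), `grid_radius`
#'   (native, in q-grid cells), `upsampling`.
#' @export
reconstruct_propagator <- function(qgrid, window = TRUE, pad_factor = 3) {
  d <- dim(qgrid)
  if (length(d) != 3 || length(unique(d)) != 1)
    stop("q-space grid must be a cube")
  if (d[1] %% 2 == 0) stop("q-space grid side must be odd (centered grid)")
  if (pad_factor %% 2 != 1 || pad_factor < 1)
    stop("pad_factor must be a positive odd integer")
  R <- (d[1] - 1) %/% 2
  if (window) {
    occ <- which(qgrid != 0, arr.ind = TRUE)
    support <- if (nrow(occ)) sqrt(max(rowSums((occ - R - 1)^2))) else R
    qgrid <- qgrid * hanning_window(R, support)
  }
  n <- d[1]
  m <- pad_factor * n
  big <- array(0, c(m, m, m))
  ctr <- (m + 1) %/% 2
  ix <- (ctr - R):(ctr + R)
  big[ix, ix, ix] <- qgrid
  pr <- Re(fftshift3(stats::fft(ifftshift3(big))))
  structure(list(values = pmax(pr, 0), raw = pr, grid_radius = R,
                 upsampling = pad_factor),
            class = "propagator_grid")
}

# trilinear interpolation of a cubic centered grid at points (m x 3), in
# grid-cell units relative to the center; outside points error
trilinear_weights <- function(pts, grid_radius) {
  n <- 2 * grid_radius + 1
  pos <- pts + grid_radius  # 0-based grid coords
  if (any(pos < 0) || any(pos > n - 1))
    stop("radial sampling range exceeds the propagator grid")
  i0 <- pmin(floor(pos), n - 2)
  f <- pos - i0
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  idx <- matrix(0L, nrow(pts), 8)
  wts <- matrix(0, nrow(pts), 8)
  for (k in 1:8) {
    c3 <- corners[k, ]
    ii <- sweep(i0, 2, c3, "+")
    idx[, k] <- ii[, 1] + n * ii[, 2] + n * n * ii[, 3] + 1L
    w <- abs(1 - c3[1] - f[, 1]) * abs(1 - c3[2] - f[, 2]) *
      abs(1 - c3[3] - f[, 3])
    wts[, k] <- w
  }
  list(idx = idx, wts = wts)
}

# K/2 x m^3 sparse matrix mapping a flattened (upsampled) propagator to
# hemisphere ODF values: psi(u) = sum_r r^2 P(r u), trilinear interpolation
# at each radius; radii run in native q-grid cells from 1 to grid_radius
odf_projection_matrix <- function(grid_radius, dirs_hemi, n_radial = 16,
                                  upsampling = 1) {
  m <- upsampling * (2 * grid_radius + 1)
  half <- (m - 1) %/% 2
  radii <- seq(1, grid_radius, length.out = n_radial)
  nh <- nrow(dirs_hemi)
  ii <- jj <- xx <- vector("list", n_radial)
  for (s in seq_len(n_radial)) {
    tw <- trilinear_weights(dirs_hemi * radii[s] * upsampling, half)
    ii[[s]] <- rep(seq_len(nh), 8)
    jj[[s]] <- as.vector(tw$idx)
    xx[[s]] <- as.vector(tw$wts) * radii[s]^2
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nh, m^3))
}

#' Compute the orientation distribution function of one propagator
#'
#' Radial projection `psi(u) = sum_r r^2 P(r * u)` over `n_radial` radii
#' from one native grid cell to the native grid edge, with trilinear
#' interpolation of the (upsampled) propagator. Values are computed on one
#' hemisphere of the direction set and mirrored, so antipodal symmetry is
#' exact.
#'
#' @param propagator A `propagator_grid` (or a cubic array, assumed
#'   unpadded).
#' @param directions K x 3 matrix of antipodally paired unit vectors in the
#'   order produced by [odf_directions()] (first K/2 one hemisphere, vertex
#'   `i + K/2` the antipode of `i`).
#' @param n_radial Number of radial samples (default 16).
#' @return Numeric K-vector `psi`, non-negative, `psi(u) = psi(-u)` exactly.
#' @export
compute_odf <- function(propagator, directions, n_radial = 16) {
  if (inherits(propagator, "propagator_grid")) {
    vals <- propagator$values
    up <- propagator$upsampling
    R <- propagator$grid_radius
  } else {
    vals <- propagator
    up <- 1
    R <- (dim(vals)[1] - 1) %/% 2
  }
  K <- nrow(directions)
  dirs_hemi <- directions[seq_len(K %/% 2), , drop = FALSE]
  W <- odf_projection_matrix(R, dirs_hemi, n_radial, up)
  psi_h <- as.vector(W %*% as.vector(vals))
  pmax(c(psi_h, psi_h), 0)
}

# -- anisotropy metrics -------------------------------------------------------

#' Generalized fractional anisotropy of an ODF
#'
#' `gFA = sd(psi) / rms(psi)` with the population (divide-by-K) standard
#' deviation, so a constant ODF gives 0 and a one-hot ODF of length K gives
#' `sqrt(1 - 1/K)`. Always in `[0, 1]`.
#'
#' @param psi Non-negative ODF sample vector (not all zero).
#' @return The gFA scalar.
#' @export
gfa <- function(psi) {
  if (any(psi < 0)) stop("ODF values must be non-negative")
  rms <- sqrt(mean(psi^2))
  if (rms == 0) stop("degenerate ODF: all samples are zero")
  sqrt(mean((psi - mean(psi))^2)) / rms
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' `FA = sqrt(3/2) * sqrt(sum (l_i - lbar)^2) / sqrt(sum l_i^2)`, in `[0,1]`.
#'
#' @param l1,l2,l3 Non-negative eigenvalues (vectors are accepted).
#' @return FA, same length as the inputs.
#' @examples
#' fa(2, 1, 1)  # 1/sqrt(6)
#' @export
fa <- function(l1, l2, l3) {
  lam <- cbind(l1, l2, l3)
  if (any(lam < 0)) stop("eigenvalues must be non-negative")
  ss <- rowSums(lam^2)
  if (any(ss == 0)) stop("eigenvalues must not all be zero")
  lbar <- rowMeans(lam)
  out <- sqrt(1.5 * rowSums((lam - lbar)^2) / ss)
  if (length(out) == 1) out <- as.vector(out)
  out
}

# -- whole-volume reconstruction ----------------------------------------------

# Fused regrid -> window -> centered DFT real part as one dense matrix
# (m^3 x n_points) for the zero-padded grid: P = M %*% S for
# conjugate-symmetric schemes. Exactly equivalent to the per-voxel fft path
# because the input is symmetric.
fourier_matrix <- function(scheme, grid_radius, window = TRUE,
                           pad_factor = 3) {
  sites <- round(scheme_lattice_sites(scheme))
  m <- pad_factor * (2 * grid_radius + 1)
  half <- (m - 1) %/% 2
  ax <- seq(-half, half)
  X <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  M <- cos(2 * pi * (X %*% t(sites)) / m)
  if (window) {
    r <- sqrt(rowSums(sites^2))
    support <- max(r, 1)
    w <- 0.5 * (1 + cos(pi * pmin(r, support) / support))
    M <- sweep(M, 2, w, "*")
  }
  M
}

#' Full DSI reconstruction of a diffusion-weighted volume
#'
#' Runs the per-voxel chain regrid -> Hanning window -> Fourier transform ->
#' radial ODF projection -> clip -> gFA for every voxel (or a mask). The
#' linear steps (regridding, windowing, Fourier transform and radial
#' projection) are fused into a single K/2 x n-points operator, so the
#' intermediate propagator is never materialized per voxel; its negative
#' ripple (small under the Hanning window) is carried through linearly and
#' the resulting ODFs are clipped at zero. Deterministic given inputs and
#' parameters.
#'
#' @param dwi 4D array (x, y, z, encoding points) or a `dsi_data` object.
#' @param scheme A `qspace_scheme` (taken from `dwi` if it is `dsi_data`).
#' @param mask Optional logical 3D array restricting reconstruction.
#' @param window Apply the radial Hanning window (default `TRUE`).
#' @param subdiv Icosphere subdivision for ODF directions (default 3,
#'   K = 642).
#' @param n_radial Radial samples for the ODF projection (default 16).
#' @param pad_factor Propagator zero-padding factor (default 3), see
#'   [reconstruct_propagator()].
#' @param voxel_size Voxel size in mm carried into the field (default
#'   `c(0.2, 0.2, 0.5)` or from `dsi_data`).
#' @return A list of class `odf_field`: `psi_hemi` (K/2 x nvox-in-mask
#'   matrix), `directions` (K x 3), `mask`, `dims`, `voxel_size`, `gfa` (a
#'   3D array of class `scalar_map`, NA outside the mask), and the
#'   reconstruction parameters.
#' @export
full_reconstruction <- function(dwi, scheme = NULL, mask = NULL,
                                window = TRUE, subdiv = 3, n_radial = 16,
                                pad_factor = 3,
                                voxel_size = c(0.2, 0.2, 0.5)) {
  if (inherits(dwi, "dsi_data")) {
    scheme <- dwi$scheme
    voxel_size <- dwi$spec$voxel_size
    dwi <- dwi$dwi
  }
  if (is.null(scheme)) stop("a qspace_scheme is required")
  d <- dim(dwi)
  if (length(d) != 4 || d[4] != nrow(scheme$points))
    stop("dwi must be 4D with ", nrow(scheme$points), " volumes")
  dims <- d[1:3]
  nvox_all <- prod(dims)
  if (is.null(mask)) mask <- array(TRUE, dims)
  vox <- which(as.vector(mask))
  S <- matrix(aperm(dwi, c(4, 1, 2, 3)), d[4], nvox_all)[, vox, drop = FALSE]
  R <- scheme$grid_radius
  tess <- get_tessellation(subdiv)
  A <- recon_operator(scheme, R, window, subdiv, n_radial, pad_factor)
  psi_hemi <- pmax(A %*% S, 0)
  m1 <- colMeans(psi_hemi)
  m2 <- colMeans(psi_hemi^2)
  gfa_vals <- ifelse(m2 > 0, sqrt(pmax(m2 - m1^2, 0) / m2), NA_real_)
  gfa_map <- array(NA_real_, dims)
  gfa_map[vox] <- gfa_vals
  class(gfa_map) <- c("scalar_map", class(gfa_map))
  attr(gfa_map, "kind") <- "gfa"
  structure(list(psi_hemi = psi_hemi, directions = tess$directions,
                 tess_subdiv = subdiv, mask = mask, voxel_indices = vox,
                 dims = dims, voxel_size = voxel_size, gfa = gfa_map,
                 params = list(window = window, subdiv = subdiv,
                               n_radial = n_radial, grid_radius = R,
                               pad_factor = pad_factor)),
            class = "odf_field")
}

# cache of the fused signal -> hemisphere-ODF operator (K/2 x n_points)
.recon_cache <- new.env(parent = emptyenv())

recon_operator <- function(scheme, grid_radius, window, subdiv, n_radial,
                           pad_factor) {
  key <- paste(nrow(scheme$points), grid_radius, window, subdiv, n_radial,
               pad_factor, round(max(scheme$points$q_radius), 6), sep = "|")
  if (!is.null(.recon_cache[[key]])) return(.recon_cache[[key]])
  tess <- get_tessellation(subdiv)
  M <- fourier_matrix(scheme, grid_radius, window, pad_factor)
  W <- odf_projection_matrix(grid_radius,
                             tess$directions[seq_len(tess$n_hemi), ],
                             n_radial, pad_factor)
  A <- as.matrix(W %*% M)
  .recon_cache[[key]] <- A
  A
}

#' Extract the full ODF sample vector of one voxel from an `odf_field`
#'
#' @param field An `odf_field`.
#' @param voxel Linear voxel index into the field's grid.
#' @return Numeric K-vector (mirrored over antipodes).
#' @export
odf_at <- function(field, voxel) {
  j <- match(voxel, field$voxel_indices)
  if (is.na(j)) stop("voxel ", voxel, " is outside the reconstructed mask")
  h <- field$psi_hemi[, j]
  c(h, h)
}

#' gFA map of an ODF field
#'
#' Recomputes `std(psi)/rms(psi)` per voxel from the stored ODF samples.
#'
#' @param field An `odf_field`.
#' @return A 3D array of class `scalar_map` (NA outside the mask).
#' @export
gfa_map <- function(field) {
  psi <- field$psi_hemi
  m1 <- colMeans(psi)
  m2 <- colMeans(psi^2)
  vals <- ifelse(m2 > 0, sqrt(pmax(m2 - m1^2, 0) / m2), NA_real_)
  out <- array(NA_real_, field$dims)
  out[field$voxel_indices] <- vals
  class(out) <- c("scalar_map", class(out))
  attr(out, "kind") <- "gfa"
  out
}
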