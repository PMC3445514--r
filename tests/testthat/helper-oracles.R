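# Shared fixtures and independent oracles, built in code at test time.

# angle between two axes (antipodally symmetric), degrees
axis_angle <- function(u, v) acos(pmin(1, abs(sum(u * v)))) * 180 / pi

# closed-form multi-tensor DSI signal for one voxel (independent of
# simulate_dwi's internals)
tensor_signal <- function(scheme, e1, lambda = c(1.7e-3, 0.3e-3, 0.3e-3),
                          S0 = 1) {
  G <- as.matrix(scheme$points[, c("gx", "gy", "gz")])
  b <- scheme$points$b_value
  dot <- as.vector(G %*% e1)
  S0 * exp(-b * (lambda[2] + (lambda[1] - lambda[2]) * dot^2))
}

random_unit <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# synthetic ODF field with a prescribed fiber direction per voxel: sharp
# Watson-like bumps on the tessellation, constant gFA map
make_direction_field <- function(dir_fun, dims, voxel_size = c(0.2, 0.2, 0.2),
                                 gfa_value = 0.5, kappa = 40) {
  dirs <- odf_directions()
  nh <- nrow(dirs) / 2
  dh <- dirs[seq_len(nh), ]
  nvox <- prod(dims)
  centers <- as.matrix(expand.grid(
    ((seq_len(dims[1])) - 0.5) * voxel_size[1],
    ((seq_len(dims[2])) - 0.5) * voxel_size[2],
    ((seq_len(dims[3])) - 0.5) * voxel_size[3]))
  E <- t(apply(centers, 1, dir_fun))
  psi_hemi <- exp(kappa * ((dh %*% t(E))^2 - 1))
  gmap <- array(gfa_value, dims)
  structure(list(psi_hemi = psi_hemi, directions = dirs, tess_subdiv = 3,
                 mask = array(TRUE, dims), voxel_indices = seq_len(nvox),
                 dims = dims, voxel_size = voxel_size, gfa = gmap,
                 params = list(synthetic = TRUE)),
            class = "odf_field")
}

# cache expensive fixtures (scheme, voxelized scenario geometry) per session
.fixture_cache <- new.env(parent = emptyenv())

cached_scheme <- function() {
  if (is.null(.fixture_cache$scheme)) .fixture_cache$scheme <- build_scheme()
  .fixture_cache$scheme
}

cached_truth <- function(scenario) {
  key <- paste0("truth_", scenario)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- voxelize_phantom(make_scenario(scenario, 1))
  .fixture_cache[[key]]
}

cached_recon <- function(scenario, seed = 1) {
  key <- paste0("recon_", scenario, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    spec <- make_scenario(scenario, seed)
    data <- simulate_dwi(spec, cached_scheme(), truth = cached_truth(scenario))
    .fixture_cache[[key]] <- list(spec = spec, data = data,
                                  field = full_reconstruction(data))
  }
  .fixture_cache[[key]]
}
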