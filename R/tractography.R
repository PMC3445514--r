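# Deterministic streamline tractography: ODF peak extraction, seeding,
# tracking (compiled core), interhemispheric-connection counting, and
# tractogram I/O (TrackVis .trk and a plain-text polyline dialect).

termination_reasons <- c("low_gfa", "sharp_turn", "out_of_volume",
                         "no_signal", "max_steps")

#' Tracking parameter set
#'
#' Defaults follow the white-matter tracking protocol: gFA threshold 0.2,
#' turning angle 63 degrees, 50,000 seeds; the step size is 0.1 mm (half the
#' in-plane voxel).
#'
#' @param gfa_threshold Minimum interpolated gFA for a step, in `[0, 1]`.
#' @param turning_angle Maximum angle between consecutive steps, degrees in
#'   (0, 90).
#' @param seed_count Number of seed points drawn in the seed mask.
#' @param step_size Step length in mm.
#' @param max_steps Step cap per tracking half.
#' @param rng_seed Seed for the seed-position RNG.
#' @return A list of class `tracking_params`.
#' @export
tracking_params <- function(gfa_threshold = 0.2, turning_angle = 63,
                            seed_count = 50000L, step_size = 0.1,
                            max_steps = 2000L, rng_seed = 1L) {
  if (gfa_threshold < 0 || gfa_threshold > 1)
    stop("gfa_threshold must be in [0, 1]")
  if (turning_angle <= 0 || turning_angle >= 90)
    stop("turning_angle must be in (0, 90) degrees")
  if (seed_count <= 0) stop("seed_count must be positive")
  if (step_size <= 0) stop("step_size must be positive")
  structure(list(gfa_threshold = gfa_threshold, turning_angle = turning_angle,
                 seed_count = as.integer(seed_count), step_size = step_size,
                 max_steps = as.integer(max_steps),
                 rng_seed = as.integer(rng_seed)),
            class = "tracking_params")
}

#' Extract fiber-direction peaks from one ODF
#'
#' Local maxima of `psi` over the sphere-tessellation neighbor graph
#' (plateau-tolerant: at least as large as every neighbor and strictly above
#' at least one, so a flat ODF has no peaks). Because the ODF rides a large
#' isotropic baseline, the 30% retention floor is applied to the
#' min-subtracted profile (peak prominence relative to the ODF range).
#' Candidates are antipodally deduplicated, greedily separated by at least
#' `min_separation_deg`, at most `max_peaks` kept, sorted by decreasing
#' `psi`.
#'
#' @param psi Full ODF sample K-vector (antipodally symmetric).
#' @param directions K x 3 direction matrix matching `psi`.
#' @param subdiv Tessellation level of `directions` (default 3).
#' @param rel_threshold Prominence floor as a fraction of the ODF range
#'   (default 0.3).
#' @param max_peaks Maximum peaks retained (default 3).
#' @param min_separation_deg Minimum angle between retained peaks (default
#'   25 degrees).
#' @return Matrix (n_peaks x 3) of unit vectors; zero rows if flat.
#' @export
extract_peaks <- function(psi, directions, subdiv = 3, rel_threshold = 0.3,
                          max_peaks = 3, min_separation_deg = 25) {
  tess <- get_tessellation(subdiv)
  nh <- tess$n_hemi
  is_max <- logical(nh)
  for (i in seq_len(nh)) {
    nb <- tess$neighbors[i, ]
    nb <- nb[!is.na(nb)]
    nb_h <- ifelse(nb > nh, nb - nh, nb)
    is_max[i] <- all(psi[i] >= psi[nb_h]) && any(psi[i] > psi[nb_h])
  }
  rng <- max(psi) - min(psi)
  if (rng <= 0) return(directions[integer(0), , drop = FALSE])
  floor_v <- min(psi) + rel_threshold * rng
  cand <- which(is_max & psi[seq_len(nh)] >= floor_v)
  if (!length(cand)) return(directions[integer(0), , drop = FALSE])
  cand <- cand[order(psi[cand], decreasing = TRUE)]
  cos_sep <- cos(min_separation_deg * pi / 180)
  kept <- integer(0)
  for (i in cand) {
    if (length(kept) >= max_peaks) break
    if (!length(kept) ||
        all(abs(directions[kept, , drop = FALSE] %*% directions[i, ]) < cos_sep))
      kept <- c(kept, i)
  }
  directions[kept, , drop = FALSE]
}

#' Peak field of a reconstructed volume
#'
#' Vectorized peak extraction for every voxel of an `odf_field`; used by the
#' tracker (nearest-voxel peak lookup).
#'
#' @param field An `odf_field`.
#' @param rel_threshold,max_peaks,min_separation_deg As in
#'   [extract_peaks()].
#' @return A list of class `peak_field`: `peaks` (nvox x 3*max_peaks matrix),
#'   `npk` (integer vector), `dims`, `voxel_size`.
#' @export
field_peaks <- function(field, rel_threshold = 0.3, max_peaks = 3,
                        min_separation_deg = 25) {
  tess <- get_tessellation(field$tess_subdiv)
  nh <- tess$n_hemi
  psi <- field$psi_hemi            # nh x nmask
  nmask <- ncol(psi)
  # plateau-tolerant local maxima on the hemisphere (antipodes duplicate)
  is_max <- matrix(TRUE, nh, nmask)
  has_strict <- matrix(FALSE, nh, nmask)
  for (i in seq_len(nh)) {
    nb <- tess$neighbors[i, ]
    nb <- nb[!is.na(nb)]
    nb_h <- unique(ifelse(nb > nh, nb - nh, nb))
    nb_h <- nb_h[nb_h != i]
    row <- psi[i, ]
    for (j in nb_h) {
      is_max[i, ] <- is_max[i, ] & (row >= psi[j, ])
      has_strict[i, ] <- has_strict[i, ] | (row > psi[j, ])
    }
  }
  is_max <- is_max & has_strict
  amax <- max.col(t(psi), ties.method = "first")
  vmax <- psi[cbind(amax, seq_len(nmask))]
  amin <- max.col(t(-psi), ties.method = "first")
  vmin <- psi[cbind(amin, seq_len(nmask))]
  nvox <- prod(field$dims)
  peaks <- matrix(0, nvox, 3 * max_peaks)
  npk <- integer(nvox)
  has_peak <- which(colSums(is_max) > 0 & vmax > vmin)
  dirs <- tess$directions
  cos_sep <- cos(min_separation_deg * pi / 180)
  for (jj in has_peak) {
    floor_v <- vmin[jj] + rel_threshold * (vmax[jj] - vmin[jj])
    cand <- which(is_max[, jj] & psi[, jj] >= floor_v)
    if (!length(cand)) next
    cand <- cand[order(psi[cand, jj], decreasing = TRUE)]
    kept <- integer(0)
    for (i in cand) {
      if (length(kept) >= max_peaks) break
      if (!length(kept) ||
          all(abs(dirs[kept, , drop = FALSE] %*% dirs[i, ]) < cos_sep))
        kept <- c(kept, i)
    }
    v <- field$voxel_indices[jj]
    npk[v] <- length(kept)
    for (k in seq_along(kept))
      peaks[v, (3 * k - 2):(3 * k)] <- dirs[kept[k], ]
  }
  structure(list(peaks = peaks, npk = npk, dims = field$dims,
                 voxel_size = field$voxel_size,
                 rel_threshold = rel_threshold, max_peaks = max_peaks),
            class = "peak_field")
}

#' Seed mask from the medial corpus-callosum analog
#'
#' The midline slab of the callosal bridge in the phantom's ground truth;
#' in the severed scenario the gap voxels are naturally excluded because
#' they carry no bundle.
#'
#' @param truth A `phantom_truth`.
#' @param spec The matching `phantom_spec`.
#' @return Logical 3D array.
#' @export
seed_corpus_callosum <- function(truth, spec) {
  m <- scenario_masks(truth, spec)$bridge
  if (!any(m)) stop("callosal seed mask is empty")
  m
}

#' Seed mask from a high-gFA region of interest
#'
#' Restricts seeding to a previously determined region (typically the
#' segmented high-anisotropy strip from [segment_high_gfa()]).
#'
#' @param roi A `roi_mask` or logical 3D array.
#' @return Logical 3D array.
#' @export
seed_high_gfa_area <- function(roi) {
  m <- if (inherits(roi, "roi_mask")) roi$mask else roi
  if (!any(m)) stop("high-gFA seed mask is empty")
  m
}

#' Deterministic streamline tractography
#'
#' Seeds are drawn uniformly inside the seed mask (voxel chosen uniformly,
#' position uniform within the voxel) with the parameter RNG seed. Tracking
#' proceeds bidirectionally from each seed along the voxel ODF peak best
#' aligned with the previous direction; a step is accepted iff the new
#' position is inside the volume in a voxel with at least one peak, the
#' turn does not exceed `turning_angle`, and the trilinearly interpolated
#' gFA at the new position is at least `gfa_threshold`. Both halves are
#' merged seed-centered. Fully reproducible given the RNG seed.
#'
#' @param field An `odf_field` (or `peaks` given explicitly).
#' @param seed_mask Logical 3D array of allowed seed voxels.
#' @param params A [tracking_params()].
#' @param gfa_map gFA array (default the field's own map).
#' @param peaks Optional precomputed [field_peaks()].
#' @return An object of class `tractogram`: flat `points` matrix (mm),
#'   `lengths`, per-streamline `reason` factor (one reason per streamline;
#'   interior causes take precedence over volume exit when the two halves
#'   differ), `reason_fwd`/`reason_bwd`, `params`, `seed_mask_count`.
#' @export
track <- function(field, seed_mask, params = tracking_params(),
                  gfa_map = NULL, peaks = NULL) {
  if (!inherits(params, "tracking_params")) stop("params must be tracking_params()")
  if (is.null(gfa_map)) gfa_map <- field$gfa
  if (is.null(peaks)) peaks <- field_peaks(field)
  dims <- peaks$dims
  vs <- peaks$voxel_size
  seed_vox <- which(as.vector(seed_mask))
  if (!length(seed_vox)) stop("seed mask is empty")
  set.seed(params$rng_seed)
  vox <- seed_vox[sample.int(length(seed_vox), params$seed_count,
                             replace = TRUE)]
  ijk <- arrayInd(vox, dims) - 1L
  offs <- matrix(stats::runif(3 * params$seed_count), ncol = 3)
  seeds <- sweep(ijk + offs, 2, vs, "*")
  res <- .track_streamlines_cpp(
    peaks$peaks, as.integer(peaks$npk), as.double(gfa_map),
    as.integer(dims), as.double(vs), seeds,
    params$step_size, cos(params$turning_angle * pi / 180),
    params$gfa_threshold, params$max_steps)
  structure(list(points = res$points, lengths = res$lengths,
                 offsets = c(0L, cumsum(res$lengths)),
                 reason = factor(termination_reasons[res$reason],
                                 levels = termination_reasons),
                 reason_fwd = factor(termination_reasons[res$reason_fwd],
                                     levels = termination_reasons),
                 reason_bwd = factor(termination_reasons[res$reason_bwd],
                                     levels = termination_reasons),
                 seeds = seeds, params = params, dims = dims,
                 voxel_size = vs, n = length(res$lengths)),
            class = "tractogram")
}

#' Extract one streamline's points
#'
#' @param tract A `tractogram`.
#' @param i Streamline index.
#' @return An n x 3 matrix of positions in mm.
#' @export
streamline_points <- function(tract, i) {
  a <- tract$offsets[i] + 1
  b <- tract$offsets[i + 1]
  tract$points[a:b, , drop = FALSE]
}

#' @export
print.tractogram <- function(x, ...) {
  cat("Tractogram:", x$n, "streamlines,", nrow(x$points), "points\n")
  print(table(x$reason))
  invisible(x)
}

#' Total tracked length of a tractogram, in mm
#'
#' @param tract A `tractogram`.
#' @return Total polyline length (mm).
#' @export
tract_length <- function(tract) {
  sl_id <- rep.int(seq_len(tract$n), tract$lengths)
  d <- diff(tract$points)
  same <- sl_id[-1] == sl_id[-length(sl_id)]
  sum(sqrt(rowSums(d^2))[same])
}

#' Count streamlines connecting the two hemispheres
#'
#' A streamline counts if it has at least one point strictly on each side of
#' the midsagittal plane and intersects the contralateral target mask.
#'
#' @param tract A `tractogram`.
#' @param midline_x Midsagittal plane position in mm.
#' @param target_mask Logical 3D array (contralateral target).
#' @return Integer count.
#' @export
count_interhemispheric <- function(tract, midline_x, target_mask) {
  if (tract$n == 0) return(0L)
  sl_id <- rep.int(seq_len(tract$n), tract$lengths)
  x <- tract$points[, 1]
  vs <- tract$voxel_size
  dims <- tract$dims
  ijk <- cbind(floor(tract$points[, 1] / vs[1]),
               floor(tract$points[, 2] / vs[2]),
               floor(tract$points[, 3] / vs[3])) + 1
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= dims[1] &
        ijk[, 2] >= 1 & ijk[, 2] <= dims[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= dims[3]
  in_target <- logical(length(x))
  in_target[ok] <- target_mask[ijk[ok, , drop = FALSE]]
  left <- rowsum((x < midline_x) + 0, sl_id) > 0
  right <- rowsum((x > midline_x) + 0, sl_id) > 0
  hit <- rowsum(in_target + 0, sl_id) > 0
  sum(left & right & hit)
}

# -- tractogram I/O -----------------------------------------------------------

#' Write a tractogram in TrackVis .trk format
#'
#' Minimal TrackVis version-2 writer; coordinates are stored in the
#' TrackVis voxel-mm convention with the grid dimensions and voxel size in
#' the header.
#'
#' @param tract A `tractogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trk <- function(tract, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), raw(1)), con)       # id_string, nul-padded
  writeBin(as.integer(tract$dims), con, size = 2, endian = "little")
  writeBin(as.numeric(tract$voxel_size), con, size = 4, endian = "little")
  writeBin(rep(0, 3), con, size = 4, endian = "little")        # origin
  writeBin(0L, con, size = 2, endian = "little")               # n_scalars
  writeBin(raw(200), con)                                      # scalar names
  writeBin(0L, con, size = 2, endian = "little")               # n_properties
  writeBin(raw(200), con)                                      # property names
  m <- diag(c(tract$voxel_size, 1))                            # vox_to_ras
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  writeBin(raw(444), con)                                      # reserved
  writeBin(c(charToRaw("RAS"), raw(1)), con)                   # voxel_order
  writeBin(raw(4), con)                                        # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4, endian = "little")
  writeBin(raw(2), con)                                        # pad1
  writeBin(raw(6), con)                                        # invert/swap flags
  writeBin(as.integer(tract$n), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")               # version
  writeBin(1000L, con, size = 4, endian = "little")            # hdr_size
  for (i in seq_len(tract$n)) {
    pts <- streamline_points(tract, i)
    writeBin(nrow(pts), con, size = 4, endian = "little")
    writeBin(as.numeric(t(pts)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read streamline geometry from a TrackVis .trk file
#'
#' @param path File to read.
#' @return A list with `points`, `lengths`, `offsets`, `dims`, `voxel_size`,
#'   `n` (geometry-only `tractogram`).
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readBin(con, "raw", 6)
  if (rawToChar(id[1:5]) != "TRACK") stop("not a TrackVis file")
  dims <- readBin(con, "integer", 3, size = 2, endian = "little")
  vs <- readBin(con, "numeric", 3, size = 4, endian = "little")
  seek(con, 988)
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdr != 1000) stop("unexpected .trk header size ", hdr)
  lengths <- integer(n_count)
  pts <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    np <- readBin(con, "integer", 1, size = 4, endian = "little")
    lengths[i] <- np
    pts[[i]] <- matrix(readBin(con, "numeric", 3 * np, size = 4,
                               endian = "little"), ncol = 3, byrow = TRUE)
  }
  points <- do.call(rbind, pts)
  list(points = points, lengths = lengths, offsets = c(0L, cumsum(lengths)),
       dims = dims, voxel_size = vs, n = n_count)
}

#' Write / read the plain-text polyline dialect
#'
#' One `# streamline <i> <n_points> <reason>` header line per streamline
#' followed by `x y z` rows in mm.
#'
#' @param tract A `tractogram`.
#' @param path File path.
#' @return `path` invisibly for the writer; a geometry list for the reader.
#' @export
write_streamlines_text <- function(tract, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(tract$n)) {
    pts <- streamline_points(tract, i)
    writeLines(sprintf("# streamline %d %d %s", i, nrow(pts),
                       as.character(tract$reason[i])), con)
    writeLines(sprintf("%.9g %.9g %.9g", pts[, 1], pts[, 2], pts[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_streamlines_text
#' @export
read_streamlines_text <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# streamline ", lines)
  if (!length(hdr)) stop("no streamlines in ", path)
  meta <- do.call(rbind, strsplit(sub("^# streamline ", "", lines[hdr]), " "))
  lengths <- as.integer(meta[, 2])
  reason <- factor(meta[, 3], levels = termination_reasons)
  body <- lines[-hdr]
  m <- do.call(rbind, lapply(strsplit(body, " "), as.numeric))
  if (nrow(m) != sum(lengths)) stop("point count mismatch in ", path)
  list(points = m, lengths = lengths, offsets = c(0L, cumsum(lengths)),
       reason = reason, n = length(lengths))
}
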