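# End-to-end orchestration: NIfTI I/O, run configuration, per-subject
# simulate -> reconstruct -> segment -> track -> BOLD pipeline, and the
# structure-function study report.

#' Write a volume as NIfTI-1
#'
#' Data are stored float32 with the voxel size in the header; the
#' description field carries provenance (config hash / seed) when given.
#'
#' @param volume 3D or 4D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel dimensions in mm.
#' @param description Optional string for the NIfTI description field
#'   (truncated to 79 bytes).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path, voxel_size = c(0.2, 0.2, 0.5),
                        description = NULL) {
  img <- RNifti::asNifti(volume)
  nd <- length(dim(volume))
  RNifti::pixdim(img) <- c(voxel_size, rep(1, max(0, nd - 3)))[seq_len(nd)]
  if (!is.null(description))
    img$descrip <- substr(description, 1, 79)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path File to read.
#' @return A list `(data, voxel_size, affine, description)`; `data` is a
#'   plain numeric array.
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  nd <- hdr$dim[1]
  list(data = array(as.numeric(img), dim(img)),
       voxel_size = RNifti::pixdim(img)[seq_len(min(nd, 3))],
       affine = structure(RNifti::xform(img), class = NULL),
       description = hdr$descrip)
}

#' Write / read an ODF field as NIfTI plus a sidecar direction table
#'
#' The hemisphere ODF samples are stored as a 4D NIfTI (K/2 volumes, one
#' per direction); the sidecar `<prefix>_dirs.txt` carries the full
#' direction set and reconstruction parameters, and `<prefix>_gfa.nii.gz`
#' the gFA map. `read_odf_field` reassembles a tracking-ready `odf_field`.
#'
#' @param field An `odf_field` (must cover the full grid).
#' @param prefix Output path prefix.
#' @return `prefix` invisibly (writer); an `odf_field` (reader).
#' @export
write_odf_field <- function(field, prefix) {
  if (length(field$voxel_indices) != prod(field$dims))
    stop("only full-grid ODF fields can be written")
  nh <- nrow(field$psi_hemi)
  vol <- array(t(field$psi_hemi), c(field$dims, nh))
  write_nifti(vol, paste0(prefix, "_odf.nii.gz"), field$voxel_size)
  write_nifti(unclass(field$gfa), paste0(prefix, "_gfa.nii.gz"),
              field$voxel_size)
  con <- file(paste0(prefix, "_dirs.txt"), "w")
  on.exit(close(con))
  writeLines(sprintf("# odf directions subdiv %d n_radial %d grid_radius %d window %d",
                     field$params$subdiv, field$params$n_radial,
                     field$params$grid_radius,
                     as.integer(isTRUE(field$params$window))), con)
  writeLines(sprintf("%.17g %.17g %.17g", field$directions[, 1],
                     field$directions[, 2], field$directions[, 3]), con)
  invisible(prefix)
}

#' @rdname write_odf_field
#' @export
read_odf_field <- function(prefix) {
  odf <- read_nifti(paste0(prefix, "_odf.nii.gz"))
  gmap <- read_nifti(paste0(prefix, "_gfa.nii.gz"))
  lines <- readLines(paste0(prefix, "_dirs.txt"))
  hdr <- as.integer(strsplit(sub("^# odf directions ", "", lines[1]),
                             " ")[[1]][c(2, 4, 6, 8)])
  dirs <- do.call(rbind, lapply(strsplit(lines[-1], " "), as.numeric))
  d <- dim(odf$data)
  dims <- d[1:3]
  psi_hemi <- t(matrix(odf$data, prod(dims), d[4]))
  g <- gmap$data
  class(g) <- c("scalar_map", class(g))
  attr(g, "kind") <- "gfa"
  structure(list(psi_hemi = psi_hemi, directions = dirs,
                 tess_subdiv = hdr[1], mask = array(TRUE, dims),
                 voxel_indices = seq_len(prod(dims)), dims = dims,
                 voxel_size = unname(odf$voxel_size), gfa = g,
                 params = list(subdiv = hdr[1], n_radial = hdr[2],
                               grid_radius = hdr[3], window = hdr[4] == 1)),
            class = "odf_field")
}

#' Build a pipeline run configuration
#'
#' Collects every stage's parameters plus the master seed; per-subject seeds
#' are derived as `seed + subject_index`, so a run is fully reproducible
#' from the configuration alone.
#'
#' @param scenario Scenario tag (see [make_scenario()]).
#' @param n_subjects Number of simulated subjects.
#' @param seed Master RNG seed.
#' @param out_dir Output directory (`NULL` = keep results in memory only).
#' @param snr Diffusion SNR per subject.
#' @param bold_effect_ipsi,bold_effect_contra Percent BOLD signal change in
#'   the ipsi-/contralesional cortical ROI. The default ipsilesional effect
#'   is 0 for `severed_bridge` (the non-recovering case) and 2 otherwise.
#' @param bold_noise_sigma Gaussian noise SD of the BOLD series.
#' @param tracking A [tracking_params()] list.
#' @param alpha Significance level for activation calls and group tests.
#' @param min_cluster BOLD cluster-extent threshold (voxels).
#' @return A list of class `run_config`.
#' @export
run_config <- function(scenario, n_subjects = 3, seed = 1L, out_dir = NULL,
                       snr = 30,
                       bold_effect_ipsi = if (scenario == "severed_bridge") 0 else 2,
                       bold_effect_contra = 2, bold_noise_sigma = 2,
                       tracking = tracking_params(), alpha = 0.05,
                       min_cluster = 4) {
  if (!scenario %in% scenario_tags)
    stop("unknown scenario ", sQuote(scenario), "; valid tags: ",
         paste(scenario_tags, collapse = ", "))
  if (n_subjects < 0) stop("n_subjects must be non-negative")
  structure(list(scenario = scenario, n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), out_dir = out_dir, snr = snr,
                 bold_effect_ipsi = bold_effect_ipsi,
                 bold_effect_contra = bold_effect_contra,
                 bold_noise_sigma = bold_noise_sigma,
                 tracking = unclass(tracking), alpha = alpha,
                 min_cluster = as.integer(min_cluster)),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `path` invisibly (writer); a `run_config` (reader).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- run_config(scenario = x$scenario, n_subjects = x$n_subjects,
                    seed = x$seed, out_dir = x$out_dir, snr = x$snr,
                    bold_effect_ipsi = x$bold_effect_ipsi,
                    bold_effect_contra = x$bold_effect_contra,
                    bold_noise_sigma = x$bold_noise_sigma,
                    tracking = do.call(tracking_params, x$tracking),
                    alpha = x$alpha, min_cluster = x$min_cluster)
  cfg
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  write_run_config(config, f)
  unname(tools::md5sum(f))
}

#' Search slab for the high-gFA segmentation stage
#'
#' The periventricular region of the ipsilesional (right) hemisphere,
#' between the midline and the descending limb: the anatomical neighborhood
#' in which the post-stroke anisotropy perturbation is expected.
#'
#' @param spec A `phantom_spec`.
#' @return Logical 3D array.
#' @export
segmentation_search_mask <- function(spec) {
  dims <- spec$grid_shape
  centers <- voxel_centers(dims, spec$voxel_size)
  array(centers[, 1] > spec$midline_x + 0.4 &
          centers[, 1] < .geom$limb_x["right"] - 0.6 &
          centers[, 3] >= .geom$strip_z[1] - 0.5 &
          centers[, 3] <= .geom$strip_z[2] + 0.5, dims)
}

# process one simulated subject; internal worker of run_pipeline
run_subject <- function(config, subject_index, scheme, truth_cache) {
  seed_s <- config$seed + subject_index
  spec <- make_scenario(config$scenario, seed = seed_s, snr = config$snr)
  truth <- truth_cache$truth
  if (is.null(truth)) {
    truth <- voxelize_phantom(spec)
    truth_cache$truth <- truth
  }
  masks <- scenario_masks(truth, spec)
  data <- simulate_dwi(spec, scheme, truth = truth)
  field <- full_reconstruction(data)
  gmap <- field$gfa
  # ROI stage: segmentation only applies when a perturbation exists
  roi_ipsi <- NULL
  if (config$scenario != "healthy") {
    roi_ipsi <- tryCatch(
      segment_high_gfa(gmap, segmentation_search_mask(spec),
                       voxel_size = spec$voxel_size),
      error = function(e) NULL)
  }
  midline_idx <- spec$midline_x / spec$voxel_size[1] + 0.5
  roi_contra <- if (!is.null(roi_ipsi))
    mirror_roi(roi_ipsi, midline_index = midline_idx) else NULL
  gfa_strip <- if (!is.null(roi_ipsi)) roi_mean_sem(gmap, roi_ipsi)$mean else NA_real_
  gfa_contra <- if (!is.null(roi_contra)) roi_mean_sem(gmap, roi_contra)$mean else NA_real_
  gfa_ic <- roi_mean_sem(gmap, masks$internal_capsule_ref)$mean
  # tractography: strip seeding where a strip exists, callosal otherwise
  tp <- do.call(tracking_params, config$tracking)
  tp$rng_seed <- seed_s
  seed_mask <- if (config$scenario == "healthy") {
    seed_corpus_callosum(truth, spec)
  } else if (!is.null(roi_ipsi)) {
    seed_high_gfa_area(roi_ipsi)
  } else {
    seed_high_gfa_area(masks$strip)
  }
  tract <- track(field, seed_mask, tp)
  n_inter <- count_interhemispheric(tract, spec$midline_x,
                                    masks$hemisphere_left)
  # BOLD stage
  par <- block_paradigm()
  bmasks <- scenario_bold_masks(spec)
  active <- bmasks$contra
  if (config$bold_effect_ipsi > 0) active <- active | bmasks$ipsi
  bold <- simulate_bold(par, active,
                        effect = max(config$bold_effect_contra,
                                     config$bold_effect_ipsi),
                        noise_sigma = config$bold_noise_sigma,
                        seed = seed_s)
  # per-ROI effects can differ: resimulate ipsi if asymmetric
  if (config$bold_effect_ipsi != config$bold_effect_contra &&
      config$bold_effect_ipsi > 0) {
    bold_i <- simulate_bold(par, bmasks$ipsi,
                            effect = config$bold_effect_ipsi,
                            noise_sigma = config$bold_noise_sigma,
                            seed = seed_s + 100000L)
    bold[rep(bmasks$ipsi, par$n_volumes)] <- bold_i[rep(bmasks$ipsi, par$n_volumes)]
  }
  tm <- t_map(bold, par)
  act_ipsi <- detect_activation(tm, bmasks$ipsi, alpha = config$alpha,
                                min_cluster = config$min_cluster)
  act_contra <- detect_activation(tm, bmasks$contra, alpha = config$alpha,
                                  min_cluster = config$min_cluster)
  if (!is.null(config$out_dir)) {
    sd <- file.path(config$out_dir, sprintf("subject_%02d", subject_index))
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    prov <- sprintf("dsitract seed=%d scenario=%s", seed_s, config$scenario)
    write_nifti(data$dwi, file.path(sd, "dwi.nii.gz"), spec$voxel_size, prov)
    write_btable(scheme, file.path(sd, "scheme.btab"))
    write_nifti(unclass(gmap), file.path(sd, "gfa.nii.gz"), spec$voxel_size, prov)
    if (!is.null(roi_ipsi))
      write_nifti(roi_ipsi$mask + 0, file.path(sd, "roi_ipsi.nii.gz"),
                  spec$voxel_size, prov)
    write_trk(tract, file.path(sd, "tracts.trk"))
    write_nifti(tm$t, file.path(sd, "bold_t.nii.gz"), spec$voxel_size, prov)
  }
  list(row = data.frame(
         subject = subject_index, scenario = config$scenario, seed = seed_s,
         gfa_strip = gfa_strip, gfa_contra = gfa_contra,
         gfa_internal_capsule = gfa_ic,
         interhemispheric_count = n_inter,
         activation_ipsi = act_ipsi$active,
         activation_contra = act_contra$active,
         failed = FALSE),
       gmap = gmap, masks = masks)
}

#' Run the full phantom study pipeline
#'
#' For each simulated subject: phantom -> diffusion simulation -> ODF/gFA
#' reconstruction -> high-gFA segmentation and homotopic mirroring -> ROI
#' gFA means -> seeded tractography with interhemispheric-connection count
#' -> BOLD simulation and activation calls. A stage error marks the subject
#' failed and the pipeline continues. When at least two subjects have
#' complete ROI data, group statistics (one-way ANOVA + Holm-Sidak over the
#' strip / contralateral / internal-capsule gFA means) are attached.
#'
#' @param config A [run_config()].
#' @param scheme Optional `qspace_scheme` (default [build_scheme()]).
#' @return An object of class `study_report`: `subjects` data frame, group
#'   `comparison` (or NULL), `config`, `config_hash`.
#' @export
run_pipeline <- function(config, scheme = build_scheme()) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  if (!is.null(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  truth_cache <- new.env()
  truth_cache$truth <- NULL
  if (config$n_subjects == 0)
    warning("subject count is 0: producing an empty report")
  for (s in seq_len(config$n_subjects)) {
    res <- tryCatch(run_subject(config, s, scheme, truth_cache),
                    error = function(e) {
                      message("subject ", s, " failed: ", conditionMessage(e))
                      list(row = data.frame(
                        subject = s, scenario = config$scenario,
                        seed = config$seed + s, gfa_strip = NA_real_,
                        gfa_contra = NA_real_,
                        gfa_internal_capsule = NA_real_,
                        interhemispheric_count = NA_integer_,
                        activation_ipsi = NA, activation_contra = NA,
                        failed = TRUE))
                    })
    rows[[s]] <- res$row
  }
  subjects <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = integer(0), scenario = character(0),
               seed = integer(0), gfa_strip = numeric(0),
               gfa_contra = numeric(0), gfa_internal_capsule = numeric(0),
               interhemispheric_count = integer(0),
               activation_ipsi = logical(0), activation_contra = logical(0),
               failed = logical(0))
  ok <- !subjects$failed & is.finite(subjects$gfa_strip)
  comparison <- NULL
  if (sum(ok) >= 2) {
    comparison <- anova_holm_sidak(
      list(internal_capsule = subjects$gfa_internal_capsule[ok],
           strip = subjects$gfa_strip[ok],
           contralateral = subjects$gfa_contra[ok]),
      alpha = config$alpha)
  }
  report <- structure(list(subjects = subjects, comparison = comparison,
                           config = config, config_hash = config_hash(config)),
                      class = "study_report")
  if (!is.null(config$out_dir)) {
    utils::write.csv(subjects,
                     file.path(config$out_dir, "study_report.csv"),
                     row.names = FALSE)
    write_run_config(config, file.path(config$out_dir, "config.yaml"))
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report:", x$config$scenario, "scenario,",
      nrow(x$subjects), "subjects (config", substr(x$config_hash, 1, 8), ")\n")
  print(x$subjects, row.names = FALSE)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
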