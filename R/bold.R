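# Block-design BOLD analysis: voxelwise rest-vs-stimulation t-maps, percent
# signal change, and ROI-level activation calls.

#' Voxelwise rest-versus-stimulation t-map
#'
#' Per voxel, a two-sample t-test (pooled variance) between the
#' stimulation-labelled and rest-labelled volumes, with percent signal
#' change `100 * (mean_stim - mean_rest) / mean_rest`. Voxels with zero
#' pooled variance get `t = NaN` (flagged, excluded from maps). An optional
#' label shift delays the stimulation labels by whole volumes to absorb
#' hemodynamic lag (default 0: the plain rest-vs-stimulation contrast).
#'
#' @param timeseries 4D array (x, y, z, volumes), e.g. from
#'   [simulate_bold()].
#' @param paradigm A [block_paradigm()]; defaults to the series' attached
#'   paradigm.
#' @param label_shift Non-negative integer; shift of the stimulation labels
#'   in volumes.
#' @return A list of class `bold_tmap`: `t`, `p` (two-sided), `pct` (3D
#'   arrays), `n_stim`, `n_rest`, `paradigm`.
#' @export
t_map <- function(timeseries, paradigm = attr(timeseries, "paradigm"),
                  label_shift = 0L) {
  if (is.null(paradigm)) stop("a block_paradigm is required")
  d <- dim(timeseries)
  if (length(d) != 4 || d[4] != paradigm$n_volumes)
    stop("time series has ", d[4], " volumes but the paradigm labels ",
         paradigm$n_volumes)
  stim <- paradigm$stim
  if (label_shift > 0)
    stim <- c(rep(FALSE, label_shift), stim)[seq_along(stim)]
  dims <- d[1:3]
  nvox <- prod(dims)
  y <- matrix(timeseries, nvox, d[4])
  ys <- y[, stim, drop = FALSE]
  yr <- y[, !stim, drop = FALSE]
  n1 <- ncol(ys); n2 <- ncol(yr)
  m1 <- rowMeans(ys); m2 <- rowMeans(yr)
  v1 <- rowSums((ys - m1)^2)
  v2 <- rowSums((yr - m2)^2)
  sp2 <- (v1 + v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  # zero pooled variance: equal means are undefined (NaN); different means
  # are a noiseless boxcar, flagged as an infinite-t surrogate with the
  # smallest representable p so they survive any threshold
  t_val <- ifelse(se > 0, (m1 - m2) / se,
                  ifelse(m1 == m2, NaN, Inf * sign(m1 - m2)))
  p_val <- ifelse(is.nan(t_val), NaN,
                  ifelse(is.finite(t_val),
                         2 * stats::pt(-abs(t_val), n1 + n2 - 2),
                         .Machine$double.xmin))
  pct <- ifelse(m2 > 0, 100 * (m1 - m2) / m2, NaN)
  structure(list(t = array(t_val, dims), p = array(p_val, dims),
                 pct = array(pct, dims), n_stim = n1, n_rest = n2,
                 df = n1 + n2 - 2, paradigm = paradigm,
                 label_shift = label_shift),
            class = "bold_tmap")
}

#' ROI activation call
#'
#' An ROI is called active iff it contains at least `min_cluster` contiguous
#' voxels (6-connectivity) with `p < alpha` and positive percent signal
#' change.
#'
#' @param tmap A [t_map()] result.
#' @param roi Logical 3D array or `roi_mask`.
#' @param alpha Voxel significance level (default 0.05).
#' @param min_cluster Minimum cluster extent in voxels (default 4).
#' @return A list `(active, n_voxels, n_clusters)` where `n_voxels` counts
#'   suprathreshold voxels in qualifying clusters.
#' @export
detect_activation <- function(tmap, roi, alpha = 0.05, min_cluster = 4) {
  mask <- if (inherits(roi, "roi_mask")) roi$mask else roi
  if (!any(mask)) stop("ROI is empty")
  sig <- mask & is.finite(tmap$p) & tmap$p < alpha &
    is.finite(tmap$pct) & tmap$pct > 0
  if (!any(sig)) return(list(active = FALSE, n_voxels = 0L, n_clusters = 0L))
  lab <- connected_components(sig)
  sizes <- tabulate(lab[lab > 0])
  good <- which(sizes >= min_cluster)
  list(active = length(good) > 0,
       n_voxels = as.integer(sum(sizes[good])),
       n_clusters = length(good))
}
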