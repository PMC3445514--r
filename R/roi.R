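# Region-of-interest machinery: two-class segmentation of the high-gFA
# perturbation area, homotopic mirroring, ROI summaries, and one-way ANOVA
# with Holm-Sidak multiple comparisons.

# 6-connected component labelling on a logical 3D array (iterative BFS)
connected_components <- function(mask) {
  dims <- dim(mask)
  labels <- array(0L, dims)
  vox <- which(mask)
  if (!length(vox)) return(labels)
  nb_off <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                  c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  current <- 0L
  for (v in vox) {
    if (labels[v] != 0L) next
    current <- current + 1L
    queue <- v
    labels[v] <- current
    while (length(queue)) {
      ijk <- arrayInd(queue, dims)
      nxt <- integer(0)
      for (k in 1:6) {
        nn <- sweep(ijk, 2, nb_off[k, ], "+")
        ok <- nn[, 1] >= 1 & nn[, 1] <= dims[1] &
              nn[, 2] >= 1 & nn[, 2] <= dims[2] &
              nn[, 3] >= 1 & nn[, 3] <= dims[3]
        if (!any(ok)) next
        lin <- nn[ok, 1] + dims[1] * (nn[ok, 2] - 1) +
          dims[1] * dims[2] * (nn[ok, 3] - 1)
        new <- lin[mask[lin] & labels[lin] == 0L]
        if (length(new)) {
          labels[new] <- current
          nxt <- c(nxt, new)
        }
      }
      queue <- unique(nxt)
    }
  }
  labels
}

roi_mask_obj <- function(mask, label, voxel_size) {
  structure(list(mask = mask, label = label,
                 n_voxels = sum(mask),
                 volume_mm3 = sum(mask) * prod(voxel_size),
                 voxel_size = voxel_size),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("ROI", sQuote(x$label), ":", x$n_voxels, "voxels,",
      format(x$volume_mm3, digits = 4), "mm^3\n")
  invisible(x)
}

# Otsu threshold on a numeric vector (histogram-based)
otsu_threshold <- function(x, n_bins = 128) {
  h <- hist(x, breaks = n_bins, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Segment the high-anisotropy perturbation area
#'
#' Two-class intensity split of the gFA values inside a search mask: a
#' two-Gaussian mixture is fitted by EM (falling back to an Otsu threshold
#' on degenerate fits) and the high-mean class is returned, reduced to its
#' largest 6-connected component. If the two fitted classes are not
#' separated (Ashman's D below `min_separation`), there is no perturbation
#' to segment and an error is raised.
#'
#' @param gfa_map 3D gFA array.
#' @param search_mask Logical 3D array to search within.
#' @param voxel_size Voxel size in mm (for the ROI volume).
#' @param min_separation Minimum Ashman separation
#'   `|mu1 - mu2| / sqrt((s1^2 + s2^2)/2)` between the two classes
#'   (default 2, the conventional bimodality cut).
#' @param min_ratio Minimum high/low class-mean ratio (default 2); guards
#'   against degenerate splits of a unimodal noise distribution, whose two
#'   half-classes have nearly equal means.
#' @return An object of class `roi_mask` labelled `"roi_ipsi"`.
#' @export
segment_high_gfa <- function(gfa_map, search_mask,
                             voxel_size = c(0.2, 0.2, 0.5),
                             min_separation = 2, min_ratio = 2) {
  if (!any(search_mask)) stop("search mask is empty")
  vals <- gfa_map[search_mask]
  vals <- vals[is.finite(vals)]
  if (length(vals) < 10) stop("too few finite voxels in the search mask")
  fit <- tryCatch({
    # precompute the BIC table so Mclust works without attaching mclust
    bic <- mclust::mclustBIC(vals, G = 2, modelNames = "V", verbose = FALSE)
    mclust::Mclust(vals, G = 2, modelNames = "V", x = bic, verbose = FALSE)
  }, error = function(e) NULL)
  reject <- function(D, ratio)
    stop("no perturbation detected: gFA distribution in the search mask ",
         "is not bimodal (separation ", format(D, digits = 3),
         ", mean ratio ", format(ratio, digits = 3), ")")
  if (!is.null(fit) && !is.null(fit$parameters)) {
    mu <- fit$parameters$mean
    sd2 <- fit$parameters$variance$sigmasq
    if (length(sd2) == 1) sd2 <- rep(sd2, 2)
    D <- abs(diff(mu)) / sqrt(mean(sd2))
    ratio <- max(mu) / max(min(mu), .Machine$double.eps)
    if (!is.finite(D) || D < min_separation || ratio < min_ratio)
      reject(D, ratio)
    hi <- which.max(mu)
    in_hi <- fit$classification == hi
  } else {
    thr <- otsu_threshold(vals)
    mu_lo <- mean(vals[vals <= thr]); mu_hi <- mean(vals[vals > thr])
    s2 <- c(stats::var(vals[vals <= thr]), stats::var(vals[vals > thr]))
    D <- abs(mu_hi - mu_lo) / sqrt(mean(s2, na.rm = TRUE))
    ratio <- mu_hi / max(mu_lo, .Machine$double.eps)
    if (!is.finite(D) || D < min_separation || ratio < min_ratio)
      reject(D, ratio)
    in_hi <- vals > thr
  }
  if (!any(in_hi)) stop("no perturbation detected: empty high-gFA class")
  mask <- array(FALSE, dim(gfa_map))
  idx <- which(search_mask)[is.finite(gfa_map[search_mask])]
  mask[idx[in_hi]] <- TRUE
  lab <- connected_components(mask)
  if (max(lab) >= 1) {
    largest <- which.max(tabulate(lab[lab > 0]))
    mask <- lab == largest
  }
  roi_mask_obj(mask, "roi_ipsi", voxel_size)
}

#' Mirror an ROI across the midsagittal plane
#'
#' Reflects the mask voxelwise across the plane `x = midline_index` (in
#' voxel units, 1-based, half-integers allowed: the default for an even
#' grid is between the two central columns). Voxels reflected outside the
#' grid are clipped with a warning.
#'
#' @param roi A `roi_mask` or logical 3D array.
#' @param midline_index Plane position in voxel units (default the grid
#'   center).
#' @param label Label of the mirrored ROI (default `"roi_contra"`).
#' @return A `roi_mask`.
#' @export
mirror_roi <- function(roi, midline_index = NULL, label = "roi_contra") {
  mask <- if (inherits(roi, "roi_mask")) roi$mask else roi
  vs <- if (inherits(roi, "roi_mask")) roi$voxel_size else c(1, 1, 1)
  dims <- dim(mask)
  if (is.null(midline_index)) midline_index <- (dims[1] + 1) / 2
  idx <- which(mask)
  if (!length(idx)) stop("cannot mirror an empty mask")
  ijk <- arrayInd(idx, dims)
  if (any(ijk[, 1] < midline_index) && any(ijk[, 1] > midline_index))
    stop("mask straddles the midline plane; mirroring is undefined")
  xr <- round(2 * midline_index - ijk[, 1])
  keep <- xr >= 1 & xr <= dims[1]
  if (!all(keep))
    warning(sum(!keep), " reflected voxels fall outside the grid and were clipped")
  out <- array(FALSE, dims)
  out[cbind(xr[keep], ijk[keep, 2], ijk[keep, 3])] <- TRUE
  roi_mask_obj(out, label, vs)
}

#' Mean and SEM of a scalar map over an ROI
#'
#' Arithmetic mean and standard error (sample SD over sqrt(n)) of the finite
#' in-mask voxels; NaN/NA voxels are excluded from n.
#'
#' @param map 3D numeric array.
#' @param roi A `roi_mask` or logical array.
#' @return A list `(mean, sem, n)`.
#' @export
roi_mean_sem <- function(map, roi) {
  mask <- if (inherits(roi, "roi_mask")) roi$mask else roi
  v <- map[mask]
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite voxels in the ROI overlap")
  list(mean = mean(v),
       sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
       n = length(v))
}

#' Holm-Sidak step-down adjustment of p-values
#'
#' Sorted ascending, the k-th smallest of m p-values is adjusted to
#' `1 - (1 - p_(k))^(m - k + 1)`, with monotonicity enforced by a running
#' maximum.
#'
#' @param p Vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_sidak_adjust <- function(p) {
  m <- length(p)
  ord <- order(p)
  k <- seq_len(m)
  adj <- 1 - (1 - p[ord])^(m - k + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

#' One-way ANOVA with Holm-Sidak pairwise comparisons
#'
#' The omnibus F-test across groups followed by all-pairs t-tests using the
#' pooled ANOVA error variance, adjusted by the Holm-Sidak step-down
#' procedure and decided at level `alpha`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha Significance level (default 0.05).
#' @return A list of class `group_comparison`: `summary` (group, n, mean,
#'   sem), `F`, `df1`, `df2`, `p`, and `pairs` (group1, group2, t, p_raw,
#'   p_adj, reject).
#' @export
anova_holm_sidak <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2) stop("need at least two groups")
  n <- lengths(groups)
  if (any(n < 2)) stop("every group needs at least two observations")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  means <- vapply(groups, mean, numeric(1))
  sems <- vapply(groups, function(g) stats::sd(g) / sqrt(length(g)), numeric(1))
  N <- sum(n)
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1
  df2 <- N - k
  if (ss_within == 0 && ss_between == 0) {
    Fv <- 0; pv <- 1
  } else if (ss_within == 0) {
    Fv <- Inf; pv <- 0
  } else {
    Fv <- (ss_between / df1) / (ss_within / df2)
    pv <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  }
  mse <- if (df2 > 0) ss_within / df2 else NA_real_
  cmb <- utils::combn(k, 2)
  t_stat <- p_raw <- numeric(ncol(cmb))
  for (j in seq_len(ncol(cmb))) {
    a <- cmb[1, j]; b <- cmb[2, j]
    se <- sqrt(mse * (1 / n[a] + 1 / n[b]))
    if (se == 0) {
      t_stat[j] <- if (means[a] == means[b]) 0 else Inf * sign(means[a] - means[b])
      p_raw[j] <- if (means[a] == means[b]) 1 else 0
    } else {
      t_stat[j] <- (means[a] - means[b]) / se
      p_raw[j] <- 2 * stats::pt(-abs(t_stat[j]), df2)
    }
  }
  p_adj <- holm_sidak_adjust(p_raw)
  pairs <- data.frame(group1 = names(groups)[cmb[1, ]],
                      group2 = names(groups)[cmb[2, ]],
                      t = t_stat, p_raw = p_raw, p_adj = p_adj,
                      reject = p_adj < alpha)
  structure(list(summary = data.frame(group = names(groups), n = as.integer(n),
                                      mean = means, sem = sems,
                                      row.names = NULL),
                 F = Fv, df1 = df1, df2 = df2, p = pv,
                 alpha = alpha, pairs = pairs),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d,%d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  print(x$summary, row.names = FALSE)
  cat("Holm-Sidak pairwise comparisons (alpha =", x$alpha, "):\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}
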