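# q-space encoding scheme: the 203-point Cartesian DSI acquisition table.

#' The twelve diffusion-weighted subsets of the 203-point DSI scheme
#'
#' Each subset is one shell of the Cartesian q-space lattice: squared lattice
#' radius `r2`, nominal b-value in s/mm^2, and the number of gradient
#' directions (all integer lattice sites at that radius; r2 = 7 is absent
#' because 7 is not a sum of three squares).
#'
#' @return A data frame with columns `subset_index` (0-11), `b_value`,
#'   `n_directions` and `r2`.
#' @export
dsi_subset_table <- function() {
  data.frame(
    subset_index = 0:11,
    b_value = c(154, 308, 462, 615, 769, 923, 1231, 1384, 1538, 1692, 1846, 2000),
    n_directions = c(6, 12, 8, 6, 24, 24, 12, 30, 24, 24, 8, 24),
    r2 = c(1, 2, 3, 4, 5, 6, 8, 9, 10, 11, 12, 13)
  )
}

#' Convert diffusion weighting b to q-space radius
#'
#' Uses the narrow-pulse relation b = (2*pi*q)^2 (Delta - delta/3), with the
#' pulse timings given in milliseconds and b in s/mm^2, so that q comes out
#' in 1/mm.
#'
#' @param b Diffusion weighting, s/mm^2 (scalar or vector, >= 0).
#' @param delta_large Diffusion time Delta, ms.
#' @param delta_small Gradient pulse duration delta, ms.
#' @return q-space radius |q| in 1/mm, same length as `b`.
#' @examples
#' b_to_q(2000, 25, 5)   # about 46.6 /mm
#' @export
b_to_q <- function(b, delta_large = 25, delta_small = 5) {
  if (any(!is.finite(b)) || any(b < 0))
    stop("b must be finite and non-negative (s/mm^2)")
  if (!is.finite(delta_large) || !is.finite(delta_small) ||
      delta_small <= 0 || delta_large <= delta_small / 3)
    stop("non-physical pulse timings: need delta_large > delta_small/3 > 0 (ms)")
  t_eff <- (delta_large - delta_small / 3) / 1000  # ms -> s
  sqrt(b / t_eff) / (2 * pi)
}

#' Build the 203-point DSI q-space encoding scheme
#'
#' Enumerates all integer lattice sites within the ball of squared radius 13
#' (202 nonzero sites, reproducing the printed per-shell direction counts)
#' plus one unweighted b = 0 measurement at the origin. Directions are the
#' normalized lattice vectors; b-values come from [dsi_subset_table()].
#'
#' @param delta_large Diffusion time Delta in ms (default 25).
#' @param delta_small Gradient duration delta in ms (default 5).
#' @param grid_radius Half-width of the Cartesian reconstruction grid the
#'   points regrid onto (default 5, an 11^3 zero-padded keyhole; must be at
#'   least 4 so the native lattice fits).
#' @return An object of class `qspace_scheme`: a list with a `points` data
#'   frame (columns `b_value`, `gx`, `gy`, `gz`, `q_radius`, `subset_index`,
#'   and native lattice sites `lx`, `ly`, `lz`), plus `delta_large`,
#'   `delta_small`, `grid_radius`.
#' @export
build_scheme <- function(delta_large = 25, delta_small = 5, grid_radius = 5) {
  if (grid_radius < 4) stop("grid_radius must be >= 4 to hold the r^2 <= 13 lattice")
  tab <- dsi_subset_table()
  g <- expand.grid(lx = -3:3, ly = -3:3, lz = -3:3)
  r2 <- g$lx^2 + g$ly^2 + g$lz^2
  keep <- r2 >= 1 & r2 <= 13  # r2 = 7 never occurs
  g <- g[keep, , drop = FALSE]
  r2 <- r2[keep]
  ord <- order(r2, g$lx, g$ly, g$lz)
  g <- g[ord, , drop = FALSE]
  r2 <- r2[ord]
  idx <- match(r2, tab$r2)
  nrm <- sqrt(r2)
  pts <- data.frame(
    b_value = tab$b_value[idx],
    gx = g$lx / nrm, gy = g$ly / nrm, gz = g$lz / nrm,
    q_radius = b_to_q(tab$b_value[idx], delta_large, delta_small),
    subset_index = tab$subset_index[idx],
    lx = g$lx, ly = g$ly, lz = g$lz
  )
  b0 <- data.frame(b_value = 0, gx = 0, gy = 0, gz = 0, q_radius = 0,
                   subset_index = -1L, lx = 0L, ly = 0L, lz = 0L)
  pts <- rbind(b0, pts)
  rownames(pts) <- NULL
  scheme <- structure(
    list(points = pts, delta_large = delta_large, delta_small = delta_small,
         grid_radius = as.integer(grid_radius)),
    class = "qspace_scheme")
  validate_scheme(scheme)
  scheme
}

#' Validate a q-space scheme against the DSI-203 invariants
#'
#' Checks the point count, per-subset (b-value, count) pairs, direction unit
#' norms, the monotone b <-> q correspondence, and that the scaled weighted
#' points fall on integer lattice sites.
#'
#' @param scheme A `qspace_scheme`.
#' @param strict If `TRUE` (default) require the exact printed subset
#'   structure; if `FALSE` only check the generic per-point invariants.
#' @return The scheme, invisibly; errors describe the violated invariant.
#' @export
validate_scheme <- function(scheme, strict = TRUE) {
  p <- scheme$points
  if (any(p$b_value < 0)) stop("negative b-value in scheme")
  w <- p$b_value > 0
  nrm <- sqrt(p$gx^2 + p$gy^2 + p$gz^2)
  if (any(abs(nrm[w] - 1) > 1e-9))
    stop("weighted directions must have unit norm (tolerance 1e-9)")
  if (any(nrm[!w] != 0))
    stop("the unweighted point must carry a zero direction vector")
  if (any((p$q_radius == 0) != (p$b_value == 0)))
    stop("q_radius must vanish exactly for b = 0")
  if (is.unsorted(p$q_radius[order(p$b_value)]))
    stop("q_radius must increase monotonically with b_value")
  if (!strict) return(invisible(scheme))
  if (nrow(p) != 203) stop("scheme must have exactly 203 points, got ", nrow(p))
  if (sum(!w) != 1) stop("scheme must contain exactly one b = 0 point")
  tab <- dsi_subset_table()
  cnt <- table(factor(p$b_value[w], levels = tab$b_value))
  if (any(as.integer(cnt) != tab$n_directions))
    stop("per-subset (b-value, count) pairs do not match the DSI-203 table")
  # distinct directions within each subset
  key <- paste(p$subset_index[w], round(p$gx[w], 9), round(p$gy[w], 9),
               round(p$gz[w], 9))
  if (anyDuplicated(key)) stop("duplicate direction within a subset")
  # scaled points sit on integer lattice sites
  sites <- scheme_lattice_sites(scheme)
  dev <- max(abs(sites - round(sites)))
  if (dev >= 0.05)
    stop("scaled q-space points deviate from the integer lattice by ", dev)
  invisible(scheme)
}

#' Native lattice coordinates of the scheme points
#'
#' Scales each point's direction by its q-radius so that the maximum q maps
#' to the scheme's native lattice radius sqrt(max r^2); for the DSI-203
#' scheme these are (nearly) integer sites in the ball of radius sqrt(13).
#'
#' @param scheme A `qspace_scheme`.
#' @return A numeric matrix (n x 3) of lattice coordinates.
#' @export
scheme_lattice_sites <- function(scheme) {
  p <- scheme$points
  q_max <- max(p$q_radius)
  native_r <- sqrt(max(p$lx^2 + p$ly^2 + p$lz^2))
  s <- p$q_radius / q_max * native_r
  cbind(x = p$gx * s, y = p$gy * s, z = p$gz * s)
}

#' Write a q-space scheme as a plain-text b-table
#'
#' One row per encoding point with columns `b gx gy gz`; header comment lines
#' carry the pulse timings and grid radius so the file round-trips exactly.
#'
#' @param scheme A `qspace_scheme`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_btable()], [write_fsl_bvecs()]
#' @export
write_btable <- function(scheme, path) {
  validate_scheme(scheme, strict = FALSE)
  p <- scheme$points
  hdr <- c("# dsitract b-table: b gx gy gz",
           sprintf("# delta_large_ms %.17g", scheme$delta_large),
           sprintf("# delta_small_ms %.17g", scheme$delta_small),
           sprintf("# grid_radius %d", scheme$grid_radius))
  rows <- sprintf("%.17g %.17g %.17g %.17g", p$b_value, p$gx, p$gy, p$gz)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a plain-text b-table back into a q-space scheme
#'
#' Inverse of [write_btable()]: parses `b gx gy gz` rows, restores the pulse
#' timings from the header (or takes them as arguments for headerless FSL
#' style tables), and re-derives q-radii and subset indices.
#'
#' @param path File to read.
#' @param delta_large,delta_small Pulse timings in ms, used when the file has
#'   no header.
#' @param grid_radius Reconstruction grid half-width when absent from header.
#' @return A `qspace_scheme`.
#' @export
read_btable <- function(path, delta_large = 25, delta_small = 5,
                        grid_radius = 5) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  get_hdr <- function(key, default) {
    m <- grep(paste0("^# ", key, " "), lines, value = TRUE)
    if (length(m)) as.numeric(sub(paste0("^# ", key, " "), "", m[1])) else default
  }
  delta_large <- get_hdr("delta_large_ms", delta_large)
  delta_small <- get_hdr("delta_small_ms", delta_small)
  grid_radius <- get_hdr("grid_radius", grid_radius)
  body <- if (length(hdr)) lines[-hdr] else lines
  body_no <- seq_along(lines)[if (length(hdr)) -hdr else TRUE]
  body_keep <- nzchar(trimws(body))
  body_no <- body_no[body_keep]
  body <- body[body_keep]
  parse_row <- function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (length(v) != 4 || any(!is.finite(v)))
      stop("malformed b-table row at line ", body_no[i], ": ",
           sQuote(body[i]))
    v
  }
  m <- t(vapply(seq_along(body), parse_row, numeric(4)))
  b <- m[, 1]; dirs <- m[, 2:4, drop = FALSE]
  nrm <- sqrt(rowSums(dirs^2))
  bad <- which(b > 0 & abs(nrm - 1) > 1e-6)
  if (length(bad))
    stop("non-unit direction (norm ", format(nrm[bad[1]]),
         ") at weighted row, line ", body_no[bad[1]])
  if (any(b < 0)) stop("negative b-value at line ", body_no[which(b < 0)[1]])
  if (!any(b == 0)) stop("missing unweighted point (no b = 0 row)")
  bw <- sort(unique(b[b > 0]))
  subset_index <- ifelse(b == 0, -1L, match(b, bw) - 1L)
  native_r2 <- (match(b, bw))  # only used via lattice round-trip below
  pts <- data.frame(
    b_value = b, gx = dirs[, 1], gy = dirs[, 2], gz = dirs[, 3],
    q_radius = b_to_q(b, delta_large, delta_small),
    subset_index = subset_index)
  # recover native lattice sites from the scaled geometry
  q_max <- max(pts$q_radius)
  tab <- dsi_subset_table()
  native_r <- if (all(bw %in% tab$b_value)) sqrt(max(tab$r2[tab$b_value %in% bw]))
              else sqrt(length(bw))
  s <- pts$q_radius / q_max * native_r
  pts$lx <- as.integer(round(pts$gx * s))
  pts$ly <- as.integer(round(pts$gy * s))
  pts$lz <- as.integer(round(pts$gz * s))
  scheme <- structure(
    list(points = pts, delta_large = delta_large, delta_small = delta_small,
         grid_radius = as.integer(grid_radius)),
    class = "qspace_scheme")
  validate_scheme(scheme, strict = FALSE)
  scheme
}

#' Write the scheme as an FSL-style bval/bvec pair
#'
#' @param scheme A `qspace_scheme`.
#' @param stem Path stem; writes `<stem>.bval` and `<stem>.bvec`.
#' @return `stem`, invisibly.
#' @export
write_fsl_bvecs <- function(scheme, stem) {
  p <- scheme$points
  writeLines(paste(sprintf("%.17g", p$b_value), collapse = " "),
             paste0(stem, ".bval"))
  writeLines(c(paste(sprintf("%.17g", p$gx), collapse = " "),
               paste(sprintf("%.17g", p$gy), collapse = " "),
               paste(sprintf("%.17g", p$gz), collapse = " ")),
             paste0(stem, ".bvec"))
  invisible(stem)
}

#' @export
print.qspace_scheme <- function(x, ...) {
  p <- x$points
  cat("DSI q-space scheme:", nrow(p), "encoding points (",
      sum(p$b_value > 0), "weighted +", sum(p$b_value == 0), "b=0 )\n")
  cat("  b range:", min(p$b_value[p$b_value > 0]), "-", max(p$b_value),
      "s/mm^2; Delta/delta =", x$delta_large, "/", x$delta_small, "ms\n")
  cat("  max |q| =", format(max(p$q_radius), digits = 4),
      "/mm; reconstruction grid half-width", x$grid_radius, "\n")
  invisible(x)
}
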