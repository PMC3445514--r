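# Icosphere tessellation of the unit sphere: ODF sample directions and the
# neighbor graph used for peak extraction.

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivide_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  midpoint_cache <- new.env(hash = TRUE)
  verts <- lapply(seq_len(nrow(v)), function(i) v[i, ])
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    if (!is.null(midpoint_cache[[key]])) return(midpoint_cache[[key]])
    m <- verts[[i]] + verts[[j]]
    m <- m / sqrt(sum(m^2))
    verts[[length(verts) + 1]] <<- m
    idx <- length(verts)
    midpoint_cache[[key]] <- idx
    idx
  }
  new_faces <- matrix(0L, nrow(f) * 4, 3)
  for (k in seq_len(nrow(f))) {
    a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    new_faces[(k - 1) * 4 + 1:4, ] <- rbind(
      c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
  }
  list(vertices = do.call(rbind, verts), faces = new_faces)
}

# Canonical hemisphere membership: z > 0, or z == 0 and y > 0, or on the
# x-axis with x > 0. Tolerance guards against subdivision round-off.
in_hemisphere <- function(v, tol = 1e-9) {
  (v[, 3] > tol) |
    (abs(v[, 3]) <= tol & v[, 2] > tol) |
    (abs(v[, 3]) <= tol & abs(v[, 2]) <= tol & v[, 1] > tol)
}

#' Sphere tessellation for ODF sampling
#'
#' Builds a subdivided icosahedron whose vertices are antipodally symmetric,
#' reordered so that the first K/2 vertices form one hemisphere and vertex
#' `i + K/2` is exactly the antipode of vertex `i`. Three subdivisions give
#' the default K = 642 directions (321 per hemisphere).
#'
#' @param subdiv Number of subdivision passes (default 3).
#' @return A list of class `sphere_tessellation` with `directions` (K x 3 unit
#'   vectors), `n_hemi` (= K/2), and `neighbors` (K x max-degree integer
#'   matrix of adjacent-vertex indices, `NA`-padded).
#' @export
sphere_tessellation <- function(subdiv = 3) {
  mesh <- icosahedron()
  for (i in seq_len(subdiv)) mesh <- subdivide_mesh(mesh)
  v <- mesh$vertices
  n <- nrow(v)
  hemi <- which(in_hemisphere(v))
  stopifnot(length(hemi) == n / 2)
  # map every original vertex to its position in (hemisphere, antipodes) order
  key <- function(m) paste(round(m[, 1], 8), round(m[, 2], 8), round(m[, 3], 8))
  new_v <- rbind(v[hemi, , drop = FALSE], -v[hemi, , drop = FALSE])
  # snap exact antipodal pairing: new_v already exact by construction
  old_to_new <- match(key(v), key(new_v))
  stopifnot(!anyNA(old_to_new), !anyDuplicated(old_to_new))
  f <- mesh$faces
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  edges <- cbind(old_to_new[edges[, 1]], old_to_new[edges[, 2]])
  edges <- unique(rbind(edges, edges[, 2:1]))
  nb <- split(edges[, 2], edges[, 1])
  deg <- max(lengths(nb))
  neighbors <- matrix(NA_integer_, n, deg)
  for (i in seq_len(n)) neighbors[i, seq_along(nb[[as.character(i)]])] <-
      sort(nb[[as.character(i)]])
  structure(list(directions = new_v, n_hemi = n %/% 2, neighbors = neighbors),
            class = "sphere_tessellation")
}

# cache: tessellations are deterministic and mildly expensive to build
.tess_cache <- new.env(parent = emptyenv())

get_tessellation <- function(subdiv = 3) {
  k <- as.character(subdiv)
  if (is.null(.tess_cache[[k]])) .tess_cache[[k]] <- sphere_tessellation(subdiv)
  .tess_cache[[k]]
}

#' ODF sample directions
#'
#' Convenience accessor returning the K x 3 matrix of unit direction vectors
#' of the (cached) icosphere tessellation; antipodal pairs are `i` and
#' `i + K/2`.
#'
#' @param subdiv Icosphere subdivision level (default 3, K = 642).
#' @return A K x 3 numeric matrix.
#' @export
odf_directions <- function(subdiv = 3) {
  get_tessellation(subdiv)$directions
}
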