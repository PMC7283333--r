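#' 3D convex hull of a point cloud
#'
#' Computes the convex hull of a set of 3D points with an incremental
#' quickhull algorithm. Points strictly inside the hull, or lying on a facet
#' without being extreme, are not vertices; this matches the convention used
#' for chromosome-surface calls and for the polymer surface term, where only
#' extreme points count as "on the surface".
#'
#' @param points numeric matrix with 3 columns (x, y, z) or a data frame with
#'   columns `x`, `y`, `z`.
#' @return A list with elements `ok` (FALSE when the input is degenerate:
#'   fewer than 4 points, or collinear/coplanar), `vertices` (row indices of
#'   hull vertices), `faces` (m x 3 matrix of triangle vertex indices) and
#'   `volume`.
#' @export
convex_hull_3d <- function(points) {
  pts <- as_point_matrix(points)
  cpp_convhull(pts)
}

#' Volume of the intersection of two convex hulls
#'
#' The intersection of two convex polytopes is itself convex; its vertices are
#' the vertices of either hull contained in the other plus the crossing points
#' of hull edges with the facets of the other hull. The exact engine hulls
#' that candidate set. A seeded uniform-sampling estimator is available as a
#' cross-check and as a fallback for numerically degenerate intersections.
#'
#' @param a,b point matrices (n x 3); the hulls of `a` and `b` are intersected.
#' @param method `"exact"` (default) or `"mc"`.
#' @param n_samples number of samples for the Monte Carlo estimator.
#' @param mc_seed fixed seed for the Monte Carlo estimator so the volume is a
#'   deterministic function of its inputs.
#' @return Intersection volume (0 when the hulls are disjoint or the
#'   intersection has zero 3D measure).
#' @export
hull_intersection_volume <- function(a, b, method = c("exact", "mc"),
                                     n_samples = 200000L, mc_seed = 20000L) {
  method <- match.arg(method)
  pa <- as_point_matrix(a)
  pb <- as_point_matrix(b)
  if (method == "exact") {
    res <- cpp_hull_intersection_volume(pa, pb)
    if (res$exact_ok) return(res$volume)
    method <- "mc" # degenerate exact construction: fall back
  }
  with_seed(mc_seed, cpp_mc_intersection_volume(pa, pb, as.integer(n_samples)))
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    cols <- intersect(c("x", "y", "z", "x_nm", "y_nm", "z_nm"), names(points))
    if (all(c("x_nm", "y_nm", "z_nm") %in% cols)) {
      points <- as.matrix(points[, c("x_nm", "y_nm", "z_nm")])
    } else if (all(c("x", "y", "z") %in% cols)) {
      points <- as.matrix(points[, c("x", "y", "z")])
    } else {
      stop("data frame must have columns x, y, z (or x_nm, y_nm, z_nm)")
    }
  }
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must have 3 columns")
  if (!is.numeric(points) || anyNA(points) || any(!is.finite(points)))
    stop("points must be finite numeric coordinates")
  storage.mode(points) <- "double"
  points
}
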