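# Bowyer-Watson Delaunay triangulation and barycentric-linear interpolation.
#
# The scatter-removal step interpolates masked EEM cells from the remaining
# (excitation, emission) points via a Delaunay triangulation of the
# wavelength plane. The point sets here are small (a few hundred points from
# the raw EEM grid), so an O(n^2) incremental construction is ample.
# Grid lattices produce many exactly-cocircular quadruples, which make the
# in-circumcircle predicate ambiguous; a tiny deterministic coordinate
# perturbation (hash-based, ~1e-6 of the coordinate span) is applied for the
# triangulation only. Barycentric weights are computed from the true
# coordinates, so affine fields are still reproduced to near machine
# precision.

delaunay_perturb <- function(x, y) {
  span <- max(diff(range(x)), diff(range(y)), 1)
  # deterministic pseudo-random jitter from the point index
  i <- seq_along(x)
  jx <- ((i * 2654435761) %% 1000003) / 1000003 - 0.5
  jy <- ((i * 40503 + 7919) %% 1000033) / 1000033 - 0.5
  list(x = x + jx * span * 1e-6, y = y + jy * span * 1e-6)
}

#' Delaunay triangulation of a planar point set
#'
#' Incremental Bowyer-Watson construction. Intended for the modest point
#' counts of raw EEM grids; returns triangle vertex indices.
#'
#' @param x,y Point coordinates.
#' @return Integer matrix with one row per triangle and columns `i, j, k`.
#' @keywords internal
#' @export
delaunay_triangulate <- function(x, y) {
  n <- length(x)
  if (n < 3) abort("need at least 3 points to triangulate")
  p <- delaunay_perturb(x, y)
  px <- p$x; py <- p$y
  # super-triangle enclosing all points
  cx <- mean(range(px)); cy <- mean(range(py))
  r <- max(diff(range(px)), diff(range(py))) * 10 + 1
  px <- c(px, cx - 2 * r, cx + 2 * r, cx)
  py <- c(py, cy - r, cy - r, cy + 2 * r)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L
  tris <- matrix(c(s1, s2, s3), ncol = 3)
  circum <- function(i, j, k) {
    ax <- px[i]; ay <- py[i]; bx <- px[j]; by <- py[j]; ccx <- px[k]; ccy <- py[k]
    d <- 2 * (ax * (by - ccy) + bx * (ccy - ay) + ccx * (ay - by))
    ux <- ((ax^2 + ay^2) * (by - ccy) + (bx^2 + by^2) * (ccy - ay) +
             (ccx^2 + ccy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (ccx - bx) + (bx^2 + by^2) * (ax - ccx) +
             (ccx^2 + ccy^2) * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
  cc <- matrix(circum(s1, s2, s3), ncol = 3)
  for (ip in seq_len(n)) {
    qx <- px[ip]; qy <- py[ip]
    bad <- (qx - cc[, 1])^2 + (qy - cc[, 2])^2 < cc[, 3]
    if (!any(bad)) next # should not happen inside the super-triangle
    bad_tris <- tris[bad, , drop = FALSE]
    # boundary of the cavity: edges appearing exactly once among bad triangles
    edges <- rbind(bad_tris[, c(1, 2)], bad_tris[, c(2, 3)], bad_tris[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    once <- names(which(table(key) == 1))
    keep <- key %in% once
    boundary <- edges[keep, , drop = FALSE]
    tris <- tris[!bad, , drop = FALSE]
    cc <- cc[!bad, , drop = FALSE]
    if (nrow(boundary) > 0) {
      new_tris <- cbind(boundary, ip)
      new_cc <- t(apply(new_tris, 1, function(tr) circum(tr[1], tr[2], tr[3])))
      tris <- rbind(tris, new_tris)
      cc <- rbind(cc, new_cc)
    }
  }
  keep <- rowSums(matrix(tris %in% c(s1, s2, s3), nrow = nrow(tris))) == 0
  tris <- tris[keep, , drop = FALSE]
  colnames(tris) <- c("i", "j", "k")
  tris
}

#' Barycentric-linear interpolation on a triangulated point set
#'
#' Linear interpolation inside each Delaunay triangle; query points outside
#' the convex hull get `fill` (default 0).
#'
#' @param x,y,z Data points and their values.
#' @param xi,yi Query points.
#' @param fill Value for queries outside the convex hull.
#' @return Numeric vector of interpolated values.
#' @keywords internal
#' @export
interp_delaunay <- function(x, y, z, xi, yi, fill = 0) {
  if (length(x) < 3) abort("interpolation requires at least 3 data points")
  tris <- delaunay_triangulate(x, y)
  out <- rep(fill, length(xi))
  assigned <- rep(FALSE, length(xi))
  tol <- -1e-6
  for (t in seq_len(nrow(tris))) {
    i <- tris[t, 1]; j <- tris[t, 2]; k <- tris[t, 3]
    x1 <- x[i]; y1 <- y[i]; x2 <- x[j]; y2 <- y[j]; x3 <- x[k]; y3 <- y[k]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(det) < 1e-300) next
    idx <- which(!assigned)
    if (length(idx) == 0) break
    l1 <- ((y2 - y3) * (xi[idx] - x3) + (x3 - x2) * (yi[idx] - y3)) / det
    l2 <- ((y3 - y1) * (xi[idx] - x3) + (x1 - x3) * (yi[idx] - y3)) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= tol & l2 >= tol & l3 >= tol
    if (any(inside)) {
      sel <- idx[inside]
      out[sel] <- l1[inside] * z[i] + l2[inside] * z[j] + l3[inside] * z[k]
      assigned[sel] <- TRUE
    }
  }
  out
}
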