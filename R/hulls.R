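#' Planar convex hull of a dendritic or axonal arbor
#'
#' Projects skeleton nodes along the optical axis (drops z) and returns the
#' convex hull as a counter-clockwise polygon. Degenerate arbors (fewer than
#' three non-collinear nodes) yield a zero-area polygon flagged as degenerate.
#'
#' @param skel A skeleton tibble with columns `x`, `y` (µm); extra columns are
#'   ignored.
#' @param compartment Optional filter on a `compartment` column
#'   (`"dendrite"`/`"axon"`); `NULL` uses all nodes.
#' @return An object of class `opl_hull`: list with `poly` (matrix of hull
#'   vertices, CCW), `area` (µm²) and `degenerate` flag.
#' @examples
#' sq <- tibble::tibble(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
#' dendritic_hull(sq)$area
#' @export
dendritic_hull <- function(skel, compartment = NULL) {
  if (!is.null(compartment) && "compartment" %in% names(skel)) {
    skel <- skel[skel$compartment == compartment, , drop = FALSE]
  }
  pts <- unique(cbind(skel$x, skel$y))
  if (nrow(pts) < 3L) {
    return(structure(list(poly = pts, area = 0, degenerate = TRUE),
                     class = "opl_hull"))
  }
  idx <- rev(chull(pts[, 1], pts[, 2]))  # chull is clockwise; reverse to CCW
  poly <- pts[idx, , drop = FALSE]
  a <- polygon_area(poly)
  structure(list(poly = poly, area = a, degenerate = a <= 0),
            class = "opl_hull")
}

#' @export
print.opl_hull <- function(x, ...) {
  cat(sprintf("<opl_hull> %d vertices, area %.2f um^2%s\n",
              nrow(x$poly), x$area, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# Shoelace area of a CCW polygon given as an n x 2 matrix.
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Sutherland-Hodgman clipping of convex polygon `subject` by convex `clip`.
# Both CCW n x 2 matrices; returns the intersection polygon (possibly empty).
clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0L) return(out)
    a <- clip[i, ]
    b <- clip[if (i == nc) 1L else i + 1L, ]
    inp <- out
    out <- matrix(numeric(0), ncol = 2)
    np <- nrow(inp)
    side <- (b[1] - a[1]) * (inp[, 2] - a[2]) - (b[2] - a[2]) * (inp[, 1] - a[1])
    for (j in seq_len(np)) {
      k <- if (j == np) 1L else j + 1L
      p <- inp[j, ]; q <- inp[k, ]
      pin <- side[j] >= -1e-12; qin <- side[k] >= -1e-12
      if (pin) out <- rbind(out, p)
      if (xor(pin, qin)) {
        t <- side[j] / (side[j] - side[k])
        out <- rbind(out, p + t * (q - p))
      }
    }
  }
  out
}

#' Intersection area of two convex hulls
#'
#' @param h1,h2 `opl_hull` objects (or CCW vertex matrices).
#' @return Overlap area in µm².
#' @export
hull_overlap_area <- function(h1, h2) {
  p1 <- if (inherits(h1, "opl_hull")) h1$poly else h1
  p2 <- if (inherits(h2, "opl_hull")) h2$poly else h2
  if (is.null(p1) || is.null(p2) || nrow(p1) < 3L || nrow(p2) < 3L) return(0)
  inter <- clip_convex(p1, p2)
  if (is.null(inter) || nrow(inter) < 3L) return(0)
  polygon_area(inter)
}

#' Area of the union of convex hulls
#'
#' Rasterises the hulls on a regular grid (cell centres) over their joint
#' bounding box and counts covered cells. Deterministic; accuracy is set by
#' the grid resolution.
#'
#' @param hulls List of `opl_hull` objects.
#' @param resolution Grid spacing in µm (default 0.25).
#' @return Union area in µm².
#' @export
hull_union_area <- function(hulls, resolution = 0.25) {
  polys <- lapply(hulls, function(h) if (inherits(h, "opl_hull")) h$poly else h)
  polys <- polys[vapply(polys, function(p) !is.null(p) && nrow(p) >= 3L, TRUE)]
  if (length(polys) == 0L) return(0)
  xr <- range(unlist(lapply(polys, function(p) p[, 1])))
  yr <- range(unlist(lapply(polys, function(p) p[, 2])))
  gx <- seq(xr[1] + resolution / 2, xr[2], by = resolution)
  gy <- seq(yr[1] + resolution / 2, yr[2], by = resolution)
  if (length(gx) == 0L || length(gy) == 0L) return(0)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  covered <- rep(FALSE, nrow(grid))
  for (p in polys) {
    todo <- which(!covered)
    if (length(todo) == 0L) break
    covered[todo] <- mgcv::in.out(rbind(p, p[1, ]), grid[todo, , drop = FALSE])
  }
  sum(covered) * resolution^2
}

#' Test which points fall inside (or on) a convex hull
#'
#' Boundary convention: points on the hull edge count as inside (tested with a
#' small outward tolerance on the half-plane inequalities).
#'
#' @param hull An `opl_hull`.
#' @param pts n x 2 matrix or data frame of planar coordinates.
#' @param tol Boundary tolerance in µm.
#' @return Logical vector of length `nrow(pts)`.
#' @export
points_in_hull <- function(hull, pts, tol = 1e-9) {
  poly <- if (inherits(hull, "opl_hull")) hull$poly else hull
  pts <- as.matrix(pts)
  if (nrow(pts) == 0L) return(logical(0))
  if (is.null(poly) || nrow(poly) < 3L) return(rep(FALSE, nrow(pts)))
  n <- nrow(poly)
  inside <- rep(TRUE, nrow(pts))
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1L else i + 1L, ]
    s <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & (s >= -tol)
  }
  inside
}
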