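# Planar polygon primitives used by the Voronoi service-area construction and
# the facility-overlap computation. Polygons are n x 2 coordinate matrices in
# metres, vertices in order (either orientation), implicitly closed.

#' Polygon area (shoelace formula)
#'
#' @param poly numeric matrix with two columns (x, y); vertices in order,
#'   implicitly closed. Orientation does not matter.
#' @return Non-negative area in squared input units.
#' @export
polygon_area <- function(poly) {
  if (is.null(poly) || nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

#' Polygon centroid
#' @param poly coordinate matrix as in [polygon_area()].
#' @return length-2 numeric (x, y).
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(poly))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

# Clip `poly` to the half-plane {p : a*x + b*y <= c}. Sutherland-Hodgman step
# against a single line; result may be empty (NULL).
clip_halfplane <- function(poly, a, b, c) {
  if (is.null(poly) || nrow(poly) < 3) return(NULL)
  n <- nrow(poly)
  val <- a * poly[, 1] + b * poly[, 2] - c
  inside <- val <= 1e-9 * max(1, abs(c))
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p1 <- poly[i, ]; p2 <- poly[j, ]
    if (inside[i]) out <- rbind(out, p1)
    if (xor(inside[i], inside[j])) {
      t <- val[i] / (val[i] - val[j])
      out <- rbind(out, p1 + t * (p2 - p1))
    }
  }
  if (nrow(out) < 3) return(NULL)
  out
}

# Clip an arbitrary (possibly concave) subject polygon against a *convex*
# clipper polygon (Sutherland-Hodgman). Returns NULL when the intersection is
# empty or degenerate.
clip_polygon_convex <- function(subject, clipper) {
  if (is.null(subject) || is.null(clipper)) return(NULL)
  # ensure counter-clockwise clipper so "inside" is to the left of each edge
  if (signed_area(clipper) < 0) clipper <- clipper[rev(seq_len(nrow(clipper))), , drop = FALSE]
  out <- subject
  n <- nrow(clipper)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e1 <- clipper[i, ]; e2 <- clipper[j, ]
    # half-plane left of e1->e2: (e2x-e1x)(y-e1y) - (e2y-e1y)(x-e1x) >= 0
    a <- e2[2] - e1[2]
    b <- -(e2[1] - e1[1])
    cc <- a * e1[1] + b * e1[2]
    out <- clip_halfplane(out, a, b, cc)
    if (is.null(out)) return(NULL)
  }
  out
}

signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

# Axis-aligned rectangle polygon.
rect_poly <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

#' Equirectangular projection of longitude/latitude to planar metres
#'
#' Adapter for real-world inputs: projects lon/lat (degrees) to local planar
#' metre coordinates around a reference point. At city scale (tens of km) the
#' projection error is negligible relative to tower-spacing measurement error.
#'
#' @param lon,lat numeric vectors, degrees.
#' @param ref optional c(lon0, lat0) reference; defaults to the centroid.
#' @return data.frame with columns `x`, `y` in metres.
#' @export
lonlat_to_xy <- function(lon, lat, ref = NULL) {
  if (is.null(ref)) ref <- c(mean(lon), mean(lat))
  r <- 6371000
  data.frame(
    x = (lon - ref[1]) * pi / 180 * r * cos(ref[2] * pi / 180),
    y = (lat - ref[2]) * pi / 180 * r
  )
}
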