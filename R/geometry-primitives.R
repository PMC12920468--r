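# Planar geometry primitives for compartment delineation.
#
# Polygons are plain numeric matrices with columns x, y (micrometres), open
# ring convention (first vertex not repeated). Polylines are the same but not
# closed. All routines are pure base-R so the geometry model carries no
# dependency beyond the language.

#' Polygon area by the shoelace formula
#'
#' @param poly numeric matrix (n x 2) of vertices in order; the ring is
#'   closed implicitly.
#' @return Area in the square of the coordinate unit (always >= 0).
#' @export
polygon_area <- function(poly) {
  abs(polygon_signed_area(poly))
}

polygon_signed_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Vectorised ray-casting point-in-polygon test
#'
#' Even-odd rule; points exactly on an edge may fall on either side and are
#' not treated specially (region assignment resolves boundaries by the
#' interface-distance rule, not by this test).
#'
#' @param x,y coordinate vectors of equal length.
#' @param poly polygon matrix.
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- (py[i] > y) != (py[j] > y)
    if (any(crosses)) {
      xint <- px[i] + (y - py[i]) * (px[j] - px[i]) / (py[j] - py[i])
      inside <- xor(inside, crosses & !is.na(xint) & x < xint)
    }
    j <- i
  }
  inside
}

# Clip a (possibly non-convex) subject polygon against one half-plane.
# The half-plane is the left side of the directed edge a -> b (inclusive).
clip_halfplane <- function(poly, ax, ay, bx, by) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(poly[0, , drop = FALSE])
  ex <- bx - ax; ey <- by - ay
  side <- ex * (poly[, 2] - ay) - ey * (poly[, 1] - ax)
  keep <- side >= 0
  out_x <- numeric(0); out_y <- numeric(0)
  j <- n
  for (i in seq_len(n)) {
    if (keep[i] != keep[j]) {
      t <- side[j] / (side[j] - side[i])
      out_x <- c(out_x, poly[j, 1] + t * (poly[i, 1] - poly[j, 1]))
      out_y <- c(out_y, poly[j, 2] + t * (poly[i, 2] - poly[j, 2]))
    }
    if (keep[i]) {
      out_x <- c(out_x, poly[i, 1])
      out_y <- c(out_y, poly[i, 2])
    }
    j <- i
  }
  cbind(x = out_x, y = out_y)
}

#' Sutherland-Hodgman clip of a polygon against a convex clipper
#'
#' Subject may be non-convex; the clipper must be convex and wound
#' counter-clockwise. Degenerate bridge edges that the algorithm can produce
#' for disconnected results have zero area and do not affect area queries.
#'
#' @keywords internal
clip_polygon_convex <- function(subject, clipper) {
  # ensure CCW clipper
  if (polygon_signed_area(clipper) < 0) clipper <- clipper[rev(seq_len(nrow(clipper))), , drop = FALSE]
  out <- subject
  n <- nrow(clipper)
  j <- n
  for (i in seq_len(n)) {
    out <- clip_halfplane(out, clipper[j, 1], clipper[j, 2], clipper[i, 1], clipper[i, 2])
    if (nrow(out) < 3) return(out[0, , drop = FALSE])
    j <- i
  }
  out
}

# Area centroid of a simple polygon (robust to uneven vertex spacing,
# unlike the vertex mean).
polygon_centroid <- function(poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

rect_polygon <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

#' Arc length of a polyline
#' @export
polyline_length <- function(line) {
  d <- diff(line)
  sum(sqrt(rowSums(d^2)))
}

# Unit left normals of each segment of a polyline.
segment_normals <- function(line) {
  d <- diff(line)
  len <- sqrt(rowSums(d^2))
  if (any(len == 0)) stop("polyline has zero-length segments", call. = FALSE)
  cbind(-d[, 2] / len, d[, 1] / len)
}

#' Offset a polyline along its normals
#'
#' Vertex normals are the mitred average of adjacent segment normals, so the
#' offset curve stays parallel at distance `d` wherever the local curvature
#' radius exceeds |d|. Positive d offsets to the left of the direction of
#' travel.
#'
#' @keywords internal
offset_polyline <- function(line, d) {
  sn <- segment_normals(line)
  n <- nrow(line)
  vn <- matrix(0, n, 2)
  vn[1, ] <- sn[1, ]
  vn[n, ] <- sn[n - 1, ]
  if (n > 2) {
    avg <- sn[-nrow(sn), , drop = FALSE] + sn[-1, , drop = FALSE]
    alen <- sqrt(rowSums(avg^2))
    alen[alen < 1e-12] <- 1  # hairpin: fall back to unscaled
    avg <- avg / alen
    # mitre scale 1/cos(theta/2), capped to avoid spikes at sharp angles
    cosh2 <- rowSums(avg * sn[-1, , drop = FALSE])
    scale <- pmin(1 / pmax(cosh2, 0.25), 4)
    vn[2:(n - 1), ] <- avg * scale
  }
  line + d * vn
}

#' Buffer a polyline into a flat-capped band polygon
#'
#' The band extends `width/2` perpendicular on each side of the polyline with
#' flat (butt) end caps: it does not extend beyond the polyline ends.
#'
#' @param line polyline matrix.
#' @param width_um total perpendicular band width (> 0).
#' @return polygon matrix.
#' @keywords internal
buffer_polyline <- function(line, width_um) {
  if (!is.numeric(width_um) || length(width_um) != 1 || !is.finite(width_um) || width_um <= 0) {
    stop("band width must be a single positive number", call. = FALSE)
  }
  h <- width_um / 2
  left <- offset_polyline(line, h)
  right <- offset_polyline(line, -h)
  poly <- rbind(left, right[rev(seq_len(nrow(right))), , drop = FALSE])
  colnames(poly) <- c("x", "y")
  poly
}

#' Flat-capped band membership test
#'
#' A point is in the band iff its perpendicular projection falls on some
#' segment at distance <= width/2, or it lies within width/2 of an interior
#' vertex (filling the mitre wedge on the convex side of a bend). End caps
#' are flat: points beyond the polyline ends are outside. The boundary is
#' closed, so a point at exactly width/2 is inside.
#'
#' @keywords internal
in_band <- function(x, y, line, width_um) {
  h2 <- (width_um / 2)^2
  n <- nrow(line)
  inb <- rep(FALSE, length(x))
  for (i in seq_len(n - 1)) {
    ax <- line[i, 1]; ay <- line[i, 2]
    dx <- line[i + 1, 1] - ax; dy <- line[i + 1, 2] - ay
    L2 <- dx * dx + dy * dy
    t <- ((x - ax) * dx + (y - ay) * dy) / L2
    perp2 <- (x - ax - t * dx)^2 + (y - ay - t * dy)^2
    inb <- inb | (t >= 0 & t <= 1 & perp2 <= h2)
  }
  if (n > 2) {
    for (i in 2:(n - 1)) {
      inb <- inb | ((x - line[i, 1])^2 + (y - line[i, 2])^2 <= h2)
    }
  }
  inb
}

#' Minimum distance from points to a polyline
#' @export
dist_to_polyline <- function(x, y, line) {
  n <- nrow(line)
  best <- rep(Inf, length(x))
  for (i in seq_len(n - 1)) {
    ax <- line[i, 1]; ay <- line[i, 2]
    dx <- line[i + 1, 1] - ax; dy <- line[i + 1, 2] - ay
    L2 <- dx * dx + dy * dy
    t <- pmin(pmax(((x - ax) * dx + (y - ay) * dy) / L2, 0), 1)
    d2 <- (x - ax - t * dx)^2 + (y - ay - t * dy)^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}
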