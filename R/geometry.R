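# Continuous 2-D geometry for head boxes, the circular feeder region and the
# tracking polygon. Image convention throughout: origin top-left, x right,
# y down, continuous pixel units; boxes are (left, top, width, height).

# absolute tolerance for boundary / equality decisions, in pixels
.bt_tol <- 1e-9

#' Circular region (feeding area)
#'
#' Constructs the circular feeder region ("feeding area") used by the feeding
#' index. The circle is the image footprint of the feeder pan, drawn manually
#' on the scene.
#'
#' @param cx,cy Center, in pixels (image coordinates, origin top-left).
#' @param r Radius in pixels; must be positive.
#' @return An object of class `bt_circle` with fields `cx`, `cy`, `r`.
#' @examples
#' feeder <- bt_circle(400, 300, 60)
#' @export
bt_circle <- function(cx, cy, r) {
  stopifnot(is.numeric(cx), is.numeric(cy), is.numeric(r),
            length(cx) == 1, length(cy) == 1, length(r) == 1)
  if (!all(is.finite(c(cx, cy, r)))) stop("circle parameters must be finite")
  if (r <= 0) stop("circle radius must be positive")
  structure(list(cx = as.numeric(cx), cy = as.numeric(cy), r = as.numeric(r)),
            class = "bt_circle")
}

#' @export
print.bt_circle <- function(x, ...) {
  cat(sprintf("<bt_circle center=(%g, %g) r=%g>\n", x$cx, x$cy, x$r))
  invisible(x)
}

#' Polygonal region (tracking area)
#'
#' Constructs the polygon within which heads are tracked. The polygon must be
#' simple (non-self-intersecting) with at least three vertices and positive
#' enclosed area.
#'
#' @param x,y Numeric vectors of vertex coordinates, in order (either winding).
#' @return An object of class `bt_polygon` with fields `x`, `y`.
#' @examples
#' arena <- bt_polygon(c(0, 100, 100, 0), c(0, 0, 100, 100))
#' @export
bt_polygon <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3) stop("polygon needs at least 3 vertices")
  if (!all(is.finite(c(x, y)))) stop("polygon vertices must be finite")
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  # shoelace area
  j <- c(n, seq_len(n - 1))
  area <- abs(sum(x[j] * y - x * y[j])) / 2
  if (area <= .bt_tol) stop("polygon has zero enclosed area")
  if (.bt_self_intersects(x, y)) stop("polygon is self-intersecting")
  structure(list(x = x, y = y), class = "bt_polygon")
}

#' @export
print.bt_polygon <- function(x, ...) {
  cat(sprintf("<bt_polygon %d vertices, area %g px^2>\n",
              length(x$x), polygon_area(x)))
  invisible(x)
}

#' Enclosed area of a polygon
#'
#' @param poly A [bt_polygon()].
#' @return Area in square pixels (shoelace formula).
#' @export
polygon_area <- function(poly) {
  stopifnot(inherits(poly, "bt_polygon"))
  n <- length(poly$x)
  j <- c(n, seq_len(n - 1))
  abs(sum(poly$x[j] * poly$y - poly$x * poly$y[j])) / 2
}

# TRUE if any two non-adjacent edges properly cross
.bt_self_intersects <- function(x, y) {
  n <- length(x)
  orient <- function(ax, ay, bx, by, cx, cy) {
    v <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    ifelse(abs(v) < .bt_tol, 0, sign(v))
  }
  for (i in seq_len(n)) {
    i2 <- i %% n + 1
    for (k in seq_len(n)) {
      if (k <= i) next
      k2 <- k %% n + 1
      # skip adjacent edges (share a vertex)
      if (i2 == k || k2 == i || (i == 1 && k == n)) next
      o1 <- orient(x[i], y[i], x[i2], y[i2], x[k], y[k])
      o2 <- orient(x[i], y[i], x[i2], y[i2], x[k2], y[k2])
      o3 <- orient(x[k], y[k], x[k2], y[k2], x[i], y[i])
      o4 <- orient(x[k], y[k], x[k2], y[k2], x[i2], y[i2])
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
        return(TRUE)
    }
  }
  FALSE
}

#' Center point of bounding boxes
#'
#' The tracker associates detections across frames by the center point of the
#' head bounding box; this computes it.
#'
#' @param x,y Left/top edge of the box(es), pixels. Vectorized.
#' @param w,h Width/height, pixels; must be positive.
#' @return A data.frame with columns `cx`, `cy`.
#' @examples
#' bbox_centroid(10, 20, 4, 6) # (12, 23)
#' @export
bbox_centroid <- function(x, y, w, h) {
  stopifnot(all(is.finite(c(x, y, w, h))))
  if (any(w <= 0) || any(h <= 0)) stop("box width and height must be positive")
  data.frame(cx = x + w / 2, cy = y + h / 2)
}

#' Euclidean distance between points
#'
#' @param x1,y1,x2,y2 Point coordinates, pixels. Vectorized.
#' @return Nonnegative distances in pixels.
#' @examples
#' euclidean_distance(0, 0, 3, 4) # 5
#' @export
euclidean_distance <- function(x1, y1, x2, y2) {
  sqrt((x1 - x2)^2 + (y1 - y2)^2)
}

#' Point-in-circle membership
#'
#' Boundary points count as inside (distance exactly `r` is a member), so the
#' decision is deterministic on the measure-zero boundary.
#'
#' @param px,py Point coordinates, pixels. Vectorized.
#' @param circle A [bt_circle()].
#' @return Logical vector.
#' @export
point_in_circle <- function(px, py, circle) {
  stopifnot(inherits(circle, "bt_circle"))
  (px - circle$cx)^2 + (py - circle$cy)^2 <= circle$r^2
}

#' Point-in-polygon membership (even-odd rule)
#'
#' Ray-casting membership with the even-odd rule; points on an edge or vertex
#' count as inside.
#'
#' @param px,py Point coordinates, pixels. Vectorized.
#' @param poly A [bt_polygon()].
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  stopifnot(inherits(poly, "bt_polygon"))
  vapply(seq_along(px), function(i) .bt_pip1(px[i], py[i], poly$x, poly$y),
         logical(1))
}

.bt_pip1 <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # boundary: point on the closed segment?
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    if (abs(cross) <= .bt_tol * max(1, abs(x2 - x1) + abs(y2 - y1))) {
      dot <- (px - x1) * (px - x2) + (py - y1) * (py - y2)
      if (dot <= .bt_tol) return(TRUE)
    }
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Signed area of disk(origin, r) ∩ triangle(origin, p1, p2).
# Classic arc/chord decomposition: the part of the edge chord inside the disk
# contributes a triangle, the parts outside contribute circular sectors.
.bt_disk_tri <- function(x1, y1, x2, y2, r) {
  tri <- function(ax, ay, bx, by) (ax * by - ay * bx) / 2
  sector <- function(ax, ay, bx, by)
    0.5 * r^2 * atan2(ax * by - ay * bx, ax * bx + ay * by)
  dx <- x2 - x1; dy <- y2 - y1
  a <- dx * dx + dy * dy
  if (a == 0) return(0)
  b <- 2 * (x1 * dx + y1 * dy)
  cc <- x1 * x1 + y1 * y1 - r * r
  disc <- b * b - 4 * a * cc
  if (disc <= 0) {
    # edge line misses the disk entirely: pure sector seen from the center
    return(sector(x1, y1, x2, y2))
  }
  sq <- sqrt(disc)
  t1 <- (-b - sq) / (2 * a)
  t2 <- (-b + sq) / (2 * a)
  s <- max(t1, 0); e <- min(t2, 1)
  if (s >= e) return(sector(x1, y1, x2, y2))
  qx1 <- x1 + s * dx; qy1 <- y1 + s * dy
  qx2 <- x1 + e * dx; qy2 <- y1 + e * dy
  sector(x1, y1, qx1, qy1) + tri(qx1, qy1, qx2, qy2) + sector(qx2, qy2, x2, y2)
}

#' Exact rectangle-circle intersection area
#'
#' Closed-form area of the intersection of an axis-aligned box with a disk, by
#' decomposing the box boundary into chords and circular sectors (Green's
#' theorem); no sampling involved. This is the numerator of the feeding index.
#'
#' @param x,y,w,h Box left/top/width/height, pixels. Vectorized over boxes.
#' @param circle A [bt_circle()].
#' @return Intersection areas in square pixels, each in
#'   `[0, min(w*h, pi*r^2)]`.
#' @examples
#' rect_circle_intersection_area(-1, -1, 2, 2, bt_circle(0, 0, 10)) # 4
#' @export
rect_circle_intersection_area <- function(x, y, w, h, circle) {
  stopifnot(inherits(circle, "bt_circle"))
  if (any(w <= 0) || any(h <= 0)) stop("box width and height must be positive")
  r <- circle$r
  vapply(seq_along(x), function(i) {
    # exact disjointness: closest box point at distance >= r means zero area
    # (the sector terms would only cancel to ~1e-16 in floating point)
    nx <- min(max(circle$cx, x[i]), x[i] + w[i])
    ny <- min(max(circle$cy, y[i]), y[i] + h[i])
    if ((nx - circle$cx)^2 + (ny - circle$cy)^2 >= r^2) return(0)
    # box corners relative to circle center, counterclockwise in math sense
    vx <- c(x[i], x[i] + w[i], x[i] + w[i], x[i]) - circle$cx
    vy <- c(y[i], y[i], y[i] + h[i], y[i] + h[i]) - circle$cy
    s <- 0
    for (k in 1:4) {
      k2 <- k %% 4 + 1
      s <- s + .bt_disk_tri(vx[k], vy[k], vx[k2], vy[k2], r)
    }
    min(abs(s), w[i] * h[i], pi * r^2)
  }, numeric(1))
}
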