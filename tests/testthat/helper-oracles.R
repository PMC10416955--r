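# Independent oracles and small generators used across the suite. These are
# deliberately implemented along different routes than the package code.

# Monte-Carlo estimate of the box/circle intersection area by uniform
# rejection sampling over the box; returns the estimate and its standard
# error so callers can assert agreement within k standard errors.
mc_rect_circle_area <- function(x, y, w, h, circ, n = 1e6) {
  px <- stats::runif(n, x, x + w)
  py <- stats::runif(n, y, y + h)
  hit <- (px - circ$cx)^2 + (py - circ$cy)^2 <= circ$r^2
  p <- mean(hit)
  list(area = p * w * h,
       se = sqrt(p * (1 - p) / n) * w * h)
}

# winding-number point-in-polygon (nonzero rule). On simple polygons the
# nonzero and even-odd rules agree, so this is a fair independent oracle for
# interior/exterior points (boundary points are avoided by the generators).
winding_point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  wn <- 0
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    is_left <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
    if (y1 <= py) {
      if (y2 > py && is_left > 0) wn <- wn + 1
    } else {
      if (y2 <= py && is_left < 0) wn <- wn - 1
    }
    j <- i
  }
  wn != 0
}

# random simple polygon: vertices at sorted angles around a center, with
# radii jittered (convex for equal radii spread, concave otherwise)
random_simple_polygon <- function(n_vertices = sample(3:9, 1),
                                  cx = runif(1, -5, 5), cy = runif(1, -5, 5),
                                  rmin = 0.5, rmax = 5) {
  # angular gaps all below pi guarantee the star-shaped polygon is simple
  repeat {
    g <- runif(n_vertices, 0.2, 1)
    if (max(g) / sum(g) < 0.45) break
  }
  ang <- 2 * pi * cumsum(g) / sum(g) + runif(1, 0, 2 * pi)
  r <- runif(n_vertices, rmin, rmax)
  bt_polygon(cx + r * cos(ang), cy + r * sin(ang))
}

# brute-force greedy one-to-one matching oracle. Enumerates every one-to-one
# matching among sub-radius (track, detection) pairs recursively, then
# selects the matching the greedy nearest-first order induces by walking the
# pair list (distance ascending, ties by detection then track index) and
# keeping each pair consistent with the previously kept ones.
oracle_greedy_match <- function(track_xy, det_xy, radius) {
  nt <- nrow(track_xy); nd <- nrow(det_xy)
  if (nt == 0 || nd == 0)
    return(data.frame(track = integer(0), det = integer(0)))
  pairs <- expand.grid(track = seq_len(nt), det = seq_len(nd))
  pairs$d <- sqrt((track_xy[pairs$track, 1] - det_xy[pairs$det, 1])^2 +
                    (track_xy[pairs$track, 2] - det_xy[pairs$det, 2])^2)
  pairs <- pairs[pairs$d < radius, , drop = FALSE]
  if (!nrow(pairs)) return(data.frame(track = integer(0), det = integer(0)))

  # full enumeration of one-to-one matchings (sanity: the greedy pick must be
  # one of them and must be maximal)
  enumerate <- function(rows, used_t, used_d) {
    out <- list(integer(0))
    for (k in rows) {
      t <- pairs$track[k]; d <- pairs$det[k]
      if (used_t[t] || used_d[d]) next
      ut <- used_t; ud <- used_d; ut[t] <- TRUE; ud[d] <- TRUE
      sub <- enumerate(rows[rows > k], ut, ud)
      out <- c(out, lapply(sub, function(s) c(k, s)))
    }
    out
  }
  all_matchings <- enumerate(seq_len(nrow(pairs)),
                             logical(nt), logical(nd))

  ord <- order(pairs$d, pairs$det, pairs$track)
  used_t <- logical(nt); used_d <- logical(nd)
  keep <- integer(0)
  for (k in ord) {
    t <- pairs$track[k]; d <- pairs$det[k]
    if (used_t[t] || used_d[d]) next
    used_t[t] <- TRUE; used_d[d] <- TRUE
    keep <- c(keep, k)
  }
  stopifnot(any(vapply(all_matchings, function(m) setequal(m, keep),
                       logical(1))))
  res <- pairs[keep, c("track", "det")]
  res[order(res$track), , drop = FALSE]
}

# convenience: a detection data.frame row set for one frame
make_frame_det <- function(frame, cx, cy, w = 10, h = 10, conf = 0.9) {
  n <- max(length(frame), length(cx))
  if (length(cx) == 0) n <- 0
  data.frame(frame = rep_len(frame, n), x = rep_len(cx, n) - rep_len(w, n) / 2,
             y = rep_len(cy, n) - rep_len(h, n) / 2,
             w = rep_len(w, n), h = rep_len(h, n), conf = rep_len(conf, n))
}

# default test scene, small and fast
test_scene <- function(...) default_scene(...)
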