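# Per-frame feeding decision, visit segmentation and frame-to-second
# conversion. A head is feeding in a frame when its bounding box overlaps the
# circular feeder region with positive area (feeding index > 0); an
# alternative center-in-circle criterion is available. Contiguous feeding
# frames of one identity form a visit; visit duration is the number of
# feeding frames divided by the frame rate.

#' Scene configuration
#'
#' Describes one camera scene: frame rate, image size, the circular feeding
#' area, the polygonal tracking area, and tracker parameters. The tracking
#' area must fully enclose the feeding circle, and both must lie within the
#' image.
#'
#' @param fps Frames per second of the source video. Default 15.
#' @param image_width,image_height Image size in pixels.
#' @param feeding_area A [bt_circle()].
#' @param tracking_area A [bt_polygon()] enclosing the feeding circle.
#' @param params A [tracker_params()].
#' @param criterion Per-frame feeding rule: `"area"` (feeding index > 0, the
#'   default) or `"center"` (box center inside the circle).
#' @param gap_tolerance Observed non-feeding frames tolerated inside one visit
#'   before it is split. Default 0.
#' @return An object of class `bt_scene`.
#' @export
scene_config <- function(fps = 15, image_width, image_height, feeding_area,
                         tracking_area, params = tracker_params(),
                         criterion = c("area", "center"), gap_tolerance = 0) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(feeding_area, "bt_circle"),
            inherits(tracking_area, "bt_polygon"),
            inherits(params, "bt_tracker_params"))
  if (fps <= 0) stop("fps must be positive")
  if (image_width <= 0 || image_height <= 0) stop("image size must be positive")
  if (gap_tolerance < 0) stop("gap_tolerance must be nonnegative")
  fa <- feeding_area
  if (fa$cx - fa$r < 0 || fa$cy - fa$r < 0 ||
      fa$cx + fa$r > image_width || fa$cy + fa$r > image_height)
    stop("feeding_area extends outside the image bounds")
  if (!.bt_polygon_contains_circle(tracking_area, fa))
    stop("tracking_area must enclose the feeding_area circle")
  structure(list(fps = as.numeric(fps),
                 image_width = as.numeric(image_width),
                 image_height = as.numeric(image_height),
                 feeding_area = fa, tracking_area = tracking_area,
                 params = params, criterion = criterion,
                 gap_tolerance = as.integer(gap_tolerance)),
            class = "bt_scene")
}

# circle inside polygon: center inside and every boundary edge at distance >= r
.bt_polygon_contains_circle <- function(poly, circ) {
  if (!point_in_polygon(circ$cx, circ$cy, poly)) return(FALSE)
  n <- length(poly$x)
  j <- c(n, seq_len(n - 1))
  d <- vapply(seq_len(n), function(i) {
    .bt_point_segment_dist(circ$cx, circ$cy,
                           poly$x[j[i]], poly$y[j[i]], poly$x[i], poly$y[i])
  }, numeric(1))
  all(d >= circ$r - .bt_tol)
}

.bt_point_segment_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx * dx + dy * dy
  t <- if (l2 == 0) 0 else max(0, min(1, ((px - x1) * dx + (py - y1) * dy) / l2))
  euclidean_distance(px, py, x1 + t * dx, y1 + t * dy)
}

#' @export
print.bt_scene <- function(x, ...) {
  cat(sprintf(paste0("<bt_scene %gx%g px @ %g fps, feeder (%g,%g) r=%g, ",
                     "criterion '%s'>\n"),
              x$image_width, x$image_height, x$fps,
              x$feeding_area$cx, x$feeding_area$cy, x$feeding_area$r,
              x$criterion))
  invisible(x)
}

#' Feeding index of a head box
#'
#' Ratio of the intersection area between the head bounding box and the
#' circular feeding area to the area of the feeding circle. A value greater
#' than 0 means the head is in the feeder; the value is 1 when the box covers
#' the whole circle.
#'
#' @param x,y,w,h Head box left/top/width/height, pixels. Vectorized.
#' @param feeding_area A [bt_circle()].
#' @return Values in `[0, 1]`.
#' @export
index_feed <- function(x, y, w, h, feeding_area) {
  stopifnot(inherits(feeding_area, "bt_circle"))
  rect_circle_intersection_area(x, y, w, h, feeding_area) /
    (pi * feeding_area$r^2)
}

#' Per-frame feeding status of tracked heads
#'
#' @param assignments Tracker output rows (`track_id`, `frame`, `x`, `y`, `w`,
#'   `h`, ...), typically from [run_tracker()].
#' @param cfg A [scene_config()]; its `criterion` selects the feeding rule.
#' @return data.frame `frame`, `track_id`, `index_feed`, `is_feeding`.
#' @export
frame_status <- function(assignments, cfg) {
  stopifnot(inherits(cfg, "bt_scene"))
  if (nrow(assignments) == 0)
    return(data.frame(frame = integer(0), track_id = integer(0),
                      index_feed = numeric(0), is_feeding = logical(0)))
  idx <- index_feed(assignments$x, assignments$y, assignments$w,
                    assignments$h, cfg$feeding_area)
  feeding <- if (cfg$criterion == "center") {
    cen <- bbox_centroid(assignments$x, assignments$y,
                         assignments$w, assignments$h)
    point_in_circle(cen$cx, cen$cy, cfg$feeding_area)
  } else {
    idx > 0
  }
  data.frame(frame = assignments$frame, track_id = assignments$track_id,
             index_feed = idx, is_feeding = feeding)
}

.bt_empty_visits <- function() {
  data.frame(track_id = integer(0), start_frame = integer(0),
             end_frame = integer(0), n_frames = integer(0),
             duration_s = numeric(0))
}

#' Segment one track's feeding frames into visits
#'
#' A visit is a maximal run of feeding-flagged observations of one identity.
#' Runs are taken over the sequence of observed statuses: an interruption is
#' an observed non-feeding frame (the head was detected outside the feeder);
#' up to `gap_tolerance` consecutive interruptions do not split a visit, and
#' interruption frames are never counted in `n_frames`. Frames in which the
#' identity produced no detection at all leave the visit open (the occupancy
#' is unobserved, not observed to end); the tracker's missed-frame expiry
#' bounds how long that can last, and losing the identity ends the visit.
#'
#' @param statuses [frame_status()] rows for a single track, sorted by frame.
#' @param fps Frames per second, for the frames-to-seconds conversion.
#' @param gap_tolerance Observed non-feeding frames bridged within a visit.
#' @return data.frame `track_id`, `start_frame`, `end_frame` (first and last
#'   feeding frame, inclusive), `n_frames` (feeding frames only),
#'   `duration_s = n_frames / fps`.
#' @export
segment_visits <- function(statuses, fps, gap_tolerance = 0) {
  if (fps <= 0) stop("fps must be positive")
  if (gap_tolerance < 0) stop("gap_tolerance must be nonnegative")
  if (nrow(statuses) == 0) return(.bt_empty_visits())
  if (length(unique(statuses$track_id)) > 1)
    stop("segment_visits expects statuses of a single track; ",
         "see segment_all_visits")
  if (is.unsorted(statuses$frame, strictly = TRUE))
    stop("statuses must be sorted by strictly increasing frame")
  id <- statuses$track_id[1]
  visits <- list()
  start <- NA_integer_; last_feed <- NA_integer_; count <- 0L; gap <- 0L
  close_visit <- function() {
    if (count > 0L)
      visits[[length(visits) + 1L]] <<- data.frame(
        track_id = id, start_frame = start, end_frame = last_feed,
        n_frames = count, duration_s = count / fps)
    start <<- NA_integer_; last_feed <<- NA_integer_; count <<- 0L; gap <<- 0L
  }
  for (i in seq_len(nrow(statuses))) {
    if (statuses$is_feeding[i]) {
      if (count == 0L) start <- statuses$frame[i]
      last_feed <- statuses$frame[i]
      count <- count + 1L
      gap <- 0L
    } else if (count > 0L) {
      gap <- gap + 1L
      if (gap > gap_tolerance) close_visit()
    }
  }
  close_visit()
  if (length(visits) == 0) return(.bt_empty_visits())
  out <- do.call(rbind, visits)
  rownames(out) <- NULL
  out
}

#' Segment visits for every track
#'
#' @param statuses [frame_status()] rows for any number of tracks.
#' @param fps Frames per second.
#' @param gap_tolerance See [segment_visits()].
#' @return Visits of all tracks, ordered by track then start frame.
#' @export
segment_all_visits <- function(statuses, fps, gap_tolerance = 0) {
  if (nrow(statuses) == 0) return(.bt_empty_visits())
  parts <- lapply(split(statuses, statuses$track_id), function(s) {
    s <- s[order(s$frame), , drop = FALSE]
    segment_visits(s, fps, gap_tolerance)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$track_id, out$start_frame), , drop = FALSE]
}

#' Per-bird feeding summary
#'
#' @param visits Visit table from [segment_all_visits()].
#' @return List with `per_track` (data.frame `track_id`, `n_visits`,
#'   `total_s`, `mean_s_per_visit`) and `overall_mean_s_per_visit` (mean
#'   duration across all visits; `NA` if there are none).
#' @export
per_bird_report <- function(visits) {
  if (nrow(visits) == 0)
    return(list(per_track = data.frame(track_id = integer(0),
                                       n_visits = integer(0),
                                       total_s = numeric(0),
                                       mean_s_per_visit = numeric(0)),
                overall_mean_s_per_visit = NA_real_))
  per <- do.call(rbind, lapply(split(visits, visits$track_id), function(v)
    data.frame(track_id = v$track_id[1], n_visits = nrow(v),
               total_s = sum(v$duration_s),
               mean_s_per_visit = mean(v$duration_s))))
  rownames(per) <- NULL
  list(per_track = per[order(per$track_id), , drop = FALSE],
       overall_mean_s_per_visit = mean(visits$duration_s))
}

#' Full feeding-time pipeline on a detection stream
#'
#' Runs the tracker over the detections (gated to the tracking area), flags
#' feeding frames, segments visits and summarizes them — the end-to-end
#' feeding-time estimation workflow.
#'
#' @param detections data.frame `frame`, `x`, `y`, `w`, `h`, `conf`.
#' @param cfg A [scene_config()].
#' @param n_frames Optional frame count (defaults to last detection frame + 1).
#' @return List of class `bt_feeding_result`: `tracks` (assignments),
#'   `statuses`, `visits`, `summary` (from [per_bird_report()]) and
#'   `head_count` (number of distinct identities).
#' @export
estimate_feeding <- function(detections, cfg, n_frames = NULL) {
  stopifnot(inherits(cfg, "bt_scene"))
  tracks <- run_tracker(detections, cfg$params, cfg$tracking_area, n_frames)
  statuses <- frame_status(tracks, cfg)
  visits <- segment_all_visits(statuses, cfg$fps, cfg$gap_tolerance)
  structure(list(tracks = tracks, statuses = statuses, visits = visits,
                 summary = per_bird_report(visits),
                 head_count = length(unique(tracks$track_id))),
            class = "bt_feeding_result")
}

#' @export
print.bt_feeding_result <- function(x, ...) {
  cat(sprintf("<bt_feeding_result: %d identities, %d visits, %.2f s total>\n",
              x$head_count, nrow(x$visits), sum(x$visits$duration_s)))
  invisible(x)
}
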