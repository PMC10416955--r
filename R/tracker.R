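# Euclidean-distance centroid tracker. Each detected head is associated to the
# nearest stored track center if the distance is below the match radius
# (default 20 px); otherwise it founds a new identity. A track survives up to
# max_missed (default 10) consecutive frames without a detection, holding its
# last centroid, and keeps a bounded history of its most recent observations.

#' Tracker parameters
#'
#' @param match_radius Maximum center-to-center distance, in pixels, for a
#'   detection to keep an existing identity. A distance exactly equal to the
#'   radius does NOT match (the rule is strictly "less than"). Default 20.
#' @param max_missed Consecutive missed frames after which a track identity is
#'   retired. Default 10.
#' @param history_length Number of recent observations stored per track.
#'   Default 10.
#' @param min_confidence Detections below this confidence are discarded before
#'   association. Default 0.5.
#' @return An object of class `bt_tracker_params`.
#' @export
tracker_params <- function(match_radius = 20, max_missed = 10,
                           history_length = 10, min_confidence = 0.5) {
  if (match_radius <= 0) stop("match_radius must be positive")
  if (max_missed < 1) stop("max_missed must be at least 1")
  if (history_length < 1) stop("history_length must be at least 1")
  if (min_confidence < 0 || min_confidence > 1)
    stop("min_confidence must be in [0, 1]")
  structure(list(match_radius = as.numeric(match_radius),
                 max_missed = as.integer(max_missed),
                 history_length = as.integer(history_length),
                 min_confidence = as.numeric(min_confidence)),
            class = "bt_tracker_params")
}

#' Fresh tracker state
#'
#' @return An empty `bt_tracker_state`: no active tracks, next identity 1,
#'   positioned before frame 0.
#' @export
tracker_state <- function() {
  structure(list(tracks = list(), next_id = 1L, frame = -1L),
            class = "bt_tracker_state")
}

# empty assignment data.frame (column template)
.bt_empty_assignments <- function() {
  data.frame(track_id = integer(0), frame = integer(0),
             x = numeric(0), y = numeric(0), w = numeric(0), h = numeric(0),
             conf = numeric(0), cx = numeric(0), cy = numeric(0))
}

.bt_check_detections <- function(det) {
  need <- c("frame", "x", "y", "w", "h", "conf")
  if (!is.data.frame(det) || !all(need %in% names(det)))
    stop("detections must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (nrow(det) && (any(det$w <= 0) || any(det$h <= 0)))
    stop("detection boxes must have positive width and height")
  if (nrow(det) && (any(det$conf < 0) || any(det$conf > 1)))
    stop("detection confidence must be in [0, 1]")
  invisible(det)
}

#' Advance the tracker by one frame
#'
#' Associates the detections of the next frame to the active tracks by greedy
#' nearest-first matching: among all (track, detection) pairs closer than
#' `match_radius`, the globally smallest distance is committed first, both
#' members are withdrawn, and the process repeats. Ties are broken by lower
#' detection input index, then by older track. Unmatched detections found new
#' tracks (identities issued in detection input order); unmatched tracks
#' accrue a missed frame and are retired once `max_missed` is reached.
#'
#' @param state A `bt_tracker_state`.
#' @param detections data.frame with columns `frame`, `x`, `y`, `w`, `h`,
#'   `conf`, all rows belonging to frame `state$frame + 1` (pass zero rows for
#'   an empty frame). Rows below `min_confidence`, or whose centroid falls
#'   outside `gate`, are discarded before association.
#' @param params A [tracker_params()].
#' @param gate Optional [bt_polygon()] tracking region.
#' @return List with elements `state` (advanced state) and `assignments`
#'   (data.frame `track_id`, `frame`, `x`, `y`, `w`, `h`, `conf`, `cx`, `cy`).
#' @export
tracker_step <- function(state, detections, params = tracker_params(),
                         gate = NULL) {
  stopifnot(inherits(state, "bt_tracker_state"),
            inherits(params, "bt_tracker_params"))
  .bt_check_detections(detections)
  new_frame <- state$frame + 1L
  if (nrow(detections)) {
    fr <- unique(detections$frame)
    if (length(fr) > 1)
      stop("mixed frame indices in one tracker step: ",
           paste(fr, collapse = ", "))
    if (fr != new_frame)
      stop(sprintf("detections are for frame %d but tracker expects frame %d",
                   fr, new_frame))
  }

  # pre-association filtering: confidence cutoff, then tracking-area gate
  det <- detections
  if (nrow(det)) det <- det[det$conf >= params$min_confidence, , drop = FALSE]
  cen <- if (nrow(det)) bbox_centroid(det$x, det$y, det$w, det$h)
         else data.frame(cx = numeric(0), cy = numeric(0))
  if (!is.null(gate) && nrow(det)) {
    keep <- point_in_polygon(cen$cx, cen$cy, gate)
    det <- det[keep, , drop = FALSE]
    cen <- cen[keep, , drop = FALSE]
  }
  nd <- nrow(det)
  nt <- length(state$tracks)

  matched_det <- integer(0)   # detection row -> track list index
  matched_trk <- integer(0)
  if (nd > 0 && nt > 0) {
    last_cx <- vapply(state$tracks, function(t) t$cx, numeric(1))
    last_cy <- vapply(state$tracks, function(t) t$cy, numeric(1))
    d <- outer(seq_len(nt), seq_len(nd), function(i, j)
      euclidean_distance(last_cx[i], last_cy[i], cen$cx[j], cen$cy[j]))
    cand <- which(d < params$match_radius, arr.ind = TRUE)
    if (nrow(cand)) {
      dv <- d[cand]
      ord <- order(dv, cand[, 2], cand[, 1])  # distance, det index, track age
      used_t <- logical(nt); used_d <- logical(nd)
      for (k in ord) {
        ti <- cand[k, 1]; di <- cand[k, 2]
        if (used_t[ti] || used_d[di]) next
        used_t[ti] <- TRUE; used_d[di] <- TRUE
        matched_trk <- c(matched_trk, ti)
        matched_det <- c(matched_det, di)
      }
    }
  }

  tracks <- state$tracks
  assign_id <- integer(nd)

  # matched tracks: append observation, reset missed counter, trim history
  for (k in seq_along(matched_det)) {
    ti <- matched_trk[k]; di <- matched_det[k]
    tr <- tracks[[ti]]
    obs <- data.frame(frame = new_frame, cx = cen$cx[di], cy = cen$cy[di],
                      x = det$x[di], y = det$y[di],
                      w = det$w[di], h = det$h[di])
    tr$history <- rbind(tr$history, obs)
    if (nrow(tr$history) > params$history_length)
      tr$history <- tr$history[
        seq(nrow(tr$history) - params$history_length + 1, nrow(tr$history)), ,
        drop = FALSE]
    tr$cx <- cen$cx[di]; tr$cy <- cen$cy[di]; tr$missed <- 0L
    tracks[[ti]] <- tr
    assign_id[di] <- tr$id
  }

  # unmatched tracks: coast at the last stored centroid; expire at max_missed
  unmatched_t <- setdiff(seq_len(nt), matched_trk)
  drop_t <- integer(0)
  for (ti in unmatched_t) {
    tracks[[ti]]$missed <- tracks[[ti]]$missed + 1L
    if (tracks[[ti]]$missed >= params$max_missed) drop_t <- c(drop_t, ti)
  }
  if (length(drop_t)) tracks <- tracks[-drop_t]

  # unmatched detections spawn new identities, in detection input order
  next_id <- state$next_id
  for (di in setdiff(seq_len(nd), matched_det)) {
    tr <- list(id = next_id, cx = cen$cx[di], cy = cen$cy[di], missed = 0L,
               history = data.frame(frame = new_frame,
                                    cx = cen$cx[di], cy = cen$cy[di],
                                    x = det$x[di], y = det$y[di],
                                    w = det$w[di], h = det$h[di]))
    tracks[[length(tracks) + 1L]] <- tr
    assign_id[di] <- next_id
    next_id <- next_id + 1L
  }

  assignments <- if (nd) {
    data.frame(track_id = assign_id, frame = new_frame,
               x = det$x, y = det$y, w = det$w, h = det$h, conf = det$conf,
               cx = cen$cx, cy = cen$cy)
  } else .bt_empty_assignments()

  state$tracks <- tracks
  state$next_id <- next_id
  state$frame <- new_frame
  list(state = state, assignments = assignments)
}

#' Run the tracker over a whole detection stream
#'
#' Drives [tracker_step()] frame by frame from frame 0 through the last frame
#' present (or `n_frames - 1`), feeding empty frames where the stream has no
#' rows, and collects every per-frame identity assignment.
#'
#' @param detections data.frame with columns `frame` (0-based), `x`, `y`, `w`,
#'   `h`, `conf`; rows may arrive in any order.
#' @param params A [tracker_params()].
#' @param gate Optional [bt_polygon()] tracking region.
#' @param n_frames Optional number of frames to process; defaults to
#'   `max(frame) + 1`.
#' @return data.frame of assignments (`track_id`, `frame`, `x`, `y`, `w`, `h`,
#'   `conf`, `cx`, `cy`), ordered by frame. Deterministic for fixed input.
#' @export
run_tracker <- function(detections, params = tracker_params(), gate = NULL,
                        n_frames = NULL) {
  .bt_check_detections(detections)
  if (nrow(detections) == 0 && is.null(n_frames))
    return(.bt_empty_assignments())
  if (nrow(detections) && min(detections$frame) < 0)
    stop("frame indices must be nonnegative")
  if (is.null(n_frames)) n_frames <- max(detections$frame) + 1L
  state <- tracker_state()
  by_frame <- split(seq_len(nrow(detections)), detections$frame)
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames) - 1L) {
    rows <- by_frame[[as.character(f)]]
    det <- if (is.null(rows)) detections[0, , drop = FALSE]
           else detections[rows, , drop = FALSE]
    res <- tracker_step(state, det, params, gate)
    state <- res$state
    out[[f + 1L]] <- res$assignments
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
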