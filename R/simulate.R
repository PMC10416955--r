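# Synthetic flock scenarios: a top-down camera view of a feeder pan, with
# bird head trajectories that approach, occupy and leave a circular feeder,
# observed through a noisy detector. Ground-truth trajectories and feeding
# intervals are recorded alongside the noisy detections, so tracking and
# feeding-time estimation can be validated without video or a trained
# detector.

#' Simulation parameters
#'
#' Each bird follows a four-state behavior model (wander, approach, feed,
#' leave). Wandering is a bounded random walk inside the tracking polygon;
#' approach walks toward a bird-specific spot on the feeder pan; feed holds
#' the head over the pan with small jitter; leave walks away from the pan.
#' The detector is emulated by Gaussian centroid jitter, per-frame missed
#' detections, and uniform false positives over the tracking area.
#'
#' Default dwell in the feed state is 18.46 s (mean per-frame leave
#' probability `1 / (18.46 * fps)`), the field-reported mean visit length for
#' broilers at a commercial pan feeder; noise defaults (sigma 2 px, 5% missed
#' detections, 0.1 false positives per frame) emulate a good but imperfect
#' head detector.
#'
#' @param n_birds Number of birds. Default 5.
#' @param n_frames Number of frames. Default 900 (60 s at 15 fps).
#' @param p_wander_approach Per-frame probability that a wandering bird heads
#'   for the feeder. Default 0.008.
#' @param p_feed_leave Per-frame probability that a feeding bird leaves.
#'   Default `1 / (18.46 * 15)`.
#' @param p_leave_wander Per-frame probability that a leaving bird (already
#'   clear of the pan) resumes wandering. Default 0.05.
#' @param step_scale Random-walk step scale, pixels/frame; individual step
#'   magnitudes are capped at `4 * step_scale`. Default 3.
#' @param head_w,head_h Mean head box size, pixels. Default 24.
#' @param head_size_sd Per-bird size jitter (s.d., pixels). Default 2.
#' @param sigma Detector centroid jitter s.d., pixels. Default 2.
#' @param p_miss Per-frame missed-detection probability. Default 0.05.
#' @param fp_rate Poisson rate of false positives per frame. Default 0.1.
#' @param conf_range True-detection confidence range (uniform). Default
#'   `c(0.7, 1)`.
#' @param fp_conf_range False-positive confidence range (uniform), below the
#'   true-detection mode so the confidence cutoff is exercised. Default
#'   `c(0.1, 0.65)`.
#' @param enforce_separation Keep birds at least `min_separation` apart
#'   (steps violating it are resampled or held). Default FALSE.
#' @param min_separation Minimum pairwise distance when enforced, pixels.
#'   Default 45 (just above twice the 20-px match radius).
#' @param seed Integer seed; all scenario randomness flows from it.
#' @return An object of class `bt_sim_params`.
#' @export
sim_params <- function(n_birds = 5, n_frames = 900,
                       p_wander_approach = 0.008,
                       p_feed_leave = 1 / (18.46 * 15),
                       p_leave_wander = 0.05,
                       step_scale = 3, head_w = 24, head_h = 24,
                       head_size_sd = 2, sigma = 2, p_miss = 0.05,
                       fp_rate = 0.1, conf_range = c(0.7, 1),
                       fp_conf_range = c(0.1, 0.65),
                       enforce_separation = FALSE, min_separation = 45,
                       seed = 1L) {
  p <- list(n_birds = as.integer(n_birds), n_frames = as.integer(n_frames),
            p_wander_approach = p_wander_approach,
            p_feed_leave = p_feed_leave, p_leave_wander = p_leave_wander,
            step_scale = step_scale, head_w = head_w, head_h = head_h,
            head_size_sd = head_size_sd, sigma = sigma, p_miss = p_miss,
            fp_rate = fp_rate, conf_range = conf_range,
            fp_conf_range = fp_conf_range,
            enforce_separation = isTRUE(enforce_separation),
            min_separation = min_separation, seed = as.integer(seed))
  probs <- c(p$p_wander_approach, p$p_feed_leave, p$p_leave_wander, p$p_miss)
  if (any(probs < 0) || any(probs > 1))
    stop("behavior and miss probabilities must be in [0, 1]")
  if (p$n_birds < 0) stop("n_birds must be nonnegative")
  if (p$n_frames < 1) stop("n_frames must be at least 1")
  if (p$sigma < 0 || p$fp_rate < 0) stop("noise parameters must be nonnegative")
  structure(p, class = "bt_sim_params")
}

#' Default scene for simulated scenarios
#'
#' An 800x600 px view at 15 fps with the feeder pan circle (radius 60 px) in
#' the image center and a rectangular tracking area 50 px in from the image
#' border.
#'
#' @param ... Overrides forwarded to [scene_config()].
#' @return A [scene_config()].
#' @export
default_scene <- function(...) {
  args <- list(...)
  defaults <- list(fps = 15, image_width = 800, image_height = 600,
                   feeding_area = bt_circle(400, 300, 60),
                   tracking_area = bt_polygon(c(50, 750, 750, 50),
                                              c(50, 50, 550, 550)),
                   params = tracker_params())
  do.call(scene_config, utils::modifyList(defaults, args))
}

# run code under a fixed seed without disturbing the caller's RNG stream
.bt_with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# uniform point inside a polygon by rejection from its bounding box
.bt_runif_polygon <- function(n, poly) {
  xr <- range(poly$x); yr <- range(poly$y)
  px <- numeric(n); py <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::runif(1, xr[1], xr[2]); y <- stats::runif(1, yr[1], yr[2])
      if (.bt_pip1(x, y, poly$x, poly$y)) break
    }
    px[i] <- x; py[i] <- y
  }
  cbind(px, py)
}

# normal step with magnitude capped at cap (resample, then shrink as fallback)
.bt_capped_step <- function(sd, cap) {
  for (k in 1:20) {
    s <- stats::rnorm(2, 0, sd)
    if (sqrt(sum(s^2)) < cap) return(s)
  }
  s * (cap * 0.9 / sqrt(sum(s^2)))
}

#' Generate a synthetic flock scenario
#'
#' @param p A [sim_params()].
#' @param scene A [scene_config()]; the feeding circle must lie inside the
#'   tracking polygon (validated at construction).
#' @return An object of class `bt_scenario` with elements:
#'   `true_tracks` (data.frame `bird_id`, `frame`, `x`, `y`, `w`, `h`),
#'   `true_visits` (data.frame `bird_id`, `start_frame`, `end_frame`,
#'   `n_frames`, `duration_s`; intervals where the true head satisfies the
#'   scene's feeding criterion), `detections` (data.frame `frame`, `x`, `y`,
#'   `w`, `h`, `conf`, `source` where source is the originating bird or 0 for
#'   a false positive), `head_count` (birds that ever appear in the tracking
#'   area), `scene` and `params`. Identical inputs give identical scenarios.
#' @export
simulate_flock <- function(p = sim_params(), scene = default_scene()) {
  stopifnot(inherits(p, "bt_sim_params"), inherits(scene, "bt_scene"))
  .bt_with_seed(p$seed, .bt_simulate_impl(p, scene))
}

.bt_simulate_impl <- function(p, scene) {
  nb <- p$n_birds; nf <- p$n_frames
  circ <- scene$feeding_area
  poly <- scene$tracking_area
  if (nb == 0) {
    # false positives can still occur in an empty pen
    det <- .bt_make_detections(NULL, p, scene)
    return(structure(list(
      true_tracks = data.frame(bird_id = integer(0), frame = integer(0),
                               x = numeric(0), y = numeric(0),
                               w = numeric(0), h = numeric(0)),
      true_visits = .bt_empty_true_visits(),
      detections = det, head_count = 0L, scene = scene, params = p),
      class = "bt_scenario"))
  }

  # per-bird head size and a private spot on the pan where it feeds
  w <- pmax(8, stats::rnorm(nb, p$head_w, p$head_size_sd))
  h <- pmax(8, stats::rnorm(nb, p$head_h, p$head_size_sd))
  ang <- 2 * pi * (seq_len(nb) - 0.5) / nb
  spot_x <- circ$cx + 0.7 * circ$r * cos(ang)
  spot_y <- circ$cy + 0.7 * circ$r * sin(ang)

  # the pan is a physical obstacle: a bird that is not feeding keeps its head
  # clear of the feeder rim (plus half a head), so wandering never grazes it
  obst_r <- circ$r + sqrt(w^2 + h^2) / 2 + 1
  clear_of_pan <- function(b, x, y)
    euclidean_distance(x, y, circ$cx, circ$cy) >= obst_r[b]

  # initial positions: uniform in the tracking area but off the pan,
  # separated if required
  pos <- .bt_runif_polygon(nb, poly)
  for (b in seq_len(nb))
    while (!clear_of_pan(b, pos[b, 1], pos[b, 2]))
      pos[b, ] <- .bt_runif_polygon(1, poly)
  if (p$enforce_separation && nb > 1) {
    for (tries in 1:200) {
      d <- as.matrix(stats::dist(pos))
      bad <- which(apply(d + diag(Inf, nb), 1, min) < p$min_separation)
      if (!length(bad)) break
      for (b in bad) {
        pos[b, ] <- .bt_runif_polygon(1, poly)
        while (!clear_of_pan(b, pos[b, 1], pos[b, 2]))
          pos[b, ] <- .bt_runif_polygon(1, poly)
      }
    }
  }
  state <- rep(1L, nb)  # 1 wander, 2 approach, 3 feed, 4 leave
  cap <- 4 * p$step_scale

  cx <- matrix(NA_real_, nf, nb); cy <- matrix(NA_real_, nf, nb)
  sep_ok <- function(b, x, y) {
    if (!p$enforce_separation || nb == 1) return(TRUE)
    others <- setdiff(seq_len(nb), b)
    all(euclidean_distance(x, y, pos[others, 1], pos[others, 2]) >=
          p$min_separation)
  }
  in_poly <- function(x, y) .bt_pip1(x, y, poly$x, poly$y)

  for (f in seq_len(nf)) {
    for (b in seq_len(nb)) {
      # behavior transitions
      if (state[b] == 1L && stats::runif(1) < p$p_wander_approach)
        state[b] <- 2L
      else if (state[b] == 3L && stats::runif(1) < p$p_feed_leave)
        state[b] <- 4L
      x <- pos[b, 1]; y <- pos[b, 2]
      if (state[b] == 4L &&
          !point_in_circle(x, y, bt_circle(circ$cx, circ$cy, 2.2 * circ$r)) &&
          stats::runif(1) < p$p_leave_wander)
        state[b] <- 1L

      prop <- c(x, y)
      if (state[b] == 1L) {            # wander: bounded walk around the pan
        for (k in 1:20) {
          cand <- c(x, y) + .bt_capped_step(p$step_scale, cap)
          if (in_poly(cand[1], cand[2]) && sep_ok(b, cand[1], cand[2]) &&
              clear_of_pan(b, cand[1], cand[2])) {
            prop <- cand; break
          }
        }
      } else if (state[b] == 2L) {     # approach: biased walk to own spot
        dvec <- c(spot_x[b] - x, spot_y[b] - y)
        dl <- sqrt(sum(dvec^2))
        if (dl <= p$step_scale) {
          cand <- c(spot_x[b], spot_y[b])
          if (sep_ok(b, cand[1], cand[2])) { prop <- cand; state[b] <- 3L }
        } else {
          for (k in 1:20) {
            cand <- c(x, y) + dvec / dl * p$step_scale +
              .bt_capped_step(0.5, 2)
            if (in_poly(cand[1], cand[2]) && sep_ok(b, cand[1], cand[2])) {
              prop <- cand; break
            }
          }
        }
      } else if (state[b] == 3L) {     # feed: hold the spot with small jitter
        for (k in 1:20) {
          cand <- c(spot_x[b], spot_y[b]) + .bt_capped_step(0.8, 3)
          if (sep_ok(b, cand[1], cand[2])) { prop <- cand; break }
        }
      } else {                          # leave: walk away from the pan
        dvec <- c(x - circ$cx, y - circ$cy)
        dl <- max(sqrt(sum(dvec^2)), 1e-6)
        for (k in 1:20) {
          cand <- c(x, y) + dvec / dl * p$step_scale + .bt_capped_step(0.5, 2)
          if (in_poly(cand[1], cand[2]) && sep_ok(b, cand[1], cand[2])) {
            prop <- cand; break
          }
        }
      }
      pos[b, ] <- prop
      cx[f, b] <- prop[1]; cy[f, b] <- prop[2]
    }
  }

  true_tracks <- data.frame(
    bird_id = rep(seq_len(nb), each = nf),
    frame = rep(seq_len(nf) - 1L, nb),
    x = as.vector(cx) - rep(w, each = nf) / 2,
    y = as.vector(cy) - rep(h, each = nf) / 2,
    w = rep(w, each = nf), h = rep(h, each = nf))

  true_visits <- .bt_true_visits(true_tracks, scene)
  det <- .bt_make_detections(true_tracks, p, scene)

  structure(list(true_tracks = true_tracks, true_visits = true_visits,
                 detections = det, head_count = nb,
                 scene = scene, params = p),
            class = "bt_scenario")
}

.bt_empty_true_visits <- function() {
  data.frame(bird_id = integer(0), start_frame = integer(0),
             end_frame = integer(0), n_frames = integer(0),
             duration_s = numeric(0))
}

# ground-truth feeding intervals from the generated geometry: frames where the
# true head box satisfies the scene's feeding criterion, as contiguous runs
.bt_true_visits <- function(true_tracks, scene) {
  if (nrow(true_tracks) == 0) return(.bt_empty_true_visits())
  parts <- lapply(split(true_tracks, true_tracks$bird_id), function(tt) {
    tt <- tt[order(tt$frame), , drop = FALSE]
    feeding <- if (scene$criterion == "center") {
      cen <- bbox_centroid(tt$x, tt$y, tt$w, tt$h)
      point_in_circle(cen$cx, cen$cy, scene$feeding_area)
    } else {
      index_feed(tt$x, tt$y, tt$w, tt$h, scene$feeding_area) > 0
    }
    r <- rle(feeding)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    if (!length(keep)) return(NULL)
    data.frame(bird_id = tt$bird_id[1],
               start_frame = tt$frame[starts[keep]],
               end_frame = tt$frame[ends[keep]],
               n_frames = r$lengths[keep],
               duration_s = r$lengths[keep] / scene$fps)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) return(.bt_empty_true_visits())
  rownames(out) <- NULL
  out
}

# observe true heads through the noisy detector and add false positives
.bt_make_detections <- function(true_tracks, p, scene) {
  rows <- list()
  if (!is.null(true_tracks) && nrow(true_tracks)) {
    tt <- true_tracks[order(true_tracks$frame, true_tracks$bird_id), ,
                      drop = FALSE]
    n <- nrow(tt)
    keep <- stats::runif(n) >= p$p_miss
    jx <- stats::rnorm(n, 0, p$sigma); jy <- stats::rnorm(n, 0, p$sigma)
    conf <- stats::runif(n, p$conf_range[1], p$conf_range[2])
    rows[[1]] <- data.frame(frame = tt$frame, x = tt$x + jx, y = tt$y + jy,
                            w = tt$w, h = tt$h, conf = conf,
                            source = tt$bird_id)[keep, , drop = FALSE]
  }
  # false positives: uniform over the tracking area, low confidence
  nfp <- stats::rpois(p$n_frames, p$fp_rate)
  tot <- sum(nfp)
  if (tot > 0) {
    xy <- .bt_runif_polygon(tot, scene$tracking_area)
    fw <- pmax(8, stats::rnorm(tot, p$head_w, p$head_size_sd))
    fh <- pmax(8, stats::rnorm(tot, p$head_h, p$head_size_sd))
    rows[[length(rows) + 1]] <- data.frame(
      frame = rep(seq_len(p$n_frames) - 1L, nfp),
      x = xy[, 1] - fw / 2, y = xy[, 2] - fh / 2, w = fw, h = fh,
      conf = stats::runif(tot, p$fp_conf_range[1], p$fp_conf_range[2]),
      source = 0L)
  }
  if (!length(rows))
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      w = numeric(0), h = numeric(0), conf = numeric(0),
                      source = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$frame, out$source), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.bt_scenario <- function(x, ...) {
  cat(sprintf(paste0("<bt_scenario: %d birds, %d frames, %d true visits, ",
                     "%d detections>\n"),
              x$params$n_birds, x$params$n_frames, nrow(x$true_visits),
              nrow(x$detections)))
  invisible(x)
}

#' Write a scenario to disk
#'
#' Emits the three files the rest of the toolchain consumes: the noisy
#' detections as MOT-Challenge CSV (`detections.csv`), the ground-truth
#' feeding intervals (`truth_visits.csv`, columns `bird_id`, `start_frame`,
#' `end_frame`), the true head count (`truth_head_count.txt`, one integer)
#' and the scene configuration (`scene.yaml`). All round-trip through the
#' package's readers.
#'
#' @param scenario A [simulate_flock()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "bt_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(detections = file.path(dir, "detections.csv"),
             truth_visits = file.path(dir, "truth_visits.csv"),
             truth_head_count = file.path(dir, "truth_head_count.txt"),
             scene = file.path(dir, "scene.yaml"))
  write_detections_mot(scenario$detections, paths[["detections"]])
  write_truth_visits(scenario$true_visits, paths[["truth_visits"]])
  writeLines(as.character(scenario$head_count), paths[["truth_head_count"]])
  write_scene_config(scenario$scene, paths[["scene"]])
  invisible(paths)
}
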