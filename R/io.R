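# File interchange. Detections travel as MOT-Challenge CSV (frame 1-based in
# file, boxes as left,top,width,height) or per-frame YOLO text (normalized
# center/size); frames are 0-based everywhere inside the package, converted
# only at the file boundary. Numbers are written with 6 decimal places and
# round-trip losslessly at that precision.

.bt_fmt <- function(x) {
  # fixed 6-decimal formatting, no scientific notation, stable across runs
  sub("\\.?0+$", "", formatC(x, format = "f", digits = 6))
}

#' Write detections as MOT-Challenge CSV
#'
#' Rows are `frame,id,x,y,w,h,conf,-1,-1,-1` with 1-based frame numbers and
#' id fixed at -1 (detections carry no identity).
#'
#' @param detections data.frame with columns `frame` (0-based), `x`, `y`,
#'   `w`, `h`, `conf`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_detections_mot <- function(detections, path) {
  .bt_check_detections(detections)
  lines <- if (nrow(detections)) {
    d <- detections[order(detections$frame), , drop = FALSE]
    paste(d$frame + 1L, -1, .bt_fmt(d$x), .bt_fmt(d$y), .bt_fmt(d$w),
          .bt_fmt(d$h), .bt_fmt(d$conf), -1, -1, -1, sep = ",")
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Read detections
#'
#' @param path For `dialect = "mot"`, one CSV file; for `dialect =
#'   "yolo_txt"`, a directory of per-frame text files (`<anything><number>.txt`,
#'   the trailing number being the 1-based frame) with rows
#'   `class cx cy w h [conf]` in coordinates normalized to the image size.
#' @param dialect `"mot"` or `"yolo_txt"`.
#' @param image_size `c(width, height)` in pixels, required to denormalize
#'   the yolo dialect.
#' @return data.frame `frame` (0-based), `x`, `y`, `w`, `h`, `conf`. Frames
#'   absent from the file simply have no rows.
#' @export
read_detections <- function(path, dialect = c("mot", "yolo_txt"),
                            image_size = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "mot") .bt_read_mot(path)
  else .bt_read_yolo(path, image_size)
}

.bt_read_mot <- function(path) {
  if (!file.exists(path)) stop("detection file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      w = numeric(0), h = numeric(0), conf = numeric(0)))
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 7)
  if (length(bad))
    stop(sprintf("malformed MOT row at line %d of %s (need >= 7 fields)",
                 bad[1], path))
  m <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[1:7]), numeric(7)))
  if (anyNA(m)) {
    bad <- which(apply(m, 2, anyNA))[1]
    stop(sprintf("non-numeric field at line %d of %s", bad, path))
  }
  det <- data.frame(frame = as.integer(m[1, ]) - 1L, x = m[3, ], y = m[4, ],
                    w = m[5, ], h = m[6, ], conf = m[7, ])
  if (any(det$frame < 0))
    stop("MOT frame numbers must be >= 1 (file is 1-based)")
  neg <- which(det$w <= 0 | det$h <= 0)
  if (length(neg))
    stop(sprintf("non-positive box extent at line %d of %s", neg[1], path))
  det[order(det$frame), , drop = FALSE]
}

.bt_read_yolo <- function(path, image_size) {
  if (is.null(image_size) || length(image_size) != 2)
    stop("image_size = c(width, height) is required for the yolo_txt dialect")
  if (!dir.exists(path)) stop("yolo_txt expects a directory: ", path)
  files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
  if (!length(files)) stop("no .txt files in ", path)
  nums <- suppressWarnings(
    as.integer(sub(".*?([0-9]+)\\.txt$", "\\1", basename(files))))
  if (anyNA(nums))
    stop("yolo_txt file names must end in a frame number, e.g. frame_0001.txt")
  out <- lapply(seq_along(files), function(i) {
    lines <- readLines(files[i])
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(NULL)
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    len <- vapply(parts, length, integer(1))
    if (any(len < 5))
      stop(sprintf("malformed yolo row at line %d of %s",
                   which(len < 5)[1], files[i]))
    vals <- lapply(parts, function(p) suppressWarnings(as.numeric(p)))
    if (anyNA(unlist(vals)))
      stop("non-numeric field in ", files[i])
    cx <- vapply(vals, `[`, numeric(1), 2) * image_size[1]
    cy <- vapply(vals, `[`, numeric(1), 3) * image_size[2]
    w <- vapply(vals, `[`, numeric(1), 4) * image_size[1]
    h <- vapply(vals, `[`, numeric(1), 5) * image_size[2]
    conf <- vapply(vals, function(v) if (length(v) >= 6) v[6] else 1,
                   numeric(1))
    if (any(w <= 0) || any(h <= 0))
      stop("non-positive box extent in ", files[i])
    data.frame(frame = nums[i] - 1L, x = cx - w / 2, y = cy - h / 2,
               w = w, h = h, conf = conf)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      w = numeric(0), h = numeric(0), conf = numeric(0)))
  out <- out[order(out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read ground-truth feeding intervals
#'
#' CSV with header `bird_id,start_frame,end_frame` (0-based, inclusive).
#'
#' @param visits data.frame with at least `bird_id`/`track_id`,
#'   `start_frame`, `end_frame`.
#' @param path File path.
#' @return `write_truth_visits` invisibly returns `path`;
#'   `read_truth_visits` returns a data.frame `bird_id`, `start_frame`,
#'   `end_frame`.
#' @export
write_truth_visits <- function(visits, path) {
  id <- if ("bird_id" %in% names(visits)) visits$bird_id else visits$track_id
  df <- data.frame(bird_id = id, start_frame = visits$start_frame,
                   end_frame = visits$end_frame)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_visits
#' @export
read_truth_visits <- function(path) {
  if (!file.exists(path)) stop("ground-truth file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("bird_id", "start_frame", "end_frame")
  if (!all(need %in% names(df)))
    stop("ground-truth file needs columns ", paste(need, collapse = ", "))
  if (nrow(df) && any(df$end_frame < df$start_frame))
    stop("ground-truth intervals must have start_frame <= end_frame")
  df[need]
}

#' Write / read an estimated visit table
#'
#' CSV with header `track_id,start_frame,end_frame,n_frames,duration_s`.
#'
#' @param visits Visit table from [segment_all_visits()].
#' @param path File path.
#' @return `write_visits` invisibly returns `path`; `read_visits` the table.
#' @export
write_visits <- function(visits, path) {
  df <- visits
  df$duration_s <- .bt_fmt(df$duration_s)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_visits
#' @export
read_visits <- function(path) {
  if (!file.exists(path)) stop("visit file not found: ", path)
  utils::read.csv(path)
}

#' Write a report as JSON
#'
#' @param report A list (e.g. an evaluation report or per-bird summary).
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  if (inherits(report, "bt_eval_report")) report <- unclass(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
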