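# Scene-configuration files. The on-disk format is a small YAML subset --
# two-level maps of scalars plus inline numeric lists -- which is all the
# schema needs; no external YAML parser is required. Example:
#
#   fps: 15
#   image_width: 800
#   image_height: 600
#   criterion: area
#   gap_tolerance: 0
#   feeding_area:
#     cx: 400
#     cy: 300
#     r: 60
#   tracking_area:
#     x: [50, 750, 750, 50]
#     y: [50, 50, 550, 550]
#   tracker:
#     match_radius: 20
#     max_missed: 10
#     history_length: 10
#     min_confidence: 0.5

.bt_yaml_scalar <- function(s) {
  s <- trimws(s)
  if (grepl("^\\[.*\\]$", s)) {
    inner <- trimws(sub("^\\[(.*)\\]$", "\\1", s))
    if (!nzchar(inner)) return(numeric(0))
    v <- suppressWarnings(as.numeric(strsplit(inner, ",")[[1]]))
    if (anyNA(v)) stop("non-numeric list entry in config: ", s)
    return(v)
  }
  n <- suppressWarnings(as.numeric(s))
  if (!is.na(n)) return(n)
  if (s %in% c("true", "True", "yes")) return(TRUE)
  if (s %in% c("false", "False", "no")) return(FALSE)
  gsub("^['\"]|['\"]$", "", s)
}

# parse the restricted YAML subset into a nested list
.bt_read_yamlish <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  section <- NULL
  for (i in seq_along(lines)) {
    line <- lines[i]
    indented <- grepl("^\\s+", line)
    m <- regmatches(line, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:(.*)$",
                                  line))[[1]]
    if (!length(m))
      stop(sprintf("cannot parse config line %d: '%s'", i, line))
    key <- m[2]; val <- trimws(m[3])
    if (!indented) {
      if (nzchar(val)) {
        out[[key]] <- .bt_yaml_scalar(val)
        section <- NULL
      } else {
        out[[key]] <- list()
        section <- key
      }
    } else {
      if (is.null(section))
        stop(sprintf("indented config line %d without a section: '%s'",
                     i, line))
      if (!nzchar(val))
        stop("config nesting deeper than two levels is not supported")
      out[[section]][[key]] <- .bt_yaml_scalar(val)
    }
  }
  out
}

.bt_yaml_num <- function(x) {
  if (is.logical(x)) return(tolower(as.character(x)))
  if (is.character(x)) return(x)
  v <- vapply(x, function(n)
    if (n == round(n) && abs(n) < 1e15) sprintf("%d", as.integer(n))
    else .bt_fmt(n), character(1))
  v
}

#' Read and write scene-configuration files
#'
#' The file is a flat YAML-style document (see the package vignette for the
#' schema). Omitted keys take the package defaults: fps 15, match radius 20,
#' missed-frame expiry 10, history 10, minimum confidence 0.5, gap tolerance
#' 0, criterion `"area"`. `feeding_area` is required; `tracking_area`
#' defaults to the full image rectangle.
#'
#' @param path File path.
#' @return `load_scene_config` returns a validated [scene_config()];
#'   `write_scene_config` invisibly returns `path`.
#' @export
load_scene_config <- function(path) {
  raw <- .bt_read_yamlish(path)
  if (is.null(raw$feeding_area))
    stop("config must define feeding_area (cx, cy, r)")
  fa <- raw$feeding_area
  if (!all(c("cx", "cy", "r") %in% names(fa)))
    stop("feeding_area needs cx, cy and r")
  if (is.null(raw$image_width) || is.null(raw$image_height))
    stop("config must define image_width and image_height")
  circ <- bt_circle(fa$cx, fa$cy, fa$r)
  poly <- if (!is.null(raw$tracking_area)) {
    ta <- raw$tracking_area
    if (is.null(ta$x) || is.null(ta$y))
      stop("tracking_area needs x and y vertex lists")
    bt_polygon(ta$x, ta$y)
  } else {
    bt_polygon(c(0, raw$image_width, raw$image_width, 0),
               c(0, 0, raw$image_height, raw$image_height))
  }
  tr <- if (is.null(raw$tracker)) list() else raw$tracker
  params <- tracker_params(
    match_radius = if (is.null(tr$match_radius)) 20 else tr$match_radius,
    max_missed = if (is.null(tr$max_missed)) 10 else tr$max_missed,
    history_length = if (is.null(tr$history_length)) 10
                     else tr$history_length,
    min_confidence = if (is.null(tr$min_confidence)) 0.5
                     else tr$min_confidence)
  scene_config(
    fps = if (is.null(raw$fps)) 15 else raw$fps,
    image_width = raw$image_width, image_height = raw$image_height,
    feeding_area = circ, tracking_area = poly, params = params,
    criterion = if (is.null(raw$criterion)) "area" else raw$criterion,
    gap_tolerance = if (is.null(raw$gap_tolerance)) 0 else raw$gap_tolerance)
}

#' @rdname load_scene_config
#' @param cfg A [scene_config()] to serialize.
#' @export
write_scene_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "bt_scene"))
  p <- cfg$params
  lines <- c(
    paste0("fps: ", .bt_yaml_num(cfg$fps)),
    paste0("image_width: ", .bt_yaml_num(cfg$image_width)),
    paste0("image_height: ", .bt_yaml_num(cfg$image_height)),
    paste0("criterion: ", cfg$criterion),
    paste0("gap_tolerance: ", .bt_yaml_num(cfg$gap_tolerance)),
    "feeding_area:",
    paste0("  cx: ", .bt_yaml_num(cfg$feeding_area$cx)),
    paste0("  cy: ", .bt_yaml_num(cfg$feeding_area$cy)),
    paste0("  r: ", .bt_yaml_num(cfg$feeding_area$r)),
    "tracking_area:",
    paste0("  x: [", paste(.bt_yaml_num(cfg$tracking_area$x),
                           collapse = ", "), "]"),
    paste0("  y: [", paste(.bt_yaml_num(cfg$tracking_area$y),
                           collapse = ", "), "]"),
    "tracker:",
    paste0("  match_radius: ", .bt_yaml_num(p$match_radius)),
    paste0("  max_missed: ", .bt_yaml_num(p$max_missed)),
    paste0("  history_length: ", .bt_yaml_num(p$history_length)),
    paste0("  min_confidence: ", .bt_yaml_num(p$min_confidence)))
  writeLines(lines, path)
  invisible(path)
}
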