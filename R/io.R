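# File ingestion and export: polyline and rating CSVs, a JSON results
# container with provenance fields, and SVG path export of fitted curves.

#' Read a polyline from CSV
#'
#' Expects a header with columns `x` and `y` (in px). Extra columns are
#' ignored with a warning. Image-derived coordinates (y growing downward)
#' can be flipped to the internal y-up convention.
#'
#' @param path CSV file path.
#' @param y_flip If `TRUE`, negate y on import (image coordinates).
#' @return An m x 2 numeric matrix with columns `x`, `y` (m >= 8).
#' @export
read_polyline_csv <- function(path, y_flip = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(read.csv(path),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  if (nrow(df) == 0) stop("empty polyline file: ", path)
  if (!all(c("x", "y") %in% names(df)))
    stop("polyline CSV needs columns x and y")
  extra <- setdiff(names(df), c("x", "y"))
  if (length(extra))
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "))
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad))
    stop(sprintf("malformed coordinate in %s at data row %d", path, bad[1]))
  pts <- cbind(x = x, y = if (y_flip) -y else y)
  as_polyline(pts)
}

#' Write a polyline to CSV
#'
#' @param points An m x 2 matrix or data frame of (x, y) points.
#' @param path Output file path.
#' @export
write_polyline_csv <- function(points, path) {
  pts <- as_polyline(points)
  write.csv(as.data.frame(pts), path, row.names = FALSE)
}

#' Read long-format ratings (and optionally choices) from CSV
#'
#' @param ratings_path CSV with columns `subject`, `line`, `rating`.
#' @param choices_path Optional CSV with columns `subject`, `choice`.
#' @return A `rating_dataset`.
#' @export
read_ratings_csv <- function(ratings_path, choices_path = NULL) {
  if (!file.exists(ratings_path)) stop("file not found: ", ratings_path)
  ratings <- read.csv(ratings_path)
  choices <- NULL
  if (!is.null(choices_path)) {
    if (!file.exists(choices_path)) stop("file not found: ", choices_path)
    choices <- read.csv(choices_path)
  }
  rating_dataset(ratings, choices)
}

# Recursively replace Inf/-Inf with string sentinels (and back).
encode_inf <- function(x) {
  if (is.list(x)) return(lapply(x, encode_inf))
  if (is.numeric(x) && any(is.infinite(x))) {
    x <- as.list(x)
    x[vapply(x, function(v) is.infinite(v) && v > 0, logical(1))] <- "inf"
    x[vapply(x, function(v) is.numeric(v) && is.infinite(v) && v < 0,
             logical(1))] <- "-inf"
  }
  x
}

decode_inf <- function(x) {
  if (is.list(x)) {
    out <- lapply(x, decode_inf)
    if (all(vapply(out, function(v) is.numeric(v) && length(v) == 1,
                   logical(1))) && length(out) > 0 && is.null(names(out)))
      return(unlist(out))
    return(out)
  }
  if (is.character(x)) {
    x[x == "inf"] <- Inf
    x[x == "-inf"] <- -Inf
    num <- suppressWarnings(as.numeric(x))
    if (!anyNA(num)) return(num)
  }
  x
}

#' Write analysis results to JSON
#'
#' Serializes a (possibly nested) list of results with stable key order,
#' 12 significant digits, package version and the seed used, so that two
#' runs with identical inputs produce byte-identical files. Infinite radii
#' are stored as the sentinel string `"inf"`.
#'
#' @param results A named list (classed results objects are unclassed).
#' @param path Output path.
#' @param seed Seed recorded for provenance (may be `NULL`).
#' @export
write_results_json <- function(results, path, seed = NULL) {
  strip <- function(x) {
    if (is.object(x) && is.list(x)) x <- unclass(x)
    if (is.data.frame(x)) x <- as.list(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  payload <- list(package = "hogarth",
                  version = as.character(utils::packageVersion("hogarth")),
                  seed = seed,
                  results = encode_inf(strip(results)))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(12),
                              null = "null", pretty = TRUE), con)
  invisible(path)
}

#' Read back a JSON results file
#'
#' @param path File written by [write_results_json()].
#' @return The `results` list, with `"inf"` sentinels restored to `Inf`.
#'   Provenance fields are attached as attributes `version` and `seed`.
#' @export
read_results_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- decode_inf(raw$results)
  attr(out, "version") <- raw$version
  attr(out, "seed") <- raw$seed
  out
}

#' Export a composite curve as an SVG path
#'
#' Writes a minimal SVG 1.1 document containing one `path` whose `d`
#' attribute is an `M` command followed by one cubic `C` command per
#' segment. The y axis is flipped to SVG's y-down convention.
#'
#' @param curve A `composite_bezier`.
#' @param path Output file path.
#' @param digits Coordinate precision (default 6).
#' @return The `d` attribute string, invisibly.
#' @export
export_svg_path <- function(curve, path, digits = 6) {
  curve <- as_composite(curve)
  fmt <- function(p) sprintf(paste0("%.", digits, "f,%.", digits, "f"),
                             p[1], -p[2])
  d <- paste0("M ", fmt(curve[[1]][1, ]))
  for (seg in curve)
    d <- paste(d, "C", fmt(seg[2, ]), fmt(seg[3, ]), fmt(seg[4, ]))
  all_pts <- do.call(rbind, lapply(curve, unclass))
  x0 <- min(all_pts[, 1]) - 10; x1 <- max(all_pts[, 1]) + 10
  y0 <- min(-all_pts[, 2]) - 10; y1 <- max(-all_pts[, 2]) + 10
  svg <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" viewBox="%g %g %g %g">',
            x0, y0, x1 - x0, y1 - y0),
    sprintf('  <path d="%s" fill="none" stroke="black" stroke-width="2"/>', d),
    '</svg>')
  writeLines(svg, path)
  invisible(d)
}
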