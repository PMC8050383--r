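# Landmark file I/O: CSV (header name,x,y,z) and JSON
# ({"frame": ..., "points": [{"name":..., "x":..., "y":..., "z":...}]}).

#' Read an ordered landmark set
#'
#' Order is preserved exactly as in the file; names must be unique. When
#' `expected_count` is given (the clinical protocol uses 18 control
#' points) a mismatch is an error.
#'
#' @param path CSV (`name,x,y,z`) or JSON file.
#' @param expected_count required number of points, or `NULL` to skip the
#'   check.
#' @param frame frame label (`"preop"`/`"postop"`); JSON input may carry
#'   its own.
#' @return A `landmark_set`.
#' @export
read_landmarks <- function(path, expected_count = NULL, frame = "preop") {
  if (!file.exists(path)) stopf("landmark file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    pts <- j$points
    if (is.null(pts)) stopf("JSON landmark file lacks a 'points' array: %s", path)
    lm <- landmark_set(cbind(pts$x, pts$y, pts$z), pts$name, j$frame %||% frame)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("name", "x", "y", "z")
    if (!all(need %in% names(df)))
      stopf("landmark CSV must have columns name,x,y,z: %s", path)
    lm <- landmark_set(as.matrix(df[, c("x", "y", "z")]), df$name, frame)
  }
  if (!is.null(expected_count) && nrow(lm$points) != expected_count)
    stopf("expected %d landmarks, found %d in %s",
          expected_count, nrow(lm$points), path)
  lm
}

#' Write a landmark set
#'
#' @param landmarks a `landmark_set`.
#' @param path output path; `.json` writes JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  p <- landmarks$points
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(
      list(frame = landmarks$frame,
           points = data.frame(name = rownames(p), x = p[, 1], y = p[, 2], z = p[, 3])),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(data.frame(name = rownames(p), x = p[, 1], y = p[, 2], z = p[, 3]),
              path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
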