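# Triangle-mesh file I/O: binary/ASCII STL, ASCII PLY (with optional
# per-face scalar), and OBJ. All formats carry coordinates in mm.

#' Write a surface mesh to file
#'
#' @param mesh a `surface_mesh`.
#' @param path output file path.
#' @param format `"stl"` (binary, deterministic byte-for-byte),
#'   `"stl_ascii"`, `"ply"` (ASCII), or `"obj"`. Defaults from the file
#'   extension.
#' @param face_scalar optional numeric vector (one value per face) written
#'   as a `quality` face property (PLY only), e.g. a thickness map.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, face_scalar = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  format <- format %||% tolower(tools::file_ext(path))
  V <- mesh$vertices
  F <- mesh$faces
  switch(format,
    stl = {
      con <- file(path, "wb")
      on.exit(close(con))
      header <- charToRaw(formatC("canal3d binary STL", width = -80))
      writeBin(header[1:80], con)
      writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
      tri <- array(0, c(3, 3, nrow(F)))
      for (f in seq_len(nrow(F))) {
        a <- V[F[f, 1], ]; b <- V[F[f, 2], ]; c3 <- V[F[f, 3], ]
        n <- crossprod3(b - a, c3 - a)
        n <- n / max(vnorm(n), 1e-300)
        writeBin(as.numeric(c(n, a, b, c3)), con, size = 4, endian = "little")
        writeBin(as.integer(0), con, size = 2, endian = "little")
      }
    },
    stl_ascii = {
      lines <- c("solid canal3d")
      for (f in seq_len(nrow(F))) {
        a <- V[F[f, 1], ]; b <- V[F[f, 2], ]; c3 <- V[F[f, 3], ]
        n <- crossprod3(b - a, c3 - a)
        n <- n / max(vnorm(n), 1e-300)
        lines <- c(lines,
          sprintf(" facet normal %.17g %.17g %.17g", n[1], n[2], n[3]),
          "  outer loop",
          sprintf("   vertex %.17g %.17g %.17g", c(a[1], b[1], c3[1]),
                  c(a[2], b[2], c3[2]), c(a[3], b[3], c3[3])),
          "  endloop", " endfacet")
      }
      writeLines(c(lines, "endsolid canal3d"), path)
    },
    ply = {
      head <- c("ply", "format ascii 1.0", "comment canal3d",
                sprintf("element vertex %d", nrow(V)),
                "property double x", "property double y", "property double z",
                sprintf("element face %d", nrow(F)),
                "property list uchar int vertex_indices")
      if (!is.null(face_scalar)) {
        if (length(face_scalar) != nrow(F))
          stopf("face_scalar must have one value per face")
        head <- append(head, "property double quality")
      }
      head <- c(head, "end_header")
      vl <- sprintf("%.17g %.17g %.17g", V[, 1], V[, 2], V[, 3])
      fl <- sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L)
      if (!is.null(face_scalar))
        fl <- paste(fl, sprintf("%.17g", face_scalar))
      writeLines(c(head, vl, fl), path)
    },
    obj = {
      writeLines(c("# canal3d",
                   sprintf("v %.17g %.17g %.17g", V[, 1], V[, 2], V[, 3]),
                   sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3])), path)
    },
    stopf("unsupported mesh format '%s'", format)
  )
  invisible(path)
}

#' Read a surface mesh from file
#'
#' Reads STL (binary or ASCII; coincident vertices are merged), ASCII PLY,
#' or OBJ. Non-triangular faces are an error.
#'
#' @param path file path.
#' @param format override the extension-derived format.
#' @return A `surface_mesh`.
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stopf("mesh file not found: %s", path)
  format <- format %||% tolower(tools::file_ext(path))
  if (file.info(path)$size == 0) stopf("mesh file is empty: %s", path)
  switch(format,
    stl = read_stl(path),
    stl_ascii = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path),
    stopf("unsupported mesh format '%s'", format)
  )
}

read_stl <- function(path) {
  # sniff binary vs ascii
  head <- readBin(path, "raw", n = 512)
  head <- head[head >= as.raw(0x20) & head < as.raw(0x7f)]
  txt <- rawToChar(head)
  is_ascii <- grepl("^\\s*solid", txt, useBytes = TRUE) &&
    grepl("facet", txt, useBytes = TRUE)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0) stopf("malformed ASCII STL: %s", path)
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (!length(nf) || nf <= 0) stopf("malformed binary STL: %s", path)
    expect <- 84 + nf * 50
    if (file.info(path)$size < expect) stopf("truncated binary STL: %s", path)
    coords <- matrix(NA_real_, nf * 3, 3)
    for (f in seq_len(nf)) {
      rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      readBin(con, "raw", n = 2)
      coords[(3 * f - 2):(3 * f), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  }
  dedupe_triangles(coords)
}

dedupe_triangles <- function(coords) {
  key <- paste(format(coords[, 1], digits = 17),
               format(coords[, 2], digits = 17),
               format(coords[, 3], digits = 17))
  ids <- match(key, unique(key))
  verts <- coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(ids, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || lines[1] != "ply") stopf("not a PLY file: %s", path)
  if (!any(grepl("^format ascii", lines))) stopf("only ASCII PLY is supported: %s", path)
  endh <- match("end_header", lines)
  if (is.na(endh)) stopf("malformed PLY (no end_header): %s", path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  if (!length(nv) || !length(nf)) stopf("malformed PLY header: %s", path)
  vl <- lines[(endh + 1):(endh + nv)]
  fl <- lines[(endh + nv + 1):(endh + nv + nf)]
  V <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p) as.numeric(p[1:3])))
  fp <- strsplit(fl, "\\s+")
  if (any(vapply(fp, function(p) as.integer(p[1]), integer(1)) != 3L))
    stopf("non-triangular faces in PLY: %s", path)
  F <- do.call(rbind, lapply(fp, function(p) as.integer(p[2:4]))) + 1L
  mesh <- surface_mesh(V, F)
  qual <- vapply(fp, function(p) if (length(p) >= 5) as.numeric(p[5]) else NA_real_,
                 numeric(1))
  if (!all(is.na(qual))) attr(mesh, "face_scalar") <- qual
  mesh
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  if (!length(vl) || !length(fl)) stopf("malformed OBJ: %s", path)
  V <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p) as.numeric(p[2:4])))
  fp <- strsplit(fl, "\\s+")
  if (any(lengths(fp) != 4L)) stopf("non-triangular faces in OBJ: %s", path)
  F <- do.call(rbind, lapply(fp, function(p) as.integer(sub("/.*", "", p[2:4]))))
  surface_mesh(V, F)
}
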