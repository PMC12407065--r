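#' Read a triangulated mesh or vertex cloud
#'
#' Minimal readers for the three mesh formats used for segmented skeletal
#' scans: Wavefront OBJ, PLY (ascii and binary little/big endian) and STL
#' (ascii and binary). Only vertex coordinates are consumed downstream (the
#' hulling step needs points, not surfaces), but OBJ/PLY triangle indices are
#' returned when present. Meshes need not be watertight or manifold.
#'
#' @param path mesh file; format chosen by extension (`.obj`, `.ply`, `.stl`,
#'   case-insensitive).
#' @return list with `vertices` (n x 3 matrix) and `faces` (m x 3 integer
#'   matrix or `NULL`).
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  out <- switch(ext,
                obj = .read_obj(path),
                ply = .read_ply(path),
                stl = .read_stl(path),
                stop("unsupported mesh format '.", ext, "': ", path, call. = FALSE))
  out$vertices <- .as_vertex_matrix(out$vertices, paste0("vertices in ", path))
  out
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  verts <- NULL
  if (length(vl) > 0L) {
    toks <- strsplit(trimws(sub("^v", "", vl)), "\\s+")
    verts <- t(vapply(toks, function(t) as.numeric(t[1:3]), numeric(3)))
  }
  fl <- lines[startsWith(lines, "f ")]
  faces <- NULL
  if (length(fl) > 0L) {
    toks <- strsplit(trimws(sub("^f", "", fl)), "\\s+")
    idx <- lapply(toks, function(t) as.integer(sub("/.*$", "", t)))
    # fan-triangulate polygons
    tris <- lapply(idx, function(ii) {
      if (length(ii) < 3L) return(NULL)
      cbind(ii[1L], ii[2:(length(ii) - 1L)], ii[3:length(ii)])
    })
    faces <- do.call(rbind, tris)
  }
  list(vertices = verts, faces = faces)
}

.read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", 80L)
  is_ascii <- identical(rawToChar(head80[1:5]), "solid") &&
    grepl("facet", suppressWarnings(
      paste(readLines(path, n = 20L, warn = FALSE), collapse = " ")))
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    toks <- strsplit(trimws(sub("vertex", "", vl)), "\\s+")
    verts <- t(vapply(toks, function(t) as.numeric(t[1:3]), numeric(3)))
  } else {
    ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    rec <- readBin(con, "raw", 50L * ntri)
    # each 50-byte record: 12 float32 (normal + 3 vertices) + uint16 attribute
    m <- matrix(rec, nrow = 50L)
    vbytes <- as.raw(m[13:48, ])  # drop normal (1:12) and attribute (49:50)
    fl <- readBin(vbytes, "numeric", 9L * ntri, size = 4L, endian = "little")
    verts <- matrix(fl, ncol = 3L, byrow = TRUE)
  }
  list(vertices = verts, faces = NULL)
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ascii, terminated by end_header
  hdr <- character()
  repeat {
    ln <- .read_bin_line(con)
    hdr <- c(hdr, ln)
    if (identical(trimws(ln), "end_header")) break
    if (length(hdr) > 1000L) stop("malformed PLY header: ", path, call. = FALSE)
  }
  fmt_line <- grep("^format\\s", hdr, value = TRUE)[1L]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1L]][2L]
  elements <- list(); cur <- NULL
  for (ln in hdr) {
    t <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (t[1L] == "element") {
      cur <- t[2L]
      elements[[cur]] <- list(count = as.integer(t[3L]), props = list())
    } else if (t[1L] == "property" && !is.null(cur)) {
      elements[[cur]]$props <- c(elements[[cur]]$props, list(t[-1L]))
    }
  }
  if (is.null(elements$vertex)) stop("PLY without vertex element: ", path, call. = FALSE)
  nv <- elements$vertex$count
  props <- elements$vertex$props
  pnames <- vapply(props, function(p) p[length(p)], "")
  xyz <- match(c("x", "y", "z"), pnames)
  if (any(is.na(xyz))) stop("PLY vertex element lacks x/y/z: ", path, call. = FALSE)

  if (fmt == "ascii") {
    lines <- vapply(seq_len(nv), function(i) .read_bin_line(con), "")
    toks <- strsplit(trimws(lines), "\\s+")
    verts <- t(vapply(toks, function(t) as.numeric(t[xyz]), numeric(3)))
    faces <- NULL
    if (!is.null(elements$face)) {
      fl <- vapply(seq_len(elements$face$count), function(i) .read_bin_line(con), "")
      ft <- strsplit(trimws(fl), "\\s+")
      tris <- lapply(ft, function(t) {
        k <- as.integer(t[1L]); ii <- as.integer(t[2:(1L + k)]) + 1L
        if (k < 3L) return(NULL)
        cbind(ii[1L], ii[2:(k - 1L)], ii[3:k])
      })
      faces <- do.call(rbind, tris)
    }
    return(list(vertices = verts, faces = faces))
  }

  endian <- if (fmt == "binary_little_endian") "little" else "big"
  sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
             short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
             int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
             float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  types <- vapply(props, `[[`, "", 1L)
  if (any(types == "list")) stop("list property in PLY vertex element: ", path, call. = FALSE)
  sz <- sizes[types]
  if (any(is.na(sz))) stop("unsupported PLY property type: ", path, call. = FALSE)
  stride <- sum(sz)
  buf <- readBin(con, "raw", stride * nv)
  offs <- cumsum(c(0L, sz))[seq_along(sz)]
  read_prop <- function(j) {
    pos <- as.vector(outer(seq_len(sz[j]), stride * (seq_len(nv) - 1L) + offs[j], `+`))
    b <- buf[pos]
    what <- if (types[j] %in% c("float", "float32", "double", "float64")) "numeric" else "integer"
    readBin(b, what, nv, size = sz[j], endian = endian,
            signed = !(types[j] %in% c("uchar", "uint8", "ushort", "uint16")))
  }
  verts <- cbind(read_prop(xyz[1L]), read_prop(xyz[2L]), read_prop(xyz[3L]))
  list(vertices = verts, faces = NULL)  # binary faces not needed downstream
}

.read_bin_line <- function(con) {
  chars <- raw()
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L || b == as.raw(10L)) break
    if (b != as.raw(13L)) chars <- c(chars, b)
  }
  rawToChar(chars)
}

#' Write vertices (and optional triangles) as Wavefront OBJ
#'
#' @param vertices n x 3 matrix.
#' @param path output path.
#' @param faces optional m x 3 integer triangle matrix (1-based).
#' @return `path`, invisibly.
#' @export
write_obj_mesh <- function(vertices, path, faces = NULL) {
  vertices <- .as_vertex_matrix(vertices)
  vl <- sprintf("v %.17g %.17g %.17g", vertices[, 1L], vertices[, 2L], vertices[, 3L])
  fl <- if (!is.null(faces)) sprintf("f %d %d %d", faces[, 1L], faces[, 2L], faces[, 3L])
  writeLines(c(vl, fl), path)
  invisible(path)
}
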