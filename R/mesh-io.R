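#' Construct a triangle mesh
#'
#' @param vertices Numeric matrix, n x 3, coordinates in mm.
#' @param faces Integer matrix, m x 3, 1-based vertex indices.
#' @param colors Optional n x 3 matrix of per-vertex RGB values in 0..255
#'   (kept for visualization only; never used in measurement).
#' @return An object of class `naso_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, colors = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (is.null(faces) || length(faces) == 0L || nrow(as.matrix(faces)) < 1L)
    stop("mesh validation: mesh has no faces")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (!all(is.finite(vertices))) stop("mesh validation: non-finite vertex coordinates")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("mesh validation: face index out of range")
  # drop exactly degenerate faces (repeated vertex or zero area)
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  cr <- cross3_rows(b - a, c_ - a)
  area2 <- sqrt(rowSums(cr * cr))
  keep <- area2 > 0
  if (!any(keep)) stop("mesh validation: all faces are degenerate (zero area)")
  faces <- faces[keep, , drop = FALSE]
  structure(list(vertices = vertices, faces = faces, colors = colors),
            class = "naso_mesh")
}

#' @export
print.naso_mesh <- function(x, ...) {
  cat(sprintf("<naso_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$colors)) "" else ", vertex colors"))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [mm]: x %.2f..%.2f  y %.2f..%.2f  z %.2f..%.2f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

cross3_rows <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Read a triangle mesh (PLY, OBJ or STL)
#'
#' Coordinates are assumed to be millimetres; there is no unit
#' auto-detection. PLY may be ascii or binary_little_endian; OBJ and STL
#' (ascii or binary) carry geometry only. Per-vertex RGB colors in PLY files
#' are preserved for visualization. Quads in OBJ files are fanned into
#' triangles.
#'
#' @param path Path to a `.ply`, `.obj` or `.stl` file.
#' @return A validated `naso_mesh`.
#' @export
load_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
              ply = read_ply(path),
              obj = read_obj(path),
              stl = read_stl(path),
              stop("unsupported mesh format: .", ext, " (expected PLY, OBJ or STL)"))
  triangle_mesh(m$vertices, m$faces, colors = m$colors)
}

#' Write a triangle mesh as ascii PLY
#'
#' @param mesh A `naso_mesh`.
#' @param path Output `.ply` path.
#' @param digits Significant digits for coordinates (default 17: exact
#'   double round-trip).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, digits = 17) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  has_col <- !is.null(mesh$colors)
  hdr <- c("ply", "format ascii 1.0", "comment naso3d export",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           if (has_col) c("property uchar red", "property uchar green",
                          "property uchar blue"),
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  vl <- apply(v, 1, function(r) paste(formatC(r, digits = digits, format = "g"),
                                      collapse = " "))
  if (has_col)
    vl <- paste(vl, apply(mesh$colors, 1, paste, collapse = " "))
  fl <- apply(f, 1, function(r) paste(c(3L, r), collapse = " "))
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ascii lines
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("format error: truncated PLY header")
    hdr <- c(hdr, ln)
    if (trimws(ln) == "end_header") break
  }
  if (trimws(hdr[1]) != "ply") stop("format error: not a PLY file")
  fmt_ln <- grep("^format", trimws(hdr), value = TRUE)
  if (!length(fmt_ln)) stop("format error: PLY missing format line")
  fmt <- strsplit(trimws(fmt_ln[1]), "\\s+")[[1]][2]
  toks <- strsplit(trimws(hdr), "\\s+")
  elems <- list(); cur <- NULL
  for (tk in toks) {
    if (tk[1] == "element") {
      cur <- tk[2]
      elems[[cur]] <- list(n = as.integer(tk[3]), props = list())
    } else if (tk[1] == "property" && !is.null(cur)) {
      elems[[cur]]$props[[length(elems[[cur]]$props) + 1L]] <- tk[-1]
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face))
    stop("format error: PLY lacks vertex or face element")
  if (fmt == "ascii") read_ply_ascii(con, elems)
  else if (fmt == "binary_little_endian") read_ply_binary(con, elems, "little")
  else if (fmt == "binary_big_endian") read_ply_binary(con, elems, "big")
  else stop("format error: unsupported PLY format '", fmt, "'")
}

ply_type_size <- function(t) {
  switch(t, char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
         short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
         int = 4L, uint = 4L, int32 = 4L, uint32 = 4L, float = 4L,
         float32 = 4L, double = 8L, float64 = 8L,
         stop("format error: unknown PLY type ", t))
}
ply_read_one <- function(con, t, endian) {
  sz <- ply_type_size(t)
  if (t %in% c("float", "float32", "double", "float64"))
    readBin(con, "double", 1L, size = sz, endian = endian)
  else
    readBin(con, "integer", 1L, size = sz, endian = endian,
            signed = !(t %in% c("uchar", "uint8", "ushort", "uint16")))
}

read_ply_ascii <- function(con, elems) {
  body <- readLines(con)
  body <- body[nzchar(trimws(body))]
  i <- 0L
  out <- list()
  for (en in names(elems)) {
    el <- elems[[en]]
    if (el$n == 0L) next
    rows <- body[(i + 1L):(i + el$n)]
    i <- i + el$n
    if (en == "vertex") {
      pnames <- vapply(el$props, function(p) p[length(p)], "")
      vals <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
      colnames(vals) <- pnames
      out$vertices <- vals[, c("x", "y", "z"), drop = FALSE]
      if (all(c("red", "green", "blue") %in% pnames))
        out$colors <- vals[, c("red", "green", "blue"), drop = FALSE]
    } else if (en == "face") {
      fl <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
      out$faces <- do.call(rbind, lapply(fl, function(r) {
        k <- r[1]
        idx <- r[1 + seq_len(k)] + 1
        if (k == 3) rbind(idx) else t(vapply(2:(k - 1), function(j)
          c(idx[1], idx[j], idx[j + 1]), numeric(3)))
      }))
    }
  }
  out
}

read_ply_binary <- function(con, elems, endian) {
  out <- list()
  for (en in names(elems)) {
    el <- elems[[en]]
    if (en == "vertex") {
      pnames <- vapply(el$props, function(p) p[length(p)], "")
      vals <- matrix(0, el$n, length(el$props))
      for (r in seq_len(el$n))
        for (j in seq_along(el$props))
          vals[r, j] <- ply_read_one(con, el$props[[j]][1], endian)
      colnames(vals) <- pnames
      out$vertices <- vals[, c("x", "y", "z"), drop = FALSE]
      if (all(c("red", "green", "blue") %in% pnames))
        out$colors <- vals[, c("red", "green", "blue"), drop = FALSE]
    } else if (en == "face") {
      pl <- el$props[[1]]  # c("list", count_type, index_type, name)
      faces <- vector("list", el$n)
      for (r in seq_len(el$n)) {
        k <- ply_read_one(con, pl[2], endian)
        idx <- vapply(seq_len(k), function(j) ply_read_one(con, pl[3], endian),
                      numeric(1)) + 1
        faces[[r]] <- if (k == 3) rbind(idx) else t(vapply(2:(k - 1), function(j)
          c(idx[1], idx[j], idx[j + 1]), numeric(3)))
      }
      out$faces <- do.call(rbind, faces)
    } else {
      # skip unknown fixed-size elements
      for (r in seq_len(el$n))
        for (p in el$props) ply_read_one(con, p[1], endian)
    }
  }
  out
}

read_obj <- function(path) {
  lns <- readLines(path, warn = FALSE)
  vt <- grep("^v\\s", lns, value = TRUE)
  ft <- grep("^f\\s", lns, value = TRUE)
  if (!length(vt)) stop("format error: OBJ has no vertices")
  vertices <- do.call(rbind, lapply(strsplit(trimws(vt), "\\s+"),
                                    function(tk) as.numeric(tk[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(ft), "\\s+"), function(tk) {
    idx <- as.integer(vapply(strsplit(tk[-1], "/"), `[[`, "", 1L))
    idx[idx < 0] <- nrow(vertices) + 1L + idx[idx < 0]
    if (length(idx) == 3L) rbind(idx) else t(vapply(2:(length(idx) - 1L),
      function(j) c(idx[1], idx[j], idx[j + 1]), numeric(3)))
  }))
  if (is.null(faces)) stop("format error: OBJ has no faces")
  list(vertices = vertices, faces = faces, colors = NULL)
}

read_stl <- function(path) {
  head <- readBin(path, "raw", 80L)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    !stl_binary_plausible(path)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  # weld identical vertices
  key <- apply(tri, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  vertices <- tri[uniq, , drop = FALSE]
  idx <- match(key, key[uniq])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = vertices, faces = faces, colors = NULL)
}

stl_binary_plausible <- function(path) {
  sz <- file.size(path)
  if (sz < 84) return(FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", 80L)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  isTRUE(sz == 84 + 50 * n)
}

read_stl_ascii <- function(path) {
  lns <- grep("vertex", readLines(path, warn = FALSE), value = TRUE)
  if (!length(lns)) stop("format error: ascii STL has no vertices")
  m <- do.call(rbind, lapply(strsplit(trimws(lns), "\\s+"),
                             function(tk) as.numeric(tk[2:4])))
  if (nrow(m) %% 3 != 0) stop("format error: STL vertex count not multiple of 3")
  m
}

read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", 80L)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (n < 1) stop("format error: binary STL with no triangles")
  tri <- matrix(0, 3 * n, 3)
  for (i in seq_len(n)) {
    vals <- readBin(con, "double", 12L, size = 4L, endian = "little")
    readBin(con, "raw", 2L)
    tri[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  tri
}
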