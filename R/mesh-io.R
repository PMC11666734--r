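#' Read a surface mesh from STL, PLY or OBJ
#'
#' The format is inferred from the file extension unless given explicitly.
#' Binary and ASCII STL and PLY are supported; OBJ is read geometry-only.
#' Coordinates are taken as millimetres (STL carries no units); duplicate
#' vertices closer than 1e-9 mm are merged so that per-facet STL soup becomes
#' a connected mesh.
#'
#' @param path file path.
#' @param format one of `"stl"`, `"ply"`, `"obj"`; default from extension.
#' @param units_scale multiplicative factor applied to coordinates on read.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = NULL, units_scale = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty input: zero-byte file ", path)
  format <- tolower(format %||% tools::file_ext(path))
  m <- switch(format,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path),
    stop("unsupported mesh format '", format, "'")
  )
  if (nrow(m$vertices) == 0L) stop("empty input: no vertices in ", path)
  if (units_scale != 1) m$vertices <- m$vertices * units_scale
  m$name <- tools::file_path_sans_ext(basename(path))
  validate_mesh(m)
  m
}

#' Write a surface mesh to STL, PLY or OBJ
#'
#' Binary STL and PLY by default (`ascii = TRUE` switches to the text
#' variants). Round-trips through [read_mesh()] are coordinate-exact to well
#' below 1e-6 mm for PLY/OBJ (doubles) and to float32 precision for STL.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param format one of `"stl"`, `"ply"`, `"obj"`; default from extension.
#' @param ascii write the ASCII variant of STL/PLY.
#' @param quality optional per-vertex scalar written as a PLY `quality`
#'   property (used for distance maps).
#' @param allow_point_clouds permit writing a mesh with zero faces.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, ascii = FALSE, quality = NULL,
                       allow_point_clouds = FALSE) {
  validate_mesh(mesh)
  if (nrow(mesh$faces) == 0L && !allow_point_clouds)
    stop("refusing to write a mesh with 0 faces (set allow_point_clouds = TRUE)")
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
    stl = write_stl(mesh, path, ascii = ascii),
    ply = write_ply(mesh, path, ascii = ascii, quality = quality),
    obj = write_obj(mesh, path),
    stop("unsupported mesh format '", format, "'")
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || identical(a, "")) b else a

# weld vertices that agree to within 1e-9 mm and drop faces made degenerate
weld_vertices <- function(vertices, faces) {
  if (nrow(vertices) == 0L) return(list(vertices = vertices, faces = faces))
  key <- paste(round(vertices[, 1] * 1e9), round(vertices[, 2] * 1e9),
               round(vertices[, 3] * 1e9))
  first <- !duplicated(key)
  map <- match(key, key[first])
  v <- vertices[first, , drop = FALSE]
  f <- matrix(map[faces], ncol = 3L)
  if (nrow(f) > 0L) {
    degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
    f <- f[!degen, , drop = FALSE]
  }
  list(vertices = v, faces = f)
}

# ---- STL --------------------------------------------------------------------

is_ascii_stl <- function(path) {
  head <- readBin(path, "raw", n = 512L)
  # keep printable ASCII + newlines only: binary STL bodies contain arbitrary
  # bytes that are not valid text
  keep <- (head >= as.raw(32) & head <= as.raw(126)) | head == as.raw(10)
  txt <- tolower(rawToChar(head[keep]))
  startsWith(trimws(txt), "solid") && grepl("facet", txt, fixed = TRUE)
}

read_stl <- function(path) {
  if (is_ascii_stl(path)) return(read_stl_ascii(path))
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(nf) || nf < 0L)
    stop("corrupt STL '", path, "': bad triangle count in bytes 80-83")
  expected <- 84 + nf * 50
  if (file.size(path) < expected)
    stop("corrupt STL '", path, "': expected ", expected, " bytes for ", nf,
         " facets, file truncated at byte ", file.size(path))
  raw <- readBin(con, "raw", n = nf * 50L)
  # each facet: 12 float32 (normal + 3 vertices) + uint16 attribute
  idx <- rep(seq_len(nf) - 1L, each = 48L) * 50L + rep(seq_len(48L), nf)
  floats <- readBin(raw[idx], "double", n = nf * 12L, size = 4L, endian = "little")
  m <- matrix(floats, ncol = 12L, byrow = TRUE)
  verts <- matrix(t(m[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
  faces <- matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE)
  w <- weld_vertices(verts, faces)
  triangle_mesh(w$vertices, w$faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3L != 0L)
    stop("corrupt ASCII STL '", path, "': vertex count ", length(vl),
         " not a multiple of 3")
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]))
  verts <- do.call(rbind, nums)
  if (any(!is.finite(verts))) stop("corrupt ASCII STL '", path, "': unparsable vertex line")
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  w <- weld_vertices(verts, faces)
  triangle_mesh(w$vertices, w$faces)
}

write_stl <- function(mesh, path, ascii = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  n <- face_normals(mesh)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", mesh$name), con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g",
                v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
        "    endloop", "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", mesh$name), con)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", substr(paste0("ssmrec ", mesh$name), 1, 79)))
  writeBin(header[1:80], con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  block <- t(cbind(n, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                   v[f[, 3], , drop = FALSE]))
  for (i in seq_len(nrow(f))) {
    writeBin(as.numeric(block[, i]), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(path)
}

# ---- PLY --------------------------------------------------------------------

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readBin(con, "raw", n = 1L)
    buf <- raw(0)
    while (length(line) == 1L && line != as.raw(10L)) {
      buf <- c(buf, line)
      line <- readBin(con, "raw", n = 1L)
    }
    txt <- trimws(rawToChar(buf[buf != as.raw(13)]))
    hdr <- c(hdr, txt)
    if (identical(txt, "end_header")) break
    if (length(hdr) > 200L) stop("corrupt PLY '", path, "': no end_header")
  }
  if (!identical(hdr[1], "ply")) stop("corrupt PLY '", path, "': missing magic in bytes 0-3")
  fmt <- sub("^format\\s+", "", grep("^format", hdr, value = TRUE)[1])
  binary <- grepl("binary_little_endian", fmt)
  if (!binary && !grepl("ascii", fmt))
    stop("unsupported PLY format line: ", fmt)
  # parse elements and their properties
  el <- list(); cur <- NULL
  for (h in hdr) {
    if (grepl("^element ", h)) {
      p <- strsplit(h, "\\s+")[[1]]
      cur <- p[2]
      el[[cur]] <- list(count = as.integer(p[3]), props = list())
    } else if (grepl("^property ", h) && !is.null(cur)) {
      p <- strsplit(h, "\\s+")[[1]]
      el[[cur]]$props[[length(el[[cur]]$props) + 1L]] <- p[-1]
    }
  }
  if (is.null(el$vertex)) stop("corrupt PLY '", path, "': no vertex element")
  typesize <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2, ushort = 2,
                int16 = 2, uint16 = 2, int = 4, uint = 4, int32 = 4, uint32 = 4,
                float = 4, float32 = 4, double = 8, float64 = 8)
  if (binary) {
    vp <- el$vertex$props
    sizes <- vapply(vp, function(p) typesize[[p[1]]], numeric(1))
    names <- vapply(vp, function(p) p[2], character(1))
    nv <- el$vertex$count
    rowbytes <- sum(sizes)
    raww <- readBin(con, "raw", n = nv * rowbytes)
    if (length(raww) < nv * rowbytes)
      stop("corrupt PLY '", path, "': vertex block truncated at byte ",
           length(raww), " of ", nv * rowbytes)
    offs <- cumsum(c(0, sizes))
    getcol <- function(j) {
      sz <- sizes[j]
      idx <- rep((seq_len(nv) - 1L) * rowbytes + offs[j], each = sz) +
        rep(seq_len(sz), nv)
      type <- vp[[j]][1]
      if (type %in% c("float", "float32", "double", "float64"))
        readBin(raww[idx], "double", n = nv, size = sz, endian = "little")
      else readBin(raww[idx], "integer", n = nv, size = sz, endian = "little")
    }
    v <- cbind(getcol(which(names == "x")), getcol(which(names == "y")),
               getcol(which(names == "z")))
    nf <- el$face$count %||% 0L
    faces <- matrix(integer(0), 0, 3)
    if (nf > 0L) {
      lp <- el$face$props[[1]]  # list <count type> <index type> name
      csz <- typesize[[lp[2]]]; isz <- typesize[[lp[3]]]
      faces <- matrix(0L, nf, 3L)
      for (i in seq_len(nf)) {
        k <- readBin(con, "integer", n = 1L, size = csz, endian = "little", signed = csz > 1)
        if (length(k) == 0L) stop("corrupt PLY '", path, "': face block truncated")
        if (k != 3L) stop("PLY face with ", k, " vertices: only triangles supported")
        faces[i, ] <- readBin(con, "integer", n = 3L, size = isz, endian = "little")
      }
    }
    return(triangle_mesh(v, faces + 1L))
  }
  # ascii body
  body <- readLines(con, warn = FALSE)
  body <- body[nzchar(trimws(body))]
  nv <- el$vertex$count
  names <- vapply(el$vertex$props, function(p) p[2], character(1))
  vm <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"), as.numeric))
  v <- vm[, match(c("x", "y", "z"), names), drop = FALSE]
  nf <- el$face$count %||% 0L
  faces <- matrix(integer(0), 0, 3)
  if (nf > 0L) {
    fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    faces <- do.call(rbind, lapply(fl, function(p) {
      if (as.integer(p[1]) != 3L) stop("PLY face with ", p[1], " vertices")
      as.integer(p[2:4])
    }))
  }
  triangle_mesh(v, faces + 1L)
}

write_ply <- function(mesh, path, ascii = FALSE, quality = NULL) {
  v <- mesh$vertices; f <- mesh$faces
  if (!is.null(quality) && length(quality) != nrow(v))
    stop("quality must have one value per vertex")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           if (ascii) "format ascii 1.0" else "format binary_little_endian 1.0",
           sprintf("comment ssmrec %s", mesh$name),
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           if (!is.null(quality)) "property double quality",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  if (ascii) {
    vl <- if (is.null(quality)) {
      sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
    } else sprintf("%.17g %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3], quality)
    fl <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
    writeBin(charToRaw(paste0(paste(c(vl, fl), collapse = "\n"), "\n")), con)
  } else {
    block <- if (is.null(quality)) t(v) else t(cbind(v, quality))
    writeBin(as.numeric(block), con, size = 8L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}

# ---- OBJ --------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                             function(p) as.numeric(p[2:4])))
  if (is.null(v)) stop("corrupt OBJ '", path, "': no vertex lines")
  if (any(!is.finite(v))) stop("corrupt OBJ '", path, "': unparsable vertex line")
  f <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(p) {
    idx <- as.integer(vapply(strsplit(p[-1], "/"), `[[`, character(1), 1))
    if (length(idx) != 3L) stop("OBJ face with ", length(idx), " vertices")
    idx
  }))
  triangle_mesh(v, f %||% matrix(integer(0), 0, 3))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ssmrec %s", mesh$name), con)
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  if (nrow(mesh$faces))
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]), con)
  invisible(path)
}
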