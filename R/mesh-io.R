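#' Read a surface mesh
#'
#' Reads a closed triangulated surface from PLY (ASCII or binary), OBJ, STL
#' (ASCII or binary) or legacy VTK polydata. Vertex order is preserved from
#' the file. Faces with more than 3 vertices are fan-triangulated; STL
#' per-facet vertices are welded on exact coordinate equality.
#'
#' @param path file path; extension must be one of ply, obj, stl, vtk.
#' @param name specimen identifier; defaults to the file stem.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, name = NULL) {
  if (!file.exists(path)) stopf("mesh file does not exist: %s", path)
  ext <- tolower(tools::file_ext(path))
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  parsed <- switch(ext,
    ply = read_ply(path),
    obj = read_obj(path),
    stl = read_stl(path),
    vtk = read_vtk(path),
    stopf("unsupported mesh format '.%s' (expected ply/obj/stl/vtk): %s", ext, path)
  )
  mesh <- structure(list(vertices = {
    v <- as.matrix(parsed$vertices); storage.mode(v) <- "double"; v
  }, faces = {
    f <- as.matrix(parsed$faces); storage.mode(f) <- "integer"; f
  }, name = name), class = "triangle_mesh")
  validate_mesh(mesh, file = path)
  mesh
}

#' Write a surface mesh
#'
#' Writes PLY, binary little-endian by default with double-precision
#' coordinates so that read/write round-trips are exact.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param format `"binary"` (little-endian) or `"ascii"`.
#' @export
write_mesh <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  validate_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces - 1L
  hdr <- c(
    "ply",
    if (format == "binary") "format binary_little_endian 1.0" else "format ascii 1.0",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (format == "binary") {
    writeBin(as.vector(t(v)), con, size = 8, endian = "little")
    rec <- rbind(3L, t(f))
    # each face record: uchar count then 3 int32
    for (j in seq_len(ncol(rec))) {
      writeBin(as.raw(3L), con)
      writeBin(rec[2:4, j], con, size = 4, endian = "little")
    }
  } else {
    writeLines(apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
    writeLines(apply(f, 1, function(r) paste(c(3L, r), collapse = " ")), con)
  }
  invisible(path)
}

# ---- PLY ----

read_ply <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  pos <- grepRaw("end_header", raw, fixed = TRUE)
  if (!length(pos)) stopf("invalid PLY (no end_header): %s", path)
  hdr_len <- pos + 9L            # position of the final 'r' of end_header
  if (hdr_len < length(raw) && raw[hdr_len + 1L] == as.raw(13L))
    hdr_len <- hdr_len + 1L      # optional \r
  if (hdr_len < length(raw) && raw[hdr_len + 1L] == as.raw(10L))
    hdr_len <- hdr_len + 1L      # the \n ending the header
  hdr_lines <- strsplit(rawToChar(raw[seq_len(pos - 1L)]), "\r?\n")[[1]]
  fmt_line <- grep("^format", hdr_lines, value = TRUE)
  if (!length(fmt_line)) stopf("invalid PLY (no format line): %s", path)
  fmt <- strsplit(trimws(fmt_line[1]), "\\s+")[[1]][2]

  elements <- list()
  cur <- NULL
  for (ln in hdr_lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(list = TRUE, count_type = tok[3], item_type = tok[4], name = tok[5])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(list = FALSE, type = tok[2], name = tok[3])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stopf("invalid PLY (missing vertex or face element): %s", path)

  if (fmt == "ascii") {
    body <- strsplit(rawToChar(raw[(hdr_len + 1L):length(raw)]), "\r?\n")[[1]]
    body <- body[nzchar(trimws(body))]
    read_ply_ascii(elements, body, path)
  } else {
    endian <- if (fmt == "binary_little_endian") "little" else "big"
    read_ply_binary(elements, raw, hdr_len, endian, path)
  }
}

ply_type_size <- function(t) {
  switch(t,
    char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
    float = 4L, float32 = 4L, double = 8L, float64 = 8L,
    stopf("unsupported PLY property type '%s'", t))
}

ply_read_scalar <- function(raw, off, type, endian) {
  sz <- ply_type_size(type)
  bytes <- raw[(off + 1L):(off + sz)]
  val <- if (type %in% c("float", "float32", "double", "float64")) {
    readBin(bytes, "double", n = 1L, size = sz, endian = endian)
  } else {
    readBin(bytes, "integer", n = 1L, size = sz, endian = endian,
            signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")) || sz >= 4)
  }
  list(val = val, off = off + sz)
}

read_ply_ascii <- function(elements, body, path) {
  pos <- 1L
  verts <- NULL
  faces <- NULL
  for (el in elements) {
    lines <- body[pos:(pos + el$count - 1L)]
    pos <- pos + el$count
    if (el$name == "vertex") {
      pnames <- vapply(el$props, `[[`, "", "name")
      tab <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
      verts <- tab[, match(c("x", "y", "z"), pnames), drop = FALSE]
    } else if (el$name == "face") {
      faces <- parse_face_lines(lines, path)
    }
  }
  list(vertices = verts, faces = faces)
}

parse_face_lines <- function(lines, path) {
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tok <- as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]])
    k <- tok[1]
    idx <- tok[2:(1 + k)] + 1L
    out[[i]] <- fan_triangulate(idx)
  }
  do.call(rbind, out)
}

fan_triangulate <- function(idx) {
  k <- length(idx)
  if (k < 3L) stopf("face with fewer than 3 vertices")
  cbind(idx[1], idx[2:(k - 1)], idx[3:k])
}

read_ply_binary <- function(elements, raw, off, endian, path) {
  verts <- NULL
  faces <- NULL
  for (el in elements) {
    if (el$name == "vertex") {
      types <- vapply(el$props, function(p) if (p$list) "list" else p$type, "")
      pnames <- vapply(el$props, `[[`, "", "name")
      if (length(unique(types)) == 1L && types[1] %in%
          c("float", "float32", "double", "float64")) {
        sz <- ply_type_size(types[1])
        np <- length(types)
        vals <- readBin(raw[(off + 1L):(off + el$count * np * sz)], "double",
                        n = el$count * np, size = sz, endian = endian)
        tab <- matrix(vals, ncol = np, byrow = TRUE)
        verts <- tab[, match(c("x", "y", "z"), pnames), drop = FALSE]
        off <- off + el$count * np * sz
      } else {
        tab <- matrix(NA_real_, el$count, length(el$props))
        for (i in seq_len(el$count)) for (j in seq_along(el$props)) {
          r <- ply_read_scalar(raw, off, el$props[[j]]$type, endian)
          tab[i, j] <- r$val
          off <- r$off
        }
        verts <- tab[, match(c("x", "y", "z"), pnames), drop = FALSE]
      }
    } else if (el$name == "face") {
      lp <- el$props[[1]]
      if (!lp$list) stopf("invalid PLY face element: %s", path)
      csz <- ply_type_size(lp$count_type)
      isz <- ply_type_size(lp$item_type)
      # fast path: uniform triangles with uchar count + 4-byte ints
      if (csz == 1L && isz == 4L) {
        rec <- 1L + 12L
        navail <- length(raw) - off
        if (navail >= el$count * rec) {
          block <- raw[(off + 1L):(off + el$count * rec)]
          mat <- matrix(block, nrow = rec)
          counts <- as.integer(mat[1, ])
          if (all(counts == 3L)) {
            ints <- readBin(as.vector(mat[2:13, ]), "integer", n = el$count * 3L,
                            size = 4L, endian = endian)
            faces <- matrix(ints, ncol = 3, byrow = TRUE) + 1L
            off <- off + el$count * rec
            next
          }
        }
      }
      flist <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        r <- ply_read_scalar(raw, off, lp$count_type, endian)
        k <- r$val
        off <- r$off
        idx <- integer(k)
        for (j in seq_len(k)) {
          r <- ply_read_scalar(raw, off, lp$item_type, endian)
          idx[j] <- r$val
          off <- r$off
        }
        flist[[i]] <- fan_triangulate(idx + 1L)
      }
      faces <- do.call(rbind, flist)
    }
  }
  list(vertices = verts, faces = faces)
}

# ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(t)
    as.numeric(t[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(t) {
    idx <- as.integer(sub("/.*$", "", t[-1]))
    fan_triangulate(idx)
  }))
  list(vertices = verts, faces = faces)
}

# ---- STL ----

read_stl <- function(path) {
  size <- file.info(path)$size
  head <- readBin(path, "raw", n = min(size, 512L))
  printable <- head[(head >= as.raw(0x20) & head <= as.raw(0x7e)) |
                      head %in% as.raw(c(9L, 10L, 13L))]
  txt <- rawToChar(printable)
  is_ascii <- grepl("^\\s*solid", txt, useBytes = TRUE) &&
    grepl("facet", txt, useBytes = TRUE)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, size)
  weld_triangle_soup(tri)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(t)
    as.numeric(t[2:4])))
}

read_stl_binary <- function(path, size) {
  raw <- readBin(path, "raw", n = size)
  n <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
  if (size < 84 + n * 50) stopf("truncated binary STL: %s", path)
  rec <- matrix(raw[85:(84 + n * 50)], nrow = 50)
  vals <- readBin(as.vector(rec[13:48, ]), "double", n = n * 9L, size = 4L,
                  endian = "little")
  matrix(vals, ncol = 3, byrow = TRUE)
}

# triangle soup (3 vertices per facet, in order) -> welded indexed mesh
weld_triangle_soup <- function(tri) {
  key <- apply(tri, 1, function(r) paste(sprintf("%.17g", r), collapse = "|"))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  verts <- tri[first, , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

# ---- legacy VTK polydata (ASCII) ----

read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks_after <- function(i) {
    # numeric token stream starting after line i
    unlist(lapply(strsplit(trimws(lines[(i + 1L):length(lines)]), "\\s+"),
                  function(t) t[nzchar(t)]))
  }
  ip <- grep("^POINTS", lines)
  if (!length(ip)) stopf("invalid VTK polydata (no POINTS): %s", path)
  np <- as.integer(strsplit(trimws(lines[ip[1]]), "\\s+")[[1]][2])
  vals <- suppressWarnings(as.numeric(toks_after(ip[1])))
  vals <- vals[!is.na(vals)][seq_len(3L * np)]
  verts <- matrix(vals, ncol = 3, byrow = TRUE)
  ig <- grep("^POLYGONS", lines)
  if (!length(ig)) stopf("invalid VTK polydata (no POLYGONS): %s", path)
  hdr <- as.integer(strsplit(trimws(lines[ig[1]]), "\\s+")[[1]][2:3])
  ints <- suppressWarnings(as.integer(toks_after(ig[1])))
  ints <- ints[!is.na(ints)][seq_len(hdr[2])]
  faces <- list()
  pos <- 1L
  while (pos <= length(ints)) {
    k <- ints[pos]
    faces[[length(faces) + 1L]] <- fan_triangulate(ints[(pos + 1L):(pos + k)] + 1L)
    pos <- pos + k + 1L
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}
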