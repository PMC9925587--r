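#' Read a triangle mesh from PLY, STL or OBJ
#'
#' Supported dialects: PLY ascii and binary little/big endian (extra numeric
#' per-vertex properties are loaded as scalar fields), STL ascii and binary
#' (triangle-soup vertices closer than 1e-6 mm are merged so downstream axis
#' estimation sees a coherent cloud), OBJ geometry (polygon faces are fan
#' triangulated). All coordinates are interpreted as millimetres; there is no
#' unit autodetection.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"ply"`, `"stl"` or `"obj"`.
#' @return a [triangle_mesh()]; vertex order is preserved as stored in the
#'   file (up to STL merging).
#' @export
read_mesh <- function(path, format = c("auto", "ply", "stl", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("cannot read mesh: file does not exist: %s", path))
  if (format == "auto") format <- ext_format(path)
  switch(format,
         ply = read_ply(path),
         stl = read_stl(path),
         obj = read_obj(path))
}

#' Write a triangle mesh to PLY, STL or OBJ
#'
#' PLY stores coordinates as doubles and every scalar field as a named float
#' per-vertex property (heatmap dialect: binary little-endian PLY with a
#' `"distance_mm"` property). STL and OBJ cannot carry per-vertex attributes;
#' writing a mesh with scalar fields to those formats drops the fields with a
#' warning.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param format `"auto"` (by extension), `"ply"`, `"stl"` or `"obj"`.
#' @param binary for PLY/STL, write the binary dialect (default) or ascii.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "stl", "obj"),
                       binary = TRUE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- match.arg(format)
  if (format == "auto") format <- ext_format(path)
  if (format != "ply" && length(mesh$fields))
    warning(sprintf("%s cannot store per-vertex scalar fields; writing geometry only",
                    toupper(format)))
  switch(format,
         ply = write_ply(mesh, path, binary = binary),
         stl = write_stl(mesh, path, binary = binary),
         obj = write_obj(mesh, path))
  invisible(path)
}

ext_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("ply", "stl", "obj"))
    stop(sprintf("cannot infer mesh format from extension of '%s'", path))
  ext
}

## ---- PLY ----------------------------------------------------------------

ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_column <- function(bytes, type, n, endian) {
  sz <- ply_type_size[[type]]
  what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16"))
  if (type %in% c("uint", "uint32")) signed <- TRUE  # values < 2^31 in practice
  readBin(bytes, what = what, n = n, size = sz, signed = if (sz < 4) signed else TRUE,
          endian = endian)
}

read_ply <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  hdr_end <- grepRaw("end_header", raw)
  if (length(hdr_end) == 0L)
    stop(sprintf("not a valid PLY file (no end_header): %s", path))
  nl <- which(raw == as.raw(10L))
  nl <- nl[nl > hdr_end[1L]][1L]
  if (is.na(nl)) stop(sprintf("truncated PLY header: %s", path))
  header <- strsplit(rawToChar(raw[1:nl]), "\r?\n")[[1L]]
  if (length(header) == 0L || trimws(header[1L]) != "ply")
    stop(sprintf("not a PLY file: %s", path))
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1L) stop(sprintf("PLY format line missing: %s", path))
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1L]][2L]
  endian <- switch(fmt, ascii = NA_character_,
                   binary_little_endian = "little",
                   binary_big_endian = "big",
                   stop(sprintf("unsupported PLY format '%s'", fmt)))
  # parse elements
  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(tok) == 0L) next
    if (tok[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property" && !is.null(cur)) {
      if (tok[2L] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5L], list = TRUE, count_type = tok[3L],
               index_type = tok[4L])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3L], list = FALSE, type = tok[2L])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex))
    stop(sprintf("PLY has no vertex element (non-mesh content): %s", path))

  if (is.na(endian)) {
    body <- rawToChar(raw[(nl + 1L):length(raw)])
    tokens <- strsplit(body, "\\s+")[[1L]]
    tokens <- tokens[tokens != ""]
    pos <- 0L
    take <- function(k) {
      if (pos + k > length(tokens)) stop(sprintf("truncated PLY file: %s", path))
      out <- tokens[(pos + 1L):(pos + k)]
      pos <<- pos + k
      out
    }
    vals <- list()
    for (el in elements) {
      if (el$name == "vertex") {
        m <- matrix(as.numeric(take(el$count * length(el$props))),
                    nrow = el$count, byrow = TRUE)
        colnames(m) <- vapply(el$props, `[[`, "", "name")
        vals$vertex <- m
      } else if (el$name == "face") {
        faces <- matrix(0L, el$count, 3L)
        for (i in seq_len(el$count)) {
          k <- as.integer(take(1L))
          if (k != 3L) stop("only triangular PLY faces are supported")
          faces[i, ] <- as.integer(take(3L))
        }
        vals$face <- faces
      } else {
        # skip unknown fixed-width element rows
        take(el$count * length(el$props))
      }
    }
  } else {
    offset <- nl
    avail <- length(raw)
    vals <- list()
    for (el in elements) {
      listy <- vapply(el$props, `[[`, TRUE, "list")
      if (!any(listy)) {
        sizes <- vapply(el$props, function(p) ply_type_size[[p$type]], 1L)
        stride <- sum(sizes)
        need <- el$count * stride
        if (offset + need > avail) stop(sprintf("truncated PLY file: %s", path))
        block <- matrix(raw[(offset + 1L):(offset + need)], nrow = stride)
        offset <- offset + need
        cols <- matrix(0, el$count, length(el$props))
        at <- 0L
        for (j in seq_along(el$props)) {
          b <- as.vector(block[(at + 1L):(at + sizes[j]), , drop = FALSE])
          cols[, j] <- ply_read_column(b, el$props[[j]]$type, el$count, endian)
          at <- at + sizes[j]
        }
        colnames(cols) <- vapply(el$props, `[[`, "", "name")
        if (el$name == "vertex") vals$vertex <- cols
      } else {
        if (el$name != "face" || length(el$props) != 1L)
          stop("unsupported PLY list element layout")
        p <- el$props[[1L]]
        csz <- ply_type_size[[p$count_type]]
        isz <- ply_type_size[[p$index_type]]
        stride <- csz + 3L * isz
        need <- el$count * stride
        if (offset + need > avail) stop(sprintf("truncated PLY file: %s", path))
        block <- matrix(raw[(offset + 1L):(offset + need)], nrow = stride)
        offset <- offset + need
        counts <- ply_read_column(as.vector(block[1:csz, , drop = FALSE]),
                                  p$count_type, el$count, endian)
        if (any(counts != 3L)) stop("only triangular PLY faces are supported")
        idx <- ply_read_column(as.vector(block[(csz + 1L):stride, , drop = FALSE]),
                               p$index_type, el$count * 3L, endian)
        vals$face <- matrix(as.integer(idx), el$count, 3L, byrow = TRUE)
      }
    }
  }
  vm <- vals$vertex
  req <- c("x", "y", "z")
  if (!all(req %in% colnames(vm)))
    stop(sprintf("PLY vertex element lacks x/y/z coordinates: %s", path))
  vertices <- vm[, req, drop = FALSE]
  extra <- setdiff(colnames(vm), req)
  fields <- stats::setNames(lapply(extra, function(nm) as.numeric(vm[, nm])), extra)
  faces <- if (is.null(vals$face)) matrix(integer(), 0L, 3L) else vals$face + 1L
  triangle_mesh(vertices, faces, fields)
}

ply_double_bytes <- function(x) {
  matrix(writeBin(as.numeric(x), raw(), size = 8L, endian = "little"), nrow = 8L)
}
ply_float_bytes <- function(x) {
  matrix(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"), nrow = 4L)
}

write_ply <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  fields <- mesh$fields
  header <- c("ply",
              sprintf("format %s 1.0",
                      if (binary) "binary_little_endian" else "ascii"),
              "comment written by bisym",
              sprintf("element vertex %d", nrow(v)),
              "property double x", "property double y", "property double z",
              vapply(names(fields), function(nm) sprintf("property float %s", nm), ""),
              sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices",
              "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (binary) {
    rows <- list(ply_double_bytes(v[, 1L]), ply_double_bytes(v[, 2L]),
                 ply_double_bytes(v[, 3L]))
    for (nm in names(fields)) rows[[length(rows) + 1L]] <- ply_float_bytes(fields[[nm]])
    writeBin(as.vector(do.call(rbind, rows)), con)
    if (nrow(f) > 0L) {
      idx <- matrix(writeBin(as.integer(t(f - 1L)), raw(), size = 4L,
                             endian = "little"), nrow = 12L)
      frows <- rbind(matrix(as.raw(3L), 1L, nrow(f)), idx)
      writeBin(as.vector(frows), con)
    }
  } else {
    cols <- cbind(v, do.call(cbind, c(lapply(fields, as.numeric), list(NULL))))
    lines <- apply(cols, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
    writeLines(lines, con, sep = "\n")
    if (nrow(f) > 0L) {
      flines <- apply(f - 1L, 1L, function(r) paste(c(3L, r), collapse = " "))
      writeLines(flines, con, sep = "\n")
    }
  }
  invisible(path)
}

## ---- STL ----------------------------------------------------------------

read_stl <- function(path) {
  size <- file.size(path)
  binary <- FALSE
  if (size >= 84L) {
    con <- file(path, "rb")
    hdr <- readBin(con, "raw", 80L)
    nf <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    close(con)
    if (length(nf) == 1L && !is.na(nf) && size == 84 + 50 * as.numeric(nf))
      binary <- TRUE
  }
  if (binary) {
    raw <- readBin(path, "raw", n = size)
    nf <- readBin(raw[81:84], "integer", 1L, size = 4L, endian = "little")
    block <- matrix(raw[85:length(raw)], nrow = 50L)
    tri <- matrix(0, nf, 9L)
    # skip the 12-byte normal and the 2-byte attribute count
    for (j in 1:9) {
      b <- as.vector(block[(12L + (j - 1L) * 4L + 1L):(12L + j * 4L), , drop = FALSE])
      tri[, j] <- readBin(b, "double", nf, size = 4L, endian = "little")
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
      stop(sprintf("not a valid STL file (truncated or non-mesh): %s", path))
    coords <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                       function(tok) as.numeric(tok[2:4]), numeric(3L)))
    nf <- nrow(coords) / 3L
    tri <- cbind(coords[seq(1L, by = 3L, length.out = nf), , drop = FALSE],
                 coords[seq(2L, by = 3L, length.out = nf), , drop = FALSE],
                 coords[seq(3L, by = 3L, length.out = nf), , drop = FALSE])
  }
  if (nrow(tri) == 0L) stop(sprintf("STL contains no triangles: %s", path))
  soup <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
                tri[, 7:9, drop = FALSE])
  # merge duplicated corner vertices (tolerance 1e-6 mm)
  key <- apply(round(soup, 6L), 1L, paste, collapse = ",")
  uidx <- !duplicated(key)
  verts <- soup[uidx, , drop = FALSE]
  map <- match(key, key[uidx])
  nf <- nrow(tri)
  faces <- cbind(map[1:nf], map[(nf + 1L):(2L * nf)], map[(2L * nf + 1L):(3L * nf)])
  keep <- faces[, 1L] != faces[, 2L] & faces[, 1L] != faces[, 3L] &
    faces[, 2L] != faces[, 3L]
  triangle_mesh(verts, faces[keep, , drop = FALSE])
}

write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  ab <- b - a; ac <- c_ - a
  nrm <- cbind(ab[, 2L] * ac[, 3L] - ab[, 3L] * ac[, 2L],
               ab[, 3L] * ac[, 1L] - ab[, 1L] * ac[, 3L],
               ab[, 1L] * ac[, 2L] - ab[, 2L] * ac[, 1L])
  len <- sqrt(rowSums(nrm^2)); len[len < 1e-300] <- 1
  nrm <- nrm / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- raw(80L)
    tag <- charToRaw("bisym binary STL")
    hdr[seq_along(tag)] <- tag
    writeBin(hdr, con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    vals <- t(cbind(nrm, a, b, c_))  # 12 floats per face
    fb <- matrix(writeBin(as.numeric(vals), raw(), size = 4L, endian = "little"),
                 nrow = 48L)
    rows <- rbind(fb, matrix(as.raw(0L), 2L, nrow(f)))
    writeBin(as.vector(rows), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid bisym", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g",
                           nrm[i, 1L], nrm[i, 2L], nrm[i, 3L]),
                   "    outer loop",
                   sprintf("      vertex %.17g %.17g %.17g",
                           c(a[i, 1L], b[i, 1L], c_[i, 1L]),
                           c(a[i, 2L], b[i, 2L], c_[i, 2L]),
                           c(a[i, 3L], b[i, 3L], c_[i, 3L])),
                   "    endloop",
                   "  endfacet"), con)
    }
    writeLines("endsolid bisym", con)
  }
  invisible(path)
}

## ---- OBJ ----------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (length(vlines) == 0L)
    stop(sprintf("not a valid OBJ file (no vertices): %s", path))
  verts <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                    function(tok) as.numeric(tok[2:4]), numeric(3L)))
  faces <- list()
  for (fl in flines) {
    tok <- strsplit(trimws(fl), "\\s+")[[1L]][-1L]
    idx <- as.integer(vapply(strsplit(tok, "/"), `[[`, "", 1L))
    if (length(idx) < 3L) stop(sprintf("OBJ face with <3 vertices: %s", path))
    for (k in 2:(length(idx) - 1L))
      faces[[length(faces) + 1L]] <- c(idx[1L], idx[k], idx[k + 1L])
  }
  fm <- if (length(faces)) do.call(rbind, faces) else matrix(integer(), 0L, 3L)
  triangle_mesh(verts, fm)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# written by bisym", con)
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  if (nrow(mesh$faces) > 0L)
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L],
                       mesh$faces[, 3L]), con)
  invisible(path)
}
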