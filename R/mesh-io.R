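# Triangle-mesh file I/O: PLY (ASCII + binary little-endian), STL (ASCII +
# binary), OBJ. Coordinates are taken to be millimetres.

#' Read a triangle mesh (PLY, STL or OBJ)
#'
#' Format is chosen from the file extension. STL files (which store
#' per-triangle vertices) are welded exactly after reading.
#'
#' @param path file path ending in .ply, .stl or .obj.
#' @return a [TriMesh-class].
#' @export
readMesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = readPly(path),
    stl = readStl(path),
    obj = readObj(path),
    stop(sprintf("unsupported mesh format '.%s'", ext)))
}

#' Write a triangle mesh (PLY, STL or OBJ)
#'
#' @param mesh a [TriMesh-class].
#' @param path output path; extension selects the format.
#' @param binary write binary PLY/STL (default TRUE; OBJ is always text).
#' @param quality optional per-vertex scalar written as a PLY `quality`
#'   property (for colour-mapped repeatability maps).
#' @return `path`, invisibly.
#' @export
writeMesh <- function(mesh, path, binary = TRUE, quality = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (!is.null(quality) && length(quality) != nVertices(mesh))
    stop("quality must have one value per vertex")
  switch(ext,
    ply = writePly(mesh, path, binary, quality),
    stl = writeStl(mesh, path, binary),
    obj = writeObj(mesh, path),
    stop(sprintf("unsupported mesh format '.%s'", ext)))
  invisible(path)
}

writePly <- function(mesh, path, binary, quality) {
  v <- mesh@vertices
  f <- mesh@faces
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    "comment limbmetric mesh",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    if (!is.null(quality)) "property double quality",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (binary) {
    vdat <- t(v)
    if (!is.null(quality)) vdat <- rbind(vdat, quality)
    writeBin(as.vector(vdat), con, size = 8, endian = "little")
    if (nrow(f) > 0) {
      for (i in seq_len(nrow(f))) {
        writeBin(as.raw(3), con)
        writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
      }
    }
  } else {
    vdat <- v
    if (!is.null(quality)) vdat <- cbind(vdat, quality)
    writeLines(apply(vdat, 1, function(r) paste(format(r, digits = 17), collapse = " ")),
               con)
    if (nrow(f) > 0)
      writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
}

readPly <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readHeaderLine <- function() {
    chars <- raw(0)
    repeat {
      ch <- readBin(con, "raw", 1)
      if (length(ch) == 0 || ch == as.raw(10)) break
      chars <- c(chars, ch)
    }
    sub("\r$", "", rawToChar(chars))
  }
  if (readHeaderLine() != "ply") stop("not a PLY file")
  fmt <- NULL
  elements <- list()
  curElem <- NULL
  repeat {
    line <- readHeaderLine()
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      curElem <- tok[2]
      elements[[curElem]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(curElem)) {
      p <- elements[[curElem]]$props
      if (tok[2] == "list")
        p[[length(p) + 1]] <- list(name = tok[5], list = TRUE,
                                   countType = tok[3], type = tok[4])
      else
        p[[length(p) + 1]] <- list(name = tok[3], list = FALSE, type = tok[2])
      elements[[curElem]]$props <- p
    } else if (tok[1] == "end_header") break
  }
  typeSize <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2, ushort = 2,
                int16 = 2, uint16 = 2, int = 4, uint = 4, int32 = 4, uint32 = 4,
                float = 4, float32 = 4, double = 8, float64 = 8)
  typeWhat <- function(tp) if (tp %in% c("float", "float32", "double", "float64"))
    "double" else "integer"
  readScalar <- function(tp) {
    readBin(con, typeWhat(tp), 1, size = typeSize[[tp]], endian = "little",
            signed = !(typeSize[[tp]] < 4 && grepl("^u", tp)))
  }
  v <- NULL
  f <- NULL
  if (fmt == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    ptr <- 1
    for (en in names(elements)) {
      el <- elements[[en]]
      rows <- txt[seq(ptr, length.out = el$count)]
      ptr <- ptr + el$count
      if (en == "vertex") {
        m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
        nm <- vapply(el$props, `[[`, "", "name")
        v <- m[, match(c("x", "y", "z"), nm), drop = FALSE]
      } else if (en == "face") {
        fl <- lapply(strsplit(trimws(rows), "\\s+"), as.integer)
        f <- do.call(rbind, lapply(fl, function(r) {
          if (r[1] != 3) stop("only triangle faces are supported")
          r[2:4] + 1L
        }))
      }
    }
  } else if (fmt == "binary_little_endian") {
    for (en in names(elements)) {
      el <- elements[[en]]
      if (en == "vertex") {
        nm <- vapply(el$props, `[[`, "", "name")
        v <- matrix(0, el$count, 3)
        for (i in seq_len(el$count)) {
          vals <- vapply(el$props, function(p) as.numeric(readScalar(p$type)),
                         numeric(1))
          v[i, ] <- vals[match(c("x", "y", "z"), nm)]
        }
      } else if (en == "face") {
        f <- matrix(0L, el$count, 3)
        for (i in seq_len(el$count)) {
          p <- el$props[[1]]
          k <- as.integer(readScalar(p$countType))
          if (k != 3) stop("only triangle faces are supported")
          f[i, ] <- vapply(1:3, function(j) as.integer(readScalar(p$type)),
                           integer(1)) + 1L
        }
      } else {
        for (i in seq_len(el$count))
          for (p in el$props) readScalar(p$type)
      }
    }
  } else stop(sprintf("unsupported PLY format '%s'", fmt))
  TriMesh(v, f)
}

writeStl <- function(mesh, path, binary) {
  v <- mesh@vertices
  f <- mesh@faces
  fn <- faceNormals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(fn[i, ], t(v[f[i, ], ]))), con, size = 4,
               endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid limbmetric", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %g %g %g", fn[i, 1], fn[i, 2], fn[i, 3]), con)
      writeLines("    outer loop", con)
      for (j in 1:3) {
        p <- v[f[i, j], ]
        writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid limbmetric", con)
  }
}

readStl <- function(path) {
  # sniff: ASCII STL starts with "solid" and contains "facet"
  head <- readBin(path, "raw", 512)
  isAscii <- identical(rawToChar(head[1:5]), "solid") &&
    grepl("facet", rawToChar(head), fixed = TRUE)
  if (isAscii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    m <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                               function(t) as.numeric(t[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    m <- matrix(0, 3 * n, 3)
    for (i in seq_len(n)) {
      vals <- readBin(con, "double", 12, size = 4, endian = "little")
      m[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
      readBin(con, "integer", 1, size = 2, endian = "little")
    }
  }
  f <- matrix(seq_len(nrow(m)), ncol = 3, byrow = TRUE)
  w <- cpp_weld_vertices(m, f, 1e-9)
  TriMesh(w$vertices, w$faces)
}

writeObj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh@vertices
  f <- mesh@faces
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}

readObj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- strsplit(trimws(grep("^v\\s", txt, value = TRUE)), "\\s+")
  v <- do.call(rbind, lapply(vl, function(t) as.numeric(t[2:4])))
  fl <- strsplit(trimws(grep("^f\\s", txt, value = TRUE)), "\\s+")
  f <- do.call(rbind, lapply(fl, function(t) {
    idx <- as.integer(vapply(strsplit(t[-1], "/"), `[[`, "", 1))
    if (length(idx) != 3) stop("only triangle faces are supported")
    idx
  }))
  TriMesh(v, f)
}
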