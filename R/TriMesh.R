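#' Construct a triangle mesh
#'
#' Builds a [TriMesh-class] from a vertex matrix (mm) and 1-based face index
#' matrix. Zero-area (degenerate) faces are dropped. If the mesh is closed and
#' its signed volume is negative (inward-facing winding), all faces are
#' re-oriented with a warning so that normals point outward.
#'
#' @param vertices numeric n x 3 matrix (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param vnormals optional n x 3 unit vertex normals; computed on demand
#'   (angle-weighted face-normal average) when absent.
#' @return a `TriMesh`.
#' @examples
#' cube <- meshCube(1)
#' meshVolume(cube)
#' @export
TriMesh <- function(vertices, faces, vnormals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0) {
    a <- vertices[faces[, 1], , drop = FALSE]
    b <- vertices[faces[, 2], , drop = FALSE]
    cc <- vertices[faces[, 3], , drop = FALSE]
    area2 <- rowNorms(crossRows(b - a, cc - a))
    degen <- area2 <= 1e-14 | faces[, 1] == faces[, 2] |
      faces[, 2] == faces[, 3] | faces[, 1] == faces[, 3]
    if (any(degen)) faces <- faces[!degen, , drop = FALSE]
  }
  if (is.null(vnormals)) vnormals <- matrix(numeric(0), 0, 3)
  mesh <- new("TriMesh", vertices = vertices, faces = faces,
              vnormals = as.matrix(vnormals))
  if (isClosedMesh(mesh) && nrow(faces) > 0) {
    vol <- sum(signedTetraVolumes(mesh))
    if (vol < 0) {
      warning("mesh winding was inward-facing; faces re-oriented outward")
      mesh@faces <- mesh@faces[, c(1, 3, 2)]
      if (nrow(mesh@vnormals) > 0) mesh@vnormals <- -mesh@vnormals
    }
  }
  mesh
}

#' @rdname TriMesh
#' @param x a `TriMesh`.
#' @export
setMethod("vertices", "TriMesh", function(x) x@vertices)

#' @rdname TriMesh
#' @export
setMethod("faces", "TriMesh", function(x) x@faces)

#' @rdname TriMesh
#' @export
setMethod("nVertices", "TriMesh", function(x) nrow(x@vertices))

#' @rdname TriMesh
#' @export
setMethod("nFaces", "TriMesh", function(x) nrow(x@faces))

#' @rdname TriMesh
#' @export
setMethod("vertexNormals", "TriMesh", function(x) {
  if (nrow(x@vnormals) > 0) return(x@vnormals)
  computeVertexNormals(x)
})

setMethod("show", "TriMesh", function(object) {
  closed <- isClosedMesh(object)
  cat(sprintf("TriMesh: %d vertices, %d faces, %s\n",
              nVertices(object), nFaces(object),
              if (closed) "closed" else
                sprintf("%d boundary edges", boundaryEdgeCount(object))))
  if (nVertices(object) > 0) {
    bb <- apply(object@vertices, 2, range)
    cat(sprintf("  bbox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
  invisible(object)
})

# per-face signed tetra volumes w.r.t. the origin
signedTetraVolumes <- function(mesh) {
  f <- mesh@faces
  v <- mesh@vertices
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  rowSums(a * crossRows(b, cc)) / 6
}

#' Face normals (unit) of a mesh
#' @param mesh a [TriMesh-class].
#' @return nFaces x 3 matrix.
#' @export
faceNormals <- function(mesh) {
  f <- mesh@faces
  v <- mesh@vertices
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  normalizeRows(crossRows(b - a, cc - a))
}

# angle-weighted average of incident face normals
computeVertexNormals <- function(mesh) {
  f <- mesh@faces
  v <- mesh@vertices
  fn <- faceNormals(mesh)
  corner <- function(i, j, k) {
    e1 <- normalizeRows(v[f[, j], , drop = FALSE] - v[f[, i], , drop = FALSE])
    e2 <- normalizeRows(v[f[, k], , drop = FALSE] - v[f[, i], , drop = FALSE])
    acos(pmax(-1, pmin(1, rowSums(e1 * e2))))
  }
  out <- matrix(0, nrow(v), 3)
  for (c in 1:3) {
    oth <- setdiff(1:3, c)
    w <- corner(c, oth[1], oth[2])
    acc <- rowsum(w * fn, group = f[, c])
    rows <- as.integer(rownames(acc))
    out[rows, ] <- out[rows, ] + acc
  }
  normalizeRows(out)
}

# directed edges as a 2-column matrix
meshEdges <- function(mesh) {
  f <- mesh@faces
  rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
}

# numeric undirected edge keys (indices stay well below 2^26)
edgeKeys <- function(mesh) {
  e <- meshEdges(mesh)
  pmin(e[, 1], e[, 2]) * 2^26 + pmax(e[, 1], e[, 2])
}

# multiplicity of each undirected edge (sorted run lengths)
edgeUseCounts <- function(mesh) rle(sort(edgeKeys(mesh)))$lengths

#' Number of boundary edges (edges used by exactly one face)
#' @param mesh a [TriMesh-class].
#' @export
boundaryEdgeCount <- function(mesh) {
  if (nFaces(mesh) == 0) return(0L)
  sum(edgeUseCounts(mesh) == 1)
}

#' Is the mesh closed (watertight)?
#'
#' TRUE when every undirected edge is shared by exactly two faces.
#' @param mesh a [TriMesh-class].
#' @export
isClosedMesh <- function(mesh) {
  if (nFaces(mesh) == 0) return(FALSE)
  all(edgeUseCounts(mesh) == 2)
}

#' Euler characteristic V - E + F
#' @param mesh a [TriMesh-class].
#' @export
eulerCharacteristic <- function(mesh) {
  nVertices(mesh) - length(edgeUseCounts(mesh)) + nFaces(mesh)
}

#' Merge coincident vertices
#'
#' Welds vertices closer than `tol` (mm) and drops faces that collapse.
#' @param mesh a [TriMesh-class].
#' @param tol weld tolerance, mm.
#' @export
weldMesh <- function(mesh, tol = 1e-6) {
  w <- cpp_weld_vertices(mesh@vertices, mesh@faces, tol)
  TriMesh(w$vertices, w$faces)
}
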