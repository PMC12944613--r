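# Generic mesh operators: signed volume, planar slicing, smoothing.

#' Enclosed volume of a closed mesh
#'
#' Signed sum of origin-tetrahedra over all faces. Positive for outward
#' orientation; an inward-wound closed mesh is reported with positive volume
#' and an orientation-flip warning.
#'
#' @param mesh a closed [TriMesh-class].
#' @return volume in mm^3.
#' @export
meshVolume <- function(mesh) {
  nb <- boundaryEdgeCount(mesh)
  if (nb > 0)
    stop(sprintf("mesh is not closed: %d boundary edges", nb))
  vol <- sum(signedTetraVolumes(mesh))
  if (vol < 0) {
    warning("mesh orientation is inward-facing; reporting |volume|")
    vol <- -vol
  }
  vol
}

#' Intersect a mesh with a plane
#'
#' Returns the closed intersection polylines (loops), ordered by descending
#' enclosed area. An empty intersection gives an empty list.
#'
#' @param mesh a [TriMesh-class].
#' @param p a [Plane-class].
#' @return list of loops; each loop is an ordered k x 3 matrix of points (mm)
#'   with attributes `perimeter` (mm) and `area` (mm^2).
#' @export
sliceMesh <- function(mesh, p) {
  v <- mesh@vertices
  f <- mesh@faces
  s <- as.vector((v %*% p@normal) - sum(p@point * p@normal))
  # nudge exact-plane vertices off the plane for a deterministic topology
  eps <- max(1e-12, 1e-12 * max(abs(s)))
  s[s == 0] <- eps
  sf <- matrix(s[f], ncol = 3)
  crossing <- (apply(sf, 1, min) < 0) & (apply(sf, 1, max) > 0)
  if (!any(crossing)) return(list())
  f <- f[crossing, , drop = FALSE]
  sf <- sf[crossing, , drop = FALSE]
  segs <- vector("list", nrow(f))
  keys <- matrix("", nrow(f), 2)
  edgeCut <- function(i, j, si, sj) {
    t <- si / (si - sj)
    v[i, ] + t * (v[j, ] - v[i, ])
  }
  for (t in seq_len(nrow(f))) {
    idx <- f[t, ]
    ss <- sf[t, ]
    pos <- which(ss > 0)
    neg <- which(ss < 0)
    apex <- if (length(pos) == 1) pos else neg
    oth <- setdiff(1:3, apex)
    p1 <- edgeCut(idx[apex], idx[oth[1]], ss[apex], ss[oth[1]])
    p2 <- edgeCut(idx[apex], idx[oth[2]], ss[apex], ss[oth[2]])
    segs[[t]] <- rbind(p1, p2)
    keys[t, ] <- c(paste(min(idx[apex], idx[oth[1]]), max(idx[apex], idx[oth[1]])),
                   paste(min(idx[apex], idx[oth[2]]), max(idx[apex], idx[oth[2]])))
  }
  # link segments into loops through shared cut edges
  edgeMap <- split(rep(seq_len(nrow(f)), 2), as.vector(keys))
  used <- rep(FALSE, nrow(f))
  loops <- list()
  for (start in seq_len(nrow(f))) {
    if (used[start]) next
    pts <- list()
    cur <- start
    curKey <- keys[cur, 1]
    repeat {
      used[cur] <- TRUE
      ends <- keys[cur, ]
      hit <- if (ends[1] == curKey) 1 else 2
      other <- 3 - hit
      pts[[length(pts) + 1]] <- segs[[cur]][hit, ]
      nextKey <- ends[other]
      cand <- setdiff(edgeMap[[nextKey]], cur)
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      cur <- cand[1]
      curKey <- nextKey
    }
    loop <- do.call(rbind, pts)
    if (nrow(loop) >= 3) loops[[length(loops) + 1]] <- loop
  }
  # in-plane basis for areas
  b1 <- if (abs(p@normal[1]) < 0.9) cross3(p@normal, c(1, 0, 0)) else
    cross3(p@normal, c(0, 1, 0))
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- cross3(p@normal, b1)
  loops <- lapply(loops, function(L) {
    u <- (L - matrix(p@point, nrow(L), 3, byrow = TRUE)) %*% cbind(b1, b2)
    nr <- nrow(u)
    nxt <- c(2:nr, 1)
    area <- abs(sum(u[, 1] * u[nxt, 2] - u[nxt, 1] * u[, 2]) / 2)
    per <- sum(sqrt(rowSums((L[nxt, , drop = FALSE] - L)^2)))
    attr(L, "area") <- area
    attr(L, "perimeter") <- per
    L
  })
  areas <- vapply(loops, attr, numeric(1), which = "area")
  loops[order(areas, decreasing = TRUE)]
}

#' Cross-section perimeter at a plane
#'
#' Perimeter of the largest-area intersection loop; additional loops (handles,
#' noise) are reported in the `extraLoops` attribute, not added to the
#' perimeter.
#'
#' @inheritParams sliceMesh
#' @return perimeter in mm (NA when the plane misses the mesh), with
#'   attribute `extraLoops`.
#' @export
slicePerimeter <- function(mesh, p) {
  loops <- sliceMesh(mesh, p)
  if (length(loops) == 0) return(structure(NA_real_, extraLoops = 0L))
  structure(attr(loops[[1]], "perimeter"),
            extraLoops = length(loops) - 1L)
}

# sparse uniform adjacency operator and boundary flags
meshUmbrella <- function(mesh) {
  f <- mesh@faces
  n <- nVertices(mesh)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- unique(rbind(e, e[, c(2, 1)]))
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  und <- meshEdges(mesh)
  key <- pmin(und[, 1], und[, 2]) * 2^26 + pmax(und[, 1], und[, 2])
  ord <- order(key)
  ks <- key[ord]
  once <- rle(ks)
  singles <- once$values[once$lengths == 1]
  bEdges <- und[ord[ks %in% singles], , drop = FALSE]
  boundary <- rep(FALSE, n)
  boundary[unique(as.vector(bEdges))] <- TRUE
  list(A = A, deg = deg, boundary = boundary)
}

faceNormalsOf <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  normalizeRows(crossRows(b - a, cc - a))
}

#' Surface-preserving Laplacian smoothing
#'
#' Uniform-umbrella Laplacian smoothing in which a vertex keeps its proposed
#' position only if no incident face normal rotates by `maxNormalAngleDeg`
#' degrees or more in that iteration; boundary vertices are pinned. Topology
#' is unchanged and `iterations = 0` is the identity.
#'
#' @param mesh a [TriMesh-class].
#' @param iterations number of smoothing passes (default 20).
#' @param maxNormalAngleDeg maximal allowed per-iteration face-normal
#'   rotation, degrees (default 90).
#' @return smoothed [TriMesh-class].
#' @export
laplacianSmoothPreserving <- function(mesh, iterations = 20,
                                      maxNormalAngleDeg = 90) {
  stopifnot(iterations >= 0)
  if (iterations == 0 || nFaces(mesh) == 0) return(mesh)
  umb <- meshUmbrella(mesh)
  v <- mesh@vertices
  f <- mesh@faces
  cosMax <- cos(maxNormalAngleDeg * pi / 180)
  for (it in seq_len(iterations)) {
    prop <- as.matrix(umb$A %*% v) / umb$deg
    prop[umb$boundary, ] <- v[umb$boundary, ]
    n0 <- faceNormalsOf(v, f)
    # guard per vertex: would moving this vertex alone rotate an incident
    # face normal by >= maxNormalAngleDeg?
    movable <- rep(TRUE, nrow(v))
    for (c in 1:3) {
      vc <- v
      idx <- f[, c]
      vc2 <- list(v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                  v[f[, 3], , drop = FALSE])
      vc2[[c]] <- prop[idx, , drop = FALSE]
      nc <- normalizeRows(crossRows(vc2[[2]] - vc2[[1]], vc2[[3]] - vc2[[1]]))
      bad <- rowSums(n0 * nc) <= cosMax
      movable[idx[bad]] <- FALSE
    }
    keep <- !movable
    prop[keep, ] <- v[keep, ]
    v <- prop
  }
  new("TriMesh", vertices = v, faces = mesh@faces,
      vnormals = matrix(numeric(0), 0, 3))
}

#' Taubin lambda/mu smoothing
#'
#' Shrink-compensating smoothing: alternating umbrella steps with positive
#' `lambda` and negative `mu`, `|mu| > lambda`. Preserves topology and (for
#' the default pair) the enclosed volume to well under 1 percent.
#'
#' @param mesh a [TriMesh-class].
#' @param lambda positive smoothing factor (default 0.5).
#' @param mu negative expansion factor (default -0.53).
#' @param iterations number of lambda+mu pairs (default 10).
#' @return smoothed [TriMesh-class].
#' @export
taubinSmooth <- function(mesh, lambda = 0.5, mu = -0.53, iterations = 10) {
  stopifnot(lambda > 0, mu < 0, abs(mu) > lambda, iterations >= 0)
  if (iterations == 0 || nFaces(mesh) == 0) return(mesh)
  umb <- meshUmbrella(mesh)
  v <- mesh@vertices
  step <- function(v, w) {
    lap <- as.matrix(umb$A %*% v) / umb$deg - v
    lap[umb$boundary, ] <- 0
    v + w * lap
  }
  for (it in seq_len(iterations)) {
    v <- step(v, lambda)
    v <- step(v, mu)
  }
  new("TriMesh", vertices = v, faces = mesh@faces,
      vnormals = matrix(numeric(0), 0, 3))
}
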