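# Analytic test-bed primitives: cube, icosphere, capped cylinder.

#' Axis-aligned cube mesh
#'
#' @param side side length, mm.
#' @param center cube centre, mm.
#' @return closed [TriMesh-class] (8 vertices, 12 faces), outward-oriented.
#' @export
meshCube <- function(side = 1, center = c(0, 0, 0)) {
  h <- side / 2
  v <- unname(as.matrix(expand.grid(c(-h, h), c(-h, h), c(-h, h))))
  v <- sweep(v, 2, center, "+")
  # faces of the unit cube with outward winding (vertex order of expand.grid)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = -h
    c(5, 6, 7), c(6, 8, 7),   # z = +h
    c(1, 2, 5), c(2, 6, 5),   # y = -h
    c(3, 7, 4), c(4, 7, 8),   # y = +h
    c(1, 5, 3), c(3, 5, 7),   # x = -h
    c(2, 4, 6), c(4, 8, 6))   # x = +h
  TriMesh(v, f)
}

#' Subdivided icosahedron sphere mesh
#'
#' @param radius sphere radius, mm.
#' @param subdivisions number of 4-to-1 triangle subdivisions (0 = icosahedron).
#' @param center sphere centre, mm.
#' @return closed [TriMesh-class] with vertices exactly at `radius`.
#' @export
meshIcosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midCache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midCache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1
      vlist[[length(vlist) + 1]] <<- matrix(m, 1, 3)
      midCache[[key]] <- nv
      nv
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4 * t - 3, ] <- c(a, ab, ca)
      nf[4 * t - 2, ] <- c(b, bc, ab)
      nf[4 * t - 1, ] <- c(cc, ca, bc)
      nf[4 * t, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  TriMesh(sweep(radius * v, 2, center, "+"), f)
}

#' Capped cylinder mesh along +z
#'
#' Flat fan caps at z = 0 and z = height; volume is exactly the prism volume
#' of the tessellated polygon, `n r^2 sin(2 pi / n) / 2 * height`.
#'
#' @param radius cylinder radius, mm.
#' @param height cylinder height, mm.
#' @param segments angular resolution.
#' @param rings axial resolution (number of vertex rings, >= 2).
#' @return closed [TriMesh-class].
#' @export
meshCylinder <- function(radius = 30, height = 200, segments = 128, rings = 2) {
  th <- 2 * pi * (seq_len(segments) - 1) / segments
  z <- seq(0, height, length.out = rings)
  ringV <- function(zz) cbind(radius * cos(th), radius * sin(th), zz)
  v <- do.call(rbind, lapply(z, ringV))
  f <- NULL
  for (r in seq_len(rings - 1)) {
    lo <- (r - 1) * segments
    hi <- r * segments
    i <- seq_len(segments)
    j <- c(seq_len(segments - 1) + 1, 1)
    f <- rbind(f,
               cbind(lo + i, lo + j, hi + i),
               cbind(lo + j, hi + j, hi + i))
  }
  # caps: centre fans
  cBot <- nrow(v) + 1
  cTop <- nrow(v) + 2
  v <- rbind(v, c(0, 0, 0), c(0, 0, height))
  i <- seq_len(segments)
  j <- c(seq_len(segments - 1) + 1, 1)
  top0 <- (rings - 1) * segments
  f <- rbind(f,
             cbind(cBot, j, i),                 # bottom cap faces -z
             cbind(cTop, top0 + i, top0 + j))   # top cap faces +z
  TriMesh(v, f)
}
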