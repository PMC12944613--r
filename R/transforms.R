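#' Construct a rigid transform
#'
#' @param rotation 3 x 3 orthonormal matrix (det +1). Slightly non-orthonormal
#'   inputs are projected onto SO(3).
#' @param translation numeric length 3, mm.
#' @return a [RigidTransform-class].
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(rotation %*% t(rotation) - diag(3))) > 1e-12)
    rotation <- projectSO3(rotation)
  new("RigidTransform", rotation = rotation,
      translation = stopifnot3(translation, "translation"))
}

#' Construct a similarity transform
#'
#' @param scale positive scalar.
#' @inheritParams rigidTransform
#' @return a [SimilarityTransform-class].
#' @export
similarityTransform <- function(scale = 1, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(rotation %*% t(rotation) - diag(3))) > 1e-12)
    rotation <- projectSO3(rotation)
  new("SimilarityTransform", scale = as.numeric(scale), rotation = rotation,
      translation = stopifnot3(translation, "translation"))
}

#' Construct a plane from a point and a normal
#'
#' @param point numeric length 3, a point on the plane (mm).
#' @param normal numeric length 3; normalized internally.
#' @return a [Plane-class].
#' @export
plane <- function(point, normal) {
  normal <- stopifnot3(normal, "normal")
  n <- sqrt(sum(normal^2))
  if (n == 0) stop("plane normal must be non-zero")
  new("Plane", point = stopifnot3(point, "point"), normal = normal / n)
}

transformPoints <- function(points, transform) {
  s <- if (is(transform, "SimilarityTransform")) transform@scale else 1
  sweep(s * points %*% t(transform@rotation), 2, transform@translation, "+")
}

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("TriMesh", "RigidTransform"),
  function(x, transform) {
    vn <- if (nrow(x@vnormals) > 0) x@vnormals %*% t(transform@rotation) else x@vnormals
    new("TriMesh", vertices = transformPoints(x@vertices, transform),
        faces = x@faces, vnormals = vn)
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("TriMesh", "SimilarityTransform"),
  function(x, transform) {
    vn <- if (nrow(x@vnormals) > 0) x@vnormals %*% t(transform@rotation) else x@vnormals
    new("TriMesh", vertices = transformPoints(x@vertices, transform),
        faces = x@faces, vnormals = vn)
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("matrix", "ANY"),
  function(x, transform) transformPoints(x, transform))

#' @rdname inverseTransform
#' @export
setMethod("inverseTransform", "RigidTransform", function(x) {
  Rt <- t(x@rotation)
  rigidTransform(Rt, -as.vector(Rt %*% x@translation))
})

#' @rdname inverseTransform
#' @export
setMethod("inverseTransform", "SimilarityTransform", function(x) {
  Rt <- t(x@rotation)
  similarityTransform(1 / x@scale, Rt, -as.vector(Rt %*% x@translation) / x@scale)
})

#' Compose two transforms (first `b`, then `a`)
#'
#' @param a,b rigid or similarity transforms.
#' @return transform equal to `x -> a(b(x))`; similarity if either input is.
#' @export
composeTransforms <- function(a, b) {
  sa <- if (is(a, "SimilarityTransform")) a@scale else 1
  sb <- if (is(b, "SimilarityTransform")) b@scale else 1
  R <- a@rotation %*% b@rotation
  t <- sa * as.vector(a@rotation %*% b@translation) + a@translation
  if (sa * sb == 1 && is(a, "RigidTransform") && is(b, "RigidTransform"))
    rigidTransform(R, t)
  else
    similarityTransform(sa * sb, R, t)
}

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform: rotation angle",
      sprintf("%.4f deg,", rotationAngleDeg(object@rotation)),
      "translation", sprintf("(%.3f, %.3f, %.3f) mm\n",
                             object@translation[1], object@translation[2],
                             object@translation[3]))
  invisible(object)
})

setMethod("show", "SimilarityTransform", function(object) {
  cat(sprintf("SimilarityTransform: scale %.6g, rotation angle %.4f deg, ",
              object@scale, rotationAngleDeg(object@rotation)),
      sprintf("translation (%.3f, %.3f, %.3f) mm\n", object@translation[1],
              object@translation[2], object@translation[3]))
  invisible(object)
})

#' 4 x 4 homogeneous matrix of a transform
#' @param transform rigid or similarity transform.
#' @export
asMatrix4 <- function(transform) {
  s <- if (is(transform, "SimilarityTransform")) transform@scale else 1
  m <- diag(4)
  m[1:3, 1:3] <- s * transform@rotation
  m[1:3, 4] <- transform@translation
  m
}
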