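#' @rdname TriMesh
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname TriMesh
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))

#' @rdname TriMesh
#' @export
setGeneric("vertexNormals", function(x) standardGeneric("vertexNormals"))

#' @rdname TriMesh
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname TriMesh
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' Apply a rigid or similarity transform
#'
#' Maps every vertex/point v to `s * R v + t` (rigid transforms have s = 1).
#' For meshes, normals are rotated; topology is unchanged. Volume scales by
#' `s^3`.
#'
#' @param x a `TriMesh`, point matrix, or transform to compose with.
#' @param transform a [RigidTransform-class] or [SimilarityTransform-class].
#' @return object of the same kind as `x`.
#' @export
setGeneric("applyTransform", function(x, transform) standardGeneric("applyTransform"))

#' Invert a transform
#' @param x a transform object.
#' @export
setGeneric("inverseTransform", function(x) standardGeneric("inverseTransform"))
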