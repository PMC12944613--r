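#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib limbmetric, .registration = TRUE
NULL

#' Triangle surface mesh in millimetres
#'
#' The universal geometry container of the package: an indexed triangle mesh
#' with vertices in mm, 1-based face indices, and optional unit per-vertex
#' normals. Use [TriMesh()] to construct (it cleans degenerate faces and
#' re-orients inverted closed meshes), and [vertices()], [faces()],
#' [vertexNormals()] to access.
#'
#' @slot vertices numeric matrix, n x 3, mm.
#' @slot faces integer matrix, m x 3, 1-based vertex indices.
#' @slot vnormals numeric matrix, n x 3 unit normals, or 0 x 3 when unset.
#' @export
setClass("TriMesh", representation(
  vertices = "matrix",
  faces = "matrix",
  vnormals = "matrix"
), validity = function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3) return("vertices must have 3 columns")
  if (ncol(f) != 3) return("faces must have 3 columns")
  if (nrow(f) > 0) {
    if (min(f) < 1 || max(f) > nrow(v)) return("face indices out of range")
    if (any(f != round(f))) return("face indices must be integral")
  }
  if (nrow(object@vnormals) > 0 && nrow(object@vnormals) != nrow(v))
    return("vnormals must match vertex count")
  TRUE
})

#' An infinite plane (point + unit normal)
#'
#' @slot point numeric length 3, a point on the plane (mm).
#' @slot normal numeric length 3, unit normal.
#' @export
setClass("Plane", representation(point = "numeric", normal = "numeric"),
  validity = function(object) {
    if (length(object@point) != 3) return("point must have length 3")
    if (length(object@normal) != 3) return("normal must have length 3")
    if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9) return("normal must be unit")
    TRUE
  })

#' Rigid (SE(3)) transform
#'
#' @slot rotation 3 x 3 orthonormal matrix with det +1.
#' @slot translation numeric length 3 (mm).
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  validity = function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
    if (length(object@translation) != 3) return("translation must have length 3")
    if (max(abs(R %*% t(R) - diag(3))) > 1e-9) return("rotation not orthonormal")
    if (det(R) < 0) return("rotation must have det +1")
    TRUE
  })

#' Similarity (scaled rigid) transform
#'
#' @slot scale positive scalar.
#' @slot rotation 3 x 3 orthonormal matrix.
#' @slot translation numeric length 3 (mm).
#' @export
setClass("SimilarityTransform",
  representation(scale = "numeric", rotation = "matrix", translation = "numeric"),
  validity = function(object) {
    if (length(object@scale) != 1 || object@scale <= 0) return("scale must be positive")
    R <- object@rotation
    if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
    if (max(abs(R %*% t(R) - diag(3))) > 1e-9) return("rotation not orthonormal")
    if (length(object@translation) != 3) return("translation must have length 3")
    TRUE
  })

#' Scalar voxel volume with isotropic spacing
#'
#' @slot intensities 3D numeric array.
#' @slot spacing isotropic voxel size, mm.
#' @slot origin world position of voxel (1,1,1) centre, mm.
#' @export
setClass("VoxelVolume",
  representation(intensities = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(dim(object@intensities)) != 3) return("intensities must be 3D")
    if (any(dim(object@intensities) < 1)) return("grid must be non-empty")
    if (length(object@spacing) != 1 || object@spacing <= 0)
      return("spacing must be a positive scalar")
    if (length(object@origin) != 3) return("origin must have length 3")
    TRUE
  })

#' Overlapping-slab decomposition along z
#'
#' Half-open 0-based voxel-layer ranges; consecutive slabs share exactly
#' `overlap` layers and their union covers the volume.
#'
#' @slot height slab height, voxels.
#' @slot overlap shared layers between consecutive slabs, voxels.
#' @slot starts,ends integer vectors of half-open 0-based z ranges.
#' @export
setClass("SlabPlan",
  representation(height = "integer", overlap = "integer",
                 starts = "integer", ends = "integer"),
  validity = function(object) {
    if (object@overlap >= object@height) return("overlap must be < slab height")
    if (length(object@starts) != length(object@ends)) return("ragged ranges")
    if (any(object@ends <= object@starts)) return("empty slab range")
    k <- length(object@starts)
    if (k > 1) {
      sh <- object@ends[-k] - object@starts[-1]
      if (any(sh != object@overlap))
        return("consecutive slabs must share exactly `overlap` layers")
    }
    TRUE
  })

#' Pinhole camera intrinsics
#'
#' @slot fx,fy focal lengths (px); @slot cx,cy principal point (px).
#' @slot distortion radial/tangential coefficients (possibly empty).
#' @export
setClass("CameraIntrinsics",
  representation(fx = "numeric", fy = "numeric", cx = "numeric", cy = "numeric",
                 distortion = "numeric"),
  validity = function(object) {
    if (object@fx <= 0 || object@fy <= 0) return("focal lengths must be positive")
    TRUE
  })

#' Square-tag corner detections in one image
#'
#' Corners per tag in fixed order: top-left, top-right, bottom-right,
#' bottom-left of the canonical tag frame.
#'
#' @slot imageId character scalar.
#' @slot tagIds integer vector.
#' @slot corners list of 4 x 2 pixel-coordinate matrices, parallel to tagIds.
#' @export
setClass("TagDetections",
  representation(imageId = "character", tagIds = "integer", corners = "list"),
  validity = function(object) {
    if (length(object@tagIds) != length(object@corners)) return("ragged detections")
    ok <- vapply(object@corners, function(m) is.matrix(m) && all(dim(m) == c(4, 2)),
                 logical(1))
    if (!all(ok)) return("each tag needs a 4 x 2 corner matrix")
    if (anyDuplicated(object@tagIds)) return("duplicate tag ids in one image")
    TRUE
  })

#' Metric map of square fiducial tags
#'
#' World pose of each tag plane (tag frame: corners at (+-s/2, +-s/2, 0)),
#' with the root tag gauge-fixed to the identity.
#'
#' @slot tagSide physical tag side length, mm.
#' @slot poses named list of [RigidTransform-class], names = tag ids.
#' @slot rootId integer id of the gauge tag.
#' @export
setClass("TagMap",
  representation(tagSide = "numeric", poses = "list", rootId = "integer"),
  validity = function(object) {
    if (object@tagSide <= 0) return("tagSide must be positive")
    root <- object@poses[[as.character(object@rootId)]]
    if (is.null(root)) return("root tag missing from map")
    if (max(abs(root@rotation - diag(3))) > 1e-6 || max(abs(root@translation)) > 1e-6)
      return("root tag pose must be the identity (gauge fix)")
    TRUE
  })

#' Camera trajectory (world-to-camera poses per image)
#'
#' @slot poses named list of [RigidTransform-class], names = image ids.
#' @export
setClass("Trajectory", representation(poses = "list"))

#' Region of interest along the limb axis
#'
#' The ROI runs from the distal limb end to the anatomical landmark plane
#' (Mid-Patellar Tendon for transtibial, adductor/ischial midpoint BAR for
#' transfemoral), `landmarkHeight` mm along `axis` from `distal`.
#'
#' @slot axis unit limb axis; @slot distal distal end point (mm).
#' @slot landmarkHeight landmark plane height along the axis, mm (> 0).
#' @slot label "MPT" or "BAR".
#' @export
setClass("RoiSpec",
  representation(axis = "numeric", distal = "numeric",
                 landmarkHeight = "numeric", label = "character"),
  validity = function(object) {
    if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-9) return("axis must be unit")
    if (object@landmarkHeight <= 0) return("landmarkHeight must be > 0")
    if (!object@label %in% c("MPT", "BAR")) return("label must be MPT or BAR")
    TRUE
  })

#' Clinical accuracy thresholds
#'
#' Defaults: |MRE| <= 0.25 mm, IQR <= 0.4 mm, RMSE < 1 mm, Hausdorff <= 1.8 mm,
#' MAE < 4 deg, |bias| <= 1 %, MDC < 3.5 %.
#'
#' @export
setClass("Thresholds",
  representation(mre = "numeric", iqr = "numeric", rmse = "numeric",
                 hausdorff = "numeric", mae = "numeric", bias = "numeric",
                 mdc = "numeric"),
  prototype(mre = 0.25, iqr = 0.4, rmse = 1.0, hausdorff = 1.8, mae = 4.0,
            bias = 1.0, mdc = 3.5),
  validity = function(object) {
    vals <- c(object@mre, object@iqr, object@rmse, object@hausdorff, object@mae,
              object@bias, object@mdc)
    if (any(vals <= 0)) return("all thresholds must be positive")
    TRUE
  })

#' Surface accuracy report
#'
#' @slot mre signed mean radial error, mm; @slot rmse root mean square, mm.
#' @slot iqr interquartile range of signed distances, mm.
#' @slot hausdorff symmetric Hausdorff distance, mm.
#' @slot mae mean angular error, degrees.
#' @slot perimeterErrors per-slice relative perimeter errors (fractions);
#'   NA where a slice plane missed either mesh.
#' @slot verel relative ROI volume error (fraction).
#' @slot flags named logical per-metric threshold compliance.
#' @export
setClass("AccuracyReport",
  representation(mre = "numeric", rmse = "numeric", iqr = "numeric",
                 hausdorff = "numeric", mae = "numeric",
                 perimeterErrors = "numeric", verel = "numeric",
                 flags = "logical"),
  validity = function(object) {
    if (object@rmse + 1e-12 < abs(object@mre)) return("RMSE must be >= |MRE|")
    if (object@iqr < 0) return("IQR must be >= 0")
    if (object@mae < 0 || object@mae > 180) return("MAE must lie in [0, 180]")
    TRUE
  })

#' Bias and minimal detectable change of repeat relative errors
#'
#' @slot bias mean of repeat relative errors, percent.
#' @slot mdc 1.96 * sqrt(2) * sample SD, percent.
#' @export
setClass("BiasMdc", representation(bias = "numeric", mdc = "numeric",
                                   sd = "numeric"),
  validity = function(object) {
    if (object@mdc < 0) return("mdc must be >= 0")
    TRUE
  })

#' Rigid registration result
#'
#' @slot transform source-to-target [RigidTransform-class].
#' @slot inlierRms RMS of matched correspondences, mm.
#' @slot fitness fraction of source points with a correspondence within the
#'   final distance threshold.
#' @slot diagnostics per-stage trace (list).
#' @export
setClass("RegistrationResult",
  representation(transform = "RigidTransform", inlierRms = "numeric",
                 fitness = "numeric", diagnostics = "list"),
  validity = function(object) {
    if (object@fitness < 0 || object@fitness > 1) return("fitness must be in [0,1]")
    if (object@inlierRms < 0) return("inlierRms must be >= 0")
    TRUE
  })

#' Inter-session repeatability report
#'
#' Per-vertex variability of repeats around the medoid mesh, plus the pooled
#' SD over all vertex x repeat signed distances and the MDC derived from it.
#'
#' @slot medoidIndex index of the medoid among the repeats.
#' @slot sd,iqr,p95 per-medoid-vertex SD / IQR / 95th percentile of |d|, mm.
#' @slot pooledSd global SD of the pooled signed distances, mm.
#' @slot mdc 1.96 * sqrt(2) * pooledSd, mm.
#' @export
setClass("RepeatabilityReport",
  representation(medoidIndex = "integer", sd = "numeric", iqr = "numeric",
                 p95 = "numeric", pooledSd = "numeric", mdc = "numeric"),
  validity = function(object) {
    n <- length(object@sd)
    if (length(object@iqr) != n || length(object@p95) != n)
      return("per-vertex arrays must have equal length")
    if (object@pooledSd < 0) return("pooledSd must be >= 0")
    if (abs(object@mdc - 1.96 * sqrt(2) * object@pooledSd) > 1e-9)
      return("mdc must equal 1.96*sqrt(2)*pooledSd")
    TRUE
  })

#' Parametric limb-phantom specification
#'
#' Four archetype families of residual-limb shapes: conical and cylindrical
#' (transtibial), bulbous "aqua" and ischial-offset (transfemoral). The limb
#' axis is +z with the distal end at z = 0.
#'
#' @slot family one of "conical", "cylindrical", "bulbous", "ischial".
#' @slot length limb length along z, mm; @slot baseRadius proximal radius, mm.
#' @slot taper distal/proximal radius ratio for the conical family.
#' @slot bulbRadius,bulbPosition bulb amplitude (fraction of base radius) and
#'   axial position (fraction of length) for the bulbous family.
#' @slot lateralOffset lateral sinusoidal centre offset amplitude, mm
#'   (ischial family).
#' @slot crest amplitude (fraction of the local radius) of a localized
#'   anterior prominence that breaks rotational symmetry, as real residual
#'   limbs do; 0 keeps the pure surface of revolution (and the closed-form
#'   volumes/perimeters of the cylindrical and conical families).
#' @slot segments angular resolution; @slot rings axial resolution.
#' @export
setClass("PhantomSpec",
  representation(family = "character", length = "numeric", baseRadius = "numeric",
                 taper = "numeric", bulbRadius = "numeric",
                 bulbPosition = "numeric", lateralOffset = "numeric",
                 crest = "numeric",
                 segments = "integer", rings = "integer"),
  validity = function(object) {
    if (!object@family %in% c("conical", "cylindrical", "bulbous", "ischial"))
      return("unknown phantom family")
    if (object@length <= 0 || object@baseRadius <= 0)
      return("length and baseRadius must be positive")
    if (object@segments < 16 || object@rings < 16)
      return("resolutions must be >= 16")
    TRUE
  })

#' Batch-validation manifest
#'
#' One row per reconstructed mesh (model x modality x repeat), a reference
#' mesh per model, an ROI per model, thresholds and the run seed.
#'
#' @slot entries data.frame with columns model, modality, repeatIndex, path.
#' @slot reference named character: model id -> reference mesh path.
#' @slot roi named list of [RoiSpec-class] per model id.
#' @slot thresholds [Thresholds-class].
#' @slot seed integer.
#' @export
setClass("RunManifest",
  representation(entries = "data.frame", reference = "character", roi = "list",
                 thresholds = "Thresholds", seed = "integer"),
  validity = function(object) {
    need <- c("model", "modality", "repeatIndex", "path")
    if (!all(need %in% names(object@entries)))
      return("entries needs columns model, modality, repeatIndex, path")
    key <- with(object@entries, paste(model, modality, repeatIndex))
    if (anyDuplicated(key)) return("repeat indices must be unique per (model, modality)")
    mods <- unique(object@entries$model)
    if (!all(mods %in% names(object@reference)))
      return("every model needs a reference mesh")
    if (!all(mods %in% names(object@roi))) return("every model needs an ROI")
    TRUE
  })
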