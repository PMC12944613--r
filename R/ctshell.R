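# CT outer-shell extraction: global Otsu threshold, slab-wise cavity-removing
# background propagation, signed distance fields, Gaussian regularization and
# isosurface extraction into one watertight mesh.

#' Voxel volume constructor
#'
#' @param intensities 3D numeric array (x, y, z).
#' @param spacing isotropic voxel size, mm (e.g. 0.1 for 100 um CT voxels).
#' @param origin world position of the first voxel centre, mm.
#' @return a [VoxelVolume-class].
#' @export
voxelVolume <- function(intensities, spacing, origin = c(0, 0, 0)) {
  new("VoxelVolume", intensities = intensities, spacing = spacing,
      origin = stopifnot3(origin, "origin"))
}

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("VoxelVolume: %d x %d x %d voxels at %.4g mm (%.1f x %.1f x %.1f mm)\n",
              d[1], d[2], d[3], object@spacing,
              d[1] * object@spacing, d[2] * object@spacing, d[3] * object@spacing))
  invisible(object)
})

#' Overlapping slab plan along z
#'
#' Slabs of `height` voxel layers stepping by `height - overlap`, so that
#' consecutive slabs share exactly `overlap` layers; the final slab is
#' shortened to end at the volume. Defaults (256 / 32) keep the overlap well
#' above the distance-field smoothing support so that slab seams never show
#' in the slab cores.
#'
#' @param nz number of z layers in the volume.
#' @param height slab height, voxels.
#' @param overlap shared layers, voxels (< height).
#' @return a [SlabPlan-class] with half-open 0-based ranges.
#' @export
slabPlan <- function(nz, height = 256, overlap = 32) {
  height <- as.integer(height)
  overlap <- as.integer(overlap)
  if (overlap >= height) stop("overlap must be smaller than slab height")
  if (nz <= height) {
    starts <- 0L
    ends <- as.integer(nz)
  } else {
    step <- height - overlap
    k <- ceiling((nz - height) / step) + 1
    starts <- as.integer((seq_len(k) - 1) * step)
    ends <- as.integer(pmin(starts + height, nz))
    # drop a redundant last slab fully inside the previous one
    keep <- c(TRUE, diff(ends) > 0)
    starts <- starts[keep]
    ends <- ends[keep]
  }
  new("SlabPlan", height = height, overlap = overlap,
      starts = starts, ends = ends)
}

setMethod("show", "SlabPlan", function(object) {
  cat(sprintf("SlabPlan: %d slab(s) of height %d, overlap %d\n",
              length(object@starts), object@height, object@overlap))
  invisible(object)
})

#' Global Otsu threshold of a volume
#'
#' Maximizes the between-class variance of the full-volume histogram over 256
#' uniform bins between the global min and max; the threshold is global, not
#' per-slab, and independent of acquisition bit depth.
#'
#' @param volume a [VoxelVolume-class] (or bare numeric array).
#' @return intensity threshold (a bin boundary strictly inside the range).
#' @export
otsuThreshold <- function(volume) {
  x <- if (is(volume, "VoxelVolume")) volume@intensities else volume
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("constant volume: Otsu threshold undefined")
  nb <- 256L
  h <- tabulate(pmin(nb, floor((x - lo) / (hi - lo) * nb) + 1L), nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(nb) - 0.5))
  muT <- mu[nb]
  k <- seq_len(nb - 1)
  sigmaB <- (muT * omega[k] - mu[k])^2 / (omega[k] * (1 - omega[k]))
  sigmaB[!is.finite(sigmaB)] <- -Inf
  kOpt <- which.max(sigmaB)
  lo + kOpt * (hi - lo) / nb
}

#' Remove internal cavities from a binary slab
#'
#' Background 6-connected to a seeded boundary face stays background; all
#' other background voxels (internal cavities) become foreground. Foreground
#' is never removed, so the operation is monotone and idempotent.
#'
#' @param binary 3D logical/numeric array (TRUE = material).
#' @param seedFaces logical length 6: which of the faces
#'   (x0, x1, y0, y1, z0, z1) seed the background propagation (default all).
#' @return 3D logical array of the solid.
#' @export
fillOuterShell <- function(binary, seedFaces = rep(TRUE, 6)) {
  d <- dim(binary)
  stopifnot(length(d) == 3, length(seedFaces) == 6)
  out <- cpp_fill_outer_shell(as.logical(binary), as.integer(d),
                              as.logical(seedFaces))
  array(out, dim = d)
}

#' Signed Euclidean distance field of a binary solid
#'
#' Exact Euclidean distance transform on both sides, in mm: negative inside,
#' positive outside, zero crossing between the two voxel layers flanking the
#' surface.
#'
#' @param solid 3D logical array.
#' @param spacing voxel size, mm.
#' @return 3D numeric array (mm).
#' @export
signedDistanceField <- function(solid, spacing) {
  d <- dim(solid)
  if (all(solid) || !any(solid))
    warning("solid is single-phase; the distance field has a single sign")
  out <- cpp_signed_distance_field(as.logical(solid), as.integer(d), spacing)
  array(out, dim = d)
}

#' Watertight outer-shell mesh from a CT volume
#'
#' Slab-wise pipeline: global Otsu binarization, per-slab cavity-removing
#' background propagation (x/y slab faces always seed; z faces only where
#' they are true volume ends, so that slab cut surfaces never appear),
#' signed distance field, Gaussian smoothing (sigma in voxels), then a single
#' isosurface extraction at level 0 over the slab cores with shared-edge
#' welding, followed by Taubin smoothing. Errors if the result is not
#' watertight.
#'
#' @param volume a [VoxelVolume-class].
#' @param plan a [SlabPlan-class]; default [slabPlan()] of the volume.
#' @param smoothSigma Gaussian sigma in voxels (default 1).
#' @param taubinIterations Taubin lambda/mu pairs applied to the final mesh
#'   (default 10; 0 disables).
#' @param threshold optional intensity threshold overriding Otsu.
#' @return closed [TriMesh-class] in mm.
#' @export
shellMeshFromVolume <- function(volume, plan = NULL, smoothSigma = 1,
                                taubinIterations = 10, threshold = NULL) {
  d <- dim(volume@intensities)
  if (is.null(plan)) plan <- slabPlan(d[3])
  validObject(plan)
  if (utils::tail(plan@ends, 1) != d[3] || plan@starts[1] != 0)
    stop("slab plan does not cover the volume")
  thr <- if (is.null(threshold)) otsuThreshold(volume) else threshold
  fg <- volume@intensities > thr
  nSlab <- length(plan@starts)
  sdfGlobal <- array(NA_real_, dim = d)
  ov2 <- plan@overlap %/% 2L
  for (s in seq_len(nSlab)) {
    z0 <- plan@starts[s]
    z1 <- plan@ends[s]
    sub <- fg[, , (z0 + 1):z1, drop = FALSE]
    seeds <- c(TRUE, TRUE, TRUE, TRUE, z0 == 0, z1 == d[3])
    solid <- fillOuterShell(sub, seeds)
    sdf <- signedDistanceField(solid, volume@spacing)
    sm <- array(cpp_gaussian3d(as.vector(sdf), as.integer(dim(sdf)), smoothSigma),
                dim = dim(sdf))
    core0 <- if (s == 1) z0 else z0 + ov2
    core1 <- if (s == nSlab) z1 else z1 - (plan@overlap - ov2)
    sdfGlobal[, , (core0 + 1):core1] <- sm[, , (core0 - z0 + 1):(core1 - z0)]
  }
  iso <- cpp_isosurface(as.vector(sdfGlobal), as.integer(d), volume@spacing,
                        volume@origin, 0L, as.integer(d[3] - 1))
  if (nrow(iso$vertices) == 0) stop("no isosurface found at the threshold")
  w <- cpp_weld_vertices(iso$vertices, iso$faces, 1e-6)
  mesh <- TriMesh(w$vertices, w$faces)
  nb <- boundaryEdgeCount(mesh)
  if (nb > 0)
    stop(sprintf("extracted shell is not watertight: %d open edges (object may touch the volume boundary)", nb))
  if (taubinIterations > 0) mesh <- taubinSmooth(mesh, iterations = taubinIterations)
  mesh
}

#' Read a multi-page TIFF stack as a voxel volume
#'
#' Pages become z layers; pixel rows/columns map to y/x.
#'
#' @param path TIFF file path.
#' @param spacing isotropic voxel size, mm (TIFF carries no reliable 3D
#'   spacing metadata, so it must be supplied).
#' @param origin world origin, mm.
#' @return a [VoxelVolume-class].
#' @export
readVolumeTiff <- function(path, spacing, origin = c(0, 0, 0)) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(d[2], d[1], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  voxelVolume(arr, spacing, origin)
}

#' Write a volume as a multi-page TIFF stack
#' @param volume a [VoxelVolume-class]; intensities are rescaled to [0, 1].
#' @param path output TIFF path.
#' @export
writeVolumeTiff <- function(volume, path) {
  x <- volume@intensities
  lo <- min(x); hi <- max(x)
  if (hi > lo) x <- (x - lo) / (hi - lo)
  pages <- lapply(seq_len(dim(x)[3]), function(k) t(x[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read an NRRD volume
#'
#' Minimal reader for 3D NRRD: ASCII header (attached), `raw`, `ascii`/`text`
#' or `gzip` encodings, little-endian scalar types. Spacing is taken from
#' `spacings` or `space directions` (must be isotropic) unless overridden.
#'
#' @param path NRRD file.
#' @param spacing optional isotropic spacing override, mm.
#' @return a [VoxelVolume-class].
#' @export
readVolumeNrrd <- function(path, spacing = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  readLine1 <- function() {
    chars <- raw(0)
    repeat {
      ch <- readBin(con, "raw", 1)
      if (length(ch) == 0 || ch == as.raw(10)) break
      chars <- c(chars, ch)
    }
    sub("\r$", "", rawToChar(chars))
  }
  magic <- readLine1()
  if (!grepl("^NRRD", magic)) stop("not an NRRD file")
  fields <- list()
  repeat {
    line <- readLine1()
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ":\\s*", perl = TRUE)[[1]]
    fields[[tolower(kv[1])]] <- paste(kv[-1], collapse = ": ")
  }
  sizes <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  if (length(sizes) != 3) stop("only 3D NRRD volumes are supported")
  type <- tolower(fields$type)
  enc <- tolower(fields$encoding)
  if (is.null(spacing)) {
    if (!is.null(fields$spacings)) {
      sp <- as.numeric(strsplit(trimws(fields$spacings), "\\s+")[[1]])
    } else if (!is.null(fields[["space directions"]])) {
      dirs <- regmatches(fields[["space directions"]],
                         gregexpr("-?[0-9.eE+]+", fields[["space directions"]]))[[1]]
      m <- matrix(as.numeric(dirs), 3, 3, byrow = TRUE)
      sp <- sqrt(rowSums(m^2))
    } else stop("NRRD has no spacing metadata; pass `spacing`")
    if (max(sp) - min(sp) > 1e-9 * max(sp))
      stop("anisotropic NRRD spacing; resample or pass `spacing`")
    spacing <- sp[1]
  }
  n <- prod(sizes)
  sizeOf <- c("uchar" = 1, "uint8" = 1, "char" = 1, "int8" = 1,
              "short" = 2, "int16" = 2, "ushort" = 2, "uint16" = 2,
              "int" = 4, "int32" = 4, "uint" = 4, "uint32" = 4,
              "float" = 4, "double" = 8)
  what <- if (type %in% c("float", "double")) "double" else "integer"
  if (enc == "raw") {
    vals <- readBin(con, what, n, size = sizeOf[[type]], endian = "little",
                    signed = !(sizeOf[[type]] < 4 && grepl("^u", type)))
  } else if (enc %in% c("ascii", "text", "txt")) {
    vals <- scan(con, what = double(), n = n, quiet = TRUE)
  } else if (enc %in% c("gzip", "gz")) {
    gz <- gzcon(con)
    vals <- readBin(gz, what, n, size = sizeOf[[type]], endian = "little",
                    signed = !(sizeOf[[type]] < 4 && grepl("^u", type)))
  } else stop(sprintf("unsupported NRRD encoding '%s'", enc))
  voxelVolume(array(as.numeric(vals), dim = sizes), spacing)
}
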