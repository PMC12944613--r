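# Parametric residual-limb phantoms and synthetic inputs: controlled
# deformations, vertex noise, voxelization with optional cavities, and
# pinhole projections of known tag layouts.

#' Phantom specification
#'
#' Archetypes of the four validated residual-limb shape families. The limb
#' axis is +z with the distal end at z = 0; cross-sections are circles (with
#' a posterior bulge and lateral centre offset for the ischial family).
#'
#' @param family "conical", "cylindrical", "bulbous" or "ischial".
#' @param length limb length, mm.
#' @param baseRadius proximal (base) radius, mm.
#' @param taper distal/proximal radius ratio (conical family).
#' @param bulbRadius bulb amplitude as a fraction of `baseRadius` (bulbous).
#' @param bulbPosition bulb axial position as a fraction of `length`.
#' @param lateralOffset lateral centre-offset amplitude, mm (ischial).
#' @param crest amplitude (fraction of the local radius) of a localized
#'   anterior prominence (an anatomical asymmetry such as a tibial crest)
#'   that makes the phantom uniquely registerable; 0 (the default) keeps the
#'   exact surface of revolution with its closed-form volume/perimeter.
#' @param segments angular resolution (>= 16).
#' @param rings axial resolution (>= 16).
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(family = c("conical", "cylindrical", "bulbous", "ischial"),
                        length = 200, baseRadius = 40, taper = 0.5,
                        bulbRadius = 0.25, bulbPosition = 0.25,
                        lateralOffset = 8, crest = 0, segments = 96,
                        rings = 60) {
  family <- match.arg(family)
  new("PhantomSpec", family = family, length = length, baseRadius = baseRadius,
      taper = taper, bulbRadius = bulbRadius, bulbPosition = bulbPosition,
      lateralOffset = lateralOffset, crest = crest,
      segments = as.integer(segments), rings = as.integer(rings))
}

# radius profile r(z, theta) and ring-centre offset per family
phantomProfile <- function(spec) {
  L <- spec@length
  R <- spec@baseRadius
  base <- phantomProfileBase(spec)
  if (spec@crest == 0) return(base)
  # localized anterior prominence (Gaussian in azimuth and height); its
  # proximal position breaks both the azimuthal symmetry and the
  # end-to-end flip near-symmetry of the simple families
  crest <- function(z, th) {
    dth <- atan2(sin(th - pi / 2), cos(th - pi / 2))
    1 + spec@crest * exp(-0.5 * (dth / 0.5)^2) *
      exp(-0.5 * ((z / L - 0.7) / 0.2)^2)
  }
  list(r = function(z, th) base$r(z, th) * crest(z, th), center = base$center)
}

phantomProfileBase <- function(spec) {
  L <- spec@length
  R <- spec@baseRadius
  switch(spec@family,
    cylindrical = list(
      r = function(z, th) rep(R, length(th)),
      center = function(z) c(0, 0)),
    conical = list(
      r = function(z, th) rep(R * (spec@taper + (1 - spec@taper) * z / L),
                              length(th)),
      center = function(z) c(0, 0)),
    bulbous = list(
      r = function(z, th) rep(R * (1 + spec@bulbRadius *
        exp(-0.5 * ((z / L - spec@bulbPosition) / 0.15)^2)), length(th)),
      center = function(z) c(0, 0)),
    ischial = list(
      r = function(z, th) R * (1 + 0.2 *
        exp(-0.5 * ((z / L - 0.6) / 0.2)^2) * pmax(0, cos(th))^2),
      center = function(z) c(spec@lateralOffset * sin(pi * z / L), 0)))
}

#' Generate a limb phantom mesh
#'
#' Lofts circular (or offset/bulged) cross-sections along +z with planar fan
#' caps at both ends. Cylindrical and conical families also return analytic
#' closed forms (tessellation-exact prism/frustum volume and chord-sum
#' perimeter) for oracle comparisons.
#'
#' @param spec a [PhantomSpec-class] from [phantomSpec()].
#' @return list with `mesh` (closed [TriMesh-class]), `spec`, and (for
#'   cylindrical/conical) `analyticVolume` (scalar, full solid),
#'   `analyticPerimeter(z)` and `analyticRadius(z)` functions.
#' @export
makePhantom <- function(spec) {
  validObject(spec)
  prof <- phantomProfile(spec)
  n <- spec@segments
  th <- 2 * pi * (seq_len(n) - 1) / n
  z <- seq(0, spec@length, length.out = spec@rings)
  v <- do.call(rbind, lapply(z, function(zz) {
    r <- prof$r(zz, th)
    ctr <- prof$center(zz)
    cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th), zz)
  }))
  f <- NULL
  i <- seq_len(n)
  j <- c(seq_len(n - 1) + 1, 1)
  for (ring in seq_len(spec@rings - 1)) {
    lo <- (ring - 1) * n
    hi <- ring * n
    f <- rbind(f,
               cbind(lo + i, lo + j, hi + i),
               cbind(lo + j, hi + j, hi + i))
  }
  cBot <- nrow(v) + 1
  cTop <- nrow(v) + 2
  v <- rbind(v, c(prof$center(0), 0), c(prof$center(spec@length), spec@length))
  top0 <- (spec@rings - 1) * n
  f <- rbind(f, cbind(cBot, j, i), cbind(cTop, top0 + i, top0 + j))
  mesh <- TriMesh(v, f)
  out <- list(mesh = mesh, spec = spec)
  chord <- n * sin(pi / n) / pi  # tessellation factor: polygon vs circle
  if (spec@crest != 0) return(out)  # no closed forms off the surface of revolution
  if (spec@family == "cylindrical") {
    R <- spec@baseRadius
    out$analyticVolume <- pi * R^2 * spec@length
    out$analyticPerimeter <- function(zq) rep(2 * pi * R, length(zq))
    out$analyticRadius <- function(zq) rep(R, length(zq))
    out$tessellationFactor <- chord
  } else if (spec@family == "conical") {
    R2 <- spec@baseRadius
    R1 <- spec@baseRadius * spec@taper
    out$analyticVolume <- pi * spec@length * (R1^2 + R1 * R2 + R2^2) / 3
    out$analyticRadius <- function(zq)
      R1 + (R2 - R1) * zq / spec@length
    out$analyticPerimeter <- function(zq) 2 * pi * out$analyticRadius(zq)
    out$tessellationFactor <- chord
  }
  out
}

#' Displace every vertex along its outward normal
#'
#' A uniform radial inflation (delta > 0) or deflation (delta < 0); the
#' nearest-point distance from the deformed to the original surface of a
#' smooth convex mesh equals |delta|.
#'
#' @param mesh a [TriMesh-class] with outward orientation.
#' @param delta displacement along the outward vertex normal, mm.
#' @return deformed [TriMesh-class].
#' @export
deformRadial <- function(mesh, delta) {
  if (delta == 0) return(mesh)
  vn <- vertexNormals(mesh)
  new("TriMesh", vertices = mesh@vertices + delta * vn, faces = mesh@faces,
      vnormals = matrix(numeric(0), 0, 3))
}

#' Add Gaussian vertex noise along normals
#'
#' i.i.d. N(0, sigma^2) displacement along outward vertex normals;
#' deterministic for a given seed.
#'
#' @param mesh a [TriMesh-class].
#' @param sigma noise SD, mm (>= 0).
#' @param seed integer seed.
#' @return noisy [TriMesh-class].
#' @export
addVertexNoise <- function(mesh, sigma, seed) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(mesh)
  vn <- vertexNormals(mesh)
  d <- withLocalSeed(seed, stats::rnorm(nVertices(mesh), 0, sigma))
  new("TriMesh", vertices = mesh@vertices + d * vn, faces = mesh@faces,
      vnormals = matrix(numeric(0), 0, 3))
}

#' Voxelize a closed mesh into a synthetic CT-like volume
#'
#' Foreground (inside the mesh, by voxel-centre ray parity) gets intensity
#' `fgIntensity`, background `bgIntensity`, plus optional Gaussian intensity
#' noise; an optional spherical internal cavity is carved to background.
#'
#' @param mesh a closed [TriMesh-class].
#' @param spacing isotropic voxel size, mm.
#' @param cavity optional `list(center = c(x, y, z), radius = r)` in mm.
#' @param fgIntensity,bgIntensity the two intensity levels (default 100 / 0).
#' @param noiseSd intensity noise SD (default 0).
#' @param seed seed for the intensity noise.
#' @param pad padding in voxels around the bounding box (default 3).
#' @return a [VoxelVolume-class].
#' @export
voxelizeMesh <- function(mesh, spacing, cavity = NULL, fgIntensity = 100,
                         bgIntensity = 0, noiseSd = 0, seed = 1, pad = 3) {
  stopifnot(spacing > 0)
  bb <- apply(mesh@vertices, 2, range)
  origin <- bb[1, ] - pad * spacing
  dims <- as.integer(ceiling((bb[2, ] - origin) / spacing)) + as.integer(pad)
  inside <- cpp_points_in_mesh_grid(mesh@vertices, mesh@faces, origin, spacing,
                                    dims)
  inside <- array(inside, dim = dims)
  if (!is.null(cavity)) {
    cc <- cavity$center
    ax <- origin[1] + (seq_len(dims[1]) - 1) * spacing
    ay <- origin[2] + (seq_len(dims[2]) - 1) * spacing
    az <- origin[3] + (seq_len(dims[3]) - 1) * spacing
    d2 <- outer(outer((ax - cc[1])^2, (ay - cc[2])^2, "+"), (az - cc[3])^2, "+")
    inside[d2 <= cavity$radius^2] <- FALSE
  }
  intens <- array(ifelse(inside, fgIntensity, bgIntensity), dim = dims)
  if (noiseSd > 0)
    intens <- intens + withLocalSeed(seed,
      array(stats::rnorm(length(intens), 0, noiseSd), dim = dims))
  new("VoxelVolume", intensities = intens, spacing = spacing, origin = origin)
}

#' Synthetic pinhole projections of a tag map
#'
#' Projects the 4 world corners of every mapped tag through every camera and
#' adds i.i.d. Gaussian pixel noise. Tags behind a camera (or with any corner
#' outside the optional frame) are omitted; a camera lying in a tag's plane
#' (|depth| below tolerance) is skipped with a warning.
#'
#' @param map a [TagMap-class].
#' @param traj a [Trajectory-class] of world-to-camera poses.
#' @param K a [CameraIntrinsics-class].
#' @param noisePx pixel noise SD (0 for exact projections).
#' @param seed integer seed for the noise.
#' @param imageSize optional `c(width, height)` px frame bound.
#' @param depthTol minimal |corner depth| in mm (default 1e-6).
#' @return list of [TagDetections-class], one per camera with >= 1 visible tag.
#' @export
renderTagCorners <- function(map, traj, K, noisePx = 0, seed = 1,
                             imageSize = NULL, depthTol = 1e-6) {
  dets <- list()
  noise <- withLocalSeed(seed, {
    nAll <- length(traj@poses) * length(map@poses) * 8
    stats::rnorm(nAll, 0, max(noisePx, 0))
  })
  ni <- 0
  for (img in names(traj@poses)) {
    pose <- traj@poses[[img]]
    ids <- integer(0)
    corners <- list()
    for (tid in names(map@poses)) {
      world <- transformPoints(tagCorners3d(map@tagSide), map@poses[[tid]])
      pc <- transformPoints(world, pose)
      ni <- ni + 1
      if (any(abs(pc[, 3]) < depthTol)) {
        warning(sprintf("camera %s lies in the plane of tag %s; omitted",
                        img, tid))
        next
      }
      if (any(pc[, 3] <= 0)) next
      px <- projectPoints(world, pose, K)
      if (noisePx > 0)
        px <- px + matrix(noise[(8 * ni - 7):(8 * ni)], 4, 2)
      if (!is.null(imageSize) &&
          (any(px[, 1] < 0 | px[, 1] > imageSize[1]) ||
           any(px[, 2] < 0 | px[, 2] > imageSize[2]))) next
      ids <- c(ids, as.integer(tid))
      corners[[length(corners) + 1]] <- px
    }
    if (length(ids) > 0)
      dets[[length(dets) + 1]] <- tagDetections(img, ids, corners)
  }
  dets
}

#' Random rigid transform (for perturbation studies)
#'
#' Uniform random rotation axis, rotation angle uniform in
#' `[0, maxAngleDeg]`, translation uniform in a cube of half-width
#' `maxTranslation`; deterministic per seed.
#'
#' @param maxAngleDeg maximal rotation angle, degrees.
#' @param maxTranslation maximal |component| of the translation, mm.
#' @param seed integer seed.
#' @return a [RigidTransform-class].
#' @export
randomRigidTransform <- function(maxAngleDeg = 15, maxTranslation = 30, seed = 1) {
  withLocalSeed(seed, {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, 0, maxAngleDeg) * pi / 180
    t <- stats::runif(3, -maxTranslation, maxTranslation)
    rigidTransform(rotvecToMatrix(ax * ang), t)
  })
}
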