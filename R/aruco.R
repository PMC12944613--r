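# Metric scaling from square fiducial tags: single-tag planar pose, two-stage
# PnP, joint tag/camera map optimization, and similarity alignment of an
# arbitrarily scaled SfM reconstruction to the metric tag frame.

#' Pinhole camera intrinsics
#'
#' @param fx,fy focal lengths, px.
#' @param cx,cy principal point, px.
#' @param distortion radial/tangential coefficients `(k1, k2, p1, p2, k3)`
#'   prefix, possibly empty (the synthetic pipeline uses none).
#' @return a [CameraIntrinsics-class].
#' @export
cameraIntrinsics <- function(fx, fy, cx, cy, distortion = numeric(0)) {
  new("CameraIntrinsics", fx = fx, fy = fy, cx = cx, cy = cy,
      distortion = distortion)
}

#' Tag detections for one image
#'
#' @param imageId image identifier.
#' @param tagIds integer tag ids.
#' @param corners list of 4 x 2 pixel corner matrices in canonical order
#'   (top-left, top-right, bottom-right, bottom-left).
#' @return a [TagDetections-class].
#' @export
tagDetections <- function(imageId, tagIds, corners) {
  new("TagDetections", imageId = as.character(imageId),
      tagIds = as.integer(tagIds), corners = corners)
}

#' Tag map constructor
#' @param tagSide physical tag side, mm.
#' @param poses named list of [RigidTransform-class] (names = tag ids).
#' @param rootId gauge-fixed root tag id.
#' @return a [TagMap-class].
#' @export
tagMap <- function(tagSide, poses, rootId) {
  new("TagMap", tagSide = tagSide, poses = poses, rootId = as.integer(rootId))
}

#' Camera trajectory constructor
#' @param poses named list of world-to-camera [RigidTransform-class].
#' @export
trajectory <- function(poses) new("Trajectory", poses = poses)

setMethod("show", "TagMap", function(object) {
  cat(sprintf("TagMap: %d tags (side %.1f mm), root id %d\n",
              length(object@poses), object@tagSide, object@rootId))
  invisible(object)
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d camera poses (world-to-camera)\n",
              length(object@poses)))
  invisible(object)
})

# canonical tag-frame corners, order TL, TR, BR, BL; tag plane z = 0,
# x to the right, y up
tagCorners3d <- function(side) {
  h <- side / 2
  rbind(c(-h, h, 0), c(h, h, 0), c(h, -h, 0), c(-h, -h, 0))
}

applyDistortion <- function(xy, distortion) {
  if (length(distortion) == 0 || all(distortion == 0)) return(xy)
  k <- c(distortion, rep(0, 5))[1:5]  # k1 k2 p1 p2 k3
  r2 <- rowSums(xy^2)
  rad <- 1 + k[1] * r2 + k[2] * r2^2 + k[5] * r2^3
  x <- xy[, 1]; y <- xy[, 2]
  cbind(x * rad + 2 * k[3] * x * y + k[4] * (r2 + 2 * x^2),
        y * rad + k[3] * (r2 + 2 * y^2) + 2 * k[4] * x * y)
}

#' Project world points through a pinhole camera
#'
#' @param points n x 3 world points (mm).
#' @param pose world-to-camera [RigidTransform-class].
#' @param K [CameraIntrinsics-class].
#' @return n x 2 pixel coordinates; rows NaN for points at or behind the
#'   camera plane.
#' @export
projectPoints <- function(points, pose, K) {
  pc <- transformPoints(points, pose)
  z <- pc[, 3]
  z[z <= 1e-9] <- NA
  xy <- applyDistortion(cbind(pc[, 1] / z, pc[, 2] / z), K@distortion)
  cbind(K@cx + K@fx * xy[, 1], K@cy + K@fy * xy[, 2])
}

# homography from >= 4 planar correspondences (DLT with normalization)
homographyDlt <- function(src, dst) {
  normalise <- function(p) {
    mu <- colMeans(p)
    d <- mean(sqrt(rowSums(sweep(p, 2, mu)^2)))
    if (d < 1e-12) stop("degenerate (collinear or coincident) points")
    s <- sqrt(2) / d
    T <- rbind(c(s, 0, -s * mu[1]), c(0, s, -s * mu[2]), c(0, 0, 1))
    list(T = T, p = sweep(p, 2, mu) * s)
  }
  ns <- normalise(src)
  nd <- normalise(dst)
  A <- NULL
  for (i in seq_len(nrow(src))) {
    x <- ns$p[i, 1]; y <- ns$p[i, 2]
    u <- nd$p[i, 1]; v <- nd$p[i, 2]
    A <- rbind(A,
               c(-x, -y, -1, 0, 0, 0, u * x, u * y, u),
               c(0, 0, 0, -x, -y, -1, v * x, v * y, v))
  }
  sv <- svd(A, nv = 9)
  if (sv$d[8] / sv$d[1] < 1e-10)
    stop("degenerate (collinear) corner configuration")
  H <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  H / H[3, 3]
}

# pose of the tag frame in the camera frame from one tag's 4 corners
singleTagPose <- function(corners, K, tagSide) {
  # cheirality: seen from the front, the TL-TR-BR-BL pixel polygon keeps a
  # positive winding (image y down); a view from behind the plane flips it
  nxt <- c(2:4, 1)
  winding <- sum(corners[, 1] * corners[nxt, 2] - corners[nxt, 1] * corners[, 2])
  scale2 <- max(apply(corners, 2, function(x) diff(range(x))))^2
  if (abs(winding) < 1e-9 * max(scale2, 1))
    stop("degenerate (collinear) corner configuration")
  if (winding < 0)
    stop("camera behind tag plane (reversed corner winding)")
  obj <- tagCorners3d(tagSide)
  H <- homographyDlt(obj[, 1:2], corners)
  Km <- rbind(c(K@fx, 0, K@cx), c(0, K@fy, K@cy), c(0, 0, 1))
  M <- solve(Km) %*% H
  # enforce positive depth of the tag centre (cheirality)
  if (M[3, 3] < 0) M <- -M
  l1 <- sqrt(sum(M[, 1]^2)); l2 <- sqrt(sum(M[, 2]^2))
  s <- (l1 + l2) / 2
  r1 <- M[, 1] / l1
  r2 <- M[, 2] - sum(M[, 2] * r1) * r1
  r2 <- r2 / sqrt(sum(r2^2))
  r3 <- cross3(r1, r2)
  R <- projectSO3(cbind(r1, r2, r3))
  t <- M[, 3] / s
  if (t[3] <= 0) stop("camera behind tag plane (negative tag depth)")
  rigidTransform(R, t)
}

# pack/unpack axis-angle + translation
packPose <- function(p) c(matrixToRotvec(p@rotation), p@translation)
unpackPose <- function(x) rigidTransform(rotvecToMatrix(x[1:3]), x[4:6])

# stacked (u, v) residuals of a camera seeing mapped tags
tagReprojResiduals <- function(det, map, camPose, K) {
  ids <- as.character(det@tagIds)
  inMap <- ids %in% names(map@poses)
  res <- NULL
  for (i in which(inMap)) {
    tp <- map@poses[[ids[i]]]
    world <- transformPoints(tagCorners3d(map@tagSide), tp)
    proj <- projectPoints(world, camPose, K)
    res <- rbind(res, proj - det@corners[[i]])
  }
  res
}

#' Two-stage PnP camera pose from mapped tags
#'
#' Stage 1 solves the planar pose from the single visible mapped tag with the
#' largest projected corner area; stage 2 refines by nonlinear least squares
#' over the corners of all visible mapped tags.
#'
#' @param det a [TagDetections-class] for one image.
#' @param map a [TagMap-class].
#' @param K a [CameraIntrinsics-class].
#' @return list with `pose` (world-to-camera [RigidTransform-class]) and
#'   `rmse` (corner reprojection RMSE, px).
#' @export
estimatePoseTwoStage <- function(det, map, K) {
  ids <- as.character(det@tagIds)
  inMap <- which(ids %in% names(map@poses))
  if (length(inMap) == 0) stop("no mapped tag visible in this image")
  # most reliable geometry: largest projected area
  areas <- vapply(inMap, function(i) {
    p <- det@corners[[i]]
    nxt <- c(2:4, 1)
    abs(sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2]) / 2)
  }, numeric(1))
  best <- inMap[which.max(areas)]
  Tct <- singleTagPose(det@corners[[best]], K, map@tagSide)
  Twt <- map@poses[[ids[best]]]
  pose0 <- composeTransforms(Tct, inverseTransform(Twt))
  fn <- function(x) as.vector(tagReprojResiduals(det, map, unpackPose(x), K))
  fit <- minpack.lm::nls.lm(packPose(pose0), fn = fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  pose <- unpackPose(fit$par)
  r <- fn(fit$par)
  list(pose = pose, rmse = sqrt(mean(r^2)))
}

#' Build a metric tag map by joint optimization
#'
#' Initializes tag poses by a spanning tree of relative single-tag poses from
#' shared images, then jointly refines all tag poses (the root is gauge-fixed
#' to the identity) and all camera poses by Levenberg-Marquardt on the corner
#' reprojection error, with Huber (delta = 2 px) IRLS weighting. Metric scale
#' enters only through `tagSide`.
#'
#' @param detections list of [TagDetections-class] (one per image).
#' @param K a [CameraIntrinsics-class].
#' @param tagSide physical tag side length, mm.
#' @param maxOuter Huber IRLS rounds (default 3).
#' @return list with `map` ([TagMap-class]), `trajectory`
#'   ([Trajectory-class]) and `rmse` (px).
#' @export
buildTagMap <- function(detections, K, tagSide, maxOuter = 3) {
  allIds <- sort(unique(unlist(lapply(detections, function(d) d@tagIds))))
  nT <- length(allIds)
  if (nT == 0) stop("no tags detected")
  # per-image single-tag camera<-tag poses and projected areas
  camTag <- lapply(detections, function(d) {
    lapply(seq_along(d@tagIds), function(i) {
      p <- d@corners[[i]]
      nxt <- c(2:4, 1)
      area <- abs(sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2]) / 2)
      list(id = d@tagIds[i], area = area,
           pose = tryCatch(singleTagPose(p, K, tagSide), error = function(e) NULL))
    })
  })
  # co-visibility edges; every witness image contributes a relative-pose
  # candidate and the consensus (medoid) candidate wins -- single-tag planar
  # poses have a well-known two-fold (twin) ambiguity, and occasional wrong
  # twins scatter while correct estimates cluster
  edgeCand <- list()
  for (ci in seq_along(camTag)) {
    obs <- camTag[[ci]]
    obs <- obs[!vapply(obs, function(o) is.null(o$pose), logical(1))]
    if (length(obs) < 2) next
    for (a in seq_along(obs)) for (b in seq_along(obs)) {
      if (a == b) next
      key <- paste(obs[[a]]$id, obs[[b]]$id)
      edgeCand[[key]] <- c(edgeCand[[key]], list(list(
        from = obs[[a]]$id, to = obs[[b]]$id,
        rel = composeTransforms(inverseTransform(obs[[a]]$pose),
                                obs[[b]]$pose))))
    }
  }
  poseDist <- function(p, q) {
    rotationAngleDeg(p@rotation, q@rotation) / 30 +
      sqrt(sum((p@translation - q@translation)^2)) / tagSide
  }
  edges <- lapply(edgeCand, function(cands) {
    if (length(cands) == 1) return(cands[[1]])
    D <- vapply(cands, function(a)
      vapply(cands, function(b) poseDist(a$rel, b$rel), numeric(1)),
      numeric(length(cands)))
    cands[[which.min(colSums(D))]]
  })
  # connectivity and spanning-tree initialization from the root
  rootId <- allIds[1]
  poses <- stats::setNames(vector("list", nT), as.character(allIds))
  poses[[as.character(rootId)]] <- rigidTransform()
  frontier <- rootId
  while (length(frontier) > 0) {
    cur <- frontier[1]
    frontier <- frontier[-1]
    for (e in edges) {
      if (e$from == cur && is.null(poses[[as.character(e$to)]])) {
        poses[[as.character(e$to)]] <-
          composeTransforms(poses[[as.character(cur)]], e$rel)
        frontier <- c(frontier, e$to)
      }
    }
  }
  unreached <- allIds[vapply(as.character(allIds), function(i) is.null(poses[[i]]),
                             logical(1))]
  if (length(unreached) > 0)
    stop(sprintf("tag co-visibility graph is disconnected: component with root %d does not reach tags {%s}",
                 rootId, paste(unreached, collapse = ", ")))
  map0 <- tagMap(tagSide, poses, rootId)
  # initial camera poses by two-stage PnP
  camPoses <- lapply(detections, function(d) estimatePoseTwoStage(d, map0, K)$pose)
  names(camPoses) <- vapply(detections, function(d) d@imageId, character(1))

  freeTags <- setdiff(allIds, rootId)
  nC <- length(detections)
  pack <- function(map, cams) {
    c(unlist(lapply(as.character(freeTags), function(i) packPose(map@poses[[i]]))),
      unlist(lapply(cams, packPose)))
  }
  unpack <- function(x) {
    poses <- stats::setNames(vector("list", nT), as.character(allIds))
    poses[[as.character(rootId)]] <- rigidTransform()
    for (k in seq_along(freeTags))
      poses[[as.character(freeTags[k])]] <- unpackPose(x[(6 * k - 5):(6 * k)])
    off <- 6 * length(freeTags)
    cams <- lapply(seq_len(nC), function(k)
      unpackPose(x[off + (6 * k - 5):(6 * k)]))
    names(cams) <- names(camPoses)
    list(map = tagMap(tagSide, poses, rootId), cams = cams)
  }
  # flattened observation blocks for fast residual evaluation
  canon <- tagCorners3d(tagSide)
  obsCam <- list()   # per camera: list(tagIdx = integer, px = matrix)
  for (ci in seq_len(nC)) {
    d <- detections[[ci]]
    keepT <- which(as.character(d@tagIds) %in% as.character(allIds))
    obsCam[[ci]] <- list(
      tags = as.character(d@tagIds[keepT]),
      px = do.call(rbind, d@corners[keepT]))
  }
  residAll <- function(x, w = NULL) {
    st <- unpack(x)
    # world corners per tag (4 x 3), stacked on demand per camera
    wc <- lapply(st$map@poses, function(p) transformPoints(canon, p))
    res <- vector("list", nC)
    for (ci in seq_len(nC)) {
      ob <- obsCam[[ci]]
      world <- do.call(rbind, wc[ob$tags])
      cam <- st$cams[[ci]]
      pc <- world %*% t(cam@rotation)
      pc <- sweep(pc, 2, cam@translation, "+")
      z <- pc[, 3]
      proj <- cbind(K@cx + K@fx * pc[, 1] / z, K@cy + K@fy * pc[, 2] / z)
      res[[ci]] <- proj - ob$px
    }
    r <- as.vector(t(do.call(rbind, res)))  # per-corner (u, v) contiguous
    if (!is.null(w)) r <- r * rep(w, each = 2)
    r
  }
  huberW <- function(x) {
    # per-corner Euclidean residual -> sqrt-Huber weight, delta = 2 px
    res <- residAll(x)
    e <- sqrt(res[seq(1, length(res), 2)]^2 + res[seq(2, length(res), 2)]^2)
    ifelse(e <= 2, 1, sqrt(2 / e))
  }
  x <- pack(map0, camPoses)
  rmse0 <- sqrt(mean(residAll(x)^2))
  for (outer in seq_len(maxOuter)) {
    w <- huberW(x)
    # LM with continuation: if the iteration cap is hit, restart from the
    # current estimate (resets the damping) before giving up
    info <- 5L
    for (round in 1:3) {
      fit <- minpack.lm::nls.lm(x, fn = residAll, w = w,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 200, ftol = 1e-15, ptol = 1e-15,
                                  gtol = 1e-15))
      x <- fit$par
      info <- fit$info
      if (info != 5L) break
    }
    if (info == 5L && sqrt(mean(residAll(x)^2)) > rmse0 + 1e-9)
      stop(sprintf("joint tag-map optimization did not converge after 200 iterations (RMSE %.3g px)",
                   sqrt(mean(residAll(x)^2))))
    if (all(w == 1)) break  # no outliers: IRLS is converged
  }
  # misconvergence repair: a wrong planar twin in the initialization can
  # strand single cameras or tags in a high-residual local minimum; detect
  # them against the robust residual scale, restart each from its best
  # per-view candidate pose, and re-optimize once
  blockLen <- vapply(obsCam, function(o) 2L * nrow(o$px), integer(1))
  offs <- c(0L, cumsum(blockLen))
  tagOfResid <- unlist(lapply(obsCam, function(o) rep(o$tags, each = 8L)))
  for (attempt in 1:2) {
    r <- residAll(x)
    rmse <- sqrt(mean(r^2))
    robust <- 1.4826 * stats::median(abs(r))
    if (rmse <= max(3 * robust, 1e-9)) break
    st <- unpack(x)
    # cameras: refit from the stage-1 pose of every visible mapped tag
    for (ci in seq_len(nC)) {
      rc <- r[(offs[ci] + 1):offs[ci + 1]]
      if (sqrt(mean(rc^2)) <= 3 * robust) next
      d <- detections[[ci]]
      best <- st$cams[[ci]]
      bestR <- sqrt(mean(rc^2))
      for (i in seq_along(d@tagIds)) {
        id <- as.character(d@tagIds[i])
        if (!id %in% names(st$map@poses)) next
        cand <- tryCatch({
          Tct <- singleTagPose(d@corners[[i]], K, tagSide)
          pose0 <- composeTransforms(Tct, inverseTransform(st$map@poses[[id]]))
          fn <- function(p)
            as.vector(tagReprojResiduals(d, st$map, unpackPose(p), K))
          ft <- minpack.lm::nls.lm(packPose(pose0), fn = fn,
                                   control = minpack.lm::nls.lm.control(
                                     maxiter = 100, ftol = 1e-13, ptol = 1e-13))
          unpackPose(ft$par)
        }, error = function(e) NULL)
        if (is.null(cand)) next
        rcand <- sqrt(mean(tagReprojResiduals(d, st$map, cand, K)^2))
        if (rcand < bestR) { best <- cand; bestR <- rcand }
      }
      st$cams[[ci]] <- best
    }
    # tags: restart from each witness camera's single-tag pose
    x <- pack(st$map, st$cams)
    r <- residAll(x)
    tagRes <- function(id) sqrt(mean(r[tagOfResid == id]^2))
    for (id in as.character(freeTags)) {
      if (tagRes(id) <= 3 * robust) next
      bestPose <- st$map@poses[[id]]
      bestR <- Inf
      for (ci in seq_len(nC)) {
        oi <- which(vapply(camTag[[ci]], function(o)
          as.character(o$id) == id && !is.null(o$pose), logical(1)))
        if (length(oi) == 0) next
        cand <- composeTransforms(inverseTransform(st$cams[[ci]]),
                                  camTag[[ci]][[oi[1]]]$pose)
        trialPoses <- st$map@poses
        trialPoses[[id]] <- cand
        xc <- pack(tagMap(tagSide, trialPoses, rootId), st$cams)
        rcand <- residAll(xc)
        rc <- sqrt(mean(rcand[tagOfResid == id]^2))
        if (rc < bestR) { bestR <- rc; bestPose <- cand }
      }
      st$map@poses[[id]] <- bestPose
    }
    x <- pack(st$map, st$cams)
    w <- huberW(x)
    fit <- minpack.lm::nls.lm(x, fn = residAll, w = w,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 200, ftol = 1e-15, ptol = 1e-15,
                                gtol = 1e-15))
    x <- fit$par
  }
  st <- unpack(x)
  rmse <- sqrt(mean(residAll(x)^2))
  list(map = st$map, trajectory = trajectory(st$cams), rmse = rmse)
}

#' Least-squares similarity transform between point sets (Umeyama)
#'
#' Closed-form `(s, R, t)` minimizing `sum |s R src_i + t - dst_i|^2`.
#'
#' @param src,dst n x 3 matrices of corresponding points, n >= 3,
#'   non-collinear.
#' @return list with `transform` ([SimilarityTransform-class]) and `rms`
#'   residual (mm).
#' @export
estimateSimilarityUmeyama <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) != nrow(dst)) stop("point counts differ")
  if (nrow(src) < 3) stop("need at least 3 correspondences")
  ms <- colMeans(src); md <- colMeans(dst)
  S <- sweep(src, 2, ms); D <- sweep(dst, 2, md)
  C <- t(D) %*% S / nrow(src)
  sv <- svd(C)
  if (sv$d[2] / max(sv$d[1], 1e-300) < 1e-10)
    stop("degenerate (collinear) point configuration")
  sgn <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
  R <- sv$u %*% sgn %*% t(sv$v)
  varS <- mean(rowSums(S^2))
  s <- sum(diag(diag(sv$d) %*% sgn)) / varS
  t <- md - s * as.vector(R %*% ms)
  tf <- similarityTransform(s, R, t)
  rms <- sqrt(mean(rowSums((transformPoints(src, tf) - dst)^2)))
  list(transform = tf, rms = rms)
}

#' Camera centre of a world-to-camera pose
#' @param pose [RigidTransform-class] (world-to-camera).
#' @return length-3 world position.
#' @export
cameraCenter <- function(pose) -as.vector(t(pose@rotation) %*% pose@translation)

#' Scale an SfM reconstruction to the metric tag frame
#'
#' Estimates the similarity between corresponding camera centres of an SfM
#' trajectory (arbitrary scale) and the metric tag-based trajectory, and
#' applies it to the model.
#'
#' @param sfmTrajectory,tagTrajectory [Trajectory-class] objects sharing at
#'   least 3 image ids.
#' @param model a [TriMesh-class] or point matrix in the SfM frame.
#' @param warnRms residual RMS (mm) above which a warning is raised
#'   (gross outliers among camera centres); default 5 mm.
#' @return list with `model` (transformed), `transform`
#'   ([SimilarityTransform-class]) and `rms` (mm).
#' @export
scaleReconstruction <- function(sfmTrajectory, tagTrajectory, model,
                                warnRms = 5) {
  shared <- intersect(names(sfmTrajectory@poses), names(tagTrajectory@poses))
  if (length(shared) < 3)
    stop(sprintf("only %d shared image ids between trajectories (need >= 3)",
                 length(shared)))
  src <- do.call(rbind, lapply(shared, function(i)
    cameraCenter(sfmTrajectory@poses[[i]])))
  dst <- do.call(rbind, lapply(shared, function(i)
    cameraCenter(tagTrajectory@poses[[i]])))
  est <- estimateSimilarityUmeyama(src, dst)
  if (est$rms > warnRms)
    warning(sprintf("similarity residual RMS %.2f mm exceeds %.2f mm; possible outlier camera centres",
                    est$rms, warnRms))
  out <- if (is(model, "TriMesh")) applyTransform(model, est$transform)
         else transformPoints(as.matrix(model), est$transform)
  list(model = out, transform = est$transform, rms = est$rms)
}

#' Write a trajectory in the COLMAP text images dialect
#'
#' One record per image: `IMAGE_ID qw qx qy qz tx ty tz CAMERA_ID NAME`
#' followed by an empty 2D-points line; poses are world-to-camera.
#'
#' @param traj a [Trajectory-class].
#' @param path output file.
#' @param cameraId camera id written for every image (default 1).
#' @export
writeTrajectoryColmap <- function(traj, path, cameraId = 1) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# Image list with two lines of data per image:",
               "#   IMAGE_ID, QW, QX, QY, QZ, TX, TY, TZ, CAMERA_ID, NAME",
               "#   POINTS2D[] as (X, Y, POINT3D_ID)"), con)
  ids <- names(traj@poses)
  for (i in seq_along(ids)) {
    p <- traj@poses[[ids[i]]]
    q <- matrixToQuat(p@rotation)
    writeLines(paste(i, paste(format(c(q, p@translation), digits = 17),
                              collapse = " "), cameraId, ids[i]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a COLMAP text images file as a trajectory
#' @param path file written by [writeTrajectoryColmap()] or COLMAP.
#' @return a [Trajectory-class] keyed by image name.
#' @export
readTrajectoryColmap <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^#", txt)]
  txt <- txt[nzchar(trimws(txt))]
  # image records are the lines with 10 fields (points lines were blank)
  poses <- list()
  for (line in txt) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) < 10) next
    q <- as.numeric(tok[2:5])
    t <- as.numeric(tok[6:8])
    poses[[tok[10]]] <- rigidTransform(quatToMatrix(q), t)
  }
  trajectory(poses)
}

#' Write a tag map as JSON
#' @param map a [TagMap-class].
#' @param path output JSON path.
#' @export
writeTagMap <- function(map, path) {
  tags <- lapply(map@poses, function(p) as.vector(t(asMatrix4(p))))
  jsonlite::write_json(list(tag_side_mm = map@tagSide, root_id = map@rootId,
                            tags = tags),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tag map from JSON
#' @param path JSON written by [writeTagMap()].
#' @return a [TagMap-class].
#' @export
readTagMap <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  poses <- lapply(j$tags, function(v) {
    m <- matrix(unlist(v), 4, 4, byrow = TRUE)
    rigidTransform(m[1:3, 1:3], m[1:3, 4])
  })
  tagMap(j$tag_side_mm, poses, j$root_id)
}
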