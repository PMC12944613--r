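# Two-stage rigid registration: FPFH + RANSAC coarse alignment and
# multi-scale point-to-plane ICP refinement against the exact triangle
# surface of the target.

meshCloud <- function(x) {
  if (is(x, "TriMesh")) list(points = x@vertices, normals = vertexNormals(x))
  else if (is.list(x) && !is.null(x$points)) x
  else list(points = as.matrix(x), normals = matrix(numeric(0), 0, 3))
}

# least-squares rigid transform (Kabsch) between corresponding points
kabsch <- function(src, dst) {
  ms <- colMeans(src); md <- colMeans(dst)
  C <- t(sweep(dst, 2, md)) %*% sweep(src, 2, ms)
  sv <- svd(C)
  R <- sv$u %*% diag(c(1, 1, sign(det(sv$u %*% t(sv$v))))) %*% t(sv$v)
  rigidTransform(R, md - as.vector(R %*% ms))
}

#' Coarse feature-based alignment (FPFH + RANSAC)
#'
#' Voxel-downsamples both oriented clouds, computes FPFH descriptors
#' (radius 5 x voxel), fixes one nearest-descriptor correspondence per source
#' point, and runs a seeded RANSAC over 3-point correspondence samples with
#' edge-length and distance pre-checks; the best hypothesis by inlier count
#' is refined by one least-squares step on its inliers. Deterministic for a
#' given seed.
#'
#' @param source,target [TriMesh-class] objects or `list(points, normals)`.
#' @param voxel downsampling voxel size, mm.
#' @param seed integer RANSAC seed.
#' @param maxIter maximal RANSAC hypotheses (default 100000; 0.999-confidence
#'   early exit).
#' @param distThresh inlier distance, mm (default 1.5 x voxel).
#' @param edgeTol relative edge-length mismatch tolerance (default 0.1).
#' @return a [RigidTransform-class] with attributes `fitness` (inlier
#'   fraction) and `inlierRms` (mm).
#' @export
coarseAlign <- function(source, target, voxel = 4, seed = 1,
                        maxIter = 100000, distThresh = 1.5 * voxel,
                        edgeTol = 0.1) {
  s <- meshCloud(source)
  t <- meshCloud(target)
  sd <- cpp_voxel_downsample(s$points, s$normals, voxel)
  td <- cpp_voxel_downsample(t$points, t$normals, voxel)
  if (nrow(sd$points) < 100 || nrow(td$points) < 100)
    stop(sprintf("too few points after downsampling (%d source, %d target; need >= 100)",
                 nrow(sd$points), nrow(td$points)))
  fs <- cpp_fpfh(sd$points, sd$normals, 5 * voxel)
  ft <- cpp_fpfh(td$points, td$normals, 5 * voxel)
  # cap the correspondence set (deterministic even subsample) to bound the
  # descriptor-matching and consensus-counting cost
  srcIdx <- if (nrow(fs) > 1500)
    unique(round(seq(1, nrow(fs), length.out = 1500))) else seq_len(nrow(fs))
  nn <- cpp_nn_rows(fs[srcIdx, , drop = FALSE], ft)
  corr <- cbind(srcIdx, nn)
  hyp <- cpp_ransac_align(sd$points, td$points, corr, as.integer(maxIter),
                          distThresh, edgeTol, as.numeric(seed))
  inl <- corr[hyp$inliers, , drop = FALSE]
  tf <- kabsch(sd$points[inl[, 1], , drop = FALSE],
               td$points[inl[, 2], , drop = FALSE])
  res <- transformPoints(sd$points[inl[, 1], , drop = FALSE], tf) -
    td$points[inl[, 2], , drop = FALSE]
  attr(tf, "fitness") <- length(hyp$inliers) / nrow(corr)
  attr(tf, "inlierRms") <- sqrt(mean(rowSums(res^2)))
  tf
}

#' Multi-scale point-to-plane ICP refinement
#'
#' Sequential coarse-to-fine ICP; at each scale the source vertices are
#' voxel-downsampled, matched to their closest points on the target triangle
#' surface (correspondences beyond the scale's cap are dropped), and the
#' point-to-plane objective is minimized by Gauss-Newton with step halving,
#' so the objective is non-increasing within each scale. Converges when the
#' relative RMS change falls below `tol`.
#'
#' @param source a [TriMesh-class] (or cloud) to move.
#' @param target a [TriMesh-class] (the fixed reference surface).
#' @param initial initial [RigidTransform-class] (e.g. from [coarseAlign()]).
#' @param scales list of `c(voxel mm, max correspondence mm, max iterations)`
#'   triples, coarse to fine; default `(4,8,30), (2,4,30), (1,2,30)`.
#' @param tol relative RMS convergence tolerance (default 1e-6).
#' @return a [RegistrationResult-class]; errors with a per-scale trace if the
#'   RMS grows to twice its initial value at any scale.
#' @export
refineIcpMultiscale <- function(source, target, initial,
                                scales = list(c(4, 8, 30), c(2, 4, 30),
                                              c(1, 2, 30)),
                                tol = 1e-6) {
  s <- meshCloud(source)
  stopifnot(is(target, "TriMesh"))
  tv <- target@vertices
  tf <- target@faces
  tn <- vertexNormals(target)
  cur <- initial
  trace <- list()
  finalRms <- NA_real_
  finalFit <- NA_real_
  for (sc in scales) {
    voxel <- sc[1]; maxCorr <- sc[2]; maxIt <- sc[3]
    down <- cpp_voxel_downsample(s$points, s$normals, voxel)
    p0 <- down$points
    rmsPrev <- NA_real_
    rms0 <- NA_real_
    iters <- 0
    p <- transformPoints(p0, cur)
    q <- cpp_surface_query(p, tv, tf, tn)
    for (it in seq_len(maxIt)) {
      iters <- it
      keep <- q$distance <= maxCorr
      if (sum(keep) < 6) stop("ICP lost all correspondences")
      pk <- p[keep, , drop = FALSE]
      qk <- q$closest[keep, , drop = FALSE]
      nk <- q$normal[keep, , drop = FALSE]
      r <- rowSums(nk * (pk - qk))
      rms <- sqrt(mean(r^2))
      if (it == 1) rms0 <- rms
      if (rms > 2 * rms0 + 1e-12) {
        trace[[length(trace) + 1]] <- list(voxel = voxel, rms = rms,
                                           iterations = it)
        stop(sprintf("ICP diverged at voxel %.3g mm (RMS %.3g from %.3g); trace: %s",
                     voxel, rms, rms0,
                     paste(vapply(trace, function(x)
                       sprintf("[%gmm: %.3g]", x$voxel, x$rms), character(1)),
                       collapse = " ")))
      }
      if (!is.na(rmsPrev) && abs(rmsPrev - rms) <= tol * max(rmsPrev, 1e-12))
        break
      rmsPrev <- rms
      # Gauss-Newton on (omega, t): residual n . (p + omega x p + t - q)
      A <- cbind(crossRows(pk, nk), nk)
      g <- crossprod(A, r)
      H <- crossprod(A)
      x <- tryCatch(-solve(H, g), error = function(e) rep(0, 6))
      # step halving keeps the point-to-plane objective non-increasing;
      # the accepted candidate's correspondences carry into the next
      # iteration, so each iteration costs one surface query
      step <- 1
      repeat {
        upd <- rigidTransform(rotvecToMatrix(step * x[1:3]), step * x[4:6])
        cand <- composeTransforms(upd, cur)
        pc <- transformPoints(p0, cand)
        qc <- cpp_surface_query(pc, tv, tf, tn)
        kc <- qc$distance <= maxCorr
        rc <- rowSums(qc$normal[kc, , drop = FALSE] *
                        (pc[kc, , drop = FALSE] - qc$closest[kc, , drop = FALSE]))
        if (sqrt(mean(rc^2)) <= rms || step < 1 / 64) break
        step <- step / 2
      }
      cur <- cand
      p <- pc
      q <- qc
    }
    keep <- q$distance <= maxCorr
    finalRms <- sqrt(mean(q$distance[keep]^2))
    finalFit <- mean(keep)
    trace[[length(trace) + 1]] <- list(voxel = voxel, rms = finalRms,
                                       fitness = finalFit, iterations = iters)
  }
  new("RegistrationResult", transform = cur, inlierRms = finalRms,
      fitness = finalFit, diagnostics = list(scales = trace))
}

#' Register a reconstructed mesh to a reference mesh
#'
#' Composition of [coarseAlign()] and [refineIcpMultiscale()]; all randomness
#' flows from `seed`, so repeated runs are bitwise identical.
#'
#' @param source,target [TriMesh-class] objects (source is moved onto target).
#' @param seed integer seed for the coarse stage.
#' @param coarseVoxel coarse-stage voxel size, mm (default 4).
#' @param scales fine-stage schedule, see [refineIcpMultiscale()].
#' @return a [RegistrationResult-class].
#' @export
registerMeshes <- function(source, target, seed = 1, coarseVoxel = 4,
                           scales = list(c(4, 8, 30), c(2, 4, 30),
                                         c(1, 2, 30))) {
  coarse <- coarseAlign(source, target, voxel = coarseVoxel, seed = seed)
  res <- refineIcpMultiscale(source, target, coarse, scales = scales)
  res@diagnostics$coarse <- list(fitness = attr(coarse, "fitness"),
                                 inlierRms = attr(coarse, "inlierRms"))
  res
}

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult: fitness %.3f, inlier RMS %.4g mm\n",
              object@fitness, object@inlierRms))
  print(object@transform)
  invisible(object)
})
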