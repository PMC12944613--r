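# Clinical accuracy suite: ROI clipping at anatomical landmark planes,
# signed nearest-point surface distances, MRE/RMSE/IQR/Hausdorff/MAE,
# per-slice perimeter and ROI volume errors, bias/MDC, threshold compliance.

#' Region-of-interest specification
#'
#' @param axis limb axis (normalized internally).
#' @param distal distal limb end point, mm.
#' @param landmarkHeight landmark plane height along the axis, mm (MPT height
#'   for transtibial, BAR height for transfemoral).
#' @param label "MPT" or "BAR".
#' @return a [RoiSpec-class].
#' @export
roiSpec <- function(axis = c(0, 0, 1), distal = c(0, 0, 0), landmarkHeight,
                    label = c("MPT", "BAR")) {
  axis <- stopifnot3(axis, "axis")
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("axis must be non-zero")
  new("RoiSpec", axis = axis / n, distal = stopifnot3(distal, "distal"),
      landmarkHeight = landmarkHeight, label = match.arg(label))
}

#' Default clinical thresholds
#' @export
clinicalThresholds <- function() new("Thresholds")

#' Clip a mesh to its ROI at the landmark plane
#'
#' Keeps the distal part where `axis . (p - distal) <= landmarkHeight`, cuts
#' crossing triangles exactly at the plane and closes each open boundary loop
#' with a planar fan cap, so the result is a closed solid. A landmark plane
#' above the whole mesh returns the full mesh with a warning; a plane below
#' the whole mesh is an error.
#'
#' @param mesh a closed [TriMesh-class].
#' @param roi a [RoiSpec-class].
#' @return closed [TriMesh-class] of the ROI solid.
#' @export
clipRoi <- function(mesh, roi) {
  v <- mesh@vertices
  f <- mesh@faces
  s <- as.vector(v %*% roi@axis) - sum(roi@distal * roi@axis) - roi@landmarkHeight
  eps <- 1e-12 * max(1, max(abs(s)))
  s[s == 0] <- -eps
  if (all(s > 0)) stop("landmark plane lies below the whole mesh; empty ROI")
  if (all(s < 0)) {
    warning("landmark plane lies above the whole mesh; returning the full mesh")
    return(mesh)
  }
  keepF <- s[f[, 1]] < 0 & s[f[, 2]] < 0 & s[f[, 3]] < 0
  dropF <- s[f[, 1]] > 0 & s[f[, 2]] > 0 & s[f[, 3]] > 0
  crossF <- which(!keepF & !dropF)
  newV <- list()
  newF <- list()
  cutIndex <- new.env(hash = TRUE)
  nv <- nrow(v)
  cutPoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    hit <- cutIndex[[key]]
    if (!is.null(hit)) return(hit)
    t <- s[i] / (s[i] - s[j])
    nv <<- nv + 1
    newV[[length(newV) + 1]] <<- v[i, ] + t * (v[j, ] - v[i, ])
    cutIndex[[key]] <- nv
    nv
  }
  capEdges <- list()  # directed edges on the cut plane, oriented with kept surface
  for (t in crossF) {
    idx <- f[t, ]
    ss <- s[idx]
    neg <- which(ss < 0)
    if (length(neg) == 1) {
      # keep one corner triangle
      a <- neg
      b <- (a %% 3) + 1
      cc <- (b %% 3) + 1
      pab <- cutPoint(idx[a], idx[b])
      pca <- cutPoint(idx[cc], idx[a])
      newF[[length(newF) + 1]] <- c(idx[a], pab, pca)
      capEdges[[length(capEdges) + 1]] <- c(pab, pca)
    } else {
      # keep a quad (two corners)
      a <- setdiff(1:3, neg)        # the positive corner
      b <- (a %% 3) + 1
      cc <- (b %% 3) + 1
      pab <- cutPoint(idx[a], idx[b])  # on edge a-b
      pca <- cutPoint(idx[cc], idx[a]) # on edge c-a
      newF[[length(newF) + 1]] <- c(idx[b], idx[cc], pab)
      newF[[length(newF) + 1]] <- c(idx[cc], pca, pab)
      capEdges[[length(capEdges) + 1]] <- c(pca, pab)
    }
  }
  vAll <- rbind(v, do.call(rbind, newV))
  fKeep <- rbind(f[keepF, , drop = FALSE], do.call(rbind, newF))
  # assemble cap loops from directed cut edges and fan-triangulate each
  if (length(capEdges) > 0) {
    E <- do.call(rbind, capEdges)
    nxt <- E[match(seq_len(max(E)), E[, 1]), 2]
    used <- rep(FALSE, nrow(E))
    startSet <- E[, 1]
    for (k in seq_len(nrow(E))) {
      if (used[k]) next
      loop <- integer(0)
      cur <- E[k, 1]
      repeat {
        row <- which(E[, 1] == cur & !used)
        if (length(row) == 0) break
        used[row[1]] <- TRUE
        loop <- c(loop, cur)
        cur <- E[row[1], 2]
        if (cur == loop[1]) break
      }
      if (length(loop) >= 3) {
        ctr <- colMeans(vAll[loop, , drop = FALSE])
        nv <- nrow(vAll) + 1
        vAll <- rbind(vAll, ctr)
        m <- length(loop)
        nxtl <- c(2:m, 1)
        # cap normal must face +axis: cut edges are oriented so that the
        # fan (centre, next, current) does
        fKeep <- rbind(fKeep, cbind(nv, loop[nxtl], loop))
      }
    }
  }
  out <- TriMesh(vAll, fKeep)
  # drop unreferenced vertices
  used <- sort(unique(as.vector(out@faces)))
  remap <- match(seq_len(nrow(out@vertices)), used)
  TriMesh(out@vertices[used, , drop = FALSE],
          matrix(remap[out@faces], ncol = 3))
}

#' Signed surface distances and normal deviations
#'
#' For every vertex of `test`: the nearest point on the `ref` triangle
#' surface, the signed Euclidean distance (positive when the vertex lies on
#' the outward side of `ref`, by the angle-weighted pseudonormal at the
#' nearest feature) and the angle (degrees) between the test vertex normal
#' and the barycentrically interpolated `ref` normal at the nearest point.
#'
#' @param test,ref [TriMesh-class] objects registered in a common frame.
#' @return list with `distance` (signed mm), `angle` (deg), `closest`
#'   (n x 3 matrix).
#' @export
signedSurfaceDistances <- function(test, ref) {
  if (nVertices(test) == 0 || nFaces(ref) == 0) stop("empty mesh")
  q <- cpp_surface_query(test@vertices, ref@vertices, ref@faces,
                         vertexNormals(ref))
  tn <- vertexNormals(test)
  ang <- acos(pmax(-1, pmin(1, rowSums(tn * q$normal)))) * 180 / pi
  list(distance = q$distance * q$sign, angle = ang, closest = q$closest)
}

#' Symmetric Hausdorff distance between two meshes
#'
#' Maximum over both directions of the largest vertex-to-surface distance.
#' @param a,b [TriMesh-class] objects.
#' @return distance, mm.
#' @export
hausdorffDistance <- function(a, b) {
  dab <- cpp_surface_query(a@vertices, b@vertices, b@faces,
                           matrix(numeric(0), 0, 3))$distance
  dba <- cpp_surface_query(b@vertices, a@vertices, a@faces,
                           matrix(numeric(0), 0, 3))$distance
  max(max(dab), max(dba))
}

#' Summary accuracy metrics from signed distances and angles
#'
#' MRE = mean signed distance; RMSE = sqrt(mean d^2); IQR = Q3 - Q1 of the
#' signed distances (type-7 interpolated quartiles); Hausdorff = largest
#' absolute deviation over both directions (pass `reverseDistances` from the
#' ref-to-test direction to make it symmetric); MAE = mean angle.
#'
#' @param distances signed distances, mm (test-to-ref direction).
#' @param angles normal deviations, degrees.
#' @param reverseDistances optional ref-to-test distances, mm.
#' @return named list: mre, rmse, iqr, hausdorff, mae (mm / deg).
#' @export
accuracyMetrics <- function(distances, angles, reverseDistances = NULL) {
  stopifnot(length(distances) > 0, length(angles) > 0)
  both <- c(distances,
            if (is.null(reverseDistances)) numeric(0) else reverseDistances)
  list(mre = mean(distances),
       rmse = sqrt(mean(distances^2)),
       iqr = unname(diff(stats::quantile(distances, c(0.25, 0.75), type = 7))),
       hausdorff = max(abs(both)),
       mae = mean(angles))
}

#' Per-slice relative perimeter errors within the ROI
#'
#' Slice planes at heights `landmarkHeight * (k - 1/2) / nSlices`,
#' k = 1..nSlices, along the ROI axis from the distal point; the relative
#' error per slice is `(P_test - P_ref) / P_ref` of the largest-loop
#' perimeters. A slice whose plane misses either mesh is NA (flagged,
#' excluded from summaries).
#'
#' @param test,ref registered [TriMesh-class] objects.
#' @param roi a [RoiSpec-class].
#' @param nSlices number of axial slices (default 10).
#' @return numeric vector of relative errors (fractions), length `nSlices`.
#' @export
perimeterErrors <- function(test, ref, roi, nSlices = 10) {
  h <- roi@landmarkHeight * (seq_len(nSlices) - 0.5) / nSlices
  vapply(h, function(hk) {
    p <- plane(roi@distal + hk * roi@axis, roi@axis)
    pt <- slicePerimeter(test, p)
    pr <- slicePerimeter(ref, p)
    if (is.na(pt) || is.na(pr)) return(NA_real_)
    (pt - pr) / pr
  }, numeric(1))
}

#' Relative ROI volume error
#'
#' `VErel = (V_test - V_ref) / V_ref` on the capped ROI solids.
#'
#' @param test,ref registered closed [TriMesh-class] objects.
#' @param roi a [RoiSpec-class].
#' @return relative volume error (fraction).
#' @export
volumeError <- function(test, ref, roi) {
  vt <- meshVolume(clipRoi(test, roi))
  vr <- meshVolume(clipRoi(ref, roi))
  (vt - vr) / vr
}

#' Bias and minimal detectable change over repeat sessions
#'
#' `bias` is the mean of the per-repeat relative errors and
#' `MDC = 1.96 * sqrt(2) * SD` with the sample (n-1) standard deviation;
#' both in the same percent units as the input.
#'
#' @param repeatErrors numeric vector of per-repeat relative errors, percent
#'   (>= 2 values).
#' @return a [BiasMdc-class].
#' @export
biasAndMdc <- function(repeatErrors) {
  if (length(repeatErrors) < 2) stop("need at least 2 repeats")
  s <- stats::sd(repeatErrors)
  new("BiasMdc", bias = mean(repeatErrors), mdc = 1.96 * sqrt(2) * s, sd = s)
}

setMethod("show", "BiasMdc", function(object) {
  cat(sprintf("BiasMdc: bias %.4f %%, SD %.4f %%, MDC %.4f %%\n",
              object@bias, object@sd, object@mdc))
  invisible(object)
})

#' Threshold compliance of an accuracy report
#'
#' Boundary semantics follow the clinical operators literally: |MRE|, IQR,
#' Hausdorff and |bias| are inclusive (<=); RMSE, MAE and MDC are strict (<).
#'
#' @param report an [AccuracyReport-class] or the list from
#'   [accuracyMetrics()] (optionally with `verel`).
#' @param bm optional [BiasMdc-class] for the bias/MDC flags.
#' @param th a [Thresholds-class] (defaults to [clinicalThresholds()]).
#' @return named logical vector of per-metric passes plus `overall`.
#' @export
compliance <- function(report, bm = NULL, th = clinicalThresholds()) {
  g <- function(name) {
    if (is(report, "AccuracyReport")) slot(report, name) else report[[name]]
  }
  flags <- c(
    mre = abs(g("mre")) <= th@mre,
    iqr = g("iqr") <= th@iqr,
    rmse = g("rmse") < th@rmse,
    hausdorff = g("hausdorff") <= th@hausdorff,
    mae = g("mae") < th@mae)
  if (!is.null(bm))
    flags <- c(flags, bias = abs(bm@bias) <= th@bias, mdc = bm@mdc < th@mdc)
  c(flags, overall = all(flags))
}

#' Full accuracy report for a registered mesh pair
#'
#' Signed distances and normal deviations of the test ROI against the
#' reference ROI surface (symmetric Hausdorff), per-slice perimeter errors
#' and the relative ROI volume error, with per-metric threshold flags.
#'
#' @param test,ref registered closed [TriMesh-class] objects.
#' @param roi a [RoiSpec-class].
#' @param th a [Thresholds-class].
#' @param nSlices number of perimeter slices (default 10).
#' @return an [AccuracyReport-class].
#' @export
accuracyReport <- function(test, ref, roi, th = clinicalThresholds(),
                           nSlices = 10) {
  tc <- suppressWarnings(clipRoi(test, roi))
  rc <- suppressWarnings(clipRoi(ref, roi))
  fwd <- signedSurfaceDistances(tc, rc)
  rev <- signedSurfaceDistances(rc, tc)
  m <- accuracyMetrics(fwd$distance, fwd$angle, rev$distance)
  pe <- perimeterErrors(test, ref, roi, nSlices)
  ve <- volumeError(test, ref, roi)
  flags <- compliance(m, th = th)
  rep <- new("AccuracyReport", mre = m$mre, rmse = m$rmse, iqr = m$iqr,
             hausdorff = m$hausdorff, mae = m$mae, perimeterErrors = pe,
             verel = ve, flags = flags)
  rep
}

setMethod("show", "AccuracyReport", function(object) {
  cat(sprintf(
    "AccuracyReport: MRE %.4f mm, RMSE %.4f mm, IQR %.4f mm, Hausdorff %.4f mm, MAE %.3f deg\n",
    object@mre, object@rmse, object@iqr, object@hausdorff, object@mae))
  cat(sprintf("  VErel %.4f %%; mean perimeter error %.4f %% (%d/%d slices)\n",
              100 * object@verel,
              100 * mean(object@perimeterErrors, na.rm = TRUE),
              sum(!is.na(object@perimeterErrors)),
              length(object@perimeterErrors)))
  fl <- object@flags
  cat("  compliance:", paste(sprintf("%s=%s", names(fl),
                                     ifelse(fl, "pass", "FAIL")),
                             collapse = " "), "\n")
  invisible(object)
})
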