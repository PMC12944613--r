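# Inter-session repeatability: medoid selection among registered repeats,
# per-vertex variability maps, pooled SD and global MDC.

# symmetric RMS vertex-to-surface distance between two meshes
symmetricRmsDistance <- function(a, b) {
  dab <- cpp_surface_query(a@vertices, b@vertices, b@faces,
                           matrix(numeric(0), 0, 3))$distance
  dba <- cpp_surface_query(b@vertices, a@vertices, a@faces,
                           matrix(numeric(0), 0, 3))$distance
  sqrt((sum(dab^2) + sum(dba^2)) / (length(dab) + length(dba)))
}

#' Medoid mesh among registered repeats
#'
#' The repeat minimizing the summed symmetric-RMS surface distance to all
#' other repeats; ties break to the lowest index.
#'
#' @param repeats list of >= 2 registered [TriMesh-class] objects.
#' @param distanceMatrix optional precomputed symmetric distance matrix
#'   (for injecting an oracle); computed from the meshes when NULL.
#' @return medoid index (integer), with attribute `distanceMatrix`.
#' @export
medoidMesh <- function(repeats, distanceMatrix = NULL) {
  n <- if (is.null(distanceMatrix)) length(repeats) else nrow(distanceMatrix)
  if (n < 2) stop("need at least 2 registered meshes")
  if (is.null(distanceMatrix)) {
    distanceMatrix <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      distanceMatrix[i, j] <- distanceMatrix[j, i] <-
        symmetricRmsDistance(repeats[[i]], repeats[[j]])
    }
  }
  idx <- which.min(rowSums(distanceMatrix))  # which.min takes the first tie
  structure(as.integer(idx), distanceMatrix = distanceMatrix)
}

#' Per-vertex repeatability around the medoid
#'
#' Signed point-to-surface distances from every medoid vertex to every repeat
#' surface (positive along the medoid outward normal), then per-vertex sample
#' SD, IQR and P95 of |d|, the pooled SD of all vertex-by-repeat distances in
#' one distribution, and the MDC `1.96 * sqrt(2) * pooledSD`.
#'
#' @param medoid the medoid [TriMesh-class].
#' @param repeats list of registered repeats (may include the medoid itself;
#'   its distances are zero).
#' @param medoidIndex index recorded in the report (default `NA`).
#' @return a [RepeatabilityReport-class] with attribute `distances`
#'   (vertex x repeat matrix, mm).
#' @export
pervertexRepeatability <- function(medoid, repeats, medoidIndex = NA_integer_) {
  nV <- nVertices(medoid)
  vn <- vertexNormals(medoid)
  D <- matrix(0, nV, length(repeats))
  for (k in seq_along(repeats)) {
    q <- cpp_surface_query(medoid@vertices, repeats[[k]]@vertices,
                           repeats[[k]]@faces, matrix(numeric(0), 0, 3))
    disp <- q$closest - medoid@vertices
    D[, k] <- sign(rowSums(disp * vn)) * q$distance
  }
  perSd <- apply(D, 1, stats::sd)
  perIqr <- apply(D, 1, function(x)
    unname(diff(stats::quantile(x, c(0.25, 0.75), type = 7))))
  perP95 <- apply(abs(D), 1, function(x)
    unname(stats::quantile(x, 0.95, type = 7)))
  pooled <- stats::sd(as.vector(D))
  rep <- new("RepeatabilityReport", medoidIndex = as.integer(medoidIndex),
             sd = perSd, iqr = perIqr, p95 = perP95, pooledSd = pooled,
             mdc = 1.96 * sqrt(2) * pooled)
  attr(rep, "distances") <- D
  rep
}

setMethod("show", "RepeatabilityReport", function(object) {
  cat(sprintf(
    "RepeatabilityReport: medoid #%d, pooled SD %.4f mm, MDC %.4f mm\n",
    object@medoidIndex, object@pooledSd, object@mdc))
  cat(sprintf("  per-vertex SD median %.4f mm, P95 median %.4f mm (%d vertices)\n",
              stats::median(object@sd), stats::median(object@p95),
              length(object@sd)))
  invisible(object)
})

#' Export a per-vertex repeatability map as PLY
#'
#' Writes the medoid mesh with the chosen per-vertex statistic as a `quality`
#' scalar channel for colour mapping, plus a CSV summary.
#'
#' @param medoid the medoid [TriMesh-class].
#' @param report a [RepeatabilityReport-class].
#' @param path output PLY path.
#' @param statistic "sd", "iqr" or "p95".
#' @param csvPath optional CSV summary path.
#' @export
writeRepeatabilityMap <- function(medoid, report, path, statistic = "sd",
                                  csvPath = NULL) {
  q <- slot(report, statistic)
  writeMesh(medoid, path, quality = q)
  if (!is.null(csvPath)) {
    utils::write.csv(data.frame(
      statistic = c("pooledSd", "mdc", "sdMedian", "iqrMedian", "p95Median"),
      value = c(report@pooledSd, report@mdc, stats::median(report@sd),
                stats::median(report@iqr), stats::median(report@p95))),
      csvPath, row.names = FALSE)
  }
  invisible(path)
}
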