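# CT outer-shell pipeline: Otsu threshold, cavity filling, distance fields,
# slab-wise isosurface extraction.

bruteOtsu <- function(x) {
  # exhaustive search over all 256 bin boundaries
  lo <- min(x); hi <- max(x)
  h <- tabulate(pmin(256, floor((x - lo) / (hi - lo) * 256) + 1), nbins = 256)
  p <- h / sum(h)
  mids <- seq_len(256) - 0.5
  best <- -Inf; bestK <- 1
  for (k in 1:255) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:k] * mids[1:k]) / w0
    mu1 <- sum(p[(k + 1):256] * mids[(k + 1):256]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; bestK <- k }
  }
  lo + bestK * (hi - lo) / 256
}

test_that("Otsu threshold maximizes between-class variance", {
  set.seed(10)
  x <- array(c(rep(10, 4000), rep(200, 6000)), c(10, 10, 100))
  th <- otsuThreshold(voxelVolume(x, 1))
  expect_gt(th, 10); expect_lt(th, 200)
  expect_equal(th, bruteOtsu(x))

  gm <- array(c(rnorm(5000, 50, 10), rnorm(5000, 180, 10)), c(10, 10, 100))
  thg <- otsuThreshold(voxelVolume(gm, 1))
  expect_lt(abs(thg - bruteOtsu(gm)), diff(range(gm)) / 256 + 1e-12)

  bin <- array(c(rep(0, 10), rep(1, 17)), c(3, 3, 3))
  thb <- otsuThreshold(voxelVolume(bin, 1))
  expect_gt(thb, 0); expect_lt(thb, 1)

  expect_error(otsuThreshold(voxelVolume(array(5, c(3, 3, 3)), 1)), "constant")
})

test_that("outer-shell filling removes cavities and only cavities", {
  # hollow sphere shell: outer r=20, inner r=15 (voxel units)
  n <- 45
  ax <- seq_len(n) - 23
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  shell <- r2 <= 20^2 & r2 >= 15^2
  ball <- r2 <= 20^2
  filled <- fillOuterShell(shell)
  expect_identical(filled, fillOuterShell(ball))
  # cavity voxel count transferred exactly
  expect_equal(sum(filled) - sum(shell), sum(r2 < 15^2))

  cube <- array(TRUE, c(4, 4, 4))
  expect_identical(fillOuterShell(cube), cube)
  empty <- array(FALSE, c(4, 4, 4))
  expect_identical(fillOuterShell(empty), empty)
})

test_that("filling is idempotent and monotone (property)", {
  set.seed(31)
  for (rep in 1:5) {
    g <- array(runif(12^3) < 0.35, c(12, 12, 12))
    f1 <- fillOuterShell(g)
    expect_identical(fillOuterShell(f1), f1)
    expect_true(all(f1[g]))                      # foreground never removed
    g2 <- g
    g2[sample(length(g2), 30)] <- TRUE           # adding foreground
    f2 <- fillOuterShell(g2)
    expect_true(all(f2[f1]))                     # monotonicity
  }
})

test_that("signed distance field is exact Euclidean on both sides", {
  # single foreground voxel on a 7^3 grid vs brute-force distances
  g <- array(FALSE, c(7, 7, 7))
  g[4, 4, 4] <- TRUE
  sdf <- signedDistanceField(g, 2)   # spacing 2 mm
  for (off in list(c(0, 0, 0), c(1, 0, 0), c(1, 2, 0), c(3, 2, 1))) {
    p <- c(4, 4, 4) + off
    expect_equal(sdf[p[1], p[2], p[3]],
                 if (all(off == 0)) -2 * 1 else 2 * sqrt(sum(off^2)))
  }
  # half-space: |field| equals distance to the plane in voxel units
  hs <- array(FALSE, c(8, 8, 8))
  hs[, , 1:4] <- TRUE
  sdfh <- signedDistanceField(hs, 1)
  for (k in 1:8)
    expect_equal(unique(as.vector(sdfh[, , k])),
                 if (k <= 4) -(5 - k) else k - 4)
  # centre of a solid ball is negative
  n <- 21
  ax <- seq_len(n) - 11
  ball <- outer(outer(ax^2, ax^2, "+"), ax^2, "+") <= 64
  sdfb <- signedDistanceField(ball, 1)
  expect_lt(sdfb[11, 11, 11], 0)
  expect_warning(signedDistanceField(array(TRUE, c(3, 3, 3)), 1), "single")
})

test_that("slab plans cover the volume with exact overlaps", {
  pl <- slabPlan(1000, 256, 32)
  expect_equal(pl@starts[1], 0L)
  expect_equal(tail(pl@ends, 1), 1000L)
  expect_true(all(pl@ends[-length(pl@ends)] - pl@starts[-1] == 32L))
  expect_equal(length(slabPlan(100, 256, 32)@starts), 1L)
  expect_error(slabPlan(100, 32, 32), "smaller")
})

test_that("shell extraction recovers the sphere volume and ignores cavities", {
  s <- meshIcosphere(20, 4)
  vol <- voxelizeMesh(s, 0.5)
  shell <- shellMeshFromVolume(vol)
  expect_true(isClosedMesh(shell))
  expect_lt(abs(meshVolume(shell) / 33510.32 - 1), 0.01)

  volC <- voxelizeMesh(s, 0.5, cavity = list(center = c(0, 0, 0), radius = 7.5))
  shellC <- shellMeshFromVolume(volC)
  expect_lt(abs(meshVolume(shellC) / meshVolume(shell) - 1), 0.001)

  pl <- slabPlan(dim(vol@intensities)[3], height = 40, overlap = 8)
  expect_gt(length(pl@starts), 1)
  shellS <- shellMeshFromVolume(vol, pl)
  expect_true(isClosedMesh(shellS))
  expect_lt(hausdorffDistance(shell, shellS), 0.25)
})

test_that("shell volume is invariant to slab height (property)", {
  s <- meshIcosphere(10, 3)
  vol <- voxelizeMesh(s, 0.5)
  ref <- shellMeshFromVolume(vol)
  for (h in c(20, 31)) {
    pl <- slabPlan(dim(vol@intensities)[3], height = h, overlap = 8)
    m <- shellMeshFromVolume(vol, pl)
    expect_lt(hausdorffDistance(ref, m), 0.25)
  }
})

test_that("volumes round-trip through TIFF stacks and NRRD", {
  s <- meshIcosphere(6, 3)
  vol <- voxelizeMesh(s, 1.0)
  tp <- tempfile(fileext = ".tif")
  writeVolumeTiff(vol, tp)
  back <- readVolumeTiff(tp, spacing = 1.0)
  expect_equal(dim(back@intensities), dim(vol@intensities))
  expect_equal(back@intensities > 0.5, vol@intensities > 50)

  # NRRD (raw + gzip encodings) written by hand
  np <- tempfile(fileext = ".nrrd")
  d <- dim(vol@intensities)
  con <- file(np, "wb")
  writeLines(c("NRRD0004", "type: float", "dimension: 3",
               sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
               "spacings: 1 1 1", "encoding: raw", ""), con, sep = "\n")
  writeBin(as.vector(vol@intensities), con, size = 4, endian = "little")
  close(con)
  nb <- readVolumeNrrd(np)
  expect_equal(nb@spacing, 1.0)
  expect_equal(nb@intensities > 50, vol@intensities > 50)
})

test_that("python scikit-image agrees with the Otsu threshold (oracle)", {
  skip_if_not(nzchar(Sys.which("python")))
  set.seed(77)
  x <- array(c(rnorm(4000, 40, 8), rnorm(6000, 150, 12)), c(10, 10, 100))
  csv <- tempfile(fileext = ".txt")
  writeLines(format(as.vector(x), digits = 10), csv)
  out <- tryCatch(system2("python", c("-c", shQuote(sprintf(paste0(
    "import numpy as np; from skimage.filters import threshold_otsu; ",
    "x = np.loadtxt('%s'); print(threshold_otsu(x, nbins=256))"), csv))),
    stdout = TRUE, stderr = FALSE), error = function(e) NULL)
  skip_if(is.null(out) || length(out) == 0, "scikit-image unavailable")
  ours <- otsuThreshold(voxelVolume(x, 1))
  binw <- diff(range(x)) / 256
  expect_lt(abs(ours - as.numeric(out[length(out)])), 1.5 * binw)
})
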