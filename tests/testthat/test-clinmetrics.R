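# Clinical accuracy suite: ROI clipping, signed distances, summary metrics,
# perimeter/volume errors, bias/MDC, compliance semantics.

test_that("ROI clipping reproduces the analytic cylinder volume", {
  cyl <- cyl30()
  roi <- defaultRoi(120)
  cl <- clipRoi(cyl, roi)
  expect_true(isClosedMesh(cl))
  prism <- 128 * 30^2 * sin(2 * pi / 128) / 2
  expect_equal(meshVolume(cl), prism * 120, tolerance = 1e-9)
  # cap area equals the slice cross-section area
  capFaces <- abs(vertices(cl)[faces(cl)[, 1], 3] - 120) < 1e-9 &
    abs(vertices(cl)[faces(cl)[, 2], 3] - 120) < 1e-9 &
    abs(vertices(cl)[faces(cl)[, 3], 3] - 120) < 1e-9
  v <- vertices(cl); f <- faces(cl)[capFaces, , drop = FALSE]
  capArea <- sum(sqrt(rowSums(limbmetric:::crossRows(
    v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
    v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])^2)) / 2)
  sliceArea <- attr(sliceMesh(cyl, plane(c(0, 0, 120), c(0, 0, 1)))[[1]],
                    "area")
  expect_equal(capArea, sliceArea, tolerance = 1e-6)
})

test_that("clipping handles out-of-range landmark planes", {
  cyl <- cyl30()
  high <- roiSpec(c(0, 0, 1), c(0, 0, 0), 500, "MPT")
  expect_warning(full <- clipRoi(cyl, high), "above")
  expect_equal(meshVolume(full), meshVolume(cyl))
  below <- roiSpec(c(0, 0, 1), c(0, 0, -60), 50, "BAR")
  expect_error(clipRoi(cyl, below), "below")
})

test_that("signed distances on concentric spheres are the analytic offset", {
  outer <- sphere502()
  inner <- sphere50()
  d <- signedSurfaceDistances(outer, inner)
  expect_equal(unname(d$distance), rep(0.2, nVertices(outer)),
               tolerance = 1e-9)
  expect_lt(max(d$angle), 0.5)

  same <- signedSurfaceDistances(inner, inner)
  expect_equal(max(abs(same$distance)), 0, tolerance = 1e-12)
  expect_lt(max(same$angle), 1e-4)

  flipped <- new("TriMesh", vertices = vertices(inner), faces = faces(inner),
                 vnormals = -vertexNormals(inner))
  df <- signedSurfaceDistances(flipped, inner)
  expect_equal(unname(df$distance), unname(same$distance))
  expect_gt(min(df$angle), 179.99)
})

test_that("summary metrics match hand computations", {
  m <- accuracyMetrics(rep(0.2, 10), rep(0, 10))
  expect_equal(unname(unlist(m)), c(0.2, 0.2, 0, 0.2, 0))

  d <- c(-1, 0, 1)
  m2 <- accuracyMetrics(d, c(0, 0, 0))
  expect_equal(m2$mre, 0)
  expect_equal(m2$rmse, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(m2$iqr, 1.0)   # type-7 interpolated quartiles: -0.5 .. 0.5
  expect_equal(m2$hausdorff, 1)

  set.seed(123)
  g <- rnorm(1e5, 0, 0.3)
  m3 <- accuracyMetrics(g, abs(g))
  expect_lt(abs(m3$rmse / 0.3 - 1), 0.01)
  expect_lt(abs(m3$iqr / (2 * qnorm(0.75) * 0.3) - 1), 0.02)
})

test_that("perimeter errors are exact for analytic cylinder pairs", {
  roi <- defaultRoi(120)
  expect_equal(perimeterErrors(cyl30(), cyl30(), roi), rep(0, 10))
  pe <- perimeterErrors(cyl303(), cyl30(), roi)
  expect_length(pe, 10)
  expect_equal(pe, rep(0.01, 10), tolerance = 1e-9)
  cone <- makePhantom(phantomSpec("conical", segments = 64, rings = 30))$mesh
  expect_equal(perimeterErrors(cone, cone, roi), rep(0, 10))
})

test_that("volume error matches the radial-inflation closed form", {
  roi <- defaultRoi(120)
  expect_equal(volumeError(cyl30(), cyl30(), roi), 0)
  s <- meshIcosphere(50, 4, center = c(0, 0, 60))
  s2 <- deformRadial(s, 0.05)   # exact x1.001 radial scaling
  roiS <- roiSpec(c(0, 0, 1), c(0, 0, 0), 150, "MPT")
  ve <- suppressWarnings(volumeError(s2, s, roiS))
  expect_equal(ve, 1.001^3 - 1, tolerance = 1e-5)
  # axial shift with a full-range clip changes nothing
  s3 <- applyTransform(s, rigidTransform(diag(3), c(0, 0, 5)))
  roiW <- roiSpec(c(0, 0, 1), c(0, 0, 0), 200, "MPT")
  expect_equal(suppressWarnings(volumeError(s3, s, roiW)), 0, tolerance = 1e-12)
})

test_that("bias and MDC follow the 1.96 sqrt(2) definition", {
  expect_error(biasAndMdc(0.3), "at least 2")
  bm <- biasAndMdc(rep(0.4, 5))
  expect_equal(bm@bias, 0.4)
  expect_equal(bm@mdc, 0)

  bm2 <- biasAndMdc(c(-0.5, 0.5))
  expect_equal(bm2@bias, 0)
  expect_equal(bm2@sd, sqrt(0.5), tolerance = 1e-12)
  expect_equal(bm2@mdc, 1.96 * sqrt(2) * sqrt(0.5), tolerance = 1e-12)
  expect_equal(bm2@mdc, 1.96, tolerance = 1e-4)

  set.seed(99)
  reps <- rnorm(10, 0.2, 0.3)
  bm3 <- biasAndMdc(reps)
  expect_lt(abs(bm3@bias - 0.2), 3 * 0.3 / sqrt(10))
})

test_that("compliance uses the printed boundary operators", {
  th <- clinicalThresholds()
  base <- list(mre = 0, rmse = 0, iqr = 0, hausdorff = 0, mae = 0)
  fl <- compliance(base, th = th)
  expect_true(fl[["overall"]])

  atMre <- base; atMre$mre <- 0.25
  expect_true(compliance(atMre, th = th)[["mre"]])          # <= inclusive
  overMre <- base; overMre$mre <- 0.2500001
  expect_false(compliance(overMre, th = th)[["mre"]])

  atRmse <- base; atRmse$rmse <- 1.0
  expect_false(compliance(atRmse, th = th)[["rmse"]])       # < strict
  atH <- base; atH$hausdorff <- 1.8
  expect_true(compliance(atH, th = th)[["hausdorff"]])
  atMae <- base; atMae$mae <- 4.0
  expect_false(compliance(atMae, th = th)[["mae"]])

  bmPass <- biasAndMdc(c(0.9, 1.1))
  fl2 <- compliance(base, bmPass, th)
  expect_true(fl2[["bias"]])    # |bias| = 1.0 inclusive
  bmFail <- biasAndMdc(c(3.49, 3.51))   # mdc tiny, bias over
  expect_false(compliance(base, bmFail, th)[["bias"]])
})

test_that("metrics are invariant under a common rigid transform (property)", {
  set.seed(7)
  test <- deformRadial(regPhantom("ischial"), 0.15)
  ref <- regPhantom("ischial")
  roi <- defaultRoi(120)
  base <- accuracyReport(test, ref, roi)
  for (i in 1:2) {
    g <- randomRigidTransform(40, 80, seed = 200 + i)
    axis2 <- as.vector(g@rotation %*% c(0, 0, 1))
    roi2 <- roiSpec(axis2, as.vector(g@rotation %*% c(0, 0, 0)) + g@translation,
                    120, "MPT")
    moved <- accuracyReport(applyTransform(test, g), applyTransform(ref, g),
                            roi2)
    expect_equal(moved@mre, base@mre, tolerance = 1e-9)
    expect_equal(moved@rmse, base@rmse, tolerance = 1e-9)
    expect_equal(moved@hausdorff, base@hausdorff, tolerance = 1e-9)
    expect_equal(moved@verel, base@verel, tolerance = 1e-9)
  }
})

test_that("hausdorff >= RMSE >= |MRE| on random inputs (property)", {
  set.seed(41)
  for (i in 1:5) {
    d <- rnorm(200, runif(1, -0.5, 0.5), runif(1, 0.01, 1))
    m <- accuracyMetrics(d, abs(d))
    expect_gte(m$hausdorff + 1e-12, m$rmse)
    expect_gte(m$rmse + 1e-12, abs(m$mre))
  }
})

test_that("radial inflation links MRE and VErel through S/V (property)", {
  ref <- sphere50()
  delta <- 0.1
  test <- deformRadial(ref, delta)
  roi <- roiSpec(c(0, 0, 1), c(0, 0, -60), 200, "MPT")
  rep <- suppressWarnings(accuracyReport(test, ref, roi))
  expect_equal(rep@mre, delta, tolerance = 0.01)
  # exact volume ratio of the radial offset, and its first-order S/V form
  expect_equal(rep@verel, (1 + delta / 50)^3 - 1, tolerance = 1e-3)
  expect_equal(rep@verel, 3 * delta / 50, tolerance = 0.01)
})
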