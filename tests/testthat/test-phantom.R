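# Synthetic phantom generator: analytic closed forms, deformations, noise,
# voxelization and tag projections.

test_that("cylindrical phantom volume matches the closed form", {
  ph <- makePhantom(phantomSpec("cylindrical", length = 200, baseRadius = 40,
                                segments = 720, rings = 200))
  expect_lt(abs(meshVolume(ph$mesh) / (pi * 40^2 * 200) - 1), 5e-4)
  # tessellation-exact prism volume
  exact <- 720 * 40^2 * sin(2 * pi / 720) / 2 * 200
  expect_equal(meshVolume(ph$mesh), exact, tolerance = 1e-10)
})

test_that("conical phantom perimeters follow the linear radius law", {
  ph <- makePhantom(phantomSpec("conical", length = 200, baseRadius = 40,
                                taper = 0.5, segments = 256, rings = 80))
  for (z in c(30, 100, 170)) {
    p <- slicePerimeter(ph$mesh, plane(c(0, 0, z), c(0, 0, 1)))
    expect_equal(as.numeric(p),
                 ph$analyticPerimeter(z) * ph$tessellationFactor,
                 tolerance = 1e-9)
  }
  # prismatoid volume of the polygonal frustum: frustum closed form times
  # the polygon/circle area ratio n sin(2 pi / n) / (2 pi)
  polyFactor <- 256 * sin(2 * pi / 256) / (2 * pi)
  expect_equal(meshVolume(ph$mesh),
               ph$analyticVolume * polyFactor, tolerance = 1e-10)
})

test_that("every family is watertight with Euler characteristic 2", {
  for (fam in c("conical", "cylindrical", "bulbous", "ischial")) {
    for (crest in c(0, 0.12)) {
      m <- makePhantom(phantomSpec(fam, crest = crest, segments = 32,
                                   rings = 24))$mesh
      expect_true(isClosedMesh(m), info = fam)
      expect_equal(eulerCharacteristic(m), 2, info = fam)
      expect_gt(meshVolume(m), 0)
    }
  }
})

test_that("radial deformation displaces exactly along normals", {
  s <- meshIcosphere(50, 3)
  expect_identical(vertices(deformRadial(s, 0)), vertices(s))
  s2 <- deformRadial(s, 0.2)
  expect_equal(sqrt(rowSums(vertices(s2)^2)),
               rep(50.2, nVertices(s)), tolerance = 1e-7)
  # cylinder side perimeter grows by 2 pi delta (up to chord factor)
  cyl <- meshCylinder(30, 100, 256, 8)
  c2 <- deformRadial(cyl, 0.3)
  p1 <- slicePerimeter(cyl, plane(c(0, 0, 50), c(0, 0, 1)))
  p2 <- slicePerimeter(c2, plane(c(0, 0, 50), c(0, 0, 1)))
  chord <- 256 * sin(pi / 256) / pi
  expect_equal(as.numeric(p2) - as.numeric(p1), 2 * pi * 0.3 * chord,
               tolerance = 1e-3)
})

test_that("vertex noise has the requested magnitude and is seed-deterministic", {
  s <- meshIcosphere(30, 5)   # > 10^4 vertices
  expect_identical(vertices(addVertexNoise(s, 0, 1)), vertices(s))
  n1 <- addVertexNoise(s, 0.3, seed = 7)
  n2 <- addVertexNoise(s, 0.3, seed = 7)
  expect_identical(vertices(n1), vertices(n2))
  rmse <- sqrt(mean(rowSums((vertices(n1) - vertices(s))^2)))
  expect_lt(abs(rmse / 0.3 - 1), 0.02)
  expect_false(identical(vertices(addVertexNoise(s, 0.3, seed = 8)),
                         vertices(n1)))
})

test_that("voxelization counts match analytic volumes and converge", {
  s <- meshIcosphere(20, 4)
  v1 <- voxelizeMesh(s, 1.0)
  v05 <- voxelizeMesh(s, 0.5)
  est <- function(v) sum(v@intensities > 50) * v@spacing^3
  true <- 4 / 3 * pi * 20^3
  expect_lt(abs(est(v05) / true - 1), 0.01)
  expect_lt(abs(est(v05) / true - 1), abs(est(v1) / true - 1))
  # a fully interior cavity leaves the outer boundary voxels untouched
  vc <- voxelizeMesh(s, 1.0, cavity = list(center = c(0, 0, 0), radius = 8))
  solid1 <- v1@intensities > 50
  solid2 <- vc@intensities > 50
  filled <- fillOuterShell(solid2)
  expect_identical(filled, fillOuterShell(solid1))
  expect_lt(sum(solid2), sum(solid1))
})

test_that("tag corner rendering is exact pinhole arithmetic", {
  poses <- list("0" = rigidTransform())
  map <- tagMap(20, poses, 0)
  K <- cameraIntrinsics(1000, 1000, 500, 500)
  traj <- trajectory(list(cam = topDownCamera(500)))
  dets <- renderTagCorners(map, traj, K, noisePx = 0)
  expect_length(dets, 1)
  crn <- dets[[1]]@corners[[1]]
  # world (+10, +10, 0) is the top-right canonical corner -> (520, 480)
  expect_equal(crn[2, ], c(520, 480))
  expect_equal(crn[1, ], c(480, 480))  # TL (-10, +10, 0)
  expect_equal(crn[3, ], c(520, 520))  # BR (+10, -10, 0)
  # noiseless reprojection residual of the ground truth is zero
  res <- limbmetric:::tagReprojResiduals(dets[[1]], map, traj@poses[[1]], K)
  expect_lt(max(abs(res)), 1e-10)
  # seeded noise is reproducible
  dA <- renderTagCorners(map, traj, K, noisePx = 0.5, seed = 3)
  dB <- renderTagCorners(map, traj, K, noisePx = 0.5, seed = 3)
  expect_identical(dA[[1]]@corners, dB[[1]]@corners)
  # tags behind the camera are omitted
  behind <- trajectory(list(cam = rigidTransform(diag(3), c(0, 0, -500))))
  expect_length(renderTagCorners(map, behind, K, 0), 0)
})

test_that("inflation is recovered end to end through registration", {
  # on families where a uniform normal offset is orthogonal to rigid
  # motions (not the conical family, where it mimics an axial translation)
  target <- regPhantom("cylindrical")
  roi <- defaultRoi(120)
  for (delta in c(0.1, 0.2, 0.5)) {
    infl <- deformRadial(target, delta)
    res <- registerMeshes(infl, target, seed = 17)
    moved <- applyTransform(infl, res@transform)
    d <- signedSurfaceDistances(suppressWarnings(clipRoi(moved, roi)),
                                suppressWarnings(clipRoi(target, roi)))
    expect_equal(mean(d$distance), delta, tolerance = 0.02)
  }
})
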