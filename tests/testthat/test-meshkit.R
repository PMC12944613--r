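# Core mesh operators: enclosed volume, planar slicing, smoothing,
# similarity transforms, file round-trips.

test_that("enclosed volume matches closed forms and the tetra-sum oracle", {
  expect_equal(meshVolume(unitCube()), 1.0)

  s <- meshIcosphere(10, 4)
  # independent oracle: brute-force signed tetra sum, written out directly
  v <- vertices(s)
  f <- faces(s)
  oracle <- 0
  for (t in seq_len(nrow(f))) {
    a <- v[f[t, 1], ]; b <- v[f[t, 2], ]; cc <- v[f[t, 3], ]
    oracle <- oracle + sum(a * c(b[2] * cc[3] - b[3] * cc[2],
                                 b[3] * cc[1] - b[1] * cc[3],
                                 b[1] * cc[2] - b[2] * cc[1])) / 6
  }
  expect_equal(meshVolume(s), oracle, tolerance = 1e-12)
  expect_lt(abs(meshVolume(s) / 4188.79 - 1), 0.005)
})

test_that("inverted winding is reported positive with a warning", {
  cube <- unitCube()
  flipped <- NULL
  expect_warning(
    flipped <- TriMesh(vertices(cube), faces(cube)[, c(1, 3, 2)]),
    "re-oriented")
  expect_equal(meshVolume(flipped), 1.0)
  # volume guard itself also warns when handed a raw inward mesh
  raw <- new("TriMesh", vertices = vertices(cube),
             faces = faces(cube)[, c(1, 3, 2)],
             vnormals = matrix(numeric(0), 0, 3))
  expect_warning(vol <- meshVolume(raw), "inward")
  expect_equal(vol, 1.0)
})

test_that("volume errors on open meshes, naming the boundary edge count", {
  cube <- unitCube()
  open <- new("TriMesh", vertices = vertices(cube),
              faces = faces(cube)[-1, , drop = FALSE],
              vnormals = matrix(numeric(0), 0, 3))
  expect_error(meshVolume(open), "3 boundary edges")
})

test_that("planar slicing returns closed loops with exact perimeters", {
  sq <- sliceMesh(meshCube(4), plane(c(0, 0, 0), c(0, 0, 1)))
  expect_length(sq, 1)
  expect_equal(attr(sq[[1]], "perimeter"), 16.0, tolerance = 1e-12)

  cyl <- meshCylinder(30, 100, 720, 4)
  p <- slicePerimeter(cyl, plane(c(0, 0, 37), c(0, 0, 1)))
  chord <- 2 * 720 * 30 * sin(pi / 720)   # closed-form polygon perimeter
  expect_lt(abs(p / chord - 1), 1e-12)
  expect_lt(abs(p / (2 * pi * 30) - 1), 1e-4)

  expect_length(sliceMesh(cyl, plane(c(0, 0, 500), c(0, 0, 1))), 0)
  expect_true(is.na(slicePerimeter(cyl, plane(c(0, 0, 500), c(0, 0, 1)))))
})

test_that("slice perimeter uses the largest loop; extra loops are diagnostic", {
  # two disjoint cubes in one mesh -> two loops per slice
  a <- meshCube(4)
  b <- meshCube(2, center = c(10, 0, 0))
  both <- TriMesh(rbind(vertices(a), vertices(b)),
                  rbind(faces(a), faces(b) + nVertices(a)))
  p <- slicePerimeter(both, plane(c(0, 0, 0), c(0, 0, 1)))
  expect_equal(as.numeric(p), 16.0, tolerance = 1e-12)
  expect_equal(attr(p, "extraLoops"), 1L)
})

test_that("cone slice perimeter follows the linear law between slices", {
  ph <- makePhantom(phantomSpec("conical", segments = 256, rings = 40))
  zq <- c(60, 80, 100)
  per <- vapply(zq, function(z)
    as.numeric(slicePerimeter(ph$mesh, plane(c(0, 0, z), c(0, 0, 1)))),
    numeric(1))
  chord <- ph$tessellationFactor
  expect_equal(per, ph$analyticPerimeter(zq) * chord, tolerance = 1e-9)
  # linearity: midpoint slice equals the mean of its neighbours
  expect_equal(per[2], (per[1] + per[3]) / 2, tolerance = 1e-9)
})

test_that("surface-preserving Laplacian smoothing reduces noise, keeps topology", {
  base <- meshIcosphere(10, 5)
  noisy <- addVertexNoise(base, 0.2, seed = 11)
  expect_identical(vertices(laplacianSmoothPreserving(noisy, 0)),
                   vertices(noisy))
  sm <- laplacianSmoothPreserving(noisy, 20)
  rmsDev <- function(m) sqrt(mean((sqrt(rowSums(vertices(m)^2)) - 10)^2))
  expect_lt(rmsDev(sm), rmsDev(noisy))
  expect_identical(faces(sm), faces(noisy))
  expect_equal(nVertices(sm), nVertices(noisy))
})

test_that("Laplacian smoothing keeps a plane patch coplanar", {
  g <- expand.grid(x = 0:10, y = 0:10)
  v <- cbind(g$x, g$y, 0)
  f <- NULL
  for (i in 1:10) for (j in 1:10) {
    a <- (j - 1) * 11 + i
    f <- rbind(f, c(a, a + 1, a + 11), c(a + 1, a + 12, a + 11))
  }
  patch <- TriMesh(v, f)
  sm <- laplacianSmoothPreserving(patch, 20)
  expect_lt(max(abs(vertices(sm)[, 3])), 1e-6)
})

test_that("Taubin smoothing preserves volume and reduces noise", {
  base <- meshIcosphere(10, 4)
  noisy <- addVertexNoise(base, 0.2, seed = 3)
  expect_identical(vertices(taubinSmooth(noisy, iterations = 0)),
                   vertices(noisy))
  sm <- taubinSmooth(noisy, 0.5, -0.53, 10)
  expect_lt(abs(meshVolume(sm) / meshVolume(base) - 1), 0.01)
  rmsDev <- function(m) sqrt(mean((sqrt(rowSums(vertices(m)^2)) - 10)^2))
  expect_lt(rmsDev(sm), rmsDev(noisy))
  expect_identical(faces(sm), faces(noisy))
})

test_that("similarity transforms map vertices exactly and round-trip", {
  cube <- unitCube()
  expect_equal(vertices(applyTransform(cube, similarityTransform())),
               vertices(cube))
  big <- applyTransform(cube, similarityTransform(scale = 2))
  expect_equal(meshVolume(big), 8.0, tolerance = 1e-12)

  tf <- similarityTransform(1.7,
                            limbmetric:::rotvecToMatrix(c(0.3, -0.2, 0.9)),
                            c(10, -4, 2))
  back <- applyTransform(applyTransform(cube, tf), inverseTransform(tf))
  expect_lt(max(abs(vertices(back) - vertices(cube))), 1e-9)
})

test_that("volume scales as s^3 under similarity (property)", {
  meshes <- list(unitCube(), meshIcosphere(7, 3),
                 makePhantom(phantomSpec("ischial", segments = 32,
                                         rings = 24))$mesh)
  set.seed(42)
  for (m in meshes) for (s in runif(3, 0.3, 3)) {
    tf <- similarityTransform(s, limbmetric:::rotvecToMatrix(rnorm(3)),
                              rnorm(3, 0, 10))
    expect_equal(meshVolume(applyTransform(m, tf)), s^3 * meshVolume(m),
                 tolerance = 1e-9)
  }
})

test_that("mesh files round-trip through PLY, STL and OBJ", {
  m <- meshIcosphere(5, 2)
  for (ext in c("ply", "stl", "obj")) {
    path <- tempfile(fileext = paste0(".", ext))
    writeMesh(m, path)
    back <- readMesh(path)
    expect_equal(meshVolume(back), meshVolume(m),
                 tolerance = if (ext == "ply") 1e-12 else 1e-6)
    expect_equal(nFaces(back), nFaces(m))
  }
  # ASCII variants
  for (ext in c("ply", "stl")) {
    path <- tempfile(fileext = paste0(".", ext))
    writeMesh(m, path, binary = FALSE)
    back <- readMesh(path)
    expect_equal(meshVolume(back), meshVolume(m), tolerance = 1e-6)
  }
  # PLY quality channel is accepted on read
  path <- tempfile(fileext = ".ply")
  writeMesh(m, path, quality = seq_len(nVertices(m)) / nVertices(m))
  expect_equal(nVertices(readMesh(path)), nVertices(m))
})

test_that("python mesh stack agrees on PLY volume (independent oracle)", {
  skip_if_not(nzchar(Sys.which("python")))
  m <- meshIcosphere(6, 3)
  path <- tempfile(fileext = ".ply")
  writeMesh(m, path)
  out <- tryCatch(system2("python", c("-c", shQuote(sprintf(
    "import trimesh; m = trimesh.load('%s'); print(m.volume)", path))),
    stdout = TRUE, stderr = FALSE), error = function(e) NULL)
  skip_if(is.null(out) || length(out) == 0, "python trimesh unavailable")
  expect_equal(as.numeric(out[length(out)]), meshVolume(m), tolerance = 1e-6)
})
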