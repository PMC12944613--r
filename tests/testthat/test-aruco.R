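# Tag-map construction, two-stage PnP, similarity estimation, trajectory I/O.

test_that("two-stage PnP recovers a synthetic pose exactly", {
  poses <- list("0" = rigidTransform())
  map <- tagMap(20, poses, 0)
  K <- cameraIntrinsics(1000, 1000, 500, 500)
  truth <- topDownCamera(500)
  det <- renderTagCorners(map, trajectory(list(cam = truth)), K, 0)[[1]]
  est <- estimatePoseTwoStage(det, map, K)
  expect_lt(est$rmse, 1e-8)
  expect_lt(max(abs(est$pose@translation - truth@translation)), 1e-6)
  expect_lt(rotAngleDeg(est$pose@rotation, truth@rotation) * pi / 180, 1e-8)
})

test_that("PnP rejects behind-plane views and degenerate corners", {
  poses <- list("0" = rigidTransform())
  map <- tagMap(20, poses, 0)
  K <- cameraIntrinsics(1000, 1000, 500, 500)
  det <- renderTagCorners(map, trajectory(list(cam = topDownCamera(500))),
                          K, 0)[[1]]
  mirrored <- tagDetections("m", 0L, list(det@corners[[1]][4:1, ]))
  expect_error(estimatePoseTwoStage(mirrored, map, K), "behind tag plane")
  collinear <- tagDetections("c", 0L,
                             list(cbind(480 + 10 * (0:3), 480 + 10 * (0:3))))
  expect_error(estimatePoseTwoStage(collinear, map, K), "degenerate|collinear")
  noMap <- tagDetections("n", 7L, list(det@corners[[1]]))
  expect_error(estimatePoseTwoStage(noMap, map, K), "no mapped tag")
})

test_that("PnP translation error stays below 1 mm under 0.5 px noise", {
  sc <- tagScene()
  truth <- sc$traj@poses[[1]]
  errs <- vapply(1:25, function(trial) {
    det <- renderTagCorners(sc$map, trajectory(list(cam = truth)), sc$K,
                            noisePx = 0.5, seed = 1000 + trial)[[1]]
    est <- estimatePoseTwoStage(det, sc$map, sc$K)
    cs <- cameraCenter(est$pose)
    sqrt(sum((cs - cameraCenter(truth))^2))
  }, numeric(1))
  expect_lt(median(errs), 1)
})

test_that("joint optimization recovers the tag map from a noiseless ring", {
  sc <- tagScene()
  dets <- renderTagCorners(sc$map, sc$traj, sc$K, noisePx = 0)
  res <- buildTagMap(dets, sc$K, 20)
  expect_lt(res$rmse, 1e-8)
  for (id in names(sc$map@poses)) {
    derr <- sqrt(sum((res$map@poses[[id]]@translation -
                        sc$map@poses[[id]]@translation)^2))
    expect_lt(derr, 1e-6)
  }
  # joint optimization never worsens the initialization
  expect_true(res$rmse < 1e-6)
})

test_that("a single tag in a single image yields the trivial map", {
  poses <- list("5" = rigidTransform())
  map <- tagMap(20, poses, 5)
  K <- cameraIntrinsics(1000, 1000, 500, 500)
  det <- renderTagCorners(map, trajectory(list(img = topDownCamera(400))),
                          K, 0)[[1]]
  res <- buildTagMap(list(det), K, 20)
  expect_named(res$map@poses, "5")
  expect_equal(res$map@poses[["5"]]@rotation, diag(3))
  expect_lt(res$rmse, 1e-8)
  expect_named(res$trajectory@poses, "img")
})

test_that("disconnected co-visibility graphs are rejected with components", {
  K <- cameraIntrinsics(1000, 1000, 500, 500)
  mk <- function(id, shift) {
    poses <- list()
    poses[[as.character(id)]] <- rigidTransform()
    m <- tagMap(20, poses, id)
    d <- renderTagCorners(m, trajectory(list(x = topDownCamera(400))), K, 0)[[1]]
    tagDetections(paste0("img", id), id, d@corners)
  }
  expect_error(buildTagMap(list(mk(0L), mk(3L)), K, 20), "disconnected")
})

test_that("noisy corner detections keep the map scale within 0.5 percent", {
  sc <- tagScene()
  truthD <- sqrt(sum((sc$map@poses[["3"]]@translation -
                        sc$map@poses[["0"]]@translation)^2))
  errs <- vapply(1:3, function(trial) {
    dets <- renderTagCorners(sc$map, sc$traj, sc$K, noisePx = 0.3,
                             seed = 500 + trial)
    res <- buildTagMap(dets, sc$K, 20)
    d <- sqrt(sum((res$map@poses[["3"]]@translation -
                     res$map@poses[["0"]]@translation)^2))
    abs(d / truthD - 1)
  }, numeric(1))
  expect_lt(max(errs), 0.005)
})

test_that("gauge fixing and tag-side scaling behave as symmetries", {
  sc <- tagScene()
  dets <- renderTagCorners(sc$map, sc$traj, sc$K, noisePx = 0)
  # express the same physical scene in a different world frame (gauge):
  # anchor tag 3 instead of tag 0; the projected pixels are unchanged up to
  # that re-anchoring, so recovered inter-tag distances and RMSE must match
  anchor <- sc$map@poses[["3"]]
  poses2 <- lapply(sc$map@poses, function(p)
    composeTransforms(inverseTransform(anchor), p))
  names(poses2)[match("3", names(poses2))] <- "3"
  map2 <- tagMap(20, poses2, 3)
  traj2 <- trajectory(lapply(sc$traj@poses, function(p)
    composeTransforms(p, anchor)))
  dets2 <- renderTagCorners(map2, traj2, sc$K, noisePx = 0)
  res1 <- buildTagMap(dets, sc$K, 20)
  res2 <- buildTagMap(dets2, sc$K, 20)
  d <- function(r) sqrt(sum((r$map@poses[["3"]]@translation -
                               r$map@poses[["1"]]@translation)^2))
  expect_equal(d(res1), d(res2), tolerance = 1e-9)
  # doubling the tag side doubles every recovered distance exactly
  res3 <- buildTagMap(dets, sc$K, 40)
  expect_equal(d(res3), 2 * d(res1), tolerance = 1e-9)
  c1 <- cameraCenter(res1$trajectory@poses[[1]])
  c3 <- cameraCenter(res3$trajectory@poses[[1]])
  expect_equal(sqrt(sum(c3^2)) , 2 * sqrt(sum(c1^2)), tolerance = 1e-6)
})

test_that("Umeyama similarity estimation matches closed forms", {
  set.seed(17)
  src <- matrix(rnorm(30, 0, 20), 10, 3)
  expect_error(estimateSimilarityUmeyama(src[1:2, ], src[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(estimateSimilarityUmeyama(line, line), "collinear")

  idt <- estimateSimilarityUmeyama(src, src)
  expect_equal(idt$transform@scale, 1, tolerance = 1e-12)
  expect_lt(idt$rms, 1e-10)

  dst <- 2 * src + matrix(c(10, 0, 0), 10, 3, byrow = TRUE)
  est <- estimateSimilarityUmeyama(src, dst)
  expect_equal(est$transform@scale, 2, tolerance = 1e-12)
  expect_lt(est$rms, 1e-10)

  tf <- similarityTransform(0.37, limbmetric:::rotvecToMatrix(c(1, -2, 0.5)),
                            c(4, 5, -6))
  est2 <- estimateSimilarityUmeyama(src, applyTransform(src, tf))
  expect_lt(max(abs(asMatrix4(est2$transform) - asMatrix4(tf))), 1e-9)
})

test_that("reconstruction scaling recovers the SfM scale from camera centres", {
  sc <- tagScene()
  mesh <- meshIcosphere(5, 2)
  idres <- scaleReconstruction(sc$traj, sc$traj, mesh)
  expect_equal(idres$transform@scale, 1, tolerance = 1e-12)

  # SfM trajectory shrunk 100x (arbitrary reconstruction scale)
  shrink <- lapply(sc$traj@poses, function(p)
    rigidTransform(p@rotation, p@translation / 100))
  small <- applyTransform(mesh, similarityTransform(1 / 100))
  res <- scaleReconstruction(trajectory(shrink), sc$traj, small)
  expect_equal(res$transform@scale, 100, tolerance = 1e-9)
  expect_equal(meshVolume(res$model), meshVolume(mesh), tolerance = 1e-9)

  # gross outlier centres: warned, transform still returned
  bad <- shrink
  bad[[2]] <- rigidTransform(bad[[2]]@rotation,
                             bad[[2]]@translation + c(3, 0, 0))
  expect_warning(resB <- scaleReconstruction(trajectory(bad), sc$traj, small),
                 "outlier")
  expect_s4_class(resB$transform, "SimilarityTransform")

  expect_error(scaleReconstruction(trajectory(shrink[1:2]), sc$traj, small),
               "shared image ids")
})

test_that("trajectories and tag maps round-trip through their file dialects", {
  sc <- tagScene()
  tp <- tempfile(fileext = ".txt")
  writeTrajectoryColmap(sc$traj, tp)
  back <- readTrajectoryColmap(tp)
  expect_setequal(names(back@poses), names(sc$traj@poses))
  for (id in names(sc$traj@poses)) {
    expect_lt(max(abs(back@poses[[id]]@translation -
                        sc$traj@poses[[id]]@translation)), 1e-9)
    expect_lt(rotAngleDeg(back@poses[[id]]@rotation,
                          sc$traj@poses[[id]]@rotation), 1e-5)
  }
  mp <- tempfile(fileext = ".json")
  writeTagMap(sc$map, mp)
  mback <- readTagMap(mp)
  expect_equal(mback@tagSide, 20)
  expect_equal(mback@rootId, 0L)
  expect_equal(mback@poses[["3"]]@translation,
               sc$map@poses[["3"]]@translation, tolerance = 1e-12)
})
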