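# Shared fixtures, built in code and cached per test run.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

unitCube <- function() fixture("unitCube", meshCube(1))

sphere50 <- function() fixture("sphere50", meshIcosphere(50, 4))
sphere502 <- function() fixture("sphere502", meshIcosphere(50.2, 4))

cyl30 <- function() fixture("cyl30", meshCylinder(30, 200, 128, 20))
cyl303 <- function() fixture("cyl303", meshCylinder(30.3, 200, 128, 20))

# low-resolution asymmetric phantom for registration work
regPhantom <- function(family) {
  fixture(paste0("regPhantom_", family),
          makePhantom(phantomSpec(family, crest = 0.12, segments = 64,
                                  rings = 40))$mesh)
}

defaultRoi <- function(h = 120) roiSpec(c(0, 0, 1), c(0, 0, 0), h, "MPT")

rotAngleDeg <- function(R1, R2 = diag(3)) limbmetric:::rotationAngleDeg(R1, R2)

# Ground-truth synthetic tag scene: 4 coplanar 20 mm tags on a 100 mm grid
# (the corners of a marker ring on a model base plate), 8 cameras on a ring
# at ~500 mm range, 4K-smartphone-like intrinsics.
tagScene <- function() {
  fixture("tagScene", {
    poses <- list()
    offs <- list(c(0, 0), c(100, 0), c(0, 100), c(100, 100))
    for (i in 1:4)
      poses[[as.character(i - 1)]] <- rigidTransform(diag(3), c(offs[[i]], 0))
    map <- tagMap(20, poses, 0)
    K <- cameraIntrinsics(2800, 2800, 1920, 1080)
    camPoses <- list()
    for (a in seq(0, 2 * pi, length.out = 9)[1:8]) {
      cpos <- c(50 + 300 * cos(a), 50 + 300 * sin(a), 400)
      zc <- c(50, 50, 0) - cpos
      zc <- zc / sqrt(sum(zc^2))
      xc <- limbmetric:::cross3(c(0, 0, 1), zc)
      xc <- xc / sqrt(sum(xc^2))
      yc <- limbmetric:::cross3(zc, xc)
      Rwc <- rbind(xc, yc, zc)
      camPoses[[sprintf("img%02d", length(camPoses) + 1)]] <-
        rigidTransform(Rwc, -as.vector(Rwc %*% cpos))
    }
    list(map = map, K = K, traj = trajectory(camPoses))
  })
}

# top-down camera at height z looking along -z, image x = world x
topDownCamera <- function(height = 500) {
  R <- diag(c(1, -1, -1))
  rigidTransform(R, -as.vector(R %*% c(0, 0, height)))
}
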