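# Sharpness scoring, adaptive frame selection, orientation normalization,
# mask binarization.

test_that("Laplacian sharpness matches a hand convolution oracle", {
  expect_equal(laplacianSharpness(matrix(128, 8, 8)), 0)

  img <- matrix(0, 5, 5)
  img[3, 3] <- 1
  k <- rbind(c(0, 1, 0), c(1, -4, 1), c(0, 1, 0))
  L <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    L[i, j] <- sum(k * img[i:(i + 2), j:(j + 2)])
  expect_equal(laplacianSharpness(img), mean((L - mean(L))^2))

  expect_error(laplacianSharpness(matrix(1, 1, 1)), "3 x 3")
})

test_that("blurring strictly lowers the sharpness score", {
  set.seed(5)
  tex <- matrix(runif(64 * 64), 64, 64)
  blur <- tex
  for (i in 1:4)
    blur <- (blur + blur[c(1, 1:63), ] + blur[c(2:64, 64), ] +
               blur[, c(1, 1:63)] + blur[, c(2:64, 64)]) / 5
  expect_lt(laplacianSharpness(blur), laplacianSharpness(tex))
})

test_that("sharpness is invariant to a constant offset and uses Rec.601 luma", {
  set.seed(9)
  tex <- matrix(runif(32 * 32, 0, 0.5), 32, 32)
  expect_equal(laplacianSharpness(tex + 0.25), laplacianSharpness(tex))
  rgb <- array(0, c(32, 32, 3))
  rgb[, , 1] <- tex; rgb[, , 2] <- tex; rgb[, , 3] <- tex
  expect_equal(laplacianSharpness(rgb), laplacianSharpness(tex))
})

test_that("moving-window selection keeps locally sharp frames", {
  # all equal: everything retained, then uniformly subsampled
  sel <- selectFrames(rep(3, 20), selectionConfig(5, 0.9, 150))
  expect_equal(sel, 0:19)
  sel <- selectFrames(rep(3, 20), selectionConfig(5, 0.9, 10))
  expect_length(sel, 10)
  expect_true(all(diff(sel) > 0))

  # alternating 10, 1 with window 3: median of each window is 10
  sc <- rep(c(10, 1), 10)[1:19]
  expect_equal(selectFrames(sc, selectionConfig(3, 0.9, 150)),
               seq(0, 18, by = 2))

  expect_equal(selectFrames(7, selectionConfig(15, 0.9, 150)), 0)
})

test_that("selection is idempotent on its own output", {
  set.seed(21)
  sc <- runif(60, 1, 10)
  cfg <- selectionConfig(7, 0.9, 150)
  sel <- selectFrames(sc, cfg)
  again <- selectFrames(data.frame(index = sel, sharpness = sc[sel + 1]), cfg)
  expect_equal(again, sel)
})

test_that("a blurrier adjacent duplicate never drops the original", {
  set.seed(22)
  sc <- runif(40, 5, 10)
  cfg <- selectionConfig(5, 0.9, 150)
  base <- selectFrames(sc, cfg)
  for (pos in c(3, 20, 38)) {
    sc2 <- append(sc, sc[pos] * 0.05, after = pos)
    sel2 <- selectFrames(sc2, cfg)
    # indices of original frames after insertion
    orig <- c(seq_len(pos) - 1, pos + seq_len(40 - pos))
    keptOrig <- sort(match(sel2[sel2 %in% orig], orig)) - 1
    expect_true(all(base %in% keptOrig))
  }
})

test_that("EXIF orientation cases remap pixels as a reference viewer would", {
  m <- matrix(1:6, 2, 3)   # rows = image rows
  expect_identical(normalizeOrientation(m, 1), m)
  expect_identical(normalizeOrientation(m), m)
  # tag 6: image must be rotated 90 degrees clockwise to display upright
  expect_identical(normalizeOrientation(m, 6),
                   matrix(c(2L, 4L, 6L, 1L, 3L, 5L), 3, 2))
  expect_identical(normalizeOrientation(m, 8),
                   matrix(c(5L, 3L, 1L, 6L, 4L, 2L), 3, 2))
  expect_identical(normalizeOrientation(m, 2), m[, 3:1])
  expect_identical(normalizeOrientation(m, 3), m[2:1, 3:1])
  expect_identical(normalizeOrientation(m, 4), m[2:1, ])
  expect_identical(normalizeOrientation(m, 5), t(m))
  expect_identical(normalizeOrientation(m, 7), t(m)[3:1, 2:1])
  # involutions / round trips
  expect_identical(normalizeOrientation(normalizeOrientation(m, 3), 3), m)
  expect_identical(normalizeOrientation(normalizeOrientation(m, 6), 8), m)
  expect_warning(out <- normalizeOrientation(m, 9), "unknown")
  expect_identical(out, m)
  # channelled arrays are remapped per plane
  a <- array(runif(12), c(2, 3, 2))
  r <- normalizeOrientation(a, 6)
  expect_equal(dim(r), c(3, 2, 2))
  expect_identical(r[, , 2], normalizeOrientation(a[, , 2], 6))
})

test_that("mask binarization thresholds at 50 percent inclusive", {
  m <- matrix(c(0.49, 0.51, 0.5, 0), 2, 2)
  b <- binarizeMask(m)
  expect_identical(as.vector(b), c(0L, 1L, 1L, 0L))
  # 0..255 range detected and rescaled
  b255 <- binarizeMask(matrix(c(120, 130, 127.5, 0), 2, 2))
  expect_identical(as.vector(b255), c(0L, 1L, 1L, 0L))
  expect_warning(binarizeMask(matrix(0, 3, 3)), "empty mask")
})

test_that("frame files are scored and the manifest written", {
  dir <- tempfile(); dir.create(dir)
  set.seed(1)
  tex <- matrix(runif(48 * 48), 48, 48)
  blur <- tex
  for (i in 1:5)
    blur <- (blur + blur[c(1, 1:47), ] + blur[c(2:48, 48), ] +
               blur[, c(1, 1:47)] + blur[, c(2:48, 48)]) / 5
  paths <- file.path(dir, sprintf("frame_%05d.png", 1:6))
  for (i in 1:6) png::writePNG(if (i %% 3 == 0) blur else tex, paths[i])
  sc <- scoreFrameFiles(paths)
  expect_equal(nrow(sc), 6)
  expect_true(all(sc$sharpness[c(3, 6)] < sc$sharpness[c(1, 2, 4, 5)]))
  kept <- selectFrames(sc, selectionConfig(3, 0.9, 150))
  out <- writeSelectionManifest(sc, kept, file.path(dir, "sel.csv"))
  man <- read.csv(out)
  expect_identical(man$retained, man$index %in% kept)
})
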