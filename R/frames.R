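# Frame ingestion and adaptive sharpness-based selection for handheld video.

#' Frame-selection configuration
#'
#' Moving-window selection parameters: a frame is kept when its sharpness is
#' at least `alpha` times the median sharpness of the centred `window`
#' (clipped at the sequence ends); at most `maxFrames` frames are kept, by
#' uniform order-preserving subsampling. Defaults keep roughly 1-2 fps of
#' locally sharp frames from 30 fps video.
#'
#' @param window odd window length in frames (>= 1).
#' @param alpha fraction of the windowed median required, in (0, 1].
#' @param maxFrames maximal number of retained frames (>= 1).
#' @export
selectionConfig <- function(window = 15, alpha = 0.9, maxFrames = 150) {
  window <- as.integer(window)
  if (window < 1 || window %% 2 == 0) stop("window must be an odd integer >= 1")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (maxFrames < 1) stop("maxFrames must be >= 1")
  structure(list(window = window, alpha = alpha,
                 maxFrames = as.integer(maxFrames)),
            class = "selectionConfig")
}

# Rec.601 luma for RGB(A) arrays; grayscale matrices pass through
toGray <- function(image) {
  if (is.matrix(image)) return(image)
  if (length(dim(image)) == 3) {
    w <- c(0.299, 0.587, 0.114)
    return(image[, , 1] * w[1] + image[, , 2] * w[2] + image[, , 3] * w[3])
  }
  stop("image must be a matrix or an array with channels")
}

#' Variance-of-Laplacian sharpness score
#'
#' Population variance of the 3x3 Laplacian kernel
#' `[[0,1,0],[1,-4,1],[0,1,0]]` response over all valid (interior) pixels.
#' RGB inputs are converted with Rec.601 luma weights. Higher is sharper;
#' constant images score 0.
#'
#' @param image grayscale matrix or RGB array, at least 3 x 3.
#' @return non-negative sharpness score (intensity^2 units).
#' @export
laplacianSharpness <- function(image) {
  g <- toGray(image)
  nr <- nrow(g); nc <- ncol(g)
  if (is.null(nr) || nr < 3 || nc < 3)
    stop("image must be at least 3 x 3 pixels")
  core <- g[2:(nr - 1), 2:(nc - 1)]
  L <- -4 * core +
    g[1:(nr - 2), 2:(nc - 1)] + g[3:nr, 2:(nc - 1)] +
    g[2:(nr - 1), 1:(nc - 2)] + g[2:(nr - 1), 3:nc]
  mean((L - mean(L))^2)
}

#' Adaptive moving-window frame selection
#'
#' A frame survives when its sharpness is at least `alpha` times the median
#' sharpness of its centred window (clipped at the sequence ends). The rule
#' is iterated to a fixed point on the surviving set, so selection is
#' idempotent: re-running it on its own output changes nothing. Convergence
#' is guaranteed (the set only shrinks) and immediate when local sharpness is
#' roughly homogeneous.
#'
#' @param scores data.frame with columns `index` (0-based frame ordinals) and
#'   `sharpness`, or a bare numeric vector of sharpness values (indices then
#'   default to `0:(n-1)`).
#' @param cfg a [selectionConfig()].
#' @return sorted integer vector of retained frame indices.
#' @export
selectFrames <- function(scores, cfg = selectionConfig()) {
  if (is.numeric(scores)) scores <- data.frame(index = seq_along(scores) - 1L,
                                               sharpness = as.numeric(scores))
  stopifnot(all(c("index", "sharpness") %in% names(scores)), nrow(scores) > 0)
  ord <- order(scores$index)
  idx <- scores$index[ord]
  s <- scores$sharpness[ord]
  half <- cfg$window %/% 2
  pass <- function(sv) {
    n <- length(sv)
    med <- vapply(seq_len(n), function(i) {
      lo <- max(1, i - half)
      hi <- min(n, i + half)
      stats::median(sv[lo:hi])
    }, numeric(1))
    sv >= cfg$alpha * med
  }
  alive <- seq_along(s)
  repeat {
    keep <- pass(s[alive])
    if (all(keep)) break
    alive <- alive[keep]
    if (length(alive) == 0) break
  }
  retained <- idx[alive]
  if (length(retained) > cfg$maxFrames) {
    pick <- unique(round(seq(1, length(retained), length.out = cfg$maxFrames)))
    retained <- retained[pick]
  }
  sort(unique(retained))
}

#' Normalize image orientation from an EXIF tag
#'
#' Remaps pixels so the result is upright, top-left aligned. Tag values
#' follow the EXIF Orientation convention (1..8); an absent (NULL/NA) tag is
#' the identity and an unknown value warns and returns the image unchanged.
#'
#' @param image grayscale matrix or array with channel planes.
#' @param orientation EXIF orientation tag in 1..8, or NULL/NA.
#' @return the upright image.
#' @export
normalizeOrientation <- function(image, orientation = NULL) {
  if (is.null(orientation) || is.na(orientation)) return(image)
  per <- function(m, fun) {
    if (is.matrix(m)) return(fun(m))
    planes <- lapply(seq_len(dim(m)[3]), function(k) fun(m[, , k]))
    array(unlist(planes), dim = c(dim(planes[[1]]), length(planes)))
  }
  flipH <- function(m) m[, ncol(m):1, drop = FALSE]
  flipV <- function(m) m[nrow(m):1, , drop = FALSE]
  rot180 <- function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]
  rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
  rot90ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  switch(as.character(as.integer(orientation)),
    "1" = image,
    "2" = per(image, flipH),
    "3" = per(image, rot180),
    "4" = per(image, flipV),
    "5" = per(image, t),
    "6" = per(image, rot90cw),
    "7" = per(image, function(m) rot90cw(flipH(m))),
    "8" = per(image, rot90ccw),
    {
      warning(sprintf("unknown EXIF orientation tag %s; image unchanged",
                      orientation))
      image
    })
}

#' Binarize an alpha matte at the 50 percent threshold
#'
#' A pixel is foreground when its normalized alpha is >= 0.5 (inclusive
#' boundary). Inputs in [0, 255] are detected by their range and rescaled.
#' All-background mattes trigger an "empty mask" warning.
#'
#' @param alphaMask numeric matrix in [0, 1] or [0, 255].
#' @return integer matrix with values in {0, 1}.
#' @export
binarizeMask <- function(alphaMask) {
  m <- as.matrix(alphaMask)
  if (max(m, na.rm = TRUE) > 1) m <- m / 255
  out <- matrix(as.integer(m >= 0.5), nrow(m), ncol(m))
  if (!any(out == 1L)) warning("empty mask: no foreground pixels")
  out
}

#' Score image files by sharpness
#'
#' Reads PNG frames, converts to luma, and returns a frame-score table.
#'
#' @param paths character vector of PNG file paths, in frame order.
#' @return data.frame with columns index (0-based), path, sharpness.
#' @export
scoreFrameFiles <- function(paths) {
  sharp <- vapply(paths, function(p) laplacianSharpness(png::readPNG(p)),
                  numeric(1))
  data.frame(index = seq_along(paths) - 1L, path = paths,
             sharpness = unname(sharp), row.names = NULL)
}

#' Extract frames from a video via an external decoder
#'
#' Thin adapter around `ffmpeg` (decoding codecs is delegated, not
#' reimplemented); frames are written as lossless PNGs named
#' `frame_%05d.png`. Errors if the decoder is not on the PATH.
#'
#' @param video input video path (e.g. MP4/MOV).
#' @param outDir output directory for the decoded frames.
#' @param fps optional decimation rate passed to the decoder.
#' @return character vector of written frame paths.
#' @export
framesFromVideo <- function(video, outDir, fps = NULL) {
  ffmpeg <- Sys.which("ffmpeg")
  if (!nzchar(ffmpeg)) stop("ffmpeg not found on PATH; decode frames externally")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  args <- c("-i", shQuote(video),
            if (!is.null(fps)) c("-vf", sprintf("fps=%g", fps)),
            "-y", shQuote(file.path(outDir, "frame_%05d.png")))
  status <- system2(ffmpeg, args, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("frame extraction failed")
  list.files(outDir, pattern = "^frame_\\d{5}\\.png$", full.names = TRUE)
}

#' Write a frame-selection manifest CSV
#'
#' @param scores data.frame from [scoreFrameFiles()] or with index/sharpness.
#' @param retained integer vector of retained indices.
#' @param path output CSV path.
#' @export
writeSelectionManifest <- function(scores, retained, path) {
  scores$retained <- scores$index %in% retained
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
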