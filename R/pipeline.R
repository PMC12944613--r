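# Orchestration: validated configuration, manifest-driven batch validation
# across models x modalities x repeats, report aggregation, and the thin
# command-line interface.

configDefaults <- function() {
  list(
    thresholds = list(mre = 0.25, iqr = 0.4, rmse = 1.0, hausdorff = 1.8,
                      mae = 4.0, bias = 1.0, mdc = 3.5),
    nSlices = 10,
    smoothing = list(iterations = 20, maxNormalAngleDeg = 90),
    taubin = list(lambda = 0.5, mu = -0.53, iterations = 10),
    selection = list(window = 15, alpha = 0.9, maxFrames = 150),
    registration = list(coarseVoxel = 4,
                        scales = list(c(4, 8, 30), c(2, 4, 30), c(1, 2, 30))),
    seed = 1)
}

#' Load a validated YAML configuration
#'
#' Unknown keys are rejected by name; absent keys take the pipeline defaults
#' (clinical thresholds, 10 perimeter slices, surface-preserving smoothing at
#' 20 iterations / 90 degrees, Taubin 0.5/-0.53 x 10).
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return nested configuration list.
#' @export
loadConfig <- function(path = NULL) {
  cfg <- configDefaults()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  merge <- function(base, upd, prefix = "") {
    for (k in names(upd)) {
      full <- paste0(prefix, k)
      if (!k %in% names(base))
        stop(sprintf("unknown configuration key '%s'", full))
      if (is.list(base[[k]]) && !is.null(names(base[[k]])))
        base[[k]] <- merge(base[[k]], upd[[k]], paste0(full, "."))
      else base[[k]] <- upd[[k]]
    }
    base
  }
  merge(cfg, user)
}

configThresholds <- function(cfg) {
  t <- cfg$thresholds
  new("Thresholds", mre = t$mre, iqr = t$iqr, rmse = t$rmse,
      hausdorff = t$hausdorff, mae = t$mae, bias = t$bias, mdc = t$mdc)
}

#' Build a validation run manifest
#'
#' @param entries data.frame with columns model, modality, repeatIndex, path.
#' @param reference named character vector: model id -> reference mesh path.
#' @param roi named list of [RoiSpec-class] per model id.
#' @param thresholds a [Thresholds-class].
#' @param seed integer run seed; all per-entry seeds derive from it.
#' @return a [RunManifest-class].
#' @export
runManifest <- function(entries, reference, roi,
                        thresholds = clinicalThresholds(), seed = 1) {
  new("RunManifest", entries = entries, reference = reference, roi = roi,
      thresholds = thresholds, seed = as.integer(seed))
}

fmt6 <- function(x) {
  # fixed 6-significant-digit formatting for byte-stable CSV output
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

#' Run a manifest-driven validation batch
#'
#' Per entry: register the mesh to its model reference, clip the ROI and
#' compute the accuracy metric suite. Per (model, modality): bias/MDC of the
#' repeat VErel and perimeter errors, and medoid-based per-vertex
#' repeatability. Failing entries are recorded and skipped; the run
#' continues. Fully deterministic for a given manifest seed.
#'
#' @param manifest a [RunManifest-class].
#' @param outDir optional output directory for `entries.csv`,
#'   `aggregates.csv` and `report.json`.
#' @param nSlices perimeter slices per entry (default 10).
#' @return list with `entries` (per-entry metric data.frame), `aggregates`
#'   (per model x modality bias/MDC and repeatability), `failures`
#'   (data.frame), `compliance` (per-metric pass counts).
#' @export
runValidation <- function(manifest, outDir = NULL, nSlices = 10) {
  validObject(manifest)
  ent <- manifest@entries
  ent <- ent[order(ent$model, ent$modality, ent$repeatIndex), , drop = FALSE]
  refCache <- list()
  rows <- list()
  failures <- list()
  regMeshCache <- list()
  for (i in seq_len(nrow(ent))) {
    e <- ent[i, ]
    res <- tryCatch({
      if (!file.exists(e$path)) stop(sprintf("missing file '%s'", e$path))
      refPath <- manifest@reference[[e$model]]
      if (is.null(refCache[[e$model]])) {
        if (!file.exists(refPath)) stop(sprintf("missing reference '%s'", refPath))
        refCache[[e$model]] <- readMesh(refPath)
      }
      ref <- refCache[[e$model]]
      mesh <- readMesh(e$path)
      reg <- registerMeshes(mesh, ref, seed = manifest@seed + i)
      moved <- applyTransform(mesh, reg@transform)
      roi <- manifest@roi[[e$model]]
      rep <- accuracyReport(moved, ref, roi, manifest@thresholds, nSlices)
      key <- paste(e$model, e$modality, sep = "|")
      regMeshCache[[key]] <- c(regMeshCache[[key]], list(moved))
      data.frame(
        model = e$model, modality = e$modality, repeatIndex = e$repeatIndex,
        mre = rep@mre, rmse = rep@rmse, iqr = rep@iqr,
        hausdorff = rep@hausdorff, mae = rep@mae,
        verelPct = 100 * rep@verel,
        perimMeanPct = 100 * mean(rep@perimeterErrors, na.rm = TRUE),
        fitness = reg@fitness,
        compliant = unname(rep@flags[["overall"]]),
        stringsAsFactors = FALSE)
    }, error = function(err) err)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- data.frame(
        model = e$model, modality = e$modality, repeatIndex = e$repeatIndex,
        error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(model = character(0))
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(model = character(0))
  # aggregates per (model, modality)
  aggRows <- list()
  repeatability <- list()
  if (nrow(entries) > 0) {
    for (key in sort(unique(paste(entries$model, entries$modality, sep = "|")))) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      sub <- entries[entries$model == parts[1] & entries$modality == parts[2], ]
      bmV <- if (nrow(sub) >= 2) biasAndMdc(sub$verelPct) else NULL
      bmP <- if (nrow(sub) >= 2) biasAndMdc(sub$perimMeanPct) else NULL
      meshes <- regMeshCache[[key]]
      repRep <- NULL
      if (length(meshes) >= 2) {
        med <- medoidMesh(meshes)
        repRep <- pervertexRepeatability(meshes[[med]], meshes, med)
        repeatability[[key]] <- repRep
      }
      aggRows[[length(aggRows) + 1]] <- data.frame(
        model = parts[1], modality = parts[2], nRepeats = nrow(sub),
        volumeBiasPct = if (is.null(bmV)) NA_real_ else bmV@bias,
        volumeMdcPct = if (is.null(bmV)) NA_real_ else bmV@mdc,
        perimBiasPct = if (is.null(bmP)) NA_real_ else bmP@bias,
        perimMdcPct = if (is.null(bmP)) NA_real_ else bmP@mdc,
        pooledSdMm = if (is.null(repRep)) NA_real_ else repRep@pooledSd,
        mdcMm = if (is.null(repRep)) NA_real_ else repRep@mdc,
        stringsAsFactors = FALSE)
    }
  }
  aggregates <- if (length(aggRows)) do.call(rbind, aggRows) else
    data.frame(model = character(0))
  complianceCounts <- if (nrow(entries) > 0)
    c(compliant = sum(entries$compliant), total = nrow(entries)) else
    c(compliant = 0L, total = 0L)
  out <- list(entries = entries, aggregates = aggregates,
              failures = failures, compliance = complianceCounts,
              repeatability = repeatability)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeCsvStable <- function(df, path) {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines("# limbmetric validation CSV schema v1", con)
      num <- vapply(df, is.numeric, logical(1)) &
        !vapply(df, is.integer, logical(1))
      df[num] <- lapply(df[num], fmt6)
      utils::write.csv(df, con, row.names = FALSE)
    }
    writeCsvStable(entries, file.path(outDir, "entries.csv"))
    writeCsvStable(aggregates, file.path(outDir, "aggregates.csv"))
    jsonlite::write_json(
      list(entries = entries, aggregates = aggregates,
           failures = failures,
           compliance = as.list(complianceCounts)),
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }
  out
}

# ---------------------------------------------------------------------------
# command-line interface (invoked by exec/limbmetric)

cliParse <- function(args) {
  if (length(args) == 0) return(list(cmd = "help", opts = list()))
  cmd <- args[1]
  args <- args[-1]
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i < length(args) && !grepl("^--", args[i + 1])) {
        opts[[key]] <- args[i + 1]
        i <- i + 2
      } else {
        opts[[key]] <- TRUE
        i <- i + 1
      }
    } else {
      opts$positional <- c(opts$positional, a)
      i <- i + 1
    }
  }
  list(cmd = cmd, opts = opts)
}

cliNum <- function(opts, key, default = NULL) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

#' Command-line entry point
#'
#' Dispatches the `limbmetric` subcommands (mesh-info, smooth, phantom,
#' ctshell, register, accuracy, repeat, tagmap, scale, frames, validate) onto
#' the package functions. Installed as the `exec/limbmetric` script.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
limbmetricCli <- function(args = commandArgs(trailingOnly = TRUE)) {
  p <- cliParse(args)
  o <- p$opts
  status <- 0L
  switch(p$cmd,
    "mesh-info" = {
      m <- readMesh(o$positional[1])
      show(m)
      if (isClosedMesh(m))
        cat(sprintf("volume: %.3f mm^3\n", meshVolume(m)))
    },
    "smooth" = {
      m <- readMesh(o$positional[1])
      mode <- if (is.null(o$mode)) "laplacian" else o$mode
      it <- as.integer(cliNum(o, "iterations", 20))
      m2 <- if (mode == "taubin") taubinSmooth(m, iterations = it)
            else laplacianSmoothPreserving(m, iterations = it,
                   maxNormalAngleDeg = cliNum(o, "max-normal-angle", 90))
      writeMesh(m2, o$out)
      cat("wrote", o$out, "\n")
    },
    "phantom" = {
      spec <- phantomSpec(family = if (is.null(o$family)) "conical" else o$family,
                          length = cliNum(o, "length", 200),
                          baseRadius = cliNum(o, "radius", 40))
      ph <- makePhantom(spec)
      writeMesh(ph$mesh, o$out)
      yaml::write_yaml(list(family = spec@family, length = spec@length,
                            baseRadius = spec@baseRadius),
                       paste0(tools::file_path_sans_ext(o$out), ".yaml"))
      cat("wrote", o$out, "\n")
    },
    "ctshell" = {
      vol <- if (grepl("\\.nrrd$", o$volume))
        readVolumeNrrd(o$volume, spacing = cliNum(o, "spacing-mm"))
      else readVolumeTiff(o$volume, spacing = cliNum(o, "spacing-mm"))
      pl <- slabPlan(dim(vol@intensities)[3],
                     height = cliNum(o, "slab", 256),
                     overlap = cliNum(o, "overlap", 32))
      mesh <- shellMeshFromVolume(vol, pl)
      writeMesh(mesh, o$out)
      cat("wrote", o$out, "\n")
    },
    "register" = {
      src <- readMesh(o$source)
      tgt <- readMesh(o$target)
      res <- registerMeshes(src, tgt, seed = as.integer(cliNum(o, "seed", 1)))
      show(res)
      if (!is.null(o$out)) {
        jsonlite::write_json(
          list(matrix = as.vector(t(asMatrix4(res@transform))),
               fitness = res@fitness, inlierRms = res@inlierRms),
          o$out, auto_unbox = TRUE, digits = NA)
        cat("wrote", o$out, "\n")
      }
    },
    "accuracy" = {
      test <- readMesh(o$test)
      ref <- readMesh(o$ref)
      axis <- as.numeric(strsplit(if (is.null(o$axis)) "0,0,1" else o$axis,
                                  ",")[[1]])
      distal <- as.numeric(strsplit(if (is.null(o$distal)) "0,0,0" else o$distal,
                                    ",")[[1]])
      roi <- roiSpec(axis, distal, cliNum(o, "landmark-mm"),
                     if (is.null(o$landmark)) "MPT" else o$landmark)
      rep <- accuracyReport(test, ref, roi)
      show(rep)
    },
    "repeat" = {
      meshes <- lapply(o$positional, readMesh)
      med <- medoidMesh(meshes)
      rep <- pervertexRepeatability(meshes[[med]], meshes, med)
      show(rep)
      if (!is.null(o$out))
        writeRepeatabilityMap(meshes[[med]], rep, o$out)
    },
    "tagmap" = {
      det <- jsonlite::read_json(o$detections, simplifyVector = FALSE)
      dets <- lapply(det, function(d)
        tagDetections(d$image, unlist(d$tag_ids),
                      lapply(d$corners, function(cm)
                        matrix(unlist(cm), 4, 2, byrow = TRUE))))
      kj <- jsonlite::read_json(o$intrinsics, simplifyVector = TRUE)
      K <- cameraIntrinsics(kj$fx, kj$fy, kj$cx, kj$cy,
                            if (is.null(kj$distortion)) numeric(0)
                            else unlist(kj$distortion))
      res <- buildTagMap(dets, K, cliNum(o, "tag-size-mm", 20))
      cat(sprintf("tag map: %d tags, RMSE %.4g px\n",
                  length(res$map@poses), res$rmse))
      if (!is.null(o$out)) writeTagMap(res$map, o$out)
      if (!is.null(o[["out-trajectory"]]))
        writeTrajectoryColmap(res$trajectory, o[["out-trajectory"]])
    },
    "scale" = {
      sfm <- readTrajectoryColmap(o$sfm)
      tags <- readTrajectoryColmap(o$tags)
      mesh <- readMesh(o$mesh)
      res <- scaleReconstruction(sfm, tags, mesh)
      writeMesh(res$model, o$out)
      cat(sprintf("scale %.6g, residual RMS %.4g mm; wrote %s\n",
                  res$transform@scale, res$rms, o$out))
    },
    "frames" = {
      paths <- if (!is.null(o$video))
        framesFromVideo(o$video, file.path(o[["out-dir"]], "frames"))
      else list.files(o$images, pattern = "\\.png$", full.names = TRUE)
      sc <- scoreFrameFiles(paths)
      cfg <- selectionConfig(window = cliNum(o, "window", 15),
                             alpha = cliNum(o, "alpha", 0.9),
                             maxFrames = cliNum(o, "max-frames", 150))
      kept <- selectFrames(sc, cfg)
      writeSelectionManifest(sc, kept,
                             file.path(o[["out-dir"]], "selection.csv"))
      cat(sprintf("retained %d / %d frames\n", length(kept), nrow(sc)))
    },
    "validate" = {
      cfg <- loadConfig(o$config)
      man <- jsonlite::read_json(o$manifest, simplifyVector = TRUE)
      roi <- lapply(man$roi, function(r)
        roiSpec(unlist(r$axis), unlist(r$distal), r$landmarkHeight, r$label))
      manifest <- runManifest(as.data.frame(man$entries),
                              unlist(man$reference), roi,
                              configThresholds(cfg),
                              seed = as.integer(cliNum(o, "seed", cfg$seed)))
      res <- runValidation(manifest, outDir = o[["out-dir"]],
                           nSlices = cfg$nSlices)
      cat(sprintf("validated %d entries (%d compliant, %d failures)\n",
                  res$compliance[["total"]], res$compliance[["compliant"]],
                  nrow(res$failures)))
      if (nrow(res$failures) > 0) status <- 1L
    },
    {
      cat("limbmetric subcommands: mesh-info smooth phantom ctshell register",
          "accuracy repeat tagmap scale frames validate\n")
    })
  invisible(status)
}
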