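## Pipeline runner and fixture generation: ties simulate -> preprocess ->
## reconstruct -> evaluate into one reproducible run driven by a YAML config.

#' Run the pipeline from a configuration
#'
#' Executes the requested stage subset against a shared output directory.
#' Every artifact's sidecar carries the config hash, so re-running a stage
#' with unchanged inputs rewrites identical content.  Stages read their
#' inputs from `outDir`; a missing input raises an error naming the stage
#' that produces it.
#'
#' @param config a [readRunConfig()] result, a YAML path, or a config list.
#' @param stages subset of `c("simulate", "preprocess", "reconstruct",
#'   "evaluate")`, in any order (the canonical order is enforced).
#' @param outDir output directory (created if needed).
#' @param verbose print stage-boundary progress (default `TRUE`).
#' @return Invisibly, a named list of artifact paths.
#' @export
runPipeline <- function(config,
                        stages = c("simulate", "preprocess", "reconstruct",
                                   "evaluate"),
                        outDir, verbose = TRUE) {
  if (!is(config, "RunConfig")) config <- readRunConfig(config)
  stages <- match.arg(stages, several.ok = TRUE)
  order_all <- c("simulate", "preprocess", "reconstruct", "evaluate")
  stages <- order_all[order_all %in% stages]
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  say <- function(...) if (verbose) message(sprintf(...))

  geom <- .cfg_geometry(config)
  illum <- .cfg_illuminator(config)
  grid <- .cfg_grid(config)
  plan <- .cfg_plan(config, geom, grid)
  optics <- .cfg_optics(config)
  phantom <- .cfg_phantom(config)
  dirm <- .cfg_directivity(config)

  paths <- list(scan = file.path(outDir, "scan.nii.gz"),
                clean = file.path(outDir, "clean.nii.gz"),
                denoise = file.path(outDir, "denoise_report.json"),
                recon = file.path(outDir, "recon.nii.gz"),
                model = file.path(outDir, "model.nii.gz"),
                report = file.path(outDir, "report.json"))

  if ("simulate" %in% stages) {
    say("[simulate] %d pose(s), %d elements", plan@nAngles, geom@nElements)
    scan <- simulateScan(phantom, geom, illum, plan, optics = optics,
                         directivity = dirm, noise = .cfg_noise(config),
                         nPatches = config$reconstruction$n_patches)
    writeRFScan(scan, paths$scan, extra = list(config_hash = hash))
  }

  if ("preprocess" %in% stages) {
    if (!file.exists(paths$scan))
      stop("preprocess input missing: ", paths$scan,
           " (produced by the 'simulate' stage)")
    say("[preprocess] order=%d cutoff=%.3g k=%d", config$preprocess$order,
        config$preprocess$cutoff, config$preprocess$k)
    scan <- readRFScan(paths$scan)
    pp <- preprocessScan(scan, order = config$preprocess$order,
                         cutoff = config$preprocess$cutoff,
                         k = config$preprocess$k,
                         referenceEnergy = config$preprocess$reference_energy)
    writeRFScan(pp$scan, paths$clean, extra = list(config_hash = hash))
    jsonlite::write_json(
      list(config_hash = hash, discarded_rank = pp$report@discardedRank,
           noise_fraction = pp$report@noiseFraction,
           flagged = pp$report@flagged),
      paths$denoise, auto_unbox = TRUE, digits = NA)
  }

  if ("reconstruct" %in% stages) {
    src <- if (file.exists(paths$clean)) paths$clean else paths$scan
    if (!file.exists(src))
      stop("reconstruct input missing: ", paths$clean,
           " (produced by the 'preprocess' stage)")
    rcfg <- config$reconstruction
    say("[reconstruct] directivity=%s compensation=%s", rcfg$directivity,
        rcfg$compensation)
    scan <- readRFScan(src)
    rec <- reconstructScan(scan, grid, illum = illum, optics = optics,
                           directivity = dirm,
                           compensation = isTRUE(rcfg$compensation),
                           epsilon = rcfg$epsilon,
                           nPatches = rcfg$n_patches)
    writeVolume(rec, paths$recon,
                extra = list(config_hash = hash,
                             options = rcfg[c("directivity", "compensation",
                                              "epsilon", "n_patches")]))
  }

  if ("evaluate" %in% stages) {
    if (!file.exists(paths$recon))
      stop("evaluate input missing: ", paths$recon,
           " (produced by the 'reconstruct' stage)")
    say("[evaluate] %d depth shells", config$evaluation$n_shells)
    rec <- readVolume(paths$recon)
    model <- voxelizePhantom(phantom, grid)
    writeVolume(model, paths$model, extra = list(config_hash = hash))
    de <- depthError(rec, model, grid,
                     nShells = config$evaluation$n_shells,
                     normalize = config$evaluation$normalize)
    jsonlite::write_json(
      list(config_hash = hash,
           image_error = imageError(rec, model,
                                    config$evaluation$normalize),
           rmse = rmse(.normalize_volume(values(rec), "unit-max"),
                       .normalize_volume(values(model), "unit-max")),
           ssim = ssim(.normalize_volume(values(rec), "unit-max"),
                       .normalize_volume(values(model), "unit-max")),
           depth_error = list(depth = de$depth, error = de$error),
           masked = rec@info$masked, uncovered = rec@info$uncovered),
      paths$report, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(paths)
}

#' Generate a ready-to-run fixture configuration
#'
#' Writes a deterministic YAML config (plus its wire list) for one of the
#' bundled phantoms, scaled so a laptop run completes in seconds: a reduced
#' element count and pose count, a coarse grid around the phantom, and
#' automatic time-window sizing.  Regenerating a fixture writes identical
#' bytes.
#'
#' @param name one of `"point_source"`, `"three_wire"`, `"cal_phantom"`,
#'   `"deep_rod"`.
#' @param outDir directory for `<name>.yaml`.
#' @return The config file path, invisibly.
#' @export
makeFixture <- function(name = c("point_source", "three_wire", "cal_phantom",
                                 "deep_rod"),
                        outDir = ".") {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown fixture '", name[1], "'; valid names: point_source, ",
         "three_wire, cal_phantom, deep_rod"))
  ph <- phantomFixture(name)
  w <- ph@wires
  grid <- switch(name,
    point_source = list(origin = c(-1.2, -1.2, 7.8), spacing = 0.1,
                        dim = c(25L, 25L, 25L)),
    three_wire = list(origin = c(-2, -2, 7.9), spacing = 0.1,
                      dim = c(41L, 41L, 41L)),
    cal_phantom = list(origin = c(-2.6, -2.6, 7.9), spacing = 0.1,
                       dim = c(53L, 53L, 33L)),
    deep_rod = list(origin = c(-1.5, -1.5, 8.8), spacing = 0.1,
                    dim = c(31L, 31L, 25L)))
  cfg <- list(
    geometry = list(n_elements = 64L),
    plan = list(n_angles = 16L, angular_step = 22.5, n_samples = "auto"),
    grid = grid,
    optics = list(mu_a0 = 0.0075, mu_s = 15, g = 0),   # 50/50 milk bath
    phantom = list(wires = lapply(seq_len(nrow(w)), function(i)
      as.list(w[i, c("x0", "y0", "z0", "x1", "y1", "z1", "radius",
                     "absorption")])),
      background_absorption = ph@backgroundAbsorption),
    seed = 1L)
  path <- file.path(outDir, paste0(name, ".yaml"))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
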