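## Declarative run configuration: one flat YAML file with stage-scoped
## blocks whose defaults reproduce the scanner's stated parameters.

.config_blocks <- c("geometry", "plan", "illuminator", "grid", "optics",
                    "phantom", "noise", "preprocess", "reconstruction",
                    "evaluation", "seed")

.default_config <- function() {
  list(
    geometry = list(n_elements = 384L, arc_length = 11.5, arc_radius = 12,
                    arc_center_polar = 27.5, elev_aperture = 0.5),
    plan = list(n_angles = 200L, angular_step = 1.8, sampling_rate = 40e6,
                n_samples = "auto", sound_speed = 1500),
    illuminator = list(dome_radius = 12, window_arc_length = 11.5,
                       window_center_polar = 27.5, window_azimuth = 15,
                       wide_divergence = 90, narrow_divergence = 0.24),
    grid = list(origin = c(-1.6, -1.6, 8.2), spacing = 0.05,
                dim = c(64L, 64L, 64L)),
    optics = list(mu_a0 = 0.2, mu_s = 10.0, g = 0),
    phantom = list(fixture = "three_wire"),
    noise = NULL,
    preprocess = list(order = 5L, cutoff = 14.5e6, k = 10L,
                      reference_energy = "mean"),
    reconstruction = list(directivity = TRUE, compensation = TRUE,
                          sigma_l = 18.5, sigma_e = 6.2, epsilon = 0.01,
                          n_patches = 200L),
    evaluation = list(n_shells = 50L, normalize = "unit-max"),
    seed = 1L)
}

#' Read and validate a run configuration
#'
#' Loads a YAML run configuration, rejects unknown blocks or keys, and fills
#' unspecified values with the scanner defaults (384-element 11.5 cm arc on
#' a 12 cm dome, 200 poses at 1.8 degrees, 40 MHz sampling, 1500 m/s,
#' 0.5 mm grid, order-5 Butterworth at 14.5 MHz, 10 discarded singular
#' values, Gaussian directivity 18.5/6.2 degrees, 200 fluence patches).
#'
#' @param path YAML file path, or a list already parsed.
#' @return A validated config list of class `"RunConfig"`, with
#'   `attr(, "hash")` the MD5 of its canonical YAML serialization.
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), .config_blocks)
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  def <- .default_config()
  for (blk in names(def)) {
    if (blk == "seed") next
    if (blk == "phantom" && !is.null(cfg$phantom)) {
      ## the phantom block replaces the default outright: a wire list and a
      ## fixture name are alternatives, never merged
      bad <- setdiff(names(cfg$phantom),
                     c("fixture", "wires", "background_absorption"))
      if (length(bad))
        stop("unknown key(s) in block 'phantom': ",
             paste(bad, collapse = ", "))
      def$phantom <- cfg$phantom
      next
    }
    if (!is.null(cfg[[blk]]) && !is.null(def[[blk]])) {
      bad <- setdiff(names(cfg[[blk]]), c(names(def[[blk]]), "wires",
                                          "background_absorption",
                                          "band_count", "band_rank",
                                          "band_amplitude", "white_sigma",
                                          "energy_jitter"))
      if (length(bad))
        stop("unknown key(s) in block '", blk, "': ",
             paste(bad, collapse = ", "))
      def[[blk]][names(cfg[[blk]])] <- cfg[[blk]]
    } else if (!is.null(cfg[[blk]])) def[[blk]] <- cfg[[blk]]
    else if (blk == "noise") def[[blk]] <- cfg[[blk]]
  }
  if (!is.null(cfg$noise)) def$noise <- cfg$noise
  if (!is.null(cfg$seed)) def$seed <- as.integer(cfg$seed)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(def, tmp)
  structure(def, class = "RunConfig", hash = unname(tools::md5sum(tmp)))
}

#' @rdname readRunConfig
#' @param config a `RunConfig`.
#' @return `configHash` returns the MD5 hash string stamped into every
#'   artifact the pipeline writes.
#' @export
configHash <- function(config) attr(config, "hash")

## builders from config blocks
.cfg_geometry <- function(cfg) {
  g <- cfg$geometry
  buildArray(g$n_elements, g$arc_length, g$arc_radius, g$arc_center_polar,
             g$elev_aperture)
}
.cfg_illuminator <- function(cfg) {
  il <- cfg$illuminator
  buildIlluminator(il$dome_radius, il$window_arc_length,
                   il$window_center_polar, il$window_azimuth,
                   il$wide_divergence, il$narrow_divergence)
}
.cfg_grid <- function(cfg)
  voxelGrid(unlist(cfg$grid$origin), cfg$grid$spacing,
            as.integer(unlist(cfg$grid$dim)))
.cfg_optics <- function(cfg)
  opticalProperties(cfg$optics$mu_a0, cfg$optics$mu_s, cfg$optics$g)
.cfg_phantom <- function(cfg) {
  ph <- cfg$phantom
  if (!is.null(ph$fixture)) return(phantomFixture(ph$fixture))
  wires <- as.data.frame(do.call(rbind, lapply(ph$wires, unlist)))
  bg <- if (is.null(ph$background_absorption)) 0 else ph$background_absorption
  phantomModel(wires, bg)
}
.cfg_plan <- function(cfg, geom, grid) {
  p <- cfg$plan
  ns <- p$n_samples
  if (identical(ns, "auto")) {
    plan0 <- acquisitionPlan(p$n_angles, p$angular_step, p$sampling_rate,
                             2L, p$sound_speed)
    ns <- requiredSamples(geom, grid, plan0)
  }
  acquisitionPlan(p$n_angles, p$angular_step, p$sampling_rate,
                  as.integer(ns), p$sound_speed)
}
.cfg_noise <- function(cfg) {
  nz <- cfg$noise
  if (is.null(nz)) return(NULL)
  noiseModel(
    bandCount = if (is.null(nz$band_count)) 3L else nz$band_count,
    bandRank = if (is.null(nz$band_rank)) 1L else nz$band_rank,
    bandAmplitude = if (is.null(nz$band_amplitude)) 1 else nz$band_amplitude,
    whiteSigma = if (is.null(nz$white_sigma)) 0 else nz$white_sigma,
    energyJitter = if (is.null(nz$energy_jitter)) 0.125 else nz$energy_jitter,
    seed = cfg$seed)
}
.cfg_directivity <- function(cfg) {
  r <- cfg$reconstruction
  if (isTRUE(r$directivity)) directivityModel(r$sigma_l, r$sigma_e) else NULL
}
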