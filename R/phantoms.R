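## Wire phantoms: absorbing monofilament segments suspended in the dome.

#' Construct a wire phantom
#'
#' A phantom is a set of thin absorbing cylinders (painted fishing line /
#' graphite rods) described by their segment endpoints, radius and absorption
#' coefficient, over an optional uniform background.
#'
#' @param wires a data.frame (or coercible matrix) with columns
#'   `x0, y0, z0, x1, y1, z1` (segment endpoints, cm), `radius` (cm) and
#'   `absorption` (cm^-1).  Note the 0.25 mm *diameter* line has radius
#'   0.0125 cm.
#' @param backgroundAbsorption uniform background absorption, cm^-1
#'   (default 0).
#' @return A `PhantomModel`.
#' @examples
#' ph <- phantomModel(data.frame(x0 = 0, y0 = -1, z0 = 10, x1 = 0, y1 = 1,
#'                               z1 = 10, radius = 0.0125, absorption = 1))
#' @export
phantomModel <- function(wires, backgroundAbsorption = 0) {
  wires <- as.data.frame(wires)
  if (nrow(wires) > 0 && is.null(wires$absorption)) wires$absorption <- 1
  new("PhantomModel", wires = wires,
      backgroundAbsorption = backgroundAbsorption)
}

#' @rdname phantomModel
#' @param x a `PhantomModel`.
#' @export
wires <- function(x) x@wires

setMethod("show", "PhantomModel", function(object) {
  cat(sprintf("PhantomModel: %d wire segment(s), background %.3g cm^-1\n",
              nrow(object@wires), object@backgroundAbsorption))
})

#' Voxelize a wire phantom onto a grid
#'
#' Marks every voxel whose centre lies within a wire's radius of its segment
#' with that wire's absorption; everything else gets the background value.
#' The result doubles as the ground-truth model volume for image-error
#' metrics.
#'
#' @param phantom a [phantomModel()].
#' @param grid a [voxelGrid()].
#' @return A `ReconVolume` of kind `"absorption"` holding the model volume.
#' @export
voxelizePhantom <- function(phantom, grid) {
  stopifnot(is(phantom, "PhantomModel"), is(grid, "VoxelGrid"))
  vox <- voxelCenterMatrix(grid)
  vals <- rep(phantom@backgroundAbsorption, nrow(vox))
  lo <- grid@origin - grid@spacing / 2
  hi <- grid@origin + (grid@dim - 1L + 0.5) * grid@spacing
  w <- phantom@wires
  for (i in seq_len(nrow(w))) {
    a <- c(w$x0[i], w$y0[i], w$z0[i])
    b <- c(w$x1[i], w$y1[i], w$z1[i])
    if (any(pmin(a, b) > hi + w$radius[i]) ||
        any(pmax(a, b) < lo - w$radius[i]))
      warning("wire ", i, " lies outside the grid; clipped")
    ab <- b - a
    len2 <- sum(ab^2)
    pa <- sweep(vox, 2, a)
    tt <- if (len2 > 0) pmin(pmax(as.numeric(pa %*% ab) / len2, 0), 1) else 0
    dd <- sqrt((pa[, 1] - tt * ab[1])^2 + (pa[, 2] - tt * ab[2])^2 +
               (pa[, 3] - tt * ab[3])^2)
    vals[dd <= w$radius[i]] <- w$absorption[i]
  }
  new("ReconVolume", grid = grid, values = array(vals, dim = grid@dim),
      kind = "absorption", compensation = "none", directivityUsed = FALSE,
      info = list(source = "model"))
}

#' Built-in phantom fixtures
#'
#' Ready-made phantoms for testing and demonstrations, all in the dome frame
#' (depth below the dome surface is `12 - |r|` cm):
#' \describe{
#'   \item{point_source}{a single point-like absorber on the rotation axis at
#'     3 cm depth.}
#'   \item{three_wire}{three parallel 0.25 mm wires at roughly 1, 2 and 3 cm
#'     depth.}
#'   \item{cal_phantom}{a calibration phantom emulating fishing line threaded
#'     between three scaffold columns at several heights (0.25 mm diameter,
#'     i.e. 0.0125 cm radius).}
#'   \item{deep_rod}{a 0.5 mm diameter graphite rod embedded 2 cm deep.}
#' }
#'
#' @param name one of `"point_source"`, `"three_wire"`, `"cal_phantom"`,
#'   `"deep_rod"`.
#' @return A `PhantomModel`.
#' @examples
#' phantomFixture("deep_rod")
#' @export
phantomFixture <- function(name = c("point_source", "three_wire",
                                    "cal_phantom", "deep_rod")) {
  name <- match.arg(name)
  r_line <- 0.0125        # 0.25 mm diameter fishing line
  switch(name,
    point_source = phantomModel(data.frame(
      x0 = 0, y0 = 0, z0 = 9, x1 = 0, y1 = 0, z1 = 9.01,
      radius = r_line, absorption = 1)),
    three_wire = phantomModel(data.frame(
      x0 = c(-1, 0, 1), y0 = -1.5, z0 = c(10.95, 10, 8.94),
      x1 = c(-1, 0, 1), y1 = 1.5, z1 = c(10.95, 10, 8.94),
      radius = r_line, absorption = 1)),
    cal_phantom = {
      ## three columns on a 2 cm circle; line threaded through holes at
      ## three heights, producing a closed zig-zag of six segments
      ang <- c(90, 210, 330) * pi / 180
      col_xy <- 2 * cbind(cos(ang), sin(ang))
      hz <- c(8.5, 9.5, 10.5)
      path <- rbind(
        c(1, 3), c(2, 2), c(3, 3), c(1, 1), c(2, 3), c(3, 1), c(1, 3))
      seg <- do.call(rbind, lapply(seq_len(nrow(path) - 1), function(i) {
        p <- c(col_xy[path[i, 1], ], hz[path[i, 2]])
        q <- c(col_xy[path[i + 1, 1], ], hz[path[i + 1, 2]])
        data.frame(x0 = p[1], y0 = p[2], z0 = p[3],
                   x1 = q[1], y1 = q[2], z1 = q[3])
      }))
      seg$radius <- r_line
      seg$absorption <- 1
      phantomModel(seg)
    },
    deep_rod = phantomModel(data.frame(
      x0 = 0, y0 = -0.5, z0 = 10, x1 = 0, y1 = 0.5, z1 = 10,
      radius = 0.025, absorption = 1)))
}

#' Discretize wires into point sources
#'
#' Wires are represented in the acoustic forward model as chains of point
#' sources at quarter-voxel spacing; each point carries the wire's absorption
#' times the cylinder volume it represents.
#'
#' @param phantom a [phantomModel()].
#' @param step chain spacing in cm (default 0.0125, a quarter of the 0.5 mm
#'   reconstruction voxel).
#' @return A list with `positions` (n x 3) and `strengths` (n).
#' @export
wireSources <- function(phantom, step = 0.0125) {
  w <- phantom@wires
  pos <- NULL; amp <- NULL
  for (i in seq_len(nrow(w))) {
    a <- c(w$x0[i], w$y0[i], w$z0[i])
    b <- c(w$x1[i], w$y1[i], w$z1[i])
    len <- sqrt(sum((b - a)^2))
    n <- max(1L, as.integer(ceiling(len / step)))
    tt <- if (n == 1L) 0.5 else (seq_len(n) - 0.5) / n
    pts <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]),
                 a[3] + tt * (b[3] - a[3]))
    seglen <- if (len > 0) len / n else step
    pos <- rbind(pos, pts)
    amp <- c(amp, rep(w$absorption[i] * pi * w$radius[i]^2 * seglen, n))
  }
  if (is.null(pos)) pos <- matrix(0, 0, 3)
  list(positions = pos, strengths = as.numeric(amp))
}
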