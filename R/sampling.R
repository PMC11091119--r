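#' Regular point grid over an extent
#'
#' Points at `(x0 + i*spacing, y0 + j*spacing)` with the origin inset half a
#' spacing from the extent's lower-left corner, so every point lies strictly
#' inside the extent and cells of a matching raster are sampled near their
#' centres.
#'
#' @param extent Named numeric `c(xmin, ymin, xmax, ymax)` in map metres
#'   (as from [grid_extent()]).
#' @param spacing Grid spacing in metres (default 200, the conventional
#'   sampling density for stand-level belt analysis).
#' @return Data.frame with `point_id`, `x`, `y`.
#' @export
make_grid <- function(extent, spacing = 200) {
  if (spacing <= 0) stop("`spacing` must be > 0", call. = FALSE)
  w <- extent[["xmax"]] - extent[["xmin"]]
  h <- extent[["ymax"]] - extent[["ymin"]]
  if (w <= 0 || h <= 0) stop("degenerate extent", call. = FALSE)
  if (spacing > w && spacing > h) {
    warning("spacing exceeds both extent dimensions; single-point grid")
  }
  axis_points <- function(lo, hi) {
    start <- lo + spacing / 2
    if (start >= hi) return(numeric(0))
    pts <- seq(start, hi, by = spacing)
    pts[pts < hi]
  }
  xs <- axis_points(extent[["xmin"]], extent[["xmax"]])
  ys <- axis_points(extent[["ymin"]], extent[["ymax"]])
  if (!length(xs)) xs <- extent[["xmin"]] + w / 2
  if (!length(ys)) ys <- extent[["ymin"]] + h / 2
  pts <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  data.frame(point_id = seq_len(nrow(pts)), x = pts$x, y = pts$y)
}

#' Extract raster values at points
#'
#' Containing-cell lookup: each point takes the value of the cell it falls
#' in. Points outside the raster footprint or on nodata cells are dropped
#' with a message reporting the count.
#'
#' @param points Data.frame with `x`, `y` columns.
#' @param grid An [elevation_grid()] (or any grid-shaped raster, e.g. the
#'   aspect grid).
#' @param column Name for the extracted column (default `"elevation"`).
#' @return `points` with the extracted column added, dropped rows removed.
#' @export
extract_values <- function(points, grid, column = "elevation") {
  stopifnot(inherits(grid, "elevation_grid"))
  idx <- cell_index(grid, points$x, points$y)
  val <- rep(NA_real_, nrow(points))
  inside <- !is.na(idx$row)
  val[inside] <- grid$z[cbind(idx$row[inside], idx$col[inside])]
  drop <- is.na(val)
  if (any(drop)) {
    message(sprintf("dropping %d point(s) outside footprint or on nodata",
                    sum(drop)))
  }
  points <- points[!drop, , drop = FALSE]
  points[[column]] <- val[!drop]
  rownames(points) <- NULL
  points
}

#' @rdname extract_values
#' @param dem An [elevation_grid()].
#' @export
extract_elevation <- function(points, dem) {
  extract_values(points, dem, column = "elevation")
}

#' Aspect grid from a DEM (Horn's method)
#'
#' Slope direction in degrees clockwise from north, computed with Horn's
#' 8-neighbour finite differences. Border cells use one-sided differences
#' (edge replication). Cells whose gradient magnitude falls below `flat_tol`
#' are flat and carry `NA` aspect.
#'
#' @param dem An [elevation_grid()], at least 3 x 3.
#' @param flat_tol Gradient-magnitude tolerance (elevation units per metre)
#'   below which a cell counts as flat (default 1e-8).
#' @return An `elevation_grid` whose `z` holds aspect degrees in \[0, 360)
#'   with `NA` for flat (or nodata) cells.
#' @export
compute_aspect <- function(dem, flat_tol = 1e-8) {
  stopifnot(inherits(dem, "elevation_grid"))
  z <- dem$z
  if (all(is.na(z))) stop("all-nodata DEM", call. = FALSE)
  if (nrow(z) < 3L || ncol(z) < 3L) stop("DEM must be at least 3 x 3",
                                         call. = FALSE)
  nr <- nrow(z); nc <- ncol(z)
  pad <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  # 3x3 window: a b c / d e f / g h i, rows north to south, cols west to east
  sh <- function(dr, dc) pad[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  a <- sh(0, 0); b <- sh(0, 1); c_ <- sh(0, 2)
  d <- sh(1, 0);                f  <- sh(1, 2)
  g <- sh(2, 0); h <- sh(2, 1); i  <- sh(2, 2)
  cs <- dem$cell_size
  dzdx <- ((c_ + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)   # + east
  dzdy <- ((a + 2 * b + c_) - (g + 2 * h + i)) / (8 * cs)   # + north
  mag <- sqrt(dzdx^2 + dzdy^2)
  # downhill direction is -grad; compass angle clockwise from north
  asp <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  asp[mag < flat_tol] <- NA_real_
  asp[is.na(z)] <- NA_real_
  elevation_grid(asp, cell_size = cs, xll = dem$xll, yll = dem$yll,
                 nodata = dem$nodata)
}

#' Classify aspect into sunny and shady slopes
#'
#' Sunny slopes face the south half-plane: aspect in \[112.5, 292.5)
#' degrees. Everything else — north-facing aspects and flat cells — is
#' shady.
#'
#' @param aspect_deg Aspect in degrees clockwise from north; `NA` = flat.
#' @return Character vector in `{"sunny", "shady"}`.
#' @export
classify_aspect <- function(aspect_deg) {
  ifelse(!is.na(aspect_deg) & aspect_deg >= 112.5 & aspect_deg < 292.5,
         "sunny", "shady")
}

#' Default elevation-class edges for terrain units
#'
#' Interior class edges in metres; classes are left-closed right-open with
#' open-ended extremes (`< first` and `>= last`).
#' @return Numeric vector `c(550, 900, 1100, 1350)`.
#' @export
default_elev_classes <- function() c(550, 900, 1100, 1350)

elev_class_labels <- function(edges) {
  c(paste0("<", edges[1]),
    if (length(edges) > 1)
      paste0(edges[-length(edges)], "-", edges[-1]),
    paste0(">=", edges[length(edges)]))
}

#' Assign terrain units and zones to sample points
#'
#' Each point gets an elevation class (left-closed right-open intervals over
#' the given interior edges), a terrain `unit_id` combining elevation class
#' and aspect class, and — for forest points whose type has an entry in the
#' zone scheme — a zone label (core / upper / lower) from its elevation.
#'
#' @param points Data.frame with `elevation`, `aspect_class`, `forest_type`.
#' @param elev_classes Interior class edges (m), see
#'   [default_elev_classes()].
#' @param scheme Optional `zone_scheme`; when given, a `zone` column is
#'   added (NA for nonforest or types absent from the scheme).
#' @return The points data.frame with `elev_class`, `unit_id` and (when a
#'   scheme is given) `zone` columns added.
#' @export
assign_units <- function(points, elev_classes = default_elev_classes(),
                         scheme = NULL) {
  stopifnot(all(c("elevation", "aspect_class", "forest_type") %in%
                  names(points)))
  labels <- elev_class_labels(elev_classes)
  idx <- findInterval(points$elevation, elev_classes) + 1L  # [edge, next)
  points$elev_class <- labels[idx]
  points$unit_id <- paste(points$elev_class, points$aspect_class, sep = "|")
  if (!is.null(scheme)) {
    stopifnot(inherits(scheme, "zone_scheme"))
    points$zone <- NA_character_
    for (tp in names(scheme)) {
      sel <- points$forest_type == tp
      points$zone[sel] <- zone_of(points$elevation[sel], scheme[[tp]])
    }
  }
  points
}

#' Build the full sample-point table for a landscape
#'
#' Grid construction, elevation and aspect extraction, stand-type lookup,
#' and unit/zone assignment in one call. Nonforest points are retained but
#' flagged; cloud-model fitting excludes them downstream.
#'
#' @param dem An [elevation_grid()].
#' @param stands A classified `stand_map`.
#' @param scheme A `zone_scheme` (optional).
#' @param spacing Grid spacing in metres.
#' @param elev_classes Interior elevation-class edges (m).
#' @param flat_tol Flat-aspect tolerance for [compute_aspect()].
#' @return A `SamplePointTable` data.frame: `point_id`, `x`, `y`,
#'   `elevation`, `aspect_deg`, `aspect_class`, `forest_type`, `elev_class`,
#'   `unit_id`, and `zone` when a scheme is given.
#' @export
sample_points <- function(dem, stands, scheme = NULL, spacing = 200,
                          elev_classes = default_elev_classes(),
                          flat_tol = 1e-8) {
  stopifnot(inherits(dem, "elevation_grid"), inherits(stands, "stand_map"))
  if (is.null(stands$forest_type)) {
    stop("stand map has no `forest_type`; run classify_stand_map() first",
         call. = FALSE)
  }
  check_same_dims(stands, dem)
  pts <- make_grid(grid_extent(dem), spacing = spacing)
  pts <- extract_elevation(pts, dem)
  aspect <- compute_aspect(dem, flat_tol = flat_tol)
  idx <- cell_index(dem, pts$x, pts$y)
  pts$aspect_deg <- aspect$z[cbind(idx$row, idx$col)]
  pts$aspect_class <- classify_aspect(pts$aspect_deg)
  cell <- (idx$col - 1L) * stands$n_rows + idx$row
  pts$forest_type <- stands$forest_type[cell]
  assign_units(pts, elev_classes = elev_classes, scheme = scheme)
}
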