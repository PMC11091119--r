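#' Synthetic mountain configuration
#'
#' Parameters for the synthetic single-peak landscape: a cone-shaped DEM
#' with smoothed Gaussian terrain noise, plus three stacked forest belts
#' (deciduous broadleaf low, temperate conifer middle, mixed
#' conifer-broadleaf high) whose occupancy probability over elevation is a
#' plateau of width `2 * core_halfwidth` around `center_elev` with
#' exponential tails of scale `lower_decay` below and `upper_decay` above.
#' On sunny cells each belt centre shifts by `aspect_shift`. A constant
#' background weight makes the remainder nonforest: `nonforest_frac` is the
#' nonforest share where exactly one belt is at full strength, and the
#' mountain base (all belt weights decayed) tends to pure nonforest.
#'
#' Defaults describe a temperate single-peak mountain: summit 1445 m over a
#' 150 m base on a 5 km x 5 km, 25 m-cell grid, belts centred at 650, 1000
#' and 1350 m. The lower decay (70 m) is wider than the upper decay (40 m),
#' echoing the classical internal-belt structure in which the lower
#' extension zone is the wider transition; both are short enough that the
#' mean-proportion threshold rule recovers each plateau within one 50 m bin
#' on noise-free data (the generator's documented recovery property).
#'
#' @param n_rows,n_cols Grid dimensions (cells).
#' @param cell_size Cell edge (m).
#' @param base_elev,peak_elev Elevation (m) of the cone base and summit.
#' @param roughness Standard deviation (m) of the smoothed terrain noise;
#'   generated elevations stay within 3 roughness of the noise-free cone.
#' @param belts Named list (`deciduous_broadleaf`, `temperate_conifer`,
#'   `mixed`) of lists with `center_elev`, `core_halfwidth`, `lower_decay`,
#'   `upper_decay`, `aspect_shift` (all metres). Centres must increase
#'   bottom-to-top. The topmost belt's `upper_decay` is inert: no higher
#'   belt exists, so its occupancy saturates upward.
#' @param patch_scale Stand-patch size in cells; labels are drawn on a
#'   coarse grid of this block size and upsampled, mimicking polygonal
#'   inventory stands. 1 = independent cells.
#' @param nonforest_frac Nonforest share in \[0, 1\] at full belt strength;
#'   1 makes every cell nonforest.
#' @param seed Integer seed; the whole landscape is reproducible from it.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_rows = 200L, n_cols = 200L, cell_size = 25,
                             base_elev = 150, peak_elev = 1445,
                             roughness = 15,
                             belts = default_belts(),
                             patch_scale = 2L, nonforest_frac = 0.35,
                             seed = 42L) {
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              cell_size = cell_size, base_elev = base_elev,
              peak_elev = peak_elev, roughness = roughness, belts = belts,
              patch_scale = as.integer(patch_scale),
              nonforest_frac = nonforest_frac, seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_belts <- function() {
  list(
    deciduous_broadleaf = list(center_elev = 650, core_halfwidth = 150,
                               lower_decay = 70, upper_decay = 40,
                               aspect_shift = 30),
    temperate_conifer = list(center_elev = 1000, core_halfwidth = 120,
                             lower_decay = 70, upper_decay = 40,
                             aspect_shift = -30),
    mixed = list(center_elev = 1350, core_halfwidth = 80,
                 lower_decay = 70, upper_decay = 40,
                 aspect_shift = 0)
  )
}

validate_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid synthetic_config: field `%s` %s", field, why),
         call. = FALSE)
  }
  if (cfg$n_rows < 1L) bad("n_rows", "must be a positive integer")
  if (cfg$n_cols < 1L) bad("n_cols", "must be a positive integer")
  if (cfg$cell_size <= 0) bad("cell_size", "must be > 0")
  if (cfg$base_elev >= cfg$peak_elev) bad("base_elev", "must be < peak_elev")
  if (cfg$roughness < 0) bad("roughness", "must be >= 0")
  if (cfg$patch_scale < 1L) bad("patch_scale", "must be >= 1")
  if (cfg$nonforest_frac < 0 || cfg$nonforest_frac > 1) {
    bad("nonforest_frac", "must lie in [0, 1]")
  }
  types <- setdiff(forest_types(), "nonforest")
  if (!identical(sort(names(cfg$belts)), sort(types))) {
    bad("belts", paste("must name exactly:", paste(types, collapse = ", ")))
  }
  for (tp in types) {
    b <- cfg$belts[[tp]]
    for (fld in c("core_halfwidth", "lower_decay", "upper_decay")) {
      if (is.null(b[[fld]]) || b[[fld]] <= 0) {
        bad(paste0("belts$", tp, "$", fld), "must be > 0")
      }
    }
  }
  centers <- vapply(types, function(tp) cfg$belts[[tp]]$center_elev,
                    numeric(1))
  if (any(diff(centers) <= 0)) {
    bad("belts", "centres must strictly increase bottom-to-top")
  }
  invisible(cfg)
}

# Separable Gaussian smoothing with edge replication; sigma in cells.
gaussian_smooth <- function(mat, sigma = 2) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-rad:rad, sd = sigma)
  k <- k / sum(k)
  smooth_cols <- function(m) {
    nr <- nrow(m)
    padded <- rbind(m[rep(1L, rad), , drop = FALSE], m,
                    m[rep(nr, rad), , drop = FALSE])
    out <- stats::filter(padded, k, sides = 2)
    matrix(out[(rad + 1):(rad + nr), ], nrow = nr)
  }
  t(smooth_cols(t(smooth_cols(mat))))
}

#' Generate a synthetic single-peak DEM
#'
#' A radially symmetric cone (summit `peak_elev` at the grid centre, base
#' `base_elev` at the nearest edge midpoint and beyond) plus
#' Gaussian-smoothed white noise rescaled to standard deviation `roughness`
#' and clamped to 3 roughness, so every cell lies in
#' `[base_elev - 3 roughness, peak_elev + 3 roughness]`. No nodata cells.
#' Deterministic for a fixed seed.
#'
#' @param config A [synthetic_config()].
#' @return An [elevation_grid()].
#' @export
generate_dem <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  nr <- config$n_rows; nc <- config$n_cols; cs <- config$cell_size
  ci <- (nr + 1) / 2; cj <- (nc + 1) / 2
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  r <- cs * sqrt((rows - ci)^2 + (cols - cj)^2)
  rmax <- cs * (min(nr, nc) - 1) / 2
  z <- config$peak_elev -
    (config$peak_elev - config$base_elev) * pmin(r / rmax, 1)
  if (config$roughness > 0) {
    noise <- with_local_seed(config$seed, {
      gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma = 2)
    })
    noise <- noise / stats::sd(noise) * config$roughness
    noise <- pmin(pmax(noise, -3 * config$roughness), 3 * config$roughness)
    z <- z + noise
  }
  elevation_grid(z, cell_size = cs)
}

# Raw belt weight at elevations z for one belt; the topmost belt keeps its
# plateau upward (no belt above it to hand over to).
belt_weight <- function(z, belt, sunny = FALSE, topmost = FALSE) {
  center <- belt$center_elev + if (sunny) belt$aspect_shift else 0
  lo <- center - belt$core_halfwidth
  hi <- center + belt$core_halfwidth
  w <- rep(1, length(z))
  below <- z < lo
  w[below] <- exp(-(lo - z[below]) / belt$lower_decay)
  if (!topmost) {
    above <- z > hi
    w[above] <- exp(-(z[above] - hi) / belt$upper_decay)
  }
  w
}

# Occupancy probabilities over {3 types, nonforest} at elevations z.
occupancy_probs <- function(z, config, sunny = FALSE) {
  types <- setdiff(forest_types(), "nonforest")
  if (config$nonforest_frac >= 1) {
    p <- matrix(0, length(z), length(types) + 1L,
                dimnames = list(NULL, c(types, "nonforest")))
    p[, "nonforest"] <- 1
    return(p)
  }
  w_nf <- config$nonforest_frac / (1 - config$nonforest_frac)
  top <- types[length(types)]
  w <- vapply(types, function(tp) {
    belt_weight(z, config$belts[[tp]], sunny = sunny, topmost = tp == top)
  }, numeric(length(z)))
  w <- matrix(w, nrow = length(z),
              dimnames = list(NULL, types))
  denom <- rowSums(w) + w_nf
  p <- cbind(w / denom, nonforest = w_nf / denom)
  p
}

#' Ground truth of the synthetic landscape
#'
#' The exact occupancy curves and core intervals behind
#' [generate_stand_map()], for validating the delineation pipeline.
#'
#' @param config A [synthetic_config()].
#' @return List of class `truth_record` with `curve(z, aspect_class)`
#'   returning the occupancy-probability matrix (columns: the three types
#'   plus nonforest), `cores` (named list of `c(lo_m, hi_m)` per type, the
#'   shady-slope plateau `center +/- core_halfwidth`), and `seed`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  types <- setdiff(forest_types(), "nonforest")
  cores <- lapply(config$belts[types], function(b) {
    c(b$center_elev - b$core_halfwidth, b$center_elev + b$core_halfwidth)
  })
  structure(
    list(
      curve = function(z, aspect_class = "shady") {
        occupancy_probs(z, config, sunny = identical(aspect_class, "sunny"))
      },
      cores = cores,
      seed = config$seed
    ),
    class = "truth_record"
  )
}

# Vectorised composition-string construction per drawn type label.
draw_compositions <- function(type, mode = c("stochastic", "modal")) {
  mode <- match.arg(mode)
  n <- length(type)
  comp <- character(n)
  dom <- rep(NA_character_, n)
  broad_codes <- c("QUE", "ROB"); conif_codes <- c("PIN", "PLA", "LAR")
  mk <- function(t1, c1, t2, c2) {
    ifelse(t2 == 0L, paste0(t1, c1), paste0(t1, c1, t2, c2))
  }
  for (side in c("deciduous_broadleaf", "temperate_conifer")) {
    sel <- which(type == side)
    if (!length(sel)) next
    pure_is_broad <- side == "deciduous_broadleaf"
    major_codes <- if (pure_is_broad) broad_codes else conif_codes
    minor_codes <- if (pure_is_broad) conif_codes else broad_codes
    major_p <- if (pure_is_broad) c(0.6, 0.4) else c(0.5, 0.3, 0.2)
    if (mode == "stochastic") {
      t1 <- sample(7:10, length(sel), replace = TRUE)
      c1 <- sample(major_codes, length(sel), replace = TRUE, prob = major_p)
      c2 <- sample(minor_codes, length(sel), replace = TRUE)
    } else {
      t1 <- rep(8L, length(sel))
      c1 <- rep(major_codes[1], length(sel))
      c2 <- rep(minor_codes[1], length(sel))
    }
    comp[sel] <- mk(t1, c1, 10L - t1, c2)
    dom[sel] <- c1
  }
  sel <- which(type == "mixed")
  if (length(sel)) {
    if (mode == "stochastic") {
      b <- sample(4:6, length(sel), replace = TRUE)
      bc <- sample(broad_codes, length(sel), replace = TRUE)
      cc <- sample(conif_codes, length(sel), replace = TRUE)
    } else {
      b <- rep(5L, length(sel))
      bc <- rep(broad_codes[1], length(sel))
      cc <- rep(conif_codes[1], length(sel))
    }
    comp[sel] <- paste0(b, bc, 10L - b, cc)
    dom[sel] <- ifelse(b >= 10L - b, bc, cc)
  }
  list(composition = comp, dominant = dom)
}

#' Generate a stand map over a synthetic DEM
#'
#' Draws a forest-type label for every cell from the belt occupancy
#' probabilities at the cell's elevation and aspect class, then a species
#' composition consistent with the label (the dominant group holds at least
#' 7 tenths for pure types, 4-6 tenths each for mixed stands). Labels are
#' drawn on a coarse grid of `patch_scale` cells and upsampled, mimicking
#' polygonal inventory stands. `mode = "modal"` replaces every draw by its
#' mode (argmax label, fixed composition) for noise-free checks.
#'
#' @param config A [synthetic_config()].
#' @param dem The [elevation_grid()] from [generate_dem()] (same dims).
#' @param mode `"stochastic"` (default) or `"modal"`.
#' @return List of class `stand_map`: `n_rows`, `n_cols`, `cell_size`,
#'   `xll`, `yll`, and per-cell vectors `composition` (`""` = nonforest) and
#'   `dominant` (`NA` = nonforest) in column-major cell order.
#' @export
generate_stand_map <- function(config, dem, mode = c("stochastic", "modal")) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(dem, "elevation_grid"))
  mode <- match.arg(mode)
  nr <- config$n_rows; nc <- config$n_cols
  if (nrow(dem$z) != nr || ncol(dem$z) != nc) {
    stop(sprintf("DEM is %d x %d but config expects %d x %d",
                 nrow(dem$z), ncol(dem$z), nr, nc), call. = FALSE)
  }
  types <- setdiff(forest_types(), "nonforest")
  labels <- c(types, "nonforest")

  aspect <- compute_aspect(dem)
  sunny <- classify_aspect(as.vector(aspect$z)) == "sunny"
  elev <- as.vector(dem$z)

  ps <- config$patch_scale
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  bi <- (rows - 1L) %/% ps + 1L
  bj <- (cols - 1L) %/% ps + 1L
  nbr <- max(bi)
  block <- (bj - 1L) * nbr + bi
  n_blocks <- max(block)

  cnt <- tabulate(block, nbins = n_blocks)
  block_elev <- rowsum(elev, block)[, 1] / cnt
  block_sunny <- rowsum(as.numeric(sunny), block)[, 1] / cnt > 0.5

  p <- matrix(0, n_blocks, length(labels))
  p[block_sunny, ] <- occupancy_probs(block_elev[block_sunny], config,
                                      sunny = TRUE)
  p[!block_sunny, ] <- occupancy_probs(block_elev[!block_sunny], config,
                                       sunny = FALSE)

  drawn <- with_local_seed(config$seed + 1L, {
    block_label <- if (mode == "modal") {
      labels[max.col(p, ties.method = "first")]
    } else {
      u <- stats::runif(n_blocks)
      cum <- t(apply(p, 1L, cumsum))
      labels[1L + rowSums(u > cum)]
    }
    cell_label <- block_label[block]
    draw_compositions(cell_label, mode = mode)
  })

  structure(
    list(n_rows = nr, n_cols = nc, cell_size = config$cell_size,
         xll = dem$xll, yll = dem$yll,
         composition = drawn$composition, dominant = drawn$dominant),
    class = "stand_map"
  )
}

#' @export
print.stand_map <- function(x, ...) {
  n <- length(x$composition)
  cat(sprintf("<stand_map> %d x %d cells (%d), %.1f%% nonforest%s\n",
              x$n_rows, x$n_cols, n,
              100 * mean(!nzchar(x$composition)),
              if (is.null(x$forest_type)) "" else ", classified"))
  invisible(x)
}

#' Read and write stand maps as CSV
#'
#' One row per cell (`row`, `col`, `dominant`, `composition`, and
#' `forest_type` when classified), with grid geometry in `#`-prefixed
#' header comments, so the file round-trips without a sidecar.
#'
#' @param stands A `stand_map`.
#' @param path File path.
#' @return `write_stand_map` returns `path` invisibly; `read_stand_map`
#'   returns a `stand_map`.
#' @export
write_stand_map <- function(stands, path) {
  stopifnot(inherits(stands, "stand_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_rows=%d n_cols=%d cell_size=%.10g xll=%.10g yll=%.10g",
                     stands$n_rows, stands$n_cols, stands$cell_size,
                     stands$xll, stands$yll), con)
  df <- data.frame(row = rep(seq_len(stands$n_rows), times = stands$n_cols),
                   col = rep(seq_len(stands$n_cols), each = stands$n_rows),
                   dominant = ifelse(is.na(stands$dominant), "",
                                     stands$dominant),
                   composition = stands$composition)
  if (!is.null(stands$forest_type)) df$forest_type <- stands$forest_type
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stand_map
#' @export
read_stand_map <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[-0-9.e]+", hdr))[[1]]
  meta <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(dominant = "character",
                                       composition = "character"))
  ord <- order(df$col, df$row)
  df <- df[ord, ]
  out <- list(n_rows = as.integer(meta[["n_rows"]]),
              n_cols = as.integer(meta[["n_cols"]]),
              cell_size = meta[["cell_size"]],
              xll = meta[["xll"]], yll = meta[["yll"]],
              composition = df$composition,
              dominant = ifelse(nzchar(df$dominant), df$dominant,
                                NA_character_))
  if ("forest_type" %in% names(df)) out$forest_type <- df$forest_type
  structure(out, class = "stand_map")
}

#' Write the synthetic ground truth as YAML
#'
#' Serialises the belt parameters and core intervals (curves are
#' reconstructed from the config).
#' @param truth A `truth_record`.
#' @param config The [synthetic_config()] that produced it.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, config, path) {
  yaml::write_yaml(
    list(seed = truth$seed,
         nonforest_frac = config$nonforest_frac,
         belts = config$belts,
         cores_m = lapply(truth$cores, as.list)),
    path)
  invisible(path)
}
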