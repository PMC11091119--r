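#' Cloud parameters per (forest type x zone)
#'
#' Fits [backward_cloud()] to the elevations of every (forest type, zone)
#' stratum of a sample-point table — the per-belt summary of core and
#' extension zones. Nonforest points are excluded; undersized strata are
#' reported in `skipped`.
#'
#' @param points A sample-point table with `forest_type`, `zone`,
#'   `elevation` columns (see [sample_points()]).
#' @param min_points Minimum stratum size (default 3).
#' @return List with `parameters` and `skipped` data.frames (see
#'   [fit_strata()]).
#' @export
zone_cloud_table <- function(points, min_points = 3L) {
  pts <- points[points$forest_type != "nonforest" & !is.na(points$zone), ,
                drop = FALSE]
  fit_strata(pts, c("forest_type", "zone"), min_points = min_points)
}

#' Cloud parameters per terrain analysis unit
#'
#' Fits one cloud model per (elevation class, aspect class, forest type)
#' stratum — the terrain-stratified summary used to compare belt centres
#' across aspects.
#'
#' @inheritParams zone_cloud_table
#' @return List with `parameters` and `skipped` data.frames.
#' @export
unit_cloud_table <- function(points, min_points = 3L) {
  pts <- points[points$forest_type != "nonforest", , drop = FALSE]
  fit_strata(pts, c("elev_class", "aspect_class", "forest_type"),
             min_points = min_points)
}

#' Between-type expectation differences per terrain unit
#'
#' For every terrain unit (elevation class x aspect class) where both types
#' of the pair carry a fitted cloud model, the absolute difference of their
#' expectations |Ex_a - Ex_b|, rounded to 0.01 m, plus the min-max summary
#' per elevation class and pooled over all units. Belt centres that barely
#' differ between two types in a unit indicate the types interdigitate
#' there — the signature of one type encroaching on the other's habitat.
#'
#' @param unit_table Data.frame with `elev_class`, `aspect_class`,
#'   `forest_type`, `ex_m` columns (the `parameters` element of
#'   [unit_cloud_table()], or any table in that shape).
#' @param pair Character vector of two distinct forest types.
#' @return List of class `ex_diff_table`: `differences` (per-unit rows),
#'   `by_class` (per elevation class min/max), `pooled` (`c(min, max)`).
#' @export
ex_differences <- function(unit_table, pair) {
  if (length(pair) != 2L || pair[1] == pair[2]) {
    stop("`pair` must name two distinct forest types", call. = FALSE)
  }
  stopifnot(all(c("elev_class", "aspect_class", "forest_type", "ex_m") %in%
                  names(unit_table)))
  a <- unit_table[unit_table$forest_type == pair[1], ]
  b <- unit_table[unit_table$forest_type == pair[2], ]
  m <- merge(a[, c("elev_class", "aspect_class", "ex_m")],
             b[, c("elev_class", "aspect_class", "ex_m")],
             by = c("elev_class", "aspect_class"), suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) {
    return(structure(list(
      differences = data.frame(elev_class = character(0),
                               aspect_class = character(0),
                               abs_ex_diff_m = numeric(0)),
      by_class = data.frame(elev_class = character(0), min_m = numeric(0),
                            max_m = numeric(0)),
      pooled = c(min = NA_real_, max = NA_real_),
      pair = pair), class = "ex_diff_table"))
  }
  m$abs_ex_diff_m <- round(abs(m$ex_m_a - m$ex_m_b), 2)
  m <- m[order(m$elev_class, m$aspect_class), ]
  by_class <- do.call(rbind, lapply(split(m, m$elev_class), function(g) {
    data.frame(elev_class = g$elev_class[1],
               min_m = min(g$abs_ex_diff_m), max_m = max(g$abs_ex_diff_m))
  }))
  rownames(by_class) <- NULL
  structure(
    list(differences = m[, c("elev_class", "aspect_class", "abs_ex_diff_m")],
         by_class = by_class,
         pooled = c(min = min(m$abs_ex_diff_m), max = max(m$abs_ex_diff_m)),
         pair = pair),
    class = "ex_diff_table"
  )
}

#' @export
print.ex_diff_table <- function(x, ...) {
  cat(sprintf("<ex_diff_table> |Ex(%s) - Ex(%s)| over %d unit(s)\n",
              x$pair[1], x$pair[2], nrow(x$differences)))
  print(x$differences, row.names = FALSE)
  cat(sprintf("pooled range: %.2f - %.2f m\n", x$pooled["min"],
              x$pooled["max"]))
  invisible(x)
}

#' Published reference cloud parameters for Mount Taishan analysis units
#'
#' The per-unit (elevation class x aspect class x forest type) Ex/En/He
#' values published for Mount Taishan's vertical belts, shipped as a
#' plain-text table. Useful as worked-example input for [ex_differences()]
#' and as a shape reference for [unit_cloud_table()] output.
#'
#' @return Data.frame with `elev_class`, `forest_type`, `aspect_class`,
#'   `ex_m`, `en_m`, `he_m`.
#' @export
taishan_unit_clouds <- function() {
  path <- system.file("extdata", "taishan_unit_clouds.csv",
                      package = "vertibelt", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Plot a cloud of droplets
#'
#' Scatter of droplet elevation against membership degree — the standard
#' rendering of a cloud model, with the y axis fixed to \[0, 1\].
#'
#' @param droplets Data.frame from [forward_cloud()]; must be non-empty.
#' @param out_path Output figure path; the device is chosen from the
#'   extension (`.png`, `.pdf` or `.svg`).
#' @param main Plot title.
#' @return `out_path`, invisibly.
#' @export
plot_cloud <- function(droplets, out_path, main = "Elevation cloud model") {
  if (!is.data.frame(droplets) || nrow(droplets) == 0L) {
    stop("`droplets` must be a non-empty data.frame", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(out_path))
  switch(ext,
         png = grDevices::png(out_path, width = 800, height = 500),
         pdf = grDevices::pdf(out_path, width = 8, height = 5),
         svg = grDevices::svg(out_path, width = 8, height = 5),
         stop(sprintf("unsupported figure extension %s", dQuote(ext)),
              call. = FALSE))
  on.exit(grDevices::dev.off())
  graphics::plot(droplets$x, droplets$membership, pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("steelblue", 0.5),
                 xlab = "Elevation (m)", ylab = "Membership degree",
                 ylim = c(0, 1), main = main)
  invisible(out_path)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

#' Run the full vertical-belt analysis pipeline
#'
#' Executes simulate (or load) -> classify -> profile -> zonate -> sample ->
#' cloud -> report, writing every table, the zone scheme, a figure and a run
#' manifest into `out_dir`. Identical config and seed give identical
#' numeric outputs.
#'
#' The config is a named list (or YAML file) with optional sections:
#' \describe{
#'   \item{simulate}{Arguments for [synthetic_config()]; mutually exclusive
#'     with `inputs`.}
#'   \item{inputs}{`dem` (ASCII grid path) and `stand_map` (CSV path).}
#'   \item{binning}{`width` (m, default 50).}
#'   \item{zones}{`floor_pct` (default 10) and per-type lists with `range`
#'     and/or `fixed_threshold` under the type name.}
#'   \item{sampling}{`spacing` (m, default 200), `elev_classes` (interior
#'     edges, default 550/900/1100/1350).}
#'   \item{cloud}{`min_points` (default 3), `droplets` (default 2000),
#'     `seed` (default 1).}
#'   \item{report}{`pairs`: list of 2-vectors of types to difference
#'     (default deciduous vs mixed and conifer vs mixed).}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly. Side effects: `profile.csv`,
#'   `zone_scheme.yaml`, `sample_points.csv`, `zone_clouds.csv`,
#'   `unit_clouds.csv`, `skipped_strata.csv`, `ex_differences_*.csv`,
#'   `species_profile.csv`, `cloud_*.png`, `truth.yaml` (simulated runs),
#'   `manifest.yaml`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "inputs"
  result <- tryCatch({
    if (!is.null(cfg$simulate)) {
      stage <- "simulate"
      scfg <- do.call(synthetic_config, cfg$simulate)
      dem <- generate_dem(scfg)
      stands <- generate_stand_map(scfg, dem)
      write_truth(generate_truth(scfg), scfg,
                  file.path(out_dir, "truth.yaml"))
    } else {
      if (is.null(cfg$inputs$dem) || !file.exists(cfg$inputs$dem)) {
        stop(sprintf("DEM input not found: %s",
                     if (is.null(cfg$inputs$dem)) "(unset)"
                     else cfg$inputs$dem), call. = FALSE)
      }
      if (is.null(cfg$inputs$stand_map) ||
          !file.exists(cfg$inputs$stand_map)) {
        stop(sprintf("stand map input not found: %s",
                     if (is.null(cfg$inputs$stand_map)) "(unset)"
                     else cfg$inputs$stand_map), call. = FALSE)
      }
      dem <- read_ascii_grid(cfg$inputs$dem)
      stands <- read_stand_map(cfg$inputs$stand_map)
    }

    stage <- "classify"
    stands <- classify_stand_map(stands)

    stage <- "zonate"
    width <- cfg$binning$width %||% 50
    binning <- elev_binning(dem, width = width)
    profile <- bin_proportions(stands, dem, binning)
    utils::write.csv(profile, file.path(out_dir, "profile.csv"),
                     row.names = FALSE)
    sp <- dominant_species_profile(stands, dem, binning = binning)
    utils::write.csv(sp, file.path(out_dir, "species_profile.csv"),
                     row.names = FALSE)
    zopts <- cfg$zones %||% list()
    floor_pct <- zopts$floor_pct %||% 10
    scheme <- zone_scheme(profile, floor_pct = floor_pct,
                          options = zopts[setdiff(names(zopts), "floor_pct")])
    write_zone_scheme(scheme, file.path(out_dir, "zone_scheme.yaml"))

    stage <- "sample"
    spacing <- cfg$sampling$spacing %||% 200
    classes <- cfg$sampling$elev_classes %||% default_elev_classes()
    pts <- sample_points(dem, stands, scheme, spacing = spacing,
                         elev_classes = unlist(classes))
    utils::write.csv(pts, file.path(out_dir, "sample_points.csv"),
                     row.names = FALSE)

    stage <- "cloud"
    min_points <- cfg$cloud$min_points %||% 3L
    droplets_m <- cfg$cloud$droplets %||% 2000L
    cloud_seed <- cfg$cloud$seed %||% 1L
    zc <- zone_cloud_table(pts, min_points = min_points)
    uc <- unit_cloud_table(pts, min_points = min_points)
    utils::write.csv(zc$parameters, file.path(out_dir, "zone_clouds.csv"),
                     row.names = FALSE)
    utils::write.csv(uc$parameters, file.path(out_dir, "unit_clouds.csv"),
                     row.names = FALSE)
    skipped <- merge(zc$skipped, uc$skipped, all = TRUE, sort = FALSE)
    utils::write.csv(skipped, file.path(out_dir, "skipped_strata.csv"),
                     row.names = FALSE)

    stage <- "report"
    pairs <- cfg$report$pairs %||% list(
      c("deciduous_broadleaf", "mixed"), c("temperate_conifer", "mixed"))
    for (pr in pairs) {
      pr <- unlist(pr)
      ed <- ex_differences(uc$parameters, pr)
      utils::write.csv(ed$differences,
                       file.path(out_dir, sprintf("ex_differences_%s_vs_%s.csv",
                                                  pr[1], pr[2])),
                       row.names = FALSE)
    }
    for (i in seq_len(min(1L, nrow(zc$parameters)))) {
      row <- zc$parameters[i, ]
      dr <- forward_cloud(list(ex = row$ex_m, en = row$en_m, he = row$he_m),
                          m = droplets_m, seed = cloud_seed)
      utils::write.csv(dr, file.path(out_dir, "droplets.csv"),
                       row.names = FALSE)
      plot_cloud(dr, file.path(out_dir,
                               sprintf("cloud_%s_%s.png", row$forest_type,
                                       row$zone)),
                 main = sprintf("%s / %s", row$forest_type, row$zone))
    }

    cfg_file <- file.path(out_dir, "config_used.yaml")
    yaml::write_yaml(cfg, cfg_file)
    manifest <- list(
      package = "vertibelt",
      version = as.character(utils::packageVersion("vertibelt")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      config_md5 = unname(tools::md5sum(cfg_file)),
      cloud_seed = cloud_seed,
      simulate_seed = if (!is.null(cfg$simulate)) cfg$simulate$seed else NULL
    )
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    out_dir
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage `%s`: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
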