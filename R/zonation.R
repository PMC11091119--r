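#' Elevation binning scheme
#'
#' Left-closed, right-open elevation bins `[a, a + width)` tiling the DEM's
#' elevation range. The origin defaults to `floor(min / width) * width`, so
#' 50 m bins sit at multiples of 50 m regardless of the lowest cell.
#'
#' @param dem An [elevation_grid()], or a numeric vector of elevations.
#' @param width Bin width in metres (default 50, the conventional interval
#'   for vertical-belt profiling).
#' @param origin Optional explicit lowest bin edge (m).
#' @return List of class `elev_binning` with `origin`, `width`, `n_bins`.
#' @export
elev_binning <- function(dem, width = 50, origin = NULL) {
  if (width <= 0) stop("`width` must be > 0", call. = FALSE)
  elev <- if (inherits(dem, "elevation_grid")) as.vector(dem$z) else dem
  rng <- range(elev, na.rm = TRUE)
  if (is.null(origin)) origin <- floor(rng[1] / width) * width
  n_bins <- max(1L, as.integer(ceiling((rng[2] - origin) / width + 1e-9)))
  # right-open bins: a max elevation sitting exactly on the last edge needs
  # one more bin
  if (origin + n_bins * width <= rng[2]) n_bins <- n_bins + 1L
  structure(list(origin = origin, width = width, n_bins = n_bins),
            class = "elev_binning")
}

# 1-based bin index of elevations under a binning; NA outside [origin, top).
bin_index <- function(elev, binning) {
  idx <- floor((elev - binning$origin) / binning$width) + 1L
  idx[idx < 1L | idx > binning$n_bins] <- NA_integer_
  as.integer(idx)
}

# Lower edges of all bins.
bin_edges <- function(binning) {
  binning$origin + (seq_len(binning$n_bins) - 1L) * binning$width
}

#' Area-proportion profile of forest types by elevation bin
#'
#' For each elevation bin, the percentage of bin area occupied by each
#' forest type: `(area of type in bin) / (total bin area) * 100`. The
#' remainder to 100% is nonforest. Area is cell count times cell area.
#'
#' @param stands A classified `stand_map` (run [classify_stand_map()] first).
#' @param dem The matching [elevation_grid()].
#' @param binning An [elev_binning()]; computed from the DEM when NULL.
#' @return Data.frame of class `proportion_profile` with one row per
#'   (bin, type): `bin`, `bin_low_m`, `bin_high_m`, `forest_type`,
#'   `area_pct`, `area_m2`, `bin_area_m2`. Empty bins carry 0% and zero
#'   area, flagged in the `empty` column.
#' @export
bin_proportions <- function(stands, dem, binning = NULL) {
  stopifnot(inherits(stands, "stand_map"), inherits(dem, "elevation_grid"))
  if (is.null(stands$forest_type)) {
    stop("stand map has no `forest_type`; run classify_stand_map() first",
         call. = FALSE)
  }
  check_same_dims(stands, dem)
  if (is.null(binning)) binning <- elev_binning(dem)
  elev <- as.vector(dem$z)
  keep <- !is.na(elev)
  bin <- bin_index(elev[keep], binning)
  type <- stands$forest_type[keep]
  cell_area <- dem$cell_size^2
  types <- setdiff(forest_types(), "nonforest")

  total <- tabulate(bin, nbins = binning$n_bins)
  lows <- bin_edges(binning)
  rows <- lapply(types, function(tp) {
    cnt <- tabulate(bin[type == tp], nbins = binning$n_bins)
    data.frame(bin = seq_len(binning$n_bins),
               bin_low_m = lows, bin_high_m = lows + binning$width,
               forest_type = tp,
               area_pct = ifelse(total > 0, 100 * cnt / total, 0),
               area_m2 = cnt * cell_area,
               bin_area_m2 = total * cell_area,
               empty = total == 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$bin, match(out$forest_type, types)), ]
  rownames(out) <- NULL
  attr(out, "binning") <- binning
  class(out) <- c("proportion_profile", "data.frame")
  out
}

profile_binning <- function(profile) {
  b <- attr(profile, "binning")
  if (is.null(b)) stop("profile carries no binning attribute", call. = FALSE)
  b
}

# Per-bin percentage vector for one type, ordered by bin.
type_pcts <- function(profile, type) {
  sub <- profile[profile$forest_type == type, ]
  if (nrow(sub) == 0L) {
    stop(sprintf("forest type %s absent from profile", dQuote(type)),
         call. = FALSE)
  }
  sub[order(sub$bin), ]
}

# Bin range [lo_bin, hi_bin] covered by an elevation interval [lo_m, hi_m],
# which must be aligned to bin edges.
range_to_bins <- function(range_m, binning) {
  lo <- (range_m[1] - binning$origin) / binning$width
  hi <- (range_m[2] - binning$origin) / binning$width
  if (abs(lo - round(lo)) > 1e-9 || abs(hi - round(hi)) > 1e-9) {
    stop("`range` endpoints must lie on bin edges", call. = FALSE)
  }
  lo <- as.integer(round(lo)) + 1L
  hi <- as.integer(round(hi))
  if (hi < lo) stop("`range` covers zero bins", call. = FALSE)
  c(max(1L, lo), min(binning$n_bins, hi))
}

#' Main distribution range of a forest type
#'
#' The elevation interval over which a type "mainly occurs": the longest
#' contiguous run of bins whose area percentage is at least `floor_pct`.
#' Ties between equal-length runs go to the run containing the higher
#' maximum percentage, then to the lower-elevation run. An explicit
#' `override` interval (aligned to bin edges) bypasses the rule — the
#' faithful mode when the range is chosen by inspection of the profile.
#'
#' @param profile A [bin_proportions()] result.
#' @param type One of [forest_types()] (not `"nonforest"`).
#' @param floor_pct Minimum percentage for a bin to count (default 10).
#' @param override Optional `c(lo_m, hi_m)` explicit interval.
#' @return Numeric `c(lo_m, hi_m)` on bin edges.
#' @export
main_range <- function(profile, type, floor_pct = 10, override = NULL) {
  binning <- profile_binning(profile)
  if (!is.null(override)) {
    rb <- range_to_bins(override, binning)     # validates alignment
    lows <- bin_edges(binning)
    return(c(lows[rb[1]], lows[rb[2]] + binning$width))
  }
  sub <- type_pcts(profile, type)
  ok <- sub$area_pct >= floor_pct
  if (!any(ok)) {
    stop(sprintf("no bin reaches floor_pct = %g%% for type %s", floor_pct,
                 dQuote(type)), call. = FALSE)
  }
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  len <- runs$lengths[cand]
  best <- cand[len == max(len)]
  if (length(best) > 1L) {
    peak <- vapply(best, function(r) max(sub$area_pct[starts[r]:ends[r]]),
                   numeric(1))
    best <- best[peak == max(peak)]
    best <- best[1L]                           # still tied: lowest elevation
  }
  c(sub$bin_low_m[starts[best]], sub$bin_high_m[ends[best]])
}

#' Mean-proportion threshold over a main range
#'
#' The unweighted arithmetic mean of a type's per-bin area percentages over
#' the bins of its main range — the value separating core-zone bins from
#' extension-zone bins. A `fixed` value substitutes the mean, for types
#' whose concentrated distribution is too narrow for the mean rule (the
#' conventional fallback is 30%).
#'
#' @param profile A [bin_proportions()] result.
#' @param type Forest type.
#' @param range `c(lo_m, hi_m)` aligned to bin edges.
#' @param fixed Optional fixed threshold percentage overriding the mean.
#' @return Threshold percentage.
#' @export
zone_threshold <- function(profile, type, range, fixed = NULL) {
  if (!is.null(fixed)) return(fixed)
  binning <- profile_binning(profile)
  rb <- range_to_bins(range, binning)
  sub <- type_pcts(profile, type)
  mean(sub$area_pct[rb[1]:rb[2]])
}

#' Delineate core and extension zones for one forest type
#'
#' Within the main range, the core zone is the contiguous run of bins whose
#' percentage strictly exceeds the threshold and which contains the
#' maximum-percentage bin; all elevations below the core's lower edge form
#' the lower extension zone and all above its upper edge the upper extension
#' zone (open-ended; clip to the DEM range at reporting time).
#' Super-threshold bins outside the chosen run are reported in a warning,
#' not merged — a belt is a single interval.
#'
#' @param profile A [bin_proportions()] result.
#' @param type Forest type.
#' @param range Main range `c(lo_m, hi_m)` from [main_range()].
#' @param threshold_pct Threshold from [zone_threshold()].
#' @return List of class `zone_entry`: `forest_type`, `main_range`,
#'   `threshold_pct`, `core` (`c(lo_m, hi_m)`), `lower` (`c(-Inf, lo_m)`),
#'   `upper` (`c(hi_m, Inf)`).
#' @export
delineate_zones <- function(profile, type, range, threshold_pct) {
  binning <- profile_binning(profile)
  rb <- range_to_bins(range, binning)
  sub <- type_pcts(profile, type)
  bins <- rb[1]:rb[2]
  pct <- sub$area_pct[bins]
  over <- pct > threshold_pct                  # strict: "greater than"
  if (!any(over)) {
    stop(sprintf("no bin exceeds threshold %.2f%% for type %s within range",
                 threshold_pct, dQuote(type)), call. = FALSE)
  }
  peak <- which.max(pct)
  if (!over[peak]) peak <- which(over)[which.max(pct[over])]
  lo <- peak
  while (lo > 1L && over[lo - 1L]) lo <- lo - 1L
  hi <- peak
  while (hi < length(over) && over[hi + 1L]) hi <- hi + 1L
  outside <- which(over & (seq_along(over) < lo | seq_along(over) > hi))
  if (length(outside)) {
    warning(sprintf(
      "type %s: %d super-threshold bin(s) outside the core run at %s m",
      type, length(outside),
      paste(sub$bin_low_m[bins[outside]], collapse = ", ")))
  }
  core <- c(sub$bin_low_m[bins[lo]], sub$bin_high_m[bins[hi]])
  structure(
    list(forest_type = type,
         main_range = range,
         threshold_pct = threshold_pct,
         core = core,
         lower = c(-Inf, core[1]),
         upper = c(core[2], Inf)),
    class = "zone_entry"
  )
}

#' @export
print.zone_entry <- function(x, ...) {
  cat(sprintf("<zone_entry> %s: threshold %.2f%%\n", x$forest_type,
              x$threshold_pct))
  cat(sprintf("  core  [%g, %g) m\n  lower (-Inf, %g) m\n  upper [%g, Inf) m\n",
              x$core[1], x$core[2], x$core[1], x$core[2]))
  invisible(x)
}

#' Build a full zone scheme for several forest types
#'
#' Convenience wrapper running [main_range()], [zone_threshold()] and
#' [delineate_zones()] per type. Per-type options are given as a named list,
#' e.g. `list(mixed = list(fixed_threshold = 30))`.
#'
#' @param profile A [bin_proportions()] result.
#' @param types Forest types to delineate (default: the three forest types).
#' @param floor_pct Floor percentage for [main_range()].
#' @param options Named list of per-type lists with optional members
#'   `range` (explicit main range) and `fixed_threshold`.
#' @return List of class `zone_scheme`, one `zone_entry` per type.
#' @export
zone_scheme <- function(profile, types = setdiff(forest_types(), "nonforest"),
                        floor_pct = 10, options = list()) {
  entries <- lapply(types, function(tp) {
    opt <- options[[tp]]
    rng <- main_range(profile, tp, floor_pct = floor_pct,
                      override = opt$range)
    thr <- zone_threshold(profile, tp, rng, fixed = opt$fixed_threshold)
    delineate_zones(profile, tp, rng, thr)
  })
  names(entries) <- types
  structure(entries, class = "zone_scheme")
}

#' Which zone does an elevation fall in, for a given type?
#'
#' @param elevation Numeric vector of elevations (m).
#' @param entry A `zone_entry`.
#' @return Character vector in `{"core", "upper", "lower"}` — the three
#'   zones partition the elevation axis.
#' @export
zone_of <- function(elevation, entry) {
  stopifnot(inherits(entry, "zone_entry"))
  ifelse(elevation < entry$core[1], "lower",
         ifelse(elevation >= entry$core[2], "upper", "core"))
}

#' Write a zone scheme as YAML
#'
#' @param scheme A `zone_scheme`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_zone_scheme <- function(scheme, path) {
  lst <- lapply(scheme, function(e) {
    list(forest_type = e$forest_type,
         threshold_pct = round(e$threshold_pct, 2),
         main_range_m = as.list(e$main_range),
         core_m = as.list(e$core),
         lower_below_m = e$core[1],
         upper_above_m = e$core[2])
  })
  yaml::write_yaml(lst, path)
  invisible(path)
}
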