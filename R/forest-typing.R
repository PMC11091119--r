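#' Species group table
#'
#' Maps species codes to the broadleaf/conifer grouping used for forest-type
#' classification. The default vocabulary is the synthetic one used by
#' [generate_stand_map()]: two broadleaf codes (QUE oak-like, ROB
#' locust-like) and three conifer codes (PIN, PLA, LAR pine / arborvitae /
#' larch-like).
#'
#' @return Data.frame with columns `code` and `group`
#'   (`"broadleaf"` or `"conifer"`).
#' @export
species_groups <- function() {
  data.frame(
    code = c("QUE", "ROB", "PIN", "PLA", "LAR"),
    group = c("broadleaf", "broadleaf", "conifer", "conifer", "conifer"),
    stringsAsFactors = FALSE
  )
}

#' Forest type labels
#'
#' The exhaustive, mutually exclusive label set used throughout the package.
#' @return Character vector of the four labels.
#' @export
forest_types <- function() {
  c("deciduous_broadleaf", "temperate_conifer", "mixed", "nonforest")
}

#' Parse a species-composition string
#'
#' The composition dialect writes each species' share in tenths immediately
#' before its three-letter code, with no separators: `"7QUE3PIN"` means 7
#' tenths oak-like broadleaf, 3 tenths pine-like conifer. Tenths must sum to
#' exactly 10 (the forestry convention).
#'
#' @param text A single composition string; `""` or `NA` denotes nonforest.
#' @return Data.frame with columns `code` and `tenths`; zero rows for
#'   nonforest.
#' @examples
#' parse_composition("7QUE3PIN")
#' @export
parse_composition <- function(text) {
  if (length(text) != 1L) stop("`text` must be a single string", call. = FALSE)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(code = character(0), tenths = integer(0)))
  }
  mm <- gregexpr("(10|[1-9])([A-Z]{3})", text)[[1]]
  if (mm[1] == -1L) {
    stop(sprintf("malformed composition string %s at position 1", dQuote(text)),
         call. = FALSE)
  }
  # Tokens must tile the whole string; report the first gap position.
  ends <- mm + attr(mm, "match.length") - 1L
  expected_starts <- c(1L, ends[-length(ends)] + 1L)
  gap <- which(mm != expected_starts)
  if (length(gap) || ends[length(ends)] != nchar(text)) {
    pos <- if (length(gap)) expected_starts[gap[1]] else ends[length(ends)] + 1L
    stop(sprintf("malformed composition string %s at position %d",
                 dQuote(text), pos), call. = FALSE)
  }
  tok <- regmatches(text, gregexpr("(10|[1-9])([A-Z]{3})", text))[[1]]
  tenths <- as.integer(sub("([A-Z]{3})$", "", tok))
  code <- sub("^(10|[1-9])", "", tok)
  if (sum(tenths) != 10L) {
    stop(sprintf("composition %s: tenths sum to %d, must sum to 10",
                 dQuote(text), sum(tenths)), call. = FALSE)
  }
  data.frame(code = code, tenths = tenths, stringsAsFactors = FALSE)
}

#' Write a composition data.frame back to its string form
#' @param composition Data.frame with `code` and `tenths` columns.
#' @return A single string; `""` for an empty composition.
#' @export
format_composition <- function(composition) {
  if (nrow(composition) == 0L) return("")
  paste0(composition$tenths, composition$code, collapse = "")
}

#' Classify one stand from its species composition
#'
#' A stand whose broadleaf species jointly hold at least
#' `pure_threshold_tenths` of the ten composition tenths is deciduous
#' broad-leaved forest; likewise conifer tenths give temperate coniferous
#' forest; anything between is mixed coniferous-broadleaved forest. An empty
#' composition is nonforest.
#'
#' @param composition Data.frame `(code, tenths)` as from
#'   [parse_composition()], or a composition string.
#' @param groups Species group table, see [species_groups()].
#' @param pure_threshold_tenths Minimum tenths for a pure type; the standard
#'   inventory rule uses 7, read inclusively (7 tenths of one group already
#'   makes the stand pure).
#' @return One of [forest_types()].
#' @examples
#' classify_stand("7QUE3PIN")   # deciduous_broadleaf
#' classify_stand("5QUE5PIN")   # mixed
#' @export
classify_stand <- function(composition, groups = species_groups(),
                           pure_threshold_tenths = 7L) {
  if (is.character(composition)) composition <- parse_composition(composition)
  if (nrow(composition) == 0L) return("nonforest")
  if (sum(composition$tenths) != 10L) {
    stop(sprintf("composition tenths sum to %d, must sum to 10",
                 sum(composition$tenths)), call. = FALSE)
  }
  grp <- groups$group[match(composition$code, groups$code)]
  if (anyNA(grp)) {
    stop("unknown species code(s): ",
         paste(unique(composition$code[is.na(grp)]), collapse = ", "),
         call. = FALSE)
  }
  broad <- sum(composition$tenths[grp == "broadleaf"])
  conif <- sum(composition$tenths[grp == "conifer"])
  if (broad >= pure_threshold_tenths) "deciduous_broadleaf"
  else if (conif >= pure_threshold_tenths) "temperate_conifer"
  else "mixed"
}

#' Classify every cell of a stand map
#'
#' Adds a `forest_type` vector to a stand map by applying [classify_stand()]
#' to each cell's composition. Classification is memoised over the distinct
#' composition strings, so large rasters with few distinct stand mixtures
#' classify quickly.
#'
#' @param stands A `stand_map` (see [generate_stand_map()]).
#' @inheritParams classify_stand
#' @return The stand map with a `forest_type` character vector added.
#' @export
classify_stand_map <- function(stands, groups = species_groups(),
                               pure_threshold_tenths = 7L) {
  stopifnot(inherits(stands, "stand_map"))
  comp <- stands$composition
  uniq <- unique(comp)
  lab <- vapply(uniq, classify_stand, character(1), groups = groups,
                pure_threshold_tenths = pure_threshold_tenths,
                USE.NAMES = FALSE)
  stands$forest_type <- lab[match(comp, uniq)]
  stands
}

#' Dominant-species area profile by elevation bin
#'
#' For each elevation bin, the percentage of bin area whose stand is
#' dominated by each species — the per-species analogue of the forest-type
#' proportion profile, used to see which species carry each belt.
#'
#' @param stands A `stand_map` with per-cell `dominant` codes.
#' @param dem The matching [elevation_grid()].
#' @param bin_width Bin width in metres (default 50).
#' @param binning Optional [elev_binning()]; computed from the DEM when NULL.
#' @return Data.frame `(bin_low_m, bin_high_m, species, area_pct)`;
#'   percentages are relative to total (forest + nonforest) bin area, so the
#'   per-bin sum over species is at most 100.
#' @export
dominant_species_profile <- function(stands, dem, bin_width = 50,
                                     binning = NULL) {
  stopifnot(inherits(stands, "stand_map"), inherits(dem, "elevation_grid"))
  if (bin_width <= 0) stop("`bin_width` must be > 0", call. = FALSE)
  check_same_dims(stands, dem)
  if (is.null(binning)) binning <- elev_binning(dem, width = bin_width)
  elev <- as.vector(dem$z)
  keep <- !is.na(elev)
  bin <- bin_index(elev[keep], binning)
  dom <- stands$dominant[keep]
  total <- tabulate(bin, nbins = binning$n_bins)
  if (!any(total > 0)) {
    warning("no overlap between stand map and elevation bins")
  }
  species <- sort(unique(dom[!is.na(dom)]))
  if (length(species) == 0L) {
    return(data.frame(bin_low_m = numeric(0), bin_high_m = numeric(0),
                      species = character(0), area_pct = numeric(0)))
  }
  lows <- binning$origin + (seq_len(binning$n_bins) - 1L) * binning$width
  out <- expand.grid(bin = seq_len(binning$n_bins), species = species,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  counts <- table(factor(bin[!is.na(dom)], levels = seq_len(binning$n_bins)),
                  factor(dom[!is.na(dom)], levels = species))
  out$area_pct <- ifelse(total[out$bin] > 0,
                         100 * counts[cbind(out$bin, match(out$species, species))] /
                           total[out$bin],
                         0)
  data.frame(bin_low_m = lows[out$bin], bin_high_m = lows[out$bin] + binning$width,
             species = out$species, area_pct = out$area_pct)
}

check_same_dims <- function(stands, dem) {
  if (stands$n_rows != nrow(dem$z) || stands$n_cols != ncol(dem$z)) {
    stop(sprintf("stand map is %d x %d but DEM is %d x %d",
                 stands$n_rows, stands$n_cols, nrow(dem$z), ncol(dem$z)),
         call. = FALSE)
  }
  invisible(TRUE)
}
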