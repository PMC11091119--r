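# Shared fixture builders; everything is generated in code.

# Noise-free study configuration: deterministic cone, independent cells,
# no aspect shift, so profiles reflect the belt curves alone.
noise_off_config <- function(n = 301L, seed = 1L) {
  belts <- default_belts()
  for (tp in names(belts)) belts[[tp]]$aspect_shift <- 0
  synthetic_config(n_rows = n, n_cols = n, roughness = 0, patch_scale = 1,
                   belts = belts, seed = seed)
}

# Hand-built stand map over an nr x nc grid (column-major cell order).
make_stand_map <- function(composition, nr, nc, cell_size = 10,
                           dominant = NULL, forest_type = NULL) {
  stopifnot(length(composition) == nr * nc)
  if (is.null(dominant)) {
    dominant <- vapply(composition, function(s) {
      if (!nzchar(s)) NA_character_ else parse_composition(s)$code[1]
    }, character(1), USE.NAMES = FALSE)
  }
  out <- structure(
    list(n_rows = nr, n_cols = nc, cell_size = cell_size, xll = 0, yll = 0,
         composition = composition, dominant = dominant),
    class = "stand_map")
  if (!is.null(forest_type)) out$forest_type <- forest_type
  out
}

# Fabricated proportion profile from per-type percentage vectors
# (named list, equal lengths), bins of `width` starting at `origin`.
make_profile <- function(pcts, origin = 500, width = 50, bin_area = 1e4) {
  n <- length(pcts[[1]])
  lows <- origin + (seq_len(n) - 1L) * width
  rows <- lapply(names(pcts), function(tp) {
    data.frame(bin = seq_len(n), bin_low_m = lows, bin_high_m = lows + width,
               forest_type = tp, area_pct = pcts[[tp]],
               area_m2 = pcts[[tp]] / 100 * bin_area,
               bin_area_m2 = bin_area, empty = FALSE,
               stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, rows)
  attr(prof, "binning") <- structure(
    list(origin = origin, width = width, n_bins = n), class = "elev_binning")
  class(prof) <- c("proportion_profile", "data.frame")
  prof
}

# Independent evaluation of the backward-generator moments, written as
# literal sums so it shares no code with backward_cloud().
oracle_backward <- function(x) {
  n <- length(x)
  xbar <- sum(x) / n
  s2 <- sum((x - xbar)^2) / (n - 1)
  en <- sqrt(pi / 2) * sum(abs(x - xbar)) / n
  rad <- s2 - en^2
  list(ex = xbar, en = en, he = if (rad < 0) 0 else sqrt(rad),
       degenerate = rad < 0)
}
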