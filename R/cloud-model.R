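#' Backward (reverse) cloud generator
#'
#' Estimates the three numerical features of a normal cloud model from a
#' sample of elevations: the expectation Ex (central elevation of the belt),
#' the entropy En (fuzziness of the distribution height), and the
#' hyper-entropy He (second-order dispersion of En).
#'
#' The estimator is moment-based:
#' \deqn{Ex = \bar{x}, \qquad
#'       En = \sqrt{\pi/2}\;\frac{1}{n}\sum_i |x_i - Ex|, \qquad
#'       He = \sqrt{S - En^2},}
#' where \eqn{S} is the sample variance with divisor \eqn{n - 1}. For
#' platykurtic samples the radicand \eqn{S - En^2} can be negative; He is
#' then clamped to zero and `degenerate` is set, so pipelines keep running on
#' odd strata rather than aborting.
#'
#' @param samples Numeric vector of elevations (m), all finite.
#' @param min_points Minimum sample size required to fit a cloud model;
#'   strata below it cannot support the three moments (default 3).
#' @return An object of class `cloud_parameters`: a list with `ex`, `en`,
#'   `he` (metres), `n`, and logical `degenerate`.
#' @examples
#' backward_cloud(c(1, 2, 3))
#' @seealso [forward_cloud()], [membership()], [fit_strata()]
#' @export
backward_cloud <- function(samples, min_points = 3L) {
  if (!is.numeric(samples)) stop("`samples` must be numeric", call. = FALSE)
  if (any(!is.finite(samples))) {
    stop("`samples` contains non-finite values", call. = FALSE)
  }
  n <- length(samples)
  if (n < min_points) {
    stop(sprintf("need at least %d sample points to fit a cloud model, got %d",
                 min_points, n), call. = FALSE)
  }
  ex <- mean(samples)
  s2 <- stats::var(samples)            # divisor n - 1
  en <- sqrt(pi / 2) * mean(abs(samples - ex))
  rad <- s2 - en^2
  degenerate <- rad < 0
  he <- if (degenerate) 0 else sqrt(rad)
  structure(
    list(ex = ex, en = en, he = he, n = n, degenerate = degenerate),
    class = "cloud_parameters"
  )
}

#' @export
print.cloud_parameters <- function(x, ...) {
  cat(sprintf("<cloud_parameters> Ex %.2f m, En %.2f m, He %.2f m (n = %d%s)\n",
              x$ex, x$en, x$he, x$n,
              if (isTRUE(x$degenerate)) ", He clamped" else ""))
  invisible(x)
}

#' Membership degree of an elevation in a cloud
#'
#' The bell-shaped certainty \eqn{C_T(x) = \exp(-(x - Ex)^2 / (2\,En'^2))}
#' that elevation `x` belongs to the concept with centre `ex`, given the
#' entropy realisation `en_prime` drawn for one droplet.
#'
#' @param x Elevation(s) in metres.
#' @param ex Cloud expectation (m).
#' @param en_prime Entropy realisation (m); must be strictly positive.
#' @return Membership value(s) in (0, 1]; exactly 1 iff `x == ex`.
#' @export
membership <- function(x, ex, en_prime) {
  if (!is.numeric(en_prime) || any(en_prime <= 0)) {
    stop("`en_prime` must be strictly positive", call. = FALSE)
  }
  exp(-(x - ex)^2 / (2 * en_prime^2))
}

# Evaluate `expr` under a seeded, isolated RNG stream; the caller's
# .Random.seed is untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Forward cloud generator
#'
#' Produces `m` cloud droplets from parameters (Ex, En, He): for each droplet
#' an entropy realisation En' is drawn from Normal(En, He) (redrawn while
#' non-positive), the elevation x from Normal(Ex, En'), and the membership
#' degree from [membership()]. When `En == 0` (all samples identical) the
#' generator returns `m` copies of (Ex, 1).
#'
#' @param params A `cloud_parameters` object or list with `ex`, `en`, `he`.
#' @param m Number of droplets (non-negative integer).
#' @param seed Integer seed; the droplet sequence is fully reproducible and
#'   the caller's RNG state is left untouched.
#' @return A data.frame with columns `x` (m), `membership` in (0, 1], and
#'   `en_prime` (the entropy realisation behind each droplet).
#' @examples
#' d <- forward_cloud(list(ex = 1000, en = 100, he = 20), m = 5, seed = 1)
#' d$membership
#' @export
forward_cloud <- function(params, m, seed = 1L) {
  if (!is.numeric(m) || length(m) != 1L || m < 0 || m != round(m)) {
    stop("`m` must be a single non-negative integer", call. = FALSE)
  }
  m <- as.integer(m)
  ex <- params$ex; en <- params$en; he <- params$he
  stopifnot(is.numeric(ex), is.numeric(en), is.numeric(he), en >= 0, he >= 0)
  if (m == 0L) {
    return(data.frame(x = numeric(0), membership = numeric(0),
                      en_prime = numeric(0)))
  }
  if (en == 0) {
    return(data.frame(x = rep(ex, m), membership = rep(1, m),
                      en_prime = rep(0, m)))
  }
  with_local_seed(seed, {
    en_prime <- stats::rnorm(m, mean = en, sd = he)
    # He > 0 can yield non-positive entropy realisations; rejection-resample.
    while (any(bad <- en_prime <= 0)) {
      en_prime[bad] <- stats::rnorm(sum(bad), mean = en, sd = he)
    }
    x <- stats::rnorm(m, mean = ex, sd = en_prime)
    data.frame(x = x, membership = membership(x, ex, en_prime),
               en_prime = en_prime)
  })
}

#' Fit cloud models per stratum
#'
#' Groups a sample-point table by the given keys and runs [backward_cloud()]
#' on the elevations of each stratum. Strata with fewer than `min_points`
#' points cannot support a cloud model; they are skipped and reported, never
#' silently dropped.
#'
#' @param points Data.frame with an `elevation` column (m) and the grouping
#'   columns.
#' @param group_keys Character vector of column names to stratify by, e.g.
#'   `c("forest_type", "zone")` or `c("elev_class", "aspect_class",
#'   "forest_type")`.
#' @param min_points Minimum stratum size (default 3).
#' @return List with `parameters` (one row per fitted stratum: keys, `n`,
#'   `ex_m`, `en_m`, `he_m`, `degenerate`) and `skipped` (keys and `n` of
#'   undersized strata). Rows are ordered by the grouping keys, so the output
#'   is invariant to input row order.
#' @export
fit_strata <- function(points, group_keys, min_points = 3L) {
  stopifnot(is.data.frame(points), "elevation" %in% names(points))
  missing_keys <- setdiff(group_keys, names(points))
  if (length(missing_keys)) {
    stop("grouping columns absent from `points`: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  key_df <- points[group_keys]
  key_df[] <- lapply(key_df, as.character)
  key <- do.call(paste, c(key_df, sep = "\r"))
  groups <- split(seq_len(nrow(points)), key)
  groups <- groups[order(names(groups))]

  param_rows <- list(); skip_rows <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    keys <- as.list(strsplit(g, "\r", fixed = TRUE)[[1]])
    names(keys) <- group_keys
    if (length(idx) < min_points) {
      skip_rows[[g]] <- data.frame(keys, n = length(idx),
                                   stringsAsFactors = FALSE)
      next
    }
    cp <- backward_cloud(points$elevation[idx], min_points = min_points)
    param_rows[[g]] <- data.frame(keys, n = cp$n, ex_m = cp$ex, en_m = cp$en,
                                  he_m = cp$he, degenerate = cp$degenerate,
                                  stringsAsFactors = FALSE)
  }
  empty_keys <- stats::setNames(
    rep(list(character(0)), length(group_keys)), group_keys)
  parameters <- if (length(param_rows)) {
    do.call(rbind, c(param_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(empty_keys, n = integer(0), ex_m = numeric(0),
               en_m = numeric(0), he_m = numeric(0), degenerate = logical(0))
  }
  skipped <- if (length(skip_rows)) {
    do.call(rbind, c(skip_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(empty_keys, n = integer(0))
  }
  list(parameters = parameters, skipped = skipped)
}
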