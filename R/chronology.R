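# Tree-level aggregation, truncation, detrending, mean chronologies.

#' Average several cores of one tree and compartment
#'
#' Core-level series of a tree (e.g. the two opposing stem cores, or the
#' sampled main roots) are averaged year by year into one representative
#' tree-level series. The year range of the result is the union of the input
#' ranges; years covered by only some cores average over those cores only.
#' Growth direction collapses to `"none"`: directions are averaged over
#' because post-cutting increments do not differ systematically between roots
#' growing toward the cut strip and toward the stand.
#'
#' @param series List of [ring_series] with identical `tree_id` and
#'   `compartment` and overlapping year coverage.
#' @return A tree-level [ring_series] (id `<tree_id>-<compartment>`). A year
#'   is flagged missing only when every contributing core has a missing ring.
#' @export
average_within_tree <- function(series) {
  if (!length(series)) stopf("no series to average")
  tid <- unique(vapply(series, `[[`, character(1), "tree_id"))
  comp <- unique(vapply(series, `[[`, character(1), "compartment"))
  if (length(tid) != 1L)
    stopf("cannot average across trees: %s", paste(tid, collapse = ", "),
          class = "allorings_integrity_error")
  if (length(comp) != 1L)
    stopf("tree '%s': cannot average across compartments", tid,
          class = "allorings_integrity_error")
  yr_all <- sort(unique(unlist(lapply(series, years))))
  if (any(diff(yr_all) != 1L))
    stopf("tree '%s': core year ranges leave gaps", tid,
          class = "allorings_integrity_error")
  acc <- matrix(NA_real_, nrow = length(series), ncol = length(yr_all))
  mis <- matrix(NA, nrow = length(series), ncol = length(yr_all))
  for (i in seq_along(series)) {
    idx <- match(years(series[[i]]), yr_all)
    acc[i, idx] <- series[[i]]$widths
    mis[i, idx] <- series[[i]]$missing
  }
  w <- colMeans(acc, na.rm = TRUE)
  m <- apply(mis, 2, function(z) all(z[!is.na(z)]))
  ring_series(series_id = paste0(tid, "-", comp), widths = w,
              first_year = yr_all[1], tree_id = tid,
              site = series[[1]]$site, compartment = comp,
              direction = "none", missing = m)
}

#' Truncate a series to a common interval
#'
#' @param x A [ring_series].
#' @param interval Two-element vector `(start_year, end_year)`.
#' @return The truncated series, or `NULL` when the series does not overlap
#'   the interval (callers drop and log such series).
#' @export
truncate_common_interval <- function(x, interval) {
  stopifnot(is_ring_series(x), length(interval) == 2)
  keep <- years(x) >= interval[1] & years(x) <= interval[2]
  if (!any(keep)) return(NULL)
  ring_series(x$series_id, x$widths[keep], min(years(x)[keep]),
              x$tree_id, x$site, x$compartment, x$direction,
              missing = x$missing[keep])
}

#' Screen series for sufficient pre-cutting coverage
#'
#' Series whose data do not reach back at least `window_pre` years before the
#' cutting year cannot support the pre-cutting analysis window and are
#' excluded from the dataset.
#'
#' @param series List of [ring_series].
#' @param cutting_year Year of the intervention.
#' @param window_pre Required number of years before the cutting (default 10).
#' @return Logical vector: `TRUE` for series that reach back far enough.
#' @export
reaches_back <- function(series, cutting_year, window_pre = 10L) {
  vapply(series, function(s) s$first_year <= cutting_year - window_pre,
         logical(1))
}

#' Detrend a ring-width series to unitless indices
#'
#' Removes the biological age/size trend by ratio indexing: each width is
#' divided by a fitted trend, yielding indices that fluctuate around 1.
#' Methods:
#' \describe{
#'   \item{`spline`}{cubic smoothing spline with stiffness tied to the series
#'     length (default 67 percent of the length, via an equivalent
#'     degrees-of-freedom heuristic); the dominant convention for
#'     conservative age-trend removal.}
#'   \item{`neg_exponential`}{modified negative exponential
#'     `a * exp(-b * t) + c`; falls back to a non-increasing straight line,
#'     and then to the horizontal mean, when the exponential fit fails, is
#'     non-decreasing, or is not strictly positive.}
#'   \item{`mean`}{horizontal line through the mean.}
#' }
#' Missing rings (width 0) take index 0 and are excluded from the trend fit,
#' preserving the year axis.
#'
#' @param x A [ring_series] with at least 10 non-missing rings for the
#'   curve-fitting methods.
#' @param method Detrending method.
#' @param stiffness Spline stiffness as a fraction of the series length.
#' @return An `index_series` object: fields `tree_id`, `site`, `compartment`,
#'   `first_year`, `indices`, `method`.
#' @export
detrend <- function(x, method = c("spline", "neg_exponential", "mean"),
                    stiffness = 0.67) {
  method <- match.arg(method)
  stopifnot(is_ring_series(x))
  w <- x$widths
  ok <- w > 0
  if (!any(ok))
    stopf("series '%s': all-zero series cannot be detrended", x$series_id,
          class = "allorings_degenerate_error")
  n <- sum(ok)
  if (method != "mean" && n < 10L)
    stopf("series '%s': need >= 10 non-missing rings for '%s' detrending",
          x$series_id, method)
  t_all <- seq_along(w)
  trend <- switch(method,
    mean = rep(mean(w[ok]), length(w)),
    spline = fit_spline_trend(t_all, w, ok, stiffness),
    neg_exponential = fit_negexp_trend(t_all, w, ok))
  if (any(trend <= 0)) trend <- rep(mean(w[ok]), length(w))  # last resort
  idx <- ifelse(ok, w / trend, 0)
  structure(list(tree_id = x$tree_id, site = x$site,
                 compartment = x$compartment, first_year = x$first_year,
                 indices = idx, method = method),
            class = "index_series")
}

# Equivalent-df heuristic for a smoothing spline whose 50% frequency cutoff
# sits near `stiffness * n` years: stiff enough to track only the age trend.
fit_spline_trend <- function(t_all, w, ok, stiffness) {
  n <- sum(ok)
  nyrs <- max(2, stiffness * n)
  df <- max(3, min(n - 1, round(1.2 * n / nyrs + 2)))
  sp <- stats::smooth.spline(t_all[ok], w[ok], df = df)
  stats::predict(sp, t_all)$y
}

fit_negexp_trend <- function(t_all, w, ok) {
  tt <- t_all[ok]; ww <- w[ok]
  fit <- tryCatch({
    c0 <- 0.9 * min(ww)
    a0 <- max(max(ww) - c0, 1e-3)
    nls_fit <- suppressWarnings(
      stats::nls(ww ~ a * exp(-b * tt) + c,
                 start = list(a = a0, b = 0.02, c = c0),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = TRUE)))
    cf <- stats::coef(nls_fit)
    tr <- cf["a"] * exp(-cf["b"] * t_all) + cf["c"]
    if (cf["a"] <= 0 || cf["b"] <= 0 || any(tr <= 0)) NULL else tr
  }, error = function(e) NULL)
  if (!is.null(fit)) return(fit)
  lf <- stats::lm(ww ~ tt)                       # linear fallback
  tr <- stats::coef(lf)[1] + stats::coef(lf)[2] * t_all
  if (stats::coef(lf)[2] < 0 && all(tr > 0)) return(tr)
  rep(mean(ww), length(t_all))                   # horizontal mean
}

#' @export
years.index_series <- function(x, ...) {
  x$first_year + seq_along(x$indices) - 1L
}

#' @export
print.index_series <- function(x, ...) {
  yr <- years(x)
  cat(sprintf("<index_series> tree %s %s (%s), %d-%d, method %s\n",
              x$tree_id, x$compartment, x$site, yr[1], yr[length(yr)],
              x$method))
  invisible(x)
}

#' Build a mean chronology for a group of trees
#'
#' Averages the ring-width indices of a group of trees (one site, tree
#' position, and compartment) year by year, recording the per-year sample
#' depth. Missing-ring years of a member (index 0) do not enter the mean;
#' the depth drops instead, keeping chronology values strictly positive.
#'
#' @param indices List of `index_series` (see [detrend()]).
#' @param group Named list or vector with `site`, `position`, `compartment`
#'   identifying the group; member series must match `site` and
#'   `compartment` where these are non-missing.
#' @return A `mean_chronology`: fields `group`, `years`, `values`,
#'   `sample_depth`.
#' @export
build_mean_chronology <- function(indices, group = NULL) {
  if (!length(indices)) stopf("no index series supplied")
  if (!is.null(group)) {
    for (s in indices) {
      if (!is.na(group[["site"]]) && !is.na(s$site) &&
          s$site != group[["site"]])
        stopf("series of tree '%s' is from site '%s', not group site '%s'",
              s$tree_id, s$site, group[["site"]],
              class = "allorings_integrity_error")
      if (s$compartment != group[["compartment"]])
        stopf("tree '%s': compartment '%s' does not match group '%s'",
              s$tree_id, s$compartment, group[["compartment"]],
              class = "allorings_integrity_error")
    }
  }
  yr_all <- sort(unique(unlist(lapply(indices, years))))
  vals <- depth <- numeric(length(yr_all))
  for (s in indices) {
    idx <- match(years(s), yr_all)
    use <- s$indices > 0
    vals[idx[use]] <- vals[idx[use]] + s$indices[use]
    depth[idx[use]] <- depth[idx[use]] + 1
  }
  keep <- depth > 0
  structure(list(group = group, years = yr_all[keep],
                 values = vals[keep] / depth[keep],
                 sample_depth = as.integer(depth[keep])),
            class = "mean_chronology")
}

#' @export
print.mean_chronology <- function(x, ...) {
  g <- if (is.null(x$group)) "ungrouped" else
    paste(unlist(x$group), collapse = " / ")
  cat(sprintf("<mean_chronology> %s: %d years (%d-%d), depth %d-%d\n",
              g, length(x$years), min(x$years), max(x$years),
              min(x$sample_depth), max(x$sample_depth)))
  invisible(x)
}

#' @export
as.data.frame.mean_chronology <- function(x, ...) {
  data.frame(year = x$years, value = x$values,
             sample_depth = x$sample_depth)
}
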