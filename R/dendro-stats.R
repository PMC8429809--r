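# Series-quality and cross-dating statistics.

series_values <- function(x) {
  if (is_ring_series(x)) x$widths
  else if (inherits(x, "index_series")) x$indices
  else if (inherits(x, "mean_chronology")) x$values
  else as.numeric(x)
}

series_years <- function(x) {
  if (is_ring_series(x) || inherits(x, "index_series")) years(x)
  else if (inherits(x, "mean_chronology")) x$years
  else seq_along(x)
}

#' Mean sensitivity of a series
#'
#' Year-to-year variability statistic: the mean over consecutive pairs of
#' `2 * |w_t - w_(t-1)| / (w_t + w_(t-1))`, i.e. the absolute difference of
#' two successive rings divided by their mean. Lies in \[0, 2\]; pairs where
#' both rings are zero are skipped. Scale-invariant.
#'
#' @param x A [ring_series], `index_series`, or numeric vector.
#' @return Mean sensitivity.
#' @export
mean_sensitivity <- function(x) {
  w <- series_values(x)
  if (length(w) < 2L) stopf("mean sensitivity needs at least 2 values",
                            class = "allorings_undefined_error")
  a <- w[-length(w)]; b <- w[-1]
  use <- (a + b) > 0
  if (sum(use) < 1L)
    stopf("mean sensitivity undefined: no usable pairs",
          class = "allorings_undefined_error")
  mean(2 * abs(b[use] - a[use]) / (a[use] + b[use]))
}

align_pair <- function(a, b) {
  ya <- series_years(a); yb <- series_years(b)
  common <- intersect(ya, yb)
  list(a = series_values(a)[match(common, ya)],
       b = series_values(b)[match(common, yb)],
       years = sort(common))
}

#' Gleichlaeufigkeit (sign agreement) of two series
#'
#' Percentage of overlapping year-to-year steps in which the two series move
#' in the same direction; a step that is flat in either series counts half.
#'
#' @param a,b Series (ring/index series or numeric vectors on a shared year
#'   axis); overlap of at least 3 years required.
#' @return GLK in percent, in \[0, 100\].
#' @export
glk <- function(a, b) {
  al <- align_pair(a, b)
  if (length(al$a) < 3L)
    stopf("GLK needs an overlap of at least 3 years",
          class = "allorings_overlap_error")
  sa <- sign(diff(al$a)); sb <- sign(diff(al$b))
  score <- ifelse(sa == sb & sa != 0, 1, ifelse(sa == 0 | sb == 0, 0.5, 0))
  100 * mean(score)
}

# 5-year centred moving-average high-pass: value / local mean, log scale.
# Returns NA at the two edge years and where the ratio is undefined.
highpass_ratio <- function(w, k = 5L) {
  n <- length(w)
  if (n < k) return(rep(NA_real_, n))
  ma <- stats::filter(w, rep(1 / k, k), sides = 2)
  r <- ifelse(!is.na(ma) & ma > 0 & w > 0, w / ma, NA)
  log(r)
}

#' Baillie-Pilcher t value of two series
#'
#' Pearson correlation of the 5-year high-pass components (ring width over
#' its centred 5-year mean, log scale) converted to a t statistic,
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`.
#'
#' @inheritParams glk
#' @return The t value (can be negative for antiphase series).
#' @export
tbp <- function(a, b) {
  al <- align_pair(a, b)
  ha <- highpass_ratio(al$a); hb <- highpass_ratio(al$b)
  use <- !is.na(ha) & !is.na(hb)
  n <- sum(use)
  if (n < 4L || stats::sd(ha[use]) == 0 || stats::sd(hb[use]) == 0)
    stopf("Baillie-Pilcher t undefined: too short or zero-variance overlap",
          class = "allorings_undefined_error")
  r <- stats::cor(ha[use], hb[use])
  r <- max(min(r, 0.999999), -0.999999)
  r * sqrt(n - 2) / sqrt(1 - r^2)
}

#' Cross-date index of a series against a master chronology
#'
#' Composite agreement score `CDI = GLK * t_BP / 100` combining the sign
#' agreement ([glk()]) with the Baillie-Pilcher high-pass t value ([tbp()]),
#' floored at zero. Used as a relative measure of dating quality; the exact
#' composition is configurable via its parts.
#'
#' @param series A [ring_series] (or index series).
#' @param master A `mean_chronology` or second series; overlap of at least 10
#'   years required.
#' @return CDI (unitless, >= 0).
#' @export
cdi <- function(series, master) {
  al <- align_pair(series, master)
  if (length(al$a) < 10L)
    stopf("CDI needs an overlap of at least 10 years",
          class = "allorings_overlap_error")
  g <- glk(series, master)
  t_bp <- tbp(series, master)
  max(0, g * t_bp / 100)
}

#' Pointer years of a group of trees
#'
#' A calendar year is flagged as a pointer year when at least `min_fraction`
#' of the trees deviate with a common sign by at least `min_deviation`
#' (relative) from their own mean over the surrounding `window`-year centred
#' window (the year itself excluded). Schweingruber-style criterion; all
#' three knobs are exposed.
#'
#' @param indices List of at least 5 `index_series` (or ring series).
#' @param min_fraction Minimum fraction of trees that must agree (default
#'   0.75).
#' @param min_deviation Minimum relative deviation (default 0.10 = 10%).
#' @param window Width of the centred comparison window in years (default 5).
#' @return Data frame with columns `year` and `sign` (+1 / -1); zero rows
#'   when no year qualifies.
#' @export
pointer_years <- function(indices, min_fraction = 0.75,
                          min_deviation = 0.10, window = 5L) {
  if (length(indices) < 5L)
    stopf("pointer years need at least 5 trees")
  half <- (window - 1L) %/% 2L
  yr_all <- sort(unique(unlist(lapply(indices, series_years))))
  dev <- matrix(NA_real_, length(indices), length(yr_all))
  for (i in seq_along(indices)) {
    v <- series_values(indices[[i]])
    yrs <- series_years(indices[[i]])
    idx <- match(yrs, yr_all)
    for (j in seq_along(v)) {
      lo <- max(1L, j - half); hi <- min(length(v), j + half)
      nb <- v[setdiff(lo:hi, j)]
      nb <- nb[nb > 0]
      if (length(nb) >= 2L && v[j] > 0)
        dev[i, idx[j]] <- (v[j] - mean(nb)) / mean(nb)
    }
  }
  out <- data.frame(year = integer(0), sign = integer(0))
  for (j in seq_along(yr_all)) {
    d <- dev[, j]
    avail <- sum(!is.na(d))
    if (avail < 5L) next
    if (sum(d >= min_deviation, na.rm = TRUE) / avail >= min_fraction)
      out <- rbind(out, data.frame(year = yr_all[j], sign = 1L))
    else if (sum(d <= -min_deviation, na.rm = TRUE) / avail >= min_fraction)
      out <- rbind(out, data.frame(year = yr_all[j], sign = -1L))
  }
  out
}

#' Segment-correlation cross-dating check
#'
#' Simplified COFECHA-style check: the series is split into half-overlapping
#' segments; in each segment the high-pass component (see [tbp()]) is
#' correlated with the master at year shifts `-max_lag ... +max_lag`, and the
#' segment is flagged when the best-correlating shift is not zero. The lag
#' convention: `best_lag` is the shift added to the series' year labels that
#' maximizes agreement with the master (a series dated one year too late has
#' `best_lag = -1`).
#'
#' @param series A [ring_series] at least `segment` years long.
#' @param master A `mean_chronology` (or second series).
#' @param segment Segment length in years (default 20).
#' @param max_lag Maximum shift scanned in either direction (default 5).
#' @return A `crossdate_report` data frame: `seg_start`, `seg_end`, `r0`
#'   (correlation at lag 0), `best_lag`, `r_best`, `flag`.
#' @export
crossdate_check <- function(series, master, segment = 20L, max_lag = 5L) {
  sy <- series_years(series)
  if (length(sy) < segment)
    stopf("series '%s' is shorter than one %d-year segment",
          series$series_id %||% "?", segment,
          class = "allorings_length_error")
  hs <- highpass_ratio(series_values(series))
  my <- series_years(master)
  hm <- highpass_ratio(series_values(master))
  starts <- seq(1L, length(sy) - segment + 1L, by = max(1L, segment %/% 2L))
  rows <- lapply(starts, function(s0) {
    seg_idx <- s0:(s0 + segment - 1L)
    rs <- vapply(-max_lag:max_lag, function(L) {
      m_idx <- match(sy[seg_idx] + L, my)
      ok <- !is.na(m_idx) & !is.na(hs[seg_idx])
      ok[ok] <- !is.na(hm[m_idx[ok]])
      if (sum(ok) < 5L) return(NA_real_)
      suppressWarnings(stats::cor(hs[seg_idx][ok], hm[m_idx[ok]]))
    }, numeric(1))
    if (all(is.na(rs))) return(NULL)
    best <- which.max(rs)
    lag0 <- max_lag + 1L
    data.frame(seg_start = sy[seg_idx[1]], seg_end = sy[seg_idx[segment]],
               r0 = rs[lag0], best_lag = (-max_lag:max_lag)[best],
               r_best = rs[best],
               flag = (-max_lag:max_lag)[best] != 0L)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("crossdate_report", class(out))
  out
}

#' Per-series quality statistics against a master
#'
#' Convenience wrapper computing [mean_sensitivity()], [glk()], [tbp()], and
#' [cdi()] of each series against a master chronology.
#'
#' @param series List of [ring_series].
#' @param master A `mean_chronology`.
#' @return Data frame with one row per series.
#' @export
series_stats <- function(series, master = NULL) {
  do.call(rbind, lapply(series, function(s) {
    ms <- tryCatch(mean_sensitivity(s), error = function(e) NA_real_)
    g <- t_bp <- ci <- NA_real_
    if (!is.null(master)) {
      g <- tryCatch(glk(s, master), error = function(e) NA_real_)
      t_bp <- tryCatch(tbp(s, master), error = function(e) NA_real_)
      ci <- tryCatch(cdi(s, master), error = function(e) NA_real_)
    }
    data.frame(series_id = s$series_id, tree_id = s$tree_id, site = s$site,
               compartment = s$compartment, mean_sensitivity = ms,
               glk = g, tbp = t_bp, cdi = ci, stringsAsFactors = FALSE)
  }))
}
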