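#' @keywords internal
stopf <- function(fmt, ..., class = "allorings_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "allorings_error")))
}

.COMPARTMENTS <- c("stem", "root_collar", "root")
.DIRECTIONS <- c("toward_cut", "toward_stand", "none")
.POSITIONS <- c("edge", "interior")

#' Dated ring-width series
#'
#' A `ring_series` holds one dated sequence of annual ring widths for a single
#' increment core or a tree-level average, together with the metadata the
#' allometry pipeline needs: which tree and site it belongs to, which
#' compartment it was taken from (stem, root collar, or main root), and the
#' growth direction of the cored root relative to the cut strip. Missing
#' (locally absent) rings are stored as width 0 and flagged, so the year axis
#' stays gap-free.
#'
#' @param series_id Character identifier of the core/series.
#' @param widths Numeric vector of ring widths in mm (non-negative;
#'   0.01 mm measurement resolution).
#' @param first_year Calendar year of the first ring.
#' @param tree_id Tree the series belongs to (defaults to `series_id`).
#' @param site Site/stand name.
#' @param compartment One of `"stem"`, `"root_collar"`, `"root"`.
#' @param direction Root growth direction: `"toward_cut"`, `"toward_stand"`,
#'   or `"none"` (stems, averaged series).
#' @param missing Logical vector flagging missing rings; a flagged year must
#'   have width exactly 0. Defaults to flagging all zero-width years.
#' @return An object of class `ring_series`.
#' @examples
#' rs <- ring_series("T1-S1", c(1.20, 2.50, 0.80), first_year = 2000)
#' years(rs)
#' @export
ring_series <- function(series_id, widths, first_year,
                        tree_id = series_id, site = NA_character_,
                        compartment = "stem", direction = "none",
                        missing = widths <= 0) {
  compartment <- match.arg(compartment, .COMPARTMENTS)
  direction <- match.arg(direction, .DIRECTIONS)
  widths <- as.numeric(widths)
  if (length(widths) < 1L)
    stopf("series '%s': at least one ring width required", series_id)
  if (anyNA(widths) || any(widths < 0))
    stopf("series '%s': widths must be non-negative and non-missing", series_id)
  missing <- as.logical(missing)
  if (length(missing) != length(widths))
    stopf("series '%s': missing flags must match widths in length", series_id)
  if (any(missing & widths > 0))
    stopf("series '%s': a missing-flagged year must have width 0", series_id)
  structure(
    list(series_id = as.character(series_id),
         tree_id = as.character(tree_id),
         site = as.character(site),
         compartment = compartment,
         direction = direction,
         first_year = as.integer(first_year),
         widths = widths,
         missing = missing),
    class = "ring_series")
}

#' Calendar years covered by a series
#' @param x A `ring_series`, `index_series`, or `radius_series`.
#' @param ... Unused.
#' @return Integer vector of consecutive calendar years.
#' @export
years <- function(x, ...) UseMethod("years")

#' @export
years.ring_series <- function(x, ...) {
  x$first_year + seq_along(x$widths) - 1L
}

#' @export
years.default <- function(x, ...) x$years

#' @export
print.ring_series <- function(x, ...) {
  yr <- years(x)
  cat(sprintf("<ring_series> %s  (tree %s, %s, %s, %s)\n",
              x$series_id, x$tree_id, x$site, x$compartment, x$direction))
  cat(sprintf("  %d rings, %d-%d, mean width %.2f mm, %d missing\n",
              length(x$widths), yr[1], yr[length(yr)],
              mean(x$widths), sum(x$missing)))
  invisible(x)
}

#' @export
as.data.frame.ring_series <- function(x, ...) {
  data.frame(series_id = x$series_id, tree_id = x$tree_id, site = x$site,
             compartment = x$compartment, direction = x$direction,
             year = years(x), width_mm = x$widths, missing = x$missing,
             stringsAsFactors = FALSE)
}

#' @keywords internal
is_ring_series <- function(x) inherits(x, "ring_series")

#' Validate a tree metadata table
#'
#' Checks a data frame of per-tree dimensions and positions against the
#' constraints the pipeline assumes: positive dbh, live crown ratio within
#' 0-100 %, position either `"edge"` or `"interior"`, and the height/diameter
#' ratio consistent with height and dbh where all three are present. The
#' h/d ratio (100 * height in m / dbh in cm) is computed when absent.
#'
#' @param trees Data frame with at least `tree_id`, `site`, `position`,
#'   `height_m`, `dbh_cm`; optional `ds_cm` (stem diameter at coring height),
#'   `root_d_cm` (mean diameter of the sampled main roots at coring),
#'   `lc_pct`, `hd_ratio`.
#' @return The validated (and completed) data frame.
#' @export
validate_tree_table <- function(trees) {
  req <- c("tree_id", "site", "position", "height_m", "dbh_cm")
  miss <- setdiff(req, names(trees))
  if (length(miss))
    stopf("tree table lacks required column(s): %s",
          paste(miss, collapse = ", "), class = "allorings_schema_error")
  trees$tree_id <- as.character(trees$tree_id)
  for (i in seq_len(nrow(trees))) {
    id <- trees$tree_id[i]
    if (!is.finite(trees$dbh_cm[i]) || trees$dbh_cm[i] <= 0)
      stopf("tree '%s': dbh must be a positive number", id)
    if (!trees$position[i] %in% .POSITIONS)
      stopf("tree '%s': position must be 'edge' or 'interior'", id)
    if ("lc_pct" %in% names(trees) && is.finite(trees$lc_pct[i]) &&
        (trees$lc_pct[i] < 0 || trees$lc_pct[i] > 100))
      stopf("tree '%s': live crown ratio must lie in [0, 100]", id)
  }
  if (!"hd_ratio" %in% names(trees))
    trees$hd_ratio <- round(100 * trees$height_m / trees$dbh_cm, 1)
  trees
}

#' Validate a site configuration table
#'
#' @param sites Data frame with columns `site`, `cutting_year`,
#'   `annual_ta_c`, `annual_pr_mm`, optional `window_pre`, `window_post`
#'   (analysis windows in years, default 10) and `interval_start`,
#'   `interval_end` (common truncation interval).
#' @return Completed, validated data frame.
#' @export
validate_site_table <- function(sites) {
  req <- c("site", "cutting_year")
  miss <- setdiff(req, names(sites))
  if (length(miss))
    stopf("site table lacks required column(s): %s",
          paste(miss, collapse = ", "), class = "allorings_schema_error")
  if (!"window_pre" %in% names(sites)) sites$window_pre <- 10L
  if (!"window_post" %in% names(sites)) sites$window_post <- 10L
  if (any(sites$window_pre < 1) || any(sites$window_post < 1))
    stopf("analysis windows must be at least 1 year")
  if (all(c("interval_start", "interval_end") %in% names(sites)) &&
      any(sites$interval_start >= sites$interval_end))
    stopf("common interval start must precede its end")
  sites
}
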