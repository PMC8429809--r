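# Tucson/decadal ring-width file IO.
#
# Dialect notes: measurements are stored as integers in 1/100 mm (the
# resolution of Lintab-type measuring stages); both 999 and -9999 are accepted
# as end-of-series sentinels on read, 999 is emitted on write. Series ids
# wider than the historical 8-character field are accepted because fields are
# whitespace-delimited here.

#' Read a Tucson/decadal ring-width file
#'
#' Parses a `.rwl` file in the decadal Tucson layout (one series id per block,
#' ten values per line, integer widths in 1/100 mm, end-of-series sentinel 999
#' or -9999). Zero values are kept as width-0 years and flagged as missing
#' rings, so the year axis of each series stays gap-free.
#'
#' @param path File to read.
#' @param site,compartment,direction Metadata applied to every series in the
#'   file (a Tucson file carries none of its own).
#' @param tree_id_fun Function mapping a series id to its tree id; defaults to
#'   stripping a trailing `-<core>` suffix (e.g. `"FUR_I01-S1"` -> `"FUR_I01"`).
#' @return Named list of [ring_series] objects (names are series ids).
#' @seealso [write_rwl()]
#' @export
read_rwl <- function(path, site = NA_character_, compartment = "stem",
                     direction = "none", tree_id_fun = default_tree_id) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  open <- list()    # id -> list(first_year, values)
  done <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    if (length(tok) < 3) stopf("line %d: too few fields", ln,
                               class = "allorings_parse_error")
    id <- tok[1]
    yr <- suppressWarnings(as.integer(tok[2]))
    if (is.na(yr))
      stopf("line %d: malformed year column '%s'", ln, tok[2],
            class = "allorings_parse_error")
    vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (anyNA(vals))
      stopf("line %d: non-numeric width value", ln,
            class = "allorings_parse_error")
    if (!is.null(done[[id]]))
      stopf("line %d: data for series '%s' after its end sentinel", ln, id,
            class = "allorings_integrity_error")
    cur <- open[[id]]
    if (is.null(cur)) {
      cur <- list(first_year = yr, values = numeric(0))
    } else {
      expect <- cur$first_year + length(cur$values)
      if (yr != expect)
        stopf("line %d: series '%s' year %d where %d expected (duplicate or gap)",
              ln, id, yr, expect, class = "allorings_integrity_error")
    }
    sent <- which(vals == 999 | vals == -9999)
    if (length(sent)) {
      cur$values <- c(cur$values, vals[seq_len(sent[1] - 1L)])
      done[[id]] <- cur
      open[[id]] <- NULL
    } else {
      cur$values <- c(cur$values, vals)
      open[[id]] <- cur
    }
  }
  for (id in names(open)) done[[id]] <- open[[id]]  # tolerate absent sentinel
  out <- lapply(names(done), function(id) {
    v <- done[[id]]$values
    if (!length(v)) return(NULL)
    ring_series(series_id = id, widths = v / 100,
                first_year = done[[id]]$first_year,
                tree_id = tree_id_fun(id), site = site,
                compartment = compartment, direction = direction)
  })
  names(out) <- names(done)
  out[!vapply(out, is.null, logical(1))]
}

#' @rdname read_rwl
#' @param series_id A series id.
#' @export
default_tree_id <- function(series_id) sub("-[^-]*$", "", series_id)

#' Write ring-width series to a Tucson/decadal file
#'
#' Widths are emitted as integers in 1/100 mm (rounded half up, so 0.005 mm
#' encodes as 1), laid out in decadal rows, with the -9999 end sentinel (the
#' convention for 1/100 mm precision files; a 999 sentinel would collide
#' with a genuine 9.99 mm ring). A data value that would encode exactly as
#' 999 is bumped one resolution step to 998, since readers treat 999 as a
#' sentinel. The output re-parses to the input under [read_rwl()] once
#' widths are quantized to 0.01 mm.
#'
#' @param series List of [ring_series] objects (an empty list yields an empty
#'   file).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in series) {
    if (!is_ring_series(s)) stopf("write_rwl expects ring_series objects")
    if (any(s$widths > 99.98))
      stopf("series '%s': width > 99.98 mm cannot be encoded in 1/100 mm",
            s$series_id, class = "allorings_range_error")
    vals <- floor(s$widths * 100 + 0.5)
    vals[vals == 999] <- 998    # 999 is reserved for the sentinel
    vals <- c(vals, -9999)      # end-of-series sentinel
    i <- 1L
    n <- length(vals)
    while (i <= n) {
      y0 <- s$first_year + i - 1L          # year of vals[i]
      k <- min(n - i + 1L, 10L - (y0 %% 10L))  # run to end of decade
      chunk <- vals[i:(i + k - 1L)]
      writeLines(sprintf("%-8s %6d%s", s$series_id, y0,
                         paste(sprintf("%6d", chunk), collapse = "")), con)
      i <- i + k
    }
  }
  invisible(path)
}

#' Read a delimited tree metadata table
#'
#' Reads a tab- or comma-separated table of per-tree dimensions and positions
#' and validates it (see [validate_tree_table()]). The h/d ratio is computed
#' from height and dbh when the column is absent.
#'
#' @param path Delimited text file with a header row.
#' @return Validated data frame of tree records.
#' @export
read_tree_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr(",", header))) >
             lengths(regmatches(header, gregexpr("\t", header)))) "," else "\t"
  trees <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  num <- intersect(c("height_m", "dbh_cm", "ds_cm", "root_d_cm", "lc_pct",
                     "hd_ratio"), names(trees))
  for (cl in num) {
    v <- suppressWarnings(as.numeric(trees[[cl]]))
    bad <- which(is.na(v) & !is.na(trees[[cl]]))
    if (length(bad))
      stopf("tree '%s': non-numeric value in column '%s'",
            trees$tree_id[bad[1]], cl)
    trees[[cl]] <- v
  }
  validate_tree_table(trees)
}

#' Write a tree metadata table
#' @param trees Data frame of tree records.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_tree_table <- function(trees, path) {
  utils::write.table(trees, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a site configuration file
#'
#' Site configuration is a small YAML file: one entry per site with the
#' cutting year, climate normals (annual mean temperature in deg C, annual
#' precipitation sum in mm), pre/post analysis windows in years, and the
#' common truncation interval.
#'
#' @param path YAML file.
#' @return Data frame with one row per site.
#' @export
read_site_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  y <- yaml::read_yaml(path)
  sites <- do.call(rbind, lapply(y$sites, function(s) {
    data.frame(site = s$site,
               cutting_year = as.integer(s$cutting_year),
               annual_ta_c = as.numeric(s$annual_ta_c %||% NA),
               annual_pr_mm = as.numeric(s$annual_pr_mm %||% NA),
               window_pre = as.integer(s$window_pre %||% 10L),
               window_post = as.integer(s$window_post %||% 10L),
               interval_start = as.integer(s$common_interval[[1]] %||% NA),
               interval_end = as.integer(s$common_interval[[2]] %||% NA),
               stringsAsFactors = FALSE)
  }))
  validate_site_table(sites)
}

#' @rdname read_site_config
#' @param sites Data frame with one row per site.
#' @export
write_site_config <- function(sites, path) {
  entries <- lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    list(site = s$site, cutting_year = s$cutting_year,
         annual_ta_c = s$annual_ta_c, annual_pr_mm = s$annual_pr_mm,
         window_pre = s$window_pre, window_post = s$window_post,
         common_interval = list(s$interval_start, s$interval_end))
  })
  yaml::write_yaml(list(sites = entries), path)
  invisible(path)
}

#' Read / write long-form series tables
#'
#' Long-form interchange: one row per ring with full metadata
#' (`series_id`, `tree_id`, `site`, `compartment`, `direction`, `year`,
#' `width_mm`, `missing`). Used for series whose metadata does not fit the
#' Tucson format.
#'
#' @param path Tab-separated file.
#' @return Named list of [ring_series].
#' @export
read_series_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  out <- lapply(split(d, d$series_id), function(g) {
    g <- g[order(g$year), ]
    if (any(diff(g$year) != 1L))
      stopf("series '%s': years are not consecutive", g$series_id[1],
            class = "allorings_integrity_error")
    ring_series(g$series_id[1], g$width_mm, g$year[1], g$tree_id[1],
                g$site[1], g$compartment[1], g$direction[1],
                missing = as.logical(g$missing))
  })
  out[order(names(out))]
}

#' @rdname read_series_table
#' @param series List of [ring_series].
#' @export
write_series_table <- function(series, path) {
  d <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
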