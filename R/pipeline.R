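# End-to-end analysis: read -> QC -> average/truncate -> reconstruct ->
# allometry -> alpha'/PCA -> response model -> report.

#' Run the complete root-shoot allometry analysis
#'
#' Orchestrates the pipeline on a dataset (in memory or a fixture directory):
#' cores are averaged to tree-level series per compartment, truncated to each
#' site's common interval, screened for sufficient pre-cutting coverage;
#' quality statistics and mean chronologies are computed per site, position,
#' and compartment; annual radii are reconstructed backward from the measured
#' radii at survey; the long-term allometric mixed model is fitted on
#' stand-interior trees (with the eccentricity-corrected per-site exponents);
#' annual allometric slopes and the per-tree PCA are derived from raw widths;
#' and the PCA response model (Cook's screening, backward AIC selection) and
#' per-site rank-sum comparisons are fitted. Every input tree ends up either
#' in the result tables or in the exclusion log with a reason.
#'
#' @param x An `allorings_dataset` or a fixture directory path (see
#'   [read_fixture_set()]).
#' @param out_dir Optional output directory; when given, all tables are
#'   written as delimited text/JSON together with a run manifest (no
#'   timestamps, so identical runs yield identical files).
#' @param detrend_method Method for [detrend()] used in the chronologies.
#' @param window Pre/post window length in years for [pca_statistic()]
#'   (overridden per site by the site table's `window_pre` when present).
#' @param min_valid_years Minimum usable alpha' years per window.
#' @param eccentricity_factor Root eccentricity overestimation factor
#'   applied to the fitted exponents (default 1.90).
#' @param winsor_bound Alpha' magnitude bound (see [pca_statistic()]).
#' @param reference_site Reference site for the allometry contrasts
#'   (default: alphabetically first).
#' @return An `allorings_report` list: `stats`, `chronologies`,
#'   `allometry` (fit, per-site raw and corrected exponents), `pca_table`,
#'   `response` (fit, Wilcoxon table), `exclusions`, `manifest`.
#' @export
run_pipeline <- function(x, out_dir = NULL,
                         detrend_method = "spline", window = 10L,
                         min_valid_years = 5L, eccentricity_factor = 1.90,
                         winsor_bound = 50, reference_site = NULL) {
  if (is.character(x)) x <- read_fixture_set(x)
  stopifnot(inherits(x, "allorings_dataset"))
  trees <- x$trees
  sites <- x$sites
  exclusions <- data.frame(tree_id = character(0), stage = character(0),
                           reason = character(0), stringsAsFactors = FALSE)
  drop_tree <- function(id, stage, reason) {
    exclusions <<- rbind(exclusions,
                         data.frame(tree_id = id, stage = stage,
                                    reason = reason,
                                    stringsAsFactors = FALSE))
  }

  # --- tree-level series per compartment -------------------------------
  meta <- do.call(rbind, lapply(x$series, function(s)
    data.frame(series_id = s$series_id, tree_id = s$tree_id,
               compartment = s$compartment, stringsAsFactors = FALSE)))
  tree_level <- list()  # [[compartment]][[tree_id]]
  for (comp in unique(meta$compartment)) {
    ids <- unique(meta$tree_id[meta$compartment == comp])
    tree_level[[comp]] <- lapply(stats::setNames(ids, ids), function(id) {
      cores <- x$series[meta$series_id[meta$tree_id == id &
                                         meta$compartment == comp]]
      avg <- average_within_tree(cores)
      site_row <- sites[sites$site == avg$site, ]
      if (!nrow(site_row)) stopf("series of tree '%s' name unknown site '%s'",
                                 id, avg$site)
      iv <- c(site_row$interval_start %||% min(years(avg)),
              site_row$interval_end %||% max(years(avg)))
      if (is.na(iv[1])) iv <- range(years(avg))
      truncate_common_interval(avg, iv)
    })
    tree_level[[comp]] <-
      tree_level[[comp]][!vapply(tree_level[[comp]], is.null, logical(1))]
  }

  # pre-cutting coverage screen on the stem series
  keep <- character(0)
  for (id in names(tree_level$stem)) {
    s <- tree_level$stem[[id]]
    cy <- sites$cutting_year[sites$site == s$site]
    wp <- sites$window_pre[sites$site == s$site]
    if (reaches_back(list(s), cy, wp)) keep <- c(keep, id)
    else drop_tree(id, "coverage",
                   sprintf("stem series starts %d, later than %d (cutting %d - %d yr)",
                           s$first_year, cy - wp, cy, wp))
  }
  for (id in setdiff(trees$tree_id, names(tree_level$stem)))
    drop_tree(id, "input", "no stem series")
  trees <- trees[trees$tree_id %in% keep, ]

  # --- quality statistics and chronologies -----------------------------
  grp_of <- function(id) trees[trees$tree_id == id, c("site", "position")]
  stats_rows <- list(); chronos <- list()
  for (comp in names(tree_level)) {
    members <- tree_level[[comp]][names(tree_level[[comp]]) %in% keep]
    if (!length(members)) next
    det <- lapply(members, function(s)
      tryCatch(detrend(s, detrend_method), error = function(e) NULL))
    det <- det[!vapply(det, is.null, logical(1))]
    key <- vapply(names(det), function(id) {
      gr <- grp_of(id); paste(gr$site, gr$position, sep = "|")
    }, character(1))
    for (k in unique(key)) {
      parts <- strsplit(k, "|", fixed = TRUE)[[1]]
      grp <- list(site = parts[1], position = parts[2], compartment = comp)
      ch <- build_mean_chronology(det[key == k], grp)
      chronos[[paste(k, comp, sep = "|")]] <- ch
      for (id in names(det)[key == k]) {
        st <- series_stats(members[id], master = ch)
        st$position <- parts[2]
        stats_rows[[paste(id, comp)]] <- st
      }
    }
  }
  stats_table <- do.call(rbind, c(stats_rows, make.row.names = FALSE))

  # --- radii and long-term allometry (interior trees) ------------------
  radii <- list()
  for (i in seq_len(nrow(trees))) {
    id <- trees$tree_id[i]
    stem <- tree_level$stem[[id]]
    root <- tree_level$root[[id]]
    if (is.null(root)) { drop_tree(id, "input", "no root series"); next }
    res <- tryCatch(list(
      stem = reconstruct_radii(stem, trees$ds_cm[i] * 10 / 2),
      root = reconstruct_radii(root, trees$root_d_cm[i] * 10 / 2)),
      error = function(e) e)
    if (inherits(res, "error"))
      drop_tree(id, "radii", conditionMessage(res))
    else radii[[id]] <- res
  }
  interior_ids <- trees$tree_id[trees$position == "interior" &
                                  trees$tree_id %in% names(radii)]
  pairs <- do.call(rbind, lapply(interior_ids, function(id)
    allometry_pairs(radii[[id]]$root, radii[[id]]$stem)))
  allo_fit <- fit_allometry(pairs, reference_site = reference_site)
  alpha_table <- data.frame(site = names(site_alphas(allo_fit)),
                            alpha = unname(site_alphas(allo_fit)),
                            alpha_corrected =
                              unname(correct_alpha(allo_fit,
                                                   eccentricity_factor)),
                            stringsAsFactors = FALSE)

  # --- alpha' and PCA per tree -----------------------------------------
  pca_rows <- list()
  for (id in names(radii)) {
    cy <- sites$cutting_year[sites$site == radii[[id]]$stem$site]
    wp <- sites$window_pre[sites$site == radii[[id]]$stem$site]
    res <- tryCatch({
      ap <- alpha_prime(radii[[id]]$root, radii[[id]]$stem)
      pc <- pca_statistic(ap, cy, window = wp %||% window,
                          min_years = min_valid_years,
                          winsor_bound = winsor_bound)
      tr <- trees[trees$tree_id == id, ]
      rp_mm <- radii[[id]]$stem$radii_mm[
        match(cy - 1L, radii[[id]]$stem$years)]
      data.frame(tree_id = id, site = tr$site, position = tr$position,
                 rp_cm = rp_mm / 10, Ap = pc$Ap, Aa = pc$Aa,
                 pca_pct = pc$pca_pct, n_valid_pre = pc$n_valid_pre,
                 n_valid_post = pc$n_valid_post, stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) drop_tree(id, "pca", conditionMessage(res))
    else pca_rows[[id]] <- res
  }
  pca_table <- do.call(rbind, c(pca_rows, make.row.names = FALSE))

  # --- response model and group comparisons ----------------------------
  screened <- cooks_outlier_filter(pca_table)
  if (nrow(screened$excluded))
    for (j in seq_len(nrow(screened$excluded)))
      drop_tree(screened$excluded$tree_id[j], "cooks",
                sprintf("Cook's distance %.3f > %.3f",
                        screened$excluded$cooks_d[j], screened$threshold))
  response_fit <- fit_pca_model(screened$data, select = TRUE,
                                excluded = screened$excluded)
  wilcoxon <- wilcoxon_edge_vs_interior(pca_table)

  climate <- de_martonne(sites$annual_pr_mm, sites$annual_ta_c, sites$site)

  manifest <- list(
    package_version = as.character(utils::packageVersion("allorings")),
    options = list(detrend_method = detrend_method, window = window,
                   min_valid_years = min_valid_years,
                   eccentricity_factor = eccentricity_factor,
                   winsor_bound = winsor_bound,
                   reference_site = allo_fit$reference_site),
    counts = list(series_read = length(x$series),
                  trees_in = nrow(x$trees),
                  trees_retained = nrow(trees),
                  trees_with_pca = nrow(pca_table),
                  trees_excluded = length(unique(exclusions$tree_id)),
                  missing_rings = sum(vapply(x$series,
                                             function(s) sum(s$missing),
                                             numeric(1)))))

  report <- structure(list(stats = stats_table, chronologies = chronos,
                           allometry = list(fit = allo_fit,
                                            alpha_table = alpha_table),
                           pca_table = pca_table,
                           response = list(fit = response_fit,
                                           wilcoxon = wilcoxon),
                           climate = climate,
                           exclusions = exclusions, manifest = manifest),
                      class = "allorings_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.allorings_report <- function(x, ...) {
  cat("== Root-shoot allometry pipeline report ==\n")
  m <- x$manifest$counts
  cat(sprintf("series %d | trees %d in, %d retained, %d with PCA, %d excluded\n",
              m$series_read, m$trees_in, m$trees_retained, m$trees_with_pca,
              m$trees_excluded))
  cat("\n-- long-term allometry --\n")
  print(x$allometry$alpha_table, row.names = FALSE)
  cat("\n-- PCA response model --\n")
  print(x$response$fit)
  cat("\n-- edge vs interior PCA (rank-sum) --\n")
  print(x$response$wilcoxon, row.names = FALSE)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' @param report An `allorings_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(d, file.path(out_dir, f),
                                          sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(report$stats, "series_stats.tsv")
  chron_df <- do.call(rbind, lapply(names(report$chronologies), function(k) {
    ch <- report$chronologies[[k]]
    cbind(data.frame(site = ch$group$site, position = ch$group$position,
                     compartment = ch$group$compartment),
          as.data.frame(ch))
  }))
  wt(chron_df, "chronologies.tsv")
  wt(report$allometry$alpha_table, "alpha_site.tsv")
  wt(report$allometry$fit$coef_table, "allometry_coefficients.tsv")
  wt(report$pca_table, "pca.tsv")
  wt(report$response$fit$coef_table, "response_coefficients.tsv")
  wt(report$response$wilcoxon, "wilcoxon.tsv")
  wt(report$climate, "climate.tsv")
  wt(report$exclusions, "exclusions.tsv")
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
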