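# Synthetic study-data generator.
#
# The generator is the analytic inverse of the analysis: stem growth is an
# age trend times a shared AR(1) year effect times lognormal noise, scaled to
# a drawn survey radius; root radii follow the log-log allometric law on the
# stem radii (with a tree-level random intercept and a slowly varying
# lognormal deviation), so in the noise-free limit the annual allometric
# slope equals the configured exponent exactly. A multiplicative boxcar
# release on edge-tree widths after the cutting year emulates the transient
# post-cutting growth response, with a stronger response in smaller trees.

ar1_series <- function(n, rho, sd) {
  if (sd <= 0) return(rep(0, n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) for (t in 2:n)
    x[t] <- rho * x[t - 1] + stats::rnorm(1, 0, sd * sqrt(1 - rho^2))
  x
}

#' Simulation configuration
#'
#' Assembles and validates the configuration for [simulate_dataset()]. The
#' defaults describe three alpine spruce stands over 1970-2016 with the
#' cutting years, climate normals, site-specific allometric exponents, and a
#' post-cutting release that starts 2 years after the cutting and lasts 5
#' years (so it has faded 7 years after the intervention), biased toward
#' roots and stronger in smaller trees. Roughly 1.5 percent of root rings
#' are missing.
#'
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   configuration including the seed.
#' @param sites Data frame with one row per site: `site`, `n_edge`,
#'   `n_interior`, `cutting_year`, `year_start`, `year_end`, `alpha`,
#'   `alpha0`, `target_radius_mm` (median stem radius at survey),
#'   `hd_mean` (height/diameter ratio), `annual_ta_c`, `annual_pr_mm`.
#' @param growth List of stem growth parameters: `age_trend` (a, b, c of
#'   `a * exp(-b * age) + c`, mm), `age0_range` (tree age at the first
#'   simulated year), `initial_frac` (range of the initial radius as a
#'   fraction of the survey target), `radius_sdlog` (lognormal spread of the
#'   survey radius target), `year_rho`/`year_sd` (site-shared AR(1) year
#'   effect on the log scale), `sd_stem`/`sd_collar` (lognormal width noise),
#'   `sd_root`/`rho_root` (AR(1) deviation of the root radius from the
#'   allometric law, log scale), `core_sd` (between-core measurement
#'   scatter), `collar_ratio` (root-collar to stem width ratio).
#' @param allometry List: `tree_sd`, the standard deviation of the tree-level
#'   random intercept of the law.
#' @param release List: `lag` (years after cutting before the release
#'   starts), `duration` (years), `stem_gain`/`root_gain` (baseline
#'   multiplier gains; the width multipliers are `1 + gain * f`),
#'   `size_slope` (per-cm increase of the response factor `f` for trees
#'   smaller than the site median), `size_clamp` (bounds on `f`). A
#'   positive-PCA scenario needs `root_gain >= stem_gain >= 0`.
#' @param missing_ring_rate Probability that a root ring is missing.
#' @param cores List: `stem`, `collar`, `root_interior`, `root_edge` - the
#'   number of cores generated per tree and compartment.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 42L,
                       sites = sim_site_defaults(),
                       growth = list(),
                       allometry = list(),
                       release = list(),
                       missing_ring_rate = 0.015,
                       cores = list()) {
  g <- utils::modifyList(list(
    age_trend = c(a = 3, b = 0.015, c = 0.8),
    age0_range = c(60, 140), initial_frac = c(0.25, 0.45),
    radius_sdlog = 0.15, year_rho = 0.5, year_sd = 0.10,
    sd_stem = 0.10, sd_collar = 0.20, sd_root = 0.02, rho_root = 0.90,
    core_sd = 0.05, collar_ratio = 1.7), growth)
  a <- utils::modifyList(list(tree_sd = 0.15), allometry)
  r <- utils::modifyList(list(
    lag = 2L, duration = 5L, stem_gain = 0.15, root_gain = 0.45,
    size_slope = 0.15, size_clamp = c(0.25, 2)), release)
  k <- utils::modifyList(list(stem = 2L, collar = 2L, root_interior = 2L,
                              root_edge = 4L), cores)
  if (r$root_gain < r$stem_gain || r$stem_gain < 0)
    stopf("release gains must satisfy root_gain >= stem_gain >= 0")
  if (missing_ring_rate < 0 || missing_ring_rate > 1)
    stopf("missing_ring_rate must lie in [0, 1]")
  sds <- c(g$radius_sdlog, g$year_sd, g$sd_stem, g$sd_collar, g$sd_root,
           g$core_sd, a$tree_sd)
  if (any(sds < 0)) stopf("all noise standard deviations must be >= 0")
  structure(list(seed = as.integer(seed), sites = sites, growth = g,
                 allometry = a, release = r,
                 missing_ring_rate = missing_ring_rate, cores = k),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
sim_site_defaults <- function() {
  data.frame(
    site = c("Furna", "Siat", "SurEn"),
    n_edge = c(12L, 10L, 12L), n_interior = c(13L, 11L, 13L),
    cutting_year = c(2004L, 2004L, 2006L),
    year_start = 1970L, year_end = 2016L,
    alpha = c(4.06, 3.54, 2.60),
    alpha0 = c(-17.8, -14.8, -8.9),
    target_radius_mm = c(250, 240, 180),
    hd_mean = c(60, 58, 72),
    annual_ta_c = c(3.5, 3.4, 4.2),
    annual_pr_mm = c(1290, 1496, 809),
    stringsAsFactors = FALSE)
}

# split per-year core noise so the arithmetic mean over cores reproduces the
# tree-level series exactly (the per-tree average is what the analysis uses)
core_split <- function(widths, n_cores, core_sd) {
  if (n_cores == 1L || core_sd <= 0)
    return(matrix(rep(widths, n_cores), nrow = n_cores, byrow = TRUE))
  eps <- matrix(exp(stats::rnorm(n_cores * length(widths), 0, core_sd)),
                nrow = n_cores)
  eps <- sweep(eps, 2, colMeans(eps), "/")
  sweep(eps, 2, widths, "*")
}

#' Simulate a complete synthetic study dataset
#'
#' Generates core-level ring-width series for stems, root collars, and main
#' roots, a tree metadata table, a site configuration table, and the ground
#' truth needed for parameter-recovery checks (see [expected_pca()]).
#' Identical configurations (including the seed) yield identical datasets.
#'
#' @param config A [sim_config()].
#' @return An `allorings_dataset`: list with `series` (named list of
#'   [ring_series]), `trees`, `sites`, and `truth` (a `sim_truth`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)
  g <- config$growth; rl <- config$release
  series <- list()
  trees <- list()
  truth_rows <- list()
  baselines <- list()

  for (si in seq_len(nrow(config$sites))) {
    sc <- config$sites[si, ]
    y0 <- sc$year_start; y1 <- sc$year_end
    n <- y1 - y0 + 1L
    yrs <- y0:y1
    year_eff <- ar1_series(n, g$year_rho, g$year_sd)
    ab <- toupper(substr(gsub("[^A-Za-z]", "", sc$site), 1, 3))
    pos <- c(rep("interior", sc$n_interior), rep("edge", sc$n_edge))
    ids <- sprintf("%s_%s%02d", ab, ifelse(pos == "edge", "E", "I"),
                   c(seq_len(sc$n_interior), seq_len(sc$n_edge)))

    # stem trajectories first: the release response factor depends on the
    # site-median pre-cutting radius
    st <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      target <- stats::rlnorm(1, log(sc$target_radius_mm), g$radius_sdlog)
      age0 <- stats::runif(1, g$age0_range[1], g$age0_range[2])
      r0 <- target * stats::runif(1, g$initial_frac[1], g$initial_frac[2])
      tr <- g$age_trend[["a"]] * exp(-g$age_trend[["b"]] * (age0 + yrs - y0)) +
        g$age_trend[["c"]]
      raw <- tr * exp(year_eff) * exp(stats::rnorm(n, 0, g$sd_stem))
      w <- raw * (target - r0) / sum(raw)       # hit the survey radius
      w0 <- tr * (target - r0) / sum(tr)        # noise-free baseline
      pre_idx <- which(yrs <= sc$cutting_year - 1L)
      rp_cm <- (r0 + sum(w[pre_idx])) / 10
      st[[i]] <- list(target = target, age0 = age0, r0 = r0, w = w, w0 = w0,
                      rp_cm = rp_cm)
    }
    rp_ref <- stats::median(vapply(st, `[[`, numeric(1), "rp_cm"))
    ry <- which(yrs >= sc$cutting_year + rl$lag &
                  yrs <= sc$cutting_year + rl$lag + rl$duration - 1L)

    for (i in seq_along(ids)) {
      id <- ids[i]; edge <- pos[i] == "edge"
      s <- st[[i]]
      f <- max(rl$size_clamp[1],
               min(rl$size_clamp[2],
                   1 + rl$size_slope * (rp_ref - s$rp_cm)))
      m_s <- if (edge) 1 + rl$stem_gain * f else 1
      m_r <- if (edge) 1 + rl$root_gain * f else 1

      w_stem <- s$w
      if (edge && length(ry)) w_stem[ry] <- w_stem[ry] * m_s
      s_path0 <- s$r0 + cumsum(s$w)             # law input: no stem release

      # root radii from the allometric law on the (pre-release) stem path
      u <- stats::rnorm(1, 0, config$allometry$tree_sd)
      eta <- ar1_series(n + 1L, g$rho_root, g$sd_root)
      law <- exp(sc$alpha0 + sc$alpha * log(c(s$r0, s_path0)) + u + eta)
      dr_path <- cummax(law)
      v <- diff(dr_path)
      if (edge && length(ry)) v[ry] <- v[ry] * m_r
      if (config$missing_ring_rate > 0) {
        inject <- stats::runif(n) < config$missing_ring_rate & v > 0
        v[inject] <- 0
      }
      root_final <- dr_path[1] + sum(v)

      # collar: scaled stem widths with extra noise, root-like release
      w_col <- s$w * g$collar_ratio * exp(stats::rnorm(n, 0, g$sd_collar))
      if (edge && length(ry)) w_col[ry] <- w_col[ry] * m_r

      add_cores <- function(w_tree, comp, n_cores, directions) {
        mat <- core_split(w_tree, n_cores, g$core_sd)
        code <- c(stem = "S", root_collar = "C", root = "R")[[comp]]
        for (j in seq_len(n_cores)) {
          sid <- sprintf("%s-%s%d", id, code, j)
          series[[sid]] <<- ring_series(sid, mat[j, ], y0, tree_id = id,
                                        site = sc$site, compartment = comp,
                                        direction = directions[j])
        }
      }
      add_cores(w_stem, "stem", config$cores$stem,
                rep("none", config$cores$stem))
      add_cores(w_col, "root_collar", config$cores$collar,
                rep(c("toward_cut", "toward_stand"),
                    length.out = config$cores$collar))
      n_root <- if (edge) config$cores$root_edge else
        config$cores$root_interior
      add_cores(v, "root", n_root,
                rep(c("toward_cut", "toward_stand"), length.out = n_root))

      ds_cm <- 2 * (s$r0 + sum(w_stem)) / 10
      dbh_cm <- ds_cm * 0.94 * exp(stats::rnorm(1, 0, 0.03))
      hd <- stats::rnorm(1, sc$hd_mean, 4)
      height_m <- hd * dbh_cm / 100
      lc <- min(95, max(20, stats::rnorm(1, 68, 10)))
      trees[[id]] <- data.frame(
        tree_id = id, site = sc$site, position = pos[i],
        height_m = round(height_m, 1), dbh_cm = round(dbh_cm, 1),
        ds_cm = ds_cm, root_d_cm = 2 * root_final / 10,
        lc_pct = round(lc, 1),
        hd_ratio = round(100 * height_m / dbh_cm, 1),
        n_roots = n_root, stringsAsFactors = FALSE)

      truth_rows[[id]] <- data.frame(
        tree_id = id, site = sc$site, position = pos[i],
        alpha = sc$alpha, alpha0 = sc$alpha0, u_tree = u,
        m_stem = m_s, m_root = m_r,
        release_start = if (length(ry)) yrs[ry[1]] else NA_integer_,
        release_end = if (length(ry)) yrs[ry[length(ry)]] else NA_integer_,
        cutting_year = sc$cutting_year, first_year = y0,
        rp_cm = s$rp_cm, target_radius_mm = s$target, r0_mm = s$r0,
        age0 = s$age0, stringsAsFactors = FALSE)
      baselines[[id]] <- s$w0
    }
  }

  sites_out <- data.frame(
    site = config$sites$site, cutting_year = config$sites$cutting_year,
    annual_ta_c = config$sites$annual_ta_c,
    annual_pr_mm = config$sites$annual_pr_mm,
    window_pre = 10L, window_post = 10L,
    interval_start = config$sites$year_start,
    interval_end = config$sites$year_end, stringsAsFactors = FALSE)

  structure(list(
    series = series,
    trees = validate_tree_table(do.call(rbind,
                                        c(trees, make.row.names = FALSE))),
    sites = validate_site_table(sites_out),
    truth = structure(list(trees = do.call(rbind,
                                           c(truth_rows,
                                             make.row.names = FALSE)),
                           baseline = baselines),
                      class = "sim_truth"),
    config = config),
    class = "allorings_dataset")
}

#' @export
print.allorings_dataset <- function(x, ...) {
  comp <- table(vapply(x$series, `[[`, character(1), "compartment"))
  cat(sprintf("<allorings_dataset> %d trees, %d sites, %d series (%s)\n",
              nrow(x$trees), nrow(x$sites), length(x$series),
              paste(names(comp), comp, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Expected PCA of a simulated tree under the generator
#'
#' Closed-form (noise-ignoring) expectation of the percentage change in
#' allometric slope for a tree of a simulated dataset: the deterministic
#' skeleton of the generator - baseline age-trend stem widths, the
#' allometric law for the root radii, and the tree's release multipliers
#' over their overlap with the post-cutting window - is evaluated without
#' any noise and summarized exactly as [pca_statistic()] does. Interior
#' trees (multipliers 1) have expected PCA exactly 0.
#'
#' @param truth A `sim_truth` (from [simulate_dataset()]).
#' @param tree_id Tree to evaluate.
#' @param window Window length in years (default 10).
#' @return Expected PCA in percent.
#' @export
expected_pca <- function(truth, tree_id, window = 10L) {
  stopifnot(inherits(truth, "sim_truth"))
  row <- truth$trees[truth$trees$tree_id == tree_id, ]
  if (nrow(row) != 1L)
    stopf("tree '%s' not found in the simulation truth", tree_id,
          class = "allorings_lookup_error")
  w0 <- truth$baseline[[tree_id]]
  n <- length(w0)
  yrs <- row$first_year + 0:(n - 1L)
  ry <- which(yrs >= row$release_start & yrs <= row$release_end)
  w_s <- w0
  if (length(ry) && !is.na(row$release_start)) w_s[ry] <- w_s[ry] * row$m_stem
  s0_full <- row$r0_mm + c(0, cumsum(w0))
  s_full <- row$r0_mm + c(0, cumsum(w_s))
  law <- exp(row$alpha0 + row$alpha * log(s0_full) + row$u_tree)
  v <- diff(law)
  if (length(ry) && !is.na(row$release_start)) v[ry] <- v[ry] * row$m_root
  dr_full <- law[1] + c(0, cumsum(v))
  apv <- diff(log(dr_full)) / diff(log(s_full))
  pre <- apv[yrs %in% (row$cutting_year - window):(row$cutting_year - 1L)]
  post <- apv[yrs %in% (row$cutting_year + 1L):(row$cutting_year + window)]
  100 * (mean(post) - mean(pre)) / mean(pre)
}

quantize_dataset <- function(x) {
  x$series <- lapply(x$series, function(s) {
    w <- floor(s$widths * 100 + 0.5) / 100
    w[w == 9.99] <- 9.98   # 999 is the historical sentinel; writers bump it
    ring_series(s$series_id, w, s$first_year, s$tree_id, s$site,
                s$compartment, s$direction, missing = w <= 0)
  })
  x
}

#' Write a synthetic dataset as a plain-text fixture set
#'
#' Emits one Tucson `.rwl` file per site and compartment, a series metadata
#' table (mapping series ids to tree, site, compartment, and direction), a
#' tree table, a site configuration YAML, and the simulation truth as JSON.
#' Widths are quantized to the 0.01 mm measurement resolution on write; the
#' files re-read into exactly the quantized dataset (returned invisibly).
#'
#' @param x An `allorings_dataset` (from [simulate_dataset()]) or a
#'   [sim_config()] to simulate first.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the quantized dataset as written.
#' @seealso [read_fixture_set()]
#' @export
write_fixture_set <- function(x, dir) {
  if (inherits(x, "sim_config")) x <- simulate_dataset(x)
  stopifnot(inherits(x, "allorings_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  q <- quantize_dataset(x)
  meta <- do.call(rbind, lapply(q$series, function(s)
    data.frame(series_id = s$series_id, tree_id = s$tree_id, site = s$site,
               compartment = s$compartment, direction = s$direction,
               stringsAsFactors = FALSE)))
  key <- paste(meta$site, meta$compartment, sep = "_")
  for (k in unique(key)) {
    write_rwl(q$series[meta$series_id[key == k]],
              file.path(dir, paste0(gsub("[^A-Za-z0-9_]", "", k), ".rwl")))
  }
  meta$file <- paste0(gsub("[^A-Za-z0-9_]", "", key), ".rwl")
  utils::write.table(meta, file.path(dir, "series_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_tree_table(q$trees, file.path(dir, "trees.tsv"))
  write_site_config(q$sites, file.path(dir, "sites.yml"))
  if (!is.null(q$truth))
    jsonlite::write_json(list(trees = q$truth$trees,
                              baseline = q$truth$baseline),
                         file.path(dir, "truth.json"), digits = NA)
  invisible(q)
}

#' Read a fixture set written by [write_fixture_set()]
#'
#' @param dir Directory containing `series_meta.tsv`, the `.rwl` files,
#'   `trees.tsv`, `sites.yml`, and optionally `truth.json`.
#' @return An `allorings_dataset`.
#' @export
read_fixture_set <- function(dir) {
  meta <- utils::read.table(file.path(dir, "series_meta.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  series <- list()
  for (f in unique(meta$file)) {
    got <- read_rwl(file.path(dir, f))
    for (sid in names(got)) {
      m <- meta[meta$series_id == sid, ]
      s <- got[[sid]]
      series[[sid]] <- ring_series(sid, s$widths, s$first_year,
                                   m$tree_id, m$site, m$compartment,
                                   m$direction, missing = s$missing)
    }
  }
  series <- series[meta$series_id[meta$series_id %in% names(series)]]
  trees <- read_tree_table(file.path(dir, "trees.tsv"))
  sites <- read_site_config(file.path(dir, "sites.yml"))
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    tj <- jsonlite::read_json(tf, simplifyVector = TRUE)
    truth <- structure(list(trees = tj$trees,
                            baseline = lapply(tj$baseline, as.numeric)),
                       class = "sim_truth")
  }
  structure(list(series = series, trees = trees, sites = sites,
                 truth = truth, config = NULL),
            class = "allorings_dataset")
}
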