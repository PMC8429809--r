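# Core allometric analysis: radius reconstruction, the long-term log-log
# mixed model, annual allometric slopes, PCA, eccentricity correction, and
# the de Martonne aridity index.

#' Reconstruct annual radii from ring widths
#'
#' Radii are reconstructed backward from the measured radius at survey time:
#' the radius at the end of the last ring year equals `final_radius_mm`, and
#' each earlier radius is obtained by subtracting that year's ring width.
#' First differences of the result return the input widths exactly.
#'
#' @param x Tree-level [ring_series] (already averaged over cores).
#' @param final_radius_mm Measured radius at the coring position at survey
#'   time, mm (e.g. half the stem diameter at coring height). Must be at
#'   least the sum of the ring widths.
#' @param compartment Compartment label for the result; defaults to the
#'   series' own (`root_collar` collapses to `root` for allometric use).
#' @return A `radius_series`: fields `tree_id`, `site`, `compartment`,
#'   `years`, `radii_mm` (non-decreasing; last element is
#'   `final_radius_mm`).
#' @export
reconstruct_radii <- function(x, final_radius_mm, compartment = x$compartment) {
  stopifnot(is_ring_series(x))
  total <- sum(x$widths)
  if (final_radius_mm < total - 1e-9)
    stopf("tree '%s' (%s): ring widths sum to %.2f mm > measured radius %.2f mm",
          x$tree_id, x$compartment, total, final_radius_mm,
          class = "allorings_inconsistency_error")
  n <- length(x$widths)
  radii <- final_radius_mm - rev(c(0, cumsum(rev(x$widths))[-n]))
  structure(list(tree_id = x$tree_id, site = x$site,
                 compartment = compartment, years = years(x),
                 radii_mm = radii),
            class = "radius_series")
}

#' @export
print.radius_series <- function(x, ...) {
  cat(sprintf("<radius_series> tree %s %s (%s), %d-%d, %.1f -> %.1f mm\n",
              x$tree_id, x$compartment, x$site, min(x$years), max(x$years),
              x$radii_mm[1], x$radii_mm[length(x$radii_mm)]))
  invisible(x)
}

#' Assemble log-log allometry pairs from radius series
#'
#' Builds the observation table for [fit_allometry()]: one row per tree and
#' year with the log root radius, log stem radius, tree id, and site, over
#' the years both series cover.
#'
#' @param root,stem `radius_series` of the same tree (see
#'   [reconstruct_radii()]).
#' @return Data frame with columns `tree_id`, `site`, `year`, `ln_dr`,
#'   `ln_ds`.
#' @export
allometry_pairs <- function(root, stem) {
  if (root$tree_id != stem$tree_id)
    stopf("root and stem radii belong to different trees (%s vs %s)",
          root$tree_id, stem$tree_id, class = "allorings_integrity_error")
  common <- intersect(root$years, stem$years)
  if (!length(common)) stopf("tree '%s': no overlapping years", root$tree_id)
  dr <- root$radii_mm[match(common, root$years)]
  ds <- stem$radii_mm[match(common, stem$years)]
  ok <- dr > 0 & ds > 0
  data.frame(tree_id = root$tree_id, site = root$site, year = common[ok],
             ln_dr = log(dr[ok]), ln_ds = log(ds[ok]),
             stringsAsFactors = FALSE)
}

#' Fit the long-term allometric model
#'
#' Fits the log-log allometric model of root radius on stem radius,
#' `ln(dr) = alpha0 + alpha * ln(ds) + site + ln(ds):site + b_tree`,
#' by restricted maximum likelihood with a single random intercept per tree.
#' The slope for `ln(ds)` at the reference site is the allometric exponent
#' alpha; each other site's exponent is alpha plus its slope interaction.
#' With a single site the site terms collapse and the model reduces to
#' `ln(dr) ~ ln(ds) + (1 | tree)`.
#'
#' When the residual variance is numerically zero (noise-free data) the REML
#' fit is degenerate; the fixed effects are then recovered exactly from an
#' ordinary least-squares fit with tree intercepts, and the tree-level
#' standard deviation is reported as the spread of those intercepts.
#'
#' @param data Data frame with columns `tree_id`, `site`, `ln_dr`, `ln_ds`
#'   (see [allometry_pairs()]); use stand-interior trees only, since edge
#'   trees do not represent undisturbed long-term growth.
#' @param reference_site Site used as the contrast reference (default: first
#'   in alphabetical order).
#' @return An `allometry_fit` object; see [site_alphas()],
#'   [correct_alpha()], and the `print`, `summary`, `coef`, `predict`
#'   methods.
#' @examples
#' d <- do.call(rbind, lapply(1:6, function(i) {
#'   ds <- 100 + cumsum(runif(30, 1, 3))
#'   data.frame(tree_id = paste0("T", i), site = "A",
#'              ln_ds = log(ds), ln_dr = -11.68 + 4.06 * log(ds))
#' }))
#' fit <- fit_allometry(d)
#' coef(fit)
#' @export
fit_allometry <- function(data, reference_site = NULL) {
  req <- c("tree_id", "site", "ln_dr", "ln_ds")
  if (!all(req %in% names(data)))
    stopf("allometry data needs columns %s", paste(req, collapse = ", "))
  data <- data[is.finite(data$ln_dr) & is.finite(data$ln_ds), ]
  n_trees <- length(unique(data$tree_id))
  if (n_trees < 5L)
    stopf("allometry fit needs at least 5 trees (got %d)", n_trees)
  if (any(table(data$tree_id) < 2L))
    stopf("allometry fit needs >= 2 observations per tree",
          class = "allorings_fit_error")
  sites <- sort(unique(as.character(data$site)))
  if (is.null(reference_site)) reference_site <- sites[1]
  if (!reference_site %in% sites)
    stopf("reference site '%s' not present in the data", reference_site)
  data$site <- stats::relevel(factor(data$site, levels = sites),
                              ref = reference_site)
  data$tree_id <- factor(data$tree_id)
  multi <- length(sites) > 1L

  form <- if (multi) ln_dr ~ ln_ds * site + (1 | tree_id)
          else ln_dr ~ ln_ds + (1 | tree_id)
  mm <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(form, data = data, REML = TRUE))),
    error = function(e) e)
  degenerate <- inherits(mm, "error") ||
    (inherits(mm, "merMod") && stats::sigma(mm) < 1e-6)

  if (!degenerate) {
    fe <- lme4::fixef(mm)
    se <- sqrt(diag(as.matrix(stats::vcov(mm))))
    re_sd <- sqrt(unname(lme4::VarCorr(mm)$tree_id[1]))
    sig <- stats::sigma(mm)
    model <- mm
  } else {
    # zero-residual path: exact OLS with tree intercepts
    f2 <- if (multi) ln_dr ~ 0 + tree_id + ln_ds * site
          else ln_dr ~ 0 + tree_id + ln_ds
    ols <- stats::lm(f2, data = data)
    cf <- stats::coef(ols)
    tr_cf <- cf[grep("^tree_id", names(cf))]
    names(tr_cf) <- sub("^tree_id", "", names(tr_cf))
    site_of <- tapply(as.character(data$site), data$tree_id, `[`, 1)
    ref_trees <- names(site_of)[site_of == reference_site]
    fe <- c("(Intercept)" = mean(tr_cf[ref_trees]),
            cf[setdiff(names(cf), names(cf)[grep("^tree_id", names(cf))])])
    fe <- fe[!is.na(fe)]
    # site offsets: mean tree intercept of each site minus reference
    if (multi) {
      for (s in setdiff(sites, reference_site)) {
        nm <- paste0("site", s)
        fe[nm] <- mean(tr_cf[names(site_of)[site_of == s]]) -
          fe[["(Intercept)"]]
      }
    }
    se <- rep(NA_real_, length(fe)); names(se) <- names(fe)
    re_sd <- stats::sd(tr_cf - stats::ave(tr_cf, site_of[names(tr_cf)]))
    if (!is.finite(re_sd)) re_sd <- 0
    sig <- stats::sigma(ols)
    model <- ols
  }

  alpha0 <- unname(fe[["(Intercept)"]])
  alpha <- unname(fe[["ln_ds"]])
  site_offsets <- stats::setNames(rep(0, length(sites)), sites)
  site_slopes <- stats::setNames(rep(0, length(sites)), sites)
  if (multi) {
    for (s in setdiff(sites, reference_site)) {
      off_nm <- paste0("site", s)
      int_nm <- paste0("ln_ds:site", s)
      if (off_nm %in% names(fe)) site_offsets[s] <- unname(fe[[off_nm]])
      if (int_nm %in% names(fe)) site_slopes[s] <- unname(fe[[int_nm]])
    }
  }
  coef_table <- data.frame(term = names(fe), estimate = unname(fe),
                           std_error = unname(se),
                           t_value = unname(fe) / unname(se),
                           stringsAsFactors = FALSE)
  structure(list(alpha0 = alpha0, alpha = alpha,
                 site_offsets = site_offsets, site_slopes = site_slopes,
                 reference_site = reference_site,
                 random_intercept_sd = re_sd, sigma = sig,
                 n_trees = n_trees, n_obs = nrow(data),
                 coef_table = coef_table, degenerate = degenerate,
                 model = model),
            class = "allometry_fit")
}

#' Construct an allometry fit from known coefficients
#'
#' Builds an `allometry_fit` object directly from published or simulated
#' coefficients (reference-site intercept and slope plus per-site offsets
#' and slope interactions), so that downstream summaries such as
#' [site_alphas()] and [correct_alpha()] can be applied to reported models.
#'
#' @param alpha0 Intercept (allometric factor, log-mm scale) at the
#'   reference site.
#' @param alpha Allometric exponent (slope for `ln(ds)`) at the reference
#'   site.
#' @param site_offsets,site_slopes Named numeric vectors of per-site
#'   intercept shifts and slope interactions (reference site 0, may be
#'   omitted).
#' @param reference_site Name of the reference site.
#' @return An `allometry_fit` (without a fitted model object).
#' @export
allometry_fit <- function(alpha0, alpha, site_offsets = numeric(0),
                          site_slopes = numeric(0),
                          reference_site = "reference") {
  sites <- union(reference_site, union(names(site_offsets),
                                       names(site_slopes)))
  off <- stats::setNames(rep(0, length(sites)), sites)
  slp <- stats::setNames(rep(0, length(sites)), sites)
  off[names(site_offsets)] <- site_offsets
  slp[names(site_slopes)] <- site_slopes
  structure(list(alpha0 = alpha0, alpha = alpha, site_offsets = off,
                 site_slopes = slp, reference_site = reference_site,
                 random_intercept_sd = NA_real_, sigma = NA_real_,
                 n_trees = NA_integer_, n_obs = NA_integer_,
                 coef_table = NULL, degenerate = FALSE, model = NULL),
            class = "allometry_fit")
}

#' Per-site allometric exponents
#'
#' @param fit An `allometry_fit`.
#' @return Named vector: each site's exponent, i.e. the reference slope plus
#'   that site's slope interaction.
#' @export
site_alphas <- function(fit) {
  stopifnot(inherits(fit, "allometry_fit"))
  fit$alpha + fit$site_slopes
}

#' Correct allometric exponents for root cross-section eccentricity
#'
#' Main roots grow eccentrically: radii measured from cores taken at the top
#' of the root overestimate the mean cross-sectional radius (upper radii can
#' average some 40 percent wider than the disk mean). Exponents estimated
#' from such cores are divided by an overestimation factor, 1.90 by default.
#'
#' @param x A numeric exponent (or vector) or an `allometry_fit`.
#' @param factor Positive overestimation factor (default 1.90).
#' @return Corrected exponent(s); for a fit, the corrected per-site vector.
#' @export
correct_alpha <- function(x, factor = 1.90) {
  if (!is.numeric(factor) || factor <= 0)
    stopf("eccentricity factor must be positive",
          class = "allorings_domain_error")
  if (inherits(x, "allometry_fit")) return(site_alphas(x) / factor)
  x / factor
}

#' @export
coef.allometry_fit <- function(object, ...) {
  if (!is.null(object$coef_table))
    stats::setNames(object$coef_table$estimate, object$coef_table$term)
  else c("(Intercept)" = object$alpha0, ln_ds = object$alpha)
}

#' @export
print.allometry_fit <- function(x, digits = 3, ...) {
  cat("Long-term root-shoot allometry (log-log mixed model)\n")
  cat(sprintf("  reference site: %s; %s trees, %s observations\n",
              x$reference_site, x$n_trees, x$n_obs))
  if (!is.null(x$coef_table)) {
    tab <- x$coef_table
    tab$estimate <- round(tab$estimate, digits)
    tab$std_error <- round(tab$std_error, digits)
    tab$t_value <- round(tab$t_value, 2)
    print(tab, row.names = FALSE)
  }
  cat(sprintf("  tree-level sd %.3f, residual sd %.3f%s\n",
              x$random_intercept_sd, x$sigma,
              if (x$degenerate) " (degenerate residual variance)" else ""))
  cat("  per-site alpha:\n")
  print(round(site_alphas(x), digits))
  invisible(x)
}

#' @export
summary.allometry_fit <- function(object, eccentricity_factor = 1.90, ...) {
  out <- list(coef_table = object$coef_table,
              site_alpha = site_alphas(object),
              site_alpha_corrected = correct_alpha(object,
                                                   eccentricity_factor),
              eccentricity_factor = eccentricity_factor,
              random_intercept_sd = object$random_intercept_sd,
              sigma = object$sigma, n_trees = object$n_trees,
              n_obs = object$n_obs)
  class(out) <- "summary.allometry_fit"
  out
}

#' @export
print.summary.allometry_fit <- function(x, ...) {
  print(x$coef_table, row.names = FALSE)
  cat("per-site alpha (raw):      ")
  cat(sprintf("%s=%.2f", names(x$site_alpha), x$site_alpha), sep = "  ")
  cat(sprintf("\nper-site alpha (/%.2f):    ", x$eccentricity_factor))
  cat(sprintf("%s=%.2f", names(x$site_alpha_corrected),
              x$site_alpha_corrected), sep = "  ")
  cat("\n")
  invisible(x)
}

#' @export
predict.allometry_fit <- function(object, newdata,
                                  type = c("link", "response"), ...) {
  type <- match.arg(type)
  site <- as.character(newdata$site %||% object$reference_site)
  ln_ds <- newdata$ln_ds %||% log(newdata$ds_mm)
  eta <- object$alpha0 + object$site_offsets[site] +
    (object$alpha + object$site_slopes[site]) * ln_ds
  eta <- unname(eta)
  if (type == "response") exp(eta) else eta
}

#' Annual allometric slope series
#'
#' The short-term (annual) allometric slope is
#' `alpha'_i = ln(dr_i / dr_(i-1)) / ln(ds_i / ds_(i-1))`:
#' the ratio of the relative radial growth of the root to that of the stem in
#' year i, computed from raw (non-detrended) reconstructed radii. It equals
#' the long-term exponent when growth follows the allometric law exactly and
#' 1.0 when root and stem grow at the same relative rate (steady state).
#' Years in which either compartment has a zero increment (e.g. a missing
#' ring) are flagged invalid: the slope is undefined (zero stem increment)
#' or degenerate there. The statistic is invariant to a common rescaling of
#' both radius series.
#'
#' @param root,stem `radius_series` of one tree with at least 2 overlapping
#'   years.
#' @return An `alpha_prime_series` data frame: `tree_id`, `year`,
#'   `alpha_prime` (NA where invalid), `valid`.
#' @export
alpha_prime <- function(root, stem) {
  common <- intersect(root$years, stem$years)
  if (length(common) < 2L)
    stopf("tree '%s': fewer than 2 overlapping years", root$tree_id,
          class = "allorings_insufficient_error")
  common <- sort(common)
  dr <- root$radii_mm[match(common, root$years)]
  ds <- stem$radii_mm[match(common, stem$years)]
  d_ldr <- diff(log(dr))
  d_lds <- diff(log(ds))
  inc_r <- diff(dr); inc_s <- diff(ds)
  valid <- inc_r > 0 & inc_s > 0 & is.finite(d_ldr) & is.finite(d_lds)
  ap <- ifelse(valid, d_ldr / d_lds, NA_real_)
  out <- data.frame(tree_id = root$tree_id, year = common[-1],
                    alpha_prime = ap, valid = valid,
                    stringsAsFactors = FALSE)
  class(out) <- c("alpha_prime_series", class(out))
  out
}

#' Percentage change in allometric slope around a cutting year
#'
#' Summarizes an annual allometric slope series into the pre-cutting mean
#' `Ap` (the `window` years strictly before the cutting year), the
#' post-cutting mean `Aa` (the `window` years strictly after it), and
#' `PCA = 100 * (Aa - Ap) / Ap`. Positive PCA indicates enhanced allocation
#' to roots relative to stems after the intervention. Invalid years are
#' dropped from the window means, as are slopes beyond `winsor_bound` in
#' magnitude (ratio statistics explode when a stem increment is near zero);
#' at least `min_years` usable values are required in each window.
#'
#' @param ap An `alpha_prime_series` (see [alpha_prime()]).
#' @param cutting_year Year of the intervention (excluded from both
#'   windows; set `include_cutting_year = TRUE` to add it to the post
#'   window).
#' @param window Window length in years (default 10).
#' @param min_years Minimum usable values per window (default 5).
#' @param winsor_bound Drop slopes with `|alpha'|` above this bound
#'   (default 50; `Inf` disables).
#' @param include_cutting_year Include the cutting year in the post window?
#' @return A `pca_result` list: `tree_id`, `Ap`, `Aa`, `pca_pct`,
#'   `n_valid_pre`, `n_valid_post`.
#' @export
pca_statistic <- function(ap, cutting_year, window = 10L, min_years = 5L,
                          winsor_bound = 50, include_cutting_year = FALSE) {
  usable <- ap$valid & is.finite(ap$alpha_prime) &
    abs(ap$alpha_prime) <= winsor_bound
  pre_years <- (cutting_year - window):(cutting_year - 1L)
  post_start <- if (include_cutting_year) cutting_year else cutting_year + 1L
  post_years <- post_start:(cutting_year + window)
  pre <- ap$alpha_prime[usable & ap$year %in% pre_years]
  post <- ap$alpha_prime[usable & ap$year %in% post_years]
  if (length(pre) < min_years || length(post) < min_years)
    stopf("tree '%s': fewer than %d valid alpha' years in a window (pre %d, post %d)",
          ap$tree_id[1], min_years, length(pre), length(post),
          class = "allorings_insufficient_error")
  Ap <- mean(pre); Aa <- mean(post)
  if (Ap == 0)
    stopf("tree '%s': PCA undefined, pre-cutting mean slope is zero",
          ap$tree_id[1], class = "allorings_undefined_error")
  structure(list(tree_id = ap$tree_id[1], Ap = Ap, Aa = Aa,
                 pca_pct = 100 * (Aa - Ap) / Ap,
                 n_valid_pre = length(pre), n_valid_post = length(post)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> tree %s: Ap %.3f (n=%d), Aa %.3f (n=%d), PCA %+.1f%%\n",
              x$tree_id, x$Ap, x$n_valid_pre, x$Aa, x$n_valid_post,
              x$pca_pct))
  invisible(x)
}

#' De Martonne aridity index
#'
#' `DMI = Pr / (Ta + 10)` from the annual precipitation sum (mm) and annual
#' mean air temperature (deg C). Higher values indicate moister sites; the
#' conventional classification is attached (`"arid"` below 10 up to
#' `"excessively humid"` at 60 and above).
#'
#' @param annual_pr_mm Annual precipitation sum, mm.
#' @param annual_ta_c Annual mean air temperature, deg C (must exceed -10).
#' @param site Optional site label(s).
#' @return Data frame with `site`, `annual_ta_c`, `annual_pr_mm`, `dmi`,
#'   `dmi_class`.
#' @examples
#' de_martonne(1290, 3.5)  # dmi 95.6 -> "excessively humid"
#' @export
de_martonne <- function(annual_pr_mm, annual_ta_c, site = NA_character_) {
  if (any(annual_ta_c <= -10))
    stopf("de Martonne index undefined for Ta <= -10 deg C",
          class = "allorings_domain_error")
  dmi <- annual_pr_mm / (annual_ta_c + 10)
  cls <- cut(dmi, c(-Inf, 10, 20, 24, 28, 35, 60, Inf),
             labels = c("arid", "semi-arid", "mediterranean", "semi-humid",
                        "humid", "very humid", "excessively humid"),
             right = FALSE)
  data.frame(site = site, annual_ta_c = annual_ta_c,
             annual_pr_mm = annual_pr_mm, dmi = dmi,
             dmi_class = as.character(cls), stringsAsFactors = FALSE)
}
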