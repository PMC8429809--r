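# Explaining the per-tree PCA by tree size, edge position, and site:
# Cook's-distance outlier screening, OLS with backward AIC selection
# respecting marginality, and per-site rank-sum comparisons.

pca_full_formula <- function(data) {
  multi_site <- length(unique(data$site)) > 1L
  if (multi_site)
    pca_pct ~ rp_cm + position + site + position:rp_cm + position:site
  else
    pca_pct ~ rp_cm + position + position:rp_cm
}

#' Cook's-distance outlier screening for the PCA model
#'
#' Fits the full PCA response model (size, position, site, and their
#' position interactions) once and removes observations whose Cook's
#' distance exceeds `8 / N`, where `N` is the number of rows. A single pass:
#' the screen is applied to the initial full model only, and the model is
#' refitted afterwards without iteration.
#'
#' @param data Data frame with columns `tree_id`, `site`, `position`
#'   (factor/character, `"edge"` or `"interior"`), `rp_cm` (stem radius
#'   prior to cutting, cm), `pca_pct`.
#' @param threshold Exclusion threshold; default `8 / nrow(data)`.
#' @return List with `data` (filtered rows) and `excluded` (data frame of
#'   `tree_id`, `cooks_d` for removed rows; zero rows when none).
#' @export
cooks_outlier_filter <- function(data, threshold = NULL) {
  n <- nrow(data)
  if (is.null(threshold)) threshold <- 8 / n
  form <- pca_full_formula(data)
  p <- length(attr(stats::terms(form), "term.labels")) + 1L
  if (n <= p)
    stopf("need more observations (%d) than model parameters (%d)", n, p,
          class = "allorings_fit_error")
  fit <- stats::lm(form, data = data)
  if (any(is.na(stats::coef(fit))))
    stopf("rank-deficient design in the full PCA model",
          class = "allorings_fit_error")
  cd <- stats::cooks.distance(fit)
  # a (numerically) zero-residual fit carries no influence information
  if (!is.finite(stats::sigma(fit)) ||
      stats::sigma(fit)^2 < 1e-10 * stats::var(data$pca_pct))
    cd[] <- 0
  cd[!is.finite(cd)] <- 0
  out <- cd > threshold
  list(data = data[!out, , drop = FALSE],
       excluded = data.frame(tree_id = data$tree_id[out],
                             cooks_d = unname(cd[out]),
                             stringsAsFactors = FALSE),
       threshold = threshold)
}

#' Fit the PCA response model with backward AIC selection
#'
#' Ordinary least squares on the full term set
#' `PCA ~ Rp + position + site + position:Rp + position:site`
#' followed by backward stepwise elimination: at each step the term whose
#' removal most lowers the AIC is dropped (interactions before their main
#' effects, so marginality is never violated), until no removal lowers AIC.
#' Apply [cooks_outlier_filter()] beforehand to reproduce the screened fit.
#'
#' @param data Data frame as in [cooks_outlier_filter()] (at least 10 rows;
#'   both positions present).
#' @param select Run the backward elimination? `FALSE` keeps the full model.
#' @param excluded Optional exclusion record from [cooks_outlier_filter()],
#'   carried into the result for reporting.
#' @return A `pca_response` object with the fitted `lm`, a Table-style
#'   coefficient table, `r_squared`, `retained_terms`, and `aic`.
#' @export
fit_pca_model <- function(data, select = TRUE, excluded = NULL) {
  if (nrow(data) < 10L)
    stopf("PCA response model needs at least 10 trees")
  if (length(unique(data$position)) < 2L)
    stopf("PCA response model needs both edge and interior trees")
  data$position <- stats::relevel(factor(data$position), ref = "interior")
  data$site <- factor(data$site)
  full <- stats::lm(pca_full_formula(data), data = data)
  fit <- if (select)
    MASS::stepAIC(full, direction = "backward", trace = 0)
  else full
  sm <- suppressWarnings(summary(fit))
  ct <- stats::coef(sm)
  coef_table <- data.frame(term = rownames(ct), estimate = ct[, 1],
                           std_error = ct[, 2], t_value = ct[, 3],
                           p_value = ct[, 4], stringsAsFactors = FALSE,
                           row.names = NULL)
  structure(list(model = fit, full_model = full,
                 retained_terms = attr(stats::terms(fit), "term.labels"),
                 coef_table = coef_table, r_squared = sm$r.squared,
                 aic = stats::AIC(fit), n = nrow(data),
                 excluded = excluded %||%
                   data.frame(tree_id = character(0), cooks_d = numeric(0))),
            class = "pca_response")
}

#' @export
print.pca_response <- function(x, digits = 2, ...) {
  cat("PCA response model (OLS, backward AIC selection)\n")
  cat(sprintf("  n = %d, R^2 = %.2f, AIC = %.1f\n", x$n, x$r_squared,
              x$aic))
  if (nrow(x$excluded))
    cat(sprintf("  excluded by Cook's distance: %s\n",
                paste(x$excluded$tree_id, collapse = ", ")))
  tab <- x$coef_table
  tab$estimate <- round(tab$estimate, digits)
  tab$std_error <- round(tab$std_error, digits)
  tab$t_value <- round(tab$t_value, 2)
  tab$p_value <- signif(tab$p_value, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pca_response <- function(object, ...) stats::coef(object$model)

#' @export
summary.pca_response <- function(object, ...) summary(object$model, ...)

#' Rank-sum comparison of edge vs interior PCA per site
#'
#' Two-sided Wilcoxon rank-sum test of the per-tree PCA between edge and
#' stand-interior trees within each site. The exact null distribution is
#' used when both groups have at most 10 observations and there are no
#' ties; otherwise the normal approximation with continuity correction.
#' Sites with fewer than 3 trees in either group are skipped (with a
#' message).
#'
#' @param data Data frame with columns `site`, `position`, `pca_pct`.
#' @return Data frame: `site`, `statistic` (rank-sum W for the edge group),
#'   `p_value`, `n_edge`, `n_interior`, `method`.
#' @export
wilcoxon_edge_vs_interior <- function(data) {
  rows <- lapply(split(data, data$site), function(g) {
    e <- g$pca_pct[g$position == "edge"]
    i <- g$pca_pct[g$position == "interior"]
    if (length(e) < 3L || length(i) < 3L) {
      message(sprintf("site '%s' skipped: fewer than 3 trees per group",
                      g$site[1]))
      return(NULL)
    }
    ties <- anyDuplicated(c(e, i)) > 0
    exact <- length(e) <= 10L && length(i) <= 10L && !ties
    if (length(unique(c(e, i))) == 1L) {
      # fully tied data: the statistic sits at the null centre
      wt <- list(statistic = length(e) * length(i) / 2, p.value = 1)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(e, i, exact = exact,
                                                correct = TRUE))
    }
    data.frame(site = g$site[1], statistic = unname(wt$statistic),
               p_value = wt$p.value, n_edge = length(e),
               n_interior = length(i),
               method = if (exact) "exact" else "normal approx.",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
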