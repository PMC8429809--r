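test_that("radius reconstruction works backward from the survey radius", {
  r <- make_radii(c(1, 2, 3), final = 10)
  expect_equal(r$radii_mm, c(5, 7, 10))
  expect_equal(diff(r$radii_mm), c(2, 3))          # first differences = widths

  r0 <- make_radii(rep(0, 5), final = 4)
  expect_equal(r0$radii_mm, rep(4, 5))

  expect_error(make_radii(c(1, 2, 3), final = 5),
               class = "allorings_inconsistency_error")
})

test_that("radius reconstruction then differencing returns the widths", {
  set.seed(8)
  w <- round(runif(47, 0, 3), 2)
  r <- make_radii(w, final = sum(w) + 30)
  expect_equal(diff(r$radii_mm), w[-1])
  expect_equal(r$radii_mm[length(w)], sum(w) + 30)
})

test_that("noise-free single-site data recover the generating law exactly", {
  d <- law_pairs(alpha0 = -11.68, alpha = 4.06, n_trees = 8, n_years = 40)
  fit <- fit_allometry(d)
  expect_equal(fit$alpha, 4.06, tolerance = 1e-6)
  expect_equal(fit$alpha0, -11.68, tolerance = 1e-6)

  # dr == ds for every observation -> slope 1, intercept 0
  d2 <- law_pairs(alpha0 = 0, alpha = 1, n_trees = 6)
  fit2 <- fit_allometry(d2)
  expect_equal(fit2$alpha, 1.0, tolerance = 1e-8)
  expect_equal(fit2$alpha0, 0.0, tolerance = 1e-8)
})

test_that("two-site fits recover per-site slopes and the interaction", {
  set.seed(77)
  mk_site <- function(site, alpha, n = 20) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      ds <- 150 * exp(cumsum(runif(47, 0.004, 0.012)))
      u <- rnorm(1, 0, 0.15)
      eta <- as.numeric(arima.sim(list(ar = 0.9), 47, sd = sqrt(1 - 0.9^2))) * 0.1
      data.frame(tree_id = sprintf("%s%02d", site, i), site = site,
                 ln_ds = log(ds),
                 ln_dr = -11.68 + alpha * log(ds) + u + eta)
    }))
  }
  d <- rbind(mk_site("Furna", 4.06), mk_site("SurEn", 2.60))
  fit <- fit_allometry(d, reference_site = "Furna")
  alphas <- site_alphas(fit)
  expect_equal(unname(alphas["Furna"]), 4.06, tolerance = 0.1)
  expect_equal(unname(alphas["SurEn"]), 2.60, tolerance = 0.1)
  expect_equal(unname(fit$site_slopes["SurEn"]), -1.46, tolerance = 0.15)
  expect_gt(fit$random_intercept_sd, 0.05)
  expect_s4_class(fit$model, "lmerMod")
})

test_that("allometry fit validates its inputs", {
  d <- law_pairs(-10, 3, n_trees = 3)
  expect_error(fit_allometry(d), "at least 5 trees")
  d5 <- law_pairs(-10, 3, n_trees = 5, n_years = 1)
  expect_error(fit_allometry(d5), class = "allorings_fit_error")
  expect_error(fit_allometry(law_pairs(-10, 3), reference_site = "nope"),
               "not present")
})

test_that("published coefficients can be wrapped and corrected", {
  fit <- allometry_fit(
    alpha0 = -11.68, alpha = 4.06,
    site_offsets = c(Siat = 2.04, SurEn = 5.74),
    site_slopes = c(Siat = -0.52, SurEn = -1.46),
    reference_site = "Furna")
  expect_equal(unname(site_alphas(fit)["SurEn"]), 2.60)
  corrected <- correct_alpha(fit, 1.90)
  expect_equal(round(unname(corrected), 2),
               c(2.14, 1.86, 1.37), ignore_attr = TRUE)
  expect_equal(correct_alpha(4.06, 1), 4.06)
  expect_error(correct_alpha(4.06, 0), class = "allorings_domain_error")
  # predict on the response scale inverts the log-log link
  p <- predict(fit, data.frame(ds_mm = 200, site = "Furna"),
               type = "response")
  expect_equal(log(p), -11.68 + 4.06 * log(200))
})

test_that("alpha' follows its closed form and flags zero increments", {
  stem <- make_radii(c(100, 5), final = 105)
  root <- make_radii(c(100, 10), final = 110, compartment = "root")
  ap <- alpha_prime(root, stem)
  expect_equal(ap$alpha_prime, log(1.1) / log(1.05), tolerance = 1e-12)
  expect_equal(round(ap$alpha_prime, 4), 1.9535)

  # equal relative growth -> exactly 1 (steady state)
  stem <- make_radii(c(100, 10), final = 110)
  root <- make_radii(c(200, 20), final = 220, compartment = "root")
  expect_equal(alpha_prime(root, stem)$alpha_prime, 1.0)

  # zero stem increment -> invalid year, no value
  stem <- make_radii(c(100, 0, 5), final = 105)
  root <- make_radii(c(100, 4, 6), final = 110, compartment = "root")
  ap <- alpha_prime(root, stem)
  expect_false(ap$valid[1])
  expect_true(is.na(ap$alpha_prime[1]))
  expect_true(ap$valid[2])

  expect_error(alpha_prime(make_radii(1, final = 10),
                           make_radii(1, final = 10)),
               class = "allorings_insufficient_error")
})

test_that("alpha' is invariant to a common unit rescaling", {
  set.seed(12)
  w_s <- runif(30, 0.5, 3); w_r <- runif(30, 0.2, 2)
  stem <- make_radii(w_s, final = sum(w_s) + 50)
  root <- make_radii(w_r, final = sum(w_r) + 20, compartment = "root")
  scale_radii <- function(r, c) { r$radii_mm <- r$radii_mm * c; r }
  a1 <- alpha_prime(root, stem)$alpha_prime
  a2 <- alpha_prime(scale_radii(root, 10), scale_radii(stem, 10))$alpha_prime
  expect_equal(a1, a2)
})

test_that("PCA summarizes pre/post windows as defined", {
  mk_ap <- function(vals, years) {
    out <- data.frame(tree_id = "T1", year = years, alpha_prime = vals,
                      valid = is.finite(vals))
    class(out) <- c("alpha_prime_series", class(out))
    out
  }
  yrs <- 1990:2014
  ap <- mk_ap(c(rep(1.0, 14), NA, rep(1.5, 10)), yrs)  # cutting year 2004
  pc <- pca_statistic(ap, 2004)
  expect_equal(pc$Ap, 1.0)
  expect_equal(pc$Aa, 1.5)
  expect_equal(pc$pca_pct, 50.0)
  expect_equal(pc$n_valid_pre, 10)

  expect_equal(pca_statistic(mk_ap(rep(1.2, 25), yrs), 2004)$pca_pct, 0)
  pc2 <- pca_statistic(mk_ap(c(rep(1.2, 15), rep(0.9, 10)), yrs), 2004)
  expect_equal(pc2$pca_pct, -25.0)

  # swapping windows gives 100*(Ap-Aa)/Aa, not -PCA
  swapped <- pca_statistic(mk_ap(c(rep(0.9, 15), rep(1.2, 10)), yrs), 2004)
  expect_equal(swapped$pca_pct, 100 * (1.2 - 0.9) / 0.9)
  expect_false(isTRUE(all.equal(swapped$pca_pct, -pc2$pca_pct)))

  # winsorization drops exploding ratios from the window means
  v <- rep(1, 25); v[20] <- 80
  expect_equal(pca_statistic(mk_ap(v, yrs), 2004)$pca_pct, 0)
  expect_equal(pca_statistic(mk_ap(v, yrs), 2004,
                             winsor_bound = Inf)$n_valid_post, 10)

  expect_error(pca_statistic(mk_ap(c(rep(NA, 11), rep(1, 14)), yrs), 2004),
               class = "allorings_insufficient_error")
})

test_that("de Martonne indices and humidity classes are computed", {
  dm <- de_martonne(c(1290, 809, 0), c(3.5, 4.2, 5.0))
  expect_equal(round(dm$dmi), c(96, 57, 0))
  expect_equal(dm$dmi[1], 1290 / 13.5, tolerance = 1e-12)
  expect_equal(dm$dmi_class[1:2], c("excessively humid", "very humid"))
  expect_error(de_martonne(500, -12), class = "allorings_domain_error")
})
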