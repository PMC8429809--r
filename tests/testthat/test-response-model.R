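# Independent oracles (normal equations, direct Cook's formula, Wilcoxon
# enumeration) live in helper-oracles.R.

test_that("Cook's screening matches the direct formula and the 8/N rule", {
  d <- mk_pca_data(41)
  # plant one gross outlier on otherwise planar data
  d$pca_pct <- -60 + 120 * (d$position == "edge") + 1.4 * d$rp_cm +
    rnorm(41, 0, 3)
  d$pca_pct[17] <- d$pca_pct[17] + 10 * 20
  out <- cooks_outlier_filter(d)
  expect_equal(out$excluded$tree_id, "T17")
  expect_equal(out$threshold, 8 / 41)

  X <- model.matrix(~ rp_cm + position + rp_cm:position, d)
  cd <- cooks_direct(X, d$pca_pct)
  fit <- lm(pca_pct ~ rp_cm + position + rp_cm:position, d)
  expect_equal(unname(cooks.distance(fit)), cd, tolerance = 1e-10)
  expect_equal(which(cd > 8 / 41), 17L)

  # zero-residual data: all Cook's distances 0, nothing excluded
  d2 <- mk_pca_data(30)
  d2$pca_pct <- 5 + 2 * d2$rp_cm
  expect_equal(nrow(cooks_outlier_filter(d2)$excluded), 0)

  # removal of the gross outlier improves the refit
  r2_before <- summary(lm(pca_pct ~ rp_cm + position + rp_cm:position,
                          d))$r.squared
  refit <- fit_pca_model(out$data, select = FALSE)
  expect_gt(refit$r_squared, r2_before)
})

test_that("forced full model equals the normal-equations solution", {
  d <- mk_pca_data(36, seed = 8, sites = c("A", "B", "C"))
  fit <- fit_pca_model(d, select = FALSE)
  X <- model.matrix(~ rp_cm + position + site + position:rp_cm +
                      position:site,
                    transform(d, position = relevel(factor(position),
                                                    "interior"),
                              site = factor(site)))
  beta <- normal_eq_coef(X, d$pca_pct)
  expect_equal(unname(coef(fit)), as.numeric(beta), tolerance = 1e-8)

  # noise-free planar data -> perfect fit
  d2 <- mk_pca_data(30)
  d2$pca_pct <- -10 + 3 * d2$rp_cm + 25 * (d2$position == "edge")
  expect_equal(fit_pca_model(d2, select = FALSE)$r_squared, 1.0,
               tolerance = 1e-12)
})

test_that("backward selection recovers the generating term structure", {
  set.seed(101)
  n <- 70
  res <- replicate(20, {
    d <- data.frame(tree_id = sprintf("T%02d", 1:n),
                    site = sample(c("A", "B", "C"), n, TRUE),
                    position = rep(c("edge", "interior"), length.out = n),
                    rp_cm = runif(n, 10, 35), stringsAsFactors = FALSE)
    edge <- d$position == "edge"
    d$pca_pct <- -60 + 127 * edge + 1.4 * d$rp_cm - 4 * edge * d$rp_cm +
      rnorm(n, 0, 20)
    fit <- fit_pca_model(d)
    cf <- coef(fit)
    c(pos = "position" %in% fit$retained_terms,
      inter = "rp_cm:position" %in% fit$retained_terms,
      site_dropped = !any(grepl("site", fit$retained_terms)),
      signs = cf[["positionedge"]] > 0 && cf[["rp_cm:positionedge"]] < 0)
  })
  # the generating terms are always found; the null site factor is dropped
  # in the clear majority of replicates (AIC retains a spurious multi-df
  # term with small but non-zero probability)
  expect_equal(mean(res["pos", ]), 1)
  expect_equal(mean(res["inter", ]), 1)
  expect_equal(mean(res["signs", ]), 1)
  expect_gte(mean(res["site_dropped", ]), 0.7)
})

test_that("selection respects marginality and shrinks pure-noise models", {
  set.seed(202)
  keep_rate <- mean(replicate(60, {
    d <- mk_pca_data(100, seed = sample.int(1e6, 1))
    fit <- fit_pca_model(d)
    # marginality: no interaction without both main effects
    rt <- fit$retained_terms
    if ("rp_cm:position" %in% rt)
      expect_true(all(c("rp_cm", "position") %in% rt))
    if ("position:site" %in% rt)
      expect_true(all(c("position", "site") %in% rt))
    length(rt) == 0
  }))
  # AIC keeps each spurious term with probability ~P(chisq > 2*df), so the
  # intercept-only model is the single most common outcome (~60%), never a
  # rarity
  expect_gte(keep_rate, 0.4)
})

test_that("rank-sum comparisons match full enumeration and edge cases", {
  d <- data.frame(site = "A",
                  position = rep(c("edge", "interior"), each = 3),
                  pca_pct = c(1, 2, 3, 4, 5, 6))
  out <- wilcoxon_edge_vs_interior(d)
  expect_equal(out$p_value, 0.1)      # most extreme of C(6,3)=20, two-sided
  expect_equal(out$p_value, wilcox_exact_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(out$method, "exact")

  set.seed(33)
  for (i in 1:20) {
    a <- round(rnorm(sample(3:8, 1)), 3)
    b <- round(rnorm(sample(3:8, 1)), 3)
    d <- data.frame(site = "A",
                    position = rep(c("edge", "interior"),
                                   c(length(a), length(b))),
                    pca_pct = c(a, b))
    expect_equal(wilcoxon_edge_vs_interior(d)$p_value,
                 wilcox_exact_p(a, b), tolerance = 1e-12)
  }

  # identical values in both groups: statistic at the null centre, p = 1
  d <- data.frame(site = "A", position = rep(c("edge", "interior"), 5),
                  pca_pct = rep(2, 10))
  out <- wilcoxon_edge_vs_interior(d)
  expect_equal(out$p_value, 1)
  expect_equal(out$method, "normal approx.")

  # too-small groups are skipped with a message
  d <- data.frame(site = c(rep("A", 10), rep("B", 4)),
                  position = c(rep(c("edge", "interior"), 5),
                               "edge", rep("interior", 3)),
                  pca_pct = rnorm(14))
  expect_message(out <- wilcoxon_edge_vs_interior(d), "skipped")
  expect_equal(out$site, "A")
})

test_that("a shifted edge group is detected with high power", {
  set.seed(44)
  rejections <- mean(replicate(200, {
    e <- rnorm(15, 2, 1)
    i <- rnorm(15, 0, 1)
    d <- data.frame(site = "A",
                    position = rep(c("edge", "interior"), each = 15),
                    pca_pct = c(e, i))
    wilcoxon_edge_vs_interior(d)$p_value < 0.05
  }))
  expect_gte(rejections, 0.9)
})
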