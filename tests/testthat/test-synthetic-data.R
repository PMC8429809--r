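test_that("simulation is a deterministic function of its configuration", {
  cfg <- sim_config(seed = 99)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$series, d2$series)
  expect_identical(d1$trees, d2$trees)
  expect_identical(d1$truth$trees, d2$truth$trees)
  d3 <- simulate_dataset(sim_config(seed = 100))
  expect_false(identical(d1$series, d3$series))
})

test_that("default dataset matches the intended study scale", {
  d <- simulate_dataset(sim_config(seed = 1))
  expect_equal(nrow(d$sites), 3)
  expect_equal(nrow(d$trees), 71)
  s <- d$series[[1]]
  expect_equal(years(s), 1970:2016)
  expect_length(s$widths, 47)
  comp <- vapply(d$series, `[[`, character(1), "compartment")
  expect_setequal(unique(comp), c("stem", "root_collar", "root"))
  # root-biased release: generator invariant on the multipliers
  tt <- d$truth$trees
  expect_true(all(tt$m_root >= tt$m_stem))
  expect_true(all(tt$m_stem[tt$position == "interior"] == 1))
})

test_that("noise-free limit: alpha' equals the configured exponent everywhere", {
  d <- simulate_dataset(noise_free_config(seed = 2))
  set.seed(1)
  for (id in sample(d$trees$tree_id, 8)) {
    tr <- d$trees[d$trees$tree_id == id, ]
    truth <- d$truth$trees[d$truth$trees$tree_id == id, ]
    stems <- Filter(function(s) s$tree_id == id & s$compartment == "stem",
                    d$series)
    roots <- Filter(function(s) s$tree_id == id & s$compartment == "root",
                    d$series)
    stem <- reconstruct_radii(average_within_tree(stems), tr$ds_cm * 5)
    root <- reconstruct_radii(average_within_tree(roots), tr$root_d_cm * 5)
    ap <- alpha_prime(root, stem)
    expect_equal(ap$alpha_prime[ap$valid], rep(truth$alpha, sum(ap$valid)),
                 tolerance = 1e-9)
    # interior trees: PCA exactly zero in the noise-free limit
    if (tr$position == "interior") {
      pc <- pca_statistic(ap, truth$cutting_year)
      expect_equal(pc$pca_pct, 0, tolerance = 1e-9)
      expect_equal(expected_pca(d$truth, id), 0, tolerance = 1e-9)
    }
  }
})

test_that("analytic expected PCA matches the pipeline on noise-free data", {
  cfg <- noise_free_config(seed = 3)
  cfg$release$stem_gain <- 0.0
  cfg$release$root_gain <- 0.3
  cfg$release$size_slope <- 0           # uniform multipliers
  d <- simulate_dataset(cfg)
  edge_ids <- d$trees$tree_id[d$trees$position == "edge"]
  set.seed(1)
  for (id in sample(edge_ids, 6)) {
    tr <- d$trees[d$trees$tree_id == id, ]
    truth <- d$truth$trees[d$truth$trees$tree_id == id, ]
    stem <- reconstruct_radii(average_within_tree(
      Filter(function(s) s$tree_id == id & s$compartment == "stem",
             d$series)), tr$ds_cm * 5)
    root <- reconstruct_radii(average_within_tree(
      Filter(function(s) s$tree_id == id & s$compartment == "root",
             d$series)), tr$root_d_cm * 5)
    pc <- pca_statistic(alpha_prime(root, stem), truth$cutting_year)
    expect_equal(pc$pca_pct, expected_pca(d$truth, id), tolerance = 1e-6)
    expect_gt(pc$pca_pct, 0)   # root-biased release
  }
  expect_error(expected_pca(d$truth, "nope"),
               class = "allorings_lookup_error")
})

test_that("missing-ring bookkeeping matches the configured rate", {
  sites <- sim_site_defaults()[1, ]
  sites$n_edge <- 0L
  sites$n_interior <- 220L          # >= 10,000 root tree-years
  cfg <- noise_free_config(seed = 4, sites = sites)
  cfg$missing_ring_rate <- 0.015
  cfg$cores$root_interior <- 1L
  d <- simulate_dataset(cfg)
  roots <- Filter(function(s) s$compartment == "root", d$series)
  n_rings <- sum(vapply(roots, function(s) length(s$widths), numeric(1)))
  n_missing <- sum(vapply(roots, function(s) sum(s$missing), numeric(1)))
  expect_gte(n_rings, 10000)
  rate <- n_missing / n_rings
  expect_gt(rate, 0.010)
  expect_lt(rate, 0.020)
})

test_that("allometry recovery from simulated radii stays within tolerance", {
  errs <- sapply(1:5, function(seed) {
    cfg <- sim_config(seed = seed,
                      growth = list(sd_root = 0.1, core_sd = 0),
                      release = list(stem_gain = 0, root_gain = 0))
    d <- simulate_dataset(cfg)
    interior <- d$trees[d$trees$position == "interior", ]
    pairs <- do.call(rbind, lapply(interior$tree_id, function(id) {
      tr <- interior[interior$tree_id == id, ]
      stem <- reconstruct_radii(average_within_tree(
        Filter(function(s) s$tree_id == id & s$compartment == "stem",
               d$series)), tr$ds_cm * 5)
      root <- reconstruct_radii(average_within_tree(
        Filter(function(s) s$tree_id == id & s$compartment == "root",
               d$series)), tr$root_d_cm * 5)
      allometry_pairs(root, stem)
    }))
    fit <- fit_allometry(pairs, reference_site = "Furna")
    truth <- c(Furna = 4.06, Siat = 3.54, SurEn = 2.60)
    max(abs(site_alphas(fit)[names(truth)] - truth))
  })
  expect_lt(median(errs), 0.15)
})

test_that("fixture sets round-trip through the plain-text formats", {
  cfg <- sim_config(seed = 6,
                    sites = sim_site_defaults()[1:2, ])
  dir <- withr::local_tempdir()
  written <- write_fixture_set(cfg, dir)
  expect_true(file.exists(file.path(dir, "Furna_stem.rwl")))
  back <- read_fixture_set(dir)
  expect_setequal(names(back$series), names(written$series))
  for (id in names(written$series)) {
    expect_equal(back$series[[id]]$widths, written$series[[id]]$widths)
    expect_equal(back$series[[id]]$compartment,
                 written$series[[id]]$compartment)
    expect_equal(back$series[[id]]$direction,
                 written$series[[id]]$direction)
  }
  expect_equal(back$trees$tree_id, written$trees$tree_id)
  expect_equal(back$sites$cutting_year, written$sites$cutting_year)
  expect_equal(back$truth$trees$alpha, written$truth$trees$alpha)
  expect_equal(back$truth$baseline[["FUR_I01"]],
               written$truth$baseline[["FUR_I01"]])
})
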