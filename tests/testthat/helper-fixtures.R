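# Small builders shared across the test files.

make_series <- function(widths, first_year = 2000L, id = "T1-S1",
                        tree_id = "T1", site = "A", compartment = "stem",
                        direction = "none") {
  ring_series(id, widths, first_year, tree_id, site, compartment, direction)
}

# radius series climbing from `r0` by the given widths
make_radii <- function(widths, final, first_year = 2000L, tree_id = "T1",
                       compartment = "stem", site = "A") {
  reconstruct_radii(make_series(widths, first_year, tree_id = tree_id,
                                site = site),
                    final, compartment = compartment)
}

# noise-free simulation configuration: all stochastic components off
noise_free_config <- function(seed = 1L, sites = sim_site_defaults()) {
  sim_config(seed = seed, sites = sites,
             growth = list(year_sd = 0, sd_stem = 0, sd_collar = 0,
                           sd_root = 0, core_sd = 0, radius_sdlog = 0),
             allometry = list(tree_sd = 0),
             release = list(stem_gain = 0, root_gain = 0),
             missing_ring_rate = 0)
}

# allometry observation table generated exactly on the law
law_pairs <- function(alpha0, alpha, n_trees = 6, n_years = 30, site = "A",
                      tree_sd = 0, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_trees), function(i) {
    ds <- 100 * exp(cumsum(runif(n_years, 0.005, 0.02)))
    u <- if (tree_sd > 0) rnorm(1, 0, tree_sd) else 0
    data.frame(tree_id = sprintf("%s%02d", site, i), site = site,
               ln_ds = log(ds), ln_dr = alpha0 + alpha * log(ds) + u,
               stringsAsFactors = FALSE)
  }))
}

# tree-level radius series of one tree from a simulated dataset
tree_radii <- function(d, id) {
  tr <- d$trees[d$trees$tree_id == id, ]
  stem <- reconstruct_radii(average_within_tree(
    Filter(function(s) s$tree_id == id & s$compartment == "stem",
           d$series)), tr$ds_cm * 5)
  root <- reconstruct_radii(average_within_tree(
    Filter(function(s) s$tree_id == id & s$compartment == "root",
           d$series)), tr$root_d_cm * 5)
  list(stem = stem, root = root)
}

# log-log allometry observation table over the stand-interior trees
interior_pairs <- function(d) {
  ids <- d$trees$tree_id[d$trees$position == "interior"]
  do.call(rbind, lapply(ids, function(id) {
    r <- tree_radii(d, id)
    allometry_pairs(r$root, r$stem)
  }))
}
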