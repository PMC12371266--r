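# Shared synthetic fixtures, built in code and cached per test run.

.world_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .world_cache))
    assign(key, force(expr), envir = .world_cache)
  get(key, envir = .world_cache)
}

# a scaled-down world: same structure as the defaults, seconds to build
small_sim_cfg <- function(seed = 42, n_loops = 60, ...) {
  sim_config(chrom_length = 2e7, n_enhancers = 250, n_promoters = 200,
             n_loops = n_loops, seed = seed, ...)
}

small_world <- function() {
  cached("small_world", {
    sim <- simulate_cell_line(small_sim_cfg())
    ds <- suppressWarnings(
      build_epi_dataset(sim$loops, sim$enhancers, sim$promoters,
                        dataset_config(seed = 42)))
    fm <- encode_dataset(ds$pairs, sim$profile)
    list(sim = sim, ds = ds, fm = fm)
  })
}

# a shortfall-free world: few loops, dense elements, and a 20 kb lower
# distance bound so every distance bin holds >= 20 candidates per positive
nosf_world <- function() {
  cached("nosf_world", {
    sim <- simulate_cell_line(
      sim_config(chrom_length = 2e7, n_enhancers = 400, n_promoters = 300,
                 n_loops = 25, min_distance = 2e4, seed = 7))
    ds <- build_epi_dataset(sim$loops, sim$enhancers, sim$promoters,
                            dataset_config(seed = 7, min_distance = 2e4))
    list(sim = sim, ds = ds, cfg = dataset_config(seed = 7, min_distance = 2e4))
  })
}

# the full-scale stated world used by the acceptance criteria (frozen seed)
acceptance_world <- function() {
  cached("acceptance_world", {
    cfg <- sim_config(seed = 11)
    sim <- simulate_cell_line(cfg)
    ds <- suppressWarnings(
      build_epi_dataset(sim$loops, sim$enhancers, sim$promoters,
                        dataset_config(seed = 11)))
    fm <- encode_dataset(ds$pairs, sim$profile)
    list(cfg = cfg, sim = sim, ds = ds, fm = fm)
  })
}

# a tiny feature scheme whose names still parse into anchor/scale groups:
# 2 x (1 + 1 scale x (2 up + 2 down)) = 10 features
toy_scheme <- function() feature_scheme(window_sizes = 500, bins_per_side = 2)

# toy encoded dataset with Gaussian features and an optional planted signal
# in the promoter (or enhancer) columns; labels via a noisy threshold
make_toy_fm <- function(n = 400, prevalence = 0.5, effect = 2, seed = 1,
                        planted_anchor = "prom", noise = 1) {
  scheme <- toy_scheme()
  nm <- feature_names(scheme)
  withr::with_seed(seed, {
    y <- as.integer(runif(n) < prevalence)
    x <- matrix(rnorm(n * length(nm), sd = noise), n,
                dimnames = list(NULL, nm))
    planted_cols <- grep(paste0("^", planted_anchor, "_"), nm)[1:2]
    for (j in planted_cols) x[, j] <- x[, j] + effect * y
    meta <- data.table::data.table(
      chrom = "chrT",
      enh_start = seq_len(n) * 1000, enh_end = seq_len(n) * 1000 + 500,
      prom_start = seq_len(n) * 1000 + 20000,
      prom_end = seq_len(n) * 1000 + 20500,
      distance = sample(5e3:2e6, n, replace = TRUE),
      label = ifelse(y == 1, "positive", "negative"),
      source = "toy")
    structure(list(x = x, meta = meta, scheme = scheme), class = "epi_fm")
  })
}

# step profile fixture: constant `left` left of `edge`, `right` to its right
step_profile <- function(edge = 10000, left = 2, right = 4, len = 20000,
                         chrom = "chrF") {
  rt_profile(data.table::data.table(
    chrom = chrom, start = c(0, edge), end = c(edge, len),
    value = c(left, right)))
}
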