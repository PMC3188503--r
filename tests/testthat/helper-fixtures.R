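# Shared miniature fixtures, built in code.

# small spec factory; year defaults to 1000 min so renewal is easy to reason
# about in toy scenarios
tiny_spec <- function(side = 50, mode = "uniform", n_patches = 1,
                      radius = 3, year_min = 1000) {
  environment_spec(side_length = side, mode = mode, n_patches = n_patches,
                   patch_radius = radius, items_per_patch_cell = 2,
                   uniform_density = 0.5, day_length = year_min,
                   year_days = 1)
}

# a 20-cell strip world with known appearance times 0, 50, 100, ... 950
strip_world <- function() {
  world_from_cells(tiny_spec(side = 50), x = 0:19, y = 0,
                   count = 1, app_time = seq(0, 950, by = 50))
}

# config for toy engine runs: small year, no deaths by default via caller
toy_config <- function(year_min = 1000, ...) {
  sim_config(year_length = year_min, ...)
}

# deterministic genotype that scans everything nearby with certain detection:
# long scan time + tiny area -> detection probability ~ 1
greedy_genotype <- function(kind = "extended", d_fs = 2, d_m = 2, ...) {
  genotype(kind, t_m = 0.5, t_fs = 1.99, d_m = d_m, d_fs = d_fs,
           a_fs = 360, ...)
}
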