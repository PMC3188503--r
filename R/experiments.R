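# Experiment drivers: evolutionary runs, ecological genotype comparisons,
# adaptive-landscape scans, and depletion-calibrated population sizing.

#' Reference and scaled-down experiment presets
#'
#' `preset_paper()` is the full-scale configuration: 5660-m field, 8000
#' patches or density 0.535, 262,800-min year, reproduction at the full
#' 100,000-unit store. `preset_evolution_mini()` is the desk-scale preset
#' used by the package's own evolutionary experiments: an 800-m field with
#' the patch count scaled by area (160), a 50-day year (36,000 min) and the
#' birth threshold scaled by the same time factor (13,700 units), which
#' preserves the per-minute energy economy, the local geometry (patch radius,
#' reach, detection cap, action durations) and the depleted-density regime
#' while making 80-year runs tractable. `preset_ecology_mini()` scales the
#' fixed-population comparison field the way the reference procedure does —
#' by area only, keeping the full 262,800-min year: a 1750-m field with a
#' fixed population of 20, the size at which steady-state depletion falls
#' inside the 0.01-0.05 items/m^2 band of evolving populations, so a roster
#' of 4 genotypes x 5 heads forages at the reference density and depletion
#' regime. Scaling
#' time as well (as the evolution preset must, to fit generations in) would
#' inflate forager density several-fold and distort the competitive
#' rankings.
#'
#' @param mode `"uniform"`, `"patchy"` or `"mixed"`.
#' @return list with an `env` ([environment_spec()]), a `config`
#'   ([sim_config()]) and a suggested run length `years`.
#' @export
preset_paper <- function(mode = c("patchy", "uniform", "mixed")) {
  mode <- match.arg(mode)
  env <- environment_spec(side_length = 5660, mode = mode,
                          n_patches = 8000, patch_radius = 20,
                          items_per_patch_cell = 2, uniform_density = 0.535)
  list(env = env,
       config = sim_config(year_length = env$year_length,
                           e_birth = 1e5, e_max = 1e5),
       years = 1000)
}

#' @rdname preset_paper
#' @export
preset_evolution_mini <- function(mode = c("patchy", "uniform", "mixed")) {
  mode <- match.arg(mode)
  env <- environment_spec(side_length = 800, mode = mode,
                          n_patches = 160, patch_radius = 20,
                          items_per_patch_cell = 2, uniform_density = 0.535,
                          day_length = 720, year_days = 50)
  list(env = env,
       config = sim_config(year_length = env$year_length,
                           e_birth = 13700, e_max = 1e5),
       years = 80)
}

#' @rdname preset_paper
#' @export
preset_ecology_mini <- function(mode = c("patchy", "uniform", "mixed")) {
  mode <- match.arg(mode)
  env <- environment_spec(side_length = 1750, mode = mode,
                          n_patches = 765, patch_radius = 20,
                          items_per_patch_cell = 2, uniform_density = 0.535)
  list(env = env,
       config = sim_config(year_length = env$year_length,
                           e_birth = 1e5, e_max = 1e5),
       years = 35, population = 20L)
}

#' Run an evolutionary simulation
#'
#' Starts a founder population of `rescue_floor` individuals in the "zero"
#' genotype state (every gene at its lower bound) with the rescue birth rule
#' active, mutation on, and demography emerging from the energy economy.
#' Every birth is archived for ancestor tracing.
#'
#' @param preset a preset list (see [preset_paper()]); individual fields can
#'   be overridden through `env`, `config` and `years`.
#' @param kind decision architecture of the founders.
#' @param seed integer seed (world placement uses `seed`, the engine derives
#'   its streams from it).
#' @param env,config,years overrides of the preset fields.
#' @return A `forevol_sim` (see [simulate_foraging()]).
#' @export
run_evolution <- function(preset = preset_evolution_mini("patchy"),
                          kind = c("restricted", "extended"),
                          seed = 1, env = preset$env, config = preset$config,
                          years = preset$years) {
  kind <- match.arg(kind)
  world <- build_world(env, seed)
  founders <- replicate(config$rescue_floor, genotype(kind),
                        simplify = FALSE)
  simulate_foraging(world, founders, years = years, config = config, seed = seed,
           demography = TRUE, mutation = TRUE, rescue = TRUE)
}

#' Ecological comparison of genotypes in a shared world
#'
#' A fixed population (no births, deaths or mutation) foraging together, so
#' genotypes compete only through depletion. Runs until every genotype has
#' accrued `samples` individual-year intake samples; the first
#' `burn_in_years` are discarded so samples reflect the depleted steady
#' state.
#'
#' @param roster named list of [genotype()]s.
#' @param shares integer head count per roster entry.
#' @param preset preset list (see [preset_paper()]).
#' @param samples individual-year samples wanted per genotype.
#' @param burn_in_years discarded warm-up years.
#' @param seed integer seed.
#' @param env,config overrides.
#' @return list: `samples` (data.frame genotype, year, id, eats and
#'   patch-visit aggregates), `summary` (mean/median yearly intake per
#'   genotype), and the `sim`.
#' @export
run_ecology <- function(roster = specialist_genotypes(),
                        shares = NULL,
                        preset = preset_ecology_mini("patchy"),
                        samples = 100, burn_in_years = 1, seed = 1,
                        env = preset$env, config = preset$config) {
  if (is.null(shares)) {
    pop <- preset$population %||% 64L
    shares <- rep(max(1L, pop %/% length(roster)), length(roster))
  }
  stopifnot(length(shares) == length(roster))
  world <- build_world(env, seed)
  gm <- genotype_matrix(roster)[rep(seq_along(roster), shares), ,
                                drop = FALSE]
  groups <- rep(seq_along(roster), shares)
  need_years <- burn_in_years + ceiling(samples / min(shares))
  sim <- simulate_foraging(world, gm, years = need_years, config = config,
                  seed = seed, groups = groups, demography = FALSE,
                  mutation = FALSE, rescue = FALSE)
  smp <- sim$intake[sim$intake$year > burn_in_years, , drop = FALSE]
  smp$genotype <- names(roster)[smp$group]
  smp <- do.call(rbind, lapply(split(smp, smp$group), function(d)
    utils::head(d[order(d$year, d$id), ], samples)))
  rownames(smp) <- NULL
  agg <- aggregate(eats ~ genotype, smp, function(v)
    c(mean = mean(v), median = median(v), n = length(v)))
  summary <- data.frame(genotype = agg$genotype,
                        mean_intake = agg$eats[, "mean"],
                        median_intake = agg$eats[, "median"],
                        n = agg$eats[, "n"])
  list(samples = smp, summary = summary[order(-summary$mean_intake), ], sim = sim)
}

#' Local adaptive-landscape scan over two genotype parameters
#'
#' Individuals spanning the `values_x` x `values_y` grid (all other genes at
#' the base genotype) forage together in one shared world, so fitness
#' differences express through depletion exactly as in evolving populations.
#' Per grid point the driver averages yearly food intake, inter-patch travel
#' rate (inverse mean inter-patch travel time), patch visit time and patch
#' size at visit entry over the sampled individual-years.
#'
#' @param base a [genotype()]; its values fill the unscanned genes.
#' @param param_x,param_y gene names (see [gene_bounds()]).
#' @param values_x,values_y grid values (must respect the gene bounds).
#' @param preset preset list.
#' @param n_per_point individuals per grid point.
#' @param years simulated years (first `burn_in_years` discarded).
#' @param burn_in_years warm-up years.
#' @param seed integer seed.
#' @param env,config overrides.
#' @return data.frame with one row per grid point: `x_value`, `y_value`,
#'   `intake`, `travel_rate` (1/min), `visit_time` (min), `patch_size`
#'   (items), `n` (samples averaged).
#' @export
run_landscape <- function(base, param_x, param_y, values_x, values_y,
                          preset = preset_ecology_mini("patchy"),
                          n_per_point = 2, years = 6, burn_in_years = 1,
                          seed = 1, env = preset$env, config = preset$config) {
  b <- gene_bounds()
  for (p in c(param_x, param_y))
    if (!p %in% b$gene) stop("unknown genotype parameter: ", p)
  chk <- function(p, v) {
    r <- b[b$gene == p, ]
    if (any(v < r$min | v > r$max))
      stop("grid values for ", p, " outside [", r$min, ", ", r$max, "]")
  }
  chk(param_x, values_x); chk(param_y, values_y)
  grid <- expand.grid(x_value = values_x, y_value = values_y,
                      KEEP.OUT.ATTRS = FALSE)
  gl <- lapply(seq_len(nrow(grid)), function(i) {
    g <- unclass(base)
    g[[param_x]] <- grid$x_value[i]
    g[[param_y]] <- grid$y_value[i]
    validate_genotype(g)
  })
  world <- build_world(env, seed)
  gm <- genotype_matrix(gl)[rep(seq_len(nrow(grid)), each = n_per_point), ,
                            drop = FALSE]
  groups <- rep(seq_len(nrow(grid)), each = n_per_point)
  sim <- simulate_foraging(world, gm, years = years, config = config, seed = seed,
                  groups = groups, demography = FALSE, mutation = FALSE,
                  rescue = FALSE)
  smp <- sim$intake[sim$intake$year > burn_in_years, , drop = FALSE]
  agg <- lapply(split(smp, smp$group), function(d) {
    data.frame(
      intake = mean(d$eats),
      travel_rate = if (sum(d$travel_time) > 0)
        sum(d$n_travels) / sum(d$travel_time) else NA_real_,
      visit_time = if (sum(d$n_visits) > 0)
        sum(d$visit_time) / sum(d$n_visits) else NA_real_,
      patch_size = if (sum(d$n_visits) > 0)
        sum(d$entry_items) / sum(d$n_visits) else NA_real_,
      n = nrow(d))
  })
  out <- cbind(grid[as.integer(names(agg)), , drop = FALSE],
               do.call(rbind, agg))
  rownames(out) <- NULL
  out[order(out$y_value, out$x_value), ]
}

#' Calibrate population size to a target depletion band
#'
#' Doubles the population until the steady-state resource density (measured
#' at the end of a one-year run, after warm-up) falls below the band's upper
#' edge, then bisects to land inside the band. Larger populations deplete
#' further, so the search is monotone.
#'
#' @param env an [environment_spec()].
#' @param pool list of [genotype()]s cycled over the population.
#' @param band numeric length-2, target items per square metre (low, high).
#' @param config a [sim_config()].
#' @param years measurement run length.
#' @param seed integer seed.
#' @param max_pop hard cap (diagnostic error if the band needs more).
#' @return list: `size` (population used), `depletion` (items/m^2 achieved),
#'   `trace` (data.frame of sizes tried).
#' @export
calibrate_depletion <- function(env, pool, band = c(0.01, 0.05),
                                config = sim_config(year_length =
                                                      env$year_length),
                                years = 2, seed = 1, max_pop = 4096) {
  stopifnot(length(band) == 2, band[1] < band[2])
  world <- build_world(env, seed)
  built <- depletion_level(world)
  if (band[2] >= built)
    stop("band upper edge is above the built density (", round(built, 3), ")")
  measure <- function(n) {
    gm <- genotype_matrix(pool)[rep_len(seq_along(pool), n), , drop = FALSE]
    sim <- simulate_foraging(world, gm, years = years, config = config, seed = seed,
                    demography = FALSE, mutation = FALSE, rescue = FALSE)
    utils::tail(sim$snapshots$depletion, 1)
  }
  trace <- data.frame(size = integer(), depletion = numeric())
  n <- max(2L, length(pool))
  d <- measure(n)
  trace <- rbind(trace, data.frame(size = n, depletion = d))
  while (d > band[2] && n < max_pop) {
    n <- n * 2L
    d <- measure(n)
    trace <- rbind(trace, data.frame(size = n, depletion = d))
  }
  if (d > band[2])
    stop("depletion band unreachable below max_pop = ", max_pop,
         " (reached ", signif(d, 3), " items/m^2)")
  lo <- n %/% 2L; hi <- n
  while (d < band[1] && hi - lo > 1) {
    # overshot below the band: bisect back up
    mid <- (lo + hi) %/% 2L
    d <- measure(mid)
    trace <- rbind(trace, data.frame(size = mid, depletion = d))
    if (d > band[2]) lo <- mid else hi <- mid
    n <- mid
  }
  list(size = n, depletion = d, trace = trace)
}
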