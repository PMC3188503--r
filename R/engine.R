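# Event scheduler front end and demography helpers.

#' Simulation configuration
#'
#' Non-evolvable constants. Defaults are the reference parameterization:
#' 10-s minimal action duration (eat, approach), 2 energy units per item,
#' 1 unit/min metabolism, 100,000-unit store maximum, reproduction when the
#' store fills (energy then halves, the other half founding a single
#' offspring), 0.1/year background mortality, 10-year maximum age, a 10-head
#' rescue floor for non-viable founder populations, 0.9-m reach, 2-m
#' detection cap, 0.1 m/s (360 m/h) speed cap, and a 0.05 per-gene mutation
#' rate with the [gene_bounds()] step sizes.
#'
#' @param year_length minutes per year (365 x 720 = 262,800 by default).
#' @param e_birth energy threshold for reproduction (units).
#' @param e_max store maximum (units).
#' @param energy_per_item energy per eaten item (units).
#' @param metabolism basal drain (units/min).
#' @param death_rate background mortality (per year).
#' @param max_age_years maximum age (years).
#' @param rescue_floor minimum head count maintained while non-viable.
#' @param reach eating reach (m); `approach_stop` is half of it.
#' @param approach_stop stopping distance of MOVETOFOOD (m).
#' @param detect_max detection cap (m).
#' @param detect_rate detection rate (per s per m^2).
#' @param eat_time,mtf_time handling and approach durations (min).
#' @param speed_cap maximum speed (m/min; 6 m/min = 0.1 m/s).
#' @param mutation a [mutation_spec()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(year_length = 365 * 720,
                       e_birth = 1e5, e_max = 1e5,
                       energy_per_item = 2, metabolism = 1,
                       death_rate = 0.1, max_age_years = 10,
                       rescue_floor = 10,
                       reach = 0.9, approach_stop = 0.45,
                       detect_max = 2, detect_rate = 1,
                       eat_time = 10 / 60, mtf_time = 10 / 60,
                       speed_cap = 6,
                       mutation = mutation_spec()) {
  structure(list(
    year_len = year_length, e_birth = e_birth, e_max = e_max,
    energy_per_item = energy_per_item, metabolism = metabolism,
    death_rate = death_rate, max_age_years = max_age_years,
    rescue_floor = as.integer(rescue_floor),
    reach = reach, approach_stop = approach_stop,
    detect_max = detect_max, detect_rate = detect_rate,
    eat_time = eat_time, mtf_time = mtf_time, speed_cap = speed_cap,
    mutation = mutation
  ), class = "sim_config")
}

#' Survival over an elapsed interval
#'
#' Death is certain past the maximum age; otherwise the annual background
#' rate is compounded continuously over the interval:
#' hazard `1 - (1 - death_rate)^(elapsed / year)`.
#'
#' @param age_min age at the end of the interval (min).
#' @param elapsed interval length (min).
#' @param config a [sim_config()].
#' @return Probability of surviving the interval.
#' @export
survival_probability <- function(age_min, elapsed, config = sim_config()) {
  stopifnot(elapsed >= 0)
  if (age_min >= config$max_age_years * config$year_len) return(0)
  (1 - config$death_rate)^(elapsed / config$year_len)
}

#' Energy-proportional rescue weights
#'
#' While a founder population is below the rescue floor, a parent is chosen
#' with probability proportional to its energy, `e_i / sum(e)`; if every
#' store is empty the choice is uniform.
#'
#' @param energies numeric vector of energy stores.
#' @return Normalized selection probabilities.
#' @export
rescue_weights <- function(energies) {
  e <- pmax(energies, 0)
  if (sum(e) <= 0) return(rep(1 / length(e), length(e)))
  e / sum(e)
}

#' Halve energy at birth
#'
#' @param energy mother's energy store at the reproduction event.
#' @return list(mother, child): each half the pre-birth store.
#' @export
split_energy <- function(energy) {
  list(mother = energy / 2, child = energy / 2)
}

#' Run the event-driven simulation
#'
#' Individuals carry their own action-completion times; the scheduler always
#' advances the individual with the earliest completion (ties broken by id).
#' At each completion the engine charges metabolism accrued since the
#' individual's previous event (exact for a constant rate), applies
#' starvation, age and background mortality, applies the finished action's
#' effect, checks reproduction, asks the decision state machine for the next
#' action and reschedules. Resources renew at their fixed annual times as the
#' clock passes them.
#'
#' @param world a `resource_world` (its spec's `year_length` is used unless
#'   the config overrides it).
#' @param genotypes a [genotype()], list of genotypes, or genotype matrix.
#' @param years run duration in years (may be fractional).
#' @param config a [sim_config()].
#' @param seed integer; three internal streams (behavior, demography,
#'   mutation) are derived from it.
#' @param groups optional integer label per founder, reported in the intake
#'   table (defaults to the genotype's position in `genotypes`).
#' @param n_per_genotype replicate count per genotype row (founders are
#'   `rep(genotypes, each = n_per_genotype)`).
#' @param energy0 founder energy (defaults to `e_birth / 2`, the offspring
#'   endowment).
#' @param x0,y0,heading0 optional founder placement (default: uniform random
#'   positions and headings).
#' @param demography if `FALSE`, no births, deaths or rescue occur and
#'   energy is bookkeeping only (the ecological-simulation mode).
#' @param mutation inherit with per-gene mutation at births?
#' @param rescue keep the population at the rescue floor until viable?
#' @param log_trajectory record every event (time, id, action, position,
#'   ate, energy)? Memory-bound; for toy runs and analysis examples.
#' @param log_max maximum logged events.
#' @return A `forevol_sim` object: data.frames `population`, `lineage`,
#'   `snapshots` (yearly population size, per-gene means, depletion),
#'   `intake` (per individual-year eats and patch-visit aggregates),
#'   `trajectory`, plus `counters`, `clock`, `extinct`, `viable` and the
#'   final per-cell `world_count`.
#' @export
simulate_foraging <- function(world, genotypes, years,
                     config = sim_config(year_length = world$spec$year_length),
                     seed = 1, groups = NULL, n_per_genotype = 1,
                     energy0 = NULL, x0 = NULL, y0 = NULL, heading0 = NULL,
                     demography = TRUE, mutation = demography,
                     rescue = demography,
                     log_trajectory = FALSE, log_max = 2e6) {
  gm <- if (is.matrix(genotypes)) genotypes else genotype_matrix(genotypes)
  if (n_per_genotype > 1) {
    rows <- rep(seq_len(nrow(gm)), each = n_per_genotype)
    if (is.null(groups)) groups <- rows
    gm <- gm[rows, , drop = FALSE]
  }
  n <- nrow(gm)
  if (is.null(groups)) groups <- seq_len(n)
  stopifnot(length(groups) == n)
  if (is.null(energy0)) energy0 <- rep(config$e_birth / 2, n)
  if (length(energy0) == 1) energy0 <- rep(energy0, n)
  na_or <- function(v) if (is.null(v)) rep(NA_real_, n) else rep_len(v, n)

  cfg <- config
  cfg$mut_rate <- config$mutation$rate
  cfg$mut_sd <- config$mutation$sd
  cfg$mut_lo <- config$mutation$lo
  cfg$mut_hi <- config$mutation$hi

  flags <- list(births = demography, deaths = demography,
                mutation = mutation, rescue = rescue && demography,
                log_trajectory = log_trajectory, log_max = log_max,
                record_intake = TRUE)
  seeds <- as.integer((as.numeric(seed) * c(13, 29, 47) + c(101, 211, 307)) %%
                        2147483647)
  raw <- cpp_run_sim(world_for_engine(world), cfg, gm,
                     as.integer(groups), as.numeric(energy0),
                     na_or(x0), na_or(y0), na_or(heading0),
                     years * cfg$year_len, flags, seeds)
  as_forevol_sim(raw, world, cfg)
}

as_forevol_sim <- function(raw, world, cfg) {
  gn <- GENE_NAMES
  pop <- as.data.frame(raw$population[setdiff(names(raw$population),
                                              "genotype")])
  pg <- raw$population$genotype; colnames(pg) <- gn
  pop <- cbind(pop, as.data.frame(pg))
  lin <- as.data.frame(raw$lineage[setdiff(names(raw$lineage), "genotype")])
  lg <- raw$lineage$genotype; colnames(lg) <- gn
  lin <- cbind(lin, as.data.frame(lg))
  sn <- as.data.frame(raw$snapshots[setdiff(names(raw$snapshots),
                                            "genotype")])
  sg <- raw$snapshots$genotype; colnames(sg) <- paste0("mean_", gn)
  sn <- cbind(sn, as.data.frame(sg))
  traj <- as.data.frame(raw$trajectory)
  if (nrow(traj))
    traj$action <- c("MOVE", "FOODSCAN", "MOVETOFOOD", "EAT")[traj$action + 1]
  structure(list(
    population = pop, lineage = lin, snapshots = sn,
    intake = as.data.frame(raw$intake), trajectory = traj,
    world_count = raw$final_count,
    counters = raw$counters, clock = raw$clock,
    extinct = raw$extinct, viable = raw$viable, n_alive = raw$n_alive,
    world_spec = world$spec, config = cfg
  ), class = "forevol_sim")
}

#' @export
print.forevol_sim <- function(x, ...) {
  yrs <- x$clock / x$config$year_len
  cat("<forevol_sim>", format(yrs, digits = 4), "simulated years,",
      x$n_alive, "alive",
      if (x$extinct) "(extinct)" else "", "\n")
  cat("  births logged:", nrow(x$lineage),
      " items consumed:", x$counters$consumed, "\n")
  invisible(x)
}

#' Update a world to a simulation's final resource state
#'
#' @param world the `resource_world` the simulation was started from.
#' @param sim the returned `forevol_sim`.
#' @return The world with counts, consumed and renewed totals advanced.
#' @export
world_after <- function(world, sim) {
  world$count <- as.integer(sim$world_count)
  world$consumed <- world$consumed + sim$counters$consumed
  world$renewed <- world$renewed + sim$counters$renewed
  world
}
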