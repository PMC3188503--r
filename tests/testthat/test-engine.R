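# helper: run a tiny engine simulation with demography off unless asked
toy_sim <- function(world, genotypes, years = 1, cfg = toy_config(), ...) {
  simulate_foraging(world, genotypes, years = years, config = cfg, ...)
}

test_that("clock and unit constants are coherent", {
  spec <- environment_spec()
  expect_identical(spec$year_length, 365 * 720)
  expect_identical(spec$year_length, 262800)
  cfg <- sim_config()
  expect_equal(cfg$speed_cap, 6)          # m/min
  expect_equal(cfg$speed_cap / 60, 0.1)   # m/s
  expect_equal(cfg$speed_cap * 60, 360)   # m/h
})

test_that("the earliest action completion acts first; ties break by id", {
  w <- world_from_cells(tiny_spec(), x = integer(), y = integer())
  slow <- genotype("restricted", t_fs = 1.5, d_m = 1, t_m = 1.5)
  fast <- genotype("restricted", t_fs = 0.5, d_m = 1, t_m = 0.5)
  s <- toy_sim(w, list(slow, fast), years = 0.02, demography = FALSE,
               log_trajectory = TRUE)
  tr <- s$trajectory
  expect_true(all(diff(tr$time_min) >= 0))       # clock monotone
  expect_equal(tr$id[1], 2)                      # 0.5-min scan finishes first
  expect_equal(tr$time_min[1], 0.5)
  # identical genotypes: equal completion times resolve by ascending id
  s2 <- toy_sim(w, list(slow, slow), years = 0.02, demography = FALSE,
                log_trajectory = TRUE)
  tr2 <- s2$trajectory
  first <- tr2[tr2$time_min == tr2$time_min[1], ]
  expect_equal(first$id, sort(first$id))
})

test_that("metabolism drains one unit per minute and starves at zero", {
  # no food anywhere: a forager with 60 units dies at the event after t = 60
  w <- world_from_cells(tiny_spec(), x = integer(), y = integer())
  g <- genotype("restricted", d_m = 1, t_m = 1, t_fs = 1)
  cfg <- toy_config(death_rate = 0, e_birth = 1e9)
  s <- simulate_foraging(w, g, years = 0.2, config = cfg, seed = 1,
                         energy0 = 60, demography = TRUE, mutation = FALSE,
                         rescue = FALSE, log_trajectory = TRUE)
  expect_true(s$extinct)
  tr <- s$trajectory
  expect_equal(tr$energy, 60 - tr$time_min)      # exact linear drain
  expect_lte(max(tr$time_min), 61)
})

test_that("reproduction halves the mother's store into the child", {
  w <- world_from_cells(tiny_spec(), x = integer(), y = integer())
  g <- genotype("restricted", d_m = 1, t_m = 1, t_fs = 1)
  cfg <- toy_config(e_birth = 100, death_rate = 0)
  s <- simulate_foraging(w, g, years = 0.003, config = cfg, seed = 2,
                         energy0 = 120, demography = TRUE, mutation = FALSE,
                         rescue = FALSE)
  lin <- s$lineage
  expect_equal(nrow(lin), 2)                     # founder + one birth
  birth_t <- lin$birth_time[2]
  pop <- s$population
  # energy ledger across the birth: each side holds (120 - t)/2 at the birth
  half <- (120 - birth_t) / 2
  e_now <- function(id) pop$energy[pop$id == id] +
    (s$clock - pmax(birth_t, pop$birth_time[pop$id == id]))
  expect_equal(e_now(1), half, tolerance = 1e-8)
  expect_equal(e_now(2), half, tolerance = 1e-8)
})

test_that("background mortality realizes the compounded annual hazard", {
  expect_equal(survival_probability(0, 0), 1)
  expect_equal(survival_probability(11 * 262800, 1), 0)
  expect_equal(survival_probability(0, 262800), 0.9)
  # engine: 300 idle immortal-by-energy foragers over one short year
  w <- world_from_cells(tiny_spec(), x = integer(), y = integer())
  g <- genotype("restricted", d_m = 1, t_m = 1, t_fs = 1)
  cfg <- toy_config(year_min = 1000, death_rate = 0.1, e_birth = 1e9)
  s <- simulate_foraging(w, replicate(300, g, simplify = FALSE), years = 1,
                         config = cfg, seed = 4, energy0 = 5000,
                         demography = TRUE, mutation = FALSE, rescue = FALSE)
  survivors <- s$n_alive
  expect_gt(stats::binom.test(survivors, 300, 0.9)$p.value, 1e-4)
})

test_that("age never exceeds the maximum", {
  w <- world_from_cells(tiny_spec(), x = integer(), y = integer())
  g <- genotype("restricted", d_m = 1, t_m = 1, t_fs = 1)
  # 10-year cap with a 100-min year: everyone dies just past t = 1000
  cfg <- toy_config(year_min = 100, death_rate = 0, e_birth = 1e9)
  s <- simulate_foraging(w, list(g, g), years = 30, config = cfg, seed = 5,
                         energy0 = 1e5, demography = TRUE, mutation = FALSE,
                         rescue = FALSE, log_trajectory = TRUE)
  expect_true(s$extinct)
  expect_lte(max(s$trajectory$time_min), 1001)
})

test_that("rescue maintains the floor with energy-proportional parents", {
  expect_equal(rescue_weights(c(10, 30)), c(0.25, 0.75))
  expect_equal(rescue_weights(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(split_energy(1e5)$child, 5e4)
  # engine: 3 starving founders, rescue floor 10 -> births tagged rescue
  w <- world_from_cells(tiny_spec(), x = integer(), y = integer())
  g <- genotype("restricted", d_m = 1, t_m = 1, t_fs = 1)
  cfg <- toy_config(death_rate = 0, e_birth = 1000, rescue_floor = 10)
  s <- simulate_foraging(w, list(g, g, g), years = 1, config = cfg, seed = 6,
                         energy0 = 400, demography = TRUE, mutation = FALSE,
                         rescue = TRUE)
  expect_gt(sum(s$lineage$rescue), 0)
  expect_false(s$extinct)   # the floor holds despite zero food
  expect_gte(s$n_alive, 10)
})

test_that("runs are reproducible bit-for-bit under a fixed seed", {
  w <- toy_world("toy-patchy-200", seed = 9)
  g <- specialist_genotypes()[["R-Patchy"]]
  cfg <- sim_config(year_length = 2000)
  a <- simulate_foraging(w, list(g, g), years = 1, config = cfg, seed = 7,
                         demography = FALSE, log_trajectory = TRUE)
  b <- simulate_foraging(w, list(g, g), years = 1, config = cfg, seed = 7,
                         demography = FALSE, log_trajectory = TRUE)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$population, b$population)
  expect_identical(a$counters, b$counters)
  c <- simulate_foraging(w, list(g, g), years = 1, config = cfg, seed = 8,
                         demography = FALSE, log_trajectory = TRUE)
  expect_false(identical(a$trajectory, c$trajectory))
})

test_that("with demography off the population is constant", {
  w <- toy_world("toy-uniform-200", seed = 2)
  gs <- specialist_genotypes()
  cfg <- sim_config(year_length = 3000)
  s <- simulate_foraging(w, gs, years = 2, config = cfg, seed = 3,
                         demography = FALSE)
  expect_equal(s$n_alive, 4)
  expect_equal(nrow(s$lineage), 4)          # founders only
  expect_equal(unique(s$snapshots$pop), 4)
})

test_that("the resource ledger balances for any event sequence", {
  w <- toy_world("toy-patchy-200", seed = 4)
  gs <- rep(specialist_genotypes()["Ext-Patchy"], 3)
  cfg <- sim_config(year_length = 5000)
  s <- simulate_foraging(w, gs, years = 2.3, config = cfg, seed = 11,
                         demography = FALSE)
  ct <- s$counters
  expect_equal(ct$placed - ct$consumed + ct$renewed, ct$available)
  expect_equal(sum(s$world_count), ct$available)
  expect_equal(ct$placed, w$total_placed)
  # renewal never creates items at never-placed cells
  expect_equal(length(s$world_count), length(w$idx))
  expect_true(all(s$world_count <= w$init_count))
})

test_that("engine intake matches the trajectory log's eat count", {
  w <- toy_world("toy-patchy-200", seed = 6)
  g <- specialist_genotypes()[["Ext-Patchy"]]
  cfg <- sim_config(year_length = 4000)
  s <- simulate_foraging(w, list(g, g), years = 2, config = cfg, seed = 12,
                         demography = FALSE, log_trajectory = TRUE)
  yi <- yearly_intake(s$trajectory, year_length = 4000)
  eng <- s$intake[order(s$intake$year, s$intake$id), ]
  for (i in seq_len(nrow(eng))) {
    row <- yi[yi$id == eng$id[i] & yi$year == eng$year[i], ]
    got <- if (nrow(row) == 0) 0L else row$eats
    expect_equal(got, eng$eats[i])
  }
  # energy ledger at each individual's last event:
  # E = E(0) + 2*eats - minutes elapsed (cap never binds here, no births)
  pop <- s$population
  for (i in 1:2) {
    mine <- s$trajectory[s$trajectory$id == i, ]
    t_last <- max(mine$time_min)
    expect_equal(pop$energy[i],
                 cfg$e_birth / 2 + cfg$energy_per_item * sum(mine$ate)
                 - t_last,
                 tolerance = 1e-6)
  }
})
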