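test_that("scan area follows the sector formula", {
  expect_equal(scan_area(1, 360), pi)
  expect_equal(scan_area(5, 0), 0)
  expect_equal(scan_area(2, 90), pi)         # quarter disc of radius 2
  expect_equal(scan_area(3, 120), 3 * pi)
})

test_that("detection probability has the stated form and monotonicities", {
  expect_equal(detection_probability(0, 10), 0)
  expect_equal(detection_probability(1, 1), 1 - exp(-1))
  expect_lt(detection_probability(5, 1e9), 1e-8)   # vast area: nothing found
  expect_equal(detection_probability(2, 0), 1)     # co-located limit
  expect_equal(detection_probability(0, 0), 0)
  # monotone over a sampled grid
  ts <- seq(0, 30, by = 3); as <- seq(0.5, 20, by = 1.3)
  for (a in as) {
    p <- vapply(ts, detection_probability, numeric(1), area = a)
    expect_true(all(diff(p) >= 0))
  }
  for (t in ts[-1]) {
    p <- vapply(as, function(a) detection_probability(t, a), numeric(1))
    expect_true(all(diff(p) <= 0))
  }
  expect_true(all(vapply(ts, detection_probability, numeric(1), area = 2)
                  >= 0))
})

test_that("empirical detection frequency matches the stated probability", {
  # one item at 1 m; scan radius 2 m, full circle, 10-s scan
  spec <- environment_spec(side_length = 20, mode = "uniform")
  w <- world_from_cells(spec, x = 11, y = 10)
  g <- genotype("restricted", t_fs = 0.167, d_fs = 2, a_fs = 360)
  ind <- forager(g, x = 10, y = 10)
  p_theory <- detection_probability(0.167 * 60, scan_area(2, 360))
  set.seed(99)
  hits <- sum(vapply(1:3000, function(i) {
    perform_foodscan(ind, w)$ind$found
  }, logical(1)))
  ci <- stats::binom.test(hits, 3000, p_theory)$p.value
  expect_gt(ci, 1e-4)   # frequency consistent with the closed form
})

test_that("restricted decisions are blind to the scan outcome", {
  g <- genotype("restricted", p_ss = 0.37, d_fs = 2)
  draw_freq <- function(found) {
    ind <- forager(g)
    ind$last_action <- "FOODSCAN"
    ind$found <- found
    ind$in_reach <- FALSE
    mean(vapply(1:4000, function(i) next_action(ind) == "FOODSCAN",
                logical(1)))
  }
  after_eat_freq <- function() {
    ind <- forager(g)
    ind$last_action <- "EAT"
    mean(vapply(1:4000, function(i) next_action(ind) == "FOODSCAN",
                logical(1)))
  }
  set.seed(1)
  f_nofood <- draw_freq(FALSE)
  f_eat <- after_eat_freq()
  expect_equal(f_nofood, 0.37, tolerance = 0.1)
  expect_equal(f_eat, 0.37, tolerance = 0.1)
  # the extended model can differentiate the same two states
  ge <- genotype("extended", p_se = 1, p_sn = 0)
  ind <- forager(ge); ind$last_action <- "EAT"
  expect_true(all(replicate(50, next_action(ind)) == "FOODSCAN"))
  ind$last_action <- "FOODSCAN"; ind$found <- FALSE
  expect_true(all(replicate(50, next_action(ind)) == "MOVE"))
})

test_that("degenerate probabilities give the deterministic transitions", {
  # zero probabilities: strict MOVE <-> FOODSCAN alternation
  g <- genotype("restricted", p_mm = 0, p_ss = 0, d_m = 1)
  w <- world_from_cells(tiny_spec(), x = integer(), y = integer())
  ind <- forager(g, x = 25, y = 25)
  acts <- character(12)
  for (i in 1:12) {
    st <- step_forager(ind, w)
    ind <- st$ind; acts[i] <- st$record$action
  }
  expect_equal(acts, rep(c("FOODSCAN", "MOVE"), 6))
  # after eating, p_se = 1 always rescans; in-reach food is always eaten
  ge <- genotype("extended", p_se = 1)
  ind <- forager(ge); ind$last_action <- "EAT"
  expect_equal(next_action(ind), "FOODSCAN")
  ind$last_action <- "FOODSCAN"; ind$found <- TRUE; ind$in_reach <- TRUE
  expect_equal(next_action(ind), "EAT")
})

test_that("MOVE geometry, edge handling and the speed cap behave", {
  w <- world_from_cells(tiny_spec(side = 100), x = integer(), y = integer())
  # straight step: heading 0, no turn
  g <- genotype("restricted", d_m = 5, t_m = 1, a_t = 0)
  set.seed(3)
  r <- perform_move(forager(g, x = 10, y = 10, heading = 0), w)
  expect_equal(c(r$ind$x, r$ind$y), c(15, 10))
  expect_equal(r$elapsed, 1)
  # zero distance: position fixed, heading changes by +/- a_t
  g0 <- genotype("restricted", d_m = 0, a_t = 30)
  r0 <- perform_move(forager(g0, x = 10, y = 10, heading = 90), w)
  expect_equal(c(r0$ind$x, r0$ind$y), c(10, 10))
  expect_true(r0$ind$heading %in% c(60, 120))
  # speed cap: 12 m in 1 min exceeds 6 m/min -> duration extended to 2 min
  gc <- genotype("restricted", d_m = 12, t_m = 1, a_t = 0)
  rc <- perform_move(forager(gc, x = 20, y = 20, heading = 0), w)
  expect_equal(rc$elapsed, 2)
  expect_equal(rc$ind$x, 32)
  # edge contact: clamped inside with a fresh random heading
  re <- perform_move(forager(gc, x = 95, y = 50, heading = 0), w)
  expect_equal(re$ind$x, 99)
  expect_true(re$ind$heading >= 0 && re$ind$heading < 360)
})

test_that("MOVETOFOOD stops half a reach short, towards the target", {
  w <- world_from_cells(tiny_spec(side = 100), x = 50, y = 50)
  cell <- 50 + 100 * 50
  # target 2.45 m ahead -> final distance exactly 0.45
  ind <- forager(greedy_genotype(), x = 50 - 2.45, y = 50, heading = 0)
  r <- perform_movetofood(ind, cell, w)
  expect_equal(sqrt((r$ind$x - 50)^2 + (r$ind$y - 50)^2), 0.45)
  expect_equal(r$ind$heading, 0)
  expect_equal(r$elapsed, 10 / 60)
  # target behind: heading flips
  ind2 <- forager(greedy_genotype(), x = 53, y = 50, heading = 0)
  r2 <- perform_movetofood(ind2, cell, w)
  expect_equal(r2$ind$heading, 180)
  expect_equal(r2$ind$x, 50.45)
  # a target already in reach is a logic error
  ind3 <- forager(greedy_genotype(), x = 50.5, y = 50)
  expect_error(perform_movetofood(ind3, cell, w), "within reach")
})

test_that("EAT transfers energy, caps the store, and errors when empty", {
  cfg <- toy_config()
  w <- world_from_cells(tiny_spec(), x = 5, y = 5, count = 1)
  cell <- 5 + 50 * 5
  ind <- forager(greedy_genotype(), x = 5.2, y = 5, energy = 10)
  r <- perform_eat(ind, w, cell, cfg)
  expect_equal(r$ind$energy, 12)
  expect_equal(r$elapsed, 10 / 60)
  expect_error(perform_eat(r$ind, r$world, cell, cfg), "without an available")
  # store cap binds
  ind2 <- forager(greedy_genotype(), x = 5.2, y = 5, energy = cfg$e_max)
  r2 <- perform_eat(ind2, w, cell, cfg)
  expect_equal(r2$ind$energy, cfg$e_max)
})

test_that("ties between equally close items break uniformly", {
  spec <- tiny_spec(side = 21)
  w <- world_from_cells(spec, x = c(9, 11), y = c(10, 10))  # both at 1 m
  g <- greedy_genotype(d_fs = 2)
  ind <- forager(g, x = 10, y = 10)
  set.seed(5)
  picks <- vapply(1:2000, function(i)
    as.numeric(perform_foodscan(ind, w, force_detect = TRUE)$result$chosen),
    numeric(1))
  frac <- mean(picks == 9 + 21 * 10)
  expect_gt(stats::binom.test(sum(picks == 9 + 21 * 10), 2000, 0.5)$p.value,
            1e-4)
  expect_true(frac > 0.4 && frac < 0.6)
})

test_that("a rescanning forager sweeps a dense patch nearest-first", {
  # forced detection + p_se = 1: chained MTF/EAT visits items in greedy
  # nearest-neighbour order until the neighbourhood is empty
  spec <- tiny_spec(side = 40)
  xs <- c(20, 21, 22, 23)
  w0 <- world_from_cells(spec, x = xs, y = rep(20, 4), count = 1)
  g <- genotype("extended", t_m = 0.5, t_fs = 1.99, d_m = 0, d_fs = 2,
                a_fs = 360, p_se = 1, p_sn = 0, p_mtf = 1)
  ind <- forager(g, x = 19.5, y = 20, energy = 1000)
  w <- w0
  eaten <- integer()
  set.seed(8)
  for (i in 1:60) {
    st <- step_forager(ind, w, force_detect = TRUE)
    if (st$record$action == "EAT")
      eaten <- c(eaten, w$idx[w$count != st$world$count])
    ind <- st$ind; w <- st$world
    if (sum(w$count) == 0) break
  }
  # greedy nearest-neighbour oracle: from x = 19.5 the order is 20,21,22,23
  expect_equal(eaten, xs + 40L * 20L)
  expect_equal(ind$eats, 4L)
})
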