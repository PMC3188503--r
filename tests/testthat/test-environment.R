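test_that("spec validation rejects impossible configurations", {
  expect_error(environment_spec(side_length = 30, mode = "patchy",
                                patch_radius = 20), "radius")
  expect_error(environment_spec(uniform_density = 1.2), "density")
})

test_that("uniform placement matches the binomial expectation", {
  spec <- environment_spec(side_length = 200, mode = "uniform",
                           uniform_density = 0.535)
  w <- build_uniform(spec, seed = 7)
  n <- 200^2
  expect_equal(w$total_placed, n * 0.535,
               tolerance = 4 * sqrt(n * 0.535 * 0.465) / (n * 0.535))
  expect_true(all(w$app_time >= 0 & w$app_time < spec$year_length))
  # degenerate densities are certain
  s0 <- environment_spec(side_length = 10, mode = "uniform",
                         uniform_density = 0)
  expect_identical(build_uniform(s0, 1)$total_placed, 0L)
  s1 <- environment_spec(side_length = 10, mode = "uniform",
                         uniform_density = 1)
  expect_identical(build_uniform(s1, 1)$total_placed, 100L)
})

test_that("a single r = 3 patch covers exactly the 29 integer-disc cells", {
  spec <- environment_spec(side_length = 100, mode = "patchy",
                           n_patches = 1, patch_radius = 3,
                           items_per_patch_cell = 2)
  w <- build_patchy_at(spec, centers = c(50, 50))
  # brute-force enumeration of integer offsets with dx^2 + dy^2 <= 9
  offs <- expand.grid(dx = -3:3, dy = -3:3)
  expect_equal(length(w$idx), sum(offs$dx^2 + offs$dy^2 <= 9))
  expect_equal(length(w$idx), 29)
  expect_equal(w$total_placed, 58)
  expect_true(all((w$x - 50)^2 + (w$y - 50)^2 <= 9))
  expect_true(all(w$patch_id == 0))
})

test_that("random patchy builder agrees with the R oracle at fixed centers", {
  spec <- environment_spec(side_length = 120, mode = "patchy",
                           n_patches = 6, patch_radius = 9,
                           items_per_patch_cell = 2)
  w <- build_patchy(spec, seed = 11)
  oracle <- build_patchy_at(spec, centers = cbind(w$patches$x, w$patches$y),
                            times = w$patches$appearance_time)
  expect_identical(w$idx, oracle$idx)
  expect_identical(w$count, oracle$count)
  expect_identical(w$patch_id, oracle$patch_id)
  expect_equal(w$app_time, oracle$app_time)
  # overlap cells are claimed once, by the first-placed patch
  expect_equal(w$total_placed, 2 * length(w$idx))
  expect_equal(sum(w$patches$n_cells), length(w$idx))
})

test_that("zero patches give an empty world", {
  spec <- environment_spec(side_length = 50, mode = "patchy", n_patches = 0)
  expect_identical(build_patchy(spec, 1)$total_placed, 0L)
})

test_that("mixed worlds union the two half-layouts", {
  spec <- environment_spec(side_length = 150, mode = "mixed",
                           n_patches = 6, patch_radius = 8,
                           uniform_density = 0.4)
  w <- build_mixed(spec, seed = 3)
  wu <- build_uniform(local({s <- spec; s$uniform_density <- 0.2; s}), 3)
  wp <- build_patchy(local({s <- spec; s$n_patches <- 3L; s}), 4)
  expect_setequal(w$idx, union(wu$idx, wp$idx))
  # overlap cells take the patch count (the max), never the sum
  expect_true(all(w$count <= 2))
  expect_equal(sum(w$count), length(union(wu$idx, wp$idx)) +
                 length(wp$idx))  # patch cells contribute one extra item
  # degenerate mix: uniform half only
  s2 <- environment_spec(side_length = 60, mode = "mixed", n_patches = 0,
                         uniform_density = 0.5)
  w2 <- build_mixed(s2, seed = 5)
  expect_true(all(is.na(w2$patch_id)))
})

test_that("renewal restores depleted cells at their fixed annual times", {
  w <- strip_world()  # times 0, 50, ..., 950 in a 1000-min year
  # nothing depleted -> nothing renewed
  expect_equal(renew(w, 0, 1000)$renewed, 0)
  # deplete cells with times 100 and 150 (cells 2 and 3)
  w2 <- consume(consume(w, w$idx[3]), w$idx[4])
  expect_equal(sum(w2$count), 18)
  r <- renew(w2, 60, 120)       # window catches time 100 only
  expect_equal(r$renewed, 1)
  expect_equal(r$world$count[3], 1L)
  expect_equal(r$world$count[4], 0L)
  # wrap-around: a time-0 cell renews when the clock crosses a year boundary
  w3 <- consume(consume(w, w$idx[1]), w$idx[2])  # times 0 and 50
  expect_equal(renew(w3, 980, 1049)$renewed, 1)  # boundary at 1000 in window
  expect_equal(renew(w3, 1, 49)$renewed, 0)      # neither time inside (1,49]
  expect_equal(renew(w3, 49, 1000)$renewed, 2)   # catches 50 and 0-at-1000
  # a full-year window renews every depleted cell exactly once
  wall <- w
  for (i in seq_along(wall$idx)) wall <- consume(wall, wall$idx[i])
  expect_equal(sum(wall$count), 0)
  rall <- renew(wall, 0, 1000)
  expect_equal(rall$renewed, 20)
  expect_equal(sum(rall$world$count), 20)
})

test_that("consume decrements and errors on absent items", {
  w <- strip_world()
  w2 <- consume(w, w$idx[1])
  expect_equal(w2$count[1], 0L)
  expect_equal(w2$consumed, 1)
  expect_error(consume(w2, w$idx[1]), "without an available item")
  expect_error(consume(w2, 4999L), "without an available item")
})

test_that("visible_items matches a brute-force all-cell filter", {
  spec <- tiny_spec(side = 60, mode = "patchy")
  w <- build_patchy_at(environment_spec(side_length = 60, mode = "patchy",
                                        n_patches = 2, patch_radius = 6,
                                        items_per_patch_cell = 1),
                       centers = rbind(c(20, 20), c(35, 28)))
  brute <- function(pos, heading, range, angle) {
    R <- min(range, 2)
    keep <- logical(length(w$idx))
    for (i in seq_along(w$idx)) {
      if (w$count[i] < 1) next
      d <- sqrt((w$x[i] - pos[1])^2 + (w$y[i] - pos[2])^2)
      if (d > R + 1e-12) next
      if (angle < 360 && d > 1e-9) {
        b <- atan2(w$y[i] - pos[2], w$x[i] - pos[1]) * 180 / pi
        diff <- ((b - heading + 540) %% 360) - 180
        if (abs(diff) > angle / 2 + 1e-9) next
      }
      keep[i] <- TRUE
    }
    sort(w$idx[keep])
  }
  set.seed(42)
  for (k in 1:25) {
    pos <- runif(2, 15, 40)
    heading <- runif(1, 0, 360)
    range <- runif(1, 0, 4)
    angle <- sample(c(0, 60, 120, 360), 1)
    got <- visible_items(w, pos, heading, range, angle)
    expect_identical(sort(got$cell), brute(pos, heading, range, angle))
  }
})

test_that("sector membership follows the bearing geometry", {
  spec <- environment_spec(side_length = 20, mode = "uniform")
  w <- world_from_cells(spec, x = 1, y = 1)  # bearing 45 deg from origin
  at <- function(angle) nrow(visible_items(w, c(0, 0), 0, 2, angle))
  expect_equal(at(120), 1)   # 45 <= 60
  expect_equal(at(60), 0)    # 45 > 30
  expect_equal(at(360), 1)
  expect_equal(at(0), 0)     # zero-measure sector misses generic positions
})

test_that("depletion level tracks consumption", {
  spec <- environment_spec(side_length = 100, mode = "uniform",
                           uniform_density = 0.535)
  w <- build_uniform(spec, 2)
  expect_equal(depletion_level(w), 0.535, tolerance = 0.05)
  half <- w
  take <- w$idx[seq_len(floor(length(w$idx) / 2))]
  for (cell in take) half <- consume(half, cell)
  expect_equal(depletion_level(half) / depletion_level(w),
               1 - length(take) / length(w$idx), tolerance = 1e-10)
  empty <- world_from_cells(spec, x = integer(), y = integer())
  expect_equal(depletion_level(empty), 0)
})

test_that("world snapshots round-trip through TSV", {
  w <- strip_world()
  w <- consume(w, w$idx[5])
  path <- tempfile(fileext = ".tsv")
  write_world_tsv(w, path)
  w2 <- read_world_tsv(path, w$spec)
  expect_equal(w2$count, w$count)
  expect_equal(w2$app_time, w$app_time)
  expect_equal(w2$consumed, 1)
})

test_that("shipped toy presets build at their stated scale", {
  wu <- toy_world("toy-uniform-200", seed = 1)
  expect_equal(wu$side, 200)
  expect_equal(wu$total_placed / 200^2, 0.535, tolerance = 0.03)
  wp <- toy_world("toy-patchy-200", seed = 1)
  expect_equal(wp$n_patches, 10)
  expect_true(all(wp$count == 2))
})
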