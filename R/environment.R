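# Lattice resource worlds: construction, renewal, depletion, spatial queries.
#
# Cells are unit squares whose centers sit at integer coordinates
# (0 .. side-1); positions are continuous; distances are measured from the
# cell center to the query point. Cell indices are 0-based, idx = x + side*y.

#' Specify a resource environment
#'
#' The reference configuration is a 5660 x 5660 lattice (1-m spacing,
#' 32,035,600 grid points). In the patchy mode, `n_patches` circular patches
#' of `patch_radius` metres are dropped at uniform random centers and every
#' covered cell holds `items_per_patch_cell` items; overlapping patches do not
#' stack items and a cell belongs to the patch that claimed it first. In the
#' uniform mode each cell independently holds one item with probability
#' `uniform_density`. The mixed mode combines half of each budget. Every item
#' reappears once per year at a fixed, randomly assigned time (whole patches
#' share one time). Days are 720 minutes and years 365 days, so the reference
#' year is 262,800 minutes.
#'
#' @param side_length lattice side (m).
#' @param mode `"uniform"`, `"patchy"` or `"mixed"`.
#' @param n_patches number of patches (patchy/mixed).
#' @param patch_radius patch radius (m).
#' @param items_per_patch_cell items per covered cell.
#' @param uniform_density per-cell placement probability (uniform/mixed).
#' @param day_length minutes per day.
#' @param year_days days per year.
#' @param max_detect_distance detection cap (m).
#' @return An `environment_spec` object.
#' @export
environment_spec <- function(side_length = 5660,
                             mode = c("uniform", "patchy", "mixed"),
                             n_patches = 8000, patch_radius = 20,
                             items_per_patch_cell = 2,
                             uniform_density = 0.535,
                             day_length = 720, year_days = 365,
                             max_detect_distance = 2) {
  mode <- match.arg(mode)
  stopifnot(side_length >= 2, side_length == round(side_length),
            day_length > 0, year_days > 0, patch_radius > 0,
            items_per_patch_cell >= 1, n_patches >= 0)
  if (uniform_density < 0 || uniform_density > 1)
    stop("uniform_density must lie in [0, 1]")
  if (mode %in% c("patchy", "mixed") && side_length < 2 * patch_radius)
    stop("patch radius too large for the field (need side >= 2*radius)")
  structure(list(
    side_length = as.integer(side_length), mode = mode,
    n_patches = as.integer(n_patches), patch_radius = patch_radius,
    items_per_patch_cell = as.integer(items_per_patch_cell),
    uniform_density = uniform_density,
    day_length = day_length, year_days = year_days,
    year_length = day_length * year_days,
    max_detect_distance = max_detect_distance
  ), class = "environment_spec")
}

new_world <- function(spec, idx, count, app_time, patch_id, patches) {
  side <- spec$side_length
  structure(list(
    spec = spec, side = side,
    idx = as.integer(idx),
    x = as.integer(idx %% side), y = as.integer(idx %/% side),
    count = as.integer(count), init_count = as.integer(count),
    app_time = as.numeric(app_time),
    patch_id = patch_id,
    patches = patches,
    n_patches = if (is.null(patches)) 0L else nrow(patches),
    total_placed = sum(count), consumed = 0, renewed = 0
  ), class = "resource_world")
}

#' Build a resource world
#'
#' `build_world()` dispatches on `spec$mode`; the `build_uniform()`,
#' `build_patchy()` and `build_mixed()` workers can also be called directly.
#'
#' @param spec an [environment_spec()].
#' @param seed integer seed for item/patch placement.
#' @return A `resource_world` object: occupied cells (`idx`, `x`, `y`),
#'   current and initial item counts, per-cell annual appearance times,
#'   patch membership, a `patches` table, and running totals
#'   (`total_placed`, `consumed`, `renewed`).
#' @export
build_world <- function(spec, seed = 1) {
  switch(spec$mode,
         uniform = build_uniform(spec, seed),
         patchy = build_patchy(spec, seed),
         mixed = build_mixed(spec, seed))
}

#' @rdname build_world
#' @export
build_uniform <- function(spec, seed = 1) {
  raw <- cpp_build_uniform(spec$side_length, spec$uniform_density,
                           spec$year_length, as.integer(seed))
  new_world(spec, raw$idx, raw$count, raw$app_time,
            rep(NA_integer_, length(raw$idx)), NULL)
}

#' @rdname build_world
#' @export
build_patchy <- function(spec, seed = 1) {
  raw <- cpp_build_patchy(spec$side_length, spec$n_patches,
                          spec$patch_radius, spec$items_per_patch_cell,
                          spec$year_length, as.integer(seed))
  patches <- if (spec$n_patches > 0) {
    data.frame(id = seq_len(spec$n_patches) - 1L,
               x = raw$patch_x, y = raw$patch_y,
               radius = spec$patch_radius,
               appearance_time = raw$patch_time,
               n_cells = raw$patch_cells,
               initial_items = raw$patch_cells * spec$items_per_patch_cell)
  } else {
    data.frame(id = integer(), x = numeric(), y = numeric(),
               radius = numeric(), appearance_time = numeric(),
               n_cells = integer(), initial_items = integer())
  }
  new_world(spec, raw$idx, raw$count, raw$app_time, raw$patch_id, patches)
}

#' @rdname build_world
#' @export
build_mixed <- function(spec, seed = 1) {
  half_u <- spec; half_u$uniform_density <- spec$uniform_density / 2
  half_p <- spec; half_p$n_patches <- as.integer(spec$n_patches / 2)
  wu <- build_uniform(half_u, seed)
  wp <- build_patchy(half_p, seed + 1L)
  # union; a uniform item on a patch cell takes the max count (the patch's)
  dup <- wu$idx %in% wp$idx
  idx <- c(wp$idx, wu$idx[!dup])
  count <- c(wp$count, wu$count[!dup])
  app <- c(wp$app_time, wu$app_time[!dup])
  pid <- c(wp$patch_id, rep(NA_integer_, sum(!dup)))
  o <- order(idx)
  new_world(spec, idx[o], count[o], app[o], pid[o], wp$patches)
}

#' @export
print.resource_world <- function(x, ...) {
  cat("<resource_world>", x$spec$mode, "mode,",
      x$side, "x", x$side, "lattice\n")
  cat("  occupied cells:", length(x$idx),
      " items placed:", x$total_placed,
      " available:", sum(x$count), "\n")
  if (x$n_patches > 0) cat("  patches:", x$n_patches, "\n")
  invisible(x)
}

#' Annual renewal
#'
#' Every depleted cell whose fixed annual appearance time falls in the
#' elapsed window `(t_prev, t_now]` (taken modulo the year length, with
#' wrap-around) is restored to its initial item count.
#'
#' @param world a `resource_world`.
#' @param t_prev,t_now absolute times (min), `t_prev <= t_now`.
#' @return A list with the updated `world` and the number of items `renewed`.
#' @export
renew <- function(world, t_prev, t_now) {
  stopifnot(t_prev <= t_now)
  Y <- world$spec$year_length
  depleted <- world$count < world$init_count
  if (!any(depleted) || t_now == t_prev)
    return(list(world = world, renewed = 0))
  if (t_now - t_prev >= Y) {
    hit <- depleted
  } else {
    a <- t_prev %% Y
    b <- t_now %% Y
    tt <- world$app_time
    inwin <- if (a < b) tt > a & tt <= b else tt > a | tt <= b
    hit <- depleted & inwin
  }
  n <- sum(world$init_count[hit] - world$count[hit])
  world$count[hit] <- world$init_count[hit]
  world$renewed <- world$renewed + n
  list(world = world, renewed = n)
}

#' Consume one item from a cell
#'
#' @param world a `resource_world`.
#' @param cell 0-based cell index (`x + side * y`).
#' @return The updated world.
#' @export
consume <- function(world, cell) {
  i <- match(cell, world$idx)
  if (is.na(i) || world$count[i] < 1)
    stop("consume() called on a cell without an available item (engine bug)")
  world$count[i] <- world$count[i] - 1L
  world$consumed <- world$consumed + 1
  world
}

#' Items visible from a position
#'
#' All cells holding at least one available item whose center lies within
#' `min(range, max_detect_distance)` of `pos` and inside the sector spanning
#' `angle/2` either side of `heading`. This is candidate visibility only;
#' per-item detection is stochastic and applied by [perform_foodscan()].
#'
#' @param world a `resource_world`.
#' @param pos numeric length-2 position (m).
#' @param heading heading (degrees; 0 is +x, counter-clockwise).
#' @param range scan radius (m).
#' @param angle full sector angle (degrees, 0-360). Items co-located with the
#'   observer are always inside the sector.
#' @return data.frame with `cell`, `x`, `y`, `distance`, sorted by distance.
#' @export
visible_items <- function(world, pos, heading, range, angle) {
  stopifnot(range >= 0, angle >= 0, angle <= 360)
  R <- min(range, world$spec$max_detect_distance)
  sel <- world$count > 0 &
    abs(world$x - pos[1]) <= R & abs(world$y - pos[2]) <= R
  if (!any(sel))
    return(data.frame(cell = integer(), x = integer(), y = integer(),
                      distance = numeric()))
  dx <- world$x[sel] - pos[1]
  dy <- world$y[sel] - pos[2]
  d <- sqrt(dx^2 + dy^2)
  ok <- d <= R + 1e-12
  if (angle < 360) {
    bearing <- atan2(dy, dx) * 180 / pi
    diff <- ((bearing - heading + 540) %% 360) - 180
    ok <- ok & (abs(diff) <= angle / 2 + 1e-9 | d < 1e-9)
  }
  out <- data.frame(cell = world$idx[sel][ok], x = world$x[sel][ok],
                    y = world$y[sel][ok], distance = d[ok])
  out[order(out$distance), , drop = FALSE]
}

#' Current resource density
#'
#' @param world a `resource_world`.
#' @return Available items per square metre of field.
#' @export
depletion_level <- function(world) {
  sum(world$count) / (as.numeric(world$side)^2)
}

#' Shipped toy-world presets
#'
#' Miniature 200-m worlds with the reference density and patch geometry
#' (patch count scaled by area), convenient for examples and tests.
#'
#' @param name `"toy-uniform-200"` or `"toy-patchy-200"`.
#' @param seed placement seed.
#' @return A `resource_world`.
#' @export
toy_world <- function(name = c("toy-uniform-200", "toy-patchy-200"),
                      seed = 1) {
  name <- match.arg(name)
  if (name == "toy-uniform-200") {
    build_uniform(environment_spec(side_length = 200, mode = "uniform"), seed)
  } else {
    build_patchy(environment_spec(side_length = 200, mode = "patchy",
                                  n_patches = 10), seed)
  }
}

#' Construct a world from explicit cells
#'
#' Fixture constructor: builds a `resource_world` directly from cell
#' coordinates, counts and appearance times, bypassing random placement.
#'
#' @param spec an [environment_spec()].
#' @param x,y integer cell coordinates (0-based).
#' @param count items per cell.
#' @param app_time annual appearance time per cell (min), default 0.
#' @param patch_id optional 0-based patch membership.
#' @param patches optional patch table (`id`, `x`, `y`, `radius`,
#'   `appearance_time`, `n_cells`, `initial_items`).
#' @return A `resource_world`.
#' @export
world_from_cells <- function(spec, x, y, count = 1, app_time = 0,
                             patch_id = NA_integer_, patches = NULL) {
  n <- length(x)
  idx <- x + spec$side_length * y
  o <- order(idx)
  new_world(spec, idx[o], rep_len(count, n)[o], rep_len(app_time, n)[o],
            rep_len(as.integer(patch_id), n)[o], patches)
}

#' Patchy world at fixed centers
#'
#' Deterministic patchy construction from given patch centers and appearance
#' times, applying the same claiming rule as [build_patchy()] (first-placed
#' patch wins overlap cells; items never stack). Pure R; used as the
#' independent oracle for the random builder and for hand-made fixtures.
#'
#' @param spec an [environment_spec()] in patchy mode.
#' @param centers 2-column matrix of patch centers (m).
#' @param times annual appearance time per patch (min).
#' @return A `resource_world`.
#' @export
build_patchy_at <- function(spec, centers, times = 0) {
  centers <- matrix(centers, ncol = 2)
  np <- nrow(centers)
  times <- rep_len(times, np)
  side <- spec$side_length
  r <- spec$patch_radius
  owner <- integer(0); cells <- integer(0)
  ncl <- integer(np)
  for (p in seq_len(np)) {
    x0 <- centers[p, 1]; y0 <- centers[p, 2]
    xs <- max(0, ceiling(x0 - r)):min(side - 1, floor(x0 + r))
    grid <- expand.grid(x = xs,
                        y = max(0, ceiling(y0 - r)):min(side - 1,
                                                        floor(y0 + r)))
    hit <- (grid$x - x0)^2 + (grid$y - y0)^2 <= r^2
    idx <- grid$x[hit] + side * grid$y[hit]
    new <- setdiff(idx, cells)
    cells <- c(cells, new)
    owner <- c(owner, rep(p - 1L, length(new)))
    ncl[p] <- length(new)
  }
  o <- order(cells)
  patches <- data.frame(id = seq_len(np) - 1L,
                        x = centers[, 1], y = centers[, 2],
                        radius = r, appearance_time = times,
                        n_cells = ncl,
                        initial_items = ncl * spec$items_per_patch_cell)
  new_world(spec, cells[o], rep(spec$items_per_patch_cell, length(cells))[o],
            times[owner + 1L][o], owner[o], patches)
}

#' Export / import a world snapshot as TSV
#'
#' Columns: `x`, `y`, `count`, `init_count`, `appearance_time`, `patch_id`.
#' `read_world_tsv()` rebuilds a `resource_world` from the snapshot plus its
#' spec (patch geometry is restored from the `patches` attribute file only in
#' so far as cell membership; centers are not stored in the cell table).
#'
#' @param world a `resource_world`.
#' @param path output path.
#' @export
write_world_tsv <- function(world, path) {
  df <- data.frame(x = world$x, y = world$y, count = world$count,
                   init_count = world$init_count,
                   appearance_time = world$app_time,
                   patch_id = world$patch_id)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_world_tsv
#' @param spec the [environment_spec()] the snapshot was built from.
#' @export
read_world_tsv <- function(path, spec) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  idx <- df$x + spec$side_length * df$y
  w <- new_world(spec, idx, df$init_count, df$appearance_time,
                 df$patch_id, NULL)
  w$count <- as.integer(df$count)
  w$consumed <- sum(df$init_count - df$count)
  w
}

# engine-facing view of a world
world_for_engine <- function(world) {
  list(side = world$side, idx = world$idx, count = world$count,
       app_time = world$app_time,
       patch_id = ifelse(is.na(world$patch_id), -1L, world$patch_id),
       n_patches = world$n_patches)
}
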