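# Behavioral primitives: perception, the four actions, and the decision
# state machines. These are pure-R reference implementations operating on a
# `forager` + `resource_world`; the C++ engine mirrors them and is
# cross-checked against them in the test suite.

#' Area covered by a food scan
#'
#' Sector area `pi * d_fs^2 * a_fs / 360` (square metres). The genotype's
#' scan distance is used even where it exceeds the 2-m detection cap: effort
#' spent scanning ground on which nothing can be detected is wasted, which is
#' exactly what makes over-long scan radii costly.
#'
#' @param d_fs scan radius (m).
#' @param a_fs full sector angle (degrees, 0-360).
#' @export
scan_area <- function(d_fs, a_fs) {
  stopifnot(d_fs >= 0, a_fs >= 0, a_fs <= 360)
  pi * d_fs^2 * a_fs / 360
}

#' Per-item detection probability
#'
#' Saturating in scanning effort per unit area:
#' `P = 1 - exp(-rate * scan_time / area)`, with the reference rate of 1 per
#' second per square metre (one second of scanning one square metre gives
#' `1 - exp(-1)`). Monotone increasing in `scan_time`, decreasing in `area`.
#' A zero area is the co-located limit: detection is certain for any positive
#' scan time.
#'
#' @param scan_time scanning time (seconds).
#' @param area area scanned (square metres), see [scan_area()].
#' @param rate detection rate (per second per square metre).
#' @export
detection_probability <- function(scan_time, area, rate = 1) {
  stopifnot(scan_time >= 0, area >= 0, rate >= 0)
  if (area == 0) return(as.numeric(scan_time > 0 & rate > 0))
  -expm1(-rate * scan_time / area)
}

#' Create a forager
#'
#' @param genotype a [genotype()].
#' @param x,y position (m).
#' @param heading heading (degrees; 0 is +x, counter-clockwise).
#' @param energy energy store (units).
#' @return A `forager` object carrying position, heading, energy and the
#'   behavioral state (last action, last scan outcome, pending target).
#' @export
forager <- function(genotype, x = 0, y = 0, heading = 0, energy = 1000) {
  structure(list(genotype = genotype, x = x, y = y,
                 heading = heading %% 360, energy = energy,
                 last_action = "NONE", found = FALSE, in_reach = FALSE,
                 target = NA_integer_, eats = 0L),
            class = "forager")
}

#' Decision state machine: choose the next action
#'
#' Implements both architectures. After MOVE: repeat MOVE with probability
#' `p_mm`, else FOODSCAN. After a FOODSCAN that found food: EAT if the chosen
#' item is within reach, else MOVETOFOOD with probability `p_mtf` (declining
#' the approach falls through to the no-food branch). After EAT: FOODSCAN
#' with probability `p_ss` (restricted) or `p_se` (extended), else MOVE.
#' After a scan that found nothing: FOODSCAN with probability `p_ss`
#' (restricted) or `p_sn` (extended), else MOVE. The restricted architecture
#' cannot condition the repeat-scan probability on the scan outcome. After
#' MOVETOFOOD the forager always eats.
#'
#' @param ind a [forager()] (its `last_action`, `found`, `in_reach` fields
#'   are the behavioral state).
#' @return One of `"MOVE"`, `"FOODSCAN"`, `"MOVETOFOOD"`, `"EAT"`.
#' @export
next_action <- function(ind) {
  g <- ind$genotype
  restricted <- g$kind == "restricted"
  switch(ind$last_action,
    NONE = "FOODSCAN",
    MOVE = if (runif(1) < g$p_mm) "MOVE" else "FOODSCAN",
    MOVETOFOOD = "EAT",
    EAT = {
      pr <- if (restricted) g$p_ss else g$p_se
      if (runif(1) < pr) "FOODSCAN" else "MOVE"
    },
    FOODSCAN = {
      if (ind$found) {
        if (ind$in_reach) return("EAT")
        if (runif(1) < g$p_mtf) return("MOVETOFOOD")
      }
      pr <- if (restricted) g$p_ss else g$p_sn
      if (runif(1) < pr) "FOODSCAN" else "MOVE"
    },
    stop("unknown behavioral state: ", ind$last_action)
  )
}

#' Perform a MOVE
#'
#' Rotates the heading by the turning angle (sign drawn uniformly left or
#' right), steps the move distance forward, and draws a fresh uniform heading
#' on contact with the field edge (the position is clamped inside). Realized
#' speed is capped at 0.1 m/s (6 m/min, 360 m/h) by extending the duration
#' when the evolved distance outruns the evolved duration.
#'
#' @param ind a [forager()].
#' @param world a `resource_world`.
#' @param config a [sim_config()].
#' @return list with the updated `ind` and `elapsed` minutes.
#' @export
perform_move <- function(ind, world, config = sim_config()) {
  g <- ind$genotype
  sgn <- if (runif(1) < 0.5) -1 else 1
  ind$heading <- (ind$heading + sgn * g$a_t) %% 360
  h <- ind$heading * pi / 180
  nx <- ind$x + cos(h) * g$d_m
  ny <- ind$y + sin(h) * g$d_m
  hi <- world$side - 1
  if (nx < 0 || nx > hi || ny < 0 || ny > hi) {
    nx <- min(max(nx, 0), hi)
    ny <- min(max(ny, 0), hi)
    ind$heading <- runif(1) * 360
  }
  ind$x <- nx; ind$y <- ny
  ind$last_action <- "MOVE"
  elapsed <- max(g$t_m, g$d_m / config$speed_cap)
  list(ind = ind, elapsed = elapsed)
}

#' Perform a FOODSCAN
#'
#' Candidate items come from [visible_items()] (radius `min(d_fs, 2)` m,
#' sector `a_fs` about the heading); each is detected independently with
#' [detection_probability()] evaluated at the genotype's scan time and
#' [scan_area()]. The closest detected item is chosen, ties broken uniformly
#' at random; the chosen item is within reach when its distance is at most
#' 0.9 m.
#'
#' @inheritParams perform_move
#' @param force_detect if `TRUE` the detection draw is skipped (probability
#'   treated as 1); used by deterministic test oracles.
#' @return list with updated `ind`, the `result` (data.frame of detected
#'   items, `chosen` cell, `in_reach` flag) and `elapsed` minutes.
#' @export
perform_foodscan <- function(ind, world, config = sim_config(),
                             force_detect = FALSE) {
  g <- ind$genotype
  cand <- visible_items(world, c(ind$x, ind$y), ind$heading, g$d_fs, g$a_fs)
  p <- detection_probability(g$t_fs * 60, scan_area(g$d_fs, g$a_fs),
                             config$detect_rate)
  det <- if (force_detect || p >= 1) {
    cand
  } else {
    cand[runif(nrow(cand)) < p, , drop = FALSE]
  }
  chosen <- NA_integer_
  in_reach <- FALSE
  if (nrow(det) > 0) {
    dmin <- min(det$distance)
    ties <- which(det$distance <= dmin + 1e-12)
    pick <- if (length(ties) > 1) sample(ties, 1) else ties
    chosen <- det$cell[pick]
    in_reach <- det$distance[pick] <= config$reach + 1e-12
  }
  ind$found <- !is.na(chosen)
  ind$in_reach <- in_reach
  ind$target <- chosen
  ind$last_action <- "FOODSCAN"
  list(ind = ind,
       result = list(detected = det, chosen = chosen, in_reach = in_reach),
       elapsed = g$t_fs)
}

#' Perform a MOVETOFOOD
#'
#' Straight-line approach towards the target cell, stopping half a reach
#' (0.45 m) short of it; the heading turns to the travel direction. Takes the
#' fixed approach duration (10 s).
#'
#' @inheritParams perform_move
#' @param target 0-based cell index; must hold the item chosen by the
#'   preceding scan, beyond reach (> 0.9 m).
#' @export
perform_movetofood <- function(ind, target, world, config = sim_config()) {
  tx <- target %% world$side
  ty <- target %/% world$side
  d <- sqrt((tx - ind$x)^2 + (ty - ind$y)^2)
  if (d <= config$reach)
    stop("MOVETOFOOD called on a target already within reach (engine bug)")
  f <- (d - config$approach_stop) / d
  ind$heading <- (atan2(ty - ind$y, tx - ind$x) * 180 / pi) %% 360
  ind$x <- ind$x + (tx - ind$x) * f
  ind$y <- ind$y + (ty - ind$y) * f
  ind$in_reach <- TRUE
  ind$target <- target
  ind$last_action <- "MOVETOFOOD"
  list(ind = ind, elapsed = config$mtf_time)
}

#' Perform an EAT
#'
#' Consumes the item at the target cell (handling time 10 s), adding 2 energy
#' units capped at the 100,000-unit store maximum.
#'
#' @inheritParams perform_movetofood
#' @return list with updated `ind`, updated `world` and `elapsed` minutes.
#' @export
perform_eat <- function(ind, world, target, config = sim_config()) {
  world <- consume(world, target)   # errors if no item (logic error)
  ind$energy <- min(ind$energy + config$energy_per_item, config$e_max)
  ind$eats <- ind$eats + 1L
  ind$found <- FALSE
  ind$in_reach <- FALSE
  ind$target <- NA_integer_
  ind$last_action <- "EAT"
  list(ind = ind, world = world, elapsed = config$eat_time)
}

#' Advance a forager by one complete action
#'
#' Chooses the next action with [next_action()], performs it, charges
#' metabolism for the elapsed time, and returns an event record. This is the
#' slow, fully R reference path used to validate the C++ engine on toy
#' scenarios.
#'
#' @inheritParams perform_move
#' @param force_detect passed to [perform_foodscan()].
#' @return list(ind, world, record) where `record` has the action name,
#'   elapsed minutes, position and whether an item was eaten.
#' @export
step_forager <- function(ind, world, config = sim_config(),
                         force_detect = FALSE) {
  act <- next_action(ind)
  ate <- 0L
  if (act == "MOVE") {
    r <- perform_move(ind, world, config)
    ind <- r$ind
  } else if (act == "FOODSCAN") {
    r <- perform_foodscan(ind, world, config, force_detect)
    ind <- r$ind
  } else if (act == "MOVETOFOOD") {
    r <- perform_movetofood(ind, ind$target, world, config)
    ind <- r$ind
  } else {
    r <- perform_eat(ind, world, ind$target, config)
    ind <- r$ind
    world <- r$world
    ate <- 1L
  }
  ind$energy <- ind$energy - config$metabolism * r$elapsed
  list(ind = ind, world = world,
       record = list(action = act, elapsed = r$elapsed,
                     x = ind$x, y = ind$y, ate = ate,
                     energy = ind$energy))
}
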