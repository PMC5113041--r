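# The agent-based engine: founder setup, per-tick movement (split phase /
# interphase), stochastic division, eggshell containment, clocked snapshots.

#' Define an ellipsoidal eggshell
#'
#' The eggshell is the rigid ellipsoid confining all cells. A point p is
#' inside when sum(((p - center) / semi_axes)^2) <= 1 (closed surface).
#'
#' @param semi_axes Three positive semi-axis lengths (embryo coordinate units).
#' @param center Center of the ellipsoid (default origin).
#' @return An object of class `eggshell`.
#' @examples
#' eggshell(c(25, 15, 15))
#' @export
eggshell <- function(semi_axes, center = c(0, 0, 0)) {
  semi_axes <- as.numeric(semi_axes)
  center <- as.numeric(center)
  stopifnot(length(semi_axes) == 3L, length(center) == 3L)
  if (any(!is.finite(semi_axes)) || any(semi_axes <= 0)) {
    rlang::abort("eggshell semi-axes must be positive and finite",
                 class = "elegansim_validation_error")
  }
  structure(list(semi_axes = semi_axes, center = center), class = "eggshell")
}

#' @export
print.eggshell <- function(x, ...) {
  cat(sprintf("<eggshell> semi-axes (%g, %g, %g), center (%g, %g, %g)\n",
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3],
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

as_point_matrix <- function(point) {
  if (is.matrix(point)) {
    stopifnot(ncol(point) == 3L)
    point
  } else {
    matrix(as.numeric(point), ncol = 3L, byrow = TRUE)
  }
}

#' Test whether points lie inside the eggshell
#'
#' @param point A length-3 numeric vector or an n x 3 matrix of points.
#' @param shell An [eggshell()].
#' @return Logical vector: `TRUE` where the point satisfies the (closed)
#'   ellipsoid inequality.
#' @export
in_eggshell <- function(point, shell) {
  p <- as_point_matrix(point)
  q <- sweep(sweep(p, 2L, shell$center, "-"), 2L, shell$semi_axes, "/")
  rowSums(q^2) <= 1
}

#' Project points back into the eggshell
#'
#' Points inside the shell are returned unchanged; points outside are scaled
#' radially (about the shell center) onto the surface, so the result always
#' satisfies [in_eggshell()]. The projection is idempotent.
#'
#' @inheritParams in_eggshell
#' @return Points in the same shape as the input (vector in, vector out).
#' @export
contain <- function(point, shell) {
  p <- as_point_matrix(point)
  off <- sweep(p, 2L, shell$center, "-")
  q <- rowSums(sweep(off, 2L, shell$semi_axes, "/")^2)
  out <- q > 1
  if (any(out)) {
    f <- 1 / sqrt(q[out])
    proj <- sweep(off[out, , drop = FALSE], 1L, f, "*")
    # guard against landing a float ulp outside the closed surface
    still <- rowSums(sweep(proj, 2L, shell$semi_axes, "/")^2) > 1
    if (any(still)) proj[still, ] <- proj[still, , drop = FALSE] * (1 - 1e-12)
    p[out, ] <- sweep(proj, 2L, shell$center, "+")
  }
  if (is.matrix(point)) p else as.numeric(p)
}

#' Simulation configuration
#'
#' @param end_time Simulated duration, seconds.
#' @param seed Integer seed for the run's single random stream (`NULL` leaves
#'   the current RNG state untouched).
#' @param div_cycle_time Duration of the post-division split phase in which
#'   the two daughters separate, seconds (default 90).
#' @param out_time_resolution Interval between snapshot emissions, seconds
#'   (default 60); must be a positive multiple of `tick_length`.
#' @param tick_length Seconds per simulation tick (default 1).
#' @param shell An [eggshell()], or `NULL` to derive one from the target
#'   positions (semi-axes 1.1 x the per-axis maximum target offset from the
#'   target centroid).
#' @param sd_policy Which table column drives division-time noise:
#'   `"div_time"` (default) perturbs the absolute division time with its SD;
#'   `"cycle"` adds a perturbed cycle duration to the birth time. Either
#'   policy falls back to the other column when its own is unavailable.
#' @param size_rule Daughter sizing: `"halve_volume"` (default; diameter x
#'   2^(-1/3), conserving volume) or `"inherit"` (daughters keep the parent
#'   diameter).
#' @param deterministic If `TRUE`, all SDs are treated as zero (every run is
#'   identical regardless of seed).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(end_time,
                       seed = NULL,
                       div_cycle_time = 90,
                       out_time_resolution = 60,
                       tick_length = 1,
                       shell = NULL,
                       sd_policy = c("div_time", "cycle"),
                       size_rule = c("halve_volume", "inherit"),
                       deterministic = FALSE) {
  sd_policy <- match.arg(sd_policy)
  size_rule <- match.arg(size_rule)
  stopifnot(end_time > 0, div_cycle_time > 0, tick_length > 0)
  if (out_time_resolution <= 0 ||
      abs(out_time_resolution / tick_length - round(out_time_resolution / tick_length)) > 1e-9) {
    rlang::abort("out_time_resolution must be a positive multiple of tick_length",
                 class = "elegansim_validation_error")
  }
  structure(list(
    end_time = end_time, seed = seed,
    div_cycle_time = div_cycle_time,
    out_time_resolution = out_time_resolution,
    tick_length = tick_length, shell = shell,
    sd_policy = sd_policy, size_rule = size_rule,
    deterministic = deterministic
  ), class = "sim_config")
}

round_half_up <- function(x) floor(x + 0.5)

#' Draw a concrete division time for one cell
#'
#' The schedule table stores times in minutes; the engine works in seconds.
#' Under the `"div_time"` policy the draw is `60 * (div_time + e)` with
#' `e ~ Normal(0, div_sd)`; under the `"cycle"` policy it is
#' `born_time + 60 * (cycle_time + e)` with `e ~ Normal(0, cycle_sd)`.
#' An unavailable SD (`NA`) means zero noise, and an unavailable primary
#' column makes the draw fall back to the other policy. Draws consume the
#' session RNG stream, so seeded runs are reproducible.
#'
#' @param entry One schedule-table row (list or one-row tibble with
#'   `div_time`, `div_sd`, `cycle_time`, `cycle_sd`, minutes).
#' @param born_time Birth time of the cell, seconds (used by the cycle
#'   policy).
#' @param sd_policy `"div_time"` or `"cycle"`.
#' @param deterministic If `TRUE`, no noise is added.
#' @return Scheduled absolute division time in seconds, or `NA` if neither
#'   column is available.
#' @examples
#' sample_division_time(list(div_time = 41.8, div_sd = NA,
#'                           cycle_time = 14.8, cycle_sd = NA))
#' @export
sample_division_time <- function(entry, born_time = 0,
                                 sd_policy = c("div_time", "cycle"),
                                 deterministic = FALSE) {
  sd_policy <- match.arg(sd_policy)
  noise <- function(s) {
    if (deterministic || is.na(s) || s == 0) 0 else stats::rnorm(1L, 0, s)
  }
  from_div <- function() 60 * (entry$div_time + noise(entry$div_sd))
  from_cycle <- function() born_time + 60 * (entry$cycle_time + noise(entry$cycle_sd))
  has_div <- !is.null(entry$div_time) && !is.na(entry$div_time)
  has_cycle <- !is.null(entry$cycle_time) && !is.na(entry$cycle_time)
  if (sd_policy == "div_time") {
    if (has_div) from_div() else if (has_cycle) from_cycle() else NA_real_
  } else {
    if (has_cycle) from_cycle() else if (has_div) from_div() else NA_real_
  }
}

#' One split-phase movement step
#'
#' During the `div_cycle_time` seconds after a division the two daughters
#' separate: each tick a daughter advances along its division direction by
#' `(cell_size / 2) / div_cycle_time`, so that over the whole phase it
#' displaces by half its diameter and the siblings (moving in opposite
#' directions) end up one diameter apart, fully split.
#'
#' @param position Current position (length-3, or n x 3 matrix).
#' @param direction Unit division direction (same shape).
#' @param cell_size Cell diameter(s).
#' @param div_cycle_time Split-phase duration, seconds.
#' @return The next position, same shape as `position`.
#' @export
split_step <- function(position, direction, cell_size, div_cycle_time) {
  p <- as_point_matrix(position)
  d <- as_point_matrix(direction)
  res <- p + d * (cell_size / 2) / div_cycle_time
  if (is.matrix(position)) res else as.numeric(res)
}

#' One interphase movement step
#'
#' Outside the split phase a cell heads for its target destination (where its
#' next division takes place): the displacement is the remaining offset
#' divided by the number of seconds left until the scheduled division, so
#' repeated application lands the cell exactly on target when the clock
#' reaches `div_time`. If the division time has already passed (terminal
#' cells) the cell is placed at the target.
#'
#' @param position Current position (length-3, or n x 3 matrix).
#' @param target Target position (same shape).
#' @param div_time Scheduled division time(s), seconds.
#' @param clock Current time, seconds.
#' @return The next position, same shape as `position`.
#' @export
interphase_step <- function(position, target, div_time, clock) {
  p <- as_point_matrix(position)
  tg <- as_point_matrix(target)
  denom <- div_time - clock
  res <- p
  late <- denom <= 0
  if (any(late)) res[late, ] <- tg[late, , drop = FALSE]
  if (any(!late)) {
    res[!late, ] <- p[!late, , drop = FALSE] +
      (tg[!late, , drop = FALSE] - p[!late, , drop = FALSE]) / denom[!late]
  }
  if (is.matrix(position)) res else as.numeric(res)
}

default_shell_from_targets <- function(position_table) {
  ctr <- c(mean(position_table$tgt_x), mean(position_table$tgt_y),
           mean(position_table$tgt_z))
  semi <- 1.1 * c(max(abs(position_table$tgt_x - ctr[1])),
                  max(abs(position_table$tgt_y - ctr[2])),
                  max(abs(position_table$tgt_z - ctr[3])))
  semi[semi <= 0] <- 1   # degenerate axis: give it unit clearance
  eggshell(semi, ctr)
}

lookup_row <- function(tb, name, key = "name") {
  i <- match(name, tb[[key]])
  if (is.na(i)) NULL else tb[i, , drop = FALSE]
}

# Build the agent rows for a set of cells. `split_active` controls whether
# the cells start in the split phase (daughters) or in interphase (founders).
new_agents <- function(names, sizes, pos, dirs, div_times, tables, config,
                       founder, split_active) {
  tibble::tibble(
    name = names, size = sizes,
    x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
    div_time = div_times,
    terminal = !(names %in% tables$direction$parent),
    dir_x = dirs[, 1L], dir_y = dirs[, 2L], dir_z = dirs[, 3L],
    div_tick = if (split_active) 0 else config$div_cycle_time,
    tgt_x = NA_real_, tgt_y = NA_real_, tgt_z = NA_real_,
    founder = founder,
    newborn = split_active
  )
}

fill_targets <- function(cells, position_table) {
  i <- match(cells$name, position_table$name)
  hit <- !is.na(i)
  cells$tgt_x[hit] <- position_table$tgt_x[i[hit]]
  cells$tgt_y[hit] <- position_table$tgt_y[i[hit]]
  cells$tgt_z[hit] <- position_table$tgt_z[i[hit]]
  cells
}

#' Initialize a simulation state
#'
#' Hatches one agent per founder cell: name, diameter and starting position
#' from the initial-cell table; a per-founder lineage tag for later coloring;
#' a division time drawn through [sample_division_time()]; the split phase
#' disabled (founders start in interphase); and the migration target imported
#' from the position table.
#'
#' @param initial Tibble of founder cells ([read_initial_cells()] format).
#' @param tables Named list with elements `time`, `direction`, `position`
#'   (the three loaded input tables).
#' @param config A [sim_config()].
#' @return A `sim_state` object (clock at 0).
#' @export
sim_setup <- function(initial, tables, config) {
  stopifnot(inherits(config, "sim_config"))
  initial <- as_tibble(initial)
  for (nm in initial$name) {
    if (!(nm %in% tables$time$name)) {
      rlang::abort(sprintf("initial cell %s is missing from the time table", nm),
                   class = "elegansim_setup_error")
    }
    if (!(nm %in% tables$position$name)) {
      rlang::abort(sprintf("initial cell %s is missing from the position table", nm),
                   class = "elegansim_setup_error")
    }
  }
  shell <- config$shell %||% default_shell_from_targets(tables$position)
  config$shell <- shell

  ord <- order(initial$name, method = "radix")
  initial <- initial[ord, , drop = FALSE]
  div_times <- vapply(initial$name, function(nm) {
    entry <- lookup_row(tables$time, nm)
    dt <- sample_division_time(entry, born_time = 0,
                               sd_policy = config$sd_policy,
                               deterministic = config$deterministic)
    round_half_up(dt / config$tick_length) * config$tick_length
  }, numeric(1))

  # founders carry a placeholder division axis; their split phase is disabled
  cells <- new_agents(
    names = initial$name, sizes = initial$size,
    pos = cbind(initial$x, initial$y, initial$z),
    dirs = matrix(rep(c(1, 0, 0), nrow(initial)), ncol = 3L, byrow = TRUE),
    div_times = div_times, tables = tables, config = config,
    founder = initial$name, split_active = FALSE
  )
  cells <- fill_targets(cells, tables$position)
  cells$newborn <- FALSE
  # plain data.frame: column-vector updates in the tick loop are much cheaper
  cells <- as.data.frame(cells)

  structure(list(
    clock = 0,
    cells = cells,
    tables = tables,
    config = config,
    divisions = list(),
    snapshots = list(list(time = 0, cells = cells[, c("name", "x", "y", "z", "size")])),
    parent_of = character()
  ), class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> t = %gs, %d cell(s), %d division(s) so far\n",
              x$clock, nrow(x$cells), length(x$divisions)))
  invisible(x)
}

#' Divide one cell into its two daughters
#'
#' Looks up the daughters' names and the division axis in the direction
#' table; daughter 1 receives the tabulated direction, daughter 2 its
#' negation. Both daughters start at the parent position with the split phase
#' active, a freshly drawn division time (in daughter-name order, so seeded
#' runs are reproducible) and their migration targets from the position
#' table. Daughter diameters follow `config$size_rule`.
#'
#' @param cell One-row tibble: the dividing agent (from a `sim_state`).
#' @param tables The input-table triple (named list `time`, `direction`,
#'   `position`).
#' @param clock Current time, seconds (the daughters' birth time).
#' @param config A [sim_config()].
#' @return A two-row tibble of daughter agents.
#' @export
divide_cell <- function(cell, tables, clock, config) {
  dir_row <- lookup_row(tables$direction, cell$name, key = "parent")
  if (is.null(dir_row)) {
    rlang::abort(sprintf("cell %s has no direction-table row; it is terminal and cannot divide",
                         cell$name),
                 class = "elegansim_division_error")
  }
  d_names <- c(dir_row$daughter1, dir_row$daughter2)
  d_dir <- rbind(c(dir_row$dir_x, dir_row$dir_y, dir_row$dir_z),
                 -c(dir_row$dir_x, dir_row$dir_y, dir_row$dir_z))
  d_size <- switch(config$size_rule,
                   halve_volume = cell$size * 2^(-1 / 3),
                   inherit = cell$size)
  div_times <- vapply(d_names, function(nm) {
    entry <- lookup_row(tables$time, nm)
    if (is.null(entry)) {
      if (nm %in% tables$direction$parent) {
        rlang::abort(sprintf("daughter %s divides later but has no time-table row", nm),
                     class = "elegansim_division_error")
      }
      return(NA_real_)   # terminal leaf without a schedule: persists
    }
    dt <- sample_division_time(entry, born_time = clock,
                               sd_policy = config$sd_policy,
                               deterministic = config$deterministic)
    round_half_up(dt / config$tick_length) * config$tick_length
  }, numeric(1))

  daughters <- new_agents(
    names = d_names, sizes = rep(d_size, 2L),
    pos = rbind(c(cell$x, cell$y, cell$z), c(cell$x, cell$y, cell$z)),
    dirs = d_dir, div_times = div_times,
    tables = tables, config = config,
    founder = rep(cell$founder, 2L), split_active = TRUE
  )
  fill_targets(daughters, tables$position)
}

#' Advance the simulation by one tick
#'
#' The clock advances by `tick_length`; then, in lexicographic cell-name
#' order, each cell whose scheduled division time has been reached (and that
#' has a direction-table row) divides; all other cells move -- by
#' [split_step()] while their split phase is active, by [interphase_step()]
#' otherwise -- and are projected back into the eggshell. Newborn daughters
#' do not move on their birth tick. A snapshot is recorded whenever the clock
#' lands on a multiple of `out_time_resolution`.
#'
#' @param state A `sim_state`.
#' @return The advanced `sim_state`.
#' @export
sim_step <- function(state) {
  cfg <- state$config
  clock <- state$clock + cfg$tick_length
  cells <- state$cells
  if (any(cells$newborn)) cells$newborn <- FALSE

  dividing <- !cells$terminal & !is.na(cells$div_time) & clock >= cells$div_time
  divided_any <- any(dividing)
  if (divided_any) {
    div_names <- sort(cells$name[dividing], method = "radix")
    for (nm in div_names) {
      i <- match(nm, cells$name)
      mother <- cells[i, , drop = FALSE]
      daughters <- divide_cell(mother, state$tables, clock, cfg)
      state$divisions[[length(state$divisions) + 1L]] <- tibble::tibble(
        time = clock, parent = nm,
        daughter1 = daughters$name[1L], daughter2 = daughters$name[2L],
        x = mother$x, y = mother$y, z = mother$z
      )
      state$parent_of[daughters$name] <- nm
      cells <- rbind(cells[-i, , drop = FALSE], as.data.frame(daughters))
    }
    cells <- cells[order(cells$name, method = "radix"), , drop = FALSE]
    rownames(cells) <- NULL
  }

  moving <- !cells$newborn
  if (any(moving)) {
    px <- cells$x; py <- cells$y; pz <- cells$z
    splitting <- moving & cells$div_tick < cfg$div_cycle_time
    if (any(splitting)) {
      k <- (cells$size[splitting] / 2) / cfg$div_cycle_time
      px[splitting] <- px[splitting] + cells$dir_x[splitting] * k
      py[splitting] <- py[splitting] + cells$dir_y[splitting] * k
      pz[splitting] <- pz[splitting] + cells$dir_z[splitting] * k
    }
    inter <- moving & !splitting & !is.na(cells$div_time) & !is.na(cells$tgt_x)
    denom <- cells$div_time - clock
    late <- inter & denom <= 0
    if (any(late)) {
      px[late] <- cells$tgt_x[late]
      py[late] <- cells$tgt_y[late]
      pz[late] <- cells$tgt_z[late]
    }
    mv <- inter & denom > 0
    if (any(mv)) {
      px[mv] <- px[mv] + (cells$tgt_x[mv] - px[mv]) / denom[mv]
      py[mv] <- py[mv] + (cells$tgt_y[mv] - py[mv]) / denom[mv]
      pz[mv] <- pz[mv] + (cells$tgt_z[mv] - pz[mv]) / denom[mv]
    }
    # eggshell containment, inlined on the coordinate vectors
    sh <- cfg$shell
    ox <- px - sh$center[1L]; oy <- py - sh$center[2L]; oz <- pz - sh$center[3L]
    q <- (ox / sh$semi_axes[1L])^2 + (oy / sh$semi_axes[2L])^2 +
      (oz / sh$semi_axes[3L])^2
    out <- moving & q > 1
    if (any(out)) {
      f <- 1 / sqrt(q[out])
      f <- f * ifelse(q[out] * f^2 > 1, 1 - 1e-12, 1)
      px[out] <- sh$center[1L] + ox[out] * f
      py[out] <- sh$center[2L] + oy[out] * f
      pz[out] <- sh$center[3L] + oz[out] * f
    }
    cells$x <- px; cells$y <- py; cells$z <- pz
    cells$div_tick[moving] <- cells$div_tick[moving] + cfg$tick_length
  }

  state$cells <- cells
  state$clock <- clock

  res <- cfg$out_time_resolution
  if (abs(clock / res - round(clock / res)) < 1e-9) {
    state$snapshots[[length(state$snapshots) + 1L]] <-
      list(time = clock, cells = cells[, c("name", "x", "y", "z", "size")])
  }
  state
}

# Link consecutive snapshots into the 20-field record table: per-time-point
# indices in name order, predecessor via the division registry, successor
# slots filled by inverting the predecessor map.
link_snapshots <- function(snaps, parent_of) {
  k <- length(snaps)
  recs <- vector("list", k)
  names_at <- lapply(snaps, function(s) s$cells$name)
  prev_idx <- vector("list", k)
  for (i in seq_len(k)) {
    nm <- names_at[[i]]
    if (i == 1L) {
      prev_idx[[i]] <- rep(-1L, length(nm))
    } else {
      before <- names_at[[i - 1L]]
      prev_idx[[i]] <- vapply(nm, function(n) {
        anc <- n
        hops <- 0L
        while (!(anc %in% before)) {
          if (!(anc %in% names(parent_of)) || hops > 64L) {
            rlang::abort(sprintf(
              "snapshot linkage: cell %s at time %g has no ancestor at the previous time point",
              n, snaps[[i]]$time
            ), class = "elegansim_structural_error")
          }
          anc <- parent_of[[anc]]
          hops <- hops + 1L
        }
        match(anc, before)
      }, integer(1), USE.NAMES = FALSE)
    }
  }
  next1 <- lapply(names_at, function(nm) rep(-1L, length(nm)))
  next2 <- next1
  for (i in seq_len(k - 1L)) {
    for (j in seq_along(names_at[[i + 1L]])) {
      p <- prev_idx[[i + 1L]][j]
      if (next1[[i]][p] == -1L) {
        next1[[i]][p] <- j
      } else if (next2[[i]][p] == -1L) {
        next2[[i]][p] <- j
      } else {
        rlang::abort(sprintf(
          "snapshot linkage: more than two successors for cell %s at time %g (increase out_time_resolution granularity)",
          names_at[[i]][p], snaps[[i]]$time
        ), class = "elegansim_structural_error")
      }
    }
  }
  for (i in seq_len(k)) {
    s <- snaps[[i]]
    recs[[i]] <- tibble::tibble(
      time = s$time,
      index = seq_along(s$cells$name),
      valid = 1L,
      prev = prev_idx[[i]],
      next1 = next1[[i]],
      next2 = next2[[i]],
      x = s$cells$x, y = s$cells$y, z = s$cells$z,
      diameter = s$cells$size,
      name = s$cells$name
    )
  }
  dplyr::bind_rows(recs)
}

#' Run a complete embryo simulation
#'
#' Seeds the RNG, hatches the founders ([sim_setup()]), advances the clock
#' tick by tick ([sim_step()]) until `end_time`, and assembles the emitted
#' snapshots into a linked 20-field record table. With a fixed seed the
#' output is bit-reproducible.
#'
#' @param initial Tibble of founder cells ([read_initial_cells()] format).
#' @param tables Named list `time`, `direction`, `position` of loaded input
#'   tables, or an `embryo_fixture` (whose tables and eggshell are used).
#' @param config A [sim_config()].
#' @return An object of class `embryo_sim`: list with `snapshots` (linked
#'   record tibble, see [write_snapshot()]), `divisions` (one row per
#'   division: time, parent, daughters, dividing position), `final_cells`,
#'   and `config`. Use [generics::tidy()] / [generics::glance()] to extract
#'   tidy views.
#' @examples
#' fx <- make_fixture(n_founders = 2, generations = 1, mean_cycle = 3,
#'                    sd_level = 0, seed = 1)
#' sim <- simulate_embryo(fx$initial, fx, sim_config(end_time = 300, seed = 1))
#' glance(sim)
#' @export
simulate_embryo <- function(initial, tables, config) {
  if (inherits(tables, "embryo_fixture")) {
    if (is.null(config$shell)) config$shell <- tables$shell
    tables <- tables$tables
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- sim_setup(initial, tables, config)
  n_ticks <- round(config$end_time / config$tick_length)
  for (i in seq_len(n_ticks)) state <- sim_step(state)
  snapshots <- link_snapshots(state$snapshots, state$parent_of)
  divisions <- if (length(state$divisions) > 0L) {
    dplyr::bind_rows(state$divisions)
  } else {
    tibble::tibble(time = double(), parent = character(),
                   daughter1 = character(), daughter2 = character(),
                   x = double(), y = double(), z = double())
  }
  structure(list(
    snapshots = snapshots,
    divisions = divisions,
    final_cells = as_tibble(state$cells[, setdiff(names(state$cells), "newborn")]),
    config = state$config
  ), class = "embryo_sim")
}

#' @export
print.embryo_sim <- function(x, ...) {
  cat(sprintf("<embryo_sim> %d -> %d cells over %gs (%d divisions, %d snapshots)\n",
              sum(x$snapshots$time == min(x$snapshots$time)),
              nrow(x$final_cells), x$config$end_time,
              nrow(x$divisions), length(unique(x$snapshots$time))))
  invisible(x)
}

#' @rdname simulate_embryo
#' @param x An `embryo_sim` object.
#' @param ... Unused.
#' @export
tidy.embryo_sim <- function(x, ...) x$snapshots

#' @rdname simulate_embryo
#' @export
glance.embryo_sim <- function(x, ...) {
  tibble::tibble(
    n_founders = sum(x$snapshots$time == min(x$snapshots$time)),
    n_final = nrow(x$final_cells),
    n_divisions = nrow(x$divisions),
    n_snapshots = length(unique(x$snapshots$time)),
    end_time = x$config$end_time,
    seed = x$config$seed %||% NA_integer_
  )
}
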