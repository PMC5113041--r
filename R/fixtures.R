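# Synthetic, mutually consistent input-table triples with a known ground
# truth lineage, so the engine and the validation suite are fully testable
# without any external data.

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3L)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

sample_point_in_shell <- function(shell, margin = 0.9) {
  a <- shell$semi_axes * margin
  for (i in 1:1000) {
    p <- stats::runif(3L, -1, 1) * a
    if (sum((p / a)^2) <= 1) return(p + shell$center)
  }
  shell$center
}

#' Generate a synthetic fixture: input tables plus ground-truth lineage
#'
#' Builds a complete binary lineage of the requested depth with systematic
#' names (founder name plus `a`/`p` suffixes, echoing C. elegans
#' nomenclature) and emits the mutually consistent table triple that makes
#' the engine reproduce exactly that lineage: a schedule row for every cell
#' (absolute division times accumulated root-to-leaf, per-cell SD =
#' `sd_level`), a direction row with a random unit vector for every internal
#' cell, and a target strictly inside the eggshell for every cell. Defaults
#' mirror a wild-type early embryo: ~15 min cell cycles with a few minutes
#' of cell-to-cell spread, sub-minute timing SDs, and a 50 x 30 x 30 unit
#' ellipsoidal eggshell.
#'
#' @param n_founders Number of founder cells (default 4; the first four are
#'   named ABa, ABp, EMS, P2).
#' @param generations Number of division rounds (0 = founders never divide).
#' @param mean_cycle Mean cell-cycle length, minutes (default 15).
#' @param cycle_jitter Half-width of the uniform spread of per-cell cycle
#'   means, minutes (default 3).
#' @param sd_level Per-cell timing SD written to the schedule table, minutes
#'   (default 0.5; 0 gives a fully deterministic fixture).
#' @param shell An [eggshell()] (default semi-axes 25, 15, 15 at the
#'   origin). Targets are placed inside 0.9 x the shell so split-phase
#'   excursions do not clip.
#' @param founder_size Founder cell diameter, embryo units (default 8).
#' @param seed Optional RNG seed for fixture construction.
#' @return An `embryo_fixture`: list with `initial` (founder tibble),
#'   `tables` (named list `time`, `direction`, `position`), `truth` (the
#'   generating `lineage_tree`, times in seconds), `shell`, and `spec` (the
#'   generating parameters).
#' @examples
#' fx <- make_fixture(n_founders = 4, generations = 2, seed = 1)
#' nrow(fx$tables$time)   # 4 + 8 + 16 cells
#' @export
make_fixture <- function(n_founders = 4, generations = 3,
                         mean_cycle = 15, cycle_jitter = 3, sd_level = 0.5,
                         shell = eggshell(c(25, 15, 15)),
                         founder_size = 8, seed = NULL) {
  stopifnot(n_founders >= 1, generations >= 0, mean_cycle > 0,
            cycle_jitter >= 0, sd_level >= 0)
  if (!is.null(seed)) set.seed(seed)

  base_names <- c("ABa", "ABp", "EMS", "P2")
  founders <- if (n_founders <= 4L) base_names[seq_len(n_founders)] else {
    c(base_names, sprintf("F%02d", seq_len(n_founders - 4L) + 4L))
  }

  # one cycle draw per cell, in whole seconds so scheduled times sit exactly
  # on the tick grid (the floor keeps every cycle longer than the split phase)
  draw_cycle <- function() {
    max(round(60 * (mean_cycle + stats::runif(1L, -cycle_jitter, cycle_jitter))), 150)
  }

  time_rows <- list(); dir_rows <- list(); pos_rows <- list(); tree_rows <- list()
  walk <- function(name, born_s, depth, parent) {
    cycle_s <- draw_cycle()
    div_s <- born_s + cycle_s
    time_rows[[length(time_rows) + 1L]] <<- tibble(
      name = name, div_time = div_s / 60, div_sd = sd_level,
      cycle_time = cycle_s / 60, cycle_sd = sd_level
    )
    tgt <- sample_point_in_shell(shell)
    pos_rows[[length(pos_rows) + 1L]] <<- tibble(
      name = name, tgt_x = tgt[1L], tgt_y = tgt[2L], tgt_z = tgt[3L]
    )
    if (depth < generations) {
      d1 <- paste0(name, "a"); d2 <- paste0(name, "p")
      dv <- random_unit_vector()
      dir_rows[[length(dir_rows) + 1L]] <<- tibble(
        parent = name, daughter1 = d1, daughter2 = d2,
        dir_x = dv[1L], dir_y = dv[2L], dir_z = dv[3L]
      )
      tree_rows[[length(tree_rows) + 1L]] <<- tibble(
        name = name, parent = parent, daughter1 = d1, daughter2 = d2,
        born = born_s, divided = div_s
      )
      walk(d1, div_s, depth + 1L, name)
      walk(d2, div_s, depth + 1L, name)
    } else {
      tree_rows[[length(tree_rows) + 1L]] <<- tibble(
        name = name, parent = parent, daughter1 = NA_character_,
        daughter2 = NA_character_, born = born_s, divided = NA_real_
      )
    }
  }

  init_x <- if (n_founders == 1L) 0 else
    (2 * (seq_len(n_founders) - 1) / (n_founders - 1) - 1) * 0.6 * shell$semi_axes[1L]
  for (i in seq_len(n_founders)) walk(founders[i], 0, 0L, NA_character_)

  truth_df <- dplyr::bind_rows(tree_rows)
  end_time <- if (all(is.na(truth_df$divided))) 0 else max(truth_df$divided, na.rm = TRUE)
  empty_dir <- tibble(parent = character(), daughter1 = character(),
                      daughter2 = character(), dir_x = double(),
                      dir_y = double(), dir_z = double())
  structure(list(
    initial = tibble(
      name = founders,
      x = init_x + shell$center[1L],
      y = shell$center[2L], z = shell$center[3L],
      size = founder_size
    ),
    tables = list(
      time = dplyr::bind_rows(time_rows),
      direction = if (length(dir_rows) > 0L) dplyr::bind_rows(dir_rows) else empty_dir,
      position = dplyr::bind_rows(pos_rows)
    ),
    truth = new_lineage_tree(truth_df, end_time = end_time),
    shell = shell,
    spec = list(n_founders = n_founders, generations = generations,
                mean_cycle = mean_cycle, cycle_jitter = cycle_jitter,
                sd_level = sd_level, founder_size = founder_size, seed = seed)
  ), class = "embryo_fixture")
}

#' @export
print.embryo_fixture <- function(x, ...) {
  cat(sprintf("<embryo_fixture> %d founder(s), %d generation(s): %d cells, %d internal\n",
              x$spec$n_founders, x$spec$generations,
              nrow(x$tables$time), nrow(x$tables$direction)))
  invisible(x)
}

#' Derive a noisy observational reference from a ground-truth lineage
#'
#' Stands in for wild-type observational timing data: birth and division
#' times of every internal (dividing) cell of the truth tree, perturbed by
#' independent Gaussian noise, with stated SD columns, in the format
#' [cycle_report()] consumes. With `noise_sd = 0` the reference equals the
#' truth and all cycle-report deviations are zero.
#'
#' @param truth A `lineage_tree` (e.g. `make_fixture(...)$truth`).
#' @param noise_sd SD of the Gaussian perturbation applied to each time,
#'   seconds (default 0).
#' @param born_sd,divided_sd The SD values stated in the reference columns,
#'   seconds (defaults 36 and 90, typical observational uncertainties).
#' @return A tibble with columns `name`, `born`, `born_sd`, `divided`,
#'   `divided_sd` (internal cells only).
#' @export
make_observational_reference <- function(truth, noise_sd = 0,
                                         born_sd = 36, divided_sd = 90) {
  internal <- truth[!is.na(truth$divided), , drop = FALSE]
  n <- nrow(internal)
  tibble(
    name = internal$name,
    born = internal$born + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0,
    born_sd = born_sd,
    divided = internal$divided + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0,
    divided_sd = divided_sd
  )
}

#' Write a fixture's input files to a directory
#'
#' Emits the four plain-text inputs the simulator reads (`timeTable.txt`,
#' `directionTable.txt`, `positionTable.txt`, `initialCells.txt`; an
#' unavailable SD is written as `-1`) plus the ground-truth lineage as
#' Newick (`truth.nwk`).
#'
#' @param fixture An `embryo_fixture`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sd_out <- function(x) {
    vapply(x, function(v) if (is.na(v)) "-1" else fmt_num(v), character(1))
  }
  tt <- fixture$tables$time
  paths <- c(
    time = file.path(dir, "timeTable.txt"),
    direction = file.path(dir, "directionTable.txt"),
    position = file.path(dir, "positionTable.txt"),
    initial = file.path(dir, "initialCells.txt"),
    truth = file.path(dir, "truth.nwk")
  )
  writeLines(sprintf("%s\t%s\t%s\t%s\t%s", tt$name, fmt_num(tt$div_time),
                     sd_out(tt$div_sd), fmt_num(tt$cycle_time), sd_out(tt$cycle_sd)),
             paths[["time"]])
  dt <- fixture$tables$direction
  writeLines(sprintf("%s\t%s\t%s\t%s\t%s\t%s", dt$parent, dt$daughter1,
                     dt$daughter2, fmt_num(dt$dir_x), fmt_num(dt$dir_y),
                     fmt_num(dt$dir_z)),
             paths[["direction"]])
  pt <- fixture$tables$position
  writeLines(sprintf("%s\t%s\t%s\t%s", pt$name, fmt_num(pt$tgt_x),
                     fmt_num(pt$tgt_y), fmt_num(pt$tgt_z)),
             paths[["position"]])
  it <- fixture$initial
  writeLines(sprintf("%s\t%s\t%s\t%s\t%s", it$name, fmt_num(it$x),
                     fmt_num(it$y), fmt_num(it$z), fmt_num(it$size)),
             paths[["initial"]])
  writeLines(to_newick(fixture$truth), paths[["truth"]])
  invisible(paths)
}
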