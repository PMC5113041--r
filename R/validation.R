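# The quantitative validation suite: RMSE statistics, 5-minute count
# sampling, founder-cell cycle analysis with SD propagation, dividing-position
# analysis, and summary plots.

#' Root-mean-square error of a deviation vector
#'
#' Two variants coexist in the validation conventions this package follows:
#' the default divides the summed squares by n - 1 before the square root
#' (used for the cell-count and cycle-length comparisons), while
#' `use_bessel = FALSE` takes the plain square root of the summed squares
#' (the convention the per-axis dividing-position aggregates follow). Both
#' are exposed because neither reproduces the other's reference values; see
#' the methods vignette.
#'
#' @param deviations Numeric vector of deviations.
#' @param use_bessel If `TRUE` (default), compute `sqrt(sum(d^2) / (n - 1))`;
#'   otherwise `sqrt(sum(d^2))`.
#' @return A single number.
#' @examples
#' rmse(c(3, 4))          # sqrt(25 / 1) = 5
#' rmse(c(3, 4), FALSE)   # 5
#' @export
rmse <- function(deviations, use_bessel = TRUE) {
  d <- as.numeric(deviations)
  if (anyNA(d)) {
    rlang::abort("rmse: deviations contain NA", class = "elegansim_validation_error")
  }
  n <- length(d)
  if (use_bessel && n < 2L) {
    rlang::abort("rmse: at least two deviations are required with the n-1 divisor",
                 class = "elegansim_validation_error")
  }
  if (!use_bessel && n < 1L) {
    rlang::abort("rmse: at least one deviation is required",
                 class = "elegansim_validation_error")
  }
  if (use_bessel) sqrt(sum(d^2) / (n - 1)) else sqrt(sum(d^2))
}

#' Pair simulated and observed cell counts at regular sampling points
#'
#' Counts are sampled every `interval` minutes from both series. At each
#' target minute: (1) if both series have a count exactly there, it is used;
#' (2) otherwise the nearest minute at which *both* series have data is
#' chosen; (3) otherwise (both series sampled at incommensurate times, as
#' happens during rapid division phases) the pair of one simulation time and
#' one observation time with the minimum time difference is chosen, and the
#' two sampling times may then differ. Ties are broken toward earlier times.
#' Candidates are confined to the half-open window of width `interval`
#' centred on the target, and the target grid starts at the first interval
#' multiple covered by both series.
#'
#' @param sim_counts,obs_counts Tibbles with columns `time` (minutes) and
#'   `count`.
#' @param interval Sampling interval in minutes (default 5).
#' @return A tibble with one row per sampling point: `sample_time`,
#'   `sim_time`, `obs_time`, `sim_count`, `obs_count`, `deviation`
#'   (`abs(sim - obs)`).
#' @export
sample_counts <- function(sim_counts, obs_counts, interval = 5) {
  sim_counts <- dplyr::arrange(as_tibble(sim_counts), .data$time)
  obs_counts <- dplyr::arrange(as_tibble(obs_counts), .data$time)
  if (nrow(sim_counts) == 0L || nrow(obs_counts) == 0L) {
    rlang::abort("sample_counts: both series must be nonempty",
                 class = "elegansim_validation_error")
  }
  t_min <- max(min(sim_counts$time), min(obs_counts$time))
  t_max <- min(max(sim_counts$time), max(obs_counts$time))
  start <- max(ceiling(t_min / interval), 1) * interval
  targets <- if (start <= t_max) seq(start, t_max, by = interval) else numeric(0)
  if (length(targets) == 0L) {
    rlang::abort("sample_counts: series do not overlap for a full interval",
                 class = "elegansim_validation_error")
  }
  pick <- function(m) {
    lo <- m - interval / 2
    hi <- m + interval / 2
    sim_w <- sim_counts[sim_counts$time > lo & sim_counts$time <= hi, , drop = FALSE]
    obs_w <- obs_counts[obs_counts$time > lo & obs_counts$time <= hi, , drop = FALSE]
    if (nrow(sim_w) == 0L || nrow(obs_w) == 0L) {
      rlang::abort(sprintf(
        "sample_counts: no data in the window around minute %g for %s",
        m, if (nrow(sim_w) == 0L) "the simulation series" else "the observation series"
      ), class = "elegansim_validation_error")
    }
    common <- intersect(sim_w$time, obs_w$time)
    if (m %in% common) {
      ts <- to <- m
    } else if (length(common) > 0L) {
      # nearest common minute; earlier wins a tie
      common <- sort(common)
      ts <- to <- common[order(abs(common - m), common)][1L]
    } else {
      grid <- expand.grid(ts = sim_w$time, to = obs_w$time)
      grid <- grid[order(abs(grid$ts - grid$to), grid$ts, grid$to), , drop = FALSE]
      ts <- grid$ts[1L]; to <- grid$to[1L]
    }
    sc <- sim_w$count[match(ts, sim_w$time)]
    oc <- obs_w$count[match(to, obs_w$time)]
    tibble(sample_time = m, sim_time = ts, obs_time = to,
           sim_count = sc, obs_count = oc, deviation = abs(sc - oc))
  }
  dplyr::bind_rows(lapply(targets, pick))
}

#' Propagate birth- and division-time SDs to a cell-cycle SD
#'
#' A cell's cycle length is the difference of its division and birth times,
#' so its standard deviation combines the two in quadrature:
#' `sqrt(born_sd^2 + divided_sd^2)`.
#'
#' @param born_sd,divided_sd Standard deviations in seconds (each >= 0).
#' @return Cycle-length SD in seconds.
#' @examples
#' cycle_sd(36, 102)   # 108.1665
#' @export
cycle_sd <- function(born_sd, divided_sd) {
  if (any(born_sd < 0) || any(divided_sd < 0)) {
    rlang::abort("cycle_sd: standard deviations must be nonnegative",
                 class = "elegansim_validation_error")
  }
  sqrt(born_sd^2 + divided_sd^2)
}

#' Founder-cell cycle-length analysis
#'
#' Compares simulated and observed birth, division and cycle times for a set
#' of founder cells. The observation table carries per-cell SDs of birth and
#' division times; the cycle-length SD is propagated with [cycle_sd()]. The
#' summary reports the cycle-length RMSE (n - 1 divisor) and how many cells
#' deviate by less than `sd_factor` times their propagated cycle SD.
#'
#' @param sim A `lineage_tree`, or a tibble with columns `name`, `born`,
#'   `divided` (seconds).
#' @param obs Tibble with columns `name`, `born`, `born_sd`, `divided`,
#'   `divided_sd` (seconds).
#' @param names Cells to analyse (default: all cells in `obs`).
#' @param sd_factor Pass threshold as a fraction of the propagated cycle SD
#'   (default 0.6).
#' @return A `cycle_report` object; [generics::tidy()] gives the per-cell
#'   rows, [generics::glance()] the summary (`rmse`, `n_within_sd`, `n`,
#'   `sd_factor`).
#' @export
cycle_report <- function(sim, obs, names = NULL, sd_factor = 0.6) {
  sim <- as_tibble(sim)
  obs <- as_tibble(obs)
  names <- names %||% obs$name
  miss <- c(setdiff(names, sim$name), setdiff(names, obs$name))
  if (length(miss) > 0L) {
    rlang::abort(paste0("cycle_report: cell(s) not resolvable in both inputs: ",
                        paste(unique(miss), collapse = ", ")),
                 class = "elegansim_validation_error")
  }
  si <- match(names, sim$name)
  oi <- match(names, obs$name)
  rows <- tibble(
    name = names,
    sim_born = sim$born[si],
    sim_divided = sim$divided[si],
    sim_cycle = sim$divided[si] - sim$born[si],
    obs_born = obs$born[oi],
    obs_born_sd = obs$born_sd[oi],
    obs_divided = obs$divided[oi],
    obs_divided_sd = obs$divided_sd[oi],
    obs_cycle = obs$divided[oi] - obs$born[oi],
    obs_cycle_sd = cycle_sd(obs$born_sd[oi], obs$divided_sd[oi])
  )
  if (anyNA(rows$sim_divided)) {
    rlang::abort(paste0("cycle_report: cell(s) without a division time in the simulation: ",
                        paste(rows$name[is.na(rows$sim_divided)], collapse = ", ")),
                 class = "elegansim_validation_error")
  }
  rows$deviation <- abs(rows$sim_cycle - rows$obs_cycle)
  summary <- tibble(
    rmse = rmse(rows$deviation, use_bessel = TRUE),
    n_within_sd = sum(rows$deviation < sd_factor * rows$obs_cycle_sd),
    n = nrow(rows),
    sd_factor = sd_factor
  )
  structure(list(rows = rows, summary = summary), class = "cycle_report")
}

#' @export
print.cycle_report <- function(x, ...) {
  cat(sprintf("<cycle_report> %d cells: cycle RMSE %.3f s, %d of %d within %g x cycle SD\n",
              x$summary$n, x$summary$rmse, x$summary$n_within_sd,
              x$summary$n, x$summary$sd_factor))
  print(x$rows)
  invisible(x)
}

#' @rdname cycle_report
#' @param x A `cycle_report`.
#' @param ... Unused.
#' @export
tidy.cycle_report <- function(x, ...) x$rows

#' @rdname cycle_report
#' @export
glance.cycle_report <- function(x, ...) x$summary

#' Dividing-position analysis
#'
#' Compares, per coordinate axis, the positions at which named cells divide
#' in simulation and in the observational reference. Per-axis deviations are
#' absolute differences; the per-axis aggregate defaults to the plain
#' root-sum-of-squares (`use_bessel = FALSE`), the convention under which
#' the reference per-axis values bundled with this package were produced
#' (see [rmse()] and the methods vignette).
#'
#' @param sim_positions,obs_positions Tibbles with columns `name`, `x`,
#'   `y`, `z` (positions at division).
#' @param names Cells to analyse (default: all cells in `obs_positions`).
#' @param use_bessel Passed to [rmse()] for the per-axis aggregates
#'   (default `FALSE`).
#' @return A `position_report`; [generics::tidy()] gives per-cell rows with
#'   `dev_x`, `dev_y`, `dev_z`, [generics::glance()] the per-axis aggregates
#'   (`sigma_x`, `sigma_y`, `sigma_z`).
#' @export
position_report <- function(sim_positions, obs_positions, names = NULL,
                            use_bessel = FALSE) {
  sim_positions <- as_tibble(sim_positions)
  obs_positions <- as_tibble(obs_positions)
  names <- names %||% obs_positions$name
  miss <- c(setdiff(names, sim_positions$name), setdiff(names, obs_positions$name))
  if (length(miss) > 0L) {
    rlang::abort(paste0("position_report: cell(s) not resolvable in both inputs: ",
                        paste(unique(miss), collapse = ", ")),
                 class = "elegansim_validation_error")
  }
  si <- match(names, sim_positions$name)
  oi <- match(names, obs_positions$name)
  rows <- tibble(
    name = names,
    sim_x = sim_positions$x[si], sim_y = sim_positions$y[si], sim_z = sim_positions$z[si],
    obs_x = obs_positions$x[oi], obs_y = obs_positions$y[oi], obs_z = obs_positions$z[oi]
  )
  rows$dev_x <- abs(rows$sim_x - rows$obs_x)
  rows$dev_y <- abs(rows$sim_y - rows$obs_y)
  rows$dev_z <- abs(rows$sim_z - rows$obs_z)
  summary <- tibble(
    sigma_x = rmse(rows$dev_x, use_bessel = use_bessel),
    sigma_y = rmse(rows$dev_y, use_bessel = use_bessel),
    sigma_z = rmse(rows$dev_z, use_bessel = use_bessel),
    n = nrow(rows),
    use_bessel = use_bessel
  )
  structure(list(rows = rows, summary = summary), class = "position_report")
}

#' @export
print.position_report <- function(x, ...) {
  cat(sprintf("<position_report> %d cells: sigma (x, y, z) = (%.4g, %.4g, %.4g)\n",
              x$summary$n, x$summary$sigma_x, x$summary$sigma_y, x$summary$sigma_z))
  print(x$rows)
  invisible(x)
}

#' @rdname position_report
#' @param x A `position_report`.
#' @param ... Unused.
#' @export
tidy.position_report <- function(x, ...) x$rows

#' @rdname position_report
#' @export
glance.position_report <- function(x, ...) x$summary

#' Cell count over time
#'
#' Number of cells at each emitted snapshot time. The series is
#' non-decreasing: the model has no cell death, and every division adds
#' exactly one cell.
#'
#' @param snapshots Snapshot tibble or `embryo_sim`.
#' @return A tibble with columns `time` (seconds), `minutes`, and `n_cells`.
#' @export
count_curve <- function(snapshots) {
  if (inherits(snapshots, "embryo_sim")) snapshots <- snapshots$snapshots
  snapshots |>
    dplyr::count(.data$time, name = "n_cells") |>
    dplyr::arrange(.data$time) |>
    dplyr::mutate(minutes = .data$time / 60, .after = "time")
}

#' Plot simulated (and optionally observed) cell-count curves
#'
#' @param counts A count tibble from [count_curve()].
#' @param obs_counts Optional second count series for comparison (columns
#'   `time` in minutes and `count`, or a [count_curve()] tibble).
#' @return A ggplot object (step curves).
#' @export
plot_count_curve <- function(counts, obs_counts = NULL) {
  sim_df <- tibble(minutes = counts$minutes, n_cells = counts$n_cells,
                   series = "simulation")
  df <- sim_df
  if (!is.null(obs_counts)) {
    obs_counts <- as_tibble(obs_counts)
    obs_df <- if ("n_cells" %in% names(obs_counts)) {
      tibble(minutes = obs_counts$minutes, n_cells = obs_counts$n_cells)
    } else {
      tibble(minutes = obs_counts$time, n_cells = obs_counts$count)
    }
    obs_df$series <- "observation"
    df <- dplyr::bind_rows(df, obs_df)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$minutes, .data$n_cells,
                                   colour = .data$series)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (min)", y = "number of cells", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cell migration trajectories colored by founder lineage
#'
#' Draws every cell's path through the embryo as a polyline in the chosen
#' coordinate plane, colored by the founder (root) lineage the cell belongs
#' to, so the coherent outward migration of each sublineage is visible.
#'
#' @param snapshots Snapshot tibble or `embryo_sim`.
#' @param axes Which two coordinates to draw (default `c("x", "y")`).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(snapshots, axes = c("x", "y")) {
  if (inherits(snapshots, "embryo_sim")) snapshots <- snapshots$snapshots
  tree <- build_lineage(snapshots)
  root_of <- stats::setNames(rep(NA_character_, nrow(tree)), tree$name)
  for (nm in tree$name) {
    anc <- nm
    while (!is.na(tree$parent[match(anc, tree$name)])) {
      anc <- tree$parent[match(anc, tree$name)]
    }
    root_of[nm] <- anc
  }
  df <- as_tibble(snapshots)
  df$founder <- unname(root_of[df$name])
  ggplot2::ggplot(df, ggplot2::aes(.data[[axes[1L]]], .data[[axes[2L]]],
                                   group = .data$name,
                                   colour = .data$founder)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "founder") +
    ggplot2::theme_minimal()
}

#' Plot per-cell position spread over repeated runs
#'
#' Over a set of seeded replicate runs, each cell's positions at a chosen
#' time are summarized as their mean with one-standard-deviation extents on
#' each axis (drawn as error bars in the chosen plane) -- a planar rendering
#' of the mean +/- SD position ellipsoids. A single run gives degenerate
#' (zero-radius) extents.
#'
#' @param runs List of snapshot tibbles (or `embryo_sim` objects).
#' @param time Snapshot time (seconds) at which to compare positions.
#' @param axes Which two coordinates to draw (default `c("x", "y")`).
#' @return A ggplot object; the summarized tibble is attached as attribute
#'   `"spread"`.
#' @export
plot_position_spread <- function(runs, time, axes = c("x", "y")) {
  snaps <- lapply(runs, function(r) {
    if (inherits(r, "embryo_sim")) r <- r$snapshots
    r[r$time == time, , drop = FALSE]
  })
  df <- dplyr::bind_rows(snaps, .id = "run")
  spread <- df |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c("x", "y", "z")),
                    list(mean = mean, sd = ~ if (dplyr::n() > 1L) stats::sd(.x) else 0)),
      .groups = "drop"
    )
  a1 <- axes[1L]; a2 <- axes[2L]
  p <- ggplot2::ggplot(spread, ggplot2::aes(.data[[paste0(a1, "_mean")]],
                                            .data[[paste0(a2, "_mean")]])) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data[[paste0(a2, "_mean")]] - .data[[paste0(a2, "_sd")]],
      ymax = .data[[paste0(a2, "_mean")]] + .data[[paste0(a2, "_sd")]]
    ), width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data[[paste0(a1, "_mean")]] - .data[[paste0(a1, "_sd")]],
      xmax = .data[[paste0(a1, "_mean")]] + .data[[paste0(a1, "_sd")]]
    ), height = 0) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = a1, y = a2) +
    ggplot2::theme_minimal()
  attr(p, "spread") <- spread
  p
}
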