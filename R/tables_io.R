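# Readers and writers for the plain-text tables that drive the simulator and
# for the 20-field nuclei-style snapshot format.

#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Split a source (path or character vector of lines) into non-empty,
# non-comment lines, keeping original line numbers for error messages.
read_source_lines <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

parse_fields <- function(src, n_fields, what) {
  if (length(src$lines) == 0L) {
    return(matrix(character(), nrow = 0L, ncol = n_fields))
  }
  parts <- strsplit(trimws(src$lines), "[\t ]+")
  arity <- lengths(parts)
  if (any(arity != n_fields)) {
    bad <- which(arity != n_fields)[1L]
    abort(sprintf(
      "%s: line %d has %d fields, expected %d",
      what, src$lineno[bad], arity[bad], n_fields
    ), class = "elegansim_parse_error")
  }
  matrix(unlist(parts), ncol = n_fields, byrow = TRUE)
}

num_field <- function(x, src, what, field) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    abort(sprintf(
      "%s: line %d has non-numeric %s ('%s')",
      what, src$lineno[bad], field, x[bad]
    ), class = "elegansim_parse_error")
  }
  out
}

check_unique <- function(names, what, field = "cell name") {
  dup <- unique(names[duplicated(names)])
  if (length(dup) > 0L) {
    abort(sprintf("%s: duplicate %s(s): %s", what, field,
                  paste(dup, collapse = ", ")),
          class = "elegansim_validation_error")
  }
  invisible(names)
}

# "-1" marks an unavailable standard deviation in the schedule table; it is
# carried as NA so it can never leak into arithmetic.
sd_or_na <- function(x) ifelse(x < 0, NA_real_, x)

#' Read a division-schedule table
#'
#' The schedule table (one row per cell) drives division timing: the absolute
#' time at which each named cell divides, the duration of its cell cycle, and
#' the standard deviations of both, as measured in wild-type embryos. Times are
#' in minutes, as tabulated; they are converted to seconds only when a concrete
#' division time is drawn (see [sample_division_time()]). An SD recorded as
#' `-1` means "not available" and is returned as `NA`.
#'
#' @param source Path to a whitespace- or tab-delimited file with five fields
#'   per row (`name div_time div_sd cycle_time cycle_sd`), or a character
#'   vector holding such lines.
#' @return A tibble with columns `name`, `div_time`, `div_sd`, `cycle_time`,
#'   `cycle_sd` (times in minutes; unavailable SDs are `NA`).
#' @examples
#' read_time_table("ABal 41.8 0.6 14.8 0.6")
#' @export
read_time_table <- function(source) {
  src <- read_source_lines(source)
  m <- parse_fields(src, 5L, "time table")
  tb <- tibble(
    name       = m[, 1L],
    div_time   = num_field(m[, 2L], src, "time table", "division time"),
    div_sd     = sd_or_na(num_field(m[, 3L], src, "time table", "division-time SD")),
    cycle_time = num_field(m[, 4L], src, "time table", "cycle time"),
    cycle_sd   = sd_or_na(num_field(m[, 5L], src, "time table", "cycle-time SD"))
  )
  check_unique(tb$name, "time table")
  if (any(tb$div_time <= 0)) {
    abort("time table: division times must be positive",
          class = "elegansim_validation_error")
  }
  tb
}

#' Read a division-direction table
#'
#' One row per dividing (parent) cell: the names of its two daughters and the
#' 3-D direction along which daughter 1 moves during the post-division split
#' phase (daughter 2 moves in the opposite direction). Directions are
#' normalized to unit length on load; a warning is raised when the raw norm
#' deviates from 1 by more than `norm_tol`.
#'
#' @param source Path or character lines; six fields per row
#'   (`parent daughter1 daughter2 dir_x dir_y dir_z`).
#' @param norm_tol Relative deviation of the raw vector norm from 1 above
#'   which a warning is recorded (default 0.1, i.e. 10%).
#' @return A tibble with columns `parent`, `daughter1`, `daughter2`,
#'   `dir_x`, `dir_y`, `dir_z`; direction rows have unit norm.
#' @examples
#' read_direction_table("ABa ABal ABar 0.285 -0.547 0.686")
#' @export
read_direction_table <- function(source, norm_tol = 0.1) {
  src <- read_source_lines(source)
  m <- parse_fields(src, 6L, "direction table")
  dx <- num_field(m[, 4L], src, "direction table", "direction x")
  dy <- num_field(m[, 5L], src, "direction table", "direction y")
  dz <- num_field(m[, 6L], src, "direction table", "direction z")
  nrm <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(nrm == 0)) {
    bad <- which(nrm == 0)[1L]
    abort(sprintf("direction table: zero-norm direction on line %d",
                  src$lineno[bad]),
          class = "elegansim_validation_error")
  }
  off <- abs(nrm - 1) > norm_tol
  if (any(off)) {
    warn(sprintf(
      "direction table: %d direction(s) deviate from unit norm by more than %g%% (normalized on load)",
      sum(off), 100 * norm_tol
    ))
  }
  tb <- tibble(
    parent = m[, 1L], daughter1 = m[, 2L], daughter2 = m[, 3L],
    dir_x = dx / nrm, dir_y = dy / nrm, dir_z = dz / nrm
  )
  check_unique(tb$parent, "direction table", "parent name")
  same <- tb$daughter1 == tb$daughter2
  if (any(same)) {
    abort(sprintf("direction table: identical daughter names for parent %s",
                  tb$parent[which(same)[1L]]),
          class = "elegansim_validation_error")
  }
  tb
}

#' Read a target-position table
#'
#' One row per cell: the 3-D destination the cell migrates toward during
#' interphase (the position at which its next division takes place), in embryo
#' coordinate units.
#'
#' @param source Path or character lines; four fields per row
#'   (`name target_x target_y target_z`).
#' @return A tibble with columns `name`, `tgt_x`, `tgt_y`, `tgt_z`.
#' @examples
#' read_position_table("ABal -10.371 0.649 2.536")
#' @export
read_position_table <- function(source) {
  src <- read_source_lines(source)
  m <- parse_fields(src, 4L, "position table")
  tb <- tibble(
    name  = m[, 1L],
    tgt_x = num_field(m[, 2L], src, "position table", "target x"),
    tgt_y = num_field(m[, 3L], src, "position table", "target y"),
    tgt_z = num_field(m[, 4L], src, "position table", "target z")
  )
  check_unique(tb$name, "position table")
  tb
}

#' Read an initial-cell file
#'
#' The founder cells present when the simulation starts (classically the four
#' cells ABa, ABp, EMS and P2), with their starting positions and diameters.
#'
#' @param source Path or character lines; five fields per row
#'   (`name x y z size`).
#' @return A tibble with columns `name`, `x`, `y`, `z`, `size`.
#' @examples
#' read_initial_cells(c("ABa -10 3 0 8", "ABp 0 5 0 8"))
#' @export
read_initial_cells <- function(source) {
  src <- read_source_lines(source)
  m <- parse_fields(src, 5L, "initial-cell file")
  tb <- tibble(
    name = m[, 1L],
    x    = num_field(m[, 2L], src, "initial-cell file", "x"),
    y    = num_field(m[, 3L], src, "initial-cell file", "y"),
    z    = num_field(m[, 4L], src, "initial-cell file", "z"),
    size = num_field(m[, 5L], src, "initial-cell file", "size")
  )
  check_unique(tb$name, "initial-cell file")
  if (nrow(tb) == 0L) {
    abort("initial-cell file: at least one founder cell is required",
          class = "elegansim_validation_error")
  }
  if (any(tb$size <= 0)) {
    abort("initial-cell file: cell sizes must be positive",
          class = "elegansim_validation_error")
  }
  tb
}

# full-precision number formatting so snapshots round-trip bit-exactly
fmt_num <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  # trim the %.17g noise where a shorter form already round-trips
  short <- vapply(x, function(v) sprintf("%.15g", v), character(1))
  ok <- !is.na(x) & suppressWarnings(as.numeric(short) == x)
  out[ok] <- short[ok]
  out[is.na(x)] <- "NA"
  out
}

#' Write a snapshot stream in the 20-field nuclei format
#'
#' Each snapshot row becomes one line of 20 comma-separated fields: the first
#' five code the mother--daughter linkage (per-time-point index, a validity
#' flag that is always 1, the index of the same cell or its mother at the
#' previous time point, and the indices of the same cell or its two daughters
#' at the next time point, with -1 for "none"); fields 6--10 give x, y, z,
#' diameter and name; fields 11--20 are reserved (zero, except field 15 which
#' is left blank). Time points are separated by header lines of the form
#' `# time <seconds>`. The writer and [read_snapshot()] round-trip exactly.
#'
#' @param snapshots A snapshot tibble as produced by [simulate_embryo()] /
#'   [read_snapshot()]: columns `time`, `index`, `valid`, `prev`, `next1`,
#'   `next2`, `x`, `y`, `z`, `diameter`, `name`.
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(snapshots, path) {
  snapshots <- as_tibble(snapshots)
  need <- c("time", "index", "valid", "prev", "next1", "next2",
            "x", "y", "z", "diameter", "name")
  missing_cols <- setdiff(need, names(snapshots))
  if (length(missing_cols) > 0L) {
    abort(paste0("snapshot table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "elegansim_validation_error")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (tp in unique(snapshots$time)) {
    writeLines(sprintf("# time %s", fmt_num(tp)), con)
    rec <- snapshots[snapshots$time == tp, , drop = FALSE]
    writeLines(sprintf(
      "%d, %d, %d, %d, %d, %s, %s, %s, %s, %s, 0, 0, 0, 0, , 0, 0, 0, 0, 0",
      rec$index, rec$valid, rec$prev, rec$next1, rec$next2,
      fmt_num(rec$x), fmt_num(rec$y), fmt_num(rec$z), fmt_num(rec$diameter),
      rec$name
    ), con)
  }
  invisible(path)
}

#' Read a snapshot stream written in the 20-field nuclei format
#'
#' @param source Path to (or character lines of) a file written by
#'   [write_snapshot()].
#' @return A tibble with one row per cell per time point, ordered by
#'   increasing time: columns `time`, `index`, `valid`, `prev`, `next1`,
#'   `next2`, `x`, `y`, `z`, `diameter`, `name`. A blank file gives a
#'   zero-row tibble.
#' @export
read_snapshot <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  empty <- tibble(
    time = double(), index = integer(), valid = integer(), prev = integer(),
    next1 = integer(), next2 = integer(), x = double(), y = double(),
    z = double(), diameter = double(), name = character()
  )
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) return(empty)

  is_header <- grepl("^#", lines)
  if (!is_header[1L]) {
    abort("snapshot stream: first line must be a '# time <t>' header",
          class = "elegansim_parse_error")
  }
  times_here <- rep(NA_real_, length(lines))
  cur <- NA_real_
  for (i in seq_along(lines)) {
    if (is_header[i]) {
      tv <- suppressWarnings(as.numeric(sub("^#\\s*time\\s*", "", lines[i])))
      if (is.na(tv)) {
        abort(sprintf("snapshot stream: bad time header on line %d", lineno[i]),
              class = "elegansim_parse_error")
      }
      cur <- tv
    }
    times_here[i] <- cur
  }
  rec_lines <- lines[!is_header]
  rec_lineno <- lineno[!is_header]
  rec_time <- times_here[!is_header]
  if (length(rec_lines) == 0L) return(empty)

  parts <- strsplit(rec_lines, ",", fixed = TRUE)
  arity <- lengths(parts)
  if (any(arity != 20L)) {
    bad <- which(arity != 20L)[1L]
    abort(sprintf("snapshot stream: line %d has %d fields, expected 20",
                  rec_lineno[bad], arity[bad]),
          class = "elegansim_parse_error")
  }
  m <- matrix(trimws(unlist(parts)), ncol = 20L, byrow = TRUE)
  int_col <- function(j) as.integer(m[, j])
  num_col <- function(j) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      abort(sprintf("snapshot stream: non-numeric field %d on line %d",
                    j, rec_lineno[bad]),
            class = "elegansim_parse_error")
    }
    v
  }
  out <- tibble(
    time = rec_time,
    index = int_col(1L), valid = int_col(2L), prev = int_col(3L),
    next1 = int_col(4L), next2 = int_col(5L),
    x = num_col(6L), y = num_col(7L), z = num_col(8L),
    diameter = num_col(9L), name = m[, 10L]
  )
  out[order(out$time), , drop = FALSE]
}

#' Cross-check the three input tables for mutual consistency
#'
#' Every daughter named in the direction table must either appear in both the
#' schedule and position tables, or be a terminal leaf (a cell that never
#' divides, i.e. is not itself a parent in the direction table). Terminal
#' leaves may be absent from the other tables; they then simply persist
#' without dividing.
#'
#' @param time_table,direction_table,position_table Tibbles as returned by the
#'   corresponding readers.
#' @return A tibble of issues (`cell`, `issue`); zero rows when the triple is
#'   consistent.
#' @export
lint_tables <- function(time_table, direction_table, position_table) {
  daughters <- c(direction_table$daughter1, direction_table$daughter2)
  internal <- daughters[daughters %in% direction_table$parent]
  issues <- list()
  miss_t <- setdiff(internal, time_table$name)
  if (length(miss_t) > 0L) {
    issues <- c(issues, list(tibble(cell = miss_t, issue = "dividing daughter missing from time table")))
  }
  miss_p <- setdiff(internal, position_table$name)
  if (length(miss_p) > 0L) {
    issues <- c(issues, list(tibble(cell = miss_p, issue = "dividing daughter missing from position table")))
  }
  if (length(issues) == 0L) {
    return(tibble(cell = character(), issue = character()))
  }
  dplyr::bind_rows(issues)
}
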