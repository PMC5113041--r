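test_that("schedule-table rows parse, with -1 SDs flagged unavailable", {
  tb <- read_time_table(c("ABal 41.8 0.6 14.8 0.6", "X 10.0 -1 5.0 -1"))
  expect_equal(tb$name, c("ABal", "X"))
  expect_equal(tb$div_time, c(41.8, 10.0))
  expect_equal(tb$div_sd, c(0.6, NA))
  expect_equal(tb$cycle_time, c(14.8, 5.0))
  expect_equal(tb$cycle_sd, c(0.6, NA))

  expect_equal(nrow(read_time_table(character())), 0L)
  expect_error(read_time_table("A 1 0 1"), "line 1.*expected 5")
  expect_error(read_time_table("A x 0 1 0"), "non-numeric")
  expect_error(read_time_table(c("A 1 0 1 0", "A 2 0 1 0")), "duplicate")
  expect_error(read_time_table("A -5 0 1 0"), "positive")
})

test_that("direction rows are unit-normalized on load", {
  tb <- read_direction_table("ABa ABal ABar 0.285 -0.547 0.686")
  nrm <- sqrt(0.285^2 + 0.547^2 + 0.686^2)
  expect_equal(c(tb$dir_x, tb$dir_y, tb$dir_z),
               c(0.285, -0.547, 0.686) / nrm, tolerance = 1e-12)
  expect_equal(tb$dir_x^2 + tb$dir_y^2 + tb$dir_z^2, 1, tolerance = 1e-9)

  tb2 <- suppressWarnings(read_direction_table("P Pa Pp 2 0 0"))
  expect_equal(c(tb2$dir_x, tb2$dir_y, tb2$dir_z), c(1, 0, 0))
})

test_that("direction norm warning fires only past the deviation threshold", {
  # raw norm 0.9226 deviates 7.7% from 1: silent at the default 10% threshold
  expect_no_warning(read_direction_table("ABa ABal ABar 0.285 -0.547 0.686"))
  expect_warning(read_direction_table("ABa ABal ABar 0.285 -0.547 0.686",
                                      norm_tol = 0.05),
                 "unit norm")
  expect_error(read_direction_table("A B C 0 0 0"), "zero-norm")
  expect_error(read_direction_table(c("A B C 1 0 0", "A D E 0 1 0")),
               "duplicate")
  expect_error(read_direction_table("A B B 1 0 0"), "identical daughter")
})

test_that("position-table rows parse and malformed rows are rejected", {
  tb <- read_position_table("ABal -10.371 0.649 2.536")
  expect_equal(c(tb$tgt_x, tb$tgt_y, tb$tgt_z), c(-10.371, 0.649, 2.536))
  expect_equal(nrow(read_position_table(character())), 0L)
  expect_error(read_position_table("ABal -10.371 0.649"), "expected 4")
})

test_that("the snapshot line layout matches the 20-field convention", {
  rec <- tibble::tibble(
    time = 0, index = 1L, valid = 1L, prev = 1L, next1 = 1L, next2 = -1L,
    x = 48, y = -121, z = 4, diameter = 78, name = "ABp"
  )
  f <- withr::local_tempfile()
  write_snapshot(rec, f)
  lines <- readLines(f)
  expect_equal(lines[2],
               "1, 1, 1, 1, -1, 48, -121, 4, 78, ABp, 0, 0, 0, 0, , 0, 0, 0, 0, 0")
  back <- read_snapshot(f)
  expect_equal(back$name, "ABp")
  expect_equal(back$diameter, 78)
  expect_equal(back$next2, -1L)
})

test_that("snapshot write/read round-trips exactly for generated record sets", {
  for (seed in 1:6) {
    recs <- random_snapshot_table(seed)
    f <- withr::local_tempfile()
    write_snapshot(recs, f)
    expect_equal(read_snapshot(f), recs, tolerance = 0)
  }
  expect_equal(nrow(read_snapshot(character())), 0L)
  expect_error(read_snapshot("1, 2, 3"), "header")
})

test_that("a 300 s run at 60 s resolution yields six snapshot times", {
  fx <- make_fixture(n_founders = 2, generations = 0, mean_cycle = 10,
                     sd_level = 0, seed = 1)
  sim <- simulate_embryo(fx$initial, fx, sim_config(end_time = 300, seed = 1))
  f <- withr::local_tempfile()
  write_snapshot(sim$snapshots, f)
  expect_equal(unique(read_snapshot(f)$time), seq(0, 300, by = 60))
})

test_that("table lint flags dividing daughters absent from the other tables", {
  fx <- small_fixture()
  expect_equal(nrow(lint_tables(fx$tables$time, fx$tables$direction,
                                fx$tables$position)), 0L)
  # drop the schedule row of a daughter that itself divides
  internal_daughter <- intersect(fx$tables$direction$daughter1,
                                 fx$tables$direction$parent)[1]
  broken <- fx$tables$time[fx$tables$time$name != internal_daughter, ]
  issues <- lint_tables(broken, fx$tables$direction, fx$tables$position)
  expect_true(internal_daughter %in% issues$cell)
  # terminal leaves may be absent without complaint
  leaf <- setdiff(fx$tables$direction$daughter1, fx$tables$direction$parent)[1]
  ok <- fx$tables$time[fx$tables$time$name != leaf, ]
  expect_equal(nrow(lint_tables(ok, fx$tables$direction, fx$tables$position)), 0L)
})

test_that("initial-cell files parse and validate", {
  tb <- read_initial_cells(c("ABa -10 3 0 8", "ABp 0 5 0 8"))
  expect_equal(tb$name, c("ABa", "ABp"))
  expect_equal(tb$size, c(8, 8))
  expect_error(read_initial_cells(character()), "at least one")
  expect_error(read_initial_cells("A 0 0 0 -1"), "positive")
})
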