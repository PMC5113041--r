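test_that("split-phase kinematics displace each daughter by half its diameter", {
  p <- split_step(c(0, 0, 0), c(1, 0, 0), cell_size = 2, div_cycle_time = 90)
  expect_equal(p, c(2 / 2 / 90, 0, 0))

  pos <- c(0, 0, 0)
  for (i in 1:90) pos <- split_step(pos, c(1, 0, 0), 2, 90)
  expect_equal(pos, c(1, 0, 0))

  # opposite directions: siblings end one diameter apart
  a <- b <- c(0, 0, 0)
  for (i in 1:90) {
    a <- split_step(a, c(0, 1, 0), 2, 90)
    b <- split_step(b, c(0, -1, 0), 2, 90)
  }
  expect_equal(sqrt(sum((a - b)^2)), 2)
})

test_that("interphase kinematics land the cell exactly on target at division", {
  expect_equal(interphase_step(c(0, 0, 0), c(10, 0, 0), 110, 100), c(1, 0, 0))
  pos <- c(0, 0, 0)
  for (clock in 100:109) pos <- interphase_step(pos, c(10, 0, 0), 110, clock)
  expect_identical(pos, c(10, 0, 0))
  # fixed point and the passed-division guard
  expect_equal(interphase_step(c(10, 0, 0), c(10, 0, 0), 110, 100), c(10, 0, 0))
  expect_equal(interphase_step(c(3, 0, 0), c(10, 0, 0), 110, 110), c(10, 0, 0))
})

test_that("eggshell membership uses the closed ellipsoid inequality", {
  sh <- eggshell(c(25, 15, 15))
  expect_true(in_eggshell(c(0, 0, 0), sh))
  expect_false(in_eggshell(c(26, 0, 0), sh))
  expect_true(in_eggshell(c(25, 0, 0), sh))
  expect_error(eggshell(c(0, 1, 1)), "positive")
})

test_that("containment projects radially, is idempotent, and always lands inside", {
  sh <- eggshell(c(25, 15, 15))
  expect_equal(contain(c(1, 2, 3), sh), c(1, 2, 3))
  expect_equal(contain(c(50, 0, 0), sh), c(25, 0, 0))
  set.seed(42)
  pts <- matrix(stats::rnorm(300, 0, 40), ncol = 3)
  inside <- contain(pts, sh)
  expect_true(all(in_eggshell(inside, sh)))
  expect_equal(contain(inside, sh), inside)
  # off-center shells project about their own center
  sh2 <- eggshell(c(10, 10, 10), center = c(5, 0, 0))
  expect_equal(contain(c(25, 0, 0), sh2), c(15, 0, 0))
})

test_that("division-time draws honor the table, its SDs and the minute scale", {
  entry <- list(div_time = 41.8, div_sd = NA, cycle_time = 14.8, cycle_sd = NA)
  expect_identical(sample_division_time(entry), 60 * 41.8)  # 2508 s exactly

  entry0 <- list(div_time = 41.8, div_sd = 0, cycle_time = 14.8, cycle_sd = 0)
  set.seed(99)
  expect_identical(sample_division_time(entry0), 2508)

  set.seed(123)
  draws <- replicate(10000, sample_division_time(
    list(div_time = 41.8, div_sd = 0.6, cycle_time = NA, cycle_sd = NA))) / 60
  expect_equal(mean(draws), 41.8, tolerance = 0.02 / 41.8)
  expect_lt(abs(stats::sd(draws) - 0.6), 0.02)

  # cycle fallback: absolute time = born + cycle
  entry_c <- list(div_time = NA, div_sd = NA, cycle_time = 10, cycle_sd = NA)
  expect_identical(sample_division_time(entry_c, born_time = 120), 120 + 600)
})

test_that("division replaces the parent by its two named daughters", {
  tabs <- aba_tables()
  cfg <- sim_config(end_time = 100, seed = 1, shell = eggshell(c(25, 15, 15)))
  cell <- tibble::tibble(
    name = "ABa", size = 8, x = -8.2, y = 1.1, z = 0.4,
    div_time = 2508, terminal = FALSE,
    dir_x = 1, dir_y = 0, dir_z = 0, div_tick = 90,
    tgt_x = -8.2, tgt_y = 1.1, tgt_z = 0.4, founder = "ABa", newborn = FALSE
  )
  set.seed(5)
  d <- divide_cell(cell, tabs, clock = 2508, config = cfg)
  expect_equal(d$name, c("ABal", "ABar"))
  nrm <- sqrt(0.285^2 + 0.547^2 + 0.686^2)
  expect_equal(c(d$dir_x[1], d$dir_y[1], d$dir_z[1]),
               c(0.285, -0.547, 0.686) / nrm, tolerance = 1e-12)
  expect_equal(c(d$dir_x[2], d$dir_y[2], d$dir_z[2]),
               -c(d$dir_x[1], d$dir_y[1], d$dir_z[1]))
  expect_equal(c(d$tgt_x[1], d$tgt_y[1], d$tgt_z[1]), c(-10.371, 0.649, 2.536))
  expect_equal(d$size, rep(8 * 2^(-1 / 3), 2))
  expect_equal(d$div_tick, c(0, 0))
  expect_equal(c(d$x, d$y, d$z), rep(c(-8.2, 1.1, 0.4), each = 2))

  # a daughter that divides later but lacks a schedule row is an error
  tabs2 <- tabs
  tabs2$direction <- dplyr::bind_rows(
    tabs2$direction,
    read_direction_table("ABal ABala ABalp 0 0 1"))
  tabs2$time <- tabs2$time[tabs2$time$name != "ABal", ]
  expect_error(divide_cell(cell, tabs2, 2508, cfg), "ABal")
})

test_that("setup hatches founders in interphase with their table entries", {
  fx <- small_fixture()
  cfg <- sim_config(end_time = 100, seed = 3, shell = fx$shell)
  set.seed(3)
  st <- sim_setup(fx$initial, fx$tables, cfg)
  expect_s3_class(st, "sim_state")
  expect_equal(st$clock, 0)
  expect_equal(nrow(st$cells), 4L)
  expect_equal(sort(unique(st$cells$founder)), sort(fx$initial$name))
  expect_true(all(st$cells$div_tick >= cfg$div_cycle_time))  # no split phase

  missing <- fx$tables
  missing$position <- missing$position[missing$position$name != "ABa", ]
  expect_error(sim_setup(fx$initial, missing, cfg), "ABa.*position table")
})

test_that("a cell divides on the first tick at or past its scheduled time", {
  fx <- make_fixture(n_founders = 1, generations = 1, mean_cycle = 2.5,
                     cycle_jitter = 0, sd_level = 0, seed = 2)
  cfg <- sim_config(end_time = 200, seed = 1, shell = fx$shell)
  set.seed(1)
  st <- sim_setup(fx$initial, fx$tables, cfg)
  div_t <- st$cells$div_time[1]
  while (st$clock < div_t - 1) st <- sim_step(st)
  expect_equal(nrow(st$cells), 1L)
  st <- sim_step(st)
  expect_equal(nrow(st$cells), 2L)
})

test_that("runs are seed-deterministic and topology is seed-invariant", {
  fx <- small_fixture(sd_level = 0.2)
  s1 <- run_fixture(fx, seed = 11)
  s2 <- run_fixture(fx, seed = 11)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_snapshot(s1$snapshots, f1)
  write_snapshot(s2$snapshots, f2)
  expect_identical(readLines(f1), readLines(f2))

  s3 <- run_fixture(fx, seed = 12)
  expect_false(identical(s1$divisions$time, s3$divisions$time))
  t1 <- build_lineage(s1); t3 <- build_lineage(s3)
  cols <- c("name", "parent", "daughter1", "daughter2")
  expect_equal(as.data.frame(t1)[order(t1$name), cols],
               as.data.frame(t3)[order(t3$name), cols],
               ignore_attr = TRUE)
})

test_that("population growth is monotone, +1 per division, and stays in the shell", {
  fx <- small_fixture(sd_level = 0.2)
  sim <- run_fixture(fx, seed = 4)
  cc <- count_curve(sim)
  expect_true(all(diff(cc$n_cells) >= 0))
  expect_equal(nrow(sim$final_cells), nrow(fx$initial) + nrow(sim$divisions))
  expect_true(all(in_eggshell(
    as.matrix(sim$snapshots[, c("x", "y", "z")]), sim$config$shell)))
})

test_that("deterministic runs put every dividing cell exactly on its target", {
  fx <- small_fixture(sd_level = 0)
  sim <- run_fixture(fx, seed = 21, deterministic = TRUE)
  tg <- fx$tables$position
  i <- match(sim$divisions$parent, tg$name)
  err <- c(sim$divisions$x - tg$tgt_x[i],
           sim$divisions$y - tg$tgt_y[i],
           sim$divisions$z - tg$tgt_z[i])
  expect_lt(max(abs(err)), 1e-9)
})
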