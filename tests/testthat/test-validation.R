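test_that("both RMSE variants agree with a brute-force recomputation", {
  expect_equal(rmse(c(3, 4)), 5)
  expect_equal(rmse(c(3, 4), use_bessel = FALSE), 5)
  expect_equal(rmse(rep(0, 10)), 0)
  set.seed(31)
  for (i in 1:10) {
    d <- stats::rnorm(sample(2:40, 1))
    acc <- 0
    for (v in d) acc <- acc + v * v      # explicit-sum oracle
    expect_equal(rmse(d), sqrt(acc / (length(d) - 1)), tolerance = 1e-12)
    expect_equal(rmse(d, FALSE), sqrt(acc), tolerance = 1e-12)
  }
  expect_error(rmse(3), "at least two")
  expect_error(rmse(numeric(0), FALSE), "at least one")
})

test_that("cycle SD propagation is quadrature with the expected symmetries", {
  expect_equal(cycle_sd(36, 102), sqrt(36^2 + 102^2))
  expect_equal(cycle_sd(36, 102), cycle_sd(102, 36))
  expect_equal(cycle_sd(0, 7), 7)
  expect_equal(cycle_sd(5, 0), 5)
  expect_error(cycle_sd(-1, 2), "nonnegative")
})

test_that("count sampling follows the exact / nearest-common / min-difference rules", {
  # rule 1: both series have the target minute
  s <- tibble::tibble(time = c(44, 45, 46), count = c(24, 24, 25))
  o <- tibble::tibble(time = c(43, 45, 47), count = c(24, 24, 26))
  got <- sample_counts(s, o, interval = 5)
  r45 <- got[got$sample_time == 45, ]
  expect_equal(c(r45$sim_time, r45$obs_time), c(45, 45))

  # rule 2: target absent from both, nearest common minute wins (41 over 38)
  s2 <- tibble::tibble(time = c(38, 41), count = c(20, 24))
  o2 <- tibble::tibble(time = c(38, 41, 44), count = c(21, 24, 25))
  got2 <- sample_counts(s2, o2, interval = 5)    # one target at minute 40
  expect_equal(got2$sample_time, 40)
  expect_equal(got2$sim_time, 41)
  expect_equal(got2$obs_time, 41)
  expect_equal(got2$deviation, 0)

  # equidistant common minutes: the earlier one wins
  s3 <- tibble::tibble(time = c(4, 6), count = c(10, 12))
  o3 <- tibble::tibble(time = c(4, 6), count = c(10, 13))
  got3 <- sample_counts(s3, o3, interval = 5)
  expect_equal(got3$sim_time, 4)

  # rule 3: no common time in the window; minimum-difference pair chosen,
  # and the two sampling times may differ
  s4 <- tibble::tibble(time = c(4.2464, 6.9), count = c(107, 110))
  o4 <- tibble::tibble(time = c(3.0, 4.2027, 6.5), count = c(100, 111, 113))
  got4 <- sample_counts(s4, o4, interval = 5)
  expect_equal(got4$sim_time, 4.2464)
  expect_equal(got4$obs_time, 4.2027)
  expect_equal(got4$deviation, abs(107 - 111))

  expect_error(sample_counts(tibble::tibble(time = numeric(), count = integer()),
                             o, interval = 5), "nonempty")
  expect_error(sample_counts(tibble::tibble(time = 201, count = 5),
                             tibble::tibble(time = 200.4, count = 5),
                             interval = 5), "overlap")
})

test_that("a run compared against its own schedule yields zero cycle deviations", {
  fx <- small_fixture(sd_level = 0)
  ref <- make_observational_reference(fx$truth, noise_sd = 0,
                                      born_sd = 36, divided_sd = 90)
  cr <- cycle_report(fx$truth, ref)
  expect_equal(tidy(cr)$deviation, rep(0, nrow(ref)))
  expect_equal(glance(cr)$rmse, 0)
  expect_equal(glance(cr)$n_within_sd, glance(cr)$n)
  expect_equal(tidy(cr)$obs_cycle_sd, rep(cycle_sd(36, 90), nrow(ref)))
  expect_error(cycle_report(fx$truth, ref, names = "missing_cell"),
               "missing_cell")
})

test_that("cycle analysis of a stochastic run stays within snapshot quantization plus noise", {
  fx <- small_fixture(sd_level = 0.2, seed = 13)
  sim <- run_fixture(fx, seed = 5)
  tree <- build_lineage(sim)
  ref <- make_observational_reference(fx$truth, noise_sd = 0)
  cr <- cycle_report(tree, ref)
  # per-cell deviation bounded by two snapshot intervals of quantization
  # plus realized timing noise (sd 12 s per endpoint, bound at ~5 sigma)
  expect_true(all(tidy(cr)$deviation <= 2 * 60 + 5 * sqrt(2) * 12))
})

test_that("position reports recompute per-axis deviations and aggregates", {
  sim_pos <- tibble::tibble(name = c("a", "b"), x = c(1, 2), y = c(0, 1), z = c(3, 4))
  pr <- position_report(sim_pos, sim_pos)
  expect_equal(tidy(pr)$dev_x, c(0, 0))
  expect_equal(unlist(glance(pr)[, c("sigma_x", "sigma_y", "sigma_z")]),
               c(sigma_x = 0, sigma_y = 0, sigma_z = 0))
  obs_pos <- sim_pos
  obs_pos$x <- obs_pos$x + c(0.3, -0.4)
  pr2 <- position_report(sim_pos, obs_pos)
  expect_equal(glance(pr2)$sigma_x, 0.5)                     # sqrt(.09 + .16)
  expect_equal(glance(position_report(sim_pos, obs_pos, use_bessel = TRUE))$sigma_x,
               0.5)                                          # n = 2: same here
  expect_error(position_report(sim_pos, obs_pos[1, ], names = c("a", "b")),
               "not resolvable")
})

test_that("the bundled wild-type reference tables are internally consistent", {
  counts <- wt_reference("counts")
  cycles <- wt_reference("cycles")
  positions <- wt_reference("positions")
  expect_equal(nrow(counts), 30L)
  expect_equal(nrow(cycles), 12L)
  expect_equal(nrow(positions), 12L)
  expect_equal(counts$deviation, abs(counts$sim_count - counts$obs_count))
  expect_equal(cycles$sim_cycle, cycles$sim_divided - cycles$sim_born)
  expect_equal(cycles$obs_cycle, cycles$obs_divided - cycles$obs_born)
  expect_equal(cycles$deviation, abs(cycles$sim_cycle - cycles$obs_cycle))
  expect_equal(cycles$obs_cycle_sd,
               round(cycle_sd(cycles$obs_born_sd, cycles$obs_divided_sd), 4))
})

test_that("count curves and plots summarize a run faithfully", {
  fx <- small_fixture(sd_level = 0)
  sim <- run_fixture(fx, seed = 2)
  cc <- count_curve(sim)
  expect_equal(cc$n_cells[cc$time == 0], 4L)
  expect_true(all(diff(cc$n_cells) >= 0))
  expect_equal(max(cc$n_cells), 16L)
  expect_s3_class(plot_count_curve(cc), "ggplot")
  expect_s3_class(plot_count_curve(cc, tibble::tibble(time = cc$minutes,
                                                      count = cc$n_cells)),
                  "ggplot")
  expect_s3_class(plot_trajectories(sim), "ggplot")
  runs <- lapply(1:3, function(s) run_fixture(small_fixture(sd_level = 0.3), seed = s))
  p <- plot_position_spread(runs, time = 300)
  expect_s3_class(p, "ggplot")
  spread <- attr(p, "spread")
  expect_true(all(spread$x_sd >= 0))
  # a single run gives degenerate (zero-radius) spreads
  p1 <- plot_position_spread(runs[1], time = 300)
  expect_true(all(attr(p1, "spread")$x_sd == 0))
})
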