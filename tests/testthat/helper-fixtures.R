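# Shared helpers: small fixtures and canned table triples built in code.

# a compact, fast fixture: 4 founders, 2 generations, ~5 min cycles
small_fixture <- function(sd_level = 0, seed = 7, ...) {
  make_fixture(n_founders = 4, generations = 2, mean_cycle = 5,
               cycle_jitter = 1, sd_level = sd_level, seed = seed, ...)
}

run_fixture <- function(fx, seed = 1, extra_time = 120, ...) {
  end <- max(fx$truth$divided, na.rm = TRUE) + extra_time
  simulate_embryo(fx$initial, fx, sim_config(end_time = end, seed = seed, ...))
}

# hand-written three-table triple around the classic ABa division
aba_tables <- function() {
  list(
    time = read_time_table(c(
      "ABa 41.8 0.6 14.8 0.6",
      "ABal 60 -1 18.2 -1",
      "ABar 61 -1 19.2 -1"
    )),
    direction = read_direction_table("ABa ABal ABar 0.285 -0.547 0.686"),
    position = read_position_table(c(
      "ABa -8.2 1.1 0.4",
      "ABal -10.371 0.649 2.536",
      "ABar -6.4 -2.2 1.9"
    ))
  )
}

random_snapshot_table <- function(seed) {
  set.seed(seed)
  n_times <- sample(2:4, 1)
  recs <- lapply(seq_len(n_times), function(k) {
    n <- sample(1:5, 1)
    tibble::tibble(
      time = (k - 1) * 60,
      index = seq_len(n),
      valid = 1L,
      prev = if (k == 1) rep(-1L, n) else sample(c(-1L, 1L, 2L), n, replace = TRUE),
      next1 = sample(c(-1L, 1L), n, replace = TRUE),
      next2 = sample(c(-1L, 2L), n, replace = TRUE),
      x = round(stats::rnorm(n, 0, 10), 6),
      y = stats::rnorm(n, 0, 10),
      z = stats::rnorm(n, 0, 10) / 3,
      diameter = stats::runif(n, 2, 80),
      name = paste0("cell", k, "_", seq_len(n))
    )
  })
  dplyr::bind_rows(recs)
}
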