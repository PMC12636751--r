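test_that("zero-force zero-temperature steps leave positions unchanged", {
  two <- cell_state(rbind(c(0, 0), c(1.5, 0)), c("membrane", "membrane"),
                    data.frame(i = 1L, j = 2L, rest_length = 1.5,
                               stiffness = 10, kind = "membrane"),
                    empty_angles_df())
  p <- small_params(kT = 0)
  out <- step_overdamped(two, p)
  expect_identical(out$positions, two$positions)
  expect_equal(out$time, p$dt)
})

test_that("overdamped relaxation in a harmonic trap matches the closed form", {
  # two beads joined by a spring of stiffness kb relax their separation as
  # (s - r0) ~ exp(-2 kb t / gamma); with kb = k/2 this is the single-bead
  # harmonic-trap law x0 * exp(-k t / gamma)
  k <- 1; kb <- k / 2; x0 <- 0.5; r0 <- 1
  p <- sim_params(kT = 0, dt = 1e-3, gamma = 1, n_steps = 0L)
  st <- cell_state(rbind(c(0, 0), c(r0 + x0, 0)), c("membrane", "membrane"),
                   data.frame(i = 1L, j = 2L, rest_length = r0,
                              stiffness = kb, kind = "membrane"),
                   empty_angles_df())
  n_steps <- 1000L  # t = 1
  for (s in seq_len(n_steps)) st <- step_overdamped(st, p)
  sep <- st$positions[2, 1] - st$positions[1, 1]
  expect_equal(sep - r0, x0 * exp(-k * 1), tolerance = 0.01)
})

test_that("free-bead mean-squared displacement obeys the Einstein relation", {
  # 1000 independent beads on a wide grid (no interactions) double as 1000
  # replicates; MSD(t) must match 4 D t with D = kT/gamma within 3 SE
  n_side <- 32L
  n <- 1000L
  g <- expand.grid(x = seq_len(n_side), y = seq_len(n_side))[seq_len(n), ]
  pos0 <- cbind(g$x * 10, g$y * 10)
  st <- cell_state(pos0, rep("membrane", n), empty_bonds_df(),
                   empty_angles_df())
  p <- sim_params(kT = 1, gamma = 1, dt = 1e-3, n_steps = 0L)
  set.seed(99)
  for (s in 1:200) st <- step_overdamped(st, p)
  t_final <- 0.2
  d2 <- rowSums((st$positions - pos0)^2)
  msd <- mean(d2)
  se <- sd(d2) / sqrt(n)
  expect_lt(abs(msd - 4 * 1 * t_final), 3 * se)
})

test_that("tip growth honors rate, increment, cap and the binomial law", {
  p <- small_params()
  cell <- build_cell(p)
  # rate 0: unchanged
  set.seed(1)
  expect_identical(grow_filaments(cell, small_params(growth_rate = 0)),
                   cell)
  # rate 1, 10 calls, increment 0.05: every uncapped terminal bond +0.5
  p1 <- small_params(growth_rate = 1, growth_increment = 0.05,
                     max_filament_length = 1e6)
  st <- cell
  set.seed(2)
  for (s in 1:10) st <- grow_filaments(st, p1)
  info <- neuritesim:::terminal_bond_info(cell, p1)
  expect_equal(st$bonds$rest_length[info$terminal],
               cell$bonds$rest_length[info$terminal] + 0.5)
  # cap: total filament rest length never exceeds max_filament_length
  pc <- small_params(growth_rate = 1, growth_increment = 0.3,
                     max_filament_length = 6)
  st <- cell
  set.seed(3)
  for (s in 1:50) st <- grow_filaments(st, pc)
  for (f in 1:4) {
    rows <- which(st$bonds$kind == "filament" &
                    (st$filament_id[st$bonds$i] == f |
                       st$filament_id[st$bonds$j] == f))
    expect_lte(sum(st$bonds$rest_length[rows]), 6)
  }
  # binomial oracle: 500 calls x 4 filaments at rate 0.2
  pb <- small_params(growth_rate = 0.2, growth_increment = 0.01,
                     max_filament_length = 1e6)
  st <- cell
  set.seed(4)
  for (s in 1:500) st <- grow_filaments(st, pb)
  events <- sum(st$bonds$rest_length - cell$bonds$rest_length) / 0.01
  n_trials <- 500 * 4
  expect_lt(abs(events - n_trials * 0.2),
            3 * sqrt(n_trials * 0.2 * 0.8))
})

test_that("identical parameters and seed give bitwise-identical trajectories", {
  p <- small_params(n_steps = 1000L, record_every = 250L, seed = 42L)
  t1 <- run_simulation(p)
  t2 <- run_simulation(p)
  for (fr in seq_along(t1$snapshots)) {
    expect_identical(t1$snapshots[[fr]]$positions,
                     t2$snapshots[[fr]]$positions)
    expect_identical(t1$snapshots[[fr]]$bonds$rest_length,
                     t2$snapshots[[fr]]$bonds$rest_length)
  }
  t3 <- run_simulation(small_params(n_steps = 1000L, record_every = 250L,
                                    seed = 43L))
  expect_false(identical(t1$snapshots[[5]]$positions,
                         t3$snapshots[[5]]$positions))
})

test_that("bead count is conserved in every frame and times increase strictly", {
  traj <- run_simulation(small_params(n_steps = 1000L, record_every = 100L))
  counts <- vapply(traj$snapshots, function(s) nrow(s$positions), 1L)
  expect_true(all(counts == 60L))
  expect_true(all(diff(traj$times) > 0))
})

test_that("zero-temperature zero-growth dynamics never increase total energy", {
  p <- small_params(kT = 0, growth_rate = 0, n_steps = 4000L,
                    record_every = 100L, init_noise = 0.2)
  traj <- run_simulation(p)
  e <- traj$energies[, "total"]
  tol <- 1e-8 * max(abs(e)) * (p$n_steps / p$record_every)
  expect_true(all(diff(e) <= tol))
})

test_that("halving the timestep changes the fixture projection length by < 5%", {
  # deterministic comparison: kT = 0, no growth, relaxation from a large
  # initial perturbation; only integration error separates the two runs
  m1 <- analyze_trajectory(run_simulation(
    small_params(n_steps = 4000L, record_every = 1000L, kT = 0,
                 growth_rate = 0, init_noise = 0.15)), threshold = 1)
  m2 <- analyze_trajectory(run_simulation(
    small_params(n_steps = 8000L, dt = 5e-5, record_every = 2000L, kT = 0,
                 growth_rate = 0, init_noise = 0.15)), threshold = 1)
  expect_lt(abs(m1$max_projection_length - m2$max_projection_length),
            max(0.05 * m1$max_projection_length, 0.02))
})

test_that("exploding runs raise a numerical-instability error naming the step", {
  p <- small_params(dt = 0.05, kappa00 = 500, kappa = 1000,
                    n_steps = 2000L, record_every = 500L)
  expect_error(run_simulation(p), "numerical instability")
})
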