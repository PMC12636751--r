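test_that("spring term matches Hooke's law closed forms", {
  # at rest: zero energy and forces
  r <- spring_energy_force(c(0, 0), c(1, 0), stiffness = 3, rest_length = 1)
  expect_equal(r$energy, 0)
  expect_equal(r$force_i, c(0, 0))
  # k=1, r0=1, d=2: E = 1/2, |F| = 1, attractive, equal and opposite
  r <- spring_energy_force(c(0, 0), c(2, 0), stiffness = 1, rest_length = 1)
  expect_equal(r$energy, 0.5)
  expect_equal(r$force_i, c(1, 0))
  expect_equal(r$force_j, -r$force_i)
  expect_error(spring_energy_force(c(0, 0), c(0, 0), 1, 1), "degenerate")
})

test_that("per-term forces equal minus the numerical energy gradient", {
  set.seed(301)
  h <- 1e-6
  # spring, random pairs
  for (rep in 1:5) {
    pi_ <- rnorm(2); pj_ <- rnorm(2) + c(2, 0)
    k <- runif(1, 0.5, 5); r0 <- runif(1, 0.5, 2)
    ana <- spring_energy_force(pi_, pj_, k, r0)
    for (d in 1:2) {
      dp <- c(0, 0); dp[d] <- h
      g <- -(spring_energy_force(pi_ + dp, pj_, k, r0)$energy -
               spring_energy_force(pi_ - dp, pj_, k, r0)$energy) / (2 * h)
      expect_equal(ana$force_i[d], g, tolerance = 1e-6)
    }
  }
  # bending, random triples (general theta0)
  for (rep in 1:5) {
    ps <- matrix(rnorm(6, sd = 2), 3, 2)
    k <- runif(1, 1, 20); th0 <- runif(1, 0.5, 1.5 * pi)
    ana <- bending_energy_force(ps[1, ], ps[2, ], ps[3, ], k, th0)
    num <- matrix(0, 3, 2)
    for (b in 1:3) for (d in 1:2) {
      pp <- ps; pp[b, d] <- pp[b, d] + h
      pm <- ps; pm[b, d] <- pm[b, d] - h
      num[b, d] <- -(bending_energy_force(pp[1, ], pp[2, ], pp[3, ], k, th0)$energy -
                       bending_energy_force(pm[1, ], pm[2, ], pm[3, ], k, th0)$energy) / (2 * h)
    }
    ana_m <- rbind(ana$force_i, ana$force_j, ana$force_k)
    expect_equal(ana_m, num, tolerance = 1e-5, ignore_attr = TRUE)
    # Newton: net force and net torque vanish
    expect_equal(colSums(ana_m), c(0, 0), tolerance = 1e-12)
    torque <- sum(ps[, 1] * ana_m[, 2] - ps[, 2] * ana_m[, 1])
    expect_equal(torque, 0, tolerance = 1e-10)
  }
  # attraction and excluded volume on a distance grid
  grid <- seq(0.8, 2.6, by = 0.06)
  for (fn in list(function(d) attraction_energy_force(d, U3 = 4),
                  function(d) excluded_volume_energy_force(d))) {
    ana <- fn(grid)
    num <- -(vapply(grid + h, function(d) fn(d)$energy, 1) -
               vapply(grid - h, function(d) fn(d)$energy, 1)) / (2 * h)
    smooth <- abs(grid - 2^(1 / 6)) > 2 * h & abs(grid - 2.5) > 2 * h
    expect_equal(ana$force[smooth], num[smooth], tolerance = 1e-5)
  }
})

test_that("bending energy of a regular N-gon matches the closed-form sum", {
  for (N in c(6, 24, 240)) {
    k00 <- 7.5
    ang <- 2 * pi * (seq_len(N) - 1) / N
    pos <- cbind(cos(ang), sin(ang)) * 10
    tot <- 0
    for (j in seq_len(N)) {
      i <- if (j == 1) N else j - 1
      kk <- if (j == N) 1 else j + 1
      tot <- tot + bending_energy_force(pos[i, ], pos[j, ], pos[kk, ],
                                        k00, theta0 = pi)$energy
    }
    expect_equal(tot, N * k00 * (1 - cos(2 * pi / N)), tolerance = 1e-9)
  }
})

test_that("attraction honors its cutoff, depth and zero-depth contracts", {
  U3 <- 6
  # zero at and beyond the cutoff, continuous approach
  expect_equal(attraction_energy_force(2.5, U3)$energy, 0)
  expect_equal(attraction_energy_force(3.0, U3)$energy, 0)
  expect_equal(attraction_energy_force(2.5 - 1e-7, U3)$energy, 0,
               tolerance = 1e-5)
  # minimum at 2^(1/6): -U3 * (1 - shift)
  rmin <- 2^(1 / 6)
  sc6 <- (1 / 2.5)^6
  expect_equal(attraction_energy_force(rmin, U3)$energy,
               -U3 - 4 * U3 * (sc6^2 - sc6), tolerance = 1e-12)
  expect_equal(attraction_energy_force(rmin, U3)$force, 0, tolerance = 1e-9)
  # U3 = 0: pure repulsive branch below the minimum, zero beyond
  expect_gt(attraction_energy_force(1.0, 0)$energy, 0)
  expect_equal(attraction_energy_force(1.2, 0)$energy, 0)
  expect_equal(attraction_energy_force(2.0, 0)$energy, 0)
  expect_error(attraction_energy_force(0, U3), "degenerate")
})

test_that("excluded volume is zero beyond 2^(1/6) sigma and monotone below", {
  expect_equal(excluded_volume_energy_force(2^(1 / 6))$energy, 0)
  expect_equal(excluded_volume_energy_force(1.5)$energy, 0)
  e_a <- excluded_volume_energy_force(0.9)$energy
  e_b <- excluded_volume_energy_force(1.05)$energy
  expect_gt(e_a, e_b)
  expect_gt(e_b, 0)
})

test_that("total energy equals the brute-force all-pairs oracle on the fixture cell", {
  p <- small_params()
  cell <- perturb_positions(build_cell(p), 0.08, seed = 5)
  got <- total_energy(cell, p)
  want <- oracle_energy(cell, p)
  for (term in c("spring", "bending", "attraction", "excluded_volume", "total"))
    expect_equal(got[[term]], want[[term]], tolerance = 1e-10)
  expect_equal(got$total,
               got$spring + got$bending + got$attraction + got$excluded_volume,
               tolerance = 1e-9)
  # heads-only pair rule changes the breakdown and still matches the oracle
  p2 <- small_params(attract_heads_only = TRUE)
  got2 <- total_energy(cell, p2)
  want2 <- oracle_energy(cell, p2)
  expect_equal(got2$attraction, want2$attraction, tolerance = 1e-10)
  expect_equal(got2$excluded_volume, want2$excluded_volume, tolerance = 1e-10)
})

test_that("total energy is translation invariant and totals two isolated rest bonds to zero", {
  p <- small_params()
  cell <- perturb_positions(build_cell(p), 0.08, seed = 6)
  shifted <- cell
  shifted$positions <- sweep(cell$positions, 2, c(-17.3, 42.1))
  expect_equal(total_energy(cell, p)$total, total_energy(shifted, p)$total,
               tolerance = 1e-9)
  # two bonded beads at rest distance: all terms zero
  two <- cell_state(rbind(c(0, 0), c(1.5, 0)), c("membrane", "membrane"),
                    data.frame(i = 1L, j = 2L, rest_length = 1.5,
                               stiffness = 10, kind = "membrane"),
                    empty_angles_df())
  expect_equal(total_energy(two, p)$total, 0)
})

test_that("cell-list and brute-force pair enumeration agree to 1e-10", {
  p <- small_params()
  cell <- perturb_positions(build_cell(p), 0.08, seed = 7)
  e_cell <- total_energy(cell, p, method = "cell")
  e_brute <- total_energy(cell, p, method = "brute")
  for (term in c("spring", "bending", "attraction", "excluded_volume", "total"))
    expect_equal(e_cell[[term]], e_brute[[term]], tolerance = 1e-10)
  expect_equal(total_forces(cell, p, "cell"), total_forces(cell, p, "brute"),
               tolerance = 1e-10)
})

test_that("total forces sum to zero and equal minus the gradient of total energy", {
  p <- small_params()
  cell <- perturb_positions(build_cell(p), 0.08, seed = 8)
  F <- total_forces(cell, p)
  expect_equal(colSums(F), c(0, 0), tolerance = 1e-8)
  h <- 1e-6
  set.seed(302)
  for (i in sample(nrow(cell$positions), 6)) {
    for (d in 1:2) {
      cp <- cell; cp$positions[i, d] <- cp$positions[i, d] + h
      cm <- cell; cm$positions[i, d] <- cm$positions[i, d] - h
      g <- -(total_energy(cp, p)$total - total_energy(cm, p)$total) / (2 * h)
      expect_equal(F[i, d], g, tolerance = 1e-5)
    }
  }
})
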