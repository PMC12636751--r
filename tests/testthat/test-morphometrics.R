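test_that("projection length is zero for a circle and exact for a displaced bead", {
  st <- ring_state(rep(10, 48))
  expect_equal(projection_length(st), 0)
  # one bead pushed out radially by d: the median baseline is unmoved, so
  # the projection equals d up to the O(d/n) centroid shift the outlier causes
  r <- rep(10, 48); r[7] <- 13.2
  st <- ring_state(r)
  expect_equal(projection_length(st), 3.2, tolerance = 2 / 48)
  # and exactly d measured from the undisplaced circle's own centre
  pos <- st$positions
  dctr <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  expect_equal(max(dctr) - median(dctr), 3.2, tolerance = 1e-9)
  expect_error(projection_length(ring_state(rep(10, 2))), "membrane beads")
})

test_that("projection length equals an exhaustive per-bead scan on random outlines", {
  set.seed(77)
  for (rep in 1:5) {
    r <- 10 + rnorm(60, sd = 0.8)
    st <- ring_state(r)
    pos <- st$positions
    ctr <- colMeans(pos)
    d <- sqrt((pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2)
    expect_equal(projection_length(st), max(0, max(d) - median(d)),
                 tolerance = 1e-12)
  }
})

test_that("protrusion counting handles disjoint arcs and the ring seam", {
  expect_equal(count_protrusions(ring_state(rep(10, 48)), 1), 0L)
  # two disjoint displaced arcs
  r <- rep(10, 48); r[5:8] <- 13; r[30:31] <- 14
  expect_equal(count_protrusions(ring_state(r), 2), 2L)
  # an arc spanning the index seam counts once, matching a rotated recount
  r <- rep(10, 48); r[c(46:48, 1:3)] <- 13
  st <- ring_state(r)
  expect_equal(count_protrusions(st, 2), 1L)
  r_rot <- r[c(25:48, 1:24)]  # same outline, relabeled start
  expect_equal(count_protrusions(ring_state(r_rot), 2), 1L)
})

test_that("circularity matches regular-polygon closed forms and falls with protrusions", {
  # regular 240-gon: 4*pi*A/P^2 = (pi/N)/tan(pi/N)
  st <- ring_state(rep(10, 240))
  expect_equal(circularity(st), (pi / 240) / tan(pi / 240), tolerance = 1e-9)
  # square
  sq <- ring_state(rep(1, 4))
  expect_equal(circularity(sq), pi / 4, tolerance = 1e-12)
  # adding a protrusion strictly decreases circularity
  r <- rep(10, 240); r[11:14] <- 14
  expect_lt(circularity(ring_state(r)), circularity(st))
  # self-intersecting outline (bowtie) warns but still returns a value
  bow <- cell_state(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1)),
                    rep("membrane", 4),
                    data.frame(i = 1:4, j = c(2:4, 1L), rest_length = 1,
                               stiffness = 1, kind = "membrane"),
                    empty_angles_df())
  expect_warning(v <- circularity(bow), "self-intersect")
  expect_true(is.finite(v))
})

test_that("protrusion stability counts qualifying late frames", {
  mk_traj <- function(radii_list) {
    snaps <- lapply(seq_along(radii_list), function(i) {
      st <- ring_state(radii_list[[i]])
      st$time <- i
      st
    })
    structure(list(snapshots = snaps,
                   times = seq_along(radii_list), energies = NULL,
                   record_every = 1L, params = NULL, wall_metadata = list()),
              class = "trajectory")
  }
  bump <- rep(10, 48); bump[5:7] <- 14
  flat <- rep(10, 48)
  expect_equal(protrusion_stability(mk_traj(rep(list(bump), 6)), 2, 4), 1)
  expect_equal(protrusion_stability(mk_traj(rep(list(flat), 6)), 2, 4), 0)
  alt <- rep(list(bump, flat), 4)
  expect_equal(protrusion_stability(mk_traj(alt), 2, 4), 0.5)
  expect_error(protrusion_stability(mk_traj(alt), 2, 99), "window")
})

test_that("analysis composes the per-frame operators and rejects empty trajectories", {
  p <- small_params(n_steps = 600L, record_every = 200L)
  traj <- run_simulation(p)
  m <- analyze_trajectory(traj, threshold = 1.5, window = 2L)
  expect_equal(nrow(m$per_frame), length(traj$snapshots))
  expect_equal(m$per_frame$projection_length,
               vapply(traj$snapshots, projection_length, 1))
  expect_equal(m$max_projection_length, max(m$per_frame$projection_length))
  expect_equal(m$stability, protrusion_stability(traj, 1.5, 2L))
  empty <- traj
  empty$snapshots <- list()
  expect_error(analyze_trajectory(empty), "no frames")
})

test_that("morphometrics are invariant under rigid motion and index relabeling", {
  set.seed(78)
  r <- 10 + rnorm(60, sd = 0.5); r[12:15] <- 14
  st <- ring_state(r)
  moved <- st
  moved$positions <- rigid_motion(st$positions, angle = 1.1,
                                  shift = c(5.5, -3.3))
  expect_equal(projection_length(moved), projection_length(st),
               tolerance = 1e-9)
  expect_equal(count_protrusions(moved, 2), count_protrusions(st, 2))
  expect_equal(circularity(moved), circularity(st), tolerance = 1e-9)
  # relabel: rotate the radius vector; same geometry up to rotation
  st2 <- ring_state(r[c(31:60, 1:30)])
  expect_equal(projection_length(st2), projection_length(st),
               tolerance = 1e-9)
  expect_equal(count_protrusions(st2, 2), count_protrusions(st, 2))
  expect_equal(circularity(st2), circularity(st), tolerance = 1e-9)
})

test_that("enlarging a protrusion never decreases projection length", {
  r <- rep(10, 60); r[20:23] <- 12
  base <- projection_length(ring_state(r))
  for (d in seq(12.5, 16, by = 0.5)) {
    r[20:23] <- d
    nxt <- projection_length(ring_state(r))
    expect_gte(nxt, base)
    base <- nxt
  }
})
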