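th300 <- thermo_state(300)

test_that("sampling is bit-reproducible for identical seeds", {
  sys <- toy_single_well()
  t1 <- sample_trajectory(sys, th300, lambda = 1, n_frames = 200, seed = 11)
  t2 <- sample_trajectory(sys, th300, lambda = 1, n_frames = 200, seed = 11)
  expect_identical(t1$coords[100, , ], t2$coords[100, , ])
  expect_identical(t1$u_site, t2$u_site)
  t3 <- sample_trajectory(sys, th300, lambda = 1, n_frames = 200, seed = 12)
  expect_false(identical(t1$coords[100, , ], t3$coords[100, , ]))
})

test_that("a decoupled ligand samples the box uniformly", {
  sys <- toy_single_well()
  traj <- sample_trajectory(sys, th300, lambda = 0, n_frames = 50000,
                            seed = 3, step_sizes = c(3, 1), jump_prob = 0.5)
  o <- traj$coords[, "O1", ]
  expect_true(all(o >= 0 & o <= 10))
  # chi-square over the 8 octants of the box
  cell <- 1 + (o[, 1] > 5) + 2 * (o[, 2] > 5) + 4 * (o[, 3] > 5)
  counts <- tabulate(cell, nbins = 8)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("coupled single-well energies match the Boltzmann quadrature", {
  sys <- toy_single_well()
  traj <- sample_trajectory(sys, th300, lambda = 1, n_frames = 50000,
                            seed = 5, jump_prob = 0.4)
  q <- site_config_integral(sys, th300, lambda = 1)
  se <- batch_se(traj$u_site)
  expect_lt(abs(mean(traj$u_site) - q$mean_u), 3 * se + 0.005)
})

test_that("acceptance rate is strictly between 0 and 1 on a non-flat potential", {
  traj <- sample_trajectory(toy_three_well(), th300, lambda = 1,
                            n_frames = 5000, seed = 2)
  expect_gt(traj$accept_rate, 0)
  expect_lt(traj$accept_rate, 1)
})

test_that("two-well occupancy obeys detailed balance against quadrature", {
  sys <- toy_host_guest(
    box_lengths = c(10, 10, 10),
    wells = data.frame(x = c(3, 7), y = 5, z = 5, depth = c(1.2, 0.6),
                       width = 0.8),
    site_region = list(center = c(5, 5, 5), radius = 3))
  traj <- sample_trajectory(sys, th300, lambda = 1, n_frames = 60000,
                            seed = 8, step_sizes = c(1.5, 1), jump_prob = 0.4)
  left <- as.numeric(traj$coords[, "O1", 1] < 5)
  # quadrature occupancy of the left half-box
  q <- site_config_integral(sys, th300, lambda = 1)
  half <- sys
  half$box_lengths <- c(5, 10, 10)
  zl <- site_config_integral(half, th300, lambda = 1)$z
  expect_lt(abs(mean(left) - zl / q$z), 3 * batch_se(left) + 0.003)
})

test_that("window samples vanish for a flat site and follow the oracle otherwise", {
  flat <- toy_host_guest(
    box_lengths = c(10, 10, 10),
    wells = data.frame(x = 5, y = 5, z = 5, depth = 0, width = 1),
    site_region = list(center = c(5, 5, 5), radius = 3))
  w <- window_work_samples(flat, th300, lambda_schedule(2, 500, 100), seed = 1)
  expect_true(all(vapply(w, function(x) all(x$delta_u == 0), logical(1))))

  sys <- toy_single_well()
  sch <- lambda_schedule(values = c(1, 0.5, 0), samples_per_window = 20000,
                         equilibration_per_window = 2000)
  w <- window_work_samples(sys, th300, sch, seed = 4)
  expect_equal(length(w), 2L)
  expect_equal(w[[1]]$n, 20000)
  q <- site_config_integral(sys, th300, lambda = 1)
  se <- batch_se(w[[1]]$delta_u)
  expect_lt(abs(mean(w[[1]]$delta_u) - (0.5 - 1) * q$mean_u), 3 * se + 0.005)
})

test_that("seeded window sampling is reproducible", {
  sys <- toy_three_well()
  sch <- lambda_schedule(4, 300, 100)
  w1 <- window_work_samples(sys, th300, sch, seed = 9)
  w2 <- window_work_samples(sys, th300, sch, seed = 9)
  expect_identical(lapply(w1, `[[`, "delta_u"), lapply(w2, `[[`, "delta_u"))
})

test_that("invalid sampler inputs raise parameter errors", {
  sys <- toy_single_well()
  expect_error(sample_trajectory(sys, th300, 1, 10, step_sizes = c(0, 1)),
               "step_sizes")
  expect_error(sample_trajectory(sys, th300, 1.2, 10), "lambda")
  expect_error(sample_trajectory(sys, th300, 1, 0), "n_frames")
})

test_that("system validation enforces the declared invariants", {
  expect_error(toy_host_guest(c(10, 10, 10),
                              data.frame(x = 5, y = 5, z = 5, depth = -1,
                                         width = 1),
                              list(center = c(5, 5, 5), radius = 3)),
               "depth")
  expect_error(toy_host_guest(c(10, 10, 10),
                              data.frame(x = 5, y = 5, z = 5, depth = 1,
                                         width = 0),
                              list(center = c(5, 5, 5), radius = 3)),
               "width")
  expect_error(toy_host_guest(c(10, 10, 10),
                              data.frame(x = 5, y = 5, z = 5, depth = 1,
                                         width = 1),
                              list(center = c(9, 5, 5), radius = 3)),
               "inside the box")
  # site potential is never positive
  sys <- toy_three_well()
  r <- matrix(stats::runif(300, 0, 10), ncol = 3)
  expect_true(all(site_potential(sys, r) <= 0))
  expect_gt(site_volume(sys), 0)
})

test_that("lambda schedules enforce endpoints and monotonicity", {
  expect_error(lambda_schedule(values = c(1, 0.5)), "endpoints")
  expect_error(lambda_schedule(values = c(1, 0.6, 0.6, 0)), "decreasing")
  s <- lambda_schedule(24)
  expect_equal(length(s$values), 25L)
  expect_equal(s$values[1], 1)
  expect_equal(s$values[25], 0)
})
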