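crit <- hbond_criterion()

test_that("the geometric criterion applies both cutoffs with ties bonded", {
  # distance failure regardless of angle
  r <- detect_hbond(c(0, 0, 0), c(1, 0, 0), c(5, 0, 0), crit)
  expect_false(r$bonded)
  expect_equal(r$d_da, 5)
  # ideal collinear geometry
  r <- detect_hbond(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0), crit)
  expect_true(r$bonded)
  expect_equal(r$deviation, 0)
  # deviation angle slightly over the cutoff at an admissible distance
  r <- detect_hbond(c(0, 0, 0), c(1, 0, 0), c(2.4, 2.1, 0), crit)
  expect_equal(r$d_da, sqrt(2.4^2 + 2.1^2), tolerance = 1e-12)
  expect_lt(r$d_da, 3.3)
  expect_equal(r$deviation, acos(2.4 / sqrt(2.4^2 + 2.1^2)) * 180 / pi,
               tolerance = 1e-12)
  expect_gt(r$deviation, 40)
  expect_false(r$bonded)
  # ties at the exact cutoffs count as bonded
  expect_true(detect_hbond(c(0, 0, 0), c(1, 0, 0), c(3.3, 0, 0), crit)$bonded)
  expect_error(detect_hbond(c(0, 0, 0), c(0, 0, 0), c(2, 0, 0), crit),
               "coincident")
})

test_that("the alternative angle convention measures deviation at the hydrogen", {
  alt <- hbond_criterion(convention = "dha_from_180")
  # collinear D-H-A: angle at H is 180, deviation 0 in this convention
  expect_true(detect_hbond(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0), alt)$bonded)
  # a bent geometry that passes at the donor but fails at the hydrogen
  d <- c(0, 0, 0); h <- c(1, 0, 0); a <- c(2, 1.2, 0)
  at_donor <- detect_hbond(d, h, a, crit)
  at_h <- detect_hbond(d, h, a, alt)
  expect_true(at_donor$bonded)
  expect_false(at_h$bonded)
})

test_that("frame_bonded scans candidate triples in both donation directions", {
  atoms <- ligand_acceptor_atoms()
  traj <- make_trajectory(atoms, list(bonded_frame(), unbonded_frame()))
  expect_true(frame_bonded(traj, 1))
  expect_false(frame_bonded(traj, 2))

  # ligand as acceptor only: site donor-H pointing at the ligand O
  atoms2 <- data.frame(
    id = c("O1", "H1", "C1", "SD1", "SDH1"),
    role = c("donor", "hydrogen", "other", "donor", "hydrogen"),
    parent = c(NA, "O1", NA, NA, "SD1"),
    group = c("ligand", "ligand", "ligand", "site", "site"),
    stringsAsFactors = FALSE)
  # site donor 2.9 A from ligand O, its H on the D->O axis (10 deg off),
  # ligand's own H pointing away so the ligand cannot donate
  ang <- 10 * pi / 180
  frame <- rbind(O1 = c(0, 0, 0), H1 = c(-1, 0, 0), C1 = c(0.5, 1.3, 0),
                 SD1 = c(2.9, 0, 0),
                 SDH1 = c(2.9, 0, 0) - 1.0 * c(cos(ang), sin(ang), 0))
  traj2 <- make_trajectory(atoms2, list(frame))
  expect_true(frame_bonded(traj2, 1))

  expect_error(frame_bonded(traj, 1, partner_ids = character(0)),
               "empty partner")
})

test_that("occupancy bookkeeping matches prescribed bond indicators exactly", {
  atoms <- ligand_acceptor_atoms()
  # 200 frames; of the 150 post-burn-in frames exactly 60 are bonded
  set.seed(99)
  bonded_idx <- 50 + sample(150, 60)
  frames <- lapply(1:200, function(f) {
    if (f %in% bonded_idx) bonded_frame() else unbonded_frame()
  })
  traj <- make_trajectory(atoms, frames)
  occ <- occupancy(traj, burn_in_fraction = 0.25)
  expect_equal(occ$p_hb, 0.4)
  expect_equal(occ$frames_used, 150)
  expect_equal(occ$frames_excluded, 50)

  all_bonded <- make_trajectory(atoms, lapply(1:40, function(f) bonded_frame()))
  expect_equal(occupancy(all_bonded)$p_hb, 1.0)
  expect_error(occupancy(traj, burn_in_fraction = 1), "burn_in")

  # arbitrary prescribed post-burn-in mean is recovered exactly
  ind <- rep(c(TRUE, FALSE, FALSE, TRUE, TRUE), 20)
  traj3 <- make_trajectory(atoms, lapply(ind, function(b) {
    if (b) bonded_frame() else unbonded_frame()
  }))
  occ3 <- occupancy(traj3, burn_in_fraction = 0.25)
  expect_equal(occ3$p_hb, mean(ind[26:100]))
})

test_that("occupancy is invariant under rigid motions of all coordinates", {
  sys <- demo_interfaces()[["deep-hb-1"]]
  traj <- sample_trajectory(sys, thermo_state(300), lambda = 1,
                            n_frames = 2000, seed = 6)
  p0 <- occupancy(traj)$p_hb
  for (s in 1:3) {
    expect_equal(occupancy(apply_rigid_motion(traj, seed = s))$p_hb, p0,
                 tolerance = 1e-12)
  }
})

test_that("enlarging either cutoff never decreases occupancy", {
  sys <- demo_interfaces()[["deep-hb-2"]]
  traj <- sample_trajectory(sys, thermo_state(300), lambda = 1,
                            n_frames = 3000, seed = 13)
  p <- function(d, a) occupancy(traj, criterion = hbond_criterion(d, a))$p_hb
  for (d in c(2.8, 3.3, 3.8)) {
    expect_true(all(diff(vapply(c(20, 40, 60, 90), function(a) p(d, a),
                                numeric(1))) >= 0))
  }
  for (a in c(20, 40, 80)) {
    expect_true(all(diff(vapply(c(2.5, 3.0, 3.3, 4.0), function(d) p(d, a),
                                numeric(1))) >= 0))
  }
})

test_that("occupancy equals the exhaustive triple-enumeration oracle", {
  sys <- demo_interfaces()[["deep-hb-1"]]
  traj <- sample_trajectory(sys, thermo_state(300), lambda = 1,
                            n_frames = 400, seed = 31)
  expect_equal(occupancy(traj)$p_hb, oracle_phb(traj))
  # also on a hand-built mixed trajectory
  atoms <- ligand_acceptor_atoms()
  set.seed(12)
  frames <- lapply(1:60, function(f) {
    fr <- unbonded_frame()
    fr["SA1", ] <- c(stats::runif(1, 1.5, 4.5), stats::runif(1, -2, 2), 0)
    fr
  })
  traj2 <- make_trajectory(atoms, frames)
  expect_equal(occupancy(traj2)$p_hb, oracle_phb(traj2))
})

test_that("P_hb classification thresholds are strict", {
  expect_equal(classify_site_by_phb(0.85), "high")
  expect_equal(classify_site_by_phb(0.25), "low")
  expect_equal(classify_site_by_phb(0.55), "intermediate")
  expect_equal(classify_site_by_phb(0.8), "intermediate")
  expect_equal(classify_site_by_phb(0.3), "intermediate")
  expect_equal(classify_site_by_phb(c(0.9, 0.1)), c("high", "low"))
  expect_error(classify_site_by_phb(1.2), "0, 1")
})
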