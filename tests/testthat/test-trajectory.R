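# backbone RMSD, stability flag, H-bond occupancy, triage timeline

test_that("backbone RMSD: identical frames zero, rigid rotation zero", {
  cx <- make_complex(contact_plan(), seed = 3)
  traj <- make_trajectory(cx, n_frames = 5, seed = 3)
  rs <- backbone_rmsd(traj)
  expect_equal(nrow(rs), 5)
  expect_lt(max(rs$rmsd), 1e-9)
  # rotate one frame rigidly: still zero after superposition
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3))); if (det(R) < 0) R[, 1] <- -R[, 1]
  fr <- traj$frames
  fr[[3]] <- sweep(fr[[3]] %*% t(R), 2, c(5, -2, 9), "+")
  traj2 <- trajectory(traj$topology, fr, traj$times)
  expect_lt(max(backbone_rmsd(traj2)$rmsd), 1e-9)
  # reference = same frame is identically zero
  for (f in c(1L, 3L)) {
    one <- trajectory(traj$topology, traj$frames[f], traj$times[f])
    expect_lt(backbone_rmsd(one, reference_frame = 1L)$rmsd, 1e-9)
  }
})

test_that("noisy-frame backbone RMSD matches the sqrt(2) prediction", {
  set.seed(99)
  cx <- make_complex(contact_plan(), seed = 99)
  sigma <- 0.5
  traj <- make_trajectory(cx, n_frames = 51, noise_sigma = sigma, seed = 99)
  rs <- backbone_rmsd(traj)
  m <- mean(rs$rmsd[-1])   # frame 1 is the reference
  expect_lt(abs(m - sigma * sqrt(2)) / (sigma * sqrt(2)), 0.15)
})

test_that("stability flag is a strict threshold", {
  expect_true(is_stable(c(0.5, 1.2, 2.49)))
  expect_false(is_stable(c(0.5, 1.2, 2.50)))
  expect_true(is_stable(rep(0, 10)))
  expect_error(is_stable(numeric(0)), "empty")
  # monotone: stable at t implies stable at larger t
  v <- c(1.1, 2.2, 1.7)
  expect_true(is_stable(v, 2.3))
  expect_true(is_stable(v, 3.0))
})

test_that("occupancy counts planted schedules exactly", {
  plan <- contact_plan(hbonds = list(
    list(residue = "Gln421", distance = 2.9, angle = 170),
    list(residue = "His373", distance = 3.0, angle = 165)))
  cx <- make_complex(plan, seed = 17)
  sched <- list(hbond_Gln421 = rep(c(TRUE, FALSE), c(8, 12)))
  traj <- make_trajectory(cx, schedule = sched, n_frames = 20, seed = 17)
  occ <- hbond_occupancy(traj, "Gln421", window = c(0, 0.19))
  expect_equal(occ$frames_in_window, 20L)
  expect_equal(occ$frames_with_contact, 8L)
  expect_equal(occ$occupancy, 0.40)
  occH <- hbond_occupancy(traj, "His373", window = c(0, 0.19))
  expect_equal(occH$occupancy, 1.0)
  expect_gt(occH$occupancy, occ$occupancy)  # His373 persists, Gln421 breaks
  # absent everywhere: occupancy 0, no angle statistics
  none <- make_trajectory(cx, schedule = list(
    hbond_Gln421 = rep(FALSE, 10), hbond_His373 = rep(FALSE, 10)),
    n_frames = 10, seed = 17)
  occ0 <- hbond_occupancy(none, "Gln421", window = c(0, 0.09))
  expect_equal(occ0$occupancy, 0)
  expect_true(is.na(occ0$mean_angle))
  expect_error(hbond_occupancy(traj, "Gln421", window = c(5, 20)),
               "outside")
})

test_that("occupancy is invariant to frame reordering and duplication", {
  plan <- contact_plan(hbonds = list(
    list(residue = "Gln421", distance = 2.9, angle = 170)))
  cx <- make_complex(plan, seed = 2)
  sched <- list(hbond_Gln421 = c(TRUE, FALSE, TRUE, TRUE, FALSE,
                                 FALSE, TRUE, FALSE, FALSE, FALSE))
  traj <- make_trajectory(cx, schedule = sched, n_frames = 10, seed = 2)
  base <- hbond_occupancy(traj, "Gln421", window = c(0, 0.09))$occupancy
  set.seed(31)
  perm <- sample(10)
  shuffled <- trajectory(traj$topology, traj$frames[perm], traj$times)
  expect_equal(hbond_occupancy(shuffled, "Gln421",
                               window = c(0, 0.09))$occupancy, base)
  doubled <- trajectory(traj$topology,
                        traj$frames[rep(1:10, each = 2)],
                        seq(0, by = 0.005, length.out = 20))
  expect_equal(hbond_occupancy(doubled, "Gln421",
                               window = c(0, 0.099))$occupancy, base)
})

test_that("planted angle distribution is recovered by the angle statistics", {
  set.seed(77)
  angles <- pmin(179.5, rnorm(100, 160, 5))
  prot <- gln_protein(c(0, 0, 0))
  frames <- lapply(angles, function(a) {
    lig <- donor_ligand(c(2.9, 0, 0), c(0, 0, 0), angle = a)
    rbind(protein_coords(prot), lig$conformers[[1]])
  })
  lig0 <- donor_ligand(c(2.9, 0, 0), c(0, 0, 0), angle = 160)
  traj <- trajectory(list(protein = prot, ligand = lig0), frames,
                     times = (seq_along(frames) - 1) * 0.01)
  occ <- hbond_occupancy(traj, "Gln421", window = c(0, 1))
  expect_equal(occ$occupancy, 1)
  expect_lt(abs(occ$mean_angle - 160), 2)
  expect_lt(abs(occ$sd_angle - 5), 2)
})

test_that("contact timeline fraction follows the schedule", {
  plan <- contact_plan(
    hbonds = list(list(residue = "Gln421", distance = 2.9, angle = 175)),
    stacks = list(list(residue = "Phe424", distance = 3.8, interplanar = 5)))
  cx <- make_complex(plan, seed = 5)
  stat <- make_trajectory(cx, n_frames = 6, seed = 5)
  tl <- contact_timeline(stat)
  expect_equal(attr(tl, "fraction_round1"), 1.0)
  # break the only anchor halfway -> round 1 fails in those frames
  half <- make_trajectory(cx, schedule = list(
    hbond_Gln421 = rep(c(TRUE, FALSE), each = 3)), n_frames = 6, seed = 5)
  tl2 <- contact_timeline(half)
  expect_equal(attr(tl2, "fraction_round1"), 0.5)
  expect_equal(tl2$round1_pass, rep(c(TRUE, FALSE), each = 3))
})

test_that("window slicing keeps in-window frames only", {
  cx <- make_complex(contact_plan(), seed = 1)
  traj <- make_trajectory(cx, n_frames = 10, seed = 1)
  sl <- slice_window(traj, c(0.03, 0.07))
  expect_equal(sl$times, seq(0.03, 0.07, by = 0.01))
  expect_error(slice_window(traj, c(5, 6)), "no frames")
})
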