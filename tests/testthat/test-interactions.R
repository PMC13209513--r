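# geometric contact detectors and the two-round pose triage

test_that("H-bonds: colinear accepted, long rejected, 125 vs 115 degrees", {
  prot <- gln_protein(c(0, 0, 0))
  # N-H...O colinear at 2.9 A
  lig <- donor_ligand(c(2.9, 0, 0), c(0, 0, 0), angle = 180)
  hb <- detect_hbonds(prot, lig, residues = "Gln421")
  lighb <- hb[hb$donor_side == "ligand", ]
  expect_equal(nrow(lighb), 1)
  expect_equal(lighb$distance, 2.9, tolerance = 1e-6)
  expect_equal(lighb$angle, 180, tolerance = 1e-6)
  # 4.0 A exceeds the 3.5 A default
  far <- donor_ligand(c(4.0, 0, 0), c(0, 0, 0), angle = 180)
  expect_equal(nrow(detect_hbonds(prot, far, residues = "Gln421")), 0)
  # 3.4 A: angle 125 passes, 115 fails
  ok <- donor_ligand(c(3.4, 0, 0), c(0, 0, 0), angle = 125)
  bad <- donor_ligand(c(3.4, 0, 0), c(0, 0, 0), angle = 115)
  expect_equal(nrow(detect_hbonds(prot, ok, residues = "Gln421")), 1)
  expect_equal(nrow(detect_hbonds(prot, bad, residues = "Gln421")), 0)
})

test_that("H-bond distance cutoff relaxation yields a superset", {
  set.seed(4)
  cx <- make_complex(contact_plan(hbonds = list(
    list(residue = "Gln421", distance = 3.3, angle = 150))), seed = 4)
  tight <- detect_hbonds(cx$protein, cx$ligand, dist_max = 3.5)
  loose <- detect_hbonds(cx$protein, cx$ligand, dist_max = 4.5)
  key <- function(d) paste(d$donor_side, d$residue, d$protein_atom,
                           d$ligand_atom)
  expect_true(all(key(tight) %in% key(loose)))
  expect_gte(nrow(loose), nrow(tight))
})

test_that("ring stacks: parallel close, far apart, perpendicular", {
  phe <- function() {
    ring <- hexagon_xyz(c(0, 0, 0))
    nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    protein_structure("phe", data.frame(
      eleno = 1:6, name = nm, element = "C", resname = "PHE", chain = "A",
      resno = 424L, het = FALSE, x = ring[, 1], y = ring[, 2], z = ring[, 3]))
  }
  prot <- phe()
  parallel <- make_benzene("b", ctr = c(0, 0, 3.8))
  st <- detect_ring_stacks(prot, parallel, residues = "Phe424")
  expect_equal(nrow(st), 1)
  expect_identical(st$geometry, "face_to_face")
  expect_equal(st$distance, 3.8, tolerance = 1e-6)
  expect_lt(st$offset, 1e-6)

  far <- make_benzene("b", ctr = c(0, 0, 8))
  expect_equal(nrow(detect_ring_stacks(prot, far, residues = "Phe424")), 0)

  perp <- make_benzene("b", ctr = c(0, 0, 5), normal = c(1, 0, 0))
  st2 <- detect_ring_stacks(prot, perp, residues = "Phe424")
  expect_equal(nrow(st2), 1)
  expect_identical(st2$geometry, "edge_to_face")
  expect_equal(st2$interplanar, 90, tolerance = 1e-6)
})

test_that("pocket contacts hit the planted set only; absent residue errors", {
  set.seed(6)
  cx <- make_complex(contact_plan(pockets = list(
    list(set = "H-loop", distance = 3.9))), seed = 6)
  hl <- pocket_contact(cx$protein, cx$ligand, pocket_residues("H-loop"))
  q2 <- pocket_contact(cx$protein, cx$ligand, pocket_residues("Q2"))
  expect_true(hl$contact)
  expect_false(q2$contact)
  expect_equal(min(hl$pairs$distance), 3.9, tolerance = 1e-6)
  expect_error(pocket_contact(cx$protein, cx$ligand, "Trp999"), "Trp999")
  # nearest approach beyond the cutoff -> no contact
  farcx <- make_complex(contact_plan(), seed = 6)
  expect_false(pocket_contact(farcx$protein, farcx$ligand,
                              pocket_residues("Q2"))$contact)
})

test_that("clash counting: clean pose 0, planted overlaps exact", {
  cx0 <- make_complex(contact_plan(), seed = 8)
  expect_equal(count_clashes(cx0$protein, cx0$ligand), 0L)
  for (k in c(1L, 3L)) {
    cxk <- make_complex(contact_plan(clashes = k), seed = 8)
    expect_equal(count_clashes(cxk$protein, cxk$ligand), k)
  }
  # a single atom 1.5 A from a backbone C clashes
  prot <- toy_pde1_scaffold()
  crow <- which(prot$atoms$name == "C")[1]
  probe <- molecule("x", "C", NULL, list(matrix(
    unlist(prot$atoms[crow, c("x", "y", "z")]) + c(1.5, 0, 0), 1, 3)))
  expect_gte(count_clashes(prot, probe), 1L)
})

test_that("triage: conjunction of anchors, stack and no-clash; round 2", {
  full <- contact_plan(
    hbonds = list(list(residue = "Gln421", distance = 2.9, angle = 175)),
    stacks = list(list(residue = "Phe424", distance = 3.8, interplanar = 5)),
    pockets = list(list(set = "H-loop", distance = 3.9)))
  cx <- make_complex(full, seed = 17)
  td <- triage_pose(cx$protein, cx$ligand)
  expect_true(td$round1_pass)
  expect_true(td$round2_preferred)   # H-loop arm engaged
  expect_equal(td$clash_count, 0L)

  nostack <- contact_plan(
    hbonds = list(list(residue = "Gln421", distance = 2.9, angle = 175)))
  td2 <- triage_pose(make_complex(nostack, seed = 17)$protein,
                     make_complex(nostack, seed = 17)$ligand)
  expect_false(td2$round1_pass)
  expect_false(td2$round2_preferred)

  his_only <- contact_plan(
    hbonds = list(list(residue = "His373", distance = 3.0, angle = 160)),
    stacks = list(list(residue = "Phe424", distance = 4.0, interplanar = 10)))
  td3 <- triage_pose(make_complex(his_only, seed = 17)$protein,
                     make_complex(his_only, seed = 17)$ligand)
  expect_true(td3$round1_pass)
  expect_false(td3$round2_preferred)
  expect_true(td3$reasons[["hbond_His373"]])
  expect_false(td3$reasons[["hbond_Gln421"]])

  # a clash vetoes round 1 even with anchors present
  clashed <- contact_plan(
    hbonds = list(list(residue = "Gln421", distance = 2.9, angle = 175)),
    stacks = list(list(residue = "Phe424", distance = 3.8, interplanar = 5)),
    clashes = 2)
  td4 <- triage_pose(make_complex(clashed, seed = 17)$protein,
                     make_complex(clashed, seed = 17)$ligand)
  expect_false(td4$round1_pass)
  expect_equal(td4$clash_count, 2L)
})

test_that("detectors are invariant under a joint rigid transform", {
  set.seed(13)
  plan <- contact_plan(
    hbonds = list(list(residue = "Gln421", distance = 3.1, angle = 150)),
    stacks = list(list(residue = "Phe424", distance = 4.2, interplanar = 20)),
    pockets = list(list(set = "Q2", distance = 3.6)))
  cx <- make_complex(plan, seed = 13)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3))); if (det(R) < 0) R[, 1] <- -R[, 1]
  tr <- c(12, -7, 30)
  prot2 <- cx$protein
  prot2$atoms[, c("x", "y", "z")] <-
    sweep(protein_coords(cx$protein) %*% t(R), 2, tr, "+")
  lig2 <- cx$ligand
  lig2$conformers[[1]] <- sweep(cx$ligand$conformers[[1]] %*% t(R), 2, tr, "+")
  td1 <- triage_pose(cx$protein, cx$ligand)
  td2 <- triage_pose(prot2, lig2)
  expect_identical(td1$round1_pass, td2$round1_pass)
  expect_identical(td1$round2_preferred, td2$round2_preferred)
  expect_identical(td1$reasons, td2$reasons)
  expect_identical(td1$clash_count, td2$clash_count)
})

test_that("pose RMSD: identity, translation, hand-computed case, symmetry", {
  b <- make_benzene()
  expect_equal(pose_rmsd(b, b), 0)
  shifted <- b
  shifted$conformers[[1]] <- sweep(b$conformers[[1]], 2, c(3, 0, 0), "+")
  expect_equal(pose_rmsd(b, shifted, superpose = FALSE), 3.0,
               tolerance = 1e-9)
  expect_lt(pose_rmsd(b, shifted, superpose = TRUE), 1e-9)
  # two-atom toy: deviations 1 and 2 -> sqrt((1+4)/2)
  a <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  bb <- matrix(c(1, 0, 0, 1, 2, 0), 2, 3, byrow = TRUE)
  expect_equal(pose_rmsd(a, bb), sqrt(5 / 2))
  expect_equal(pose_rmsd(a, bb), pose_rmsd(bb, a))
  expect_lte(pose_rmsd(a, bb, superpose = TRUE), pose_rmsd(a, bb))
  expect_error(pose_rmsd(make_benzene(), make_acetone()), "mismatch")
})
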