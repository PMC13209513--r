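# feature perception, consensus model construction, matching, screening,
# refinement

test_that("perception: benzene, acetone, biphenyl, diphenylmethane", {
  fb <- perceive_features(make_benzene())
  expect_equal(nrow(fb), 1)
  expect_setequal(fb$kinds[[1]], c("AROMATIC_RING", "HYDROPHOBIC"))
  expect_equal(c(fb$x, fb$y, fb$z), c(0, 0, 0), tolerance = 1e-9)

  fa <- perceive_features(make_acetone())
  expect_equal(nrow(fa), 1)
  expect_identical(fa$kinds[[1]], "HBA")
  expect_equal(c(fa$x, fa$y, fa$z), c(0, 1.22, 0))

  fbi <- perceive_features(make_biphenyl())
  expect_equal(sum(vapply(fbi$kinds, function(k) "AROMATIC_RING" %in% k,
                          TRUE)), 2)
  expect_false(any(vapply(fbi$kinds, function(k) "LINKER" %in% k, TRUE)))

  fdp <- perceive_features(make_diphenylmethane())
  expect_equal(sum(vapply(fdp$kinds, function(k) "AROMATIC_RING" %in% k,
                          TRUE)), 2)
  link <- which(vapply(fdp$kinds, function(k) "LINKER" %in% k, TRUE))
  expect_length(link, 1)
  expect_equal(c(fdp$x[link], fdp$y[link], fdp$z[link]), c(2.6, 1.4, 0))
})

test_that("perception flags donors/acceptors from explicit and implied H", {
  # methanol-like: C-O-H explicit
  meoh <- molecule("meoh", c("C", "O", "H"),
                   data.frame(i = c(1, 2), j = c(2, 3), order = 1L),
                   list(rbind(c(0, 0, 0), c(1.4, 0, 0), c(1.8, 0.9, 0))))
  f <- perceive_features(meoh)
  expect_setequal(f$kinds[[1]], c("HBA", "HBD"))
  # dimethyl-ether-like O: two heavy bonds, no H -> acceptor only
  ether <- molecule("ether", c("C", "O", "C"),
                    data.frame(i = c(1, 2), j = c(2, 3), order = 1L),
                    list(rbind(c(-1.4, 0, 0), c(0, 0, 0), c(1.4, 0, 0))))
  fe <- perceive_features(ether)
  expect_identical(fe$kinds[[1]], "HBA")
  expect_error(perceive_features(meoh, conformer = 3L), "out of range")
})

test_that("exact and rigidly moved copies of the model match with RMSD 0", {
  m <- default_pde1_model()
  pts <- make_points(as.matrix(m$features[, c("x", "y", "z")]),
                     as.list(m$features$kind))
  r <- match_points(m, pts)
  expect_false(is.null(r))
  expect_lt(r$fit_rmsd, 1e-9)

  set.seed(42)
  moved <- make_points(random_rigid(as.matrix(m$features[, c("x", "y", "z")])),
                       as.list(m$features$kind))
  r2 <- match_points(m, moved)
  expect_false(is.null(r2))
  expect_lt(r2$fit_rmsd, 1e-9)
})

test_that("matching decision and fit RMSD are rigid-transform invariant", {
  set.seed(101)
  m <- default_pde1_model()
  deck <- make_screen_deck(m, n_actives = 3, n_decoys = 2,
                           jitter_frac = 0.6, seed = 101)
  for (mol in deck$molecules) {
    r1 <- match_pharmacophore(m, mol)
    mol2 <- mol
    mol2$conformers[[1]] <- random_rigid(mol$conformers[[1]])
    r2 <- match_pharmacophore(m, mol2)
    expect_identical(r1$matched, r2$matched)
    if (r1$matched) expect_equal(r1$fit_rmsd, r2$fit_rmsd, tolerance = 1e-6)
  }
})

test_that("matching is monotone in tolerance radii", {
  set.seed(7)
  m <- default_pde1_model()
  deck <- make_screen_deck(m, n_actives = 4, n_decoys = 4,
                           jitter_frac = 0.7, seed = 7)
  bigger <- m
  bigger$features$radius <- pmin(m$features$radius * 1.5, 3)
  for (mol in deck$molecules) {
    if (match_pharmacophore(m, mol)$matched)
      expect_true(match_pharmacophore(bigger, mol)$matched)
  }
})

test_that("any-conformer rule: a hit through a later conformer is a hit", {
  m <- default_pde1_model()
  deck <- make_screen_deck(m, n_actives = 1, n_decoys = 1,
                           jitter_frac = 0, seed = 12)
  good <- deck$molecules[[1]]; bad <- deck$molecules[[2]]
  # same atom table: stack decoy-like scrambled conformers before the match
  scrambled <- good$conformers[[1]] + matrix(30, n_atoms(good), 3) +
    matrix(rnorm(3 * n_atoms(good), 0, 5), ncol = 3)
  multi <- molecule(good$id, good$elements, good$bonds,
                    list(scrambled, scrambled + 40, good$conformers[[1]],
                         scrambled + 80, scrambled + 120))
  r <- match_pharmacophore(m, multi)
  expect_true(r$matched)
  expect_equal(r$conformer, 3L)
  scr <- screen_library(m, list(multi, bad))
  expect_identical(attr(scr, "hits"), good$id)
  expect_identical(scr$id, c(good$id, bad$id))   # input order preserved
})

test_that("consensus model from identical copies reproduces perception", {
  set.seed(3)
  lig <- make_diphenylmethane()
  model <- build_consensus_model(rep(list(lig), 5))
  f <- perceive_features(lig)
  expect_equal(nrow(model$features), nrow(f))
  got <- as.matrix(model$features[, c("x", "y", "z")])
  want <- as.matrix(f[, c("x", "y", "z")])
  # order-insensitive comparison
  d <- as.matrix(stats::dist(rbind(got, want)))[seq_len(nrow(got)),
                                                nrow(got) + seq_len(nrow(want))]
  expect_lt(max(apply(d, 1, min)), 1e-9)
  expect_true(all(model$features$radius == 1.0))
})

test_that("consensus: shared centers 0.5 A apart merge at the midpoint", {
  mk <- function(id, aro_ctr) {
    xyz <- rbind(hexagon_xyz(aro_ctr),
                 c(4, 0, 0), c(4, 0, 1.23),       # carbonyl O + C
                 c(2, 3, 0), c(2, 3.6, 0.8))      # amine N + H
    molecule(id, c(rep("C", 6), "O", "C", "N", "H"),
             rbind(data.frame(i = 1:6, j = c(2:6, 1), order = 4L),
                   data.frame(i = 7L, j = 8L, order = 2L),
                   data.frame(i = 9L, j = 10L, order = 1L)),
             list(xyz))
  }
  l1 <- mk("l1", c(0, 0, 0)); l2 <- mk("l2", c(0.5, 0, 0))
  m <- build_consensus_model(list(l1, l2), min_support = 2)
  aro <- which(m$features$kind == "AROMATIC_RING")
  expect_length(aro, 1)
  expect_equal(unlist(m$features[aro, c("x", "y", "z")], use.names = FALSE),
               c(0.25, 0, 0), tolerance = 1e-9)
  expect_true(all(m$features$radius == 1.0))
  expect_error(build_consensus_model(list(l1)), ">= 2")
  far <- mk("l3", c(40, 0, 0))
  far$conformers[[1]] <- far$conformers[[1]] + 100
  expect_error(build_consensus_model(list(l1, far), cluster_radius = 1.5,
                                     min_support = 2), "support")
})

test_that("consensus recovers a planted 5-feature overlay under noise", {
  set.seed(55)
  centers <- rbind(c(0, 0, 0), c(3, 0.5, 0), c(-1, 2.4, 0.3),
                   c(4.5, -1.5, 0.5), c(-2.8, -2, -0.4))
  kinds <- c("AROMATIC_RING", "AROMATIC_RING", "HBA", "HYDROPHOBIC", "HBD")
  ligs <- lapply(1:5, function(li) {
    jit <- centers + matrix(rnorm(15, 0, 0.3), 5, 3)
    # one fragment per feature, mirroring the deck generator's chemistry
    els <- character(0); xyz <- NULL
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
    for (k in 1:5) {
      off <- length(els)
      if (kinds[k] == "AROMATIC_RING") {
        els <- c(els, rep("C", 6)); xyz <- rbind(xyz, hexagon_xyz(jit[k, ]))
        bonds <- rbind(bonds, data.frame(i = off + 1:6, j = off + c(2:6, 1),
                                         order = 4L))
      } else if (kinds[k] == "HBA") {
        els <- c(els, "O", "C")
        xyz <- rbind(xyz, jit[k, ], jit[k, ] + c(1.23, 0, 0))
        bonds <- rbind(bonds, data.frame(i = off + 1L, j = off + 2L,
                                         order = 2L))
      } else if (kinds[k] == "HBD") {
        els <- c(els, "N", "H")
        xyz <- rbind(xyz, jit[k, ], jit[k, ] + c(1.01, 0, 0))
        bonds <- rbind(bonds, data.frame(i = off + 1L, j = off + 2L,
                                         order = 1L))
      } else {
        els <- c(els, rep("C", 4))
        loc <- rbind(c(0, 0, 0), c(1.54, 0, 0), c(-0.7, 1.4, 0),
                     c(-0.7, -1.4, 0))
        loc <- sweep(loc, 2, colMeans(loc))
        xyz <- rbind(xyz, sweep(loc, 2, jit[k, ], "+"))
        bonds <- rbind(bonds, data.frame(i = off + 1L, j = off + 2:4,
                                         order = 1L))
      }
    }
    molecule(paste0("lig", li), els, bonds, list(xyz))
  })
  m <- build_consensus_model(ligs, cluster_radius = 1.5, min_support = 5)
  expect_equal(nrow(m$features), 5)
  got <- as.matrix(m$features[, c("x", "y", "z")])
  d <- sqrt(outer(rowSums(got^2), rowSums(centers^2), "+") -
              2 * got %*% t(centers))
  expect_lt(max(apply(d, 2, min)), 0.5)
})

test_that("refinement: planted-decoy shrinkage, tie rule, monotone GH", {
  set.seed(21)
  # two aromatic features + one acceptor; the acceptor's sphere (F3) is the
  # one refinement must shrink
  centers <- rbind(c(0, 0, 0), c(4, 0, 0), c(2, 3, 0))
  m <- make_model(centers, c("AROMATIC_RING", "AROMATIC_RING", "HBA"),
                  c(1.0, 1.0, 1.0))
  # place the acceptor so its distance to F1 stretches by `delta` while its
  # distance to F2 is unchanged (circle-circle intersection in the plane)
  stretched_p3 <- function(delta) {
    r1 <- sqrt(13) + delta; r2 <- sqrt(13)
    x <- (16 + r1^2 - r2^2) / 8
    c(x, sqrt(r1^2 - x^2), 0)
  }
  make_lig <- function(id, p3, jit = 0) {
    p12 <- centers[1:2, ] + matrix(runif(6, -jit, jit), 2, 3)
    xyz <- rbind(hexagon_xyz(p12[1, ]), hexagon_xyz(p12[2, ]),
                 p3, p3 + c(0, 0, 1.23))
    bonds <- rbind(data.frame(i = 1:6, j = c(2:6, 1), order = 4L),
                   data.frame(i = 7:12, j = c(8:12, 7), order = 4L),
                   data.frame(i = 13L, j = 14L, order = 2L))
    molecule(id, c(rep("C", 12), "O", "C"), bonds, list(xyz))
  }
  # three near-exact actives; one with the acceptor stretched 1.1 A (kept at
  # radius 0.7, lost at 0.5); decoys stretched 1.75 A (lost at 0.7, where
  # 1.75 exceeds the 1.0 + 0.7 pair tolerance)
  actives <- c(lapply(1:3, function(k)
    make_lig(paste0("a", k), centers[3, ], jit = 0.1)),
    list(make_lig("a4", stretched_p3(1.1))))
  decoys <- lapply(1:4, function(k) make_lig(paste0("d", k),
                                             stretched_p3(1.75)))
  gh0 <- pharmfunnel:::model_gh(m, actives, decoys)$gh
  rf <- refine_model(m, actives, decoys)
  gh1 <- pharmfunnel:::model_gh(rf$model, actives, decoys)$gh
  expect_gte(gh1, gh0)
  expect_equal(gh1, 1.0)
  expect_equal(rf$model$features$radius[3], 0.7)
  # refined model keeps every active and rejects every decoy
  expect_true(all(vapply(actives, function(x)
    match_pharmacophore(rf$model, x)$matched, TRUE)))
  expect_false(any(vapply(decoys, function(x)
    match_pharmacophore(rf$model, x)$matched, TRUE)))
  expect_error(refine_model(m, list(), decoys), "degenerate")
})

test_that("refinement keeps the incumbent when it is already optimal", {
  set.seed(33)
  centers <- rbind(c(0, 0, 0), c(4, 0, 0), c(2, 3, 0))
  m <- make_model(centers, c("AROMATIC_RING", "AROMATIC_RING", "HBA"),
                  c(0.8, 0.8, 0.8))
  mk <- function(id) {
    xyz <- rbind(hexagon_xyz(centers[1, ]), hexagon_xyz(centers[2, ]),
                 centers[3, ], centers[3, ] + c(0, 0, 1.23))
    molecule(id, c(rep("C", 12), "O", "C"),
             rbind(data.frame(i = 1:6, j = c(2:6, 1), order = 4L),
                   data.frame(i = 7:12, j = c(8:12, 7), order = 4L),
                   data.frame(i = 13L, j = 14L, order = 2L)),
             list(xyz))
  }
  actives <- lapply(1:3, function(k) mk(paste0("a", k)))
  # grid without smaller winners: incumbent 0.8 not on grid, all radii give
  # GH = 1 with no decoys lost -> tie rule picks the smallest candidate
  rf <- refine_model(m, actives, list(), radius_grid = c(1.0, 1.2))
  expect_true(all(rf$model$features$radius == 0.8))
  expect_equal(rf$trace$gh, rep(1, 3))
})
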