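# Synthetic-fixture generators: pharmacophore screening decks with planted
# actives/decoys, toy protein-ligand complexes with planted contacts,
# multi-frame trajectories with planted contact schedules, and the packaged
# 26-compound screening table. Identical (spec, seed) pairs give identical
# outputs; per-generator substreams are derived from the one seed.
#
# Toy protein scaffolds are minimal residue placements (hotspot residues
# with correct atom names and locally sensible geometry), not folded
# proteins: the detectors only need local geometry.

# ----------------------------------------------------- molecular fragments

frag_hexagon <- function(center, normal, radius = 1.39) {
  p1 <- perp_vector(normal); p2 <- unit(pracma_cross(normal, p1))
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  t(vapply(ang, function(a)
    center + radius * (cos(a) * p1 + sin(a) * p2), numeric(3)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# fragment builders return list(elements, coords, bonds, point_atoms);
# bonds are local 1-based; point_atoms = atoms whose centroid is the
# planted feature point
frag_aromatic_ring <- function(center) {
  coords <- frag_hexagon(center, unit(stats::rnorm(3)))
  list(elements = rep("C", 6), coords = coords,
       bonds = data.frame(i = 1:6, j = c(2:6, 1), order = 4L),
       point_atoms = 1:6)
}

frag_aliphatic_ring <- function(center) {
  p1 <- unit(stats::rnorm(3)); n <- unit(stats::rnorm(3))
  p1 <- unit(p1 - sum(p1 * n) * n); p2 <- unit(pracma_cross(n, p1))
  ang <- seq(0, 2 * pi, length.out = 6)[1:5]
  coords <- t(vapply(ang, function(a)
    center + 1.21 * (cos(a) * p1 + sin(a) * p2), numeric(3)))
  list(elements = rep("C", 5), coords = coords,
       bonds = data.frame(i = 1:5, j = c(2:5, 1), order = 1L),
       point_atoms = 1:5)
}

frag_tert_butyl <- function(center) {
  # central C + 3 terminal methyls; centroid of the 4 carbons at `center`
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1)) / sqrt(3)
  R <- random_rotation()
  local <- rbind(c(0, 0, 0), 1.54 * dirs %*% t(R))
  local <- sweep(local, 2, colMeans(local))
  list(elements = rep("C", 4),
       coords = sweep(local, 2, center, "+"),
       bonds = data.frame(i = 1L, j = 2:4, order = 1L),
       point_atoms = 1:4)
}

frag_carbonyl_acceptor <- function(center) {
  d <- unit(stats::rnorm(3))
  list(elements = c("O", "C"),
       coords = rbind(center, center + 1.23 * d),
       bonds = data.frame(i = 1L, j = 2L, order = 2L),
       point_atoms = 1L)
}

frag_amine_donor <- function(center, toward = NULL, angle = 175) {
  # N at `center` with one explicit H; when `toward` (an acceptor position)
  # is given, the H realises the requested D-H...A angle
  u <- if (is.null(toward)) unit(stats::rnorm(3)) else unit(toward - center)
  h <- if (is.null(toward)) {
    center + 1.01 * u
  } else {
    place_h_for_angle(center, toward, angle)
  }
  cstub <- center + 1.5 * perp_vector(u)
  list(elements = c("N", "H", "C"),
       coords = rbind(center, h, cstub),
       bonds = data.frame(i = c(1L, 1L), j = c(2L, 3L), order = 1L),
       point_atoms = 1L)
}

# H on donor D such that |DH| = 1.01 and the D-H...A angle equals `angle`
place_h_for_angle <- function(D, A, angle) {
  u <- unit(A - D); p <- perp_vector(u)
  f <- function(alpha) {
    h <- D + 1.01 * (cos(alpha) * u + sin(alpha) * p)
    angle_deg(D, h, A) - angle
  }
  if (abs(f(0)) < 1e-9) return(D + 1.01 * u)
  alpha <- stats::uniroot(f, c(0, pi * 0.98), tol = 1e-12)$root
  D + 1.01 * (cos(alpha) * u + sin(alpha) * p)
}

frag_methyl_probe <- function(position) {
  list(elements = "C", coords = matrix(position, 1, 3),
       bonds = data.frame(i = integer(0), j = integer(0), order = integer(0)),
       point_atoms = 1L)
}

# assemble fragments into one molecule; linker features are resolved last
# by bonding a carbon to the two nearest ring fragments
assemble_molecule <- function(id, targets, kinds) {
  frags <- vector("list", length(kinds))
  ring_frag <- logical(length(kinds))
  for (k in seq_along(kinds)) {
    frags[[k]] <- switch(kinds[k],
      AROMATIC_RING = { ring_frag[k] <- TRUE; frag_aromatic_ring(targets[k, ]) },
      HYDROPHOBIC = {
        if (k %% 2 == 0) { ring_frag[k] <- TRUE; frag_aliphatic_ring(targets[k, ]) }
        else frag_tert_butyl(targets[k, ])
      },
      HBA = frag_carbonyl_acceptor(targets[k, ]),
      HBD = frag_amine_donor(targets[k, ]),
      LINKER = frag_methyl_probe(targets[k, ]),
      stopf("assemble_molecule: unsupported kind '%s'", kinds[k]))
  }
  elements <- character(0); coords <- NULL
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  offset <- integer(length(kinds))
  for (k in seq_along(frags)) {
    offset[k] <- length(elements)
    f <- frags[[k]]
    elements <- c(elements, f$elements)
    coords <- rbind(coords, f$coords)
    if (nrow(f$bonds))
      bonds <- rbind(bonds, data.frame(i = f$bonds$i + offset[k],
                                       j = f$bonds$j + offset[k],
                                       order = f$bonds$order))
  }
  # bond each LINKER carbon to one atom of its two nearest ring fragments
  rings <- which(ring_frag)
  for (k in which(kinds == "LINKER")) {
    if (length(rings) < 2L)
      stopf("assemble_molecule: LINKER feature needs >= 2 ring fragments")
    ctrs <- t(vapply(rings, function(r) colMeans(frags[[r]]$coords),
                     numeric(3)))
    near <- rings[order(cross_dist(matrix(targets[k, ], 1), ctrs)[1, ])[1:2]]
    for (r in near) {
      ring_xyz <- frags[[r]]$coords
      a_local <- which.min(cross_dist(matrix(targets[k, ], 1), ring_xyz)[1, ])
      bonds <- rbind(bonds, data.frame(i = offset[k] + 1L,
                                       j = offset[r] + a_local, order = 1L))
    }
  }
  molecule(id, elements, bonds, list(coords))
}

# uniform point in the unit ball, scaled
runif_ball <- function(radius) {
  repeat {
    v <- stats::runif(3, -1, 1)
    if (sum(v^2) <= 1) return(radius * v)
  }
}

#' Generate a screening deck with planted actives and decoys
#'
#' Actives are molecules whose perceived feature points sit within
#' \code{jitter_frac} times the tolerance radius of each model feature
#' center (uniform in the sphere), then rigidly rotated and translated at
#' random. Decoys carry the same kinds of feature points but scattered with
#' pairwise distances far larger than any model distance plus twice the
#' radii, so no distance-compatible assignment exists.
#'
#' @param model a \code{pf_model} (default: the packaged PDE1 model).
#' @param n_actives,n_decoys deck composition (defaults 20 and 2000, the
#'   published test-set composition).
#' @param jitter_frac fraction of each radius used for active jitter, in
#'   [0, 1) (default 0.5).
#' @param seed integer seed (default 17).
#' @param out optional directory; writes \code{deck.sdf} and
#'   \code{truth.csv} there.
#' @return List: \code{molecules} (actives then decoys), \code{truth}
#'   data.frame (\code{id}, \code{active}).
#' @export
make_screen_deck <- function(model = default_pde1_model(), n_actives = 20,
                             n_decoys = 2000, jitter_frac = 0.5, seed = 17,
                             out = NULL) {
  if (jitter_frac < 0 || jitter_frac >= 1)
    stopf("make_screen_deck: jitter_frac must lie in [0, 1)")
  set.seed(substream_seed(seed, "screen_deck"))
  centers <- model_centers(model)
  kinds <- model$features$kind
  radii <- model$features$radius
  mols <- list()
  for (a in seq_len(n_actives)) {
    targets <- centers + t(vapply(radii, function(r)
      runif_ball(jitter_frac * r), numeric(3)))
    mol <- assemble_molecule(sprintf("active-%03d", a), targets, kinds)
    R <- random_rotation(); tr <- stats::runif(3, -20, 20)
    mol$conformers[[1]] <- apply_rigid(mol$conformers[[1]], R, tr)
    mols[[length(mols) + 1L]] <- mol
  }
  # decoys: same feature-kind inventory strung out along a jittered line
  # with spacing beyond any model distance + 2 x radii
  spacing <- max(cross_dist(centers, centers)) + 2 * max(radii) + 4
  for (d in seq_len(n_decoys)) {
    dir <- unit(stats::rnorm(3))
    base <- stats::runif(3, -50, 50)
    targets <- t(vapply(seq_along(kinds), function(k)
      base + (k - 1) * spacing * dir + stats::rnorm(3, 0, 0.5), numeric(3)))
    mols[[length(mols) + 1L]] <-
      assemble_molecule(sprintf("decoy-%04d", d), targets, kinds)
  }
  truth <- data.frame(id = vapply(mols, `[[`, "", "id"),
                      active = rep(c(TRUE, FALSE), c(n_actives, n_decoys)))
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_sdf(mols, file.path(out, "deck.sdf"))
    utils::write.csv(truth, file.path(out, "truth.csv"), row.names = FALSE)
  }
  list(molecules = mols, truth = truth)
}

# ------------------------------------------------ toy protein scaffolding

# local residue templates: backbone + side-chain heavy atoms, approximate
# but locally sensible geometry; aromatic rings are exact planar polygons
residue_template <- function(resname) {
  bb <- rbind(N = c(0, 0, 0), CA = c(1.46, 0, 0), C = c(2.02, 1.35, 0),
              O = c(1.38, 2.40, 0))
  ring6 <- function(ctr, nrm, names) {
    xy <- frag_hexagon(ctr, nrm)
    rownames(xy) <- names
    xy
  }
  ring5 <- function(ctr, nrm, names) {
    p1 <- perp_vector(nrm); p2 <- unit(pracma_cross(nrm, p1))
    ang <- seq(0, 2 * pi, length.out = 6)[1:5]
    xy <- t(vapply(ang, function(a)
      ctr + 1.17 * (cos(a) * p1 + sin(a) * p2), numeric(3)))
    rownames(xy) <- names
    xy
  }
  sc <- switch(resname,
    GLN = rbind(CB = c(2.0, -0.8, 1.2), CG = c(3.5, -0.9, 1.3),
                CD = c(4.1, -2.2, 1.8), OE1 = c(3.5, -3.25, 2.2),
                NE2 = c(5.42, -2.3, 1.85)),
    HIS = rbind(CB = c(2.0, -0.8, 1.2),
                ring5(c(4.0, -1.6, 1.6), c(0.2, 0.3, 0.93),
                      c("CG", "ND1", "CE1", "NE2", "CD2"))),
    PHE = rbind(CB = c(2.0, -0.8, 1.2),
                ring6(c(4.3, -1.7, 1.7), c(0.2, 0.3, 0.93),
                      c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"))),
    TYR = rbind(CB = c(2.0, -0.8, 1.2),
                ring6(c(4.3, -1.7, 1.7), c(0.2, 0.3, 0.93),
                      c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
                OH = c(5.75, -2.25, 2.0)),
    LEU = rbind(CB = c(2.0, -0.8, 1.2), CG = c(3.5, -0.9, 1.3),
                CD1 = c(4.2, -2.2, 1.0), CD2 = c(4.2, 0.3, 0.6)),
    VAL = rbind(CB = c(2.0, -0.8, 1.2), CG1 = c(3.4, -1.3, 1.6),
                CG2 = c(1.9, -1.6, 2.45)),
    THR = rbind(CB = c(2.0, -0.8, 1.2), OG1 = c(3.3, -1.3, 1.6),
                CG2 = c(1.9, -1.6, 2.45)),
    MET = rbind(CB = c(2.0, -0.8, 1.2), CG = c(3.5, -0.9, 1.3),
                SD = c(4.3, -2.3, 1.9), CE = c(6.05, -2.0, 2.1)),
    ALA = rbind(CB = c(2.0, -0.8, 1.2)),
    rbind(CB = c(2.0, -0.8, 1.2)))
  rbind(bb, sc)
}

PDE1_SCAFFOLD_RESIDUES <- data.frame(
  resname = c("GLN", "HIS", "PHE", "LEU", "PHE", "LEU", "VAL", "HIS",
              "THR", "TYR", "MET", "ALA", "ALA", "ALA", "ALA"),
  resno = c(421, 373, 424, 388, 392, 409, 417, 267, 271, 222, 336,
            601, 602, 603, 604),
  stringsAsFactors = FALSE)

#' Build the toy PDE1 hotspot scaffold
#'
#' Minimal placement of the hotspot residues (Gln421, His373, Phe424, the
#' Q2 pocket Leu388/Phe392/Leu409/Val417, the H-loop His267/Thr271, plus
#' Tyr222, Met336 and four alanine spacers) with correct atom names, spread
#' on a wide circle so planted contacts stay local. Synthetic geometry for
#' detector testing, not a folded protein.
#'
#' @return A \code{pf_protein}.
#' @export
toy_pde1_scaffold <- function() {
  res <- PDE1_SCAFFOLD_RESIDUES
  nres <- nrow(res)
  rows <- list(); eleno <- 0L
  for (r in seq_len(nres)) {
    tmpl <- residue_template(res$resname[r])
    theta <- 2 * pi * (r - 1) / nres
    slot <- 40 * c(cos(theta), sin(theta), 0) + c(0, 0, 4 * ((r %% 5) - 2))
    xyz <- sweep(tmpl, 2, slot, "+")
    for (a in seq_len(nrow(xyz))) {
      eleno <- eleno + 1L
      nm <- rownames(xyz)[a]
      rows[[length(rows) + 1L]] <- data.frame(
        eleno = eleno, name = nm,
        element = substr(gsub("[0-9]", "", nm), 1, 1),
        resname = res$resname[r], chain = "A", resno = res$resno[r],
        het = FALSE, x = xyz[a, 1], y = xyz[a, 2], z = xyz[a, 3],
        stringsAsFactors = FALSE)
    }
  }
  protein_structure("toy-pde1", do.call(rbind, rows))
}

#' Specify a contact plan for a toy complex
#'
#' @param hbonds list of \code{list(residue, distance, angle)}; the ligand
#'   donates an N-H to the residue's acceptor atom.
#' @param stacks list of \code{list(residue, distance, interplanar, offset)}.
#' @param pockets list of \code{list(set, distance)} with set "Q2" or
#'   "H-loop".
#' @param clashes integer count of planted steric overlaps (default 0).
#' @return A list of class \code{pf_contact_plan}.
#' @export
contact_plan <- function(hbonds = list(), stacks = list(), pockets = list(),
                         clashes = 0L) {
  structure(list(hbonds = hbonds, stacks = stacks, pockets = pockets,
                 clashes = as.integer(clashes)),
            class = "pf_contact_plan")
}

RESIDUE_ACCEPTOR_ATOM <- c(GLN = "OE1", HIS = "NE2", THR = "OG1",
                           TYR = "OH", ASN = "OD1")

#' Build a toy protein-ligand complex satisfying a contact plan
#'
#' The ligand is assembled fragment by fragment so that every planned
#' contact holds under the default detector criteria: amine N-H donors at
#' the planned distance/angle to the residue acceptor atom, benzene rings
#' stacked over the residue ring at the planned centroid distance and
#' interplanar angle, methyl probes at the planned pocket distance, and
#' clash atoms placed against the alanine spacers.
#'
#' @param plan a \code{\link{contact_plan}}.
#' @param seed integer seed (default 17).
#' @param out optional directory; writes \code{complex.pdb},
#'   \code{ligand.sdf} and \code{truth.json}.
#' @return List of class \code{pf_complex}: \code{protein}, \code{ligand},
#'   \code{plan}, \code{contacts} (per-contact ligand atom indices and
#'   break-out directions, consumed by \code{\link{make_trajectory}}).
#' @export
make_complex <- function(plan = contact_plan(), seed = 17, out = NULL) {
  set.seed(substream_seed(seed, "complex"))
  prot <- toy_pde1_scaffold()
  pxyz <- protein_coords(prot)
  pctr <- colMeans(pxyz)
  elements <- character(0); coords <- NULL
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  contacts <- list()
  add_frag <- function(f, name, direction) {
    off <- length(elements)
    elements <<- c(elements, f$elements)
    coords <<- rbind(coords, f$coords)
    if (nrow(f$bonds))
      bonds <<- rbind(bonds, data.frame(i = f$bonds$i + off,
                                        j = f$bonds$j + off,
                                        order = f$bonds$order))
    contacts[[length(contacts) + 1L]] <<-
      list(name = name, atoms = off + seq_along(f$elements),
           direction = direction)
  }
  for (hb in plan$hbonds) {
    key <- parse_residue_key(hb$residue)
    accname <- RESIDUE_ACCEPTOR_ATOM[[key$resname]]
    if (is.null(accname))
      stopf("make_complex: no acceptor atom mapped for %s", hb$residue)
    rows <- residue_atom_rows(prot, hb$residue)
    acc <- pxyz[rows[match(accname, prot$atoms$name[rows])], ]
    ca <- pxyz[rows[match("CA", prot$atoms$name[rows])], ]
    u <- unit(acc - ca)   # out along the side chain, clear of its atoms
    N <- acc + (hb$distance %||% 2.9) * u
    f <- frag_amine_donor(N, toward = acc, angle = hb$angle %||% 175)
    add_frag(f, paste0("hbond_", hb$residue), u)
  }
  for (st in plan$stacks) {
    rings <- protein_aromatic_rings(prot, st$residue)
    if (!length(rings))
      stopf("make_complex: residue %s has no aromatic ring", st$residue)
    rc <- colMeans(rings[[1]]$coords)
    nrm <- plane_normal(rings[[1]]$coords)
    if (sum(nrm * (rc - pctr)) < 0) nrm <- -nrm
    p <- perp_vector(nrm)
    ctr <- rc + (st$distance %||% 3.8) * nrm + (st$offset %||% 0) * p
    # tilt the ligand ring normal by the planned interplanar angle
    ang <- (st$interplanar %||% 0) * pi / 180
    lnrm <- unit(cos(ang) * nrm + sin(ang) * p)
    xy <- frag_hexagon(ctr, lnrm)
    f <- list(elements = rep("C", 6), coords = xy,
              bonds = data.frame(i = 1:6, j = c(2:6, 1), order = 4L),
              point_atoms = 1:6)
    add_frag(f, paste0("stack_", st$residue), nrm)
  }
  for (pk in plan$pockets) {
    keys <- pocket_residues(pk$set)
    rkey <- keys[[pk$residue_index %||% 2L]]
    rows <- residue_atom_rows(prot, rkey)
    sc <- rows[!prot$atoms$name[rows] %in% c(BACKBONE_NAMES, "OXT")]
    # anchor at the side-chain atom farthest from the residue centroid and
    # step outward along that axis: every other residue atom then lies at
    # least the planned distance away, so the planted distance is the
    # nearest approach
    ctr <- colMeans(pxyz[rows, , drop = FALSE])
    ref_row <- sc[which.max(rowSums(sweep(pxyz[sc, , drop = FALSE],
                                          2, ctr)^2))]
    ref <- pxyz[ref_row, ]
    u <- unit(ref - ctr)
    pos <- ref + (pk$distance %||% 3.5) * u
    add_frag(frag_methyl_probe(pos), paste0("pocket_", pk$set), u)
  }
  if (plan$clashes > 0L) {
    spacers <- PDE1_SCAFFOLD_RESIDUES$resno[PDE1_SCAFFOLD_RESIDUES$resname ==
                                              "ALA"]
    if (plan$clashes > length(spacers))
      stopf("make_complex: at most %d planted clashes supported",
            length(spacers))
    for (k in seq_len(plan$clashes)) {
      rows <- residue_atom_rows(prot, sprintf("Ala%d", spacers[k]))
      o <- pxyz[rows[match("O", prot$atoms$name[rows])], ]
      cc <- pxyz[rows[match("C", prot$atoms$name[rows])], ]
      u <- unit(o - cc)
      add_frag(frag_methyl_probe(o + 1.5 * u),
               sprintf("clash_%d", k), u)
    }
  }
  # anchor atom so an empty plan still yields a valid molecule, far away
  add_frag(frag_methyl_probe(pctr + c(0, 0, 30)), "anchor", c(0, 0, 1))
  lig <- molecule("LIG", elements, bonds, list(coords))
  cx <- structure(list(protein = prot, ligand = lig, plan = plan,
                       contacts = contacts),
                  class = "pf_complex")
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_pdb(cx, file.path(out, "complex.pdb"))
    write_sdf(lig, file.path(out, "ligand.sdf"))
    jsonlite::write_json(plan, file.path(out, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  cx
}

#' Build a multi-frame trajectory from a toy complex with a contact schedule
#'
#' Frames replicate the complex; for every contact whose schedule marks a
#' frame absent, that contact's ligand fragment is displaced 8 Angstrom
#' outward, cleanly breaking it under the default criteria. Isotropic
#' Gaussian noise is then added to all atoms (\code{noise_sigma} is the
#' per-atom RMS displacement in Angstrom; each coordinate gets sd
#' \code{noise_sigma/sqrt(3)}).
#'
#' @param complex a \code{\link{make_complex}} result.
#' @param schedule named list: contact name (as in \code{complex$contacts})
#'   -> logical presence vector of length \code{n_frames}. Contacts not
#'   listed stay present throughout.
#' @param n_frames number of frames (>= 1).
#' @param noise_sigma per-atom RMS displacement in Angstrom (default 0).
#' @param dt frame spacing in ns (default 0.01).
#' @param seed integer seed (default 17).
#' @param out optional path for a multi-MODEL PDB.
#' @return A \code{pf_traj} with \code{list(protein, ligand)} topology.
#' @export
make_trajectory <- function(complex, schedule = list(), n_frames = 20,
                            noise_sigma = 0, dt = 0.01, seed = 17,
                            out = NULL) {
  if (n_frames < 1L) stopf("make_trajectory: n_frames must be >= 1")
  set.seed(substream_seed(seed, "trajectory"))
  known <- vapply(complex$contacts, `[[`, "", "name")
  for (nm in names(schedule)) {
    if (!nm %in% known)
      stopf("make_trajectory: schedule names unknown contact '%s'", nm)
    if (length(schedule[[nm]]) != n_frames)
      stopf("make_trajectory: schedule '%s' length != n_frames", nm)
  }
  np <- nrow(complex$protein$atoms)
  base <- rbind(protein_coords(complex$protein),
                complex$ligand$conformers[[1]])
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- base
    for (ct in complex$contacts) {
      sch <- schedule[[ct$name]]
      if (!is.null(sch) && !sch[f]) {
        idx <- np + ct$atoms
        xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2,
                            8 * ct$direction, "+")
      }
    }
    if (noise_sigma > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0,
                                       noise_sigma / sqrt(3)),
                          nrow(xyz), 3)
    frames[[f]] <- xyz
  }
  traj <- trajectory(list(protein = complex$protein,
                          ligand = complex$ligand),
                     frames, times = (seq_len(n_frames) - 1) * dt)
  if (!is.null(out)) write_pdb(traj, out)
  traj
}

#' The packaged 26-compound screening table
#'
#' Predicted binding free energies (MM-GBSA, kcal/mol, mean and sd) and
#' percent PDE1 inhibition at 10 and 1 micromolar for the 26 purchased
#' screening candidates; "n.d." entries are preserved as missing. The
#' values are transcribed once into a versioned CSV asset guarded by a
#' checksum test.
#'
#' @return A \code{pf_screening} data.frame with 26 rows.
#' @export
table2_fixture <- function() {
  read_screening_csv(system.file("extdata", "table2_screening.csv",
                                 package = "pharmfunnel", mustWork = TRUE))
}
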