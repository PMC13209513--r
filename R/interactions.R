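# Geometric protein-ligand interaction detectors and the two-round pose
# triage. All criteria are config, with crystallographic-convention defaults:
# H-bond heavy-atom distance <= 3.5 A and D-H...A angle >= 120 deg (the angle
# applies only when an explicit hydrogen is present; otherwise the
# heavy-atom-only criterion stands); face-to-face stacking <= 5.5 A centroid
# distance, <= 30 deg interplanar, <= 2.0 A lateral offset; edge-to-face
# > 60 deg and <= 6.0 A; steric clash < 2.0 A; pocket contact <= 4.0 A to a
# side-chain heavy atom.

# protein donor/acceptor heavy atoms by residue+atom name (no hydrogens in
# typical PDB input, so capability is assigned by name)
PROTEIN_DONOR_ATOMS <- list(
  "*" = "N",              # backbone amide
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH", CYS = "SG")
PROTEIN_ACCEPTOR_ATOMS <- list(
  "*" = "O",              # backbone carbonyl
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1",
  GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"), MET = "SD",
  SER = "OG", THR = "OG1", TYR = "OH")

AROMATIC_RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))

protein_capability_rows <- function(protein, table) {
  a <- protein$atoms
  ok <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    if (a$het[i]) next
    nm <- table[[a$resname[i]]]
    ok[i] <- a$name[i] %in% c(table[["*"]], nm)
  }
  which(ok)
}

# ligand donor/acceptor info from perception rules
ligand_da_info <- function(mol, conformer = 1L) {
  info <- atom_valence_info(mol)
  xyz <- mol$conformers[[conformer]]
  feats <- perceive_features(mol, conformer)
  single <- feats[feats$n_atoms == 1L, ]
  hba <- integer(0); hbd <- integer(0)
  for (r in seq_len(nrow(single))) {
    a <- single$atoms[[r]][1]
    if ("HBA" %in% single$kinds[[r]]) hba <- c(hba, a)
    if ("HBD" %in% single$kinds[[r]]) hbd <- c(hbd, a)
  }
  # explicit hydrogens attached to each donor
  hs <- lapply(seq_len(n_atoms(mol)), function(a) integer(0))
  if (nrow(mol$bonds)) {
    for (rw in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[rw]; j <- mol$bonds$j[rw]
      if (mol$elements[j] == "H") hs[[i]] <- c(hs[[i]], j)
      if (mol$elements[i] == "H") hs[[j]] <- c(hs[[j]], i)
    }
  }
  list(xyz = xyz, acceptors = hba, donors = hbd, hydrogens = hs)
}

#' Detect protein-ligand hydrogen bonds
#'
#' A contact is reported iff the donor-heavy-atom to acceptor distance is at
#' most \code{dist_max} and, when an explicit hydrogen is present on the
#' donor, the best D-H...A angle is at least \code{angle_min}. Both
#' protein-to-ligand and ligand-to-protein directions are scanned; protein
#' donor/acceptor capability is assigned by residue and atom name.
#'
#' @param protein a \code{pf_protein}.
#' @param ligand a \code{pf_mol} pose.
#' @param dist_max heavy-atom distance cutoff in Angstrom (default 3.5).
#' @param angle_min minimum D-H...A angle in degrees (default 120).
#' @param residues optional character vector of residue keys (e.g.
#'   \code{"Gln421"}) restricting the protein side.
#' @param conformer ligand conformer index.
#' @return data.frame with one row per contact: \code{donor_side},
#'   \code{residue}, \code{protein_atom}, \code{ligand_atom},
#'   \code{distance}, \code{angle} (NA without explicit H).
#' @export
detect_hbonds <- function(protein, ligand, dist_max = 3.5, angle_min = 120,
                          residues = NULL, conformer = 1L) {
  prot_rows <- if (is.null(residues)) {
    which(!protein$atoms$het)
  } else {
    unlist(lapply(residues, residue_atom_rows, protein = protein))
  }
  da <- ligand_da_info(ligand, conformer)
  pxyz <- protein_coords(protein)
  pdon <- intersect(prot_rows, protein_capability_rows(protein,
                                                       PROTEIN_DONOR_ATOMS))
  pacc <- intersect(prot_rows, protein_capability_rows(protein,
                                                       PROTEIN_ACCEPTOR_ATOMS))
  out <- list()
  add <- function(donor_side, prow, latom, dist, ang) {
    out[[length(out) + 1L]] <<- data.frame(
      donor_side = donor_side,
      residue = paste0(protein$atoms$resname[prow], protein$atoms$resno[prow]),
      protein_atom = protein$atoms$name[prow],
      ligand_atom = latom, distance = dist, angle = ang,
      stringsAsFactors = FALSE)
  }
  # ligand donor -> protein acceptor
  for (d in da$donors) for (p in pacc) {
    dist <- vdist(da$xyz[d, ], pxyz[p, ])
    if (dist > dist_max) next
    hs <- da$hydrogens[[d]]
    if (length(hs)) {
      ang <- max(vapply(hs, function(h)
        angle_deg(da$xyz[d, ], da$xyz[h, ], pxyz[p, ]), 1))
      if (ang >= angle_min) add("ligand", p, d, dist, ang)
    } else {
      add("ligand", p, d, dist, NA_real_)
    }
  }
  # protein donor -> ligand acceptor (no explicit protein hydrogens: the
  # heavy-atom criterion applies)
  for (p in pdon) for (a in da$acceptors) {
    dist <- vdist(pxyz[p, ], da$xyz[a, ])
    if (dist <= dist_max) add("protein", p, a, dist, NA_real_)
  }
  if (!length(out)) {
    return(data.frame(donor_side = character(0), residue = character(0),
                      protein_atom = character(0), ligand_atom = integer(0),
                      distance = numeric(0), angle = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$distance), , drop = FALSE]
}

# planar rings of a protein's aromatic residues
protein_aromatic_rings <- function(protein, residues = NULL) {
  a <- protein$atoms
  sel <- if (is.null(residues)) {
    unique(which(!a$het & a$resname %in% names(AROMATIC_RING_ATOMS)))
  } else {
    unlist(lapply(residues, residue_atom_rows, protein = protein))
  }
  keys <- unique(paste(a$chain[sel], a$resno[sel], a$resname[sel]))
  rings <- list()
  for (k in keys) {
    f <- strsplit(k, " ")[[1]]
    rows <- which(a$chain == f[1] & a$resno == as.integer(f[2]) &
                    a$resname == f[3])
    names_needed <- AROMATIC_RING_ATOMS[[f[3]]]
    if (is.null(names_needed)) next
    ring_rows <- rows[match(names_needed, a$name[rows])]
    if (any(is.na(ring_rows))) next
    rings[[length(rings) + 1L]] <- list(
      residue = paste0(f[3], f[2]),
      coords = as.matrix(a[ring_rows, c("x", "y", "z")]))
  }
  rings
}

stack_geometry <- function(ringA, ringB) {
  cA <- colMeans(ringA); cB <- colMeans(ringB)
  nA <- plane_normal(ringA); nB <- plane_normal(ringB)
  ang <- acos(min(1, abs(sum(nA * nB)))) * 180 / pi
  d <- vdist(cA, cB)
  v <- cB - cA
  offA <- sqrt(max(0, sum(v^2) - sum(v * nA)^2))
  offB <- sqrt(max(0, sum(v^2) - sum(v * nB)^2))
  list(distance = d, interplanar = ang, offset = min(offA, offB))
}

#' Detect protein-ligand aromatic ring stacks
#'
#' Face-to-face: interplanar angle <= 30 deg, centroid distance <=
#' \code{dist_max}, lateral offset <= \code{offset_max}. Edge-to-face:
#' interplanar angle > 60 deg and centroid distance <= \code{dist_ef}.
#' Protein pi systems are located by residue ring-atom name sets
#' (Phe/Tyr/His/Trp); the ligand contributes every perceived aromatic ring.
#'
#' @param protein a \code{pf_protein}.
#' @param ligand a \code{pf_mol} pose.
#' @param dist_max face-to-face centroid distance cutoff (default 5.5 A).
#' @param offset_max face-to-face lateral offset cutoff (default 2.0 A).
#' @param dist_ef edge-to-face centroid distance cutoff (default 6.0 A).
#' @param residues optional residue keys restricting the protein side.
#' @param conformer ligand conformer index.
#' @return data.frame: \code{residue}, \code{distance}, \code{interplanar},
#'   \code{offset}, \code{geometry} ("face_to_face" or "edge_to_face").
#' @export
detect_ring_stacks <- function(protein, ligand, dist_max = 5.5,
                               offset_max = 2.0, dist_ef = 6.0,
                               residues = NULL, conformer = 1L) {
  prings <- protein_aromatic_rings(protein, residues)
  feats <- perceive_features(ligand, conformer)
  xyz <- ligand$conformers[[conformer]]
  lrings <- feats$atoms[vapply(feats$kinds, function(k)
    "AROMATIC_RING" %in% k, TRUE)]
  out <- list()
  for (pr in prings) for (la in lrings) {
    geo <- stack_geometry(pr$coords, xyz[la, , drop = FALSE])
    cls <- if (geo$interplanar <= 30 && geo$distance <= dist_max &&
                 geo$offset <= offset_max) {
      "face_to_face"
    } else if (geo$interplanar > 60 && geo$distance <= dist_ef) {
      "edge_to_face"
    } else NA_character_
    if (!is.na(cls)) {
      out[[length(out) + 1L]] <- data.frame(
        residue = pr$residue, distance = geo$distance,
        interplanar = geo$interplanar, offset = geo$offset,
        geometry = cls, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(residue = character(0), distance = numeric(0),
                      interplanar = numeric(0), offset = numeric(0),
                      geometry = character(0)))
  }
  do.call(rbind, out)
}

#' Pocket contact test
#'
#' TRUE iff any ligand heavy atom lies within \code{cutoff} of any side-chain
#' heavy atom of one of the listed residues. Backbone atoms (N, CA, C, O,
#' OXT) are excluded: pocket occupancy refers to side-chain-lined space.
#'
#' @param protein a \code{pf_protein}.
#' @param ligand a \code{pf_mol} pose.
#' @param residue_keys character vector, e.g. \code{c("Leu388", "Phe392")};
#'   the named sets \code{pocket_residues("Q2")} and
#'   \code{pocket_residues("H-loop")} are predefined.
#' @param cutoff distance cutoff in Angstrom (default 4.0).
#' @param conformer ligand conformer index.
#' @return List: \code{contact} flag and \code{pairs} data.frame
#'   (\code{residue}, \code{protein_atom}, \code{ligand_atom},
#'   \code{distance}).
#' @export
pocket_contact <- function(protein, ligand, residue_keys, cutoff = 4.0,
                           conformer = 1L) {
  lx <- ligand$conformers[[conformer]]
  lheavy <- heavy_atoms(ligand)
  pairs <- list()
  for (key in residue_keys) {
    rows <- residue_atom_rows(protein, key)   # errors if absent, naming it
    sc <- rows[!protein$atoms$name[rows] %in% c(BACKBONE_NAMES, "OXT") &
                 protein$atoms$element[rows] != "H"]
    if (!length(sc)) next
    d <- cross_dist(as.matrix(protein$atoms[sc, c("x", "y", "z")]),
                    lx[lheavy, , drop = FALSE])
    hit <- which(d <= cutoff, arr.ind = TRUE)
    for (r in seq_len(nrow(hit))) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        residue = key, protein_atom = protein$atoms$name[sc[hit[r, 1]]],
        ligand_atom = lheavy[hit[r, 2]], distance = d[hit[r, 1], hit[r, 2]],
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(residue = character(0), protein_atom = character(0),
               ligand_atom = integer(0), distance = numeric(0))
  list(contact = nrow(pairs) > 0, pairs = pairs)
}

#' Named PDE1 pocket residue sets
#'
#' @param which \code{"Q2"} (hydrophobic subpocket: Leu388, Phe392, Leu409,
#'   Val417) or \code{"H-loop"} (flexible loop: His267, Thr271). Numbering
#'   follows the crystal structure used for docking; treat as configuration,
#'   not truth, across isoforms.
#' @return Character vector of residue keys.
#' @export
pocket_residues <- function(which = c("Q2", "H-loop")) {
  which <- match.arg(which)
  if (which == "Q2") c("Leu388", "Phe392", "Leu409", "Val417")
  else c("His267", "Thr271")
}

#' Count protein-ligand steric clashes
#'
#' Number of protein/ligand heavy-atom pairs closer than \code{clash_dist}.
#'
#' @param protein a \code{pf_protein}.
#' @param ligand a \code{pf_mol} pose.
#' @param clash_dist clash threshold in Angstrom (default 2.0).
#' @param conformer ligand conformer index.
#' @return Integer pair count.
#' @export
count_clashes <- function(protein, ligand, clash_dist = 2.0, conformer = 1L) {
  prows <- which(protein$atoms$element != "H" & !protein$atoms$het)
  lx <- ligand$conformers[[conformer]][heavy_atoms(ligand), , drop = FALSE]
  if (!length(prows) || !nrow(lx)) return(0L)
  d <- cross_dist(as.matrix(protein$atoms[prows, c("x", "y", "z")]), lx)
  sum(d < clash_dist)
}

#' Triage configuration
#'
#' All thresholds and hotspot residue sets of the two-round pose triage.
#'
#' @param hbond_residues residues an anchoring H-bond may engage.
#' @param stack_residue residue whose ring must stack with the ligand.
#' @param q2,hloop pocket residue sets for round-2 preference.
#' @param hbond_dist_max,hbond_angle_min H-bond criteria.
#' @param stack_dist_max,stack_offset_max,stack_dist_ef stacking criteria.
#' @param clash_dist steric clash threshold.
#' @param pocket_cutoff pocket contact cutoff.
#' @return A named list of class \code{pf_triage_config}.
#' @export
triage_config <- function(hbond_residues = c("Gln421", "His373"),
                          stack_residue = "Phe424",
                          q2 = pocket_residues("Q2"),
                          hloop = pocket_residues("H-loop"),
                          hbond_dist_max = 3.5, hbond_angle_min = 120,
                          stack_dist_max = 5.5, stack_offset_max = 2.0,
                          stack_dist_ef = 6.0,
                          clash_dist = 2.0, pocket_cutoff = 4.0) {
  structure(list(hbond_residues = hbond_residues,
                 stack_residue = stack_residue, q2 = q2, hloop = hloop,
                 hbond_dist_max = hbond_dist_max,
                 hbond_angle_min = hbond_angle_min,
                 stack_dist_max = stack_dist_max,
                 stack_offset_max = stack_offset_max,
                 stack_dist_ef = stack_dist_ef,
                 clash_dist = clash_dist, pocket_cutoff = pocket_cutoff),
            class = "pf_triage_config")
}

#' Two-round triage of a docked pose
#'
#' Round 1 passes iff the pose (a) hydrogen-bonds at least one of the
#' anchoring residues (Gln421 or His373 by default), (b) forms a pi-pi stack
#' with the Phe424 ring, and (c) has zero steric clashes. Round 2 prefers a
#' round-1 pose that additionally contacts the Q2 pocket or the H-loop
#' region. Every sub-result is recorded in \code{reasons}.
#'
#' @param protein a \code{pf_protein} containing the hotspot residues.
#' @param ligand a \code{pf_mol} pose.
#' @param config a \code{\link{triage_config}}.
#' @param conformer ligand conformer index.
#' @return A list of class \code{pf_triage}: \code{round1_pass},
#'   \code{round2_preferred}, \code{clash_count}, \code{reasons}
#'   (named logical), \code{detail} (detector outputs).
#' @export
triage_pose <- function(protein, ligand, config = triage_config(),
                        conformer = 1L) {
  hb <- lapply(config$hbond_residues, function(res)
    detect_hbonds(protein, ligand, config$hbond_dist_max,
                  config$hbond_angle_min, residues = res,
                  conformer = conformer))
  names(hb) <- config$hbond_residues
  hb_ok <- vapply(hb, nrow, 1L) > 0L
  st <- detect_ring_stacks(protein, ligand, config$stack_dist_max,
                           config$stack_offset_max, config$stack_dist_ef,
                           residues = config$stack_residue,
                           conformer = conformer)
  clashes <- count_clashes(protein, ligand, config$clash_dist, conformer)
  q2 <- pocket_contact(protein, ligand, config$q2, config$pocket_cutoff,
                       conformer)
  hl <- pocket_contact(protein, ligand, config$hloop, config$pocket_cutoff,
                       conformer)
  reasons <- c(stats::setNames(hb_ok, paste0("hbond_", config$hbond_residues)),
               stack = nrow(st) > 0L,
               no_clash = clashes == 0L,
               q2_pocket = q2$contact,
               h_loop = hl$contact)
  round1 <- any(hb_ok) && nrow(st) > 0L && clashes == 0L
  structure(list(id = ligand$id,
                 round1_pass = round1,
                 round2_preferred = round1 && (q2$contact || hl$contact),
                 clash_count = clashes,
                 reasons = reasons,
                 detail = list(hbonds = hb, stacks = st, q2 = q2,
                               hloop = hl)),
            class = "pf_triage")
}

#' @export
print.pf_triage <- function(x, ...) {
  cat(sprintf("<pf_triage> %s: round1 %s, round2 %s (%d clash(es))\n",
              x$id %||% "?",
              if (x$round1_pass) "PASS" else "fail",
              if (x$round2_preferred) "PREFERRED" else "-", x$clash_count))
  cat("  ", paste(sprintf("%s=%s", names(x$reasons),
                          ifelse(x$reasons, "y", "n")), collapse = " "), "\n")
  invisible(x)
}

#' Heavy-atom RMSD between two poses
#'
#' @param pose_a,pose_b \code{pf_mol} objects (same atoms, same order) or
#'   N x 3 coordinate matrices.
#' @param superpose superpose optimally (Kabsch) before measuring
#'   (default FALSE: in-place deviation, the docking re-dock convention).
#' @param conformer conformer index used when poses are molecules.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(pose_a, pose_b, superpose = FALSE, conformer = 1L) {
  get_xyz <- function(p) {
    if (inherits(p, "pf_mol"))
      p$conformers[[conformer]][heavy_atoms(p), , drop = FALSE]
    else as.matrix(p)
  }
  if (inherits(pose_a, "pf_mol") && inherits(pose_b, "pf_mol")) {
    if (!identical(pose_a$elements, pose_b$elements))
      stopf("pose_rmsd: atom count or order mismatch")
  }
  a <- get_xyz(pose_a); b <- get_xyz(pose_b)
  if (!all(dim(a) == dim(b))) stopf("pose_rmsd: atom count mismatch")
  if (superpose) kabsch_fit(a, b)$rmsd else coord_rmsd(a, b)
}
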