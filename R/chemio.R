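# Data model for small molecules, protein structures and trajectories,
# plus readers/writers for SDF V2000, PDB and screening CSV tables.
#
# Conventions: coordinates are Angstrom everywhere; atom indices are 1-based
# internally (R norm) and at file boundaries (as the formats themselves are);
# residue identity is (chain, residue number, residue name); insertion codes
# are rejected.

HALOGENS <- c("F", "Cl", "Br", "I")
BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Construct a small molecule
#'
#' A molecule is an atom list (elements, optional atom names), a bond table
#' and one or more conformers (coordinate sets). All conformers must have the
#' same atom count; a deck read from SDF merges successive records with
#' identical titles into conformers of one molecule.
#'
#' @param id compound identifier string.
#' @param elements character vector of element symbols, one per atom.
#' @param bonds data.frame with integer columns \code{i}, \code{j} and
#'   \code{order} (1, 2, 3 or 4 = aromatic). May have zero rows.
#' @param conformers list of N x 3 coordinate matrices (Angstrom).
#' @param atom_names optional character vector of atom names.
#' @param max_conformers upper bound on stored conformers (default 250).
#' @return An object of class \code{pf_mol}.
#' @export
molecule <- function(id, elements, bonds, conformers, atom_names = NULL,
                     max_conformers = 250L) {
  n <- length(elements)
  if (n < 1L) stopf("molecule '%s': needs at least one atom", id)
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  }
  bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                      order = as.integer(bonds$order))
  if (nrow(bonds)) {
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stopf("molecule '%s': bond endpoint out of range", id)
    if (any(bonds$i == bonds$j))
      stopf("molecule '%s': self-bond not allowed", id)
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key))
      stopf("molecule '%s': duplicate bond", id)
  }
  if (!is.list(conformers) || length(conformers) < 1L)
    stopf("molecule '%s': needs at least one conformer", id)
  if (length(conformers) > max_conformers)
    stopf("molecule '%s': %d conformers exceeds limit %d", id,
          length(conformers), max_conformers)
  conformers <- lapply(conformers, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != n || ncol(m) != 3L)
      stopf("molecule '%s': conformer must be %d x 3", id, n)
    if (!all(is.finite(m)))
      stopf("molecule '%s': non-finite coordinates", id)
    dimnames(m) <- NULL
    m
  })
  structure(list(id = id,
                 elements = as.character(elements),
                 atom_names = atom_names %||% paste0(elements, seq_len(n)),
                 bonds = bonds,
                 conformers = conformers),
            class = "pf_mol")
}

#' @export
print.pf_mol <- function(x, ...) {
  cat(sprintf("<pf_mol> %s: %d atoms (%d heavy), %d bonds, %d conformer(s)\n",
              x$id, length(x$elements), sum(x$elements != "H"),
              nrow(x$bonds), length(x$conformers)))
  invisible(x)
}

#' Number of atoms of a molecule
#' @param mol a \code{pf_mol}.
#' @return integer count.
#' @export
n_atoms <- function(mol) length(mol$elements)

#' Number of conformers of a molecule
#' @param mol a \code{pf_mol}.
#' @return integer count.
#' @export
n_conformers <- function(mol) length(mol$conformers)

heavy_atoms <- function(mol) which(mol$elements != "H")

#' Construct a protein structure
#'
#' @param id structure identifier.
#' @param atoms data.frame with columns \code{eleno}, \code{name},
#'   \code{element}, \code{resname}, \code{chain}, \code{resno}, \code{het}
#'   (logical), \code{x}, \code{y}, \code{z}.
#' @return An object of class \code{pf_protein}.
#' @export
protein_structure <- function(id, atoms) {
  need <- c("eleno", "name", "element", "resname", "chain", "resno",
            "het", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stopf("protein '%s': missing atom columns %s", id,
                          paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stopf("protein '%s': non-finite coordinates", id)
  atoms$resname <- toupper(atoms$resname)
  structure(list(id = id, atoms = atoms), class = "pf_protein")
}

#' @export
print.pf_protein <- function(x, ...) {
  rk <- residue_keys(x)
  cat(sprintf("<pf_protein> %s: %d atoms, %d residues (%d HET)\n",
              x$id, nrow(x$atoms), length(unique(rk)),
              length(unique(rk[x$atoms$het]))))
  invisible(x)
}

#' Coordinate matrix of a protein structure
#' @param p a \code{pf_protein}.
#' @return N x 3 matrix in Angstrom.
#' @export
protein_coords <- function(p) as.matrix(p$atoms[, c("x", "y", "z")])

residue_keys <- function(p) {
  paste(p$atoms$chain, p$atoms$resno, p$atoms$resname, sep = ":")
}

# parse "Gln421" / "GLN421" / "A:421:GLN" into list(resname, resno, chain)
parse_residue_key <- function(key) {
  if (grepl(":", key)) {
    f <- strsplit(key, ":")[[1]]
    return(list(chain = f[1], resno = as.integer(f[2]),
                resname = toupper(f[3])))
  }
  m <- regmatches(key, regexec("^([A-Za-z]{3})\\s*([0-9]+)$", key))[[1]]
  if (length(m) != 3) stopf("cannot parse residue key '%s'", key)
  list(chain = NA_character_, resno = as.integer(m[3]),
       resname = toupper(m[2]))
}

# row indices of a residue's atoms; error if absent
residue_atom_rows <- function(protein, key) {
  k <- parse_residue_key(key)
  sel <- protein$atoms$resname == k$resname & protein$atoms$resno == k$resno
  if (!is.na(k$chain)) sel <- sel & protein$atoms$chain == k$chain
  rows <- which(sel)
  if (!length(rows))
    stopf("residue '%s' absent from structure '%s'", key, protein$id)
  rows
}

#' Construct a trajectory
#'
#' Ordered coordinate frames over a shared topology. The topology is either a
#' \code{pf_protein} (possibly containing HETATM ligand atoms) or a list with
#' elements \code{protein} and \code{ligand} (a \code{pf_mol}); in the latter
#' case frames stack protein atoms first, then ligand atoms.
#'
#' @param topology topology as described above.
#' @param frames list of N x 3 coordinate matrices.
#' @param times numeric frame times in ns, strictly increasing, first >= 0.
#' @return An object of class \code{pf_traj}.
#' @export
trajectory <- function(topology, frames, times) {
  na <- topology_n_atoms(topology)
  if (!length(frames)) stopf("trajectory: needs at least one frame")
  frames <- lapply(frames, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != na || ncol(m) != 3L)
      stopf("trajectory: frame atom count %d differs from topology %d",
            nrow(m), na)
    dimnames(m) <- NULL
    m
  })
  if (length(times) != length(frames))
    stopf("trajectory: %d times for %d frames", length(times), length(frames))
  if (times[1] < 0) stopf("trajectory: times must start at >= 0 ns")
  if (length(times) > 1 && any(diff(times) <= 0))
    stopf("trajectory: frame times must be strictly increasing")
  structure(list(topology = topology, frames = frames, times = as.numeric(times)),
            class = "pf_traj")
}

topology_n_atoms <- function(topology) {
  if (inherits(topology, "pf_protein")) return(nrow(topology$atoms))
  if (is.list(topology) && inherits(topology$protein, "pf_protein")) {
    return(nrow(topology$protein$atoms) +
             if (!is.null(topology$ligand)) n_atoms(topology$ligand) else 0L)
  }
  stopf("trajectory: unsupported topology")
}

#' @export
print.pf_traj <- function(x, ...) {
  cat(sprintf("<pf_traj> %d frames x %d atoms, t = %.3f..%.3f ns\n",
              length(x$frames), topology_n_atoms(x$topology),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

# ---------------------------------------------------------------- SDF ------

#' Read an SDF (V2000) file into molecules
#'
#' Successive records with identical titles are merged as conformers of one
#' molecule (they must agree in atom count, elements and bonds). Explicit
#' hydrogens are retained.
#'
#' @param path SDF file path.
#' @param max_conformers cap on conformers per molecule (default 250).
#' @return List of \code{pf_mol}.
#' @export
read_sdf <- function(path, max_conformers = 250L) {
  if (!file.exists(path)) stopf("read_sdf: no such file '%s'", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines)))) return(list())
  # validate counts lines up front so errors carry a line number
  starts <- c(1L, which(lines == "$$$$") + 1L)
  starts <- starts[starts <= length(lines)]
  starts <- starts[c(TRUE, diff(starts) > 0)]
  for (s in starts) {
    if (s + 3L > length(lines)) break
    if (!nzchar(trimws(paste(lines[s:min(s + 3L, length(lines))], collapse = ""))))
      next
    cl <- lines[s + 3L]
    na <- suppressWarnings(as.integer(substr(cl, 1, 3)))
    nb <- suppressWarnings(as.integer(substr(cl, 4, 6)))
    if (is.na(na) || is.na(nb))
      stopf("read_sdf: malformed counts line at line %d of '%s'", s + 3L, path)
  }
  sdfs <- ChemmineR::read.SDFset(path)
  titles <- character(length(sdfs))
  parsed <- vector("list", length(sdfs))
  for (k in seq_along(sdfs)) {
    sdf <- sdfs[[k]]
    titles[k] <- unname(ChemmineR::header(sdf)[1])
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
      data.frame(i = integer(0), j = integer(0), order = integer(0))
    } else {
      data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    }
    parsed[[k]] <- list(elements = elements, coords = coords, bonds = bonds)
  }
  # merge successive identical titles
  out <- list()
  r <- rle(titles)
  pos <- 1L
  for (g in seq_along(r$lengths)) {
    idx <- pos:(pos + r$lengths[g] - 1L)
    pos <- pos + r$lengths[g]
    first <- parsed[[idx[1]]]
    for (k in idx[-1]) {
      pk <- parsed[[k]]
      if (!identical(pk$elements, first$elements) ||
          !identical(pk$bonds, first$bonds))
        stopf("read_sdf: conformers of '%s' differ in atoms or bonds",
              r$values[g])
    }
    out[[length(out) + 1L]] <-
      molecule(r$values[g], first$elements, first$bonds,
               lapply(parsed[idx], `[[`, "coords"),
               max_conformers = max_conformers)
  }
  out
}

#' Write molecules to an SDF (V2000) file
#'
#' Each conformer becomes one record titled with the molecule id, so
#' \code{read_sdf()} re-groups them on read.
#'
#' @param mols a \code{pf_mol} or list of them.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "pf_mol")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    for (cf in mol$conformers) {
      lines <- c(mol$id, "  pharmfunnel", "",
                 sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                         n_atoms(mol), nrow(mol$bonds)))
      for (a in seq_len(n_atoms(mol))) {
        lines <- c(lines, sprintf(
          "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
          cf[a, 1], cf[a, 2], cf[a, 3], mol$elements[a]))
      }
      if (nrow(mol$bonds)) {
        lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                  mol$bonds$i, mol$bonds$j, mol$bonds$order))
      }
      lines <- c(lines, "M  END", "$$$$")
      writeLines(lines, con)
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------- PDB ------

#' Read a PDB file
#'
#' Returns a \code{pf_protein} when the file has no MODEL records and a
#' \code{pf_traj} when it has two or more (frame times from a fixed spacing).
#' HETATM atoms are retained with the het residue as their residue key.
#' Insertion codes are not supported and are rejected.
#'
#' @param path PDB file path.
#' @param frame_dt frame spacing in ns for multi-MODEL input (default 0.01).
#' @return \code{pf_protein} or \code{pf_traj}.
#' @export
read_pdb <- function(path, frame_dt = 0.01) {
  if (!file.exists(path)) stopf("read_pdb: no such file '%s'", path)
  raw <- readLines(path, warn = FALSE)
  starts <- grepl("^MODEL", raw)
  if (any(starts)) {
    blk <- cumsum(starts)
    atom_line <- grepl("^(ATOM|HETATM)", raw)
    counts <- table(blk[atom_line & blk > 0])
    if (length(unique(as.integer(counts))) > 1L)
      stopf("read_pdb: structural error: models in '%s' differ in atom count",
            path)
  }
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stopf("read_pdb: structural error in '%s': %s",
                          path, conditionMessage(e)))
  at <- pdb$atom
  ins <- at$insert
  if (any(!is.na(ins) & nzchar(trimws(as.character(ins)))))
    stopf("read_pdb: insertion codes unsupported ('%s')", path)
  element <- trimws(as.character(at$elesy))
  guess <- toupper(substr(gsub("[0-9]", "", trimws(at$elety)), 1, 1))
  element[!nzchar(element) | is.na(element)] <-
    guess[!nzchar(element) | is.na(element)]
  atoms <- data.frame(eleno = at$eleno,
                      name = trimws(at$elety),
                      element = element,
                      resname = trimws(at$resid),
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      resno = at$resno,
                      het = at$type == "HETATM",
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  id <- sub("\\.pdb$", "", basename(path))
  nmodels <- nrow(pdb$xyz)
  if (is.null(nmodels) || nmodels <= 1L) return(protein_structure(id, atoms))
  if (anyNA(pdb$xyz))
    stopf("read_pdb: models in '%s' differ in atom count", path)
  na <- nrow(atoms)
  frames <- lapply(seq_len(nmodels), function(m) {
    matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
  })
  if (any(vapply(frames, nrow, 1L) != na))
    stopf("read_pdb: models in '%s' differ in atom count", path)
  topo <- protein_structure(id, atoms)
  trajectory(topo, frames, times = (seq_len(nmodels) - 1) * frame_dt)
}

# fixed-width PDB atom line
pdb_atom_line <- function(type, eleno, name, resname, chain, resno, xyz,
                          element) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else substr(name, 1, 4)
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          type, eleno %% 100000, nm, resname, chain, resno %% 10000,
          xyz[1], xyz[2], xyz[3], element)
}

protein_pdb_lines <- function(protein, coords = NULL) {
  a <- protein$atoms
  xyz <- if (is.null(coords)) protein_coords(protein) else as.matrix(coords)
  vapply(seq_len(nrow(a)), function(i) {
    pdb_atom_line(if (a$het[i]) "HETATM" else "ATOM", a$eleno[i], a$name[i],
                  a$resname[i], a$chain[i], a$resno[i], xyz[i, ], a$element[i])
  }, character(1))
}

ligand_pdb_lines <- function(mol, conformer = 1L, start_eleno = 1L,
                             resname = "LIG", chain = "X", resno = 900L) {
  cf <- mol$conformers[[conformer]]
  vapply(seq_len(n_atoms(mol)), function(i) {
    pdb_atom_line("HETATM", start_eleno + i - 1L,
                  paste0(mol$elements[i], i %% 100),
                  resname, chain, resno, cf[i, ], mol$elements[i])
  }, character(1))
}

#' Write a protein, complex or trajectory to a PDB file
#'
#' A \code{pf_traj} is written as MODEL/ENDMDL blocks. A complex (list with
#' \code{protein} and \code{ligand}) writes the ligand as HETATM records with
#' residue name \code{LIG}.
#'
#' @param x \code{pf_protein}, \code{pf_traj}, or complex list.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_pdb <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  emit_complex <- function(topology, coords) {
    if (inherits(topology, "pf_protein")) {
      writeLines(protein_pdb_lines(topology, coords), con)
    } else {
      np <- nrow(topology$protein$atoms)
      writeLines(protein_pdb_lines(topology$protein, coords[seq_len(np), ]), con)
      if (!is.null(topology$ligand)) {
        lig <- topology$ligand
        lig$conformers[[1]] <- coords[np + seq_len(n_atoms(lig)), , drop = FALSE]
        writeLines(ligand_pdb_lines(lig, 1L, start_eleno = np + 1L), con)
      }
    }
  }
  if (inherits(x, "pf_traj")) {
    for (f in seq_along(x$frames)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      emit_complex(x$topology, x$frames[[f]])
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else if (inherits(x, "pf_protein")) {
    writeLines(protein_pdb_lines(x), con)
    writeLines("END", con)
  } else if (is.list(x) && inherits(x$protein, "pf_protein")) {
    np <- nrow(x$protein$atoms)
    writeLines(protein_pdb_lines(x$protein), con)
    if (!is.null(x$ligand))
      writeLines(ligand_pdb_lines(x$ligand, 1L, start_eleno = np + 1L), con)
    writeLines("END", con)
  } else stopf("write_pdb: unsupported object")
  invisible(path)
}

#' Extract a HETATM ligand from a protein structure as a molecule
#'
#' Bonds are perceived by distance (heavy-heavy 1.85 A, X-H 1.25 A) since PDB
#' carries no connectivity; rings found this way may be flagged aromatic by
#' planarity (see \code{perceive_features}).
#'
#' @param protein a \code{pf_protein} containing the ligand as HETATM rows.
#' @param resname het residue name of the ligand (default "LIG").
#' @return A \code{pf_mol} with attribute \code{bonds_perceived = TRUE} and
#'   attribute \code{protein_rows} giving the source row indices.
#' @export
extract_ligand <- function(protein, resname = "LIG") {
  rows <- which(protein$atoms$het & protein$atoms$resname == toupper(resname))
  if (!length(rows)) stopf("extract_ligand: no HETATM residue '%s'", resname)
  a <- protein$atoms[rows, ]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(a)
  bonds <- list()
  if (n > 1) {
    d <- cross_dist(xyz, xyz)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      cut <- if (a$element[i] == "H" || a$element[j] == "H") 1.25 else 1.85
      if (d[i, j] <= cut && d[i, j] > 0.4)
        bonds[[length(bonds) + 1L]] <- c(i, j, 1L)
    }
  }
  bonds <- if (length(bonds)) {
    m <- do.call(rbind, bonds)
    data.frame(i = m[, 1], j = m[, 2], order = m[, 3])
  } else data.frame(i = integer(0), j = integer(0), order = integer(0))
  mol <- molecule(resname, a$element, bonds, list(xyz), atom_names = a$name)
  attr(mol, "bonds_perceived") <- TRUE
  attr(mol, "protein_rows") <- rows
  mol
}

# ---------------------------------------------------------------- CSV ------

#' Read a screening-record CSV
#'
#' Expected columns: \code{id}, \code{dg_mean}, \code{dg_sd} (predicted
#' binding free energy, kcal/mol), then one column per assay concentration in
#' micromolar, named by the concentration (e.g. \code{10}, \code{1}), holding
#' percent inhibition. The value \code{n.d.} (not determined) is preserved as
#' missing, never as zero.
#'
#' @param path CSV file path.
#' @return data.frame of class \code{pf_screening} with columns \code{id},
#'   \code{dg_mean}, \code{dg_sd} and one \code{inh_<conc>} column per
#'   concentration; attribute \code{concentrations} lists them (numeric, uM).
#' @export
read_screening_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  need <- c("id", "dg_mean", "dg_sd")
  if (!all(need %in% names(raw)))
    stopf("read_screening_csv: need columns id, dg_mean, dg_sd in '%s'", path)
  conc_cols <- setdiff(names(raw), need)
  concs <- suppressWarnings(as.numeric(conc_cols))
  if (length(conc_cols) && any(is.na(concs)))
    stopf("read_screening_csv: non-numeric concentration column(s): %s",
          paste(conc_cols[is.na(concs)], collapse = ", "))
  num <- function(x, what) {
    x[x %in% c("n.d.", "nd", "ND", "NA", "")] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad))
      stopf("read_screening_csv: non-numeric %s value '%s' (row %d)",
            what, x[bad[1]], bad[1])
    v
  }
  out <- data.frame(id = raw$id,
                    dg_mean = num(raw$dg_mean, "dg_mean"),
                    dg_sd = num(raw$dg_sd, "dg_sd"),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$dg_mean)))
    stopf("read_screening_csv: missing dg_mean in '%s'", path)
  if (any(!is.na(out$dg_sd) & out$dg_sd < 0))
    stopf("read_screening_csv: negative dg_sd")
  ord <- order(-concs)
  for (k in ord) {
    v <- num(raw[[conc_cols[k]]], sprintf("inhibition@%g", concs[k]))
    if (any(!is.na(v) & (v < -10 | v > 110)))
      stopf("read_screening_csv: inhibition outside [-10, 110] at %g uM",
            concs[k])
    out[[paste0("inh_", format(concs[k]))]] <- v
  }
  attr(out, "concentrations") <- concs[ord]
  class(out) <- c("pf_screening", "data.frame")
  out
}

inh_column <- function(records, concentration) {
  col <- paste0("inh_", format(concentration))
  if (!col %in% names(records))
    stopf("no inhibition data at %g uM", concentration)
  records[[col]]
}
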