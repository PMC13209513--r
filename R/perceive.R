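# Pharmacophore feature perception: rings (smallest set of smallest rings),
# aromaticity, H-bond donors/acceptors, hydrophobic centers, linker atoms.
#
# Feature kinds form a closed set; a single point may carry several kinds
# (a benzene centroid is both AROMATIC_RING and HYDROPHOBIC).

FEATURE_KINDS <- c("AROMATIC_RING", "HBA", "HBD", "HYDROPHOBIC", "LINKER")

STANDARD_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                      F = 1, Cl = 1, Br = 1, I = 1, H = 1)

# heavy-atom molecular graph as igraph
mol_graph <- function(mol, heavy_only = TRUE) {
  keep <- if (heavy_only) {
    b <- mol$bonds
    b[mol$elements[b$i] != "H" & mol$elements[b$j] != "H", , drop = FALSE]
  } else mol$bonds
  igraph::graph_from_data_frame(
    d = keep[, c("i", "j")],
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(mol))))
}

# SSSR-style ring list: for each ring bond, the smallest cycle through it
perceive_rings <- function(mol, max_size = 8L) {
  b <- mol$bonds
  b <- b[mol$elements[b$i] != "H" & mol$elements[b$j] != "H", , drop = FALSE]
  if (!nrow(b)) return(list())
  g <- mol_graph(mol)
  rings <- list()
  seen <- character(0)
  for (e in seq_len(nrow(b))) {
    g2 <- igraph::delete_edges(
      g, igraph::get_edge_ids(g, as.character(c(b$i[e], b$j[e]))))
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = as.character(b$i[e]), to = as.character(b$j[e])))$vpath[[1]]
    if (!length(sp)) next
    cyc <- as.integer(names(sp))
    if (length(cyc) > max_size) next
    key <- paste(sort(cyc), collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    rings[[length(rings) + 1L]] <- cyc   # kept in cyclic path order
  }
  rings
}

# sum of bond orders at each atom (aromatic order 4 counts 1.5), plus
# explicit H neighbours and implied H counts from standard valences
atom_valence_info <- function(mol) {
  n <- n_atoms(mol)
  bsum <- numeric(n); hexp <- integer(n); deg_heavy <- integer(n)
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
      o <- if (mol$bonds$order[r] == 4L) 1.5 else mol$bonds$order[r]
      bsum[i] <- bsum[i] + o; bsum[j] <- bsum[j] + o
      if (mol$elements[j] == "H") hexp[i] <- hexp[i] + 1L
      if (mol$elements[i] == "H") hexp[j] <- hexp[j] + 1L
      if (mol$elements[i] != "H" && mol$elements[j] != "H") {
        deg_heavy[i] <- deg_heavy[i] + 1L
        deg_heavy[j] <- deg_heavy[j] + 1L
      }
    }
  }
  val <- STANDARD_VALENCE[mol$elements]
  val[is.na(val)] <- 4
  himp <- pmax(0L, as.integer(round(val - bsum)))
  himp[hexp > 0L] <- 0L   # explicit hydrogens override the valence guess
  list(bond_order_sum = bsum, explicit_h = hexp, implied_h = himp,
       heavy_degree = deg_heavy)
}

ring_is_aromatic <- function(mol, ring, coords) {
  b <- mol$bonds
  orders <- integer(length(ring))
  for (k in seq_along(ring)) {
    i <- ring[k]; j <- ring[if (k == length(ring)) 1L else k + 1L]
    row <- which((b$i == i & b$j == j) | (b$i == j & b$j == i))
    if (!length(row)) return(FALSE)
    orders[k] <- b$order[row[1]]
  }
  if (all(orders == 4L)) return(TRUE)
  # Kekule benzene-like: even ring, strictly alternating single/double
  if (length(ring) %% 2 == 0 && all(orders %in% c(1L, 2L)) &&
      all(abs(diff(c(orders, orders[1]))) == 1L)) return(TRUE)
  # geometric fallback for connectivity-perceived molecules (e.g. from PDB):
  # planar 5/6-ring of C/N only
  if (isTRUE(attr(mol, "bonds_perceived")) && length(ring) %in% c(5L, 6L) &&
      all(mol$elements[ring] %in% c("C", "N"))) {
    X <- coords[ring, , drop = FALSE]
    nrm <- plane_normal(X)
    dev <- abs(sweep(X, 2, colMeans(X)) %*% nrm)
    return(max(dev) < 0.15)
  }
  FALSE
}

#' Perceive pharmacophore feature points of a conformer
#'
#' Deterministic rule-based perception:
#' \itemize{
#'   \item AROMATIC_RING: centroid of each aromatic ring (smallest rings;
#'     aromatic = all ring bonds order 4, or a Kekule-alternating even ring,
#'     or -- for distance-perceived molecules -- a planar 5/6-ring of C/N).
#'   \item HBA: N or O with an available lone pair (not a pyrrole-type N
#'     whose lone pair is part of the ring system).
#'   \item HBD: N or O bearing at least one hydrogen, explicit or implied by
#'     standard valence.
#'   \item HYDROPHOBIC: centroid of each all-carbon(/halogen) ring, and of
#'     terminal branched alkyl groups of >= 3 carbons.
#'   \item LINKER: any non-ring heavy atom directly bonded to two distinct
#'     ring systems.
#' }
#'
#' @param mol a \code{pf_mol}.
#' @param conformer conformer index (default 1).
#' @return data.frame of class \code{pf_features} with columns \code{x},
#'   \code{y}, \code{z}, \code{n_atoms} and a list column \code{kinds}
#'   (character vector per point) plus list column \code{atoms} (source atom
#'   indices).
#' @export
perceive_features <- function(mol, conformer = 1L) {
  if (conformer < 1L || conformer > n_conformers(mol))
    stopf("perceive_features: conformer %d out of range for '%s'",
          conformer, mol$id)
  xyz <- mol$conformers[[conformer]]
  info <- atom_valence_info(mol)
  rings <- perceive_rings(mol)
  pts <- list()
  add_point <- function(kinds, atoms) {
    atoms <- as.integer(atoms)
    ctr <- colMeans(xyz[atoms, , drop = FALSE])
    pts[[length(pts) + 1L]] <<- list(kinds = kinds, xyz = ctr, atoms = atoms)
  }
  # ring features
  ring_atoms <- integer(0)
  for (ring in rings) {
    ring_atoms <- union(ring_atoms, ring)
    kinds <- character(0)
    if (ring_is_aromatic(mol, ring, xyz)) kinds <- c(kinds, "AROMATIC_RING")
    if (all(mol$elements[ring] %in% c("C", HALOGENS)))
      kinds <- c(kinds, "HYDROPHOBIC")
    if (length(kinds)) add_point(kinds, ring)
  }
  # atom-centred features
  in_aromatic_ring <- rep(FALSE, n_atoms(mol))
  for (ring in rings)
    if (ring_is_aromatic(mol, ring, xyz)) in_aromatic_ring[ring] <- TRUE
  for (a in seq_len(n_atoms(mol))) {
    el <- mol$elements[a]
    if (!el %in% c("N", "O")) next
    kinds <- character(0)
    n_h <- info$explicit_h[a] + info$implied_h[a]
    conn <- info$heavy_degree[a] + info$explicit_h[a] + info$implied_h[a]
    pyrrole_type <- el == "N" && in_aromatic_ring[a] && conn >= 3
    if (!pyrrole_type) kinds <- c(kinds, "HBA")
    if (n_h >= 1L) kinds <- c(kinds, "HBD")
    if (length(kinds)) add_point(kinds, a)
  }
  # terminal branched alkyl hydrophobes
  nb <- vector("list", n_atoms(mol))
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
      if (mol$elements[i] != "H" && mol$elements[j] != "H") {
        nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
      }
    }
  }
  sp3 <- rep(TRUE, n_atoms(mol))
  if (nrow(mol$bonds)) {
    multi <- mol$bonds$order > 1L
    sp3[c(mol$bonds$i[multi], mol$bonds$j[multi])] <- FALSE
  }
  for (a in seq_len(n_atoms(mol))) {
    if (mol$elements[a] != "C" || a %in% ring_atoms || !sp3[a]) next
    term <- nb[[a]][mol$elements[nb[[a]]] == "C" &
                      info$heavy_degree[nb[[a]]] == 1L]
    if (length(term) >= 2L && (1L + length(term)) >= 3L)
      add_point("HYDROPHOBIC", c(a, term))
  }
  # linker atoms bridging two ring systems
  if (length(rings) >= 2L && length(ring_atoms)) {
    g <- mol_graph(mol)
    sub <- igraph::induced_subgraph(g, as.character(ring_atoms))
    comp <- igraph::components(sub)$membership
    names(comp) <- igraph::V(sub)$name
    for (a in seq_len(n_atoms(mol))) {
      if (mol$elements[a] == "H" || a %in% ring_atoms) next
      ring_nb <- nb[[a]][nb[[a]] %in% ring_atoms]
      if (length(unique(comp[as.character(ring_nb)])) >= 2L)
        add_point("LINKER", a)
    }
  }
  # merge atom-centred duplicates is unnecessary (one point per atom already)
  df <- data.frame(
    x = vapply(pts, function(p) p$xyz[1], 1),
    y = vapply(pts, function(p) p$xyz[2], 1),
    z = vapply(pts, function(p) p$xyz[3], 1),
    n_atoms = vapply(pts, function(p) length(p$atoms), 1L))
  df$kinds <- lapply(pts, `[[`, "kinds")
  df$atoms <- lapply(pts, `[[`, "atoms")
  class(df) <- c("pf_features", "data.frame")
  df
}

feature_coords <- function(features) {
  as.matrix(features[, c("x", "y", "z")])
}
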